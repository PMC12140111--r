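#' Build a normalization lexicon
#'
#' A lexicon maps raw fluency tokens (as transcribed, with misspellings,
#' plural and offspring variants) to canonical exemplars, and labels each
#' canonical form as an accepted category member or as an exclusion
#' (`fictional` for imaginary category members, `non_category` for
#' out-of-category responses). The mapping is deterministic: the same raw
#' token always resolves to the same canonical form, which makes cleaning
#' reproducible and testable.
#'
#' @param raw character vector of surface forms.
#' @param canonical character vector of canonical exemplars, same length.
#' @param status one of `"ok"`, `"fictional"`, `"non_category"` per row
#'   (recycled if length 1).
#' @return A tibble of class `fluenet_lexicon` with columns `raw`,
#'   `canonical`, `status`. Lookup keys are normalized (lower-case,
#'   accent-stripped, trimmed).
#' @examples
#' lexicon(c("cat", "cats", "dog", "dragon"),
#'         c("cat", "cat", "dog", "dragon"),
#'         c("ok", "ok", "ok", "fictional"))
#' @export
lexicon <- function(raw, canonical, status = "ok") {
  stopifnot(length(raw) == length(canonical))
  status <- rep_len(status, length(raw))
  bad <- setdiff(unique(status), c("ok", "fictional", "non_category"))
  if (length(bad) > 0) {
    stop("unknown lexicon status: ", paste(bad, collapse = ", "))
  }
  lex <- tibble::tibble(
    raw = normalize_key(raw),
    canonical = normalize_key(canonical),
    status = status
  )
  lex <- dplyr::distinct(lex, .data$raw, .keep_all = TRUE)
  dup <- lex$raw[duplicated(lex$raw)]
  if (length(dup) > 0) stop("non-deterministic lexicon: duplicate raw keys")
  class(lex) <- c("fluenet_lexicon", class(lex))
  lex
}

#' Read / write a lexicon CSV (`raw,canonical,status`)
#'
#' Columns: `raw`, `canonical`, `status` with status in
#' `ok`/`fictional`/`non_category`.
#'
#' @param path file path.
#' @return [read_lexicon()] returns a `fluenet_lexicon` tibble.
#' @export
read_lexicon <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("raw", "canonical", "status") %in% names(x))) {
    stop("lexicon CSV needs columns raw, canonical, status")
  }
  lexicon(x$raw, x$canonical, x$status)
}

#' @rdname read_lexicon
#' @param lex a `fluenet_lexicon`.
#' @export
write_lexicon <- function(lex, path) {
  readr::write_csv(tibble::as_tibble(unclass(lex))[c("raw", "canonical", "status")], path)
  invisible(path)
}

# canonical key form: trimmed, lower-case, accents transliterated away.
# iconv TRANSLIT leaves markers (e.g. "c^at"), so residual punctuation is
# stripped; internal whitespace is squeezed to single spaces.
normalize_key <- function(x) {
  x <- trimws(tolower(x))
  out <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  out[is.na(out)] <- x[is.na(out)]
  out <- gsub("[^a-z0-9 ]+", "", out)
  gsub(" +", " ", trimws(out))
}

#' Normalize one raw fluency response against a lexicon
#'
#' Lookup is case- and accent-insensitive. An unmapped token is retried
#' with its trailing plural marker (`s` / `es`) stripped, but only when
#' the de-pluralized form is itself a lexicon key; tokens that still fail
#' to map are rejected as `non_category`. Mapped tokens are accepted only
#' when their canonical form has status `ok`.
#'
#' @param raw a single raw token (non-empty after trimming).
#' @param lex a [lexicon()].
#' @return A list with `token` (canonical exemplar, or `NA` if rejected)
#'   and `reason` (`NA` if accepted, else `"fictional"` or
#'   `"non_category"`).
#' @examples
#' lex <- lexicon(c("cat", "cats"), c("cat", "cat"))
#' normalize_token("Cats ", lex)
#' @export
normalize_token <- function(raw, lex) {
  key <- normalize_key(raw)
  if (is.na(key) || !nzchar(key)) stop("empty response")
  i <- match(key, lex$raw)
  if (is.na(i)) {
    # built-in de-pluralization: only into forms the lexicon knows
    for (suf in c("es", "s")) {
      if (endsWith(key, suf) && nchar(key) > nchar(suf)) {
        j <- match(substr(key, 1L, nchar(key) - nchar(suf)), lex$raw)
        if (!is.na(j)) {
          i <- j
          break
        }
      }
    }
  }
  if (is.na(i)) {
    return(list(token = NA_character_, reason = "non_category"))
  }
  st <- lex$status[i]
  if (st == "ok") {
    list(token = lex$canonical[i], reason = NA_character_)
  } else {
    list(token = NA_character_, reason = st)
  }
}
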