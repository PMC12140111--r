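#' Read fluency lists from CSV
#'
#' Long format has one row per response:
#' `participant_id,group,position,response`. Wide format has one row per
#' participant (`participant_id,group,responses`) with the ordered
#' responses in a single comma-separated field.
#'
#' @param path CSV file, UTF-8.
#' @param format `"long"` or `"wide"`.
#' @return A long tibble `participant_id, group, position, response`.
#' @export
read_fluency <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (format == "wide") {
    if (!all(c("participant_id", "group", "responses") %in% names(x))) {
      stop("wide fluency CSV needs participant_id, group, responses")
    }
    x <- x |>
      dplyr::mutate(response = strsplit(.data$responses, ",", fixed = TRUE)) |>
      dplyr::select("participant_id", "group", "response") |>
      tidyr::unnest_longer("response") |>
      dplyr::mutate(response = trimws(.data$response)) |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::mutate(position = dplyr::row_number()) |>
      dplyr::ungroup()
  } else {
    if (!all(c("participant_id", "group", "position", "response") %in% names(x))) {
      stop("long fluency CSV needs participant_id, group, position, response")
    }
    x$position <- as.integer(x$position)
  }
  dplyr::arrange(
    x[c("participant_id", "group", "position", "response")],
    .data$participant_id, .data$position
  )
}

#' Read a participant covariate table
#'
#' Expects `participant_id` plus numeric covariate columns; the study
#' design uses `ses` (socioeconomic status on a 0-100 percentage scale)
#' and `nvi` (non-verbal intelligence as a 0-100 success rate).
#'
#' @param path CSV file.
#' @return tibble with `participant_id` and numeric covariates.
#' @export
read_covariates <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!"participant_id" %in% names(x)) {
    stop("covariate CSV needs a participant_id column")
  }
  x$participant_id <- as.character(x$participant_id)
  x
}

#' Clean raw fluency lists
#'
#' Applies the exclusion rules used for category fluency: repeated
#' answers (perseverations), out-of-category responses (intrusions) and
#' fictional category members are removed; misspellings and plural or
#' offspring variants are folded onto their canonical root via the
#' lexicon. The first occurrence of each accepted exemplar is kept in
#' its original position; every removal is logged with its reason
#' (`duplicate`, `fictional`, `non_category`).
#'
#' Participants whose entire list is rejected are retained with
#' `n_cleaned = 0` (and a warning), so group sizes are preserved for
#' resampling.
#'
#' @param fluency long tibble `participant_id, group, position, response`
#'   (see [read_fluency()]).
#' @param lex a [lexicon()].
#' @return A tibble with one row per participant: `participant_id`,
#'   `group`, `tokens` (list-column of canonical exemplars in order of
#'   first production), `n_cleaned`, and `exclusions` (list-column of
#'   tibbles `raw, reason`).
#' @examples
#' lex <- lexicon(c("dog", "dogs", "cat", "dragon", "table"),
#'                c("dog", "dog", "cat", "dragon", "table"),
#'                c("ok", "ok", "ok", "fictional", "non_category"))
#' fl <- tibble::tibble(participant_id = "p1", group = "A", position = 1:5,
#'                      response = c("dog", "dogs", "dragon", "table", "cat"))
#' clean_fluency(fl, lex)$tokens[[1]]
#' @export
clean_fluency <- function(fluency, lex) {
  stopifnot(inherits(lex, "fluenet_lexicon"))
  need <- c("participant_id", "group", "position", "response")
  if (!all(need %in% names(fluency))) {
    stop("fluency data needs columns ", paste(need, collapse = ", "))
  }
  fluency <- dplyr::arrange(fluency, .data$participant_id, .data$position)
  grp <- dplyr::distinct(fluency, .data$participant_id, .data$group)
  if (anyDuplicated(grp$participant_id)) {
    stop("participant assigned to more than one group")
  }
  out <- fluency |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(
      cleaned = list(clean_token_list(.data$response, lex)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      tokens = purrr::map(.data$cleaned, "tokens"),
      n_cleaned = purrr::map_int(.data$tokens, length),
      exclusions = purrr::map(.data$cleaned, "exclusions")
    ) |>
    dplyr::select("participant_id", "group", "tokens", "n_cleaned", "exclusions")
  if (any(out$n_cleaned == 0)) {
    warning(sum(out$n_cleaned == 0),
            " participant(s) with zero accepted responses retained")
  }
  out
}

# core per-participant rule application; responses in production order
clean_token_list <- function(responses, lex) {
  tokens <- character(0)
  raw_log <- character(0)
  reason_log <- character(0)
  for (r in responses) {
    nt <- normalize_token(r, lex)
    if (is.na(nt$token)) {
      raw_log <- c(raw_log, r)
      reason_log <- c(reason_log, nt$reason)
    } else if (nt$token %in% tokens) {
      raw_log <- c(raw_log, r)
      reason_log <- c(reason_log, "duplicate")
    } else {
      tokens <- c(tokens, nt$token)
    }
  }
  list(tokens = tokens,
       exclusions = tibble::tibble(raw = raw_log, reason = reason_log))
}

#' Binary participant-by-exemplar response matrix
#'
#' One column per canonical exemplar produced by at least one
#' participant; cell is 1 iff the participant produced the exemplar.
#' Columns are ordered lexicographically so node indexing is
#' reproducible; row sums equal each participant's cleaned response
#' count.
#'
#' @param cleaned output of [clean_fluency()] (or any tibble with
#'   `participant_id` and a `tokens` list-column).
#' @return integer 0/1 matrix, rownames participant ids, colnames
#'   exemplars (lexicographic).
#' @export
response_matrix <- function(cleaned) {
  stopifnot(nrow(cleaned) >= 1)
  if (anyDuplicated(cleaned$participant_id)) {
    stop("duplicate participant ids")
  }
  exemplars <- sort_lex(unique(unlist(cleaned$tokens)))
  m <- matrix(0L, nrow = nrow(cleaned), ncol = length(exemplars),
              dimnames = list(cleaned$participant_id, exemplars))
  for (i in seq_len(nrow(cleaned))) {
    m[i, match(cleaned$tokens[[i]], exemplars)] <- 1L
  }
  m
}

# locale-independent lexicographic sort (C collation)
sort_lex <- function(x) {
  if (length(x) == 0) return(character(0))
  x[order(x, method = "radix")]
}

#' Restrict a response matrix to exemplars given by enough participants
#'
#' "Finalizing": only responses produced by at least `min_producers`
#' participants are kept as candidate network nodes. Rows (participants)
#' are always preserved, even when left all-zero.
#'
#' @param m response matrix from [response_matrix()].
#' @param min_producers minimum column sum to keep a column (default 2).
#' @return the column-filtered matrix.
#' @export
finalize_matrix <- function(m, min_producers = 2) {
  stopifnot(min_producers >= 1)
  m[, colSums(m) >= min_producers, drop = FALSE]
}

#' Equate two response matrices onto their shared exemplars
#'
#' Both groups' networks must be estimated over the same node set so
#' their coefficients are comparable; this restricts both matrices to
#' the intersection of their exemplar sets, in identical lexicographic
#' order.
#'
#' @param m_a,m_b finalized response matrices.
#' @return list of the two restricted matrices (`a`, `b`).
#' @export
equate_matrices <- function(m_a, m_b) {
  shared <- sort_lex(intersect(colnames(m_a), colnames(m_b)))
  if (length(shared) < 4) stop("too few shared nodes")
  list(a = m_a[, shared, drop = FALSE], b = m_b[, shared, drop = FALSE])
}

#' Export a per-participant cleaning report
#'
#' @param cleaned output of [clean_fluency()].
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
write_cleaning_report <- function(cleaned, path) {
  rep <- purrr::pmap(
    list(cleaned$participant_id, cleaned$tokens, cleaned$n_cleaned,
         cleaned$exclusions),
    function(id, tokens, n, excl) {
      list(participant_id = id, tokens = tokens, n_cleaned = n,
           exclusions = excl)
    }
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
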