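test_that("token normalization maps variants, rejects intrusions and fictional animals", {
  lex <- toy_lexicon()
  expect_equal(normalize_token("cats", lex)$token, "cat")
  expect_equal(normalize_token("cat", lex)$token, "cat")
  expect_equal(normalize_token("  CAT ", lex)$token, "cat")
  # accent-insensitive lookup
  expect_equal(normalize_token("cât", lex)$token, "cat")
  # de-pluralization rule applies only when the root is known
  expect_equal(normalize_token("foxes", lex)$token, "fox")
  expect_equal(normalize_token("owls", lex)$token, "owl")
  expect_equal(normalize_token("tables", lex)$reason, "non_category")
  expect_equal(normalize_token("dragon", lex)$reason, "fictional")
  expect_equal(normalize_token("unicorn", lex)$reason, "non_category")
  expect_error(normalize_token("   ", lex), "empty response")
})

test_that("cleaning applies exclusion rules in order and logs every removal", {
  lex <- toy_lexicon()
  fl <- long_fluency(list(p1 = c("dog", "dogs", "dragon", "table", "cat")))
  cl <- clean_fluency(fl, lex)
  expect_equal(cl$tokens[[1]], c("dog", "cat"))
  expect_equal(cl$n_cleaned, 2L)
  log <- cl$exclusions[[1]]
  expect_equal(log$raw, c("dogs", "dragon", "table"))
  expect_equal(log$reason, c("duplicate", "fictional", "non_category"))

  # pure repetition collapses to a single exemplar
  cl2 <- clean_fluency(long_fluency(list(p1 = c("cat", "cat", "cat"))), lex)
  expect_equal(cl2$tokens[[1]], "cat")
  expect_equal(cl2$n_cleaned, 1L)

  # fully rejected participant is retained with a warning
  expect_warning(
    cl3 <- clean_fluency(long_fluency(list(p1 = c("table", "dragon"))), lex),
    "zero accepted"
  )
  expect_equal(cl3$n_cleaned, 0L)
})

test_that("accepted plus logged rejections account for every raw response", {
  lex <- toy_lexicon()
  pool <- c("dog", "dogs", "cat", "cats", "fox", "owl", "hen", "dragon",
            "table", "unicorns")
  withr::with_seed(5, {
    for (i in 1:20) {
      raw <- sample(pool, sample(1:12, 1), replace = TRUE)
      cl <- suppressWarnings(clean_fluency(long_fluency(list(p = raw)), lex))
      expect_equal(cl$n_cleaned + nrow(cl$exclusions[[1]]), length(raw))
    }
  })
})

test_that("cleaning is idempotent on already-clean token lists", {
  lex <- toy_lexicon()
  fl <- long_fluency(list(p1 = c("dog", "cats", "foxes", "dragon", "dog")))
  cl <- clean_fluency(fl, lex)
  again <- clean_fluency(long_fluency(setNames(list(cl$tokens[[1]]), "p1")), lex)
  expect_equal(again$tokens[[1]], cl$tokens[[1]])
  expect_equal(nrow(again$exclusions[[1]]), 0L)
})

test_that("response matrix has lexicographic columns and row sums = n_cleaned", {
  cl <- small_cleaned(list(a = c("cat", "dog"), b = "dog"), c("G1", "G1"))
  m <- response_matrix(cl)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(colnames(m), c("cat", "dog"))
  expect_equal(unname(colSums(m)), c(1, 2))
  expect_equal(unname(rowSums(m)), cl$n_cleaned)

  one <- response_matrix(small_cleaned(list(a = c("x", "b", "k")), "G1"))
  expect_true(all(one == 1) && ncol(one) == 3)
  expect_equal(colnames(one), c("b", "k", "x"))

  dup <- small_cleaned(list(a = "cat", a = "dog"), c("G1", "G1"))
  expect_error(response_matrix(dup), "duplicate")
})

test_that("finalizing drops rare exemplars, keeps participants, and is idempotent", {
  cl <- small_cleaned(list(a = c("u", "v", "w"), b = c("v", "w"), c = "w"),
                      rep("G", 3))
  m <- response_matrix(cl)  # column sums u=1 v=2 w=3
  f <- finalize_matrix(m, 2)
  expect_equal(colnames(f), c("v", "w"))
  expect_equal(nrow(f), 3L)
  expect_identical(finalize_matrix(f, 2), f)
  expect_identical(finalize_matrix(m, 1), m)
  # all-singleton columns leave an empty exemplar set
  solo <- response_matrix(small_cleaned(list(a = "u", b = "v"), c("G", "G")))
  expect_equal(ncol(finalize_matrix(solo, 2)), 0L)
})

test_that("equating restricts both groups to identically ordered shared nodes", {
  ma <- response_matrix(small_cleaned(
    list(a1 = c("cat", "dog", "fox", "owl", "hen")), "A"))
  mb <- response_matrix(small_cleaned(
    list(b1 = c("dog", "fox", "owl", "hen", "eel")), "B"))
  eq <- equate_matrices(ma, mb)
  expect_identical(colnames(eq$a), colnames(eq$b))
  expect_equal(colnames(eq$a), c("dog", "fox", "hen", "owl"))
  expect_equal(nrow(eq$a), 1L)

  # identical column sets pass through unchanged
  eq2 <- equate_matrices(ma, ma)
  expect_identical(eq2$a, ma)

  # below four shared nodes is an error, disjoint included
  mc <- response_matrix(small_cleaned(list(c1 = c("cat", "dog", "fox")), "C"))
  expect_error(equate_matrices(ma, mc), "too few shared nodes")
  md <- response_matrix(small_cleaned(list(d1 = c("yak", "zebu")), "D"))
  expect_error(equate_matrices(ma, md), "too few shared nodes")
})

test_that("fluency CSV round-trips in long and wide formats", {
  fl <- long_fluency(list(p1 = c("dog", "cat"), p2 = c("hen", "owl", "fox")),
                     c("A", "B"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(fl, tmp)
  expect_equal(read_fluency(tmp, "long"), fl)

  wide <- tibble::tibble(participant_id = c("p1", "p2"), group = c("A", "B"),
                         responses = c("dog,cat", "hen, owl, fox"))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(wide, tmp2)
  expect_equal(read_fluency(tmp2, "wide"), fl)
})
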