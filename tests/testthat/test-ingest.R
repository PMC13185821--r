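toy_key <- function() {
  tibble::tibble(item_id = c("i1", "i2", "i3", "i4"),
                 instrument = "toy",
                 dimension = c("N", "E", "O", "A"),
                 keyed = c("+", "-", "+", "-"))
}

toy_rm <- function(values = NULL) {
  if (is.null(values)) {
    values <- matrix(c(1L, 5L, 3L, 2L,
                       4L, 2L, 5L, 1L,
                       3L, 3L, 1L, 5L), 3, 4, byrow = TRUE,
                     dimnames = list(paste0("s", 1:3),
                                     c("i1", "i2", "i3", "i4")))
  }
  response_matrix(values, toy_key())
}

test_that("CSV loading validates columns, types and range", {
  dir <- withr::local_tempdir()
  resp <- file.path(dir, "r.csv"); key <- file.path(dir, "k.csv")
  readr::write_csv(tibble::tibble(subject_id = c("a", "b"),
                                  i1 = c(1, 5), i2 = c(2, NA),
                                  i3 = c(3, 4), i4 = c(4, 1)), resp, na = "")
  readr::write_csv(toy_key(), key)
  rm <- load_responses(resp, key)
  expect_s3_class(rm, "response_matrix")
  expect_equal(dim(rm), c(2, 4))
  expect_true(is.na(rm$values["b", "i2"]))

  # a column absent from the key is named in the error
  readr::write_csv(tibble::tibble(i1 = 1, mystery = 2), resp)
  expect_error(load_responses(resp, key), "mystery")

  # out-of-range value names row and column
  readr::write_csv(tibble::tibble(i1 = c(1, 7), i2 = c(2, 2),
                                  i3 = c(3, 3), i4 = c(4, 4)), resp)
  expect_error(load_responses(resp, key), "7.*row 2.*i1")

  # non-integer cell
  readr::write_csv(tibble::tibble(i1 = c(1, 2.5), i2 = c(2, 2),
                                  i3 = c(3, 3), i4 = c(4, 4)), resp)
  expect_error(load_responses(resp, key), "non-integer")

  expect_error(load_responses(file.path(dir, "none.csv"), key), "not found")
})

test_that("reverse scoring maps 6 - x on negative items only, single pass", {
  rm <- toy_rm()
  scored <- apply_reverse_scoring(rm)
  expect_identical(scored$values[, "i1"], rm$values[, "i1"])      # '+' unchanged
  expect_identical(scored$values[, "i2"], 6L - rm$values[, "i2"]) # '-' flipped
  expect_identical(scored$values["s1", "i4"], 4L)                 # 2 -> 4
  # midpoint is a fixed point
  rm3 <- toy_rm(matrix(3L, 2, 4, dimnames = list(NULL, toy_key()$item_id)))
  expect_true(all(apply_reverse_scoring(rm3)$values == 3L))
  # involution on values, but a second pass is refused
  twice <- scored
  twice$scored <- FALSE
  expect_identical(apply_reverse_scoring(twice)$values, rm$values)
  expect_error(apply_reverse_scoring(scored), "already")
})

test_that("imputation fills item means, preserves observed cells, transposes", {
  v <- matrix(c(1L, NA, 3L,
                3L, 2L, 5L,
                NA, 4L, 1L,
                5L, 2L, NA), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("i1", "i2", "i3")))
  key <- tibble::tibble(item_id = c("i1", "i2", "i3"), keyed = "+")
  rm <- response_matrix(v, key, scored = TRUE)
  td <- impute_missing(rm)
  expect_equal(dim(td$X), c(3, 4))           # items x subjects
  expect_false(anyNA(td$X))
  # observed cells exact
  expect_equal(td$X["i1", "s1"], 1)
  expect_equal(td$X["i3", "s2"], 5)
  # imputed values are the item means over observed subjects
  expect_equal(td$X["i1", "s3"], mean(c(1, 3, 5)))
  expect_equal(td$X["i2", "s1"], mean(c(2, 4, 2)))
  # unscored input refused; fully missing item refused
  rm_raw <- response_matrix(v, key, scored = FALSE)
  expect_error(impute_missing(rm_raw), "reverse_scoring")
  v2 <- v; v2[, 2] <- NA
  expect_error(impute_missing(response_matrix(v2, key, scored = TRUE)),
               "entirely missing")
  # no missing cells: X equals the transposed input
  v3 <- matrix(2L, 3, 3, dimnames = list(NULL, key$item_id))
  expect_equal(impute_missing(response_matrix(v3, key, scored = TRUE))$X,
               t(v3) * 1.0, ignore_attr = TRUE)
})

test_that("within-subject centering removes row means and restores X >= 0", {
  set.seed(1)
  v <- matrix(sample(1:5, 60, replace = TRUE), 10, 6,
              dimnames = list(NULL, paste0("i", 1:6)))
  key <- tibble::tibble(item_id = paste0("i", 1:6), keyed = "+")
  rm <- response_matrix(v, key, scored = TRUE)
  td <- center_within_subject(rm)
  centered <- t(td$X) - td$shift            # subjects x items, before shift
  expect_true(all(abs(rowMeans(centered)) < 1e-12))
  expect_gte(min(td$X), 0)
  expect_lt(abs(min(td$X)), 1e-12)          # minimum is exactly zero
  # constant-response subject: all-zero centered row -> all-shift after
  v[1, ] <- 3L
  td2 <- center_within_subject(response_matrix(v, key, scored = TRUE))
  expect_true(all(abs(td2$X[, 1] - td2$shift) < 1e-12))
  # each subject's row is shifted by a constant, so the rank order of that
  # subject's item responses is preserved
  for (s in c(2, 5, 9)) {
    expect_equal(order(td2$X[, s]), order(v[s, ]))
  }
})

test_that("response_matrix constructor validates structure", {
  v <- matrix(1L, 2, 2, dimnames = list(NULL, c("i1", "i2")))
  key <- tibble::tibble(item_id = c("i1", "i2"), keyed = c("+", "+"))
  expect_s3_class(response_matrix(v, key), "response_matrix")
  expect_error(response_matrix(v, key[1, ]), "absent from item key")
  key_dup <- tibble::tibble(item_id = c("i1", "i1"), keyed = "+")
  expect_error(response_matrix(v, key_dup), "unique")
  v_bad <- v; v_bad[1, 1] <- 9L
  expect_error(response_matrix(v_bad, key), "out of 1..5")
})
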