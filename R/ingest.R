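#' Construct a response matrix from values, item key and subject metadata
#'
#' The container every downstream stage consumes: an integer subjects x items
#' matrix of five-point Likert responses (missing allowed before imputation),
#' the item key (one row per item: `item_id`, `instrument`, `dimension` in
#' N/E/O/A/C, `keyed` in "+"/"-") and optional per-subject metadata.
#'
#' @param values Integer matrix or data frame, subjects x items; column names
#'   must match the item key's `item_id`s.
#' @param item_key Data frame with columns `item_id` and `keyed` (and
#'   optionally `instrument`, `dimension`, `item_text`).
#' @param subject_meta Optional data frame with a `subject_id` column and
#'   e.g. `sex`, `age_group`, `culture`, `family_id`, `group`.
#' @param scored Whether reverse scoring has already been applied.
#' @return A `response_matrix` object.
#' @export
response_matrix <- function(values, item_key, subject_meta = NULL,
                            scored = FALSE) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop_arg("response values must have item ids as column names")
  }
  item_key <- tibble::as_tibble(item_key)
  if (!all(c("item_id", "keyed") %in% names(item_key))) {
    stop_arg("item_key needs columns item_id and keyed")
  }
  if (anyDuplicated(item_key$item_id)) {
    stop_arg("item_key item_ids must be unique")
  }
  unknown <- setdiff(colnames(values), item_key$item_id)
  if (length(unknown)) {
    stop_arg("response column(s) absent from item key: ",
             paste(unknown, collapse = ", "))
  }
  item_key <- item_key[match(colnames(values), item_key$item_id), ]
  if (!all(item_key$keyed %in% c("+", "-"))) {
    stop_arg("keyed must be '+' or '-'")
  }
  check_likert_range(values)
  if (is.null(subject_meta)) {
    subject_meta <- tibble::tibble(
      subject_id = rownames(values) %||% paste0("s", seq_len(nrow(values)))
    )
  } else {
    subject_meta <- tibble::as_tibble(subject_meta)
    if (nrow(subject_meta) != nrow(values)) {
      stop_arg("subject_meta rows (", nrow(subject_meta),
               ") do not match subjects (", nrow(values), ")")
    }
  }
  if (is.null(rownames(values))) rownames(values) <- subject_meta$subject_id
  storage.mode(values) <- "integer"
  structure(
    list(values = values, item_key = item_key, subject_meta = subject_meta,
         scored = scored),
    class = "response_matrix"
  )
}

check_likert_range <- function(values, max_likert = 5) {
  bad <- which(!is.na(values) & (values < 1 | values > max_likert |
                                   values != round(values)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(values))
    stop_arg("response value ", values[bad[1]], " out of 1..", max_likert,
             " at row ", rc[1], " (subject '",
             rownames(values)[rc[1]] %||% rc[1], "'), column '",
             colnames(values)[rc[2]], "'")
  }
  invisible(values)
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", nrow(x$values), " subjects x ", ncol(x$values),
      " items; ", sum(is.na(x$values)), " missing; ",
      if (x$scored) "reverse-scored" else "raw keying", "\n", sep = "")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Load questionnaire responses, item key and subject metadata from CSV
#'
#' Reads comma-delimited UTF-8 files with header rows. Response cells must be
#' integers 1..5; empty cells and "NA" are both read as missing. Validation
#' errors name the offending row and column. Reverse scoring is *not* applied
#' here; see [apply_reverse_scoring()].
#'
#' @param responses_path CSV of responses: a `subject_id` column (optional)
#'   plus one column per item.
#' @param item_key_path CSV item key (`item_id`, `keyed`, ...).
#' @param subject_meta_path Optional CSV of subject metadata.
#' @return A [response_matrix()].
#' @export
load_responses <- function(responses_path, item_key_path,
                           subject_meta_path = NULL) {
  for (p in c(responses_path, item_key_path, subject_meta_path)) {
    if (!file.exists(p)) stop_arg("input file not found: ", p)
  }
  resp <- readr::read_csv(responses_path, show_col_types = FALSE,
                          na = c("", "NA"))
  key <- readr::read_csv(item_key_path, show_col_types = FALSE)
  meta <- NULL
  if (!is.null(subject_meta_path)) {
    meta <- readr::read_csv(subject_meta_path, show_col_types = FALSE)
  }
  id_col <- intersect(c("subject_id", "subject"), names(resp))
  subject_id <- NULL
  if (length(id_col)) {
    subject_id <- as.character(resp[[id_col[1]]])
    resp <- resp[setdiff(names(resp), id_col)]
  }
  for (cn in names(resp)) {
    col <- resp[[cn]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col))[1]
      stop_arg("non-integer response at row ", bad %||% 1, ", column '", cn, "'")
    }
  }
  values <- as.matrix(resp)
  nonint <- which(!is.na(values) & values != round(values))
  if (length(nonint)) {
    rc <- arrayInd(nonint[1], dim(values))
    stop_arg("non-integer response ", values[nonint[1]], " at row ", rc[1],
             ", column '", colnames(values)[rc[2]], "'")
  }
  rownames(values) <- subject_id %||% paste0("s", seq_len(nrow(values)))
  if (!is.null(meta) && length(id_col) && "subject_id" %in% names(meta)) {
    meta <- meta[match(rownames(values), as.character(meta$subject_id)), ]
  }
  response_matrix(values, key, meta)
}

#' Apply reverse scoring to negatively keyed items
#'
#' Maps negatively keyed items `x -> 6 - x` (five-point scale) so higher
#' values consistently indicate higher standing on the intended trait pole;
#' positively keyed items are unchanged. The matrix is flagged as scored and
#' a second pass is refused, since the value map is an involution and double
#' application would silently restore raw keying.
#'
#' @param R A [response_matrix()].
#' @return The reverse-scored `response_matrix`.
#' @export
apply_reverse_scoring <- function(R) {
  stopifnot(inherits(R, "response_matrix"))
  if (R$scored) {
    stop_arg("reverse scoring has already been applied to this response matrix")
  }
  rev <- R$item_key$keyed == "-"
  R$values[, rev] <- 6L - R$values[, rev]
  R$scored <- TRUE
  R
}

new_trait_data <- function(X, shift = 0, preprocessing = character()) {
  structure(list(X = X, shift = shift, preprocessing = preprocessing),
            class = "trait_data")
}

#' @export
print.trait_data <- function(x, ...) {
  cat("<trait_data> ", nrow(x$X), " items x ", ncol(x$X), " subjects (",
      paste(x$preprocessing, collapse = " + "), ")\n", sep = "")
  invisible(x)
}

#' Impute missing responses and expose the internal data matrix
#'
#' Replaces each missing cell by the item's mean over observed subjects and
#' transposes to the items x subjects orientation used by the factorization.
#' Observed cells are preserved exactly. Requires reverse scoring to have
#' been applied so imputation averages consistently oriented values.
#'
#' @param R A reverse-scored [response_matrix()].
#' @param strategy Imputation strategy; only `"item_mean"` is implemented.
#' @return A `trait_data` object holding the non-negative items x subjects
#'   matrix `X`.
#' @export
impute_missing <- function(R, strategy = c("item_mean")) {
  stopifnot(inherits(R, "response_matrix"))
  strategy <- match.arg(strategy)
  if (!R$scored) {
    stop_arg("apply_reverse_scoring() must be called before imputation")
  }
  V <- R$values * 1.0
  n_obs <- colSums(!is.na(V))
  if (any(n_obs == 0)) {
    stop_arg("item(s) entirely missing: ",
             paste(colnames(V)[n_obs == 0], collapse = ", "))
  }
  if (anyNA(V)) {
    mu <- colMeans(V, na.rm = TRUE)
    idx <- which(is.na(V), arr.ind = TRUE)
    V[idx] <- mu[idx[, 2]]
  }
  new_trait_data(t(V), shift = 0, preprocessing = strategy)
}

#' Within-subject mean-centering with non-negativity restoration
#'
#' Subtracts each subject's own mean response (removing additive
#' acquiescence-style response bias), then shifts the whole matrix by the
#' absolute global minimum so the result is non-negative again as required
#' by the factorization. The shift is recorded in the returned object.
#' Missing cells are item-mean imputed first.
#'
#' @inheritParams impute_missing
#' @return A `trait_data` object (items x subjects), `shift` recording the
#'   restoration constant.
#' @export
center_within_subject <- function(R, strategy = c("item_mean")) {
  td <- impute_missing(R, strategy)
  V <- t(td$X)                       # subjects x items
  V <- V - rowMeans(V)
  shift <- abs(min(V))
  new_trait_data(t(V) + shift, shift = shift,
                 preprocessing = c(td$preprocessing, "center_within_subject"))
}
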