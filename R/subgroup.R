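subgroup_labels <- function(R, label_field) {
  if (!label_field %in% names(R$subject_meta)) {
    stop_arg("subject metadata has no column '", label_field, "'")
  }
  as.character(R$subject_meta[[label_field]])
}

#' Generalizability of an overall model to labelled subgroups
#'
#' For each subgroup the normalized reconstruction error of the overall
#' model on that group's data is compared with a permutation null obtained
#' by shuffling the subject-to-group assignment globally (`n_null` times,
#' every group's size preserved). Generalizability is the mean
#' actual-minus-null difference — negative values mean the overall model
#' explains the group better than a random subset of equal size — with a
#' two-tailed one-sample t-test of the `n_null` differences against zero
#' (`t_stat`, `p_value`). Because the actual error is itself a single draw
#' from the null when labels carry no information, the t-test is
#' anti-conservative under exchangeability; `p_perm`, the two-sided
#' empirical rank of the actual error within the null distribution, is the
#' calibrated alternative and is what the package's own calibration checks
#' use.
#'
#' @param model_overall An `opnmf_fit` fitted on the whole sample.
#' @param R A reverse-scored [response_matrix()].
#' @param label_field Subject-metadata column holding the group label.
#' @param n_null Number of label shuffles (default 100).
#' @param seed Integer seed.
#' @param preprocess Preprocessing applied to obtain the data matrix; must
#'   match what the overall model was fitted on.
#' @return A tibble: `group_label`, `n`, `actual_re`, `null_mean_re`,
#'   `generalizability`, `t_stat`, `p_value`, `p_perm`.
#' @export
subgroup_generalizability <- function(model_overall, R, label_field,
                                      n_null = 100, seed = 1,
                                      preprocess = c("item_mean", "center")) {
  preprocess <- match.arg(preprocess)
  if (n_null < 2) stop_arg("n_null must be >= 2")
  labels <- subgroup_labels(R, label_field)
  X <- if (preprocess == "center") center_within_subject(R)$X else
    impute_missing(R)$X
  groups <- unique(labels)
  if (length(groups) < 2) stop_arg("need at least 2 groups")
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("skipping group(s) with fewer than 2 subjects: ",
            paste(small, collapse = ", "))
    groups <- setdiff(groups, small)
  }

  actual <- vapply(groups, function(g) {
    reconstruction_error(model_overall, X[, labels == g, drop = FALSE])
  }, numeric(1))

  null_re <- matrix(NA_real_, n_null, length(groups),
                    dimnames = list(NULL, groups))
  for (b in seq_len(n_null)) {
    set.seed(derive_seed(seed, 41, b))
    shuffled <- sample(labels)
    for (g in groups) {
      null_re[b, g] <- reconstruction_error(
        model_overall, X[, shuffled == g, drop = FALSE])
    }
  }

  out <- lapply(groups, function(g) {
    d <- actual[g] - null_re[, g]
    tt <- t.test(d, mu = 0)
    tibble::tibble(
      group_label = g, n = as.integer(sizes[g]),
      actual_re = unname(actual[g]),
      null_mean_re = mean(null_re[, g]),
      generalizability = mean(d),
      t_stat = unname(tt$statistic), p_value = tt$p.value,
      p_perm = perm_rank_p(actual[g], null_re[, g])
    )
  })
  dplyr::bind_rows(out)
}

# two-sided empirical rank of an observation within its permutation null
perm_rank_p <- function(actual, nulls) {
  n <- length(nulls)
  lo <- (1 + sum(nulls <= actual)) / (n + 1)
  hi <- (1 + sum(nulls >= actual)) / (n + 1)
  min(1, 2 * min(lo, hi))
}

#' Intra-group heterogeneity via group-specific models
#'
#' Fits a separate model on each subgroup alone and measures its
#' reconstruction error on that same group; the permutation null refits on
#' random subject sets of the same size (shuffled membership). The
#' heterogeneity of a group is the mean actual-minus-null difference:
#' positive values mean the group is harder to model than a random subset
#' of equal size.
#'
#' @inheritParams subgroup_generalizability
#' @param rank Rank of the group-specific fits.
#' @param control Fit controls passed to [fit_opnmf()] (`max_iter`, `tol`).
#' @return A tibble: `group_label`, `n`, `actual_re`, `null_mean_re`,
#'   `heterogeneity`, `t_stat`, `p_value`, plus the group models in the
#'   `model` list-column.
#' @export
intra_group_heterogeneity <- function(R, label_field, rank, n_null = 100,
                                      seed = 1,
                                      preprocess = c("item_mean", "center"),
                                      control = list()) {
  preprocess <- match.arg(preprocess)
  labels <- subgroup_labels(R, label_field)
  X <- if (preprocess == "center") center_within_subject(R)$X else
    impute_missing(R)$X
  groups <- unique(labels)
  sizes <- table(labels)
  small <- names(sizes)[sizes < rank]
  if (length(small)) {
    warning("skipping group(s) too small to fit rank ", rank, ": ",
            paste(small, collapse = ", "))
    groups <- setdiff(groups, small)
  }
  fit_re <- function(idx) {
    Xg <- X[, idx, drop = FALSE]
    mg <- fit_opnmf(Xg, rank, max_iter = control$max_iter %||% 2000,
                    tol = control$tol %||% 1e-5)
    list(model = mg, re = reconstruction_error(mg, Xg))
  }

  actual <- lapply(groups, function(g) fit_re(which(labels == g)))
  names(actual) <- groups

  null_re <- matrix(NA_real_, n_null, length(groups),
                    dimnames = list(NULL, groups))
  for (b in seq_len(n_null)) {
    set.seed(derive_seed(seed, 43, b))
    shuffled <- sample(labels)
    for (g in groups) {
      null_re[b, g] <- fit_re(which(shuffled == g))$re
    }
  }

  out <- lapply(groups, function(g) {
    d <- actual[[g]]$re - null_re[, g]
    tt <- t.test(d, mu = 0)
    tibble::tibble(
      group_label = g, n = as.integer(sizes[g]),
      actual_re = actual[[g]]$re,
      null_mean_re = mean(null_re[, g]),
      heterogeneity = mean(d),
      t_stat = unname(tt$statistic), p_value = tt$p.value,
      p_perm = perm_rank_p(actual[[g]]$re, null_re[, g]),
      model = list(actual[[g]]$model)
    )
  })
  dplyr::bind_rows(out)
}

#' Similarity between an overall and a group-specific model
#'
#' Delegates to [concordance_index()] on the two bases.
#'
#' @param model_overall,model_group Fitted models over the same items.
#' @return A scalar in `[-1, 1]`.
#' @export
model_similarity <- function(model_overall, model_group) {
  concordance_index(model_overall, model_group)
}

#' Full per-subgroup report: generalizability, heterogeneity, similarity
#'
#' Convenience wrapper running [subgroup_generalizability()],
#' [intra_group_heterogeneity()] (reusing its group models for
#' [model_similarity()]) and joining the results into one row per group.
#'
#' @inheritParams intra_group_heterogeneity
#' @param model_overall The overall `opnmf_fit`.
#' @return A tibble with one row per group: `group_label`, `n`,
#'   `generalizability`, `t_stat`, `p_value`, `heterogeneity`, `similarity`.
#' @export
subgroup_report <- function(model_overall, R, label_field, rank = NULL,
                            n_null = 100, seed = 1,
                            preprocess = c("item_mean", "center"),
                            control = list()) {
  preprocess <- match.arg(preprocess)
  rank <- rank %||% model_overall$rank
  gen <- subgroup_generalizability(model_overall, R, label_field, n_null,
                                   seed, preprocess)
  het <- intra_group_heterogeneity(R, label_field, rank, n_null,
                                   derive_seed(seed, 2), preprocess, control)
  het$similarity <- vapply(het$model, function(mg) {
    model_similarity(model_overall, mg)
  }, numeric(1))
  dplyr::left_join(
    gen[c("group_label", "n", "generalizability", "t_stat", "p_value",
          "p_perm")],
    het[c("group_label", "heterogeneity", "similarity")],
    by = "group_label"
  )
}

#' Explain subgroup generalizability by heterogeneity, similarity and size
#'
#' Three univariate linear regressions of group generalizability on (a)
#' intra-group heterogeneity, (b) model similarity, (c) sample size,
#' reporting r-squared and the two-tailed p of the slope. A predictor with
#' zero variance is flagged and reported as r-squared 0.
#'
#' @param reports Tibble with columns `generalizability`, `heterogeneity`,
#'   `similarity`, `n` (one row per group; >= 4 groups).
#' @return A tibble: `predictor`, `r_squared`, `p_value`, `slope`,
#'   `degenerate`.
#' @export
explain_generalizability <- function(reports) {
  need <- c("generalizability", "heterogeneity", "similarity", "n")
  if (!all(need %in% names(reports))) {
    stop_arg("reports must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(reports) < 4) stop_arg("need at least 4 groups")
  y <- reports$generalizability
  one <- function(name, x) {
    if (sd(x) < 1e-14) {
      return(tibble::tibble(predictor = name, r_squared = 0,
                            p_value = NA_real_, slope = NA_real_,
                            degenerate = TRUE))
    }
    fit <- lm(y ~ x)
    sm <- summary(fit)
    tibble::tibble(predictor = name, r_squared = sm$r.squared,
                   p_value = sm$coefficients[2, 4],
                   slope = sm$coefficients[2, 1], degenerate = FALSE)
  }
  dplyr::bind_rows(
    one("heterogeneity", reports$heterogeneity),
    one("similarity", reports$similarity),
    one("sample_size", as.numeric(reports$n))
  )
}
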