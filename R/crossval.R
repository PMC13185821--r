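#' PCA and EFA baseline factorizations
#'
#' Signed linear baselines for the stability comparison: `"pca"` takes the
#' singular vectors of the item-centered data (loadings scaled by singular
#' value, i.e. classical component loadings); `"efa"` performs
#' principal-axis factoring (iterated communalities, initialized at squared
#' multiple correlations) with varimax rotation. Items are centered
#' internally for both. The partition assigns each item by maximal
#' *absolute* loading.
#'
#' @param X Items x subjects matrix or `trait_data`.
#' @param rank Number of components/factors.
#' @param method `"pca"` or `"efa"`.
#' @param max_iter,tol Communality-iteration controls for EFA.
#' @return A `linear_baseline` object: signed `loadings` (items x rank),
#'   `method`, convergence info; use [assign_items()] for the partition.
#' @export
fit_linear_baseline <- function(X, rank, method = c("pca", "efa"),
                                max_iter = 500, tol = 1e-4) {
  method <- match.arg(method)
  X <- as_items_by_subjects(X)
  m <- nrow(X); n <- ncol(X)
  if (rank > min(m, n)) stop_arg("rank exceeds min(items, subjects)")
  center <- rowMeans(X)
  Xc <- X - center
  n_iter <- 0L
  if (method == "pca") {
    sv <- svd(Xc, nu = rank, nv = 0)
    L <- sv$u %*% diag(sv$d[seq_len(rank)] / sqrt(n - 1), rank)
    converged <- TRUE
  } else {
    Rm <- cor(t(X))
    smc <- tryCatch(1 - 1 / diag(solve(Rm)), error = function(e) {
      apply(abs(Rm - diag(m)), 1, max)
    })
    h2 <- pmin(pmax(smc, 0.05), 0.995)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Rh <- Rm
      diag(Rh) <- h2
      e <- eigen(Rh, symmetric = TRUE)
      L <- e$vectors[, seq_len(rank), drop = FALSE] %*%
        diag(sqrt(pmax(e$values[seq_len(rank)], 0)), rank)
      h2_new <- pmin(rowSums(L^2), 0.995)
      delta <- max(abs(h2_new - h2))
      h2 <- h2_new
      n_iter <- it
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop_arg("EFA communalities did not converge within ", max_iter,
               " iterations (last change ", signif(delta, 3), ")")
    }
    if (rank > 1) L <- unclass(varimax(L)$loadings)
  }
  rownames(L) <- rownames(X)
  colnames(L) <- paste0("factor_", seq_len(rank))
  structure(
    list(loadings = L, rank = rank, method = method, center = center,
         converged = converged, n_iter = n_iter),
    class = "linear_baseline"
  )
}

#' @export
print.linear_baseline <- function(x, ...) {
  cat("<linear_baseline> ", toupper(x$method), ", rank ", x$rank, ", ",
      nrow(x$loadings), " items\n", sep = "")
  invisible(x)
}

# Reconstruction error of a signed baseline: projection of item-centered
# data onto the loading column space (loadings need not be orthonormal).
baseline_re <- function(model, X, normalized = TRUE) {
  X <- as_items_by_subjects(X)
  L <- model$loadings
  Xc <- X - rowMeans(X)
  P <- L %*% solve(crossprod(L) + diag(1e-12, ncol(L)), t(L))
  R <- Xc - P %*% Xc
  err <- sqrt(sum(R^2))
  if (normalized) err / sqrt(sum(Xc^2)) else err
}

model_re <- function(model, X) {
  if (inherits(model, "linear_baseline")) baseline_re(model, X)
  else reconstruction_error(model, X, normalized = TRUE)
}

#' Split a signed loading matrix into positive and negative poles
#'
#' For each factor of a signed (PCA/EFA) loading matrix, lists the items
#' loading positively and negatively; zero loadings are excluded. Sorting
#' items by loading sign separates the opposing poles that bipolar linear
#' factors conflate.
#'
#' @param signed_loadings Items x factors matrix (or `linear_baseline`).
#' @return A tibble `factor`, `pole` ("positive"/"negative"), `item_id`,
#'   `loading`.
#' @export
split_poles <- function(signed_loadings) {
  L <- model_basis(signed_loadings)
  ids <- rownames(L) %||% as.character(seq_len(nrow(L)))
  out <- tidyr::expand_grid(factor = seq_len(ncol(L)),
                            item = seq_len(nrow(L)))
  out$loading <- L[cbind(out$item, out$factor)]
  out <- out[out$loading != 0, ]
  tibble::tibble(
    factor = out$factor,
    pole = ifelse(out$loading > 0, "positive", "negative"),
    item_id = ids[out$item],
    loading = out$loading
  )
}

fit_fold_model <- function(X, rank, method, control, seed) {
  if (method == "opnmf") {
    fit_opnmf(X, rank, init = control$init %||% "nndsvd",
              max_iter = control$max_iter %||% 2000,
              tol = control$tol %||% 1e-5, seed = seed)
  } else {
    fit_linear_baseline(X, rank, method = method)
  }
}

#' Repeated cross-validated stability and generalizability evaluation
#'
#' The evaluation framework behind rank selection: per repetition the
#' subjects are split into folds; each fold in turn is the hold sample and
#' the complementary folds the main sample; both are factorized
#' independently at each candidate rank, and the two models are compared by
#' the adjusted Rand index and variation of information of their item
#' partitions, the concordance index of their bases, the increased
#' reconstruction error of the main basis on the hold data, and per-item
#' variability.
#'
#' Schemes: `"kfold"` reshuffles subject folds every repetition;
#' `"group_stratified_kfold"` assigns whole groups (e.g. countries) to
#' folds, so no group is split between main and hold sample;
#' `"cross_sample_bootstrap"` compares two response tables sharing items
#' (e.g. two questionnaire versions) by bootstrap-resampling each sample
#' and fitting one model per sample.
#'
#' @param R A [response_matrix()] (reverse-scored; missing cells allowed).
#' @param ranks Candidate factor numbers (default 2..8).
#' @param scheme Cross-validation scheme (see above).
#' @param n_reps Repetitions (default 1000; scale down for desk-size runs).
#' @param n_folds Folds per repetition (default 5).
#' @param seed Master seed; each repetition derives its own substream.
#' @param method `"opnmf"` (default), `"pca"` or `"efa"` — the latter two
#'   run the identical protocol with the linear baselines.
#' @param R2 Second response table, required for `"cross_sample_bootstrap"`.
#' @param group_field Subject-metadata column holding the group label for
#'   the stratified scheme.
#' @param preprocess `"item_mean"` imputation (default) or `"center"`
#'   (within-subject mean-centering, then global shift).
#' @param impute_per_fold Impute inside each fold instead of once on the
#'   full table: item means are computed on the main sample only and used
#'   to fill both main and hold sample, so no information crosses the fold
#'   boundary. Only meaningful with `preprocess = "item_mean"` and the fold
#'   schemes. Identical to full-table imputation when nothing is missing.
#' @param control List of fit controls for the per-fold factorizations
#'   (`max_iter`, `tol`, `init`); CV fits default to `max_iter = 2000`.
#'
#' @return A tibble of per-(repetition, fold, rank) records with columns
#'   `repetition`, `fold`, `rank`, `ari`, `vi`, `ci`, `ire`, `iv_mean` and
#'   list-column `iv` (per-item variability for that model pair).
#' @seealso [summarize_rank_selection()]
#' @export
run_crossvalidation <- function(R, ranks = 2:8,
                                scheme = c("kfold", "group_stratified_kfold",
                                           "cross_sample_bootstrap"),
                                n_reps = 1000, n_folds = 5, seed = 1,
                                method = c("opnmf", "pca", "efa"),
                                R2 = NULL, group_field = "culture",
                                preprocess = c("item_mean", "center"),
                                impute_per_fold = FALSE,
                                control = list()) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  preprocess <- match.arg(preprocess)
  stopifnot(inherits(R, "response_matrix"))
  prep <- function(rm) {
    if (preprocess == "center") center_within_subject(rm) else impute_missing(rm)
  }

  if (scheme == "cross_sample_bootstrap") {
    if (is.null(R2)) stop_arg("scheme 'cross_sample_bootstrap' needs R2")
    shared <- intersect(colnames(R$values), colnames(R2$values))
    if (length(shared) < 2) stop_arg("samples share fewer than 2 items")
    RA <- response_matrix(R$values[, shared, drop = FALSE],
                          R$item_key[R$item_key$item_id %in% shared, ],
                          R$subject_meta, scored = R$scored)
    RB <- response_matrix(R2$values[, shared, drop = FALSE],
                          R2$item_key[R2$item_key$item_id %in% shared, ],
                          R2$subject_meta, scored = R2$scored)
    XA <- prep(RA)$X
    XB <- prep(RB)$X
    recs <- vector("list", n_reps * length(ranks))
    k <- 0L
    for (rep_i in seq_len(n_reps)) {
      rs <- derive_seed(seed, 31, rep_i)
      set.seed(rs)
      ia <- sample.int(ncol(XA), replace = TRUE)
      ib <- sample.int(ncol(XB), replace = TRUE)
      Xa <- XA[, ia, drop = FALSE]
      Xb <- XB[, ib, drop = FALSE]
      for (r in ranks) {
        ma <- fit_fold_model(Xa, r, method, control, rs)
        mb <- fit_fold_model(Xb, r, method, control, rs)
        k <- k + 1L
        recs[[k]] <- cv_record(rep_i, 1L, r, ma, mb, Xb)
      }
    }
    return(dplyr::bind_rows(recs[seq_len(k)]))
  }

  if (impute_per_fold && preprocess != "item_mean") {
    stop_arg("impute_per_fold requires preprocess = 'item_mean'")
  }
  X <- prep(R)$X
  V_raw <- if (impute_per_fold) t(R$values) * 1.0 else NULL  # items x subjects
  n <- ncol(X)
  if (n / n_folds < max(ranks)) {
    stop_arg("hold folds of ", floor(n / n_folds),
             " subjects cannot support rank ", max(ranks))
  }
  groups <- NULL
  if (scheme == "group_stratified_kfold") {
    if (!group_field %in% names(R$subject_meta)) {
      stop_arg("subject metadata has no column '", group_field, "'")
    }
    groups <- as.character(R$subject_meta[[group_field]])
    if (length(unique(groups)) < 2) {
      stop_arg("group-stratified cross-validation needs at least 2 groups")
    }
  }

  recs <- vector("list", n_reps * n_folds * length(ranks))
  k <- 0L
  for (rep_i in seq_len(n_reps)) {
    rs <- derive_seed(seed, 17, rep_i)
    folds <- if (scheme == "kfold") {
      fold_assignment(n, n_folds, rs)
    } else {
      grouped_fold_assignment(groups, n_folds, rs)
    }
    for (f in seq_len(n_folds)) {
      hold <- folds == f
      if (impute_per_fold) {
        # item means from the main sample only; fill both samples with them
        mu <- rowMeans(V_raw[, !hold, drop = FALSE], na.rm = TRUE)
        if (anyNA(mu)) {
          stop_arg("an item is entirely missing in a main sample; cannot ",
                   "impute per fold")
        }
        fill <- function(V) {
          idx <- which(is.na(V), arr.ind = TRUE)
          V[idx] <- mu[idx[, 1]]
          V
        }
        X_main <- fill(V_raw[, !hold, drop = FALSE])
        X_hold <- fill(V_raw[, hold, drop = FALSE])
      } else {
        X_main <- X[, !hold, drop = FALSE]
        X_hold <- X[, hold, drop = FALSE]
      }
      for (r in ranks) {
        mm <- fit_fold_model(X_main, r, method, control, rs)
        mh <- fit_fold_model(X_hold, r, method, control, rs)
        k <- k + 1L
        recs[[k]] <- cv_record(rep_i, f, r, mm, mh, X_hold)
      }
    }
  }
  dplyr::bind_rows(recs[seq_len(k)])
}

cv_record <- function(rep_i, fold, rank, model_main, model_hold, X_hold) {
  p_main <- assign_items(model_main)
  p_hold <- assign_items(model_hold)
  iv <- item_variability(list(p_main, p_hold))
  tibble::tibble(
    repetition = rep_i, fold = fold, rank = rank,
    ari = adjusted_rand_index(p_main, p_hold),
    vi = variation_of_information(p_main, p_hold),
    ci = concordance_index(model_main, model_hold),
    ire = model_re(model_main, X_hold) - model_re(model_hold, X_hold),
    iv_mean = mean(iv$iv),
    iv = list(setNames(iv$iv, iv$item_id))
  )
}

#' Write cross-validation records as long-format CSV
#'
#' One row per (repetition, fold, rank, index): columns `repetition`,
#' `fold`, `rank`, `index`, `value`.
#'
#' @param records Output of [run_crossvalidation()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cv_records <- function(records, path) {
  long <- tidyr::pivot_longer(
    records[c("repetition", "fold", "rank", "ari", "vi", "ci", "ire", "iv_mean")],
    cols = c("ari", "vi", "ci", "ire", "iv_mean"),
    names_to = "index", values_to = "value"
  )
  readr::write_csv(long, path)
  invisible(path)
}

normalize_index <- function(x, higher_is_better = TRUE) {
  rng <- range(x)
  if (diff(rng) < 1e-12) return(rep(0.5, length(x)))
  z <- (x - rng[1]) / diff(rng)
  if (higher_is_better) z else 1 - z
}

composite_from_medians <- function(med) {
  (normalize_index(med$ari, TRUE) + normalize_index(med$ci, TRUE) +
     normalize_index(med$vi, FALSE) + normalize_index(med$ire, FALSE)) / 4
}

#' Summarize cross-validation records into a rank-selection table
#'
#' Per rank: the median of each evaluation index over all records; indices
#' are oriented (aRI, CI up; VI, iRE down), min-max normalized across ranks
#' within the assessment, and averaged into a composite in `[0, 1]` whose
#' 95% confidence interval is obtained by bootstrap-resampling records
#' within each rank. An index constant across ranks contributes 0.5
#' everywhere (degenerate-range rule). Optimal ranks are the composite
#' maxima. Mean item variability is summarized alongside but not folded
#' into the composite (it lives on the item, not the model, unit).
#'
#' @param records Tibble from [run_crossvalidation()] covering >= 2 ranks.
#' @param n_boot Bootstrap resamples for the composite CI.
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level.
#' @return A `rank_selection` object: `summary` tibble (per-rank medians,
#'   normalized indices, `composite`, `composite_lo`, `composite_hi`) and
#'   `optimal_ranks`.
#' @export
summarize_rank_selection <- function(records, n_boot = 200, seed = 1,
                                     conf = 0.95) {
  ranks <- sort(unique(records$rank))
  if (length(ranks) < 2) {
    stop_arg("rank selection needs records for at least 2 ranks")
  }
  med_by_rank <- function(rec) {
    rec |>
      dplyr::group_by(.data$rank) |>
      dplyr::summarise(ari = median(.data$ari), vi = median(.data$vi),
                       ci = median(.data$ci), ire = median(.data$ire),
                       iv_mean = median(.data$iv_mean), .groups = "drop") |>
      dplyr::arrange(.data$rank)
  }
  med <- med_by_rank(records)
  comp <- composite_from_medians(med)

  set.seed(seed)
  idx_by_rank <- split(seq_len(nrow(records)), records$rank)
  boot <- matrix(NA_real_, n_boot, length(ranks))
  for (b in seq_len(n_boot)) {
    take <- unlist(lapply(idx_by_rank, function(ix) {
      ix[sample.int(length(ix), replace = TRUE)]
    }), use.names = FALSE)
    boot[b, ] <- composite_from_medians(med_by_rank(records[take, ]))
  }
  alpha <- (1 - conf) / 2
  lo <- apply(boot, 2, quantile, alpha)
  hi <- apply(boot, 2, quantile, 1 - alpha)

  summary <- tibble::tibble(
    rank = ranks,
    median_ari = med$ari, median_vi = med$vi, median_ci = med$ci,
    median_ire = med$ire, median_iv = med$iv_mean,
    norm_ari = normalize_index(med$ari, TRUE),
    norm_vi = normalize_index(med$vi, FALSE),
    norm_ci = normalize_index(med$ci, TRUE),
    norm_ire = normalize_index(med$ire, FALSE),
    composite = comp,
    composite_mean_boot = colMeans(boot),
    composite_lo = lo, composite_hi = hi
  )
  structure(
    list(summary = summary,
         optimal_ranks = ranks[comp >= max(comp) - 1e-12],
         n_records = nrow(records), n_boot = n_boot, conf = conf),
    class = "rank_selection"
  )
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("<rank_selection> over ranks ", paste(x$summary$rank, collapse = ", "),
      " (", x$n_records, " CV records)\n", sep = "")
  cat("  optimal rank(s): ", paste(x$optimal_ranks, collapse = ", "),
      "\n", sep = "")
  print(x$summary[, c("rank", "median_ari", "median_vi", "median_ci",
                      "median_ire", "composite")])
  invisible(x)
}
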