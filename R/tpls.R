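pheno_features <- function(F) {
  if (inherits(F, "phenotype_matrix")) F$features else as.matrix(F)
}

pheno_family <- function(F, family_id = NULL, n = NULL) {
  if (!is.null(family_id)) return(family_id)
  if (inherits(F, "phenotype_matrix") && !is.null(F$family_id)) {
    return(F$family_id)
  }
  seq_len(n %||% nrow(pheno_features(F)))
}

# PLS1 coefficient vectors for components 1..Kmax on column-standardized
# training features and a centered response; thin wrapper over the
# compiled Krylov solver.
pls1_coefficients <- function(X_std, y_centered, Kmax) {
  C <- crossprod(X_std)
  s <- crossprod(X_std, y_centered)
  .pls1_beta_all(C, s, as.integer(Kmax))
}

threshold_beta <- function(beta, keep) {
  p <- length(beta)
  if (keep >= p) return(beta)
  ord <- order(abs(beta), decreasing = TRUE)
  out <- numeric(p)
  out[ord[seq_len(keep)]] <- beta[ord[seq_len(keep)]]
  out
}

# Pick the best grid cell: maximum score, ties towards fewer components
# then stronger retention (larger eta).
select_grid_cell <- function(grid, score) {
  score[!is.finite(score)] <- -Inf
  best <- which(score >= max(score) - 1e-12)
  best <- best[order(grid$K[best], -grid$eta[best])]
  best[1]
}

#' Thresholded partial least squares (T-PLS) regression
#'
#' Fits a K-component univariate-response PLS regression on
#' column-standardized features, back-projects to a feature-space
#' coefficient vector, and zeroes all but the top `ceiling(eta * p)`
#' coefficients by absolute value. The hyperparameters (number of
#' components K and retention fraction eta) are tuned by inner
#' cross-validation whose folds keep each family in a single fold; the
#' score of a grid cell is the correlation between the response and its
#' out-of-fold predictions. Ties prefer fewer components, then larger eta.
#' At `eta = 1` the model is exactly plain PLS.
#'
#' @param F Subjects x features matrix or a `phenotype_matrix`.
#' @param y Numeric response (one value per subject).
#' @param K_grid Candidate component counts; default `1:min(25, n - 1, p)`.
#' @param eta_grid Candidate retention fractions in `(0, 1]`.
#' @param family_id Optional family labels for grouped inner folds
#'   (defaults to the phenotype matrix's families, else each subject its
#'   own family).
#' @param n_folds Inner cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @return A `tpls` object: thresholded coefficient vector `beta` (on the
#'   standardized feature scale), selected `K` and `eta`, `keep` (the
#'   nonzero-coefficient budget), the inner-CV `cv_grid`, and the
#'   feature/response centering needed by [predict.tpls()].
#' @export
fit_tpls <- function(F, y, K_grid = NULL,
                     eta_grid = seq(0.05, 1, by = 0.05),
                     family_id = NULL, n_folds = 5, seed = 1) {
  Fm <- pheno_features(F)
  n <- nrow(Fm); p <- ncol(Fm)
  if (length(y) != n) stop_arg("y length does not match subjects")
  K_grid <- K_grid %||% seq_len(min(25, n - 1, p))
  if (length(K_grid) == 0 || length(eta_grid) == 0) {
    stop_arg("empty hyperparameter grid")
  }
  if (max(K_grid) > min(n - 1, p)) {
    stop_arg("K may not exceed min(n - 1, p) = ", min(n - 1, p))
  }
  if (any(eta_grid <= 0 | eta_grid > 1)) stop_arg("eta must be in (0, 1]")
  family <- pheno_family(F, family_id, n)

  grid <- tidyr::expand_grid(K = sort(unique(K_grid)),
                             eta = sort(unique(eta_grid)))
  keep_of <- ceiling(grid$eta * p)
  Kmax <- max(grid$K)

  folds <- grouped_fold_assignment(family, n_folds, seed)
  oof <- matrix(NA_real_, n, nrow(grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    std <- standardize_columns(Fm[tr, , drop = FALSE])
    ymu <- mean(y[tr])
    B_all <- pls1_coefficients(std$F, y[tr] - ymu, Kmax)
    BIG <- matrix(0, p, nrow(grid))
    for (g in seq_len(nrow(grid))) {
      BIG[, g] <- threshold_beta(B_all[, grid$K[g]], keep_of[g])
    }
    Xva <- sweep(sweep(Fm[!tr, , drop = FALSE], 2, std$center, "-"),
                 2, std$scale, "/")
    Xva[, std$constant] <- 0
    oof[!tr, ] <- Xva %*% BIG + ymu
  }
  score <- suppressWarnings(as.numeric(cor(y, oof)))
  sel <- select_grid_cell(grid, score)

  std <- standardize_columns(Fm)
  ymu <- mean(y)
  beta_full <- pls1_coefficients(std$F, y - ymu, grid$K[sel])[, grid$K[sel]]
  beta <- threshold_beta(beta_full, keep_of[sel])
  names(beta) <- colnames(Fm) %||% sprintf("x%03d", seq_len(p))

  structure(
    list(beta = beta, K = grid$K[sel], eta = grid$eta[sel],
         keep = keep_of[sel],
         cv_grid = tibble::tibble(K = grid$K, eta = grid$eta, score = score),
         cv_score = score[sel],
         center = std$center, scale = std$scale, constant = std$constant,
         y_mean = ymu, n = n, p = p, seed = as.integer(seed)),
    class = "tpls"
  )
}

#' @export
print.tpls <- function(x, ...) {
  cat("<tpls> K = ", x$K, ", eta = ", x$eta, " (", sum(x$beta != 0), "/",
      x$p, " features retained); inner-CV r = ", signif(x$cv_score, 3),
      "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted T-PLS model
#'
#' @param object A `tpls` fit.
#' @param newdata Subjects x features matrix (or `phenotype_matrix`) with
#'   the same features.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.tpls <- function(object, newdata, ...) {
  Fm <- pheno_features(newdata)
  if (ncol(Fm) != object$p) stop_arg("newdata feature count mismatch")
  Xs <- sweep(sweep(Fm, 2, object$center, "-"), 2, object$scale, "/")
  Xs[, object$constant] <- 0
  as.numeric(Xs %*% object$beta + object$y_mean)
}

#' Bootstrap z-scores for T-PLS feature weights
#'
#' Resamples subjects with replacement, refits the T-PLS model at fixed
#' `(K, eta)` on each resample, and summarizes each feature's coefficient
#' as `z = mean / SD` over the bootstrap distribution (a feature whose
#' coefficient SD is zero gets z = 0 by rule, flagged). Two-tailed p-values
#' come from the normal tail and are Benjamini-Hochberg adjusted across
#' features.
#'
#' @param F Subjects x features matrix or `phenotype_matrix`.
#' @param y Numeric response.
#' @param K,eta The fixed hyperparameters (e.g. from a [fit_tpls()] run).
#' @param n_boot Bootstrap resamples (>= 100; 5000 in a full run).
#' @param seed Integer seed.
#' @param alpha_fdr FDR level for the significance flags.
#' @return A tibble: `feature`, `mean_beta`, `sd_beta`, `z`, `p_value`,
#'   `q_value`, `fdr_significant`, `degenerate`.
#' @export
bootstrap_feature_z <- function(F, y, K, eta, n_boot = 5000, seed = 1,
                                alpha_fdr = 0.05) {
  if (n_boot < 100) stop_arg("n_boot must be >= 100")
  Fm <- pheno_features(F)
  n <- nrow(Fm); p <- ncol(Fm)
  keep <- ceiling(eta * p)
  betas <- matrix(NA_real_, n_boot, p)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    std <- standardize_columns(Fm[idx, , drop = FALSE])
    yb <- y[idx]
    beta <- pls1_coefficients(std$F, yb - mean(yb), K)[, K]
    betas[b, ] <- threshold_beta(beta, keep)
  }
  mb <- colMeans(betas)
  sb <- apply(betas, 2, sd)
  degenerate <- sb < 1e-14
  z <- ifelse(degenerate, 0, mb / ifelse(degenerate, 1, sb))
  pv <- 2 * pnorm(-abs(z))
  qv <- p.adjust(pv, method = "BH")
  tibble::tibble(
    feature = colnames(Fm) %||% sprintf("x%03d", seq_len(p)),
    mean_beta = mb, sd_beta = sb, z = z,
    p_value = pv, q_value = qv,
    fdr_significant = qv < alpha_fdr & !degenerate,
    degenerate = degenerate
  )
}
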