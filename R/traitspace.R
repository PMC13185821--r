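#' Standardize 2D trait scores
#'
#' Z-scores each axis of a per-subject (SA, SM) score table so directional
#' projections and the variance profile live on a common scale. Axis
#' convention throughout the package: 0 degrees = +SA (first axis),
#' 90 degrees = +SM (second axis), counterclockwise.
#'
#' @param raw Subjects x 2 matrix or data frame; columns `SA`/`SM` if named,
#'   otherwise the first two numeric columns. An optional `family_id`
#'   column is carried along for grouped cross-validation.
#' @return A `trait_scores` tibble with z-scored `SA`, `SM` (means 0, SDs 1)
#'   and optionally `family_id`.
#' @export
standardize_scores <- function(raw) {
  df <- as.data.frame(raw)
  if (all(c("SA", "SM") %in% names(df))) {
    sa <- df$SA; sm <- df$SM
  } else {
    num <- which(vapply(df, is.numeric, logical(1)))
    if (length(num) < 2) stop_arg("need two numeric score columns")
    sa <- df[[num[1]]]; sm <- df[[num[2]]]
  }
  if (length(sa) < 3) stop_arg("need at least 3 subjects")
  if (sd(sa) < 1e-14 || sd(sm) < 1e-14) {
    stop_arg("zero-variance axis; scores cannot be standardized")
  }
  out <- tibble::tibble(SA = as.numeric(scale(sa)), SM = as.numeric(scale(sm)))
  if ("family_id" %in% names(df)) out$family_id <- df$family_id
  class(out) <- c("trait_scores", class(out))
  attr(out, "standardized") <- TRUE
  out
}

as_trait_scores <- function(scores) {
  if (inherits(scores, "trait_scores")) scores else standardize_scores(scores)
}

#' Directional projection in the 2D trait plane
#'
#' The scalar trait-orientation score
#' `p_i = cos(theta) SA_i + sin(theta) SM_i` expressing how strongly each
#' subject expresses the direction `theta` (degrees, in `(0, 180]`).
#'
#' @param scores A `trait_scores` table (or anything
#'   [standardize_scores()] accepts).
#' @param theta_deg Direction in degrees, in `(0, 180]`.
#' @return Numeric vector, one projection per subject.
#' @export
directional_projection <- function(scores, theta_deg) {
  if (theta_deg <= 0 || theta_deg > 180) {
    stop_arg("theta_deg must be in (0, 180]")
  }
  sc <- as_trait_scores(scores)
  th <- theta_deg * pi / 180
  cos(th) * sc$SA + sin(th) * sc$SM
}

#' Directional variance profile of the trait plane
#'
#' The standard deviation of the directional projection per angle. For
#' exactly z-scored axes with correlation rho the closed form is
#' `Var(theta) = 1 + rho * sin(2 theta)`, so the profile peaks at 45
#' degrees for positively correlated axes and at 135 degrees for negative
#' correlation.
#'
#' @param scores A `trait_scores` table.
#' @param angles Angles in degrees (non-empty, each in `(0, 180]`).
#' @return A `direction_profile` object: `profile` tibble (`angle`, `sd`)
#'   and `peak_angle`.
#' @export
direction_variance_profile <- function(scores, angles = 1:180) {
  if (length(angles) == 0) stop_arg("empty angle list")
  sc <- as_trait_scores(scores)
  sds <- vapply(angles, function(a) sd(directional_projection(sc, a)),
                numeric(1))
  structure(
    list(profile = tibble::tibble(angle = angles, sd = sds),
         peak_angle = angles[which.max(sds)]),
    class = "direction_profile"
  )
}

#' @export
print.direction_profile <- function(x, ...) {
  cat("<direction_profile> ", nrow(x$profile), " angles; peak at ",
      x$peak_angle, " degrees (sd ", signif(max(x$profile$sd), 4), ")\n",
      sep = "")
  invisible(x)
}

# Nested-CV out-of-fold accuracy for one or more targets sharing the same
# feature matrix. Y is n x q (each column a target); returns fold-level
# accuracies plus the selected hyperparameters per (target, rep, fold).
# Inner-fold standardizations and Gram matrices are shared across targets.
nested_cv_accuracy <- function(Fm, Y, family, n_reps, n_folds,
                               K_grid, eta_grid, seed) {
  n <- nrow(Fm); p <- ncol(Fm); q <- ncol(Y)
  grid <- tidyr::expand_grid(K = sort(unique(K_grid)),
                             eta = sort(unique(eta_grid)))
  keep_of <- ceiling(grid$eta * p)
  Kmax <- max(grid$K)
  out <- vector("list", n_reps * n_folds * q)
  k <- 0L
  for (rep_i in seq_len(n_reps)) {
    folds <- grouped_fold_assignment(family, n_folds,
                                     derive_seed(seed, 51, rep_i))
    for (f in seq_len(n_folds)) {
      tr <- which(folds != f)
      va <- which(folds == f)
      std <- standardize_columns(Fm[tr, , drop = FALSE])
      Xtr <- std$F
      Xva <- sweep(sweep(Fm[va, , drop = FALSE], 2, std$center, "-"),
                   2, std$scale, "/")
      Xva[, std$constant] <- 0
      # inner folds within the training part, grouped by family
      ifolds <- grouped_fold_assignment(family[tr], n_folds,
                                        derive_seed(seed, 52, rep_i, f))
      inner <- lapply(seq_len(n_folds), function(g) {
        itr <- ifolds != g
        istd <- standardize_columns(Fm[tr[itr], , drop = FALSE])
        Xiva <- sweep(sweep(Fm[tr[!itr], , drop = FALSE], 2, istd$center, "-"),
                      2, istd$scale, "/")
        Xiva[, istd$constant] <- 0
        list(itr = itr, Xitr = istd$F, Xiva = Xiva)
      })
      for (j in seq_len(q)) {
        y <- Y[, j]
        y_tr <- y[tr]
        oof <- matrix(NA_real_, length(tr), nrow(grid))
        for (g in seq_len(n_folds)) {
          iv <- inner[[g]]
          yi <- y_tr[iv$itr]
          B_all <- pls1_coefficients(iv$Xitr, yi - mean(yi), Kmax)
          BIG <- matrix(0, p, nrow(grid))
          for (cidx in seq_len(nrow(grid))) {
            BIG[, cidx] <- threshold_beta(B_all[, grid$K[cidx]], keep_of[cidx])
          }
          oof[!iv$itr, ] <- iv$Xiva %*% BIG + mean(yi)
        }
        score <- suppressWarnings(as.numeric(cor(y_tr, oof)))
        sel <- select_grid_cell(grid, score)
        beta <- threshold_beta(
          pls1_coefficients(Xtr, y_tr - mean(y_tr), grid$K[sel])[, grid$K[sel]],
          keep_of[sel])
        pred <- as.numeric(Xva %*% beta) + mean(y_tr)
        acc <- suppressWarnings(cor(y[va], pred))
        if (!is.finite(acc)) acc <- 0
        k <- k + 1L
        out[[k]] <- tibble::tibble(target = j, repetition = rep_i, fold = f,
                                   K = grid$K[sel], eta = grid$eta[sel],
                                   accuracy = acc)
      }
    }
  }
  dplyr::bind_rows(out[seq_len(k)])
}

#' Directional prediction scan over the 2D trait plane
#'
#' For every angle (default 1..180 degrees) the directional projection of
#' the trait scores is predicted from the phenotype features with T-PLS
#' under repeated grouped cross-validation (families never split across
#' folds); the observed accuracy of an angle is the mean out-of-fold
#' Pearson correlation between actual and predicted projections over all
#' repetitions and folds, with hyperparameters re-selected by inner
#' cross-validation inside every training fold. Permutation inference
#' shuffles the target across subjects and recomputes the cross-validated
#' accuracy with the angle's full-data-selected hyperparameters held fixed
#' (one fold pass per permutation);
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, Benjamini-Hochberg
#' adjusted across angles.
#'
#' @param F Subjects x features matrix or `phenotype_matrix`.
#' @param scores A `trait_scores` table aligned with `F`.
#' @param angles Angles scanned, degrees in `(0, 180]`.
#' @param n_reps Repetitions of the outer cross-validation (default 30).
#' @param n_folds Folds (default 5).
#' @param n_perm Permutations (default 5000).
#' @param alpha_fdr FDR level for the significance flags.
#' @param seed Master seed.
#' @param K_grid,eta_grid T-PLS hyperparameter grids (see [fit_tpls()]).
#' @param family_id Optional family labels; defaults to the scores' or
#'   phenotype matrix's families.
#' @param permute_within_family Permute the target within families instead
#'   of freely across subjects.
#' @return A `direction_scan` object: per-angle tibble `table` (`angle`,
#'   `accuracy`, `accuracy_sd`, `K`, `eta`, `p_value`, `q_value`,
#'   `fdr_significant`), fold-level `accuracies`, `peak_angle`,
#'   `peak_accuracy`, and the full-data models' coefficients.
#' @export
direction_scan <- function(F, scores, angles = 1:180, n_reps = 30,
                           n_folds = 5, n_perm = 5000, alpha_fdr = 0.05,
                           seed = 1, K_grid = NULL,
                           eta_grid = seq(0.05, 1, by = 0.05),
                           family_id = NULL,
                           permute_within_family = FALSE) {
  if (n_perm < 1) stop_arg("n_perm must be >= 1")
  if (any(angles <= 0 | angles > 180)) stop_arg("angles must be in (0, 180]")
  Fm <- pheno_features(F)
  sc <- as_trait_scores(scores)
  n <- nrow(Fm)
  if (nrow(sc) != n) stop_arg("scores and features have different subjects")
  p <- ncol(Fm)
  K_grid <- K_grid %||% seq_len(min(25, n - 1, p))
  family <- family_id %||% sc[["family_id"]] %||% pheno_family(F, NULL, n)

  Y <- vapply(angles, function(a) directional_projection(sc, a), numeric(n))

  acc_tbl <- nested_cv_accuracy(Fm, Y, family, n_reps, n_folds,
                                K_grid, eta_grid, seed)
  obs <- acc_tbl |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(accuracy = mean(.data$accuracy),
                     accuracy_sd = sd(.data$accuracy), .groups = "drop")

  # full-data hyperparameter selection per angle (drives the permutations
  # and the reported per-angle model)
  full <- lapply(seq_along(angles), function(j) {
    fit_tpls(Fm, Y[, j], K_grid = K_grid, eta_grid = eta_grid,
             family_id = family, n_folds = n_folds,
             seed = derive_seed(seed, 53, j))
  })
  K_sel <- vapply(full, function(m) as.numeric(m$K), numeric(1))
  keep_sel <- vapply(full, function(m) as.numeric(m$keep), numeric(1))

  # permutation null: fixed fold split, fixed (K, eta) per angle
  set.seed(derive_seed(seed, 61))
  P <- replicate(n_perm, if (permute_within_family) {
    ave(seq_len(n), family, FUN = sample)
  } else {
    sample.int(n)
  })
  pfolds <- grouped_fold_assignment(family, n_folds, derive_seed(seed, 62))
  null_acc <- matrix(0, length(angles), n_perm)
  for (f in seq_len(n_folds)) {
    tr <- which(pfolds != f)
    va <- which(pfolds == f)
    std <- standardize_columns(Fm[tr, , drop = FALSE])
    Xtr <- std$F
    Xva <- sweep(sweep(Fm[va, , drop = FALSE], 2, std$center, "-"),
                 2, std$scale, "/")
    Xva[, std$constant] <- 0
    C <- crossprod(Xtr)
    for (j in seq_along(angles)) {
      Yp <- matrix(Y[P, j], n, n_perm)
      Ytr <- Yp[tr, , drop = FALSE]
      Ytr_c <- sweep(Ytr, 2, colMeans(Ytr), "-")
      S <- crossprod(Xtr, Ytr_c)
      B <- .pls1_beta_batch(C, S, as.integer(K_sel[j]),
                            as.integer(keep_sel[j]))
      Pred <- Xva %*% B
      Yva <- Yp[va, , drop = FALSE]
      pc <- sweep(Pred, 2, colMeans(Pred), "-")
      yc <- sweep(Yva, 2, colMeans(Yva), "-")
      r <- colSums(pc * yc) / sqrt(colSums(pc^2) * colSums(yc^2))
      r[!is.finite(r)] <- 0
      null_acc[j, ] <- null_acc[j, ] + r / n_folds
    }
  }
  pv <- vapply(seq_along(angles), function(j) {
    (1 + sum(null_acc[j, ] >= obs$accuracy[j])) / (1 + n_perm)
  }, numeric(1))
  qv <- p.adjust(pv, method = "BH")

  table <- tibble::tibble(
    angle = angles,
    accuracy = obs$accuracy,
    accuracy_sd = obs$accuracy_sd,
    K = K_sel,
    eta = vapply(full, function(m) as.numeric(m$eta), numeric(1)),
    p_value = pv, q_value = qv,
    fdr_significant = qv < alpha_fdr
  )
  peak <- which.max(table$accuracy)
  acc_tbl$angle <- angles[acc_tbl$target]
  structure(
    list(table = table,
         accuracies = acc_tbl[c("angle", "repetition", "fold", "K", "eta",
                                "accuracy")],
         peak_angle = angles[peak],
         peak_accuracy = table$accuracy[peak],
         beta = lapply(full, `[[`, "beta"),
         params = list(n_reps = n_reps, n_folds = n_folds, n_perm = n_perm,
                       alpha_fdr = alpha_fdr, seed = seed)),
    class = "direction_scan"
  )
}

#' @export
print.direction_scan <- function(x, ...) {
  sig <- sum(x$table$fdr_significant)
  cat("<direction_scan> ", nrow(x$table), " angles; peak ",
      x$peak_angle, " degrees (r = ", signif(x$peak_accuracy, 3), "); ",
      sig, " FDR-significant\n", sep = "")
  invisible(x)
}

#' Write a direction scan as CSV plus JSON metadata
#'
#' @param scan A `direction_scan`.
#' @param prefix Path prefix; writes `<prefix>.csv` and `<prefix>_meta.json`.
#' @return Invisibly, the files written.
#' @export
write_direction_scan <- function(scan, prefix) {
  csv <- paste0(prefix, ".csv")
  meta <- paste0(prefix, "_meta.json")
  readr::write_csv(scan$table, csv)
  jsonlite::write_json(
    c(scan$params, list(peak_angle = scan$peak_angle,
                        peak_accuracy = scan$peak_accuracy)),
    meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, meta))
}

#' Signature responses from bootstrap z-weights
#'
#' The per-subject dot product of the feature z-weights with the
#' column-standardized phenotype features: a composite score expressing how
#' strongly a subject's phenotype matches the predictive pattern.
#'
#' @param z_weights Named numeric vector of per-feature z-scores (e.g.
#'   column `z` of [bootstrap_feature_z()]), or that tibble itself.
#' @param F Subjects x features matrix or `phenotype_matrix`.
#' @return Numeric vector of per-subject signature responses.
#' @export
signature_response <- function(z_weights, F) {
  if (is.data.frame(z_weights)) {
    z_weights <- setNames(z_weights$z, z_weights$feature)
  }
  Fm <- pheno_features(F)
  if (!is.null(names(z_weights)) && !is.null(colnames(Fm))) {
    if (!setequal(names(z_weights), colnames(Fm))) {
      stop_arg("z-weight names do not match feature names")
    }
    z_weights <- z_weights[colnames(Fm)]
  } else if (length(z_weights) != ncol(Fm)) {
    stop_arg("z-weight length does not match feature count")
  }
  std <- standardize_columns(Fm)
  as.numeric(std$F %*% z_weights)
}

#' Correlate signature responses with trait scores
#'
#' Pearson correlation of a per-subject signature with each trait column.
#' Zero-variance columns are flagged and reported as `NA`.
#'
#' @param signatures Numeric vector of per-subject signatures.
#' @param trait_scores Data frame of numeric trait columns aligned to the
#'   same subjects.
#' @return A tibble: `trait`, `r`, `degenerate`.
#' @export
correlate_signatures <- function(signatures, trait_scores) {
  df <- as.data.frame(trait_scores)
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  if (!length(num)) stop_arg("trait_scores has no numeric columns")
  if (nrow(df) != length(signatures)) {
    stop_arg("signatures and trait scores have different subjects")
  }
  out <- lapply(num, function(cn) {
    x <- df[[cn]]
    degen <- sd(x) < 1e-14 || sd(signatures) < 1e-14
    tibble::tibble(trait = cn,
                   r = if (degen) NA_real_ else cor(signatures, x),
                   degenerate = degen)
  })
  dplyr::bind_rows(out)
}

#' Compare predictive performance across named targets
#'
#' Runs the identical repeated grouped nested-CV T-PLS protocol on every
#' target (e.g. the two trait-plane peak directions and the five Big Five
#' scores) and additionally reports the Pearson similarity between the
#' final full-data coefficient vectors of each target pair.
#'
#' @param F Subjects x features matrix or `phenotype_matrix`.
#' @param targets Named list (or data frame) of numeric target vectors.
#' @param n_reps,n_folds Cross-validation protocol.
#' @param seed Master seed.
#' @param K_grid,eta_grid T-PLS grids.
#' @param family_id Optional family labels for grouped folds.
#' @return A `target_comparison`: `accuracies` (target, repetition, fold,
#'   accuracy; `n_reps * n_folds` values per target), `summary` (mean/sd
#'   accuracy per target), `weight_similarity` (targets x targets Pearson
#'   matrix), `models` (full-data `tpls` fits).
#' @export
compare_targets <- function(F, targets, n_reps = 30, n_folds = 5, seed = 1,
                            K_grid = NULL, eta_grid = seq(0.05, 1, by = 0.05),
                            family_id = NULL) {
  tl <- as.list(targets)
  if (is.null(names(tl)) || any(names(tl) == "")) {
    stop_arg("targets must be named")
  }
  if (anyDuplicated(names(tl))) stop_arg("duplicate target names")
  Fm <- pheno_features(F)
  n <- nrow(Fm)
  if (any(lengths(tl) != n)) stop_arg("targets must align to subjects")
  K_grid <- K_grid %||% seq_len(min(25, n - 1, ncol(Fm)))
  family <- pheno_family(F, family_id, n)
  Y <- do.call(cbind, tl)

  acc <- nested_cv_accuracy(Fm, Y, family, n_reps, n_folds,
                            K_grid, eta_grid, seed)
  acc$target <- names(tl)[acc$target]
  models <- lapply(seq_along(tl), function(j) {
    fit_tpls(Fm, Y[, j], K_grid = K_grid, eta_grid = eta_grid,
             family_id = family, n_folds = n_folds,
             seed = derive_seed(seed, 71, j))
  })
  names(models) <- names(tl)
  W <- vapply(models, `[[`, numeric(ncol(Fm)), "beta")
  ws <- suppressWarnings(cor(W))
  ws[!is.finite(ws)] <- NA_real_
  summary <- acc |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = sd(.data$accuracy), .groups = "drop")
  structure(
    list(accuracies = acc[c("target", "repetition", "fold", "accuracy")],
         summary = summary, weight_similarity = ws, models = models),
    class = "target_comparison"
  )
}

#' @export
print.target_comparison <- function(x, ...) {
  cat("<target_comparison> ", length(x$models), " targets\n", sep = "")
  print(x$summary)
  invisible(x)
}
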