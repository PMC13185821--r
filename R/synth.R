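#' Build planted non-negative factor loadings for synthetic questionnaires
#'
#' Constructs the ground truth of the synthetic-data generator: a block
#' non-negative loading matrix with one dominant block per Big Five dimension
#' (N, E, O, A, C), a latent score covariance, per-item keying directions,
#' and the noise/missingness settings used by [simulate_responses()].
#'
#' Two structures are available. `"big5"` plants five independent factors.
#' `"big2_hier"` keeps the five loading blocks but couples the latent scores
#' of \{E, A, C\} (correlation `rho_social`) and of \{N, O\} (correlation
#' `rho_mentation`) positively, planting a hierarchical "Big Two"
#' super-structure: a Social-Adaptation-like cluster (E+A+C) and a
#' Spontaneous-Mentation-like cluster (N+O) on top of the five blocks. The
#' N-O cluster is slightly more cohesive by default (0.55 vs 0.5), so both
#' the two- and the five-factor descriptions of the data are natural scales
#' while three- and four-factor solutions face a genuine ambiguity about
#' which cluster to split — the hallmark of a trait hierarchy.
#'
#' Dominant-block loadings are drawn uniformly on \[0.6, 1\] and off-block
#' cross-loadings uniformly on \[0, `cross_loading`\], so dominant entries
#' strictly exceed cross-loadings whenever `cross_loading < 0.5`. Every
#' fourth item within a dimension is negatively keyed, mimicking the
#' reverse-scored items of real inventories.
#'
#' @param n_items_per_dimension Number of items per Big Five dimension
#'   (at least 2).
#' @param structure `"big5"` or `"big2_hier"`.
#' @param cross_loading Upper bound of off-block loadings, in `[0, 0.5)`.
#' @param seed Integer seed; identical calls are bit-identical.
#' @param noise_sd Response noise SD on the latent (approximately Likert)
#'   scale; see [simulate_responses()].
#' @param missing_rate Fraction of cells set missing, in `[0, 1)`.
#' @param acquiescence_sd SD of the per-subject additive acquiescence shift.
#' @param rho_social Latent score correlation planted among E, A, C under
#'   `"big2_hier"`.
#' @param rho_mentation Latent score correlation planted between N and O
#'   under `"big2_hier"`.
#' @param group_spec Optional tibble with columns `label`, `n`, `perturb_sd`,
#'   `noise_mult` describing heterogeneous subgroups for
#'   [simulate_subgroups()].
#'
#' @return A `synthetic_truth` object: list with `W_true` (items x 5,
#'   non-negative), `score_cov` (5 x 5), `dimension_of_item`,
#'   `keyed_direction` (+1/-1), the noise settings and the seed.
#' @export
#' @examples
#' truth <- build_true_loadings(4, "big5", cross_loading = 0, seed = 1)
#' dim(truth$W_true)
build_true_loadings <- function(n_items_per_dimension,
                                structure = c("big5", "big2_hier"),
                                cross_loading = 0,
                                seed = 1,
                                noise_sd = 0.5,
                                missing_rate = 0,
                                acquiescence_sd = 0,
                                rho_social = 0.5,
                                rho_mentation = 0.55,
                                group_spec = NULL) {
  structure <- match.arg(structure)
  if (n_items_per_dimension < 2) {
    stop_arg("n_items_per_dimension must be >= 2")
  }
  if (cross_loading < 0 || cross_loading >= 0.5) {
    stop_arg("cross_loading must be in [0, 0.5)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_arg("missing_rate must be in [0, 1)")
  }

  dims <- c("N", "E", "O", "A", "C")
  r <- length(dims)
  m <- n_items_per_dimension * r
  dimension_of_item <- rep(dims, each = n_items_per_dimension)
  item_id <- paste0(dimension_of_item,
                    sprintf("%02d", sequence(rep(n_items_per_dimension, r))))

  set.seed(seed)
  W <- matrix(runif(m * r, 0, cross_loading), m, r,
              dimnames = list(item_id, dims))
  if (cross_loading == 0) W[] <- 0
  for (j in seq_len(r)) {
    block <- dimension_of_item == dims[j]
    W[block, j] <- runif(n_items_per_dimension, 0.6, 1)
  }

  score_cov <- diag(r)
  dimnames(score_cov) <- list(dims, dims)
  if (structure == "big2_hier") {
    couple <- function(a, b, rho) {
      score_cov[a, b] <<- rho
      score_cov[b, a] <<- rho
    }
    couple("E", "A", rho_social)
    couple("E", "C", rho_social)
    couple("A", "C", rho_social)
    couple("N", "O", rho_mentation)
  }

  keyed_direction <- rep(1L, m)
  keyed_direction[seq(4, m, by = 4)] <- -1L

  structure(
    list(W_true = W,
         score_cov = score_cov,
         dimension_of_item = dimension_of_item,
         keyed_direction = keyed_direction,
         item_id = item_id,
         structure = structure,
         cross_loading = cross_loading,
         noise_sd = noise_sd,
         missing_rate = missing_rate,
         acquiescence_sd = acquiescence_sd,
         rho_social = rho_social,
         rho_mentation = rho_mentation,
         group_spec = group_spec,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$W_true), " items x ", ncol(x$W_true),
      " factors (", x$structure, ")\n", sep = "")
  cat("  noise_sd = ", x$noise_sd, ", missing_rate = ", x$missing_rate,
      ", acquiescence_sd = ", x$acquiescence_sd, "\n", sep = "")
  invisible(x)
}

# Draw latent subject scores: multivariate normal with mean 2 and covariance
# score_cov, left-censored at zero so scores are non-negative (censoring
# touches ~2% of draws at unit variance). Returns r x n.
draw_latent_scores <- function(score_cov, n) {
  ev <- eigen(score_cov, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
    stop_arg("score_cov is not positive semi-definite")
  }
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow = length(ev$values))
  r <- nrow(score_cov)
  Z <- matrix(rnorm(r * n), r, n)
  H <- 2 + A %*% Z
  pmax(H, 0)
}

# Continuous latent responses for one homogeneous population (before any
# discretization): L = W H + acquiescence + noise, items x subjects.
simulate_continuous <- function(truth, W, n_subjects, noise_sd, seed) {
  m <- nrow(W)
  set.seed(seed)
  H <- draw_latent_scores(truth$score_cov, n_subjects)
  L <- W %*% H
  if (truth$acquiescence_sd > 0) {
    acq <- rnorm(n_subjects, 0, truth$acquiescence_sd)
    L <- sweep(L, 2, acq, "+")
  }
  if (noise_sd > 0) {
    L <- L + matrix(rnorm(m * n_subjects, 0, noise_sd), m, n_subjects)
  }
  list(L = L, H = H)
}

# Discretize pooled continuous responses to raw-keyed Likert integers: each
# item is affinely rescaled to [1, 5] by its own 1st/99th percentiles over
# the *whole* sample (a single instrument has one response mapping for
# everyone), rounded, reverse-keyed items flipped, missing cells inserted.
discretize_responses <- function(L, truth, miss_seed) {
  m <- nrow(L)
  n <- ncol(L)
  for (i in seq_len(m)) {
    q <- quantile(L[i, ], c(0.01, 0.99), names = FALSE, type = 7)
    if (q[2] - q[1] < 1e-12) {
      L[i, ] <- 3
    } else {
      L[i, ] <- 1 + 4 * (L[i, ] - q[1]) / (q[2] - q[1])
    }
  }
  V <- round(pmin(pmax(L, 1), 5))
  rev <- truth$keyed_direction == -1L
  V[rev, ] <- 6 - V[rev, ]
  if (truth$missing_rate > 0) {
    set.seed(miss_seed)
    V[runif(m * n) < truth$missing_rate] <- NA
  }
  values <- t(V)
  storage.mode(values) <- "integer"
  colnames(values) <- truth$item_id
  values
}

truth_item_key <- function(truth) {
  tibble::tibble(
    item_id = truth$item_id,
    instrument = "synthetic",
    dimension = truth$dimension_of_item,
    keyed = ifelse(truth$keyed_direction == 1L, "+", "-")
  )
}

#' Simulate Likert questionnaire responses from planted loadings
#'
#' Generates five-point Likert responses from the generative model
#' `X = W_true H + acquiescence + noise`: latent subject scores `H` are drawn
#' from a zero-censored multivariate normal with the planted covariance, a
#' per-subject acquiescence constant and item-level Gaussian noise are added,
#' each item is affinely rescaled to \[1, 5\] by its own 1st/99th percentiles
#' and rounded, negatively keyed items are flipped (`6 - x`) so the stored
#' table mimics raw keying, and missing cells are inserted uniformly at
#' random at `missing_rate`.
#'
#' @param truth A `synthetic_truth` from [build_true_loadings()].
#' @param n_subjects Number of subjects (at least twice the number of
#'   factors).
#' @param seed Integer seed; defaults to the truth's seed.
#'
#' @return List with `responses` (a [response_matrix()], raw keying, not yet
#'   reverse-scored), `true_scores` (subjects x factors matrix of latent
#'   scores), and `truth`.
#' @export
simulate_responses <- function(truth, n_subjects, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  r <- ncol(truth$W_true)
  if (n_subjects < 2 * r) {
    stop_arg("n_subjects must be at least 2 * number of factors (", 2 * r, ")")
  }
  cont <- simulate_continuous(truth, truth$W_true, n_subjects,
                              truth$noise_sd, seed)
  values <- discretize_responses(cont$L, truth, derive_seed(seed, 303))
  rownames(values) <- paste0("s", seq_len(n_subjects))
  true_scores <- t(cont$H)
  dimnames(true_scores) <- list(rownames(values), colnames(truth$W_true))
  meta <- tibble::tibble(subject_id = rownames(values))
  rm <- response_matrix(values, truth_item_key(truth), meta)
  list(responses = rm, true_scores = true_scores, truth = truth)
}

#' Simulate heterogeneous demographic subgroups
#'
#' Draws each group of `truth$group_spec` from its own perturbed loading
#' matrix `pmax(W_true + perturb_sd * E, 0)` (E standard normal) with noise
#' SD `noise_sd * noise_mult`, then stacks the groups. The group label is
#' stored in the subject metadata column `group`.
#'
#' @inheritParams simulate_responses
#' @return As [simulate_responses()], with a `group` column in the subject
#'   metadata.
#' @export
simulate_subgroups <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  spec <- truth$group_spec
  if (is.null(spec) || nrow(spec) == 0) {
    stop_arg("truth$group_spec is empty; supply group_spec in build_true_loadings()")
  }
  r <- ncol(truth$W_true)
  if (any(spec$n < r)) {
    stop_arg("every group size must be at least the number of factors (", r, ")")
  }
  pieces <- vector("list", nrow(spec))
  for (g in seq_len(nrow(spec))) {
    set.seed(derive_seed(seed, 101, g))
    Wg <- pmax(truth$W_true +
                 spec$perturb_sd[g] * matrix(rnorm(length(truth$W_true)),
                                             nrow(truth$W_true)), 0)
    pieces[[g]] <- simulate_continuous(truth, Wg, spec$n[g],
                                       truth$noise_sd * spec$noise_mult[g],
                                       derive_seed(seed, 202, g))
  }
  # one instrument, one response mapping: discretize the pooled sample
  L <- do.call(cbind, lapply(pieces, `[[`, "L"))
  values <- discretize_responses(L, truth, derive_seed(seed, 303))
  subject_id <- unlist(lapply(seq_len(nrow(spec)), function(g) {
    paste0(spec$label[g], "_s", seq_len(spec$n[g]))
  }))
  rownames(values) <- subject_id
  true_scores <- t(do.call(cbind, lapply(pieces, `[[`, "H")))
  dimnames(true_scores) <- list(subject_id, colnames(truth$W_true))
  meta <- tibble::tibble(
    subject_id = subject_id,
    group = rep(spec$label, spec$n)
  )
  rm <- response_matrix(values, truth_item_key(truth), meta)
  list(responses = rm, true_scores = true_scores, truth = truth)
}

#' Simulate phenotype features aligned with a direction in a 2D trait plane
#'
#' A `signal_fraction` subset of features is a noisy linear encoding of the
#' projection of the z-scored 2D trait scores onto the direction
#' `theta_true` (degrees; 0 deg = +axis 1, 90 deg = +axis 2); the remaining
#' features are pure standard-normal noise. True feature weights are +-1
#' with random sign, so the amplitude signal-to-noise ratio of a signal
#' feature is `1 / noise_sd`. Subjects are grouped into consecutive families
#' of `family_size` for grouped cross-validation.
#'
#' @param true_scores_2d Subjects x 2 matrix (or data frame) of trait scores.
#' @param theta_true Planted direction in degrees, in `(0, 180]`.
#' @param n_features Number of features (>= 1).
#' @param signal_fraction Fraction of features carrying signal, in `(0, 1]`.
#' @param noise_sd Noise SD added to signal features.
#' @param family_size Subjects per synthetic family block.
#' @param seed Integer seed.
#'
#' @return A `phenotype_matrix`: list with `features` (subjects x features),
#'   `feature_names`, `family_id`, `true_weights`, `theta_true`, and
#'   `domain = "synthetic"`.
#' @export
simulate_phenotypes <- function(true_scores_2d, theta_true, n_features,
                                signal_fraction = 0.5, noise_sd = 0.5,
                                family_size = 1, seed = 1) {
  if (n_features < 1) stop_arg("n_features must be >= 1")
  if (theta_true <= 0 || theta_true > 180) {
    stop_arg("theta_true must be in (0, 180] degrees")
  }
  if (signal_fraction <= 0 || signal_fraction > 1) {
    stop_arg("signal_fraction must be in (0, 1]")
  }
  S <- as.matrix(true_scores_2d)[, 1:2, drop = FALSE]
  n <- nrow(S)
  z1 <- as.numeric(scale(S[, 1]))
  z2 <- as.numeric(scale(S[, 2]))
  th <- theta_true * pi / 180
  target <- cos(th) * z1 + sin(th) * z2

  set.seed(seed)
  n_signal <- max(1L, round(signal_fraction * n_features))
  w <- numeric(n_features)
  w[seq_len(n_signal)] <- sample(c(-1, 1), n_signal, replace = TRUE)
  F <- matrix(rnorm(n * n_features), n, n_features)
  for (j in seq_len(n_signal)) {
    F[, j] <- w[j] * target + noise_sd * rnorm(n)
  }
  feature_names <- sprintf("pheno_%03d", seq_len(n_features))
  colnames(F) <- feature_names
  family_id <- rep(seq_len(ceiling(n / family_size)),
                   each = family_size)[seq_len(n)]

  structure(
    list(features = F,
         feature_names = feature_names,
         family_id = family_id,
         true_weights = setNames(w, feature_names),
         theta_true = theta_true,
         domain = "synthetic"),
    class = "phenotype_matrix"
  )
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat("<phenotype_matrix> ", nrow(x$features), " subjects x ",
      ncol(x$features), " features (", x$domain, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset as delimited text plus a JSON sidecar
#'
#' Writes responses, item key, subject metadata, true scores and (when
#' present) true feature weights as CSV, plus `spec.json` recording the full
#' generator specification and seed.
#'
#' @param sim Output of [simulate_responses()] or [simulate_subgroups()].
#' @param dir Output directory (created if needed).
#' @param phenotypes Optional `phenotype_matrix` to write alongside.
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic <- function(sim, dir, phenotypes = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rm <- sim$responses
  resp <- tibble::as_tibble(rm$values, rownames = "subject_id")
  files <- c(
    responses = file.path(dir, "responses.csv"),
    item_key = file.path(dir, "item_key.csv"),
    subject_meta = file.path(dir, "subject_meta.csv"),
    true_scores = file.path(dir, "true_scores.csv"),
    spec = file.path(dir, "spec.json")
  )
  readr::write_csv(resp, files["responses"], na = "")
  readr::write_csv(rm$item_key, files["item_key"])
  readr::write_csv(rm$subject_meta, files["subject_meta"])
  readr::write_csv(tibble::as_tibble(sim$true_scores, rownames = "subject_id"),
                   files["true_scores"])
  truth <- sim$truth
  spec <- list(
    structure = truth$structure,
    n_items_per_dimension = nrow(truth$W_true) / ncol(truth$W_true),
    cross_loading = truth$cross_loading,
    noise_sd = truth$noise_sd,
    missing_rate = truth$missing_rate,
    acquiescence_sd = truth$acquiescence_sd,
    rho_social = truth$rho_social,
    rho_mentation = truth$rho_mentation,
    seed = truth$seed,
    n_subjects = nrow(rm$values),
    group_spec = truth$group_spec
  )
  if (!is.null(phenotypes)) {
    pf <- file.path(dir, "phenotypes.csv")
    readr::write_csv(tibble::as_tibble(phenotypes$features), pf)
    wf <- file.path(dir, "true_weights.csv")
    readr::write_csv(tibble::tibble(feature = phenotypes$feature_names,
                                    true_weight = unname(phenotypes$true_weights)),
                     wf)
    files <- c(files, phenotypes = pf, true_weights = wf)
    spec$phenotypes <- list(theta_true = phenotypes$theta_true,
                            n_features = ncol(phenotypes$features))
  }
  jsonlite::write_json(spec, files["spec"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(files)
}
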