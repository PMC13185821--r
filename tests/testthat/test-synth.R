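test_that("planted loadings have the requested block structure", {
  truth <- build_true_loadings(4, "big5", cross_loading = 0, seed = 1)
  W <- truth$W_true
  expect_equal(dim(W), c(20, 5))
  expect_true(all(W >= 0))
  # zero cross-loading: exactly one nonzero block per column
  for (j in 1:5) {
    block <- truth$dimension_of_item == colnames(W)[j]
    expect_true(all(W[block, j] > 0))
    expect_true(all(W[!block, j] == 0))
  }
  # dominant entries strictly exceed cross-loadings at nonzero cross_loading
  truth2 <- build_true_loadings(4, "big5", cross_loading = 0.3, seed = 2)
  W2 <- truth2$W_true
  for (j in 1:5) {
    block <- truth2$dimension_of_item == colnames(W2)[j]
    expect_gt(min(W2[block, j]), max(W2[!block, j]))
  }
})

test_that("big2_hier couples the planted clusters positively", {
  truth <- build_true_loadings(4, "big2_hier", cross_loading = 0.1, seed = 1)
  sc <- truth$score_cov
  expect_gt(sc["E", "A"], 0)
  expect_gt(sc["E", "C"], 0)
  expect_gt(sc["N", "O"], 0)
  expect_equal(sc["N", "E"], 0)
  expect_true(isSymmetric(sc))
  expect_true(all(eigen(sc, symmetric = TRUE, only.values = TRUE)$values > 0))
  # realized latent scores carry the planted correlation
  sim <- simulate_responses(truth, 2000)
  cors <- cor(sim$true_scores)
  expect_gt(cors["E", "A"], 0.2)
  expect_gt(cors["N", "O"], 0.2)
})

test_that("generator calls are seed-deterministic", {
  t1 <- build_true_loadings(4, "big2_hier", cross_loading = 0.1, seed = 3)
  t2 <- build_true_loadings(4, "big2_hier", cross_loading = 0.1, seed = 3)
  expect_identical(t1$W_true, t2$W_true)
  s1 <- simulate_responses(t1, 50)
  s2 <- simulate_responses(t2, 50)
  expect_identical(s1$responses$values, s2$responses$values)
  expect_identical(s1$true_scores, s2$true_scores)
})

test_that("invalid generator arguments error", {
  expect_error(build_true_loadings(1, "big5"), "n_items_per_dimension")
  expect_error(build_true_loadings(4, "big3"), "arg")
  expect_error(build_true_loadings(4, "big5", cross_loading = 0.6),
               "cross_loading")
  truth <- build_true_loadings(4, "big5")
  expect_error(simulate_responses(truth, 5), "n_subjects")
  truth$score_cov[1, 2] <- truth$score_cov[2, 1] <- 2  # not PSD
  expect_error(simulate_responses(truth, 50), "positive semi-definite")
})

test_that("responses are Likert 1..5 with missingness at the planted rate", {
  truth <- build_true_loadings(4, "big5", seed = 5, noise_sd = 0.5,
                               missing_rate = 0.1)
  sim <- simulate_responses(truth, 100)
  v <- sim$responses$values
  expect_true(all(is.na(v) | (v >= 1 & v <= 5)))
  expect_true(is.integer(v))
  # 100 x 20 cells at rate 0.1: binomial(2000, 0.1), +-4 sd ~ 54
  n_miss <- sum(is.na(v))
  expect_gt(n_miss, 200 - 54)
  expect_lt(n_miss, 200 + 54)
})

test_that("zero-noise responses are the exact discretization and keying flips", {
  truth <- build_true_loadings(4, "big5", cross_loading = 0, seed = 7,
                               noise_sd = 0, missing_rate = 0,
                               acquiescence_sd = 0)
  sim <- simulate_responses(truth, 200)
  # reconstruct the expected discretization from the returned true scores
  L <- truth$W_true %*% t(sim$true_scores)
  for (i in seq_len(nrow(L))) {
    q <- quantile(L[i, ], c(0.01, 0.99), names = FALSE)
    L[i, ] <- 1 + 4 * (L[i, ] - q[1]) / (q[2] - q[1])
  }
  expected <- round(pmin(pmax(L, 1), 5))
  rev <- truth$keyed_direction == -1L
  expected[rev, ] <- 6 - expected[rev, ]
  storage.mode(expected) <- "integer"
  expect_identical(sim$responses$values, t(expected))
  # reverse-keyed item: stored value is the 6 - x flip of the scored value
  scored <- apply_reverse_scoring(sim$responses)
  ri <- which(rev)[1]
  expect_identical(sim$responses$values[, ri],
                   6L - scored$values[, ri])
})

test_that("latent score covariance converges to the planted one", {
  truth <- build_true_loadings(2, "big2_hier", seed = 11)
  sim <- simulate_responses(truth, 10000)
  emp <- cov(sim$true_scores)
  # censoring at zero shrinks the covariance slightly; 10% Frobenius band
  rel <- norm(emp - truth$score_cov, "F") / norm(truth$score_cov, "F")
  expect_lt(rel, 0.10)
})

test_that("subgroup simulation is exchangeable when unperturbed and flags groups", {
  spec <- tibble::tibble(label = c("a", "b"), n = c(60, 60),
                         perturb_sd = 0, noise_mult = 1)
  truth <- build_true_loadings(4, "big5", seed = 1, noise_sd = 0.5,
                               group_spec = spec)
  sim <- simulate_subgroups(truth)
  expect_equal(nrow(sim$responses$values), 120)
  expect_equal(as.vector(table(sim$responses$subject_meta$group)), c(60, 60))
  # same seed twice -> identical
  sim2 <- simulate_subgroups(truth)
  expect_identical(sim$responses$values, sim2$responses$values)
  # unperturbed groups are statistically exchangeable: mean response close
  ma <- mean(sim$responses$values[sim$responses$subject_meta$group == "a", ])
  mb <- mean(sim$responses$values[sim$responses$subject_meta$group == "b", ])
  expect_lt(abs(ma - mb), 0.15)
  # too-small group errors
  spec_bad <- tibble::tibble(label = "tiny", n = 3, perturb_sd = 0,
                             noise_mult = 1)
  truth_bad <- build_true_loadings(4, "big5", group_spec = spec_bad)
  expect_error(simulate_subgroups(truth_bad), "group size")
})

test_that("a high-noise group has the worst within-group reconstruction", {
  spec <- tibble::tibble(label = c("g1", "g2", "g3"), n = 150,
                         perturb_sd = 0, noise_mult = c(1, 1, 3))
  truth <- build_true_loadings(4, "big5", seed = 2, noise_sd = 0.4,
                               group_spec = spec)
  sim <- simulate_subgroups(truth)
  R <- apply_reverse_scoring(sim$responses)
  X <- impute_missing(R)$X
  g <- sim$responses$subject_meta$group
  res <- vapply(unique(g), function(lab) {
    Xg <- X[, g == lab, drop = FALSE]
    fit <- fit_opnmf(Xg, 5, max_iter = 2000)
    reconstruction_error(fit, Xg)
  }, numeric(1))
  expect_equal(names(which.max(res)), "g3")
})

test_that("phenotype simulation plants the stated signal geometry", {
  set.seed(4)
  S <- matrix(rnorm(400 * 2), 400, 2)
  ph <- simulate_phenotypes(S, theta_true = 90, n_features = 200,
                            signal_fraction = 0.1, noise_sd = 0.5, seed = 4)
  expect_equal(sum(ph$true_weights != 0), 20)
  z1 <- as.numeric(scale(S[, 1])); z2 <- as.numeric(scale(S[, 2]))
  sig <- which(ph$true_weights != 0)
  r2 <- abs(cor(ph$features[, sig], z2))
  r1 <- abs(cor(ph$features[, sig], z1))
  expect_gt(mean(r2), 0.75)       # signal aligned with axis 2 at 90 degrees
  expect_lt(mean(r1), 0.15)       # orthogonal to axis 1
  # noiseless, all-signal: projection is an exact linear function of features
  ph0 <- simulate_phenotypes(S, theta_true = 45, n_features = 5,
                             signal_fraction = 1, noise_sd = 0, seed = 5)
  target <- (cos(pi / 4) * z1 + sin(pi / 4) * z2)
  pred <- ph0$features %*% (ph0$true_weights / sum(ph0$true_weights^2))
  expect_gt(abs(cor(pred, target)), 1 - 1e-10)
  # family blocks
  ph_f <- simulate_phenotypes(S, 45, 10, family_size = 4, seed = 6)
  expect_equal(length(unique(ph_f$family_id)), 100)
  expect_error(simulate_phenotypes(S, 200, 10), "theta_true")
  expect_error(simulate_phenotypes(S, 45, 0), "n_features")
})

test_that("synthetic datasets round-trip through CSV + JSON sidecar", {
  dir <- withr::local_tempdir()
  truth <- build_true_loadings(3, "big5", seed = 9, noise_sd = 0.3,
                               missing_rate = 0.05)
  sim <- simulate_responses(truth, 40)
  files <- write_synthetic(sim, dir)
  expect_true(all(file.exists(files)))
  rm <- load_responses(files["responses"], files["item_key"],
                       files["subject_meta"])
  expect_identical(rm$values, sim$responses$values)
  spec <- jsonlite::read_json(files["spec"], simplifyVector = TRUE)
  expect_equal(spec$seed, 9)
  expect_equal(spec$missing_rate, 0.05)
})
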