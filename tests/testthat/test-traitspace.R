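ortho_scores <- function(n = 200, rho = 0, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * 2), n, 2)
  # exact in-sample orthogonalization + standardization
  Z <- qr.Q(qr(sweep(Z, 2, colMeans(Z))))
  Z <- scale(Z)
  if (rho != 0) Z[, 2] <- rho * Z[, 1] + sqrt(1 - rho^2) * Z[, 2]
  standardize_scores(data.frame(SA = Z[, 1], SM = Z[, 2]))
}

test_that("standardization z-scores both axes and validates input", {
  set.seed(1)
  raw <- data.frame(SA = rnorm(50, 10, 3), SM = rnorm(50, -2, 0.5))
  sc <- standardize_scores(raw)
  expect_lt(max(abs(colMeans(cbind(sc$SA, sc$SM)))), 1e-10)
  expect_equal(c(sd(sc$SA), sd(sc$SM)), c(1, 1), tolerance = 1e-10)
  # affine transforms leave the standardized scores unchanged
  sc2 <- standardize_scores(data.frame(SA = 3 * raw$SA - 7,
                                       SM = 0.1 * raw$SM + 2))
  expect_equal(sc$SA, sc2$SA)
  expect_equal(sc$SM, sc2$SM)
  expect_error(standardize_scores(raw[1:2, ]), "at least 3")
  raw$SA <- 1
  expect_error(standardize_scores(raw), "zero-variance")
})

test_that("directional projections follow the angle conventions exactly", {
  sc <- ortho_scores()
  expect_equal(directional_projection(sc, 90), sc$SM)
  expect_equal(directional_projection(sc, 180), -sc$SA, tolerance = 1e-12)
  # linearity: p(theta) = cos(theta) p(SA axis would be 0, use 180) ...
  th <- 37
  p <- directional_projection(sc, th)
  expect_equal(p, cos(th * pi / 180) * sc$SA + sin(th * pi / 180) * sc$SM)
  # orthogonal angles are empirically uncorrelated on orthogonalized scores
  expect_lt(abs(cor(directional_projection(sc, 30),
                    directional_projection(sc, 120))), 1e-10)
  expect_error(directional_projection(sc, 0), "theta")
  expect_error(directional_projection(sc, 181), "theta")
})

test_that("variance profile matches the closed form 1 + rho sin(2 theta)", {
  for (rho in c(0.5, -0.4)) {
    sc <- ortho_scores(rho = rho, seed = 2)
    prof <- direction_variance_profile(sc, 1:180)
    rho_hat <- cor(sc$SA, sc$SM)
    expected <- sqrt(1 + rho_hat * sin(2 * (1:180) * pi / 180)) *
      sqrt((nrow(sc) - 1) / (nrow(sc) - 1))
    # sample sd uses n-1; projections built from exactly unit-sd axes
    expect_equal(prof$profile$sd, expected, tolerance = 1e-10)
    expect_equal(prof$peak_angle, if (rho > 0) 45 else 135)
  }
  # rho = 0: constant profile
  sc0 <- ortho_scores(rho = 0, seed = 3)
  prof0 <- direction_variance_profile(sc0, c(10, 55, 100, 145))
  expect_lt(diff(range(prof0$profile$sd)), 1e-10)
  expect_error(direction_variance_profile(sc0, numeric(0)), "empty")
})

test_that("signature responses are linear in the z-weights", {
  set.seed(4)
  F <- matrix(rnorm(60 * 5), 60, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  z0 <- setNames(numeric(5), colnames(F))
  expect_equal(signature_response(z0, F), rep(0, 60))
  z1 <- z0; z1["f3"] <- 1
  expect_equal(signature_response(z1, F), as.numeric(scale(F[, 3])),
               tolerance = 1e-12)
  expect_equal(signature_response(2 * z1, F),
               2 * signature_response(z1, F))
  names(z1)[1] <- "oops"
  expect_error(signature_response(z1, F), "do not match")
})

test_that("signature correlations flag degenerate traits and find true links", {
  set.seed(5)
  n <- 500
  trait <- rnorm(n)
  F <- cbind(a = trait + rnorm(n, 0, 0.1), b = rnorm(n))
  z <- c(a = 1, b = 0)
  sig <- signature_response(z, F)
  tab <- correlate_signatures(sig, data.frame(t1 = trait, t2 = rnorm(n),
                                              flat = rep(1, n)))
  expect_gt(tab$r[tab$trait == "t1"], 0.9)
  expect_lt(abs(tab$r[tab$trait == "t2"]), 0.1)
  expect_true(tab$degenerate[tab$trait == "flat"])
  expect_true(is.na(tab$r[tab$trait == "flat"]))
  # signature equal to a trait column gives r = 1
  tab2 <- correlate_signatures(sig, data.frame(self = sig))
  expect_equal(tab2$r, 1)
})

test_that("direction scan recovers a planted direction with valid inference", {
  set.seed(6)
  n <- 250
  S <- matrix(rnorm(n * 2), n, 2)
  ph <- simulate_phenotypes(S, theta_true = 91, n_features = 30,
                            signal_fraction = 0.4, noise_sd = 0.5,
                            family_size = 2, seed = 6)
  sc <- standardize_scores(data.frame(SA = S[, 1], SM = S[, 2],
                                      family_id = ph$family_id))
  scan <- direction_scan(ph, sc, n_reps = 1, n_folds = 5, n_perm = 99,
                         seed = 7, K_grid = c(1, 2, 3),
                         eta_grid = c(0.25, 0.5, 1))
  expect_equal(nrow(scan$table), 180)
  expect_lte(abs(scan$peak_angle - 91), 10)
  expect_true(scan$table$fdr_significant[scan$table$angle == scan$peak_angle])
  # p-values bounded below by 1 / (n_perm + 1)
  expect_gte(min(scan$table$p_value), 1 / 100)
  # perfect features: the projection itself at 90 degrees predicts itself
  F_perfect <- cbind(directional_projection(sc, 90),
                     matrix(rnorm(n * 4), n, 4))
  scan90 <- direction_scan(F_perfect, sc, angles = c(45, 90, 135),
                           n_reps = 1, n_folds = 5, n_perm = 19, seed = 8,
                           K_grid = 1, eta_grid = c(0.2, 1))
  expect_gt(scan90$table$accuracy[scan90$table$angle == 90], 0.99)
  expect_error(direction_scan(ph, sc, n_perm = 0), "n_perm")
  expect_error(direction_scan(ph, sc, angles = c(0, 90), n_perm = 10),
               "angles")
})

test_that("target comparison runs the shared protocol and compares weights", {
  set.seed(9)
  n <- 200
  lat1 <- rnorm(n); lat2 <- rnorm(n)
  # disjoint true features with random signs, plus pure-noise features
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  F <- cbind(outer(lat1, sgn(8)) + matrix(rnorm(n * 8, 0, 0.4), n, 8),
             outer(lat2, sgn(8)) + matrix(rnorm(n * 8, 0, 0.4), n, 8),
             matrix(rnorm(n * 24), n, 24))
  colnames(F) <- paste0("f", 1:40)
  targets <- list(t_one = lat1, t_two = lat2, t_one_copy = lat1)
  cmp <- compare_targets(F, targets, n_reps = 2, n_folds = 4, seed = 10,
                         K_grid = c(1, 2), eta_grid = c(0.25, 1))
  expect_equal(nrow(cmp$accuracies), 3 * 2 * 4)
  expect_equal(dim(cmp$weight_similarity), c(3, 3))
  # identical targets -> weight similarity ~ 1; disjoint latents -> near 0
  expect_gt(cmp$weight_similarity["t_one", "t_one_copy"], 0.98)
  expect_lt(abs(cmp$weight_similarity["t_one", "t_two"]), 0.3)
  expect_gt(cmp$summary$mean_accuracy[cmp$summary$target == "t_one"], 0.7)
  expect_error(compare_targets(F, list(a = lat1, a = lat2)), "duplicate")
  expect_error(compare_targets(F, list(lat1)), "named")
})
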