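# Shared fixtures and independent oracles, all built in code.

# planted dimension partition of a synthetic truth (N/E/O/A/C labels -> int)
planted_partition <- function(truth) {
  setNames(as.integer(factor(truth$dimension_of_item)), truth$item_id)
}

# small reverse-scored planted dataset, imputed
planted_data <- function(n_items = 4, n_subjects = 300, noise_sd = 0,
                         structure = "big5", seed = 1, ...) {
  truth <- build_true_loadings(n_items, structure, seed = seed,
                               noise_sd = noise_sd, ...)
  sim <- simulate_responses(truth, n_subjects)
  X <- impute_missing(apply_reverse_scoring(sim$responses))
  list(truth = truth, sim = sim, X = X)
}

# -- independent oracles ------------------------------------------------------

# adjusted Rand by explicit enumeration of item pairs
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  npairs <- n * (n - 1) / 2
  expected <- (n11 + n10) * (n11 + n01) / npairs
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (abs(maxi - expected) < 1e-15) return(1)
  (n11 - expected) / (maxi - expected)
}

# variation of information from explicitly enumerated cluster probabilities
vi_entropy_oracle <- function(a, b) {
  n <- length(a)
  H <- function(labels) {
    p <- table(labels) / n
    -sum(p * log(p))
  }
  joint <- table(a, b) / n
  joint <- joint[joint > 0]
  Hab <- -sum(joint * log(joint))
  2 * Hab - H(a) - H(b)
}

# Lin's CCC, straight-line recomputation
ccc_oracle <- function(x, y) {
  n <- length(x)
  sx <- mean((x - mean(x))^2); sy <- mean((y - mean(y))^2)
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  2 * sxy / (sx + sy + (mean(x) - mean(y))^2)
}

# cosine-similarity upper triangle of a non-negative basis
cosine_ut <- function(W) {
  nrm <- sqrt(rowSums(W^2)); nrm[nrm == 0] <- 1
  C <- tcrossprod(W / nrm)
  C[upper.tri(C)]
}

# textbook NIPALS PLS1 with explicit X deflation (independent of the
# package's Krylov solver)
nipals_pls1 <- function(X, y, K) {
  E <- X; f <- y; W <- NULL; P <- NULL; Q <- NULL
  for (k in seq_len(K)) {
    w <- crossprod(E, f); w <- w / sqrt(sum(w^2))
    t <- E %*% w
    pk <- crossprod(E, t) / sum(t^2)
    q <- sum(f * t) / sum(t^2)
    E <- E - t %*% t(pk)
    f <- f - q * t
    W <- cbind(W, w); P <- cbind(P, pk); Q <- c(Q, q)
  }
  as.numeric(W %*% solve(t(P) %*% W, Q))
}
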