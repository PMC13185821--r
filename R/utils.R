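# Internal helpers shared across modules.

# Deterministic substream seeds: every stochastic stage derives its own seed
# from the master seed plus a stage/repetition index, so any single
# repetition can be re-run in isolation. Arithmetic stays below 2^53 so the
# double-precision modulo is exact, and the result fits in a 32-bit integer.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

# k-fold assignment of n units, shuffled; returns integer vector of fold ids.
fold_assignment <- function(n, n_folds, seed) {
  set.seed(seed)
  folds <- rep_len(seq_len(n_folds), n)
  sample(folds, n)
}

# Grouped k-fold: every unit of a group lands in the same fold. Groups are
# visited in random order and greedily assigned to the currently smallest
# fold, which balances fold sizes even for unequal groups.
grouped_fold_assignment <- function(group_id, n_folds, seed) {
  groups <- unique(group_id)
  if (length(groups) < n_folds) {
    stop_arg("need at least as many groups (", length(groups),
             ") as folds (", n_folds, ") for grouped fold assignment")
  }
  set.seed(seed)
  ord <- sample(groups)
  sizes <- table(group_id)[as.character(ord)]
  fold_of_group <- integer(length(ord))
  names(fold_of_group) <- as.character(ord)
  load <- numeric(n_folds)
  for (i in order(-as.numeric(sizes))) {
    f <- which.min(load)
    fold_of_group[i] <- f
    load[f] <- load[f] + sizes[i]
  }
  unname(fold_of_group[as.character(group_id)])
}

# Column-standardize a matrix; constant columns become all-zero (flagged).
standardize_columns <- function(F, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(F)
  if (is.null(scale)) {
    scale <- apply(F, 2, sd)
  }
  constant <- scale < 1e-12 | !is.finite(scale)
  scale[constant] <- 1
  Fs <- sweep(sweep(F, 2, center, "-"), 2, scale, "/")
  Fs[, constant] <- 0
  list(F = Fs, center = center, scale = scale, constant = constant)
}

as_items_by_subjects <- function(X) {
  if (inherits(X, "trait_data")) X$X else as.matrix(X)
}
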