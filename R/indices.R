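#' Adjusted Rand index between two item partitions
#'
#' Hubert-Arabie chance-corrected agreement between two hard item-to-factor
#' assignments: 1 iff the partitions are identical up to label permutation,
#' 0 expected under independent random assignments.
#'
#' @param p1,p2 `item_partition` tibbles (from [assign_items()]) or bare
#'   label vectors over the same items.
#' @return A scalar `<= 1`.
#' @export
adjusted_rand_index <- function(p1, p2) {
  al <- align_partitions(p1, p2)
  tab <- table(al$a, al$b)
  n <- length(al$a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < 1e-15) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Variation of information between two item partitions (nats)
#'
#' The information-theoretic distance `VI = H(p1) + H(p2) - 2 I(p1; p2)`
#' (natural logarithms): 0 iff the partitions are identical, and a metric on
#' the space of partitions.
#'
#' @inheritParams adjusted_rand_index
#' @return A non-negative scalar in nats.
#' @export
variation_of_information <- function(p1, p2) {
  al <- align_partitions(p1, p2)
  n <- length(al$a)
  tab <- table(al$a, al$b) / n
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  h1 <- ent(rowSums(tab))
  h2 <- ent(colSums(tab))
  hj <- ent(as.numeric(tab))
  mi <- h1 + h2 - hj
  max(h1 + h2 - 2 * mi, 0)
}

cosine_similarity_matrix <- function(W, signed = FALSE) {
  A <- if (signed) W else abs(W)
  nrm <- sqrt(rowSums(A^2))
  nrm[nrm < 1e-16] <- 1
  tcrossprod(A / nrm)
}

# Lin's concordance correlation coefficient (population moments).
lin_ccc <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom < 1e-300) return(1)
  2 * cxy / denom
}

#' Concordance index between two loading matrices
#'
#' Agreement between the item-item cosine-similarity matrices implied by two
#' bases: Lin's concordance correlation coefficient between the vectorized
#' upper triangles (diagonal excluded). Invariant to column order, so bases
#' of different ranks are comparable. For signed loading matrices (PCA/EFA)
#' cosines are computed on absolute loadings so polarity is not conflated
#' with structure; OPNMF bases are non-negative and unaffected.
#'
#' @param W1,W2 Loading matrices (or fitted models) over the same items;
#'   ranks may differ.
#' @param method `"ccc"` (Lin's concordance, default) or `"pearson"`.
#' @return A scalar in `[-1, 1]`.
#' @export
concordance_index <- function(W1, W2, method = c("ccc", "pearson")) {
  method <- match.arg(method)
  W1 <- model_basis(W1)
  W2 <- model_basis(W2)
  if (nrow(W1) != nrow(W2)) {
    stop_arg("bases have different item counts: ", nrow(W1), " vs ", nrow(W2))
  }
  C1 <- cosine_similarity_matrix(W1)
  C2 <- cosine_similarity_matrix(W2)
  ut <- upper.tri(C1)
  x <- C1[ut]; y <- C2[ut]
  if (method == "ccc") lin_ccc(x, y) else cor(x, y)
}

#' Increased reconstruction error of a transferred basis
#'
#' Out-of-sample generalizability penalty: the normalized reconstruction
#' error of a basis learned in one sample on held-out data, minus the error
#' of the basis fitted on that held-out data itself;
#' `iRE = RE(W_train, X_test) - RE(W_test, X_test)`.
#'
#' @param W_train Basis (or fit) learned on the training sample.
#' @param W_test Basis (or fit) learned on the held-out sample.
#' @param X_test Held-out items x subjects matrix.
#' @return A scalar (near zero when the training basis transfers well).
#' @export
increased_reconstruction_error <- function(W_train, W_test, X_test) {
  reconstruction_error(W_train, X_test, normalized = TRUE) -
    reconstruction_error(W_test, X_test, normalized = TRUE)
}

#' Item variability across resampled partitions
#'
#' Instability of each item's factor affiliation over a set of partitions.
#' For item i and each unordered pair of partitions (A, B), the Jaccard
#' overlap `J = |S_A(i) n S_B(i)| / |S_A(i) u S_B(i)|` between the item sets
#' of i's factor is computed; `IV_i = 1 - mean(J)` over all pairs. 0 means
#' the item always travels with the same companions, values near 1 mean its
#' factor membership is essentially unstable.
#'
#' @param partitions List of two or more partitions over the same items.
#' @return A tibble `item_id`, `iv` with entries in `[0, 1]`.
#' @export
item_variability <- function(partitions) {
  if (length(partitions) < 2) {
    stop_arg("item_variability needs at least 2 partitions")
  }
  labs <- lapply(partitions, partition_labels)
  n <- length(labs[[1]])
  ids <- names(labs[[1]]) %||% as.character(seq_len(n))
  labs <- lapply(labs, function(l) {
    if (length(l) != n) stop_arg("partitions cover different item sets")
    if (!is.null(names(l))) l[ids] else l
  })
  npart <- length(labs)
  jac_sum <- numeric(n)
  n_pairs <- 0L
  for (a in seq_len(npart - 1)) {
    for (b in (a + 1):npart) {
      la <- labs[[a]]; lb <- labs[[b]]
      # size of intersection/union of the two factor item-sets per item
      tab <- table(la, lb)
      size_a <- rowSums(tab)[as.character(la)]
      size_b <- colSums(tab)[as.character(lb)]
      inter <- tab[cbind(as.character(la), as.character(lb))]
      jac_sum <- jac_sum + inter / (size_a + size_b - inter)
      n_pairs <- n_pairs + 1L
    }
  }
  tibble::tibble(item_id = ids, iv = unname(1 - jac_sum / n_pairs))
}
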