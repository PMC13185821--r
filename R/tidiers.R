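#' @importFrom generics tidy glance
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns one row per estimated quantity,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name traitfactor-tidiers
NULL

#' @rdname traitfactor-tidiers
#' @export
tidy.opnmf_fit <- function(x, ...) {
  tibble::as_tibble(x$W, rownames = "item_id") |>
    tidyr::pivot_longer(-"item_id", names_to = "factor",
                        values_to = "loading")
}

#' @rdname traitfactor-tidiers
#' @export
glance.opnmf_fit <- function(x, ...) {
  tibble::tibble(
    rank = x$rank, n_items = nrow(x$W), n_iter = x$n_iter,
    converged = x$converged,
    final_objective = utils::tail(x$objective_trace, 1),
    max_offdiag_wtw = {
      G <- crossprod(x$W)
      if (x$rank > 1) max(abs(G[upper.tri(G)])) else 0
    }
  )
}

#' @rdname traitfactor-tidiers
#' @export
tidy.rank_selection <- function(x, ...) x$summary

#' @rdname traitfactor-tidiers
#' @export
glance.rank_selection <- function(x, ...) {
  tibble::tibble(
    optimal_ranks = paste(x$optimal_ranks, collapse = ","),
    best_composite = max(x$summary$composite),
    n_records = x$n_records
  )
}

#' @rdname traitfactor-tidiers
#' @export
tidy.tpls <- function(x, ...) {
  tibble::tibble(feature = names(x$beta), beta = unname(x$beta),
                 retained = x$beta != 0)
}

#' @rdname traitfactor-tidiers
#' @export
glance.tpls <- function(x, ...) {
  tibble::tibble(K = x$K, eta = x$eta, n_retained = sum(x$beta != 0),
                 n_features = x$p, n_subjects = x$n,
                 inner_cv_r = x$cv_score)
}

#' @rdname traitfactor-tidiers
#' @export
tidy.direction_scan <- function(x, ...) x$table

#' @rdname traitfactor-tidiers
#' @export
glance.direction_scan <- function(x, ...) {
  tibble::tibble(
    peak_angle = x$peak_angle, peak_accuracy = x$peak_accuracy,
    n_significant = sum(x$table$fdr_significant),
    n_angles = nrow(x$table),
    n_perm = x$params$n_perm
  )
}

#' @rdname traitfactor-tidiers
#' @export
tidy.direction_profile <- function(x, ...) x$profile

#' Plot methods
#'
#' `autoplot()` renders the standard diagnostic figure of each result type
#' with ggplot2: loading heatmaps for factorizations, composite-vs-rank
#' curves with bootstrap bands for rank selection, and accuracy-vs-angle
#' profiles with FDR marks for direction scans.
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot.
#' @name traitfactor-plots
NULL

#' @rdname traitfactor-plots
#' @importFrom ggplot2 autoplot
#' @export
autoplot.opnmf_fit <- function(object, ...) {
  df <- tidy.opnmf_fit(object)
  df$item_id <- factor(df$item_id, levels = rev(rownames(object$W)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$item_id,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading",
                  title = paste0("OPNMF basis (rank ", object$rank, ")")) +
    ggplot2::theme_minimal()
}

#' @rdname traitfactor-plots
#' @export
autoplot.rank_selection <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$rank, y = .data$composite)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$composite_lo,
                                      ymax = .data$composite_hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = s$rank) +
    ggplot2::labs(x = "number of factors", y = "normalized composite",
                  title = "Cross-validated rank selection") +
    ggplot2::theme_minimal()
}

#' @rdname traitfactor-plots
#' @export
autoplot.direction_scan <- function(object, ...) {
  t <- object$table
  ggplot2::ggplot(t, ggplot2::aes(x = .data$angle, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = t[t$fdr_significant, ],
                        color = "grey40", size = 1) +
    ggplot2::geom_vline(xintercept = object$peak_angle, linetype = 2) +
    ggplot2::labs(x = "direction (degrees)",
                  y = "predictive accuracy (r)",
                  title = paste0("Direction scan (peak ", object$peak_angle,
                                 "°)")) +
    ggplot2::theme_minimal()
}

#' @rdname traitfactor-plots
#' @export
autoplot.direction_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$angle,
                                               y = .data$sd)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak_angle, linetype = 2) +
    ggplot2::labs(x = "direction (degrees)", y = "projection SD",
                  title = "Directional variance profile") +
    ggplot2::theme_minimal()
}
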