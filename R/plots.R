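#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_hline
#'   geom_abline labs theme_minimal facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot the raised-cosine history basis
#'
#' @param object A [raised_cosine_basis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.history_basis <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$lag_ms, y = .data$value,
                group = .data$basis, colour = factor(.data$basis))) +
    geom_line(show.legend = FALSE) +
    labs(x = "lag (ms)", y = "basis value",
         title = "Raised-cosine spike-history basis (log-spaced peaks)") +
    theme_minimal()
}

#' ROC curve with its convex hull
#'
#' @inheritParams roc_hull_pp
#' @param max_points Thin the raw ROC to at most this many points.
#' @return A ggplot of the ROC operating points and the hull whose area
#'   defines predictive power.
#' @export
plot_roc <- function(prob, y, max_points = 2000) {
  d <- roc_hull_curve(prob, y)
  roc <- d[d$part == "roc", ]
  if (nrow(roc) > max_points) {
    roc <- roc[unique(round(seq(1, nrow(roc), length.out = max_points))), ]
  }
  hull <- d[d$part == "hull", ]
  pp <- roc_hull_pp(prob, y)
  ggplot(roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line(colour = "grey50") +
    geom_line(data = hull, colour = "firebrick") +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey70") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC convex hull, PP = %.3f", pp)) +
    theme_minimal()
}

#' Per-fold predictive power of a cross-validated model
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot of per-fold PP with the pooled value overlaid.
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = factor(.data$fold), y = .data$pp)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = object$pp_pooled, linetype = 2) +
    labs(x = "outer fold", y = "predictive power",
         title = sprintf("'%s': pooled PP = %.3f",
                         object$feature_set, object$pp_pooled)) +
    theme_minimal()
}

#' Unit-by-unit scatter of two feature sets' predictive power
#'
#' The standard nested-model redundancy display: each point is one unit;
#' points on the identity line mean the extended feature set adds nothing.
#'
#' @param pp_tbl Tibble with `unit`, `feature_set`, `pp`.
#' @param base,extended Feature-set names for the x and y axes.
#' @return A ggplot.
#' @export
plot_pp_scatter <- function(pp_tbl, base, extended) {
  b <- pp_tbl[pp_tbl$feature_set == base, c("unit", "pp")]
  e <- pp_tbl[pp_tbl$feature_set == extended, c("unit", "pp")]
  m <- dplyr::inner_join(b, e, by = "unit", suffix = c("_base", "_ext"))
  lim <- range(c(m$pp_base, m$pp_ext, 0))
  ggplot(m, aes(x = .data$pp_base, y = .data$pp_ext)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    labs(x = sprintf("PP (%s)", base), y = sprintf("PP (%s)", extended)) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
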