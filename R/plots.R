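#' Plot a component as mean ± 1 SD effect curves
#'
#' The standard visualization of a functional principal component: the mean
#' daily activity curve, and the mean plus/minus one SD of the component
#' score times the eigenfunction.
#'
#' @param model An `fpca_model`.
#' @param k Component index.
#' @return A ggplot object (x in hours from midnight).
#' @export
plot_component <- function(model, k) {
  cur <- component_effect_curves(model, k)
  h <- model$basis$grid / 60
  df <- data.frame(
    hour = rep(h, 3),
    activity = c(cur$mean, cur$plus, cur$minus),
    curve = rep(factor(c("mean", "+1 SD", "-1 SD"),
                       levels = c("mean", "+1 SD", "-1 SD")), each = length(h)))
  ggplot2::ggplot(df, ggplot2::aes(x = hour, y = activity,
                                   colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c("black", "red3", "blue3")) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4)) +
    ggplot2::labs(x = "Hour of day", y = "Activity",
                  colour = NULL,
                  title = sprintf("Component %d (%.1f%% of variance)", k,
                                  100 * model$variance_proportions[k])) +
    ggplot2::theme_minimal()
}

#' Plot FoSR coefficient functions with pointwise bands
#'
#' @param fit A `fosr_fit`.
#' @param terms Terms to plot (default all non-intercept).
#' @param level Band level (default 0.95).
#' @return A ggplot object faceted by term.
#' @export
plot_fosr <- function(fit, terms = NULL, level = 0.95) {
  bands <- pointwise_bands(fit, level)
  if (is.null(terms)) terms <- setdiff(fit$terms, "(Intercept)")
  bands <- bands[bands$term %in% terms, ]
  bands$hour <- bands$t / 60
  ggplot2::ggplot(bands, ggplot2::aes(x = hour, y = beta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Hour of day", y = expression(beta(t))) +
    ggplot2::theme_minimal()
}

#' Plot mean diurnal curves stratified by a subject-level variable
#'
#' @param subject_curves A `subject_curves` object.
#' @param groups Vector (length = number of curves) defining the strata,
#'   e.g. an age tertile or modal season.
#' @param label Legend title.
#' @return A ggplot object.
#' @export
plot_mean_curves_by <- function(subject_curves, groups, label = "group") {
  stopifnot(inherits(subject_curves, "subject_curves"))
  g <- factor(groups)
  df <- do.call(rbind, lapply(levels(g), function(lev) {
    rows <- which(g == lev)
    data.frame(hour = subject_curves$grid / 60,
               activity = colMeans(subject_curves$values[rows, ,
                                                         drop = FALSE]),
               stratum = lev, stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = hour, y = activity,
                                   colour = stratum)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Hour of day", y = "Activity", colour = label) +
    ggplot2::theme_minimal()
}
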