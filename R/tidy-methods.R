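# broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' Tidy a coupling fit
#'
#' @param x A `"coupling_fit"`.
#' @param ... Unused.
#' @return One row per fixed-effect term: `term`, `estimate`, `std.error`,
#'   `statistic` (F), `num.df`, `den.df`, `p.value`.
#' @export
tidy.coupling_fit <- function(x, ...) {
  tibble(term = x$term,
         estimate = x$estimate,
         std.error = x$std_error,
         statistic = rep(x$F_statistic, length(x$term)),
         num.df = rep(x$num_df, length(x$term)),
         den.df = rep(x$den_df, length(x$term)),
         p.value = rep(x$p_value, length(x$term)))
}

#' Glance at a coupling fit
#'
#' @param x A `"coupling_fit"`.
#' @param ... Unused.
#' @return One-row tibble with sample sizes, variance components (bird,
#'   sequence-within-bird, residual) and the boundary (singular-fit) flag.
#' @export
glance.coupling_fit <- function(x, ...) {
  vc <- setNames(x$varcomp$variance, x$varcomp$component)
  tibble(n = x$n, n_birds = x$n_birds,
         var_bird = unname(vc["bird"]),
         var_sequence = unname(vc["sequence_in_bird"]),
         var_residual = unname(vc["residual"]),
         boundary = x$boundary,
         REMLcrit = as.numeric(lme4::REMLcrit(x$fit)))
}

#' Augment coupling-fit data with fitted values and residuals
#'
#' @param x A `"coupling_fit"`.
#' @param ... Unused.
#' @return The model rows with `.fitted` and `.resid` columns (conditional
#'   on the estimated random effects).
#' @export
augment.coupling_fit <- function(x, ...) {
  out <- as_tibble(x$rows)
  out$.fitted <- unname(fitted(x$fit))
  out$.resid <- x$residuals
  out
}

#' @export
tidy.change_coupling <- function(x, ...) {
  bind_rows(
    mutate(tidy(x$dlog10_fit), response = "dlog10_gap", .before = 1),
    mutate(tidy(x$pct_fit), response = "pct_gap_change", .before = 1))
}

#' @export
tidy.category_contrast <- function(x, ...) {
  out <- x$tukey
  names(out)[names(out) == "p.value"] <- "adj.p.value"
  out
}

#' @export
glance.category_contrast <- function(x, ...) {
  f <- x$fit
  tibble(statistic = f$F_statistic, num.df = f$num_df, den.df = f$den_df,
         p.value = f$p_value, n = f$n, boundary = f$boundary)
}

#' Plot a coupling fit
#'
#' Scatter of the response against the predictor with the fixed-effect
#' (population-level) regression line.
#'
#' @param object A `"coupling_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coupling_fit <- function(object, ...) {
  d <- as_tibble(object$rows)
  xvar <- object$predictor
  yvar <- object$response
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]]))
  if (is.numeric(d[[xvar]])) {
    icpt <- unname(lme4::fixef(object$fit)["(Intercept)"])
    p <- p +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_abline(intercept = icpt, slope = object$estimate[1],
                           colour = "firebrick", linewidth = 0.8)
  } else {
    p <- p + ggplot2::geom_boxplot()
  }
  p + ggplot2::labs(
    title = sprintf("%s ~ %s: estimate %.3f +/- %.3f (p = %.3g)",
                    yvar, xvar, object$estimate[1], object$std_error[1],
                    object$p_value),
    x = xvar, y = yvar) +
    ggplot2::theme_minimal()
}

#' Plot a paired-condition change analysis
#'
#' Change in log10 gap duration against change in transition probability,
#' with the fitted fixed-effect line; the age-like (coupled) pattern shows a
#' negative slope, the context-like (decoupled) pattern a flat line.
#'
#' @param object A `"change_coupling"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.change_coupling <- function(object, ...) {
  autoplot(object$dlog10_fit) +
    ggplot2::labs(x = "change in transition probability (p_B - p_A)",
                  y = "change in log10 gap duration")
}

#' Plot percent gap change by change category
#'
#' @param records A `"change_records"` table (with `category`).
#' @return A ggplot object.
#' @export
plot_category_changes <- function(records) {
  d <- as_tibble(records)
  d$category <- factor(d$category, levels = c("increased", "unchanged",
                                              "stereotyped", "decreased"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$pct_gap_change)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = "transition-probability change category",
                  y = "percent change in median gap duration") +
    ggplot2::theme_minimal()
}
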