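#' Plot the four-model support profile of a BETS result
#'
#' Log marginal likelihoods of the four clock/dating combinations, relative
#' to the best model (0 = best supported).
#'
#' @param object A `bets_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bets_result
#' @export
autoplot.bets_result <- function(object, ...) {
  d <- tidy(object)
  d$delta <- d$log_ml - max(d$log_ml)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$delta,
                                  fill = .data$dating)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "log ML relative to best model",
                  fill = "dating") +
    ggplot2::theme_minimal()
}

#' Trace plots of sampled parameters
#'
#' @param object A `bets_trace` from [run_chain()].
#' @param pars Parameters to show (default all numeric columns except
#'   bookkeeping).
#' @param ... Unused.
#' @return A ggplot object, one facet per parameter.
#' @method autoplot bets_trace
#' @export
autoplot.bets_trace <- function(object, pars = NULL, ...) {
  drop <- c("iteration", "beta")
  pars <- pars %||% setdiff(names(object), drop)
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[c("iteration", pars)],
                              -"iteration",
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Pairs-style view of prior predictive draws
#'
#' Marginal histograms (diagonal-style, one facet per statistic, log10
#' scale) of the joint prior draws; the long-format data behind the plot is
#' what [sample_prior_predictive()] returns, ready for custom pair plots.
#'
#' @param object A `prior_draws` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prior_draws
#' @export
autoplot.prior_draws <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), dplyr::everything(),
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = NULL, y = "draws") +
    ggplot2::theme_minimal()
}
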