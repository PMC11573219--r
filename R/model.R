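#' Specify one cell of the temporal-signal model grid
#'
#' A `model_spec` fixes everything the sampler needs to target one model: the
#' molecular clock (strict or uncorrelated-lognormal relaxed), the dating
#' mode (heterochronous = tip sampling times used, rate estimated under the
#' CTMC-rate reference prior; isochronous = all tips at the present, rate
#' fixed to `fixed_rate`), the coalescent tree prior and the hyperprior on
#' its population-size parameter, an optional hard `Uniform(0, B)` bound on
#' the root height, and the substitution model. The four-model comparison of
#' a temporal-signal test varies only clock and dating mode while holding
#' everything else constant.
#'
#' @param clock `"strict"` or `"ucln"`.
#' @param dating `"heterochronous"` or `"isochronous"`.
#' @param tree_prior `"constant"` (constant-size coalescent) or `"growth"`
#'   (exponential-growth coalescent, with a `Laplace(0, 1)` prior on the
#'   growth rate).
#' @param theta_prior Hyperprior on `theta`/`Phi`: `"exponential"`,
#'   `"lognormal"` or `"gamma"` (see [hyperprior_log_density()]).
#' @param root_bound Upper bound for a `Uniform(0, B)` root-height prior, or
#'   `NULL` for none.
#' @param fixed_rate Clock rate fixed in isochronous mode (> 0,
#'   substitutions/site/time). Ignored for heterochronous analyses.
#' @param subst A [subst_model()].
#' @param lognormal_real_mean See [hyperprior_log_density()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(clock = c("strict", "ucln"),
                       dating = c("heterochronous", "isochronous"),
                       tree_prior = c("constant", "growth"),
                       theta_prior = c("exponential", "lognormal", "gamma"),
                       root_bound = NULL,
                       fixed_rate = NULL,
                       subst = subst_model("JC"),
                       lognormal_real_mean = FALSE) {
  clock <- match.arg(clock)
  dating <- match.arg(dating)
  tree_prior <- match.arg(tree_prior)
  theta_prior <- match.arg(theta_prior)
  if (dating == "isochronous") {
    if (is.null(fixed_rate) || !is.finite(fixed_rate) || fixed_rate <= 0) {
      stop_betsig("isochronous mode requires a finite fixed clock rate > 0",
                  "betsig_config_error")
    }
  }
  if (!is.null(root_bound) && root_bound <= 0) {
    stop_betsig("root bound must be positive", "betsig_config_error")
  }
  structure(
    list(clock = clock, dating = dating, tree_prior = tree_prior,
         theta_prior = theta_prior, root_bound = root_bound,
         fixed_rate = fixed_rate, subst = subst,
         lognormal_real_mean = lognormal_real_mean),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> %s clock | %s | %s coalescent | %s theta prior | root bound %s\n",
    x$clock, x$dating, x$tree_prior, x$theta_prior,
    if (is.null(x$root_bound)) "none" else format(x$root_bound)
  ))
  invisible(x)
}
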