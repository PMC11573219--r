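#' Log density of the serial (heterochronous) constant-size coalescent
#'
#' The probability density of a dated tree under the coalescent with constant
#' effective population size `theta`: going backward in time, with `k` active
#' lineages the coalescent rate is `k(k-1)/(2 theta)`. Each of the `n - 1`
#' coalescent events contributes `-log(theta)` and every inter-event interval
#' contributes `-k(k-1)/2 * dt / theta`. Tips activate at their sampling
#' ages.
#'
#' @param tree A [timetree()].
#' @param theta Effective population size (> 0), proportional to time units.
#' @return Log density (scalar).
#' @export
coalescent_log_density <- function(tree, theta) {
  if (theta <= 0) stop_betsig("theta must be positive", "betsig_domain_error")
  ev <- coalescent_intervals(tree)
  -(n_tips(tree) - 1L) * log(theta) - sum(ev$kchoose2 * ev$dt) / theta
}

#' Log density of the exponential-growth coalescent
#'
#' As [coalescent_log_density()], but with population size trajectory
#' `N(t) = Phi * exp(-g * t)` at age `t` before the present: `Phi` is the
#' scaled population size at present and `g` the (forward-time) exponential
#' growth rate. Each coalescent event at age `t` contributes `-log N(t)` and
#' intervals contribute `-k(k-1)/2 * integral dt / N(t)`, in closed form.
#' `g = 0` recovers the constant-size density exactly; `g < 0` is permitted
#' (the density of any fixed tree is finite even though the growth-reversed
#' process is not guaranteed to coalesce).
#'
#' @param tree A [timetree()].
#' @param phi Scaled population size (> 0).
#' @param growth Exponential growth rate (per unit time, any sign).
#' @return Log density (scalar).
#' @export
exp_growth_log_density <- function(tree, phi, growth) {
  if (phi <= 0) stop_betsig("phi must be positive", "betsig_domain_error")
  if (growth == 0) return(coalescent_log_density(tree, phi))
  ev <- coalescent_intervals(tree)
  # events: -log N(t) = -log(phi) + g * t at each coalescent age
  ntip <- n_tips(tree)
  coal_ages <- tree$ages[(ntip + 1L):(2L * ntip - 1L)]
  event_term <- -(ntip - 1L) * log(phi) + growth * sum(coal_ages)
  # intervals: integral of exp(g t)/phi over [t0, t1]
  integral <- (exp(growth * ev$t1) - exp(growth * ev$t0)) / (growth * phi)
  event_term - sum(ev$kchoose2 * integral)
}

# inter-event intervals of a serial tree: for each interval [t0, t1] between
# consecutive event ages, the active lineage count k, k(k-1)/2 and duration
coalescent_intervals <- function(tree) {
  interval_stats(tree$ages, n_tips(tree))
}

interval_stats <- function(ages, ntip) {
  # +1 lineage at each tip age, -1 at each coalescent age
  times <- c(ages[seq_len(ntip)], ages[(ntip + 1L):(2L * ntip - 1L)])
  step <- c(rep(1L, ntip), rep(-1L, ntip - 1L))
  o <- order(times, -step)  # at ties, coalescences after activations
  times <- times[o]
  k <- cumsum(step[o])
  m <- length(times)
  t0 <- times[-m]
  t1 <- times[-1L]
  kk <- k[-m]
  keep <- t1 > t0
  list(
    t0 = t0[keep], t1 = t1[keep], dt = (t1 - t0)[keep],
    k = kk[keep], kchoose2 = (kk * (kk - 1) / 2)[keep]
  )
}

# fast paths used by the sampler (raw age vectors, no tree object)
coal_logdens_ages <- function(ages, ntip, theta) {
  ev <- interval_stats(ages, ntip)
  -(ntip - 1L) * log(theta) - sum(ev$kchoose2 * ev$dt) / theta
}

growth_logdens_ages <- function(ages, ntip, phi, growth) {
  if (growth == 0) return(coal_logdens_ages(ages, ntip, phi))
  ev <- interval_stats(ages, ntip)
  coal_ages <- ages[(ntip + 1L):(2L * ntip - 1L)]
  integral <- (exp(growth * ev$t1) - exp(growth * ev$t0)) / (growth * phi)
  -(ntip - 1L) * log(phi) + growth * sum(coal_ages) - sum(ev$kchoose2 * integral)
}

#' CTMC-rate reference prior on the clock rate
#'
#' The conditional reference prior for the molecular clock rate given the
#' tree: given `T`, the rate follows `Gamma(shape = 0.5, rate = L)` with `L`
#' the tree length, so
#' the prior mean is `0.5 / L`. Because `L` changes with the tree, this term
#' is re-evaluated whenever the tree moves.
#'
#' @param rate Clock rate (> 0), substitutions/site/time.
#' @param tree_length Sum of branch durations (> 0), time units.
#' @return Log density (scalar).
#' @export
ctmc_reference_log_density <- function(rate, tree_length) {
  if (rate <= 0 || tree_length <= 0) {
    stop_betsig("rate and tree length must be positive", "betsig_domain_error")
  }
  0.5 * log(tree_length) - lgamma(0.5) - 0.5 * log(rate) - tree_length * rate
}

#' Hyperprior densities for the population-size parameter
#'
#' The three proper priors considered for the effective population size
#' `theta` (or scaled size `Phi`): `Exponential(mean 1)`,
#' `LogNormal(mu = 1, sigma = 5)` (log-space location and scale; set
#' `lognormal_real_mean = TRUE` to read `mu` as the real-space mean instead)
#' and `Gamma(shape = 0.001, scale = 1000)`. All integrate to 1, a
#' requirement for marginal-likelihood comparison; the improper `1/x` prior
#' is deliberately not offered.
#'
#' @param value Parameter value (> 0).
#' @param which One of `"exponential"`, `"lognormal"`, `"gamma"`.
#' @param lognormal_real_mean If `TRUE`, parameterise the lognormal by its
#'   real-space mean 1.0 rather than log-space location 1.0.
#' @return Log density (scalar).
#' @export
hyperprior_log_density <- function(value,
                                   which = c("exponential", "lognormal", "gamma"),
                                   lognormal_real_mean = FALSE) {
  which <- match.arg(which)
  if (any(value <= 0)) stop_betsig("value must be positive", "betsig_domain_error")
  switch(which,
    exponential = dexp(value, rate = 1, log = TRUE),
    lognormal = {
      mu <- if (lognormal_real_mean) log(1.0) - 25 / 2 else 1.0
      dlnorm(value, meanlog = mu, sdlog = 5, log = TRUE)
    },
    gamma = dgamma(value, shape = 0.001, scale = 1000, log = TRUE)
  )
}

# draws from the same hyperpriors (used by prior-predictive simulation and
# prior-only checks)
hyperprior_draw <- function(n, which, lognormal_real_mean = FALSE) {
  switch(which,
    exponential = rexp(n, rate = 1),
    lognormal = {
      mu <- if (lognormal_real_mean) log(1.0) - 25 / 2 else 1.0
      rlnorm(n, meanlog = mu, sdlog = 5)
    },
    gamma = rgamma(n, shape = 0.001, scale = 1000)
  )
}

#' Uniform hard-bound prior on the root height
#'
#' A `Uniform(0, bound)` prior on the age of the root: contributes
#' `-log(bound)` inside the support and `-Inf` (state rejected) beyond it.
#' With `bound = NULL` (no bound) the contribution is 0.
#'
#' @param root_height Root age (time units).
#' @param bound Upper bound B (> 0), or `NULL` for no bound.
#' @return Log density contribution (scalar, possibly `-Inf`).
#' @export
root_bound_log_density <- function(root_height, bound) {
  if (is.null(bound)) return(0)
  if (bound <= 0) stop_betsig("root bound must be positive", "betsig_argument_error")
  if (root_height >= 0 && root_height <= bound) -log(bound) else -Inf
}

#' Joint log prior of a model state
#'
#' Sums every prior term active under a model specification: the coalescent
#' tree prior (constant-size or exponential-growth), the hyperprior on
#' `theta`/`Phi`, the `Laplace(0, 1)` prior on the growth rate (growth model
#' only), the CTMC-rate reference prior on the clock rate (strict clock) or
#' on the relaxed-clock mean plus an `Exponential(mean 0.33)` prior on the
#' relaxed-clock log-space standard deviation and i.i.d. lognormal branch
#' rates, and the root-height bound. Isochronous analyses fix the clock rate,
#' so no rate prior enters.
#'
#' @param state A model state as used by the sampler: a list with elements
#'   `tree`, `theta`, optionally `growth`, and clock parameters (`rate` for
#'   the strict clock; `ucln_mean`, `ucln_sd`, `branch_rates` for the relaxed
#'   clock).
#' @param spec A [model_spec()].
#' @param parent Optional precomputed parent-pointer vector (as produced by
#'   the internal topology tables); supplied by the sampler to avoid
#'   recomputation.
#' @return Log prior density (scalar, `-Inf` if a hard bound is violated).
#' @export
joint_log_prior <- function(state, spec, parent = NULL) {
  tree <- state$tree
  lp <- root_bound_log_density(max(tree$ages), spec$root_bound)
  if (!is.finite(lp)) return(-Inf)
  lp <- lp + if (spec$tree_prior == "constant") {
    coalescent_log_density(tree, state$theta)
  } else {
    dlaplace_log(state$growth, 0, 1) +
      exp_growth_log_density(tree, state$theta, state$growth)
  }
  lp <- lp + hyperprior_log_density(state$theta, spec$theta_prior,
                                    spec$lognormal_real_mean)
  L <- tree_length(tree)
  if (spec$clock == "strict") {
    if (spec$dating == "heterochronous") {
      lp <- lp + ctmc_reference_log_density(state$rate, L)
    }
  } else {
    if (spec$dating == "heterochronous") {
      lp <- lp + ctmc_reference_log_density(state$ucln_mean, L)
    }
    lp <- lp + dexp(state$ucln_sd, rate = 1 / 0.33, log = TRUE)
    mulog <- log(state$ucln_mean) - state$ucln_sd^2 / 2
    if (is.null(parent)) parent <- tree_tables(tree)$parent
    nonroot <- which(parent > 0L)
    lp <- lp + sum(dlnorm(state$branch_rates[nonroot], meanlog = mulog,
                          sdlog = state$ucln_sd, log = TRUE))
  }
  lp
}
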