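#' Power-posterior ladder from Beta(0.3, 1) quantiles
#'
#' The `K + 1` powers `beta_k = (k/K)^(1/0.3)`, `k = 0..K`, i.e. equally
#' spaced quantiles of a `Beta(0.3, 1)` distribution. The ladder concentrates
#' near `beta = 0`, where the integrand of the marginal-likelihood path
#' changes fastest.
#'
#' @param K Number of steps (>= 2).
#' @return An object of class `bets_ladder`: list with `K` and the numeric
#'   vector `beta` (increasing, `beta[1] = 0`, `beta[K+1] = 1`).
#' @export
make_ladder <- function(K) {
  if (K < 2) stop_betsig("need at least 2 ladder steps", "betsig_argument_error")
  structure(list(K = as.integer(K), beta = (0:K / K)^(1 / 0.3)),
            class = "bets_ladder")
}

#' Stepping-stone estimate of the log marginal likelihood
#'
#' Combines per-power traces into the stepping-stone estimator
#' `log ML = sum_k log (1/J) sum_j exp((beta_{k+1} - beta_k) * ll_kj)` where
#' `ll_kj` are log-likelihood samples drawn under power `beta_k`; each step
#' is centred on its maximum for overflow safety. The standard error
#' aggregates per-step delta-method errors with an ESS-based effective
#' sample size.
#'
#' @param traces List of [run_chain()] traces (or any data frames with a
#'   `logLikelihood` column and constant `beta` column), one per ladder power
#'   `beta_0 .. beta_{K-1}`; a trace at `beta_K = 1` may be present and is
#'   ignored.
#' @param ladder A [make_ladder()] object.
#' @return List with `log_ml`, `se`, and `steps` (per-step tibble with
#'   `beta`, `delta_beta`, `contribution`, `ess`, `se`).
#' @export
stepping_stone <- function(traces, ladder) {
  beta_of <- vapply(traces, function(tr) tr$beta[1L], numeric(1))
  traces <- traces[order(beta_of)]
  beta_of <- sort(beta_of)
  need <- ladder$beta[seq_len(ladder$K)]
  idx <- vapply(need, function(b) {
    hit <- which(abs(beta_of - b) < 1e-12)
    if (!length(hit)) NA_integer_ else hit[1L]
  }, integer(1))
  if (anyNA(idx)) {
    stop_betsig("missing trace for one or more ladder powers", "betsig_estimator_error")
  }
  terms <- numeric(ladder$K)
  ses <- numeric(ladder$K)
  esss <- numeric(ladder$K)
  for (k in seq_len(ladder$K)) {
    dbeta <- ladder$beta[k + 1L] - ladder$beta[k]
    ll <- traces[[idx[k]]]$logLikelihood
    m <- max(ll)
    x <- exp(dbeta * (ll - m))
    terms[k] <- dbeta * m + log(mean(x))
    ess <- if (length(x) >= 10) effective_sample_size(x) else length(x)
    esss[k] <- ess
    ses[k] <- sqrt(stats::var(x) / ess) / mean(x)
  }
  list(
    log_ml = sum(terms),
    se = sqrt(sum(ses^2)),
    steps = tibble(beta = need, delta_beta = diff(ladder$beta),
                   contribution = terms, ess = esss, se = ses)
  )
}

#' Estimate a log marginal likelihood by stepping-stone sampling
#'
#' Runs one MCMC chain per ladder power, annealing from the posterior
#' (`beta = 1`) down to the prior (`beta = 0`) with warm starts (each chain
#' starts at the previous power's final state), then applies
#' [stepping_stone()]. All priors in the model are proper, so the path from
#' the prior is a valid marginal-likelihood path.
#'
#' @inheritParams run_chain
#' @param K Number of ladder steps.
#' @param n_iter Iterations per power.
#' @param thin Thinning interval within each power's chain.
#' @param burnin Burn-in fraction per power.
#' @param keep_traces Keep the full per-power traces in the result?
#' @return An object of class `bets_ml`: list with `log_ml`, `se`, `ladder`,
#'   `steps`, `posterior` (the `beta = 1` trace), and optionally `traces`.
#' @export
marginal_likelihood <- function(aln, ages, spec, K = 30, n_iter = 2e4,
                                thin = NULL, burnin = 0.25, seed = NULL,
                                keep_traces = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  thin <- thin %||% max(1L, floor(n_iter * (1 - burnin) / 200))
  ladder <- make_ladder(K)
  # posterior first: longer warm-up and adaptation, reused as warm start
  post <- run_chain(aln, ages, spec, beta = 1, n_iter = n_iter, thin = thin,
                    burnin = burnin, tune = TRUE)
  state <- attr(post, "final_state")
  traces <- vector("list", K)
  for (k in rev(seq_len(K))) {     # beta_{K-1} down to beta_0
    tr <- run_chain(aln, ages, spec, beta = ladder$beta[k], n_iter = n_iter,
                    thin = thin, burnin = burnin, init = state, tune = TRUE)
    state <- attr(tr, "final_state")
    traces[[k]] <- tr
  }
  est <- stepping_stone(traces, ladder)
  structure(
    list(log_ml = est$log_ml, se = est$se, ladder = ladder, steps = est$steps,
         posterior = post, traces = if (keep_traces) traces),
    class = "bets_ml"
  )
}

#' @export
print.bets_ml <- function(x, ...) {
  cat(sprintf("<bets_ml> log marginal likelihood %.3f (SE %.3f), %d-step ladder\n",
              x$log_ml, x$se, x$ladder$K))
  invisible(x)
}

#' Repeatability of the marginal-likelihood estimate
#'
#' Reruns the stepping-stone estimator with fresh seeds and reports the
#' spread (max - min) of the log marginal likelihoods. Spreads above
#' `tolerance` (default 1.0 log unit, the conventional adequacy criterion)
#' are flagged: chain lengths or ladder size should then be increased.
#'
#' @inheritParams marginal_likelihood
#' @param n_repeats Number of independent estimates (>= 2).
#' @param tolerance Maximum acceptable spread in log units.
#' @param ... Passed on to [marginal_likelihood()].
#' @return List with `log_ml` (vector), `spread`, `ok`.
#' @export
repeatability_check <- function(aln, ages, spec, n_repeats = 2, seed = 1,
                                tolerance = 1.0, ...) {
  if (n_repeats < 2) stop_betsig("need at least 2 repeats", "betsig_argument_error")
  seeds <- spawn_seeds(seed, n_repeats)
  vals <- vapply(seeds, function(s) {
    marginal_likelihood(aln, ages, spec, seed = s, ...)$log_ml
  }, numeric(1))
  spread <- max(vals) - min(vals)
  list(log_ml = vals, spread = spread, ok = spread <= tolerance)
}
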