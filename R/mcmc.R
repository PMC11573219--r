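#' Metropolis-Hastings sampling of the (power) posterior
#'
#' Samples tree, coalescent and clock parameters from the tempered target
#' `likelihood^beta x prior` for one [model_spec()]. `beta = 1` is the
#' posterior, `beta = 0` the (proper) joint prior. The move set comprises
#' multiplier (scale) moves on `theta`/`Phi`, the clock rate, the
#' relaxed-clock mean/sd and single branch rates, a uniform node-age move, a
#' root-age multiplier, a whole-tree scale move, and narrow/wide exchanges of
#' time-compatible subtrees; multiplier moves carry the standard `log m`
#' Hastings correction per scaled dimension. Proposal scales are adapted
#' towards a target acceptance rate during burn-in only (Robbins-Monro), so
#' recorded samples come from a fixed, Markovian kernel.
#'
#' @param aln A [bets_alignment()], or `NULL` to sample the prior only
#'   (the likelihood is then identically 0).
#' @param ages Tip sampling ages, named by taxon (ignored - treated as all
#'   zero - in isochronous mode).
#' @param spec A [model_spec()].
#' @param beta Power on the likelihood, in `[0, 1]`.
#' @param n_iter Number of MCMC iterations.
#' @param thin Record every `thin`-th iteration.
#' @param burnin Fraction of `n_iter` discarded (and used for tuning).
#' @param seed Optional RNG seed.
#' @param init Optional starting state (the `final_state` attribute of a
#'   previous trace) for warm starts.
#' @param tune Adapt proposal scales during burn-in?
#' @param target_acceptance Tuning target (default 0.234).
#' @return A tibble of class `bets_trace`: one row per recorded sample with
#'   columns `iteration`, model parameters, `root_height`, `tree_length`,
#'   `logLikelihood`, `logPrior` and `beta`. Attributes: `final_state`,
#'   `acceptance` (per-move rates), `proposal_scales`.
#' @export
run_chain <- function(aln, ages, spec, beta = 1, n_iter = 2e5, thin = 100,
                      burnin = 0.1, seed = NULL, init = NULL, tune = TRUE,
                      target_acceptance = 0.234) {
  if (!is.null(seed)) set.seed(seed)
  if (beta < 0 || beta > 1) stop_betsig("beta must be in [0, 1]", "betsig_argument_error")
  have_data <- !is.null(aln)

  st <- init %||% init_state(aln, ages, spec)
  ntip <- st$ntip
  internals <- (ntip + 1L):(2L * ntip - 1L)
  root <- st$root
  nonroot <- setdiff(seq_len(2L * ntip - 1L), root)
  int_nonroot <- setdiff(internals, root)

  # pattern data in state tip order (tips are 1..ntip by construction)
  if (have_data) {
    idx <- match(st$tip.label, aln$tip.label)
    if (anyNA(idx)) stop_betsig("alignment labels do not match dates/tree", "betsig_data_error")
    pat0 <- aln$patterns[idx, , drop = FALSE] - 1L
    pat0[is.na(pat0)] <- -1L
    storage.mode(pat0) <- "integer"
    wts <- aln$weights
  }
  pi <- spec$subst$pi
  kappa <- spec$subst$kappa
  grates <- model_gamma_rates(spec$subst)

  loglik_of <- function(s) {
    if (!have_data) return(0)
    postorder <- internals[order(s$ages[internals])]
    d <- numeric(2L * ntip - 1L)
    r <- if (spec$clock == "strict") s$rate else s$branch_rates[nonroot]
    d[nonroot] <- r * (s$ages[s$parent[nonroot]] - s$ages[nonroot])
    pruning_loglik_cpp(s$children, postorder, d, pat0, wts, pi, kappa, grates)
  }

  logprior_of <- function(s) {
    rh <- max(s$ages[internals])
    if (!is.null(spec$root_bound)) {
      if (rh > spec$root_bound) return(-Inf)
      lp <- -log(spec$root_bound)
    } else {
      lp <- 0
    }
    lp <- lp + if (spec$tree_prior == "constant") {
      coal_logdens_ages(s$ages, ntip, s$theta)
    } else {
      dlaplace_log(s$growth, 0, 1) +
        growth_logdens_ages(s$ages, ntip, s$theta, s$growth)
    }
    lp <- lp + hyperprior_log_density(s$theta, spec$theta_prior, spec$lognormal_real_mean)
    L <- sum(s$ages[s$parent[nonroot]] - s$ages[nonroot])
    if (spec$clock == "strict") {
      if (spec$dating == "heterochronous") {
        lp <- lp + ctmc_reference_log_density(s$rate, L)
      }
    } else {
      if (spec$dating == "heterochronous") {
        lp <- lp + ctmc_reference_log_density(s$ucln_mean, L)
      }
      lp <- lp + dexp(s$ucln_sd, rate = 1 / 0.33, log = TRUE)
      mulog <- log(s$ucln_mean) - s$ucln_sd^2 / 2
      lp <- lp + sum(dlnorm(s$branch_rates[nonroot], meanlog = mulog,
                            sdlog = s$ucln_sd, log = TRUE))
    }
    lp
  }

  # ---- move set ----------------------------------------------------------
  scalar_moves <- c("theta")
  if (spec$tree_prior == "growth") scalar_moves <- c(scalar_moves, "growth")
  if (spec$clock == "strict") {
    if (spec$dating == "heterochronous") scalar_moves <- c(scalar_moves, "rate")
  } else {
    scalar_moves <- c(scalar_moves, "ucln_sd")
    if (spec$dating == "heterochronous") scalar_moves <- c(scalar_moves, "ucln_mean")
  }
  move_names <- c(scalar_moves, "node_age", "root_age", "tree_scale",
                  "updown", "narrow", "wide")
  if (spec$clock == "ucln") move_names <- c(move_names, "branch_rate")
  move_wt <- setNames(rep(1, length(move_names)), move_names)
  move_wt["node_age"] <- max(2, ntip / 8)
  move_wt["narrow"] <- 2
  move_wt["updown"] <- 3  # the theta-tree ridge dominates prior-end mixing
  move_wt["theta"] <- 2
  if (spec$clock == "ucln") move_wt["branch_rate"] <- max(2, ntip / 8)
  if (ntip == 2L) move_wt[c("node_age", "narrow", "wide")] <- 0
  move_p <- move_wt / sum(move_wt)

  lambda <- setNames(rep(0.8, length(move_names)), move_names)
  lambda[names(lambda) %in% c("narrow", "wide", "node_age")] <- NA  # untuned
  if (!is.null(st$lambda)) {
    keep <- intersect(names(st$lambda), move_names)
    lambda[keep] <- st$lambda[keep]
  }
  n_prop <- setNames(numeric(length(move_names)), move_names)
  n_acc <- n_prop

  # affects-likelihood flags for scalar moves
  lik_flag <- c(theta = FALSE, growth = FALSE, rate = TRUE,
                ucln_mean = FALSE, ucln_sd = FALSE)

  is_ancestor <- function(s, a, b) {
    # TRUE if a is an ancestor of b
    while (b != 0L) {
      b <- s$parent[b]
      if (b == a) return(TRUE)
    }
    FALSE
  }
  swap_child <- function(s, p, from, to) {
    row <- p - ntip
    s$children[row, which(s$children[row, ] == from)[1L]] <- to
    s
  }

  propose <- function(s, mv) {
    # returns list(s, lhr, lik) or NULL for an auto-rejected proposal
    if (mv %in% scalar_moves) {
      if (mv == "growth") {
        s$growth <- s$growth + rnorm(1, 0, lambda[[mv]])
        return(list(s = s, lhr = 0, lik = FALSE))
      }
      m <- exp(lambda[[mv]] * (runif(1) - 0.5))
      s[[mv]] <- s[[mv]] * m
      return(list(s = s, lhr = log(m), lik = lik_flag[[mv]]))
    }
    switch(mv,
      node_age = {
        v <- if (length(int_nonroot) == 1L) int_nonroot else sample(int_nonroot, 1L)
        kids <- s$children[v - ntip, ]
        lo <- max(s$ages[kids])
        hi <- s$ages[s$parent[v]]
        s$ages[v] <- runif(1, lo, hi)
        list(s = s, lhr = 0, lik = TRUE)
      },
      root_age = {
        kids <- s$children[root - ntip, ]
        base <- max(s$ages[kids])
        m <- exp(lambda[[mv]] * (runif(1) - 0.5))
        s$ages[root] <- base + (s$ages[root] - base) * m
        list(s = s, lhr = log(m), lik = TRUE)
      },
      tree_scale = {
        m <- exp(lambda[[mv]] * (runif(1) - 0.5))
        s$ages[internals] <- s$ages[internals] * m
        if (any(s$ages[s$parent[nonroot]] <= s$ages[nonroot])) return(NULL)
        list(s = s, lhr = (ntip - 1) * log(m), lik = TRUE)
      },
      updown = {
        # ride the theta-tree ridge: theta and node ages up, clock rates down
        m <- exp(lambda[[mv]] * (runif(1) - 0.5))
        s$theta <- s$theta * m
        s$ages[internals] <- s$ages[internals] * m
        if (any(s$ages[s$parent[nonroot]] <= s$ages[nonroot])) return(NULL)
        nd <- ntip  # theta + (ntip - 1) internal ages
        if (spec$dating == "heterochronous") {
          if (spec$clock == "strict") {
            s$rate <- s$rate / m
            nd <- nd - 1L
          } else {
            s$ucln_mean <- s$ucln_mean / m
            s$branch_rates <- s$branch_rates / m
            nd <- nd - 1L - (2L * ntip - 2L)
          }
        }
        list(s = s, lhr = nd * log(m), lik = TRUE)
      },
      narrow = {
        v <- if (length(int_nonroot) == 1L) int_nonroot else sample(int_nonroot, 1L)
        p <- s$parent[v]
        prow <- s$children[p - ntip, ]
        sib <- prow[prow != v]
        if (s$ages[sib] >= s$ages[v]) return(NULL)
        x <- s$children[v - ntip, sample.int(2L, 1L)]
        s <- swap_child(s, p, sib, x)
        s <- swap_child(s, v, x, sib)
        s$parent[x] <- p
        s$parent[sib] <- v
        list(s = s, lhr = 0, lik = TRUE)
      },
      wide = {
        ab <- sample(nonroot, 2L)
        a <- ab[1L]; b <- ab[2L]
        pa <- s$parent[a]; pb <- s$parent[b]
        if (pa == pb) return(NULL)
        if (s$ages[a] >= s$ages[pb] || s$ages[b] >= s$ages[pa]) return(NULL)
        if (a > ntip && is_ancestor(s, a, b)) return(NULL)
        if (b > ntip && is_ancestor(s, b, a)) return(NULL)
        s <- swap_child(s, pa, a, b)
        s <- swap_child(s, pb, b, a)
        s$parent[a] <- pb
        s$parent[b] <- pa
        list(s = s, lhr = 0, lik = TRUE)
      },
      branch_rate = {
        v <- sample(nonroot, 1L)
        m <- exp(lambda[[mv]] * (runif(1) - 0.5))
        s$branch_rates[v] <- s$branch_rates[v] * m
        list(s = s, lhr = log(m), lik = TRUE)
      }
    )
  }

  # ---- main loop ---------------------------------------------------------
  st$logprior <- logprior_of(st)
  if (!is.finite(st$logprior)) {
    stop_betsig("initial state has zero prior probability (root bound too tight?)",
                "betsig_config_error")
  }
  st$loglik <- if (beta > 0 || have_data) loglik_of(st) else 0

  n_burn <- floor(burnin * n_iter)
  rec_iters <- seq.int(n_burn + thin, n_iter, by = thin)
  nrec <- length(rec_iters)
  param_cols <- c("theta",
                  if (spec$tree_prior == "growth") "growth",
                  if (spec$clock == "strict") "rate" else c("ucln_mean", "ucln_sd"),
                  "root_height", "tree_length", "logLikelihood", "logPrior")
  out <- matrix(NA_real_, nrec, length(param_cols),
                dimnames = list(NULL, param_cols))
  ri <- 0L

  for (it in seq_len(n_iter)) {
    mv <- sample(move_names, 1L, prob = move_p)
    n_prop[mv] <- n_prop[mv] + 1
    prop <- propose(st, mv)
    accepted <- FALSE
    if (!is.null(prop)) {
      lp2 <- logprior_of(prop$s)
      if (is.finite(lp2)) {
        ll2 <- st$loglik
        if (prop$lik && beta > 0) ll2 <- loglik_of(prop$s)
        lik_delta <- if (beta > 0) beta * (ll2 - st$loglik) else 0
        if (is.nan(lik_delta)) lik_delta <- 0  # -Inf minus -Inf: both impossible
        log_alpha <- lik_delta + lp2 - st$logprior + prop$lhr
        if (log_alpha >= 0 || log(runif(1)) < log_alpha) {
          st <- prop$s
          st$logprior <- lp2
          st$loglik <- if (prop$lik && beta == 0) NA_real_ else ll2
          accepted <- TRUE
        }
      }
    }
    n_acc[mv] <- n_acc[mv] + accepted
    if (tune && it <= n_burn && is.finite(lambda[mv])) {
      delta <- min(0.25, 1 / sqrt(n_prop[mv]))
      lambda[mv] <- lambda[mv] * exp(delta * ((accepted) - target_acceptance))
    }
    if (ri < nrec && it == rec_iters[ri + 1L]) {
      ri <- ri + 1L
      if (is.na(st$loglik)) st$loglik <- loglik_of(st)
      L <- sum(st$ages[st$parent[nonroot]] - st$ages[nonroot])
      vals <- c(st$theta,
                if (spec$tree_prior == "growth") st$growth,
                if (spec$clock == "strict") st$rate else c(st$ucln_mean, st$ucln_sd),
                max(st$ages[internals]), L, st$loglik, st$logprior)
      out[ri, ] <- vals
    }
  }
  if (is.na(st$loglik)) st$loglik <- loglik_of(st)
  st$lambda <- lambda[!is.na(lambda)]

  trace <- as_tibble(as.data.frame(out))
  trace <- tibble::add_column(trace, iteration = rec_iters, .before = 1L)
  trace$beta <- beta
  acc <- ifelse(n_prop > 0, n_acc / n_prop, NA_real_)
  attr(trace, "final_state") <- st
  attr(trace, "acceptance") <- acc
  attr(trace, "proposal_scales") <- lambda
  class(trace) <- c("bets_trace", class(trace))
  trace
}

# starting state: a serial coalescent tree drawn at a moderate theta, rate at
# the CTMC-reference mean (heterochronous) or the fixed value (isochronous)
init_state <- function(aln, ages, spec) {
  if (spec$dating == "heterochronous") {
    if (is.null(ages) || is.null(names(ages))) {
      stop_betsig("heterochronous mode needs tip ages named by taxon",
                  "betsig_config_error")
    }
  } else {
    if (is.null(ages)) {
      if (is.null(aln)) stop_betsig("need taxa via `aln` or `ages`", "betsig_config_error")
      ages <- setNames(rep(0, length(aln$tip.label)), aln$tip.label)
    }
    ages <- setNames(rep(0, length(ages)), names(ages))
  }
  theta0 <- switch(spec$theta_prior, exponential = 1, gamma = 1, lognormal = exp(1))
  tree <- NULL
  for (try in 1:60) {
    cand <- sample_coalescent_tree(ages, theta = theta0)
    if (is.null(spec$root_bound) || max(cand$ages) <= spec$root_bound) {
      tree <- cand
      break
    }
    theta0 <- theta0 * 0.7
  }
  if (is.null(tree)) {
    stop_betsig("could not draw a starting tree inside the root bound",
                "betsig_config_error")
  }
  tt <- tree_tables(tree)
  ntip <- n_tips(tree)
  L <- tree_length(tree)
  st <- list(
    ntip = ntip, root = ntip + 1L, tip.label = tree$tip.label,
    ages = tree$ages, parent = tt$parent, children = tt$children,
    theta = theta0,
    growth = if (spec$tree_prior == "growth") 0 else NULL
  )
  if (spec$clock == "strict") {
    st$rate <- if (spec$dating == "heterochronous") 0.5 / L else spec$fixed_rate
  } else {
    st$ucln_mean <- if (spec$dating == "heterochronous") 0.5 / L else spec$fixed_rate
    st$ucln_sd <- 0.33
    st$branch_rates <- rep(st$ucln_mean, 2L * ntip - 1L)
  }
  st
}

#' Write or read an MCMC trace as a tab-separated log
#'
#' One header row (`iteration`, the sampled parameters, `logLikelihood`,
#' `logPrior`, `beta`), one row per recorded sample.
#'
#' @param trace A `bets_trace` tibble from [run_chain()].
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   a `bets_trace` tibble (without sampler state attributes).
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- as_tibble(utils::read.delim(path, check.names = FALSE))
  class(tr) <- c("bets_trace", class(tr))
  tr
}

#' Extract the timetree of a sampler state
#'
#' Rebuilds a [timetree()] from the `final_state` attribute of a
#' [run_chain()] trace (or from the state directly).
#'
#' @param x A `bets_trace` or a sampler state list.
#' @return A [timetree()].
#' @export
state_tree <- function(x) {
  st <- if (inherits(x, "bets_trace")) attr(x, "final_state") else x
  kid <- which(st$parent > 0L)
  edge <- cbind(st$parent[kid], kid)
  timetree(edge, st$ages, st$tip.label)
}

#' Effective sample size of an MCMC series
#'
#' `n / (1 + 2 sum of autocorrelations)`, with the autocorrelation sum
#' truncated at the first negative pair (Geyer initial positive sequence).
#' A constant series is reported as ESS `n` with attribute
#' `degenerate = TRUE`.
#'
#' @param x Numeric vector of at least 10 samples.
#' @return ESS (scalar); attribute `degenerate` flags constant input.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10) stop_betsig("need at least 10 samples", "betsig_argument_error")
  if (sd(x) == 0 || !is.finite(sd(x))) {
    return(structure(as.numeric(n), degenerate = TRUE))
  }
  rho <- acf(x, lag.max = min(n - 2L, 2000L), plot = FALSE)$acf[-1]
  npair <- floor(length(rho) / 2)
  s <- 0
  for (k in seq_len(npair)) {
    pair <- rho[2 * k - 1] + rho[2 * k]
    if (pair < 0) break
    s <- s + pair
  }
  # include a dangling positive first lag if the loop never ran
  if (npair == 0 && length(rho) >= 1 && rho[1] > 0) s <- rho[1]
  max(1, n / (1 + 2 * s))
}
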