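#' Draw tip sampling ages for a simulation design
#'
#' Three sampling-time schemes: `"four_epoch"` draws each age independently
#' and uniformly from \{0, 0.10, 0.35, 0.50\} (four discrete sampling
#' periods, e.g. sequencing blitzes or archaeological strata);
#' `"isochronous"` returns all zeros; `"exponential"` draws i.i.d.
#' exponential ages with the given mean (most samples near the present).
#' Ages are shifted so the youngest tip sits at 0.
#'
#' @param scheme One of `"four_epoch"`, `"isochronous"`, `"exponential"`.
#' @param n Number of tips (>= 2).
#' @param mean Mean of the exponential scheme (time units).
#' @return Numeric vector of `n` tip ages.
#' @export
assign_tip_ages <- function(scheme = c("four_epoch", "isochronous", "exponential"),
                            n, mean = 1) {
  scheme <- match.arg(scheme)
  if (n < 2) stop_betsig("need at least 2 tips", "betsig_argument_error")
  ages <- switch(scheme,
    four_epoch = sample(c(0, 0.10, 0.35, 0.50), n, replace = TRUE),
    isochronous = rep(0, n),
    exponential = rexp(n, rate = 1 / mean)
  )
  ages - min(ages)
}

#' Simulate a dated tree under the serial coalescent
#'
#' Samples a rooted binary time-tree conditional on tip sampling ages, under
#' a constant-size coalescent (`N(t) = theta`) or an exponential-growth
#' coalescent (`N(t) = phi * exp(-growth * t)`, `t` = age before present;
#' here `theta` plays the role of `phi`). Going backward in time lineages
#' activate at their tip ages, and with `k` active lineages the coalescent
#' hazard is `k(k-1) / (2 N(t))`; waiting times are drawn by exact inversion
#' (closed form under growth). With `growth < 0` the backward hazard decays
#' and coalescence is not guaranteed; such draws raise an error.
#'
#' @param ages Tip ages (youngest = 0), optionally named with tip labels.
#' @param theta Effective (or scaled) population size (> 0).
#' @param growth Exponential growth rate (default 0 = constant size).
#' @param labels Tip labels (default `t1..tn` or the names of `ages`).
#' @return A [timetree()].
#' @export
sample_coalescent_tree <- function(ages, theta = 1, growth = 0, labels = NULL) {
  n <- length(ages)
  if (n < 2) stop_betsig("need at least 2 tips", "betsig_argument_error")
  if (theta <= 0) stop_betsig("theta must be positive", "betsig_argument_error")
  labels <- labels %||% names(ages) %||% paste0("t", seq_len(n))
  ages <- ages - min(ages)

  ord <- order(ages)
  pending <- ord          # tip ids not yet active, by increasing age
  pool <- integer(0)      # active lineage node ids
  node_age <- c(ages, rep(NA_real_, n - 1L))
  edges <- matrix(0L, 2L * (n - 1L), 2L)
  erow <- 0L
  next_internal <- n + 1L
  t <- 0

  repeat {
    # activate tips sampled at or before the current time
    while (length(pending) && ages[pending[1L]] <= t + 1e-15) {
      pool <- c(pool, pending[1L])
      pending <- pending[-1L]
    }
    k <- length(pool)
    if (k < 2L && !length(pending)) break
    next_tip <- if (length(pending)) ages[pending[1L]] else Inf
    w <- if (k >= 2L) {
      E <- rexp(1)
      kk <- k * (k - 1) / 2
      if (growth == 0) {
        theta * E / kk
      } else {
        arg <- exp(growth * t) + E * growth * theta / kk
        if (arg <= 0) {
          stop_betsig("growth-reversed coalescent failed to coalesce (growth < 0 too strong)",
                      "betsig_domain_error")
        }
        log(arg) / growth - t
      }
    } else {
      Inf
    }
    if (t + w < next_tip) {
      t_new <- t + w
      # guard against floating-point collapse under extreme theta: node ages
      # must stay strictly increasing
      if (t_new <= t) t_new <- t * (1 + 1e-12) + 1e-308
      t <- t_new
      pick <- sample.int(k, 2L)
      p <- next_internal
      next_internal <- next_internal + 1L
      node_age[p] <- t
      edges[erow + 1L, ] <- c(p, pool[pick[1L]])
      edges[erow + 2L, ] <- c(p, pool[pick[2L]])
      erow <- erow + 2L
      pool <- c(pool[-pick], p)
    } else {
      t <- next_tip
    }
  }

  # renumber internals so the root (created last) is node n + 1, per ape
  remap <- seq_len(2L * n - 1L)
  created <- (n + 1L):(2L * n - 1L)
  remap[created] <- rev(created)
  edges[] <- remap[edges]
  node_age[remap] <- node_age
  timetree(edges, node_age, labels)
}

#' Molecular clock models for simulation
#'
#' A strict clock assigns one rate `r` to every branch; an uncorrelated
#' lognormal (UCLN) relaxed clock draws i.i.d. branch rates from a lognormal
#' with real-space mean `mean` and log-space standard deviation `sd`
#' (log-space location `log(mean) - sd^2 / 2`, the convention of common
#' relaxed-clock software).
#'
#' @param kind `"strict"` or `"ucln"`.
#' @param rate Strict-clock rate (> 0), substitutions/site/time.
#' @param mean,sd UCLN real-space mean (> 0) and log-space sd (> 0).
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(kind = c("strict", "ucln"), rate = 0.05,
                        mean = 0.05, sd = 0.25) {
  kind <- match.arg(kind)
  if (kind == "strict" && rate <= 0) {
    stop_betsig("strict clock rate must be positive", "betsig_argument_error")
  }
  if (kind == "ucln" && (mean <= 0 || sd <= 0)) {
    stop_betsig("UCLN mean and sd must be positive", "betsig_argument_error")
  }
  structure(list(kind = kind, rate = rate, mean = mean, sd = sd),
            class = "clock_model")
}

#' Draw per-branch substitution rates
#'
#' @param clock A [clock_model()].
#' @param tree A [timetree()].
#' @return Numeric vector of length `2n - 1`: the rate on the branch above
#'   each node (root entry `NA`).
#' @export
sample_branch_rates <- function(clock, tree) {
  nnode <- length(tree$ages)
  root <- n_tips(tree) + 1L
  rates <- if (clock$kind == "strict") {
    rep(clock$rate, nnode)
  } else {
    rlnorm(nnode, meanlog = log(clock$mean) - clock$sd^2 / 2, sdlog = clock$sd)
  }
  rates[root] <- NA_real_
  rates
}

#' Simulate a nucleotide alignment along a dated tree
#'
#' Root states are drawn from the model's stationary frequencies and evolved
#' down each branch with transition probabilities for a distance of
#' `branch rate x branch duration` expected substitutions/site; columns are
#' i.i.d. Delegates the per-site simulation to [phangorn::simSeq()] on the
#' rate-scaled tree (with +Gamma models, sites are partitioned across the
#' discrete category rates).
#'
#' @param tree A [timetree()].
#' @param rates Per-branch rates as from [sample_branch_rates()], or one
#'   scalar rate.
#' @param model A [subst_model()].
#' @param length Number of sites (>= 1).
#' @return A [bets_alignment()].
#' @export
simulate_alignment <- function(tree, rates, model, length = 1000L) {
  if (length < 1) stop_betsig("length must be >= 1", "betsig_argument_error")
  ph <- as.phylo(tree)
  r <- if (length(rates) == 1L) rep(rates, nrow(ph$edge)) else rates[ph$edge[, 2L]]
  ph$edge.length <- ph$edge.length * r
  Q <- if (model$kind == "JC") rep(1, 6) else {
    k <- model$kappa
    c(1, k, 1, 1, k, 1)  # ac, ag, at, cg, ct, gt
  }
  cat_rates <- model_gamma_rates(model)
  nsite <- as.integer(length)
  if (length(cat_rates) == 1L) {
    sim <- phangorn::simSeq(ph, l = nsite, Q = Q, bf = model$pi, type = "DNA")
  } else {
    ncat <- length(cat_rates)
    alloc <- tabulate(sample.int(ncat, nsite, replace = TRUE), nbins = ncat)
    parts <- lapply(which(alloc > 0L), function(c_i) {
      phangorn::simSeq(ph, l = alloc[c_i], Q = Q, bf = model$pi,
                       rate = cat_rates[c_i], type = "DNA")
    })
    sim <- do.call(c, parts)
  }
  m <- toupper(as.character(sim))
  rownames(m) <- tree$tip.label
  bets_alignment(m)
}

#' Generate seeded replicate data sets for a simulation design
#'
#' Reproducible replicates of the two study designs. `"epoch2x2"`: trees of
#' `n_tips` taxa under a constant-size coalescent with `theta = 1`,
#' heterochronous (four-epoch tip ages) or isochronous, sequences of 1,000 nt
#' under JC at rate 0.05 substitutions/site/time (strict clock) or UCLN
#' branch rates (mean 0.05, sd 0.25). `"cholera_like"`: 50-taxon isochronous
#' trees with `theta = 100`; sequence length and rate default to values
#' calibrated to give a site-pattern count of the order of the empirical SNP
#' alignment this design mimics. For isochronous-truth replicates a seeded
#' vector of randomly assigned "fake" sampling ages is recorded (four-epoch
#' draws for `"epoch2x2"`, exponential with mean root height / 10 for
#' `"cholera_like"`), for use in deliberately misspecified heterochronous
#' analyses.
#'
#' @param design `"epoch2x2"` or `"cholera_like"`.
#' @param true_clock A [clock_model()] used to generate branch rates.
#' @param dating `"heterochronous"` or `"isochronous"` truth.
#' @param n_reps Number of replicates.
#' @param seed Master seed; each replicate gets an independent child seed.
#' @param n_tips,theta,length,rate Design parameters (defaults per design).
#' @param subst A [subst_model()].
#' @return A list of replicates; each is a list with elements `tree`, `aln`,
#'   `tip_ages`, `fake_ages` (iso truth only), `true` (true parameters) and
#'   `seed`.
#' @export
make_replicates <- function(design = c("epoch2x2", "cholera_like"),
                            true_clock = clock_model("strict"),
                            dating = c("heterochronous", "isochronous"),
                            n_reps = 10L, seed = 1L,
                            n_tips = 50L, theta = NULL, length = NULL,
                            rate = NULL, subst = subst_model("JC")) {
  design <- match.arg(design)
  dating <- match.arg(dating)
  if (design == "cholera_like") {
    theta <- theta %||% 100
    length <- length %||% 2000L
    if (!is.null(rate)) true_clock$rate <- rate
    else if (true_clock$kind == "strict") true_clock$rate <- 0.003
  } else {
    theta <- theta %||% 1
    length <- length %||% 1000L
    if (!is.null(rate)) true_clock$rate <- rate
  }
  seeds <- spawn_seeds(seed, n_reps)
  lapply(seq_len(n_reps), function(i) {
    set.seed(seeds[i])
    ages <- if (dating == "isochronous") {
      assign_tip_ages("isochronous", n_tips)
    } else if (design == "cholera_like") {
      stop_betsig("the cholera-like design is isochronous-truth only",
                  "betsig_config_error")
    } else {
      assign_tip_ages("four_epoch", n_tips)
    }
    tree <- sample_coalescent_tree(ages, theta = theta)
    rates <- sample_branch_rates(true_clock, tree)
    aln <- simulate_alignment(tree, rates, subst, length = length)
    fake_ages <- if (dating == "isochronous") {
      fa <- if (design == "cholera_like") {
        assign_tip_ages("exponential", n_tips, mean = max(tree$ages) / 10)
      } else {
        assign_tip_ages("four_epoch", n_tips)
      }
      setNames(fa, tree$tip.label)
    } else {
      NULL
    }
    list(
      tree = tree, aln = aln,
      tip_ages = tip_ages(tree),
      fake_ages = fake_ages,
      true = list(clock = true_clock, theta = theta,
                  rate = if (true_clock$kind == "strict") true_clock$rate else true_clock$mean,
                  branch_rates = rates),
      seed = seeds[i]
    )
  })
}
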