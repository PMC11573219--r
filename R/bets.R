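#' Bayesian evaluation of temporal signal (BETS)
#'
#' Fits the same phylogenetic model to the data four ways - strict or
#' relaxed (UCLN) clock, each with the true sampling times (heterochronous)
#' and with all samples placed at the present (isochronous, clock rate fixed
#' to `iso_rate`) - and compares log marginal likelihoods. A log Bayes
#' factor (heterochronous minus isochronous) of at least +3 is strong
#' evidence for temporal signal; at most -3, strong evidence against.
#' Substitution model, tree prior, hyperpriors and any root-height bound are
#' shared across the four fits.
#'
#' @param aln A [bets_alignment()].
#' @param ages Tip sampling ages named by taxon (used by the heterochronous
#'   fits).
#' @param iso_rate Clock rate fixed in the isochronous fits
#'   (substitutions/site/time); for simulated data the true simulation rate,
#'   for empirical data a value of the expected order of magnitude.
#' @param theta_prior,tree_prior,root_bound,subst,lognormal_real_mean Shared
#'   model settings, see [model_spec()].
#' @param clocks Clock models to evaluate (default both).
#' @param K,n_iter,thin,burnin Stepping-stone settings, see
#'   [marginal_likelihood()].
#' @param seed Master seed (each of the four runs gets a child seed).
#' @return An object of class `bets_result`: per-model log marginal
#'   likelihoods and SEs, per-clock log Bayes factors, the best-model log
#'   Bayes factor, and classifications. Use [tidy()] / [glance()] for tabular
#'   views.
#' @export
run_bets <- function(aln, ages, iso_rate,
                     theta_prior = "exponential", tree_prior = "constant",
                     root_bound = NULL, subst = subst_model("JC"),
                     lognormal_real_mean = FALSE,
                     clocks = c("strict", "ucln"),
                     K = 30, n_iter = 2e4, thin = NULL, burnin = 0.25,
                     seed = 1) {
  clocks <- match.arg(clocks, several.ok = TRUE)
  grid <- expand.grid(clock = clocks,
                      dating = c("heterochronous", "isochronous"),
                      stringsAsFactors = FALSE)
  seeds <- spawn_seeds(seed, nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- model_spec(
      clock = grid$clock[i], dating = grid$dating[i],
      tree_prior = tree_prior, theta_prior = theta_prior,
      root_bound = root_bound, fixed_rate = iso_rate, subst = subst,
      lognormal_real_mean = lognormal_real_mean
    )
    fits[[i]] <- marginal_likelihood(aln, ages, spec, K = K, n_iter = n_iter,
                                     thin = thin, burnin = burnin,
                                     seed = seeds[i])
  }
  key <- paste(ifelse(grid$clock == "strict", "sc", "ucln"),
               ifelse(grid$dating == "heterochronous", "het", "iso"), sep = "_")
  log_ml <- setNames(vapply(fits, `[[`, numeric(1), "log_ml"), key)
  se <- setNames(vapply(fits, `[[`, numeric(1), "se"), key)
  bets_result(log_ml, se = se, fits = setNames(fits, key))
}

#' Assemble a BETS result from four log marginal likelihoods
#'
#' Mostly called by [run_bets()], but usable directly on externally computed
#' log marginal likelihoods (e.g. published values).
#'
#' @param log_ml Named numeric vector with entries among `sc_het`, `sc_iso`,
#'   `ucln_het`, `ucln_iso` (at least one het/iso pair for a clock).
#' @param se Optional standard errors (same names).
#' @param fits Optional list of `bets_ml` objects (same names).
#' @param threshold Log Bayes factor threshold (default 3).
#' @return An object of class `bets_result`.
#' @export
bets_result <- function(log_ml, se = NULL, fits = NULL, threshold = 3) {
  clocks <- intersect(c("sc", "ucln"), unique(sub("_(het|iso)$", "", names(log_ml))))
  log_bf <- sapply(clocks, function(cl) {
    h <- log_ml[paste0(cl, "_het")]
    i <- log_ml[paste0(cl, "_iso")]
    unname(h - i)
  })
  best <- best_model_comparison_values(log_ml)
  structure(
    list(
      log_ml = log_ml, se = se, log_bf = log_bf,
      best = best, threshold = threshold,
      classification = vapply(log_bf, classify, character(1), threshold = threshold),
      best_classification = classify(best$log_bf, threshold = threshold),
      fits = fits
    ),
    class = "bets_result"
  )
}

#' Classify a log Bayes factor for temporal signal
#'
#' @param log_bf Log Bayes factor of heterochronous vs isochronous.
#' @param threshold Decision threshold (default 3, "strong" evidence).
#' @return `"temporal signal"` (`log_bf >= threshold`), `"no temporal
#'   signal"` (`log_bf <= -threshold`) or `"inconclusive"`.
#' @export
classify <- function(log_bf, threshold = 3) {
  if (!is.finite(log_bf)) stop_betsig("log Bayes factor must be finite",
                                      "betsig_argument_error")
  if (log_bf >= threshold) "temporal signal"
  else if (log_bf <= -threshold) "no temporal signal"
  else "inconclusive"
}

best_model_comparison_values <- function(log_ml) {
  het <- log_ml[grepl("_het$", names(log_ml))]
  iso <- log_ml[grepl("_iso$", names(log_ml))]
  list(
    best_het = names(het)[which.max(het)],
    best_iso = names(iso)[which.max(iso)],
    log_bf = unname(max(het) - max(iso))
  )
}

#' Best-model log Bayes factor
#'
#' Compares the best-supported heterochronous model against the
#' best-supported isochronous model: `log BF = max(het log MLs) - max(iso
#' log MLs)`. Because incorrectly included sampling times can also mislead
#' clock-model selection, this comparison can err more often than comparing
#' within the relaxed clock alone.
#'
#' @param result A [bets_result()].
#' @return List with `best_het`, `best_iso` (model names) and `log_bf`.
#' @export
best_model_comparison <- function(result) {
  result$best
}

#' Model posterior probability implied by a log Bayes factor
#'
#' Under equal prior model probabilities, `P = e^B / (1 + e^B)`; a log Bayes
#' factor of 3 corresponds to a posterior probability of about 0.95.
#'
#' @param log_bf Log Bayes factor.
#' @return Posterior probability of the favoured model.
#' @export
posterior_prob_from_log_bf <- function(log_bf) {
  stats::plogis(log_bf)
}

#' @export
print.bets_result <- function(x, ...) {
  cat("<bets_result>\n")
  for (nm in names(x$log_ml)) {
    cat(sprintf("  %-9s log ML %10.3f%s\n", nm, x$log_ml[[nm]],
                if (!is.null(x$se)) sprintf(" (SE %.3f)", x$se[[nm]]) else ""))
  }
  for (cl in names(x$log_bf)) {
    cat(sprintf("  %-9s log BF (het - iso) %8.2f -> %s\n", cl, x$log_bf[[cl]],
                x$classification[[cl]]))
  }
  cat(sprintf("  best models: %s vs %s, log BF %.2f -> %s\n",
              x$best$best_het, x$best$best_iso, x$best$log_bf,
              x$best_classification))
  invisible(x)
}

#' @rdname run_bets
#' @param x A `bets_result`.
#' @param ... Unused.
#' @method tidy bets_result
#' @export
tidy.bets_result <- function(x, ...) {
  nm <- names(x$log_ml)
  tibble(
    model = nm,
    clock = ifelse(grepl("^sc", nm), "strict", "ucln"),
    dating = ifelse(grepl("het$", nm), "heterochronous", "isochronous"),
    log_ml = unname(x$log_ml),
    se = if (is.null(x$se)) NA_real_ else unname(x$se)
  )
}

#' @rdname run_bets
#' @method glance bets_result
#' @export
glance.bets_result <- function(x, ...) {
  tibble(
    log_bf_strict = if ("sc" %in% names(x$log_bf)) x$log_bf[["sc"]] else NA_real_,
    log_bf_ucln = if ("ucln" %in% names(x$log_bf)) x$log_bf[["ucln"]] else NA_real_,
    log_bf_best = x$best$log_bf,
    best_het = x$best$best_het,
    best_iso = x$best$best_iso,
    classification_best = x$best_classification
  )
}
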