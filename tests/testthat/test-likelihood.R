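test_that("transition matrices have the closed-form JC/HKY properties", {
  jc <- subst_model("JC")
  expect_equal(transition_matrix(jc, 0), diag(4), ignore_attr = TRUE)
  expect_equal(unname(transition_matrix(jc, 500)), matrix(0.25, 4, 4),
               tolerance = 1e-12)
  P <- transition_matrix(jc, 0.1)
  expect_equal(unname(diag(P)), rep(0.25 + 0.75 * exp(-0.4 / 3), 4),
               tolerance = 1e-10)
  expect_equal(unname(diag(P)[1]), 0.90638, tolerance = 1e-5)
  expect_error(transition_matrix(jc, -0.1), class = "betsig_argument_error")

  # rows sum to 1 and HKY reduces to JC at kappa = 1, uniform pi
  hky <- subst_model("HKY", pi = c(0.3, 0.2, 0.35, 0.15), kappa = 4)
  for (d in c(0.01, 0.3, 2)) {
    expect_equal(unname(rowSums(transition_matrix(hky, d))), rep(1, 4),
                 tolerance = 1e-12)
    hky1 <- subst_model("HKY", pi = rep(0.25, 4), kappa = 1)
    expect_equal(transition_matrix(hky1, d), transition_matrix(jc, d),
                 tolerance = 1e-12)
  }
})

test_that("HKY closed form agrees with matrix exponentiation", {
  pi <- c(0.35, 0.15, 0.25, 0.25)
  kappa <- 3.2
  # build the normalised rate matrix independently and exponentiate by eigen
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    transition <- (i %in% c(1, 3)) == (j %in% c(1, 3))
    Q[i, j] <- pi[j] * if (transition) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * pi)
  eig <- eigen(Q)
  for (d in c(0.05, 0.5, 3)) {
    Pref <- Re(eig$vectors %*% diag(exp(eig$values * d)) %*% solve(eig$vectors))
    P <- transition_matrix(subst_model("HKY", pi = pi, kappa = kappa), d)
    expect_equal(unname(P), Pref, tolerance = 1e-9)
  }
})

test_that("discrete-gamma category rates have mean one", {
  for (alpha in c(0.2, 0.5, 1, 5)) {
    r <- discrete_gamma_rates(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
})

test_that("pruning equals exhaustive state enumeration on small trees", {
  set.seed(301)
  models <- list(
    subst_model("JC"),
    subst_model("HKY", pi = c(0.4, 0.1, 0.2, 0.3), kappa = 2.5),
    subst_model("HKY", pi = c(0.3, 0.2, 0.3, 0.2), kappa = 4, gamma_shape = 0.5)
  )
  for (rep in 1:6) {
    ntax <- sample(3:5, 1)
    tr <- sample_coalescent_tree(assign_tip_ages("four_epoch", ntax), theta = 1)
    m <- random_alignment_matrix(ntax, 4, missing = if (rep %% 2) 2 else 0)
    rownames(m) <- tr$tip.label
    aln <- bets_alignment(m)
    model <- models[[(rep %% 3) + 1]]
    rate <- runif(1, 0.05, 0.6)
    expect_equal(phylo_log_likelihood(tr, rate, model, aln),
                 brute_force_loglik(tr, rate, model, aln),
                 tolerance = 1e-10)
  }
})

test_that("degenerate and invariant cases evaluate exactly", {
  # two identical 1-nt sequences at zero distance: log(1/4)
  two <- timetree(rbind(c(3, 1), c(3, 2)), c(0, 0, 1), c("a", "b"))
  aln <- bets_alignment(matrix(c("A", "A"), 2, 1, dimnames = list(c("a", "b"), NULL)))
  expect_equal(phylo_log_likelihood(two, 0, subst_model("JC"), aln), log(0.25),
               tolerance = 1e-12)
  # label mismatch is a data error
  bad <- bets_alignment(matrix(c("A", "A"), 2, 1, dimnames = list(c("a", "zz"), NULL)))
  expect_error(phylo_log_likelihood(two, 0.1, subst_model("JC"), bad),
               class = "betsig_data_error")
})

test_that("likelihood is invariant to pattern order and augmentation bookkeeping", {
  set.seed(302)
  tr <- sample_coalescent_tree(rep(0, 6), theta = 1)
  m <- random_alignment_matrix(6, 40)
  rownames(m) <- tr$tip.label
  aln <- bets_alignment(m)
  perm <- sample(n_patterns(aln))
  shuffled <- aln
  shuffled$patterns <- aln$patterns[, perm, drop = FALSE]
  shuffled$weights <- aln$weights[perm]
  jc <- subst_model("JC")
  expect_equal(phylo_log_likelihood(tr, 0.1, jc, aln),
               phylo_log_likelihood(tr, 0.1, jc, shuffled), tolerance = 1e-12)

  # augmentation equals the explicit full alignment
  counts <- c(7, 3, 0, 5)
  aug <- augment_constant_sites(aln, counts)
  explicit <- cbind(m, matrix(rep(c("A", "C", "T"), times = c(7, 3, 5)),
                              nrow = 6, ncol = 15, byrow = TRUE))
  expect_equal(phylo_log_likelihood(tr, 0.1, jc, aug),
               phylo_log_likelihood(tr, 0.1, jc, bets_alignment(explicit)),
               tolerance = 1e-10)
  expect_equal(phylo_log_likelihood(tr, 0.1, jc, augment_constant_sites(aln, rep(0, 4))),
               phylo_log_likelihood(tr, 0.1, jc, aln), tolerance = 1e-12)
})

test_that("pruning agrees with phangorn on realistic alignments", {
  set.seed(303)
  tr <- sample_coalescent_tree(assign_tip_ages("four_epoch", 20), theta = 1)
  aln <- simulate_alignment(tr, 0.05, subst_model("JC"), 500)
  ph <- as.phylo(tr)
  ph$edge.length <- ph$edge.length * 0.05
  pd <- phangorn::phyDat(decompress_alignment(aln))
  expect_equal(phylo_log_likelihood(tr, 0.05, subst_model("JC"), aln),
               phangorn::pml(ph, pd)$logLik, tolerance = 1e-8)

  hky <- subst_model("HKY", pi = c(0.3, 0.2, 0.3, 0.2), kappa = 3)
  aln2 <- simulate_alignment(tr, 0.05, hky, 400)
  pd2 <- phangorn::phyDat(decompress_alignment(aln2))
  fit <- phangorn::pml(ph, pd2, bf = hky$pi, Q = c(1, 3, 1, 1, 3, 1))
  expect_equal(phylo_log_likelihood(tr, 0.05, hky, aln2), fit$logLik,
               tolerance = 1e-8)
})

test_that("sampling span fraction quantifies tree extension", {
  # span 0.5 at root height 1000: 0.05% of the height
  deep <- timetree(rbind(c(3, 1), c(3, 2)), c(0, 0.5, 1000), c("a", "b"))
  expect_equal(sampling_span_fraction(deep), 5e-4)
  iso <- timetree(rbind(c(3, 1), c(3, 2)), c(0, 0, 1), c("a", "b"))
  expect_equal(sampling_span_fraction(iso), 0)
  quarter <- timetree(rbind(c(3, 1), c(3, 2)), c(0, 0.5, 2), c("a", "b"))
  expect_equal(sampling_span_fraction(quarter), 0.25)
})
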