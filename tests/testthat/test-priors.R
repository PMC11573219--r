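test_that("constant-size coalescent density matches hand computation", {
  two <- timetree(rbind(c(3, 1), c(3, 2)), c(0, 0, 2), c("a", "b"))
  expect_equal(coalescent_log_density(two, 1), -2)          # -log(1) - 2/1
  expect_equal(coalescent_log_density(two, 2), -log(2) - 1) # -log(2) - 2/2
  expect_error(coalescent_log_density(two, 0), class = "betsig_domain_error")

  # 3-taxon serial tree: intervals computed by hand
  tr <- three_taxon_serial_tree()
  # events: +t1@0, +t3@0.1, +t2@0.3, coal@0.8, coal@1.5
  # k over [0,.1]=1, [.1,.3]=2, [.3,.8]=3, [.8,1.5]=2
  A <- 0 * 0.1 + 1 * 0.2 + 3 * 0.5 + 1 * 0.7
  theta <- 1.7
  expect_equal(coalescent_log_density(tr, theta), -2 * log(theta) - A / theta,
               tolerance = 1e-12)
  # the density maximiser over theta is A / (n - 1)
  opt <- optimize(function(th) coalescent_log_density(tr, th), c(0.01, 10),
                  maximum = TRUE)
  expect_equal(opt$maximum, A / 2, tolerance = 1e-4)
})

test_that("exponential-growth coalescent reduces to and extends the constant case", {
  set.seed(401)
  for (i in 1:100) {
    tr <- sample_coalescent_tree(assign_tip_ages("four_epoch", sample(3:12, 1)),
                                 theta = runif(1, 0.3, 3))
    phi <- runif(1, 0.3, 3)
    expect_equal(exp_growth_log_density(tr, phi, 0),
                 coalescent_log_density(tr, phi), tolerance = 1e-12)
  }

  # 2-tip tree, closed form vs numerical quadrature of the hazard integral
  two <- timetree(rbind(c(3, 1), c(3, 2)), c(0, 0, 1), c("a", "b"))
  for (g in c(1, -0.7, 2.5)) {
    integral <- integrate(function(t) exp(g * t), 0, 1, rel.tol = 1e-12)$value
    expected <- -integral + log(exp(g * 1))  # -int 1/N + log(1/N(t_coal)), phi = 1
    expect_equal(exp_growth_log_density(two, 1, g), expected, tolerance = 1e-9)
    expect_true(is.finite(exp_growth_log_density(two, 1, g)))
  }
})

test_that("CTMC-rate reference prior is a proper Gamma(0.5, L)", {
  for (L in c(1, 10)) {
    expect_equal(ctmc_reference_log_density(0.3, L),
                 dgamma(0.3, shape = 0.5, rate = L, log = TRUE), tolerance = 1e-12)
    Z <- integrate(function(r) exp(Vectorize(ctmc_reference_log_density)(r, L)),
                   0, Inf, rel.tol = 1e-9)$value
    expect_equal(Z, 1, tolerance = 1e-6)
    mu <- integrate(function(r) r * dgamma(r, 0.5, rate = L), 0, Inf)$value
    expect_equal(mu, 0.5 / L, tolerance = 1e-5)  # mean 0.5 / tree length
  }
  expect_error(ctmc_reference_log_density(-1, 1), class = "betsig_domain_error")
})

test_that("population-size hyperpriors are proper with the stated parameters", {
  # quadrature in log space between extreme quantiles; the Gamma(0.001)
  # prior keeps appreciable mass below the smallest representable double,
  # so its window is the representable support and the target mass is the
  # corresponding distribution-function difference
  windows <- list(
    exponential = c(qexp(1e-6), qexp(1 - 1e-6), 1 - 2e-6),
    lognormal = c(qlnorm(1e-6, 1, 5), qlnorm(1 - 1e-6, 1, 5), 1 - 2e-6),
    gamma = c(1e-300, qgamma(1 - 1e-8, 0.001, scale = 1000),
              pgamma(qgamma(1 - 1e-8, 0.001, scale = 1000), 0.001, scale = 1000) -
                pgamma(1e-300, 0.001, scale = 1000))
  )
  for (w in names(windows)) {
    win <- windows[[w]]
    Z <- integrate(function(u) exp(hyperprior_log_density(exp(u), w) + u),
                   log(win[1]), log(win[2]), subdivisions = 5000L,
                   rel.tol = 1e-7)$value
    expect_equal(Z, win[3], tolerance = 1e-3)
  }
  expect_equal(hyperprior_log_density(2, "exponential"), -2)
  # lognormal(mu=1, sigma=5): median exp(1)
  med <- exp(1)
  expect_equal(exp(hyperprior_log_density(med, "lognormal")),
               dlnorm(med, 1, 5), tolerance = 1e-12)
  expect_equal(qlnorm(0.5, 1, 5), exp(1))
  # gamma(0.001, scale 1000): quadrature mean 1
  mu <- integrate(function(x) x * dgamma(x, 0.001, scale = 1000), 0, Inf)$value
  expect_equal(mu, 1, tolerance = 1e-6)
})

test_that("root-height bound contributes a proper uniform factor", {
  expect_equal(root_bound_log_density(2, 5), -log(5))
  expect_identical(root_bound_log_density(6, 5), -Inf)
  expect_identical(root_bound_log_density(2, NULL), 0)
})

test_that("joint log prior sums its terms exactly", {
  set.seed(402)
  ages <- setNames(assign_tip_ages("four_epoch", 8), paste0("t", 1:8))
  tree <- sample_coalescent_tree(ages, theta = 1)
  L <- tree_summaries(tree)$tree_length

  spec <- model_spec("strict", "heterochronous", theta_prior = "exponential",
                     root_bound = 50)
  st <- list(tree = tree, theta = 0.8, rate = 0.07)
  expect_equal(
    joint_log_prior(st, spec),
    coalescent_log_density(tree, 0.8) + dexp(0.8, 1, log = TRUE) +
      ctmc_reference_log_density(0.07, L) - log(50),
    tolerance = 1e-12
  )
  # bound violation kills the density
  spec_tight <- model_spec("strict", "heterochronous", theta_prior = "exponential",
                           root_bound = max(tree$ages) / 2)
  expect_identical(joint_log_prior(st, spec_tight), -Inf)

  # relaxed clock, isochronous: no CTMC term, UCLN terms present
  iso <- sample_coalescent_tree(rep(0, 8), theta = 1)
  iso$tip.label <- paste0("t", 1:8)
  spec2 <- model_spec("ucln", "isochronous", theta_prior = "gamma", fixed_rate = 0.05)
  br <- sample_branch_rates(clock_model("ucln", mean = 0.05, sd = 0.3), iso)
  br[is.na(br)] <- 0.05
  st2 <- list(tree = iso, theta = 2, ucln_mean = 0.05, ucln_sd = 0.3,
              branch_rates = br)
  nonroot <- setdiff(seq_len(15), 9)
  expect_equal(
    joint_log_prior(st2, spec2),
    coalescent_log_density(iso, 2) + dgamma(2, 0.001, scale = 1000, log = TRUE) +
      dexp(0.3, 1 / 0.33, log = TRUE) +
      sum(dlnorm(br[nonroot], log(0.05) - 0.3^2 / 2, 0.3, log = TRUE)),
    tolerance = 1e-12
  )
})
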