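test_that("isochronous coalescent matches Kingman expectations", {
  set.seed(201)
  tm2 <- replicate(4000, max(sample_coalescent_tree(rep(0, 2), theta = 1)$ages))
  se2 <- sd(tm2) / sqrt(length(tm2))
  expect_lt(abs(mean(tm2) - 1), 3 * se2)

  tm10 <- replicate(3000, max(sample_coalescent_tree(rep(0, 10), theta = 1)$ages))
  se10 <- sd(tm10) / sqrt(length(tm10))
  expect_lt(abs(mean(tm10) - 2 * (1 - 1 / 10)), 3 * se10)
})

test_that("tip-age schemes follow their distributions", {
  expect_equal(assign_tip_ages("isochronous", 5), rep(0, 5))
  set.seed(202)
  ages <- assign_tip_ages("four_epoch", 10000)
  freq <- table(factor(ages, levels = c(0, 0.10, 0.35, 0.50))) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))
  ee <- assign_tip_ages("exponential", 10000, mean = 10)
  # shifted so the youngest is 0; with 1e4 draws the shift is ~mean/1e4
  expect_lt(abs(mean(ee) - 10), 3 * 10 / sqrt(10000) + 0.01)
})

test_that("exponential-growth simulator with g = 0 reduces to constant size", {
  # same seed: identical trees
  set.seed(203)
  t1 <- sample_coalescent_tree(c(0, 0.2, 0.4, 0, 0.1), theta = 2, growth = 0)
  set.seed(203)
  t2 <- sample_coalescent_tree(c(0, 0.2, 0.4, 0, 0.1), theta = 2)
  expect_identical(t1, t2)

  # small positive growth shrinks TMRCA stochastically; KS against g=0 differs,
  # while two independent g=0 batches do not
  set.seed(204)
  a <- replicate(800, max(sample_coalescent_tree(rep(0, 6), theta = 1, growth = 0)$ages))
  b <- replicate(800, max(sample_coalescent_tree(rep(0, 6), theta = 1, growth = 0)$ages))
  g <- replicate(800, max(sample_coalescent_tree(rep(0, 6), theta = 1, growth = 3)$ages))
  expect_gt(stats::ks.test(a, b)$p.value, 0.001)
  expect_lt(stats::ks.test(a, g)$p.value, 1e-6)
  expect_lt(mean(g), mean(a))
})

test_that("branch-rate models have the stated moments", {
  set.seed(205)
  tr <- sample_coalescent_tree(rep(0, 5))
  strict <- sample_branch_rates(clock_model("strict", rate = 0.05), tr)
  expect_true(all(strict[-6] == 0.05))  # root entry is NA
  tiny <- sample_branch_rates(clock_model("ucln", mean = 0.05, sd = 1e-8), tr)
  expect_equal(unname(tiny[-6]), rep(0.05, 8), tolerance = 1e-6)

  big_tr <- sample_coalescent_tree(rep(0, 2001))
  r <- sample_branch_rates(clock_model("ucln", mean = 0.05, sd = 0.25), big_tr)
  r <- r[!is.na(r)]
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 0.05), 3 * se)
})

test_that("sequence simulation follows the substitution process", {
  set.seed(206)
  # (near-)zero branch distances: every column is monomorphic
  tr <- sample_coalescent_tree(rep(0, 6))
  a0 <- simulate_alignment(tr, 1e-12, subst_model("JC"), 200)
  m0 <- decompress_alignment(a0)
  expect_true(all(apply(m0, 2, function(col) length(unique(col)) == 1)))

  # two taxa at JC divergence d: mismatch fraction ~ (3/4)(1 - exp(-4d/3))
  two <- timetree(rbind(c(3, 1), c(3, 2)), c(0, 0, 0.5), c("a", "b"))
  d <- 2 * 0.5 * 0.1  # rate 0.1 both branches
  aln <- simulate_alignment(two, 0.1, subst_model("JC"), 20000)
  m <- decompress_alignment(aln)
  p_hat <- mean(m[1, ] != m[2, ])
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  expect_lt(abs(p_hat - p_exp), 3.5 * sqrt(p_exp * (1 - p_exp) / 20000))
})

test_that("the study design yields a few hundred unique site patterns", {
  set.seed(207)
  tr <- sample_coalescent_tree(assign_tip_ages("four_epoch", 50), theta = 1)
  aln <- simulate_alignment(tr, 0.05, subst_model("JC"), 1000)
  expect_gt(n_patterns(aln), 120)
  expect_lt(n_patterns(aln), 450)
})

test_that("replicate generation is reproducible and records the truth", {
  r1 <- make_replicates("epoch2x2", clock_model("strict"), "heterochronous",
                        n_reps = 3, seed = 1, n_tips = 10, length = 100)
  r2 <- make_replicates("epoch2x2", clock_model("strict"), "heterochronous",
                        n_reps = 3, seed = 1, n_tips = 10, length = 100)
  expect_identical(r1, r2)
  expect_length(r1, 3)
  expect_true(all(vapply(r1, function(r) max(tip_ages(r$tree)) > 0, logical(1))))
  expect_true(all(vapply(r1, function(r) r$true$rate == 0.05, logical(1))))

  iso <- make_replicates("epoch2x2", clock_model("strict"), "isochronous",
                         n_reps = 2, seed = 2, n_tips = 10, length = 100)
  expect_true(all(vapply(iso, function(r) all(tip_ages(r$tree) == 0), logical(1))))
  expect_true(all(vapply(iso, function(r) all(r$fake_ages %in% c(0, 0.10, 0.35, 0.50)),
                         logical(1))))
})

test_that("the cholera-like design produces old, large-theta trees", {
  ch <- make_replicates("cholera_like", clock_model("strict"), "isochronous",
                        n_reps = 3, seed = 3, length = 500)
  for (r in ch) {
    expect_equal(n_tips(r$tree), 50L)
    expect_equal(r$true$theta, 100)
    h <- max(r$tree$ages)
    expect_gt(h, 30)
    expect_lt(h, 600)
    expect_gt(max(r$fake_ages), 0)
  }
})
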