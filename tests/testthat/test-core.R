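test_that("site-pattern compression is lossless and conserves site counts", {
  # sequences "AC"/"AC": columns A|A and C|C stay distinct
  a <- bets_alignment(rbind(s1 = c("A", "C"), s2 = c("A", "C")))
  expect_equal(n_patterns(a), 2L)
  expect_equal(a$weights, c(1, 1))

  # sequences "AA"/"AA": identical columns merge into one pattern of weight 2
  b <- bets_alignment(rbind(s1 = c("A", "A"), s2 = c("A", "A")))
  expect_equal(n_patterns(b), 1L)
  expect_equal(b$weights, 2)

  set.seed(101)
  for (i in 1:5) {
    m <- random_alignment_matrix(10, 100, missing = if (i > 3) 25 else 0)
    aln <- bets_alignment(m)
    expect_equal(sum(aln$weights), 100)
    expect_equal(column_multiset(decompress_alignment(aln)), column_multiset(m))
  }
})

test_that("FASTA round trip preserves labels and column multiset", {
  set.seed(102)
  m <- random_alignment_matrix(8, 60, missing = 10)
  aln <- bets_alignment(m)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(aln, path)
  back <- read_fasta(path)
  expect_equal(back$tip.label, rownames(m))
  expect_equal(column_multiset(decompress_alignment(back)),
               column_multiset(m))
})

test_that("malformed FASTA input is rejected", {
  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), ragged)
  expect_error(read_fasta(ragged), class = "betsig_format_error")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_fasta(dup), class = "betsig_format_error")
})

test_that("Newick round trips preserve topology and ages", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tr <- read_newick(path)
  expect_equal(max(tr$ages), 2)
  expect_equal(unname(tip_ages(tr)), c(0, 0, 0))

  # serial tree with tip ages {0, 0.5}
  serial <- timetree(rbind(c(3, 1), c(3, 2)), ages = c(0, 0.5, 2),
                     tip_label = c("a", "b"))
  write_newick(serial, path)
  back <- read_newick(path)
  expect_equal(back$ages, serial$ages, tolerance = 1e-9)

  set.seed(103)
  big <- sample_coalescent_tree(assign_tip_ages("four_epoch", 50), theta = 1)
  write_newick(big, path)
  back <- read_newick(path)
  expect_true(ape::all.equal.phylo(as.phylo(big), as.phylo(back),
                                   use.edge.length = FALSE))
  expect_equal(sort(back$ages), sort(big$ages), tolerance = 1e-6)
})

test_that("invalid trees are rejected", {
  # polytomy: three children on one node
  expect_error(
    timetree(rbind(c(4, 1), c(4, 2), c(4, 3)), ages = c(0, 0, 0, 1),
             tip_label = c("a", "b", "c")),
    class = "betsig_tree_error"
  )
  # child older than parent
  expect_error(
    timetree(rbind(c(3, 1), c(3, 2)), ages = c(0, 2, 1), tip_label = c("a", "b")),
    class = "betsig_tree_error"
  )
})

test_that("parse_dates maps times and ages to tip ages", {
  expect_equal(parse_dates(c(x = 2010, y = 1937)), c(x = 0, y = 73))
  expect_equal(unname(parse_dates(c(a = 5, b = 5, c = 5))), c(0, 0, 0))
  # ages dialect: values used as given
  ages <- parse_dates(c(a = 0, b = 0.10, c = 0.35, d = 0.50), dialect = "ages")
  expect_equal(unname(ages), c(0, 0.10, 0.35, 0.50))
  expect_error(parse_dates(c(a = 1), taxa = c("a", "b")),
               class = "betsig_config_error")
})

test_that("tree summaries match independent computation", {
  two <- timetree(rbind(c(3, 1), c(3, 2)), c(0, 0, 1), c("a", "b"))
  s <- tree_summaries(two)
  expect_equal(s$root_height, 1)
  expect_equal(s$tree_length, 2)
  expect_equal(s$sampling_span, 0)

  serial <- timetree(rbind(c(3, 1), c(3, 2)), c(0, 0.5, 2), c("a", "b"))
  expect_equal(tree_summaries(serial)$sampling_span, 0.5)

  set.seed(104)
  tr <- sample_coalescent_tree(assign_tip_ages("four_epoch", 50), theta = 1)
  ph <- as.phylo(tr)
  expect_equal(tree_summaries(tr)$tree_length, sum(ph$edge.length),
               tolerance = 1e-9)
})

test_that("tree length >= root height >= max tip age on random serial trees", {
  set.seed(105)
  for (i in 1:20) {
    ages <- assign_tip_ages(sample(c("four_epoch", "isochronous", "exponential"), 1),
                            n = sample(3:30, 1), mean = 0.5)
    tr <- sample_coalescent_tree(ages, theta = runif(1, 0.2, 3))
    s <- tree_summaries(tr)
    expect_gte(s$tree_length, s$root_height)
    expect_gte(s$root_height, max(tip_ages(tr)))
  }
})

test_that("constant-site augmentation updates the pattern table", {
  # no all-A column present: augmentation adds one pattern of weight 10
  a <- bets_alignment(rbind(s1 = c("G", "C"), s2 = c("G", "C")))
  expect_identical(augment_constant_sites(a, c(0, 0, 0, 0))$weights, a$weights)
  aug <- augment_constant_sites(a, c(10, 0, 0, 0))
  expect_equal(n_patterns(aug), 3L)
  expect_equal(sum(aug$weights), 12)
  # all-A column already present: weight incremented, no new pattern
  b <- bets_alignment(rbind(s1 = "A", s2 = "A"))
  aug2 <- augment_constant_sites(b, c(5, 0, 0, 0))
  expect_equal(n_patterns(aug2), 1L)
  expect_equal(aug2$weights, 6)
})
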