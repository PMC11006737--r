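test_that("simulate_tree yields a scaled, deterministic Yule tree", {
  tr <- simulate_tree(3, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(nrow(tr$edge), 4L)   # 2n - 2 branches for a rooted binary tree
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(simulate_tree(20, seed = 9)),
                   ape::write.tree(simulate_tree(20, seed = 9)))
  expect_error(simulate_tree(2, seed = 1), "at least 3")
  # mean root-to-tip depth is rescaled to 1 (checked by direct traversal)
  tr50 <- simulate_tree(50, seed = 4)
  depths <- ape::node.depth.edgelength(tr50)[1:50]
  expect_gt(mean(depths), 0.8)
  expect_lt(mean(depths), 1.2)
  expect_equal(mean(depths), 1.0, tolerance = 1e-12)
})

test_that("assign_branch_rates has unit mean and degenerates at sigma 0", {
  tr <- simulate_tree(10, seed = 2)
  expect_equal(assign_branch_rates(tr, 0, seed = 1),
               rep(1, nrow(tr$edge)), ignore_attr = TRUE)
  r1 <- assign_branch_rates(tr, 0.5, seed = 3)
  expect_identical(as.numeric(r1),
                   as.numeric(assign_branch_rates(tr, 0.5, seed = 3)))
  # lognormal mean identity, checked on a large sample
  big <- simulate_tree(5001, seed = 5)   # 10^4 branches
  rates <- assign_branch_rates(big, 0.5, seed = 6)
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 1), 3 * se)
})

test_that("correlate_rates hits the target log-rate correlation", {
  big <- simulate_tree(5001, seed = 7)
  ra <- assign_branch_rates(big, 0.5, seed = 8)
  # rho = 1: exact copy
  expect_identical(as.numeric(correlate_rates(ra, 1, 0.5, seed = 9)),
                   as.numeric(ra))
  ga <- attr(ra, "log_rates")
  for (rho in c(0, 0.8)) {
    rb <- correlate_rates(ra, rho, 0.5, seed = 10)
    gb <- attr(rb, "log_rates")
    emp <- cor(ga, gb)
    se <- 1 / sqrt(length(ga) - 3)   # Fisher-scale SE, adequate here
    expect_lt(abs(atanh(emp) - atanh(rho)), 3 * se)
    # unit-mean multipliers preserved
    expect_lt(abs(mean(rb) - 1), 3 * sd(rb) / sqrt(length(rb)))
  }
  expect_error(correlate_rates(ra, 1.2, 0.5, seed = 1), "rho")
})

test_that("evolve_sequences is deterministic and copies under zero length", {
  tr <- simulate_tree(6, seed = 12)
  a1 <- evolve_sequences(tr, length = 200, seed = 13)
  a2 <- evolve_sequences(tr, length = 200, seed = 13)
  expect_identical(a1$seqs, a2$seqs)
  expect_s3_class(a1, "coev_alignment")
  expect_equal(a1$length, 200L)
  expect_equal(a1$species, sort(tr$tip.label))
  # all-zero branch lengths: every tip identical to the root draw
  tr0 <- tr
  tr0$edge.length[] <- 0
  a0 <- evolve_sequences(tr0, length = 50, seed = 14)
  expect_equal(length(unique(a0$seqs)), 1L)
})

test_that("evolved p-distance matches the uniform-exchange expectation", {
  # two tips joined by a total path of 0.4 expected events per site
  tr <- ape::read.tree(text = "(tip_a:0.15,tip_b:0.25);")
  aln <- evolve_sequences(tr, length = 2e4, seed = 15)
  d <- as.numeric(p_distance(aln$seqs[["tip_a"]], aln$seqs[["tip_b"]]))
  expected <- expected_p_distance(0.4)
  se <- sqrt(expected * (1 - expected) / 2e4)
  expect_lt(abs(d - expected), 3 * se)
})

test_that("make_coevolving_pair wires tree, rates and alignments together", {
  pair <- make_coevolving_pair(8, length = 150, sigma = 0.5, rho = 1,
                               seed = 21, length_b = 100)
  expect_s3_class(pair, "simulated_pair")
  expect_identical(as.numeric(pair$rates_a), as.numeric(pair$rates_b))
  expect_equal(pair$alignment_a$species, pair$alignment_b$species)
  expect_equal(common_species(pair$alignment_a, pair$alignment_b),
               sort(pair$tree$tip.label))
  expect_equal(pair$alignment_a$length, 150L)
  expect_equal(pair$alignment_b$length, 100L)
  # full determinism of the master seed
  twin <- make_coevolving_pair(8, length = 150, sigma = 0.5, rho = 1,
                               seed = 21, length_b = 100)
  expect_identical(pair$alignment_a$seqs, twin$alignment_a$seqs)
  expect_identical(pair$alignment_b$seqs, twin$alignment_b$seqs)
  # sigma = 0: both families evolve at identical unit rates
  flat <- make_coevolving_pair(8, length = 150, sigma = 0, rho = 1,
                               seed = 22)
  expect_equal(as.numeric(flat$rates_a), rep(1, nrow(flat$tree$edge)))
})

test_that("mirror-tree correlation trends upward with rho", {
  r_at <- function(rho, seed) {
    p <- make_coevolving_pair(20, length = 600, sigma = 0.5, rho = rho,
                              seed = seed)
    mirror_tree(p$alignment_a, p$alignment_b)$r_ab
  }
  rhos <- c(0, 0.5, 1)
  for (seed in c(101, 202)) {
    rs <- vapply(rhos, r_at, 0, seed = seed)
    expect_gt(cor(rhos, rs, method = "spearman"), 0)
  }
})

test_that("a shared tree inflates rho=0 correlations above independent trees", {
  shared <- make_coevolving_pair(20, length = 800, sigma = 0.5, rho = 0,
                                 seed = 31)
  r_shared <- mirror_tree(shared$alignment_a, shared$alignment_b)$r_ab
  other <- make_coevolving_pair(20, length = 800, sigma = 0.5, rho = 0,
                                seed = 32)
  # same species labels, but families evolved on two unrelated phylogenies
  r_indep <- mirror_tree(shared$alignment_a, other$alignment_b)$r_ab
  expect_gt(r_shared, r_indep)
  expect_gt(r_shared, 0.5)   # the confound is large, not marginal
})

test_that("simulated pairs export to newick and FASTA", {
  pair <- make_coevolving_pair(6, length = 80, sigma = 0.3, rho = 0.5,
                               seed = 41)
  dir <- tempfile()
  paths <- export_simulated_pair(pair, dir)
  expect_true(all(file.exists(paths)))
  tr <- ape::read.tree(paths[["tree"]])
  expect_setequal(tr$tip.label, pair$tree$tip.label)
  back <- read_fasta(paths[["family_a"]])
  expect_warning(validate_alignment(back), NA)
  expect_equal(sort(back$residues), sort(unname(pair$alignment_a$seqs)))
})
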