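test_that("zero-branch simulation returns identical sequences for every seed", {
  for (s in c(1, 17, 202)) {
    p <- simulate_codon_pair(simulation_config(60, branch_length = 0, seed = s))
    expect_identical(p$seq_a, p$seq_b)
  }
})

test_that("omega = 0 simulation never produces nonsynonymous differences", {
  for (s in 1:5) {
    p <- simulate_codon_pair(simulation_config(
      150, omega_true = 0, branch_length = 0.8, seed = s))
    expect_identical(translate_codons(p$seq_a), translate_codons(p$seq_b))
  }
})

test_that("simulated pairs are deterministic given the seed and leave the RNG alone", {
  set.seed(99)
  before <- .Random.seed
  p1 <- simulate_codon_pair(simulation_config(50, seed = 5))
  expect_identical(.Random.seed, before)
  p2 <- simulate_codon_pair(simulation_config(50, seed = 5))
  expect_identical(p1, p2)
  p3 <- simulate_codon_pair(simulation_config(50, seed = 6))
  expect_false(identical(p2$seq_b, p3$seq_b))
})

test_that("simulator rejects invalid configurations", {
  expect_error(simulation_config(0), "length_codons")
  expect_error(simulation_config(10, kappa = -1), "kappa")
  expect_error(simulation_config(10, omega_true = -0.1), "omega")
  expect_error(simulation_config(10, branch_length = -1), "branch_length")
})

test_that("simulated sequences contain no stop codons", {
  p <- simulate_codon_pair(simulation_config(
    200, omega_true = 1, branch_length = 1.5, seed = 11))
  expect_false("*" %in% translate_codons(p$seq_a))
  expect_false("*" %in% translate_codons(p$seq_b))
})

test_that("pool tag counts are exact and omega laws hit their means", {
  pool <- simulate_ortholog_pool(10, tag_fraction = 0.5, seed = 1)
  expect_identical(sum(pool_has_tag(pool, "Galpha")), 5L)
  for (case in list(c(9, 1 / 3, 3), c(100, 0.13, 13))) {
    p <- simulate_ortholog_pool(case[1], tag_fraction = case[2], seed = 2)
    expect_identical(sum(pool_has_tag(p, "Galpha")), as.integer(case[3]))
  }
  pt <- simulate_ortholog_pool(50, omega_law("point", mean = 0.1), seed = 3)
  expect_equal(mean(pt$omega), 0.1)
  expect_error(simulate_ortholog_pool(0), "n_pairs")
})

test_that("gamma pool sample mean sits within 3 SE of the law mean", {
  law <- omega_law("gamma", mean = 0.14, shape = 0.6)
  pool <- simulate_ortholog_pool(5666, law, seed = 42)
  se <- (law$mean / sqrt(law$shape)) / sqrt(5666)  # analytic sd / sqrt(n)
  expect_lt(abs(mean(pool$omega) - 0.14), 3 * se)
  expect_true(all(pool$omega >= 0))
  expect_false(anyDuplicated(pool$pair_id) > 0)
})

test_that("random graphs are simple, seeded, and match model expectations", {
  g1 <- simulate_network(1, "erdos_renyi", 0.5, seed = 1)
  expect_identical(nrow(g1$edges), 0L)
  full <- simulate_network(4, "erdos_renyi", 1, seed = 1)
  expect_identical(nrow(full$edges), 6L)
  expect_error(simulate_network(5, "no_such_model"), "arg")
  expect_identical(simulate_network(10, "erdos_renyi", 0.3, seed = 9),
                   simulate_network(10, "erdos_renyi", 0.3, seed = 9))
  tc <- simulate_network(12, "tree_plus_chords", 3, seed = 4)
  expect_identical(nrow(tc$edges), 14L)  # 11 tree edges + 3 chords
})

test_that("Erdos-Renyi edge counts match the binomial expectation", {
  p <- 2 / 15
  counts <- vapply(1:1000, function(s)
    nrow(simulate_network(16, "erdos_renyi", p, seed = s)$edges), numeric(1))
  se <- sqrt(choose(16, 2) * p * (1 - p)) / sqrt(1000)
  expect_lt(abs(mean(counts) - choose(16, 2) * p), 3 * se)
})

test_that("the odor fixture reproduces the published chemotaxis table verbatim", {
  fx <- make_odor_fixture()
  expect_identical(length(fx$network$nodes), 16L)
  expect_identical(unname(fx$categories[c("goa-1", "egl-30", "dgk-1", "eat-4")]),
                   rep("actuator", 4))
  chem <- fx$chemotaxis
  get_diff <- function(g, n, a = "odortaxis")
    chem$ci_diff[chem$gene == g & chem$neuron == n & chem$assay == a]
  # wildtype references
  expect_identical(unname(wildtype_ci()), c(0.9, -0.95, 0.85))
  expect_identical(get_diff("wildtype", "AWA", "LTA"), 0.5)
  expect_identical(get_diff("wildtype", "AWC", "LTA"), 0.65)
  # every published mutant value
  published <- list(
    `odr-3` = c(AWA = 0.6, AWB = -0.7, AWC = 0.5),
    `rgs-3` = c(AWC = 0.85),
    `daf-11` = c(AWB = 0.6, AWC = 0.5),
    `dgk-1` = c(AWC = 0),
    `eat-4` = c(AWC = 0.55),
    `egl-30` = c(AWC = 0.65),
    `goa-1` = c(AWA = 0.6, AWC = 0.6),
    `odr-1` = c(AWA = 0, AWC = 0.85),
    `tax-2` = c(AWA = 0.2, AWB = -0.8, AWC = 0.75),
    `tax-4` = c(AWA = 0.5, AWC = 0.75),
    `egl-4` = c(AWA = 0.8, AWC = 0.65))
  for (g in names(published)) for (n in names(published[[g]]))
    expect_identical(get_diff(g, n), unname(published[[g]][n]))
  # absent assays are absent records, not zeros
  expect_identical(sum(chem$gene %in%
                         c("gpa-3", "gpa-5", "gpa-13", "arr-1", "tax-6")), 0L)
})
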