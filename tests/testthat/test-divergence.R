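test_that("both estimators return exactly 0/0 on identical sequences", {
  p <- codon_pair("ATGAAACCTGGG", "ATGAAACCTGGG")
  for (est in list(estimate_ng86(p), estimate_yn00(p))) {
    expect_identical(est$dN, 0)
    expect_identical(est$dS, 0)
  }
})

test_that("a single synonymous difference is counted as Sd = 1, Nd = 0", {
  est <- estimate_ng86(codon_pair("TTTGGG", "TTCGGG"))
  expect_identical(est$Sd, 1)
  expect_identical(est$Nd, 0)
  expect_identical(est$dN, 0)
  longer <- estimate_ng86(codon_pair("TTTGGGAAACCC", "TTCGGGAAACCC"))
  expect_identical(longer$Sd, 1)
  expect_identical(longer$Nd, 0)
  expect_gt(longer$dS, 0)
})

test_that("a nonsynonymous-only pair flags omega as undefined", {
  est <- estimate_ng86(codon_pair("TTTGGG", "GTTGGG"))
  expect_identical(est$Sd, 0)
  expect_gt(est$Nd, 0)
  expect_true(is.na(est$omega))
  expect_true("undefined_omega" %in% est$flags)
})

test_that("NG86 site counts sum to 3n exactly", {
  for (s in 1:5) {
    L <- sample(20:80, 1)
    p <- simulate_codon_pair(simulation_config(L, branch_length = 0.4,
                                               seed = s))
    est <- estimate_ng86(p)
    expect_equal(est$S_sites + est$N_sites, 3 * L)
  }
})

test_that("estimates are symmetric under sequence exchange", {
  for (s in 1:4) {
    p <- simulate_codon_pair(simulation_config(120, branch_length = 0.5,
                                               seed = s))
    rev <- codon_pair(p$seq_b, p$seq_a)
    for (fn in list(estimate_ng86, estimate_yn00)) {
      a <- fn(p); b <- fn(rev)
      expect_equal(a$dN, b$dN)
      expect_equal(a$dS, b$dS)
    }
  }
})

test_that("omega = 0 simulations yield (near-)zero dN under both estimators", {
  # Path-averaged counting can assign a fractional nonsynonymous difference
  # to a purely synonymous multi-position codon change (e.g. the serine
  # TCN/AGY classes), so NG86's dN is bounded near zero rather than exactly
  # zero; YN00's omega-weighted paths drive it to zero.
  for (s in 1:3) {
    p <- simulate_codon_pair(simulation_config(
      150, omega_true = 0, branch_length = 0.6, seed = s))
    expect_lt(estimate_ng86(p)$dN, 0.01)
    expect_equal(estimate_yn00(p)$dN, 0, tolerance = 1e-6)
  }
})

test_that("YN00 and NG86 agree strongly across simulated pairs", {
  ests <- t(vapply(1:60, function(s) {
    p <- simulate_codon_pair(simulation_config(
      200, omega_true = 0.2, branch_length = 0.4, seed = s))
    c(ng = estimate_ng86(p)$omega, yn = estimate_yn00(p)$omega)
  }, numeric(2)))
  expect_gt(spearman(ests[, "ng"], ests[, "yn"])$estimate, 0.9)
})

test_that("kappa estimation responds to the simulated ts/tv bias", {
  kap <- vapply(1:30, function(s) c(
    k1 = estimate_yn00(simulate_codon_pair(simulation_config(
      200, kappa = 1, branch_length = 0.4, seed = s)))$kappa_hat,
    k5 = estimate_yn00(simulate_codon_pair(simulation_config(
      200, kappa = 5, branch_length = 0.4, seed = s)))$kappa_hat),
    numeric(2))
  expect_gt(mean(kap["k5", ]), mean(kap["k1", ]))
})

test_that("network_mean_omega averages defined values and flags exclusions", {
  expect_identical(network_mean_omega(0.1), 0.1)
  expect_equal(network_mean_omega(c(0.0041, 0.0054)), 0.00475)
  expect_equal(network_mean_omega(rep(0.3, 16)), 0.3)
  expect_message(m <- network_mean_omega(c(0.1, NA, 0.3)), "excluded")
  expect_equal(m, 0.2)
  expect_error(network_mean_omega(c(NA_real_, NA_real_)), "undefined")
  expect_error(network_mean_omega(numeric(0)), "no estimates")
})

test_that("divergence_table carries pair ids, estimates and flags", {
  ests <- list(a = estimate_ng86(codon_pair("TTTGGG", "TTCGGG")),
               b = estimate_yn00(codon_pair("ATGAAA", "ATGAAA")))
  tab <- divergence_table(ests)
  expect_identical(tab$pair_id, c("a", "b"))
  expect_identical(tab$method, c("NG86", "YN00"))
  expect_identical(tab$dS[2], 0)
})
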