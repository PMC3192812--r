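test_that("simulation is deterministic given a seed and validates inputs", {
  net <- default_net("I")
  t1 <- simulate_pathway(net, seq(0, 600, 60), seed = 11)
  t2 <- simulate_pathway(net, seq(0, 600, 60), seed = 11)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$occ_post, t2$occ_post)
  t3 <- simulate_pathway(net, seq(0, 600, 60), seed = 12)
  expect_false(identical(t1$counts, t3$counts))
  expect_error(simulate_pathway(net, c(0, 0, 60)), "strictly increasing")
  expect_error(simulate_pathway(net, c(-10, 60)), "non-negative")
})

test_that("ensemble mean of one run equals the trajectory and is reproducible", {
  net <- default_net("I")
  ens1 <- ensemble_mean(net, seq(0, 600, 60), n_runs = 1, base_seed = 5)
  tr <- simulate_pathway(net, seq(0, 600, 60), seed = 5)
  expect_equal(ens1$mean, tr$counts)
  expect_true(all(ens1$var == 0))
  e1 <- ensemble_mean(net, seq(0, 600, 60), n_runs = 20, base_seed = 5)
  e2 <- ensemble_mean(net, seq(0, 600, 60), n_runs = 20, base_seed = 5)
  expect_identical(e1$mean, e2$mean)
  expect_true(all(e1$var >= 0))
})

test_that("nothing splices while splicing is inactive (k_on = 0)", {
  r <- do.call(rate_set, utils::modifyList(unclass(default_rates()),
                                           list(k_on = 0)))
  net <- build_pathway(pathway_variant("I"), gene_geometry(), r)
  tr <- simulate_pathway(net, seq(0, 900, 90), seed = 3)
  expect_true(all(tr$counts[, c("U_lar", "P_lar", "U_mRNA", "P_mRNA",
                                "lariat")] == 0))
  # pre-mRNA forms do appear (the burst) but initiation stops at the budget
  expect_lte(max(tr$counts[, "cum_init"]), default_rates()$n_burst)
  expect_gt(max(tr$counts[, "U_pre"] + tr$counts[, "P_pre"]), 0)
})

test_that("ss5 mutant never produces lariat or mRNA species", {
  net <- default_net("I", mutant = "ss5")
  tr <- simulate_pathway(net, seq(0, 900, 90), seed = 4)
  expect_true(all(tr$counts[, c("U_lar", "P_lar", "U_mRNA", "P_mRNA",
                                "lariat")] == 0))
  expect_gt(max(tr$counts[, "P_pre"]), 0)
})

test_that("exclusion and conservation audits hold across pathways and seeds", {
  for (pw in c("I", "V", "VIII")) {
    for (seed in 1:3) {
      net <- default_net(pw)
      tr <- simulate_pathway(net, seq(0, 900, 45), seed = seed, audit = TRUE)
      expect_true(tr$audit$exclusion_ok, info = paste(pw, seed))
      expect_true(tr$audit$conservation_ok, info = paste(pw, seed))
      cts <- tr$counts
      inflight <- cts[, "pol_post"] + cts[, "pol_co"] + cts[, "apc"]
      exits <- cts[, "cum_post_exit"] + cts[, "cum_co_exit"]
      expect_equal(unname(cts[, "cum_init"]), unname(exits + inflight))
      released <- rowSums(cts[, c("U_pre", "P_pre", "U_lar", "P_lar",
                                  "U_mRNA", "P_mRNA", "deg_pre", "deg_lar",
                                  "deg_mrna")])
      expect_equal(unname(exits), unname(released))
      # no section ever carries two polymerases (indicator matrices disjoint)
      expect_true(all(tr$occ_post + tr$occ_co <= 1L))
    }
  }
})

test_that("feedback enzyme count never decreases along a run", {
  net <- default_net("I")
  tr <- simulate_pathway(net, seq(0, 900, 30), seed = 6)
  expect_true(all(diff(tr$counts[, "y_co2"]) >= 0))
  expect_true(all(tr$counts[, "y_co2"] >= 1))
})

test_that("a single-species sink decays exponentially in the ensemble mean", {
  # burst of transcripts released as uncleaved pre-mRNA with maturation off:
  # the pool then only degrades, at first order with rate d
  d <- 0.01
  r <- rate_set(k_init = 5, k_elong = 20, k_on = 0, c1 = 0, d_ppre = d,
                t_act = 0, n_burst = 15L)
  net <- build_pathway(pathway_variant("I"), gene_geometry(), r)
  times <- c(0, 150, 300, 450, 600)
  ens <- ensemble_mean(net, times, n_runs = 400, base_seed = 9)
  upre <- ens$mean[, "U_pre"]
  # loading is fast (~15 s); compare decay from the 150 s snapshot onward
  expected <- upre[2] * exp(-d * (times[-(1:2)] - times[2]))
  mc_se <- sqrt(ens$var[-(1:2), "U_pre"] / ens$n_runs)
  expect_true(all(abs(upre[-(1:2)] - expected) < 4 * mc_se + 0.05))
})

test_that("single-polymerase exit fraction matches the closed form across eta", {
  n <- 3e4
  for (eta in c(0.5, 2, 11.39, 30)) {
    p <- p_post(eta, 25)
    frac <- single_pol_exit_fraction(gene_geometry(), eta = eta,
                                     n_walkers = n, seed = 21)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(frac - p), 3 * se + 1e-12)
  }
})

test_that("exit fraction is invariant to the elongation rate", {
  f1 <- single_pol_exit_fraction(gene_geometry(), k_elong = 1, eta = 11.39,
                                 n_walkers = 3e4, seed = 33)
  f10 <- single_pol_exit_fraction(gene_geometry(), k_elong = 10, eta = 11.39,
                                  n_walkers = 3e4, seed = 34)
  se <- sqrt(0.122 * 0.878 / 3e4)
  expect_lt(abs(f1 - f10), 4 * se)
  # and vanishes when the transition dominates
  expect_lt(single_pol_exit_fraction(gene_geometry(), eta = 1e-6,
                                     n_walkers = 1000, seed = 35), 1e-3)
})
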