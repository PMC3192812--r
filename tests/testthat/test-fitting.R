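test_that("error_E is the RMSE over all points and series", {
  sim <- toy_timeseries(c(3, 4))
  obs <- toy_timeseries(c(0, 0))
  expect_equal(error_E(sim, obs), sqrt(25 / 2))
  expect_equal(error_E(sim, sim), 0)
  # homogeneity: scaling all residuals by c scales E by |c|
  sim2 <- sim; sim2$value <- 3 * sim2$value
  obs2 <- obs
  expect_equal(error_E(sim2, obs2), 3 * error_E(sim, obs))
})

test_that("replicates are averaged before the error is computed", {
  obs <- rbind(toy_timeseries(c(0, 0), replicate = 1),
               toy_timeseries(c(2, 2), replicate = 2))
  sim <- toy_timeseries(c(1, 1))
  expect_equal(error_E(sim, obs), 0)
})

test_that("key mismatches are reported", {
  sim <- toy_timeseries(c(1, 2, 3))
  obs <- toy_timeseries(c(1, 2))
  expect_error(error_E(sim, obs), "missing keys")
})

test_that("proposals stay within bounds, are centred, and reflect", {
  lower <- list(p = 0); upper <- list(p = 10)
  set.seed(1)
  props <- replicate(5000, propose_params(c(p = 5), lower, upper, 0.2)[["p"]])
  expect_true(all(props >= 0 & props <= 10))
  expect_lt(abs(mean(props) - 5), 0.1)
  # zero step size is the identity
  expect_equal(propose_params(c(p = 5), lower, upper, 0)[["p"]], 5)
  # from the upper bound, any positive draw reflects back inside
  set.seed(2)
  at_max <- replicate(200, propose_params(c(p = 10), lower, upper, 0.1)[["p"]])
  expect_true(all(at_max <= 10))
})

test_that("annealing validates inputs and honours its contracts", {
  spec <- synth_spec(sample_times = seq(0, 900, 180),
                     truth_ensemble_runs = 20, seed = 3)
  gen <- generate_synthetic(spec)
  v <- pathway_variant("I")
  g <- gene_geometry()
  sa <- sa_config(n_stages = 2L, iters_per_stage = 3L,
                  ensemble_runs_per_eval = 5L, final_ensemble_runs = 5L,
                  seed = 42L)
  expect_error(
    anneal(v, g, default_rates(), gen$data, "eta",
           lower = list(eta = 20), upper = list(eta = 50), sa = sa),
    "outside bounds")
  expect_error(
    anneal(v, g, default_rates(), gen$data, "not_a_rate",
           lower = list(not_a_rate = 0), upper = list(not_a_rate = 1), sa = sa),
    "not optimisable")

  fit1 <- anneal(v, g, default_rates(), gen$data, "eta",
                 lower = list(eta = 1), upper = list(eta = 50), sa = sa)
  fit2 <- anneal(v, g, default_rates(), gen$data, "eta",
                 lower = list(eta = 1), upper = list(eta = 50), sa = sa)
  # determinism: identical seeds give identical results
  expect_identical(fit1$fitted, fit2$fitted)
  expect_identical(fit1$E, fit2$E)
  expect_equal(fit1$k_params, 1L)
  expect_true(all(c("rss", "n") %in% names(fit1$per_series)))
  expect_equal(sum(fit1$per_series$n), fit1$n_points)
})

test_that("with zero step size the error trace is constant (fixed point)", {
  spec <- synth_spec(sample_times = seq(0, 900, 300),
                     truth_ensemble_runs = 10, seed = 4)
  gen <- generate_synthetic(spec)
  sa <- sa_config(n_stages = 2L, iters_per_stage = 4L, step_scale = 0,
                  ensemble_runs_per_eval = 5L, final_ensemble_runs = 5L,
                  seed = 1L)
  fit <- anneal(pathway_variant("I"), gene_geometry(), default_rates(),
                gen$data, "eta", lower = list(eta = 1),
                upper = list(eta = 50), sa = sa)
  expect_equal(length(unique(fit$trace$E)), 1L)
  expect_equal(unname(fit$fitted["eta"]), default_rates()$eta)
})

test_that("best-ever error never increases along the trace", {
  spec <- synth_spec(sample_times = seq(0, 900, 180),
                     truth_ensemble_runs = 10, seed = 5)
  gen <- generate_synthetic(spec)
  sa <- sa_config(n_stages = 3L, iters_per_stage = 5L,
                  ensemble_runs_per_eval = 5L, final_ensemble_runs = 5L,
                  seed = 9L)
  fit <- anneal(pathway_variant("I"), gene_geometry(), default_rates(),
                gen$data, "eta", lower = list(eta = 1),
                upper = list(eta = 50), sa = sa)
  acc <- fit$trace$E
  acc[!fit$trace$accepted] <- NA
  running_best <- cummin(ifelse(is.na(acc), Inf, acc))
  expect_true(all(diff(running_best[is.finite(running_best)]) <= 0))
  expect_lte(fit$E_search, min(fit$trace$E[fit$trace$accepted], na.rm = TRUE))
})
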