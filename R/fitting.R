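## Simulated-annealing parameter estimation against multi-series time courses.

#' Simulated-annealing configuration
#'
#' @param T0 Initial temperature.
#' @param alpha Geometric cooling factor per stage (0 < alpha < 1).
#' @param iters_per_stage Proposals evaluated at each temperature.
#' @param n_stages Number of cooling stages.
#' @param step_scale Proposal step as a fraction of each parameter's bound
#'   range: `p' = p + N(0,1) * step_scale * (p_max - p_min)`, reflected at the
#'   bounds. Constant across stages.
#' @param scale_rule How the Metropolis scale constant `k` is set from the
#'   initial error `E0`; `"inverse_E0"` gives `k = 1/E0`, so a worsening of
#'   size `E0` at `T = T0 = 1` is accepted with probability `exp(-1)`.
#' @param ensemble_runs_per_eval Runs per objective evaluation (common random
#'   numbers make the objective deterministic).
#' @param final_ensemble_runs Runs used for the final reported error.
#' @param seed Seed controlling proposals, acceptances and the common random
#'   numbers of the objective.
#' @return An object of class `"sa_config"`.
#' @export
sa_config <- function(T0 = 1, alpha = 0.9, iters_per_stage = 50L,
                      n_stages = 40L, step_scale = 0.1,
                      scale_rule = c("inverse_E0", "unit"),
                      ensemble_runs_per_eval = 100L,
                      final_ensemble_runs = 500L,
                      seed = 1L) {
  scale_rule <- match.arg(scale_rule)
  stopifnot(alpha > 0, alpha < 1, iters_per_stage >= 1, n_stages >= 1,
            T0 > 0, step_scale >= 0)
  structure(list(T0 = T0, alpha = alpha,
                 iters_per_stage = as.integer(iters_per_stage),
                 n_stages = as.integer(n_stages),
                 step_scale = step_scale, scale_rule = scale_rule,
                 ensemble_runs_per_eval = as.integer(ensemble_runs_per_eval),
                 final_ensemble_runs = as.integer(final_ensemble_runs),
                 seed = as.integer(seed)),
            class = "sa_config")
}

## internal: average data replicates to one value per (experiment, species, time)
average_replicates <- function(data) {
  stats::aggregate(value ~ experiment + species + time_s, data = data,
                   FUN = mean)
}

#' Root-mean-square error between simulated and observed series
#'
#' `E = sqrt( sum (S - D)^2 / (n * d) )` over all `n` time points and `d`
#' series; replicates in `data` are averaged first. The simulated and observed
#' series must cover identical `(experiment, species, time_s)` keys.
#'
#' @param sim Simulated series (`timeseries_data` layout, one value per key).
#' @param data Observed series (may contain replicates).
#' @return Non-negative scalar error.
#' @export
error_E <- function(sim, data) {
  d <- average_replicates(data)
  s <- average_replicates(sim)
  key <- function(x) paste(x$experiment, x$species, x$time_s, sep = "\r")
  mis_d <- setdiff(key(d), key(s))
  mis_s <- setdiff(key(s), key(d))
  if (length(mis_d) || length(mis_s)) {
    stop("sim/data key mismatch; missing keys: ",
         paste(utils::head(gsub("\r", "/", c(mis_d, mis_s)), 5L),
               collapse = ", "))
  }
  mrg <- merge(s, d, by = c("experiment", "species", "time_s"),
               suffixes = c(".sim", ".obs"))
  sqrt(mean((mrg$value.sim - mrg$value.obs)^2))
}

#' Gaussian proposal with reflection at the bounds
#'
#' Each parameter moves by `N(0,1) * step_scale * (upper - lower)` and is
#' reflected at its bounds so the proposal stays inside `[lower, upper]`.
#' Uses the current R RNG stream.
#'
#' @param params Named numeric vector of current values (within bounds).
#' @param lower,upper Named bounds (same names as `params`).
#' @param step_scale Step size as a fraction of the bound range.
#' @return Named numeric vector of proposed values.
#' @export
propose_params <- function(params, lower, upper, step_scale) {
  stopifnot(all(names(params) %in% names(lower)),
            all(names(params) %in% names(upper)))
  out <- params
  for (nm in names(params)) {
    lo <- lower[[nm]]; hi <- upper[[nm]]
    p <- params[[nm]] + stats::rnorm(1) * step_scale * (hi - lo)
    # reflect into [lo, hi]
    if (hi > lo) {
      span <- hi - lo
      p <- (p - lo) %% (2 * span)
      if (p > span) p <- 2 * span - p
      p <- p + lo
    } else {
      p <- lo
    }
    out[[nm]] <- p
  }
  out
}

## internal: deterministic objective via common random numbers.
## The reaction table of the template network is rate-independent apart from
## the rate column, which the engine does not read, so only the rate set is
## swapped per evaluation.
make_objective <- function(variant, geometry, rates, data, sa) {
  times <- sort(unique(data$time_s))
  eval_seed <- sa$seed + 10000L
  template <- build_pathway(variant, geometry, rates)
  function(theta, n_runs = sa$ensemble_runs_per_eval, keep_series = FALSE) {
    r <- do.call(rate_set, utils::modifyList(unclass(rates), as.list(theta)))
    validate_variant_rates(variant, r)
    net <- template
    net$rates <- r
    ens <- ensemble_mean(net, times, n_runs = n_runs, base_seed = eval_seed)
    sim <- observe(ens, geometry)
    sim <- sim[sim$species %in% unique(data$species) &
                 sim$experiment %in% unique(data$experiment), ]
    E <- error_E(sim, data)
    if (!keep_series) return(E)
    d <- average_replicates(data)
    mrg <- merge(average_replicates(sim), d,
                 by = c("experiment", "species", "time_s"),
                 suffixes = c(".sim", ".obs"))
    mrg$sq <- (mrg$value.sim - mrg$value.obs)^2
    per <- stats::aggregate(sq ~ experiment + species, data = mrg, FUN = sum)
    per$n <- stats::aggregate(sq ~ experiment + species, data = mrg,
                              FUN = length)$sq
    names(per)[names(per) == "sq"] <- "rss"
    list(E = E, per_series = per, n_points = nrow(mrg))
  }
}

#' Fit a pathway to time-series data by simulated annealing
#'
#' Metropolis simulated annealing over a chosen subset of kinetic parameters:
#' improvements are always accepted; a worsening `dE` is accepted with
#' probability `exp(-k * dE / T)`, where `k` is set from the error of the
#' initial parameter set (which must give a finite error, i.e. an approximate
#' fit) and `T` cools geometrically. Each error evaluation simulates a reduced
#' ensemble with common random numbers, so the whole fit is deterministic
#' given `sa$seed`. The best-ever parameter set is returned, re-evaluated with
#' a larger ensemble.
#'
#' @param variant A [pathway_variant()].
#' @param geometry A [gene_geometry()].
#' @param rates Initial [rate_set()]; parameters not being fitted stay at
#'   these values.
#' @param data Observed series (`timeseries_data` layout).
#' @param fit_params Character vector of parameters to optimise (subset of
#'   [free_parameter_names()]).
#' @param lower,upper Named bounds for `fit_params`.
#' @param sa An [sa_config()].
#' @return An object of class `"fit_result"`: fitted values, final rates,
#'   error `E`, per-series residuals, point count `n_points`, parameter count
#'   `k_params`, acceptance trace and seed.
#' @export
anneal <- function(variant, geometry, rates, data, fit_params,
                   lower, upper, sa = sa_config()) {
  stopifnot(inherits(variant, "pathway_variant"))
  validate_timeseries(as.data.frame(data))
  allowed <- free_parameter_names(variant)
  bad <- setdiff(fit_params, allowed)
  if (length(bad)) stop("not optimisable for this variant: ",
                        paste(bad, collapse = ", "))
  lower <- lower[fit_params]; upper <- upper[fit_params]
  if (any(!is.finite(unlist(lower))) || any(!is.finite(unlist(upper))) ||
      any(unlist(lower) >= unlist(upper))) {
    stop("bounds must be finite with lower < upper for every fitted parameter")
  }
  theta <- unlist(rates[fit_params])
  out_of_bounds <- names(theta)[theta < unlist(lower) | theta > unlist(upper)]
  if (length(out_of_bounds)) {
    stop("initial value outside bounds: ", paste(out_of_bounds, collapse = ", "))
  }

  objective <- make_objective(variant, geometry, rates, data, sa)
  E <- objective(theta)
  if (!is.finite(E)) stop("initial parameters give non-finite error; ",
                          "provide a better initial guess")
  E0 <- E
  kscale <- if (sa$scale_rule == "inverse_E0" && E0 > 0) 1 / E0 else 1

  best_theta <- theta
  best_E <- E
  trace <- vector("list", sa$n_stages * sa$iters_per_stage)
  ti <- 0L
  set.seed(sa$seed)
  for (stage in seq_len(sa$n_stages)) {
    Temp <- sa$T0 * sa$alpha^(stage - 1L)
    for (it in seq_len(sa$iters_per_stage)) {
      prop <- propose_params(theta, lower, upper, sa$step_scale)
      # proposal/acceptance randomness must not be perturbed by the
      # objective's simulation seeds; snapshot and restore the stream
      rng_state <- get(".Random.seed", envir = globalenv())
      Eprop <- objective(prop)
      assign(".Random.seed", rng_state, envir = globalenv())
      accept <- Eprop <= E || stats::runif(1) < exp(-kscale * (Eprop - E) / Temp)
      if (accept) {
        theta <- prop
        E <- Eprop
        if (E < best_E) { best_E <- E; best_theta <- theta }
      }
      ti <- ti + 1L
      trace[[ti]] <- data.frame(stage = stage, iter = it, E = Eprop,
                                accepted = accept)
    }
  }

  final <- objective(best_theta, n_runs = sa$final_ensemble_runs,
                     keep_series = TRUE)
  fitted_rates <- do.call(rate_set, utils::modifyList(unclass(rates),
                                                      as.list(best_theta)))
  res <- list(
    fitted = best_theta,
    rates = fitted_rates,
    variant = variant,
    geometry = geometry,
    E = final$E,
    E_search = best_E,
    per_series = final$per_series,
    n_points = final$n_points,
    k_params = length(fit_params),
    bounds = list(lower = lower, upper = upper),
    trace = do.call(rbind, trace),
    seed = sa$seed
  )
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Simulated-annealing fit:", x$k_params, "parameter(s), E =",
      signif(x$E, 4), "over", x$n_points, "points\n")
  print(signif(x$fitted, 4))
  invisible(x)
}
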