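## Synthetic RT-qPCR data generator with known ground truth, and the
## parameter-recovery harness built on it.

#' Specification of a synthetic dataset
#'
#' Defines the ground-truth model and the measurement layout of a synthetic
#' nine-series RT-qPCR experiment: a noise-free ensemble mean is computed from
#' the truth, then `n_replicates` noisy replicates are drawn with
#' heteroscedastic multiplicative noise plus an additive floor, mimicking
#' error bars that grow with copy number.
#'
#' @param variant Ground-truth [pathway_variant()].
#' @param geometry [gene_geometry()].
#' @param rates Ground-truth [rate_set()].
#' @param sample_times Measurement grid (s).
#' @param n_replicates Biological replicates to emit.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param noise_floor Additive noise SD in copies/cell.
#' @param truth_ensemble_runs Runs averaged for the noise-free truth.
#' @param seed Master seed (truth ensemble and replicate noise).
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(variant = pathway_variant("I"),
                       geometry = gene_geometry(),
                       rates = default_rates(variant$mutant),
                       sample_times = seq(0, 900, by = 60),
                       n_replicates = 3L,
                       noise_cv = 0.15,
                       noise_floor = 0.2,
                       truth_ensemble_runs = 500L,
                       seed = 1L) {
  stopifnot(noise_cv >= 0, noise_floor >= 0, n_replicates >= 1)
  structure(list(variant = variant, geometry = geometry, rates = rates,
                 sample_times = as.numeric(sample_times),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, noise_floor = noise_floor,
                 truth_ensemble_runs = as.integer(truth_ensemble_runs),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic nine-series dataset
#'
#' Simulates the ground-truth ensemble, observes the nine RT-qPCR series, and
#' emits `n_replicates` noisy copies of each:
#' `value = max(0, mean * (1 + noise_cv * N(0,1)) + noise_floor * N(0,1))`.
#'
#' @param spec A [synth_spec()].
#' @return A list with `data` (replicated noisy series, `timeseries_data`),
#'   `noise_free` (the underlying ensemble-mean series) and `truth` (manifest
#'   of ground-truth parameters and seeds).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  net <- build_pathway(spec$variant, spec$geometry, spec$rates)
  ens <- ensemble_mean(net, spec$sample_times,
                       n_runs = spec$truth_ensemble_runs,
                       base_seed = spec$seed)
  noise_free <- observe(ens, spec$geometry)
  set.seed(spec$seed + 777L)
  reps <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(r) {
    d <- noise_free
    d$replicate <- r
    noisy <- d$value * (1 + spec$noise_cv * stats::rnorm(nrow(d))) +
      spec$noise_floor * stats::rnorm(nrow(d))
    d$value <- pmax(0, noisy)
    d
  }))
  rownames(reps) <- NULL
  class(reps) <- c("timeseries_data", "data.frame")
  list(
    data = reps,
    noise_free = noise_free,
    truth = list(
      rates = unclass(spec$rates),
      variant = unclass(spec$variant),
      geometry = unclass(spec$geometry),
      seed = spec$seed,
      truth_ensemble_runs = spec$truth_ensemble_runs,
      noise_cv = spec$noise_cv,
      noise_floor = spec$noise_floor
    )
  )
}

#' Parameter-recovery experiment
#'
#' Generates a synthetic dataset from known truth, fits the chosen parameters
#' by [anneal()] under several optimiser seeds, and reports the relative error
#' of each recovered parameter, providing an end-to-end check of the
#' simulate/observe/fit loop.
#'
#' @param spec A [synth_spec()] (the truth).
#' @param fit_targets Parameters to recover (subset of
#'   [free_parameter_names()]).
#' @param lower,upper Named bounds for `fit_targets`.
#' @param initial Named starting values (default: truth perturbed to the
#'   geometric mid-point of the bounds for each target).
#' @param sa An [sa_config()]; its seed is offset per repetition.
#' @param n_seeds Number of optimiser repetitions.
#' @return A data frame with columns `seed, param, truth, estimate,
#'   rel_error, E`.
#' @export
recovery_experiment <- function(spec, fit_targets, lower, upper,
                                initial = NULL, sa = sa_config(),
                                n_seeds = 10L) {
  stopifnot(inherits(spec, "synth_spec"))
  gen <- generate_synthetic(spec)
  truth <- unlist(unclass(spec$rates)[fit_targets])
  if (length(fit_targets) == 0L) {
    # nothing to optimise: report the noise-only residual at the truth
    net <- build_pathway(spec$variant, spec$geometry, spec$rates)
    ens <- ensemble_mean(net, spec$sample_times,
                         n_runs = sa$final_ensemble_runs,
                         base_seed = sa$seed + 10000L)
    E0 <- error_E(observe(ens, spec$geometry), gen$data)
    out <- data.frame(seed = integer(0), param = character(0),
                      truth = numeric(0), estimate = numeric(0),
                      rel_error = numeric(0), E = numeric(0))
    attr(out, "baseline_E") <- E0
    return(out)
  }
  start_rates <- unclass(spec$rates)
  if (is.null(initial)) {
    for (nm in fit_targets) {
      start_rates[[nm]] <- sqrt(lower[[nm]] * max(upper[[nm]], 1e-12))
      if (!is.finite(start_rates[[nm]]) || start_rates[[nm]] <= 0) {
        start_rates[[nm]] <- (lower[[nm]] + upper[[nm]]) / 2
      }
    }
  } else {
    for (nm in names(initial)) start_rates[[nm]] <- initial[[nm]]
  }
  start_rates <- do.call(rate_set, start_rates)

  rows <- lapply(seq_len(n_seeds), function(i) {
    sa_i <- sa
    sa_i$seed <- sa$seed + i - 1L
    fit <- anneal(spec$variant, spec$geometry, start_rates, gen$data,
                  fit_params = fit_targets, lower = lower, upper = upper,
                  sa = sa_i)
    data.frame(seed = sa_i$seed, param = fit_targets,
               truth = as.numeric(truth[fit_targets]),
               estimate = as.numeric(fit$fitted[fit_targets]),
               rel_error = abs(as.numeric(fit$fitted[fit_targets]) -
                               as.numeric(truth[fit_targets])) /
                           as.numeric(truth[fit_targets]),
               E = fit$E, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
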