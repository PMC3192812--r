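## SSA engine wrappers: single trajectories, ensemble means and the
## single-polymerase exit-fraction estimator.

.mech_code <- function(m) switch(m, single = 0L, multistep = 1L, feedback = 2L)
.mut_code <- function(m) switch(m, none = 0L, ss3 = 1L, ss5 = 2L)

## internal: flatten network into the parameter list the engine expects
engine_params <- function(network) {
  v <- network$variant
  g <- network$geometry
  r <- network$rates
  list(
    n_sections = g$n_sections,
    branch_section = g$branch_section,
    n_substeps = v$n_substeps,
    co2_mech = .mech_code(v$co2_mech),
    post_mech = .mech_code(v$post_mech),
    elong_multi = if (v$elongation_mech == "multistep") 1L else 0L,
    mutant = .mut_code(v$mutant),
    allow_ulp = v$allow_ulariat_polyadenylation,
    k_init = r$k_init, k_elong = r$k_elong, eta = r$eta, k_on = r$k_on,
    c1 = r$c1, c2 = r$c2, k1_post = r$k1_post, k2_post = r$k2_post,
    k2_co = r$k2_co, ks = r$ks, ke = r$ke,
    d_ppre = r$d_ppre, d_plar = r$d_plar, d_mrna = r$d_mrna,
    t_act = r$t_act, n_burst = r$n_burst
  )
}

#' Simulate one stochastic trajectory of a pathway
#'
#' Runs the Gillespie direct method from an empty, inactive gene at t = 0
#' under the staged activation schedule: the gene activates at `t_act`
#' (enabling an initiation burst of `n_burst` transcripts) and splicing
#' activates after an exponential delay at rate `k_on`, which enables the
#' co-transcriptional transition, all splicing steps and unlimited initiation.
#'
#' @param network A [build_pathway()] result.
#' @param sample_times Increasing vector of snapshot times (s).
#' @param seed Integer RNG seed for this run.
#' @param audit If `TRUE`, verify the exclusion and conservation invariants at
#'   every snapshot (results in `$audit`).
#' @return An object of class `"ssa_trajectory"`: `sample_times`, a `counts`
#'   matrix (snapshots x species, including cumulative event counters),
#'   per-track occupancy indicator matrices `occ_post` / `occ_co`
#'   (snapshots x sections), the `seed`, and `audit` flags.
#' @examples
#' net <- build_pathway(pathway_variant("I"), gene_geometry(), default_rates())
#' tr <- simulate_pathway(net, seq(0, 900, by = 60), seed = 1)
#' tr$counts[, c("U_pre", "P_pre", "P_mRNA")]
#' @export
simulate_pathway <- function(network, sample_times = seq(0, 900, by = 30),
                             seed = 1L, audit = FALSE) {
  stopifnot(inherits(network, "reaction_network"))
  sample_times <- as.numeric(sample_times)
  if (is.unsorted(sample_times, strictly = TRUE)) {
    stop("sample_times must be strictly increasing")
  }
  if (any(sample_times < 0)) stop("sample_times must be non-negative")
  set.seed(as.integer(seed))
  res <- .ssa_run_cpp(engine_params(network), sample_times, audit)
  out <- list(
    sample_times = sample_times,
    counts = res$counts,
    occ_post = res$occ_post,
    occ_co = res$occ_co,
    seed = as.integer(seed),
    audit = if (audit) list(conservation_ok = res$conservation_ok,
                            exclusion_ok = res$exclusion_ok) else NULL,
    network = network
  )
  class(out) <- "ssa_trajectory"
  out
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  n <- nrow(x$counts)
  cat("SSA trajectory:", n, "snapshots over [",
      min(x$sample_times), ",", max(x$sample_times), "] s, seed", x$seed, "\n")
  cat("  final counts: P_mRNA =", x$counts[n, "P_mRNA"],
      " initiations =", x$counts[n, "cum_init"], "\n")
  invisible(x)
}

#' Ensemble mean over independent trajectories
#'
#' Averages `n_runs` independent trajectories (seeds `base_seed`,
#' `base_seed + 1`, ...) to give population means in copies/cell, the scale on
#' which RT-qPCR data are reported. Deterministic given
#' `(network, sample_times, n_runs, base_seed)`.
#'
#' @inheritParams simulate_pathway
#' @param n_runs Number of independent runs.
#' @param base_seed Seed of the first run.
#' @return An object of class `"ensemble_summary"`: `sample_times`, matrices
#'   `mean` and `var` (snapshots x species), mean occupancy matrices
#'   `occ_post_mean` / `occ_co_mean`, `n_runs`, `base_seed`.
#' @export
ensemble_mean <- function(network, sample_times = seq(0, 900, by = 30),
                          n_runs = 100L, base_seed = 1L) {
  stopifnot(n_runs >= 1L)
  sum_c <- NULL; sumsq_c <- NULL; sum_op <- NULL; sum_oc <- NULL
  for (i in seq_len(n_runs)) {
    tr <- simulate_pathway(network, sample_times, seed = base_seed + i - 1L)
    if (is.null(sum_c)) {
      sum_c <- tr$counts; sumsq_c <- tr$counts^2
      sum_op <- tr$occ_post; sum_oc <- tr$occ_co
    } else {
      sum_c <- sum_c + tr$counts; sumsq_c <- sumsq_c + tr$counts^2
      sum_op <- sum_op + tr$occ_post; sum_oc <- sum_oc + tr$occ_co
    }
  }
  mu <- sum_c / n_runs
  vr <- pmax(sumsq_c / n_runs - mu^2, 0)
  out <- list(
    sample_times = sample_times,
    mean = mu,
    var = vr,
    occ_post_mean = sum_op / n_runs,
    occ_co_mean = sum_oc / n_runs,
    n_runs = as.integer(n_runs),
    base_seed = as.integer(base_seed),
    network = network
  )
  class(out) <- "ensemble_summary"
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Ensemble summary over", x$n_runs, "runs (base seed", x$base_seed,
      "),", length(x$sample_times), "snapshots\n")
  invisible(x)
}

#' Monte-Carlo fraction of polymerases exiting without the co-transition
#'
#' Simulates independent single polymerases through the transition window
#' (ignoring excluded-volume interactions with other polymerases, splicing
#' assumed active): on each of the window's sections the hop onward (rate
#' `k_elong`) races the transition to the co-transcriptional track (rate
#' `k_elong / eta`). Returns the fraction exiting without transitioning,
#' i.e. the post-transcriptional splicing fraction. This is the stochastic
#' twin of the closed form [p_post()], against which it can be checked.
#'
#' @param geometry A [gene_geometry()]; supplies the number of choice points.
#' @param k_elong Elongation rate (sections/s); the exit fraction is invariant
#'   to it (the ratio of the competing rates is all that matters).
#' @param eta Ratio constant (> 0).
#' @param n_walkers Number of independent polymerases.
#' @param seed RNG seed.
#' @return Fraction in `[0, 1]`.
#' @examples
#' single_pol_exit_fraction(gene_geometry(), eta = 11.39,
#'                          n_walkers = 1e4, seed = 1)
#' @export
single_pol_exit_fraction <- function(geometry = gene_geometry(),
                                     k_elong = 2.27, eta = 11.39,
                                     n_walkers = 1e5, seed = 1L) {
  if (eta <= 0) stop("eta must be > 0")
  if (n_walkers < 1) stop("n_walkers must be >= 1")
  set.seed(as.integer(seed))
  n_post <- .single_pol_walkers_cpp(as.integer(n_walkers),
                                    geometry$n_transition_sections,
                                    k_elong, eta)
  n_post / n_walkers
}
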