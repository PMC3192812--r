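# Shared fixtures: small networks and hand-built states.

default_net <- function(pathway = "I", mutant = "none", ...) {
  v <- pathway_variant(pathway, mutant = mutant, ...)
  build_pathway(v, gene_geometry(), default_rates(mutant))
}

# a hand-built trajectory-like state for observation-model tests:
# one snapshot with the given pool counts and polymerase positions
fake_state <- function(pools = list(), post_sections = integer(0),
                       co_sections = integer(0), n_sections = 40L) {
  cols <- c("U_pre", "P_pre", "U_lar", "P_lar", "U_mRNA", "P_mRNA")
  counts <- matrix(0, nrow = 1, ncol = length(cols),
                   dimnames = list(NULL, cols))
  for (nm in names(pools)) counts[1, nm] <- pools[[nm]]
  occ_post <- matrix(0L, nrow = 1, ncol = n_sections)
  occ_co <- matrix(0L, nrow = 1, ncol = n_sections)
  occ_post[1, post_sections] <- 1L
  occ_co[1, co_sections] <- 1L
  structure(list(sample_times = 0, counts = counts,
                 occ_post = occ_post, occ_co = occ_co, seed = NA_integer_),
            class = "ssa_trajectory")
}

# tiny noise-free dataset in the canonical long layout
toy_timeseries <- function(values, species = "mRNA", experiment = "expt1",
                           times = NULL, replicate = 1L) {
  if (is.null(times)) times <- seq(0, by = 30, length.out = length(values))
  data.frame(experiment = experiment, species = species, time_s = times,
             replicate = replicate, value = values, stringsAsFactors = FALSE)
}
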