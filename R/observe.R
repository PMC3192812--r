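## RT-qPCR observation model: maps molecular state (released pools + nascent
## transcripts gated by cDNA-primer position) to the nine reported signals.

#' Canonical RT-qPCR species names
#'
#' Experiment 1 (exon-2 primer, total species): `pre-mRNA`, `lariat-exon2`,
#' `mRNA`. Experiment 2 (downstream primer / oligo-dT, 3' status resolved):
#' uncleaved (`U-`) and polyadenylated (`P-`) forms of each species.
#'
#' @return Character vector of the nine canonical species names.
#' @export
canonical_species <- function() {
  c("pre-mRNA", "lariat-exon2", "mRNA",
    "U-pre-mRNA", "P-pre-mRNA", "U-lariat-exon2", "P-lariat-exon2",
    "U-mRNA", "P-mRNA")
}

#' Assay configuration
#'
#' Defines which experiment a signal set belongs to and the primer section
#' that gates detection of nascent transcripts: a nascent molecule contributes
#' to a signal only once its polymerase has transcribed the primer sequence
#' (i.e. occupies a section at or beyond `primer_section`). Released molecules
#' always contribute. Maturation sub-stages count as uncleaved until the final
#' sub-step fires; splicing sub-stages retain the identity of their substrate.
#'
#' @param experiment `"expt1"` (total species via the exon-2 primer) or
#'   `"expt2"` (uncleaved via the downstream primer; polyadenylated via
#'   oligo-dT).
#' @param geometry A [gene_geometry()] supplying the default primer section.
#' @param primer_section Optional override of the primer section.
#' @return An object of class `"assay_config"`.
#' @export
assay_config <- function(experiment = c("expt1", "expt2"),
                         geometry = gene_geometry(),
                         primer_section = NULL) {
  experiment <- match.arg(experiment)
  if (is.null(primer_section)) {
    primer_section <- if (experiment == "expt1") geometry$primer_section_expt1
                      else geometry$primer_section_expt2
  }
  if (primer_section < 1 || primer_section > geometry$n_sections) {
    stop("primer_section must lie in 1..n_sections")
  }
  structure(list(experiment = experiment,
                 primer_section = as.integer(primer_section),
                 species = if (experiment == "expt1") {
                   canonical_species()[1:3]
                 } else {
                   canonical_species()[4:9]
                 }),
            class = "assay_config")
}

## internal: nascent molecules per snapshot past the primer on one track.
## occ is a snapshots x sections matrix of occupancy indicators (or means).
.nascent_past <- function(occ, primer_section) {
  if (is.null(occ)) return(0)
  rowSums(occ[, primer_section:ncol(occ), drop = FALSE])
}

#' Compute assay signals from simulated state
#'
#' Maps a trajectory or ensemble summary to the reported signal values of one
#' assay. Experiment 1 signals are totals: `pre-mRNA` counts post-track
#' nascent transcripts past the primer plus all released pre-mRNA pools
#' (uncleaved maturation stages and polyadenylated molecules, including
#' step-one sub-stages); `lariat-exon2` the co-track analogue; `mRNA` all
#' mRNA pools. Experiment 2 resolves 3' status: `U-` signals count uncleaved
#' molecules (nascent past the downstream primer plus released uncleaved
#' pools), `P-` signals fully matured pools.
#'
#' @param x An `"ssa_trajectory"` or `"ensemble_summary"`.
#' @param assay An [assay_config()].
#' @return Matrix (snapshots x signals) with the assay's species as columns.
#' @export
signals <- function(x, assay) {
  stopifnot(inherits(assay, "assay_config"))
  counts <- if (inherits(x, "ssa_trajectory")) x$counts
            else if (inherits(x, "ensemble_summary")) x$mean
            else stop("x must be an ssa_trajectory or ensemble_summary")
  occ_post <- if (inherits(x, "ssa_trajectory")) x$occ_post else x$occ_post_mean
  occ_co <- if (inherits(x, "ssa_trajectory")) x$occ_co else x$occ_co_mean
  need <- c("U_pre", "P_pre", "U_lar", "P_lar", "U_mRNA", "P_mRNA")
  missing <- setdiff(need, colnames(counts))
  if (length(missing)) stop("unknown species in state: ",
                            paste(missing, collapse = ", "))
  ps <- assay$primer_section
  nas_post <- .nascent_past(occ_post, ps)
  nas_co <- .nascent_past(occ_co, ps)
  if (assay$experiment == "expt1") {
    out <- cbind(
      `pre-mRNA` = nas_post + counts[, "U_pre"] + counts[, "P_pre"],
      `lariat-exon2` = nas_co + counts[, "U_lar"] + counts[, "P_lar"],
      `mRNA` = counts[, "U_mRNA"] + counts[, "P_mRNA"]
    )
  } else {
    out <- cbind(
      `U-pre-mRNA` = nas_post + counts[, "U_pre"],
      `P-pre-mRNA` = counts[, "P_pre"],
      `U-lariat-exon2` = nas_co + counts[, "U_lar"],
      `P-lariat-exon2` = counts[, "P_lar"],
      `U-mRNA` = counts[, "U_mRNA"],
      `P-mRNA` = counts[, "P_mRNA"]
    )
  }
  rownames(out) <- NULL
  out
}

#' Observe the nine RT-qPCR series from an ensemble
#'
#' Applies both assay configurations to an ensemble summary (or single
#' trajectory) and returns the nine series in the long time-series layout
#' used throughout the package.
#'
#' @param x An `"ensemble_summary"` or `"ssa_trajectory"`.
#' @param geometry A [gene_geometry()]; defaults to the geometry stored in the
#'   simulated object's network.
#' @param replicate Replicate label for the emitted rows (`NA` for noise-free
#'   model output).
#' @return A `data.frame` with columns
#'   `experiment, species, time_s, replicate, value` (copies/cell).
#' @export
observe <- function(x, geometry = NULL, replicate = NA_integer_) {
  if (is.null(geometry)) geometry <- x$network$geometry
  times <- x$sample_times
  rows <- lapply(c("expt1", "expt2"), function(e) {
    sig <- signals(x, assay_config(e, geometry))
    do.call(rbind, lapply(colnames(sig), function(sp) {
      data.frame(experiment = e, species = sp, time_s = times,
                 replicate = replicate, value = as.numeric(sig[, sp]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("timeseries_data", "data.frame")
  out
}
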