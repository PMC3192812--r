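#' Gene geometry for the sectioned-lattice transcription model
#'
#' The reporter gene is discretised into sections of roughly one Pol II
#' footprint (~31 nt); each section can hold at most one polymerase
#' (excluded volume). From `branch_section` onwards a nascent transcript can
#' commit to the co-transcriptional splicing track, so the transition choice
#' exists on `n_transition_sections` consecutive sections ending at the last
#' section. Primer sections gate when a nascent transcript becomes visible to
#' each RT-qPCR assay: a molecule is detected only once its polymerase has
#' transcribed the cDNA-primer sequence.
#'
#' @param length_nt Gene length in nucleotides.
#' @param section_nt Nucleotides per lattice section (Pol II footprint).
#' @param n_sections Number of sections; must equal `ceiling(length_nt / section_nt)`.
#' @param branch_section First (1-based) section at which the transition to
#'   the co-transcriptional splicing track is possible.
#' @param n_transition_sections Number of sections on which the choice exists;
#'   must satisfy `branch_section + n_transition_sections - 1 == n_sections`.
#' @param primer_section_expt1 Section of the exon-2 cDNA primer (experiment 1,
#'   total-species assay).
#' @param primer_section_expt2 Section of the downstream-of-cleavage-site
#'   primer (experiment 2, uncleaved/polyadenylated assay).
#' @return An object of class `"gene_geometry"`.
#' @examples
#' geom <- gene_geometry()
#' geom$n_sections  # 40 sections of 31 nt for a 1240 nt reporter
#' @export
gene_geometry <- function(length_nt = 1240L,
                          section_nt = 31L,
                          n_sections = 40L,
                          branch_section = 16L,
                          n_transition_sections = 25L,
                          primer_section_expt1 = 35L,
                          primer_section_expt2 = 40L) {
  g <- list(
    length_nt = as.integer(length_nt),
    section_nt = as.integer(section_nt),
    n_sections = as.integer(n_sections),
    branch_section = as.integer(branch_section),
    n_transition_sections = as.integer(n_transition_sections),
    primer_section_expt1 = as.integer(primer_section_expt1),
    primer_section_expt2 = as.integer(primer_section_expt2)
  )
  class(g) <- "gene_geometry"
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  stopifnot(inherits(g, "gene_geometry"))
  if (g$n_sections != ceiling(g$length_nt / g$section_nt)) {
    stop("n_sections must equal ceiling(length_nt / section_nt): expected ",
         ceiling(g$length_nt / g$section_nt), ", got ", g$n_sections)
  }
  if (g$branch_section + g$n_transition_sections - 1L != g$n_sections) {
    stop("transition window mismatch: branch_section + n_transition_sections - 1 ",
         "must equal n_sections (window ",
         g$n_sections - g$branch_section + 1L, " sections != n_transition_sections ",
         g$n_transition_sections, ")")
  }
  if (g$branch_section <= 1L) stop("branch_section must be > 1")
  for (fld in c("primer_section_expt1", "primer_section_expt2")) {
    if (g[[fld]] < 1L || g[[fld]] > g$n_sections) {
      stop(fld, " must lie in 1..n_sections")
    }
  }
  invisible(g)
}

#' @export
print.gene_geometry <- function(x, ...) {
  cat("Gene geometry:", x$length_nt, "nt in", x$n_sections, "sections of",
      x$section_nt, "nt\n")
  cat("  co-transcriptional transition possible on sections",
      x$branch_section, "..", x$n_sections,
      sprintf("(%d choice points)\n", x$n_transition_sections))
  cat("  cDNA primers at sections", x$primer_section_expt1, "(expt1) and",
      x$primer_section_expt2, "(expt2)\n")
  invisible(x)
}
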