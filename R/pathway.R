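## Pathway variants, kinetic rate sets and the declarative reaction network.

# Table of the eight candidate pathways: mechanism used for co-transcriptional
# splicing step two (Co), post-transcriptional steps one and two (Po) and
# elongation (El). F = positive feedback, M = multi-step, S = single step.
.pathway_defs <- data.frame(
  pathway = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"),
  co2 = c("feedback", "feedback", "feedback", "feedback",
          "multistep", "multistep", "single", "single"),
  post = c("multistep", "multistep", "feedback", "feedback",
           "multistep", "multistep", "single", "single"),
  elongation = c("multistep", "single", "multistep", "single",
                 "multistep", "single", "multistep", "single"),
  stringsAsFactors = FALSE
)

#' The eight candidate pathway definitions
#'
#' Returns the mechanism table for the eight pathway models compared by AIC:
#' each pathway is identified by the mechanism used for co-transcriptional
#' splicing step two (`co2`), for both post-transcriptional splicing steps
#' (`post`) and for elongation (`elongation`).
#'
#' @return A data frame with columns `pathway`, `co2`, `post`, `elongation`.
#' @export
pathway_definitions <- function() .pathway_defs

#' Define a pathway variant
#'
#' A variant selects the mechanism for each RNA-processing step: positive
#' feedback (`"feedback"`), a chain of `n_substeps` identical-rate stages
#' (`"multistep"`), or a single first-order reaction (`"single"`). The eight
#' named pathways of [pathway_definitions()] can be selected directly via
#' `pathway`. Splice-site mutants modify the network: `"ss3"` (3' splice-site
#' mutation) blocks splicing step two everywhere and instead routes uncleaved
#' lariat-exon2 through 3' maturation; `"ss5"` (5' splice-site mutation)
#' removes the co-transcriptional track and post-transcriptional step one, so
#' only pre-mRNA forms are produced.
#'
#' @param pathway Optional pathway name "I".."VIII"; sets the three mechanisms.
#' @param co2_mech Mechanism for co-transcriptional splicing step two.
#' @param post_mech Mechanism for both post-transcriptional splicing steps.
#' @param elongation_mech Mechanism for elongation: `"multistep"` (sectioned
#'   lattice with excluded volume) or `"single"` (two competing single-step
#'   exits from the active promoter complex).
#' @param mutant `"none"`, `"ss3"` or `"ss5"`.
#' @param n_substeps Number of stages used by every multistep process.
#' @param allow_ulariat_polyadenylation If `TRUE`, add the (normally rejected)
#'   slow transition from uncleaved to polyadenylated lariat-exon2.
#' @return An object of class `"pathway_variant"`.
#' @examples
#' pathway_variant("I")
#' pathway_variant("I", mutant = "ss5")
#' @export
pathway_variant <- function(pathway = NULL,
                            co2_mech = "feedback",
                            post_mech = "multistep",
                            elongation_mech = "multistep",
                            mutant = c("none", "ss3", "ss5"),
                            n_substeps = 5L,
                            allow_ulariat_polyadenylation = FALSE) {
  mutant <- match.arg(mutant)
  if (!is.null(pathway)) {
    row <- .pathway_defs[.pathway_defs$pathway == pathway, ]
    if (nrow(row) != 1L) stop("unknown pathway: ", pathway,
                              " (expected one of I..VIII)")
    co2_mech <- row$co2
    post_mech <- row$post
    elongation_mech <- row$elongation
  }
  co2_mech <- match.arg(co2_mech, c("feedback", "multistep", "single"))
  post_mech <- match.arg(post_mech, c("feedback", "multistep", "single"))
  elongation_mech <- match.arg(elongation_mech, c("multistep", "single"))
  n_substeps <- as.integer(n_substeps)
  if (n_substeps < 1L) stop("n_substeps must be >= 1")
  v <- list(
    pathway = if (is.null(pathway)) NA_character_ else pathway,
    co2_mech = co2_mech,
    post_mech = post_mech,
    elongation_mech = elongation_mech,
    mutant = mutant,
    n_substeps = n_substeps,
    allow_ulariat_polyadenylation = isTRUE(allow_ulariat_polyadenylation)
  )
  class(v) <- "pathway_variant"
  v
}

#' @export
print.pathway_variant <- function(x, ...) {
  cat("Pathway variant",
      if (!is.na(x$pathway)) paste0("(", x$pathway, ")") else "", "\n")
  cat("  co-transcriptional step 2 :", x$co2_mech, "\n")
  cat("  post-transcriptional steps:", x$post_mech, "\n")
  cat("  elongation                :", x$elongation_mech, "\n")
  cat("  mutant                    :", x$mutant,
      " substeps:", x$n_substeps, "\n")
  invisible(x)
}

#' Kinetic rate set
#'
#' All kinetic constants of the transcription/splicing/3'-maturation model,
#' in events per second unless noted. Defaults are the wild-type reporter
#' values; [default_rates()] provides the mutant presets.
#'
#' @param k_init Transcription initiation rate (events/s).
#' @param k_elong Elongation rate in sections/s (multistep elongation).
#' @param eta Dimensionless ratio constant: the co-transcriptional transition
#'   fires at `k_elong / eta`, so per-section odds of hopping vs transitioning
#'   are `eta : 1`.
#' @param k_on Splicing-activation rate (/s); activation is an exponential
#'   delay started at gene induction.
#' @param c1 Per-stage 3'-maturation rate for pre-mRNA (/s).
#' @param c2 Per-stage 3'-maturation rate for mRNA (and, in the ss3 mutant,
#'   for uncleaved lariat-exon2) (/s).
#' @param k1_post Post-transcriptional splicing step-1 rate (/s; per stage when
#'   multistep, per molecule of substrate and enzyme when feedback).
#' @param k2_post Post-transcriptional splicing step-2 rate (/s).
#' @param k2_co Co-transcriptional splicing step-2 rate constant
#'   (/(molecule s) when feedback, /s otherwise).
#' @param ks,ke Competing single-step exit rates from the active promoter
#'   complex, used only when `elongation_mech == "single"`: `ks` releases
#'   uncleaved lariat-exon2 (step one completed), `ke` uncleaved pre-mRNA.
#' @param d_ppre,d_plar,d_mrna First-order degradation rates for the pre-mRNA,
#'   lariat-exon2 and mRNA pools (/s).
#' @param t_act Deterministic delay from induction (t = 0) to gene
#'   activation (s).
#' @param n_burst Number of initiation events permitted between gene
#'   activation and splicing activation (the initial burst).
#' @return An object of class `"rate_set"`.
#' @export
rate_set <- function(k_init = 0.25,
                     k_elong = 2.27,
                     eta = 11.39,
                     k_on = 0.03,
                     c1 = 4.6709 / 35,
                     c2 = 4.6709 / 49,
                     k1_post = 4.6709 / 34,
                     k2_post = 4.6709 / 36,
                     k2_co = 0.0063,
                     ks = 0.2,
                     ke = 0.027,
                     d_ppre = 0.002,
                     d_plar = 0.002,
                     d_mrna = 0,
                     t_act = 400,
                     n_burst = 8L) {
  r <- list(k_init = k_init, k_elong = k_elong, eta = eta, k_on = k_on,
            c1 = c1, c2 = c2, k1_post = k1_post, k2_post = k2_post,
            k2_co = k2_co, ks = ks, ke = ke,
            d_ppre = d_ppre, d_plar = d_plar, d_mrna = d_mrna,
            t_act = t_act, n_burst = as.integer(n_burst))
  class(r) <- "rate_set"
  validate_rates(r)
  r
}

validate_rates <- function(r) {
  num <- r[setdiff(names(r), "n_burst")]
  bad <- names(num)[!vapply(num, function(x) is.numeric(x) && length(x) == 1L
                            && is.finite(x) && x >= 0, logical(1))]
  if (length(bad)) stop("rate fields must be single non-negative numbers: ",
                        paste(bad, collapse = ", "))
  if (r$eta <= 0) stop("eta must be > 0")
  if (r$n_burst < 0L) stop("n_burst must be >= 0")
  invisible(r)
}

#' Default rate sets for the wild-type and mutant reporters
#'
#' Wild-type defaults are the fitted pathway-I values where published
#' (`eta = 11.39`, `k_on = 0.03`, `k_init = 0.25`, `k2_co = 0.0063`); the ss3
#' mutant uses `eta = 30`, `k_on = 0.015`, `k_init = 0.175` with splicing step
#' two abolished (`k2_co = k2_post = 0`), and the ss5 mutant uses
#' `k_init = 0.1` with no co-transcriptional path and no post-transcriptional
#' splicing (`k1_post = 0`).
#'
#' @param mutant `"none"`, `"ss3"` or `"ss5"`.
#' @return A [rate_set()].
#' @export
default_rates <- function(mutant = c("none", "ss3", "ss5")) {
  mutant <- match.arg(mutant)
  switch(mutant,
    none = rate_set(),
    ss3 = rate_set(k_init = 0.175, eta = 30, k_on = 0.015,
                   k2_co = 0, k2_post = 0),
    ss5 = rate_set(k_init = 0.1, k1_post = 0, k2_co = 0, ks = 0)
  )
}

## internal: check variant/rates consistency (RateSet invariants)
validate_variant_rates <- function(variant, rates) {
  if (variant$mutant == "ss3") {
    if (rates$k2_co != 0) stop("mutant ss3 requires k2_co = 0")
    if (rates$k2_post != 0) stop("mutant ss3 requires k2_post = 0")
  }
  if (variant$mutant == "ss5") {
    if (rates$k1_post != 0) stop("mutant ss5 requires k1_post = 0")
  }
  invisible(TRUE)
}

#' Specification of a positive-feedback splicing reaction
#'
#' The feedback mechanism posits an enzyme Y, one per feedback reaction, with
#' initial copy number 1, incremented on each firing. The reaction propensity
#' follows the bimolecular mass-action form
#' `rate_constant * substrate_count * y_count`, so successive splicing events
#' accelerate the reaction.
#'
#' @param step Identifier for the feedback step (e.g. `"co2"`, `"post1"`).
#' @param rate_constant Bimolecular rate constant in /(molecule s).
#' @return A list with the step name, rate constant, initial Y copy number and
#'   a `propensity(substrate, y)` function.
#' @examples
#' fb <- feedback_reaction_spec("co2", 0.0063)
#' fb$propensity(1, 1)    # first firing hazard
#' fb$propensity(1, 20)   # 20x faster after 19 splicing events
#' @export
feedback_reaction_spec <- function(step, rate_constant) {
  if (!is.numeric(rate_constant) || rate_constant < 0) {
    stop("rate_constant must be >= 0")
  }
  list(
    step = step,
    rate_constant = rate_constant,
    y_initial = 1L,
    y_increment = 1L,
    propensity = function(substrate, y) rate_constant * substrate * y
  )
}

## ---- reaction network -------------------------------------------------

## internal: species names for pool stages
.stage_names <- function(prefix, n) paste0(prefix, "_", seq_len(n))

#' Build the reaction network for a pathway variant
#'
#' Assembles the full reaction list for the chosen variant: gated initiation
#' into the active promoter complex (APC), per-section elongation hops on the
#' excluded-volume lattice (or the two competing single-step exits when
#' elongation is single-step), the co-transcriptional transition at rate
#' `k_elong / eta` on the transition window, transcript release, 3' end
#' maturation, co- and post-transcriptional splicing steps realised by the
#' variant's mechanisms, and first-order degradation sinks. The returned
#' object is a declarative description used for validation, inspection and
#' structural tests; [simulate_pathway()] executes the same reaction set.
#'
#' @param variant A [pathway_variant()].
#' @param geometry A [gene_geometry()].
#' @param rates A [rate_set()]; must satisfy the mutant invariants (see
#'   [default_rates()]).
#' @return An object of class `"reaction_network"` with elements `variant`,
#'   `geometry`, `rates`, `reactions` (data frame: name, substrate, product,
#'   rate, gate, mechanism) and `species` (registry of species names).
#' @examples
#' net <- build_pathway(pathway_variant("I"), gene_geometry(), default_rates())
#' nrow(net$reactions)
#' @export
build_pathway <- function(variant, geometry = gene_geometry(),
                          rates = default_rates(variant$mutant)) {
  stopifnot(inherits(variant, "pathway_variant"))
  validate_geometry(geometry)
  validate_rates(rates)
  validate_variant_rates(variant, rates)

  m <- variant$n_substeps
  NS <- geometry$n_sections
  mut <- variant$mutant
  rx <- list()
  add <- function(name, substrate, product, rate, gate = "none",
                  mechanism = "mass_action") {
    rx[[length(rx) + 1L]] <<- data.frame(
      name = name, substrate = substrate, product = product, rate = rate,
      gate = gate, mechanism = mechanism, stringsAsFactors = FALSE)
  }

  add("initiation", "gene", "APC", rates$k_init, gate = "gene_active+burst_budget_remaining")

  if (variant$elongation_mech == "multistep") {
    add("promoter_escape", "APC", "pol_post_1", rates$k_elong,
        gate = "target_section_empty")
    for (i in seq_len(NS - 1L)) {
      add(sprintf("hop_post_%d", i), sprintf("pol_post_%d", i),
          sprintf("pol_post_%d", i + 1L), rates$k_elong,
          gate = "target_section_empty")
    }
    add("complete_post", sprintf("pol_post_%d", NS), "U_pre_1", rates$k_elong)
    if (mut != "ss5") {
      for (i in seq(geometry$branch_section, NS)) {
        add(sprintf("co_transition_%d", i), sprintf("pol_post_%d", i),
            sprintf("pol_co_%d", i), rates$k_elong / rates$eta,
            gate = "splicing_active")
      }
      for (i in seq(geometry$branch_section, NS - 1L)) {
        add(sprintf("hop_co_%d", i), sprintf("pol_co_%d", i),
            sprintf("pol_co_%d", i + 1L), rates$k_elong,
            gate = "target_section_empty")
      }
      add("complete_co", sprintf("pol_co_%d", NS), "U_lar_1", rates$k_elong)
    }
  } else {
    add("single_exit_pre", "APC", "U_pre_1", rates$ke)
    if (mut != "ss5") {
      add("single_exit_lar", "APC", "U_lar_1", rates$ks,
          gate = "splicing_active")
    }
  }

  ## 3' maturation of uncleaved pre-mRNA: m stages at c1 -> P_pre_1
  for (j in seq_len(m)) {
    add(sprintf("mature_pre_%d", j), sprintf("U_pre_%d", j),
        if (j < m) sprintf("U_pre_%d", j + 1L) else "P_pre_1", rates$c1)
  }

  mech_chain <- function(step, mech, n_from, prefix_from, product_final, rate) {
    ## realises one processing step per mechanism over the substrate pool
    if (mech == "multistep") {
      for (j in seq_len(m)) {
        add(sprintf("%s_%d", step, j), sprintf("%s_%d", prefix_from, j),
            if (j < m) sprintf("%s_%d", prefix_from, j + 1L) else product_final,
            rate, gate = "splicing_active", mechanism = "multistep")
      }
    } else if (mech == "feedback") {
      add(step, sprintf("%s_1", prefix_from), product_final, rate,
          gate = "splicing_active", mechanism = "feedback")
    } else {
      add(step, sprintf("%s_1", prefix_from), product_final, rate,
          gate = "splicing_active", mechanism = "single")
    }
  }

  if (mut != "ss5") {
    mech_chain("post_step1", variant$post_mech, m, "P_pre", "P_lar_1",
               rates$k1_post)
  }
  if (mut != "ss3") {
    mech_chain("post_step2", variant$post_mech, m, "P_lar", "P_mRNA + lariat",
               rates$k2_post)
  }
  if (mut == "ss3") {
    ## uncleaved lariat-exon2 cannot complete step two; it matures instead
    for (j in seq_len(m)) {
      add(sprintf("mature_lar_%d", j), sprintf("U_lar_%d", j),
          if (j < m) sprintf("U_lar_%d", j + 1L) else "P_lar_1", rates$c2)
    }
  } else if (mut != "ss5") {
    mech_chain("co_step2", variant$co2_mech, m, "U_lar", "U_mRNA_1 + lariat",
               rates$k2_co)
    if (variant$allow_ulariat_polyadenylation) {
      add("ulariat_polyadenylation", "U_lar_1", "P_lar_1", rates$c2)
    }
  }

  for (j in seq_len(m)) {
    add(sprintf("mature_mrna_%d", j), sprintf("U_mRNA_%d", j),
        if (j < m) sprintf("U_mRNA_%d", j + 1L) else "P_mRNA", rates$c2)
  }

  ## degradation sinks (first order, always on)
  pre_pools <- c(.stage_names("U_pre", m), pool_names(variant, "P_pre"))
  lar_pools <- c(pool_names_ular(variant), pool_names(variant, "P_lar"))
  mrna_pools <- c(.stage_names("U_mRNA", m), "P_mRNA")
  if (variant$mutant == "ss5") lar_pools <- character(0)
  if (rates$d_ppre > 0) for (s in pre_pools) {
    add(paste0("deg_", s), s, "deg_pre", rates$d_ppre)
  }
  if (rates$d_plar > 0) for (s in lar_pools) {
    add(paste0("deg_", s), s, "deg_lar", rates$d_plar)
  }
  if (rates$d_mrna > 0) for (s in mrna_pools) {
    add(paste0("deg_", s), s, "deg_mrna", rates$d_mrna)
  }

  reactions <- do.call(rbind, rx)
  species <- unique(c("gene", "APC",
                      unlist(strsplit(reactions$substrate, " \\+ ")),
                      unlist(strsplit(reactions$product, " \\+ "))))
  net <- list(variant = variant, geometry = geometry, rates = rates,
              reactions = reactions, species = species)
  class(net) <- "reaction_network"
  net
}

## internal: stage pool names for a post-mech-dependent pool
pool_names <- function(variant, prefix) {
  n <- if (variant$post_mech == "multistep") variant$n_substeps else 1L
  .stage_names(prefix, n)
}

## internal: U_lar pool names depend on co2 mech / mutant
pool_names_ular <- function(variant) {
  n <- if (variant$mutant == "ss3") variant$n_substeps
       else if (variant$co2_mech == "multistep") variant$n_substeps
       else 1L
  .stage_names("U_lar", n)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", nrow(x$reactions), "reactions,",
      length(x$species), "species\n")
  print(x$variant)
  invisible(x)
}

#' Species reachable from a starting species
#'
#' Breadth-first search over the substrate -> product edges of a reaction
#' network. Used to verify pathway structure (e.g. that in the ss5 mutant no
#' lariat or mRNA species is reachable from the promoter complex).
#'
#' @param network A [build_pathway()] result.
#' @param from Starting species name.
#' @return Character vector of reachable species (excluding `from`).
#' @export
network_reachable <- function(network, from = "APC") {
  edges <- network$reactions
  subs <- strsplit(edges$substrate, " \\+ ")
  prods <- strsplit(edges$product, " \\+ ")
  seen <- character(0)
  frontier <- from
  while (length(frontier)) {
    hits <- vapply(subs, function(s) any(s %in% frontier), logical(1))
    nxt <- setdiff(unique(unlist(prods[hits])), c(seen, from))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Number of free kinetic parameters of a pathway variant
#'
#' Counts the kinetic constants the fitter optimises for a variant: this is
#' the `k` entering the 2k AIC penalty. Always counted: `k_init`, `k_on`,
#' `c1`, `c2`. Elongation contributes `k_elong` and `eta` (multistep) or `ks`
#' and `ke` (single). The splicing steps contribute one rate constant each
#' (`k2_co`, `k1_post`, `k2_post`) unless removed by a mutant: ss3 zeroes
#' `k2_co` and `k2_post`; ss5 removes the co track (`eta`/`ks`, `k2_co`) and
#' `k1_post`. Degradation rates and schedule parameters are fixed.
#'
#' @param variant A [pathway_variant()].
#' @return Integer parameter count.
#' @export
count_free_parameters <- function(variant) {
  length(free_parameter_names(variant))
}

#' Names of the optimisable kinetic parameters of a variant
#' @rdname count_free_parameters
#' @export
free_parameter_names <- function(variant) {
  stopifnot(inherits(variant, "pathway_variant"))
  p <- c("k_init", "k_on", "c1", "c2")
  if (variant$elongation_mech == "multistep") {
    p <- c(p, "k_elong", if (variant$mutant != "ss5") "eta")
  } else {
    p <- c(p, "ke", if (variant$mutant != "ss5") "ks")
  }
  if (!variant$mutant %in% c("ss3", "ss5")) p <- c(p, "k2_co")
  if (variant$mutant != "ss5") p <- c(p, "k1_post")
  if (variant$mutant == "none") p <- c(p, "k2_post")
  p
}
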