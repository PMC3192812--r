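---
title: "Stochastic modelling of co-transcriptional splicing kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic modelling of co-transcriptional splicing kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicekin)
```

## The model

`splicekin` simulates the induction of an intron-containing reporter gene in
budding yeast, following each transcript through elongation, splicing and
3′ end maturation at single-molecule resolution.

**Elongation on an excluded-volume lattice.** The 1240 nt reporter is divided
into 40 sections of 31 nt, roughly one Pol II footprint. Initiation places a
polymerase in the active promoter complex (APC); it escapes into section 1 and
hops section to section at rate $k_\mathrm{elong}$ (sections/s), each hop
requiring the target section to be empty. At the final section the transcript
is released. A many-step elongation process has much lower variance in
completion time than a single reaction of the same mean — the waiting time is
Erlang rather than exponential — and the lattice also caps how many
polymerases the gene can carry.

**The co-transcriptional splicing track.** From the branch-site section
(section 16) to the end of the gene — 25 choice points — a polymerase on the
default (post) track can switch to the co-transcriptional track at rate
$k_\mathrm{elong}/\eta$, representing completion of splicing step one on the
nascent transcript. The per-section odds of hopping onward versus switching
are $\eta : 1$, so a lone polymerase exits unswitched with probability

$$P_\mathrm{post} = \left(\frac{\eta}{\eta + 1}\right)^{25},$$

independent of $k_\mathrm{elong}$ (`p_post()`). Both tracks share the
excluded-volume constraint: the two copies of a section are the same physical
DNA. A transcript released from the post track is uncleaved pre-mRNA; from the
co track, uncleaved lariat-exon2 (step one complete).

**Released-species processing.** Uncleaved pre-mRNA is 3′-matured (cleaved,
polyadenylated, released from the template) into polyadenylated pre-mRNA;
polyadenylated pre-mRNA undergoes post-transcriptional splicing step one, then
step two, yielding mature mRNA plus the excised lariat. On the co track,
splicing step two converts uncleaved lariat-exon2 into uncleaved mRNA, which
is then 3′-matured. Each processing step can be realised as

* a **single** first-order reaction,
* a **multistep** chain of five identical-rate stages (Erlang kinetics, which
  produce the sharp transitions seen in the data), or
* a **positive-feedback** reaction: a dedicated enzyme counter $Y$ starts at 1
  and increments on each firing, with bimolecular propensity
  $k \cdot [\mathrm{substrate}] \cdot Y$, so splicing accelerates as products
  accumulate.

The eight candidate pathways of `pathway_definitions()` are the combinations
of mechanisms for co-transcriptional step two (feedback/multistep/single),
the two post-transcriptional steps (same options, shared mechanism), and
elongation (lattice vs a pair of competing single-step exits from the APC at
rates $k_s$, $k_e$).

**Staged activation.** All counts start at zero. The gene activates at
$t_\mathrm{act}$ (default 400 s, deterministic, matching the reproducible
induction delay); a burst budget of $n_\mathrm{burst}$ initiations (default 8)
is then available. Splicing activation follows after an exponential delay at
rate $k_\mathrm{on}$; it enables the co-transition, all splicing steps, and
unlimited initiation. Before splicing activation the burst transcripts can
only be 3′-matured or degrade — this produces the early uncleaved pre-mRNA
peak followed ~30 s later by the polyadenylated pre-mRNA peak, while mature
mRNA appears only after activation, uncleaved (co-track) mRNA first.

**Mutants.** The 3′ splice-site mutant (`mutant = "ss3"`) abolishes step two
everywhere ($k_{2,\mathrm{co}} = k_{2,\mathrm{post}} = 0$); uncleaved
lariat-exon2 instead passes through the five-stage 3′ maturation at rate
$c_2$. Its rate preset raises $\eta$ to 30 (co fraction 56% instead of 88%),
halves $k_\mathrm{on}$ and lowers $k_\mathrm{init}$ to 0.175. The 5′
splice-site mutant (`mutant = "ss5"`) removes the co track and
post-transcriptional step one entirely, so only pre-mRNA forms appear; its
preset lowers $k_\mathrm{init}$ to 0.1.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `k_init` | 0.25 /s | initiation (0.175 ss3, 0.1 ss5) |
| `k_elong` | 2.27 sections/s | ~70 nt/s elongation |
| `eta` | 11.39 | co-transition odds (30 in ss3) |
| `k_on` | 0.03 /s | splicing activation (0.015 in ss3) |
| `c1` | 4.6709/35 /s | per-stage pre-mRNA 3′ maturation |
| `c2` | 4.6709/49 /s | per-stage mRNA (and ss3 lariat-exon2) maturation |
| `k1_post`, `k2_post` | 4.6709/34, 4.6709/36 /s | per-stage post splicing |
| `k2_co` | 0.0063 /(molecule·s) | feedback step-two constant |
| `d_ppre`, `d_plar`, `d_mrna` | 0.002, 0.002, 0 /s | degradation sinks |
| `t_act`, `n_burst` | 400 s, 8 | activation schedule |

The multi-stage rates are chosen so the Erlang(5) half-time
(`erlang_half_time(5, r)`, median $\approx 4.6709/r$) equals the reported
characteristic times: 35 s for pre-mRNA 3′ maturation, 49 s for mRNA
maturation, 34 s and 36 s for post-transcriptional splicing steps one and
two. `k2_co = 0.0063` sits inside the reported 0.0061–0.0068 range (the
first-event half-life $\ln 2 / k$ is then ~110 s; with $Y = 20$ it drops
20-fold to 5.5 s). Degradation rates and the burst size are package
conventions: the sources constrain them only loosely, and they are fully
configurable.

## The observation model

RT-qPCR detects a transcript only once its cDNA-primer sequence has been
transcribed. Experiment 1 (exon-2 primer, default section 35) reports total
pre-mRNA, lariat-exon2 and mRNA; a co-track polymerase past the primer counts
as lariat-exon2 because step one is complete on its nascent transcript.
Experiment 2 resolves 3′ status: the uncleaved (`U-`) signals use a primer
downstream of the cleavage sites (default the final section, making nascent
contributions negligible), the polyadenylated (`P-`) signals use oligo-dT and
therefore count only fully matured pools. Molecules midway through a
multistep conversion retain the identity of their substrate: maturation
sub-stages are still uncleaved; splicing sub-stages are still the precursor
species. The exact exon-2 primer section is not pinned down by the assay
description; section 35 is a declared convention and configurable
(`gene_geometry(primer_section_expt1 = ...)`). The background subtraction
applied to the experimental lariat-exon2 signal (a primer cross-detection
correction) is not simulated; simulated signals are direct species counts.

## Simulation engine

The simulator is an exact Gillespie direct method, implemented in C++ (as in
`GillespieSSA2`/`adaptivetau`) because fitting evaluates hundreds of
ensembles. Propensities are rebuilt per event over a sparse list of
polymerase positions plus the released-species pools; scheduled events (gene
activation, the pre-drawn splicing-activation time) pre-empt any reaction
firing beyond them. Zero total propensity with no pending scheduled event
terminates the run and holds the state for remaining snapshots. With `audit =
TRUE` every snapshot checks the exclusion invariant (at most one polymerase
per section across both tracks) and two conservation identities (initiations
= exits + in-flight; releases = pools + products + degraded). All randomness
flows through R's RNG: a run is reproducible from its integer seed, an
ensemble from its base seed (seeds `base_seed .. base_seed + n_runs - 1`),
and every artifact records the seeds used.

## Fitting and model comparison

The error of a parameter set is the root-mean-square deviation between the
simulated ensemble-mean series and the replicate-averaged data over all time
points and series, $E = \sqrt{\sum (S - D)^2 / (nd)}$ — absolute copies/cell
are comparable across series by the design of the assay calibration (a
relative-error variant is a possible extension; the absolute form is the
package's convention, as the exact normalisation is not fixed by the sources
we follow). Simulated annealing proposes
$p' = p + N(0,1) \cdot s \cdot (p_\max - p_\min)$ with constant step fraction
$s$ (default 0.1), reflected at the bounds; worsenings are accepted with
probability $\exp(-k\,\Delta E/T)$ with $k = 1/E_0$ set from the initial
error and $T$ cooling geometrically. These are declared conventions: the
precise forms of the error normalisation, the scale rule and whether the
proposal anneals are not fixed by the sources, and the defaults were chosen
for robustness, not tuned to any test. Each objective evaluation uses a
reduced ensemble with common random numbers (a fixed evaluation seed), making
the objective deterministic and the whole fit reproducible from `sa$seed`;
the final error is re-evaluated with a larger ensemble.

Model comparison pools each fit's residuals over all series into
$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2k$, where $k$ counts only the rate
constants optimised for that variant (`count_free_parameters()`). Akaike
weights $w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$ are invariant to the
normalisation (reference-model or minimum), and the per-series AIC matrix is
column-shifted to minimum 0 for heat-map display. Pooling all residuals into
one total AIC (rather than summing per-series AICs) follows the description
of the total as computed "from all residuals in all species"; the per-series
matrix is provided for the column-normalised view either way.

## Synthetic data and what passing tests show

`generate_synthetic()` produces the nine-series layout of the two assays from
a ground-truth ensemble (default 500 runs), then draws replicates with
multiplicative noise (CV 0.15) plus an additive floor (SD 0.2 copies/cell) —
heteroscedastic like the real error bars, which grow with copy number. The
default grid is 0–900 s every 60 s with 3 replicates. The generator emulates
the documented qualitative features (induction delay, transient uncleaved
pre-mRNA peak before the polyadenylated peak, uncleaved mRNA before
polyadenylated mRNA, mRNA accumulating to tens of copies/cell); it is not a
statistical emulator of the real measurements — real data add primer
cross-detection, calibration error and replicate-level biological variation
that the noise model does not represent. Passing recovery tests therefore
demonstrate that the pipeline is self-consistent and that the target
parameters are identifiable at realistic noise, not that the original
experimental estimates are reproduced (reproducing the published fitted
values and absolute AICs would require the original data and the
supplementary parameter table, which are not bundled).

`recovery_experiment()` fixes one synthetic dataset and repeats the fit under
different optimiser seeds. With the test configuration (objective ensembles
of 60–100 runs, 100–300 annealing evaluations — sizes chosen to keep the
suite at desk scale) $\eta$ alone is recovered with median relative error
well inside 25% over 10 seeds, and the joint $(\eta, k_\mathrm{on},
k_{2,\mathrm{co}})$ fit recovers each within 30% in at least 8 of 10 seeds.
The joint problem has a genuine compensation ridge — lowering $\eta$ (more
co-transcriptional flux) can be partly offset by slower activation — which is
why under-sized searches drift along it; the test configuration is sized to
cross it.

## Numerical choices and edge cases

* Erlang medians are found by root-finding on the gamma survival function
  (`uniroot` on `pgamma`, bracketed on $[0, 10m/r]$); `erlang_half_time(1, k)`
  returns $\ln 2 / k$ exactly.
* The median of an isolated cohort is what `erlang_half_time()` computes; the
  time for a pool under continuous inflow to halve is a different quantity
  and depends on the inflow history.
* Simultaneous scheduled events are processed before reaction selection; a
  sample time coinciding exactly with an event records the pre-event state.
* Co-transitions are permitted for a polymerase currently blocked by the
  excluded volume (the transition changes track, not position).
* The APC is a distinct slot of capacity 1 upstream of section 1; promoter
  escape occurs at $k_\mathrm{elong}$ and requires section 1 empty. The
  sources name the APC but give no separate escape rate; reusing
  $k_\mathrm{elong}$ is the package's convention.
* Whether initiation continues at a reduced rate during the burst phase is
  not specified; the budget model (initiation fully available until
  `n_burst` is spent, then gated until splicing activation) is the package's
  reading, and `n_burst` is configurable.
* The two post-transcriptional steps have independent rates `k1_post`,
  `k2_post` (their reported characteristic times differ: 34 s vs 36 s).
* Each feedback reaction has its own enzyme counter, initial copy 1; counters
  are never shared between steps.
* The optional `allow_ulariat_polyadenylation` flag adds the slow uncleaved →
  polyadenylated lariat-exon2 transition (a variant known to worsen the fit,
  kept for completeness). It fires at rate $c_2$ on entry-stage molecules
  only; no separate rate is documented for it.
* Degradation removes a molecule from a stage pool chosen proportionally to
  occupancy; `d_ppre` covers all pre-mRNA pools, `d_plar` all lariat-exon2
  pools, `d_mrna` all mRNA pools.

## Known limitations

No promoter on/off switching (needed for steady-state mRNA distributions,
irrelevant on the 900 s induction window modelled here); no tau-leaping or
hybrid acceleration; no explicit snRNP/spliceosome species (treated as
non-limiting); no sequence-level splice-site model; no qPCR amplification or
reverse-transcription yield modelling (upstream of the copies/cell
calibration).

## A worked example

```{r example, eval = FALSE}
net <- build_pathway(pathway_variant("I"), gene_geometry(), default_rates())
ens <- ensemble_mean(net, seq(0, 900, 30), n_runs = 500, base_seed = 1)
obs <- observe(ens)
subset(obs, species == "mRNA" & time_s %in% c(420, 600, 900))

# closed-form splicing route split
p_post(11.39, 25)          # 0.122: 12% post-, 88% co-transcriptional
1 - p_post(30, 25)         # 0.56: mutant co-transcriptional fraction

# pathway comparison on published normalised AICs
akaike_weights(c(0, 40.9, 3.43, 31.2, 16.5, 36.1, 11.7, 28.4))
```
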