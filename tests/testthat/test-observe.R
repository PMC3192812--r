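test_that("nascent transcripts are invisible until the primer is transcribed", {
  g <- gene_geometry()
  # one post-track polymerase upstream of the exon-2 primer (section 35)
  st <- fake_state(post_sections = 10)
  s1 <- signals(st, assay_config("expt1", g))
  expect_true(all(s1 == 0))
  # at section 35 it is counted as pre-mRNA
  st <- fake_state(post_sections = 35)
  s1 <- signals(st, assay_config("expt1", g))
  expect_equal(unname(s1[1, "pre-mRNA"]), 1)
  expect_equal(unname(s1[1, "lariat-exon2"]), 0)
  # a co-track polymerase past the primer has completed splicing step one:
  # it reports as lariat-exon2, not pre-mRNA
  st <- fake_state(co_sections = 38)
  s1 <- signals(st, assay_config("expt1", g))
  expect_equal(unname(s1[1, "lariat-exon2"]), 1)
  expect_equal(unname(s1[1, "pre-mRNA"]), 0)
  # the same polymerase is upstream of the expt2 primer (section 40): unseen
  s2 <- signals(st, assay_config("expt2", g))
  expect_true(all(s2 == 0))
})

test_that("maturation stages stay uncleaved until the final stage fires", {
  g <- gene_geometry()
  mid <- fake_state(pools = list(U_mRNA = 1))   # midway through maturation
  s2 <- signals(mid, assay_config("expt2", g))
  expect_equal(unname(s2[1, "U-mRNA"]), 1)
  expect_equal(unname(s2[1, "P-mRNA"]), 0)
  done <- fake_state(pools = list(P_mRNA = 1))  # final stage completed
  s2 <- signals(done, assay_config("expt2", g))
  expect_equal(unname(s2[1, "U-mRNA"]), 0)
  expect_equal(unname(s2[1, "P-mRNA"]), 1)
})

test_that("moving a primer downstream never increases a nascent signal", {
  st <- fake_state(post_sections = c(12, 20, 33, 39), co_sections = c(25, 40))
  g <- gene_geometry()
  pre <- vapply(1:40, function(ps) {
    signals(st, assay_config("expt1", g, primer_section = ps))[1, "pre-mRNA"]
  }, numeric(1))
  lar <- vapply(1:40, function(ps) {
    signals(st, assay_config("expt1", g, primer_section = ps))[1, "lariat-exon2"]
  }, numeric(1))
  expect_true(all(diff(pre) <= 0))
  expect_true(all(diff(lar) <= 0))
})

test_that("expt1 mRNA equals the sum of the expt2 mRNA signals", {
  net <- default_net("I")
  ens <- ensemble_mean(net, seq(0, 900, 90), n_runs = 30, base_seed = 2)
  obs <- observe(ens)
  wide <- function(sp, e) obs$value[obs$species == sp & obs$experiment == e]
  expect_equal(wide("mRNA", "expt1"),
               wide("U-mRNA", "expt2") + wide("P-mRNA", "expt2"))
})

test_that("expt2 signals partition each species against the raw state", {
  net <- default_net("I")
  tr <- simulate_pathway(net, seq(0, 900, 90), seed = 8)
  g <- gene_geometry()
  s2 <- signals(tr, assay_config("expt2", g))
  nascent_post <- rowSums(tr$occ_post[, g$primer_section_expt2:40, drop = FALSE])
  nascent_co <- rowSums(tr$occ_co[, g$primer_section_expt2:40, drop = FALSE])
  expect_equal(unname(s2[, "U-pre-mRNA"] + s2[, "P-pre-mRNA"]),
               unname(tr$counts[, "U_pre"] + tr$counts[, "P_pre"] + nascent_post))
  expect_equal(unname(s2[, "U-lariat-exon2"] + s2[, "P-lariat-exon2"]),
               unname(tr$counts[, "U_lar"] + tr$counts[, "P_lar"] + nascent_co))
})

test_that("observation emits nine canonical series and zero state maps to zero", {
  net <- default_net("I")
  ens <- ensemble_mean(net, c(0, 100, 200), n_runs = 5, base_seed = 1)
  obs <- observe(ens)
  expect_setequal(unique(obs$species), canonical_species())
  expect_equal(nrow(obs), 9 * 3)
  # before gene activation (t_act = 400) everything is zero
  expect_true(all(obs$value == 0))
  st <- fake_state()
  expect_true(all(signals(st, assay_config("expt1")) == 0))
})

test_that("unknown species in the state are reported by name", {
  st <- fake_state()
  colnames(st$counts)[1] <- "U_bogus"
  expect_error(signals(st, assay_config("expt1")), "U_pre")
})
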