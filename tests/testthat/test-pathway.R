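test_that("geometry invariants are enforced", {
  g <- gene_geometry()
  expect_equal(g$n_sections, ceiling(g$length_nt / g$section_nt))
  expect_equal(g$branch_section + g$n_transition_sections - 1L, g$n_sections)
  expect_error(gene_geometry(n_sections = 39L), "n_sections")
  expect_error(gene_geometry(branch_section = 17L), "transition window")
  expect_error(gene_geometry(primer_section_expt1 = 41L), "primer")
  expect_error(gene_geometry(length_nt = 1200L), "n_sections")
})

test_that("the eight pathways map to the documented mechanisms", {
  defs <- pathway_definitions()
  expected <- list(
    I = c("feedback", "multistep", "multistep"),
    II = c("feedback", "multistep", "single"),
    III = c("feedback", "feedback", "multistep"),
    IV = c("feedback", "feedback", "single"),
    V = c("multistep", "multistep", "multistep"),
    VI = c("multistep", "multistep", "single"),
    VII = c("single", "single", "multistep"),
    VIII = c("single", "single", "single")
  )
  for (pw in names(expected)) {
    v <- pathway_variant(pw)
    expect_equal(c(v$co2_mech, v$post_mech, v$elongation_mech),
                 expected[[pw]], info = pw)
    # and the built network realises those mechanisms structurally
    net <- build_pathway(v, gene_geometry(), default_rates())
    rx <- net$reactions
    n_post1 <- sum(grepl("^post_step1", rx$name))
    expect_equal(n_post1, if (v$post_mech == "multistep") 5L else 1L,
                 info = pw)
    n_co2 <- sum(grepl("^co_step2", rx$name))
    expect_equal(n_co2, if (v$co2_mech == "multistep") 5L else 1L, info = pw)
    if (v$elongation_mech == "single") {
      expect_true(all(c("single_exit_pre", "single_exit_lar") %in% rx$name))
      expect_false(any(grepl("^hop_", rx$name)))
    } else {
      expect_equal(sum(grepl("^hop_post_", rx$name)), 39L)
      expect_equal(sum(grepl("^co_transition_", rx$name)), 25L)
    }
  }
})

test_that("multistep splicing steps comprise sequential stages of one rate", {
  net <- default_net("I")
  rx <- net$reactions
  st1 <- rx[grepl("^post_step1", rx$name), ]
  expect_equal(nrow(st1), 5L)
  expect_equal(unique(st1$rate), default_rates()$k1_post)
  # stage j feeds stage j+1; the last stage releases the product
  expect_equal(st1$substrate, paste0("P_pre_", 1:5))
  expect_equal(st1$product[5], "P_lar_1")
})

test_that("pathway-I routes to mature mRNA are exactly the co and post tracks", {
  net <- default_net("I")
  reach_apc <- network_reachable(net, "APC")
  expect_true("P_mRNA" %in% reach_apc)
  # removing the co entry point must leave only the post route, and vice versa
  no_co <- net
  no_co$reactions <- net$reactions[!grepl("^co_transition_", net$reactions$name), ]
  expect_true("P_mRNA" %in% network_reachable(no_co, "APC"))
  expect_false("U_mRNA_1" %in% network_reachable(no_co, "APC"))
  no_post1 <- net
  no_post1$reactions <- net$reactions[!grepl("^post_step1", net$reactions$name), ]
  expect_true("U_mRNA_1" %in% network_reachable(no_post1, "APC"))
  expect_false("P_lar_1" %in% network_reachable(no_post1, "APC"))
})

test_that("ss5 mutant reaches only pre-mRNA forms downstream of the APC", {
  net <- default_net("I", mutant = "ss5")
  reach <- network_reachable(net, "APC")
  expect_false(any(grepl("lar|mRNA", reach)))
  expect_true("U_pre_1" %in% reach)
  expect_true("P_pre_1" %in% reach)
})

test_that("variant/rates consistency is validated with the offending field named", {
  v3 <- pathway_variant("I", mutant = "ss3")
  expect_error(build_pathway(v3, gene_geometry(), default_rates("none")),
               "k2_co")
  v5 <- pathway_variant("I", mutant = "ss5")
  expect_error(build_pathway(v5, gene_geometry(), default_rates("none")),
               "k1_post")
  expect_silent(build_pathway(v3, gene_geometry(), default_rates("ss3")))
})

test_that("feedback reaction spec follows bimolecular mass action with Y", {
  fb <- feedback_reaction_spec("co2", 0.0063)
  expect_equal(fb$propensity(1, 1), 0.0063)
  expect_equal(fb$y_initial, 1L)
  # after 19 firings Y = 20: per-molecule hazard is 20x the initial one
  expect_equal(fb$propensity(1, 20) / fb$propensity(1, 1), 20)
  expect_equal(fb$propensity(0, 7), 0)
  expect_error(feedback_reaction_spec("co2", -1), ">= 0")
})

test_that("free-parameter counts follow the variant structure", {
  k1 <- count_free_parameters(pathway_variant("I"))
  k8 <- count_free_parameters(pathway_variant("VIII"))
  expect_lte(k8, k1)
  # one rate constant per mechanism: feedback vs multistep post have equal k
  kF <- count_free_parameters(pathway_variant(co2_mech = "feedback",
                                              post_mech = "feedback"))
  kM <- count_free_parameters(pathway_variant(co2_mech = "feedback",
                                              post_mech = "multistep"))
  expect_equal(kF, kM)
  p5 <- free_parameter_names(pathway_variant("I", mutant = "ss5"))
  expect_false(any(c("eta", "k1_post", "k2_post", "k2_co") %in% p5))
  p3 <- free_parameter_names(pathway_variant("I", mutant = "ss3"))
  expect_false(any(c("k2_co", "k2_post") %in% p3))
  expect_true("eta" %in% p3)
})

test_that("exclusion is encoded: every lattice move requires an empty target", {
  net <- default_net("I")
  moves <- net$reactions[grepl("^hop_|^promoter_escape", net$reactions$name), ]
  expect_true(all(moves$gate == "target_section_empty"))
  # co- and post-track copies of a section are the same physical section:
  # a transition row keeps the section index unchanged
  tr <- net$reactions[grepl("^co_transition_", net$reactions$name), ]
  idx_from <- as.integer(sub("pol_post_", "", tr$substrate))
  idx_to <- as.integer(sub("pol_co_", "", tr$product))
  expect_equal(idx_from, idx_to)
})
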