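test_that("the mutant benchmark scores every catalogue row", {
  m <- cc_model()
  bm <- run_mutant_benchmark(m)
  expect_identical(nrow(bm), 109L)
  expect_false(any(bm$skipped))
  expect_true(all(bm$predicted %in% c("Viable", "Arrest_G1", "Arrest_S",
                                      "Arrest_G2", "Arrest_M", "Unresolved")))
  ## reconciliation: inviable reports predicted as arrests become Inviable
  inv <- bm[bm$reported == "inviable" & grepl("^Arrest", bm$predicted), ]
  expect_true(all(inv$final_label == "Inviable"))
  expect_true(all(inv$correct))
  g <- glance(bm)
  expect_identical(g$n_mutants, 109L)
  expect_identical(g$n_correct, sum(bm$correct))
  expect_identical(ncol(tidy(bm)), 4L)
  expect_error(run_mutant_benchmark(m, catalogue = bm[0, ]), "empty")
})

test_that("random ensembles are seed-reproducible and checkpoint-silent", {
  m <- cc_model()
  e1 <- run_random_ensemble(60, seed = 123, model = m)
  e2 <- run_random_ensemble(60, seed = 123, model = m)
  expect_identical(e1$labels, e2$labels)
  expect_identical(e1$functional_fraction, e2$functional_fraction)
  e3 <- run_random_ensemble(60, seed = 124, model = m)
  expect_false(identical(e1$labels, e3$labels))
  ## counts sum to n and the fraction is a proportion
  expect_identical(sum(e1$arrest_breakdown) +
                     sum(e1$labels == "Viable"), 60L)
  expect_gte(e1$functional_fraction, 0)
  expect_lte(e1$functional_fraction, 1)
})

test_that("a degenerate ensemble from the regular preset is 100% functional", {
  m <- cc_model()
  reg <- preset_state(m, "regular")
  S0 <- matrix(rep(reg, each = 20), 20,
               dimnames = list(NULL, m$nodes$node))
  storage.mode(S0) <- "integer"
  cls <- yeastcyc:::ensemble_classify(m, S0)
  expect_true(all(cls$labels == "Viable"))
  ## all runs share one attractor grouping
  expect_identical(length(unique(cls$keys)), 1L)
})

test_that("the G1 scan fixes one node per run and is reproducible", {
  m <- cc_model()
  g1 <- run_g1_scan(40, seed = 5, model = m)
  g2 <- run_g1_scan(40, seed = 5, model = m)
  expect_identical(g1$labels, g2$labels)
  expect_identical(g1$fixed_node, g2$fixed_node)
  ## fixing MASS at 2 in every run gives one repeated deterministic outcome
  S0 <- matrix(rep(preset_state(m, "G1_start"), each = 10), 10,
               dimnames = list(NULL, m$nodes$node))
  storage.mode(S0) <- "integer"
  fx <- matrix(NA_integer_, 10, 67, dimnames = list(NULL, m$nodes$node))
  fx[, "MASS"] <- 2L
  cls <- yeastcyc:::ensemble_classify(m, S0, fix_mat = fx)
  expect_identical(length(unique(cls$labels)), 1L)
  expect_identical(length(unique(cls$keys)), 1L)
  ## sampling without replacement refuses oversized draws
  expect_error(run_g1_scan(10000, seed = 1, model = m, replace = FALSE),
               "distinct")
})

test_that("checkpoint fixation forces arrest at peak level but not at 1", {
  m <- cc_model()
  res <- run_checkpoint_suite(m)
  expect_identical(nrow(res), 9L)  # 3x2 + Mating + all@min + all@max
  at2 <- res[grepl("@2$", res$configuration), ]
  expect_true(all(grepl("^Arrest", at2$outcome)))
  at1 <- res[res$configuration %in%
               c("Unattached_Kinetochores@1", "Misaligned_Spindle@1",
                 "DNA_Damage@1"), ]
  expect_true(all(at1$outcome == "Viable"))
  expect_identical(res$outcome[res$configuration == "Mating@1"], "Arrest_G1")
  expect_true(all(grepl("^Arrest",
                        res$outcome[res$configuration %in%
                                      c("all@min", "all@max")])))
})

test_that("ethanol constraint sets reproduce the phenotype arrests", {
  m <- cc_model()
  lt <- run_ethanol_suite("LT", m)
  expect_identical(lt$outcome, "Arrest_M")
  ht <- run_ethanol_suite("HT", m)
  expect_identical(ht$outcome, "Arrest_G1")
  ## few mitotic-cyclin states in the arrested HT trajectory
  expect_lte(sum(ht$trajectory$Clb1_2 >= 1L), 3L)
  ## deterministic: identical on a re-run
  lt2 <- run_ethanol_suite("LT", m)
  expect_identical(as.data.frame(lt$trajectory), as.data.frame(lt2$trajectory))
})

test_that("DNA-damage constraints arrest LT strains and spare HT strains", {
  m <- cc_model()
  for (s in c("S288C", "BY4741", "SEY6210")) {
    expect_match(run_dna_damage_suite(s, model = m)$outcome, "^Arrest")
  }
  for (s in c("X2180-1A", "BY4742")) {
    expect_identical(run_dna_damage_suite(s, model = m)$outcome, "Viable")
  }
  expect_identical(run_dna_damage_suite("BMA64-1A")$outcome, "not analyzable")
  expect_error(run_dna_damage_suite("W303"), "unknown strain")
  ## lnc10883 keeps BY4742 cycling under the damage constraints
  expect_identical(
    run_dna_damage_suite("BY4742", with_lnc10883 = TRUE, model = m)$outcome,
    "Viable")
})

test_that("lncRNA suite contexts reproduce the published grid outcomes", {
  m <- cc_model()
  ## lnc10883 never rescues the HT G1 arrest
  g <- run_lncrna_suite("lnc10883", context = "HT_ethanol", model = m)
  expect_true(all(g$outcome == "Arrest_G1"))
  ## but its inhibitor overexpression bypasses an active spindle checkpoint
  g2 <- run_lncrna_suite("lnc10883", mode = "inhibitor", regime = "up",
                         context = "spindle_active", model = m)
  expect_identical(g2$outcome, "Viable")
  expect_error(run_lncrna_suite("lnc9136", context = "marsian"), "context")
})
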