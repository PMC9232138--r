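test_that("lncRNA injection rewires partners but is neutral at level zero", {
  m <- cc_model()
  inj <- inject_lncrna(m, "lnc9136", mode = "inhibitor", regime = "normal")
  ## structure: two new interactions, same nodes
  expect_identical(nrow(inj$model$nodes), 67L)
  expect_identical(nrow(inj$model$edges), 146L)
  expect_setequal(
    inj$model$edges$to[inj$model$edges$from == "lnc9136"],
    c("Gin4", "Hsl1"))
  ## with the lncRNA at 0 the dynamics are untouched
  tr0 <- simulate_model(m, preset_state(m, "regular"))
  tr1 <- simulate_model(inj$model, preset_state(inj$model, "regular"),
                        inj$constraints)
  expect_identical(as.data.frame(tr0), as.data.frame(tr1))

  expect_error(inject_lncrna(m, "lncX", mode = "inhibitor"), "unknown")
  expect_error(inject_lncrna(m, "lnc9136", targets = "Nope"), "Nope")
  expect_error(inject_lncrna(m, "lnc9136", mode = "sponge"))
})

test_that("inhibitor arithmetic suppresses partners fully at level 3", {
  m <- cc_model()
  inj <- inject_lncrna(m, "lnc9136", mode = "inhibitor", regime = "up",
                       timing = "constitutive")
  tr <- simulate_model(inj$model, preset_state(inj$model, "regular"),
                       inj$constraints)
  ## Gin4 and Hsl1 never activate anywhere in the run
  expect_identical(max(tr$Gin4), 0L)
  expect_identical(max(tr$Hsl1), 0L)
  ## the untargeted septin kinase is unaffected
  expect_gte(max(tr$Kcc4), 1L)
})

test_that("G2-triggered overexpression climbs to 3 after G2 entry", {
  m <- cc_model()
  inj <- inject_lncrna(m, "lnc9136", mode = "inhibitor", regime = "up",
                       timing = "G2_triggered")
  tr <- simulate_model(inj$model, preset_state(inj$model, "regular"),
                       inj$constraints)
  first_g2 <- which(tr$G2_proteins >= 1L)[1L]
  first_lnc <- which(tr$lnc9136 >= 1L)[1L]
  expect_gte(first_lnc, first_g2)
  expect_identical(max(tr$lnc9136), 3L)
  ## before G2 the lncRNA is silent
  expect_true(all(tr$lnc9136[seq_len(first_g2 - 1L)] == 0L))
})

test_that("lnc9136 releases the ethanol M arrest only when G2-triggered", {
  m <- cc_model()
  lt <- load_constraint_set("LT_phenotype", m)
  reg <- function(mod) preset_state(mod, "regular")

  inj <- inject_lncrna(m, "lnc9136", mode = "inhibitor", regime = "up",
                       timing = "G2_triggered")
  tr <- simulate_model(inj$model, reg(inj$model), c(lt, inj$constraints))
  expect_identical(classify_outcome(tr), "Viable")
  ## the APC/C-Cdc20 node reaches 2 in the late (attractor) states
  expect_identical(max(attractor(tr)$states[, "APCC_Cdc20"]), 2L)

  injc <- inject_lncrna(m, "lnc9136", mode = "inhibitor", regime = "up",
                        timing = "constitutive")
  trc <- simulate_model(injc$model, reg(injc$model), c(lt, injc$constraints))
  expect_match(classify_outcome(trc), "^Arrest")

  ## the same rescue with APC/C-Cdc20 off arrests in M
  tr2 <- simulate_model(inj$model, reg(inj$model),
                        c(lt, inj$constraints, list(knockout("APCC_Cdc20"))))
  expect_identical(classify_outcome(tr2), "Arrest_M")
})

test_that("without ethanol constraints the lncRNA grids are neutral except
           the lnc10883 activator overexpression", {
  m <- cc_model()
  g9 <- run_lncrna_suite("lnc9136", context = "none",
                         timing = c("constitutive", "G2_triggered"),
                         model = m)
  expect_true(all(g9$outcome == "Viable"))
  g10 <- run_lncrna_suite("lnc10883", context = "none", model = m)
  bad <- dplyr::filter(g10, .data$outcome != "Viable")
  expect_identical(nrow(bad), 1L)
  expect_identical(bad$mode, "activator")
  expect_identical(bad$regime, "up")
  expect_identical(bad$outcome, "Arrest_M")
})

test_that("boost-style injections never leave the admissible range", {
  m <- cc_model()
  for (mode in c("inhibitor", "activator")) {
    inj <- inject_lncrna(m, "lnc10883", mode = mode, regime = "up",
                         timing = "constitutive")
    tr <- simulate_model(inj$model, preset_state(inj$model, "regular"),
                         inj$constraints)
    mx <- stats::setNames(m$nodes$max, m$nodes$node)
    for (nd in c("Mec1", "Bub1", "lnc10883")) {
      expect_true(all(tr[[nd]] >= 0L & tr[[nd]] <= mx[[nd]]))
    }
  }
})
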