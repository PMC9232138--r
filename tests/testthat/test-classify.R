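test_that("functional-cycle detection requires activation, exit and reset", {
  m <- cc_model()
  reg <- preset_state(m, "regular")
  tr <- simulate_model(m, reg)
  expect_true(is_functional_cycle(tr))
  expect_identical(classify_outcome(tr), "Viable")
  expect_error(classify_arrest(tr), "functional")

  ## a point attractor is never a functional cycle
  tr_m <- simulate_model(m, reg, parse_constraints("Mating=1", m))
  expect_false(is_functional_cycle(tr_m))

  ## a cyclic-looking run missing a milestone is not functional:
  ## holding Spindle at 0 stalls before mitosis
  tr_s <- simulate_model(m, reg, list(fix_node("Spindle", 0)))
  expect_false(isTRUE(is_functional_cycle(tr_s)))

  ## unresolved trajectories classify as Unresolved, not FALSE
  tr_u <- simulate_model(m, reg, max_steps = 0)
  expect_identical(is_functional_cycle(tr_u), NA)
  expect_identical(classify_outcome(tr_u), "Unresolved")
})

test_that("arrest phases follow the attractor marker clauses with M>G2>S>G1", {
  m <- cc_model()
  reg <- preset_state(m, "regular")

  ## persistent mass with MITOSIS_EXIT = 1: M arrest
  tr <- simulate_model(m, reg, parse_constraints("Unattached_Kinetochores=2", m))
  A <- attractor(tr)$states
  expect_true(all(A[, "MASS"] > 0L & A[, "MITOSIS_EXIT"] == 1L))
  expect_identical(classify_arrest(tr), "Arrest_M")

  ## persistent mass without DNA replication: G1 arrest
  tr <- simulate_model(m, reg, parse_constraints("Mating=1", m))
  A <- attractor(tr)$states
  expect_true(all(A[, "MASS"] > 0L & A[, "DNA_Replication"] == 0L))
  expect_identical(classify_arrest(tr), "Arrest_G1")

  ## replicated DNA with the G2 driver active and no M entry: G2 arrest
  tr <- simulate_model(m, reg, parse_constraints("Clb1_2[0,1]", m))
  expect_identical(classify_arrest(tr), "Arrest_G2")

  ## consistency of the clause invariants on those attractors
  expect_true(all(attractor(tr)$states[, "DNA_Replication"] > 0L))

  ## dead state with MASS = 0 matches no clause: Unresolved
  tr <- simulate_model(m, reg, list(fix_node("MASS", 0)))
  expect_identical(classify_outcome(tr), "Unresolved")
})

test_that("literature reconciliation follows the inviable-arrest rule", {
  r <- reconcile_with_literature("Arrest_G1", "inviable")
  expect_true(r$correct)
  expect_identical(r$final_label, "Inviable")

  r <- reconcile_with_literature("Viable", "viable")
  expect_true(r$correct)
  expect_identical(r$final_label, "Viable")

  r <- reconcile_with_literature("Viable", "arrest in M")
  expect_false(r$correct)
  expect_identical(r$final_label, "Viable")

  ## a specific reported arrest is never satisfied by a different phase
  r <- reconcile_with_literature("Arrest_G2", "arrest in M")
  expect_false(r$correct)

  expect_error(reconcile_with_literature("Viable", "dead"), "unknown")
})

test_that("benchmark metrics match a hand-computed confusion matrix", {
  ## six results, one error: predicted Viable for a reported M arrest
  res <- tibble::tibble(
    reported_label = c("Viable", "Inviable", "Arrest_G1", "Arrest_M",
                       "Arrest_M", "Viable"),
    final_label = c("Viable", "Inviable", "Arrest_G1", "Arrest_M",
                    "Viable", "Viable"),
    correct = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  mt <- benchmark_metrics(res)
  expect_equal(mt$accuracy, 5 / 6)
  by <- mt$by_class
  ## Arrest_M: TP=1 FN=1 -> sensitivity 0.5; specificity 4/4
  expect_equal(by$sensitivity[by$class == "Arrest_M"], 0.5)
  expect_equal(by$specificity[by$class == "Arrest_M"], 1)
  ## Viable: TP=2 FN=0; FP=1 TN=3
  expect_equal(by$sensitivity[by$class == "Viable"], 1)
  expect_equal(by$specificity[by$class == "Viable"], 0.75)
  ## a class absent from the reports has undefined sensitivity, not zero
  expect_true(is.na(by$sensitivity[by$class == "Arrest_S"]))

  ## all-correct toy set
  res2 <- tibble::tibble(reported_label = c("Viable", "Arrest_M"),
                         final_label = c("Viable", "Arrest_M"),
                         correct = c(TRUE, TRUE))
  mt2 <- benchmark_metrics(res2)
  expect_equal(mt2$accuracy, 1)
  expect_true(all(mt2$by_class$sensitivity %in% c(1, NA)))
})
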