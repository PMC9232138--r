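test_that("constraint notation parses into the right variants", {
  m <- cc_model()
  con <- parse_constraint("Rad53[0,1]", m)
  expect_identical(con$variant, "range")
  expect_identical(c(con$lo, con$hi), c(0L, 1L))

  con <- parse_constraint("Chk1[Mec1@2]", m)
  expect_identical(con$variant, "clamp_regulator")
  expect_identical(con$regulator, "Mec1")
  expect_identical(con$value, 2L)

  expect_identical(parse_constraint("Cln3!", m)$value, 0L)
  expect_identical(parse_constraint("Cln3=3", m)$value, 3L)
  expect_identical(parse_constraint("Cln3%2", m)$value, 2L)
  expect_identical(parse_constraint("Clb1_2^", m)$variant,
                   "boost_on_activation")

  expect_error(parse_constraint("Foo[0,1]", m), "unknown node")
  expect_error(parse_constraint("Rad53[0 1]", m), "malformed")
  expect_error(parse_constraint("Mec1=9", m), "malformed|exceeds")
})

test_that("fix dominates the dynamics and conflicts are rejected", {
  m <- cc_model()
  s <- preset_state(m, "regular")
  cons <- list(fix_node("MASS", 0))
  for (i in 1:5) {
    s <- step(m, s, cons)
    expect_identical(s[["MASS"]], 0L)
  }
  expect_error(
    validate_constraints(list(fix_node("MASS", 0), fix_node("MASS", 2)), m),
    "conflicting")
  expect_error(
    validate_constraints(list(range_node("Sic1", 0, 1), fix_node("Sic1", 3)), m),
    "conflicting")
  ## disjoint constraints compose order-independently
  a <- parse_constraints("Sic1[0,1] Cdh1[0,1]", m)
  s1 <- step(m, preset_state(m, "regular"), a)
  s2 <- step(m, preset_state(m, "regular"), rev(a))
  expect_identical(s1, s2)
})

test_that("range constraints clip targets without breaking range safety", {
  m <- cc_model()
  cons <- list(range_node("Cln3", 0, 1))
  s <- preset_state(m, "regular")
  for (i in 1:30) {
    s <- step(m, s, cons)
    expect_lte(s[["Cln3"]], 1L)
  }
})

test_that("clamp_regulator re-reads one regulator without fixing it", {
  m <- cc_model()
  s <- model_state(m, MASS = 1)
  cons <- list(parse_constraint("Mec1[DNA_Damage@2]", m))
  s1 <- step(m, s, cons)
  ## Mec1 sees DNA_Damage = 2 and climbs, while DNA_Damage itself stays 0
  expect_identical(s1[["Mec1"]], 1L)
  expect_identical(s1[["DNA_Damage"]], 0L)
  s2 <- step(m, s1, cons)
  expect_identical(s2[["Mec1"]], 2L)
})

test_that("boost drives a node to its maximum on first activation only", {
  m <- cc_model()
  cons <- list(boost_on_activation("Cln3"))
  tr <- simulate_model(m, preset_state(m, "regular"), cons)
  ## the node climbs to its maximum soon after first activation ...
  expect_identical(max(tr$Cln3), 3L)
  expect_true(all(tr$Cln3 <= m$nodes$max[m$nodes$node == "Cln3"]))
  ## ... and the boost is one-shot: in the steady cycle the unmodified rule
  ## governs, so the level peaks at its normal target and resets to 0
  expect_identical(max(tr$Cln3[tr$in_attractor]), 2L)
  expect_identical(min(tr$Cln3[tr$in_attractor]), 0L)
})

test_that("expression records map to the documented constraint variants", {
  m <- cc_model()
  rec <- tibble::tibble(
    gene = c("SIC1", "CLB2", "MIH1"),
    log2fc = c(-1.2, 1.1, -1.5),
    significant = c(TRUE, TRUE, TRUE))
  cons <- constraints_from_expression(rec, m)
  expect_identical(cons[[1L]]$variant, "range")       # down -> [0,1]
  expect_identical(c(cons[[1L]]$lo, cons[[1L]]$hi), c(0L, 1L))
  expect_identical(cons[[2L]]$variant, "boost_on_activation")  # up
  expect_identical(cons[[3L]]$variant, "fix")         # Boolean down -> fix 0
  expect_identical(cons[[3L]]$value, 0L)
  ## non-differentially-expressed gene -> [0,2]
  nde <- constraints_from_expression(
    tibble::tibble(gene = "SIC1", log2fc = 0, significant = FALSE), m)[[1L]]
  expect_identical(nde$variant, "range")
  expect_identical(c(nde$lo, nde$hi), c(0L, 2L))

  ## upregulated checkpoint effectors become regulator clamps
  rec2 <- tibble::tibble(gene = "CHK1", log2fc = 0.9, significant = TRUE)
  con2 <- constraints_from_expression(rec2, m)[[1L]]
  expect_identical(con2$variant, "clamp_regulator")
  expect_identical(con2$regulator, "Mec1")

  expect_error(
    constraints_from_expression(
      tibble::tibble(gene = "NOPE", log2fc = 1, significant = TRUE), m),
    "NOPE")
})
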