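test_that("rule evaluation returns the first firing clause, else zero", {
  m <- cc_model()
  s0 <- model_state(m)
  ## MASS self-activates from the all-zero state
  expect_identical(evaluate_target(m, s0, "MASS"), 1L)
  ## a node with no firing clause decays toward 0
  expect_identical(evaluate_target(m, s0, "Cln3"), 0L)
  expect_error(evaluate_target(m, s0, "NotANode"), "NotANode")

  ## complex node: smallest value of its components
  toy <- toy_catalogue()$min_complex$model
  s <- model_state(toy, A = 1, B = 2)
  expect_identical(evaluate_target(toy, s, "C"), 1L)
  s <- model_state(toy, A = 3, B = 2, C = 1)
  expect_identical(evaluate_target(toy, s, "C"), 2L)
})

test_that("synchronous step moves every node one unit toward its target", {
  relay <- toy_catalogue()$relay$model
  s <- model_state(relay, T = 1)
  v <- integer(0)
  for (i in 1:4) {
    s <- step(relay, s)
    v <- c(v, s[["R"]])
  }
  ## target 3 is reached through the intermediate levels, one per step
  expect_identical(v, c(1L, 2L, 3L, 3L))

  ## fixed point maps to itself
  gate <- toy_catalogue()$gate$model
  fp <- model_state(gate, CP = 2, E = 2, G = 0)
  expect_identical(step(gate, fp), fp)

  ## full successor of a 3-node model matches hand evaluation of every rule:
  ## from (CP=2, E=0, G=0): CP holds 2, E climbs toward 2, G fires (E < 2)
  s <- model_state(gate, CP = 2)
  expect_identical(unname(step(gate, s)), c(2L, 1L, 1L))
})

test_that("simulate detects point and cyclic attractors by first recurrence", {
  toys <- toy_catalogue()
  tg <- toys$toggle$model
  tr <- simulate_model(tg, model_state(tg))        # 00 -> 11 -> 00 ...
  a <- attractor(tr)
  expect_identical(a$kind, "cyclic")
  expect_identical(nrow(a$states), 2L)
  tr2 <- simulate_model(tg, model_state(tg, A = 1))
  expect_identical(attractor(tr2)$kind, "point")

  ## max_steps = 0: only the initial state, unresolved
  tr3 <- simulate_model(tg, model_state(tg), max_steps = 0)
  expect_identical(nrow(tr3), 1L)
  expect_identical(attractor(tr3)$kind, "unresolved")
  expect_false(attr(tr3, "resolved"))
})

test_that("dynamics are deterministic and respect range and unit-step bounds", {
  set.seed(42)
  for (toy in toy_catalogue()) {
    m <- toy$model
    for (rep in 1:10) {
      s <- random_state(m)
      s1 <- step(m, s)
      expect_identical(s1, step(m, s))                   # determinism
      expect_true(all(abs(s1 - s) <= 1L))                # unit-step bound
      expect_true(all(s1 >= 0L & s1 <= m$nodes$max))     # range safety
    }
  }
  m <- cc_model()
  for (rep in 1:10) {
    s <- random_state(m)
    s1 <- step(m, s)
    expect_identical(s1, step(m, s))
    expect_true(all(abs(s1 - s) <= 1L))
    expect_true(all(s1 >= 0L & s1 <= m$nodes$max))
  }
})

test_that("attractor closure: stepping an attractor state walks the cycle", {
  set.seed(7)
  for (toy in toy_catalogue()) {
    m <- toy$model
    tr <- simulate_model(m, random_state(m))
    A <- attractor(tr)$states
    k <- nrow(A)
    for (i in seq_len(k)) {
      nxt <- step(m, stats::setNames(A[i, ], colnames(A)))
      expect_identical(unname(nxt), unname(A[(i %% k) + 1L, ]))
    }
  }
})

test_that("trajectories recur within the theoretical state-space bound", {
  set.seed(8)
  for (toy in toy_catalogue()) {
    m <- toy$model
    bound <- prod(m$nodes$max + 1) + 1
    tr <- simulate_model(m, random_state(m))
    expect_true(attr(tr, "resolved"))
    expect_lte(nrow(tr), bound + 1)
  }
})

test_that("model validation rejects structural errors", {
  nodes <- dplyr::bind_rows(lm_node("A", 1), lm_node("B", 1))
  expect_error(
    logic_model("bad", nodes, list(
      logic_rule("A", clause("C == 1", 1)), logic_rule("B"))),
    "undefined regulator")
  expect_error(
    logic_model("bad", nodes, list(logic_rule("A"))),
    "without a rule")
  expect_error(
    logic_model("bad", nodes, list(
      logic_rule("A", clause("B == 1", 2)), logic_rule("B"))),
    "outside")
  expect_error(clause("system('ls')", 1), "disallowed")
})
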