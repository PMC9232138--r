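## Shared fixtures: build the (expensive) cell-cycle model once per test run.
.helper_env <- new.env()

cc_model <- function() {
  if (is.null(.helper_env$cc)) .helper_env$cc <- build_cellcycle_model()
  .helper_env$cc
}

## A model whose every rule is constant zero (no clauses).
zero_model <- function(n_nodes = 3L) {
  nodes <- dplyr::bind_rows(lapply(seq_len(n_nodes), function(i) {
    lm_node(paste0("Z", i), 2)
  }))
  rules <- lapply(nodes$node, logic_rule)
  logic_model("all_zero", nodes, rules)
}

random_state <- function(model) {
  s <- vapply(model$nodes$max, function(mx) sample(0:mx, 1L), integer(1))
  stats::setNames(s, model$nodes$node)
}

expect_outcome <- function(model, init, constraints, outcome) {
  traj <- simulate_model(model, init, constraints)
  expect_identical(classify_outcome(traj), outcome)
}
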