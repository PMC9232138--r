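#' Catalogue of small hand-enumerable test models
#'
#' Four toy networks whose full state-transition graphs were enumerated by
#' hand; each entry stores the expected attractor structure alongside the
#' model, so the simulation engine and the exhaustive enumerator can be
#' cross-checked against ground truth:
#' \describe{
#'   \item{toggle}{two Boolean mutually repressing nodes (synchronous): two
#'     point attractors (01, 10) and one 2-cycle (00 <-> 11);}
#'   \item{relay}{a self-sustaining Boolean trigger drives a 0-3 node, which
#'     switches a Boolean output at level 3; exercises unit-step climbing;}
#'   \item{min_complex}{two held components and a complex node whose target
#'     is the smallest component value (the complex-formation motif);}
#'   \item{gate}{a checkpoint-style node that holds only at its peak level
#'     and blocks a "go" node while peaked.}
#' }
#'
#' @return A named list; each element has `model`, `n_attractors`,
#'   `kinds` and `basin_sizes` (sorted descending).
#' @export
toy_catalogue <- function() {
  toggle <- logic_model(
    "toy_toggle",
    nodes = dplyr::bind_rows(lm_node("A", 1), lm_node("B", 1)),
    rules = list(
      logic_rule("A", clause("B == 0", 1)),
      logic_rule("B", clause("A == 0", 1))
    )
  )

  relay <- logic_model(
    "toy_relay",
    nodes = dplyr::bind_rows(lm_node("T", 1), lm_node("R", 3),
                             lm_node("O", 1)),
    rules = list(
      logic_rule("T", clause("T >= 1", 1)),
      logic_rule("R", clause("T >= 1", 3)),
      logic_rule("O", clause("R >= 3", 1))
    )
  )

  min_complex <- logic_model(
    "toy_min_complex",
    nodes = dplyr::bind_rows(lm_node("A", 3), lm_node("B", 3),
                             lm_node("C", 3, class = "complex")),
    rules = list(
      logic_rule("A", clause("A == 3", 3), clause("A == 2", 2),
                 clause("A == 1", 1)),
      logic_rule("B", clause("B == 3", 3), clause("B == 2", 2),
                 clause("B == 1", 1)),
      logic_rule("C", clause("A >= 3 & B >= 3", 3),
                 clause("A >= 2 & B >= 2", 2),
                 clause("A >= 1 & B >= 1", 1))
    )
  )

  gate <- logic_model(
    "toy_gate",
    nodes = dplyr::bind_rows(lm_node("CP", 2, class = "checkpoint"),
                             lm_node("E", 2), lm_node("G", 1)),
    rules = list(
      logic_rule("CP", clause("CP == 2", 2)),
      logic_rule("E", clause("CP == 2", 2), clause("CP == 1", 1)),
      logic_rule("G", clause("E < 2", 1))
    )
  )

  list(
    toggle = list(model = toggle, n_attractors = 3L,
                  kinds = c("point", "point", "cyclic"),
                  basin_sizes = c(2L, 1L, 1L)),
    relay = list(model = relay, n_attractors = 2L,
                 kinds = c("point", "point"),
                 basin_sizes = c(8L, 8L)),
    min_complex = list(model = min_complex, n_attractors = 16L,
                       kinds = rep("point", 16L),
                       basin_sizes = rep(4L, 16L)),
    gate = list(model = gate, n_attractors = 2L,
                kinds = c("point", "point"),
                basin_sizes = c(12L, 6L))
  )
}
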