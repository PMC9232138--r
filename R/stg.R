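#' Exhaustively enumerate the state-transition graph of a small model
#'
#' Enumerates every admissible state (respecting fix/range constraints),
#' computes its unique synchronous successor, finds the terminal cycles
#' (attractors) of the resulting functional graph, and counts the basin of
#' attraction of each attractor. The sum of basin sizes equals the number of
#' states. Boost-on-activation constraints are stateful and therefore have no
#' state-transition graph; they are rejected.
#'
#' @inheritParams step
#' @param limit Refuse to enumerate state spaces larger than this (default
#'   `1e6`); the error reports the size estimate.
#' @return A list with `states` (tibble: one row per state with its successor
#'   index and attractor id), `attractors` (list of state matrices),
#'   `attractor_kind`, `basin_sizes` (named integer vector, names are
#'   attractor ids) and `n_states`.
#' @export
enumerate_stg <- function(model, constraints = NULL, limit = 1e6) {
  stopifnot(inherits(model, "logic_model"))
  cc <- compile_constraints(constraints, model)
  if (length(cc$boost)) {
    stop("boost_on_activation constraints are stateful and cannot be ",
         "enumerated into a state-transition graph", call. = FALSE)
  }
  nodes <- model$nodes$node
  ranges <- lapply(seq_along(nodes), function(j) {
    nd <- nodes[j]
    if (!is.na(cc$fixed[[nd]])) return(cc$fixed[[nd]])
    seq.int(cc$lo[[nd]], min(cc$hi[[nd]], model$nodes$max[j]))
  })
  size <- prod(vapply(ranges, length, numeric(1)))
  if (size > limit) {
    stop("state space has ", format(size, big.mark = ","),
         " states, above the enumeration limit of ",
         format(limit, big.mark = ","), call. = FALSE)
  }
  grid <- do.call(expand.grid, stats::setNames(ranges, nodes))
  S <- as.matrix(grid)
  storage.mode(S) <- "integer"
  succ_mat <- engine_step_mat(model, S, cc)$S
  idx <- stats::setNames(seq_len(nrow(S)), state_hash(S))
  succ <- unname(idx[state_hash(succ_mat)])
  if (anyNA(succ)) {
    ## can only happen when range constraints admit an initial value whose
    ## successor leaves the constrained grid; ranges clip targets, so the
    ## chain stays inside after one step -- add those states defensively
    stop("successor left the enumerated grid; inconsistent constraints",
         call. = FALSE)
  }

  ## functional-graph attractor labelling
  n <- nrow(S)
  attr_id <- integer(n)         # 0 = unknown
  order_seen <- integer(n)      # step index on current path, 0 = not on path
  n_attr <- 0L
  attractor_states <- list()
  for (v in seq_len(n)) {
    if (attr_id[v] > 0L) next
    path <- integer(0)
    u <- v
    while (attr_id[u] == 0L && order_seen[u] == 0L) {
      path[length(path) + 1L] <- u
      order_seen[u] <- length(path)
      u <- succ[u]
    }
    if (attr_id[u] > 0L) {
      aid <- attr_id[u]
    } else {
      ## new cycle: from u's position on the current path to the end
      n_attr <- n_attr + 1L
      aid <- n_attr
      cyc <- path[order_seen[u]:length(path)]
      attractor_states[[aid]] <- S[cyc, , drop = FALSE]
    }
    attr_id[path] <- aid
    order_seen[path] <- 0L
  }

  basin <- table(factor(attr_id, levels = seq_len(n_attr)))
  kinds <- vapply(attractor_states,
                  function(m) if (nrow(m) == 1L) "point" else "cyclic",
                  character(1))
  states <- dplyr::bind_cols(
    tibble::as_tibble(as.data.frame(S)),
    tibble::tibble(successor = succ, attractor = attr_id)
  )
  list(states = states,
       attractors = attractor_states,
       attractor_kind = kinds,
       basin_sizes = stats::setNames(as.integer(basin), seq_len(n_attr)),
       n_states = n)
}

#' Export a state-transition graph as GraphML
#'
#' Each state becomes a graph vertex with a `basin` attribute (the id of the
#' attractor its trajectory reaches) and an `in_attractor` flag; edges are
#' the synchronous transitions.
#'
#' @param stg Output of [enumerate_stg()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stg_graphml <- function(stg, path) {
  n <- stg$n_states
  in_attr <- rep(FALSE, n)
  for (m in stg$attractors) {
    in_attr[match(state_hash(m), state_hash(as.matrix(
      stg$states[, seq_len(ncol(m)), drop = FALSE]))) ] <- TRUE
  }
  g <- igraph::make_graph(rbind(seq_len(n), stg$states$successor), n = n)
  igraph::V(g)$name <- state_hash(as.matrix(
    stg$states[, setdiff(names(stg$states), c("successor", "attractor"))]))
  igraph::V(g)$basin <- stg$states$attractor
  igraph::V(g)$in_attractor <- in_attr
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
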