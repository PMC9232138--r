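#' @keywords internal
#' Build the evaluation environment for a runs-by-nodes state matrix.
target_env <- function(S) {
  env <- new.env(parent = baseenv())
  nd <- colnames(S)
  for (j in seq_along(nd)) assign(nd[j], S[, j], envir = env)
  env
}

#' @keywords internal
#' Rule-derived (unconstrained) targets for every node, vectorized over runs.
#' S: runs x nodes integer matrix with node column names.
#' clamps: list keyed by node -> named integer vector of regulator overrides.
engine_targets <- function(model, S, clamps = list()) {
  n <- nrow(S)
  env <- target_env(S)
  Tm <- matrix(0L, n, ncol(S), dimnames = list(NULL, colnames(S)))
  for (nd in colnames(S)) {
    rule <- model$rules[[nd]]
    if (!length(rule$clauses)) next
    e <- env
    cl_over <- clamps[[nd]]
    if (!is.null(cl_over)) {
      e <- new.env(parent = env)
      for (rg in names(cl_over)) assign(rg, rep(cl_over[[rg]], n), envir = e)
    }
    fired <- rep(FALSE, n)
    tj <- integer(n)
    for (cl in rule$clauses) {
      if (all(fired)) break
      hit <- !fired & cond_eval(cl$expr, e, n)
      if (any(hit)) {
        tj[hit] <- cl$target
        fired <- fired | hit
      }
    }
    Tm[, nd] <- tj
  }
  Tm
}

#' @keywords internal
#' One synchronous unit step for a chunk of runs.
#' cc: compile_constraints() output. boost_state: runs x boosted-nodes integer
#' matrix (0 = untriggered, 1 = boosting toward max, 2 = done). fix_mat:
#' optional runs x nodes matrix of per-run fixed values (NA = free).
engine_step_mat <- function(model, S, cc, boost_state = NULL, fix_mat = NULL) {
  Tm <- engine_targets(model, S, cc$clamps)
  maxes <- model$nodes$max
  if (length(cc$boost)) {
    for (k in seq_along(cc$boost)) {
      b <- cc$boost[k]
      mx <- maxes[match(b, model$nodes$node)]
      st <- boost_state[, k]
      st[st == 1L & S[, b] >= mx] <- 2L
      st[st == 0L & Tm[, b] >= 1L] <- 1L
      Tm[st == 1L, b] <- mx
      boost_state[, k] <- st
    }
  }
  ## range clipping of targets (per-node scalar bounds)
  for (j in seq_len(ncol(S))) {
    nd <- colnames(S)[j]
    if (cc$lo[[nd]] > 0L) Tm[, j] <- pmax(Tm[, j], cc$lo[[nd]])
    if (cc$hi[[nd]] < maxes[j]) Tm[, j] <- pmin(Tm[, j], cc$hi[[nd]])
  }
  S2 <- S + sign(Tm - S)
  ## hard range safety (unit step from an admissible state cannot leave the
  ## range, but constrained initial states are clipped defensively)
  S2 <- pmin(pmax(S2, 0L), rep(maxes, each = nrow(S2)))
  ## fixes dominate
  for (nd in names(cc$fixed)) {
    v <- cc$fixed[[nd]]
    if (!is.na(v)) S2[, nd] <- v
  }
  if (!is.null(fix_mat)) {
    sel <- !is.na(fix_mat)
    S2[sel] <- fix_mat[sel]
  }
  storage.mode(S2) <- "integer"
  list(S = S2, boost_state = boost_state)
}

#' Evaluate a node's rule-derived target level
#'
#' Returns the target level of `node` in `state`: the target of the first
#' clause whose condition holds, or 0 when no clause fires. This is the raw
#' rule evaluation before unit-step movement and before any constraint.
#'
#' @param model A `logic_model`.
#' @param state Named state vector (see [model_state()]).
#' @param node Node name.
#' @return Integer target in `[0, max(node)]`.
#' @export
evaluate_target <- function(model, state, node) {
  if (!node %in% model$nodes$node) {
    stop("unknown node `", node, "`", call. = FALSE)
  }
  state <- check_state(model, state)
  S <- matrix(state, 1L, dimnames = list(NULL, names(state)))
  Tm <- engine_targets(model, S)
  as.integer(Tm[1L, node])
}

#' Advance a state by one synchronous unit step
#'
#' Every node moves by at most one level toward its (constraint-modified)
#' rule target; all nodes are updated simultaneously from the same input
#' state, so the step is deterministic. Boost-on-activation constraints are
#' stateful; [simulate_model()] threads their activation flags along a
#' trajectory, and `step()` accepts/returns them via the `"boost"` attribute.
#'
#' @inheritParams evaluate_target
#' @param constraints List of [constraints] (or `NULL`).
#' @return The successor state (named integer vector). Carries a `"boost"`
#'   attribute when boost constraints are present.
#' @export
step <- function(model, state, constraints = NULL) {
  state <- check_state(model, state)
  cc <- compile_constraints(constraints, model)
  bs <- attr(state, "boost")
  if (length(cc$boost)) {
    if (is.null(bs)) bs <- matrix(0L, 1L, length(cc$boost),
                                  dimnames = list(NULL, cc$boost))
    else bs <- matrix(bs, 1L, dimnames = list(NULL, cc$boost))
  } else bs <- NULL
  ## fixes also pin the input state
  for (nd in names(cc$fixed)) {
    if (!is.na(cc$fixed[[nd]])) state[[nd]] <- cc$fixed[[nd]]
  }
  S <- matrix(state, 1L, dimnames = list(NULL, names(state)))
  out <- engine_step_mat(model, S, cc, boost_state = bs)
  s2 <- stats::setNames(as.integer(out$S[1L, ]), colnames(out$S))
  if (!is.null(out$boost_state)) {
    attr(s2, "boost") <- stats::setNames(as.integer(out$boost_state[1L, ]),
                                         cc$boost)
  }
  s2
}

#' @keywords internal
default_max_steps <- function(model) {
  if (nrow(model$nodes) <= 20L) {
    bound <- prod(model$nodes$max + 1)
    as.integer(min(4 * (bound + 1), 1e5))
  } else 5000L
}

#' @keywords internal
#' Simulate a chunk of runs in lockstep until every run revisits a state.
#' S0: runs x nodes matrix. Returns per-run recurrence bookkeeping and
#' attractor matrices (the cycle segment between the first and second visit
#' of the recurring state).
sim_chunk <- function(model, S0, cc, fix_mat = NULL, max_steps = 5000L,
                      keep_history = FALSE) {
  n <- nrow(S0)
  ## fixes pin the initial state too
  for (nd in names(cc$fixed)) {
    if (!is.na(cc$fixed[[nd]])) S0[, nd] <- cc$fixed[[nd]]
  }
  if (!is.null(fix_mat)) {
    sel <- !is.na(fix_mat)
    S0[sel] <- fix_mat[sel]
  }
  boost_state <- if (length(cc$boost)) {
    matrix(0L, n, length(cc$boost), dimnames = list(NULL, cc$boost))
  } else NULL

  hist <- vector("list", max_steps + 1L)
  hist[[1L]] <- S0
  seen <- lapply(seq_len(n), function(i) {
    e <- new.env(hash = TRUE, parent = emptyenv())
    e
  })
  h0 <- state_hash(S0)
  for (i in seq_len(n)) assign(h0[i], 0L, envir = seen[[i]])

  t1 <- rep(NA_integer_, n)
  t2 <- rep(NA_integer_, n)
  active <- rep(TRUE, n)
  S <- S0
  t <- 0L
  while (any(active) && t < max_steps) {
    out <- engine_step_mat(model, S, cc, boost_state, fix_mat)
    S <- out$S
    boost_state <- out$boost_state
    t <- t + 1L
    hist[[t + 1L]] <- S
    hh <- state_hash(S)
    for (i in which(active)) {
      prev <- get0(hh[i], envir = seen[[i]], inherits = FALSE)
      if (!is.null(prev)) {
        t1[i] <- prev
        t2[i] <- t
        active[i] <- FALSE
      } else {
        assign(hh[i], t, envir = seen[[i]])
      }
    }
  }
  n_steps <- t
  attractors <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.na(t1[i])) next
    rows <- seq.int(t1[i], t2[i] - 1L)
    A <- do.call(rbind, lapply(rows + 1L, function(r) hist[[r]][i, , drop = FALSE]))
    colnames(A) <- colnames(S0)
    attractors[[i]] <- A
  }
  list(
    t1 = t1, t2 = t2, resolved = !is.na(t1), n_steps = n_steps,
    attractors = attractors,
    history = if (keep_history) hist[seq_len(n_steps + 1L)] else NULL
  )
}

#' Simulate a trajectory to its attractor
#'
#' Iterates the synchronous unit step from `initial` until a previously
#' visited state recurs (the dynamics are deterministic, so recurrence
#' identifies the attractor: the cycle is the segment between the first and
#' second visit of the recurring state; a segment of length one is a point
#' attractor) or until `max_steps` is exhausted, in which case the trajectory
#' is flagged unresolved rather than silently truncated.
#'
#' @inheritParams step
#' @param initial Initial state, e.g. from [preset_state()] or [model_state()].
#' @param max_steps Step budget. Defaults to four times the theoretical
#'   recurrence bound for models of at most 20 nodes, and 5,000 otherwise.
#' @return A `yc_trajectory`: a tibble with `step`, one column per node and
#'   `in_attractor`, plus attributes `attractor` (list with `kind`,
#'   `states`, `transient_length`), `resolved`, and `model_name`.
#' @export
simulate_model <- function(model, initial, constraints = NULL,
                           max_steps = default_max_steps(model)) {
  stopifnot(inherits(model, "logic_model"))
  initial <- check_state(model, initial)
  cc <- compile_constraints(constraints, model)
  S0 <- matrix(initial, 1L, dimnames = list(NULL, names(initial)))
  if (max_steps == 0L) {
    traj <- tibble::as_tibble(as.data.frame(S0))
    traj <- dplyr::bind_cols(tibble::tibble(step = 0L), traj,
                             tibble::tibble(in_attractor = FALSE))
    return(new_trajectory(traj, kind = "unresolved", states = NULL,
                          transient_length = NA_integer_, resolved = FALSE,
                          model = model))
  }
  res <- sim_chunk(model, S0, cc, max_steps = max_steps, keep_history = TRUE)
  states <- do.call(rbind, lapply(res$history, function(m) m[1L, , drop = FALSE]))
  traj <- tibble::as_tibble(as.data.frame(states))
  n_states <- nrow(traj)
  if (res$resolved[1L]) {
    t1 <- res$t1[1L]; t2 <- res$t2[1L]
    in_attr <- seq_len(n_states) - 1L >= t1
    A <- res$attractors[[1L]]
    kind <- if (nrow(A) == 1L) "point" else "cyclic"
    traj <- dplyr::bind_cols(tibble::tibble(step = seq_len(n_states) - 1L),
                             traj, tibble::tibble(in_attractor = in_attr))
    new_trajectory(traj, kind = kind, states = A, transient_length = t1,
                   resolved = TRUE, model = model)
  } else {
    traj <- dplyr::bind_cols(tibble::tibble(step = seq_len(n_states) - 1L),
                             traj, tibble::tibble(in_attractor = FALSE))
    new_trajectory(traj, kind = "unresolved", states = NULL,
                   transient_length = NA_integer_, resolved = FALSE,
                   model = model)
  }
}

#' @keywords internal
new_trajectory <- function(tbl, kind, states, transient_length, resolved,
                           model) {
  structure(tbl,
            class = c("yc_trajectory", "tbl_df", "tbl", "data.frame"),
            attractor = list(kind = kind, states = states,
                             transient_length = transient_length),
            resolved = resolved,
            model_name = model$name,
            node_names = model$nodes$node)
}

#' Attractor report of a trajectory
#'
#' @param traj A `yc_trajectory`.
#' @return A list with `kind` (`"point"`, `"cyclic"` or `"unresolved"`),
#'   `states` (matrix, one row per attractor state) and `transient_length`.
#' @export
attractor <- function(traj) {
  stopifnot(inherits(traj, "yc_trajectory"))
  attr(traj, "attractor")
}

#' @export
print.yc_trajectory <- function(x, ...) {
  a <- attr(x, "attractor")
  cat("<yc_trajectory> ", attr(x, "model_name"), ": ",
      nrow(x), " states, attractor ", a$kind,
      if (a$kind == "cyclic") paste0(" (length ", nrow(a$states), ")"),
      "\n", sep = "")
  NextMethod()
}
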