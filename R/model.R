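#' Create a logical-model node specification
#'
#' A node holds an integer level in `0:max`. `max` is 1 for Boolean-limited
#' nodes and up to 3 for fully multivalued nodes. The node class records the
#' biological reading of the levels (protein yield, complex activity,
#' phenomenological milestone, checkpoint signal, regulatory-element activity,
#' gene/lncRNA expression); it does not alter the dynamics.
#'
#' @param name Node identifier (syntactic R name).
#' @param max Maximum admissible level, an integer in 1:3.
#' @param class One of `"protein"`, `"complex"`, `"phenomenological"`,
#'   `"checkpoint"`, `"regulatory_element"`, `"gene_or_lncRNA"`.
#' @return A one-row tibble.
#' @export
lm_node <- function(name, max = 3L,
                    class = c("protein", "complex", "phenomenological",
                              "checkpoint", "regulatory_element",
                              "gene_or_lncRNA")) {
  class <- match.arg(class)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (make.names(name) != name) {
    stop("node name `", name, "` is not a syntactic identifier", call. = FALSE)
  }
  max <- as.integer(max)
  if (is.na(max) || max < 1L || max > 3L) {
    stop("node `", name, "`: max level must be 1, 2 or 3", call. = FALSE)
  }
  tibble::tibble(node = name, max = max, class = class)
}

#' Create a logical update rule
#'
#' A rule is an ordered list of clauses `condition -> target level`; the first
#' clause whose condition holds in the current state supplies the node's target
#' level, and a node with no firing clause has target 0 (levels never reached
#' by any clause decay to 0, matching the behavior of synchronous logical
#' simulators).
#'
#' @param node Name of the node the rule updates.
#' @param ... Clauses created with [clause()], evaluated in order.
#' @return A `yc_rule` object.
#' @export
logic_rule <- function(node, ...) {
  clauses <- list(...)
  if (length(clauses) == 1L && is.list(clauses[[1L]]) &&
      !inherits(clauses[[1L]], "yc_clause")) {
    clauses <- clauses[[1L]]
  }
  for (cl in clauses) {
    if (!inherits(cl, "yc_clause")) {
      stop("rule for `", node, "`: clauses must be built with clause()",
           call. = FALSE)
    }
  }
  structure(list(node = node, clauses = clauses), class = "yc_rule")
}

#' @rdname logic_rule
#' @param when Condition string (see Details in [logic_rule()]).
#' @param target Target level when the condition holds.
#' @export
clause <- function(when, target) {
  expr <- cond_parse(when)
  cond_check(expr, when)
  structure(list(when = when, expr = expr, target = as.integer(target),
                 vars = cond_vars(expr)),
            class = "yc_clause")
}

#' Assemble a multivalued logical model
#'
#' Binds node specifications, one update rule per node, and a signed edge
#' list into a validated model object for the synchronous unit-step engine.
#'
#' @param name Model name (used in printing and file headers).
#' @param nodes Tibble of node specs, usually `dplyr::bind_rows()` of
#'   [lm_node()] calls. Declaration order is the canonical node order used for
#'   state vectors, hashing and file formats.
#' @param rules List of [logic_rule()] objects, one per node (any order).
#' @param edges Optional tibble with columns `from`, `to`, `sign`
#'   (`sign` in `c("+", "-")`). When omitted, edges are derived from the rule
#'   regulators with sign `"+"`. When supplied, the (from, to) pairs must
#'   exactly match the regulators referenced by the rules.
#' @return A `logic_model` object.
#' @export
logic_model <- function(name, nodes, rules, edges = NULL) {
  stopifnot(is.data.frame(nodes), all(c("node", "max", "class") %in% names(nodes)))
  nodes <- tibble::as_tibble(nodes)
  if (anyDuplicated(nodes$node)) {
    stop("duplicate node names: ",
         paste(unique(nodes$node[duplicated(nodes$node)]), collapse = ", "),
         call. = FALSE)
  }
  rule_nodes <- vapply(rules, function(r) r$node, character(1))
  if (anyDuplicated(rule_nodes)) {
    stop("more than one rule for node(s): ",
         paste(unique(rule_nodes[duplicated(rule_nodes)]), collapse = ", "),
         call. = FALSE)
  }
  missing_rules <- setdiff(nodes$node, rule_nodes)
  if (length(missing_rules)) {
    stop("nodes without a rule: ", paste(missing_rules, collapse = ", "),
         call. = FALSE)
  }
  extra_rules <- setdiff(rule_nodes, nodes$node)
  if (length(extra_rules)) {
    stop("rules for undeclared node(s): ", paste(extra_rules, collapse = ", "),
         call. = FALSE)
  }
  rules <- rules[match(nodes$node, rule_nodes)]
  names(rules) <- nodes$node

  ## regulator sanity + per-node regulator sets
  reg_sets <- lapply(rules, function(r) {
    vars <- unique(unlist(lapply(r$clauses, `[[`, "vars")))
    bad <- setdiff(vars, nodes$node)
    if (length(bad)) {
      stop("rule for `", r$node, "` references undefined regulator(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (cl in r$clauses) {
      if (cl$target < 0L || cl$target > nodes$max[nodes$node == r$node]) {
        stop("rule for `", r$node, "`: clause target ", cl$target,
             " outside [0, max]", call. = FALSE)
      }
    }
    vars
  })

  derived <- dplyr::bind_rows(purrr::imap(reg_sets, function(regs, nd) {
    if (!length(regs)) return(NULL)
    tibble::tibble(from = regs, to = nd)
  }))
  if (is.null(edges)) {
    edges <- dplyr::mutate(derived, sign = "+")
  } else {
    edges <- tibble::as_tibble(edges)
    stopifnot(all(c("from", "to", "sign") %in% names(edges)))
    key <- function(d) paste(d$from, d$to, sep = "\r")
    miss <- setdiff(key(derived), key(edges))
    extra <- setdiff(key(edges), key(derived))
    if (length(miss) || length(extra)) {
      fmt <- function(k) paste(sub("\r", " -> ", k), collapse = "; ")
      msg <- c(
        if (length(miss)) paste0("regulations used by rules but not declared: ", fmt(miss)),
        if (length(extra)) paste0("declared edges never used by rules: ", fmt(extra))
      )
      stop("edge list inconsistent with rules.\n  ",
           paste(msg, collapse = "\n  "), call. = FALSE)
    }
  }

  model <- structure(
    list(name = name, nodes = nodes, rules = rules,
         edges = tibble::as_tibble(edges)),
    class = "logic_model"
  )
  model
}

#' @export
print.logic_model <- function(x, ...) {
  cat("<logic_model> ", x$name, "\n", sep = "")
  cat("  nodes: ", nrow(x$nodes), "  interactions: ", nrow(x$edges), "\n", sep = "")
  cls <- table(x$nodes$class)
  cat("  classes: ", paste(names(cls), cls, sep = "=", collapse = ", "), "\n", sep = "")
  sp <- prod(x$nodes$max + 1)
  cat("  state space: ", format(sp, big.mark = ","), " states\n", sep = "")
  invisible(x)
}

#' Per-node structure report of a model
#'
#' @param model A `logic_model`.
#' @return A tibble with one row per node: level range, class, regulators,
#'   and number of clauses.
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "logic_model"))
  regs <- vapply(model$rules, function(r) {
    v <- unique(unlist(lapply(r$clauses, `[[`, "vars")))
    paste(v, collapse = ",")
  }, character(1))
  tibble::tibble(
    node = model$nodes$node,
    max = model$nodes$max,
    class = model$nodes$class,
    n_clauses = vapply(model$rules, function(r) length(r$clauses), integer(1)),
    regulators = unname(regs[model$nodes$node])
  )
}

#' Construct a valid system state for a model
#'
#' @param model A `logic_model`.
#' @param ... Named node levels; unnamed nodes default to 0.
#' @param values Optional named vector/list used instead of `...`.
#' @return A named integer vector in canonical node order.
#' @export
model_state <- function(model, ..., values = NULL) {
  if (is.null(values)) values <- c(...)
  s <- stats::setNames(integer(nrow(model$nodes)), model$nodes$node)
  if (length(values)) {
    bad <- setdiff(names(values), model$nodes$node)
    if (length(bad)) {
      stop("unknown node(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    s[names(values)] <- as.integer(values)
  }
  check_state(model, s)
  s
}

#' @keywords internal
check_state <- function(model, state) {
  if (is.null(names(state)) || !identical(names(state), model$nodes$node)) {
    if (!all(model$nodes$node %in% names(state))) {
      stop("state does not cover all model nodes", call. = FALSE)
    }
    state <- state[model$nodes$node]
  }
  if (any(state < 0L | state > model$nodes$max)) {
    bad <- model$nodes$node[state < 0L | state > model$nodes$max]
    stop("state outside admissible range for node(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(state)
}

#' @keywords internal
state_hash <- function(mat) {
  ## mat: runs x nodes integer matrix -> one compact key per run
  do.call(paste, c(lapply(seq_len(ncol(mat)), function(j) mat[, j]),
                   list(sep = ".")))
}
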