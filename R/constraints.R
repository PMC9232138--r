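#' Perturbation constraints
#'
#' Constraints modify how a simulation updates node levels:
#' \describe{
#'   \item{fix}{the node holds a single value for the whole run (knockout =
#'     fix at 0, overexpression = fix at the maximum level);}
#'   \item{range}{the node's rule-derived target is clipped into `[lo, hi]`;}
#'   \item{clamp_regulator}{the rule of one node is evaluated with a chosen
#'     regulator read at a fixed level, while the regulator itself continues
#'     to evolve normally (the `X[Y@n]` notation);}
#'   \item{boost_on_activation}{the first time the node's unmodified target
#'     reaches 1 or more, the target is forced to the node's maximum until the
#'     node gets there; afterwards the unmodified rule governs. This encodes
#'     an upregulated gene that climbs to full yield soon after activation and
#'     is then sustained or degraded by its normal regulation.}
#' }
#'
#' @param node,target_node,regulator Node names.
#' @param value,lo,hi Integer levels.
#' @param provenance Free-text note on where the constraint comes from.
#' @return A `yc_constraint` object.
#' @name constraints
NULL

new_constraint <- function(variant, node, lo = NA_integer_, hi = NA_integer_,
                           regulator = NA_character_, value = NA_integer_,
                           provenance = "") {
  structure(list(variant = variant, node = node, lo = as.integer(lo),
                 hi = as.integer(hi), regulator = regulator,
                 value = as.integer(value), provenance = provenance),
            class = "yc_constraint")
}

#' @rdname constraints
#' @export
fix_node <- function(node, value, provenance = "") {
  new_constraint("fix", node, value = value, provenance = provenance)
}

#' @rdname constraints
#' @export
knockout <- function(node, provenance = "") fix_node(node, 0L, provenance)

#' @rdname constraints
#' @export
range_node <- function(node, lo, hi, provenance = "") {
  if (lo > hi) stop("range constraint on `", node, "`: lo > hi", call. = FALSE)
  new_constraint("range", node, lo = lo, hi = hi, provenance = provenance)
}

#' @rdname constraints
#' @export
clamp_regulator <- function(target_node, regulator, value, provenance = "") {
  new_constraint("clamp_regulator", target_node, regulator = regulator,
                 value = value, provenance = provenance)
}

#' @rdname constraints
#' @export
boost_on_activation <- function(node, provenance = "") {
  new_constraint("boost_on_activation", node, provenance = provenance)
}

#' @export
print.yc_constraint <- function(x, ...) {
  cat(format_constraint(x), "\n")
  invisible(x)
}

#' @keywords internal
format_constraint <- function(con) {
  switch(con$variant,
    fix = if (con$value == 0L) paste0(con$node, "!")
          else paste0(con$node, "=", con$value),
    range = paste0(con$node, "[", con$lo, ",", con$hi, "]"),
    clamp_regulator = paste0(con$node, "[", con$regulator, "@", con$value, "]"),
    boost_on_activation = paste0(con$node, "^")
  )
}

#' Parse a constraint from its text notation
#'
#' Recognized forms: `Name!` (knockout, fix at 0), `Name=v` or GINsim-style
#' `Name%v` (fix at `v`; overexpression is fix at the node maximum),
#' `Name[lo,hi]` (admissible-value range), `Name[Reg@v]` (evaluate `Name`'s
#' rule with regulator `Reg` read at level `v`), and `Name^`
#' (boost-on-activation).
#'
#' @param text A single constraint string.
#' @param model The model the constraint applies to (names are validated).
#' @return A `yc_constraint`.
#' @export
parse_constraint <- function(text, model) {
  stopifnot(inherits(model, "logic_model"))
  txt <- trimws(text)
  nm <- "[A-Za-z][A-Za-z0-9_.]*"
  con <-
    if (grepl(paste0("^", nm, "!$"), txt)) {
      knockout(sub("!$", "", txt))
    } else if (grepl(paste0("^", nm, "\\^$"), txt)) {
      boost_on_activation(sub("\\^$", "", txt))
    } else if (grepl(paste0("^", nm, "[=%][0-9]$"), txt)) {
      parts <- strsplit(txt, "[=%]")[[1L]]
      fix_node(parts[1L], as.integer(parts[2L]))
    } else if (grepl(paste0("^", nm, "\\[[0-9],[0-9]\\]$"), txt)) {
      node <- sub("\\[.*$", "", txt)
      lohi <- as.integer(strsplit(gsub("^.*\\[|\\]$", "", txt), ",")[[1L]])
      range_node(node, lohi[1L], lohi[2L])
    } else if (grepl(paste0("^", nm, "\\[", nm, "@[0-9]\\]$"), txt)) {
      node <- sub("\\[.*$", "", txt)
      inner <- strsplit(gsub("^.*\\[|\\]$", "", txt), "@")[[1L]]
      clamp_regulator(node, inner[1L], as.integer(inner[2L]))
    } else {
      stop("malformed constraint `", text, "` (at position ",
           regexpr("[^A-Za-z0-9_.]", txt)[1L], ")", call. = FALSE)
    }
  validate_constraints(list(con), model)
  con
}

#' @rdname parse_constraint
#' @param texts Character vector of constraint strings, or a single string
#'   with constraints separated by whitespace.
#' @export
parse_constraints <- function(texts, model) {
  toks <- unlist(strsplit(texts, "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  lapply(toks, parse_constraint, model = model)
}

#' Validate and compose a constraint set
#'
#' Checks node names against the model, level bounds, and rejects conflicting
#' constraints on the same node (composition is order-independent for
#' disjoint nodes).
#'
#' @param constraints List of `yc_constraint`.
#' @param model A `logic_model`.
#' @return The (invisibly) validated list.
#' @export
validate_constraints <- function(constraints, model) {
  if (is.null(constraints)) return(invisible(list()))
  if (inherits(constraints, "yc_constraint")) constraints <- list(constraints)
  maxes <- stats::setNames(model$nodes$max, model$nodes$node)
  for (con in constraints) {
    if (!inherits(con, "yc_constraint")) {
      stop("constraints must be yc_constraint objects", call. = FALSE)
    }
    if (!con$node %in% names(maxes)) {
      stop("constraint names unknown node `", con$node, "`", call. = FALSE)
    }
    if (con$variant == "clamp_regulator") {
      if (!con$regulator %in% names(maxes)) {
        stop("constraint on `", con$node, "` names unknown regulator `",
             con$regulator, "`", call. = FALSE)
      }
      if (con$value > maxes[[con$regulator]]) {
        stop("clamp level ", con$value, " exceeds max of `", con$regulator,
             "`", call. = FALSE)
      }
    }
    if (con$variant == "fix" && con$value > maxes[[con$node]]) {
      stop("fix level ", con$value, " exceeds max of `", con$node, "`",
           call. = FALSE)
    }
    if (con$variant == "range" && con$hi > maxes[[con$node]]) {
      stop("range upper bound ", con$hi, " exceeds max of `", con$node, "`",
           call. = FALSE)
    }
  }
  ## conflict detection
  vt <- vapply(constraints, `[[`, character(1), "variant")
  nd <- vapply(constraints, `[[`, character(1), "node")
  on_node <- split(seq_along(constraints), nd)
  for (idx in on_node) {
    level_cons <- idx[vt[idx] %in% c("fix", "range", "boost_on_activation")]
    if (length(level_cons) > 1L) {
      sigs <- vapply(constraints[level_cons], format_constraint, character(1))
      if (length(unique(sigs)) > 1L) {
        stop("conflicting constraints on node `", nd[idx[1L]], "`: ",
             paste(sigs, collapse = " vs "), call. = FALSE)
      }
    }
    clamps <- idx[vt[idx] == "clamp_regulator"]
    if (length(clamps) > 1L) {
      key <- vapply(constraints[clamps],
                    function(c) paste0(c$regulator), character(1))
      dup <- duplicated(key)
      if (any(dup)) {
        vals <- vapply(constraints[clamps], `[[`, integer(1), "value")
        if (any(tapply(vals, key, function(v) length(unique(v))) > 1L)) {
          stop("conflicting regulator clamps on node `", nd[idx[1L]], "`",
               call. = FALSE)
        }
      }
    }
  }
  invisible(constraints)
}

#' @keywords internal
#' Split a validated constraint list into the internal pieces the engine uses.
compile_constraints <- function(constraints, model) {
  constraints <- validate_constraints(constraints, model)
  nodes <- model$nodes$node
  fixed <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  lo <- stats::setNames(rep(0L, length(nodes)), nodes)
  hi <- stats::setNames(model$nodes$max, nodes)
  clamps <- list()
  boost <- character(0)
  for (con in constraints) {
    switch(con$variant,
      fix = { fixed[[con$node]] <- con$value },
      range = {
        lo[[con$node]] <- max(lo[[con$node]], con$lo)
        hi[[con$node]] <- min(hi[[con$node]], con$hi)
      },
      clamp_regulator = {
        clamps[[con$node]] <- c(clamps[[con$node]],
                                stats::setNames(con$value, con$regulator))
      },
      boost_on_activation = { boost <- union(boost, con$node) }
    )
  }
  list(fixed = fixed, lo = lo, hi = hi, clamps = clamps, boost = boost)
}
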