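#' Read and write models in the native text format
#'
#' One block per node: a header line
#' `node <name> max=<m> class=<class>` followed by one indented line per
#' clause, `when <condition> -> <target>`, in priority order. Nodes appear in
#' canonical declaration order; a node with no clause lines has the
#' constant-zero rule. Lines starting with `#` are comments. The format
#' round-trips exactly.
#'
#' @param model A `logic_model`.
#' @param path File path.
#' @return `write_model_native()` returns `path` invisibly;
#'   `read_model_native()` returns a `logic_model`.
#' @export
write_model_native <- function(model, path) {
  stopifnot(inherits(model, "logic_model"))
  out <- c(paste0("# logic model: ", model$name),
           paste0("# nodes: ", nrow(model$nodes),
                  "  interactions: ", nrow(model$edges)))
  for (i in seq_len(nrow(model$nodes))) {
    nd <- model$nodes$node[i]
    out <- c(out, paste0("node ", nd, " max=", model$nodes$max[i],
                         " class=", model$nodes$class[i]))
    for (cl in model$rules[[nd]]$clauses) {
      out <- c(out, paste0("  when ", cl$when, " -> ", cl$target))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_model_native
#' @param name Model name for the loaded object (defaults to the name in the
#'   file header, or the file name).
#' @export
read_model_native <- function(path, name = NULL) {
  lines <- readLines(path)
  if (is.null(name)) {
    hdr <- grep("^# logic model:", lines, value = TRUE)
    name <- if (length(hdr)) trimws(sub("^# logic model:", "", hdr[1L]))
            else sub("\\.[^.]*$", "", basename(path))
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  node_idx <- grep("^node ", lines)
  if (!length(node_idx)) stop("no node blocks in ", path, call. = FALSE)
  nodes <- list(); rules <- list()
  bounds <- c(node_idx, length(lines) + 1L)
  for (k in seq_along(node_idx)) {
    hdr <- lines[node_idx[k]]
    mt <- regmatches(hdr, regexec(
      "^node ([A-Za-z][A-Za-z0-9_.]*) max=([0-9]) class=([A-Za-z_]+)\\s*$", hdr))[[1L]]
    if (length(mt) != 4L) stop("malformed node header: ", hdr, call. = FALSE)
    nodes[[k]] <- lm_node(mt[2L], as.integer(mt[3L]), mt[4L])
    body <- if (bounds[k + 1L] - 1L >= node_idx[k] + 1L) {
      lines[(node_idx[k] + 1L):(bounds[k + 1L] - 1L)]
    } else character(0)
    clauses <- lapply(body, function(ln) {
      mc <- regmatches(ln, regexec("^\\s*when (.*) -> ([0-9])\\s*$", ln))[[1L]]
      if (length(mc) != 3L) stop("malformed clause line: ", ln, call. = FALSE)
      clause(mc[2L], as.integer(mc[3L]))
    })
    rules[[k]] <- logic_rule(mt[2L], clauses)
  }
  logic_model(name, dplyr::bind_rows(nodes), rules)
}

#' Export a trajectory as TSV
#'
#' One row per simulation step, one column per node (the tabular twin of the
#' trajectory heat maps), plus an `in_attractor` flag in the final column.
#'
#' @param traj A `yc_trajectory`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "yc_trajectory"))
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
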