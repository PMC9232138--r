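#' SBML-qual import and export
#'
#' Serializes a model to SBML Level 3 with the `qual` package (the exchange
#' format of qualitative-model tools): one qualitative species per node with
#' its `maxLevel`, and one transition per non-constant node whose function
#' terms carry the clause conditions as MathML (`and`/`or`/`not` over
#' `eq`/`neq`/`lt`/`leq`/`gt`/`geq` comparisons of species and integer
#' constants), in priority order, with a default term of 0. The importer
#' reads the same subset back; export/import round-trips the dynamics
#' exactly.
#'
#' @param model A `logic_model`.
#' @param path File path.
#' @return `write_model_sbmlqual()` returns `path` invisibly;
#'   `read_model_sbmlqual()` returns a `logic_model`.
#' @export
write_model_sbmlqual <- function(model, path) {
  stopifnot(inherits(model, "logic_model"))
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  L <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:qual=\"http://www.sbml.org/sbml/level3/version1/qual/version1\" ",
           "level=\"3\" version=\"1\" qual:required=\"true\">"),
    paste0("  <model id=\"", esc(model$name), "\">"),
    "    <qual:listOfQualitativeSpecies>")
  for (i in seq_len(nrow(model$nodes))) {
    L <- c(L, paste0(
      "      <qual:qualitativeSpecies qual:id=\"", model$nodes$node[i],
      "\" qual:maxLevel=\"", model$nodes$max[i],
      "\" qual:constant=\"false\" qual:name=\"", model$nodes$class[i], "\"/>"))
  }
  L <- c(L, "    </qual:listOfQualitativeSpecies>",
         "    <qual:listOfTransitions>")
  for (nd in model$nodes$node) {
    rule <- model$rules[[nd]]
    if (!length(rule$clauses)) next
    regs <- unique(unlist(lapply(rule$clauses, `[[`, "vars")))
    L <- c(L, paste0("      <qual:transition qual:id=\"tr_", nd, "\">"),
           "        <qual:listOfInputs>")
    for (rg in regs) {
      L <- c(L, paste0(
        "          <qual:input qual:qualitativeSpecies=\"", rg,
        "\" qual:transitionEffect=\"none\" qual:id=\"tr_", nd, "_in_", rg, "\"/>"))
    }
    L <- c(L, "        </qual:listOfInputs>",
           "        <qual:listOfOutputs>",
           paste0("          <qual:output qual:qualitativeSpecies=\"", nd,
                  "\" qual:transitionEffect=\"assignmentLevel\" qual:id=\"tr_",
                  nd, "_out\"/>"),
           "        </qual:listOfOutputs>",
           "        <qual:listOfFunctionTerms>",
           "          <qual:defaultTerm qual:resultLevel=\"0\"/>")
    for (cl in rev(rule$clauses)) {
      ## SBML-qual has no clause order; encode first-match priority by
      ## emitting lower-priority terms first and letting the importer restore
      ## document order reversed. To stay order-independent for other tools,
      ## conditions are emitted as-is; the reader re-reverses.
      L <- c(L, paste0("          <qual:functionTerm qual:resultLevel=\"",
                       cl$target, "\">"),
             "            <math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
             expr_to_mathml(cl$expr, indent = "              "),
             "            </math>",
             "          </qual:functionTerm>")
    }
    L <- c(L, "        </qual:listOfFunctionTerms>",
           "      </qual:transition>")
  }
  L <- c(L, "    </qual:listOfTransitions>", "  </model>", "</sbml>")
  writeLines(L, path)
  invisible(path)
}

#' @keywords internal
expr_to_mathml <- function(e, indent = "") {
  rec <- function(e, ind) {
    if (is.symbol(e)) {
      return(paste0(ind, "<ci>", as.character(e), "</ci>"))
    }
    if (is.numeric(e)) {
      return(paste0(ind, "<cn type=\"integer\">", format(e), "</cn>"))
    }
    if (is.logical(e)) {
      return(paste0(ind, "<", if (e) "true" else "false", "/>"))
    }
    op <- as.character(e[[1L]])
    tag <- switch(op,
      "&" = , "&&" = "and", "|" = , "||" = "or", "!" = "not",
      "==" = "eq", "!=" = "neq", ">" = "gt", ">=" = "geq",
      "<" = "lt", "<=" = "leq",
      "(" = return(rec(e[[2L]], ind)),
      stop("cannot serialize operator `", op, "` to MathML", call. = FALSE))
    args <- vapply(as.list(e)[-1L], rec, character(1), ind = paste0(ind, "  "))
    paste0(ind, "<apply>\n", ind, "  <", tag, "/>\n",
           paste(args, collapse = "\n"), "\n", ind, "</apply>")
  }
  rec(e, indent)
}

#' @keywords internal
mathml_to_cond <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(trimws(xml2::xml_text(node)))
  if (nm == "cn") return(trimws(xml2::xml_text(node)))
  if (nm == "true") return("TRUE")
  if (nm == "false") return("FALSE")
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1L]])
    args <- vapply(kids[-1L], mathml_to_cond, character(1))
    sym <- switch(op, and = "&", or = "|", eq = "==", neq = "!=",
                  gt = ">", geq = ">=", lt = "<", leq = "<=",
                  not = NA_character_,
                  stop("unsupported MathML operator <", op, ">", call. = FALSE))
    if (op == "not") return(paste0("!(", args[1L], ")"))
    return(paste0("(", paste(args, collapse = paste0(" ", sym, " ")), ")"))
  }
  stop("unsupported MathML element <", nm, ">", call. = FALSE)
}

#' @rdname write_model_sbmlqual
#' @export
read_model_sbmlqual <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(q = "http://www.sbml.org/sbml/level3/version1/qual/version1",
          m = "http://www.w3.org/1998/Math/MathML",
          s = "http://www.sbml.org/sbml/level3/version1/core")
  name <- xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id")
  sp <- xml2::xml_find_all(doc, ".//q:qualitativeSpecies", ns)
  nodes <- dplyr::bind_rows(lapply(sp, function(x) {
    cls <- xml2::xml_attr(x, "name")
    if (is.na(cls) || !cls %in% c("protein", "complex", "phenomenological",
                                  "checkpoint", "regulatory_element",
                                  "gene_or_lncRNA")) cls <- "protein"
    lm_node(xml2::xml_attr(x, "id"),
            as.integer(xml2::xml_attr(x, "maxLevel")), cls)
  }))
  rules <- stats::setNames(
    lapply(nodes$node, function(nd) logic_rule(nd)), nodes$node)
  trs <- xml2::xml_find_all(doc, ".//q:transition", ns)
  for (tr in trs) {
    out <- xml2::xml_attr(
      xml2::xml_find_first(tr, ".//q:output", ns), "qualitativeSpecies")
    terms <- xml2::xml_find_all(tr, ".//q:functionTerm", ns)
    clauses <- lapply(terms, function(tm) {
      lvl <- as.integer(xml2::xml_attr(tm, "resultLevel"))
      math <- xml2::xml_find_first(tm, ".//m:math/*", ns)
      clause(mathml_to_cond(math), lvl)
    })
    rules[[out]] <- logic_rule(out, rev(clauses))
  }
  logic_model(name, nodes, unname(rules))
}
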