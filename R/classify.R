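#' Outcome classification of cell-cycle trajectories
#'
#' A simulation is a *functional cell cycle* when its attractor is cyclic and,
#' within the attractor, every phenomenological node (MASS, BUD,
#' DNA_Replication, Spindle, MITOSIS_EXIT) activates (level >= 1),
#' MITOSIS_EXIT reaches its peak level 2 (mitotic exit), and every
#' phenomenological node -- most importantly MASS -- returns to 0 so the cycle
#' can restart. Anything else with persistent mass and incomplete mitotic
#' exit is an arrest, assigned a phase from the attractor states:
#' \itemize{
#'   \item G1 arrest: MASS > 0, MITOSIS_EXIT < 2, DNA not replicated;
#'   \item S arrest: DNA replicated but the S-phase driver node back at 0;
#'   \item G2 arrest: DNA replicated and the G2-phase driver node active;
#'   \item M arrest: MITOSIS_EXIT stalled at 1.
#' }
#' When several phase clauses hold simultaneously the later phase wins
#' (M > G2 > S > G1): later-phase markers are strictly more informative.
#' @name classification
NULL

.phen_nodes <- c("MASS", "BUD", "DNA_Replication", "Spindle", "MITOSIS_EXIT")

.outcome_levels <- c("Viable", "Inviable", "Arrest_G1", "Arrest_S",
                     "Arrest_G2", "Arrest_M", "Unresolved")

#' @keywords internal
attractor_matrix <- function(traj) {
  a <- attractor(traj)
  if (is.null(a$states)) NULL else a$states
}

#' @rdname classification
#' @param traj A `yc_trajectory` from [simulate_model()] over a model that
#'   contains the phenomenological nodes.
#' @return `is_functional_cycle()`: `TRUE`/`FALSE`, or `NA` for an unresolved
#'   trajectory.
#' @export
is_functional_cycle <- function(traj) {
  a <- attractor(traj)
  if (a$kind == "unresolved") return(NA)
  if (a$kind != "cyclic") return(FALSE)
  A <- a$states
  miss <- setdiff(.phen_nodes, colnames(A))
  if (length(miss)) {
    stop("model lacks phenomenological node(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok_act <- all(apply(A[, .phen_nodes, drop = FALSE], 2, max) >= 1L)
  ok_reset <- all(apply(A[, .phen_nodes, drop = FALSE], 2, min) == 0L)
  ok_exit <- max(A[, "MITOSIS_EXIT"]) == 2L
  ok_act && ok_reset && ok_exit
}

#' @keywords internal
#' Phase labels from the arrest clauses, evaluated on a matrix of attractor
#' states; returns the most informative phase or NA.
arrest_phase <- function(A) {
  arr <- A[, "MASS"] > 0L & A[, "MITOSIS_EXIT"] < 2L
  if (!any(arr)) return(NA_character_)
  A <- A[arr, , drop = FALSE]
  m <- A[, "MITOSIS_EXIT"] == 1L
  g2 <- A[, "DNA_Replication"] > 0L & A[, "G2_proteins"] > 0L
  s <- A[, "DNA_Replication"] > 0L & A[, "S_proteins"] == 0L
  g1 <- A[, "DNA_Replication"] == 0L
  if (any(m)) "Arrest_M"
  else if (any(g2)) "Arrest_G2"
  else if (any(s)) "Arrest_S"
  else if (any(g1)) "Arrest_G1"
  else NA_character_
}

#' @rdname classification
#' @return `classify_arrest()`: one of `"Arrest_G1"`, `"Arrest_S"`,
#'   `"Arrest_G2"`, `"Arrest_M"`, or `"Unresolved"` when no arrest clause
#'   matches (e.g. a dead state with MASS = 0).
#' @export
classify_arrest <- function(traj) {
  a <- attractor(traj)
  if (a$kind == "unresolved") return("Unresolved")
  fc <- is_functional_cycle(traj)
  if (isTRUE(fc)) {
    stop("trajectory is a functional cycle; classify_arrest() requires a ",
         "non-functional trajectory", call. = FALSE)
  }
  ph <- arrest_phase(a$states)
  if (is.na(ph)) "Unresolved" else ph
}

#' @rdname classification
#' @return `classify_outcome()`: `"Viable"` for a functional cycle, an
#'   `"Arrest_*"` label otherwise, `"Unresolved"` when the trajectory did not
#'   reach an attractor or no clause matches.
#' @export
classify_outcome <- function(traj) {
  fc <- is_functional_cycle(traj)
  if (is.na(fc)) return("Unresolved")
  if (fc) "Viable" else classify_arrest(traj)
}

#' Reconcile a predicted outcome with a literature phenotype
#'
#' Publications often report a mutant only as "inviable" without naming the
#' arrested phase; a predicted arrest of any phase is then counted as a
#' correct prediction and the mutant is relabeled `Inviable` before metrics
#' are computed. A reported specific arrest is only correct when the
#' predicted phase matches exactly.
#'
#' @param predicted Outcome label from [classify_outcome()].
#' @param reported Literature phenotype: `"viable"`, `"inviable"`, or
#'   `"arrest in G1"` / `"arrest in S"` / `"arrest in G2"` / `"arrest in M"`.
#' @return A list with `correct` (flag) and `final_label` (outcome label used
#'   for metrics).
#' @export
reconcile_with_literature <- function(predicted, reported) {
  stopifnot(predicted %in% .outcome_levels)
  rep_norm <- tolower(trimws(reported))
  known <- c("viable", "inviable", "arrest in g1", "arrest in s",
             "arrest in g2", "arrest in m")
  if (!rep_norm %in% known) {
    stop("unknown reported phenotype `", reported, "`", call. = FALSE)
  }
  reported_label <- switch(rep_norm,
    viable = "Viable", inviable = "Inviable",
    `arrest in g1` = "Arrest_G1", `arrest in s` = "Arrest_S",
    `arrest in g2` = "Arrest_G2", `arrest in m` = "Arrest_M")
  is_arrest <- grepl("^Arrest_", predicted)
  if (reported_label == "Inviable" && is_arrest) {
    list(correct = TRUE, final_label = "Inviable")
  } else if (predicted == reported_label) {
    list(correct = TRUE, final_label = predicted)
  } else {
    list(correct = FALSE, final_label = predicted)
  }
}

#' Accuracy and per-class sensitivity/specificity of a benchmark
#'
#' One-vs-rest sensitivity (TP / (TP + FN)) and specificity (TN / (TN + FP))
#' are computed over the reconciled final labels against the reported
#' phenotype classes. A class absent from the reported labels has undefined
#' (NA) sensitivity, not 0.
#'
#' @param results A data frame with columns `final_label`, `reported_label`
#'   and `correct` (as produced by [run_mutant_benchmark()]).
#' @return A list with `accuracy` and a tibble `by_class`.
#' @export
benchmark_metrics <- function(results) {
  stopifnot(nrow(results) > 0L,
            all(c("final_label", "reported_label", "correct") %in% names(results)))
  acc <- mean(results$correct)
  classes <- c("Viable", "Inviable", "Arrest_G1", "Arrest_S", "Arrest_G2",
               "Arrest_M")
  by_class <- purrr::map_dfr(classes, function(cl) {
    pos <- results$reported_label == cl
    pred_pos <- results$final_label == cl
    tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
    fp <- sum(!pos & pred_pos); tn <- sum(!pos & !pred_pos)
    tibble::tibble(
      class = cl, n_reported = sum(pos),
      sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_
    )
  })
  list(accuracy = acc, by_class = by_class)
}
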