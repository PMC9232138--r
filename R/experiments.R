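#' @keywords internal
#' Classify one attractor matrix (rows = attractor states).
classify_attractor_mat <- function(A) {
  if (nrow(A) > 1L &&
      all(apply(A[, .phen_nodes, drop = FALSE], 2, max) >= 1L) &&
      all(apply(A[, .phen_nodes, drop = FALSE], 2, min) == 0L) &&
      max(A[, "MITOSIS_EXIT"]) == 2L) {
    return("Viable")
  }
  ph <- arrest_phase(A)
  if (is.na(ph)) "Unresolved" else ph
}

#' @keywords internal
#' Canonical key of a cyclic/point attractor (rotation-invariant).
attractor_key <- function(A) {
  h <- state_hash(A)
  k <- length(h)
  min(vapply(seq_len(k), function(i) {
    paste(h[c(i:k, seq_len(i - 1L))], collapse = "|")
  }, character(1)))
}

#' @keywords internal
#' Vectorized ensemble run + per-run classification.
ensemble_classify <- function(model, S0, constraints = NULL, fix_mat = NULL,
                              max_steps = 5000L, chunk_size = 512L) {
  cc <- compile_constraints(constraints, model)
  n <- nrow(S0)
  labels <- character(n)
  keys <- character(n)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    res <- sim_chunk(model, S0[idx, , drop = FALSE], cc,
                     fix_mat = if (is.null(fix_mat)) NULL
                               else fix_mat[idx, , drop = FALSE],
                     max_steps = max_steps)
    for (j in seq_along(idx)) {
      if (!res$resolved[j]) {
        labels[idx[j]] <- "Unresolved"
        keys[idx[j]] <- NA_character_
      } else {
        A <- res$attractors[[j]]
        labels[idx[j]] <- classify_attractor_mat(A)
        keys[idx[j]] <- attractor_key(A)
      }
    }
  }
  list(labels = labels, keys = keys)
}

#' Run the literature mutant benchmark
#'
#' Simulates every catalogue entry from the general preset (the regular-cycle
#' setting: MASS and the non-Mating checkpoints at 1) with the mutant's
#' perturbation constraints, classifies the attractor, reconciles the
#' prediction with the reported literature phenotype, and computes accuracy
#' and per-class sensitivity/specificity. Rows whose perturbation fails to
#' parse are skipped with a warning and flagged in the output.
#'
#' @param model The cell-cycle model; defaults to [build_cellcycle_model()].
#' @param catalogue Catalogue tibble from [load_mutant_catalogue()].
#' @return A `yc_benchmark` object: a tibble (one row per mutant with
#'   `predicted`, `reported_label`, `final_label`, `correct`) carrying the
#'   metrics of [benchmark_metrics()] as attributes. Use [tidy()] /
#'   [glance()] to extract them.
#' @export
run_mutant_benchmark <- function(model = build_cellcycle_model(),
                                 catalogue = load_mutant_catalogue()) {
  if (nrow(catalogue) == 0L) stop("empty mutant catalogue", call. = FALSE)
  init <- preset_state(model, "regular")
  rows <- purrr::pmap(catalogue, function(mutant_id, perturbation, reported, ...) {
    cons <- tryCatch(parse_constraints(perturbation, model),
                     error = function(e) {
                       warning("skipping mutant ", mutant_id, ": ",
                               conditionMessage(e), call. = FALSE)
                       NULL
                     })
    if (is.null(cons)) {
      return(tibble::tibble(mutant_id = mutant_id, perturbation = perturbation,
                            reported = reported, predicted = NA_character_,
                            reported_label = NA_character_,
                            final_label = NA_character_, correct = NA,
                            skipped = TRUE))
    }
    traj <- simulate_model(model, init, cons)
    predicted <- classify_outcome(traj)
    rec <- reconcile_with_literature(predicted, reported)
    reported_label <- switch(tolower(reported),
      viable = "Viable", inviable = "Inviable",
      `arrest in g1` = "Arrest_G1", `arrest in s` = "Arrest_S",
      `arrest in g2` = "Arrest_G2", `arrest in m` = "Arrest_M")
    tibble::tibble(mutant_id = mutant_id, perturbation = perturbation,
                   reported = reported, predicted = predicted,
                   reported_label = reported_label,
                   final_label = rec$final_label, correct = rec$correct,
                   skipped = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  scored <- dplyr::filter(out, !.data$skipped)
  metrics <- benchmark_metrics(scored)
  structure(out, class = c("yc_benchmark", class(out)),
            accuracy = metrics$accuracy, by_class = metrics$by_class)
}

#' @export
print.yc_benchmark <- function(x, ...) {
  cat("<yc_benchmark> ", sum(!x$skipped), " mutants, accuracy ",
      sprintf("%.1f%%", 100 * attr(x, "accuracy")), "\n", sep = "")
  NextMethod()
}

#' Random-perturbation robustness ensemble
#'
#' Runs `n` independent simulations from random initial states: every node
#' except the four checkpoint nodes draws a uniform initial level (over its
#' own admissible range by default, or over 0-3 clamped into the range when
#' `clamp_draw = TRUE`); checkpoint nodes start at 0 so observed arrests are
#' consequences of the dynamics, not of preset checkpoint signals. Each
#' trajectory is classified, and runs are grouped by their attractor to
#' count the largest functional-cycle grouping.
#'
#' @param n Number of simulations.
#' @param seed RNG seed (one seed per suite run; reproducible).
#' @param model The cell-cycle model.
#' @param clamp_draw Draw 0-3 then clamp into the node range (biases toward
#'   the maximum for narrower nodes); default draws uniformly per range.
#' @param chunk_size Runs simulated per vectorized block.
#' @return A `yc_ensemble` list: `n_runs`, `seed`, `functional_fraction`,
#'   `arrest_breakdown` (named counts), `basin_note` (runs in the largest
#'   functional-attractor grouping), and `labels`.
#' @export
run_random_ensemble <- function(n, seed, model = build_cellcycle_model(),
                                clamp_draw = FALSE, chunk_size = 512L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  chk <- model$nodes$node[model$nodes$class == "checkpoint"]
  nodes <- model$nodes$node
  maxes <- model$nodes$max
  S0 <- vapply(seq_along(nodes), function(j) {
    if (nodes[j] %in% chk) rep(0L, n)
    else if (clamp_draw) pmin(sample(0:3, n, replace = TRUE), maxes[j])
    else sample.int(maxes[j] + 1L, n, replace = TRUE) - 1L
  }, integer(n))
  if (n == 1L) S0 <- matrix(S0, 1L)
  colnames(S0) <- nodes
  cls <- ensemble_classify(model, S0, chunk_size = chunk_size)
  new_ensemble(cls, n, seed)
}

#' @keywords internal
new_ensemble <- function(cls, n, seed) {
  labels <- cls$labels
  functional <- labels == "Viable"
  grp <- table(cls$keys[functional])
  structure(list(
    n_runs = n, seed = seed,
    functional_fraction = mean(functional),
    arrest_breakdown = table(labels[!functional]),
    basin_note = if (any(functional)) max(grp) else 0L,
    labels = labels
  ), class = "yc_ensemble")
}

#' @export
print.yc_ensemble <- function(x, ...) {
  cat("<yc_ensemble> ", x$n_runs, " runs (seed ", x$seed, ")\n",
      "  functional cycles: ", sprintf("%.1f%%", 100 * x$functional_fraction),
      " (largest functional grouping: ", x$basin_note, " runs)\n", sep = "")
  if (length(x$arrest_breakdown)) {
    cat("  arrests: ",
        paste(names(x$arrest_breakdown), x$arrest_breakdown,
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Single-node perturbation scan from the G1 preset
#'
#' Each of `n` simulations starts from the G1 preset with one randomly
#' selected node held at one randomly selected admissible level for the
#' whole run (sampling with replacement over (node, value) pairs; checkpoint
#' nodes are eligible). Levels are drawn over each node's own range by
#' default, or 0-3 clamped with `clamp_draw = TRUE`.
#'
#' @inheritParams run_random_ensemble
#' @param include_checkpoints Allow checkpoint nodes to be selected.
#' @param replace Sample (node, value) pairs with replacement.
#' @return A `yc_ensemble` (see [run_random_ensemble()]).
#' @export
run_g1_scan <- function(n, seed, model = build_cellcycle_model(),
                        include_checkpoints = TRUE, replace = TRUE,
                        clamp_draw = FALSE, chunk_size = 512L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  nodes <- model$nodes$node
  maxes <- model$nodes$max
  eligible <- if (include_checkpoints) seq_along(nodes)
              else which(model$nodes$class != "checkpoint")
  if (!replace) {
    pairs <- do.call(rbind, lapply(eligible, function(j) cbind(j, 0:maxes[j])))
    if (n > nrow(pairs)) {
      stop("n exceeds the ", nrow(pairs),
           " distinct (node, value) pairs; use replace = TRUE", call. = FALSE)
    }
    sel <- pairs[sample.int(nrow(pairs), n), , drop = FALSE]
    node_i <- sel[, 1L]; val <- sel[, 2L]
  } else {
    node_i <- sample(eligible, n, replace = TRUE)
    val <- vapply(node_i, function(j) {
      if (clamp_draw) min(sample(0:3, 1L), maxes[j])
      else sample.int(maxes[j] + 1L, 1L) - 1L
    }, integer(1))
  }
  g1 <- preset_state(model, "G1_start")
  S0 <- matrix(rep(g1, each = n), n, dimnames = list(NULL, nodes))
  storage.mode(S0) <- "integer"
  fx <- matrix(NA_integer_, n, length(nodes), dimnames = list(NULL, nodes))
  fx[cbind(seq_len(n), node_i)] <- val
  cls <- ensemble_classify(model, S0, fix_mat = fx, chunk_size = chunk_size)
  out <- new_ensemble(cls, n, seed)
  out$fixed_node <- nodes[node_i]
  out$fixed_value <- val
  out
}

#' Checkpoint fixation suite
#'
#' Fixes each checkpoint node independently at its minimum (1) and maximum
#' activated level (2; Mating is Boolean, so only 1), plus the two combined
#' configurations with every checkpoint at its minimum or maximum, always
#' from the general preset, and classifies each outcome.
#'
#' @param model The cell-cycle model.
#' @return A tibble with `configuration`, `constraints`, `outcome`.
#' @export
run_checkpoint_suite <- function(model = build_cellcycle_model()) {
  chk <- model$nodes$node[model$nodes$class == "checkpoint"]
  maxes <- stats::setNames(model$nodes$max, model$nodes$node)
  init <- preset_state(model, "regular")
  configs <- list()
  for (c0 in chk) {
    for (v in unique(c(1L, maxes[[c0]]))) {
      configs[[paste0(c0, "@", v)]] <- stats::setNames(v, c0)
    }
  }
  configs[["all@min"]] <- stats::setNames(rep(1L, length(chk)), chk)
  configs[["all@max"]] <- stats::setNames(maxes[chk], chk)
  purrr::imap_dfr(configs, function(vals, nm) {
    cons <- purrr::imap(as.list(vals), function(v, node) fix_node(node, v))
    traj <- simulate_model(model, init, unname(cons))
    tibble::tibble(
      configuration = nm,
      constraints = paste0(names(vals), "=", vals, collapse = " "),
      outcome = classify_outcome(traj)
    )
  })
}

#' Ethanol-stress simulation (first experimental suite)
#'
#' Simulates the general preset under the transcriptome-derived constraint
#' set of one ethanol-tolerance phenotype (`"LT"` arrests in M phase for
#' lack of Clb1/2 inhibition; `"HT"` arrests in G1 through peak SCF-Cdc4
#' activity blocking origin licensing).
#'
#' @param phenotype `"LT"` or `"HT"`.
#' @param model The cell-cycle model.
#' @return A list with `trajectory` (a `yc_trajectory`), `outcome`, and the
#'   `constraints` used.
#' @export
run_ethanol_suite <- function(phenotype = c("LT", "HT"),
                              model = build_cellcycle_model()) {
  phenotype <- match.arg(phenotype)
  cons <- load_constraint_set(paste0(phenotype, "_phenotype"), model)
  traj <- simulate_model(model, preset_state(model, "regular"), cons)
  list(trajectory = traj, outcome = classify_outcome(traj),
       constraints = cons)
}

#' LncRNA simulation grid (third and fourth experimental suites)
#'
#' Runs every requested combination of lncRNA, decoy mode, expression regime
#' and overexpression timing in a given context: no stress, LT/HT ethanol
#' constraints, an active spindle checkpoint (Misaligned_Spindle and
#' Unattached_Kinetochores fixed at 2), or a strain's DNA-damage constraint
#' set (simulated from the MASS-only initial state, as in the DNA-damage
#' suite).
#'
#' @param lncrna,mode,regime,timing Vectors of values accepted by
#'   [inject_lncrna()]; the full grid of combinations is run.
#' @param context One of `"none"`, `"LT_ethanol"`, `"HT_ethanol"`,
#'   `"spindle_active"`, or `"dna_damage_<strain>"`.
#' @param model The cell-cycle model.
#' @return A tibble with one row per combination and its `outcome`.
#' @export
run_lncrna_suite <- function(lncrna = c("lnc9136", "lnc10883"),
                             mode = c("inhibitor", "activator"),
                             regime = c("normal", "down", "up"),
                             timing = "constitutive",
                             context = "none",
                             model = build_cellcycle_model()) {
  valid_ctx <- c("none", "LT_ethanol", "HT_ethanol", "spindle_active",
                 paste0("dna_damage_", dna_damage_strains()))
  if (!context %in% valid_ctx) {
    stop("invalid context `", context, "`; one of: ",
         paste(valid_ctx, collapse = ", "), call. = FALSE)
  }
  ctx_cons <- switch(context,
    none = list(),
    LT_ethanol = load_constraint_set("LT_phenotype", model),
    HT_ethanol = load_constraint_set("HT_phenotype", model),
    spindle_active = list(fix_node("Misaligned_Spindle", 2),
                          fix_node("Unattached_Kinetochores", 2)),
    load_constraint_set(context, model)
  )
  init_name <- if (startsWith(context, "dna_damage")) "mass_only" else "regular"
  grid <- tidyr::expand_grid(lncrna = lncrna, mode = mode, regime = regime,
                             timing = timing)
  grid <- dplyr::filter(grid, .data$regime == "up" |
                          .data$timing == "constitutive")
  grid$outcome <- purrr::pmap_chr(grid, function(lncrna, mode, regime, timing) {
    inj <- inject_lncrna(model, lncrna, mode = mode, regime = regime,
                         timing = timing)
    init <- if (init_name == "mass_only") {
      model_state(inj$model, MASS = 1)
    } else preset_state(inj$model, "regular")
    traj <- simulate_model(inj$model, init, c(ctx_cons, inj$constraints))
    classify_outcome(traj)
  })
  grid$context <- context
  grid
}

#' DNA-damage checkpoint suite (second experimental suite)
#'
#' Simulates each strain's DNA-damage constraint set from the MASS-only
#' initial state (only MASS at 1). LT strains (S288C, BY4741, SEY6210)
#' arrest; HT strains (X2180-1A, BY4742) complete a functional cycle.
#' BMA64-1A shows no differential expression of MEC1, CHK1 or RAD53 and is
#' explicitly not analyzable. Optionally the simulation is repeated with
#' lnc10883 wired in as an inhibitor fixed at 3 (checkpoint bypass).
#'
#' @param strain One of [dna_damage_strains()], or `"BMA64-1A"`.
#' @param with_lnc10883 Also inject constitutively overexpressed lnc10883
#'   as an inhibitor of its partners.
#' @param model The cell-cycle model.
#' @return A one-row tibble with `strain`, `with_lnc10883`, `outcome`.
#' @export
run_dna_damage_suite <- function(strain, with_lnc10883 = FALSE,
                                 model = build_cellcycle_model()) {
  if (identical(strain, "BMA64-1A")) {
    return(tibble::tibble(strain = strain, with_lnc10883 = with_lnc10883,
                          outcome = "not analyzable"))
  }
  if (!strain %in% dna_damage_strains()) {
    stop("unknown strain `", strain, "`", call. = FALSE)
  }
  cons <- load_constraint_set(paste0("dna_damage_", strain), model)
  if (with_lnc10883) {
    inj <- inject_lncrna(model, "lnc10883", mode = "inhibitor",
                         regime = "up", timing = "constitutive")
    model <- inj$model
    cons <- c(cons, inj$constraints)
  }
  traj <- simulate_model(model, model_state(model, MASS = 1), cons)
  tibble::tibble(strain = strain, with_lnc10883 = with_lnc10883,
                 outcome = classify_outcome(traj))
}

#' @rdname run_dna_damage_suite
#' @export
dna_damage_strains <- function() {
  c("S288C", "BY4741", "SEY6210", "X2180-1A", "BY4742")
}
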