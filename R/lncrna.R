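#' Wire a lncRNA into the network as a decoy regulator
#'
#' Rewrites the rules of the lncRNA's protein partners so the lncRNA acts as
#' an additional regulator, and returns the constraint encoding the lncRNA's
#' own expression regime. LncRNAs are modeled as molecular decoys: as an
#' *inhibitor*, a partner's rule-derived target is reduced by the lncRNA
#' level (full suppression at level 3); as an *activator*, the target is
#' raised by the lncRNA level (and the lncRNA floors the partner's activity
#' even when no clause fires), both clipped into the partner's admissible
#' range. The expansion preserves clause priority exactly, so with the
#' lncRNA at 0 the dynamics are unchanged.
#'
#' Expression regimes follow the transcriptome-to-logic mapping:
#' `down` restricts the lncRNA to `[0,1]`, `normal` to `[0,2]` (the base rule
#' keeps the node at 0, so unperturbed simulations are lncRNA-neutral), and
#' `up` either fixes the lncRNA at 3 (`constitutive`) or gives it the rule
#' "target 3 once the G2-phase driver activates" (`G2_triggered`), under
#' which it climbs to 3 soon after G2 entry.
#'
#' @param model The cell-cycle model (or any model containing the nodes).
#' @param lncrna LncRNA node name (`"lnc9136"` or `"lnc10883"`).
#' @param targets Protein partners; defaults to the predicted interaction
#'   partners: Gin4/Hsl1 for lnc9136 and Mec1/Bub1 for lnc10883.
#' @param mode `"inhibitor"` or `"activator"`.
#' @param regime `"normal"`, `"down"` or `"up"`.
#' @param timing `"constitutive"` or `"G2_triggered"` (only meaningful for
#'   `regime = "up"`).
#' @return A list with the rewired `model` and the list of `constraints` to
#'   pass to [simulate_model()].
#' @export
inject_lncrna <- function(model, lncrna,
                          targets = lncrna_partners(lncrna),
                          mode = c("inhibitor", "activator"),
                          regime = c("normal", "down", "up"),
                          timing = c("constitutive", "G2_triggered")) {
  mode <- match.arg(mode)
  regime <- match.arg(regime)
  timing <- match.arg(timing)
  stopifnot(inherits(model, "logic_model"))
  if (!lncrna %in% model$nodes$node) {
    stop("unknown lncRNA node `", lncrna, "`", call. = FALSE)
  }
  bad <- setdiff(targets, model$nodes$node)
  if (length(bad)) {
    stop("unknown target node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  maxes <- stats::setNames(model$nodes$max, model$nodes$node)
  lmax <- maxes[[lncrna]]

  rules <- model$rules
  for (tg in targets) {
    old <- rules[[tg]]$clauses
    tmax <- maxes[[tg]]
    new <- list()
    for (cl0 in old) {
      for (v in 0:lmax) {
        t2 <- if (mode == "inhibitor") max(0L, cl0$target - v)
              else min(tmax, cl0$target + v)
        new[[length(new) + 1L]] <- clause(
          paste0("(", cl0$when, ") & ", lncrna, " == ", v), t2)
      }
    }
    if (mode == "activator") {
      ## the lncRNA floors the partner's activity even without a firing clause
      for (v in seq.int(lmax, 1L)) {
        new[[length(new) + 1L]] <- clause(paste0(lncrna, " == ", v),
                                          min(tmax, v))
      }
    }
    rules[[tg]] <- logic_rule(tg, new)
  }

  cons <- list()
  if (regime == "up" && timing == "G2_triggered") {
    if (!"G2_proteins" %in% model$nodes$node) {
      stop("G2_triggered timing requires a G2_proteins node", call. = FALSE)
    }
    rules[[lncrna]] <- logic_rule(lncrna, clause("G2_proteins >= 1", lmax))
  } else {
    cons <- switch(regime,
      down = list(range_node(lncrna, 0, 1, provenance = "lncRNA downregulated")),
      normal = list(range_node(lncrna, 0, 2, provenance = "lncRNA normal expression")),
      up = list(fix_node(lncrna, lmax, provenance = "lncRNA constitutive overexpression"))
    )
  }

  model2 <- logic_model(model$name, model$nodes, unname(rules))
  list(model = model2, constraints = cons)
}

#' Predicted lncRNA-protein interaction partners
#'
#' lnc9136 (SEY6210) binds the septin kinases Gin4 and Hsl1; lnc10883
#' (BY4742) binds Mec1 and Bub1.
#'
#' @param lncrna LncRNA name.
#' @return Character vector of partner node names.
#' @export
lncrna_partners <- function(lncrna) {
  switch(lncrna,
    lnc9136 = c("Gin4", "Hsl1"),
    lnc10883 = c("Mec1", "Bub1"),
    stop("no recorded interaction partners for `", lncrna, "`", call. = FALSE)
  )
}
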