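#' The multivalued logical model of the budding-yeast cell cycle
#'
#' Builds the 67-node, 144-interaction logical network: cyclin/CDK waves
#' (Cdc28 implicit in the cyclin nodes), the G1 transcription factors SBF/MBF
#' and their repressor Whi5, replication licensing and firing (ORC, Cdc6,
#' Tah11/Cdt1, MCM, ARS, pre_RC as a min-of-components complex), the
#' Swe1/Mih1 morphogenesis branch with the septin kinases Hsl1/Gin4/Kcc4,
#' mitotic exit through APC/C-Cdc20, the FEAR and MEN routes of Cdc14
#' release, Sic1 re-accumulation, the four checkpoint nodes
#' (DNA_Damage, Unattached_Kinetochores, Misaligned_Spindle, Mating) with
#' their effector kinases, five phenomenological milestone nodes (MASS, BUD,
#' DNA_Replication, Spindle, MITOSIS_EXIT), the S/G2 phase-driver nodes, the
#' genomic regulatory elements (SCB, MCB, ECB, ARS), and two ethanol
#' stress-responsive lncRNA nodes (lnc9136, lnc10883) that are inert until a
#' perturbation wires them to their protein partners.
#'
#' Value semantics: most protein/complex nodes range over 0-3 (absent, low,
#' normal, high). Nodes with scarce literature support (Cak1, Mih1, Mating,
#' Far1, Fus3) are Boolean. Checkpoint-influenced effectors peak at 1 or 2
#' according to their checkpoint's level; level 2 forces arrest, level 1 is
#' tolerated. MASS is self-activating: it returns to 1 even after mitotic
#' exit, and its peak (2) starts the cycle by activating Mcm1.
#'
#' @return A `logic_model` with exactly 67 nodes and 144 interactions (the
#'   builder self-checks both counts and fails loudly on any discrepancy).
#' @export
build_cellcycle_model <- function() {
  n <- function(...) lm_node(...)
  nodes <- dplyr::bind_rows(
    ## phenomenological milestones
    n("MASS", 2, "phenomenological"),
    n("BUD", 2, "phenomenological"),
    n("DNA_Replication", 1, "phenomenological"),
    n("Spindle", 2, "phenomenological"),
    n("MITOSIS_EXIT", 2, "phenomenological"),
    ## checkpoints
    n("Mating", 1, "checkpoint"),
    n("Unattached_Kinetochores", 2, "checkpoint"),
    n("Misaligned_Spindle", 2, "checkpoint"),
    n("DNA_Damage", 2, "checkpoint"),
    ## genomic regulatory elements
    n("SCB", 3, "regulatory_element"),
    n("ECB", 3, "regulatory_element"),
    n("MCB", 3, "regulatory_element"),
    n("ARS", 3, "regulatory_element"),
    ## phase drivers
    n("S_proteins", 3, "complex"),
    n("G2_proteins", 3, "complex"),
    ## lncRNAs (inert in the base model)
    n("lnc9136", 3, "gene_or_lncRNA"),
    n("lnc10883", 3, "gene_or_lncRNA"),
    ## checkpoint effector kinases (peak at 1 or 2 with their checkpoint)
    n("Mec1", 2), n("Chk1", 2), n("Rad53", 2),
    n("Bub1", 2), n("Mps1", 2), n("Bub3", 2), n("Mad3", 2),
    n("Mad1_Mad2", 2, "complex"), n("MCC", 2, "complex"),
    n("Bfa1_Bub2", 2, "complex"),
    n("Far1", 1), n("Fus3", 1),
    ## cyclins (Cdc28 implicit)
    n("Cln3", 3), n("Cln1_2", 3), n("Clb5_6", 3), n("Clb3_4", 3),
    n("Clb1_2", 3),
    ## transcription factors and their repressor
    n("SBF", 3, "complex"), n("MBF", 3, "complex"), n("Mcm1", 3),
    n("Swi5", 3), n("Whi5", 3),
    ## replication licensing and firing
    n("Cdc45", 3), n("Tah11", 3), n("Cdc6", 3), n("MCM", 3), n("ORC", 3),
    n("pre_RC", 3, "complex"), n("Cdc7_Dbf4", 3, "complex"),
    ## S-phase entry control
    n("Sic1", 3), n("SCF_Cdc4", 3, "complex"),
    ## G2/M morphogenesis branch
    n("Swe1", 3), n("Mih1", 1), n("Cak1", 1),
    n("Hsl1", 3), n("Gin4", 3), n("Kcc4", 3), n("Cdc5", 3),
    ## mitotic exit machinery
    n("Cdc20", 3), n("Cdh1", 3),
    n("APCC_Cdc20", 3, "complex"), n("APCC_Cdh1", 3, "complex"),
    n("Cdc14", 3), n("Net1", 3), n("Esp1", 3), n("Pds1", 3),
    n("Tem1", 3), n("Cdc15", 3), n("Dbf2_Mob1", 3, "complex"), n("Lte1", 3)
  )

  r <- logic_rule
  cl <- clause
  rules <- list(
    ## -- phenomenological backbone ------------------------------------
    ## MASS self-activates to 1 even after mitotic exit; its peak starts
    ## the cycle; MITOSIS_EXIT = 2 resets it to 0.
    r("MASS",
      cl("MITOSIS_EXIT == 2", 0),
      cl("MASS == 0", 1),
      cl("TRUE", 2)),
    r("BUD",
      cl("MITOSIS_EXIT == 2", 0),
      cl("BUD >= 1", 2),
      cl("(Cln1_2 >= 2 | Clb5_6 >= 2) & MASS == 2", 2)),
    ## replication needs a licensed origin plus S-CDK and Cdc45; the
    ## replicated flag persists until mitotic exit
    r("DNA_Replication",
      cl("MITOSIS_EXIT == 2", 0),
      cl("DNA_Replication == 1", 1),
      cl("pre_RC >= 2 & Clb5_6 >= 2 & Cdc45 >= 2", 1)),
    r("Spindle",
      cl("MITOSIS_EXIT == 2", 0),
      cl("Spindle >= 1 & DNA_Replication == 1", 2),
      cl("Clb3_4 >= 2 & DNA_Replication == 1", 2)),
    ## M entry (1) requires every earlier milestone plus mitotic CDK;
    ## exit (2) requires Clb1_2 destruction; 2 is held until MASS resets
    r("MITOSIS_EXIT",
      cl("MITOSIS_EXIT == 2 & MASS > 0", 2),
      cl("MITOSIS_EXIT == 1 & Clb1_2 == 0 & Spindle == 2", 2),
      cl("BUD == 2 & DNA_Replication == 1 & Spindle == 2 & Clb1_2 >= 2", 1),
      cl("MITOSIS_EXIT == 1 & DNA_Replication == 1", 1)),
    ## -- checkpoints ---------------------------------------------------
    r("Mating"),
    ## negative feedback from the assembled spindle clears the spindle
    ## checkpoints below their arrest level
    r("Unattached_Kinetochores",
      cl("Unattached_Kinetochores == 2 & Spindle < 2", 2)),
    r("Misaligned_Spindle",
      cl("Misaligned_Spindle == 2 & Spindle < 2", 2)),
    r("DNA_Damage",
      cl("DNA_Damage == 2", 2)),
    ## -- regulatory elements -------------------------------------------
    r("SCB", cl("SBF >= 2", 2), cl("SBF == 1", 1)),
    r("ECB", cl("Mcm1 >= 1", 2)),
    r("MCB", cl("MBF >= 2", 2), cl("MBF == 1", 1)),
    r("ARS", cl("ORC >= 2", 2)),
    ## -- phase drivers ---------------------------------------------------
    r("S_proteins", cl("MCB >= 2", 2)),
    r("G2_proteins", cl("DNA_Replication == 1 & MITOSIS_EXIT < 2", 3)),
    ## -- lncRNAs: constant zero until a perturbation wires them in ------
    r("lnc9136"),
    r("lnc10883"),
    ## -- checkpoint effectors -------------------------------------------
    r("Mec1", cl("DNA_Damage == 2", 2), cl("DNA_Damage == 1", 1)),
    r("Chk1", cl("Mec1 == 2", 2), cl("Mec1 == 1", 1)),
    r("Rad53", cl("Mec1 == 2", 2), cl("Mec1 == 1", 1)),
    r("Bub1",
      cl("Unattached_Kinetochores == 2 | Misaligned_Spindle == 2 | Mps1 == 2", 2),
      cl("Unattached_Kinetochores == 1 | Misaligned_Spindle == 1", 1)),
    r("Mps1",
      cl("Unattached_Kinetochores == 2", 2),
      cl("Unattached_Kinetochores == 1", 1)),
    r("Bub3", cl("Bub1 == 2", 2), cl("Bub1 == 1", 1)),
    r("Mad3", cl("Bub1 == 2", 2), cl("Bub1 == 1", 1)),
    r("Mad1_Mad2",
      cl("Bub1 == 2", 2),
      cl("Bub1 == 1", 1)),
    r("MCC",
      cl("Mad3 == 2 & Bub3 == 2 & Mad1_Mad2 == 2", 2),
      cl("Mad3 >= 1 & Bub3 >= 1 & Mad1_Mad2 >= 1", 1)),
    r("Bfa1_Bub2",
      cl("Misaligned_Spindle == 2 & Bub1 >= 1", 2),
      cl("Misaligned_Spindle == 1", 1)),
    r("Far1", cl("Mating == 1 & Fus3 == 1", 1)),
    r("Fus3", cl("Mating == 1", 1)),
    ## -- cyclins ---------------------------------------------------------
    r("Cln3",
      cl("Far1 == 1", 0),
      cl("ECB >= 1 & MASS == 2", 2)),
    r("Cln1_2",
      cl("Far1 == 1", 0),
      cl("SCB >= 1", 2)),
    r("Clb5_6",
      cl("Sic1 >= 2", 0),
      cl("MCB >= 2", 2)),
    r("Clb3_4", cl("G2_proteins >= 2 & MCB >= 1", 2)),
    ## mitotic cyclin: destroyed by APC/C together with a stoichiometric
    ## inhibitor; level 3 (overexpression/upregulation) is self-sustaining;
    ## activation is vetoed by Swe1 unless Mih1 counteracts
    r("Clb1_2",
      cl("(APCC_Cdc20 >= 2 | APCC_Cdh1 >= 2) & (Sic1 >= 2 | Swe1 >= 2)", 0),
      cl("(APCC_Cdc20 >= 2 | APCC_Cdh1 >= 2) & Cdc14 == 3 & Clb1_2 <= 2", 0),
      cl("Clb1_2 == 3 & G2_proteins >= 1", 3),
      cl("Swe1 >= 2 & Mih1 == 0 & Clb1_2 <= 1", 0),
      cl("G2_proteins == 3 & MCB >= 1 & Cak1 == 1", 2),
      cl("Clb1_2 >= 1 & G2_proteins >= 1", 2)),
    ## -- transcription factors -------------------------------------------
    ## Whi5 cannot completely inhibit SBF/MBF: mass-driven basal activity
    ## persists, and Cln-CDK overrides Whi5 entirely
    r("SBF",
      cl("Clb1_2 >= 2", 0),
      cl("Cln1_2 >= 2 | Cln3 >= 2", 2),
      cl("ECB >= 2", 1)),
    r("MBF",
      cl("Cln1_2 >= 2 | (Cln3 >= 2 & Whi5 == 0)", 2),
      cl("Cln3 >= 2", 1)),
    r("Mcm1", cl("MASS == 2", 2)),
    r("Swi5", cl("Cdc14 == 3 & Clb1_2 <= 1", 2)),
    r("Whi5",
      cl("Cln3 >= 2", 0),
      cl("TRUE", 2)),
    ## -- replication licensing/firing ------------------------------------
    r("Cdc45", cl("S_proteins >= 2 & Cdc7_Dbf4 >= 2", 2)),
    r("Tah11", cl("MBF >= 2", 2)),
    ## peak SCF-Cdc4 activity prevents Cdc6 accumulation (origin licensing)
    ## origin licensing happens outside mitosis (no spindle present)
    r("Cdc6",
      cl("SCF_Cdc4 == 3", 0),
      cl("ECB >= 2 & Spindle == 0", 2)),
    r("MCM", cl("Cdc6 >= 2 & Tah11 >= 2", 2)),
    r("ORC", cl("TRUE", 2)),
    ## complex: smallest value of its components; disassembled on firing
    r("pre_RC",
      cl("DNA_Replication == 1", 0),
      cl("ORC >= 2 & Cdc6 >= 2 & Tah11 >= 2 & MCM >= 2 & ARS >= 2", 2),
      cl("ORC >= 1 & Cdc6 >= 1 & Tah11 >= 1 & MCM >= 1 & ARS >= 1", 1)),
    r("Cdc7_Dbf4", cl("S_proteins >= 2", 2)),
    ## -- S-phase entry ----------------------------------------------------
    r("Sic1",
      cl("SCF_Cdc4 >= 2 & (Cln1_2 >= 2 | Cln3 >= 2)", 0),
      cl("Swi5 >= 2 | Cdc14 == 3", 3),
      cl("Sic1 >= 1", 2)),
    r("SCF_Cdc4",
      cl("SCF_Cdc4 == 3", 3),
      cl("Cln1_2 >= 1 | Cln3 >= 2", 2)),
    ## -- morphogenesis branch ---------------------------------------------
    ## complete Swe1 inhibition needs Hsl1 plus Cdc5; Gin4/Kcc4 only
    ## reduce Swe1 without full inhibition
    r("Swe1",
      cl("Hsl1 >= 2 & Cdc5 >= 2", 0),
      cl("Gin4 >= 2 | Hsl1 >= 2", 1),
      cl("G2_proteins >= 1", 2)),
    r("Mih1", cl("G2_proteins >= 2", 1)),
    r("Cak1", cl("TRUE", 1)),
    r("Hsl1", cl("DNA_Replication == 1", 3)),
    r("Gin4", cl("DNA_Replication == 1", 3)),
    r("Kcc4", cl("DNA_Replication == 1", 1)),
    r("Cdc5",
      cl("Rad53 == 2", 0),
      cl("Clb1_2 >= 1", 2)),
    ## -- mitotic exit -----------------------------------------------------
    r("Cdc20", cl("Clb1_2 >= 2", 2)),
    r("Cdh1",
      cl("Cdc14 >= 2 & Clb1_2 <= 1", 3),
      cl("Cdh1 >= 1 & Clb1_2 == 0", 2)),
    r("APCC_Cdc20",
      cl("MCC == 2", 0),
      cl("Cdc20 >= 2 & Clb1_2 >= 2 & Cdc5 >= 2", 2),
      cl("Cdc20 >= 1 & Clb1_2 >= 1", 1)),
    r("APCC_Cdh1", cl("Cdh1 >= 2", 2)),
    r("Cdc14",
      cl("Net1 == 0 & Dbf2_Mob1 >= 2", 3),
      cl("Net1 == 0", 2)),
    r("Net1",
      cl("(Esp1 >= 2 & Cdc5 >= 2) | Dbf2_Mob1 >= 2", 0),
      cl("TRUE", 2)),
    r("Esp1", cl("Pds1 <= 1 & Spindle == 2", 2)),
    ## securin: stabilized at peak by Chk1, degraded by APC/C-Cdc20
    r("Pds1",
      cl("Chk1 == 2", 3),
      cl("APCC_Cdc20 >= 2", 0),
      cl("G2_proteins >= 1", 2)),
    ## MEN: anaphase-gated, vetoed by Bfa1-Bub2
    r("Tem1",
      cl("Bfa1_Bub2 == 2", 0),
      cl("Esp1 >= 2 & (Lte1 >= 2 | Spindle == 2)", 2)),
    r("Cdc15", cl("Tem1 >= 2", 2)),
    r("Dbf2_Mob1", cl("Cdc15 >= 2 & Cdc5 >= 2", 2)),
    r("Lte1", cl("BUD == 2 & G2_proteins >= 1", 2))
  )

  model <- logic_model("yeast_cell_cycle", nodes, rules)
  check_cellcycle_structure(model)
  model
}

#' @keywords internal
check_cellcycle_structure <- function(model) {
  problems <- character(0)
  if (nrow(model$nodes) != 67L) {
    problems <- c(problems, paste0("expected 67 nodes, found ", nrow(model$nodes)))
  }
  if (nrow(model$edges) != 144L) {
    problems <- c(problems, paste0("expected 144 interactions, found ",
                                   nrow(model$edges)))
  }
  if (model$nodes$max[model$nodes$node == "Mating"] != 1L) {
    problems <- c(problems, "Mating must be Boolean")
  }
  if (length(problems)) {
    stop("cell-cycle model structural self-check failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(model)
}

#' Canonical initial states
#'
#' `regular` is the unperturbed cell-cycle preset: MASS and every checkpoint
#' node except Mating start at 1, everything else at 0 (checkpoints decay
#' unless held, so a transient level 1 does not arrest). `G1_start` puts the
#' system in G1: MASS, Cln3, Whi5, SBF and MBF active at level 1 with
#' DNA_Replication (and everything else) inactive.
#'
#' @param model The cell-cycle model from [build_cellcycle_model()].
#' @param name `"regular"` or `"G1_start"`.
#' @return A named state vector.
#' @export
preset_state <- function(model, name = c("regular", "G1_start")) {
  name <- match.arg(name)
  switch(name,
    regular = model_state(model,
      MASS = 1, Unattached_Kinetochores = 1, Misaligned_Spindle = 1,
      DNA_Damage = 1),
    G1_start = model_state(model,
      MASS = 1, Cln3 = 1, Whi5 = 1, SBF = 1, MBF = 1)
  )
}
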