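#' Convert differential-expression records into model constraints
#'
#' Implements the transcriptome-to-logic mapping
#' (downregulated < non-differentially-expressed < upregulated, FDR < 0.01):
#' \itemize{
#'   \item downregulated gene: the node may only take values 0 or 1
#'     (absence or low yield);
#'   \item upregulated gene: the node climbs to 3 (high yield) soon after
#'     activation and is then sustained or reduced by its normal regulation
#'     ([boost_on_activation()]);
#'   \item non-differentially-expressed gene: the node varies from 0 to 2.
#' }
#' Two special cases arise from node-range limits. A Boolean node cannot
#' express "low yield" as a range, so downregulation fixes it at 0. A
#' checkpoint-effector node (peak level 2, driven by its upstream signal)
#' cannot be boosted to 3; its upregulation is encoded as a regulator clamp,
#' `X[driver@2]`: the node's rule operates as if its driver were at the
#' arrest level, while the driver itself evolves normally.
#'
#' @param records Data frame with columns `gene`, `log2fc`, `significant`
#'   (and optionally `phenotype_or_strain`, already filtered to one
#'   phenotype/strain).
#' @param node_map Named character vector, gene -> node; defaults to the
#'   cell-cycle gene map.
#' @param model Model used for validation and node ranges.
#' @param checkpoint_drivers Named character vector node -> upstream driver
#'   used for the clamp encoding of upregulated effectors.
#' @return A list of [constraints].
#' @export
constraints_from_expression <- function(records, model,
                                        node_map = cellcycle_gene_map(),
                                        checkpoint_drivers = cellcycle_checkpoint_drivers()) {
  stopifnot(all(c("gene", "log2fc", "significant") %in% names(records)))
  unmapped <- setdiff(records$gene, names(node_map))
  if (length(unmapped)) {
    stop("no node mapping for gene(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  maxes <- stats::setNames(model$nodes$max, model$nodes$node)
  cons <- purrr::pmap(records[, c("gene", "log2fc", "significant")],
                      function(gene, log2fc, significant) {
    node <- node_map[[gene]]
    prov <- paste0(gene, " log2FC=", log2fc)
    cls <- if (isTRUE(significant) && log2fc < 0) "down"
           else if (isTRUE(significant) && log2fc > 0) "up"
           else "nonDE"
    switch(cls,
      down = if (maxes[[node]] == 1L) fix_node(node, 0, provenance = prov)
             else range_node(node, 0, 1, provenance = prov),
      up = if (node %in% names(checkpoint_drivers)) {
             clamp_regulator(node, checkpoint_drivers[[node]], 2,
                             provenance = prov)
           } else boost_on_activation(node, provenance = prov),
      nonDE = range_node(node, 0, min(2L, maxes[[node]]), provenance = prov)
    )
  })
  validate_constraints(cons, model)
  cons
}

#' Gene-to-node mapping for the cell-cycle model
#'
#' @return Named character vector mapping gene symbols (as used in the
#'   expression fixture) to model node names.
#' @export
cellcycle_gene_map <- function() {
  c(SIC1 = "Sic1", CDH1 = "Cdh1", MIH1 = "Mih1", CLB2 = "Clb1_2",
    CDC4 = "SCF_Cdc4", CLN3 = "Cln3", CLN2 = "Cln1_2", SWE1 = "Swe1",
    CDC20 = "Cdc20", CLB5 = "Clb5_6",
    MEC1 = "Mec1", CHK1 = "Chk1", RAD53 = "Rad53", PDS1 = "Pds1",
    lnc9136 = "lnc9136", lnc10883 = "lnc10883")
}

#' @rdname cellcycle_gene_map
#' @export
cellcycle_checkpoint_drivers <- function() {
  c(Mec1 = "DNA_Damage", Chk1 = "Mec1", Rad53 = "Mec1")
}
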