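#' @keywords internal
yc_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "yeastcyc")
  if (!nzchar(p)) {
    stop("fixture file not found: ", file.path(...), call. = FALSE)
  }
  p
}

#' Load the 109-entry mutant benchmark catalogue
#'
#' The catalogue is a synthetic reconstruction: each row pairs a knockout or
#' overexpression perturbation of one or more model nodes with the phenotype
#' reported in the classical genetics literature for the corresponding
#' mutant allele (`viable`, `inviable`, or an `arrest in G1/S/G2/M`).
#'
#' @param path Optional path to an alternative catalogue file.
#' @return A tibble with columns `mutant_id`, `perturbation`, `reported`.
#' @export
load_mutant_catalogue <- function(path = NULL) {
  if (is.null(path)) path <- yc_extdata("mutant_catalogue_synthetic.tsv")
  cat_df <- utils::read.delim(path, comment.char = "#",
                              stringsAsFactors = FALSE)
  cat_df <- tibble::as_tibble(cat_df)
  if (nrow(cat_df) != 109L) {
    stop("mutant catalogue must have 109 rows, found ", nrow(cat_df),
         call. = FALSE)
  }
  known <- c("viable", "inviable", "arrest in G1", "arrest in S",
             "arrest in G2", "arrest in M")
  bad <- setdiff(unique(cat_df$reported), known)
  if (length(bad)) {
    stop("unknown reported phenotype(s) in catalogue: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cat_df
}

#' Load the expression fixture
#'
#' Log2 fold-changes (ethanol treatment vs control) for the ten selected
#' cell-cycle genes at the tolerance-phenotype level (LT/HT), the DNA-damage
#' checkpoint genes per strain, and the two ethanol-responsive lncRNAs
#' (lnc9136 = 1.25, lnc10883 = 1.4). A log2 fold-change of 0 marks
#' non-differentially-expressed genes; `significant` encodes FDR < 0.01.
#'
#' @param path Optional path to an alternative table.
#' @return A tibble with columns `phenotype_or_strain`, `gene`, `log2fc`,
#'   `significant`.
#' @export
load_expression_fixture <- function(path = NULL) {
  if (is.null(path)) path <- yc_extdata("expression_synthetic.tsv")
  ex <- tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                            stringsAsFactors = FALSE))
  ex$significant <- as.logical(ex$significant)
  need <- list(LT = c("SIC1", "CDH1", "MIH1", "CLB2", "CDC4", "CLN3", "CLN2",
                      "SWE1", "CDC20", "CLB5"),
               HT = c("SIC1", "CDH1", "MIH1", "CLB2", "CDC4", "CLN3", "CLN2",
                      "SWE1", "CDC20", "CLB5"),
               SEY6210 = c("MEC1", "CHK1", "RAD53", "PDS1", "lnc9136"),
               BY4742 = c("MEC1", "CHK1", "RAD53", "PDS1", "lnc10883"))
  for (grp in names(need)) {
    have <- ex$gene[ex$phenotype_or_strain == grp]
    miss <- setdiff(need[[grp]], have)
    if (length(miss)) {
      stop("expression fixture lacks ", grp, " record(s) for: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  ex
}

#' Named constraint sets in S4-style notation
#'
#' Constraint sets ship as plain-text files, one constraint per line
#' (`Node[lo,hi]`, `Node[Reg@v]`, `Node!`, `Node=v`, `Node^`), under
#' `inst/extdata/constraint_sets/`.
#'
#' @param name Set name, e.g. `"LT_phenotype"`, `"HT_phenotype"`,
#'   `"dna_damage_BY4742"`.
#' @param model Model used to validate the constraints.
#' @param dir Optional directory of constraint-set files.
#' @return `load_constraint_set()`: a list of [constraints];
#'   `constraint_set_names()`: available set names.
#' @export
load_constraint_set <- function(name, model, dir = NULL) {
  if (is.null(dir)) dir <- yc_extdata("constraint_sets")
  path <- file.path(dir, paste0(name, ".txt"))
  if (!file.exists(path)) {
    stop("no constraint set named `", name, "` (looked in ", dir, ")",
         call. = FALSE)
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cons <- lapply(lines, parse_constraint, model = model)
  for (i in seq_along(cons)) {
    cons[[i]]$provenance <- paste0("constraint set ", name)
  }
  validate_constraints(cons, model)
  cons
}

#' @rdname load_constraint_set
#' @export
constraint_set_names <- function(dir = NULL) {
  if (is.null(dir)) dir <- yc_extdata("constraint_sets")
  sub("\\.txt$", "", list.files(dir, pattern = "\\.txt$"))
}
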