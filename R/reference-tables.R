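# Published summary tables of the reference cohort: 101 stage III colorectal
# carcinomas treated with FOLFOX adjuvant chemotherapy plus 35 matched normal
# mucosa samples (expression data deposited as GEO series GSE83889). The
# cohort's NMF subtyping, CMS cross-classification, clinical covariate counts
# and marker fold changes are reproduced here as plain data objects so the
# tabulation, matching, association and ranking machinery can be replayed
# against them without the microarray data.

#' Reference cross-tabulation of NMF groups versus CMS classes
#'
#' The published contingency table of the cohort's four NMF expression
#' groups against the consensus molecular subtype (CMS1-4) calls of the
#' same samples; 21 of the 101 tumors had no consensus CMS call
#' ("undetermined").
#'
#' @return List: `counts` (CMS x group matrix), `undetermined` (per group),
#'   `group_sizes`.
#' @export
reference_crosstab_counts <- function() {
  counts <- matrix(
    c(0, 10, 0, 0,    # CMS1 over groups 1..4
      3, 4, 0, 31,    # CMS2
      12, 1, 0, 0,    # CMS3
      1, 0, 10, 8),   # CMS4
    nrow = 4, byrow = TRUE,
    dimnames = list(c("CMS1", "CMS2", "CMS3", "CMS4"), paste0("group", 1:4)))
  list(counts = counts,
       undetermined = stats::setNames(c(6L, 6L, 6L, 3L), paste0("group", 1:4)),
       group_sizes = stats::setNames(c(22L, 21L, 16L, 42L), paste0("group", 1:4)))
}

#' Per-sample labels consistent with the reference cross-tabulation
#'
#' Expands [reference_crosstab_counts()] into one row per tumor sample with
#' its NMF group and CMS class (or `"undetermined"`). Any per-sample
#' labeling with these margins reproduces the published table; sample ids
#' are synthetic placeholders.
#'
#' @return Data frame: `sample_id`, `group`, `cms` (101 rows).
#' @export
reference_cohort_labels <- function() {
  rc <- reference_crosstab_counts()
  rows <- list()
  for (g in colnames(rc$counts)) {
    cms <- c(rep(rownames(rc$counts), rc$counts[, g]),
             rep("undetermined", rc$undetermined[[g]]))
    rows[[g]] <- data.frame(group = g, cms = cms, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- data.frame(sample_id = sprintf("T%03d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reference clinicopathologic counts per NMF group
#'
#' Selected covariate count tables of the reference cohort (categories x
#' groups): KRAS mutation status, MSI status, tumor location, and group
#' sizes.
#'
#' @return List of integer matrices `kras`, `msi`, `location`, plus
#'   `group_sizes`.
#' @export
reference_clinical_counts <- function() {
  gs <- paste0("group", 1:4)
  list(
    kras = matrix(c(8, 15, 7, 31, 14, 6, 9, 11), nrow = 2, byrow = TRUE,
                  dimnames = list(c("wild", "mutant"), gs)),
    msi = matrix(c(20, 15, 16, 42, 2, 6, 0, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("MSS/MSI-low", "MSI-high"), gs)),
    location = matrix(c(12, 12, 6, 6, 10, 9, 10, 36), nrow = 2, byrow = TRUE,
                      dimnames = list(c("right", "left"), gs)),
    group_sizes = stats::setNames(c(22L, 21L, 16L, 42L), gs))
}

#' Reference subtype-marker fold changes
#'
#' The published top-10 marker panel per NMF group with each gene's fold
#' change in the group's tumors versus normal mucosa (`fc_t_vs_n`) and in
#' the group versus the other tumor groups (`fc_group_vs_rest`).
#'
#' @return Data frame: `gene`, `group`, `fc_t_vs_n`, `fc_group_vs_rest`.
#' @export
reference_marker_fcs <- function() {
  tab <- rbind(
    c("DEFA5", 1, 4.56, 4.65), c("DUOX2", 1, 4.28, 3.91),
    c("KLK12", 1, 3.19, 2.77), c("ALDOB", 1, 5.37, 2.61),
    c("GABRP", 1, 1.84, 1.95), c("LOC653061", 1, 2.62, 1.95),
    c("APOBEC1", 1, 3.31, 1.88), c("C2CD4B", 1, 2.93, 1.82),
    c("MUC5AC", 1, 2.27, 1.79), c("SEZ6L2", 1, 2.35, 1.73),
    c("CCDC58", 2, 6.19, 2.81), c("MOCOS", 2, 2.92, 2.11),
    c("FAM81A", 2, 2.59, 2.06), c("MTHFD2", 2, 3.10, 1.99),
    c("SLC7A11", 2, 2.52, 1.93), c("PBK", 2, 2.78, 1.91),
    c("MAD2L1", 2, 3.49, 1.90), c("LDHB", 2, 3.18, 1.86),
    c("SEH1L", 2, 2.14, 1.83), c("CDCA2", 2, 2.38, 1.77),
    c("HOPX", 3, 4.26, 4.11), c("TAGLN", 3, 2.66, 3.73),
    c("GREM1", 3, 2.12, 3.59), c("THBS4", 3, 2.85, 3.58),
    c("COL3A1", 3, 5.33, 3.34), c("PRRX1", 3, 4.29, 3.23),
    c("RAB31", 3, 3.60, 3.21), c("MYL9", 3, 2.38, 3.13),
    c("CTSK", 3, 2.59, 3.11), c("SPARC", 3, 2.35, 3.05),
    c("DSC3", 4, 2.66, 2.21), c("CAB39L", 4, 2.22, 2.07),
    c("ASXL1", 4, 1.99, 1.80), c("ERP27", 4, 2.55, 1.70),
    c("ZMYND8", 4, 1.90, 1.69), c("ACSL6", 4, 1.94, 1.67),
    c("GMEB2", 4, 1.78, 1.66), c("HPDL", 4, 2.79, 1.66),
    c("TSPAN6", 4, 2.11, 1.64), c("C8orf33", 4, 2.15, 1.63))
  data.frame(gene = tab[, 1], group = paste0("group", tab[, 2]),
             fc_t_vs_n = as.numeric(tab[, 3]),
             fc_group_vs_rest = as.numeric(tab[, 4]),
             stringsAsFactors = FALSE)
}
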