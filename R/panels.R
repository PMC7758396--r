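#' Biomarker panel presets
#'
#' Gene panels used for urine- and tissue-based prostate-cancer
#' classification. `"panel14"` is the 14-gene urine panel; `"panel6"` is the
#' six-gene subset with the most differential expression between Gleason
#' grade groups; `"panel8"` is the earlier tissue-cohort panel (it contains
#' *HPN* and *FN1*, which are not part of the urine assay).
#'
#' @param panel Preset name (`"panel14"`, `"panel8"`, `"panel6"`) or a
#'   character vector of gene symbols, which is validated and returned as-is.
#'
#' @return Character vector of unique gene symbols, in panel order.
#' @examples
#' panel_genes("panel6")
#' @export
panel_genes <- function(panel = "panel14") {
  if (length(panel) > 1L) {
    genes <- as.character(panel)
    if (anyDuplicated(genes)) {
      rlang::abort("Panel gene symbols must be unique.")
    }
    return(genes)
  }
  presets <- list(
    panel14 = c(
      "PMP22", "GOLM1", "LMTK2", "EZH2", "GSTP1", "PCA3", "VEGFA",
      "CST3", "PTEN", "PIP5K1A", "CDK1", "TMPRSS2", "ANXA3", "CCND1"
    ),
    panel8 = c("PMP22", "GOLM1", "LMTK2", "EZH2", "GSTP1", "PCA3", "HPN", "FN1"),
    panel6 = c("PMP22", "GOLM1", "LMTK2", "EZH2", "GSTP1", "PCA3")
  )
  if (panel %in% names(presets)) {
    return(presets[[panel]])
  }
  if (grepl("^panel", panel)) {
    rlang::abort(sprintf(
      "Unknown panel preset '%s'; use one of %s or give the gene symbols directly.",
      panel, paste(sQuote(names(presets)), collapse = ", ")
    ))
  }
  as.character(panel) # a single gene symbol
}

#' @noRd
default_reference_gene <- function() "ACTB"

# Resolve which gene columns of a profile table belong to the active panel.
#' @noRd
resolve_genes <- function(data, genes = NULL) {
  if (is.null(genes)) {
    genes <- intersect(panel_genes("panel14"), names(data))
    if (length(genes) == 0L) {
      rlang::abort("No panel gene columns found; pass `genes` explicitly.")
    }
  } else {
    genes <- panel_genes(genes)
    missing <- setdiff(genes, names(data))
    if (length(missing) > 0L) {
      rlang::abort(sprintf(
        "Profile table is missing panel gene column(s): %s.",
        paste(missing, collapse = ", ")
      ))
    }
  }
  genes
}
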