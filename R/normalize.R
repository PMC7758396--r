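#' Average replicate Ct readings per (patient, gene)
#'
#' Replicate PCRs are combined by the arithmetic mean of their Ct values.
#' No replicate is rejected; pairs whose replicate range exceeds one cycle
#' are counted and reported via a message so unstable wells can be audited.
#'
#' @param measurements Long tibble with columns `patient_id`, `gene`,
#'   `replicate`, `ct` (see [read_ct_table()]).
#' @param genes Optional gene symbols that every patient must have (the
#'   reference gene is added automatically); missing (patient, gene) pairs
#'   raise an error listing them.
#' @param reference_gene Reference symbol appended to `genes`, default
#'   `"ACTB"`.
#' @return Tibble with one row per (patient, gene): `patient_id`, `gene`,
#'   `ct` (mean), `n_replicates`, `ct_range`.
#' @examples
#' x <- tibble::tibble(
#'   patient_id = "P1", gene = "CST3", replicate = 1:2, ct = c(28.7, 29.1)
#' )
#' average_replicates(x)$ct
#' @export
average_replicates <- function(measurements, genes = NULL,
                               reference_gene = default_reference_gene()) {
  required <- c("patient_id", "gene", "ct")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf(
      "Measurement table is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(!is.finite(measurements$ct)) || any(measurements$ct <= 0)) {
    rlang::abort("All Ct values must be positive and finite.")
  }
  out <- measurements |>
    dplyr::group_by(.data$patient_id, .data$gene) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      ct_range = diff(range(.data$ct)),
      ct = mean(.data$ct),
      .groups = "drop"
    ) |>
    dplyr::select("patient_id", "gene", "ct", "n_replicates", "ct_range")

  unstable <- sum(out$ct_range > 1, na.rm = TRUE)
  if (unstable > 0L) {
    rlang::inform(sprintf(
      "%d (patient, gene) pair(s) have replicate Ct range > 1 cycle; none rejected.",
      unstable
    ))
  }

  if (!is.null(genes)) {
    need <- unique(c(panel_genes(genes), reference_gene))
    full <- tidyr::expand_grid(
      patient_id = unique(out$patient_id), gene = need
    )
    miss <- dplyr::anti_join(full, out, by = c("patient_id", "gene"))
    if (nrow(miss) > 0L) {
      rlang::abort(sprintf(
        "No replicates for %d required (patient, gene) pair(s): %s.",
        nrow(miss),
        paste(utils::head(
          paste0(miss$patient_id, "/", miss$gene), 10L
        ), collapse = ", ")
      ))
    }
  }
  out
}

#' Normalize mean Ct values against the reference gene
#'
#' Implements the panel's reference-gene normalization: each gene's mean Ct
#' is divided by the beta-actin Ct of the same sample,
#' `CtS = Ct(gene) / Ct(actin)`, optionally reported on the x1,000 scale
#' used for presentation. The reference gene is excluded from the output.
#' Classification downstream is invariant to the choice of scale (the fitted
#' discriminant absorbs any common affine rescaling of the features).
#'
#' @param mean_cts Tibble of averaged Ct values (`patient_id`, `gene`, `ct`),
#'   as returned by [average_replicates()].
#' @param reference_gene Symbol of the reference channel (default `"ACTB"`).
#' @param scale `1000` (presentation scale, default) or `1` (bare ratio).
#' @param genes Optional panel restriction; defaults to all non-reference
#'   genes present.
#' @return Wide tibble: `patient_id`, then one CtS column per gene.
#' @examples
#' x <- tibble::tibble(
#'   patient_id = "P1", gene = c("CST3", "ACTB"), ct = c(27.6, 24)
#' )
#' normalize_cts(x)$CST3 # 1150
#' @export
normalize_cts <- function(mean_cts, reference_gene = default_reference_gene(),
                          scale = 1000, genes = NULL) {
  if (!scale %in% c(1, 1000)) {
    rlang::abort("`scale` must be 1 (ratio) or 1000 (presentation scale).")
  }
  ref <- mean_cts |> dplyr::filter(.data$gene == reference_gene)
  if (nrow(ref) == 0L) {
    rlang::abort(sprintf(
      "Cannot normalize: reference gene '%s' is absent.", reference_gene
    ))
  }
  if (any(ref$ct <= 0)) {
    rlang::abort(sprintf(
      "Cannot normalize: non-positive reference Ct for patient(s) %s.",
      paste(ref$patient_id[ref$ct <= 0], collapse = ", ")
    ))
  }
  panel <- mean_cts |> dplyr::filter(.data$gene != reference_gene)
  if (!is.null(genes)) {
    genes <- panel_genes(genes)
    panel <- panel |> dplyr::filter(.data$gene %in% genes)
  }
  no_ref <- setdiff(unique(panel$patient_id), ref$patient_id)
  if (length(no_ref) > 0L) {
    rlang::abort(sprintf(
      "Cannot normalize: no reference Ct for patient(s) %s.",
      paste(no_ref, collapse = ", ")
    ))
  }
  panel |>
    dplyr::left_join(
      ref |> dplyr::select("patient_id", ref_ct = "ct"),
      by = "patient_id"
    ) |>
    dplyr::mutate(cts = scale * .data$ct / .data$ref_ct) |>
    dplyr::select("patient_id", "gene", "cts") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "cts")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
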