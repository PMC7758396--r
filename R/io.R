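#' Read a long-format Ct measurement table
#'
#' Reads delimited text (comma or tab; the delimiter is sniffed from the
#' header line) with columns `patient_id`, `gene`, `replicate`, `ct`.
#'
#' @param path File path.
#' @param genes Optional vector/preset of allowed genes (the reference gene
#'   is always allowed); unknown genes raise an error listing them.
#' @param reference_gene Reference symbol, default `"ACTB"`.
#' @return Typed tibble of measurements.
#' @export
read_ct_table <- function(path, genes = NULL,
                          reference_gene = default_reference_gene()) {
  header <- read_header(path)
  delim <- sniff_delim(header)
  x <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c("patient_id", "gene", "replicate", "ct")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf(
      "Ct table %s is missing required column(s): %s.",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  ct <- suppressWarnings(as.numeric(x$ct))
  if (any(is.na(ct) & !is.na(x$ct))) {
    bad <- x$ct[is.na(ct) & !is.na(x$ct)]
    rlang::abort(sprintf(
      "Non-numeric ct value(s) in %s: %s.",
      path, paste(utils::head(unique(bad), 5L), collapse = ", ")
    ))
  }
  replicate <- suppressWarnings(as.integer(x$replicate))
  if (any(is.na(replicate))) {
    rlang::abort(sprintf("Non-integer replicate value(s) in %s.", path))
  }
  out <- tibble::tibble(
    patient_id = x$patient_id, gene = x$gene,
    replicate = replicate, ct = ct
  )
  dup <- duplicated(out[c("patient_id", "gene", "replicate")])
  if (any(dup)) {
    rlang::abort(sprintf(
      "Duplicate (patient, gene, replicate) row(s) in %s, e.g. %s/%s/%d.",
      path, out$patient_id[dup][1], out$gene[dup][1], out$replicate[dup][1]
    ))
  }
  if (!is.null(genes)) {
    allowed <- c(panel_genes(genes), reference_gene)
    unknown <- setdiff(unique(out$gene), allowed)
    if (length(unknown) > 0L) {
      rlang::abort(sprintf(
        "Unknown gene(s) in %s: %s.", path, paste(unknown, collapse = ", ")
      ))
    }
  }
  out
}

#' Write a long-format Ct measurement table
#'
#' @param measurements Tibble with `patient_id`, `gene`, `replicate`, `ct`.
#' @param path Output path (written as CSV).
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(measurements, path) {
  readr::write_csv(measurements, path, progress = FALSE)
  invisible(path)
}

#' @noRd
read_header <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s.", path))
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L || !nzchar(header)) {
    rlang::abort(sprintf("File %s is empty.", path))
  }
  header
}

#' @noRd
sniff_delim <- function(header) {
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Read a patient label table
#'
#' Reads delimited text with columns `patient_id` and `label`, plus any of
#' the optional covariates `psa` (ng/ml), `gleason` (tokens such as
#' `"<=6"`, `"3+4"`, `"4+3"`, `"8"`, `"9-10"`), `stage` (TNM T stage) and
#' `core_fraction` (fraction of biopsy cores with cancer, 0-1).
#'
#' @param path File path.
#' @return Typed tibble, one row per patient.
#' @export
read_labels <- function(path) {
  header <- read_header(path)
  delim <- sniff_delim(header)
  x <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  missing_cols <- setdiff(c("patient_id", "label"), names(x))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf(
      "Label table %s is missing column(s): %s.",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  vocab <- c("higher_risk", "lower_risk", "cancer", "benign", "unknown")
  unknown <- setdiff(unique(x$label), vocab)
  if (length(unknown) > 0L) {
    rlang::abort(sprintf(
      "Unknown label token(s) in %s: %s (allowed: %s).",
      path, paste(unknown, collapse = ", "), paste(vocab, collapse = ", ")
    ))
  }
  if (anyDuplicated(x$patient_id)) {
    rlang::abort(sprintf("Duplicate patient_id in %s.", path))
  }
  out <- tibble::tibble(patient_id = x$patient_id, label = x$label)
  if ("psa" %in% names(x)) out$psa <- suppressWarnings(as.numeric(x$psa))
  if ("gleason" %in% names(x)) out$gleason <- x$gleason
  if ("stage" %in% names(x)) out$stage <- x$stage
  if ("core_fraction" %in% names(x)) {
    out$core_fraction <- suppressWarnings(as.numeric(x$core_fraction))
  }
  out
}

#' Total Gleason score from a pattern token
#'
#' @param gleason Character vector of tokens: `"<=6"`, `"6"`, `"3+4"`,
#'   `"4+3"`, `"7"`, `"8"`, `"9"`, `"10"`, `"9-10"` (case/space tolerant).
#' @return Integer vector of total scores (`"<=6"` maps to 6, `"9-10"` to
#'   9); unrecognized tokens give `NA` with a warning.
#' @examples
#' gleason_total(c("3+4", "4+3", "<=6", "9-10"))
#' @export
gleason_total <- function(gleason) {
  g <- gsub("[[:space:]]", "", as.character(gleason))
  out <- rep(NA_integer_, length(g))
  out[g %in% c("<=6", "6", "5", "4", "3", "2")] <- 6L
  out[g %in% c("3+4", "4+3", "7", "7(3+4)", "7(4+3)")] <- 7L
  out[g == "8"] <- 8L
  out[g %in% c("9", "9-10")] <- 9L
  out[g == "10"] <- 10L
  bad <- !is.na(g) & is.na(out)
  if (any(bad)) {
    rlang::warn(sprintf(
      "Unrecognized Gleason token(s): %s.",
      paste(unique(g[bad]), collapse = ", ")
    ))
  }
  out
}

#' @noRd
gleason_is_4plus3 <- function(gleason) {
  g <- gsub("[[:space:]]", "", as.character(gleason))
  !is.na(g) & g %in% c("4+3", "7(4+3)")
}

#' @noRd
stage_number <- function(stage) {
  s <- toupper(gsub("[[:space:]]", "", as.character(stage)))
  num <- suppressWarnings(as.integer(sub("^T([0-9]).*$", "\\1", s)))
  num
}

#' Derive the higher-/lower-risk label from clinical criteria
#'
#' Applies the guideline-derived binarization used throughout the package:
#' a patient is **higher-risk** when ANY of the following holds — Gleason
#' total score above 7; Gleason pattern 4 + 3 = 7; clinical T stage 3 or
#' above; PSA strictly greater than 20 ng/ml; more than half of biopsy
#' cores with cancer. Otherwise the patient is lower-risk. A missing
#' criterion never qualifies (a warning reports how many values were
#' missing); a patient with every criterion missing is an error.
#'
#' @param data Tibble of patients.
#' @param gleason,stage,psa,core_fraction Unquoted column names (defaults
#'   match [read_labels()]); pass `NULL` for criteria absent from the data.
#' @return `data` with a `risk_label` column added.
#' @examples
#' d <- tibble::tibble(gleason = "4+3", stage = NA, psa = NA,
#'                     core_fraction = NA)
#' derive_risk_label(d)$risk_label # higher_risk
#' @export
derive_risk_label <- function(data, gleason = gleason, stage = stage,
                              psa = psa, core_fraction = core_fraction) {
  pull_or_na <- function(expr) {
    tryCatch(
      {
        v <- rlang::eval_tidy(expr, data = data)
        if (is.null(v)) rep(NA, nrow(data)) else v
      },
      error = function(e) rep(NA, nrow(data))
    )
  }
  g <- pull_or_na(rlang::enquo(gleason))
  st <- pull_or_na(rlang::enquo(stage))
  ps <- pull_or_na(rlang::enquo(psa))
  cf <- pull_or_na(rlang::enquo(core_fraction))

  all_missing <- is.na(g) & is.na(st) & is.na(ps) & is.na(cf)
  if (any(all_missing)) {
    rlang::abort(sprintf(
      "%d patient(s) have no risk criterion available (all fields missing).",
      sum(all_missing)
    ))
  }
  n_missing <- sum(is.na(g)) + sum(is.na(st)) + sum(is.na(ps)) + sum(is.na(cf))
  if (n_missing > 0L) {
    rlang::warn(sprintf(
      "%d missing criterion value(s) treated as non-qualifying.", n_missing
    ))
  }
  gt <- gleason_total(g)
  qualifies <-
    (!is.na(gt) & gt > 7L) |
    gleason_is_4plus3(g) |
    (!is.na(stage_number(st)) & stage_number(st) >= 3L) |
    (!is.na(ps) & ps > 20) |
    (!is.na(cf) & cf > 0.5)
  data$risk_label <- ifelse(qualifies, "higher_risk", "lower_risk")
  data
}
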