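#' Read a stem-loop qPCR Ct table
#'
#' @param path TSV with columns `mirna`, `condition` (`control` /
#'   `treatment`), `replicate`, `ct_target`, `ct_u6`.
#' @return tibble with those columns.
#' @export
read_ct_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    mirna = readr::col_character(), condition = readr::col_character(),
    replicate = readr::col_integer(), ct_target = readr::col_double(),
    ct_u6 = readr::col_double()), progress = FALSE)
}

#' Delta-Ct against the U6 internal control
#'
#' `delta_ct = mean(Ct_miRNA) - mean(Ct_U6)`: replicates are averaged on the
#' Ct scale first, then differenced. Lower delta-Ct means higher abundance.
#'
#' @param ct_mirna replicate Ct values for the miRNA assay.
#' @param ct_u6 replicate Ct values for the U6 assay.
#' @return a single delta-Ct value.
#' @export
delta_ct <- function(ct_mirna, ct_u6) {
  if (length(ct_u6) == 0 || all(is.na(ct_u6))) abort("missing U6 control assay")
  if (!all(is.finite(ct_mirna)) || !all(is.finite(ct_u6)))
    abort("Ct values must be finite")
  mean(ct_mirna) - mean(ct_u6)
}

#' Per-miRNA qPCR relative expression and direction
#'
#' Computes delta-Ct per condition, the delta-delta-Ct
#' (`ddct = delta_ct_treatment - delta_ct_control`), and the qPCR direction
#' `sign(-ddct)` (positive = up in treatment, since fewer cycles means more
#' template).
#'
#' @param ct tibble from [read_ct_table()].
#' @return tibble with `mirna`, `delta_ct_control`, `delta_ct_treatment`,
#'   `ddct`, `qpcr_direction`.
#' @export
qpcr_relative <- function(ct) {
  stopifnot(all(c("mirna", "condition", "ct_target", "ct_u6") %in% names(ct)))
  if (any(ct$ct_target <= 0 | ct$ct_u6 <= 0)) abort("Ct values must be positive")
  wide <- ct |>
    group_by(.data$mirna, .data$condition) |>
    summarise(dct = delta_ct(.data$ct_target, .data$ct_u6), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "dct",
                       names_prefix = "delta_ct_")
  if (!all(c("delta_ct_control", "delta_ct_treatment") %in% names(wide)))
    abort("both conditions are required for every miRNA")
  wide |>
    mutate(ddct = .data$delta_ct_treatment - .data$delta_ct_control,
           qpcr_direction = sign(-.data$ddct))
}

#' Directional concordance between qPCR and sequencing
#'
#' Percentage of miRNAs whose qPCR direction (sign of -ddCt) agrees with the
#' sequencing direction (sign of log2FC), over the miRNAs present in both
#' inputs with a nonzero direction on both sides (ties are excluded from
#' the denominator). Reported to two decimals.
#'
#' @param qpcr tibble with `mirna`, `qpcr_direction` (see [qpcr_relative()]),
#'   or a named numeric vector of directions.
#' @param rnaseq tibble with `mirna` and `log2fc` (e.g. `tidy()` of a
#'   [diff_expression()] fit), or a named numeric vector of directions.
#' @return list with `rate` (percent, two decimals), `n_agree`,
#'   `n_compared`, and the per-miRNA comparison tibble.
#' @export
concordance_rate <- function(qpcr, rnaseq) {
  as_dir <- function(x, col) {
    if (is.data.frame(x)) setNames(sign(x[[col]]), x$mirna)
    else setNames(sign(x), names(x))
  }
  qd <- as_dir(qpcr, "qpcr_direction")
  sd_ <- as_dir(rnaseq, if (is.data.frame(rnaseq) && "log2fc" %in% names(rnaseq))
    "log2fc" else "direction")
  shared <- intersect(names(qd), names(sd_))
  cmp <- tibble(mirna = shared, qpcr_direction = unname(qd[shared]),
                seq_direction = unname(sd_[shared])) |>
    filter(.data$qpcr_direction != 0, .data$seq_direction != 0)
  if (nrow(cmp) == 0) abort("no comparable miRNAs between qPCR and sequencing")
  n_agree <- sum(cmp$qpcr_direction == cmp$seq_direction)
  list(rate = round(100 * n_agree / nrow(cmp), 2),
       n_agree = n_agree, n_compared = nrow(cmp), comparison = cmp)
}
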