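#' Thresholds for the five-way regulation classification
#'
#' @param min_tpm retain a miRNA iff its TPM reaches this in at least one
#'   library (inclusive; default 2).
#' @param strong_lfc |log2FC| bound for the significant tier (default 1).
#' @param weak_lfc |log2FC| bound for the slight tier (default 0.25).
#' @param alpha p-value bound for the significant tier (default 0.05).
#' @param zero_substitute TPM substituted for exact zero before fold-change
#'   computation (default 0.01).
#' @return a `de_thresholds` list.
#' @export
de_thresholds <- function(min_tpm = 2, strong_lfc = 1, weak_lfc = 0.25,
                          alpha = 0.05, zero_substitute = 0.01) {
  stopifnot(0 < weak_lfc, weak_lfc < strong_lfc, 0 < alpha, alpha < 1,
            zero_substitute > 0)
  structure(list(min_tpm = min_tpm, strong_lfc = strong_lfc,
                 weak_lfc = weak_lfc, alpha = alpha,
                 zero_substitute = zero_substitute),
            class = "de_thresholds")
}

#' Transcripts-per-million normalization
#'
#' `TPM = count / total_clean_reads * 1e6`. Zero counts stay zero here;
#' the zero substitution used for fold changes is a separate, explicit step
#' ([substitute_zero()]).
#'
#' @param count non-negative read count (vectorized).
#' @param total_clean_reads library total (> 0).
#' @return TPM values.
#' @export
tpm_normalize <- function(count, total_clean_reads) {
  if (any(count < 0)) abort("negative count")
  if (any(total_clean_reads <= 0)) abort("total_clean_reads must be > 0")
  count / total_clean_reads * 1e6
}

#' Zero substitution for fold-change computation
#'
#' Replaces exact zeros by `zero_substitute` (default 0.01); any nonzero
#' value — including values below the substitute — passes through unchanged.
#'
#' @param tpm non-negative TPM values.
#' @param zero_substitute replacement for exact zero.
#' @return substituted TPM values.
#' @export
substitute_zero <- function(tpm, zero_substitute = 0.01) {
  stopifnot(all(tpm >= 0))
  ifelse(tpm == 0, zero_substitute, tpm)
}

#' Audic-Claverie point probability
#'
#' The exact conditional probability of observing `y` reads of a tag in the
#' second library given `x` reads in the first, under Poisson sampling:
#' `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))`.
#' Evaluated in log space via log-gamma, so it is overflow-safe for library
#' scale counts.
#'
#' @param y,x observed counts (vectorized over `y`).
#' @param n1,n2 total clean reads in the first / second library.
#' @param log return the log probability.
#' @return point probabilities (or their logs).
#' @export
audic_pmf <- function(y, x, n1, n2, log = FALSE) {
  if (n1 <= 0 || n2 <= 0) abort("library totals must be positive")
  stopifnot(all(x >= 0), all(y >= 0))
  r <- n2 / n1
  lp <- y * base::log(r) + lgamma(x + y + 1) - lgamma(x + 1) -
    lgamma(y + 1) - (x + y + 1) * log1p(r)
  if (log) lp else exp(lp)
}

# log(sum(exp(lx))) without underflow
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + base::log(sum(exp(lx - m)))
}

#' Audic-Claverie tail probability
#'
#' Two-sided p-value (default): `min(1, 2 min(P(Y <= y | x), P(Y >= y | x)))`
#' with tails accumulated from the log-space point masses of [audic_pmf()].
#' One-sided lower/upper variants are available; the paper-style usage is
#' the doubled tail.
#'
#' @param x,y counts in the first / second library (scalars, vectorized via
#'   [audic_test()]).
#' @param n1,n2 library totals.
#' @param alternative `"two.sided"`, `"less"` (Y low), or `"greater"`.
#' @return p-value in (0, 1].
#' @export
audic_pvalue <- function(x, y, n1, n2,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  lp <- audic_pmf(0:max(y, 1), x, n1, n2, log = TRUE)
  lower <- exp(logsumexp(lp[seq_len(y + 1)]))           # P(Y <= y)
  upper <- 1 - (if (y == 0) 0 else exp(logsumexp(lp[seq_len(y)])))  # P(Y >= y)
  lower <- min(lower, 1); upper <- min(max(upper, 0), 1)
  switch(alternative,
         two.sided = min(1, 2 * min(lower, upper)),
         less = lower,
         greater = upper)
}

#' Vectorized Audic-Claverie test over a count table
#'
#' @param count_c,count_t integer count vectors (control, treatment).
#' @param n1,n2 library totals.
#' @param alternative see [audic_pvalue()].
#' @return numeric vector of p-values.
#' @export
audic_test <- function(count_c, count_t, n1, n2, alternative = "two.sided") {
  vapply(seq_along(count_c), function(i)
    audic_pvalue(count_c[i], count_t[i], n1, n2, alternative = alternative),
    numeric(1))
}

#' Five-way regulation classification
#'
#' `significantly_up` / `significantly_down` iff `|log2FC| >= strong_lfc`
#' and `p < alpha`; `slightly_up` / `slightly_down` iff
#' `weak_lfc <= |log2FC| < strong_lfc` (no p-value requirement); otherwise
#' `unobvious`. Direction follows the sign of log2FC (treatment over
#' control).
#'
#' @param log2fc log2 fold changes (treatment / control, zero-substituted
#'   TPM).
#' @param p_value Audic-Claverie p-values (raw counts, never substituted
#'   TPM).
#' @param thresholds a [de_thresholds()].
#' @return factor with levels `significantly_up`, `significantly_down`,
#'   `slightly_up`, `slightly_down`, `unobvious`.
#' @export
classify_regulation <- function(log2fc, p_value, thresholds = de_thresholds()) {
  lv <- c("significantly_up", "significantly_down",
          "slightly_up", "slightly_down", "unobvious")
  out <- dplyr::case_when(
    abs(log2fc) >= thresholds$strong_lfc & p_value < thresholds$alpha &
      log2fc > 0 ~ "significantly_up",
    abs(log2fc) >= thresholds$strong_lfc & p_value < thresholds$alpha &
      log2fc < 0 ~ "significantly_down",
    abs(log2fc) >= thresholds$weak_lfc & abs(log2fc) < thresholds$strong_lfc &
      log2fc > 0 ~ "slightly_up",
    abs(log2fc) >= thresholds$weak_lfc & abs(log2fc) < thresholds$strong_lfc &
      log2fc < 0 ~ "slightly_down",
    TRUE ~ "unobvious")
  factor(out, levels = lv)
}

#' Low-abundance filter
#'
#' Retains a miRNA iff its TPM reaches `min_tpm` in at least one library
#' (inclusive boundary): rows below the threshold in both samples are
#' removed.
#'
#' @param profiles tibble with `tpm_c`, `tpm_t` columns.
#' @param min_tpm threshold (default 2).
#' @return the retained rows.
#' @export
filter_low_abundance <- function(profiles, min_tpm = 2) {
  profiles |> filter(pmax(.data$tpm_c, .data$tpm_t) >= min_tpm)
}

#' Differential expression analysis of a two-library miRNA count table
#'
#' Normalizes to TPM, applies the low-abundance filter, computes log2 fold
#' changes on zero-substituted TPM, Audic-Claverie p-values on the raw
#' counts, the five-way regulation category, and the exclusive
#' (library-private) flag. Returns a fitted-object wrapper with
#' [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()]
#' methods.
#'
#' @param counts tibble with columns `mirna`, `count_c`, `count_t`.
#' @param n1,n2 total clean reads in control / treatment.
#' @param thresholds a [de_thresholds()].
#' @param alternative p-value sidedness (see [audic_pvalue()]).
#' @param adjust add a Benjamini-Hochberg `p_adjusted` column (the
#'   classification itself never uses it).
#' @return object of class `mirtap_de`.
#' @export
diff_expression <- function(counts, n1, n2, thresholds = de_thresholds(),
                            alternative = "two.sided", adjust = FALSE) {
  stopifnot(all(c("mirna", "count_c", "count_t") %in% names(counts)))
  prof <- counts |>
    mutate(tpm_c = tpm_normalize(.data$count_c, n1),
           tpm_t = tpm_normalize(.data$count_t, n2)) |>
    filter_low_abundance(min_tpm = thresholds$min_tpm) |>
    mutate(
      tpm_c_sub = substitute_zero(.data$tpm_c, thresholds$zero_substitute),
      tpm_t_sub = substitute_zero(.data$tpm_t, thresholds$zero_substitute),
      log2fc = log2(.data$tpm_t_sub / .data$tpm_c_sub),
      p_value = audic_test(.data$count_c, .data$count_t, n1, n2,
                           alternative = alternative),
      category = classify_regulation(.data$log2fc, .data$p_value, thresholds),
      exclusive_flag = dplyr::case_when(
        .data$count_c > 0 & .data$count_t == 0 ~ "control_only",
        .data$count_c == 0 & .data$count_t > 0 ~ "treatment_only",
        TRUE ~ "shared"))
  if (adjust) prof$p_adjusted <- stats::p.adjust(prof$p_value, method = "BH")
  out <- list(profiles = prof |> select(-"tpm_c_sub", -"tpm_t_sub"),
              n_input = nrow(counts), n1 = n1, n2 = n2,
              thresholds = thresholds, alternative = alternative)
  class(out) <- "mirtap_de"
  out
}

#' @export
print.mirtap_de <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("<mirtap_de> %d miRNAs in, %d over %g TPM; ",
                     "%d responsive (%d significant, %d slight)\n"),
              x$n_input, g$n_retained, x$thresholds$min_tpm,
              g$n_responsive, g$n_significant, g$n_slight))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-miRNA expression profiles of a differential expression fit
#'
#' @param x a `mirtap_de` object.
#' @param ... unused.
#' @return tibble with columns `mirna`, `count_c`, `count_t`, `tpm_c`,
#'   `tpm_t`, `log2fc`, `p_value`, `category`, `exclusive_flag`.
#' @export
tidy.mirtap_de <- function(x, ...) x$profiles

#' One-row summary of a differential expression fit
#'
#' @param x a `mirtap_de` object.
#' @param ... unused.
#' @return one-row tibble: retained / responsive / significant / slight /
#'   unobvious tallies, per-direction splits, and library-exclusive counts.
#' @export
glance.mirtap_de <- function(x, ...) {
  p <- x$profiles
  tibble(n_input = x$n_input,
         n_retained = nrow(p),
         n_responsive = sum(p$category != "unobvious"),
         n_significant = sum(p$category %in%
                               c("significantly_up", "significantly_down")),
         n_significant_up = sum(p$category == "significantly_up"),
         n_significant_down = sum(p$category == "significantly_down"),
         n_slight = sum(p$category %in% c("slightly_up", "slightly_down")),
         n_slight_up = sum(p$category == "slightly_up"),
         n_slight_down = sum(p$category == "slightly_down"),
         n_unobvious = sum(p$category == "unobvious"),
         n_control_only = sum(p$exclusive_flag == "control_only"),
         n_treatment_only = sum(p$exclusive_flag == "treatment_only"))
}
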