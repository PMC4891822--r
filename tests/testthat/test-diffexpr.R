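test_that("TPM normalization matches the printed example and unit scale", {
  expect_equal(tpm_normalize(2, 1e6), 2)
  expect_equal(tpm_normalize(0, 1e7), 0)
  # printed library: 1,985,940 miRNA reads of 18,179,025 clean reads
  expect_equal(tpm_normalize(1985940, 18179025), 109243.5, tolerance = 1e-6)
  expect_equal(mirtap:::pct2(1985940, 18179025), 10.92)
  expect_error(tpm_normalize(-1, 100), "negative")
  # conservation: per-library TPM sums to 1e6 before substitution
  counts <- withr::with_seed(109, rpois(500, 40))
  expect_equal(sum(tpm_normalize(counts, sum(counts))), 1e6,
               tolerance = 1e-6)
})

test_that("zero substitution touches exact zeros only", {
  expect_equal(substitute_zero(0), 0.01)
  expect_equal(substitute_zero(5.3), 5.3)
  expect_equal(substitute_zero(0.005), 0.005)  # below 0.01 but nonzero
})

test_that("point probabilities match exact small-count arithmetic", {
  # equal-depth libraries: p(0|0) = 1/2, p(5|5) = C(10,5)/2^11
  expect_equal(audic_pmf(0, 0, 1e6, 1e6), 0.5)
  expect_equal(audic_pmf(5, 5, 1e6, 1e6), 252 / 2048)
  expect_equal(audic_pmf(5, 5, 7, 7), 0.123046875)
})

test_that("point masses agree with the negative binomial identity to 12 digits", {
  # p(y|x; N1, N2) is the NB density with size x+1, prob N1/(N1+N2):
  # an independent evaluation path through stats::dnbinom
  n1 <- 18179025; n2 <- 17763348
  for (x in c(0, 1, 5, 20, 47)) {
    for (y in c(0, 1, 8, 53, 100 - x)) {
      mine <- audic_pmf(y, x, n1, n2)
      ref <- dnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
      expect_equal(mine, ref, tolerance = 1e-12)
    }
  }
})

test_that("point masses normalize and obey the symmetry identity", {
  for (x in c(0, 1, 5, 20)) {
    for (r in c(0.5, 1, 2.3)) {
      total <- sum(audic_pmf(0:2000, x, 1e6, r * 1e6))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
  # role-swap identity: p(y|x; N1, N2) = (N1/N2) p(x|y; N2, N1); plain
  # symmetry holds at equal depths
  for (k in 1:20) {
    x <- k; y <- 25 - k
    expect_equal(audic_pmf(y, x, 1.2e6, 3.4e6),
                 (1.2 / 3.4) * audic_pmf(x, y, 3.4e6, 1.2e6),
                 tolerance = 1e-12)
    expect_equal(audic_pmf(y, x, 2e6, 2e6), audic_pmf(x, y, 2e6, 2e6),
                 tolerance = 1e-12)
  }
})

test_that("tail p-values are valid and react to strong imbalance", {
  expect_equal(audic_pvalue(100, 100, 1e6, 1e6), 1, tolerance = 0.05)
  expect_lt(audic_pvalue(200, 50, 1e6, 1e6), 1e-10)
  expect_lt(audic_pvalue(0, 40, 1e6, 1e6), 1e-6)
  # one-sided variants bracket the doubled tail
  p2 <- audic_pvalue(80, 120, 1e6, 1e6)
  pl <- audic_pvalue(80, 120, 1e6, 1e6, alternative = "less")
  pg <- audic_pvalue(80, 120, 1e6, 1e6, alternative = "greater")
  expect_equal(p2, min(1, 2 * min(pl, pg)))
})

test_that("classification matches the direct threshold oracle on a grid", {
  th <- de_thresholds()
  lfc <- c(-14, -2, -1, -0.99, -0.5, -0.25, -0.24, 0, 0.24, 0.25, 0.6, 1, 3)
  pv <- c(0.001, 0.049, 0.05, 0.2, 0.9)
  grid <- expand.grid(lfc = lfc, p = pv)
  got <- as.character(classify_regulation(grid$lfc, grid$p, th))
  want <- mapply(oracle_classify, grid$lfc, grid$p)
  expect_equal(got, unname(want))
})

test_that("published profile examples classify as described", {
  th <- de_thresholds()
  # miR172a: 2508.94 -> 1796.79 TPM, |log2FC| ~ 0.48: slight, down
  lfc <- log2(1796.79 / 2508.94)
  expect_equal(abs(lfc), 0.48, tolerance = 0.01)
  expect_equal(as.character(classify_regulation(lfc, 0.5, th)), "slightly_down")
  # miR6024-3p: 132.63 TPM (2411 reads of 18,179,025) to 0 reads
  counts <- tibble::tibble(mirna = "miR6024-3p", count_c = 2411L, count_t = 0L)
  fit <- diff_expression(counts, n1 = 18179025, n2 = 17763348)
  prof <- tidy(fit)
  expect_equal(round(prof$tpm_c, 2), 132.63)
  expect_equal(substitute_zero(prof$tpm_t), 0.01)
  expect_equal(prof$log2fc, log2(0.01 / 132.63), tolerance = 0.01)
  expect_equal(as.character(prof$category), "significantly_down")
  expect_equal(prof$exclusive_flag, "control_only")
  # equal TPM: unobvious
  expect_equal(as.character(classify_regulation(0, 0.9, th)), "unobvious")
})

test_that("low-abundance filter keeps anything reaching 2 TPM in one library", {
  prof <- tibble::tibble(tpm_c = c(1.5, 1.5, 2.0, 8), tpm_t = c(1.9, 2.4, 0, 9))
  kept <- filter_low_abundance(prof)
  expect_equal(nrow(kept), 3)
  expect_false(any(kept$tpm_c == 1.5 & kept$tpm_t == 1.9))
  expect_true(any(kept$tpm_c == 2.0))  # inclusive boundary
})

test_that("classification is direction-symmetric under library swap", {
  counts <- tibble::tibble(mirna = sprintf("m%d", 1:6),
                           count_c = c(400L, 100L, 52L, 0L, 30L, 10L),
                           count_t = c(100L, 400L, 48L, 30L, 0L, 10L))
  a <- tidy(diff_expression(counts, 1e5, 1e5))
  swapped <- counts |>
    dplyr::rename(count_c = count_t, count_t = count_c)
  b <- tidy(diff_expression(swapped, 1e5, 1e5))
  flip <- c(significantly_up = "significantly_down",
            significantly_down = "significantly_up",
            slightly_up = "slightly_down", slightly_down = "slightly_up",
            unobvious = "unobvious")
  expect_equal(as.character(b$category),
               unname(flip[as.character(a$category)]))
  expect_equal(b$log2fc, -a$log2fc)
  # the doubled tail is not exactly swap-symmetric on discrete counts, but
  # it stays on the same side of alpha here
  expect_equal(b$p_value < 0.05, a$p_value < 0.05)
})

test_that("glance tallies are consistent with tidy categories", {
  counts <- tibble::tibble(mirna = sprintf("m%d", 1:8),
                           count_c = c(500L, 40L, 300L, 90L, 1L, 0L, 80L, 70L),
                           count_t = c(100L, 160L, 360L, 88L, 1L, 60L, 0L, 71L))
  fit <- diff_expression(counts, 2e5, 2e5)
  g <- glance(fit)
  p <- tidy(fit)
  expect_equal(g$n_retained, nrow(p))
  expect_equal(g$n_significant + g$n_slight + g$n_unobvious, g$n_retained)
  expect_equal(g$n_responsive, g$n_significant + g$n_slight)
  expect_equal(g$n_control_only, sum(p$exclusive_flag == "control_only"))
  # p-values are computed from raw counts, not substituted TPM
  expect_equal(p$p_value[p$mirna == "m6"],
               audic_pvalue(0, 60, 2e5, 2e5))
})
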