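test_that("identical configs give byte-identical libraries and genomes", {
  cfg <- sim_config(seed = 7, genome_length = 3e4, n_known_mirna = 3,
                    n_novel_mirna = 2, n_decoy_loci = 1,
                    library_depths = c(2000, 2000))
  a <- simulate_srna_experiment(cfg)
  b <- simulate_srna_experiment(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$features, b$features)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads, b$reads)
  # and the FASTQ bytes themselves
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fastq(a$reads$control, file.path(d1, "c.fastq"))
  write_fastq(b$reads$control, file.path(d2, "c.fastq"))
  expect_identical(readBin(file.path(d1, "c.fastq"), "raw", 1e6),
                   readBin(file.path(d2, "c.fastq"), "raw", 1e6))
})

test_that("planted loci occupy non-overlapping intervals clear of features", {
  sim <- simulate_srna_experiment(sim_config(
    seed = 3, genome_length = 5e4, n_known_mirna = 3, n_novel_mirna = 2,
    n_decoy_loci = 0, library_depths = c(1000, 1000)))
  tr <- sim$truth
  expect_equal(nrow(tr), 5)
  # exhaustive pairwise interval scan
  for (i in seq_len(nrow(tr))) {
    for (j in seq_len(nrow(tr))) {
      if (i == j) next
      expect_true(tr$pre_end[i] < tr$pre_start[j] ||
                    tr$pre_start[i] > tr$pre_end[j])
    }
    overlaps_feature <- any(sim$features$start <= tr$pre_end[i] &
                              sim$features$end >= tr$pre_start[i])
    expect_false(overlaps_feature)
  }
  # precursor really sits in the genome, mature inside the precursor
  for (i in seq_len(nrow(tr))) {
    expect_gte(tr$mature_start[i], tr$pre_start[i])
    expect_lte(tr$mature_end[i], tr$pre_end[i])
    expect_identical(substr(sim$genome[["chr1"]], tr$mature_start[i],
                            tr$mature_end[i]), tr$mature_seq[i])
  }
})

test_that("a config with no planted loci yields only background features", {
  sim <- simulate_srna_experiment(sim_config(
    seed = 5, genome_length = 3e4, n_known_mirna = 0, n_novel_mirna = 0,
    n_decoy_loci = 0, library_depths = c(500, 500)))
  expect_equal(nrow(sim$truth), 0)
  expect_gt(nrow(sim$features), 0)
  expect_equal(nrow(sim$known_db), 0)
})

test_that("designed hairpins have the constructed duplex geometry", {
  withr::with_seed(13, {
    hp <- design_hairpin("TTGCACTGATAGAGAGCACAA")
    # star core is the reverse complement of mature[1..L-2]; 2-nt 3' tail
    expect_identical(substr(hp$star, 1, 19),
                     revcomp(substr("TTGCACTGATAGAGAGCACAA", 1, 19)))
    expect_equal(nchar(hp$star), 21)
    # terminal loop at least 4 nt
    expect_gte(hp$star_start - hp$mature_end - 1, 4)
    expect_error(design_hairpin("ACGT"), "20-24")
  })
})

test_that("truth expected counts are conserved within library depth", {
  sim <- tiny_sim(seed = 17)
  expect_lte(sum(sim$truth$expected_count_c), sim$config$library_depths[1])
  expect_lte(sum(sim$truth$expected_count_t), sim$config$library_depths[2])
  expect_equal(sim$truth$expected_count_t,
               sim$truth$expected_count_c * 2^sim$truth$true_log2fc)
})

test_that("null effects give count ratios centred on N2/N1 and planted log2FC is recovered", {
  # all loci at expected (200, 50): true log2FC -2 everywhere
  n_loci <- 24
  cfg <- sim_config(seed = 23, genome_length = 1e5, n_known_mirna = n_loci,
                    n_novel_mirna = 0, n_decoy_loci = 0,
                    library_depths = c(3e4, 3e4),
                    base_abundance = c(log10(200), log10(200)),
                    de_effects = tibble::tibble(
                      locus_id = sprintf("known_mir_%03d", 1:n_loci),
                      true_log2fc = -2),
                    noise = 0, star_fraction = 0, isomir_fraction = 0)
  sim <- simulate_srna_experiment(cfg)
  tags <- collapse_tags(
    trim_and_filter(sim$reads$control)$inserts,
    trim_and_filter(sim$reads$treatment)$inserts)
  cnt <- tags[match(sim$truth$mature_seq, tags$sequence), ]
  lfc <- log2(cnt$count_t / cnt$count_c)
  expect_true(all(abs(lfc - (-2)) < 0.9))     # per locus, Poisson at (200, 50)
  expect_lt(abs(mean(lfc) - (-2)), 0.3)       # ensemble mean much tighter

  # null tier: ratios centred on N2/N1 = 1
  cfg0 <- sim_config(seed = 29, genome_length = 2e5, n_known_mirna = 100,
                     n_novel_mirna = 0, n_decoy_loci = 0,
                     library_depths = c(3e4, 3e4),
                     de_effects = tibble::tibble(
                       locus_id = sprintf("known_mir_%03d", 1:100),
                       true_log2fc = 0),
                     noise = 0, star_fraction = 0, isomir_fraction = 0)
  sim0 <- simulate_srna_experiment(cfg0)
  tags0 <- collapse_tags(
    trim_and_filter(sim0$reads$control)$inserts,
    trim_and_filter(sim0$reads$treatment)$inserts)
  cnt0 <- tags0[match(sim0$truth$mature_seq, tags0$sequence), ]
  ratio <- cnt0$count_t / cnt0$count_c
  expect_gt(nrow(cnt0), 99)
  expect_lt(abs(median(ratio, na.rm = TRUE) - 1), 0.15)
})

test_that("five_prime_u_prob = 1 makes every planted-locus read start with T", {
  sim <- simulate_srna_experiment(sim_config(
    seed = 31, genome_length = 4e4, n_known_mirna = 4, n_novel_mirna = 3,
    n_decoy_loci = 0, library_depths = c(3000, 3000),
    five_prime_u_prob = 1, noise = 0, star_fraction = 0))
  expect_true(all(startsWith(sim$truth$mature_seq, "T")))
  # reads drawn from loci are mature (or 3'-shifted mature): first base T
  locus_reads <- sim$reads$control$sequence[
    substr(sim$reads$control$sequence, 1, 15) %in%
      substr(sim$truth$mature_seq, 1, 15)]
  expect_gt(length(locus_reads), 0)
  expect_true(all(startsWith(locus_reads, "T")))
})

test_that("written experiment files round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_srna_experiment(sim_config(
    seed = 37, genome_length = 3e4, n_known_mirna = 3, n_novel_mirna = 0,
    n_decoy_loci = 0, library_depths = c(800, 800)), out_dir = dir)
  expect_true(all(file.exists(sim$paths)))
  g <- Biostrings::readDNAStringSet(sim$paths[["genome"]])
  expect_identical(as.character(g[[1]]), sim$genome[["chr1"]])
  feats <- read_features(sim$paths[["features"]])
  expect_equal(nrow(feats), nrow(sim$features))
  expect_setequal(feats$feature_id, sim$features$feature_id)
  reads <- read_fastq_tbl(sim$paths[["control"]])
  expect_equal(reads$sequence, sim$reads$control$sequence)
  db <- read_mature_db(sim$paths[["known"]])
  expect_identical(db$sequence, sim$known_db$sequence)
})
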