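test_that("exact and reverse-complement tags are located on the right strands", {
  g <- withr::with_seed(41, c(chr1 = rand_dna(3000)))
  tag_fwd <- substr(g[["chr1"]], 501, 521)
  tag_rev <- revcomp(substr(g[["chr1"]], 1001, 1024))
  aln <- map_tags(c(tag_fwd, tag_rev), g, max_mismatch = 0)
  fwd <- aln[aln$sequence == tag_fwd, ]
  expect_equal(fwd$start, 501L)
  expect_equal(fwd$end, 521L)
  expect_equal(fwd$strand, "+")
  rev <- aln[aln$sequence == tag_rev, ]
  expect_equal(rev$start, 1001L)
  expect_equal(rev$strand, "-")
})

test_that("mapping agrees with the brute-force scan for 0-2 mismatches", {
  withr::with_seed(43, {
    g <- c(chr1 = rand_dna(20000))
    # tags: planted exact, planted with 1 and 2 substitutions, random
    mk_var <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      pos <- sample(length(ch), k)
      for (p in pos) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
      paste(ch, collapse = "")
    }
    tags <- c(
      substr(g, 101, 121), substr(g, 5001, 5024),
      mk_var(substr(g, 900, 920), 1), mk_var(substr(g, 1500, 1523), 2),
      revcomp(mk_var(substr(g, 7000, 7021), 2)),
      replicate(5, rand_dna(21)))
    for (mm in 0:2) {
      aln <- map_tags(tags, g, max_mismatch = mm)
      for (tg in tags) {
        got <- aln[aln$sequence == tg, c("start", "end", "strand", "mismatches")]
        want <- oracle_scan(tg, g[["chr1"]], mm)
        if (is.null(want)) {
          expect_equal(nrow(got), 0)
        } else {
          got <- got[order(got$start, got$strand), ]
          want <- want[order(want$start, want$strand), ]
          expect_equal(got$start, want$start)
          expect_equal(got$mismatches, want$mismatches)
          expect_equal(got$strand, want$strand)
        }
      }
    }
  })
})

test_that("random tags almost never map, as the scan oracle confirms", {
  withr::with_seed(47, {
    g <- c(chr1 = rand_dna(100000))
    tags <- replicate(20, rand_dna(21))
    aln <- map_tags(tags, g, max_mismatch = 0)
    for (tg in tags) {
      o <- oracle_scan(tg, g[["chr1"]], 0)
      expect_equal(nrow(aln[aln$sequence == tg, ]),
                   if (is.null(o)) 0L else nrow(o))
    }
  })
})

# --- classification cascade ------------------------------------------------

features <- tibble::tibble(
  chrom = "chr1",
  start = c(101L, 201L, 301L, 401L),
  end = c(180L, 280L, 380L, 480L),
  strand = c("+", "+", "-", "+"),
  type = c("rRNA", "exon", "exon", "intron"),
  feature_id = c("rrna_1", "exon_1", "exon_2", "intron_1"))

test_that("precedence places known miRNAs above features and splits exon strands", {
  g <- withr::with_seed(53, c(chr1 = rand_dna(600)))
  tag_mirna <- substr(g[["chr1"]], 210, 230)   # inside exon_1, but known
  tag_rrna <- substr(g[["chr1"]], 120, 140)
  tag_sense <- substr(g[["chr1"]], 240, 260)    # exon_1 on +
  tag_anti <- substr(g[["chr1"]], 320, 340)     # + alignment over a - exon
  tag_none <- substr(g[["chr1"]], 540, 560)
  tag_unmapped <- withr::with_seed(54, rand_dna(25))
  tags <- collapse_tags(c(tag_mirna, tag_rrna, tag_sense, tag_anti,
                          tag_none, tag_unmapped))
  aln <- map_tags(tags, g, 0)
  cls <- classify_tags(tags, aln, features, known_mirna = tag_mirna)
  got <- setNames(as.character(cls$category), cls$sequence)
  expect_equal(got[[tag_mirna]], "miRNA")
  expect_equal(got[[tag_rrna]], "rRNA")
  expect_equal(got[[tag_sense]], "exon_sense")
  expect_equal(got[[tag_anti]], "exon_antisense")
  expect_equal(got[[tag_none]], "un_annotated")
  expect_equal(got[[tag_unmapped]], "un_annotated")
  expect_false(cls$mapped[cls$sequence == tag_unmapped])
})

test_that("classification is independent of tag order and partitions reads", {
  sim <- tiny_sim(seed = 59, depth = 3000)
  tags <- collapse_tags(trim_and_filter(sim$reads$control)$inserts,
                        trim_and_filter(sim$reads$treatment)$inserts)
  aln <- map_tags(tags, sim$genome, 0)
  known <- match_known(tags, sim$known_db)
  cls1 <- classify_tags(tags, aln, sim$features, known$matched$sequence)
  shuf <- withr::with_seed(60, tags[sample(nrow(tags)), ])
  cls2 <- classify_tags(shuf, aln, sim$features, known$matched$sequence)
  merged <- dplyr::inner_join(
    cls1[, c("sequence", "category")], cls2[, c("sequence", "category")],
    by = "sequence")
  expect_equal(merged$category.x, merged$category.y)
  # partition: every tag exactly one category; totals conserved
  expect_false(anyNA(cls1$category))
  summ <- summarize_categories(cls1)
  expect_equal(sum(summ$total_c), sum(tags$count_c))
  expect_equal(sum(summ$total_t), sum(tags$count_t))
  expect_equal(sum(summ$total_pct_c), 100, tolerance = 0.05)
})

test_that("category percentages reproduce the published miRNA shares", {
  # printed inputs: miRNA totals over library totals
  expect_equal(mirtap:::pct2(1985940, 18179025), 10.92)
  expect_equal(mirtap:::pct2(1732993, 17763348), 9.76)
  # single category degenerate case
  one <- tibble::tibble(sequence = "ACGTACGTACGTACGT",
                        count_c = 5L, count_t = 3L,
                        category = factor("miRNA",
                                          levels = mirtap:::CATEGORY_LEVELS))
  s <- summarize_categories(one)
  expect_equal(s$total_pct_c[s$category == "miRNA"], 100)
})

test_that("length histogram reports every bin and matches planted mixture", {
  tags21 <- tibble::tibble(sequence = replicate(5, rand_dna(21)),
                           count_c = 10L, count_t = 2L)
  ld <- length_distribution(tags21)
  expect_equal(nrow(ld), 16)                   # 15..30 all present
  expect_equal(ld$total_pct_c[ld$length == 21], 100)
  expect_equal(ld$total_pct_c[ld$length == 22], 0)

  # simulated mixture: 21/24 shares land within 2 points of the weights
  sim <- simulate_srna_experiment(sim_config(
    seed = 61, genome_length = 4e4, n_known_mirna = 0, n_novel_mirna = 0,
    n_decoy_loci = 0, library_depths = c(20000, 20000),
    length_mode_weights = c(len21 = 0.2, len24 = 0.5, other = 0.3)))
  tags <- collapse_tags(trim_and_filter(sim$reads$control)$inserts,
                        trim_and_filter(sim$reads$treatment)$inserts)
  ld2 <- length_distribution(tags)
  expect_lt(abs(ld2$total_pct_c[ld2$length == 21] - 20), 2)
  expect_lt(abs(ld2$total_pct_c[ld2$length == 24] - 50), 2)
})
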