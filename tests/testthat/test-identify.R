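test_that("known matching honors the two-mismatch boundary", {
  withr::with_seed(71, {
    db <- tibble::tibble(name = sprintf("mir-%d", 1:20),
                         sequence = replicate(20, rand_dna(21)))
    mutate_at <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      pos <- sample(length(ch), k)
      for (p in pos) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
      paste(ch, collapse = "")
    }
    exact <- db$sequence[3]
    two <- mutate_at(db$sequence[7], 2)
    three <- mutate_at(db$sequence[12], 3)
    res <- match_known(c(exact, two, three), db)
    expect_equal(nrow(res$matched), 2)
    expect_equal(res$matched$mismatches[res$matched$sequence == exact], 0L)
    expect_equal(res$matched$mirna_name[res$matched$sequence == two], "mir-7")
    expect_equal(res$matched$mismatches[res$matched$sequence == two], 2L)
    expect_equal(res$unmatched$sequence, three)
  })
})

test_that("known matching agrees with exhaustive Hamming search", {
  withr::with_seed(73, {
    db <- tibble::tibble(name = sprintf("m%d", 1:200),
                         sequence = replicate(200, rand_dna(21)))
    queries <- c(
      db$sequence[sample(200, 5)],
      replicate(10, rand_dna(21)),
      vapply(db$sequence[sample(200, 5)], function(s) {
        ch <- strsplit(s, "")[[1]]
        p <- sample(21, 2)
        for (q in p) ch[q] <- sample(setdiff(c("A","C","G","T"), ch[q]), 1)
        paste(ch, collapse = "")
      }, character(1)))
    res <- match_known(queries, db)
    for (q in queries) {
      oracle <- oracle_hamming_match(q, db$sequence, 2)
      if (is.na(oracle$index)) {
        expect_false(q %in% res$matched$sequence)
      } else {
        row <- res$matched[res$matched$sequence == q, ]
        expect_equal(row$mismatches[1], oracle$mismatches)
      }
    }
  })
})

test_that("length-shifted tags still match within the end-shift allowance", {
  db <- tibble::tibble(name = "mir-x", sequence = "TTGCACTGATAGAGAGCACAA")
  shifted <- paste0(db$sequence, "G")     # +1 nt at the 3' end
  trimmed <- substr(db$sequence, 1, 19)   # -2 nt
  res <- match_known(c(shifted, trimmed), db)
  expect_equal(nrow(res$matched), 2)
})

test_that("precursor windows follow the flank arithmetic and clip at ends", {
  g <- withr::with_seed(79, c(chr1 = rand_dna(10000)))
  aln <- tibble::tibble(sequence = substr(g, 1001, 1021), chrom = "chr1",
                        start = 1001L, end = 1021L, strand = "+")
  win <- extract_precursor_windows(aln, g, flank = 300)
  sym <- win[win$kind == "symmetric", ]
  expect_equal(sym$window_start, 701L)
  expect_equal(sym$window_end, 1321L)
  expect_false(sym$clipped)
  a5 <- win[win$kind == "anchor5", ]
  expect_equal(c(a5$window_start, a5$window_end), c(1001L, 1621L))

  near_edge <- tibble::tibble(sequence = substr(g, 11, 31), chrom = "chr1",
                              start = 11L, end = 31L, strand = "+")
  win2 <- extract_precursor_windows(near_edge, g, flank = 300)
  sym2 <- win2[win2$kind == "symmetric", ]
  expect_equal(sym2$window_start, 1L)
  expect_true(sym2$clipped)
})

test_that("tags within the cluster gap merge into one cluster", {
  g <- withr::with_seed(83, c(chr1 = rand_dna(5000)))
  aln <- tibble::tibble(
    sequence = c(substr(g, 2001, 2021), substr(g, 2027, 2047)),
    chrom = "chr1", start = c(2001L, 2027L), end = c(2021L, 2047L),
    strand = "+")
  win <- extract_precursor_windows(aln, g, flank = 100, cluster_gap = 10)
  expect_equal(length(unique(win$cluster_id)), 1)
  expect_equal(win$cluster_start[1], 2001L)
  expect_equal(win$cluster_end[1], 2047L)
  # beyond the gap: two clusters
  aln2 <- aln; aln2$start[2] <- 2040L; aln2$end[2] <- 2060L
  aln2$sequence[2] <- substr(g, 2040, 2060)
  win2 <- extract_precursor_windows(aln2, g, flank = 100, cluster_gap = 10)
  expect_equal(length(unique(win2$cluster_id)), 2)
})

test_that("planted hairpins pass all six qualifications; read support gates them", {
  withr::with_seed(89, {
    fh <- flanked_hairpin()
    f <- fold_rna(fh$window)
    ok <- evaluate_hairpin(fh$window, f, fh$mature_start, fh$mature_end,
                           supporting_reads = 20)
    expect_true(ok$pass)
    expect_true(all(ok$flags))
    expect_equal(ok$mature_arm, "5p")
    # derived star overlaps the planted star interval
    expect_lt(abs(ok$star_start - (fh$mature_start + 30 - 1)), 4)

    low <- evaluate_hairpin(fh$window, f, fh$mature_start, fh$mature_end,
                            supporting_reads = 4)
    expect_false(low$pass)
    expect_false(low$flags[["reads"]])
    expect_true(all(low$flags[names(low$flags) != "reads"]))
  })
})

test_that("hairpin verdict is monotone in supporting reads", {
  withr::with_seed(97, {
    fh <- flanked_hairpin()
    f <- fold_rna(fh$window)
    passes <- vapply(1:30, function(k)
      evaluate_hairpin(fh$window, f, fh$mature_start, fh$mature_end,
                       supporting_reads = k)$pass, logical(1))
    # once passing, adding reads never turns pass into fail
    expect_false(is.unsorted(passes))
  })
})

test_that("shuffled decoy windows fail the structural qualifications", {
  withr::with_seed(101, {
    fails <- 0
    for (i in 1:100) {
      fh <- flanked_hairpin(flank = 60)
      shuf <- shuffle_dinucleotide(fh$window)
      f <- fold_rna(shuf)
      cand <- evaluate_hairpin(shuf, f, fh$mature_start, fh$mature_end,
                               supporting_reads = 20)
      if (!cand$pass) fails <- fails + 1
    }
    expect_gte(fails, 95)
  })
})

test_that("dinucleotide shuffle preserves the dinucleotide spectrum", {
  withr::with_seed(103, {
    s <- rand_dna(200)
    sh <- shuffle_dinucleotide(s)
    din <- function(x) table(substring(x, 1:(nchar(x) - 1), 2:nchar(x)))
    expect_identical(as.list(din(s)), as.list(din(sh)))
    expect_false(identical(s, sh))
  })
})

test_that("expression counting enforces the core/terminal mismatch rule", {
  mature <- "TTGCACTGATAGAGAGCACAA"  # 21 nt
  mk <- function(seq, c_, t_, off = 0L)
    tibble::tibble(sequence = seq, count_c = c_, count_t = t_, offset = off)
  # identity contributes its full counts
  res <- count_mirna_expression(mature, mk(mature, 7L, 2L))
  expect_equal(c(res$count_c, res$count_t), c(7L, 2L))
  # substitution at position 11 (core) excludes the tag
  core_mm <- mature
  substr(core_mm, 11, 11) <- if (substr(mature, 11, 11) == "A") "C" else "A"
  res2 <- count_mirna_expression(mature, mk(core_mm, 5L, 5L))
  expect_equal(c(res2$count_c, res2$count_t), c(0L, 0L))
  # 3'-shifted tag with intact core is included (checked against the
  # enumeration of all one-edit variants below)
  shift <- paste0(substr(mature, 2, 21), "G")
  res3 <- count_mirna_expression(mature, mk(shift, 3L, 1L, off = 1L))
  expect_equal(c(res3$count_c, res3$count_t), c(3L, 1L))
})

test_that("one-edit enumeration matches the stated counting rule", {
  mature <- "TTGCACTGATAGAGAGCACAA"
  L <- nchar(mature)
  # every single-substitution variant at offset 0: included iff the edited
  # position is in a terminal 3-nt window
  for (pos in seq_len(L)) {
    var <- mature
    substr(var, pos, pos) <- if (substr(mature, pos, pos) == "G") "T" else "G"
    res <- count_mirna_expression(
      mature, tibble::tibble(sequence = var, count_c = 1L, count_t = 0L,
                             offset = 0L))
    in_terminal <- pos <= 3 || pos >= L - 2
    expect_equal(res$count_c == 1L, in_terminal, label = paste("pos", pos))
  }
})

test_that("full discovery drive recovers a planted locus and reports flags", {
  sim <- tiny_sim(seed = 107, depth = 6000)
  tags <- collapse_tags(trim_and_filter(sim$reads$control)$inserts,
                        trim_and_filter(sim$reads$treatment)$inserts)
  aln <- map_tags(tags, sim$genome, 0)
  known <- match_known(tags, sim$known_db)
  cls <- classify_tags(tags, aln, sim$features, known$matched$sequence)
  nov <- discover_mirna(cls, sim$genome)
  truth_nov <- sim$truth[sim$truth$class == "novel", ]
  hit <- vapply(seq_len(nrow(truth_nov)), function(i) any(
    nov$pass & nov$precursor_start <= truth_nov$mature_start[i] &
      nov$precursor_end >= truth_nov$mature_end[i]), logical(1))
  expect_gte(mean(hit), 0.75)
  # decoys never pass
  truth_dec <- sim$truth[sim$truth$class == "decoy", ]
  dec_hit <- vapply(seq_len(nrow(truth_dec)), function(i) any(
    nov$pass & nov$precursor_start <= truth_dec$mature_start[i] &
      nov$precursor_end >= truth_dec$mature_end[i]), logical(1))
  expect_equal(sum(dec_hit), 0)
  expect_true(all(nov$supporting_reads[nov$pass] >= 5))
})
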