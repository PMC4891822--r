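#' Read a mature-miRNA database from FASTA
#'
#' Accepts miRBase-style headers; only the first whitespace-delimited token
#' is kept as the name. U is converted to T.
#'
#' @param path FASTA file of mature miRNA sequences.
#' @return tibble with columns `name`, `sequence`.
#' @export
read_mature_db <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(name = sub("\\s.*$", "", names(x)),
         sequence = unname(as_dna(as.character(x))))
}

#' Assign tags to known mature miRNAs
#'
#' A tag is assigned to the mature miRNA with the fewest substitutions,
#' allowing at most `max_mismatch` mismatches, a length difference of at
#' most 2 nt, and 5'/3' end shifts of up to 2 nt (mismatches counted over
#' the overlap of the end-shifted ungapped alignment). Ties go to the longer
#' overlap, then the first database entry.
#'
#' @param tags tibble with `sequence` (and any other columns, preserved), or
#'   a character vector.
#' @param mature_db tibble with `name`, `sequence` (see [read_mature_db()]).
#' @param max_mismatch mismatch budget (default 2).
#' @return list with `matched` (tags tibble plus `mirna_name`, `mismatches`)
#'   and `unmatched` (pass-through tags tibble).
#' @export
match_known <- function(tags, mature_db, max_mismatch = 2L) {
  if (nrow(mature_db) == 0) abort("mature_db is empty")
  if (anyDuplicated(mature_db$name)) abort("mature miRNA names must be unique")
  if (is.character(tags)) tags <- tibble(sequence = tags)
  tags <- tags |> mutate(sequence = as_dna(.data$sequence))
  res <- match_known_cpp(tags$sequence, as_dna(mature_db$sequence),
                         as.integer(max_mismatch), 2L, 2L)
  hit <- !is.na(res$db_index)
  matched <- tags[hit, , drop = FALSE] |>
    mutate(mirna_name = mature_db$name[res$db_index[hit]],
           mismatches = res$mismatches[hit])
  list(matched = matched, unmatched = tags[!hit, , drop = FALSE])
}

#' Candidate precursor windows around un-annotated tag clusters
#'
#' Clusters mapped un-annotated tags per chromosome and strand (joining
#' alignments separated by at most `cluster_gap` nt), then emits, for every
#' cluster, the symmetric window extending `flank` nt on both sides and the
#' two asymmetric windows (cluster at the 5' end, cluster at the 3' end of
#' the window), deduplicated by interval. Windows clipped at chromosome ends
#' are kept and flagged.
#'
#' @param alignments tibble of best alignments for un-annotated tags
#'   (columns `sequence`, `chrom`, `start`, `end`, `strand`; e.g. the mapped
#'   un-annotated rows of [classify_tags()] output).
#' @param genome named character vector / `DNAStringSet` / FASTA path.
#' @param flank window flank in nt (default 150).
#' @param cluster_gap maximum gap joining two alignments into one cluster.
#' @return tibble with `cluster_id`, `chrom`, `strand`, `cluster_start`,
#'   `cluster_end`, `window_start`, `window_end`, `kind` (symmetric /
#'   anchor5 / anchor3), `clipped` (logical), `window_seq` (strand
#'   orientation: the cluster strand).
#' @export
extract_precursor_windows <- function(alignments, genome, flank = 150L,
                                      cluster_gap = 10L) {
  genome <- load_genome(genome)
  if (nrow(alignments) == 0)
    return(tibble(cluster_id = character(0), chrom = character(0),
                  strand = character(0), cluster_start = integer(0),
                  cluster_end = integer(0), window_start = integer(0),
                  window_end = integer(0), kind = character(0),
                  clipped = logical(0), window_seq = character(0)))
  gr <- GenomicRanges::GRanges(alignments$chrom,
                               IRanges::IRanges(alignments$start, alignments$end),
                               strand = alignments$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = cluster_gap + 1L)
  cl <- tibble(chrom = as.character(GenomicRanges::seqnames(red)),
               strand = as.character(GenomicRanges::strand(red)),
               cluster_start = GenomicRanges::start(red),
               cluster_end = GenomicRanges::end(red)) |>
    mutate(cluster_id = sprintf("cluster_%04d", row_number()))
  win <- cl |>
    tidyr::expand_grid(kind = c("symmetric", "anchor5", "anchor3")) |>
    mutate(
      window_start = dplyr::case_when(
        kind == "symmetric" ~ .data$cluster_start - flank,
        kind == "anchor5" ~ .data$cluster_start,
        TRUE ~ .data$cluster_start - 2L * flank),
      window_end = dplyr::case_when(
        kind == "symmetric" ~ .data$cluster_end + flank,
        kind == "anchor5" ~ .data$cluster_end + 2L * flank,
        TRUE ~ .data$cluster_end))
  chrom_len <- setNames(nchar(genome), names(genome))
  win <- win |>
    mutate(clip_lo = .data$window_start < 1L,
           clip_hi = .data$window_end > chrom_len[.data$chrom],
           clipped = .data$clip_lo | .data$clip_hi,
           window_start = pmax(.data$window_start, 1L),
           window_end = pmin(.data$window_end,
                             unname(chrom_len[.data$chrom]))) |>
    distinct(.data$cluster_id, .data$window_start, .data$window_end,
             .keep_all = TRUE) |>
    select(-"clip_lo", -"clip_hi")
  seqs <- substr(genome[win$chrom], win$window_start, win$window_end)
  seqs <- ifelse(win$strand == "-", revcomp(seqs), seqs)
  win |> mutate(window_seq = unname(seqs)) |>
    select("cluster_id", "chrom", "strand", "cluster_start", "cluster_end",
           "window_start", "window_end", "kind", "clipped", "window_seq")
}

#' Evaluate the six novel-miRNA hairpin qualifications
#'
#' Given a folded candidate window and the position of the putative mature
#' within it, sets six boolean flags; the candidate passes iff all are true:
#'
#' 1. un-annotated genomic origin (supplied by the caller from the
#'    annotation cascade);
#' 2. stem-loop with the mature wholly on one arm (no base of the mature
#'    pairs with another mature base, and the duplex-defining positions
#'    pair into a single opposite arm);
#' 3. the mature/star duplex shows 2-nt 3' overhangs (the star is derived
#'    from the fold as the partners of the mature with the canonical 2-nt
#'    offset);
#' 4. no large internal loops or bulges in the duplex, quantified as at most
#'    `max_duplex_mismatch` unpaired mature positions and no asymmetric
#'    bulge larger than `max_bulge` nt;
#' 5. fold energy at most `max_energy` kcal/mol (whole-window fold);
#' 6. mature-read support of at least `min_reads` (both libraries summed).
#'
#' @param window_seq candidate precursor window sequence (5'->3').
#' @param fold a [fold_rna()] result for `window_seq`.
#' @param mature_start,mature_end 1-based mature position within the window.
#' @param supporting_reads read count supporting the mature.
#' @param unannotated logical, qualification 1.
#' @param max_energy,min_reads,max_duplex_mismatch,max_bulge thresholds
#'   (defaults -18 kcal/mol, 5 reads, 4 mismatches, 2 nt).
#' @return list of class `hairpin_candidate`: `flags` (named logical, six),
#'   `pass`, `mature_arm` (`"5p"`/`"3p"`/NA), `star_start`, `star_end`,
#'   `energy`, `structure`, plus the inputs.
#' @export
evaluate_hairpin <- function(window_seq, fold, mature_start, mature_end,
                             supporting_reads, unannotated = TRUE,
                             max_energy = -18, min_reads = 5L,
                             max_duplex_mismatch = 4L, max_bulge = 2L) {
  n <- nchar(window_seq)
  if (mature_start < 1 || mature_end > n || mature_start >= mature_end)
    abort("mature not contained in window")
  partner <- fold$partner
  mpos <- mature_start:mature_end
  L <- length(mpos)

  flags <- c(unannotated = isTRUE(unannotated),
             one_arm = FALSE, overhang = FALSE, duplex = FALSE,
             energy = fold$energy <= max_energy,
             reads = supporting_reads >= min_reads)

  # qualification 2: no self-pairing within the mature, and the mature's
  # partners lie predominantly (>= 80 % of its paired bases) on one side —
  # a stray terminal base captured by a distant helix does not disqualify
  pm <- partner[mpos]
  self_paired <- any(!is.na(pm) & pm >= mature_start & pm <= mature_end)
  outside <- pm[!is.na(pm)]
  mature_arm <- NA_character_
  star_start <- NA_integer_; star_end <- NA_integer_
  if (!self_paired && length(outside) > 0) {
    frac_right <- mean(outside > mature_end)
    if (frac_right >= 0.8) { flags["one_arm"] <- TRUE; mature_arm <- "5p" }
    if (frac_right <= 0.2) { flags["one_arm"] <- TRUE; mature_arm <- "3p" }
  }

  if (flags["one_arm"]) {
    # duplex region: the mature minus its own 2-nt 3' overhang; the star is
    # derived arithmetically from the dominant antiparallel register C
    # (position + partner ~ C within one helix), with the canonical 2-nt
    # 3' overhang built into the derivation
    d_lo <- mature_start; d_hi <- mature_end - 2L
    dpos <- d_lo:d_hi
    dp <- partner[dpos]
    dlen <- length(dpos)
    paired <- !is.na(dp) & (if (mature_arm == "5p") dp > mature_end
                            else dp < mature_start)
    if (any(paired)) {
      reg <- dpos[paired] + dp[paired]
      C <- as.integer(names(sort(table(reg), decreasing = TRUE))[1])
      ss <- C - mature_end + 2L
      se <- C - mature_start + 2L
      # qualification 3: a coherent duplex with 2-nt 3' overhangs — the
      # star interval must fit the window, stay clear of the mature, and
      # capture at least half of the duplex positions
      in_star <- paired & dp >= ss & dp <= se
      star_ok <- ss >= 1L && se <= n &&
        (se < mature_start || ss > mature_end)
      flags["overhang"] <- star_ok && sum(in_star) >= ceiling(dlen / 2)
      if (star_ok) { star_start <- ss; star_end <- se }
      # qualification 4: duplex positions not pairing into the star count
      # as mismatches; bulge asymmetry over consecutive in-star pairs
      n_mismatch <- dlen - sum(in_star)
      paired_idx <- which(in_star)
      max_asym <- 0L
      if (length(paired_idx) >= 2) {
        for (k in seq_len(length(paired_idx) - 1)) {
          i <- paired_idx[k]; j <- paired_idx[k + 1]
          gap_m <- j - i - 1L
          gap_s <- abs(dp[i] - dp[j]) - 1L
          max_asym <- max(max_asym, abs(gap_m - gap_s))
        }
      }
      flags["duplex"] <- n_mismatch <= max_duplex_mismatch &&
        max_asym <= max_bulge
    }
  }

  out <- list(flags = flags, pass = all(flags),
              mature_arm = mature_arm,
              star_start = star_start, star_end = star_end,
              energy = fold$energy, structure = fold$structure,
              window_seq = window_seq,
              mature_start = mature_start, mature_end = mature_end,
              supporting_reads = supporting_reads)
  class(out) <- "hairpin_candidate"
  out
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat(sprintf("<hairpin_candidate> %s (energy %.1f, reads %d)\n",
              if (x$pass) "PASS" else "fail", x$energy, x$supporting_reads))
  cat("  flags:", paste(names(x$flags)[!x$flags], collapse = ", "),
      if (all(x$flags)) "(all true)" else "(false)", "\n")
  invisible(x)
}

#' Count per-library miRNA expression with the end-tolerant matching rule
#'
#' A tag contributes to a mature miRNA's count iff, when placed at its
#' aligned offset relative to the mature, it matches the mature exactly over
#' the core (mature positions 4..L-3) and accumulates at most
#' `max_end_mismatch` mismatching or overhanging nt across the two terminal
#' 3-nt windows combined (overhang = tag bases extending beyond the mature,
#' or mature terminal bases the tag leaves uncovered). Each tag contributes
#' to at most one mature.
#'
#' @param mature mature sequence (character scalar).
#' @param tags tibble with `sequence`, `count_c`, `count_t` and an `offset`
#'   column (tag start minus mature start, in mature coordinates; 0 =
#'   5'-aligned). If `offset` is missing, offsets -3..3 are tried and the
#'   best (fewest end mismatches) is used.
#' @param max_end_mismatch combined terminal budget (default 3).
#' @return list with `count_c`, `count_t` (integers) and `contributing`
#'   (the subset of `tags` that contributed).
#' @export
count_mirna_expression <- function(mature, tags, max_end_mismatch = 3L) {
  mature <- as_dna(mature)
  L <- nchar(mature)
  if (nrow(tags) == 0)
    return(list(count_c = 0L, count_t = 0L, contributing = tags))
  eval_offset <- function(tag, off) {
    lt <- nchar(tag)
    # tag position p (1-based) sits at mature position p + off
    m_covered_lo <- 1L + off
    m_covered_hi <- lt + off
    core <- 4:(L - 3)
    if (any(core < m_covered_lo) || any(core > m_covered_hi)) return(NA_integer_)
    core_tag <- substr(tag, core[1] - off, core[length(core)] - off)
    core_mat <- substr(mature, core[1], core[length(core)])
    if (core_tag != core_mat) return(NA_integer_)
    bad <- 0L
    # terminal windows of the mature: 1..3 and L-2..L
    for (m in c(1:3, (L - 2):L)) {
      p <- m - off
      if (p < 1 || p > lt) bad <- bad + 1L            # uncovered mature base
      else if (substr(tag, p, p) != substr(mature, m, m)) bad <- bad + 1L
    }
    # tag bases overhanging the mature on either end
    bad <- bad + max(0L, 1L - m_covered_lo) + max(0L, m_covered_hi - L)
    bad
  }
  has_offset <- "offset" %in% names(tags)
  contrib <- logical(nrow(tags))
  for (i in seq_len(nrow(tags))) {
    tag <- as_dna(tags$sequence[i])
    offs <- if (has_offset) tags$offset[i] else -3:3
    bads <- vapply(offs, function(o) eval_offset(tag, o), integer(1))
    contrib[i] <- any(!is.na(bads) & bads <= max_end_mismatch)
  }
  list(count_c = as.integer(sum(tags$count_c[contrib])),
       count_t = as.integer(sum(tags$count_t[contrib])),
       contributing = tags[contrib, , drop = FALSE])
}

#' Discover novel miRNA candidates from un-annotated tags
#'
#' Drives the full discovery path: cluster mapped un-annotated tags, extract
#' candidate precursor windows, fold each window with the reference backend,
#' evaluate the six hairpin qualifications with the cluster's most abundant
#' tag as the putative mature, and keep, per cluster, the best candidate
#' (passing preferred, then lowest energy). Mature-read support uses the
#' end-tolerant counting rule of [count_mirna_expression()].
#'
#' @param classified output of [classify_tags()].
#' @param genome genome (named character / `DNAStringSet` / FASTA path).
#' @param flank,cluster_gap window parameters (see
#'   [extract_precursor_windows()]).
#' @param max_energy,min_reads,max_duplex_mismatch,max_bulge qualification
#'   thresholds (see [evaluate_hairpin()]).
#' @param prefilter skip folding clusters whose total read support is below
#'   `min_reads` (they cannot pass qualification 6; the reported candidate
#'   set is unchanged).
#' @param exclude optional tibble of genomic regions (`chrom`, `start`,
#'   `end`) around known miRNA loci; un-annotated tags aligning within
#'   `exclude_flank` nt of these are not used to seed novel candidates
#'   (matches the cascade's screening of reads against known precursors, so
#'   a known locus' star arm is not re-reported as novel).
#' @param exclude_flank widening of the excluded regions in nt.
#' @param backend folding backend passed to [fold_rna()].
#' @return tibble with one row per evaluated cluster: `cluster_id`, `chrom`,
#'   `strand`, `precursor_start`, `precursor_end`, `mature_seq`,
#'   `mature_arm`, `star_seq`, `energy`, `structure`, `count_c`, `count_t`,
#'   `supporting_reads`, the six flag columns, and `pass`.
#' @export
discover_mirna <- function(classified, genome, flank = 150L, cluster_gap = 10L,
                           max_energy = -18, min_reads = 5L,
                           max_duplex_mismatch = 4L, max_bulge = 2L,
                           prefilter = TRUE,
                           exclude = NULL, exclude_flank = 60L,
                           backend = "reference") {
  genome <- load_genome(genome)
  una <- classified |>
    filter(.data$category == "un_annotated", .data$mapped)
  if (!is.null(exclude) && nrow(exclude) > 0 && nrow(una) > 0) {
    drop <- rep(FALSE, nrow(una))
    for (k in seq_len(nrow(exclude))) {
      drop <- drop | (una$chrom == exclude$chrom[k] &
                        una$start <= exclude$end[k] + exclude_flank &
                        una$end >= exclude$start[k] - exclude_flank)
    }
    una <- una[!drop, , drop = FALSE]
  }
  empty <- tibble(cluster_id = character(0), chrom = character(0),
                  strand = character(0), precursor_start = integer(0),
                  precursor_end = integer(0), mature_seq = character(0),
                  mature_arm = character(0), star_seq = character(0),
                  energy = numeric(0), structure = character(0),
                  count_c = integer(0), count_t = integer(0),
                  supporting_reads = integer(0),
                  unannotated = logical(0), one_arm = logical(0),
                  overhang = logical(0), duplex = logical(0),
                  energy_ok = logical(0), reads_ok = logical(0),
                  pass = logical(0))
  if (nrow(una) == 0) return(empty)
  wins <- extract_precursor_windows(
    una |> select("sequence", "chrom", "start", "end", "strand"),
    genome, flank = flank, cluster_gap = cluster_gap)
  if (nrow(wins) == 0) return(empty)

  rows <- list()
  for (cid in unique(wins$cluster_id)) {
    w <- wins |> filter(.data$cluster_id == cid)
    cl_tags <- una |>
      filter(.data$chrom == w$chrom[1], .data$strand == w$strand[1],
             .data$start <= w$cluster_end[1] + cluster_gap,
             .data$end >= w$cluster_start[1] - cluster_gap)
    if (nrow(cl_tags) == 0) next
    total_support <- sum(cl_tags$count_c + cl_tags$count_t)
    if (prefilter && total_support < min_reads) next
    dom <- cl_tags |>
      arrange(dplyr::desc(.data$count_c + .data$count_t), .data$sequence) |>
      slice(1)
    # mature support under the end-tolerant counting rule, offsets from the
    # genomic alignment relative to the dominant tag
    minus <- w$strand[1] == "-"
    off <- if (minus) dom$end - cl_tags$end else cl_tags$start - dom$start
    support <- count_mirna_expression(
      dom$sequence, cl_tags |> mutate(offset = off))
    supporting <- support$count_c + support$count_t

    best <- NULL
    for (k in seq_len(nrow(w))) {
      wseq <- w$window_seq[k]
      nW <- nchar(wseq)
      if (nW < 40) next
      if (minus) {
        m_start <- w$window_end[k] - dom$end + 1L
      } else {
        m_start <- dom$start - w$window_start[k] + 1L
      }
      m_end <- m_start + nchar(dom$sequence) - 1L
      if (m_start < 1 || m_end > nW) next
      fold <- fold_rna(wseq, backend = backend)
      cand <- evaluate_hairpin(wseq, fold, m_start, m_end,
                               supporting_reads = supporting,
                               unannotated = TRUE,
                               max_energy = max_energy, min_reads = min_reads,
                               max_duplex_mismatch = max_duplex_mismatch,
                               max_bulge = max_bulge)
      cand$window_row <- k
      if (is.null(best) || (cand$pass && !best$pass) ||
          (cand$pass == best$pass && cand$energy < best$energy))
        best <- cand
      if (cand$pass) break
    }
    if (is.null(best)) next
    k <- best$window_row
    star_seq <- if (!is.na(best$star_start))
      substr(best$window_seq, best$star_start, best$star_end) else NA_character_
    rows[[length(rows) + 1]] <- tibble(
      cluster_id = cid, chrom = w$chrom[1], strand = w$strand[1],
      precursor_start = w$window_start[k], precursor_end = w$window_end[k],
      mature_seq = dom$sequence, mature_arm = best$mature_arm,
      star_seq = star_seq, energy = best$energy, structure = best$structure,
      count_c = support$count_c, count_t = support$count_t,
      supporting_reads = supporting,
      unannotated = unname(best$flags["unannotated"]),
      one_arm = unname(best$flags["one_arm"]),
      overhang = unname(best$flags["overhang"]),
      duplex = unname(best$flags["duplex"]),
      energy_ok = unname(best$flags["energy"]),
      reads_ok = unname(best$flags["reads"]),
      pass = best$pass)
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows)
}
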