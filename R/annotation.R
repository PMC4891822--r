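#' Read a GFF3 feature file into a tidy feature table
#'
#' Uses `rtracklayer` when available, with a base fallback parser for the
#' plain single-source GFF3 the simulator writes. Coordinates are kept in the
#' GFF3/Bioconductor convention (1-based, closed).
#'
#' @param path GFF3 file with feature types among `rRNA`, `tRNA`, `snRNA`,
#'   `snoRNA`, `repeat_region`, `exon`, `intron`.
#' @return tibble with columns `chrom`, `start`, `end`, `strand`, `type`,
#'   `feature_id`.
#' @export
read_features <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    id <- if (!is.null(gr$ID)) gr$ID else sprintf("feature_%d", seq_along(gr))
    return(tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  type = as.character(gr$type),
                  feature_id = id))
  }
  x <- readr::read_tsv(path, comment = "#",
                       col_names = c("chrom", "source", "type", "start", "end",
                                     "score", "strand", "phase", "attributes"),
                       col_types = "cccddcccc", progress = FALSE)
  x |>
    mutate(feature_id = sub("^.*ID=([^;]+).*$", "\\1", .data$attributes)) |>
    select("chrom", "start", "end", "strand", "type", "feature_id") |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

features_to_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand,
    type = features$type, feature_id = features$feature_id)
}

#' Map tags to a genome (substitution-only, both strands)
#'
#' Reports all alignments with at most `max_mismatch` substitutions (no
#' indels) on either strand. Exact matching uses a `Biostrings` PDict per tag
#' width; the mismatch path scans per tag with [Biostrings::matchPattern()].
#' Coordinates are 1-based closed; a minus-strand alignment means the
#' reverse complement of the tag matches the plus-strand genome there.
#'
#' @param tags tibble with a `sequence` column (e.g. from [collapse_tags()]),
#'   or a character vector.
#' @param genome named character vector of chromosome sequences, or a
#'   `DNAStringSet`, or a FASTA path.
#' @param max_mismatch 0, 1 or 2 substitutions.
#' @return tibble with columns `sequence`, `chrom`, `start`, `end`, `strand`,
#'   `mismatches`; tags without any alignment are absent (see
#'   [classify_tags()] for the un-annotated fallback).
#' @export
map_tags <- function(tags, genome, max_mismatch = 0L) {
  stopifnot(max_mismatch %in% 0:2)
  if (is.character(tags)) tags <- tibble(sequence = tags)
  genome <- load_genome(genome)
  if (sum(nchar(genome)) == 0) abort("empty genome")
  seqs <- unique(as_dna(tags$sequence))
  empty <- tibble(sequence = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  mismatches = integer(0))
  if (length(seqs) == 0) return(empty)
  subj <- Biostrings::DNAStringSet(genome)

  one_strand <- function(query_seqs, strand) {
    q <- if (strand == "+") query_seqs else revcomp(query_seqs)
    res <- list()
    if (max_mismatch == 0) {
      for (w in unique(nchar(q))) {
        idx <- which(nchar(q) == w)
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(q[idx]))
        for (ci in seq_along(subj)) {
          m <- Biostrings::matchPDict(pd, subj[[ci]])
          starts <- IRanges::start(m)
          nh <- lengths(starts)
          if (sum(nh) == 0) next
          res[[length(res) + 1]] <- tibble(
            sequence = rep(query_seqs[idx], nh),
            chrom = names(genome)[ci],
            start = unlist(starts, use.names = FALSE),
            end = unlist(starts, use.names = FALSE) + w - 1L,
            strand = strand, mismatches = 0L)
        }
      }
    } else {
      for (i in seq_along(q)) {
        for (ci in seq_along(subj)) {
          m <- Biostrings::matchPattern(q[i], subj[[ci]],
                                        max.mismatch = max_mismatch,
                                        with.indels = FALSE, fixed = TRUE)
          if (length(m) == 0) next
          mm <- vapply(seq_along(m), function(k)
            hamming(as.character(m[[k]]), q[i]), integer(1))
          res[[length(res) + 1]] <- tibble(
            sequence = query_seqs[i], chrom = names(genome)[ci],
            start = IRanges::start(m), end = IRanges::end(m),
            strand = strand, mismatches = mm)
        }
      }
    }
    bind_rows(res)
  }

  out <- bind_rows(one_strand(seqs, "+"), one_strand(seqs, "-"))
  if (nrow(out) == 0) return(empty)
  out |> arrange(.data$sequence, .data$chrom, .data$start, .data$strand)
}

load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    return(setNames(as.character(genome), names(genome)))
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome)) &&
      file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    names(x) <- sub("\\s.*$", "", names(x))
    return(setNames(as.character(x), names(x)))
  }
  if (is.null(names(genome))) names(genome) <- sprintf("chr%d", seq_along(genome))
  as_dna(genome)
}

# category precedence for the mutually exclusive Table-1 accounting
CATEGORY_LEVELS <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "repeat",
                     "exon_sense", "exon_antisense",
                     "intron_sense", "intron_antisense", "un_annotated")
CATEGORY_RANK <- setNames(seq_along(CATEGORY_LEVELS), CATEGORY_LEVELS)

feature_category <- function(type, feat_strand, aln_strand) {
  base <- dplyr::case_when(
    type == "repeat_region" ~ "repeat",
    type %in% c("exon", "intron") ~
      paste0(type, ifelse(feat_strand == aln_strand, "_sense", "_antisense")),
    TRUE ~ type)
  base
}

#' Classify every tag into one annotation category
#'
#' Assigns exactly one category per tag by precedence:
#' known miRNA > rRNA > tRNA > snRNA > snoRNA > repeat > exon > intron >
#' un-annotated; exon/intron are split into sense/antisense by strand
#' agreement between the alignment and the feature. Multimapping tags are
#' classified once from their best alignment (fewest mismatches, ties broken
#' by category precedence, then longest feature overlap, then lexicographic
#' feature id); read counts are not split, so categories partition the
#' library exactly. Unmapped tags fall through to `un_annotated`.
#'
#' @param tags tibble from [collapse_tags()] (`sequence`, `count_c`, `count_t`).
#' @param alignments tibble from [map_tags()].
#' @param features tibble from [read_features()] (or the simulator).
#' @param known_mirna sequences assigned to known mature miRNAs (character
#'   vector, e.g. `match_known()$matched$sequence`).
#' @return the `tags` tibble with added columns `category` (factor over all
#'   eleven categories), `mapped` (logical), and for mapped tags the best
#'   alignment's `chrom`, `start`, `end`, `strand`.
#' @export
classify_tags <- function(tags, alignments, features,
                          known_mirna = character(0)) {
  aln <- alignments
  out <- tags |> mutate(sequence = as_dna(.data$sequence))
  # feature category per alignment via interval overlap
  if (nrow(aln) > 0 && nrow(features) > 0) {
    agr <- GenomicRanges::GRanges(aln$chrom, IRanges::IRanges(aln$start, aln$end),
                                  strand = aln$strand)
    fgr <- features_to_granges(features)
    ov <- GenomicRanges::findOverlaps(agr, fgr, ignore.strand = TRUE)
    ovl <- tibble(
      aln_idx = S4Vectors::queryHits(ov),
      category = feature_category(features$type[S4Vectors::subjectHits(ov)],
                                  features$strand[S4Vectors::subjectHits(ov)],
                                  aln$strand[S4Vectors::queryHits(ov)]),
      overlap_width = IRanges::width(IRanges::pintersect(
        IRanges::IRanges(aln$start, aln$end)[S4Vectors::queryHits(ov)],
        IRanges::IRanges(features$start, features$end)[S4Vectors::subjectHits(ov)])),
      feature_id = features$feature_id[S4Vectors::subjectHits(ov)])
  } else {
    ovl <- tibble(aln_idx = integer(0), category = character(0),
                  overlap_width = integer(0), feature_id = character(0))
  }
  aln_tab <- aln |>
    mutate(aln_idx = row_number()) |>
    left_join(ovl, by = "aln_idx") |>
    mutate(category = ifelse(is.na(.data$category), "un_annotated", .data$category),
           overlap_width = ifelse(is.na(.data$overlap_width), 0L, .data$overlap_width),
           feature_id = ifelse(is.na(.data$feature_id), "zzz_none", .data$feature_id),
           rank = CATEGORY_RANK[.data$category]) |>
    arrange(.data$sequence, .data$mismatches, .data$rank,
            dplyr::desc(.data$overlap_width), .data$feature_id) |>
    group_by(.data$sequence) |>
    slice(1) |>
    ungroup() |>
    select("sequence", "chrom", "start", "end", "strand",
           best_category = "category")
  out <- out |>
    left_join(aln_tab, by = "sequence") |>
    mutate(mapped = !is.na(.data$best_category),
           category = dplyr::case_when(
             .data$sequence %in% as_dna(known_mirna) ~ "miRNA",
             !.data$mapped ~ "un_annotated",
             TRUE ~ .data$best_category)) |>
    select(-"best_category") |>
    mutate(category = factor(.data$category, levels = CATEGORY_LEVELS))
  out
}

#' Per-category unique/total accounting for both libraries
#'
#' Emits, for every annotation category, the unique tag count, total read
#' count, and each as a percentage of the library total (two decimals,
#' round-half-even), per library. Categories with no tags are reported as
#' zero, and percentages are exact shares of the library total, so category
#' totals sum to the library total.
#'
#' @param classified tibble from [classify_tags()].
#' @return tibble with columns `category`, `unique_c`, `unique_pct_c`,
#'   `total_c`, `total_pct_c`, `unique_t`, `unique_pct_t`, `total_t`,
#'   `total_pct_t`.
#' @export
summarize_categories <- function(classified) {
  tot_u_c <- sum(classified$count_c > 0)
  tot_u_t <- sum(classified$count_t > 0)
  tot_r_c <- sum(classified$count_c)
  tot_r_t <- sum(classified$count_t)
  if (tot_r_c == 0 || tot_r_t == 0) abort("zero-total library")
  classified |>
    group_by(category = factor(.data$category, levels = CATEGORY_LEVELS)) |>
    summarise(unique_c = sum(.data$count_c > 0),
              total_c = sum(.data$count_c),
              unique_t = sum(.data$count_t > 0),
              total_t = sum(.data$count_t), .groups = "drop") |>
    tidyr::complete(category,
                    fill = list(unique_c = 0L, total_c = 0L,
                                unique_t = 0L, total_t = 0L)) |>
    mutate(unique_pct_c = pct2(.data$unique_c, tot_u_c),
           total_pct_c = pct2(.data$total_c, tot_r_c),
           unique_pct_t = pct2(.data$unique_t, tot_u_t),
           total_pct_t = pct2(.data$total_t, tot_r_t)) |>
    select("category", "unique_c", "unique_pct_c", "total_c", "total_pct_c",
           "unique_t", "unique_pct_t", "total_t", "total_pct_t")
}

#' Tag length histogram per library
#'
#' Unique and total counts (with percentages) per insert length over the
#' full `[min_len, max_len]` window; empty bins are reported as zero rather
#' than omitted.
#'
#' @param tags tibble with `sequence`, `count_c`, `count_t`.
#' @param min_len,max_len histogram support (defaults 15-30 nt).
#' @return tibble with `length`, `unique_c`, `total_c`, `total_pct_c`,
#'   `unique_t`, `total_t`, `total_pct_t`.
#' @export
length_distribution <- function(tags, min_len = 15L, max_len = 30L) {
  if (nrow(tags) == 0) abort("no tags")
  tot_c <- sum(tags$count_c); tot_t <- sum(tags$count_t)
  tags |>
    mutate(length = nchar(.data$sequence)) |>
    group_by(.data$length) |>
    summarise(unique_c = sum(.data$count_c > 0), total_c = sum(.data$count_c),
              unique_t = sum(.data$count_t > 0), total_t = sum(.data$count_t),
              .groups = "drop") |>
    tidyr::complete(length = min_len:max_len,
                    fill = list(unique_c = 0L, total_c = 0L,
                                unique_t = 0L, total_t = 0L)) |>
    filter(.data$length >= min_len, .data$length <= max_len) |>
    mutate(total_pct_c = pct2(.data$total_c, max(tot_c, 1)),
           total_pct_t = pct2(.data$total_t, max(tot_t, 1)))
}
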