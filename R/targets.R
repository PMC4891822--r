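#' Score a miRNA/target-site duplex (plant scoring scheme)
#'
#' Ungapped, antiparallel complementarity scoring in the plant miRNA target
#' convention: per miRNA position (5'->3') a mismatch costs 1.0, a G:U
#' wobble 0.5 and a Watson-Crick match 0; penalties at core positions
#' `core[1]`..`core[2]` (default 2-13, 1-based from the miRNA 5' end) are
#' doubled. miRNA position i faces site position `L - i + 1` of the site as
#' written on the transcript.
#'
#' @param mirna miRNA sequence (5'->3', RNA or DNA alphabet).
#' @param site target site as it appears on the transcript (5'->3', same
#'   length as the miRNA).
#' @param core doubled-penalty positions, inclusive bounds.
#' @return list with `score` (total penalty) and `alignment` (one symbol per
#'   miRNA position: `|` match, `o` G:U wobble, `x` mismatch).
#' @export
score_duplex <- function(mirna, site, core = c(2L, 13L)) {
  mirna <- as_dna(mirna); site <- as_dna(site)
  L <- nchar(mirna)
  if (nchar(site) != L) abort("site length must equal miRNA length")
  m <- strsplit(mirna, "")[[1]]
  t <- rev(strsplit(site, "")[[1]])  # antiparallel
  wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
        (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
  pen <- ifelse(wc, 0, ifelse(gu, 0.5, 1))
  idx <- seq_len(L)
  dbl <- idx >= core[1] & idx <= core[2]
  score <- sum(pen * ifelse(dbl, 2, 1))
  alignment <- paste(ifelse(wc, "|", ifelse(gu, "o", "x")), collapse = "")
  list(score = score, alignment = alignment)
}

#' Predict miRNA target sites over a transcript set
#'
#' Slides the miRNA across every window of every transcript, scores each
#' window with [score_duplex()], and keeps hits with penalty at most
#' `cutoff` (default 4), sorted by score, transcript id, then position.
#' Coordinates are 1-based closed on the transcript.
#'
#' @param mirna named character vector of miRNA sequences (names are ids),
#'   or a tibble with `name`, `sequence`.
#' @param transcripts named character vector of transcript sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param cutoff maximum penalty score retained.
#' @param core doubled-penalty miRNA positions.
#' @return tibble with columns `mirna`, `transcript`, `start`, `end`,
#'   `score`, `alignment`.
#' @export
predict_targets <- function(mirna, transcripts, cutoff = 4.0,
                            core = c(2L, 13L)) {
  if (is.data.frame(mirna)) mirna <- setNames(mirna$sequence, mirna$name)
  if (is.null(names(mirna)))
    names(mirna) <- sprintf("mirna_%d", seq_along(mirna))
  mirna <- vapply(mirna, as_dna, character(1))
  transcripts <- load_genome(transcripts)
  empty <- tibble(mirna = character(0), transcript = character(0),
                  start = integer(0), end = integer(0), score = numeric(0),
                  alignment = character(0))
  if (length(transcripts) == 0) return(empty)
  rows <- list()
  for (mi in seq_along(mirna)) {
    L <- nchar(mirna[[mi]])
    for (ti in seq_along(transcripts)) {
      hit <- scan_target_cpp(mirna[[mi]], transcripts[[ti]],
                             core[1], core[2], cutoff)
      if (length(hit$start) == 0) next
      aln <- vapply(hit$start, function(s)
        score_duplex(mirna[[mi]],
                     substr(transcripts[[ti]], s, s + L - 1), core)$alignment,
        character(1))
      rows[[length(rows) + 1]] <- tibble(
        mirna = names(mirna)[mi], transcript = names(transcripts)[ti],
        start = hit$start, end = hit$start + L - 1L,
        score = hit$score, alignment = aln)
    }
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows) |> arrange(.data$score, .data$transcript, .data$start)
}

#' Collapse target hits to distinct gene counts per miRNA
#'
#' @param hits tibble from [predict_targets()].
#' @param gene_map tibble with `transcript`, `gene`. Transcripts missing
#'   from the map raise a warning and count as their own gene.
#' @return tibble with `mirna`, `n_genes` (distinct genes hit).
#' @export
summarize_targets_per_mirna <- function(hits, gene_map) {
  if (nrow(hits) == 0) return(tibble(mirna = character(0), n_genes = integer(0)))
  joined <- hits |> left_join(gene_map, by = "transcript")
  miss <- is.na(joined$gene)
  if (any(miss)) {
    warn(sprintf("%d hit(s) on transcripts absent from the gene map; counted as their own gene",
                 sum(miss)))
    joined$gene[miss] <- joined$transcript[miss]
  }
  joined |>
    group_by(.data$mirna) |>
    summarise(n_genes = dplyr::n_distinct(.data$gene), .groups = "drop")
}
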