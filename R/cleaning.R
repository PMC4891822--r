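#' Read-cleaning policy
#'
#' Controls 3' adapter trimming and insert filtering. Defaults follow the
#' standard plant sRNA-seq protocol the package models: clean inserts of
#' 15-30 nt, polyA artifacts discarded, adapter located by seed-and-extend
#' (first `seed_len` adapter bases, at most 1 mismatch in the seed, at most
#' `max_adapter_mismatch` over the full matched prefix).
#'
#' @param adapter3 3' adapter (RNA or DNA alphabet).
#' @param adapter5 optional 5' adapter; when non-empty, reads still carrying
#'   its 3' end as a prefix are rejected as adapter dimers.
#' @param min_len,max_len accepted insert length window (defaults 15 / 30 nt).
#' @param max_adapter_mismatch mismatches tolerated across the matched
#'   adapter prefix.
#' @param discard_polyA reject inserts that are >= 80 % adenosine.
#' @param seed_len adapter seed length for matching.
#' @return a `clean_read_policy` object.
#' @export
clean_read_policy <- function(adapter3 = "UGGAAUUCUCGGGUGCCAAGG",
                              adapter5 = "GUUCAGAGUUCUACAGUCCGACGAUC",
                              min_len = 15L, max_len = 30L,
                              max_adapter_mismatch = 2L,
                              discard_polyA = TRUE,
                              seed_len = 8L) {
  stopifnot(min_len <= max_len, nchar(adapter3) >= seed_len)
  out <- list(adapter3 = as_dna(adapter3), adapter5 = as_dna(adapter5),
              min_len = as.integer(min_len), max_len = as.integer(max_len),
              max_adapter_mismatch = as.integer(max_adapter_mismatch),
              discard_polyA = isTRUE(discard_polyA),
              seed_len = as.integer(seed_len))
  class(out) <- "clean_read_policy"
  out
}

#' Read a FASTQ file into a tibble
#'
#' Thin tidy wrapper over [Biostrings::readDNAStringSet()]; qualities are
#' ignored (the pipeline does no quality-based trimming). Malformed records
#' raise an error naming the offending record index.
#'
#' @param path FASTQ file (Phred+33).
#' @return tibble with columns `id`, `sequence`.
#' @export
read_fastq_tbl <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      # locate the first structurally broken record for the error message
      lines <- readLines(path, warn = FALSE)
      idx <- which(!startsWith(lines[seq(1, length(lines), by = 4)], "@"))
      rec <- if (length(idx)) idx[1] else (length(lines) %/% 4) + 1
      abort(sprintf("malformed FASTQ record %d in %s: %s",
                    rec, path, conditionMessage(e)))
    })
  tibble(id = names(x), sequence = unname(as.character(x)))
}

#' Trim 3' adapters and filter small RNA reads
#'
#' Removes the 3' adapter at its leftmost seed-and-extend match and filters
#' the resulting inserts. A read is rejected (with the class recorded in the
#' tally) when: no 3' adapter is detectable (`no_adapter`), the insert
#' contains an ambiguous base (`has_n`), it is shorter than `min_len`
#' (`too_short`) or longer than `max_len` (`too_long`), or it is >= 80 %
#' A after trimming (`polya`). Rejection classes are tested in that order.
#'
#' @param reads a tibble with columns `id`, `sequence` (see
#'   [read_fastq_tbl()]), a character vector of read sequences, or a path to
#'   a FASTQ file.
#' @param policy a [clean_read_policy()].
#' @return list with `inserts` (tibble: id, sequence) and `tally` (tibble:
#'   class, n — classes `accepted`, `no_adapter`, `has_n`, `too_short`,
#'   `too_long`, `polya`; conservation: sum(n) = number of input reads).
#' @export
trim_and_filter <- function(reads, policy = clean_read_policy()) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq_tbl(reads)
  if (is.character(reads))
    reads <- tibble(id = sprintf("read_%d", seq_along(reads)), sequence = reads)
  seqs <- as_dna(reads$sequence)
  n <- length(seqs)

  trim_pos <- trim_adapter_cpp(seqs, policy$adapter3, policy$seed_len,
                               1L, policy$max_adapter_mismatch)

  insert <- ifelse(is.na(trim_pos), NA_character_,
                   substr(seqs, 1, pmax(0L, trim_pos - 1L)))
  klass <- rep("accepted", n)
  klass[is.na(trim_pos)] <- "no_adapter"
  ok <- klass == "accepted"
  klass[ok & grepl("N", insert, fixed = TRUE)] <- "has_n"
  ok <- klass == "accepted"
  klass[ok & nchar(insert) < policy$min_len] <- "too_short"
  ok <- klass == "accepted"
  klass[ok & nchar(insert) > policy$max_len] <- "too_long"
  if (policy$discard_polyA) {
    ok <- klass == "accepted"
    frac_a <- vapply(strsplit(insert[ok], ""), function(ch) mean(ch == "A"),
                     numeric(1))
    idx <- which(ok)[frac_a >= 0.8]
    klass[idx] <- "polya"
  }

  classes <- c("accepted", "no_adapter", "has_n", "too_short", "too_long", "polya")
  tally <- tibble(class = classes,
                  n = unname(vapply(classes, function(k) sum(klass == k),
                                    integer(1))))
  list(inserts = tibble(id = reads$id[klass == "accepted"],
                        sequence = insert[klass == "accepted"]),
       tally = tally)
}

#' Collapse clean inserts into unique tags with per-library counts
#'
#' @param control character vector (or tibble with `sequence`) of clean
#'   control-library inserts.
#' @param treatment same for the treatment library (optional).
#' @return tibble with columns `sequence`, `count_c`, `count_t`, ordered by
#'   decreasing total count then sequence. `sum(count_c)` equals the number
#'   of control inserts (likewise treatment).
#' @export
collapse_tags <- function(control, treatment = character(0)) {
  getseq <- function(x) if (is.data.frame(x)) x$sequence else x
  c_seq <- as_dna(getseq(control))
  t_seq <- as_dna(getseq(treatment))
  tc <- table(c_seq)
  tt <- table(t_seq)
  all_seq <- union(names(tc), names(tt))
  out <- tibble(sequence = all_seq,
                count_c = as.integer(ifelse(all_seq %in% names(tc),
                                            tc[all_seq], 0L)),
                count_t = as.integer(ifelse(all_seq %in% names(tt),
                                            tt[all_seq], 0L)))
  out |> arrange(dplyr::desc(.data$count_c + .data$count_t), .data$sequence)
}

#' Write collapsed tags as FASTA with `tag{serial}_x{count}` headers
#'
#' @param tags tibble from [collapse_tags()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_tag_fasta <- function(tags, path) {
  total <- tags$count_c + tags$count_t
  nm <- sprintf("tag%d_x%d", seq_len(nrow(tags)), total)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(tags$sequence, nm)), path)
  invisible(path)
}
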