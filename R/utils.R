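#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib mirtap, .registration = TRUE
#' @importFrom rlang .data abort warn hash
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols count n rename distinct row_number across
#'   first if_else pull slice
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rpois rbinom runif rnorm setNames
#' @importFrom methods is
NULL

# internal DNA alphabet: everything is stored with T (U -> T at ingest)
DNA_BASES <- c("A", "C", "G", "T")

#' Normalize a sequence to the internal DNA alphabet
#'
#' Uppercases and converts U to T. All sequence comparisons in the package
#' happen in this alphabet.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector in `ACGTN` alphabet.
#' @export
as_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement in the internal DNA alphabet
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len[min(i, length(len))], replace = TRUE),
          collapse = "")
  }, character(1))
}

# Hamming distance between two equal-length sequences (exact, small inputs)
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: returns a random sequence with exactly the same
#' dinucleotide (and therefore mononucleotide) composition as the input.
#' Used to build negative controls for hairpin qualification: a shuffle keeps
#' base composition and local correlation but destroys the stem-loop.
#'
#' @param x a single sequence (character scalar).
#' @return a shuffled sequence of the same length.
#' @export
shuffle_dinucleotide <- function(x) {
  s <- strsplit(as_dna(x), "")[[1]]
  n <- length(s)
  if (n <= 2) return(paste(s, collapse = ""))
  letters_used <- unique(s)
  # edge multiset: s[i] -> s[i+1]
  edges <- split(s[-1], factor(s[-n], levels = letters_used))
  last <- s[n]
  # pick, for every vertex except the final one, a random "last edge" such
  # that the chosen edges form paths into the final vertex (Euler condition)
  repeat {
    last_edge <- vapply(letters_used, function(v) {
      if (v == last || length(edges[[v]]) == 0) NA_character_
      else sample(edges[[v]], 1)
    }, character(1))
    ok <- TRUE
    for (v in letters_used) {
      if (v == last || is.na(last_edge[[v]])) next
      cur <- v; seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute the remaining edges and append the reserved last edge
  ordered <- lapply(letters_used, function(v) {
    e <- edges[[v]]
    if (!is.na(last_edge[[v]]) && v != last) {
      drop_at <- match(last_edge[[v]], e)
      e <- e[-drop_at]
    }
    e <- if (length(e) > 1) sample(e) else e
    if (v != last && !is.na(last_edge[[v]])) e <- c(e, last_edge[[v]])
    e
  })
  names(ordered) <- letters_used
  ptr <- setNames(rep(1L, length(letters_used)), letters_used)
  out <- character(n)
  out[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

# round-half-even percentage to two decimals
pct2 <- function(x, total) round(100 * x / total, 2)
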