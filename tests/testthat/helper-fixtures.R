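# Shared fixtures and independent oracles. Oracles are deliberately written
# as direct, brute-force procedures that never call the implementation path
# they check.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a window with a designed hairpin in the middle of random flanks
flanked_hairpin <- function(mature = rand_dna(21), flank = 80) {
  hp <- design_hairpin(mature)
  left <- rand_dna(flank)
  right <- rand_dna(flank)
  list(window = paste0(left, hp$precursor, right),
       mature_start = flank + hp$mature_start,
       mature_end = flank + hp$mature_end,
       hp = hp)
}

# Brute-force substitution-only alignment scan: every position, both
# strands, positional integer comparison. Independent of Biostrings
# matching.
oracle_scan <- function(tag, genome_seq, max_mismatch) {
  g <- utf8ToInt(genome_seq)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") tag else revcomp(tag)
    t <- utf8ToInt(q)
    L <- length(t)
    n <- length(g)
    if (n < L) next
    mm <- integer(n - L + 1)
    for (j in seq_len(L)) {
      mm <- mm + (g[j:(n - L + j)] != t[j])
    }
    ok <- which(mm <= max_mismatch)
    if (length(ok))
      hits[[strand]] <- data.frame(start = ok, end = ok + L - 1,
                                   strand = strand, mismatches = mm[ok])
  }
  if (length(hits) == 0) return(NULL)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# Brute-force Hamming search over a mature database (equal lengths only)
oracle_hamming_match <- function(tag, db_seqs, max_mismatch) {
  best <- NA_integer_; best_mm <- max_mismatch + 1L
  for (d in seq_along(db_seqs)) {
    if (nchar(db_seqs[d]) != nchar(tag)) next
    mm <- sum(strsplit(tag, "")[[1]] != strsplit(db_seqs[d], "")[[1]])
    if (mm < best_mm) { best_mm <- mm; best <- d }
  }
  list(index = best, mismatches = if (is.na(best)) NA_integer_ else best_mm)
}

# Exhaustive target-site scoring: per-position penalty table restated from
# first principles (mismatch 1, G:U 0.5, core doubled), nested loops only.
oracle_target_scores <- function(mirna, transcript, core = c(2, 13)) {
  m <- strsplit(mirna, "")[[1]]
  tr <- strsplit(transcript, "")[[1]]
  L <- length(m)
  n <- length(tr)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- numeric(max(0, n - L + 1))
  for (s in seq_len(n - L + 1)) {
    total <- 0
    for (i in seq_len(L)) {
      t <- tr[s + L - i]
      pen <- if (comp[[m[i]]] == t) 0
      else if ((m[i] == "G" && t == "T") || (m[i] == "T" && t == "G")) 0.5
      else 1
      if (i >= core[1] && i <= core[2]) pen <- pen * 2
      total <- total + pen
    }
    out[s] <- total
  }
  out
}

# Direct nested-if restatement of the five-way classification rule
oracle_classify <- function(lfc, p, strong = 1, weak = 0.25, alpha = 0.05) {
  if (abs(lfc) >= strong && p < alpha) {
    if (lfc > 0) "significantly_up" else "significantly_down"
  } else if (abs(lfc) >= weak && abs(lfc) < strong) {
    if (lfc > 0) "slightly_up" else "slightly_down"
  } else "unobvious"
}

# small simulated experiment reused by several module tests
tiny_sim <- function(seed = 101, depth = 8000, ...) {
  simulate_srna_experiment(sim_config(
    seed = seed, genome_length = 6e4, n_known_mirna = 5, n_novel_mirna = 4,
    n_decoy_loci = 2, library_depths = c(depth, depth), ...))
}
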