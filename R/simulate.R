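#' Simulation configuration for a two-library small RNA experiment
#'
#' Defines the study conditions the generator emulates: a random-background
#' genome with planted structural RNA / repeat / exon / intron features, a set
#' of hairpin miRNA loci (known, novel and shuffled decoys), and two read
#' libraries (control and treatment) with condition-specific abundance shifts
#' spanning three regulation tiers. Defaults follow the experiment the package
#' models at desk scale: two libraries of 2e5 reads, insert length modes at
#' 21 and 24 nt (~22 % and ~45 % of reads), a strong 5'-uridine preference,
#' and the 3' sequencing adapter that must be trimmed from every read.
#'
#' @param seed integer RNG seed; identical configs give byte-identical output.
#' @param genome_length genome size in bases (single chromosome `chr1`).
#' @param n_known_mirna,n_novel_mirna,n_decoy_loci numbers of planted hairpin
#'   loci whose matures are in / absent from the known-mature database, and of
#'   dinucleotide-shuffled decoy loci that receive reads but are not hairpins.
#' @param library_depths integer vector `c(control, treatment)` of read depths.
#' @param length_mode_weights named numeric `c(len21=, len24=, other=)`
#'   probabilities of the background insert length classes; `other` is spread
#'   uniformly over the remaining 15-30 nt lengths.
#' @param five_prime_u_prob probability that a planted-locus mature or an
#'   intergenic background species starts with U.
#' @param de_effects optional tibble `(locus_id, true_log2fc)`; by default loci
#'   are split evenly into strong (`|lfc|` in 1-2.5), slight (0.3-0.9) and
#'   null (0) tiers.
#' @param adapter3 3' adapter sequence ligated to every insert (RNA or DNA
#'   alphabet; stored as DNA).
#' @param noise per-base substitution error probability.
#' @param noise_model `"poisson"` (default) or `"nb"` for negative-binomial
#'   locus counts with dispersion `nb_size` (NB as `rnbinom(mu=, size=)`).
#' @param nb_size NB size parameter when `noise_model = "nb"`.
#' @param base_abundance numeric range (log10) of expected control read counts
#'   per planted locus.
#' @param star_fraction fraction of a locus' reads drawn from the star arm.
#' @param isomir_fraction fraction of a locus' reads with a 1-nt 3' end shift.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 5e5,
                       n_known_mirna = 40L,
                       n_novel_mirna = 30L,
                       n_decoy_loci = 10L,
                       library_depths = c(2e5, 2e5),
                       length_mode_weights = c(len21 = 0.22, len24 = 0.45,
                                               other = 0.33),
                       five_prime_u_prob = 0.7,
                       de_effects = NULL,
                       adapter3 = "UGGAAUUCUCGGGUGCCAAGG",
                       noise = 0.001,
                       noise_model = c("poisson", "nb"),
                       nb_size = 20,
                       base_abundance = c(1.5, 2.5),
                       star_fraction = 0.05,
                       isomir_fraction = 0.10) {
  noise_model <- match.arg(noise_model)
  stopifnot(genome_length >= 1e4,
            all(library_depths > 0), length(library_depths) == 2,
            all(length_mode_weights >= 0), sum(length_mode_weights) > 0,
            five_prime_u_prob >= 0, five_prime_u_prob <= 1,
            noise >= 0, noise <= 1, nchar(adapter3) > 0)
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              n_known_mirna = as.integer(n_known_mirna),
              n_novel_mirna = as.integer(n_novel_mirna),
              n_decoy_loci = as.integer(n_decoy_loci),
              library_depths = as.integer(library_depths),
              length_mode_weights = length_mode_weights / sum(length_mode_weights),
              five_prime_u_prob = five_prime_u_prob,
              de_effects = de_effects,
              adapter3 = as_dna(adapter3),
              noise = noise,
              noise_model = noise_model,
              nb_size = nb_size,
              base_abundance = base_abundance,
              star_fraction = star_fraction,
              isomir_fraction = isomir_fraction)
  class(cfg) <- "sim_config"
  cfg
}

# sample n non-overlapping intervals of the given widths on [1, glen],
# avoiding `occupied` (IRanges); returns IRanges. Errors when space runs out.
place_intervals <- function(n, widths, glen, occupied, max_tries = 200L) {
  out_start <- integer(0); out_width <- integer(0)
  for (i in seq_len(n)) {
    w <- widths[min(i, length(widths))]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(glen - w + 1L, 1L)
      cand <- IRanges::IRanges(start = s, width = w)
      if (length(IRanges::findOverlaps(cand, occupied)) == 0) {
        occupied <- c(occupied, cand)
        out_start <- c(out_start, s); out_width <- c(out_width, w)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort("genome too short to place all requested features")
  }
  list(ranges = IRanges::IRanges(start = out_start, width = out_width),
       occupied = occupied)
}

#' Design a hairpin precursor around a mature sequence
#'
#' Builds a near-perfect stem-loop: the mature on the 5' arm, a star strand
#' derived from the reverse complement of the mature such that the
#' mature/star duplex has the canonical 2-nt 3' overhangs on both strands,
#' and a terminal loop of at least 4 nt between the arms.
#'
#' @param mature mature sequence, 20-24 nt (DNA or RNA alphabet).
#' @param loop_len terminal loop length (default 9).
#' @return list with `precursor`, `star`, and 1-based `mature_start`,
#'   `mature_end`, `star_start`, `star_end` within the precursor.
#' @export
design_hairpin <- function(mature, loop_len = 9L) {
  mature <- as_dna(mature)
  L <- nchar(mature)
  if (L < 20 || L > 24) abort("mature length must be 20-24 nt")
  if (loop_len < 4) abort("terminal loop must be >= 4 nt")
  # star core pairs mature[1..L-2]; 2 extra unpaired nt at the star 3' end
  star_core <- revcomp(substr(mature, 1, L - 2))
  star_tail <- paste(sample(DNA_BASES, 2, replace = TRUE), collapse = "")
  star <- paste0(star_core, star_tail)
  loop <- paste(sample(c("A", "C", "A", "A", "C"), loop_len, replace = TRUE),
                collapse = "")
  pre <- paste0(mature, loop, star)
  list(precursor = pre, star = star,
       mature_start = 1L, mature_end = L,
       star_start = L + loop_len + 1L,
       star_end = L + loop_len + nchar(star))
}

#' Simulate a complete two-library small RNA experiment
#'
#' Generates (deterministically, from `config$seed`) a background genome with
#' planted annotation features, hairpin miRNA loci with known ground truth,
#' and two FASTQ read libraries with adapter-ligated reads, then optionally
#' writes everything (FASTA genome, GFF3 features, FASTQ pair, known-mature
#' FASTA, truth TSV) to `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory for on-disk output.
#' @return list with `genome` (named character), `features` (tibble:
#'   chrom, start, end, strand, type, feature_id; 1-based closed), `truth`
#'   (tibble: locus_id, class, mature_seq, star_seq, chrom, strand, pre_start,
#'   pre_end, mature_start, mature_end, expected_count_c, expected_count_t,
#'   true_log2fc, tier), `known_db` (tibble: name, sequence), `reads` (list of
#'   two tibbles `control` / `treatment` with id, sequence), and `paths` when
#'   written.
#' @export
simulate_srna_experiment <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  glen <- config$genome_length
  genome_chars <- sample(DNA_BASES, glen, replace = TRUE)

  # ---- plant annotation features ------------------------------------------
  occupied <- IRanges::IRanges()
  feat <- list()
  # feature counts scale with genome size (reference plan at 500 kb) so the
  # planted annotation keeps roughly constant genome occupancy
  fscale <- max(0.12, glen / 5e5)
  spec_tab <- tibble(
    type  = c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat_region", "exon", "intron"),
    n     = pmax(2L, as.integer(round(fscale * c(3L, 12L, 4L, 4L, 15L, 25L, 25L)))),
    wmin  = c(1500L, 72L, 100L, 70L, 400L, 150L, 250L),
    wmax  = c(3500L, 90L, 200L, 140L, 1500L, 700L, 1200L))
  for (r in seq_len(nrow(spec_tab))) {
    widths <- sample(spec_tab$wmin[r]:spec_tab$wmax[r], spec_tab$n[r], replace = TRUE)
    pl <- place_intervals(spec_tab$n[r], widths, glen, occupied)
    occupied <- pl$occupied
    feat[[r]] <- tibble(
      chrom = "chr1",
      start = IRanges::start(pl$ranges), end = IRanges::end(pl$ranges),
      strand = sample(c("+", "-"), spec_tab$n[r], replace = TRUE),
      type = spec_tab$type[r],
      feature_id = sprintf("%s_%02d", tolower(spec_tab$type[r]), seq_len(spec_tab$n[r])))
  }
  features <- bind_rows(feat) |> arrange(.data$start)

  # ---- plant hairpin loci --------------------------------------------------
  n_mirna <- config$n_known_mirna + config$n_novel_mirna
  n_loci <- n_mirna + config$n_decoy_loci
  truth <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    cls <- if (i <= config$n_known_mirna) "known"
           else if (i <= n_mirna) "novel" else "decoy"
    L <- sample(20:24, 1, prob = c(0.1, 0.5, 0.15, 0.05, 0.2))
    first <- if (runif(1) < config$five_prime_u_prob) "T" else sample(c("A", "C", "G"), 1)
    mature <- paste0(first, paste(sample(DNA_BASES, L - 1, replace = TRUE), collapse = ""))
    hp <- design_hairpin(mature)
    pre <- hp$precursor
    if (cls == "decoy") {
      pre <- shuffle_dinucleotide(pre)
      # the decoy "mature" is the same-position window of the shuffled locus
      mature <- substr(pre, 1, L)
      hp$star <- NA_character_
    }
    w <- nchar(pre)
    pl <- place_intervals(1L, w, glen, occupied)
    occupied <- pl$occupied
    s <- IRanges::start(pl$ranges)
    genome_chars[s:(s + w - 1L)] <- strsplit(pre, "")[[1]]
    truth[[i]] <- tibble(
      locus_id = sprintf("%s_mir_%03d", cls, i),
      class = cls, mature_seq = mature, star_seq = hp$star,
      chrom = "chr1", strand = "+",
      pre_start = s, pre_end = s + w - 1L,
      mature_start = s + hp$mature_start - 1L,
      mature_end = s + hp$mature_end - 1L)
  }
  empty_truth <- tibble(
    locus_id = character(0), class = character(0), mature_seq = character(0),
    star_seq = character(0), chrom = character(0), strand = character(0),
    pre_start = integer(0), pre_end = integer(0),
    mature_start = integer(0), mature_end = integer(0))
  truth <- if (n_loci == 0) empty_truth else bind_rows(truth)

  # ---- regulation tiers ----------------------------------------------------
  if (is.null(config$de_effects)) {
    tier <- rep(c("strong", "slight", "null"), length.out = n_loci)
    lfc <- numeric(n_loci)
    lfc[tier == "strong"] <- sample(c(-1, 1), sum(tier == "strong"), TRUE) *
      runif(sum(tier == "strong"), 1, 2.5)
    lfc[tier == "slight"] <- sample(c(-1, 1), sum(tier == "slight"), TRUE) *
      runif(sum(tier == "slight"), 0.3, 0.9)
    de <- tibble(locus_id = truth$locus_id, true_log2fc = lfc, tier = tier)
  } else {
    de <- config$de_effects |>
      mutate(tier = dplyr::case_when(
        abs(.data$true_log2fc) >= 1 ~ "strong",
        abs(.data$true_log2fc) >= 0.25 ~ "slight",
        TRUE ~ "null"))
    if (!all(de$locus_id %in% truth$locus_id))
      abort("de_effects references unknown loci")
  }
  base <- 10^runif(n_loci, config$base_abundance[1], config$base_abundance[2])
  truth <- truth |>
    left_join(de, by = "locus_id") |>
    mutate(expected_count_c = base,
           expected_count_t = base * 2^.data$true_log2fc)

  genome_seq <- paste(genome_chars, collapse = "")
  genome <- c(chr1 = genome_seq)

  known_db <- truth |>
    filter(.data$class == "known") |>
    mutate(name = sprintf("syn-miR%03d", row_number())) |>
    select("name", sequence = "mature_seq")
  truth$known_name <- NA_character_
  truth$known_name[truth$class == "known"] <- known_db$name

  reads <- simulate_read_libraries(genome, features, truth, config)

  out <- list(genome = genome, features = features, truth = truth,
              known_db = known_db, reads = reads, config = config)
  if (!is.null(out_dir)) out$paths <- write_sim_experiment(out, out_dir)
  out
}

# draw background insert lengths from the configured mixture
draw_insert_lengths <- function(n, w) {
  cls <- sample(c("len21", "len24", "other"), n, replace = TRUE, prob = w)
  len <- integer(n)
  len[cls == "len21"] <- 21L
  len[cls == "len24"] <- 24L
  other_lens <- setdiff(15:30, c(21L, 24L))
  len[cls == "other"] <- sample(other_lens, sum(cls == "other"), replace = TRUE)
  len
}

# internal: build the two read libraries (called inside the seeded block of
# simulate_srna_experiment)
simulate_read_libraries <- function(genome, features, truth, config) {
  glen <- nchar(genome[[1]])
  gchars <- strsplit(genome[[1]], "")[[1]]
  depth <- config$library_depths

  # background species pool: subwindows of planted features + intergenic;
  # pool sizes scale with genome size (reference plan at 500 kb)
  fscale <- max(0.12, glen / 5e5)
  bg_spec <- tibble(
    type = c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat_region", "exon", "intron", "intergenic"),
    frac = c(0.085, 0.015, 4e-4, 1e-4, 0.15, 0.045, 0.125, 0.36),
    n_species = pmax(4L, as.integer(round(
      fscale * c(300L, 60L, 10L, 8L, 700L, 350L, 700L, 1800L)))))
  mirna_frac <- sum(truth$expected_count_c) / depth[1]
  species <- list()
  occ_mirna <- IRanges::IRanges(truth$pre_start, truth$pre_end)
  for (r in seq_len(nrow(bg_spec))) {
    ty <- bg_spec$type[r]; ns <- bg_spec$n_species[r]
    lens <- draw_insert_lengths(ns, config$length_mode_weights)
    if (ty == "intergenic") {
      occupied <- c(IRanges::IRanges(features$start, features$end), occ_mirna)
      starts <- integer(ns)
      for (i in seq_len(ns)) {
        repeat {
          s <- sample.int(glen - lens[i] + 1L, 1L)
          if (length(IRanges::findOverlaps(
                IRanges::IRanges(s, width = lens[i]), occupied)) == 0) break
        }
        starts[i] <- s
      }
      strands <- sample(c("+", "-"), ns, replace = TRUE)
    } else {
      ftab <- features |> filter(.data$type == ty)
      fi <- sample.int(nrow(ftab), ns, replace = TRUE)
      starts <- integer(ns); strands <- character(ns)
      for (i in seq_len(ns)) {
        f <- ftab[fi[i], ]
        wmax <- f$end - lens[i] + 1L
        starts[i] <- if (wmax <= f$start) f$start else sample(f$start:wmax, 1L)
        # mostly sense reads off the feature strand; some antisense
        strands[i] <- if (runif(1) < 0.75) f$strand else setdiff(c("+", "-"), f$strand)
      }
    }
    seqs <- vapply(seq_len(ns), function(i)
      paste(gchars[starts[i]:(starts[i] + lens[i] - 1L)], collapse = ""), character(1))
    flip <- strands == "-"
    seqs[flip] <- revcomp(seqs[flip])
    if (ty == "intergenic") {
      # apply the 5'-U preference to intergenic species (their tags are
      # compared to the genome only through their own planted coordinates)
      u <- runif(ns) < config$five_prime_u_prob
      seqs[u] <- paste0("T", substr(seqs[u], 2, lens[u]))
    }
    ab <- 10^rnorm(ns, 0, 0.8)
    species[[r]] <- tibble(sequence = seqs, type = ty,
                           weight = bg_spec$frac[r] * ab / sum(ab))
  }
  species <- bind_rows(species)
  # calibrate weights to both margins (category fractions and the insert
  # length mixture) by alternating proportional fitting, ending on the
  # length margin so realized length shares track the configured mixture
  len <- nchar(species$sequence)
  other_lens <- setdiff(15:30, c(21L, 24L))
  w <- config$length_mode_weights
  ltarget <- c(setNames(rep(w[["other"]] / length(other_lens),
                            length(other_lens)), other_lens),
               "21" = unname(w[["len21"]]), "24" = unname(w[["len24"]]))
  ltarget <- ltarget[names(ltarget) %in% as.character(unique(len))]
  ltarget <- ltarget / sum(ltarget)
  ctarget <- setNames(bg_spec$frac / sum(bg_spec$frac), bg_spec$type)
  wt <- species$weight
  for (it in 1:4) {
    cs <- tapply(wt, species$type, sum)
    wt <- wt * unname(ctarget[species$type] / cs[species$type])
    ls <- tapply(wt, as.character(len), sum)
    wt <- wt * unname(ltarget[as.character(len)] / ls[as.character(len)])
  }
  bg_total_frac <- max(0, 1 - mirna_frac)
  species$weight <- wt / sum(wt) * bg_total_frac

  draw_library <- function(lib) {
    exp_mirna <- if (lib == "control") truth$expected_count_c else truth$expected_count_t
    n_mirna_reads <- if (config$noise_model == "poisson") rpois(nrow(truth), exp_mirna)
      else stats::rnbinom(nrow(truth), mu = exp_mirna, size = config$nb_size)
    mir_seqs <- rep(truth$mature_seq, n_mirna_reads)
    mir_locus <- rep(truth$locus_id, n_mirna_reads)
    # isomiR 3' end shifts and star reads
    nm <- length(mir_seqs)
    if (nm > 0) {
      u <- runif(nm)
      shift_plus <- u < config$isomir_fraction / 2
      shift_minus <- u >= config$isomir_fraction / 2 & u < config$isomir_fraction
      star_idx <- u >= config$isomir_fraction &
        u < config$isomir_fraction + config$star_fraction
      star_seq <- truth$star_seq[match(mir_locus, truth$locus_id)]
      # +1 3' extension uses the genomic base after the mature
      ext <- substr(genome[[1]],
                    truth$mature_end[match(mir_locus, truth$locus_id)] + 1L,
                    truth$mature_end[match(mir_locus, truth$locus_id)] + 1L)
      mir_seqs[shift_plus] <- paste0(mir_seqs[shift_plus], ext[shift_plus])
      mir_seqs[shift_minus] <- substr(mir_seqs[shift_minus], 1,
                                      nchar(mir_seqs[shift_minus]) - 1L)
      ok_star <- star_idx & !is.na(star_seq)
      mir_seqs[ok_star] <- star_seq[ok_star]
    }
    n_bg <- max(0L, depth[ifelse(lib == "control", 1, 2)] - nm)
    bg_idx <- if (n_bg > 0) {
      pr <- if (sum(species$weight) > 0) species$weight
            else rep(1, nrow(species))  # loci saturate the library
      sample.int(nrow(species), n_bg, replace = TRUE, prob = pr)
    } else integer(0)
    inserts <- c(mir_seqs, species$sequence[bg_idx])
    # per-base substitution errors
    if (config$noise > 0) {
      len <- nchar(inserts)
      nerr <- rbinom(length(inserts), len, config$noise)
      for (i in which(nerr > 0)) {
        pos <- sample.int(len[i], nerr[i])
        ch <- strsplit(inserts[i], "")[[1]]
        ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
        inserts[i] <- paste(ch, collapse = "")
      }
    }
    tibble(id = sprintf("%s_%07d", substr(lib, 1, 1), seq_along(inserts)),
           sequence = paste0(inserts, config$adapter3))
  }
  list(control = draw_library("control"), treatment = draw_library("treatment"))
}

#' Write a simulated experiment to disk
#'
#' Emits genome FASTA, features GFF3, Phred+33 FASTQ pair (constant high
#' quality), known-mature FASTA, and the ground-truth TSV.
#'
#' @param sim result of [simulate_srna_experiment()].
#' @param out_dir output directory (created if absent).
#' @return named character vector of file paths.
#' @export
write_sim_experiment <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(genome = file.path(out_dir, "genome.fa"),
         features = file.path(out_dir, "features.gff3"),
         control = file.path(out_dir, "control.fastq"),
         treatment = file.path(out_dir, "treatment.fastq"),
         known = file.path(out_dir, "known_mature.fa"),
         truth = file.path(out_dir, "truth.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), p[["genome"]])
  write_gff3(sim$features, p[["features"]])
  write_fastq(sim$reads$control, p[["control"]])
  write_fastq(sim$reads$treatment, p[["treatment"]])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(sim$known_db$sequence, sim$known_db$name)),
    p[["known"]])
  truth_out <- sim$truth |>
    select("locus_id", "class", "mature_seq",
           expected_count_c = "expected_count_c",
           expected_count_t = "expected_count_t",
           true_log2fc = "true_log2fc", tier = "tier")
  readr::write_tsv(truth_out, p[["truth"]])
  p
}

#' Write reads as Phred+33 FASTQ with constant quality
#'
#' @param reads tibble with columns `id`, `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$sequence), function(n)
    strrep("I", n), character(1))
  con <- file(path, "wb")  # binary mode: stable bytes across platforms
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qual),
             con, sep = "\n")
  close(con)
  invisible(path)
}

# minimal GFF3 writer for the simulator's feature table (1-based closed,
# matching the GFF3 convention directly)
write_gff3 <- function(features, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmirtap_sim\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     features$chrom, features$type, features$start,
                     features$end, features$strand, features$feature_id))
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}
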