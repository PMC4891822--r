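#' Pipeline configuration
#'
#' Bundles stage parameters and input locations for [run_pipeline()]. Inputs
#' can be given either as file paths (`genome`, `features`, `mature_db`,
#' `fastq_control`, `fastq_treatment`, optionally `transcripts`) or as a
#' simulated experiment object (`sim`), in which case no files are read.
#'
#' @param genome,features,mature_db,fastq_control,fastq_treatment,transcripts
#'   input paths (ignored when `sim` is given).
#' @param sim optional result of [simulate_srna_experiment()].
#' @param policy a [clean_read_policy()].
#' @param max_mismatch genome mapping mismatch allowance (0-2).
#' @param flank,cluster_gap novel-discovery window parameters.
#' @param max_energy,min_reads hairpin qualification thresholds (kcal/mol,
#'   reads).
#' @param thresholds a [de_thresholds()].
#' @param target_cutoff target-prediction penalty cutoff.
#' @param seed RNG seed recorded in the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genome = NULL, features = NULL, mature_db = NULL,
                            fastq_control = NULL, fastq_treatment = NULL,
                            transcripts = NULL, sim = NULL,
                            policy = clean_read_policy(),
                            max_mismatch = 0L, flank = 150L, cluster_gap = 10L,
                            max_energy = -18, min_reads = 5L,
                            thresholds = de_thresholds(),
                            target_cutoff = 4.0, seed = 1L) {
  if (is.null(sim)) {
    paths <- c(genome = genome, features = features, mature_db = mature_db,
               fastq_control = fastq_control, fastq_treatment = fastq_treatment)
    missing <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing))
      abort(sprintf("input path(s) not found: %s",
                    paste(missing, collapse = ", ")))
  }
  structure(list(genome = genome, features = features, mature_db = mature_db,
                 fastq_control = fastq_control,
                 fastq_treatment = fastq_treatment,
                 transcripts = transcripts, sim = sim, policy = policy,
                 max_mismatch = as.integer(max_mismatch),
                 flank = as.integer(flank),
                 cluster_gap = as.integer(cluster_gap),
                 max_energy = max_energy, min_reads = as.integer(min_reads),
                 thresholds = thresholds, target_cutoff = target_cutoff,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the complete two-library analysis
#'
#' Executes clean -> collapse -> map -> annotate -> identify (known +
#' novel) -> differential expression (-> targets when transcripts are
#' given), returning every stage result and, when `out_dir` is given,
#' writing the report files: the category summary shaped like the standard
#' per-class accounting table, the length histogram, per-miRNA expression
#' profiles, the regulation-category tallies with the library-exclusive
#' lists, novel candidates, target hits, and a machine-readable run
#' manifest (config hash + seed). Reruns with identical config and inputs
#' produce byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional report directory.
#' @return list of class `mirtap_run` with elements `clean` (per-library
#'   tallies), `tags`, `classified`, `category_summary`, `length_dist`,
#'   `known`, `novel`, `de` (a `mirtap_de`), `mirna_counts`, `targets`
#'   (NULL without transcripts), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
    message(sprintf("[mirtap] %-10s %6.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  if (!is.null(config$sim)) {
    reads_c <- config$sim$reads$control
    reads_t <- config$sim$reads$treatment
    genome <- config$sim$genome
    features <- config$sim$features
    mature_db <- config$sim$known_db
  } else {
    reads_c <- read_fastq_tbl(config$fastq_control)
    reads_t <- read_fastq_tbl(config$fastq_treatment)
    genome <- load_genome(config$genome)
    features <- read_features(config$features)
    mature_db <- read_mature_db(config$mature_db)
  }

  clean_c <- stage("clean_c", trim_and_filter(reads_c, config$policy))
  clean_t <- stage("clean_t", trim_and_filter(reads_t, config$policy))
  n1 <- nrow(clean_c$inserts); n2 <- nrow(clean_t$inserts)
  tags <- stage("collapse",
                collapse_tags(clean_c$inserts, clean_t$inserts))
  aln <- stage("map", map_tags(tags, genome, config$max_mismatch))
  known <- if (nrow(mature_db) == 0) {
    list(matched = tags[0, ] |> mutate(mirna_name = character(0),
                                       mismatches = integer(0)),
         unmatched = tags)
  } else {
    stage("known", match_known(tags, mature_db))
  }
  classified <- stage("classify",
                      classify_tags(tags, aln, features,
                                    known_mirna = known$matched$sequence))
  category_summary <- summarize_categories(classified)
  length_dist <- length_distribution(classified,
                                     config$policy$min_len, config$policy$max_len)
  known_regions <- classified |>
    filter(.data$category == "miRNA", .data$mapped) |>
    select("chrom", "start", "end")
  novel <- stage("discover",
                 discover_mirna(classified, genome,
                                flank = config$flank,
                                cluster_gap = config$cluster_gap,
                                max_energy = config$max_energy,
                                min_reads = config$min_reads,
                                exclude = known_regions))
  novel_pass <- novel |> filter(.data$pass)

  # per-miRNA expression: known matures via end-tolerant tag assignment,
  # novel candidates from their own cluster counts
  known_counts <- known$matched |>
    group_by(mirna = .data$mirna_name) |>
    summarise(count_c = sum(.data$count_c), count_t = sum(.data$count_t),
              .groups = "drop")
  novel_counts <- novel_pass |>
    mutate(mirna = sprintf("novel_mir_%03d", row_number())) |>
    select("mirna", "count_c", "count_t")
  mirna_counts <- bind_rows(known_counts, novel_counts)
  de <- stage("diffexpr",
              diff_expression(mirna_counts, n1 = n1, n2 = n2,
                              thresholds = config$thresholds))

  targets <- NULL
  if (!is.null(config$transcripts)) {
    mature_set <- bind_rows(
      known$matched |> distinct(.data$mirna_name) |>
        left_join(mature_db, by = c(mirna_name = "name")) |>
        rename(name = "mirna_name"),
      novel_pass |>
        mutate(name = novel_counts$mirna) |>
        select("name", sequence = "mature_seq"))
    targets <- stage("targets",
                     predict_targets(mature_set, config$transcripts,
                                     cutoff = config$target_cutoff))
  }

  manifest <- list(
    package = "mirtap",
    version = as.character(utils::packageVersion("mirtap")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "sim")]),
    n_clean_c = n1, n_clean_t = n2,
    n_tags = nrow(tags), n_known = nrow(known_counts),
    n_novel = nrow(novel_counts))

  out <- list(clean = list(control = clean_c$tally, treatment = clean_t$tally),
              tags = tags, classified = classified,
              category_summary = category_summary, length_dist = length_dist,
              known = known, novel = novel, de = de,
              mirna_counts = mirna_counts, targets = targets,
              manifest = manifest)
  class(out) <- "mirtap_run"
  if (!is.null(out_dir)) write_run_reports(out, out_dir)
  out
}

#' @export
print.mirtap_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<mirtap_run> %d/%d clean reads, %d tags, %d known + %d novel miRNAs\n",
              m$n_clean_c, m$n_clean_t, m$n_tags, m$n_known, m$n_novel))
  print(x$de)
  invisible(x)
}

write_run_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f))
  w(render_table1(run$category_summary), "category_summary.tsv")
  w(run$length_dist, "length_distribution.tsv")
  w(bind_rows(control = run$clean$control, treatment = run$clean$treatment,
              .id = "library"), "rejection_tally.tsv")
  prof <- tidy(run$de) |> mutate(category = as.character(.data$category))
  w(prof, "expression_profiles.tsv")
  w(glance(run$de) |> tidyr::pivot_longer(dplyr::everything(),
                                          names_to = "statistic",
                                          values_to = "n"),
    "category_tallies.tsv")
  w(prof |> filter(.data$exclusive_flag != "shared") |>
      select("mirna", "exclusive_flag", "tpm_c", "tpm_t", "log2fc"),
    "exclusive_mirnas.tsv")
  w(run$novel, "novel_candidates.tsv")
  if (!is.null(run$targets)) w(run$targets, "target_hits.tsv")
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Render the per-category accounting table
#'
#' One row per annotation category in the fixed publication order (total
#' first, then the classes alphabetically as printed: exon antisense/sense,
#' intron antisense/sense, miRNA, rRNA, repeat, snRNA, snoRNA, tRNA,
#' un-annotated), with Unique / Percent / Total / Percent columns per
#' library, percentages to two decimals (round-half-even).
#'
#' @param summary tibble from [summarize_categories()] (both libraries).
#' @return tibble shaped like the publication table.
#' @export
render_table1 <- function(summary) {
  order_ <- c("exon_antisense", "exon_sense", "intron_antisense",
              "intron_sense", "miRNA", "rRNA", "repeat", "snRNA", "snoRNA",
              "tRNA", "un_annotated")
  total_row <- tibble(
    category = "total",
    unique_c = sum(summary$unique_c), unique_pct_c = 100,
    total_c = sum(summary$total_c), total_pct_c = 100,
    unique_t = sum(summary$unique_t), unique_pct_t = 100,
    total_t = sum(summary$total_t), total_pct_t = 100)
  body <- summary |>
    mutate(category = as.character(.data$category)) |>
    arrange(match(.data$category, order_))
  bind_rows(total_row, body) |>
    mutate(across(dplyr::ends_with("pct_c") | dplyr::ends_with("pct_t"),
                  ~ round(.x, 2)))
}
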