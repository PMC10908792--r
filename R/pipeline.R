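# End-to-end workflow: raw peak lists -> annotated, normalized, merged,
# consensus-filtered per-subject table -> statistics and class coverage.

#' Pipeline configuration
#'
#' @param seed Integer seed used by every stochastic stage.
#' @param tol_ppm Annotation and binning mass tolerance, ppm (default 1).
#' @param max_score Maximum isotopic fine-structure score (default 300).
#' @param recalibrate Apply local-list recalibration when calibrants are
#'   available (default TRUE).
#' @param prevalence_first First prevalence filter at table assembly
#'   (fraction of subjects, default 0.05).
#' @param prevalence_second Second prevalence filter before statistics
#'   (default 0.15).
#' @param lod Detection limit in counts (default 1e6).
#' @param impute_fraction Fraction of the LOD imputed for missing values
#'   (default 1/5).
#' @param group Phenotype column used for the two-group statistics
#'   (default `"gender"`).
#' @param thresholds Consensus thresholds (VIP, MDA, alpha, log2fc_min).
#' @param n_components PLS-DA components (default 5).
#' @param n_trees Random-forest trees (default 500).
#' @param run_stats,run_coverage Stage toggles.
#' @return Configuration list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, tol_ppm = 1.0, max_score = 300,
                            recalibrate = TRUE,
                            prevalence_first = 0.05, prevalence_second = 0.15,
                            lod = 1e6, impute_fraction = 0.2,
                            group = "gender",
                            thresholds = list(vip = 1.5, mda = 0.00016,
                                              alpha = 0.1, log2fc_min = 1),
                            n_components = 5, n_trees = 500,
                            run_stats = TRUE, run_coverage = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

# tiny FNV-1a hash for provenance records (no external digest dependency)
config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(x), auto_unbox = TRUE,
                                      force = TRUE, digits = NA))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h %% 2^31, b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Preprocess a set of peak lists into per-subject feature tables
#'
#' Runs the fixed stage order: (optional) recalibration, per-mode/method
#' feature-table assembly, exact-mass annotation, PQN against the QC pools,
#' batch correction, stacking of the two acquisition methods, ionisation-mode
#' merging, deduplication, replicate consensus (2-of-3), and the first
#' prevalence filter.
#'
#' @param peak_lists List of [peak_list()]s (a whole study).
#' @param reference Reference list (`data.frame` or TSV path).
#' @param calibrants Optional calibrant list (`formula`, `adduct`).
#' @param config A [pipeline_config()].
#' @return List: `tables` (per mode/method, annotated), `merged`,
#'   `per_subject`, `filtered` (after the first prevalence filter),
#'   `reports` (PQN, batch, QC RSD), `counts` (features in/out per stage).
#' @export
preprocess_study <- function(peak_lists, reference, calibrants = NULL,
                             config = pipeline_config()) {
  if (is.character(reference)) reference <- read_reference_list(reference)
  counts <- list()
  if (!is.null(calibrants) && isTRUE(config$recalibrate))
    peak_lists <- lapply(peak_lists, recalibrate, calibrants = calibrants)

  key <- vapply(peak_lists, function(p) paste(p$mode, p$method, sep = "."), "")
  tables <- lapply(split(peak_lists, key), build_feature_table,
                   tol_ppm = config$tol_ppm)
  counts$binned <- vapply(tables, function(t) nrow(t$values), integer(1))

  reports <- list(pqn = list(), batch = list(), qc_rsd = list())
  for (k in names(tables)) {
    hits <- annotate_features(tables[[k]], reference,
                              tol_ppm = config$tol_ppm,
                              max_score = config$max_score)
    tables[[k]] <- assign_annotations(tables[[k]], hits)
    pq <- pqn_normalize(tables[[k]], reference = "qc_median")
    tables[[k]] <- pq$table
    reports$pqn[[k]] <- pq$report
    bc <- batch_correct(tables[[k]])
    tables[[k]] <- bc$table
    reports$batch[[k]] <- bc$factors
    reports$qc_rsd[[k]] <- tryCatch(qc_rsd_report(tables[[k]]),
                                    error = function(e) NULL)
  }
  counts$annotated <- vapply(tables, function(t)
    sum(!is.na(t$features$formula)), integer(1))

  modes <- sub("\\..*$", "", names(tables))
  pos <- stack_methods(tables[modes == "positive"])
  neg <- stack_methods(tables[modes == "negative"])
  merged <- merge_modes(pos, neg)
  counts$after_mode_merge <- nrow(merged$values)
  merged <- deduplicate(merged)
  counts$after_dedup <- nrow(merged$values)

  per_subject <- replicate_consensus(merged)
  counts$subjects <- ncol(per_subject$values)
  filtered <- prevalence_filter(per_subject, config$prevalence_first)
  counts$after_first_filter <- nrow(filtered$values)

  list(tables = tables, merged = merged, per_subject = per_subject,
       filtered = filtered, reports = reports, counts = counts)
}

#' Prepare the statistics table from a preprocessed study
#'
#' Applies the second prevalence filter, imputes missing values at a
#' fraction of the detection limit, and median-normalizes.
#'
#' @param filtered Per-subject [feature_table()] (first filter applied).
#' @param config A [pipeline_config()].
#' @return The statistics-ready [feature_table()] (raw intensity scale).
#' @export
prepare_stats_table <- function(filtered, config = pipeline_config()) {
  tab <- prevalence_filter(filtered, config$prevalence_second)
  tab <- impute_missing(tab, lod = config$lod, fraction = config$impute_fraction)
  median_normalize(tab)
}

#' Run the full pipeline
#'
#' Executes every stage in the fixed order on a simulated study or a
#' directory of peak-list TSVs, writes each stage's output table and a JSON
#' provenance record (parameters, feature counts in/out, config hash) to the
#' output directory, and returns all in-memory results.
#'
#' @param study A [simulate_study()] result, or `NULL` to read peak lists
#'   from `peaks_dir`.
#' @param reference Reference list (`data.frame` or TSV path).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @param calibrants Optional calibrant list.
#' @param phenotypes Phenotype table; taken from `study` when omitted.
#' @param peaks_dir Directory of peak-list TSVs (used when `study` is NULL).
#' @return List of class `"pipeline_result"`: `preprocess`, `stats_table`,
#'   `consensus`, `coverage`, `config`, `counts`.
#' @export
run_pipeline <- function(study = NULL, reference = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         calibrants = NULL, phenotypes = NULL,
                         peaks_dir = NULL) {
  if (is.null(study)) {
    if (is.null(peaks_dir)) stop("provide a study or a peaks_dir")
    files <- list.files(peaks_dir, pattern = "\\.tsv$", full.names = TRUE)
    peak_lists <- lapply(files, read_peak_list)
    names(peak_lists) <- vapply(peak_lists, `[[`, "", "sample_id")
  } else {
    peak_lists <- study$peak_lists
    if (is.null(phenotypes)) phenotypes <- study$phenotypes
    if (is.null(reference)) reference <- synthetic_reference(study$panel,
                                                            seed = config$seed)
  }
  if (is.null(phenotypes)) stop("phenotypes required for grouping")
  hash <- config_hash(config)

  pre <- preprocess_study(peak_lists, reference, calibrants, config)
  stats_table <- prepare_stats_table(pre$filtered, config)
  counts <- pre$counts
  counts$after_second_filter <- nrow(stats_table$values)

  cons <- NULL
  if (isTRUE(config$run_stats)) {
    g <- phenotypes[[config$group]][match(stats_table$samples$subject_id,
                                          phenotypes$subject_id)]
    cons <- consensus(stats_table, as.character(g),
                      thresholds = config$thresholds,
                      n_components = config$n_components,
                      n_trees = config$n_trees, seed = config$seed)
  }
  cov <- NULL
  if (isTRUE(config$run_coverage)) {
    if (is.character(reference)) reference <- read_reference_list(reference)
    cov <- filter_classes(class_coverage(pre$filtered, reference),
                          min_share = 0.02)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(pre$filtered, file.path(out_dir, "per_subject_filtered.tsv"))
    write_feature_table(stats_table, file.path(out_dir, "stats_table.tsv"))
    if (!is.null(cov)) write_coverage(cov, file.path(out_dir, "class_coverage.tsv"))
    if (!is.null(cons)) {
      utils::write.table(cons$volcano, file.path(out_dir, "volcano.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cons$consensus, file.path(out_dir, "consensus.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(as.list(cons$venn), file.path(out_dir, "venn.json"),
                           auto_unbox = TRUE)
    }
    jsonlite::write_json(
      list(config_hash = hash, config = unclass(config),
           counts = counts,
           stage_order = c("recalibrate", "build", "annotate", "pqn", "batch",
                           "stack_methods", "merge_modes", "deduplicate",
                           "replicate_consensus", "prevalence_first",
                           "prevalence_second", "impute", "median_normalize",
                           "statistics")),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(preprocess = pre, stats_table = stats_table, consensus = cons,
                 coverage = cov, config = config, counts = counts,
                 config_hash = hash),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  features after first prevalence filter: ",
      x$counts$after_first_filter, "\n", sep = "")
  cat("  features entering statistics: ",
      x$counts$after_second_filter, "\n", sep = "")
  if (!is.null(x$consensus))
    cat("  consensus metabolites (all three methods): ",
        nrow(x$consensus$consensus), "\n", sep = "")
  invisible(x)
}
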