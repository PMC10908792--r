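# TSV dialects: peak lists (metadata in commented header lines), feature
# tables (features in rows, metadata columns first), and the
# samples-in-columns statistics export with a group-label row.

#' Write a peak list to TSV
#'
#' Metadata is stored as `#key=value` comment lines before the header.
#'
#' @param peaks A [peak_list()].
#' @param path Output path.
#' @export
write_peak_list <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(sample_id = peaks$sample_id, subject_id = peaks$subject_id,
            replicate = peaks$replicate, mode = peaks$mode,
            method = peaks$method, batch = peaks$batch,
            qc = tolower(as.character(peaks$qc)))
  writeLines(sprintf("#%s=%s", names(meta), meta), con)
  writeLines("mz\tintensity", con)
  if (nrow(peaks$peaks))
    writeLines(sprintf("%.10g\t%.10g", peaks$peaks$mz, peaks$peaks$intensity), con)
  invisible(path)
}

#' Read a peak list from TSV
#'
#' @param path File written by [write_peak_list()] (or any TSV with `mz` and
#'   `intensity` columns and optional `#key=value` metadata lines).
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- strsplit(sub("^#", "", l), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- if (length(kv) > 1) kv[2] else ""
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  for (col in c("mz", "intensity"))
    if (is.null(tab[[col]])) stop("peak list missing column: ", col)
  if (!is.numeric(tab$intensity)) stop("non-numeric intensity values")
  if (is.null(meta$mode)) stop("peak list missing mode metadata")
  peak_list(
    sample_id = meta$sample_id %||% basename(path),
    mz = tab$mz, intensity = tab$intensity,
    mode = meta$mode, method = meta$method %||% "small",
    subject_id = meta$subject_id %||% NA_character_,
    replicate = suppressWarnings(as.integer(meta$replicate %||% NA)),
    batch = meta$batch %||% "B1",
    qc = identical(meta$qc, "true")
  )
}

#' Write a feature table to TSV
#'
#' Features in rows; the leading columns are feature metadata
#' (`feature_id`, `formula`, `name`, `mode`, `main_class`, ...), followed by
#' one intensity column per sample. Sample metadata goes to a side file
#' `<path>.samples.tsv`.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param digits Significant digits for intensities (default 10).
#' @export
write_feature_table <- function(table, path, digits = 10) {
  vals <- as.data.frame(signif(table$values, digits))
  colnames(vals) <- table$samples$sample_id
  out <- cbind(table$features, vals)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$samples, paste0(path, ".samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path (expects `<path>.samples.tsv` alongside).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  samples <- utils::read.delim(paste0(path, ".samples.tsv"),
                               stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- which(!(names(tab) %in% samples$sample_id))
  values <- as.matrix(tab[, samples$sample_id, drop = FALSE])
  feature_table(values, tab[, meta_cols, drop = FALSE], samples)
}

#' Write a statistics export (samples in columns, group label row)
#'
#' The layout used for two-group statistics uploads: first row sample ids,
#' second row the group label of each sample, then one row per feature.
#'
#' @param table A [feature_table()].
#' @param groups Group labels per sample or a sample-metadata column name.
#' @param path Output path.
#' @export
write_stats_export <- function(table, groups, path) {
  g <- group_vector(table, groups)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Sample", table$samples$sample_id), collapse = "\t"), con)
  writeLines(paste(c("Label", g), collapse = "\t"), con)
  for (i in seq_len(nrow(table$values)))
    writeLines(paste(c(table$features$feature_id[i],
                       sprintf("%.10g", table$values[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' Write all acquisitions of a simulated study to a run directory
#'
#' One TSV peak list per acquisition plus `phenotypes.csv`,
#' `truth_manifest.json` and a design echo (`design.yaml`).
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  # one file per acquisition: the breath-sample id is shared by the four
  # mode x method acquisitions, so the filename carries all three
  for (nm in names(study$peak_lists)) {
    p <- study$peak_lists[[nm]]
    write_peak_list(p, file.path(dir, "peaks",
                                 paste0(p$sample_id, ".", p$mode, ".",
                                        p$method, ".tsv")))
  }
  utils::write.csv(study$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(dilution = as.list(study$truth$dilution),
         batch_factors = as.list(study$truth$batch_factors),
         effects = study$truth$effects,
         panel = study$panel$panel),
    file.path(dir, "truth_manifest.json"),
    auto_unbox = TRUE, digits = NA)
  design <- study$design
  class(design) <- NULL
  yaml::write_yaml(design, file.path(dir, "design.yaml"))
  invisible(dir)
}
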