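# The central data container: features x samples intensity matrix with
# feature and sample metadata, in the style of limma's EList.

#' Construct a feature table
#'
#' @param values Numeric matrix, features in rows, samples in columns;
#'   0 means "not detected".
#' @param features `data.frame` with at least `feature_id`; typically also
#'   `mz`, `mode`, `method`, `formula`, `name`, `db_id`, `main_class`, `key`.
#' @param samples `data.frame` with at least `sample_id`; typically also
#'   `subject_id`, `replicate`, `batch`, `qc`.
#' @return Object of class `"feature_table"` with elements `values`,
#'   `features`, `samples`.
#' @export
feature_table <- function(values, features, samples) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(features), ncol(values) == nrow(samples))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (any(values < 0)) stop("intensities must be non-negative")
  rownames(values) <- features$feature_id
  colnames(values) <- samples$sample_id
  rownames(features) <- NULL
  rownames(samples) <- NULL
  structure(list(values = values, features = features, samples = samples),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%d QC)\n",
              nrow(x$values), ncol(x$values), sum(x$samples$qc %||% FALSE)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

`%||%` <- function(a, b) if (is.null(a)) b else a

# subset rows (i) and/or columns (j) keeping metadata in sync
ft_subset <- function(table, i = NULL, j = NULL) {
  if (!is.null(i)) {
    table$values <- table$values[i, , drop = FALSE]
    table$features <- table$features[i, , drop = FALSE]
    rownames(table$features) <- NULL
  }
  if (!is.null(j)) {
    table$values <- table$values[, j, drop = FALSE]
    table$samples <- table$samples[j, , drop = FALSE]
    rownames(table$samples) <- NULL
  }
  table
}

#' Build a feature table from peak lists of one mode and method
#'
#' Peaks from all acquisitions are pooled, sorted by m/z and split into
#' features wherever the gap between consecutive peaks exceeds the ppm
#' tolerance; each feature's m/z is the intensity-weighted centroid. Multiple
#' peaks of one acquisition falling in the same bin keep the maximum
#' intensity.
#'
#' @param peak_lists List of [peak_list()] objects sharing `mode` and `method`.
#' @param tol_ppm Binning tolerance in ppm (default 1): consecutive sorted
#'   peaks closer than this are the same feature.
#' @return A [feature_table()] with features keyed by binned centroid m/z.
#' @export
build_feature_table <- function(peak_lists, tol_ppm = 1.0) {
  stopifnot(length(peak_lists) > 0)
  modes <- unique(vapply(peak_lists, `[[`, "", "mode"))
  methods <- unique(vapply(peak_lists, `[[`, "", "method"))
  if (length(modes) != 1L || length(methods) != 1L)
    stop("all peak lists must share one mode and one method")
  ids <- vapply(peak_lists, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")

  n_peaks <- vapply(peak_lists, function(p) nrow(p$peaks), integer(1))
  mz <- unlist(lapply(peak_lists, function(p) p$peaks$mz), use.names = FALSE)
  intensity <- unlist(lapply(peak_lists, function(p) p$peaks$intensity), use.names = FALSE)
  sample_idx <- rep(seq_along(peak_lists), n_peaks)

  samples <- data.frame(
    sample_id = ids,
    subject_id = vapply(peak_lists, `[[`, "", "subject_id"),
    replicate = vapply(peak_lists, function(p) p$replicate, integer(1)),
    batch = vapply(peak_lists, `[[`, "", "batch"),
    qc = vapply(peak_lists, function(p) p$qc, logical(1)),
    stringsAsFactors = FALSE
  )

  if (!length(mz)) {
    return(feature_table(matrix(0, 0, length(peak_lists)),
                         data.frame(feature_id = character(), mz = numeric(),
                                    mode = character(), method = character(),
                                    key = character(), stringsAsFactors = FALSE),
                         samples))
  }
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]; sample_idx <- sample_idx[o]
  gap <- diff(mz) > tol_ppm * 1e-6 * mz[-length(mz)]
  bin <- cumsum(c(1L, as.integer(gap)))
  centroid <- as.numeric(rowsum(mz * intensity, bin) / rowsum(intensity, bin))
  n_bins <- length(centroid)

  values <- matrix(0, n_bins, length(peak_lists))
  # max intensity per (bin, sample)
  agg <- tapply(intensity, list(bin, sample_idx), max)
  values[cbind(rep(as.integer(rownames(agg)), ncol(agg)),
               rep(as.integer(colnames(agg)), each = nrow(agg)))] <-
    ifelse(is.na(as.vector(agg)), 0, as.vector(agg))

  features <- data.frame(
    feature_id = sprintf("%s_%s_%010.5f", substr(modes, 1, 3), methods, centroid),
    mz = centroid, mode = modes, method = methods,
    formula = NA_character_, name = NA_character_, db_id = NA_character_,
    main_class = NA_character_,
    stringsAsFactors = FALSE
  )
  features$key <- features$feature_id
  feature_table(values, features, samples)
}

#' Attach annotation results to a feature table
#'
#' The top-ranked hit per feature fills `formula`, `name`, `db_id` and
#' `main_class`; annotated features are re-keyed by formula (so the same
#' molecule found in both polarities or both acquisition methods shares a
#' key), unannotated features keep their m/z-based key.
#'
#' @param table A [feature_table()].
#' @param hits Result of [annotate_features()].
#' @return The annotated table.
#' @export
assign_annotations <- function(table, hits) {
  if (NROW(hits)) {
    top <- hits[hits$rank == 1L, , drop = FALSE]
    i <- match(table$features$feature_id, top$feature_id)
    got <- !is.na(i)
    for (col in c("formula", "name", "db_id", "main_class"))
      table$features[[col]][got] <- top[[col]][i[got]]
    table$features$adduct <- NA_character_
    table$features$adduct[got] <- top$adduct[i[got]]
    table$features$key[got] <- top$formula[i[got]]
  }
  table
}
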