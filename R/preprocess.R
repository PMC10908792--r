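# Normalization, mode/method merging, replicate consensus and filtering.
#
# Stage order in the full pipeline: build (per mode x method) -> PQN ->
# batch correction -> merge acquisition methods -> merge ionisation modes ->
# deduplicate -> replicate consensus -> prevalence filter -> (statistics
# branch) imputation -> median normalization -> log/Pareto.

nz_median <- function(x) {
  x <- x[x > 0]
  if (!length(x)) return(0)
  stats::median(x)
}

#' Probabilistic quotient normalization
#'
#' The reference spectrum is the feature-wise median over the QC (pooled
#' sample) columns by default. For each sample, quotients value/reference are
#' formed over features where both are non-zero and the sample is divided by
#' the median quotient, removing per-sample dilution.
#'
#' @param table A [feature_table()].
#' @param reference `"qc_median"` (default; requires QC columns) or
#'   `"overall_median"`.
#' @return List with `table` (normalized) and `report` (per-sample quotient
#'   factors and the reference used).
#' @export
pqn_normalize <- function(table, reference = c("qc_median", "overall_median")) {
  reference <- match.arg(reference)
  v <- table$values
  qc <- table$samples$qc %||% rep(FALSE, ncol(v))
  if (reference == "qc_median" && !any(qc)) {
    warning("no QC columns; falling back to overall median reference")
    reference <- "overall_median"
  }
  ref_cols <- if (reference == "qc_median") v[, qc, drop = FALSE] else v
  ref <- apply(ref_cols, 1, nz_median)
  if (sum(ref > 0) < 10)
    stop("reference spectrum has fewer than 10 non-zero features")
  factors <- vapply(seq_len(ncol(v)), function(j) {
    shared <- v[, j] > 0 & ref > 0
    if (!any(shared)) stop("sample ", colnames(v)[j],
                           " shares no non-zero features with the reference")
    stats::median(v[shared, j] / ref[shared])
  }, numeric(1))
  names(factors) <- colnames(v)
  table$values <- sweep(v, 2, factors, "/")
  list(table = table,
       report = list(method = "pqn", reference = reference, factors = factors))
}

#' Median normalization
#'
#' Each sample is scaled so that its non-zero median equals the global median
#' of the per-sample non-zero medians. Idempotent.
#'
#' @param table A [feature_table()].
#' @return The normalized table.
#' @export
median_normalize <- function(table) {
  v <- table$values
  med <- apply(v, 2, nz_median)
  if (any(med == 0)) stop("sample(s) with no non-zero values")
  target <- stats::median(med)
  table$values <- sweep(v, 2, med / target, "/")
  table
}

#' Batch correction via QC-anchored global factors
#'
#' Each batch is divided by the ratio of its QC-pool median intensity to the
#' global QC median, removing multiplicative batch shifts. Batches without a
#' QC injection fall back to the batch sample median, with a warning.
#'
#' @param table A [feature_table()] whose `samples` carry `batch` and `qc`.
#' @return List with `table` (corrected) and `factors` (per batch).
#' @export
batch_correct <- function(table) {
  v <- table$values
  batch <- table$samples$batch
  qc <- table$samples$qc %||% rep(FALSE, ncol(v))
  batches <- unique(batch)
  if (length(batches) == 1L)
    return(list(table = table, factors = stats::setNames(1, batches)))
  batch_med <- vapply(batches, function(b) {
    cols <- batch == b & qc
    if (!any(cols)) {
      warning("batch ", b, " has no QC sample; using batch sample median")
      cols <- batch == b
    }
    nz_median(v[, cols, drop = FALSE])
  }, numeric(1))
  global <- if (any(qc)) nz_median(v[, qc, drop = FALSE]) else nz_median(v)
  factors <- batch_med / global
  names(factors) <- batches
  table$values <- sweep(v, 2, factors[batch], "/")
  list(table = table, factors = factors)
}

#' Stack feature tables over the two acquisition methods
#'
#' Row-binds per-method tables of one ionisation mode, aligning columns on
#' the shared sample set (subject, replicate, QC identity).
#'
#' @param tables List of [feature_table()]s with identical sample sets.
#' @return One table containing all rows.
#' @export
stack_methods <- function(tables) {
  base_ids <- sort(tables[[1]]$samples$sample_id)
  for (t in tables[-1])
    if (!identical(sort(t$samples$sample_id), base_ids))
      stop("sample sets differ between tables")
  ord <- lapply(tables, function(t) match(base_ids, t$samples$sample_id))
  values <- do.call(rbind, lapply(seq_along(tables), function(i)
    tables[[i]]$values[, ord[[i]], drop = FALSE]))
  fcols <- Reduce(intersect, lapply(tables, function(t) names(t$features)))
  features <- do.call(rbind, lapply(tables, function(t) t$features[fcols]))
  samples <- tables[[1]]$samples[ord[[1]], , drop = FALSE]
  feature_table(values, features, samples)
}

#' Merge the two ionisation modes of one metabolite
#'
#' For every formula key present in both polarities, the mode in which the
#' metabolite was detected in more samples is retained and the other mode's
#' rows are dropped; on a tie the mode with the larger total intensity wins.
#' Keys present in one mode only pass through. The chosen mode is recorded in
#' the feature metadata (`mode_selected`).
#'
#' @param table_pos,table_neg Positive- and negative-mode
#'   [feature_table()]s over the same sample set.
#' @return The merged table.
#' @export
merge_modes <- function(table_pos, table_neg) {
  ids <- sort(table_pos$samples$sample_id)
  if (!identical(ids, sort(table_neg$samples$sample_id)))
    stop("sample sets differ between modes")
  table_neg <- ft_subset(table_neg, j = match(table_pos$samples$sample_id,
                                              table_neg$samples$sample_id))
  shared <- intersect(table_pos$features$key, table_neg$features$key)
  mode_stats <- function(t, key) {
    rows <- which(t$features$key == key)
    m <- t$values[rows, , drop = FALSE]
    c(det = max(rowSums(m > 0)), total = sum(m))
  }
  drop_pos <- integer(0); drop_neg <- integer(0)
  chosen <- character(0)
  for (key in shared) {
    sp <- mode_stats(table_pos, key)
    sn <- mode_stats(table_neg, key)
    pick_pos <- if (sp["det"] != sn["det"]) sp["det"] > sn["det"] else sp["total"] >= sn["total"]
    if (pick_pos) drop_neg <- c(drop_neg, which(table_neg$features$key == key))
    else drop_pos <- c(drop_pos, which(table_pos$features$key == key))
    chosen[key] <- if (pick_pos) "positive" else "negative"
  }
  if (length(drop_pos)) table_pos <- ft_subset(table_pos, i = -drop_pos)
  if (length(drop_neg)) table_neg <- ft_subset(table_neg, i = -drop_neg)
  out <- stack_methods(list(table_pos, table_neg))
  out$features$mode_selected <- out$features$mode
  out$features$mode_selected[out$features$key %in% names(chosen)] <-
    chosen[out$features$key[out$features$key %in% names(chosen)]]
  out
}

#' Remove duplicate features sharing a formula key
#'
#' Duplicates arise from the overlapping mass range of the two acquisition
#' methods (95-300 m/z) and from residual multi-adduct rows. Per key, the row
#' with the highest total intensity across all samples is retained.
#'
#' @param table A [feature_table()].
#' @return The deduplicated table; attribute `"dropped"` lists removed
#'   feature ids.
#' @export
deduplicate <- function(table) {
  key <- table$features$key
  totals <- rowSums(table$values)
  keep <- unlist(lapply(split(seq_along(key), key), function(rows) {
    rows[which.max(totals[rows])]
  }), use.names = FALSE)
  keep <- sort(keep)
  dropped <- table$features$feature_id[-keep]
  out <- ft_subset(table, i = keep)
  attr(out, "dropped") <- if (length(key) > length(keep)) dropped else character(0)
  out
}

#' Replicate consensus: the 2-of-3 detection rule
#'
#' A metabolite counts for a subject only when detected (non-zero) in at
#' least `min_detect` of the subject's replicates; its subject-level value is
#' then the mean of the detected (non-zero) replicate intensities, otherwise
#' 0 ("not detected"). QC columns are dropped.
#'
#' @param table A [feature_table()] with `subject_id` and `replicate` sample
#'   metadata.
#' @param min_detect Minimum number of detected replicates (default 2).
#' @return A per-subject [feature_table()] (one column per subject).
#' @export
replicate_consensus <- function(table, min_detect = 2L) {
  keep <- !(table$samples$qc %||% rep(FALSE, ncol(table$values)))
  table <- ft_subset(table, j = which(keep))
  subjects <- unique(table$samples$subject_id)
  v <- table$values
  out <- vapply(subjects, function(s) {
    cols <- which(table$samples$subject_id == s)
    if (length(cols) < 2L) stop("subject ", s, " has fewer than 2 replicate columns")
    m <- v[, cols, drop = FALSE]
    n_det <- rowSums(m > 0)
    val <- rowSums(m) / pmax(n_det, 1L)   # mean over detected values only
    val[n_det < min_detect] <- 0
    val
  }, numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v))
  samples <- data.frame(sample_id = subjects, subject_id = subjects,
                        replicate = NA_integer_, batch = NA_character_,
                        qc = FALSE, stringsAsFactors = FALSE)
  feature_table(out, table$features, samples)
}

#' Prevalence filter
#'
#' Keeps features detected in at least `ceiling(min_fraction * n)` of the n
#' (non-QC) columns — applied to per-subject tables after replicate
#' consensus, so "samples" are subjects.
#'
#' @param table A [feature_table()].
#' @param min_fraction Minimum detection fraction in (0, 1]; 0 disables.
#' @return The filtered table; attribute `"n_removed"` gives the count.
#' @export
prevalence_filter <- function(table, min_fraction) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  if (min_fraction == 0) return(table)
  analytic <- !(table$samples$qc %||% rep(FALSE, ncol(table$values)))
  need <- ceiling(min_fraction * sum(analytic))
  n_det <- rowSums(table$values[, analytic, drop = FALSE] > 0)
  out <- ft_subset(table, i = which(n_det >= need))
  attr(out, "n_removed") <- nrow(table$values) - nrow(out$values)
  out
}

#' Impute missing values as a fraction of the limit of detection
#'
#' Zeros ("not detected") are replaced by `lod * fraction`
#' (default 1e6 x 1/5 = 2e5 counts); detected values are untouched.
#'
#' @param table A [feature_table()].
#' @param lod Limit of detection in counts (default 1e6).
#' @param fraction Fraction of the LOD used (default 1/5).
#' @return The imputed table.
#' @export
impute_missing <- function(table, lod = 1e6, fraction = 0.2) {
  stopifnot(lod > 0)
  table$values[table$values == 0] <- lod * fraction
  table
}

#' Log-transform and Pareto-scale
#'
#' Element-wise log (base 10 by default), then per feature: centre on the
#' mean and divide by the square root of the standard deviation. Constant
#' features are left centred at 0.
#'
#' @param table A [feature_table()] with all values positive (impute first).
#' @param base Logarithm base (default 10).
#' @return The transformed table.
#' @export
log_pareto <- function(table, base = 10) {
  v <- table$values
  if (any(v <= 0)) stop("all values must be positive; run impute_missing first")
  v <- log(v, base)
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  v <- v - mu
  pos <- sdv > 0
  v[pos, ] <- v[pos, , drop = FALSE] / sqrt(sdv[pos])
  table$values <- v
  table
}

#' Per-feature relative standard deviation across QC injections
#'
#' @param table A [feature_table()] with at least 2 QC columns.
#' @return List with `per_feature` RSD (sd/mean of raw intensities over QC
#'   columns, NA where the QC mean is 0), `median` and `quantiles`.
#' @export
qc_rsd_report <- function(table) {
  qc <- table$samples$qc %||% rep(FALSE, ncol(table$values))
  if (sum(qc) < 2L) stop("at least 2 QC columns required")
  m <- table$values[, qc, drop = FALSE]
  mu <- rowMeans(m)
  rsd <- ifelse(mu > 0, apply(m, 1, stats::sd) / mu, NA_real_)
  names(rsd) <- table$features$feature_id
  list(per_feature = rsd,
       median = stats::median(rsd, na.rm = TRUE),
       quantiles = stats::quantile(rsd, c(0.25, 0.5, 0.75, 0.9), na.rm = TRUE))
}
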