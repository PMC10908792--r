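#' Annotate features against a reference list by exact mass
#'
#' For every feature and every (reference record, adduct) pair whose
#' theoretical m/z lies within the ppm tolerance of the observed m/z — and,
#' when an observed isotope pattern is available, whose fine-structure fit
#' score is below the maximum — an annotation hit is emitted. Hits are ranked
#' per feature by absolute ppm error, then isotope score. Features without a
#' hit are simply absent from the result (they stay in the table unannotated).
#'
#' @param features `data.frame` with columns `feature_id`, `mz` and `mode`
#'   (`"positive"`/`"negative"`), or a [feature_table()].
#' @param reference `data.frame` with columns `formula`, `name`, `db_id`,
#'   `main_class` (see [read_reference_list()]).
#' @param adducts Adduct rules, default [default_adducts()].
#' @param tol_ppm Mass tolerance in ppm (default 1).
#' @param max_score Maximum isotopic fine-structure fit score (default 300).
#' @param patterns Optional named list (by `feature_id`) of observed isotope
#'   patterns; when present for a feature the fit score gates its hits, when
#'   absent the score is reported as 0 (no fine-structure evidence against
#'   the assignment).
#' @param resolving_power Resolving power for simulated patterns.
#' @return `data.frame` of hits: `feature_id`, `formula`, `adduct`,
#'   `mz_observed`, `mz_theoretical`, `ppm_error`, `isotope_score`, `name`,
#'   `db_id`, `main_class`, `rank`.
#' @export
annotate_features <- function(features, reference, adducts = default_adducts(),
                              tol_ppm = 1.0, max_score = 300,
                              patterns = NULL, resolving_power = 488000) {
  if (inherits(features, "feature_table"))
    features <- data.frame(feature_id = features$features$feature_id,
                           mz = features$features$mz,
                           mode = features$features$mode,
                           stringsAsFactors = FALSE)
  if (NROW(reference) == 0L) stop("empty reference list")
  stopifnot(tol_ppm > 0)
  ref_formula <- as.character(reference$formula)
  uf <- unique(ref_formula)
  umass <- vapply(uf, monoisotopic_mass, numeric(1))
  mass <- umass[match(ref_formula, uf)]

  # candidate table: every record x adduct, sorted by theoretical m/z
  cand <- do.call(rbind, lapply(seq_len(nrow(adducts)), function(a) {
    data.frame(record = seq_len(nrow(reference)), adduct = a,
               polarity = adducts$polarity[a],
               theo = (mass + adducts$mass_delta[a]) / abs(adducts$charge[a]))
  }))
  pattern_cache <- new.env(parent = emptyenv())
  hits <- vector("list", nrow(features))
  for (f in seq_len(nrow(features))) {
    mz <- features$mz[f]
    sel <- which(cand$polarity == features$mode[f] &
                 abs(cand$theo - mz) <= tol_ppm * 1e-6 * mz)
    if (!length(sel)) next
    err <- ppm_error(mz, cand$theo[sel])
    keep <- abs(err) < tol_ppm
    sel <- sel[keep]; err <- err[keep]
    if (!length(sel)) next
    fid <- features$feature_id[f]
    obs_pat <- if (!is.null(patterns)) patterns[[fid]] else NULL
    score <- vapply(seq_along(sel), function(k) {
      if (is.null(obs_pat)) return(0)
      fo <- ref_formula[cand$record[sel[k]]]
      pat <- get0(fo, envir = pattern_cache)
      if (is.null(pat)) {
        pat <- isotope_pattern(fo, resolving_power = resolving_power)
        assign(fo, pat, envir = pattern_cache)
      }
      th <- shift_pattern(pat, adducts[cand$adduct[sel[k]], ])
      tryCatch(isotope_fit_score(obs_pat, th, tol_ppm = max(tol_ppm, 2)),
               error = function(e) Inf)
    }, numeric(1))
    keep <- score < max_score
    if (!any(keep)) next
    sel <- sel[keep]; err <- err[keep]; score <- score[keep]
    o <- order(abs(err), score)
    rec <- cand$record[sel][o]
    hits[[f]] <- data.frame(
      feature_id = fid,
      formula = ref_formula[rec],
      adduct = adducts$name[cand$adduct[sel][o]],
      mz_observed = mz,
      mz_theoretical = cand$theo[sel][o],
      ppm_error = err[o],
      isotope_score = score[o],
      name = as.character(reference$name[rec]),
      db_id = as.character(reference$db_id[rec]),
      main_class = as.character(reference$main_class[rec]),
      rank = seq_along(o),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(feature_id = character(), formula = character(),
                      adduct = character(), mz_observed = numeric(),
                      mz_theoretical = numeric(), ppm_error = numeric(),
                      isotope_score = numeric(), name = character(),
                      db_id = character(), main_class = character(),
                      rank = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a reference annotation list from TSV
#'
#' Expected header columns: `formula`, `name`, `db_id`, `main_class`
#' (the export format of metabolite databases such as HMDB/HBDB lists).
#'
#' @param path TSV file path.
#' @return `data.frame` with those columns; `db_id` must be unique.
#' @export
read_reference_list <- function(path) {
  ref <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("formula", "name", "db_id", "main_class")
  miss <- setdiff(need, names(ref))
  if (length(miss)) stop("reference list missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ref$db_id)) stop("db_id values must be unique in a reference list")
  ref[need]
}

#' Write annotation hits to TSV
#' @param hits Result of [annotate_features()].
#' @param path Output path.
#' @export
write_annotation <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
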