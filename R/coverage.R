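# Chemical-class coverage of the detected metabolome against a reference
# list: how much of each class's potential (everything in the reference)
# was actually seen in breath.

#' Per-class coverage of detected metabolites
#'
#' Each detected feature contributes the main class of its top-ranked
#' annotation (one class per feature). Per class, `potential` is the number
#' of reference records carrying the class label and `coverage` is
#' `100 * detected / potential`.
#'
#' @param detected Annotation hits ([annotate_features()] output), an
#'   annotated [feature_table()], or a character vector of class labels
#'   (one per detected feature).
#' @param reference Reference list with a `main_class` column.
#' @return `data.frame` of class counts sorted by decreasing coverage:
#'   `main_class`, `detected`, `potential`, `coverage`.
#' @export
class_coverage <- function(detected, reference) {
  if (is.null(reference$main_class)) stop("reference carries no main_class labels")
  if (inherits(detected, "feature_table")) {
    cls <- detected$features$main_class
  } else if (is.data.frame(detected)) {
    top <- detected[detected$rank == 1L, , drop = FALSE]
    cls <- top$main_class
  } else {
    cls <- as.character(detected)
  }
  cls <- cls[!is.na(cls)]
  potential <- table(reference$main_class)
  det <- table(factor(cls, levels = names(potential)))
  out <- data.frame(
    main_class = names(potential),
    detected = as.integer(det),
    potential = as.integer(potential),
    stringsAsFactors = FALSE
  )
  out$coverage <- 100 * out$detected / out$potential
  out <- out[order(-out$coverage, out$main_class), ]
  rownames(out) <- NULL
  out
}

#' Keep classes with a substantial share of the detected hits
#'
#' Retains classes whose detected count is at least `min_share` of the total
#' detected hits (boundary inclusive).
#'
#' @param coverages [class_coverage()] output.
#' @param min_share Minimum share of total detected hits (default 0.02).
#' @return The filtered coverage table.
#' @export
filter_classes <- function(coverages, min_share = 0.02) {
  total <- sum(coverages$detected)
  if (total == 0) return(coverages[0, , drop = FALSE])
  out <- coverages[coverages$detected >= min_share * total, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a class-coverage report to TSV
#' @param coverages [class_coverage()] output.
#' @param path Output path.
#' @export
write_coverage <- function(coverages, path) {
  utils::write.table(coverages, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
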