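# Three-method significance machinery: volcano (Welch t + BH FDR),
# PLS-DA with VIP scores, random forest with OOB error — plus ANOVA/Tukey
# for multi-group comparisons and the Venn consensus.

group_vector <- function(table, groups) {
  if (is.character(groups) && length(groups) == 1L &&
      !is.null(table$samples[[groups]]))
    groups <- table$samples[[groups]]
  g <- as.character(groups)
  if (length(g) != ncol(table$values))
    stop("group assignment length does not match sample count")
  g
}

#' Per-feature fold change between two groups
#'
#' Ratio of group means of raw (unlogged) intensities,
#' numerator over denominator.
#'
#' @param table A [feature_table()] on the raw intensity scale.
#' @param groups Group labels per sample, or the name of a sample-metadata
#'   column.
#' @param numerator,denominator Group labels forming the ratio.
#' @return Named numeric vector of fold changes; attribute `"orientation"`
#'   records `"numerator/denominator"`.
#' @export
fold_change <- function(table, groups, numerator, denominator) {
  g <- group_vector(table, groups)
  stopifnot(numerator %in% g, denominator %in% g)
  num <- rowMeans(table$values[, g == numerator, drop = FALSE])
  den <- rowMeans(table$values[, g == denominator, drop = FALSE])
  if (any(den == 0)) stop("zero denominator group mean; impute first")
  fc <- num / den
  names(fc) <- table$features$feature_id
  attr(fc, "orientation") <- paste0(numerator, "/", denominator)
  fc
}

# vectorized Welch two-sample t-test on a matrix (features x samples)
.welch_rows <- function(m, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(m[, idx1, drop = FALSE]); m2 <- rowMeans(m[, idx2, drop = FALSE])
  v1 <- apply(m[, idx1, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, idx2, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- 1  # identical constant groups carry no evidence
  list(t = t, df = df, p = p)
}

#' Volcano analysis: fold change vs FDR-adjusted significance
#'
#' Per feature, a Welch two-sample t-test on log-transformed, Pareto-scaled
#' intensities and a raw-scale fold change. P-values are Benjamini-Hochberg
#' adjusted; a feature is significant when `|log2 FC| >= log2fc_min` and the
#' adjusted p-value is below `alpha`.
#'
#' @param table A [feature_table()] on the raw intensity scale (imputed).
#' @param groups Group labels per sample or a sample-metadata column name;
#'   exactly two groups. The fold change is second-listed group over
#'   first-listed (sorted order).
#' @param log2fc_min Minimum absolute log2 fold change (default 1, i.e. a
#'   doubling).
#' @param alpha Adjusted-p threshold (default 0.1).
#' @param adjust Multiple-testing method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @return `data.frame`: `feature_id`, `log2fc`, `t`, `p`, `p_adj`,
#'   `significant`; attribute `"orientation"`.
#' @export
volcano <- function(table, groups, log2fc_min = 1, alpha = 0.1, adjust = "BH") {
  g <- group_vector(table, groups)
  lv <- sort(unique(g))
  if (length(lv) != 2L) stop("volcano requires exactly two groups")
  idx1 <- which(g == lv[1]); idx2 <- which(g == lv[2])
  if (min(length(idx1), length(idx2)) < 2L) stop("each group needs >= 2 samples")
  fc <- fold_change(table, g, lv[2], lv[1])
  tm <- log_pareto(table)$values
  w <- .welch_rows(tm, idx2, idx1)
  p_adj <- stats::p.adjust(w$p, method = adjust)
  out <- data.frame(
    feature_id = table$features$feature_id,
    log2fc = log2(fc), t = w$t, p = w$p, p_adj = p_adj,
    significant = abs(log2(fc)) >= log2fc_min & p_adj < alpha,
    stringsAsFactors = FALSE
  )
  attr(out, "orientation") <- attr(fc, "orientation")
  out
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Per feature, a one-way ANOVA on log-transformed, Pareto-scaled values
#' followed by Tukey honestly-significant-difference pairwise comparisons.
#' A feature is significant when any pairwise Tukey-adjusted p-value is
#' below `alpha`.
#'
#' @param table A [feature_table()] on the raw intensity scale (imputed).
#' @param groups Group labels (>= 2 groups, each >= 2 samples) or a
#'   sample-metadata column name.
#' @param alpha Adjusted-p threshold (default 0.1).
#' @return List with `per_feature` (`feature_id`, `f`, `p_anova`,
#'   `min_p_tukey`, `significant`), `pairwise` (long table of Tukey
#'   comparisons), and `significant` (feature ids).
#' @export
anova_tukey <- function(table, groups, alpha = 0.1) {
  g <- factor(group_vector(table, groups))
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  if (any(table(g) < 2L)) stop("singleton group")
  tm <- log_pareto(table)$values
  rows <- lapply(seq_len(nrow(tm)), function(i) {
    y <- tm[i, ]
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    data.frame(
      feature_id = table$features$feature_id[i],
      f = an[1, "F value"], p_anova = an[1, "Pr(>F)"],
      comparison = rownames(tk), diff = tk[, "diff"], p_tukey = tk[, "p adj"],
      stringsAsFactors = FALSE
    )
  })
  pairwise <- do.call(rbind, rows)
  rownames(pairwise) <- NULL
  agg <- stats::aggregate(p_tukey ~ feature_id, pairwise, min)
  per_feature <- unique(pairwise[c("feature_id", "f", "p_anova")])
  per_feature$min_p_tukey <- agg$p_tukey[match(per_feature$feature_id, agg$feature_id)]
  per_feature$significant <- per_feature$min_p_tukey < alpha
  rownames(per_feature) <- NULL
  list(per_feature = per_feature, pairwise = pairwise,
       significant = per_feature$feature_id[per_feature$significant])
}

#' Fit a PLS-DA model with VIP scores
#'
#' NIPALS partial least squares against a centred class-indicator matrix.
#' Reports cumulative explained Y-variance (R2Y), cross-validated predictive
#' ability (Q2Y, stratified k-fold), and per-feature variable importance in
#' projection: `VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)`, so that
#' the mean of VIP^2 over features is 1.
#'
#' @param X Numeric matrix, samples in rows, features in columns (scale
#'   upstream, e.g. [log_pareto()]).
#' @param y Class labels (2 or more classes).
#' @param n_components Number of latent components (default 5).
#' @param cv_folds Folds for Q2Y cross-validation (default 10, stratified).
#' @param seed Seed for the fold assignment.
#' @return Object of class `"plsda_model"`: `scores`, `loadings`, `weights`,
#'   `y_loadings`, `R2Y` (cumulative per component), `Q2Y`, `vip`,
#'   `n_components`.
#' @export
plsda_fit <- function(X, y, n_components = 5, cv_folds = 10, seed = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  if (n_components > min(dim(X))) stop("n_components exceeds the rank of X")
  core <- .pls_core(X, y, n_components)
  q2 <- .pls_q2(X, y, n_components, cv_folds, seed)
  structure(list(
    scores = core$scores, loadings = core$loadings, weights = core$weights,
    y_loadings = core$y_loadings, R2Y = core$R2Y, Q2Y = q2,
    vip = core$vip, n_components = n_components, levels = levels(y)
  ), class = "plsda_model")
}

# NIPALS PLS2 with deflation of X and Y
.pls_core <- function(X, y, ncomp, tol = 1e-10, max_iter = 500) {
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(Yc)
  ssy_total <- sum(Yc^2)
  E <- Xc; F_ <- Yc
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); T_ <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp); r2y <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- F_[, which.max(colSums(F_^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u)); w <- w / sqrt(sum(w^2))
      t_ <- drop(E %*% w)
      q_ <- drop(crossprod(F_, t_)) / sum(t_^2)
      u <- drop(F_ %*% q_) / sum(q_^2)
      if (sum((t_ - t_old)^2) < tol * sum(t_^2)) break
      t_old <- t_
    }
    p_ <- drop(crossprod(E, t_)) / sum(t_^2)
    F_fit <- tcrossprod(t_, q_)
    ssy[a] <- sum(F_fit^2)
    E <- E - tcrossprod(t_, p_)
    F_ <- F_ - F_fit
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q_; T_[, a] <- t_
    r2y[a] <- 1 - sum(F_^2) / ssy_total
  }
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(X)
  list(scores = T_, loadings = P, weights = W, y_loadings = Q,
       R2Y = r2y, vip = vip,
       x_center = attr(Xc, "scaled:center"), y_center = attr(Yc, "scaled:center"))
}

# regression coefficients for prediction: B = W (P'W)^-1 Q'
.pls_coef <- function(core, ncomp) {
  W <- core$weights[, seq_len(ncomp), drop = FALSE]
  P <- core$loadings[, seq_len(ncomp), drop = FALSE]
  Q <- core$y_loadings[, seq_len(ncomp), drop = FALSE]
  W %*% solve(crossprod(P, W)) %*% t(Q)
}

.pls_q2 <- function(X, y, ncomp, folds, seed) {
  n <- nrow(X)
  set.seed(seed)
  fold <- integer(n)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  Y <- stats::model.matrix(~ y - 1)
  press <- 0; tss <- 0
  for (k in seq_len(folds)) {
    test <- which(fold == k); train <- which(fold != k)
    if (!length(test) || length(unique(y[train])) < 2L) next
    core <- .pls_core(X[train, , drop = FALSE], droplevels(y[train]),
                      min(ncomp, length(train) - 1L))
    B <- .pls_coef(core, ncol(core$weights))
    Xt <- sweep(X[test, , drop = FALSE], 2, core$x_center)
    pred <- sweep(Xt %*% B, 2, core$y_center, "+")
    obs <- Y[test, , drop = FALSE]
    press <- press + sum((obs - pred)^2)
    tss <- tss + sum(sweep(obs, 2, colMeans(Y[train, , drop = FALSE]))^2)
  }
  1 - press / tss
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d components: R2Y = %.3f, Q2Y = %.3f\n",
              x$n_components, x$R2Y[x$n_components], x$Q2Y))
  invisible(x)
}

#' Number of random-forest predictors per split
#'
#' The nearest integer to the square root of the feature count
#' (e.g. 2656 features -> 52 predictors).
#'
#' @param n_features Feature count (>= 1).
#' @return Integer mtry.
#' @export
mtry_rule <- function(n_features) {
  stopifnot(n_features >= 1)
  as.integer(round(sqrt(n_features)))
}

#' Random-forest classification with OOB error and permutation importance
#'
#' Bootstrap-aggregated classification trees (via the randomForest package)
#' with the out-of-bag misclassification rate, per-class errors, the
#' confusion matrix, and unscaled mean decrease in accuracy (OOB permutation
#' importance) per feature.
#'
#' @param X Numeric matrix, samples in rows, features in columns.
#' @param y Class labels.
#' @param n_trees Number of trees (default 500; capped at 1000).
#' @param n_predictors Predictors sampled per split; default [mtry_rule()].
#' @param seed RNG seed (mandatory for reproducibility).
#' @return Object of class `"rf_result"`: `oob_error`, `class_error`,
#'   `confusion`, `importance` (mean decrease in accuracy), `n_trees`,
#'   `n_predictors`.
#' @export
rf_classify <- function(X, y, n_trees = 500, n_predictors = NULL, seed = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  n_trees <- min(n_trees, 1000L)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  if (is.null(n_predictors)) n_predictors <- mtry_rule(ncol(X))
  set.seed(seed)
  fit <- randomForest::randomForest(x = as.data.frame(X), y = y,
                                    ntree = n_trees, mtry = n_predictors,
                                    importance = TRUE)
  conf <- fit$confusion[, levels(y), drop = FALSE]
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  names(imp) <- colnames(X)
  structure(list(
    oob_error = unname(fit$err.rate[n_trees, "OOB"]),
    class_error = fit$confusion[, "class.error"],
    confusion = conf,
    importance = imp,
    n_trees = n_trees, n_predictors = n_predictors
  ), class = "rf_result")
}

#' @export
print.rf_result <- function(x, ...) {
  cat(sprintf("<rf_result> %d trees, %d predictors, OOB error %.4f\n",
              x$n_trees, x$n_predictors, x$oob_error))
  invisible(x)
}

#' Partition three sets into the seven Venn regions
#'
#' @param a,b,c Vectors of feature ids.
#' @return Named integer vector with counts for `a_only`, `b_only`,
#'   `c_only`, `ab_only`, `ac_only`, `bc_only`, `abc`; the counts sum to
#'   the size of the union.
#' @export
venn_partition <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  c(a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab_only = sum(ina & inb & !inc),
    ac_only = sum(ina & !inb & inc),
    bc_only = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
}

#' Three-method significance consensus
#'
#' Runs the volcano analysis, PLS-DA (VIP scores) and random forest (mean
#' decrease in accuracy) on a binary grouping, forms the three significant
#' sets at the configured thresholds (VIP > 1.5, MDA > 0.00016, adjusted
#' p < 0.1 and |log2 FC| >= 1 by default), and partitions them into the
#' seven Venn regions. The ranked intersection of all three methods is the
#' consensus list.
#'
#' @param table A [feature_table()] on the raw intensity scale (imputed,
#'   median-normalized).
#' @param groups Binary group labels or a sample-metadata column name.
#' @param thresholds List with `vip`, `mda`, `alpha`, `log2fc_min`.
#' @param n_components PLS-DA components (default 5).
#' @param n_trees Random-forest trees (default 500).
#' @param seed RNG seed for PLS-DA folds and the forest.
#' @return Object of class `"consensus_result"`: `volcano`, `plsda`, `rf`,
#'   `sets` (three significant id sets), `venn`, `consensus` (ranked
#'   data.frame of features significant in all three).
#' @export
consensus <- function(table, groups,
                      thresholds = list(vip = 1.5, mda = 0.00016,
                                        alpha = 0.1, log2fc_min = 1),
                      n_components = 5, n_trees = 500, seed = 1) {
  g <- group_vector(table, groups)
  if (length(unique(g)) != 2L) stop("consensus requires a binary grouping")
  vol <- volcano(table, g, log2fc_min = thresholds$log2fc_min,
                 alpha = thresholds$alpha)
  scaled <- log_pareto(table)
  X <- t(scaled$values)
  pls <- plsda_fit(X, g, n_components = min(n_components, min(dim(X)) - 1L),
                   seed = seed)
  rf <- rf_classify(X, g, n_trees = n_trees, seed = seed)
  ids <- table$features$feature_id
  sets <- list(
    volcano = ids[vol$significant],
    vip = ids[pls$vip > thresholds$vip],
    mda = ids[rf$importance > thresholds$mda]
  )
  venn <- venn_partition(sets$volcano, sets$vip, sets$mda)
  core_ids <- Reduce(intersect, sets)
  cons <- vol[vol$feature_id %in% core_ids, c("feature_id", "log2fc", "p", "p_adj")]
  cons$vip <- pls$vip[match(cons$feature_id, ids)]
  cons$mda <- rf$importance[match(cons$feature_id, ids)]
  cons <- cons[order(cons$p_adj, cons$p), ]
  rownames(cons) <- NULL
  structure(list(volcano = vol, plsda = pls, rf = rf, sets = sets,
                 venn = venn, consensus = cons, thresholds = thresholds),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result>\n")
  cat(sprintf("  volcano: %d significant\n", length(x$sets$volcano)))
  cat(sprintf("  PLS-DA VIP > %.2f: %d\n", x$thresholds$vip, length(x$sets$vip)))
  cat(sprintf("  RF MDA > %g: %d\n", x$thresholds$mda, length(x$sets$mda)))
  cat(sprintf("  consensus (all three): %d\n", nrow(x$consensus)))
  invisible(x)
}
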