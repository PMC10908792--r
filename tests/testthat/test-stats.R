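make_group_table <- function(n_feat = 20, n_per = 10, shift_rows = NULL,
                             fold = 4, seed = 1) {
  set.seed(seed)
  v <- matrix(10^(7 + matrix(rnorm(n_feat * 2 * n_per, 0, 0.1), n_feat)),
              n_feat, 2 * n_per)
  if (length(shift_rows)) v[shift_rows, 1:n_per] <- v[shift_rows, 1:n_per] * fold
  rownames(v) <- paste0("F", seq_len(n_feat))
  colnames(v) <- paste0("S", seq_len(2 * n_per))
  list(table = ft_from_matrix(v),
       groups = rep(c("female", "male"), each = n_per))
}

test_that("fold change is the ratio of raw group means", {
  d <- make_group_table(shift_rows = 1:3, fold = 2)
  fc <- fold_change(d$table, d$groups, "female", "male")
  expect_equal(attr(fc, "orientation"), "female/male")
  expect_true(all(abs(fc[1:3] - 2) < 0.3))
  expect_true(all(abs(fc[4:20] - 1) < 0.2))
  # identical groups give exactly 1
  v <- d$table$values; v[, 11:20] <- v[, 1:10]
  t2 <- ft_from_matrix(v)
  expect_equal(as.numeric(fold_change(t2, d$groups, "female", "male")),
               rep(1, 20))
})

test_that("volcano flags planted markers and nothing on identical groups", {
  d <- make_group_table(n_feat = 50, shift_rows = 1:5, fold = 4)
  res <- volcano(d$table, d$groups)
  expect_true(all(res$significant[1:5]))
  expect_lt(sum(res$significant[6:50]), 3)
  expect_true(all(res$p_adj >= res$p))
  # identical groups: nothing significant
  v <- d$table$values; v[, 11:20] <- v[, 1:10]
  res0 <- volcano(ft_from_matrix(v), d$groups)
  expect_equal(sum(res0$significant), 0L)
  expect_error(volcano(d$table, rep("a", 20)), "two groups")
})

test_that("volcano is invariant to column order and group relabeling", {
  d <- make_group_table(n_feat = 30, shift_rows = 1:4)
  r1 <- volcano(d$table, d$groups)
  perm <- sample(ncol(d$table$values))
  t2 <- ft_subset(d$table, j = perm)
  r2 <- volcano(t2, d$groups[perm])
  expect_identical(r1$feature_id[r1$significant], r2$feature_id[r2$significant])
  relab <- ifelse(d$groups == "female", "zebra", "aard")
  r3 <- volcano(d$table, relab)
  expect_identical(r1$feature_id[r1$significant], r3$feature_id[r3$significant])
  expect_equal(r1$p, r3$p, tolerance = 1e-12)
})

test_that("vectorized Welch t matches stats::t.test", {
  d <- make_group_table(n_feat = 10, shift_rows = 1:2)
  tm <- log_pareto(d$table)$values
  res <- volcano(d$table, d$groups)
  for (i in c(1, 5, 10)) {
    ref <- t.test(tm[i, d$groups == "male"], tm[i, d$groups == "female"])
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the step-up formula", {
  # worked example: (0.01, 0.02, 0.03, 0.04) all adjust to 0.04
  expect_equal(bh_stepup(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(3)
  for (trial in 1:100) {
    p <- runif(sample(1:1000, 1))
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("ANOVA/Tukey finds nothing for equal groups, reduces to t at k=2", {
  set.seed(4)
  v <- matrix(10^(7 + rnorm(20 * 12, 0, 0.1)), 20, 12)
  rownames(v) <- paste0("F", 1:20); colnames(v) <- paste0("S", 1:12)
  g3 <- rep(c("a", "b", "c"), each = 4)
  tab <- ft_from_matrix(v)
  res <- anova_tukey(tab, g3, alpha = 0.01)
  expect_lt(length(res$significant), 3)
  # two-group reduction: Tukey p equals pooled-variance t-test p
  g2 <- rep(c("a", "b"), each = 6)
  res2 <- anova_tukey(tab, g2)
  tm <- log_pareto(tab)$values
  for (i in c(1, 7)) {
    tt <- t.test(tm[i, g2 == "a"], tm[i, g2 == "b"], var.equal = TRUE)
    p_tukey <- res2$pairwise$p_tukey[res2$pairwise$feature_id ==
                                     paste0("pos_F", i)]
    expect_equal(p_tukey, tt$p.value, tolerance = 1e-6)
  }
  expect_error(anova_tukey(tab, c(rep("a", 11), "b")), "singleton")
})

test_that("ANOVA/Tukey detects a planted multi-group effect", {
  set.seed(5)
  v <- matrix(10^(7 + rnorm(10 * 30, 0, 0.1)), 10, 30)
  g <- rep(c("FOC", "FnOC", "male"), each = 10)
  v[1, g == "FnOC"] <- v[1, g == "FnOC"] * 3
  rownames(v) <- paste0("F", 1:10); colnames(v) <- paste0("S", 1:30)
  res <- anova_tukey(ft_from_matrix(v), g)
  expect_true("pos_F1" %in% res$significant)
  cmp <- res$pairwise[res$pairwise$feature_id == "pos_F1", ]
  expect_lt(cmp$p_tukey[grepl("FnOC-FOC", cmp$comparison)], 0.05)
})

test_that("PLS-DA separates well-separated blobs and satisfies VIP identity", {
  set.seed(6)
  n <- 40; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", 1:3] <- X[y == "b", 1:3] + 5
  colnames(X) <- paste0("F", 1:p)
  fit <- plsda_fit(X, y, n_components = 5, seed = 1)
  expect_gte(fit$R2Y[5], 0.9)
  expect_gt(fit$Q2Y, 0.8)
  # VIP identity: mean of VIP^2 = 1 i.e. sum = p
  expect_equal(sum(fit$vip^2), p, tolerance = 1e-8)
  # informative features carry the top VIPs
  expect_true(all(rank(-fit$vip)[1:3] <= 4))
  # R2Y non-decreasing in components
  expect_true(all(diff(fit$R2Y) >= -1e-12))
})

test_that("permuted labels give near-zero predictive ability", {
  set.seed(7)
  X <- matrix(rnorm(40 * 25), 40, 25)
  colnames(X) <- paste0("F", 1:25)
  q2s <- vapply(1:5, function(s) {
    set.seed(s)
    y <- sample(rep(c("a", "b"), each = 20))
    plsda_fit(X, y, n_components = 3, seed = s)$Q2Y
  }, numeric(1))
  expect_true(all(q2s <= 0.2))
})

test_that("VIP scores agree with an independent PLS-DA implementation", {
  set.seed(8)
  n <- 30; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", 1:2] <- X[y == "b", 1:2] + 3
  colnames(X) <- paste0("F", 1:p)
  fit <- plsda_fit(X, y, n_components = 2, seed = 1)
  mo <- mixOmics::plsda(X, factor(y), ncomp = 2, scale = FALSE)
  vip_mo <- mixOmics::vip(mo)[, 2]
  expect_gt(cor(fit$vip, vip_mo), 0.95)
})

test_that("mtry rule is the rounded square root", {
  expect_equal(mtry_rule(2656), 52L)
  expect_equal(mtry_rule(100), 10L)
  expect_equal(mtry_rule(2), 1L)
  expect_error(mtry_rule(0))
})

test_that("random forest separates planted structure and is seed-stable", {
  set.seed(9)
  n <- 60; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", 1:5] <- X[y == "b", 1:5] + 4
  colnames(X) <- paste0("F", 1:p)
  rf <- rf_classify(X, y, seed = 3)
  expect_lte(rf$oob_error, 0.05)
  expect_equal(rf$n_predictors, mtry_rule(p))
  expect_true(all(rank(-rf$importance)[1:5] <= 8))
  rf2 <- rf_classify(X, y, seed = 3)
  expect_identical(rf$oob_error, rf2$oob_error)
  expect_identical(rf$importance, rf2$importance)
  # permuted labels: OOB near the majority-class baseline
  set.seed(10)
  yp <- sample(y)
  rfp <- rf_classify(X, yp, seed = 4)
  expect_gt(rfp$oob_error, 0.4)
  expect_error(rf_classify(X, rep("a", n), seed = 1), "2 classes")
})

test_that("Venn partition enumerates the seven regions consistently", {
  v <- venn_partition(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  expect_equal(unname(v), c(1, 0, 1, 1, 0, 1, 1))
  expect_equal(sum(v), length(union(union(1:3, 2:4), 3:5)))
  # disjoint sets populate only singleton regions
  d <- venn_partition(1:2, 3:4, 5:6)
  expect_equal(unname(d), c(2, 2, 2, 0, 0, 0, 0))
  # identical sets collapse to the triple intersection
  s <- venn_partition(1:4, 1:4, 1:4)
  expect_equal(unname(s), c(0, 0, 0, 0, 0, 0, 4))
  # inclusion-exclusion against directly computed sizes
  set.seed(11)
  for (trial in 1:20) {
    a <- sample(1:30, sample(5:20, 1)); b <- sample(1:30, sample(5:20, 1))
    c_ <- sample(1:30, sample(5:20, 1))
    v <- venn_partition(a, b, c_)
    expect_equal(unname(v["a_only"] + v["ab_only"] + v["ac_only"] + v["abc"]),
                 length(unique(a)))
    expect_equal(sum(v), length(union(union(a, b), c_)))
  }
})

test_that("consensus combines the three methods; infinite thresholds empty it", {
  d <- make_group_table(n_feat = 60, n_per = 15, shift_rows = 1:6, fold = 4,
                        seed = 12)
  res <- consensus(d$table, d$groups, seed = 2)
  planted <- paste0("pos_F", 1:6)
  expect_true(all(planted %in% res$consensus$feature_id))
  expect_equal(sum(res$venn), length(Reduce(union, res$sets)))
  hi <- consensus(d$table, d$groups,
                  thresholds = list(vip = Inf, mda = Inf, alpha = 0.1,
                                    log2fc_min = Inf), seed = 2)
  expect_equal(sum(vapply(hi$sets, length, integer(1))), 0L)
  expect_equal(unname(hi$venn), rep(0L, 7))
})
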