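test_that("feature-table binning groups peaks by ppm proximity", {
  mz0 <- 200.000000
  p1 <- peak_list("s1", c(mz0, 300.0), c(1e7, 2e7), mode = "positive")
  p2 <- peak_list("s2", c(mz0 * (1 + 0.5e-6), 300.0 * (1 + 3e-6)),
                  c(1.2e7, 2.2e7), mode = "positive")
  tab <- build_feature_table(list(p1, p2), tol_ppm = 1)
  # 0.5 ppm apart -> same bin; 3 ppm apart -> distinct bins
  expect_equal(nrow(tab$values), 3L)
  near200 <- which(abs(tab$features$mz - mz0) < 0.01)
  expect_equal(sum(tab$values[near200, ] > 0), 2L)
  # two acquisitions sharing one formula -> one row, two columns filled
  expect_error(build_feature_table(list(p1, p1)), "duplicate sample ids")
})

test_that("empty acquisitions become all-zero columns", {
  p1 <- peak_list("s1", c(150.1, 200.2), c(1e7, 1e7), mode = "positive")
  p2 <- peak_list("s2", numeric(0), numeric(0), mode = "positive")
  tab <- build_feature_table(list(p1, p2))
  expect_equal(unname(tab$values[, "s2"]), c(0, 0))
})

test_that("PQN recovers scalar dilution exactly", {
  set.seed(2)
  a <- runif(30, 1e6, 1e8)
  v <- cbind(A = a, B = 2 * a, QC = a)
  tab <- ft_from_matrix(v, keys = paste0("F", 1:30), qc = c(FALSE, FALSE, TRUE))
  res <- pqn_normalize(tab)
  expect_equal(unname(res$report$factors["B"]), 2, tolerance = 1e-12)
  expect_equal(unname(res$table$values[, "B"]), unname(a), tolerance = 1e-9)
  # already-normalized samples get factor 1
  expect_equal(unname(res$report$factors["A"]), 1, tolerance = 1e-12)
})

test_that("PQN reproduces the reference up to a constant for scalar multiples", {
  set.seed(5)
  ref <- runif(25, 1e6, 1e8)
  scales <- c(0.5, 1, 1.7, 3)
  v <- vapply(scales, function(s) ref * s, numeric(25))
  colnames(v) <- paste0("S", 1:4)
  rownames(v) <- paste0("F", 1:25)
  tab <- ft_from_matrix(v)
  out <- pqn_normalize(tab, reference = "overall_median")$table$values
  for (j in 2:4) expect_equal(unname(out[, j] / out[, 1]), rep(1, 25), tolerance = 1e-9)
})

test_that("PQN factor correlates with true dilution on a synthetic cohort", {
  design <- cohort_design(n_subjects = 40, n_batches = 1, seed = 5)
  study <- simulate_study(design, generate_panel(200, seed = 5))
  key <- vapply(study$peak_lists, function(p) paste(p$mode, p$method, sep = "."), "")
  tab <- build_feature_table(study$peak_lists[key == "positive.small"])
  factors <- pqn_normalize(tab)$report$factors
  truth <- study$truth$dilution
  shared <- intersect(names(factors), names(truth))
  expect_gt(length(shared), 100)
  expect_gt(cor(factors[shared], truth[shared]), 0.95)
})

test_that("median normalization equalizes non-zero medians and is idempotent", {
  v <- matrix(c(10, 20, 30, 0, 20, 40, 60, 80), 4, 2)
  rownames(v) <- paste0("F", 1:4); colnames(v) <- c("A", "B")
  tab <- ft_from_matrix(v)
  out <- median_normalize(tab)
  meds <- apply(out$values, 2, function(x) median(x[x > 0]))
  expect_equal(unname(meds[1]), unname(meds[2]))
  out2 <- median_normalize(out)
  expect_equal(out2$values, out$values, tolerance = 1e-12)
  # single sample passes through unchanged
  one <- ft_from_matrix(v[, 1, drop = FALSE])
  expect_equal(unname(median_normalize(one)$values[, 1]), unname(v[, 1]), tolerance = 1e-12)
})

test_that("batch correction removes a uniform multiplicative shift", {
  set.seed(8)
  base <- runif(20, 1e6, 1e7)
  v <- cbind(qc1 = base, s1 = base * runif(20, 0.9, 1.1),
             qc2 = base * 1.5, s2 = base * 1.5 * runif(20, 0.9, 1.1))
  tab <- ft_from_matrix(v, qc = c(TRUE, FALSE, TRUE, FALSE))
  tab$samples$batch <- c("B1", "B1", "B2", "B2")
  out <- batch_correct(tab)
  expect_equal(unname(out$factors["B2"] / out$factors["B1"]), 1.5,
               tolerance = 1e-9)
  # corrected batch QC medians agree across batches
  corrected <- out$table$values
  expect_equal(median(corrected[, "qc1"]), median(corrected[, "qc2"]),
               tolerance = 1e-9)
  # single batch is the identity
  tab1 <- ft_from_matrix(v[, 1:2], qc = c(TRUE, FALSE))
  expect_equal(batch_correct(tab1)$table$values, tab1$values)
})

test_that("mode merge follows the detection-count rule with intensity ties", {
  # detected 91x positive vs 81x negative -> positive retained
  n <- 100
  vp <- matrix(0, 1, n); vp[1, 1:91] <- 1e6
  vn <- matrix(0, 1, n); vn[1, 1:81] <- 5e6
  rownames(vp) <- rownames(vn) <- "C6H12O6"
  colnames(vp) <- colnames(vn) <- paste0("S", 1:n)
  tp <- ft_from_matrix(vp, mode = "positive")
  tn <- ft_from_matrix(vn, mode = "negative")
  m <- merge_modes(tp, tn)
  expect_equal(nrow(m$values), 1L)
  expect_equal(m$features$mode, "positive")
  # 50/50 tie with total intensities 1e9 vs 2e9 -> negative retained
  vp2 <- matrix(0, 1, n); vp2[1, 1:50] <- 2e7   # total 1e9
  vn2 <- matrix(0, 1, n); vn2[1, 51:100] <- 4e7 # total 2e9
  rownames(vp2) <- rownames(vn2) <- "C5H9NO2"
  colnames(vp2) <- colnames(vn2) <- paste0("S", 1:n)
  m2 <- merge_modes(ft_from_matrix(vp2, mode = "positive"),
                    ft_from_matrix(vn2, mode = "negative"))
  expect_equal(m2$features$mode, "negative")
  # formula present in one mode only passes through
  vn3 <- rbind(vn2, C4H6O5 = 0); vn3["C4H6O5", 1:10] <- 1e6
  m3 <- merge_modes(ft_from_matrix(vp2, mode = "positive"),
                    ft_from_matrix(vn3, mode = "negative"))
  expect_true("C4H6O5" %in% m3$features$key)
  expect_error(merge_modes(tp, ft_from_matrix(vn2[, 1:50, drop = FALSE],
                                              mode = "negative")),
               "sample sets differ")
})

test_that("mode merge equals the brute-force reference on random tables", {
  set.seed(42)
  for (trial in 1:1000) {
    nf <- sample(1:10, 1); ns <- sample(2:10, 1)
    vp <- random_mode_table(nf, ns, "positive")
    vn <- random_mode_table(sample(1:10, 1), ns, "negative")
    # overlap some formulas
    shared <- intersect(rownames(vp), rownames(vn))
    m <- merge_modes(ft_from_matrix(vp, mode = "positive"),
                     ft_from_matrix(vn, mode = "negative"))
    expected <- merge_modes_brute(vp, vn)
    got <- setNames(m$features$mode, m$features$key)
    expect_identical(got[names(expected)], expected)
  }
})

test_that("deduplication keeps the highest-total row per formula", {
  v <- matrix(c(5e8, 0, 7e8, 0, 1e6, 2e6), 3, 2, byrow = TRUE)
  rownames(v) <- c("r1", "r2", "r3"); colnames(v) <- c("A", "B")
  tab <- ft_from_matrix(v, keys = c("C6H12O6", "C6H12O6", "C5H9NO2"))
  out <- deduplicate(tab)
  expect_equal(nrow(out$values), 2L)
  kept <- out$features$feature_id[out$features$key == "C6H12O6"]
  expect_equal(kept, "pos_r2")  # the 7e8 row
  # three-way duplicate -> single max-total survivor
  v3 <- matrix(c(1, 3, 2), 3, 1) * 1e6
  rownames(v3) <- paste0("d", 1:3); colnames(v3) <- "A"
  t3 <- deduplicate(ft_from_matrix(v3, keys = rep("C4H6O5", 3)))
  expect_equal(nrow(t3$values), 1L)
  expect_equal(unname(t3$values[1, 1]), 3e6)
  # no duplicates -> identity
  expect_equal(nrow(deduplicate(tab)$values), 2L)
})

test_that("replicate consensus applies the 2-of-3 rule with nonzero means", {
  v <- matrix(c(1e7, 1.2e7, 0,
                5e6, 0, 0,
                2e6, 3e6, 4e6), 3, 3, byrow = TRUE)
  rownames(v) <- paste0("F", 1:3)
  colnames(v) <- paste0("S1_r", 1:3)
  tab <- ft_from_matrix(v, subject = rep("S1", 3), replicate = 1:3)
  out <- replicate_consensus(tab)
  expect_equal(unname(out$values[, "S1"]), c(1.1e7, 0, 3e6))
  # biconditional on exhaustive 3-replicate detection patterns
  pats <- expand.grid(a = c(0, 1), b = c(0, 1), c = c(0, 1))
  v2 <- as.matrix(pats) * 1e6
  rownames(v2) <- paste0("P", 1:8)
  colnames(v2) <- paste0("S1_r", 1:3)
  tabp <- ft_from_matrix(v2, subject = rep("S1", 3), replicate = 1:3)
  outp <- replicate_consensus(tabp)
  n_det <- rowSums(pats)
  expect_identical(unname(outp$values[, 1] > 0), unname(n_det >= 2))
  expect_error(replicate_consensus(ft_from_matrix(v[, 1, drop = FALSE],
                                                  subject = "S1",
                                                  replicate = 1L)),
               "fewer than 2")
})

test_that("prevalence filter uses a ceiling rule at the subject level", {
  n_sub <- 101
  v <- matrix(0, 3, n_sub)
  v[1, 1:16] <- 1e6   # 16 of 101 >= ceil(0.15*101)=16 -> kept
  v[2, 1:15] <- 1e6   # 15 -> removed
  rownames(v) <- paste0("F", 1:3)
  colnames(v) <- paste0("S", 1:n_sub)
  tab <- ft_from_matrix(v)
  out <- prevalence_filter(tab, 0.15)
  expect_identical(out$features$feature_id, "pos_F1")
  expect_equal(attr(out, "n_removed"), 2L)
  # min_fraction = 0 is the identity
  expect_equal(nrow(prevalence_filter(tab, 0)$values), 3L)
  # monotone: 15% output is a subset of 5% output
  set.seed(3)
  v2 <- matrix(rbinom(50 * n_sub, 1, 0.2) * 1e6, 50, n_sub)
  rownames(v2) <- paste0("G", 1:50); colnames(v2) <- paste0("S", 1:n_sub)
  t2 <- ft_from_matrix(v2)
  k15 <- prevalence_filter(t2, 0.15)$features$feature_id
  k05 <- prevalence_filter(t2, 0.05)$features$feature_id
  expect_true(all(k15 %in% k05))
})

test_that("imputation replaces zeros with lod/5 and touches nothing else", {
  v <- matrix(c(0, 5e6, 0, 1e7), 2, 2)
  rownames(v) <- c("F1", "F2"); colnames(v) <- c("A", "B")
  out <- impute_missing(ft_from_matrix(v))
  expect_equal(unname(out$values[1, 1]), 200000)
  expect_equal(unname(out$values[2, 1]), 5e6)
  allzero <- impute_missing(ft_from_matrix(matrix(0, 1, 2,
    dimnames = list("F1", c("A", "B")))))
  expect_equal(unname(allzero$values[1, ]), c(2e5, 2e5))
})

test_that("log/Pareto scaling centres features and preserves sd identity", {
  set.seed(11)
  v <- matrix(10^runif(40, 5, 8), 4, 10)
  rownames(v) <- paste0("F", 1:4); colnames(v) <- paste0("S", 1:10)
  v[4, ] <- 1e6  # constant feature
  out <- log_pareto(ft_from_matrix(v))
  expect_true(all(abs(rowMeans(out$values)) < 1e-12))
  # variance of a Pareto-scaled feature equals the sd of the logged feature
  for (i in 1:3)
    expect_equal(var(out$values[i, ]), sd(log10(v[i, ])), tolerance = 1e-10)
  expect_equal(unname(out$values[4, ]), rep(0, 10))
  expect_error(log_pareto(ft_from_matrix(matrix(c(0, 1), 1, 2,
    dimnames = list("F1", c("A", "B"))))), "positive")
})

test_that("QC RSD report flags identical and noisy QC columns correctly", {
  base <- c(1e6, 2e6, 3e6)
  v <- cbind(q1 = base, q2 = base, s1 = base * 2)
  rownames(v) <- paste0("F", 1:3)
  tab <- ft_from_matrix(v, qc = c(TRUE, TRUE, FALSE))
  rep0 <- qc_rsd_report(tab)
  expect_equal(unname(rep0$per_feature), rep(0, 3))
  expect_error(qc_rsd_report(ft_from_matrix(v, qc = c(TRUE, FALSE, FALSE))),
               "2 QC")
  # known injected noise: median RSD within +-20%
  set.seed(14)
  n_qc <- 60
  mu <- 10^runif(200, 6.3, 7.5)
  noise_sd <- 0.05
  vq <- vapply(seq_len(n_qc), function(i) 10^(log10(mu) + rnorm(200, 0, noise_sd)),
               numeric(200))
  rownames(vq) <- paste0("F", 1:200); colnames(vq) <- paste0("q", 1:n_qc)
  tq <- ft_from_matrix(vq, qc = rep(TRUE, n_qc))
  expected_rsd <- sqrt(exp((noise_sd * log(10))^2) - 1)
  expect_equal(qc_rsd_report(tq)$median, expected_rsd, tolerance = 0.2)
})
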