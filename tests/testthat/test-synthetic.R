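test_that("phenotype generation reproduces the cohort composition", {
  ph <- generate_phenotypes(101, seed = 4)
  expect_equal(nrow(ph), 101L)
  expect_equal(sum(ph$gender == "female"), 50L)
  expect_equal(sum(ph$oc_use), 16L)
  expect_false(any(ph$oc_use & ph$gender == "male"))
  expect_equal(as.vector(table(ph$diet)[c("flexitarian", "vegetarian", "vegan")]),
               c(68L, 28L, 5L))
  expect_equal(sum(ph$coffee), 92L)
  expect_equal(sum(ph$smoking), 10L)
  expect_equal(as.vector(table(ph$alcohol)[c("regular", "occasional", "none")]),
               c(53L, 28L, 20L))
  # reproducible under the same seed
  expect_identical(ph, generate_phenotypes(101, seed = 4))
})

test_that("panel generation records the planted-effect manifest", {
  spec <- list(list(covariate = "gender", level = "female", n = 30,
                    fold = c(2, 4)))
  panel <- generate_panel(200, spec, seed = 1)
  expect_equal(nrow(panel$panel), 200L)
  expect_equal(sum(panel$effects$covariate == "gender"), 30L)
  expect_true(all(panel$effects$fold >= 2 & panel$effects$fold <= 4))
  expect_false(anyDuplicated(panel$panel$formula) > 0)
  expect_identical(panel, generate_panel(200, spec, seed = 1))
  # no-effect spec leaves an empty manifest
  expect_equal(nrow(generate_panel(50, list(), seed = 1)$effects), 0L)
  expect_error(generate_panel(10, spec, seed = 1), "more affected")
})

test_that("sub-LOD metabolites drop out and zero jitter gives exact m/z", {
  design <- cohort_design(n_subjects = 1, ppm_noise_sd = 0,
                          cal_offset_ppm_sd = 0, noise_sd = 0, seed = 1)
  panel <- generate_panel(30, list(), seed = 2)
  panel$panel$detection_prob <- 1
  panel$panel$mode_eff_pos <- 1
  panel$panel$base_log_intensity[1:10] <- 4   # far below the 1e6 LOD
  panel$panel$base_log_intensity[11:30] <- 8
  ph <- generate_phenotypes(1, seed = 1)
  set.seed(3)
  acq <- simulate_sample(ph[1, ], panel, design, dilution = 1)
  pos <- acq[["positive.small"]]
  theo <- vapply(panel$panel$formula[11:30],
                 function(f) theoretical_mz(f, "[M+H]+"), numeric(1))
  in_window <- theo >= 95 & theo <= 1500
  # every above-LOD monoisotopic peak present at its exact theoretical m/z
  expect_true(all(vapply(theo[in_window], function(m)
    any(abs(pos$peaks$mz - m) < 1e-9), logical(1))))
  # no sub-LOD metabolite leaks through
  low <- vapply(panel$panel$formula[1:10],
                function(f) theoretical_mz(f, "[M+H]+"), numeric(1))
  expect_false(any(vapply(low, function(m)
    any(abs(pos$peaks$mz - m) < 0.01), logical(1))))
  expect_true(all(pos$peaks$intensity >= design$lod))
})

test_that("planted fold-2 gender effect is recovered in group means", {
  spec <- list(list(covariate = "gender", level = "female", n = 5,
                    fold = c(2, 2)))
  panel <- generate_panel(50, spec, seed = 6)
  ph <- generate_phenotypes(240, seed = 6)
  tab <- simulate_intensity_matrix(panel, ph, noise_sd = 0.1, lod = 0, seed = 7)
  markers <- match(panel$effects$db_id, panel$panel$db_id)
  fem <- ph$gender == "female"
  ratio <- rowMeans(tab$values[markers, fem]) / rowMeans(tab$values[markers, !fem])
  expect_true(all(abs(ratio - 2) < 0.2))
})

test_that("study layout: acquisition counts and QC schedule", {
  design <- cohort_design(n_subjects = 10, replicates_per_subject = 3, seed = 9)
  study <- simulate_study(design, generate_panel(40, list(), seed = 9))
  expect_equal(sum(!study$sequence$qc), 10 * 3 * 2 * 2)
  # QC positions for a 26-sample sequence at interval 12
  expect_equal(qc_positions(26, 12), c(0L, 12L, 24L, 26L))
  # per mode x method sequence: QCs at start, after 12, 24, and end (30)
  seq1 <- study$sequence[study$sequence$mode == "positive" &
                         study$sequence$method == "small", ]
  expect_equal(which(seq1$qc), c(1L, 14L, 27L, 34L))
})

test_that("identical design and seed give identical studies", {
  design <- cohort_design(n_subjects = 3, seed = 21)
  s1 <- simulate_study(design, generate_panel(60, seed = 21))
  s2 <- simulate_study(design, generate_panel(60, seed = 21))
  expect_identical(s1$peak_lists, s2$peak_lists)
  expect_identical(s1$truth, s2$truth)
})

test_that("QC pools are tighter than analytical replicates", {
  design <- cohort_design(n_subjects = 8, seed = 13)
  study <- simulate_study(design, generate_panel(60, list(), seed = 13))
  key <- vapply(study$peak_lists, function(p) paste(p$mode, p$method, sep = "."), "")
  tab <- build_feature_table(study$peak_lists[key == "positive.small"])
  qc_rsd <- qc_rsd_report(tab)$median
  ana <- tab$values[, !tab$samples$qc, drop = FALSE]
  mu <- rowMeans(ana)
  ana_rsd <- stats::median(ifelse(mu > 0, apply(ana, 1, sd) / mu, NA), na.rm = TRUE)
  expect_lt(qc_rsd, ana_rsd)
})
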