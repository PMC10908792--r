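# Synthetic cohort generator with known ground truth.
#
# Emulates the statistical structure of a direct-infusion FT-ICR breathomics
# study: per-subject phenotypes, a metabolite panel with planted covariate
# effects, per-replicate dilution, batch shifts, log-normal intensity noise,
# detection-limit dropout, sub-ppm m/z jitter, two ionisation modes, two
# overlapping acquisition mass windows, and interleaved pooled-QC injections.

#' Cohort and acquisition design parameters
#'
#' Defaults reproduce the study layout: 101 subjects, 3 breath replicates
#' each, two ionisation modes and two acquisition methods (65-300 and
#' 95-1500 m/z, overlapping 95-300), QC pool injections at the start, after
#' every 12 analytical samples and at the end of each sequence, a detection
#' limit of 1e6 counts, and 0.3 ppm mass jitter.
#'
#' @param n_subjects Number of subjects (default 101).
#' @param replicates_per_subject Breath replicates per subject (default 3).
#' @param n_batches Number of preparation batches (default 2).
#' @param qc_interval Analytical samples between QC injections (default 12).
#' @param mass_ranges Two (low, high) m/z windows.
#' @param ppm_noise_sd Random per-peak m/z jitter, ppm (default 0.3).
#' @param cal_offset_ppm_sd Systematic per-acquisition mass offset, ppm
#'   (default 0.5); this is what recalibration removes.
#' @param lod Detection limit in counts (default 1e6).
#' @param dilution_sd Per-replicate dilution, sd on the log10 scale
#'   (default 0.15); models variable exhaled micro-droplet yield.
#' @param noise_sd Per-measurement intensity noise, log10 sd (default 0.1).
#' @param qc_noise_sd Intensity noise of QC injections, log10 sd (default 0.05).
#' @param batch_sd Batch factor spread, log10 sd (default 0.15).
#' @param seed Integer seed driving all randomness.
#' @return List of class `"cohort_design"`.
#' @export
cohort_design <- function(n_subjects = 101, replicates_per_subject = 3,
                          n_batches = 2, qc_interval = 12,
                          mass_ranges = list(ultra_small = c(65, 300),
                                             small = c(95, 1500)),
                          ppm_noise_sd = 0.3, cal_offset_ppm_sd = 0.5,
                          lod = 1e6, dilution_sd = 0.15, noise_sd = 0.1,
                          qc_noise_sd = 0.05, batch_sd = 0.15, seed = 1) {
  stopifnot(replicates_per_subject >= 2, n_subjects >= 1, qc_interval >= 1)
  structure(as.list(environment()), class = "cohort_design")
}

.table1_proportions <- list(
  female = 50 / 101,
  oc_use_in_females = 16 / 50,
  allergies = 15 / 101,
  diet = c(flexitarian = 68, vegetarian = 28, vegan = 5) / 101,
  supplements = 45 / 101,
  activity = c(regular = 56, occasional = 34, none = 11) / 101,
  coffee = 92 / 101,
  smoking = 10 / 101,
  alcohol = c(regular = 53, occasional = 28, none = 20) / 101
)

# n category labels with counts proportional to p, randomly permuted
.alloc <- function(n, p) {
  counts <- floor(p * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(p * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  sample(rep(names(p), counts))
}

#' Generate subject phenotypes
#'
#' Category frequencies default to the study cohort's proportions (50/101
#' female with 16/50 on oral contraceptives, 68/28/5 flexitarian/vegetarian/
#' vegan, 92/101 coffee drinkers, 10/101 smokers, 53/28/20 regular/
#' occasional/no alcohol, 56/34/11 activity levels, 45/101 supplements,
#' 15/101 allergies).
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param proportions Override list in the shape of the default.
#' @return `data.frame` with one row per subject.
#' @export
generate_phenotypes <- function(n_subjects = 101, seed = 1,
                                proportions = .table1_proportions) {
  set.seed(seed)
  p <- proportions
  gender <- .alloc(n_subjects, c(female = p$female, male = 1 - p$female))
  oc <- rep(FALSE, n_subjects)
  fem <- which(gender == "female")
  if (length(fem))
    oc[fem] <- .alloc(length(fem), c(`TRUE` = p$oc_use_in_females,
                                     `FALSE` = 1 - p$oc_use_in_females)) == "TRUE"
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    gender = gender,
    oc_use = oc,
    alcohol = .alloc(n_subjects, p$alcohol),
    smoking = .alloc(n_subjects, c(`TRUE` = p$smoking, `FALSE` = 1 - p$smoking)) == "TRUE",
    coffee = .alloc(n_subjects, c(`TRUE` = p$coffee, `FALSE` = 1 - p$coffee)) == "TRUE",
    diet = .alloc(n_subjects, p$diet),
    activity = .alloc(n_subjects, p$activity),
    supplements = .alloc(n_subjects, c(`TRUE` = p$supplements,
                                       `FALSE` = 1 - p$supplements)) == "TRUE",
    allergies = .alloc(n_subjects, c(`TRUE` = p$allergies,
                                     `FALSE` = 1 - p$allergies)) == "TRUE",
    stringsAsFactors = FALSE
  )
}

.main_classes <- c(
  "Amino acids, peptides, and analogues" = 0.20,
  "Fatty acids and conjugates"           = 0.15,
  "Carbohydrates and conjugates"         = 0.12,
  "Organic acids and derivatives"        = 0.12,
  "Benzenoids"                           = 0.08,
  "Glycerophospholipids"                 = 0.08,
  "Organoheterocyclic compounds"         = 0.08,
  "Carnitines"                           = 0.06,
  "Purines and purine derivatives"       = 0.06,
  "Alkaloids and derivatives"            = 0.05
)

# random small-molecule-like formula with neutral mass in [65, 1490]
.random_formula <- function() {
  repeat {
    c_n <- sample(2:32, 1)
    h_n <- sample(seq(max(3, floor(c_n / 2)), 2 * c_n + 2), 1)
    n_n <- sample(0:3, 1, prob = c(0.45, 0.3, 0.15, 0.1))
    o_n <- sample(0:8, 1)
    s_n <- stats::rbinom(1, 1, 0.12)
    p_n <- stats::rbinom(1, 1, 0.08)
    counts <- c(C = c_n, H = h_n, N = n_n, O = o_n, S = s_n, P = p_n)
    counts <- counts[counts > 0]
    f <- format_formula(structure(as.integer(counts), names = names(counts),
                                  class = "chem_formula"))
    m <- monoisotopic_mass(f)
    if (m >= 65 && m <= 1490) return(f)
  }
}

#' Default planted-effect specification
#'
#' 30 gender markers at fold 2-4, 10 oral-contraceptive markers at fold
#' 1.5-2.5 (within females), 6 alcohol-abstinence markers at fold 2-3 —
#' mirroring the kinds and magnitudes of group differences the study design
#' probes (e.g. a fold change of 2.89 for the strongest gender marker).
#'
#' @param gender_fold Fold-change range for gender markers.
#' @param n_gender Number of gender-affected metabolites.
#' @return List of effect entries (`covariate`, `level`, `n`, `fold`).
#' @export
default_effects <- function(gender_fold = c(2, 4), n_gender = 30) {
  list(
    list(covariate = "gender", level = "female", n = n_gender, fold = gender_fold),
    list(covariate = "oc_use", level = "TRUE", n = 10, fold = c(1.5, 2.5)),
    list(covariate = "alcohol", level = "none", n = 6, fold = c(2, 3))
  )
}

#' Generate a ground-truth metabolite panel
#'
#' Draws `n_metabolites` distinct molecular formulas with base intensities,
#' per-polarity ionisation efficiencies, detection probabilities and chemical
#' main classes, and plants multiplicative covariate effects on disjoint
#' subsets per the effect specification. The effect manifest is the recovery
#' ground truth for downstream tests.
#'
#' @param n_metabolites Panel size (default 200).
#' @param effect_spec List of effect entries, see [default_effects()].
#' @param seed Integer seed.
#' @return List of class `"metabolite_panel"` with `panel` (one row per
#'   metabolite) and `effects` (manifest: `db_id`, `covariate`, `level`,
#'   `fold`).
#' @export
generate_panel <- function(n_metabolites = 200, effect_spec = default_effects(),
                           seed = 1) {
  set.seed(seed)
  n_affected <- sum(vapply(effect_spec, `[[`, numeric(1), "n"))
  if (n_affected > n_metabolites)
    stop("more affected metabolites requested than n_metabolites")
  formulas <- character(0)
  while (length(formulas) < n_metabolites)
    formulas <- unique(c(formulas, .random_formula()))
  formulas <- formulas[seq_len(n_metabolites)]
  panel <- data.frame(
    db_id = sprintf("SYN%04d", seq_len(n_metabolites)),
    formula = formulas,
    name = sprintf("synthetic metabolite %03d", seq_len(n_metabolites)),
    main_class = sample(names(.main_classes), n_metabolites, replace = TRUE,
                        prob = .main_classes),
    mass = vapply(formulas, monoisotopic_mass, numeric(1)),
    base_log_intensity = stats::runif(n_metabolites, 6.4, 8.5),
    mode_eff_pos = stats::runif(n_metabolites, 0.1, 1),
    mode_eff_neg = stats::runif(n_metabolites, 0.1, 1),
    detection_prob = stats::runif(n_metabolites, 0.85, 1),
    stringsAsFactors = FALSE
  )
  rownames(panel) <- NULL
  pool <- seq_len(n_metabolites)
  effects <- list()
  for (e in effect_spec) {
    if (e$n == 0) next
    idx <- sample(pool, e$n)
    pool <- setdiff(pool, idx)
    effects[[length(effects) + 1]] <- data.frame(
      db_id = panel$db_id[idx], covariate = e$covariate, level = e$level,
      fold = stats::runif(e$n, e$fold[1], e$fold[2]),
      stringsAsFactors = FALSE
    )
  }
  effects <- if (length(effects)) do.call(rbind, effects) else
    data.frame(db_id = character(), covariate = character(),
               level = character(), fold = numeric(), stringsAsFactors = FALSE)
  structure(list(panel = panel, effects = effects), class = "metabolite_panel")
}

#' Reference list for annotating a synthetic study
#'
#' The panel's metabolites plus decoy formulas (not in the panel), in the
#' TSV reference-list shape used by [annotate_features()].
#'
#' @param panel A [generate_panel()] result.
#' @param n_decoys Number of decoy records (default 100).
#' @param seed Integer seed.
#' @return `data.frame` with `formula`, `name`, `db_id`, `main_class`.
#' @export
synthetic_reference <- function(panel, n_decoys = 100, seed = 1) {
  set.seed(seed)
  decoys <- character(0)
  while (length(decoys) < n_decoys)
    decoys <- setdiff(unique(c(decoys, .random_formula())), panel$panel$formula)
  decoys <- decoys[seq_len(n_decoys)]
  rbind(
    panel$panel[c("formula", "name", "db_id", "main_class")],
    data.frame(formula = decoys,
               name = sprintf("decoy %03d", seq_along(decoys)),
               db_id = sprintf("DEC%04d", seq_along(decoys)),
               main_class = sample(names(.main_classes), n_decoys, replace = TRUE),
               stringsAsFactors = FALSE)
  )
}

#' Calibrant list drawn from a panel
#'
#' The highest-intensity panel metabolites as (formula, adduct) calibrants
#' for both polarities, emulating a local calibration list of ubiquitous
#' matrix metabolites.
#'
#' @param panel A [generate_panel()] result.
#' @param n Calibrants per polarity (default 25).
#' @return `data.frame` with `formula` and `adduct`.
#' @export
synthetic_calibrants <- function(panel, n = 25) {
  p <- panel$panel[order(panel$panel$base_log_intensity, decreasing = TRUE), ]
  p <- p[p$mass < 1000, ]
  top <- utils::head(p, n)
  rbind(data.frame(formula = top$formula, adduct = "[M+H]+", stringsAsFactors = FALSE),
        data.frame(formula = top$formula, adduct = "[M-H]-", stringsAsFactors = FALSE))
}

# per-metabolite expected intensity multiplier for one subject's phenotype
.effect_multiplier <- function(panel, profile) {
  mult <- rep(1, nrow(panel$panel))
  if (!nrow(panel$effects)) return(mult)
  idx <- match(panel$effects$db_id, panel$panel$db_id)
  for (k in seq_len(nrow(panel$effects))) {
    val <- as.character(profile[[panel$effects$covariate[k]]])
    if (identical(val, panel$effects$level[k]))
      mult[idx[k]] <- mult[idx[k]] * panel$effects$fold[k]
  }
  mult
}

# cache ion m/z and principal isotopologues per metabolite and polarity
.panel_ion_cache <- function(panel, iso_floor = 0.01) {
  lapply(c(positive = "positive", negative = "negative"), function(mode) {
    adduct <- if (mode == "positive") "[M+H]+" else "[M-H]-"
    lapply(panel$panel$formula, function(f) {
      pat <- isotope_pattern(f, floor = iso_floor)
      pat <- shift_pattern(pat, adduct)
      pat[pat$abundance >= iso_floor, , drop = FALSE]
    })
  })
}

# one acquisition: vectorized over the panel
.sim_acquisition <- function(expected, panel, cache, design, mode, method,
                             noise_sd) {
  eff <- if (mode == "positive") panel$panel$mode_eff_pos else panel$panel$mode_eff_neg
  mu <- expected * eff
  obs <- 10^(log10(pmax(mu, 1e-12)) + stats::rnorm(length(mu), 0, noise_sd))
  detected <- obs >= design$lod & stats::runif(length(mu)) < panel$panel$detection_prob
  window <- design$mass_ranges[[method]]
  offset <- stats::rnorm(1, 0, design$cal_offset_ppm_sd)
  rows <- which(detected)
  if (!length(rows)) return(data.frame(mz = numeric(), intensity = numeric()))
  pats <- cache[[mode]][rows]
  n_iso <- vapply(pats, nrow, integer(1))
  mz <- unlist(lapply(pats, `[[`, "mz"), use.names = FALSE)
  ab <- unlist(lapply(pats, `[[`, "abundance"), use.names = FALSE)
  intensity <- rep(obs[rows], n_iso) * ab
  keep <- intensity >= design$lod & mz >= window[1] & mz <= window[2]
  mz <- mz[keep]; intensity <- intensity[keep]
  mz <- mz * (1 + (offset + stats::rnorm(length(mz), 0, design$ppm_noise_sd)) * 1e-6)
  data.frame(mz = mz, intensity = intensity)
}

#' Simulate one subject-replicate's acquisitions
#'
#' Produces one peak list per ionisation mode and acquisition method (4 in
#' total). Expected intensity per metabolite is
#' `10^base x planted effects(profile) x dilution x batch factor x mode
#' efficiency`, with log-normal noise; a peak is kept only if it exceeds the
#' detection limit and a detection-probability draw succeeds. Observed m/z
#' carries a per-acquisition systematic offset plus per-peak jitter, and the
#' principal isotopologues of each metabolite are emitted.
#'
#' @param profile One row of [generate_phenotypes()].
#' @param panel A [generate_panel()] result.
#' @param design A [cohort_design()].
#' @param replicate Replicate index.
#' @param dilution Multiplicative dilution factor (default drawn from the
#'   design's `dilution_sd`).
#' @param batch,batch_factor Batch label and multiplicative factor.
#' @param cache Optional ion cache from a previous call (performance).
#' @return Named list of 4 [peak_list()]s (`positive.ultra_small`, ...).
#' @export
simulate_sample <- function(profile, panel, design, replicate = 1L,
                            dilution = NULL, batch = "B1", batch_factor = 1,
                            cache = NULL) {
  if (is.null(cache)) cache <- .panel_ion_cache(panel)
  if (is.null(dilution)) dilution <- 10^stats::rnorm(1, 0, design$dilution_sd)
  expected <- 10^panel$panel$base_log_intensity *
    .effect_multiplier(panel, profile) * dilution * batch_factor
  out <- list()
  for (mode in c("positive", "negative")) {
    for (method in names(design$mass_ranges)) {
      pk <- .sim_acquisition(expected, panel, cache, design, mode, method,
                             design$noise_sd)
      out[[paste(mode, method, sep = ".")]] <- peak_list(
        sample_id = sprintf("%s_r%d", profile$subject_id, replicate),
        mz = pk$mz, intensity = pk$intensity, mode = mode, method = method,
        subject_id = profile$subject_id, replicate = replicate,
        batch = batch, qc = FALSE
      )
    }
  }
  out
}

# QC positions in an analytical sequence: start, after every `interval`
# samples, and at the end.
qc_positions <- function(n_samples, interval) {
  after <- if (n_samples - 1 >= interval)
    seq(interval, n_samples - 1, by = interval) else integer(0)
  unique(c(0L, as.integer(after), n_samples))
}

#' Simulate a full study
#'
#' Generates all analytical acquisitions (subjects x replicates x 2 modes x
#' 2 methods), pooled-QC injections interleaved at the design's schedule
#' (start, after every `qc_interval` samples, end), the phenotype table, and
#' a ground-truth manifest (dilution factors, batch factors, planted
#' effects). All randomness derives from `design$seed`.
#'
#' @param design A [cohort_design()].
#' @param panel A [generate_panel()] result; generated from the design seed
#'   when omitted.
#' @param phenotypes A [generate_phenotypes()] table; generated when omitted.
#' @return List of class `"breath_study"`: `peak_lists`, `phenotypes`,
#'   `panel`, `design`, `truth`, `sequence`.
#' @export
simulate_study <- function(design = cohort_design(), panel = NULL,
                           phenotypes = NULL) {
  set.seed(design$seed)
  if (is.null(panel)) panel <- generate_panel(seed = design$seed)
  if (is.null(phenotypes))
    phenotypes <- generate_phenotypes(design$n_subjects, seed = design$seed)
  set.seed(design$seed + 1L)

  n_sub <- nrow(phenotypes)
  reps <- design$replicates_per_subject
  sample_key <- expand.grid(replicate = seq_len(reps),
                            subject = seq_len(n_sub))[, 2:1]
  n_samp <- nrow(sample_key)

  dilution <- 10^stats::rnorm(n_samp, 0, design$dilution_sd)
  names(dilution) <- sprintf("%s_r%d", phenotypes$subject_id[sample_key$subject],
                             sample_key$replicate)
  batch_factors <- 10^stats::rnorm(design$n_batches, 0, design$batch_sd)
  names(batch_factors) <- sprintf("B%d", seq_len(design$n_batches))
  batch_of <- names(batch_factors)[ceiling(seq_len(n_samp) / (n_samp / design$n_batches))]
  names(batch_of) <- names(dilution)

  eff_mult <- vapply(seq_len(n_sub),
                     function(s) .effect_multiplier(panel, phenotypes[s, ]),
                     numeric(nrow(panel$panel)))
  base <- 10^panel$panel$base_log_intensity
  qc_expected <- base * rowMeans(eff_mult)

  cache <- .panel_ion_cache(panel)
  qpos <- qc_positions(n_samp, design$qc_interval)
  n_qc <- length(qpos)

  peak_lists <- list()
  sequence <- list()
  for (mode in c("positive", "negative")) {
    for (method in names(design$mass_ranges)) {
      pos_in_run <- 0L
      emit_qc <- function(k) {
        pk <- .sim_acquisition(qc_expected, panel, cache, design, mode, method,
                               design$qc_noise_sd)
        # QCs are measured throughout the run; assign the batch of the
        # neighbouring analytical sample
        near <- max(1L, min(n_samp, qpos[k]))
        id <- sprintf("QC%02d", k)
        peak_list(id, pk$mz, pk$intensity, mode = mode, method = method,
                  subject_id = sprintf("QC%02d", k), replicate = NA_integer_,
                  batch = batch_of[near], qc = TRUE)
      }
      for (i in seq_len(n_samp)) {
        qk <- which(qpos == i - 1L)
        if (length(qk)) {
          q <- emit_qc(qk)
          peak_lists[[paste(q$sample_id, mode, method, sep = ".")]] <- q
          sequence[[length(sequence) + 1]] <- data.frame(
            sample_id = q$sample_id, mode = mode, method = method, qc = TRUE)
        }
        skey <- names(dilution)[i]
        profile <- phenotypes[sample_key$subject[i], ]
        expected <- base * eff_mult[, sample_key$subject[i]] * dilution[i] *
          batch_factors[batch_of[i]]
        pk <- .sim_acquisition(expected, panel, cache, design, mode, method,
                               design$noise_sd)
        p <- peak_list(skey, pk$mz, pk$intensity, mode = mode, method = method,
                       subject_id = profile$subject_id,
                       replicate = sample_key$replicate[i],
                       batch = batch_of[i], qc = FALSE)
        peak_lists[[paste(skey, mode, method, sep = ".")]] <- p
        sequence[[length(sequence) + 1]] <- data.frame(
          sample_id = skey, mode = mode, method = method, qc = FALSE)
      }
      qk <- which(qpos == n_samp)
      if (length(qk)) {
        q <- emit_qc(qk)
        peak_lists[[paste(q$sample_id, mode, method, sep = ".")]] <- q
        sequence[[length(sequence) + 1]] <- data.frame(
          sample_id = q$sample_id, mode = mode, method = method, qc = TRUE)
      }
    }
  }
  structure(list(
    peak_lists = peak_lists,
    phenotypes = phenotypes,
    panel = panel,
    design = design,
    truth = list(dilution = dilution, batch_of = batch_of,
                 batch_factors = batch_factors, effects = panel$effects,
                 n_qc_per_sequence = n_qc),
    sequence = do.call(rbind, sequence)
  ), class = "breath_study")
}

#' @export
print.breath_study <- function(x, ...) {
  cat(sprintf("<breath_study> %d subjects x %d replicates; %d acquisitions (%d QC)\n",
              nrow(x$phenotypes), x$design$replicates_per_subject,
              length(x$peak_lists), sum(x$sequence$qc)))
  invisible(x)
}

#' Subject-level expected-intensity matrix with noise (fast path)
#'
#' Direct simulation of a per-subject feature matrix from a panel and
#' phenotypes, bypassing peak lists — the intensity model of
#' [simulate_sample()] marginalised over replicates, used for calibration
#' experiments on the statistics stage (many seeds).
#'
#' @param panel A [generate_panel()] result.
#' @param phenotypes A [generate_phenotypes()] table.
#' @param noise_sd Per-subject log10 noise (default 0.1).
#' @param lod Detection limit; values below become 0.
#' @param seed Integer seed.
#' @return A [feature_table()] (features = panel metabolites, samples =
#'   subjects) on the raw intensity scale.
#' @export
simulate_intensity_matrix <- function(panel, phenotypes, noise_sd = 0.1,
                                      lod = 1e6, seed = 1) {
  set.seed(seed)
  n_sub <- nrow(phenotypes)
  eff <- vapply(seq_len(n_sub),
                function(s) .effect_multiplier(panel, phenotypes[s, ]),
                numeric(nrow(panel$panel)))
  mu <- 10^panel$panel$base_log_intensity * eff
  v <- 10^(log10(mu) + matrix(stats::rnorm(length(mu), 0, noise_sd), nrow(mu)))
  v[v < lod] <- 0
  features <- data.frame(feature_id = panel$panel$db_id,
                         mz = panel$panel$mass, mode = "positive",
                         method = "small", formula = panel$panel$formula,
                         name = panel$panel$name, db_id = panel$panel$db_id,
                         main_class = panel$panel$main_class,
                         key = panel$panel$formula, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = phenotypes$subject_id,
                        subject_id = phenotypes$subject_id,
                        replicate = NA_integer_, batch = NA_character_,
                        qc = FALSE, stringsAsFactors = FALSE)
  feature_table(v, features, samples)
}
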