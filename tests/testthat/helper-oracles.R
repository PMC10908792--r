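# Independent oracles used across the suite.

# 20 formulas with monoisotopic masses computed independently with
# pyteomics.mass.calculate_mass (IUPAC table), frozen here.
oracle_masses <- c(
  H2O = 18.010565, C5H9NO2 = 115.063329, C6H12O6 = 180.063388,
  C9H11NO3 = 181.073893, C4H6O5 = 134.021523, C5H12N2O2 = 132.089878,
  C5H4N4O3 = 168.028340, C3H7NO3 = 105.042593, C5H4N4O = 136.038511,
  C6H8O6 = 176.032088, C14H26O2 = 226.193280, C40H80NO7P = 717.567241,
  C4H8O5 = 136.037173, C6H12O5 = 164.068473, C17H31NO4 = 313.225308,
  C11H12N2O2 = 204.089878, C5H11NO2S = 149.051050, C28H50NO7P = 543.332490,
  C16H31NO4 = 301.225308, C10H19NO4 = 217.131408
)

proton_mass_oracle <- 1.00727646688

# Benjamini-Hochberg step-up written directly from its definition.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Brute-force reference for the ionisation-mode merge rule, operating on
# plain matrices keyed by shared row names (formulas).
merge_modes_brute <- function(vp, vn) {
  keys <- union(rownames(vp), rownames(vn))
  picked <- lapply(keys, function(k) {
    in_p <- k %in% rownames(vp); in_n <- k %in% rownames(vn)
    if (in_p && !in_n) return(c("positive", k))
    if (!in_p && in_n) return(c("negative", k))
    dp <- sum(vp[k, ] > 0); dn <- sum(vn[k, ] > 0)
    if (dp > dn) c("positive", k)
    else if (dn > dp) c("negative", k)
    else if (sum(vp[k, ]) >= sum(vn[k, ])) c("positive", k)
    else c("negative", k)
  })
  stats::setNames(vapply(picked, `[`, "", 1), vapply(picked, `[`, "", 2))
}

# wrap a plain matrix as a single-mode feature table
ft_from_matrix <- function(v, mode = "positive", method = "small",
                           keys = NULL, qc = NULL,
                           subject = colnames(v), replicate = NULL) {
  n <- ncol(v)
  if (is.null(rownames(v))) rownames(v) <- paste0("F", seq_len(nrow(v)))
  if (is.null(keys)) keys <- rownames(v)
  features <- data.frame(
    feature_id = paste0(substr(mode, 1, 3), "_", rownames(v)),
    mz = seq_len(nrow(v)) + 100, mode = mode, method = method,
    formula = keys, name = NA_character_, db_id = NA_character_,
    main_class = NA_character_, key = keys, stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = colnames(v), subject_id = subject,
    replicate = replicate %||% rep(NA_integer_, n),
    batch = "B1", qc = qc %||% rep(FALSE, n), stringsAsFactors = FALSE
  )
  feature_table(v, features, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_mode_table <- function(n_feat, n_samp, mode, prefix = "F") {
  v <- matrix(rpois(n_feat * n_samp, 2) * runif(n_feat * n_samp, 0.5, 2) * 1e6,
              n_feat, n_samp)
  v[runif(length(v)) < 0.4] <- 0
  rownames(v) <- paste0(prefix, seq_len(n_feat))
  colnames(v) <- paste0("S", seq_len(n_samp))
  v
}
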