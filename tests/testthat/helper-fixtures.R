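# fixtures are built in code; nothing is stored on disk

# small ct_matrix from a vector filled by row
mk_ct <- function(vals, n_assays, n_samples, stage = "raw",
                  assays = sprintf("a%02d", seq_len(n_assays)),
                  samples = sprintf("s%02d", seq_len(n_samples))) {
  m <- matrix(vals, nrow = n_assays, ncol = n_samples, byrow = TRUE,
              dimnames = list(assays, samples))
  ct_matrix(m, stage = stage)
}

rand_ct <- function(n_assays, n_samples, seed, mean = 25, sd = 2,
                    stage = "censored", p_missing = 0) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_assays * n_samples, mean, sd),
              nrow = n_assays,
              dimnames = list(sprintf("a%03d", seq_len(n_assays)),
                              sprintf("s%03d", seq_len(n_samples))))
  det <- matrix(stats::runif(length(m)) >= p_missing, nrow = n_assays,
                dimnames = dimnames(m))
  m[!det] <- NA_real_
  ct_matrix(m, detected = det, stage = stage)
}

mk_sheet <- function(n_pat, n_ctl, ...) {
  df <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n_pat + n_ctl)),
    cohort = c(rep("patient", n_pat), rep("control", n_ctl)),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  qpcrstrat:::as_sample_sheet(as.data.frame(lapply(df, as.character),
                                            stringsAsFactors = FALSE))
}

# reference set with per-sample mean zero: turns a plain matrix into delta-CT
zero_ref <- function(samples) {
  structure(list(assay_ids = character(),
                 selection_sd = stats::setNames(numeric(), character()),
                 per_sample_mean = stats::setNames(rep(0, length(samples)),
                                                   samples)),
            class = "reference_set")
}

mk_dct <- function(mat, detected = !is.na(mat)) {
  structure(list(delta_ct = mat, detected = detected,
                 reference = zero_ref(colnames(mat))),
            class = "delta_ct_matrix")
}

# scaled-down cohort configuration for fast module tests
small_sim_config <- function(seed = 1L, ...) {
  args <- list(
    n_patients = 12L, n_controls = 8L, n_assays = 80L, n_de_assays = 5L,
    n_reference_like = 10L, n_subgroup_markers = 2L,
    comorbidity_links = data.frame(flag = "headache", n_assays = 1L,
                                   shift = 1.5, stringsAsFactors = FALSE),
    seed = seed
  )
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  do.call(sim_config, args)
}

# run censor -> filter -> normalize -> reference -> delta-CT in one go
preprocess_cohort <- function(cohort, threshold = 32, min_det_frac = 0.5,
                              ref_size = 10) {
  cen <- censor_undetected(cohort$ct, threshold = threshold)
  filt <- filter_assays(cen, cohort$sheet, min_det_frac = min_det_frac,
                        quiet = TRUE)
  norm <- quantile_normalize(filt)
  ref <- select_reference(norm, size = ref_size)
  list(filt = filt, norm = norm, ref = ref,
       dct = compute_delta_ct(norm, ref),
       dct_raw = compute_delta_ct(filt, rebase_reference(ref, filt)))
}
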