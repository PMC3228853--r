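#' Simulation configuration for a synthetic qPCR cohort
#'
#' Describes a planted-truth cohort emulating the statistical structure of a
#' whole-blood low-density-array study of a chronic pain condition: a
#' patient/control cohort profiled over hundreds of assays, a mostly
#' down-regulated differential signature confined to a subset ("signature")
#' of patients, a small set of near-constant reference-like assays, an
#' analyte (cytokine) panel with a few elevated analytes of which some track
#' reported pain, and comorbidity-linked assays disjoint from the disease
#' signature.
#'
#' Defaults encode the emulated study shape: 41 patients / 20 controls, 758
#' assays, 18 differential assays (90% down-regulated) at a 2-cycle ΔCT
#' shift carried by 60% of patients, measurement noise 0.5 cycles, censoring
#' at 32 cycles, three analytes elevated two-fold of which two target a
#' Spearman correlation of 0.6 with the 0-10 pain score.
#'
#' @param n_patients,n_controls cohort sizes.
#' @param n_assays total assays on the array.
#' @param n_de_assays planted differential assays (full shift).
#' @param frac_down fraction of planted effects that are down-regulated
#'   (CT shifted up).
#' @param signature_frac fraction of patients carrying the signature.
#' @param de_shift_cycles planted |ΔCT| shift in carriers, cycles.
#' @param noise_sd_cycles measurement noise SD on the CT scale (the standard
#'   qPCR error model: Gaussian on CT, i.e. log-scale of abundance).
#' @param n_reference_like near-constant assays (noise SD / 10).
#' @param censor_threshold CT censoring limit, cycles.
#' @param baseline_ct_range range of per-assay baseline CT (uniform draw).
#' @param analytes data frame with columns `analyte`, `control_mean` (pg/mL),
#'   `cv`, `patient_shift` (multiplicative).
#' @param pain_corr_analytes analyte names tied to the latent pain severity.
#' @param pain_target_rho target Spearman correlation between pain score and
#'   the pain-linked analytes.
#' @param n_subgroup_markers signature-subgroup-only markers planted at half
#'   the main shift.
#' @param comorbidity_links data frame with columns `flag`, `n_assays`,
#'   `shift`: per binary flag, how many (disjoint, non-signature) assays are
#'   shifted in flag carriers of both cohorts.
#' @param flags data frame with columns `flag`, `p_patient`, `p_control`:
#'   binary covariate prevalences.
#' @param seed RNG seed stored with the configuration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 41L, n_controls = 20L, n_assays = 758L,
                       n_de_assays = 18L, frac_down = 0.9,
                       signature_frac = 0.60, de_shift_cycles = 2.0,
                       noise_sd_cycles = 0.5, n_reference_like = 20L,
                       censor_threshold = 32, baseline_ct_range = c(20, 31),
                       analytes = default_analyte_spec(),
                       pain_corr_analytes = c("VEGF", "IL1Ra"),
                       pain_target_rho = 0.6, n_subgroup_markers = 5L,
                       comorbidity_links = default_comorbidity_links(),
                       flags = default_flag_spec(), seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              n_assays = as.integer(n_assays),
              n_de_assays = as.integer(n_de_assays),
              frac_down = frac_down, signature_frac = signature_frac,
              de_shift_cycles = de_shift_cycles,
              noise_sd_cycles = noise_sd_cycles,
              n_reference_like = as.integer(n_reference_like),
              censor_threshold = censor_threshold,
              baseline_ct_range = as.numeric(baseline_ct_range),
              analytes = analytes, pain_corr_analytes = pain_corr_analytes,
              pain_target_rho = pain_target_rho,
              n_subgroup_markers = as.integer(n_subgroup_markers),
              comorbidity_links = comorbidity_links, flags = flags,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_patients < 2L || n_controls < 2L) qs_stop("cohorts need >= 2 samples")
    for (f in c("frac_down", "signature_frac")) {
      v <- cfg[[f]]
      if (!is_scalar_number(v) || v < 0 || v > 1) {
        qs_stop("'", f, "' must be in [0, 1]")
      }
    }
    if (!is.finite(de_shift_cycles)) qs_stop("'de_shift_cycles' must be finite")
    if (noise_sd_cycles <= 0) qs_stop("'noise_sd_cycles' must be positive")
    if (censor_threshold <= 0) qs_stop("'censor_threshold' must be positive")
    if (length(baseline_ct_range) != 2L ||
        baseline_ct_range[1L] >= baseline_ct_range[2L]) {
      qs_stop("'baseline_ct_range' must be an increasing pair")
    }
    n_linked <- if (nrow(comorbidity_links)) sum(comorbidity_links$n_assays) else 0L
    if (n_de_assays + n_reference_like + n_subgroup_markers + n_linked > n_assays) {
      qs_stop("planted assay sets exceed 'n_assays'")
    }
    if (pain_target_rho < 0 || pain_target_rho > 1) {
      qs_stop("'pain_target_rho' must be in [0, 1]")
    }
    bad <- setdiff(pain_corr_analytes, analytes$analyte)
    if (length(bad)) qs_stop("unknown pain-linked analyte '", bad[1L], "'")
    bad <- setdiff(comorbidity_links$flag, flags$flag)
    if (length(bad)) qs_stop("comorbidity link on unknown flag '", bad[1L], "'")
  })
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_analyte_spec <- function() {
  # plasma panel typical of inflammatory-marker studies; three elevated
  # analytes (growth-factor-, receptor-antagonist- and chemokine-like)
  data.frame(
    analyte = c("VEGF", "IL1Ra", "MCP1", "IL6", "IL8", "TNFa", "IL10",
                "IL4", "IL5", "IFNg"),
    control_mean = c(50, 200, 150, 2, 5, 3, 2, 1, 1, 5),
    cv = 0.4,
    patient_shift = c(2, 2, 2, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_flag_spec <- function() {
  # comorbidities balanced across cohorts; medication flags patient-only
  data.frame(
    flag = c("headache", "thyroid_disorder", "high_blood_pressure",
             "narcotics", "antiepileptics"),
    p_patient = c(0.35, 0.20, 0.30, 0.55, 0.40),
    p_control = c(0.35, 0.20, 0.30, 0.00, 0.00),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_comorbidity_links <- function() {
  # comorbidity-shifted assays sit on cohort-balanced flags only, so they do
  # not masquerade as disease signature
  data.frame(
    flag = c("headache", "thyroid_disorder"),
    n_assays = c(2L, 2L),
    shift = c(1.5, 1.5),
    stringsAsFactors = FALSE
  )
}

#' Simulate a seeded synthetic cohort with recorded ground truth
#'
#' Generative model on the CT scale:
#' `CT(i, s) = baseline_i + effect_i * [s in signature] * [i planted]
#'  + comorbidity terms + Normal(0, noise_sd)`, with per-assay baselines
#' uniform on `baseline_ct_range`, down-regulated effects `+de_shift` (with
#' probability `frac_down`) and up-regulated `-de_shift` otherwise, and
#' reference-like assays at a tenth of the noise SD. Values at or above the
#' censoring threshold are marked undetected. Assays carrying planted effects
#' are drawn from baselines low enough that the shifted values stay below the
#' censoring limit (a planted signature must be quantifiable to be a
#' signature). Analytes are log-normal with multiplicative patient shifts;
#' patients' 0-10 pain scores derive from a latent severity that also loads
#' on the pain-linked analytes through a Gaussian copula calibrated to the
#' target Spearman rho.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return A list of class `sim_cohort` with elements `ct` ([ct_matrix],
#'   stage raw with censored cells already masked), `sheet`
#'   (`sample_sheet`), `panel` (`analyte_panel`) and `truth` (`sim_truth`:
#'   the planted-effect ledger).
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  seed <- as.integer(seed %||% config$seed)
  set.seed(seed)
  cfg <- config

  patients <- sprintf("P%03d", seq_len(cfg$n_patients))
  controls <- sprintf("C%03d", seq_len(cfg$n_controls))
  samples <- c(patients, controls)
  assays <- sprintf("miR-%04d", seq_len(cfg$n_assays))

  baseline <- stats::runif(cfg$n_assays, cfg$baseline_ct_range[1L],
                           cfg$baseline_ct_range[2L])
  names(baseline) <- assays

  # assays eligible to carry an effect: shifted values must stay comfortably
  # below the censoring limit
  margin <- cfg$censor_threshold - abs(cfg$de_shift_cycles) -
    2 * cfg$noise_sd_cycles
  eligible <- assays[baseline <= margin]
  n_linked <- if (nrow(cfg$comorbidity_links)) {
    sum(cfg$comorbidity_links$n_assays)
  } else 0L
  need <- cfg$n_de_assays + cfg$n_subgroup_markers + n_linked
  if (length(eligible) < need) {
    qs_stop("only ", length(eligible), " assays below the censoring margin; ",
            "need ", need, " to place planted effects")
  }
  planted <- sample(eligible, need)
  de_assays <- planted[seq_len(cfg$n_de_assays)]
  sub_assays <- planted[cfg$n_de_assays + seq_len(cfg$n_subgroup_markers)]
  link_pool <- planted[cfg$n_de_assays + cfg$n_subgroup_markers +
                         seq_len(n_linked)]
  ref_like <- sample(setdiff(assays, planted), cfg$n_reference_like)

  sign_of <- function(ids, shift) {
    n_down <- round(cfg$frac_down * length(ids))
    down <- if (length(ids)) sample(ids, n_down) else character()
    stats::setNames(ifelse(ids %in% down, shift, -shift), ids)
  }
  de_shift <- sign_of(de_assays, cfg$de_shift_cycles)
  sub_shift <- sign_of(sub_assays, cfg$de_shift_cycles / 2)

  signature <- if (cfg$n_de_assays || cfg$n_subgroup_markers) {
    sort(sample(patients, round(cfg$signature_frac * cfg$n_patients)))
  } else character()

  # binary covariates
  flags <- cfg$flags
  flag_mat <- vapply(seq_len(nrow(flags)), function(i) {
    c(stats::rbinom(cfg$n_patients, 1L, flags$p_patient[i]),
      stats::rbinom(cfg$n_controls, 1L, flags$p_control[i]))
  }, integer(length(samples)))
  colnames(flag_mat) <- flags$flag
  rownames(flag_mat) <- samples

  # comorbidity-linked assays (disjoint from the disease signature)
  links <- list()
  used <- 0L
  if (nrow(cfg$comorbidity_links)) {
    for (i in seq_len(nrow(cfg$comorbidity_links))) {
      k <- cfg$comorbidity_links$n_assays[i]
      ids <- link_pool[used + seq_len(k)]
      used <- used + k
      links[[i]] <- data.frame(flag = cfg$comorbidity_links$flag[i],
                               assay = ids,
                               shift = cfg$comorbidity_links$shift[i],
                               stringsAsFactors = FALSE)
    }
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(flag = character(), assay = character(), shift = numeric())

  # CT matrix
  sd_vec <- rep(cfg$noise_sd_cycles, cfg$n_assays)
  sd_vec[match(ref_like, assays)] <- cfg$noise_sd_cycles / 10
  ct <- matrix(stats::rnorm(cfg$n_assays * length(samples), sd = sd_vec),
               nrow = cfg$n_assays, ncol = length(samples),
               dimnames = list(assays, samples))
  ct <- ct + baseline
  carrier <- samples %in% signature
  for (a in names(de_shift)) ct[a, carrier] <- ct[a, carrier] + de_shift[[a]]
  for (a in names(sub_shift)) ct[a, carrier] <- ct[a, carrier] + sub_shift[[a]]
  if (nrow(links)) {
    for (i in seq_len(nrow(links))) {
      on <- flag_mat[, links$flag[i]] == 1L
      ct[links$assay[i], on] <- ct[links$assay[i], on] + links$shift[i]
    }
  }
  detected <- ct < cfg$censor_threshold
  ctm <- ct_matrix(ct, detected = detected, stage = "raw")

  # clinical sheet
  severity <- stats::rnorm(cfg$n_patients)
  pain <- pmin(10, pmax(0, round(6 + 2 * severity)))
  sheet_df <- data.frame(
    sample_id = samples,
    cohort = c(rep("patient", cfg$n_patients), rep("control", cfg$n_controls)),
    pain_nrs = c(pain, rep(NA_real_, cfg$n_controls)),
    crps_type = c(sample(c(1, 2), cfg$n_patients, replace = TRUE,
                         prob = c(0.8, 0.2)), rep(NA_real_, cfg$n_controls)),
    duration_years = c(round(stats::rexp(cfg$n_patients, 1 / 5), 1),
                       rep(NA_real_, cfg$n_controls)),
    bmi = round(c(stats::rnorm(cfg$n_patients, 28.6, 4),
                  stats::rnorm(cfg$n_controls, 24.1, 3)), 1),
    stringsAsFactors = FALSE
  )
  for (f in flags$flag) sheet_df[[f]] <- flag_mat[, f]
  sheet <- as_sample_sheet(as.data.frame(lapply(sheet_df, as.character),
                                         stringsAsFactors = FALSE))

  # analyte panel: log-normal, patient shifts multiplicative; pain-linked
  # analytes share the latent severity (Gaussian copula, Pearson latent
  # correlation 2*sin(pi*rho/6) targets the Spearman rho)
  r_lat <- 2 * sin(pi * cfg$pain_target_rho / 6)
  spec <- cfg$analytes
  panel_df <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  is_patient <- seq_along(samples) <= cfg$n_patients
  for (i in seq_len(nrow(spec))) {
    sdlog <- sqrt(log(1 + spec$cv[i]^2))
    e <- stats::rnorm(length(samples))
    lat <- e
    if (spec$analyte[i] %in% cfg$pain_corr_analytes && cfg$pain_target_rho > 0) {
      lat[is_patient] <- r_lat * severity + sqrt(1 - r_lat^2) * e[is_patient]
    }
    conc <- exp(log(spec$control_mean[i]) + sdlog * lat)
    conc[is_patient] <- conc[is_patient] * spec$patient_shift[i]
    panel_df[[spec$analyte[i]]] <- conc
  }
  panel <- structure(panel_df, class = c("analyte_panel", "data.frame"))

  truth <- structure(list(
    seed = seed,
    de_assays = de_shift,
    subgroup_markers = sub_shift,
    signature_samples = signature,
    reference_like = sort(ref_like),
    comorbidity_links = links,
    analyte_shifts = stats::setNames(spec$patient_shift, spec$analyte),
    pain_corr_analytes = cfg$pain_corr_analytes,
    pain_target_rho = cfg$pain_target_rho
  ), class = "sim_truth")

  structure(list(ct = ctm, sheet = sheet, panel = panel, truth = truth),
            class = "sim_cohort")
}

#' Simulate a global-null cohort
#'
#' Convenience wrapper around [simulate_cohort()] with every effect zeroed:
#' no differential assays, no subgroup markers, no analyte shifts, no
#' pain-analyte coupling, no comorbidity-linked assays. Cohort sizes, assay
#' count, censoring, noise and covariate structure are preserved.
#'
#' @inheritParams simulate_cohort
#' @return A `sim_cohort` whose truth lists no planted effects.
#' @export
simulate_null <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cfg$n_de_assays <- 0L
  cfg$n_subgroup_markers <- 0L
  cfg$analytes$patient_shift <- 1
  cfg$pain_target_rho <- 0
  cfg$comorbidity_links <- cfg$comorbidity_links[0L, , drop = FALSE]
  simulate_cohort(cfg, seed = seed)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> seed=%d: %d assays x %d samples, %d DE + %d subgroup markers\n",
              x$truth$seed, nrow(x$ct$ct), ncol(x$ct$ct),
              length(x$truth$de_assays), length(x$truth$subgroup_markers)))
  invisible(x)
}

#' Write / read the ground-truth ledger
#'
#' Serializes a `sim_truth` to JSON and back losslessly, so recovery tests
#' can reload the planted effects without rerunning the generator.
#'
#' @param truth a `sim_truth`.
#' @param path JSON path.
#' @return `write_truth`: `path` invisibly; `read_truth`: the `sim_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  ser <- unclass(truth)
  # named numeric vectors must become objects, not arrays, to keep names
  for (f in c("de_assays", "subgroup_markers", "analyte_shifts")) {
    ser[[f]] <- as.list(ser[[f]])
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("de_assays", "subgroup_markers", "analyte_shifts")) {
    x[[f]] <- unlist(x[[f]]) %||% stats::setNames(numeric(), character())
    if (is.null(x[[f]])) x[[f]] <- stats::setNames(numeric(), character())
  }
  x$comorbidity_links <- as.data.frame(x$comorbidity_links,
                                       stringsAsFactors = FALSE)
  if (!nrow(x$comorbidity_links)) {
    x$comorbidity_links <- data.frame(flag = character(), assay = character(),
                                      shift = numeric())
  }
  x$signature_samples <- as.character(x$signature_samples %||% character())
  x$reference_like <- as.character(x$reference_like %||% character())
  x$pain_corr_analytes <- as.character(x$pain_corr_analytes %||% character())
  x$seed <- as.integer(x$seed)
  structure(x, class = "sim_truth")
}

#' Write the simulated cohort artifacts as delimited text
#'
#' Writes `ct.tsv`, `samples.tsv`, `analytes.tsv` and `truth.json` into
#' `dir`; byte-identical across runs for a fixed seed and configuration.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ct = file.path(dir, "ct.tsv"),
             samples = file.path(dir, "samples.tsv"),
             analytes = file.path(dir, "analytes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_ct_table(cohort$ct, paths[["ct"]])
  write_result_table(as.data.frame(cohort$sheet), paths[["samples"]])
  write_result_table(as.data.frame(cohort$panel), paths[["analytes"]])
  write_truth(cohort$truth, paths[["truth"]])
  invisible(paths)
}
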