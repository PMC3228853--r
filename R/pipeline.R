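#' Default pipeline configuration
#'
#' All tunable thresholds of the pipeline with their defaults; every
#' effective value is recorded in the run manifest so unstated analysis
#' choices stay auditable per run.
#'
#' @return A nested list: `simulate` (logical or a list of [sim_config()]
#'   overrides), `inputs` (paths `ct`, `samples`, `analytes` when not
#'   simulating), `seed`, and the stage parameters `censor_threshold`,
#'   `min_det_frac`, `ref_size`, `ref_stage` ("normalized" or "censored"),
#'   `fc_source` ("raw" or "normalized"), `test_source`, `variant`
#'   ("student"/"welch"), `q_threshold`, `k`, `metric`, `linkage`, `alpha`,
#'   `cor_min_n`, `cor_samples`.
#' @export
default_pipeline_config <- function() {
  list(
    simulate = TRUE,
    inputs = list(ct = NULL, samples = NULL, analytes = NULL),
    seed = 1L,
    censor_threshold = 32,
    min_det_frac = 0.5,
    ref_size = 10L,
    ref_stage = "normalized",
    fc_source = "raw",
    test_source = "normalized",
    variant = "student",
    q_threshold = 0.05,
    k = 3L,
    metric = "euclidean",
    linkage = "average",
    alpha = 0.01,
    cor_min_n = 5L,
    cor_samples = "patients"
  )
}

merge_config <- function(user, base = default_pipeline_config()) {
  if (is.null(user)) return(base)
  bad <- setdiff(names(user), names(base))
  if (length(bad)) qs_stop("unknown config key: '", bad[1L], "'")
  for (k in names(user)) base[[k]] <- user[[k]]
  base
}

#' Run the full pipeline from one configuration
#'
#' Executes simulate (optional) -> preprocess -> differential -> stratify ->
#' correlate -> report, writing every stage artifact plus a JSON run manifest
#' (config snapshot, seed, per-file MD5 digests) into `out_dir`. Any stage
#' failure aborts with an error naming the stage. Given a fixed seed and
#' configuration, all outputs are byte-reproducible.
#'
#' @param config a (possibly partial) configuration list merged over
#'   [default_pipeline_config()], or a path to a JSON file with the same
#'   structure.
#' @param out_dir output directory, created if needed.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  counts <- list()

  # --- simulate / load inputs -------------------------------------------
  if (isTRUE(cfg$simulate) || is.list(cfg$simulate)) {
    sim_over <- if (is.list(cfg$simulate)) cfg$simulate else list()
    sim_over$seed <- sim_over$seed %||% cfg$seed
    sc <- stage("simulate", do.call(sim_config, sim_over))
    cohort <- stage("simulate", simulate_cohort(sc))
    paths <- stage("simulate", write_cohort(cohort, out_dir))
    outputs <- c(outputs, paths)
    ct <- cohort$ct; sheet <- cohort$sheet; panel <- cohort$panel
  } else {
    ct <- stage("load", {
      if (is.null(cfg$inputs$ct)) qs_stop("config 'inputs$ct' is missing")
      read_ct_table(cfg$inputs$ct)
    })
    sheet <- stage("load", {
      if (is.null(cfg$inputs$samples)) qs_stop("config 'inputs$samples' is missing")
      read_sample_sheet(cfg$inputs$samples)
    })
    panel <- stage("load", {
      if (is.null(cfg$inputs$analytes)) NULL else
        read_analyte_panel(cfg$inputs$analytes)
    })
  }

  # --- preprocess -------------------------------------------------------
  res <- stage("preprocess", {
    cen <- censor_undetected(ct, threshold = cfg$censor_threshold)
    filt <- filter_assays(cen, sheet, min_det_frac = cfg$min_det_frac,
                          quiet = TRUE)
    norm <- quantile_normalize(filt)
    ref <- select_reference(if (cfg$ref_stage == "normalized") norm else filt,
                            size = cfg$ref_size)
    dct_norm <- compute_delta_ct(norm, rebase_reference(ref, norm))
    dct_raw <- compute_delta_ct(filt, rebase_reference(ref, filt))
    list(filt = filt, norm = norm, ref = ref,
         dct_norm = dct_norm, dct_raw = dct_raw)
  })
  counts$assays_total <- nrow(ct$ct)
  counts$assays_kept <- nrow(res$filt$ct)
  counts$cells_censored <- sum(!res$filt$detected)
  p_norm <- file.path(out_dir, "normalized_ct.tsv")
  write_ct_table(res$norm, p_norm)
  p_ref <- file.path(out_dir, "reference_set.tsv")
  write_result_table(data.frame(assay = res$ref$assay_ids,
                                selection_sd = unname(res$ref$selection_sd)),
                     p_ref)
  p_dct <- file.path(out_dir, "delta_ct.tsv")
  dct_as_ct <- ct_matrix(res$dct_norm$delta_ct, res$dct_norm$detected,
                         stage = "normalized")
  write_ct_table(dct_as_ct, p_dct)
  outputs <- c(outputs, normalized_ct = p_norm, reference_set = p_ref,
               delta_ct = p_dct)

  # --- differential -----------------------------------------------------
  diff_tab <- stage("differential", {
    test_dct <- if (cfg$test_source == "normalized") res$dct_norm else res$dct_raw
    fc_dct <- if (cfg$fc_source == "raw") res$dct_raw else res$dct_norm
    differential_table(test_dct, sheet, fc_dct = fc_dct,
                       q_threshold = cfg$q_threshold, variant = cfg$variant)
  })
  counts$assays_tested <- sum(diff_tab$tested)
  counts$significant_assays <- sum(diff_tab$significant)
  p_diff <- file.path(out_dir, "differential.tsv")
  write_result_table(as.data.frame(diff_tab), p_diff)
  outputs <- c(outputs, differential = p_diff)

  if (!is.null(panel)) {
    an_tab <- stage("differential", {
      analyte_differential(panel, sheet, q_threshold = cfg$q_threshold,
                           variant = cfg$variant)
    })
    counts$significant_analytes <- sum(an_tab$significant)
    p_an <- file.path(out_dir, "analyte_differential.tsv")
    write_result_table(as.data.frame(an_tab), p_an)
    outputs <- c(outputs, analyte_differential = p_an)
  }

  # --- stratify ---------------------------------------------------------
  sig <- diff_tab$assay[diff_tab$significant]
  if (length(sig) >= 2L) {
    strat <- stage("stratify", {
      rel <- relative_expression(res$dct_norm, sheet, sig)
      cl <- cluster_samples(rel, k = cfg$k, metric = cfg$metric,
                            linkage = cfg$linkage)
      comp <- group_composition(cl, sheet)
      sg <- attr(comp, "signature_group")
      sub <- if (!is.na(sg)) {
        test_dct <- if (cfg$test_source == "normalized") res$dct_norm else res$dct_raw
        fc_dct <- if (cfg$fc_source == "raw") res$dct_raw else res$dct_norm
        subgroup_differential(test_dct, sheet, cl, sg, fc_dct = fc_dct,
                              q_threshold = cfg$q_threshold,
                              variant = cfg$variant)
      } else NULL
      list(rel = rel, cl = cl, comp = comp, sub = sub, sg = sg)
    })
    p_lab <- file.path(out_dir, "cluster_labels.tsv")
    write_result_table(data.frame(sample_id = names(strat$cl$labels),
                                  group = unname(strat$cl$labels)), p_lab)
    p_comp <- file.path(out_dir, "group_composition.tsv")
    write_result_table(as.data.frame(strat$comp), p_comp)
    p_hm <- file.path(out_dir, "heatmap_matrix.tsv")
    write_result_table(heatmap_matrix(strat$rel, strat$cl), p_hm)
    outputs <- c(outputs, cluster_labels = p_lab, group_composition = p_comp,
                 heatmap_matrix = p_hm)
    if (!is.null(strat$sub)) {
      p_sub <- file.path(out_dir, "subgroup_differential.tsv")
      write_result_table(as.data.frame(strat$sub), p_sub)
      outputs <- c(outputs, subgroup_differential = p_sub)
    }
    counts$group_sizes <- tabulate(strat$cl$labels, strat$cl$k)
    counts$signature_group <- strat$sg
  } else {
    counts$group_sizes <- NULL
    counts$signature_group <- NA_integer_
  }

  # --- correlate --------------------------------------------------------
  cor_tab <- stage("correlate", {
    correlation_screen(res$dct_norm, sheet, panel, alpha = cfg$alpha,
                       min_n = cfg$cor_min_n, use_samples = cfg$cor_samples)
  })
  counts$correlation_pairs <- nrow(cor_tab)
  counts$kept_pairs <- sum(cor_tab$kept)
  p_cor <- file.path(out_dir, "correlations.tsv")
  write_result_table(as.data.frame(cor_tab), p_cor)
  p_links <- file.path(out_dir, "links.tsv")
  export_links(cor_tab, p_links)
  outputs <- c(outputs, correlations = p_cor, links = p_links)

  # --- manifest + report ------------------------------------------------
  manifest <- list(
    package = "qpcrstrat",
    version = as.character(utils::packageVersion("qpcrstrat")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "inputs")],
    inputs = cfg$inputs,
    counts = counts,
    outputs = lapply(stats::setNames(outputs, names(outputs)), function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  pipeline_report(out_dir)
  invisible(manifest)
}

#' Human-readable run summary
#'
#' Regenerates `report.md` from the artifacts of a completed [run_pipeline()]
#' directory: cohort sizes, reference set, top differential features, group
#' composition (patient-only group highlighted), subgroup-vs-rest additions
#' and top kept correlations. Idempotent; errors list any missing artifact.
#'
#' @param out_dir a pipeline output directory.
#' @return Path of the report, invisibly.
#' @export
pipeline_report <- function(out_dir) {
  man_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(man_path)) qs_stop("incomplete run: missing manifest.json")
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  need <- c("reference_set.tsv", "differential.tsv", "correlations.tsv")
  miss <- need[!file.exists(file.path(out_dir, need))]
  if (length(miss)) qs_stop("incomplete run: missing ",
                            paste(miss, collapse = ", "))

  diff_tab <- read_result_table(file.path(out_dir, "differential.tsv"))
  ref <- read_result_table(file.path(out_dir, "reference_set.tsv"))
  cors <- read_result_table(file.path(out_dir, "correlations.tsv"))

  lines <- c("# qpcrstrat run report", "",
             sprintf("Seed: %s", man$seed),
             sprintf("Assays: %s total, %s kept, %s tested",
                     man$counts$assays_total, man$counts$assays_kept,
                     man$counts$assays_tested),
             sprintf("Censored (undetected) cells after thresholding: %s",
                     man$counts$cells_censored),
             sprintf("Reference set: %d assays, SD range [%.3g, %.3g]",
                     nrow(ref), min(ref$selection_sd), max(ref$selection_sd)),
             "")
  n_sig <- sum(diff_tab$significant, na.rm = TRUE)
  lines <- c(lines, sprintf("## Differential expression: %d significant assays (q < %s)",
                            n_sig, man$config$q_threshold), "")
  if (n_sig > 0) {
    top <- utils::head(diff_tab[diff_tab$significant, ], 10L)
    lines <- c(lines, "| assay | fold change | q |", "|---|---|---|",
               sprintf("| %s | %.3g | %.3g |", top$assay, top$fold_change,
                       top$q), "")
  } else {
    lines <- c(lines, "No significant features at this threshold.", "")
  }

  comp_path <- file.path(out_dir, "group_composition.tsv")
  if (file.exists(comp_path)) {
    comp <- read_result_table(comp_path)
    lines <- c(lines, sprintf("## Stratification (k = %s)", man$config$k), "")
    lines <- c(lines, "| group | patients | controls | patient fraction |",
               "|---|---|---|---|",
               sprintf("| %d%s | %d | %d | %.0f%% |", comp$group,
                       ifelse(comp$patient_only, " (patient-only)", ""),
                       comp$n_patients, comp$n_controls,
                       100 * comp$frac_patients), "")
    sg <- man$counts$signature_group
    if (!is.null(sg) && length(sg) && !is.na(sg)) {
      row <- comp[comp$group == sg, ]
      lines <- c(lines, sprintf(
        "Signature group: group %s, patient-only, %.0f%% of all patients.",
        sg, 100 * row$frac_patients), "")
    }
    sub_path <- file.path(out_dir, "subgroup_differential.tsv")
    if (file.exists(sub_path)) {
      sub <- read_result_table(sub_path)
      extra <- setdiff(sub$assay[sub$significant],
                       diff_tab$assay[diff_tab$significant])
      lines <- c(lines, sprintf(
        "Subgroup-vs-rest comparison: %d significant assays, %d not significant in the all-patients comparison.",
        sum(sub$significant), length(extra)), "")
    }
  } else {
    lines <- c(lines, "## Stratification", "",
               "Skipped: fewer than 2 significant assays.", "")
  }

  kept <- cors[cors$kept %in% TRUE, , drop = FALSE]
  lines <- c(lines, sprintf("## Correlation screen: %d of %d pairs kept (adjusted p < %s)",
                            nrow(kept), nrow(cors), man$config$alpha), "")
  if (nrow(kept)) {
    top <- utils::head(kept[order(-abs(kept$rho)), ], 10L)
    lines <- c(lines, "| var1 | var2 | rho | q |", "|---|---|---|---|",
               sprintf("| %s | %s | %.3f | %.3g |", top$var1, top$var2,
                       top$rho, top$q), "")
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
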