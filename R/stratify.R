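#' Per-sample log2 relative expression over significant assays
#'
#' The heatmap/clustering matrix: for each significant assay,
#' `rel(i, s) = -(ΔCT(i, s) - mean over controls of ΔCT(i, .))`, i.e. log2
#' relative expression of sample `s` versus the control mean (the per-sample
#' log fold change). Controls are centered at 0 per assay by construction.
#' Cells undetected in ΔCT stay missing.
#'
#' @param dct a `delta_ct_matrix`.
#' @param sheet a `sample_sheet`; the control cohort must be nonempty.
#' @param significant_assays character vector of assay ids (typically the
#'   significant set from [differential_table()]); must be nonempty and
#'   present in `dct`.
#' @return An object of class `rel_expr_matrix`: list with `rel`
#'   (assays x samples, log2 units) and `detected`.
#' @export
relative_expression <- function(dct, sheet, significant_assays) {
  stopifnot(inherits(dct, "delta_ct_matrix"), inherits(sheet, "sample_sheet"))
  if (!length(significant_assays)) qs_stop("'significant_assays' is empty")
  miss <- setdiff(significant_assays, assay_ids(dct))
  if (length(miss)) qs_stop("assay '", miss[1L], "' absent from ΔCT matrix")
  ctrl <- intersect(sheet$sample_id[sheet$cohort == "control"],
                    sample_ids(dct))
  if (!length(ctrl)) qs_stop("control cohort is empty")
  d <- dct$delta_ct[significant_assays, , drop = FALSE]
  det <- dct$detected[significant_assays, , drop = FALSE]
  d[!det] <- NA_real_
  ctrl_mean <- rowMeans(d[, ctrl, drop = FALSE], na.rm = TRUE)
  rel <- -(d - ctrl_mean)
  structure(list(rel = rel, detected = det), class = "rel_expr_matrix")
}

#' Hierarchically cluster samples on relative expression
#'
#' Agglomerative clustering of samples (and, for heatmap row ordering, of
#' assays) on the log2 relative-expression matrix, cut to exactly `k` groups.
#' Missing cells are imputed as 0 — "no change" on the centered scale — for
#' the distance computation only. Group ids are 1..k in order of first
#' appearance in the input, so the partition (not the numbering) is what is
#' reproducible under sample reordering.
#'
#' @param rel a `rel_expr_matrix`.
#' @param k number of sample groups (default 3); must satisfy
#'   `2 <= k <= n_samples`.
#' @param metric distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage agglomeration method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return An object of class `cluster_result`: `k`, `labels` (named integer
#'   vector), `sample_order`, `assay_order` (dendrogram leaf orders for
#'   heatmap export), `sample_linkage` and `assay_linkage` (merge histories
#'   with heights), `metric`, `linkage`.
#' @export
cluster_samples <- function(rel, k = 3, metric = "euclidean",
                            linkage = "average") {
  stopifnot(inherits(rel, "rel_expr_matrix"))
  m <- rel$rel
  n <- ncol(m)
  if (!is_scalar_number(k) || k < 2 || k > n) {
    qs_stop("'k' must be between 2 and the number of samples (", n, ")")
  }
  m0 <- m
  m0[is.na(m0)] <- 0
  hc_s <- stats::hclust(stats::dist(t(m0), method = metric), method = linkage)
  hc_a <- if (nrow(m0) >= 2L) {
    stats::hclust(stats::dist(m0, method = metric), method = linkage)
  } else NULL
  raw <- stats::cutree(hc_s, k = k)
  # renumber groups by first appearance for a stable, documented convention
  labels <- match(raw, unique(raw))
  names(labels) <- colnames(m)
  structure(list(
    k = as.integer(k),
    labels = labels,
    sample_order = colnames(m)[hc_s$order],
    assay_order = if (is.null(hc_a)) rownames(m) else rownames(m)[hc_a$order],
    sample_linkage = list(merge = hc_s$merge, height = hc_s$height),
    assay_linkage = if (is.null(hc_a)) NULL else
      list(merge = hc_a$merge, height = hc_a$height),
    metric = metric, linkage = linkage
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k=%d (%s/%s): sizes %s\n", x$k, x$metric,
              x$linkage, paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Cohort composition of sample clusters
#'
#' Per group: patient and control counts, the fraction of all patients in the
#' group, and whether the group is patient-only. Also identifies the
#' "signature group" for unattended runs: the patient-only group with the
#' largest patient fraction if any exists, otherwise flagged ambiguous (NA).
#'
#' @param clusters a `cluster_result`.
#' @param sheet a `sample_sheet` covering all clustered samples.
#' @return A data frame (class `group_composition`) with one row per group
#'   and attribute `signature_group`.
#' @export
group_composition <- function(clusters, sheet) {
  stopifnot(inherits(clusters, "cluster_result"), inherits(sheet, "sample_sheet"))
  lab <- clusters$labels
  miss <- setdiff(names(lab), sheet$sample_id)
  if (length(miss)) qs_stop("sample '", miss[1L], "' not in sample sheet")
  coh <- sheet$cohort[match(names(lab), sheet$sample_id)]
  n_pat_total <- sum(coh == "patient")
  n_ctl_total <- sum(coh == "control")
  rows <- lapply(seq_len(clusters$k), function(g) {
    in_g <- lab == g
    np <- sum(in_g & coh == "patient")
    nc <- sum(in_g & coh == "control")
    data.frame(group = g, n_patients = np, n_controls = nc,
               frac_patients = if (n_pat_total) np / n_pat_total else NA_real_,
               frac_controls = if (n_ctl_total) nc / n_ctl_total else NA_real_,
               patient_only = np > 0L && nc == 0L)
  })
  out <- do.call(rbind, rows)
  sig <- out$group[out$patient_only]
  signature_group <- if (length(sig)) {
    sig[which.max(out$frac_patients[out$patient_only])]
  } else NA_integer_
  structure(out, signature_group = signature_group,
            class = c("group_composition", "data.frame"))
}

#' Re-test one cluster against all other samples
#'
#' Reuses the differential machinery with groups = (members of
#' `target_group`) vs (every other sample, controls included): the follow-up
#' comparison that surfaces markers confined to a patient subgroup and
#' diluted away in the all-patients comparison.
#'
#' @param dct a `delta_ct_matrix`.
#' @param sheet a `sample_sheet`.
#' @param clusters a `cluster_result` over the samples of `dct`.
#' @param target_group group id in `1..k`.
#' @inheritParams differential_table
#' @return A `differential_table` whose `comparison` attribute names the
#'   subgroup contrast.
#' @export
subgroup_differential <- function(dct, sheet, clusters, target_group,
                                  fc_dct = NULL, q_threshold = 0.05,
                                  variant = c("student", "welch"), min_n = 2L) {
  stopifnot(inherits(clusters, "cluster_result"))
  if (!is_scalar_number(target_group) ||
      !target_group %in% seq_len(clusters$k)) {
    qs_stop("unknown group id: ", target_group)
  }
  members <- names(clusters$labels)[clusters$labels == target_group]
  rest <- setdiff(sample_ids(dct), members)
  if (!length(members)) qs_stop("target group is empty")
  if (!length(rest)) qs_stop("complement of target group is empty")
  groups <- stats::setNames(list(members, rest),
                            c(sprintf("group%d", target_group), "rest"))
  differential_table(dct, sheet, groups = groups, fc_dct = fc_dct,
                     q_threshold = q_threshold, variant = variant,
                     min_n = min_n)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to renaming), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length (any types coercible to factor).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) qs_stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Export the reordered heatmap matrix
#'
#' The relative-expression matrix with rows and columns permuted to the
#' dendrogram leaf orders, as a plain table (rendering is left to the
#' caller).
#'
#' @param rel a `rel_expr_matrix`.
#' @param clusters the matching `cluster_result`.
#' @return A data frame: first column `assay`, one column per sample.
#' @export
heatmap_matrix <- function(rel, clusters) {
  stopifnot(inherits(rel, "rel_expr_matrix"), inherits(clusters, "cluster_result"))
  m <- rel$rel[clusters$assay_order, clusters$sample_order, drop = FALSE]
  out <- data.frame(assay = rownames(m), stringsAsFactors = FALSE)
  for (s in colnames(m)) out[[s]] <- m[, s]
  out
}
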