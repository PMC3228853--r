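#' Censor CT values at the detection limit
#'
#' qPCR readouts at or above the instrument's reliable range carry no
#' magnitude information; following standard low-density-array practice, CT
#' values at or above `threshold` cycles (default 32) are treated as
#' undetected. Values are retained in the matrix but masked; censoring is
#' idempotent and masks only ever grow.
#'
#' @param ct a [ct_matrix] at stage `"raw"` (or `"censored"`; re-censoring is
#'   a no-op at the same threshold).
#' @param threshold censoring limit in cycles; cells with `ct >= threshold`
#'   become undetected.
#' @return The matrix at stage `"censored"`.
#' @export
censor_undetected <- function(ct, threshold = 32) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!is_scalar_number(threshold) || threshold <= 0) {
    qs_stop("'threshold' must be a positive number of cycles")
  }
  if (ct$stage == "normalized") qs_stop("cannot censor a normalized matrix")
  ct$detected <- ct$detected & !(!is.na(ct$ct) & ct$ct >= threshold)
  ct$stage <- "censored"
  ct
}

#' Filter assays by per-cohort detection rate
#'
#' Keeps assays detected in at least `min_det_frac` of the samples of each
#' cohort. This inclusion rule is an explicit pipeline choice (array exports
#' carry hundreds of assays never expressed in blood); it is logged and fully
#' configurable.
#'
#' @param ct a censored [ct_matrix].
#' @param sheet a `sample_sheet` covering all samples in `ct`.
#' @param min_det_frac minimum detected fraction per cohort in `[0, 1]`.
#' @param quiet suppress the dropped-assay message.
#' @return The subset [ct_matrix].
#' @export
filter_assays <- function(ct, sheet, min_det_frac = 0.5, quiet = FALSE) {
  stopifnot(inherits(ct, "ct_matrix"))
  check_samples_covered(ct, sheet)
  if (!is_scalar_number(min_det_frac) || min_det_frac < 0 || min_det_frac > 1) {
    qs_stop("'min_det_frac' must be in [0, 1]")
  }
  keep <- rep(TRUE, nrow(ct$ct))
  for (grp in c("patient", "control")) {
    cols <- sheet$sample_id[sheet$cohort == grp]
    cols <- intersect(cols, sample_ids(ct))
    if (!length(cols)) qs_stop("cohort '", grp, "' has zero samples")
    frac <- rowMeans(ct$detected[, cols, drop = FALSE])
    keep <- keep & frac >= min_det_frac
  }
  if (!quiet) {
    message(sprintf("filter_assays: dropped %d of %d assays (< %.0f%% detected in a cohort)",
                    sum(!keep), length(keep), 100 * min_det_frac))
  }
  subset_assays(ct, keep)
}

#' Quantile-normalize CT values across samples
#'
#' Forces all samples to share one CT distribution by rank alignment,
#' restricted to detected cells (censored values carry no magnitude and are
#' excluded; they remain undetected and unaltered). Within each sample, the
#' detected values' ranks are mapped onto a target distribution: the mean
#' across samples of within-sample order statistics, aligned on the common
#' quantile grid `(r - 0.5) / n` with linear interpolation when samples differ
#' in detected count. Ties receive the average of their target values. On
#' fully detected matrices with equal counts this reduces to the classic
#' sort/row-mean construction.
#'
#' @param ct a censored [ct_matrix].
#' @return The matrix at stage `"normalized"`.
#' @export
quantile_normalize <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  det <- ct$detected
  n_det <- colSums(det)
  if (any(n_det < 2L)) {
    qs_stop("sample '", colnames(det)[which(n_det < 2L)[1L]],
            "' has fewer than 2 detected values")
  }
  n_max <- max(n_det)
  grid <- (seq_len(n_max) - 0.5) / n_max
  # pooled target curve: per-sample sorted detected values interpolated onto
  # the common grid, then averaged across samples
  curves <- vapply(seq_len(ncol(det)), function(j) {
    v <- sort(ct$ct[det[, j], j])
    if (length(v) == n_max) return(v)
    q <- (seq_along(v) - 0.5) / length(v)
    stats::approx(q, v, xout = grid, rule = 2)$y
  }, numeric(n_max))
  target <- rowMeans(curves)

  out <- ct$ct
  for (j in seq_len(ncol(det))) {
    idx <- which(det[, j])
    v <- ct$ct[idx, j]
    nj <- length(v)
    t_sorted <- if (nj == n_max) target else {
      stats::approx(grid, target, xout = (seq_len(nj) - 0.5) / nj, rule = 2)$y
    }
    res <- numeric(nj)
    res[order(v)] <- t_sorted
    # tied input values share the average of their target values
    res <- stats::ave(res, match(v, v), FUN = mean)
    out[idx, j] <- res
  }
  ct$ct <- out
  ct$stage <- "normalized"
  ct
}

#' Select the endogenous-control (reference) assay set
#'
#' Data-driven reference selection for ΔCT: among assays detected in 100% of
#' samples, the `size` assays with the lowest standard deviation across
#' samples are taken as the endogenous control set (default 10); their
#' per-sample mean CT is the reference level subtracted in [compute_delta_ct()].
#' Ties in SD are broken by assay id (lexicographic), making the selection
#' deterministic and invariant to row order.
#'
#' @param ct a censored or normalized [ct_matrix].
#' @param size number of reference assays (default 10).
#' @param allow_fewer if fewer than `size` assays are fully detected, use all
#'   of them with a warning instead of failing.
#' @return An object of class `reference_set` with elements `assay_ids`,
#'   `selection_sd` (named, the ranking SDs) and `per_sample_mean` (named by
#'   sample).
#' @export
select_reference <- function(ct, size = 10, allow_fewer = FALSE) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!is_scalar_number(size) || size < 1) qs_stop("'size' must be >= 1")
  full <- rowSums(ct$detected) == ncol(ct$detected)
  cand <- which(full)
  if (length(cand) < size) {
    if (!allow_fewer) {
      qs_stop("only ", length(cand), " fully-detected assays available, ",
              "need ", size, " (set allow_fewer = TRUE to proceed)")
    }
    warning(sprintf("select_reference: using all %d fully-detected assays (requested %d)",
                    length(cand), size))
    size <- length(cand)
  }
  if (size == 0L) qs_stop("no fully-detected assays available")
  sds <- apply(ct$ct[cand, , drop = FALSE], 1L, stats::sd)
  ids <- rownames(ct$ct)[cand]
  ord <- order(sds, ids)
  pick <- ord[seq_len(size)]
  members <- ids[pick]
  structure(list(
    assay_ids = members,
    selection_sd = stats::setNames(sds[pick], members),
    per_sample_mean = colMeans(ct$ct[members, , drop = FALSE])
  ), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d assays, SD range [%.4g, %.4g]\n",
              length(x$assay_ids), min(x$selection_sd), max(x$selection_sd)))
  invisible(x)
}

#' Recompute a reference set's per-sample means on another CT stage
#'
#' Keeps the membership fixed (e.g. selected on normalized CT) but re-derives
#' the per-sample reference mean from a different stage of the same matrix
#' (e.g. censored raw CT), so that raw-CT fold changes and normalized-CT tests
#' can share one control set.
#'
#' @param ref a `reference_set`.
#' @param ct the [ct_matrix] to take means from; must contain all members,
#'   each detected in every sample.
#' @return A `reference_set` with updated `per_sample_mean`.
#' @export
rebase_reference <- function(ref, ct) {
  stopifnot(inherits(ref, "reference_set"), inherits(ct, "ct_matrix"))
  miss <- setdiff(ref$assay_ids, assay_ids(ct))
  if (length(miss)) qs_stop("reference assay '", miss[1L], "' missing from matrix")
  det <- ct$detected[ref$assay_ids, , drop = FALSE]
  if (!all(det)) qs_stop("reference assays must be detected in all samples")
  ref$per_sample_mean <- colMeans(ct$ct[ref$assay_ids, , drop = FALSE])
  ref
}

#' Compute ΔCT against an endogenous-control reference
#'
#' ΔCT(assay, sample) = CT(assay, sample) − reference mean(sample), defined
#' only where the underlying CT is detected. ΔCT is invariant under any
#' per-sample additive shift of CT (loading differences), since the reference
#' mean shifts equally.
#'
#' @param ct a [ct_matrix].
#' @param ref a `reference_set` whose members are all present in `ct` and
#'   whose `per_sample_mean` covers the samples of `ct`.
#' @return An object of class `delta_ct_matrix`: list with `delta_ct`
#'   (assays x samples), `detected` and `reference`.
#' @export
compute_delta_ct <- function(ct, ref) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(ref, "reference_set"))
  miss <- setdiff(ref$assay_ids, assay_ids(ct))
  if (length(miss)) qs_stop("reference assay '", miss[1L], "' missing from matrix")
  miss <- setdiff(sample_ids(ct), names(ref$per_sample_mean))
  if (length(miss)) qs_stop("no reference mean for sample '", miss[1L], "'")
  d <- sweep(ct$ct, 2L, ref$per_sample_mean[sample_ids(ct)])
  d[!ct$detected] <- NA_real_
  structure(list(delta_ct = d, detected = ct$detected, reference = ref),
            class = "delta_ct_matrix")
}

#' @export
print.delta_ct_matrix <- function(x, ...) {
  cat(sprintf("<delta_ct_matrix> %d assays x %d samples (reference: %d assays)\n",
              nrow(x$delta_ct), ncol(x$delta_ct), length(x$reference$assay_ids)))
  invisible(x)
}

# every sample of the matrix must appear exactly once in the sheet
check_samples_covered <- function(ct, sheet) {
  stopifnot(inherits(sheet, "sample_sheet"))
  miss <- setdiff(sample_ids(ct), sheet$sample_id)
  if (length(miss)) qs_stop("sample '", miss[1L], "' not in sample sheet")
  invisible(TRUE)
}
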