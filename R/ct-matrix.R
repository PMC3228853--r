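#' CT matrix container
#'
#' Holds cycle-threshold (CT) values from a low-density qPCR array as an
#' assays-by-samples matrix together with a detection mask and a processing
#' stage. Undetected cells (instrument "Undetermined", blank exports, or values
#' censored at the detection limit) keep their slot in the matrix but are
#' excluded from every downstream statistic.
#'
#' @param ct numeric matrix, assays in rows and samples in columns, with
#'   row and column names. `NA` entries must be undetected.
#' @param detected logical matrix of the same shape; `TRUE` where the assay was
#'   quantified in that sample. Defaults to `!is.na(ct)`.
#' @param stage processing stage, one of `"raw"`, `"censored"`, `"normalized"`.
#'
#' @return An object of class `ct_matrix`: a list with elements `ct`,
#'   `detected` and `stage`. Row names are the assay identifiers, column names
#'   the sample identifiers (case-sensitive exact strings; no spelling
#'   normalization is ever applied).
#' @export
ct_matrix <- function(ct, detected = NULL, stage = "raw") {
  if (!is.matrix(ct) || !is.numeric(ct)) {
    qs_stop("'ct' must be a numeric matrix")
  }
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    qs_stop("'ct' must have assay row names and sample column names")
  }
  if (is.null(detected)) detected <- !is.na(ct)
  if (!is.matrix(detected) || !is.logical(detected) ||
      !identical(dim(detected), dim(ct))) {
    qs_stop("'detected' must be a logical matrix with the same shape as 'ct'")
  }
  if (anyNA(detected)) qs_stop("'detected' must not contain NA")
  if (any(is.na(ct) & detected)) {
    qs_stop("cells with NA ct cannot be marked detected")
  }
  stage <- match.arg(stage, c("raw", "censored", "normalized"))
  dup_a <- anyDuplicated(rownames(ct))
  if (dup_a) qs_stop("duplicate assay id: '", rownames(ct)[dup_a], "'")
  dup_s <- anyDuplicated(colnames(ct))
  if (dup_s) qs_stop("duplicate sample id: '", colnames(ct)[dup_s], "'")
  dimnames(detected) <- dimnames(ct)
  structure(list(ct = ct, detected = detected, stage = stage),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d assays x %d samples, stage=%s, %.1f%% detected\n",
              nrow(x$ct), ncol(x$ct), x$stage,
              100 * mean(x$detected)))
  invisible(x)
}

#' Assay and sample identifiers
#'
#' @param x a `ct_matrix`, `delta_ct_matrix` or `rel_expr_matrix`.
#' @return Character vector of identifiers.
#' @export
assay_ids <- function(x) rownames(x[[1]])

#' @rdname assay_ids
#' @export
sample_ids <- function(x) colnames(x[[1]])

# subset rows of a ct_matrix keeping class/stage
subset_assays <- function(x, keep) {
  x$ct <- x$ct[keep, , drop = FALSE]
  x$detected <- x$detected[keep, , drop = FALSE]
  x
}

# ct with undetected cells blanked to NA; the only view downstream statistics
# are allowed to touch
masked_ct <- function(x) {
  m <- x$ct
  m[!x$detected] <- NA_real_
  m
}
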