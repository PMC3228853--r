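#' Tie-corrected Spearman correlation with a t-approximation p-value
#'
#' Pearson correlation on average (mid-) ranks after pairwise deletion of
#' missing values. The p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`, two-tailed; `|rho| = 1` gives
#' p = 0. Pairs with fewer than `min_n` complete observations, or with a
#' constant argument (rho undefined), are returned with `ok = FALSE` rather
#' than raising.
#'
#' @param x,y numeric vectors of equal length.
#' @param min_n minimum complete pairs (default 5).
#' @return A list with `rho`, `p`, `n`, `ok`.
#' @export
spearman_cor <- function(x, y, min_n = 5L) {
  if (length(x) != length(y)) qs_stop("'x' and 'y' differ in length")
  keep <- is.finite(x) & is.finite(y)
  n <- sum(keep)
  if (n < min_n) return(list(rho = NA_real_, p = NA_real_, n = n, ok = FALSE))
  rx <- rank(x[keep], ties.method = "average")
  ry <- rank(y[keep], ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, ok = FALSE))
  }
  rho <- stats::cor(rx, ry)
  list(rho = rho, p = spearman_p(rho, n), n = n, ok = TRUE)
}

# two-tailed p from the t approximation (vectorized)
spearman_p <- function(rho, n) {
  rho <- pmin(1, pmax(-1, rho))
  p <- rep(NA_real_, length(rho))
  exact1 <- !is.na(rho) & abs(rho) >= 1
  p[exact1] <- 0
  rest <- !is.na(rho) & !exact1
  t <- rho[rest] * sqrt((n[rest] - 2) / (1 - rho[rest]^2))
  p[rest] <- 2 * stats::pt(-abs(t), n[rest] - 2)
  p
}

#' Pairwise Spearman screen across miRNAs, analytes and clinical covariates
#'
#' Assembles three namespaced variable sets — `mirna:` (expression scale
#' −ΔCT, monotone in abundance), `analyte:` (concentrations) and `clinical:`
#' (pain score, CRPS type as 1/2, disease duration, BMI, and 0/1 comorbidity
#' and medication flags) — and tests every cross-namespace pair plus
#' clinical–clinical pairs with tie-corrected Spearman correlation.
#' Benjamini–Hochberg adjustment is applied within each namespace-pair
#' family; a pair is kept when its adjusted p falls below `alpha` and it has
#' at least `min_n` complete observations. Constant variables are skipped.
#'
#' By default only patients enter (clinical covariates are patient-specific);
#' `use_samples = "all"` screens all samples instead.
#'
#' @param dct a `delta_ct_matrix`, or NULL to omit miRNA variables.
#' @param sheet a `sample_sheet`.
#' @param panel an `analyte_panel`, or NULL to omit analytes.
#' @param alpha cutoff on the adjusted p (default 0.01).
#' @param min_n minimum complete pairs per correlation (default 5).
#' @param use_samples `"patients"` (default) or `"all"`.
#' @return A data frame of class `correlation_table` with columns `var1`,
#'   `var2`, `family`, `rho`, `n`, `p`, `q`, `kept`, one row per unordered
#'   pair, sorted by `q` then descending |rho|.
#' @export
correlation_screen <- function(dct = NULL, sheet, panel = NULL, alpha = 0.01,
                               min_n = 5L, use_samples = c("patients", "all")) {
  stopifnot(inherits(sheet, "sample_sheet"))
  use_samples <- match.arg(use_samples)
  ids <- if (use_samples == "patients") {
    sheet$sample_id[sheet$cohort == "patient"]
  } else sheet$sample_id

  sets <- list()
  if (!is.null(dct)) {
    stopifnot(inherits(dct, "delta_ct_matrix"))
    keep <- intersect(ids, sample_ids(dct))
    d <- dct$delta_ct[, keep, drop = FALSE]
    d[!dct$detected[, keep, drop = FALSE]] <- NA_real_
    ids <- keep
    sets$mirna <- t(-d)      # samples x assays, expression scale
  }
  cl <- clinical_variables(sheet, ids)
  if (ncol(cl)) sets$clinical <- cl
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "analyte_panel"))
    m <- as.matrix(panel[match(ids, panel$sample_id),
                         setdiff(colnames(panel), "sample_id"), drop = FALSE])
    rownames(m) <- ids
    sets$analyte <- m
  }
  if (!is.null(sets$mirna)) sets$mirna <- sets$mirna[ids, , drop = FALSE]

  # all cross-namespace pairs, plus clinical-clinical below (never
  # mirna-mirna or analyte-analyte)
  pairs <- list()
  ns <- names(sets)
  for (i in seq_along(ns)) {
    for (j in seq_along(ns)) {
      if (j <= i) next
      pairs[[length(pairs) + 1L]] <-
        screen_block(sets[[i]], sets[[j]], ns[i], ns[j], min_n)
    }
  }
  if ("clinical" %in% ns && ncol(sets$clinical) >= 2L) {
    pairs[[length(pairs) + 1L]] <-
      screen_block(sets$clinical, sets$clinical, "clinical", "clinical", min_n)
  }
  out <- do.call(rbind, pairs)
  if (is.null(out) || !nrow(out)) {
    out <- data.frame(var1 = character(), var2 = character(),
                      family = character(), rho = numeric(), n = integer(),
                      p = numeric(), q = numeric(), kept = logical())
  } else {
    # BH within each namespace-pair family
    out$q <- NA_real_
    for (fam in unique(out$family)) {
      sel <- out$family == fam
      out$q[sel] <- bh_adjust(out$p[sel])
    }
    out$kept <- !is.na(out$q) & out$q < alpha & out$n >= min_n
    out <- out[order(out$q, -abs(out$rho), na.last = TRUE), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, alpha = alpha, use_samples = use_samples,
            class = c("correlation_table", "data.frame"))
}

#' @export
print.correlation_table <- function(x, n = 10L, ...) {
  cat(sprintf("<correlation_table> %d pairs, %d kept (adjusted p < %g)\n",
              nrow(x), sum(x$kept), attr(x, "alpha") %||% NA))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

# clinical covariate matrix (samples x variables); ordinal/binary covariates
# enter as numeric (0/1 flags, 1/2 CRPS type)
clinical_variables <- function(sheet, ids) {
  rows <- match(ids, sheet$sample_id)
  base <- c("pain_nrs", "crps_type", "duration_years", "bmi")
  vars <- c(base, attr(sheet, "flag_cols"))
  m <- vapply(vars, function(v) as.numeric(sheet[[v]][rows]),
              numeric(length(ids)))
  if (length(ids) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, vars))
  rownames(m) <- ids
  m
}

# all pairs between two variable matrices (or within one when A is B):
# fast path via rank-matrix correlation for complete columns, per-pair
# fallback under missingness; returns a data frame without q/kept
screen_block <- function(A, B, ns_a, ns_b, min_n) {
  within <- identical(ns_a, ns_b)
  fam <- paste(sort(c(ns_a, ns_b)), collapse = "|")
  n_samp <- nrow(A)
  ok_a <- apply(A, 2L, function(v) sum(is.finite(v)) >= max(min_n, 2L) &&
                  stats::sd(v[is.finite(v)]) > 0)
  ok_b <- apply(B, 2L, function(v) sum(is.finite(v)) >= max(min_n, 2L) &&
                  stats::sd(v[is.finite(v)]) > 0)
  A <- A[, ok_a, drop = FALSE]
  B <- B[, ok_b, drop = FALSE]
  if (!ncol(A) || !ncol(B)) return(NULL)

  comp_a <- !apply(A, 2L, anyNA)
  comp_b <- !apply(B, 2L, anyNA)
  res <- list()

  # fast path: both columns complete -> one rank-matrix correlation
  if (any(comp_a) && any(comp_b)) {
    ra <- apply(A[, comp_a, drop = FALSE], 2L, rank, ties.method = "average")
    rb <- apply(B[, comp_b, drop = FALSE], 2L, rank, ties.method = "average")
    rho <- stats::cor(ra, rb)
    idx <- which(!is.na(rho), arr.ind = TRUE)
    v1 <- colnames(ra)[idx[, 1L]]
    v2 <- colnames(rb)[idx[, 2L]]
    r <- rho[idx]
    res[[1L]] <- data.frame(var1 = paste0(ns_a, ":", v1),
                            var2 = paste0(ns_b, ":", v2),
                            raw1 = v1, raw2 = v2,
                            rho = r, n = n_samp,
                            p = spearman_p(r, rep(n_samp, length(r))),
                            stringsAsFactors = FALSE)
  }

  # slow path: any pair touching an incomplete column
  slow <- expand.grid(a = colnames(A), b = colnames(B),
                      stringsAsFactors = FALSE)
  slow <- slow[!(comp_a[slow$a] & comp_b[slow$b]), , drop = FALSE]
  if (nrow(slow)) {
    rr <- mapply(function(va, vb) {
      s <- spearman_cor(A[, va], B[, vb], min_n = min_n)
      c(s$rho, s$p, s$n, s$ok)
    }, slow$a, slow$b)
    keep <- rr[4L, ] == 1
    if (any(keep)) {
      res[[length(res) + 1L]] <-
        data.frame(var1 = paste0(ns_a, ":", slow$a[keep]),
                   var2 = paste0(ns_b, ":", slow$b[keep]),
                   raw1 = slow$a[keep], raw2 = slow$b[keep],
                   rho = rr[1L, keep], n = as.integer(rr[3L, keep]),
                   p = rr[2L, keep], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(NULL)
  if (within) {
    # each unordered pair once, no self-pairs
    out <- out[out$raw1 < out$raw2, , drop = FALSE]
  }
  if (!nrow(out)) return(NULL)
  out$family <- fam
  out$n <- as.integer(out$n)
  out[, c("var1", "var2", "family", "rho", "n", "p")]
}

#' Export kept correlations as a circular-plot link table
#'
#' Writes the kept pairs as a delimited link table (`var1`, `var2`, `rho`,
#' `q`, `sign`) sorted by descending |rho| — sufficient input for external
#' circular-diagram tools; no rendering is done here.
#'
#' @param table a `correlation_table`.
#' @param path output path.
#' @return The exported data frame, invisibly.
#' @export
export_links <- function(table, path) {
  stopifnot(inherits(table, "correlation_table"))
  kept <- table[table$kept, , drop = FALSE]
  kept <- kept[order(-abs(kept$rho)), , drop = FALSE]
  out <- data.frame(var1 = kept$var1, var2 = kept$var2, rho = kept$rho,
                    q = kept$q,
                    sign = ifelse(kept$rho < 0, "neg", "pos"),
                    stringsAsFactors = FALSE)
  write_result_table(out, path)
  invisible(out)
}
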