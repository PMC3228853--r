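#' Signed fold change from ΔΔCT
#'
#' The 2^-ΔΔCT method with the signed reporting convention: the raw ratio
#' `r = 2^(-ΔΔCT)` is returned as is when `r >= 1` and as the negative
#' reciprocal `-1/r` otherwise, so every reported magnitude is at least 1 and
#' a positive ΔΔCT (higher CT, lower abundance in group A) yields a negative
#' fold change. No output ever lies in the open interval (-1, 1).
#'
#' @param ddct ΔΔCT in cycles (vectorized); must be finite.
#' @return Signed fold change(s).
#' @export
fold_change_from_ddct <- function(ddct) {
  if (!is.numeric(ddct) || any(!is.finite(ddct))) {
    qs_stop("ΔΔCT must be finite")
  }
  r <- 2^(-ddct)
  ifelse(r >= 1, r, -1 / r)
}

#' Two-sample t test
#'
#' Independent-samples t test on two vectors, two-tailed. The default
#' `student` variant uses the pooled-variance statistic with
#' `n_a + n_b - 2` degrees of freedom; `welch` uses the unequal-variance
#' statistic with Welch-Satterthwaite degrees of freedom. Non-finite values
#' are dropped. Degenerate zero-variance cases: equal means give t = 0,
#' p = 1; unequal means give p = 0.
#'
#' @param values_a,values_b numeric vectors (>= 2 finite values each).
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return A list with `t`, `df`, `p`, `n_a`, `n_b`.
#' @export
two_sample_test <- function(values_a, values_b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) {
    qs_stop("each group needs >= 2 finite values")
  }
  res <- t_stat_vec(matrix(c(mean(a), stats::var(a)), nrow = 1,
                           dimnames = list(NULL, c("m", "v"))),
                    matrix(c(mean(b), stats::var(b)), nrow = 1,
                           dimnames = list(NULL, c("m", "v"))),
                    na, nb, variant)
  list(t = res$t, df = res$df, p = res$p, n_a = na, n_b = nb)
}

# vectorized t statistics from per-feature group means/variances; sa/sb are
# matrices with columns m (mean) and v (variance); na/nb may be vectors
t_stat_vec <- function(sa, sb, na, nb, variant) {
  dm <- sa[, "m"] - sb[, "m"]
  if (variant == "student") {
    df <- na + nb - 2
    sp2 <- ((na - 1) * sa[, "v"] + (nb - 1) * sb[, "v"]) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    va <- sa[, "v"] / na
    vb <- sb[, "v"] / nb
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  t <- dm / se
  # zero-variance degeneracies
  zero <- !is.na(se) & se == 0
  t[zero & dm == 0] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  p[zero & dm == 0] <- 1
  p[zero & dm != 0] <- 0
  list(t = unname(t), df = unname(df), p = unname(p))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(k) = min_{j >= k} p_(j) * m / j`, capped at 1 and mapped back to input
#' order. `NA` entries are passed through and do not count toward `m`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) qs_stop("p-values must be numeric")
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) qs_stop("p-values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(p_values))
  if (m) {
    o <- order(p, decreasing = TRUE)          # largest first
    qi <- pmin(1, cummin(p[o] * m / seq(m, 1)))
    q[ok] <- qi[order(o)]
  }
  q
}

#' Per-assay differential expression on ΔCT
#'
#' For each assay, tests the difference in ΔCT between two sample groups with
#' an independent-samples t test (undetected values dropped pairwise, no
#' imputation), computes ΔΔCT = mean ΔCT(group A) − mean ΔCT(group B) and the
#' signed 2^-ΔΔCT fold change, and applies Benjamini-Hochberg correction
#' across the tested assays. Assays with fewer than `min_n` detected values in
#' either group are flagged (`tested = FALSE`), not dropped silently.
#'
#' The matrix used for the fold-change ΔΔCT can differ from the one used for
#' testing (`fc_dct`): array pipelines commonly quote fold changes from raw
#' censored CT while testing on normalized CT. By default both come from
#' `dct`.
#'
#' @param dct a `delta_ct_matrix` used for the t tests.
#' @param sheet a `sample_sheet`.
#' @param groups either a character vector of two cohort labels (default
#'   `c("patient", "control")`) or a list of two character vectors of sample
#'   ids (group A, group B).
#' @param fc_dct optional `delta_ct_matrix` feeding the fold-change ΔΔCT;
#'   must share assay and sample ids with `dct`.
#' @param q_threshold significance cutoff on adjusted p (default 0.05).
#' @param variant t-test variant, `"student"` or `"welch"`.
#' @param min_n minimum detected values per group (default 2).
#' @return A data frame of class `differential_table`, sorted by q then
#'   descending |fold change|, with columns `assay`, `delta_delta_ct`,
#'   `fold_change`, `p`, `q`, `n_group1`, `n_group2`, `significant`, `tested`.
#' @export
differential_table <- function(dct, sheet, groups = c("patient", "control"),
                               fc_dct = NULL, q_threshold = 0.05,
                               variant = c("student", "welch"), min_n = 2L) {
  stopifnot(inherits(dct, "delta_ct_matrix"))
  variant <- match.arg(variant)
  sets <- resolve_groups(groups, sheet, sample_ids(dct))
  cols_a <- match(sets$a, sample_ids(dct))
  cols_b <- match(sets$b, sample_ids(dct))

  d <- dct$delta_ct
  d[!dct$detected] <- NA_real_
  st_a <- row_group_stats(d, cols_a)
  st_b <- row_group_stats(d, cols_b)
  tested <- st_a[, "n"] >= min_n & st_b[, "n"] >= min_n

  t_res <- t_stat_vec(cbind(m = st_a[, "m"], v = st_a[, "v"]),
                      cbind(m = st_b[, "m"], v = st_b[, "v"]),
                      st_a[, "n"], st_b[, "n"], variant)
  p <- ifelse(tested, t_res$p, NA_real_)
  q <- bh_adjust(p)

  if (is.null(fc_dct)) fc_dct <- dct
  stopifnot(inherits(fc_dct, "delta_ct_matrix"))
  if (!setequal(assay_ids(fc_dct), assay_ids(dct))) {
    qs_stop("'fc_dct' must cover the same assays as 'dct'")
  }
  dfc <- fc_dct$delta_ct[assay_ids(dct), , drop = FALSE]
  dfc[!fc_dct$detected[assay_ids(dct), , drop = FALSE]] <- NA_real_
  fa <- row_group_stats(dfc, match(sets$a, colnames(dfc)))
  fb <- row_group_stats(dfc, match(sets$b, colnames(dfc)))
  ddct <- fa[, "m"] - fb[, "m"]
  fc <- rep(NA_real_, length(ddct))
  fin <- is.finite(ddct)
  fc[fin] <- fold_change_from_ddct(ddct[fin])

  out <- data.frame(
    assay = assay_ids(dct),
    delta_delta_ct = ddct,
    fold_change = fc,
    p = p,
    q = q,
    n_group1 = as.integer(st_a[, "n"]),
    n_group2 = as.integer(st_b[, "n"]),
    significant = !is.na(q) & q < q_threshold,
    tested = tested,
    stringsAsFactors = FALSE
  )
  ord <- order(out$q, -abs(out$fold_change), out$assay, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            comparison = sets$label, q_threshold = q_threshold,
            variant = variant,
            class = c("differential_table", "data.frame"))
}

#' @export
print.differential_table <- function(x, n = 10L, ...) {
  cat(sprintf("<differential_table> %s: %d features, %d significant (q < %g)\n",
              attr(x, "comparison") %||% "?", nrow(x), sum(x$significant),
              attr(x, "q_threshold") %||% NA))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

# per-row n / mean / variance over a column subset, NA-aware, vectorized
row_group_stats <- function(mat, cols) {
  m <- mat[, cols, drop = FALSE]
  det <- !is.na(m)
  n <- rowSums(det)
  s <- rowSums(m, na.rm = TRUE)
  mean <- ifelse(n > 0, s / n, NA_real_)
  ss <- rowSums(m^2, na.rm = TRUE)
  v <- ifelse(n > 1, pmax(0, (ss - n * mean^2)) / (n - 1), NA_real_)
  cbind(n = n, m = mean, v = v)
}

# groups: two cohort labels, or list of two sample-id vectors
resolve_groups <- function(groups, sheet, samples) {
  if (is.list(groups)) {
    if (length(groups) != 2L) qs_stop("'groups' must have exactly two entries")
    a <- intersect(groups[[1L]], samples)
    b <- intersect(groups[[2L]], samples)
    label <- paste0(names(groups)[1L] %||% "groupA", " vs ",
                    names(groups)[2L] %||% "groupB")
  } else {
    if (length(groups) != 2L) qs_stop("'groups' must have exactly two entries")
    stopifnot(inherits(sheet, "sample_sheet"))
    bad <- setdiff(groups, unique(sheet$cohort))
    if (length(bad)) qs_stop("unknown group label: '", bad[1L], "'")
    a <- intersect(sheet$sample_id[sheet$cohort == groups[1L]], samples)
    b <- intersect(sheet$sample_id[sheet$cohort == groups[2L]], samples)
    label <- paste0(groups[1L], " vs ", groups[2L])
  }
  if (!length(a) || !length(b)) qs_stop("both groups must be nonempty")
  if (length(intersect(a, b))) qs_stop("groups must be disjoint")
  list(a = a, b = b, label = label)
}

#' Differential abundance for an analyte panel
#'
#' Applies the same test/adjustment machinery to analyte concentrations
#' (patients vs controls). Fold change is reported as the unsigned
#' patient/control mean ratio, since concentrations are on a linear scale,
#' not CT cycles. Analytes with fewer than `min_n` non-missing values in a
#' cohort (including all-missing analytes) are flagged, not errors.
#'
#' @param panel an `analyte_panel`.
#' @param sheet a `sample_sheet`.
#' @param log_transform test on log-transformed concentrations (default
#'   FALSE; raw concentrations). Zero values are excluded when logging.
#' @param q_threshold significance cutoff on adjusted p (default 0.05).
#' @param variant t-test variant.
#' @param min_n minimum non-missing values per cohort (default 2).
#' @return A data frame of class `differential_table` with columns `analyte`,
#'   `fold_change` (mean ratio), `p`, `q`, `n_group1`, `n_group2`,
#'   `significant`, `tested`.
#' @export
analyte_differential <- function(panel, sheet, log_transform = FALSE,
                                 q_threshold = 0.05,
                                 variant = c("student", "welch"), min_n = 2L) {
  stopifnot(inherits(panel, "analyte_panel"), inherits(sheet, "sample_sheet"))
  variant <- match.arg(variant)
  analytes <- setdiff(colnames(panel), "sample_id")
  coh <- sheet$cohort[match(panel$sample_id, sheet$sample_id)]
  if (anyNA(coh)) qs_stop("panel sample '",
                          panel$sample_id[which(is.na(coh))[1L]],
                          "' not in sample sheet")
  rows <- lapply(analytes, function(an) {
    x <- panel[[an]]
    a <- x[coh == "patient" & !is.na(x)]
    b <- x[coh == "control" & !is.na(x)]
    fc <- if (length(a) && length(b) && mean(b) > 0) mean(a) / mean(b) else NA_real_
    ta <- a; tb <- b
    if (log_transform) { ta <- log(a[a > 0]); tb <- log(b[b > 0]) }
    if (length(ta) < min_n || length(tb) < min_n) {
      return(data.frame(analyte = an, fold_change = fc, p = NA_real_,
                        n_group1 = length(a), n_group2 = length(b),
                        tested = FALSE, stringsAsFactors = FALSE))
    }
    tt <- two_sample_test(ta, tb, variant)
    data.frame(analyte = an, fold_change = fc, p = tt$p,
               n_group1 = tt$n_a, n_group2 = tt$n_b, tested = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- !is.na(out$q) & out$q < q_threshold
  out <- out[, c("analyte", "fold_change", "p", "q",
                 "n_group1", "n_group2", "significant", "tested")]
  out <- out[order(out$q, -abs(log(out$fold_change)), na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, comparison = "patient vs control (analytes)",
            q_threshold = q_threshold, variant = variant,
            class = c("differential_table", "data.frame"))
}
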