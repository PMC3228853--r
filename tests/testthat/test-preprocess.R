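test_that("censoring masks at the threshold, keeps values, and is idempotent", {
  x <- mk_ct(c(32.0, 31.99, 40, 10), 2, 2)
  cen <- censor_undetected(x, threshold = 32)
  expect_identical(cen$stage, "censored")
  expect_false(cen$detected["a01", "s01"])   # exactly 32 -> undetected
  expect_true(cen$detected["a01", "s02"])    # 31.99 -> detected
  expect_false(cen$detected["a02", "s01"])
  expect_identical(cen$ct["a01", "s01"], 32) # value retained, masked

  # idempotent; masks only grow
  again <- censor_undetected(cen, threshold = 32)
  expect_identical(again$detected, cen$detected)
  tighter <- censor_undetected(cen, threshold = 20)
  expect_true(all(tighter$detected <= cen$detected))

  all40 <- censor_undetected(mk_ct(rep(40, 6), 3, 2))
  expect_true(all(!all40$detected))
  expect_error(censor_undetected(x, threshold = 0), "positive")
})

test_that("detection filter keeps assays by per-cohort fraction", {
  sheet <- mk_sheet(4, 4)
  m <- matrix(25, nrow = 3, ncol = 8,
              dimnames = list(c("full", "no_ctl", "half"),
                              sprintf("s%02d", 1:8)))
  det <- matrix(TRUE, 3, 8, dimnames = dimnames(m))
  det["no_ctl", 5:8] <- FALSE            # 0% of controls
  det["half", c(1, 2, 5, 6)] <- TRUE
  det["half", c(3, 4, 7, 8)] <- FALSE    # exactly 50% in both cohorts
  x <- ct_matrix(m, detected = det, stage = "censored")
  kept <- filter_assays(x, sheet, min_det_frac = 0.5, quiet = TRUE)
  expect_identical(assay_ids(kept), c("full", "half"))

  # brute-force recount on a random mask agrees
  set.seed(5)
  x2 <- rand_ct(120, 8, seed = 5, p_missing = 0.6)
  colnames(x2$ct) <- colnames(x2$detected) <- sheet$sample_id
  kept2 <- filter_assays(x2, sheet, min_det_frac = 0.5, quiet = TRUE)
  oracle <- vapply(seq_len(120), function(i) {
    d <- x2$detected[i, ]
    mean(d[1:4]) >= 0.5 && mean(d[5:8]) >= 0.5
  }, logical(1))
  expect_identical(assay_ids(kept2), assay_ids(x2)[oracle])

  empty <- mk_sheet(8, 0)
  expect_error(filter_assays(x2, empty, quiet = TRUE), "zero samples")
})

test_that("quantile normalization matches the sort/row-mean oracle", {
  # worked example: all samples map to (2, 13/3, 20/3)
  m <- matrix(c(2, 1, 3, 4, 3, 6, 6, 5, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  qn <- quantile_normalize(ct_matrix(m, stage = "censored"))
  tgt <- c(2, 13 / 3, 20 / 3)
  for (s in 1:3) expect_equal(unname(sort(qn$ct[, s])), tgt)
  # order within sample preserved: s3 was already sorted
  expect_equal(unname(qn$ct[, "s3"]), tgt)

  # fixed point: identical samples unchanged
  same <- matrix(rep(c(20, 25, 30), 4), nrow = 3,
                 dimnames = list(c("A", "B", "C"), sprintf("s%d", 1:4)))
  expect_equal(quantile_normalize(ct_matrix(same, stage = "censored"))$ct, same)

  # property on random fully detected matrices: sorted columns all equal the
  # row means of the sorted input columns; global mean preserved
  for (seed in 1:5) {
    x <- rand_ct(40, 7, seed = seed)
    qn <- quantile_normalize(x)
    oracle <- rowMeans(apply(x$ct, 2, sort))
    for (j in 1:7) expect_equal(unname(sort(qn$ct[, j])), unname(oracle), tolerance = 1e-12)
    expect_equal(mean(qn$ct), mean(x$ct), tolerance = 1e-9)
  }
})

test_that("quantile normalization agrees with limma on fully detected input", {
  skip_if_not_installed("limma")
  x <- rand_ct(60, 9, seed = 11)
  qn <- quantile_normalize(x)
  ref <- limma::normalizeQuantiles(x$ct, ties = TRUE)
  expect_equal(unname(qn$ct), unname(ref), tolerance = 1e-9)
})

test_that("normalization under censoring aligns detected quantiles only", {
  x <- rand_ct(80, 6, seed = 3, p_missing = 0.2)
  qn <- quantile_normalize(x)
  # undetected cells untouched
  expect_identical(qn$detected, x$detected)
  expect_identical(is.na(masked_ct <- qn$ct[!qn$detected]), is.na(x$ct[!x$detected]))
  # equal detected counts => identical sorted vectors
  n_det <- colSums(x$detected)
  eq <- which(n_det == max(n_det))
  if (length(eq) >= 2) {
    v1 <- unname(sort(qn$ct[qn$detected[, eq[1]], eq[1]]))
    v2 <- unname(sort(qn$ct[qn$detected[, eq[2]], eq[2]]))
    expect_equal(v1, v2, tolerance = 1e-9)
  }
  # sample with < 2 detected values errors by name
  bad <- x
  bad$detected[, 2] <- FALSE
  bad$detected[1, 2] <- TRUE
  expect_error(quantile_normalize(bad), "s002")
})

test_that("reference selection takes the lowest-SD fully detected assays", {
  # 10 constant assays dominate
  set.seed(7)
  m <- rbind(matrix(rep(seq(20, 24.5, by = 0.5), each = 6), nrow = 10,
                    byrow = TRUE,
                    dimnames = list(sprintf("const%02d", 1:10), NULL)),
             matrix(rnorm(120, 27, 2), nrow = 20,
                    dimnames = list(sprintf("var%02d", 1:20), NULL)))
  colnames(m) <- sprintf("s%02d", 1:6)
  x <- ct_matrix(m, stage = "censored")
  ref <- select_reference(x, size = 10)
  expect_setequal(ref$assay_ids, sprintf("const%02d", 1:10))
  expect_true(all(ref$selection_sd == 0))
  # per-sample mean is the members' column mean
  expect_equal(ref$per_sample_mean,
               colMeans(m[ref$assay_ids, ]))

  # brute-force sort oracle on distinct SDs
  x2 <- rand_ct(15, 8, seed = 2)
  ref2 <- select_reference(x2, size = 10)
  sds <- apply(x2$ct, 1, sd)
  expect_identical(ref2$assay_ids,
                   names(sort(sds))[1:10])

  # permutation invariance to row order
  perm <- sample(nrow(x2$ct))
  x2p <- ct_matrix(x2$ct[perm, ], stage = "censored")
  expect_setequal(select_reference(x2p, size = 10)$assay_ids, ref2$assay_ids)

  # precondition: too few fully detected assays
  x3 <- rand_ct(9, 4, seed = 3)
  expect_error(select_reference(x3, size = 10), "9 fully-detected")
  expect_warning(ref3 <- select_reference(x3, size = 10, allow_fewer = TRUE),
                 "using all 9")
  expect_length(ref3$assay_ids, 9)
})

test_that("delta-CT matches its definition and is shift-invariant", {
  x <- rand_ct(20, 8, seed = 13, p_missing = 0.1)
  ref <- select_reference(x, size = 5, allow_fewer = TRUE)
  dct <- compute_delta_ct(x, ref)
  # brute-force cell-by-cell recomputation
  for (i in seq_len(20)) for (j in seq_len(8)) {
    if (x$detected[i, j]) {
      expect_equal(dct$delta_ct[i, j],
                   x$ct[i, j] - mean(x$ct[ref$assay_ids, j]))
    } else {
      expect_true(is.na(dct$delta_ct[i, j]))
    }
  }
  # reference members average to zero within each sample
  expect_equal(unname(colMeans(dct$delta_ct[ref$assay_ids, ])),
               rep(0, 8), tolerance = 1e-12)

  # per-sample additive shift leaves delta-CT unchanged
  shift <- x
  shift$ct[, 3] <- shift$ct[, 3] + 3
  ref_s <- rebase_reference(ref, shift)
  dct_s <- compute_delta_ct(shift, ref_s)
  expect_equal(dct_s$delta_ct[x$detected], dct$delta_ct[x$detected],
               tolerance = 1e-12)

  bad_ref <- ref
  bad_ref$assay_ids[1] <- "missing-assay"
  expect_error(compute_delta_ct(x, bad_ref), "missing-assay")
})
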