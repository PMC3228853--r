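test_that("relative expression centers controls and matches the cell oracle", {
  sheet <- mk_sheet(4, 4)
  set.seed(6)
  m <- matrix(rnorm(48, 2, 1), nrow = 6,
              dimnames = list(sprintf("a%d", 1:6), sheet$sample_id))
  m[2, 5] <- NA
  dct <- mk_dct(m)
  rel <- relative_expression(dct, sheet, sprintf("a%d", 1:6))
  ctl <- sheet$sample_id[sheet$cohort == "control"]
  # control-only means are ~0 per assay
  expect_equal(unname(rowMeans(rel$rel[, ctl], na.rm = TRUE)), rep(0, 6),
               tolerance = 1e-12)
  # cell-wise brute force
  for (i in 1:6) for (j in 1:8) {
    expect_equal(rel$rel[i, j],
                 -(m[i, j] - mean(m[i, ctl], na.rm = TRUE)))
  }
  # planted +2-cycle shift shows as rel = -2
  m2 <- m; m2[1, 1] <- mean(m[1, ctl]) + 2
  rel2 <- relative_expression(mk_dct(m2), sheet, "a1")
  expect_equal(rel2$rel["a1", 1], -2)
  expect_error(relative_expression(dct, sheet, "nope"), "absent")
  expect_error(relative_expression(dct, sheet, character()), "empty")
})

test_that("clustering separates duplicated blocks exactly and is equivariant", {
  set.seed(17)
  profile_a <- rnorm(10); profile_b <- profile_a + 4
  m <- cbind(matrix(rep(profile_a, 5), ncol = 5),
             matrix(rep(profile_b, 5), ncol = 5))
  dimnames(m) <- list(sprintf("a%d", 1:10), sprintf("s%02d", 1:10))
  rel <- structure(list(rel = m, detected = !is.na(m)),
                   class = "rel_expr_matrix")
  cl <- cluster_samples(rel, k = 2)
  truth <- rep(1:2, each = 5)
  expect_identical(adjusted_rand_index(cl$labels, truth), 1)

  # permuting samples changes at most the numbering, never the partition
  perm <- sample(10)
  m_p <- m[, perm]
  rel_p <- structure(list(rel = m_p, detected = !is.na(m_p)),
                     class = "rel_expr_matrix")
  cl_p <- cluster_samples(rel_p, k = 2)
  expect_identical(
    adjusted_rand_index(cl$labels[colnames(m_p)], cl_p$labels), 1)

  # equivariance with noise too (no exact ties)
  m2 <- m + matrix(rnorm(100, sd = 0.3), nrow = 10)
  for (k in 2:4) {
    r1 <- structure(list(rel = m2, detected = !is.na(m2)),
                    class = "rel_expr_matrix")
    r2 <- structure(list(rel = m2[, perm], detected = !is.na(m2[, perm])),
                    class = "rel_expr_matrix")
    c1 <- cluster_samples(r1, k = k)
    c2 <- cluster_samples(r2, k = k)
    expect_identical(
      adjusted_rand_index(c1$labels[names(c2$labels)], c2$labels), 1)
  }

  expect_error(cluster_samples(rel, k = 1), "between 2")
  expect_error(cluster_samples(rel, k = 11), "between 2")
})

test_that("group composition counts cohorts and finds the signature group", {
  sheet <- mk_sheet(6, 4)
  labels <- c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L)
  names(labels) <- sheet$sample_id       # patients s01-s06, controls s07-s10
  cl <- structure(list(k = 3L, labels = labels), class = "cluster_result")
  comp <- group_composition(cl, sheet)
  expect_identical(comp$n_patients, c(3L, 3L, 0L))
  expect_identical(comp$n_controls, c(0L, 2L, 2L))
  expect_identical(comp$patient_only, c(TRUE, FALSE, FALSE))
  expect_identical(attr(comp, "signature_group"), 1L)
  # fractions sum to 1 within each cohort
  expect_equal(sum(comp$frac_patients), 1)
  expect_equal(sum(comp$frac_controls), 1)

  # no patient-only group -> ambiguous signature
  labels2 <- stats::setNames(c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 1L, 2L),
                             sheet$sample_id)
  cl2 <- structure(list(k = 2L, labels = labels2), class = "cluster_result")
  expect_true(is.na(attr(group_composition(cl2, sheet), "signature_group")))
})

test_that("subgroup re-test reduces to the primary comparison for all patients", {
  set.seed(23)
  sheet <- mk_sheet(8, 6)
  m <- matrix(rnorm(14 * 12), nrow = 12,
              dimnames = list(sprintf("a%02d", 1:12), sheet$sample_id))
  dct <- mk_dct(m)
  labels <- stats::setNames(ifelse(sheet$cohort == "patient", 1L, 2L),
                            sheet$sample_id)
  cl <- structure(list(k = 2L, labels = labels), class = "cluster_result")
  sub <- subgroup_differential(dct, sheet, cl, 1L)
  main <- differential_table(dct, sheet)
  ord <- order(sub$assay); ord2 <- order(main$assay)
  expect_equal(sub$p[ord], main$p[ord2], tolerance = 1e-12)
  expect_equal(sub$delta_delta_ct[ord], main$delta_delta_ct[ord2],
               tolerance = 1e-12)
  expect_error(subgroup_differential(dct, sheet, cl, 5L), "unknown group")
})

test_that("adjusted Rand index behaves at its anchors", {
  expect_identical(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_identical(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(12)
  # independent random labelings hover near 0
  ari <- replicate(200, adjusted_rand_index(sample(1:3, 60, TRUE),
                                            sample(1:3, 60, TRUE)))
  expect_lt(abs(mean(ari)), 0.02)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("heatmap export reorders by the dendrogram leaves", {
  set.seed(33)
  sheet <- mk_sheet(4, 3)
  m <- matrix(rnorm(21), nrow = 3,
              dimnames = list(c("a1", "a2", "a3"), sheet$sample_id))
  rel <- relative_expression(mk_dct(m), sheet, c("a1", "a2", "a3"))
  cl <- cluster_samples(rel, k = 2)
  hm <- heatmap_matrix(rel, cl)
  expect_identical(hm$assay, cl$assay_order)
  expect_identical(colnames(hm)[-1], cl$sample_order)
  expect_equal(hm[[cl$sample_order[1]]],
               unname(rel$rel[cl$assay_order, cl$sample_order[1]]))
})
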