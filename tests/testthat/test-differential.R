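test_that("signed fold change follows the 2^-ddCT convention", {
  expect_identical(fold_change_from_ddct(0), 1)
  expect_identical(fold_change_from_ddct(1), -2)
  expect_identical(fold_change_from_ddct(-2), 4)
  expect_error(fold_change_from_ddct(NaN), "finite")
  expect_error(fold_change_from_ddct(Inf), "finite")

  # odd symmetry: |f(x)| = |f(-x)| and the signs mirror; never in (-1, 1)
  x <- seq(-8, 8, by = 0.37)
  f <- fold_change_from_ddct(x)
  g <- fold_change_from_ddct(-x)
  expect_equal(abs(f), abs(g), tolerance = 1e-12)
  expect_true(all((f >= 1) == (g <= -1) | x == 0))
  expect_true(all(abs(f) >= 1))
})

test_that("student t matches the pooled closed form and stats::t.test", {
  res <- two_sample_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12) # = -3.674...
  expect_identical(res$df, 4)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)

  # identical groups
  res0 <- two_sample_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(res0$t, 0)
  expect_identical(res0$p, 1)

  # swapping groups flips t, keeps p
  a <- rnorm(8); b <- rnorm(5)
  r1 <- two_sample_test(a, b); r2 <- two_sample_test(b, a)
  expect_equal(r1$t, -r2$t, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)

  # random small inputs vs the closed form and vs stats::t.test
  set.seed(21)
  for (i in 1:50) {
    a <- rnorm(sample(2:12, 1)); b <- rnorm(sample(2:12, 1), 0.5)
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t_or <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    mine <- two_sample_test(a, b)
    expect_equal(mine$t, t_or, tolerance = 1e-12)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    refw <- t.test(a, b)
    minew <- two_sample_test(a, b, variant = "welch")
    expect_equal(minew$p, refw$p.value, tolerance = 1e-12)
    expect_equal(minew$df, unname(refw$parameter), tolerance = 1e-9)
  }
  expect_error(two_sample_test(1, c(1, 2)), ">= 2")
})

test_that("BH adjustment matches a brute-force step-up and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  brute <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (k in seq_len(m)) {
      q[o[k]] <- min(1, min(p[o][k:m] * m / (k:m)))
    }
    q
  }
  set.seed(31)
  for (i in 1:40) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute(p), tolerance = 1e-14)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
  # NA pass-through
  p <- c(0.01, NA, 0.5)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], p.adjust(p, "BH")[c(1, 3)])
})

test_that("differential table recovers a planted shift and flags thin features", {
  set.seed(100)
  n_pat <- 41; n_ctl <- 20
  sheet <- mk_sheet(n_pat, n_ctl)
  m <- matrix(rnorm(50 * 61, sd = 0.5), nrow = 50,
              dimnames = list(sprintf("a%03d", 1:50), sheet$sample_id))
  m["a001", 1:n_pat] <- m["a001", 1:n_pat] + 2   # +2 cycles in patients
  det <- !is.na(m)
  det["a002", 1:60] <- FALSE                     # 1 detected value only
  dct <- mk_dct(m, det)
  tab <- differential_table(dct, sheet)
  row <- tab[tab$assay == "a001", ]
  expect_true(row$significant)
  expect_equal(row$fold_change, -4, tolerance = 0.25)
  expect_false(tab$tested[tab$assay == "a002"])
  expect_true(is.na(tab$p[tab$assay == "a002"]))

  # q >= p and q monotone in p rank order among tested features
  ok <- tab$tested
  expect_true(all(tab$q[ok] >= tab$p[ok] - 1e-15))
  o <- order(tab$p[ok])
  expect_true(all(diff(tab$q[ok][o]) >= -1e-15))

  # oracle per-feature: p equals stats::t.test on the same detected values
  for (a in c("a001", "a010", "a037")) {
    va <- m[a, 1:n_pat][det[a, 1:n_pat]]
    vb <- m[a, (n_pat + 1):61][det[a, (n_pat + 1):61]]
    expect_equal(tab$p[tab$assay == a],
                 t.test(va, vb, var.equal = TRUE)$p.value, tolerance = 1e-9)
  }
  expect_error(differential_table(dct, sheet, groups = c("patient", "cases")),
               "unknown group label")
})

test_that("fold-change source can differ from the test source", {
  set.seed(4)
  sheet <- mk_sheet(5, 5)
  m_test <- matrix(rnorm(40), nrow = 4,
                   dimnames = list(sprintf("a%d", 1:4), sheet$sample_id))
  m_fc <- m_test + 1          # shifted copy changes ddCT, not p
  t1 <- differential_table(mk_dct(m_test), sheet)
  t2 <- differential_table(mk_dct(m_test), sheet, fc_dct = mk_dct(m_fc))
  expect_equal(t1$p, t2$p)
  expect_equal(t2$delta_delta_ct[order(t2$assay)],
               t1$delta_delta_ct[order(t1$assay)])  # constant shift cancels
})

test_that("analyte differential flags the planted elevated analytes", {
  # identical cohorts -> nothing significant
  set.seed(8)
  sheet <- mk_sheet(10, 10)
  base <- rlnorm(20, log(50), 0.3)
  panel <- structure(data.frame(sample_id = sheet$sample_id, VEGF = base,
                                IL6 = rlnorm(20, log(2), 0.3),
                                stringsAsFactors = FALSE),
                     class = c("analyte_panel", "data.frame"))
  tab <- analyte_differential(panel, sheet)
  expect_false(any(tab$significant))

  # doubling one cohort with tiny noise -> p below any fixed alpha
  panel2 <- panel
  panel2$VEGF <- c(rep(100, 10), rep(50, 10)) * exp(rnorm(20, sd = 0.01))
  tab2 <- analyte_differential(panel2, sheet)
  expect_lt(tab2$p[tab2$analyte == "VEGF"], 1e-10)
  expect_equal(tab2$fold_change[tab2$analyte == "VEGF"], 2, tolerance = 0.02)

  # all-missing analyte skipped with flag, not an error
  panel2$IL6 <- NA_real_
  tab3 <- analyte_differential(panel2, sheet)
  expect_false(tab3$tested[tab3$analyte == "IL6"])

  # planted three-analyte elevation on the default generator: all three
  # recovered in every seed; false extras bounded by the BH guarantee
  hits <- logical(12); extras <- integer(12)
  for (s in 1:12) {
    co <- simulate_cohort(sim_config(seed = 300 + s))
    tt <- analyte_differential(co$panel, co$sheet)
    sig <- tt$analyte[tt$significant]
    hits[s] <- all(c("VEGF", "IL1Ra", "MCP1") %in% sig)
    extras[s] <- length(setdiff(sig, c("VEGF", "IL1Ra", "MCP1")))
  }
  expect_true(all(hits))
  expect_lt(mean(extras), 1)
})
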