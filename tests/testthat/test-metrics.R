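# Diagnostic accuracy, weighted kappa, suppression.

test_that("confusion_2x2 matches the definitional rates", {
  perfect <- confusion_2x2(counts = c(TP = 50, FP = 0, TN = 30, FN = 0))
  expect_equal(unname(perfect$estimates), rep(1, 4))
  cc <- confusion_2x2(counts = c(TP = 90, FP = 10, TN = 60, FN = 40))
  expect_equal(cc$estimates[["sensitivity"]], 90 / 130)
  expect_equal(cc$estimates[["specificity"]], 60 / 70)
  expect_equal(cc$estimates[["ppv"]], 0.90)
  expect_equal(cc$estimates[["npv"]], 0.60)
  expect_equal(cc$n, 200)
})

test_that("zero denominators give flagged-undefined metrics, not 0 or 1", {
  cc <- confusion_2x2(claims = c(TRUE, TRUE, FALSE),
                      reference = c(TRUE, TRUE, TRUE))
  expect_true(is.na(cc$estimates[["specificity"]]))
  expect_true(cc$undefined[["specificity"]])
  expect_equal(cc$estimates[["npv"]], 0)  # TN=0, FN=1: defined, poor
  expect_false(cc$undefined[["npv"]])
  expect_false(cc$undefined[["sensitivity"]])
  expect_error(confusion_2x2(logical(0), logical(0)))
  expect_error(confusion_2x2(c(TRUE, NA), c(TRUE, TRUE)), "missing")
})

test_that("agreement_table fills counts, marginals and independence expectation", {
  tab <- agreement_table(c(1, 1, 2), c(1, 2, 2), k = 3)
  expect_equal(rowSums(tab$O), c(`1` = 2, `2` = 1, `3` = 0))
  expect_equal(colSums(tab$O), c(`1` = 1, `2` = 2, `3` = 0))
  expect_equal(sum(tab$E), sum(tab$O))
  expect_equal(tab$E[1, 2], 2 * 2 / 3)
  one <- agreement_table(rep(3, 10), rep(3, 10), k = 10)
  expect_equal(one$O[3, 3], 10)
  expect_equal(sum(one$O), 10)
  expect_error(agreement_table(integer(0), integer(0), k = 3),
               "no comparable pairs")
  expect_error(agreement_table(1:3, c(1, 2, 9), k = 3), "scheme")
})

test_that("weighted kappa: perfect agreement, chance agreement, degenerate table", {
  diag_tab <- as_agreement(diag(c(5, 7, 9)))
  expect_equal(weighted_kappa(diag_tab, "linear")$kappa, 1)
  expect_equal(weighted_kappa(diag_tab, "quadratic")$kappa, 1)
  # O exactly at independence: kappa 0
  O <- outer(c(2, 8), c(4, 6)) # N = 100... rows 2,8 cols scaled
  tab <- as_agreement(O)
  expect_equal(weighted_kappa(tab)$kappa, 0, tolerance = 1e-12)
  # all mass in one cell: undefined, flagged
  k1 <- weighted_kappa(as_agreement(matrix(c(12, 0, 0, 0), 2, 2)))
  expect_true(k1$undefined)
  expect_true(is.na(k1$kappa))
})

test_that("2x2 weighted kappa equals unweighted Cohen's kappa", {
  O <- matrix(c(20, 10, 5, 65), 2, 2)  # O[1,1]=20, O[1,2]=5, O[2,1]=10
  tab <- as_agreement(O)
  # independent hand computation of the unweighted kappa
  n <- sum(O)
  po <- sum(diag(O)) / n
  pe <- sum(rowSums(O) * colSums(O)) / n^2
  expected <- (po - pe) / (1 - pe)
  expect_equal(weighted_kappa(tab, "linear")$kappa, expected,
               tolerance = 1e-12)
  expect_equal(weighted_kappa(tab, "quadratic")$kappa, expected,
               tolerance = 1e-12)
  skip_if_not_installed("e1071")
  expect_equal(weighted_kappa(tab, "linear")$kappa,
               e1071::classAgreement(O)$kappa, tolerance = 1e-10)
})

test_that("kappa properties: bounds, reversal invariance, monotone degradation", {
  set.seed(42)
  for (r in 1:50) {
    k <- sample(2:10, 1)
    O <- random_table(k, sample(c(20, 200, 1000), 1))
    tab <- as_agreement(O)
    for (wgt in c("linear", "quadratic")) {
      kap <- weighted_kappa(tab, wgt)
      if (kap$undefined) next
      expect_gte(kap$kappa, -1)
      expect_lte(kap$kappa, 1)
      # invariant under simultaneous row/column order reversal
      rev_tab <- as_agreement(O[k:1, k:1, drop = FALSE])
      expect_lt(abs(weighted_kappa(rev_tab, wgt)$kappa - kap$kappa),
                1e-12)
    }
  }
  # moving mass off the diagonal never increases kappa
  set.seed(7)
  for (r in 1:20) {
    k <- sample(3:8, 1)
    O <- random_table(k, 500) + diag(k) * 5
    i <- sample(which(diag(O) >= 1), 1)
    j <- sample(setdiff(1:k, i), 1)
    O2 <- O
    O2[i, i] <- O2[i, i] - 1
    O2[i, j] <- O2[i, j] + 1
    k1 <- weighted_kappa(as_agreement(O))
    k2 <- weighted_kappa(as_agreement(O2))
    if (!k1$undefined && !k2$undefined)
      expect_lte(k2$kappa, k1$kappa + 1e-12)
  }
})

test_that("interpretation bands use the 0.40 / 0.75 cutpoints", {
  t_hi <- as_agreement(diag(c(40, 40)) + 1)
  expect_equal(weighted_kappa(t_hi)$band, "excellent")
  O <- matrix(c(30, 20, 20, 30), 2, 2)
  expect_equal(weighted_kappa(as_agreement(O))$band, "poor")
})

test_that("asymptotic and bootstrap intervals agree on a large table", {
  set.seed(314)
  # simulate a plausible 10-level table, N = 3000
  lev_p <- c(0.01, 0.02, 0.05, 0.12, 0.2, 0.25, 0.15, 0.12, 0.05, 0.03)
  truth <- sample(1:10, 3000, TRUE, lev_p)
  claims <- pmin(10, pmax(1, truth + sample(c(-1, 0, 1), 3000, TRUE,
                                            c(0.1, 0.8, 0.1))))
  tab <- agreement_table(claims, truth, 10)
  a <- kappa_ci(tab, method = "asymptotic")
  b <- kappa_ci(tab, method = "bootstrap", B = 2000, seed = 99)
  expect_lt(abs(a$ci$lower - b$ci$lower), 0.02)
  expect_lt(abs(a$ci$upper - b$ci$upper), 0.02)
  expect_equal(a$kappa, b$kappa)
  # bootstrap is reproducible for a fixed seed
  b2 <- kappa_ci(tab, method = "bootstrap", B = 2000, seed = 99)
  expect_identical(b$ci, b2$ci)
})

test_that("degenerate and small-sample intervals are flagged", {
  perf <- as_agreement(diag(c(30, 40)))
  ci <- kappa_ci(perf)
  expect_equal(c(ci$ci$lower, ci$ci$upper), c(1, 1))
  expect_true(ci$ci$degenerate)
  small <- as_agreement(matrix(c(5, 1, 2, 6), 2, 2))
  expect_warning(kappa_ci(small, method = "asymptotic"), "N < 30")
})

test_that("per-level metrics collapse one-vs-rest correctly", {
  d <- as_agreement(diag(c(12, 15, 20)))
  pl <- per_level_metrics(d)
  expect_true(all(pl$sensitivity == 1 & pl$specificity == 1 &
                    pl$ppv == 1 & pl$npv == 1))
  O <- matrix(0, 3, 3)
  O[1, 1] <- 8; O[1, 2] <- 2; O[2, 2] <- 10
  pl <- per_level_metrics(as_agreement(O))
  expect_equal(pl$ppv[1], 0.8)
  expect_equal(pl$sensitivity[1], 1)  # all reference-1 caught
  # level with zero reference count: sensitivity not calculated
  expect_true(pl$sensitivity_undefined[3])
  expect_true(is.na(pl$sensitivity[3]))
})

test_that("small-cell suppression masks at the threshold boundary with bounds", {
  O <- matrix(0, 2, 2)
  O[1, 1] <- 100; O[1, 2] <- 10; O[2, 2] <- 11; O[2, 1] <- 40
  pl <- per_level_metrics(as_agreement(O))
  sup <- suppress_small_cells(pl, threshold = 10)
  # level 1: TP=100 (kept), FP=10 (masked), FN=40, TN=11
  expect_equal(sup$TP_display[1], "100")
  expect_equal(sup$FP_display[1], "--")
  expect_equal(sup$TN_display[1], "11")
  # PPV = TP/(TP+FP) with FP masked: one-sided lower bound 100/110
  expect_equal(sup$ppv_display[1], "> 91")
  # sensitivity unaffected: 100/140
  expect_equal(sup$sensitivity_display[1], "71")
  # masked numerator gives an upper bound: level 2 sensitivity TP=11? no:
  # level 2: TP=11 kept, FN=10 masked -> bound
  expect_equal(sup$sensitivity_display[2], "> 52")  # 11/(11+10)
})

test_that("printed percentages round half-up to one decimal", {
  expect_equal(round_half_up(c(0.05, 0.15, 2.345), c(1, 1, 2)),
               c(0.1, 0.2, 2.35))
  expect_equal(format_pct(0.93355), 93.4)
  expect_equal(format_pct(1 / 3), 33.3)
})
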