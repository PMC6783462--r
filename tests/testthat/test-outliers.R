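test_that("standardization is an affine z-score within each drug", {
  expect_equal(unname(standardize_random_effects(c(a = -1, b = 0, c = 1))),
               c(-1, 0, 1))
  # affine invariance
  expect_equal(unname(standardize_random_effects(c(a = 2, b = 4, c = 6))),
               c(-1, 0, 1))
  set.seed(5)
  x <- setNames(rnorm(40, 3, 2), sprintf("c%02d", 1:40))
  s <- standardize_random_effects(x)
  expect_lt(abs(mean(s)), 1e-12)
  expect_lt(abs(sd(s) - 1), 1e-12)
  # degenerate all-equal column
  d <- standardize_random_effects(c(a = 1, b = 1, c = 1))
  expect_true(all(is.na(d)))
  expect_true(attr(d, "degenerate"))
  expect_error(standardize_random_effects(c(a = 1)), ">= 2")
})

test_that("SRE classification matches the confidence-boundary typology", {
  cl <- classify_sre(c(-2.7, 0, 3.2))
  expect_equal(cl$type, c("II", "neutral", "III"))
  expect_equal(cl$side, c("sensitive", "none", "resistant"))
})

test_that("the five SRE regions partition the line exactly", {
  eps <- 1e-9
  pts <- c(-3 - eps, -3, -3 + eps, -2.5 - eps, -2.5, -2.5 + eps,
           -1.65 - eps, -1.65, -1.65 + eps, 0,
           1.65 - eps, 1.65, 1.65 + eps, 2.5 - eps, 2.5, 2.5 + eps,
           3 - eps, 3, 3 + eps)
  cl <- classify_sre(pts)
  # every point maps to exactly one label
  expect_false(anyNA(cl$type))
  lab <- function(s) cl$type[match(s, cl$sre)]
  # sensitive side: (-2.5, -1.65] is I, (-3, -2.5] is II, beyond -3 is III
  expect_equal(lab(-1.65), "I")
  expect_equal(lab(-1.65 + eps), "neutral")
  expect_equal(lab(-2.5), "II")
  expect_equal(lab(-2.5 + eps), "I")
  expect_equal(lab(-3), "III")
  expect_equal(lab(-3 + eps), "II")
  # resistant side: [1.65, 2.5) is I, [2.5, 3) is II, 3 and beyond III
  expect_equal(lab(1.65), "I")
  expect_equal(lab(1.65 - eps), "neutral")
  expect_equal(lab(2.5), "II")
  expect_equal(lab(2.5 - eps), "I")
  expect_equal(lab(3), "III")
  expect_equal(lab(3 - eps), "II")
  expect_error(classify_sre(c(1, NA)), "finite")
  expect_error(classify_sre(Inf), "finite")
})

test_that("worked proportion examples classify as published screens report", {
  # resistant in a third of drugs beyond 1.65 and all drugs above zero
  expect_equal(unname(outlier_verdicts(0, 0, 0.33, 1)["combined"]),
               "resistant")
  # sensitive in 43% beyond -1.65 and 86% below zero
  expect_equal(unname(outlier_verdicts(0.43, 0.86, 0, 0)["combined"]),
               "sensitive")
  # below every threshold
  v <- outlier_verdicts(0.10, 0.50, 0.10, 0.50)
  expect_equal(unname(v), c("neutral", "neutral", "neutral"))
})

test_that("combined verdict implies both single-rule verdicts", {
  set.seed(11)
  for (k in 1:200) {
    p_lt0 <- runif(1)
    p_ltm <- runif(1) * p_lt0       # extreme subset of negative
    p_gt0 <- runif(1) * (1 - p_lt0)
    p_gtm <- runif(1) * p_gt0
    v <- outlier_verdicts(p_ltm, p_lt0, p_gtm, p_gt0)
    if (v[["combined"]] != "neutral") {
      expect_equal(v[["ci"]], v[["combined"]])
      expect_equal(v[["dist"]], v[["combined"]])
    }
  }
})

test_that("outlier calls respect missingness and the minimum-drug rule", {
  M <- matrix(NA_real_, 3, 6,
              dimnames = list(c("s1", "s2", "s3"), sprintf("d%d", 1:6)))
  M["s1", ] <- c(-2, -1, -0.5, -2.2, -0.1, -0.3)  # sensitive pattern
  M["s2", 1:2] <- c(2, 2.5)                       # only 2 modeled drugs
  M["s3", ] <- c(0.1, -0.2, 0.3, -0.1, 0.2, -0.3)
  calls <- call_outliers(M)
  s1 <- calls[calls$cell_line == "s1", ]
  expect_equal(s1$n_drugs_modeled, 6L)
  expect_equal(s1$p_lt_m165, 2 / 6)
  expect_equal(s1$p_lt_0, 1)
  expect_equal(s1$verdict_combined, "sensitive")
  s2 <- calls[calls$cell_line == "s2", ]
  expect_true(s2$verdict_withheld)
  expect_true(is.na(s2$verdict_combined))
  s3 <- calls[calls$cell_line == "s3", ]
  expect_equal(s3$verdict_combined, "neutral")
})

test_that("boundary SREs count toward the proportion rules", {
  # exactly -1.65 is Type I and counts as beyond the boundary, so the
  # interval typology and the proportion rule agree at the threshold
  M <- matrix(c(-1.65, -1.65, -0.5, -0.2, -0.4), 1, 5,
              dimnames = list("s", sprintf("d%d", 1:5)))
  calls <- call_outliers(M)
  expect_equal(calls$p_lt_m165, 0.4)
  expect_equal(calls$verdict_combined, "sensitive")
})

test_that("threshold coverages reproduce the stated confidence levels", {
  cov <- threshold_coverage()
  expect_equal(cov[1], 95, tolerance = 0.001)    # 95.05
  expect_equal(cov[2], 99.4, tolerance = 0.0005) # 99.38
  expect_equal(cov[3], 99.9, tolerance = 0.0005) # 99.87
})

test_that("sre_table standardizes per drug over the fitted lines only", {
  blups <- data.frame(
    cell_line = c("a", "b", "c", "a", "b", "c", "d"),
    drug = c("d1", "d1", "d1", "d2", "d2", "d2", "d2"),
    b3 = c(2, 4, 6, 0.5, 0.7, 0.9, 0.3))
  M <- sre_table(blups)
  expect_equal(dim(M), c(4L, 2L))
  expect_equal(unname(M[c("a", "b", "c"), "d1"]), c(-1, 0, 1))
  expect_true(is.na(M["d", "d1"]))
  expect_lt(abs(mean(M[, "d2"], na.rm = TRUE)), 1e-12)
})
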