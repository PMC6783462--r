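test_that("identical seed and config reproduce the panel bit-for-bit", {
  s1 <- generate_panel(10, 3, truth = truth_config(outlier_fraction = 0.2),
                       seed = 7)
  s2 <- generate_panel(10, 3, truth = truth_config(outlier_fraction = 0.2),
                       seed = 7)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$truth$b, s2$truth$b)
  expect_identical(s1$truth$outliers, s2$truth$outliers)
  s3 <- generate_panel(10, 3, truth = truth_config(outlier_fraction = 0.2),
                       seed = 8)
  expect_false(identical(s1$panel$response, s3$panel$response))
})

test_that("noiseless all-4P panels lie exactly on the generating curves", {
  sim <- generate_panel(5, 2, truth = truth_config(sigma = 0), seed = 3)
  for (cl in rownames(sim$truth$b)) {
    for (d in colnames(sim$truth$forms)) {
      g <- sim$panel[sim$panel$cell_line == cl & sim$panel$drug == d, ]
      tr <- series_truth(sim, cl, d)
      expect_equal(g$response,
                   evaluate_curve(tr$form, tr$params, g$dose_uM))
      fit <- fit_single_curve(g$dose_uM, g$response, "4P")
      expect_lt(fit$rss, 1e-8)
    }
  }
})

test_that("injected outlier lines shift true b3 by the configured delta", {
  tr <- truth_config(outlier_fraction = 0.05, sigma = 5)
  sim <- generate_panel(50, 10, truth = tr, seed = 12)
  out <- sim$truth$outliers
  expect_length(out, round(0.05 * 50))
  b3 <- sim$truth$b[, "b3"]
  gap <- mean(b3[out]) - mean(b3[setdiff(names(b3), out)])
  # delta = -3 sd(b3) = -2.4; sampling noise of the non-outlier mean and
  # the 2-3 outlier draws allows roughly +- 2 sd(b3)/sqrt(n_out)
  expect_lt(gap, -2.4 + 2 * 0.8 / sqrt(length(out)) + 0.35)
  expect_gt(gap, -2.4 - 2 * 0.8 / sqrt(length(out)) - 0.35)
})

test_that("form reassignment hits the requested proportions", {
  sim <- generate_panel(100, 10, truth = truth_config(sigma = 2), seed = 5)
  fr <- c("4P" = 0.5, "3P" = 0.3, "linear" = 0.2)
  sim <- inject_form_heterogeneity(sim, fr, seed = 6)
  counts <- table(factor(sim$truth$forms, levels = form_labels()))
  n <- sum(counts)
  expect_equal(n, 1000)
  for (fm in names(fr)) {
    bounds <- qbinom(c(0.005, 0.995), n, fr[[fm]])
    expect_gte(counts[[fm]], bounds[1])
    expect_lte(counts[[fm]], bounds[2])
  }
})

test_that("all-4P reassignment leaves the panel unchanged", {
  sim <- generate_panel(8, 2, seed = 9)
  sim2 <- inject_form_heterogeneity(sim, c("4P" = 1), seed = 10)
  expect_identical(sim$panel, sim2$panel)
})

test_that("noiseless linear-assigned series are exactly linear", {
  sim <- generate_panel(6, 2, truth = truth_config(sigma = 0), seed = 14)
  sim <- inject_form_heterogeneity(sim, c("linear" = 1), seed = 15)
  for (cl in c("CL001", "CL004")) {
    g <- sim$panel[sim$panel$cell_line == cl & sim$panel$drug == "D02", ]
    fit <- fit_single_curve(g$dose_uM, g$response, "linear")
    expect_lt(fit$rss, 1e-16)
  }
})

test_that("stored random effects reproduce the configured covariance", {
  tr <- truth_config(sd_b3 = 0.8, sd_b4 = 0.3, corr = 0.4)
  sim <- generate_panel(2000, 1, truth = tr, seed = 20)
  S <- cov(sim$truth$b)
  D <- sim$truth$D
  # Monte-Carlo bounds at m = 2000: about 4 standard errors elementwise
  expect_lt(abs(S[1, 1] - D[1, 1]), 4 * sqrt(2 / 2000) * D[1, 1])
  expect_lt(abs(S[2, 2] - D[2, 2]), 4 * sqrt(2 / 2000) * D[2, 2])
  expect_lt(abs(S[1, 2] - D[1, 2]), 4 * sqrt((D[1, 1] * D[2, 2] +
                                                D[1, 2]^2) / 2000))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(truth_config(corr = 1.2), "correlation")
  expect_error(truth_config(sd_b3 = -1), "non-negative")
  expect_error(truth_config(outlier_fraction = 1), "outlier_fraction")
  expect_error(generate_panel(1, 2, seed = 1), "at least 2")
  sim <- generate_panel(5, 2, seed = 1)
  expect_error(inject_form_heterogeneity(sim, c("5P" = 1), seed = 1),
               "named with forms")
  expect_error(inject_form_heterogeneity(sim, c("4P" = 0.7), seed = 1),
               "sum to 1")
})

test_that("dose designs are decreasing geometric series with presets", {
  for (preset in c("CCLE", "GDSC-9pt", "GDSC-5pt")) {
    des <- dose_design(preset)
    expect_length(des$doses, des$n_doses)
    expect_true(all(diff(des$doses) < 0))
    ratios <- des$doses[-des$n_doses] / des$doses[-1]
    expect_equal(ratios, rep(des$dilution_factor, des$n_doses - 1))
  }
  expect_equal(dose_design("GDSC-5pt")$doses, 10 / 4^(0:4))
  expect_error(dose_design(n_doses = 1), "n_doses")
  expect_error(dose_design(dilution_factor = 1), "dilution_factor")
})
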