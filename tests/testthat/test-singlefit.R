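test_that("noiseless 4P series are recovered to high accuracy", {
  truth <- c(0, 100, 0, 1.5)
  s <- make_series("4P", truth)
  fit <- fit_single_curve(s$dose, s$response, "4P")
  expect_lt(fit$rss, 1e-8)
  expect_lt(max(abs(fit$params - truth) / (abs(truth) + 1)), 1e-3)
  expect_true(fit$converged)
  expect_equal(fit$ec50, 1, tolerance = 1e-3)
})

test_that("constant response gives the degenerate linear solution", {
  fit <- fit_single_curve(ccle_doses(), rep(50, 8), "linear")
  expect_equal(unname(fit$params), c(50, 0))
  expect_equal(fit$rss, 0)
  expect_true(fit$perfect_fit)
  # AIC parsimony tie-break on ties at -Inf picks the linear form
  sel <- select_best_form(ccle_doses(), rep(50, 8))
  expect_equal(sel$best_form, "linear")
})

test_that("optimum is not beaten by a brute-force parameter grid", {
  ps <- random_logistic_params(8, "4P", seed = 31)
  ps[, 4] <- abs(ps[, 4])  # decreasing viability orientation
  for (i in seq_len(nrow(ps))) {
    s <- make_series("4P", ps[i, ])
    fit <- fit_single_curve(s$dose, s$response, "4P")
    gmin <- grid_min_rss_4p(s$dose, s$response, ps[i, ],
                            span = c(5, 5, 0.4, 0.4), n_grid = 9L)
    expect_gte(gmin, fit$rss - 1e-10)
  }
})

test_that("AIC follows the concentrated Gaussian form and the full-likelihood oracle", {
  # rss = n makes the log term vanish
  expect_equal(compute_aic(8, 8, 4), 10)
  expect_equal(compute_aic(10, 10, 2), 6)
  a0 <- compute_aic(0, 8, 4)
  expect_identical(as.numeric(a0), -Inf)
  expect_true(attr(a0, "perfect_fit"))
  expect_error(compute_aic(5, 4, 4), "more observations")

  # AIC differences equal those from a full Gaussian log-likelihood with
  # sigma^2 profiled at rss/n (the additive constants cancel)
  full_aic <- function(y, mu, k) {
    s2 <- sum((y - mu)^2) / length(y)
    -2 * sum(dnorm(y, mu, sqrt(s2), log = TRUE)) + 2 * k
  }
  s <- make_series("4P", c(5, 95, 0, 1.2), sigma = 4, seed = 2)
  f4 <- fit_single_curve(s$dose, s$response, "4P")
  fl <- fit_single_curve(s$dose, s$response, "linear")
  mu4 <- evaluate_curve("4P", f4$params, s$dose)
  mul <- evaluate_curve("linear", fl$params, s$dose)
  d_ours <- as.numeric(f4$aic) - as.numeric(fl$aic)
  d_full <- full_aic(s$response, mu4, 5) - full_aic(s$response, mul, 3)
  expect_equal(d_ours, d_full, tolerance = 1e-10)
})

test_that("nested 3P never fits better than 4P at converged optima", {
  for (seed in 1:5) {
    s <- make_series("4P", c(10, 100, -0.5, 2), sigma = 3, seed = seed)
    f4 <- fit_single_curve(s$dose, s$response, "4P")
    f3 <- fit_single_curve(s$dose, s$response, "3P")
    expect_lte(f4$rss, f3$rss + 1e-8)
  }
})

test_that("the generating form is selected on noiseless data", {
  cases <- list(list(form = "4P", params = c(20, 100, 0, 1.5)),
                list(form = "3P", params = c(100, 0, 1.5)),
                list(form = "linear", params = c(60, -12)))
  for (cs in cases) {
    s <- make_series(cs$form, cs$params)
    sel <- select_best_form(s$dose, s$response)
    expect_equal(sel$best_form, cs$form)
  }
})

test_that("insufficient data raises rather than returning a fit", {
  expect_error(fit_single_curve(c(1, 2, 4), c(90, 60, 30), "4P"),
               "insufficient data")
  expect_error(fit_single_curve(rep(c(1, 2), 3), rep(50, 6), "3P"),
               "insufficient data")
})

test_that("majority-form selection follows the counted verdicts", {
  v <- c(rep("4P", 6), rep("3P", 4), rep("linear", 2))
  names(v) <- sprintf("c%02d", seq_along(v))
  maj <- select_majority_form(v)
  expect_true(maj$modelable)
  expect_equal(maj$form, "4P")
  expect_length(maj$included, 6)
  expect_setequal(maj$included, names(v)[v == "4P"])

  # 3P/4P tie resolves to the richer 4P model even when linear dominates
  v2 <- c(rep("4P", 3), rep("3P", 3), rep("linear", 10))
  names(v2) <- sprintf("c%02d", seq_along(v2))
  expect_equal(select_majority_form(v2)$form, "4P")

  # clear 3P majority
  v3 <- c(rep("3P", 5), rep("4P", 2))
  names(v3) <- sprintf("c%02d", seq_along(v3))
  expect_equal(select_majority_form(v3)$form, "3P")

  # all-linear group is non-modelable
  v4 <- rep("linear", 12)
  names(v4) <- sprintf("c%02d", seq_along(v4))
  maj4 <- select_majority_form(v4)
  expect_false(maj4$modelable)
  expect_length(maj4$included, 0)
})

test_that("form proportions summarize the selection table", {
  sim <- generate_panel(12, 2, truth = truth_config(sigma = 2), seed = 44)
  fits <- fit_panel_curves(sim$panel)
  expect_equal(nrow(fits), 24)
  pr <- form_proportions(fits)
  expect_equal(nrow(pr), 2)
  expect_equal(pr$prop_4P + pr$prop_3P + pr$prop_linear, rep(1, 2))
  expect_equal(pr$n, rep(12, 2))
})
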