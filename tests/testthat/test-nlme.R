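test_that("population parameters and random effects are recovered", {
  res <- experiment_nlme_recovery(n_reps = 3L, m = 30L, sigma = 3,
                                  seed = 42L)
  expect_true(all(res$converged))
  expect_true(all(res$cor_b3 >= 0.9))
  expect_true(all(res$ec50_rel_err < 0.2))
  expect_true(all(res$monotone))
})

test_that("the cell-line gate is strict and config-exposed", {
  sim <- generate_panel(10, 1, seed = 2)
  expect_error(fit_nlme(sim$panel, "4P"), class = "nlme_gate_error")
  # m = 11 passes the default > 10 gate
  sim11 <- generate_panel(11, 1, truth = truth_config(sigma = 3), seed = 3)
  fit <- fit_nlme(sim11$panel, "4P")
  expect_s3_class(fit, "nlme_fit")
  expect_length(fit$included, 11)
  # lowering the gate admits small groups
  fit_small <- fit_nlme(sim$panel, "4P",
                        nlme_control(min_cell_lines = 5L))
  expect_length(fit_small$included, 10)
})

test_that("zero-heterogeneity data collapse toward the pooled fit", {
  sim <- generate_panel(20, 1,
                        truth = truth_config(sd_b3 = 0, sd_b4 = 0,
                                             sigma = 2), seed = 30)
  fit <- fit_nlme(sim$panel, "4P")
  pg <- sim$panel
  nls_b3 <- vapply(split(pg, pg$cell_line), function(g) {
    fit_single_curve(g$dose_uM, g$response, "4P")$params[["beta3"]]
  }, numeric(1))
  # the estimated between-line sd is well below the raw spread of the
  # per-line estimates (that spread is pure sampling noise here)
  expect_lt(sqrt(fit$D_hat[1, 1]), 0.5 * sd(nls_b3))
  # fixed effects agree with one curve fitted to all data pooled
  pooled <- fit_single_curve(pg$dose_uM, pg$response, "4P")
  expect_equal(unname(fit$beta0), unname(pooled$params),
               tolerance = 1e-2)
  # and the variance components match the reference NLME implementation
  suppressMessages(requireNamespace("nlme"))
  pgl <- transform(pg, ld = log(dose_uM))
  ref <- nlme::nlme(response ~ b1 + (b2 - b1) /
                      (1 + exp(b4 * (ld - b3))), data = pgl,
                    fixed = b1 + b2 + b3 + b4 ~ 1,
                    random = b3 + b4 ~ 1 | cell_line,
                    start = c(b1 = 0, b2 = 100, b3 = 0, b4 = 1.5),
                    method = "ML",
                    control = nlme::nlmeControl(returnObject = TRUE))
  expect_equal(unname(fit$beta0), unname(nlme::fixef(ref)),
               tolerance = 1e-2)
  expect_equal(sqrt(fit$sigma2_hat), ref$sigma, tolerance = 0.02)
})

test_that("linear limit agrees with a directly-implemented LMM ML solution", {
  # random intercept + slope on log-dose: the model is an exact LMM, so
  # the alternating scheme must land on the ML optimum
  set.seed(77)
  m <- 15
  l <- log(dose_design("CCLE")$doses)
  b <- cbind(rnorm(m, 0, 3), rnorm(m, 0, 0.5))
  df <- do.call(rbind, lapply(seq_len(m), function(i) {
    data.frame(cell_line = sprintf("c%02d", i), dose_uM = exp(l),
               response = (60 + b[i, 1]) + (-12 + b[i, 2]) * l +
                 rnorm(length(l), 0, 1))
  }))
  fit <- fit_nlme(df, "linear", nlme_control(min_cell_lines = 5L))
  expect_true(fit$converged)

  ## independent oracle: full-matrix marginal likelihood, GLS fixed
  ## effects, variance parameters maximized directly
  groups <- split(df, df$cell_line)
  Zs <- lapply(groups, function(g) cbind(1, log(g$dose_uM)))
  ys <- lapply(groups, function(g) g$response)
  oracle_ll <- function(sigma2, D, beta = NULL) {
    Vs <- lapply(Zs, function(Z) sigma2 * diag(nrow(Z)) +
                   Z %*% D %*% t(Z))
    if (is.null(beta)) {
      A <- Reduce(`+`, Map(function(Z, V) t(Z) %*% solve(V, Z), Zs, Vs))
      rhs <- Reduce(`+`, Map(function(Z, V, y) t(Z) %*% solve(V, y),
                             Zs, Vs, ys))
      beta <- solve(A, rhs)
    }
    ll <- 0
    for (i in seq_along(Zs)) {
      r <- ys[[i]] - Zs[[i]] %*% beta
      ll <- ll - 0.5 * (determinant(Vs[[i]])$modulus +
                          t(r) %*% solve(Vs[[i]], r) +
                          nrow(Zs[[i]]) * log(2 * pi))
    }
    list(ll = as.numeric(ll), beta = as.vector(beta))
  }
  # (a) reported log-likelihood is exact at the returned parameters
  at_fit <- oracle_ll(fit$sigma2_hat, fit$D_hat, unname(fit$beta0))
  expect_equal(fit$loglik, at_fit$ll, tolerance = 1e-9)
  # (b) independent maximization cannot beat the returned solution
  nll <- function(th) {
    L <- matrix(c(exp(th[2]), th[3], 0, exp(th[4])), 2, 2)
    -oracle_ll(exp(2 * th[1]), L %*% t(L))$ll
  }
  o <- optim(c(0, 1, 0, -0.5), nll, method = "Nelder-Mead",
             control = list(maxit = 2000, reltol = 1e-13))
  o <- optim(o$par, nll, method = "Nelder-Mead",
             control = list(maxit = 2000, reltol = 1e-13))
  expect_lte(-o$value, fit$loglik + 1e-6)
  # (c) GLS fixed effects at the fitted variances match
  expect_equal(unname(fit$beta0),
               oracle_ll(fit$sigma2_hat, fit$D_hat)$beta,
               tolerance = 1e-6)
  # (d) BLUPs match the closed form D Z' V^{-1} (y - X beta)
  for (i in seq_along(Zs)) {
    Z <- Zs[[i]]
    V <- fit$sigma2_hat * diag(nrow(Z)) + Z %*% fit$D_hat %*% t(Z)
    bi <- fit$D_hat %*% t(Z) %*%
      solve(V, ys[[i]] - Z %*% unname(fit$beta0))
    expect_equal(unlist(fit$blups[i, c("b3", "b4")], use.names = FALSE),
                 as.vector(bi), tolerance = 1e-6)
  }
  # (e) lme4 lands on the same maximum
  suppressMessages(requireNamespace("lme4"))
  lf <- lme4::lmer(response ~ ld + (ld | cell_line),
                   data = transform(df, ld = log(dose_uM)), REML = FALSE)
  expect_equal(unname(fit$beta0), unname(lme4::fixef(lf)),
               tolerance = 1e-6)
  expect_gte(fit$loglik, as.numeric(stats::logLik(lf)) - 1e-6)
})

test_that("BLUPs are shrunk relative to single-curve estimates", {
  # aggregate shrinkage: BLUP dispersion below single-fit dispersion in
  # the typical replicate (per-replicate the ratio hovers a few percent
  # below 1 and sampling noise can tip individual replicates over)
  ratios <- experiment_shrinkage(n_reps = 5L, m = 30L, sigma = 5,
                                 seed = 7L)
  expect_lt(median(ratios), 1)
})

test_that("pooling stabilizes a wildly deviant, weakly identified line", {
  # a line whose EC50 sits beyond the top dose: its own series barely
  # identifies log-EC50, so single fits swing wildly between local
  # solutions while the mixed model pins the estimate via the population
  des <- dose_design("CCLE")
  true_shift <- 3
  blups <- singles <- numeric(6)
  for (r in seq_along(blups)) {
    set.seed(60 + r)
    sim <- generate_panel(40, 1, truth = truth_config(sigma = 5),
                          seed = 60 + r)
    pg <- sim$panel
    dev_resp <- evaluate_curve("4P", c(0, 100, true_shift, 1.5),
                               des$doses) + rnorm(des$n_doses, 0, 5)
    pg$response[pg$cell_line == "CL001"] <- dev_resp
    fit <- fit_nlme(pg, "4P")
    single <- fit_single_curve(des$doses, dev_resp, "4P")
    singles[r] <- single$params[["beta3"]] - fit$beta0[["beta3"]]
    blups[r] <- fit$blups$b3[fit$blups$cell_line == "CL001"]
  }
  # BLUPs are far more stable and accurate than single-fit deviations
  expect_lt(sd(blups), 0.5 * sd(singles))
  expect_lt(mean(abs(blups - true_shift)),
            mean(abs(singles - true_shift)))
  expect_lt(max(abs(blups)), max(abs(singles)))
  expect_true(all(blups > 0))
})

test_that("diagnostics: perfect fits give zero residuals, Gaussian data are not flagged", {
  sim <- generate_panel(15, 1, truth = truth_config(sigma = 0), seed = 31)
  fit <- fit_nlme(sim$panel, "4P")
  dg <- diagnose_nlme(fit, sim$panel)
  expect_true(all(abs(dg$std_residuals) < 1e-6))
  expect_false(dg$heavy_tail)

  simg <- generate_panel(40, 1, truth = truth_config(sigma = 3), seed = 32)
  fitg <- fit_nlme(simg$panel, "4P")
  dgg <- diagnose_nlme(fitg, simg$panel)
  expect_false(dgg$heavy_tail)
  expect_gt(dgg$ranef_normality$b3$p, 0.01)
})

test_that("heavy-tailed random effects raise the flag in most replicates", {
  flags <- logical(7)
  for (r in seq_along(flags)) {
    set.seed(300 + r)
    m <- 80
    b3 <- 0.8 * rt(m, df = 3) / sqrt(3)   # heavy-tailed log-EC50 effects
    doses <- ccle_doses()
    pg <- do.call(rbind, lapply(seq_len(m), function(i) {
      data.frame(cell_line = sprintf("c%02d", i),
                 drug = "D1", cancer_type = "pan", dose_uM = doses,
                 response = evaluate_curve("4P", c(0, 100, b3[i], 1.5),
                                           doses) +
                   rnorm(length(doses), 0, 3))
    }))
    fit <- fit_nlme(pg, "4P")
    flags[r] <- diagnose_nlme(fit, pg)$heavy_tail
  }
  expect_gte(sum(flags), 4)
})

test_that("diagnostics are refused for unconverged fits", {
  sim <- generate_panel(12, 1, truth = truth_config(sigma = 3), seed = 40)
  fit <- fit_nlme(sim$panel, "4P", nlme_control(max_iter = 1L))
  if (!fit$converged) {
    expect_error(diagnose_nlme(fit, sim$panel), "refused")
  } else {
    succeed("fit converged in one iteration; refusal path not reachable")
  }
})

test_that("shrinkage check demands aligned cell lines", {
  sim <- generate_panel(12, 1, truth = truth_config(sigma = 3), seed = 41)
  fit <- fit_nlme(sim$panel, "4P")
  expect_error(shrinkage_check(fit, c(bogus = 1)), "missing")
})
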