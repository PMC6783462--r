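#' Calibration experiments on synthetic panels
#'
#' These drivers run the pipeline's stages on simulated panels at fixed
#' study conditions and summarize how well each stage recovers the known
#' ground truth. They are used by the analysis scripts and the package's
#' own verification.
#'
#' `experiment_form_selection()` measures how often AIC selection recovers
#' the generating functional form. 4P-generated series use a nonzero
#' infinite-dose asymptote (`beta1 = 20` percent residual viability):
#' with `beta1 = 0` a "4P-generated" curve is mathematically a 3P curve
#' and form recovery would be undefined. 3P- and linear-generated series
#' use the default population curve.
#'
#' @param n_series Series per generating form.
#' @param n_drugs Drugs per simulated panel (cell-line count is derived).
#' @param sigma Residual standard deviation, percent viability.
#' @param seed Integer seed.
#' @param beta1_4p Infinite-dose asymptote of the 4P-generated condition.
#' @return List with per-form selection rates (`rate_4P`, `rate_3P`,
#'   `rate_linear`), each the proportion of series whose generating form
#'   was AIC-selected, and the counts behind them.
#' @export
experiment_form_selection <- function(n_series = 500L, n_drugs = 5L,
                                      sigma = 2, seed = 1L,
                                      beta1_4p = 20) {
  m <- ceiling(n_series / n_drugs)
  rate <- function(sim, form) {
    fits <- fit_panel_curves(sim$panel)
    fits <- fits[seq_len(min(n_series, nrow(fits))), ]
    mean(fits$best_form == form, na.rm = TRUE)
  }
  sim4 <- generate_panel(m, n_drugs,
                         truth = truth_config(beta0 = c(beta1_4p, 100, 0,
                                                        1.5),
                                              sigma = sigma),
                         seed = seed)
  sim3 <- generate_panel(m, n_drugs, truth = truth_config(sigma = sigma),
                         seed = seed + 1L)
  sim3 <- inject_form_heterogeneity(sim3, c("3P" = 1), seed = seed + 2L)
  siml <- generate_panel(m, n_drugs, truth = truth_config(sigma = sigma),
                         seed = seed + 3L)
  siml <- inject_form_heterogeneity(siml, c("linear" = 1),
                                    seed = seed + 4L)
  list(n_series = m * n_drugs,
       rate_4P = rate(sim4, "4P"),
       rate_3P = rate(sim3, "3P"),
       rate_linear = rate(siml, "linear"))
}

#' @rdname experiment_form_selection
#' @details `experiment_nlme_recovery()` fits the mixed model to
#'   replicated one-drug panels and reports, per replicate, the relative
#'   error of the population EC50 `exp(beta03)`, the Pearson correlation
#'   between true and estimated (BLUP) log-EC50 random effects, and
#'   whether every penalized-objective trace was non-increasing.
#' @param n_reps Number of replicate panels.
#' @param m Cell lines per panel.
#' @export
experiment_nlme_recovery <- function(n_reps = 20L, m = 40L, sigma = 3,
                                     seed = 1L) {
  ec50_rel_err <- cor_b3 <- numeric(n_reps)
  monotone <- logical(n_reps)
  converged <- logical(n_reps)
  truth <- truth_config(sigma = sigma)
  for (r in seq_len(n_reps)) {
    sim <- generate_panel(m, 1L, truth = truth, seed = seed + 97L * r)
    fit <- fit_nlme(sim$panel, "4P")
    ec50_true <- exp(truth$beta0[3L])
    ec50_rel_err[r] <- abs(exp(fit$beta0[["beta3"]]) - ec50_true) /
      ec50_true
    b3t <- sim$truth$b[fit$blups$cell_line, "b3"]
    cor_b3[r] <- stats::cor(b3t, fit$blups$b3)
    monotone[r] <- all(vapply(fit$pnls_trace,
                              function(tr) all(diff(tr) <= 1e-8),
                              logical(1)))
    converged[r] <- fit$converged
  }
  list(ec50_rel_err = ec50_rel_err, cor_b3 = cor_b3,
       monotone = monotone, converged = converged)
}

#' @rdname experiment_form_selection
#' @details `experiment_shrinkage()` compares, per replicate, the
#'   dispersion of the BLUP log-EC50 random effects with the dispersion of
#'   per-cell-line single-fit log-EC50 estimates (see
#'   [shrinkage_check()]).
#' @export
experiment_shrinkage <- function(n_reps = 10L, m = 30L, sigma = 5,
                                 seed = 1L) {
  ratios <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- generate_panel(m, 1L, truth = truth_config(sigma = sigma),
                          seed = seed + 131L * r)
    fit <- fit_nlme(sim$panel, "4P")
    pg <- sim$panel
    singles <- vapply(split(pg, pg$cell_line), function(g) {
      fit_single_curve(g$dose_uM, g$response, "4P")$params[["beta3"]]
    }, numeric(1))
    ratios[r] <- shrinkage_check(fit, singles)$ratio
  }
  ratios
}

#' @rdname experiment_form_selection
#' @details `experiment_outlier_detection()` injects globally sensitive
#'   cell lines (log-EC50 random effect shifted by `-3 sd(b3)` across all
#'   drugs), runs the mixed model per drug, standardizes the random
#'   effects and applies the combined outlier rule; reports the detection
#'   sensitivity on injected lines and the false-positive rate on the
#'   remaining lines.
#' @param outlier_fraction Fraction of cell lines injected.
#' @export
experiment_outlier_detection <- function(n_reps = 20L, m = 50L,
                                         n_drugs = 12L,
                                         outlier_fraction = 0.05,
                                         seed = 1L) {
  sens_num <- sens_den <- fp_num <- fp_den <- 0L
  fp_sens <- fp_res <- 0L
  for (r in seq_len(n_reps)) {
    sim <- generate_panel(m, n_drugs,
                          truth = truth_config(
                            outlier_fraction = outlier_fraction),
                          seed = seed + 211L * r)
    drugs <- colnames(sim$truth$forms)
    blups <- lapply(drugs, function(d) {
      fit <- fit_nlme(sim$panel[sim$panel$drug == d, ], "4P")
      data.frame(cell_line = fit$blups$cell_line, drug = d,
                 b3 = fit$blups$b3, stringsAsFactors = FALSE)
    })
    sre <- sre_table(do.call(rbind, blups))
    calls <- call_outliers(sre)
    inj <- sim$truth$outliers
    hit <- calls$verdict_combined[match(inj, calls$cell_line)]
    sens_num <- sens_num + sum(hit == "sensitive", na.rm = TRUE)
    sens_den <- sens_den + length(inj)
    rest <- calls[!calls$cell_line %in% inj, ]
    fp_num <- fp_num + sum(rest$verdict_combined != "neutral",
                           na.rm = TRUE)
    fp_sens <- fp_sens + sum(rest$verdict_combined == "sensitive",
                             na.rm = TRUE)
    fp_res <- fp_res + sum(rest$verdict_combined == "resistant",
                           na.rm = TRUE)
    fp_den <- fp_den + nrow(rest)
  }
  list(sensitivity = sens_num / sens_den, fpr = fp_num / fp_den,
       fpr_sensitive_side = fp_sens / fp_den,
       fpr_resistant_side = fp_res / fp_den,
       n_injected = sens_den, n_clean = fp_den)
}
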