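#' Control settings for single-curve fitting
#'
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @param n_restarts Number of times the simplex is restarted from the best
#'   point found (a fresh simplex escapes premature collapse).
#' @return A list of class `singlefit_control`.
#' @export
singlefit_control <- function(maxit = 2000L, reltol = 1e-10,
                              n_restarts = 4L) {
  structure(list(maxit = as.integer(maxit), reltol = reltol,
                 n_restarts = as.integer(n_restarts)),
            class = "singlefit_control")
}

#' Fit one functional form to one dose-response series
#'
#' Least-squares fit of a single (cell line, drug) series. The logistic
#' forms are fitted by Nelder-Mead minimization of the residual sum of
#' squares from a small grid of starting values (upper asymptote at the
#' maximum response, lower at the minimum or 0, log-EC50 at the minimum,
#' median and maximum observed log-dose, slope at +1 and -1), keeping the
#' best start; the linear form uses the closed-form least-squares solution.
#' All responses are weighted equally.
#'
#' @param dose Strictly positive concentrations (uM).
#' @param response Observed responses (percent viability scale; values
#'   outside \[0, 100\] are permitted and never clipped).
#' @param form Functional form label (see [form_labels()]).
#' @param control A [singlefit_control()].
#' @return A list of class `curve_fit`: `form`, `params`, `rss`, `n_obs`,
#'   `aic`, `converged`, `ec50` (NA for the linear form), `perfect_fit`.
#' @examples
#' d <- dose_design("CCLE")$doses
#' y <- evaluate_curve("4P", c(0, 100, 0, 1.5), d)
#' fit <- fit_single_curve(d, y, "4P")
#' fit$params
#' @export
fit_single_curve <- function(dose, response, form,
                             control = singlefit_control()) {
  form <- match_form(form)
  check_dose(dose)
  if (length(dose) != length(response) || anyNA(response)) {
    stop("dose and response must be equal-length and non-missing",
         call. = FALSE)
  }
  p <- form_n_params(form)
  if (length(unique(dose)) < p) {
    stop("insufficient data: need at least ", p, " distinct doses to fit ",
         form, call. = FALSE)
  }
  l <- log(dose)
  y <- response
  n <- length(y)

  if (form == "linear") {
    co <- unname(stats::coef(stats::lm.fit(cbind(1, l), y)))
    rss <- sum((y - co[1L] - co[2L] * l)^2)
    return(new_curve_fit(form, co, rss, n, TRUE))
  }

  rss_fun <- if (form == "4P") {
    function(b) sum((y - logistic4(l, b[1L], b[2L], b[3L], b[4L]))^2)
  } else {
    function(b) sum((y - logistic4(l, 0, b[1L], b[2L], b[3L]))^2)
  }

  starts <- logistic_starts(form, l, y)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], rss_fun, method = "Nelder-Mead",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  for (r in seq_len(control$n_restarts)) {
    o <- stats::optim(best$par, rss_fun, method = "Nelder-Mead",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
    if (o$value < best$value) best <- o else break
  }
  par <- unname(best$par)
  if (form == "4P") par <- canonicalize_4p(par)
  new_curve_fit(form, par, best$value, n, best$convergence == 0L)
}

logistic_starts <- function(form, logdose, y) {
  b2 <- max(y); b1 <- min(y)
  l3 <- c(min(logdose), stats::median(logdose), max(logdose))
  g <- expand.grid(b3 = l3, b4 = c(1, -1))
  if (form == "4P") {
    as.matrix(cbind(b1 = b1, b2 = b2, g))
  } else {
    as.matrix(cbind(b2 = b2, g))
  }
}

new_curve_fit <- function(form, params, rss, n_obs, converged) {
  p <- form_n_params(form)
  names(params) <- switch(form,
    "4P" = c("beta1", "beta2", "beta3", "beta4"),
    "3P" = c("beta2", "beta3", "beta4"),
    "linear" = c("intercept", "slope"))
  rss <- max(rss, 0)
  # residuals at the floating-point floor (1e-8 response units on a
  # percent scale) are an exact fit for every practical purpose
  if (rss <= 1e-16 * n_obs) rss <- 0
  aic <- compute_aic(rss, n_obs, p)
  structure(list(form = form, params = params, rss = rss, n_obs = n_obs,
                 aic = aic, converged = converged,
                 ec50 = if (form == "linear") NA_real_
                        else ec50_from_params(form, params),
                 perfect_fit = isTRUE(attr(aic, "perfect_fit"))),
            class = "curve_fit")
}

#' Akaike information criterion for a least-squares fit
#'
#' Concentrated Gaussian form `n * log(rss / n) + 2 * (n_params + 1)`: the
#' residual variance counts as an estimated parameter, and the same
#' convention is applied to every functional form so that AIC differences
#' between forms are meaningful. A perfect fit (`rss = 0`) returns
#' `-Inf` with attribute `perfect_fit = TRUE`.
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n_obs Number of observations (> `n_params`).
#' @param n_params Number of curve parameters.
#' @return Numeric scalar.
#' @examples
#' compute_aic(8, 8, 4)   # log term vanishes: 2 * 5 = 10
#' @export
compute_aic <- function(rss, n_obs, n_params) {
  if (rss < 0) stop("rss must be non-negative", call. = FALSE)
  if (n_obs <= n_params) {
    stop("need more observations than parameters", call. = FALSE)
  }
  if (rss == 0) {
    return(structure(-Inf, perfect_fit = TRUE))
  }
  n_obs * log(rss / n_obs) + 2 * (n_params + 1)
}

#' Fit all three forms to a series and select the best by AIC
#'
#' Fits the 4P logistic, 3P logistic and linear forms and returns the form
#' with the smallest AIC among converged fits. AIC ties (within `1e-9`) are
#' broken toward the form with fewer parameters. If no fit converges the
#' series is flagged unfit.
#'
#' @inheritParams fit_single_curve
#' @return A list of class `model_selection`: `fits` (named list of
#'   `curve_fit`), `aic` (named vector), `best_form` (NA when unfit),
#'   `fitted` (logical).
#' @export
select_best_form <- function(dose, response,
                             control = singlefit_control()) {
  fits <- list()
  for (fm in form_labels()) {
    fits[[fm]] <- tryCatch(fit_single_curve(dose, response, fm, control),
                           error = function(e) NULL)
  }
  ok <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  aic <- vapply(fits, function(f) if (is.null(f)) NA_real_
                                   else as.numeric(f$aic), numeric(1))
  if (!any(ok)) {
    return(structure(list(fits = fits, aic = aic, best_form = NA_character_,
                          fitted = FALSE), class = "model_selection"))
  }
  cand <- names(fits)[ok]
  a <- aic[cand]
  npar <- vapply(cand, form_n_params, integer(1))
  # min AIC; ties broken toward parsimony
  o <- order(ifelse(is.finite(a), a, -.Machine$double.xmax), npar)
  best <- cand[o[1L]]
  for (k in seq_along(cand)) {
    if (cand[k] != best &&
        abs_tie(a[cand[k]], a[best]) && npar[k] < form_n_params(best)) {
      best <- cand[k]
    }
  }
  structure(list(fits = fits, aic = aic, best_form = best, fitted = TRUE),
            class = "model_selection")
}

abs_tie <- function(x, y) {
  (is.infinite(x) && is.infinite(y) && x == y) ||
    (is.finite(x) && is.finite(y) && abs(x - y) < 1e-9)
}

#' Majority logistic form for one cancer type x drug group
#'
#' Given the per-cell-line best forms within one cancer type and drug, the
#' mixed-effects stage models all cell lines with whichever of the two
#' logistic forms wins the majority of best-fit verdicts; linear-best cell
#' lines never set the form. Only the cell lines whose best form equals the
#' winning form are included in the joint fit. A 3P/4P tie goes to 4P (the
#' richer model). A group with no logistic-best cell line is flagged
#' non-modelable.
#'
#' @param best_forms Named character vector, one best-form verdict per cell
#'   line (names are cell-line ids); `NA` entries (unfit series) are
#'   ignored.
#' @return List of class `majority_form`: `modelable`, `form`, `included`
#'   (cell-line ids), `counts` (named tally over forms).
#' @examples
#' v <- c(A = "4P", B = "4P", C = "3P", D = "linear")
#' select_majority_form(v)
#' @export
select_majority_form <- function(best_forms) {
  if (length(best_forms) == 0L) stop("empty group", call. = FALSE)
  bf <- best_forms[!is.na(best_forms)]
  counts <- c("4P" = sum(bf == "4P"), "3P" = sum(bf == "3P"),
              "linear" = sum(bf == "linear"))
  if (counts[["4P"]] == 0L && counts[["3P"]] == 0L) {
    return(structure(list(modelable = FALSE, form = NA_character_,
                          included = character(0), counts = counts),
                     class = "majority_form"))
  }
  form <- if (counts[["3P"]] > counts[["4P"]]) "3P" else "4P"
  included <- names(bf)[bf == form]
  structure(list(modelable = TRUE, form = form, included = included,
                 counts = counts),
            class = "majority_form")
}

#' Per-series fits and form selection for a whole panel
#'
#' Runs [select_best_form()] on every (cell line, drug) series of a long
#' panel table and returns one row per series with the three AICs, the
#' selected form, and the best logistic fit's log-EC50 when available.
#'
#' @param panel Long data.frame with columns `cell_line`, `drug`,
#'   `cancer_type`, `dose_uM`, `response` (see [read_panel()]).
#' @inheritParams fit_single_curve
#' @return data.frame with one row per series: identifiers, `aic_4P`,
#'   `aic_3P`, `aic_linear`, `best_form`, `fitted`, `log_ec50` and `ec50`
#'   of the AIC-best logistic fit (NA if neither logistic fit converged).
#' @export
fit_panel_curves <- function(panel, control = singlefit_control()) {
  check_panel(panel)
  key <- interaction(panel$drug, panel$cell_line, drop = TRUE)
  idx <- split(seq_len(nrow(panel)), key)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    rows <- idx[[k]]
    sel <- select_best_form(panel$dose_uM[rows], panel$response[rows],
                            control)
    # log-EC50 comparator: AIC-best logistic fit
    lf <- best_logistic(sel)
    out[[k]] <- data.frame(
      cell_line = panel$cell_line[rows[1L]],
      drug = panel$drug[rows[1L]],
      cancer_type = panel$cancer_type[rows[1L]],
      aic_4P = as.numeric(sel$aic[["4P"]]),
      aic_3P = as.numeric(sel$aic[["3P"]]),
      aic_linear = as.numeric(sel$aic[["linear"]]),
      best_form = sel$best_form,
      fitted = sel$fitted,
      log_ec50 = if (is.null(lf)) NA_real_ else log(lf$ec50),
      ec50 = if (is.null(lf)) NA_real_ else lf$ec50,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

best_logistic <- function(sel) {
  cand <- c("4P", "3P")
  ok <- vapply(cand, function(fm) {
    f <- sel$fits[[fm]]; !is.null(f) && f$converged
  }, logical(1))
  cand <- cand[ok]
  if (length(cand) == 0L) return(NULL)
  a <- sel$aic[cand]
  a[is.infinite(a)] <- -.Machine$double.xmax
  sel$fits[[cand[which.min(a)]]]
}

#' Proportion of cell lines best fit by each form, per cancer type x drug
#'
#' Tabular equivalent of the screen-wide heatmaps: for each cancer type and
#' drug, the proportion of fitted series whose AIC-best form was 4P, 3P or
#' linear.
#'
#' @param fits data.frame from [fit_panel_curves()].
#' @return data.frame with columns `cancer_type`, `drug`, `n`, `prop_4P`,
#'   `prop_3P`, `prop_linear`.
#' @export
form_proportions <- function(fits) {
  sp <- split(fits, list(fits$cancer_type, fits$drug), drop = TRUE)
  out <- lapply(sp, function(g) {
    bf <- g$best_form[!is.na(g$best_form)]
    n <- length(bf)
    data.frame(cancer_type = g$cancer_type[1L], drug = g$drug[1L], n = n,
               prop_4P = mean(bf == "4P"), prop_3P = mean(bf == "3P"),
               prop_linear = mean(bf == "linear"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cancer_type, res$drug), , drop = FALSE]
}
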