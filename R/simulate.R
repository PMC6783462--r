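#' Dose design for a simulated screen
#'
#' A dose design is a strictly decreasing geometric dilution series:
#' `n_doses` concentrations starting at `top_dose` (uM) and dividing by
#' `dilution_factor` at each step. Presets mirror the layouts of the two
#' large public screens: `"CCLE"` (8 points, half-log dilution from 8 uM),
#' `"GDSC-9pt"` (9 points, 2-fold from 10 uM) and `"GDSC-5pt"` (5 points,
#' 4-fold from 10 uM).
#'
#' @param preset Optional preset name; when given, the other arguments are
#'   ignored.
#' @param n_doses Number of concentrations (>= 2).
#' @param dilution_factor Ratio between successive concentrations (> 1).
#' @param top_dose Highest concentration, uM (> 0).
#' @return An object of class `dose_design` with elements `n_doses`,
#'   `dilution_factor`, `top_dose` and the computed `doses` vector
#'   (decreasing, uM).
#' @examples
#' dose_design("CCLE")$doses
#' dose_design(n_doses = 5, dilution_factor = 4, top_dose = 10)
#' @export
dose_design <- function(preset = NULL, n_doses = 8L,
                        dilution_factor = sqrt(10), top_dose = 8) {
  if (!is.null(preset)) {
    des <- switch(preset,
      "CCLE"     = list(n_doses = 8L, dilution_factor = sqrt(10), top_dose = 8),
      "GDSC-9pt" = list(n_doses = 9L, dilution_factor = 2, top_dose = 10),
      "GDSC-5pt" = list(n_doses = 5L, dilution_factor = 4, top_dose = 10),
      stop("unknown dose design preset: ", preset, call. = FALSE)
    )
    n_doses <- des$n_doses
    dilution_factor <- des$dilution_factor
    top_dose <- des$top_dose
  }
  if (n_doses < 2L) stop("n_doses must be >= 2", call. = FALSE)
  if (dilution_factor <= 1) stop("dilution_factor must be > 1", call. = FALSE)
  if (top_dose <= 0) stop("top_dose must be positive", call. = FALSE)
  doses <- top_dose / dilution_factor^(seq_len(n_doses) - 1L)
  structure(list(n_doses = as.integer(n_doses),
                 dilution_factor = dilution_factor,
                 top_dose = top_dose, doses = doses),
            class = "dose_design")
}

#' Population and variance settings for panel simulation
#'
#' Defaults describe a plausible viability screen: full kill at high dose
#' (`beta0[1] = 0`), 100 percent viability at zero dose, population EC50 of
#' 1 uM (`beta0[3] = log(1)`), slope 1.5; cell-line heterogeneity of
#' sd 0.8 on log-EC50 and 0.3 on slope, uncorrelated; residual noise of 5
#' percent viability. Outlier cell lines receive a constant shift `delta`
#' on their log-EC50 random effect in every drug, mimicking lines that are
#' consistently sensitive (`delta < 0`) or resistant (`delta > 0`).
#'
#' @param beta0 Population curve parameters `c(beta1, beta2, beta3, beta4)`
#'   of the 4P logistic (response units, response units, log-uM, unitless).
#' @param sd_b3,sd_b4 Standard deviations of the random effects on log-EC50
#'   and slope (>= 0).
#' @param corr Correlation between the two random effects, in \[-1, 1\].
#' @param sigma Residual standard deviation, response units (>= 0).
#' @param outlier_fraction Fraction of cell lines injected as outliers,
#'   in \[0, 1).
#' @param outlier_delta Shift applied to the log-EC50 random effect of each
#'   outlier line (default `-3 * sd_b3`, i.e. globally sensitive).
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(beta0 = c(0, 100, log(1), 1.5),
                         sd_b3 = 0.8, sd_b4 = 0.3, corr = 0, sigma = 5,
                         outlier_fraction = 0,
                         outlier_delta = -3 * sd_b3) {
  if (length(beta0) != 4L || anyNA(beta0)) {
    stop("beta0 must be 4 finite values", call. = FALSE)
  }
  if (sd_b3 < 0 || sd_b4 < 0 || sigma < 0) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  if (abs(corr) > 1) {
    stop("random-effect correlation must lie in [-1, 1]", call. = FALSE)
  }
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stop("outlier_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(list(beta0 = beta0, sd_b3 = sd_b3, sd_b4 = sd_b4, corr = corr,
                 sigma = sigma, outlier_fraction = outlier_fraction,
                 outlier_delta = outlier_delta),
            class = "truth_config")
}

# 2x2 covariance of (b3, b4) and its lower-triangular factor
truth_D <- function(cfg) {
  matrix(c(cfg$sd_b3^2, cfg$corr * cfg$sd_b3 * cfg$sd_b4,
           cfg$corr * cfg$sd_b3 * cfg$sd_b4, cfg$sd_b4^2), 2L, 2L)
}

truth_L <- function(cfg) {
  # explicit factor so zero variances are allowed (chol() would fail)
  matrix(c(cfg$sd_b3, cfg$corr * cfg$sd_b4,
           0, cfg$sd_b4 * sqrt(max(0, 1 - cfg$corr^2))), 2L, 2L)
}

# Deterministic seed splitting: every random draw in a panel flows from the
# panel seed through this hash, keyed by a stream id and up to two indices,
# so any single series can be regenerated in isolation. Arithmetic is done
# in doubles mod the Mersenne prime 2^31 - 1 to stay inside R's integers.
split_seed <- function(seed, stream, i = 0L, j = 0L) {
  m <- 2147483647
  h <- (as.double(seed) %% m)
  h <- (h * 48271 + as.double(stream) * 69621) %% m
  h <- (h * 16807 + as.double(i) * 39373) %% m
  h <- (h * 69621 + as.double(j) * 48271) %% m
  as.integer(h)
}

# generating parameter vector for one series given its form
series_params <- function(form, beta0, b_i, logdoses) {
  beta <- beta0
  beta[3:4] <- beta[3:4] + b_i
  switch(form,
    "4P" = beta,
    "3P" = beta[2:4],
    "linear" = {
      # line closest (least squares) to the cell line's own 4P mean curve
      # on the design's log-dose grid, so potency stays comparable
      y <- logistic4(logdoses, beta[1L], beta[2L], beta[3L], beta[4L])
      co <- stats::coef(stats::lm.fit(cbind(1, logdoses), y))
      unname(co)
    })
}

# draw one series' response vector under its generating form
simulate_series <- function(form, beta0, b_i, doses, sigma, seed) {
  pars <- series_params(form, beta0, b_i, log(doses))
  mu <- evaluate_curve(form, pars, doses)
  if (sigma > 0) {
    set.seed(seed)
    mu <- mu + stats::rnorm(length(doses), 0, sigma)
  }
  mu
}

#' Simulate a dose-response panel with known ground truth
#'
#' Generates a complete panel of `n_cell_lines` x `n_drugs` dose-response
#' series under the hierarchical model: each cell line draws random effects
#' `(b3, b4)` on log-EC50 and slope from `N(0, D)`, shared across drugs;
#' responses are the 4P logistic at the shifted parameters plus i.i.d.
#' Gaussian noise. A configurable fraction of cell lines is injected as
#' global outliers by shifting their `b3` by `outlier_delta` in every drug.
#' All series are generated under the 4P form; use
#' [inject_form_heterogeneity()] to reassign a fraction of series to 3P or
#' linear truth.
#'
#' The same `seed` and configuration reproduce the panel bit-for-bit; each
#' (cell line, drug) series has its own deterministic sub-stream.
#'
#' @param n_cell_lines Number of cell lines (>= 2).
#' @param n_drugs Number of drugs (>= 1).
#' @param design A [dose_design()].
#' @param truth A [truth_config()].
#' @param seed Integer seed for the whole panel.
#' @param cancer_type Label attached to every row (one type per panel).
#' @return A list of class `dr_sim` with `$panel` (long data.frame:
#'   `cell_line`, `drug`, `cancer_type`, `dose_uM`, `response`) and
#'   `$truth` (population parameters, `D`, `sigma`, realized random-effect
#'   matrix `b`, outlier ids and delta, per-series form matrix, seed).
#' @examples
#' sim <- generate_panel(6, 2, seed = 1)
#' head(sim$panel)
#' sim$truth$outliers
#' @export
generate_panel <- function(n_cell_lines, n_drugs,
                           design = dose_design("CCLE"),
                           truth = truth_config(), seed,
                           cancer_type = "pan") {
  stopifnot(inherits(design, "dose_design"), inherits(truth, "truth_config"))
  if (n_cell_lines < 2L) stop("need at least 2 cell lines", call. = FALSE)
  if (n_drugs < 1L) stop("need at least 1 drug", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)

  m <- as.integer(n_cell_lines)
  cells <- sprintf("CL%03d", seq_len(m))
  drugs <- sprintf("D%02d", seq_len(n_drugs))
  L <- truth_L(truth)

  # per-cell-line random effects, one sub-stream per line
  b <- matrix(0, m, 2L, dimnames = list(cells, c("b3", "b4")))
  for (i in seq_len(m)) {
    set.seed(split_seed(seed, 1L, i))
    b[i, ] <- as.vector(L %*% stats::rnorm(2L))
  }

  # outlier injection: fixed count, panel-level sub-stream
  n_out <- round(truth$outlier_fraction * m)
  outliers <- character(0)
  if (n_out > 0L) {
    set.seed(split_seed(seed, 2L))
    outliers <- sort(sample(cells, n_out))
    b[outliers, "b3"] <- b[outliers, "b3"] + truth$outlier_delta
  }

  forms <- matrix("4P", m, n_drugs, dimnames = list(cells, drugs))
  panel <- build_panel(cells, drugs, cancer_type, design, truth, b, forms, seed)

  structure(list(
    panel = panel,
    truth = list(beta0 = truth$beta0, D = truth_D(truth), sigma = truth$sigma,
                 b = b, outliers = outliers,
                 outlier_delta = truth$outlier_delta, forms = forms,
                 design = design, config = truth, seed = as.integer(seed),
                 cancer_type = cancer_type)
  ), class = "dr_sim")
}

build_panel <- function(cells, drugs, cancer_type, design, truth, b, forms,
                        seed) {
  m <- length(cells); nd <- length(drugs); k <- design$n_doses
  res <- vector("list", m * nd)
  idx <- 0L
  for (j in seq_len(nd)) {
    for (i in seq_len(m)) {
      idx <- idx + 1L
      y <- simulate_series(forms[i, j], truth$beta0, b[i, ], design$doses,
                           truth$sigma, split_seed(seed, 4L, i, j))
      res[[idx]] <- y
    }
  }
  data.frame(
    cell_line = rep(rep(cells, times = nd), each = k),
    drug = rep(drugs, each = m * k),
    cancer_type = cancer_type,
    dose_uM = rep(design$doses, times = m * nd),
    response = unlist(res, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Reassign a fraction of series to alternative generating forms
#'
#' Randomly assigns each (cell line, drug) series of a simulated panel to a
#' generating form according to `fractions`, then regenerates the responses
#' of every series whose form changed. Regeneration reuses the panel's
#' per-series noise streams, so series whose assignment is unchanged keep
#' their exact values, and the operation is reproducible.
#'
#' @param sim A `dr_sim` from [generate_panel()].
#' @param fractions Named numeric vector of proportions over
#'   `c("4P", "3P", "linear")` (missing names mean 0); must sum to 1.
#' @param seed Integer seed for the assignment draw.
#' @return The modified `dr_sim`; `sim$truth$forms` records the assignment.
#' @examples
#' sim <- generate_panel(10, 3, seed = 2)
#' sim <- inject_form_heterogeneity(sim, c("4P" = 0.5, "3P" = 0.3,
#'                                         "linear" = 0.2), seed = 3)
#' table(sim$truth$forms)
#' @export
inject_form_heterogeneity <- function(sim, fractions, seed) {
  stopifnot(inherits(sim, "dr_sim"))
  if (is.null(names(fractions)) || !all(names(fractions) %in% form_labels())) {
    stop("fractions must be named with forms among: ",
         paste(form_labels(), collapse = ", "), call. = FALSE)
  }
  pr <- stats::setNames(numeric(3L), form_labels())
  pr[names(fractions)] <- fractions
  if (abs(sum(pr) - 1) > 1e-8) stop("fractions must sum to 1", call. = FALSE)

  tr <- sim$truth
  forms_old <- tr$forms
  n_series <- length(forms_old)
  set.seed(split_seed(seed, 3L))
  new_forms <- sample(form_labels(), n_series, replace = TRUE, prob = pr)
  forms <- matrix(new_forms, nrow(forms_old), ncol(forms_old),
                  dimnames = dimnames(forms_old))

  changed <- which(forms != forms_old, arr.ind = TRUE)
  panel <- sim$panel
  k <- tr$design$n_doses
  cells <- rownames(forms); drugs <- colnames(forms)
  # panel rows are ordered drug-major then cell-line, k doses per series
  m <- length(cells)
  for (r in seq_len(nrow(changed))) {
    i <- changed[r, 1L]; j <- changed[r, 2L]
    y <- simulate_series(forms[i, j], tr$beta0, tr$b[i, ], tr$design$doses,
                         tr$sigma, split_seed(tr$seed, 4L, i, j))
    off <- ((j - 1L) * m + (i - 1L)) * k
    panel$response[(off + 1L):(off + k)] <- y
  }
  sim$panel <- panel
  sim$truth$forms <- forms
  sim
}

# true generating parameters of one series (exported for tests/analyses)
#' Generating parameters of one simulated series
#'
#' @param sim A `dr_sim`.
#' @param cell_line,drug Identifiers as they appear in the panel.
#' @return List with the series' generating `form` and parameter vector.
#' @export
series_truth <- function(sim, cell_line, drug) {
  tr <- sim$truth
  form <- tr$forms[cell_line, drug]
  list(form = form,
       params = series_params(form, tr$beta0, tr$b[cell_line, ],
                              log(tr$design$doses)))
}
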