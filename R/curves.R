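#' Candidate dose-response functional forms
#'
#' Three functional forms are considered for viability dose-response data:
#' a four-parameter (4P) logistic, a three-parameter (3P) logistic (the 4P
#' curve with its infinite-dose asymptote fixed at zero), and a linear
#' regression of response on log-dose. All three share the natural-log dose
#' axis so that their fits are comparable on identical data.
#'
#' The 4P logistic is
#' \deqn{f(x, \beta) = \beta_1 + \frac{\beta_2 - \beta_1}{1 +
#'   e^{\beta_4(\log x - \beta_3)}}}
#' where \eqn{\beta_1} and \eqn{\beta_2} are the responses at infinite and
#' zero concentration, \eqn{\beta_3} is the natural log of the relative EC50
#' (the concentration giving a response midway between the asymptotes, in
#' micromolar), and \eqn{\beta_4} is the slope. The 3P form sets
#' \eqn{\beta_1 = 0}. The linear form is
#' \eqn{f(x) = a + b \log x}.
#'
#' @param form Character scalar: one of `"4P"`, `"3P"`, `"linear"`.
#' @return `form_n_params()` returns the number of curve parameters
#'   (4, 3 or 2). `form_labels()` returns the vector of valid form labels.
#' @examples
#' form_n_params("4P")
#' form_labels()
#' @export
form_n_params <- function(form) {
  form <- match_form(form)
  c("4P" = 4L, "3P" = 3L, "linear" = 2L)[[form]]
}

#' @rdname form_n_params
#' @export
form_labels <- function() c("4P", "3P", "linear")

match_form <- function(form) {
  if (length(form) != 1L || !form %in% form_labels()) {
    stop("unknown functional form: ", paste(form, collapse = ", "),
         " (expected one of ", paste(form_labels(), collapse = ", "), ")",
         call. = FALSE)
  }
  form
}

#' Evaluate a dose-response curve
#'
#' Evaluates one of the three candidate functional forms at a vector of
#' doses. Doses are concentrations in micromolar and must be strictly
#' positive (the curves live on the log-dose axis).
#'
#' Parameter vectors by form:
#' * `"4P"`: `c(beta1, beta2, beta3, beta4)` -- infinite-dose asymptote,
#'   zero-dose asymptote, log-EC50 (natural log, dose in uM), slope.
#' * `"3P"`: `c(beta2, beta3, beta4)` (the lower asymptote is fixed at 0).
#' * `"linear"`: `c(intercept, slope)` on natural-log dose.
#'
#' @param form Functional form label (see [form_labels()]).
#' @param params Numeric parameter vector of length [form_n_params()].
#' @param dose Numeric vector of strictly positive concentrations (uM).
#' @return Numeric vector of predicted responses, one per dose.
#' @examples
#' evaluate_curve("4P", c(0, 100, 0, 1), dose = 1)   # midpoint: 50
#' evaluate_curve("3P", c(100, log(0.5), 1.5), dose = 0.5)
#' @export
evaluate_curve <- function(form, params, dose) {
  form <- match_form(form)
  check_dose(dose)
  p <- form_n_params(form)
  if (length(params) != p || anyNA(params)) {
    stop("form '", form, "' needs ", p, " non-missing parameters, got ",
         length(params), call. = FALSE)
  }
  l <- log(dose)
  switch(form,
    "4P" = logistic4(l, params[1L], params[2L], params[3L], params[4L]),
    "3P" = logistic4(l, 0, params[1L], params[2L], params[3L]),
    "linear" = params[1L] + params[2L] * l
  )
}

# core 4P logistic on the log-dose axis; used by both logistic forms.
# plogis keeps the evaluation finite for arbitrarily large |b4 (l - b3)|
logistic4 <- function(logdose, b1, b2, b3, b4) {
  b1 + (b2 - b1) * stats::plogis(-b4 * (logdose - b3))
}

# analytic Jacobian of the 4P logistic wrt (b1, b2, b3, b4); n x 4
logistic4_jac <- function(logdose, b1, b2, b3, b4) {
  s <- stats::plogis(b4 * (logdose - b3))   # E / (1+E)
  w <- s * (1 - s)                          # E / (1+E)^2
  cbind(s,
        1 - s,
        (b2 - b1) * b4 * w,
        -(b2 - b1) * (logdose - b3) * w)
}

# The 4P logistic is invariant under the relabeling
# (b1, b2, b4) -> (b2, b1, -b4) (b3 unchanged). Fits are reported in the
# orientation with the zero-dose asymptote largest (b2 >= b1) so that
# parameters are comparable across cell lines.
canonicalize_4p <- function(par) {
  if (par[1L] > par[2L]) {
    par <- c(par[2L], par[1L], par[3L], -par[4L])
  }
  par
}

check_dose <- function(dose) {
  if (length(dose) == 0L || anyNA(dose) || any(dose <= 0)) {
    stop("doses must be strictly positive and non-missing", call. = FALSE)
  }
  invisible(dose)
}

#' Relative EC50 of a fitted logistic curve
#'
#' The relative EC50 is the concentration at the curve midpoint,
#' `exp(beta3)`, in micromolar. It is defined only for the logistic forms;
#' the linear form has no EC50.
#'
#' @inheritParams evaluate_curve
#' @return Positive numeric scalar, concentration in uM.
#' @examples
#' ec50_from_params("4P", c(0, 100, log(0.5), 1)) # 0.5
#' @export
ec50_from_params <- function(form, params) {
  form <- match_form(form)
  if (form == "linear") {
    stop("EC50 is not defined for the linear form", call. = FALSE)
  }
  b3 <- if (form == "4P") params[3L] else params[2L]
  exp(unname(b3))
}

# index of (log-EC50, slope) within each form's parameter vector
ranef_indices <- function(form) {
  switch(match_form(form),
    "4P" = c(3L, 4L),
    "3P" = c(2L, 3L),
    "linear" = c(1L, 2L)   # random intercept and slope in the linear limit
  )
}
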