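#' Standardize EC50 random effects within one drug
#'
#' Because a separate mixed model is fitted per cancer type x drug, the
#' estimated log-EC50 random effects are z-scored across the cell lines of
#' each drug's fit so they can be compared across drugs:
#' `SRE_i = (b3_i - mean(b3)) / sd(b3)`.
#'
#' @param b3 Named numeric vector of log-EC50 BLUPs for one drug (names are
#'   cell-line ids); at least 2 values.
#' @return Named numeric vector of SREs with mean 0 and sd 1. If the
#'   column is degenerate (zero sd) all values are returned as `NA` with
#'   attribute `degenerate = TRUE`.
#' @examples
#' standardize_random_effects(c(A = 2, B = 4, C = 6))
#' @export
standardize_random_effects <- function(b3) {
  if (length(b3) < 2L || anyNA(b3)) {
    stop("need >= 2 non-missing BLUPs to standardize", call. = FALSE)
  }
  s <- stats::sd(b3)
  if (s == 0) {
    return(structure(stats::setNames(rep(NA_real_, length(b3)), names(b3)),
                     degenerate = TRUE))
  }
  (b3 - mean(b3)) / s
}

#' Assemble the cell line x drug SRE matrix
#'
#' @param blups data.frame with columns `cell_line`, `drug`, `b3` (one row
#'   per cell line per fitted drug, e.g. pooled [fit_nlme()] BLUP tables).
#' @return Numeric matrix, rows = cell lines, columns = drugs, `NA` where a
#'   cell line was not part of that drug's fit or the column is degenerate.
#' @export
sre_table <- function(blups) {
  stopifnot(all(c("cell_line", "drug", "b3") %in% names(blups)))
  cells <- sort(unique(blups$cell_line))
  drugs <- sort(unique(blups$drug))
  M <- matrix(NA_real_, length(cells), length(drugs),
              dimnames = list(cells, drugs))
  for (d in drugs) {
    g <- blups[blups$drug == d, ]
    sre <- standardize_random_effects(
      stats::setNames(g$b3, g$cell_line))
    M[names(sre), d] <- sre
  }
  M
}

#' Classify a single SRE into the outlier typology
#'
#' Mild (Type I), moderate (Type II) and extreme (Type III) outliers are
#' defined from one-sided standard-normal confidence boundaries at 1.65,
#' 2.5 and 3 (95, 99.4 and 99.9 percent): Type I on (-2.5, -1.65\] or
#' \[1.65, 2.5), Type II on (-3, -2.5\] or \[2.5, 3), Type III beyond
#' plus/minus 3 (boundary included, so the five regions partition the
#' line), neutral on (-1.65, 1.65). Negative SREs sit on the sensitive
#' side (lower EC50 than the population), positive on the resistant side.
#'
#' @param s Finite numeric vector of SREs.
#' @return data.frame with columns `sre`, `type` (`"neutral"`, `"I"`,
#'   `"II"`, `"III"`) and `side` (`"sensitive"`, `"resistant"`, `"none"`).
#' @examples
#' classify_sre(c(-2.7, 0, 3.2))
#' @export
classify_sre <- function(s) {
  if (anyNA(s) || any(!is.finite(s))) {
    stop("SRE values must be finite", call. = FALSE)
  }
  a <- abs(s)
  type <- ifelse(a < 1.65, "neutral",
          ifelse(a < 2.5, "I",
          ifelse(a < 3, "II", "III")))
  side <- ifelse(type == "neutral", "none",
                 ifelse(s < 0, "sensitive", "resistant"))
  data.frame(sre = s, type = type, side = side, stringsAsFactors = FALSE)
}

#' Call consistently sensitive or resistant cell lines from an SRE table
#'
#' For every cell line, the proportions of its modeled drugs with SRE
#' beyond the extreme boundaries (`<= -1.65`, `>= 1.65`) and beyond zero
#' (`< 0`, `> 0`) are computed over the drugs in which the cell line
#' actually appeared in a mixed-model fit. Three verdicts are derived:
#' \describe{
#'   \item{ci}{confidence-boundary rule: sensitive (resistant) when at
#'     least `extreme_prop` of drugs have SRE `<= -1.65` (`>= 1.65`).}
#'   \item{dist}{distribution rule: sensitive (resistant) when at least
#'     `sign_prop` of drugs have SRE `< 0` (`> 0`).}
#'   \item{combined}{both conditions on the same side.}
#' }
#'
#' @param sre Matrix from [sre_table()].
#' @param extreme_threshold SRE magnitude for the boundary rule (1.65).
#' @param extreme_prop Minimum proportion of drugs beyond the boundary
#'   (0.20).
#' @param sign_prop Minimum proportion of drugs on the same sign side
#'   (0.80).
#' @param min_drugs Minimum number of modeled drugs for a verdict;
#'   cell lines below it get `NA` verdicts and `verdict_withheld = TRUE`.
#' @return data.frame with one row per cell line: `cell_line`,
#'   `n_drugs_modeled`, `p_lt_m165`, `p_lt_0`, `p_gt_165`, `p_gt_0`,
#'   `verdict_ci`, `verdict_dist`, `verdict_combined`, `verdict_withheld`.
#' @export
call_outliers <- function(sre, extreme_threshold = 1.65,
                          extreme_prop = 0.20, sign_prop = 0.80,
                          min_drugs = 3L) {
  if (is.null(dim(sre))) stop("sre must be a matrix", call. = FALSE)
  if (nrow(sre) == 0L) {
    return(data.frame(cell_line = character(0)))
  }
  out <- vector("list", nrow(sre))
  for (i in seq_len(nrow(sre))) {
    s <- sre[i, ]
    s <- s[!is.na(s)]
    n <- length(s)
    p_lt_m <- if (n) mean(s <= -extreme_threshold) else NA_real_
    p_lt_0 <- if (n) mean(s < 0) else NA_real_
    p_gt_m <- if (n) mean(s >= extreme_threshold) else NA_real_
    p_gt_0 <- if (n) mean(s > 0) else NA_real_
    withheld <- n < min_drugs
    v <- outlier_verdicts(p_lt_m, p_lt_0, p_gt_m, p_gt_0,
                          extreme_prop, sign_prop)
    if (withheld) v[] <- NA_character_
    out[[i]] <- data.frame(
      cell_line = rownames(sre)[i], n_drugs_modeled = n,
      p_lt_m165 = p_lt_m, p_lt_0 = p_lt_0,
      p_gt_165 = p_gt_m, p_gt_0 = p_gt_0,
      verdict_ci = v[["ci"]], verdict_dist = v[["dist"]],
      verdict_combined = v[["combined"]],
      verdict_withheld = withheld, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Verdicts from the four SRE proportions
#'
#' @param p_lt_m165,p_lt_0,p_gt_165,p_gt_0 Proportions in \[0, 1\] of
#'   modeled drugs with SRE at or beyond -1.65, below 0, at or beyond
#'   1.65, above 0.
#' @param extreme_prop,sign_prop Rule thresholds (0.20 and 0.80).
#' @return Named character vector: verdicts under the `ci`, `dist` and
#'   `combined` rules, each `"sensitive"`, `"resistant"` or `"neutral"`.
#' @examples
#' outlier_verdicts(0, 0, 0.33, 1)    # combined: resistant
#' outlier_verdicts(0.43, 0.86, 0, 0) # combined: sensitive
#' @export
outlier_verdicts <- function(p_lt_m165, p_lt_0, p_gt_165, p_gt_0,
                             extreme_prop = 0.20, sign_prop = 0.80) {
  pick <- function(sens, res) {
    if (isTRUE(sens)) "sensitive" else if (isTRUE(res)) "resistant"
    else "neutral"
  }
  ci <- pick(p_lt_m165 >= extreme_prop, p_gt_165 >= extreme_prop)
  dist <- pick(p_lt_0 >= sign_prop, p_gt_0 >= sign_prop)
  comb <- pick(p_lt_m165 >= extreme_prop && p_lt_0 >= sign_prop,
               p_gt_165 >= extreme_prop && p_gt_0 >= sign_prop)
  c(ci = ci, dist = dist, combined = comb)
}

#' One-sided normal coverage of the outlier boundaries
#'
#' The three outlier thresholds correspond to one-sided standard-normal
#' confidence levels: `P(Z < 1.65)`, `P(Z < 2.5)` and `P(Z < 3)`, i.e.
#' about 95, 99.4 and 99.9 percent.
#'
#' @param thresholds Numeric vector of boundaries.
#' @return Coverage in percent, one value per threshold.
#' @examples
#' threshold_coverage()
#' @export
threshold_coverage <- function(thresholds = c(1.65, 2.5, 3)) {
  100 * stats::pnorm(thresholds)
}
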