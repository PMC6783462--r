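#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of mid-ranks (average ranks for ties), computed on
#' complete pairs. Used to compare single-fit EC50 estimates with
#' standardized random effects within a study, and SREs between studies.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value
#'   in either are dropped.
#' @return Spearman's coefficient in \[-1, 1\].
#' @examples
#' spearman_rho(1:4, c(10, 20, 30, 40))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("insufficient data: need >= 3 complete pairs", call. = FALSE)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  vx <- sum(dx^2); vy <- sum(dy^2)
  if (vx == 0 || vy == 0) {
    stop("zero rank variance: correlation undefined", call. = FALSE)
  }
  sum(dx * dy) / sqrt(vx * vy)
}

#' Qualitative category of a Spearman coefficient
#'
#' Categories follow the convention used for pharmacogenomic concordance:
#' poor below 0.5, fair on \[0.5, 0.6), moderate on \[0.6, 0.7),
#' substantial on \[0.7, 0.8) and perfect at 0.8 and above (half-open bins
#' resolve the shared endpoints).
#'
#' @param rho Numeric vector of coefficients in \[-1, 1\].
#' @return Character vector of categories.
#' @examples
#' categorize_rho(c(0.75, 0.67, 0))
#' @export
categorize_rho <- function(rho) {
  if (anyNA(rho) || any(!is.finite(rho))) {
    stop("rho must be finite", call. = FALSE)
  }
  if (any(abs(rho) > 1)) stop("|rho| must not exceed 1", call. = FALSE)
  cut(rho, breaks = c(-Inf, 0.5, 0.6, 0.7, 0.8, Inf), right = FALSE,
      labels = c("poor", "fair", "moderate", "substantial", "perfect")) |>
    as.character()
}

#' Within-study concordance between SREs and single-fit EC50 estimates
#'
#' For each drug, Spearman's correlation between the cell lines' SREs from
#' the mixed model and their single-fit log-EC50 estimates.
#'
#' @param sre SRE matrix from [sre_table()].
#' @param single_fits data.frame from [fit_panel_curves()] (columns
#'   `cell_line`, `drug`, `log_ec50`).
#' @param min_pairs Minimum complete pairs per drug (3).
#' @return data.frame: `drug`, `n_pairs`, `rho`, `category`; drugs with
#'   too few pairs are dropped.
#' @export
within_study_concordance <- function(sre, single_fits, min_pairs = 3L) {
  out <- list()
  for (d in colnames(sre)) {
    s <- sre[, d]
    sf <- single_fits[single_fits$drug == d, ]
    le <- stats::setNames(sf$log_ec50, sf$cell_line)
    common <- intersect(names(s)[!is.na(s)], names(le)[!is.na(le)])
    if (length(common) < min_pairs) next
    rho <- spearman_rho(s[common], le[common])
    out[[d]] <- data.frame(drug = d, n_pairs = length(common), rho = rho,
                           category = categorize_rho(rho),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(drug = character(0))
  rownames(res) <- NULL
  res
}

#' Cross-study concordance of SREs
#'
#' For every drug present in both SRE tables, Spearman's correlation over
#' the cell lines present in both, after applying optional alias mappings
#' to bring the two studies into one identifier namespace.
#'
#' @param sre_a,sre_b SRE matrices from [sre_table()].
#' @param cell_alias,drug_alias Optional named character vectors mapping
#'   study-B identifiers to study-A identifiers.
#' @param min_pairs Minimum complete pairs per drug.
#' @return data.frame: `drug`, `n_pairs`, `rho`, `category`; empty (with a
#'   warning) when the studies share no drugs.
#' @export
cross_study_concordance <- function(sre_a, sre_b, cell_alias = NULL,
                                    drug_alias = NULL, min_pairs = 3L) {
  if (!is.null(cell_alias)) {
    hit <- rownames(sre_b) %in% names(cell_alias)
    rownames(sre_b)[hit] <- cell_alias[rownames(sre_b)[hit]]
  }
  if (!is.null(drug_alias)) {
    hit <- colnames(sre_b) %in% names(drug_alias)
    colnames(sre_b)[hit] <- drug_alias[colnames(sre_b)[hit]]
  }
  drugs <- intersect(colnames(sre_a), colnames(sre_b))
  if (length(drugs) == 0L) {
    warning("no common drugs between the two studies")
    return(data.frame(drug = character(0)))
  }
  out <- list()
  for (d in drugs) {
    a <- sre_a[, d]; b <- sre_b[, d]
    common <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
    if (length(common) < min_pairs) next
    rho <- spearman_rho(a[common], b[common])
    out[[d]] <- data.frame(drug = d, n_pairs = length(common), rho = rho,
                           category = categorize_rho(rho),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(drug = character(0))
  rownames(res) <- NULL
  res
}
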