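check_panel <- function(panel) {
  need <- c("cell_line", "drug", "cancer_type", "dose_uM", "response")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("panel is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(panel)
}

#' Read a long-format dose-response panel
#'
#' Reads a delimited text file with one row per measurement and required
#' columns `cell_line`, `drug`, `cancer_type`, `dose_uM`, `response`.
#' Rows with a non-positive or missing dose, or a non-numeric response,
#' are rejected; their file line numbers are reported in a warning and in
#' the `rejected_lines` attribute of the result.
#'
#' @param path File path.
#' @param sep Field separator (default comma; use `"\t"` for TSV).
#' @return Validated panel data.frame.
#' @export
read_panel <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty input: ", path, call. = FALSE)
  check_panel(raw)
  dose <- suppressWarnings(as.numeric(raw$dose_uM))
  resp <- suppressWarnings(as.numeric(raw$response))
  bad <- is.na(dose) | dose <= 0 | is.na(resp)
  if (any(bad)) {
    lines <- which(bad) + 1L  # header occupies line 1
    warning(sum(bad), " row(s) rejected (non-positive dose or non-numeric ",
            "response) at file line(s): ",
            paste(utils::head(lines, 20L), collapse = ", "),
            if (sum(bad) > 20L) " ..." else "")
  }
  out <- raw[!bad, , drop = FALSE]
  out$dose_uM <- dose[!bad]
  out$response <- resp[!bad]
  rownames(out) <- NULL
  attr(out, "rejected_lines") <- which(bad) + 1L
  out
}

# full-precision numeric formatting so writes round-trip exactly enough
# (1e-15 relative) and identical runs produce identical bytes
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

write_table_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- fmt_num(out[[j]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a panel to CSV
#'
#' Numeric columns are written at full precision (17 significant digits)
#' so that a write/read round trip preserves values and repeated runs are
#' byte-identical.
#'
#' @param panel Panel data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  check_panel(panel)
  write_table_precise(panel, path)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' @param sim A `dr_sim` from [generate_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  tr <- sim$truth
  doc <- list(
    beta0 = tr$beta0, D = as.vector(tr$D), sigma = tr$sigma,
    seed = tr$seed, cancer_type = tr$cancer_type,
    outliers = as.list(tr$outliers), outlier_delta = tr$outlier_delta,
    design = list(n_doses = tr$design$n_doses,
                  dilution_factor = tr$design$dilution_factor,
                  top_dose = tr$design$top_dose),
    cell_lines = rownames(tr$b),
    b3 = unname(tr$b[, 1L]), b4 = unname(tr$b[, 2L]),
    forms = list(cell_lines = rownames(tr$forms),
                 drugs = colnames(tr$forms),
                 values = as.vector(tr$forms))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Supply either an
#' existing `panel` (data.frame or CSV path) or a `simulate` list
#' (`n_cell_lines`, `n_drugs`, `design` preset or [dose_design()], `truth`
#' a [truth_config()], optional `form_fractions` passed to
#' [inject_form_heterogeneity()]).
#'
#' @param panel Panel data.frame or path to a panel CSV (optional).
#' @param simulate Simulation settings list (optional; ignored when
#'   `panel` is given).
#' @param seed Integer seed governing all randomness.
#' @param singlefit A [singlefit_control()].
#' @param nlme A [nlme_control()] (contains the `> min_cell_lines` gate).
#' @param extreme_threshold,extreme_prop,sign_prop,min_drugs Outlier-rule
#'   settings, see [call_outliers()].
#' @param out_dir Optional output directory for all result tables.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(panel = NULL, simulate = NULL, seed = 1L,
                            singlefit = singlefit_control(),
                            nlme = nlme_control(),
                            extreme_threshold = 1.65, extreme_prop = 0.20,
                            sign_prop = 0.80, min_drugs = 3L,
                            out_dir = NULL) {
  if (is.null(panel) && is.null(simulate)) {
    stop("config needs either a panel or simulate settings", call. = FALSE)
  }
  if (extreme_threshold <= 0 || extreme_prop <= 0 || sign_prop <= 0 ||
      min_drugs <= 0) {
    stop("outlier thresholds must be positive", call. = FALSE)
  }
  structure(list(panel = panel, simulate = simulate,
                 seed = as.integer(seed), singlefit = singlefit,
                 nlme = nlme, extreme_threshold = extreme_threshold,
                 extreme_prop = extreme_prop, sign_prop = sign_prop,
                 min_drugs = as.integer(min_drugs), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (optional) panel simulation, per-series curve fits
#' and AIC form selection, majority-form selection per cancer type x drug,
#' mixed-effects fits for groups passing the `> min_cell_lines` gate, SRE
#' standardization, outlier calling, and within-study concordance. Every
#' (cancer type, drug) group is accounted for in the manifest as fitted or
#' skipped with a reason. Given the same configuration and seed the output
#' is identical, byte-for-byte when written.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `panel`, `sim` (or NULL),
#'   `fits`, `form_props`, `groups` (per-group status), `nlme_fits`,
#'   `blups`, `sre`, `outliers`, `concordance`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- character(0)

  ## stage: input
  sim <- NULL
  if (!is.null(config$panel)) {
    panel <- if (is.character(config$panel)) read_panel(config$panel)
             else config$panel
    check_panel(panel)
    stages <- c(stages, "input: panel supplied")
  } else {
    s <- config$simulate
    design <- s$design
    if (is.null(design)) design <- dose_design("CCLE")
    if (is.character(design)) design <- dose_design(design)
    truth <- if (is.null(s$truth)) truth_config() else s$truth
    sim <- generate_panel(s$n_cell_lines, s$n_drugs, design, truth,
                          seed = config$seed)
    if (!is.null(s$form_fractions)) {
      sim <- inject_form_heterogeneity(sim, s$form_fractions,
                                       seed = config$seed + 1L)
    }
    panel <- sim$panel
    stages <- c(stages, sprintf("input: simulated %d cell lines x %d drugs",
                                s$n_cell_lines, s$n_drugs))
  }

  ## stage: single-curve fits + form selection
  fits <- fit_panel_curves(panel, config$singlefit)
  form_props <- form_proportions(fits)
  stages <- c(stages, sprintf("singlefit: %d series fitted", nrow(fits)))

  ## stage: per-group majority form + NLME
  groups <- split(fits, list(fits$cancer_type, fits$drug), drop = TRUE)
  group_status <- list()
  nlme_fits <- list()
  blups <- list()
  for (g in groups) {
    key <- paste(g$cancer_type[1L], g$drug[1L], sep = ":")
    maj <- select_majority_form(stats::setNames(g$best_form, g$cell_line))
    if (!maj$modelable) {
      group_status[[key]] <- data.frame(
        cancer_type = g$cancer_type[1L], drug = g$drug[1L],
        form = NA_character_, n_included = 0L, status = "skipped",
        reason = "no logistic-best cell lines", stringsAsFactors = FALSE)
      next
    }
    if (length(maj$included) <= config$nlme$min_cell_lines) {
      group_status[[key]] <- data.frame(
        cancer_type = g$cancer_type[1L], drug = g$drug[1L],
        form = maj$form, n_included = length(maj$included),
        status = "skipped",
        reason = sprintf("gate: %d included, need > %d",
                         length(maj$included), config$nlme$min_cell_lines),
        stringsAsFactors = FALSE)
      next
    }
    sub <- panel[panel$drug == g$drug[1L] &
                   panel$cancer_type == g$cancer_type[1L] &
                   panel$cell_line %in% maj$included, , drop = FALSE]
    fit <- tryCatch(fit_nlme(sub, maj$form, config$nlme),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      group_status[[key]] <- data.frame(
        cancer_type = g$cancer_type[1L], drug = g$drug[1L],
        form = maj$form, n_included = length(maj$included),
        status = "failed", reason = conditionMessage(fit),
        stringsAsFactors = FALSE)
      next
    }
    nlme_fits[[key]] <- fit
    blups[[key]] <- data.frame(cell_line = fit$blups$cell_line,
                               drug = g$drug[1L],
                               cancer_type = g$cancer_type[1L],
                               b3 = fit$blups$b3, b4 = fit$blups$b4,
                               stringsAsFactors = FALSE)
    group_status[[key]] <- data.frame(
      cancer_type = g$cancer_type[1L], drug = g$drug[1L], form = maj$form,
      n_included = length(maj$included), status = "fitted",
      reason = if (fit$converged) "" else "not converged at max_iter",
      stringsAsFactors = FALSE)
  }
  group_status <- do.call(rbind, c(group_status,
                                   list(make.row.names = FALSE)))
  stages <- c(stages, sprintf("nlme: %d fitted, %d skipped/failed",
                              length(nlme_fits),
                              sum(group_status$status != "fitted")))

  ## stage: SRE + outliers + concordance
  blup_tab <- if (length(blups)) {
    do.call(rbind, c(blups, list(make.row.names = FALSE)))
  } else {
    data.frame(cell_line = character(0), drug = character(0),
               cancer_type = character(0), b3 = numeric(0),
               b4 = numeric(0))
  }
  sre <- if (nrow(blup_tab)) sre_table(blup_tab) else
    matrix(numeric(0), 0, 0)
  outliers <- if (nrow(sre)) {
    call_outliers(sre, config$extreme_threshold, config$extreme_prop,
                  config$sign_prop, config$min_drugs)
  } else data.frame(cell_line = character(0))
  concord <- if (nrow(sre)) within_study_concordance(sre, fits) else
    data.frame(drug = character(0))
  stages <- c(stages, sprintf(
    "outliers: %d combined-rule calls over %d cell lines",
    if (nrow(outliers)) sum(outliers$verdict_combined != "neutral",
                            na.rm = TRUE) else 0L, nrow(sre)))

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dosescreen")),
    config = list(
      simulate = !is.null(sim),
      extreme_threshold = config$extreme_threshold,
      extreme_prop = config$extreme_prop, sign_prop = config$sign_prop,
      min_drugs = config$min_drugs,
      nlme_gate = config$nlme$min_cell_lines,
      nlme_tol = config$nlme$tol),
    stages = stages,
    groups = group_status
  )

  result <- structure(list(panel = panel, sim = sim, fits = fits,
                           form_props = form_props, groups = group_status,
                           nlme_fits = nlme_fits, blups = blup_tab,
                           sre = sre, outliers = outliers,
                           concordance = concord, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline(result, config$out_dir)
  result
}

#' Write all pipeline outputs to a directory
#'
#' Emits `panel.csv`, `fits.csv`, `form_proportions.csv`, `groups.csv`,
#' `blups.csv`, `sre.csv` (cell line x drug matrix, empty cells for
#' missing), `outliers.csv`, `concordance.csv`, `manifest.json` and, when
#' the panel was simulated, `truth.json`. All numerics at full precision.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_panel(result$panel, fp("panel.csv"))
  write_table_precise(result$fits, fp("fits.csv"))
  write_table_precise(result$form_props, fp("form_proportions.csv"))
  write_table_precise(result$groups, fp("groups.csv"))
  write_table_precise(result$blups, fp("blups.csv"))
  sre_df <- as.data.frame(result$sre)
  sre_df <- cbind(cell_line = rownames(result$sre), sre_df)
  write_table_precise(sre_df, fp("sre.csv"))
  write_table_precise(result$outliers, fp("outliers.csv"))
  write_table_precise(result$concordance, fp("concordance.csv"))
  man <- result$manifest
  jsonlite::write_json(man, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  if (!is.null(result$sim)) write_truth(result$sim, fp("truth.json"))
  invisible(dir)
}
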