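#!/usr/bin/env Rscript

# Simulate the study panel: a CCLE-like screen of 60 cell lines x 8 drugs
# (8-point half-log dilution from 8 uM), percent-viability responses with
# sd-5 Gaussian noise, cell-line random effects on log-EC50 (sd 0.8) and
# slope (sd 0.3), 5% of lines injected as globally sensitive outliers
# (log-EC50 shifted by -3 sd across every drug), and mixed generating
# forms (70% 4P, 20% 3P, 10% linear) to exercise form selection.

suppressMessages(library(dosescreen))

seed <- 2026L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sim <- generate_panel(
  n_cell_lines = 60, n_drugs = 8,
  design = dose_design("CCLE"),
  truth = truth_config(sigma = 5, outlier_fraction = 0.05),
  seed = seed)
sim <- inject_form_heterogeneity(
  sim, c("4P" = 0.7, "3P" = 0.2, "linear" = 0.1), seed = seed + 1L)

write_panel(sim$panel, file.path(out_dir, "panel.csv"))
write_truth(sim, file.path(out_dir, "truth.json"))

cat("panel:", length(unique(sim$panel$cell_line)), "cell lines x",
    length(unique(sim$panel$drug)), "drugs,",
    nrow(sim$panel), "measurements\n")
cat("injected sensitive outlier lines:",
    paste(sim$truth$outliers, collapse = ", "), "\n")
cat("generating forms:\n")
print(prop.table(table(sim$truth$forms)))
cat("written: panel.csv, truth.json under", out_dir, "\n")
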