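#!/usr/bin/env Rscript

# Optional full-scale benchmark against the NCI-60 cell-line panel.
#
# NOT part of automated acceptance: it needs network access and external
# data that cannot be redistributed here —
#   * RNA-seq expression (FPKM) for the NCI-60 lines, from the CellMiner
#     download portal (https://discover.nci.nih.gov/cellminer/),
#   * the published exchange-flux measurements (uptake/secretion,
#     fmol/cell/h) for the same lines,
#   * a curated human genome-scale model (SBML with fbc) plus a Kcat
#     table and alpha/gamma ratio table at genome scale.
#
# Workflow, once those files are in place (paths below):
#   1. load and curate the model; gimme_reduce() to the Kcat-covered core
#      with ATP production + biomass objectives;
#   2. pipeline_mean_fluxes() per cell line with per-line uptake bounds;
#   3. convert measured fluxes from fmol/cell/h to mmol/L/min — this
#      needs an explicit cell-volume assumption (CELL_VOLUME_L below;
#      the published protocol does not print one);
#   4. filter_experimental_fluxes() (median floor 1e-3 mmol/L/min,
#      3-MAD outlier masking) and compare_fluxes() (floor 1e-6).
#
# The headline numbers this reproduces at full scale (overall R^2 ~0.7,
# lactate secretion R^2 ~0.86) depend on the exact database versions
# downloaded and are therefore not asserted anywhere in the test suite.

suppressPackageStartupMessages(library(kinflux))

MODEL_SBML <- "data/recon_curated.xml"
KCAT_TSV <- "data/kcat.tsv"
RATIOS_TSV <- "data/alpha_gamma.tsv"
EXPR_TSV <- "data/nci60_fpkm.tsv"
MEASURED_TSV <- "data/nci60_fluxes_fmol_cell_h.tsv"
UPTAKE_TSV <- "data/uptake_bounds.tsv"
CELL_VOLUME_L <- 2e-12   # explicit assumption: ~2 pL per cell

needed <- c(MODEL_SBML, KCAT_TSV, RATIOS_TSV, EXPR_TSV, MEASURED_TSV)
missing <- needed[!file.exists(needed)]
if (length(missing)) {
  stop("missing input file(s):\n  ", paste(missing, collapse = "\n  "),
       "\nSee the header of this script for where to obtain them.")
}

fmol_cell_h_to_mmol_L_min <- function(x, cell_volume_L = CELL_VOLUME_L) {
  # fmol/cell/h = 1e-12 mmol per cell per h; concentration change rate
  # referenced to the cell volume, per minute
  x * 1e-12 / cell_volume_L / 60
}

model <- load_model(MODEL_SBML)
kcats <- read_kcat_table(KCAT_TSV)
rt <- utils::read.delim(RATIOS_TSV)
ratios <- protein_ratio_table(stats::setNames(rt$ratio, rt$gene))
expr <- as.matrix(utils::read.delim(EXPR_TSV, row.names = 1,
                                    check.names = FALSE))
uptake <- if (file.exists(UPTAKE_TSV)) read_uptake_config(UPTAKE_TSV)

reduced <- gimme_reduce(model, kcats)
pred <- pipeline_mean_fluxes(reduced, expr, kcats, ratios, uptake,
                             n_draws = 1000, warmup = 200, thinning = 100,
                             seed = 1)

measured <- fmol_cell_h_to_mmol_L_min(
  as.matrix(utils::read.delim(MEASURED_TSV, row.names = 1,
                              check.names = FALSE)))
measured <- filter_experimental_fluxes(measured)

overall <- compare_fluxes(pred, measured)
print(overall)
if ("EX_lac__L_e" %in% rownames(pred) &&
    "EX_lac__L_e" %in% rownames(measured)) {
  print(compare_fluxes(pred["EX_lac__L_e", , drop = FALSE],
                       measured["EX_lac__L_e", , drop = FALSE]))
}
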