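#!/usr/bin/env Rscript
# OPTIONAL, network-dependent: downloads published genome-scale E. coli
# models from the BiGG database and runs the consistency checks on them.
# Nothing in the package or its tests depends on this script.
#
# Usage: Rscript scripts/fetch_models.R [--check-type 0] [--dir scratch/models]
#
# Note on cost: connectivity and null-space-basis checks finish in seconds
# even at genome scale.  Full FVA (check type 1/2) solves 2n linear
# programs with the package's dense simplex backend, which is sized for
# curation-scale models; at thousands of reactions expect it to be very
# slow.  The solver abstraction (see ?runFVA) accepts pluggable backends
# for industrial use.

suppressPackageStartupMessages({
  library(optparse)
  library(fluxcheck)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--check-type", type = "integer", default = 0L,
              dest = "checkType"),
  make_option("--dir", type = "character", default = "scratch/models")
)))

models <- c(
  iAF1260 = "http://bigg.ucsd.edu/static/models/iAF1260.xml",
  iJR904 = "http://bigg.ucsd.edu/static/models/iJR904.xml"
)

dir.create(opts$dir, recursive = TRUE, showWarnings = FALSE)
for (name in names(models)) {
  dest <- file.path(opts$dir, paste0(name, ".xml"))
  if (!file.exists(dest)) {
    message("downloading ", name, " ...")
    utils::download.file(models[[name]], dest, quiet = TRUE)
  }
  message("checking ", name)
  model <- readSBMLModel(dest)
  report <- checkModel(model, checkType = opts$checkType)
  cat("==", name, "==\n")
  cat(renderReport(report))
}
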