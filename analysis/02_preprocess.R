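#!/usr/bin/env Rscript
# Preprocess the simulated probe voltages: baseline detection, Granier
# conversion, molar conversion, whole-tree aggregation and the join with
# the 10-min drivers. Writes tidy per-tree CSVs and a QC report.

suppressPackageStartupMessages(library(sapflowhm))

src <- "results/simulated"
out <- "results/preprocessed"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

probes <- read.csv(file.path(src, "probes.csv"))
probes$timestamp <- as.POSIXct(probes$timestamp, tz = "UTC",
                               format = "%Y-%m-%d %H:%M:%S")
geometry <- read.csv(file.path(src, "geometry.csv"))
meteo <- read.csv(file.path(src, "meteo.csv"))
meteo$timestamp <- as.POSIXct(meteo$timestamp, tz = "UTC",
                              format = "%Y-%m-%d %H:%M:%S")
trees <- read.csv(file.path(src, "trees.csv"))

built <- build_dataset(probes, geometry, meteo, trees)

for (id in names(built$data)) {
  d <- built$data[[id]]
  write.csv(d$rows, file.path(out, paste0(id, ".csv")), row.names = FALSE)
}
write.csv(built$qc, file.path(out, "qc_report.csv"), row.names = FALSE)

cat("per-tree valid rows after the D > 0 filter:\n")
print(built$qc)
cat("wrote tidy per-tree series and QC report to", out, "\n")
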