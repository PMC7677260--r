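#!/usr/bin/env Rscript
# Generate the synthetic sap flow campaign: 5 young + 6 old Scots pines,
# 8 days of 10-min drivers and observations, plus the raw probe-voltage
# files the preprocessing stage consumes. Writes results/simulated/.

suppressPackageStartupMessages(library(sapflowhm))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- scenario_config(seed = 1)
sc <- simulate_scenario(cfg)

# explicit second-resolution stamps: write.csv would drop " 00:00:00"
# on midnight rows and the files would no longer re-parse cleanly
stamp <- function(df) {
  df$timestamp <- format(df$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  df
}

write.csv(stamp(meteo_to_raw(sc$meteo)), file.path(out, "meteo.csv"),
          row.names = FALSE)
write.csv(sc$trees[, c("tree_id", "age_group", "height_m", "dbh_cm", "age_yr")],
          file.path(out, "trees.csv"), row.names = FALSE)

probes <- NULL; geometry <- NULL
for (d in sc$data) {
  pv <- gen_probe_voltages(d, cfg)
  probes <- rbind(probes, pv$probes)
  geometry <- rbind(geometry, pv$geometry)
}
write.csv(stamp(probes), file.path(out, "probes.csv"), row.names = FALSE)
write.csv(geometry, file.path(out, "geometry.csv"), row.names = FALSE)
write.csv(data.frame(name = names(sc$truth), value = sc$truth),
          file.path(out, "truth.csv"), row.names = FALSE)

day <- sc$meteo$I > 0
cat(sprintf("simulated %d trees x %d rows (%d with D = 0); daytime cor(D, I) = %.2f\n",
            nrow(sc$trees), nrow(sc$meteo), sum(sc$meteo$D == 0),
            cor(sc$meteo$D[day], sc$meteo$I[day])))
cat("wrote probe voltages, meteorology, tree table and truth to", out, "\n")
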