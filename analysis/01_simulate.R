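#!/usr/bin/env Rscript
# Stage 1: simulate the tracked population on the default landscape.
# Emulates 16 GPS-tagged birds (10 non-breeders, 6 breeders), 30-min fixes
# in a 06:30-22:30 daylight window over two 150-day summer seasons, and
# writes the raw artifacts every later stage reads.

library(scavnet)

seed <- 1
outdir <- "results"
dir.create(outdir, showWarnings = FALSE)

sim <- simulate_population(seed = substream_seed(seed, "simulate"))

write_trajectory_csv(sim$trajectories, file.path(outdir, "trajectories.csv"))
write_sites_csv(sim$landscape$sites, file.path(outdir, "sites.csv"))
write_esri_ascii(sim$landscape$landcover$m, sim$landscape$landcover$grid,
                 file.path(outdir, "landcover.asc"))
write_legend(sim$landscape$legend, file.path(outdir, "landcover_legend.csv"))

cat(sprintf("simulated %d fixes for %d individuals (%d sites)\n",
            nrow(sim$trajectories),
            length(unique(sim$trajectories$individual_id)),
            nrow(sim$landscape$sites)))
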