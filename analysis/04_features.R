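#!/usr/bin/env Rscript
# Stage 4: node characterization. Land-cover composition (nine classes),
# dominant food resource by UD-weighted site probability, roost and
# breeding-territory flags, and node fidelity (revisits, residence time)
# per reproductive status.

library(scavnet)

outdir <- "results"
traj <- read_trajectory_csv(file.path(outdir, "trajectories.csv"))
sites <- read_sites_csv(file.path(outdir, "sites.csv"))
lc <- read_esri_ascii(file.path(outdir, "landcover.asc"))
ud <- read_esri_ascii(file.path(outdir, "population_ud.asc"))
pud <- ud_grid(ud$grid, ud$m)
nodes <- extract_contour(pud, level = 0.5)

labeled <- label_fixes(traj, nodes)
features <- node_features(nodes, labeled, pud, sites,
                          list(grid = lc$grid, m = lc$m))
write_features_csv(features, file.path(outdir, "node_features.csv"))

cat("resource composition of nodes:\n")
print(table(features$resource[features$status == "non_breeder"]))
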