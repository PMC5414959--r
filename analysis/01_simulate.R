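#!/usr/bin/env Rscript
# Generate the synthetic study panel: a molecular-function DAG and
# functionomes for 30 genomes (10 Archaea, 10 Bacteria, 10 Eukarya)
# under the birth-spread-loss model, plus a horizontally contaminated
# variant used by the transfer-screen analysis.
#
# Writes: results/sim/ (OBO, per-genome GAF, metadata, HTP ids) and
#         results/sim_hgt/ for the contaminated panel.

library(gocensus)

dir.create("results", showWarnings = FALSE)

p <- sim_params(seed = 1)
dg <- generate_dag(p)
fx <- generate_functionomes(dg, p)
write_simulation(dg, fx, "results/sim")

cat(sprintf("clean panel: %d terminal terms, %d genomes, %d annotations\n",
            length(dg$terminals), nrow(fx$meta), nrow(fx$annotations)))

ph <- sim_params(hgt_rate = 0.3, htp_label = 1.0, seed = 1)
dgh <- generate_dag(ph)
fxh <- generate_functionomes(dgh, ph)
write_simulation(dgh, fxh, "results/sim_hgt")
cat(sprintf("contaminated panel: %d mobile terms, %d HTP genes\n",
            length(fxh$truth$mobile_terms), length(fxh$htp_genes)))
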