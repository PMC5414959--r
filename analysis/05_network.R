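#!/usr/bin/env Rscript
# Assemble the multi-level term network (levels 1 -> 2 -> 3 -> terminal)
# annotated with nd ages, and rank hub terms by their links to the next
# deeper level.
#
# Reads:  results/timelines/, results/census/, results/sim/
# Writes: results/network/

library(gocensus)

dir.create("results/network", showWarnings = FALSE, recursive = TRUE)

dag <- parse_obo("results/sim/ontology.obo")
tls <- list()
for (nm in c("1", "2", "3", "terminal")) {
  f <- sprintf("results/timelines/%s_timeline.tsv",
               if (nm == "terminal") "terminal" else paste0("level", nm))
  if (file.exists(f)) tls[[nm]] <- read.delim(f)
}
maps <- list()
for (L in as.character(1:3)) {
  f <- sprintf("results/census/mapping_level%s.tsv", L)
  if (file.exists(f)) maps[[L]] <- read_terminal_mapping(f)
}

net <- build_network(tls, dag, maps)
print(net)
write_pajek(net, "results/network/go_network.net")
write_network_tsv(net, "results/network/go_network_edges.tsv")

for (L in c("2", "3")) {
  if (!L %in% net$nodes$level) next
  # thresholds scaled to the synthetic panel: flag the upper tail of the
  # link-count distribution rather than the published absolute cutoffs
  links <- table(net$edges$from[net$edges$level_from == L])
  thr <- if (length(links)) max(2L, stats::quantile(as.integer(links), 0.75))
         else 2L
  hubs <- hub_terms(net, L, min_links = thr)
  write.table(hubs, sprintf("results/network/hubs_level%s.tsv", L),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("level %s hubs (>= %d links): %d term(s)\n",
              L, as.integer(thr), nrow(hubs)))
}
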