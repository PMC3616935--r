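#!/usr/bin/env Rscript
# Stage 4: topology of the curated interaction network: degree, closeness
# and betweenness centrality per protein.

suppressPackageStartupMessages(library(phylosel))

net <- read_network("results/study_inputs/network.tsv")
ct <- centralities(net)
utils::write.table(ct, "results/centralities.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("network: %d nodes, %d edges, %d component(s)\n",
            length(net$nodes), nrow(net$edges), max(ct$component)))
top <- ct[order(-ct$closeness), ][1:5, ]
cat("most central proteins by closeness:\n")
print(top[, c("node", "degree", "closeness", "betweenness")],
      row.names = FALSE, digits = 3)
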