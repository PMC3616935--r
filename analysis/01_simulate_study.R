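#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study that stands in for the real dataset:
# 54 phototransduction-style genes over the nine-mammal tree, 30 of them
# wired into a connected 81-edge interaction network, true omegas planted to
# fall with network closeness and to differ between functional classes.
# Everything is written in the same plain-text formats the pipeline reads,
# so the downstream stages exercise the full I/O path.

suppressPackageStartupMessages(library(phylosel))

seed <- 20260928L
out <- "results/study_inputs"
dir.create(file.path(out, "alignments"), recursive = TRUE,
           showWarnings = FALSE)

spec <- simulation_spec(seed = seed)
study <- simulate_study(spec)

for (g in names(study$alignments)) {
  write_codon_alignment(study$alignments[[g]],
                        file.path(out, "alignments", paste0(g, ".fasta")))
}
write_tree(study$tree, file.path(out, "species_tree.nwk"))
write_network(study$network, file.path(out, "network.tsv"))
write_annotations(study$annotations, file.path(out, "annotations.tsv"))
utils::write.table(study$truth, file.path(out, "truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf(
  "wrote %d gene alignments (%d codons each), a %d-node / %d-edge network,\n",
  length(study$alignments), spec$n_codons,
  length(study$network$nodes), nrow(study$network$edges)))
cat(sprintf("true omega range: %.3f - %.3f (all < 1, purifying regime)\n",
            min(study$truth$true_omega), max(study$truth$true_omega)))
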