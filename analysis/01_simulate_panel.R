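#!/usr/bin/env Rscript
# Generate the synthetic 27-allele x 636-peptide HLA class II study panel
# (15 DR, 6 DQ, 6 DP; one planted binder-prototype block per locus) plus
# the matching 15-mer binding motifs, and export data + ground truth.

suppressPackageStartupMessages(library(hlaSupertype))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 1)
sim <- simulate_affinity(cfg)
mot <- simulate_motifs(cfg)

write_affinity_table(sim$affinity, "results/affinity_panel.csv")
write_motif_fasta(mot$motifs, "results/binding_motifs.fasta")
jsonlite::write_json(list(
  cluster_of = as.list(sim$truth$cluster_of),
  locus_of = as.list(cfg$locus_of),
  motif_prototypes = as.list(mot$truth$prototypes)),
  "results/ground_truth.json", auto_unbox = TRUE, pretty = TRUE)

print(sim$affinity)
cat("Panel written to results/affinity_panel.csv;",
    "motifs to results/binding_motifs.fasta\n")
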