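#!/usr/bin/env Rscript
# Motif-based supertype classification and the consensus with the
# functional classification. Motifs are encoded as 15 x 24 = 360
# physicochemical descriptors and clustered with Euclidean distance;
# stable clusters are the functional/motif intersections.

suppressPackageStartupMessages(library(hlaSupertype))
dir.create("results", showWarnings = FALSE)

motifs <- read_fasta_seqs("results/binding_motifs.fasta")
fm <- encode_sequences(motifs, load_index_table())

ad_m <- msboot_cluster(fm, metric = "euclidean", linkage = "average",
                       nboot = 1000, seed = 202)
print(ad_m)
write_annotated_newick(ad_m, "results/motif_tree.nwk")
write_edge_table(ad_m, "results/motif_edges.tsv")

cs_m <- extract_clusters(ad_m)
print(cs_m)

cs_f <- cluster_set(jsonlite::read_json("results/functional_clusters.json",
                                        simplifyVector = TRUE),
                    universe = rownames(fm))
cons <- consensus(cs_f, cs_m)
print(cons)
jsonlite::write_json(cons$stable_pairs, "results/consensus_clusters.json",
                     pretty = TRUE)
cat("Consensus stable clusters written to results/consensus_clusters.json\n")
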