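# hlaSupertype

Consensus supertype classification of HLA class II proteins, with
binding-promiscuity statistics and a peptide-binder classification
benchmark.

## The problem

HLA class II molecules (loci **DR**, **DQ**, **DP**) present peptides to
CD4+ T cells through an open-ended, highly polymorphic binding groove.
Grouping alleles into **supertypes** — sets of alleles with overlapping
peptide-binding repertoires and/or binding-site structure — makes
epitope discovery tractable across thousands of alleles. `hlaSupertype`
is for immunoinformaticians who have an allele × peptide IC50 panel
(and optionally HLA–peptide complex structures) and want reproducible,
confidence-annotated supertypes plus the downstream statistics.

## What it computes

Two independent allele clusterings, each supported by **multiscale
bootstrap AU p-values**, are intersected:

* **Functional**: IC50 values are binarized (per-allele smallest-20%
  quantile rule, or a fixed cutoff, default IC50 < 500 nM) and alleles
  are clustered by Jaccard distance between binary repertoires.
* **Structural**: each allele's 15-residue binding-site motif (β-chain
  positions β9–β78 that contact bound peptides within 4 Å) is encoded
  with 24 amino-acid physicochemical indices (360 descriptors) and
  clustered by Euclidean distance.

Edge support: feature columns are resampled at scales
r ∈ {0.5, …, 1.4}, B replicates each; per edge the model
`Φ⁻¹(1 − BP_r) = v·√r + c/√r` is fitted by weighted least squares,
giving `AU = 1 − Φ(v − c)`, `BP = 1 − Φ(v + c)`, and a delta-method
standard error of AU. Significant clusters are extracted by iteratively
lowering the AU cutoff from α = 0.95 in steps of 0.1; consensus
supertypes are the size-≥2 intersections of the two cluster sets.

Also included: cross-locus vs locus-exclusive peptide promiscuity
statistics with binding-event heat-map export; PPA (percentage of
positive activity) binder labelling; SVM / random-forest / naive-Bayes /
ANN / k-NN benchmarking under 4:1 random subsampling and LOOCV; PDB
contact detection and motif construction; annotated-Newick I/O; and a
seeded synthetic-data generator (27 alleles × 636 peptides, three loci,
planted clusters, exported ground truth) so the whole pipeline runs
offline.

## Worked example

```r
library(hlaSupertype)

cfg <- sim_config(seed = 1)                   # 27-allele, 636-peptide panel
sim <- simulate_affinity(cfg)
bin <- binarize_by_threshold(sim$affinity, cutoff_nM = 500)
print(bin)
#> binary_binding_matrix: 27 alleles x 636 peptides, 4066 binding events
#>   rule: fixed (cutoff = 500 nM)

promiscuity(bin)
#> promiscuity_report: 614/636 peptides with >= 1 binding event
#>   cross-locus: 435 (70.85%)  locus-exclusive: 179 (29.15%)
#>   locus-exclusive event density (%): DP=2.38 DQ=2.2 DR=4.93

ad <- msboot_cluster(bin, metric = "jaccard", nboot = 200, seed = 101)
print(ad)
#> annotated_dendrogram: 27 leaves, jaccard/average, 10 scales x 200 boots
#>   3 non-root edges with AU >= 0.95; max se_au 0.1992

extract_clusters(ad, alpha_start = 0.95, alpha_step = 0.1)
#> cluster_set: 3 clusters over 27 items
#>   [1] AU=1.000 DRB1*0101, DRB1*0201, ..., DRB1*1501
#>   [2] AU=1.000 DPB1*0101, DPB1*0201, DPB1*0301, DPB1*0401, DPB1*0501, DPB1*0601
#>   [3] AU=1.000 DQB1*0101, DQB1*0201, DQB1*0301, DQB1*0401, DQB1*0501, DQB1*0601

assign_activity(compute_ppa(bin), threshold_percent = 30)
#> ppa_labels: 636 peptides, max event count 23
#>   threshold 30%: 263 positives / 373 negatives (41% positive)
```

Reading: 614 of the 636 simulated peptides bind at least one allele;
70.85% of those bind alleles from more than one locus (HLA class II
binding is highly promiscuous), while the per-locus densities of
locus-exclusive events stay in the low percent range. The AU-annotated
dendrogram recovers the three loci as the three maximal clusters with
AU = 1.0, matching the planted ground truth, and the 30% PPA threshold
splits the peptide pool into roughly balanced binder/non-binder classes
for the classifier benchmark.

The numbered scripts under `analysis/` run the same workflow end to end
(simulate → binarize/promiscuity → functional clustering → motif
clustering + consensus → PPA + classifier benchmark), writing tables,
annotated Newick trees and heat maps under `results/`.

On real data, start from `read_affinity_table()` (alleles × peptides
CSV/TSV, loci inferred from DRB/DQB/DPB prefixes), a β-chain FASTA plus
`build_motif()`/`find_contact_residues()` for the structural view, and
`load_index_table(path)` to supply a curated amino-acid index set (the
bundled one is a synthetic stand-in with the right dimensions; see the
methods vignette).

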