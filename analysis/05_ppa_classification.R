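#!/usr/bin/env Rscript
# PPA labelling of the peptide pool and the binder/non-binder classifier
# benchmark (SVM with radial kernel, gamma = 0.5, C = 2.0, versus RF, NB,
# ANN, KNN) under 3-fold random subsampling with a 4:1 train:test ratio,
# plus LOOCV for the SVM on a subsample.
#
# The affinity generator does not tie simulated binding to peptide
# sequence, so for the benchmark the peptide sequences are constructed
# with a planted sequence signal: active peptides derive from a common
# 15-mer prototype (20% per-position substitution), inactive peptides are
# random. This exercises the full procedure end to end.

suppressPackageStartupMessages(library(hlaSupertype))
dir.create("results", showWarnings = FALSE)

aff <- read_affinity_table("results/affinity_panel.csv")
bin <- binarize_by_threshold(aff, 500)
ppa <- compute_ppa(bin)

sweep <- do.call(rbind, lapply(c(10, 20, 30, 40, 50), function(t) {
  s <- assign_activity(ppa, t)$stats
  data.frame(threshold = t, n_pos = s$n_pos, n_neg = s$n_neg,
             pct_pos = s$pct_pos)
}))
write.table(sweep, "results/ppa_threshold_sweep.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("PPA threshold sweep:\n"); print(sweep)

lab <- assign_activity(ppa, 30)
set.seed(301)
proto <- paste(sample(AA_ALPHABET, 15, replace = TRUE), collapse = "")
peps <- vapply(lab$activity, function(a) {
  s <- strsplit(proto, "")[[1]]
  if (a == 1L) {
    mut <- runif(15) < 0.2
    s[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE)
  } else {
    s <- sample(AA_ALPHABET, 15, replace = TRUE)
  }
  paste(s, collapse = "")
}, "")
names(peps) <- lab$peptide_ids
fm <- encode_sequences(homogenize_length(peps), load_index_table())

# The package's SVM default gamma = 0.5 matches the original benchmark's
# feature scale; on these 360 standardized descriptors an RBF width that
# wide degenerates (squared distances ~ 2p), so the synthetic benchmark
# uses the conventional gamma = 1/p while keeping C = 2.0.
splits <- subsample_splits(lab$activity, n_splits = 3, seed = 302)
bench <- do.call(rbind, lapply(
  c("svm_rbf", "random_forest", "naive_bayes", "ann", "knn"),
  function(alg) {
    par <- if (alg == "svm_rbf") list(gamma = 1 / ncol(fm)) else list()
    rep_ <- evaluate(fm, lab$activity, splits, alg, par, seed = 303)
    data.frame(algorithm = alg, t(round(rep_$average, 4)))
  }))
write.table(bench, "results/classifier_benchmark.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nRandom-subsampling benchmark (averages over 3 splits):\n")
print(bench)

set.seed(304)
sub <- sort(c(sample(which(lab$activity == 1L), 50),
              sample(which(lab$activity == 0L), 50)))
lo <- loocv_evaluate(fm[sub, ], lab$activity[sub], "svm_rbf",
                     params = list(gamma = 1 / ncol(fm)), seed = 305)
cat("\nLOOCV (SVM, 100-peptide subsample):\n")
print(lo)
write.table(data.frame(algorithm = "svm_rbf_loocv",
                       t(round(lo$average, 4))),
            "results/loocv_svm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
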