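# Independent oracles and fixture builders used across the test files.

# Naive agglomerative clustering oracle: recomputes between-cluster
# distances from the original matrix at every step (no Lance-Williams
# update), with the package's documented tie-break (clusters ordered by
# creation, smallest (i, j) among ties).
oracle_agglomerate <- function(D, linkage = "average") {
  labels <- rownames(D)
  clusters <- lapply(order(labels), identity)  # sorted singletons
  sets <- list()
  heights <- numeric(0)
  setdist <- function(a, b) {
    vals <- D[a, b, drop = FALSE]
    switch(linkage,
           average = mean(vals),
           complete = max(vals),
           single = min(vals))
  }
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d <- setdist(clusters[[i]], clusters[[j]])
      if (is.null(best) || d < best$d) best <- list(d = d, i = i, j = j)
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    sets[[length(sets) + 1L]] <- merged
    heights <- c(heights, best$d)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(keys = vapply(sets, function(s) paste(sort(labels[s]), collapse = ";"),
                     ""),
       heights = heights)
}

clade_keys_of <- function(hc) {
  n1 <- nrow(hc$merge)
  out <- vector("list", n1)
  for (m in seq_len(n1)) {
    get1 <- function(x) if (x < 0) -x else out[[x]]
    out[[m]] <- sort(c(get1(hc$merge[m, 1]), get1(hc$merge[m, 2])))
  }
  vapply(out, function(s) paste(sort(hc$labels[s]), collapse = ";"), "")
}

# Exhaustive per-peptide locus scan oracle for promiscuity statistics.
oracle_promiscuity <- function(bits, locus) {
  loci <- sort(unique(locus))
  n_loci_hit <- apply(bits, 2, function(col)
    length(unique(locus[which(col == 1)])))
  any_pep <- sum(n_loci_hit >= 1)
  list(any = any_pep,
       cross = sum(n_loci_hit >= 2),
       excl = sum(n_loci_hit == 1),
       excl_events_by_locus = sapply(loci, function(L) {
         tot <- 0
         for (p in seq_len(ncol(bits))) {
           hit <- locus[which(bits[, p] == 1)]
           if (length(hit) > 0 && all(hit == L)) tot <- tot + sum(bits[, p])
         }
         tot
       }))
}

# Build a binary_binding_matrix from explicit bits via the public API.
make_bin <- function(bits, locus) {
  ic50 <- ifelse(bits == 1, 50, 5000)
  dimnames(ic50) <- dimnames(bits)
  binarize_by_threshold(affinity_matrix(ic50, locus = locus), 500)
}

random_bin_fixture <- function(seed, n_alleles = 6, n_peptides = 20) {
  set.seed(seed)
  bits <- matrix(rbinom(n_alleles * n_peptides, 1, runif(1, 0.1, 0.5)),
                 n_alleles, n_peptides,
                 dimnames = list(sprintf("AL%02d", seq_len(n_alleles)),
                                 sprintf("pep%03d", seq_len(n_peptides))))
  locus <- setNames(sample(c("DR", "DQ", "DP"), n_alleles, replace = TRUE),
                    rownames(bits))
  list(bits = bits, locus = locus, bin = make_bin(bits, locus))
}

# Minimal PDB writer for toy structures.
pdb_line <- function(serial, name, resn, chain, resno, x, y, z, ele)
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resn, chain, resno, x, y, z, 1, 0, ele)

write_toy_pdb <- function(path, atoms) {
  lines <- mapply(pdb_line, seq_len(nrow(atoms)), atoms$name, atoms$resn,
                  atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
                  atoms$ele)
  writeLines(c(lines, "END"), path)
  path
}

# Brute-force all-atom-pairs contact oracle.
oracle_contacts <- function(atoms, ch1, ch2, cutoff) {
  a1 <- atoms[atoms$chain == ch1 & atoms$ele != "H", ]
  a2 <- atoms[atoms$chain == ch2 & atoms$ele != "H", ]
  pairs <- list()
  for (r1 in unique(a1$resno)) for (r2 in unique(a2$resno)) {
    p1 <- a1[a1$resno == r1, c("x", "y", "z")]
    p2 <- a2[a2$resno == r2, c("x", "y", "z")]
    dmin <- Inf
    for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2)))
      dmin <- min(dmin, sqrt(sum((p1[i, ] - p2[j, ])^2)))
    if (dmin <= cutoff)
      pairs[[length(pairs) + 1L]] <- c(r1, r2, dmin)
  }
  if (length(pairs) == 0)
    return(data.frame(hla_resno = integer(0), pep_resno = integer(0),
                      min_dist = numeric(0)))
  m <- do.call(rbind, pairs)
  out <- data.frame(hla_resno = m[, 1], pep_resno = m[, 2], min_dist = m[, 3])
  out[order(out$hla_resno, out$pep_resno), ]
}

# Small annotated dendrogram for Newick round-trip tests.
make_annotated <- function(n_leaves, seed = 1) {
  X <- simulate_null(n_leaves, 30, seed = seed)
  msboot_cluster(X, metric = "euclidean", nboot = 30,
                 scales = c(0.6, 0.8, 1.0, 1.2), seed = seed)
}

# A classic 27-allele HLA class II panel (15 DR, 6 DQ, 6 DP).
reference_panel_alleles <- c(
  "DRB1*0101", "DRB1*0301", "DRB1*0401", "DRB1*0404", "DRB1*0405",
  "DRB1*0701", "DRB1*0802", "DRB1*0901", "DRB1*1101", "DRB1*1302",
  "DRB1*1501", "DRB3*0101", "DRB3*0202", "DRB4*0101", "DRB5*0101",
  "DQB1*0201", "DQB1*0301", "DQB1*0302", "DQB1*0401", "DQB1*0501",
  "DQB1*0602",
  "DPB1*0101", "DPB1*0201", "DPB1*0401", "DPB1*0402", "DPB1*0501",
  "DPB1*1401")
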