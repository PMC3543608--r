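test_that("consensus is the set of size->=2 cluster intersections", {
  fc <- cluster_set(list(c("A", "B", "C")), universe = LETTERS[1:6])
  mc <- cluster_set(list(c("A", "B", "D")), universe = LETTERS[1:6])
  cr <- consensus(fc, mc)
  expect_equal(cr$consensus_clusters, list(c("A", "B")))
  # idempotence: identical cluster sets give back the clusters
  cr2 <- consensus(fc, fc)
  expect_equal(cr2$consensus_clusters, list(c("A", "B", "C")))
  # symmetry
  cr3 <- consensus(mc, fc)
  expect_equal(cr3$consensus_clusters, cr$consensus_clusters)
  expect_error(consensus(fc, cluster_set(list(c("X", "Y")))), "no alleles")
})

test_that("the printed DQ supertype intersection is reproduced", {
  universe <- reference_panel_alleles
  fc <- cluster_set(list(c("DQB1*0302", "DQB1*0401"),
                         c("DQB1*0201", "DQB1*0501")), universe)
  mc <- cluster_set(list(c("DQB1*0301", "DQB1*0302", "DQB1*0401"),
                         c("DQB1*0201", "DQB1*0501", "DQB1*0602")), universe)
  cr <- consensus(fc, mc)
  has <- function(x) any(vapply(cr$consensus_clusters, identical, TRUE, x))
  expect_true(has(c("DQB1*0302", "DQB1*0401")))
  expect_true(has(c("DQB1*0201", "DQB1*0501")))
  expect_length(cr$consensus_clusters, 2L)
})

test_that("promiscuity classifies minimal cases by definition", {
  bits <- matrix(c(1, 1,
                   0, 0), 2, 2, byrow = FALSE,
                 dimnames = list(c("DRB1*0101", "DQB1*0201"),
                                 c("p1", "p2")))
  bits[, 2] <- 0
  bin <- make_bin(bits, c("DRB1*0101" = "DR", "DQB1*0201" = "DQ"))
  pr <- promiscuity(bin)
  expect_equal(pr$cross_locus_count, 1L)       # p1 binds one allele per locus
  expect_equal(pr$locus_exclusive_count, 0L)
  expect_equal(pr$n_peptides_binding_any, 1L)  # p2 has no events: neither class
  expect_equal(pr$cross_locus_percent + pr$locus_exclusive_percent, 100)
})

test_that("promiscuity matches the exhaustive per-peptide locus scan", {
  for (seed in 1:25) {
    fx <- random_bin_fixture(seed)
    pr <- promiscuity(fx$bin)
    orc <- oracle_promiscuity(fx$bits, fx$locus)
    expect_equal(pr$n_peptides_binding_any, orc$any)
    expect_equal(pr$cross_locus_count, orc$cross)
    expect_equal(pr$locus_exclusive_count, orc$excl)
    loci <- names(pr$locus_density_percent)
    n_alleles <- table(fx$locus)[loci]
    expect_equal(unname(pr$locus_density_percent),
                 unname(100 * orc$excl_events_by_locus[loci] /
                          (as.numeric(n_alleles) * ncol(fx$bits))))
  }
})

test_that("both density denominators are available", {
  fx <- random_bin_fixture(99)
  pr1 <- promiscuity(fx$bin, "all_peptides")
  pr2 <- promiscuity(fx$bin, "exclusive_peptides")
  orc <- oracle_promiscuity(fx$bits, fx$locus)
  loci <- names(pr2$locus_density_percent)
  n_alleles <- table(fx$locus)[loci]
  expect_equal(unname(pr2$locus_density_percent),
               unname(100 * orc$excl_events_by_locus[loci] /
                        (as.numeric(n_alleles) * max(orc$excl, 1))))
  expect_false(identical(pr1$locus_density_percent,
                         pr2$locus_density_percent))
})

test_that("a zero-event matrix reports undefined percentages, not an error", {
  bits <- matrix(0L, 2, 3, dimnames = list(c("DRB1*0101", "DQB1*0201"),
                                           c("p1", "p2", "p3")))
  bin <- make_bin(bits, c("DRB1*0101" = "DR", "DQB1*0201" = "DQ"))
  pr <- promiscuity(bin)
  expect_true(pr$undefined)
  expect_equal(pr$cross_locus_count, 0L)
  expect_true(is.na(pr$cross_locus_percent))
})

test_that("promiscuous and locus-pure generator presets separate as expected", {
  pr_p <- promiscuity(binarize_by_threshold(
    simulate_affinity(sim_config(seed = 5))$affinity, 500))
  expect_gt(pr_p$cross_locus_percent, pr_p$locus_exclusive_percent)
  pr_l <- promiscuity(binarize_by_threshold(
    simulate_affinity(sim_config(seed = 5,
                                 promiscuity_mode = "locus_pure"))$affinity,
    500))
  expect_lt(pr_l$cross_locus_percent, pr_l$locus_exclusive_percent)
})

test_that("heat-map exports are consistent with the promiscuity report", {
  fx <- random_bin_fixture(7)
  tf <- tempfile(fileext = ".tsv")
  full <- heatmap_export(fx$bin, tf)
  expect_equal(unname(as.matrix(read.delim(tf, row.names = 1,
                                           check.names = FALSE))),
               unname(full))
  tfe <- tempfile(fileext = ".tsv")
  excl <- heatmap_export(fx$bin, tfe, exclusive_only = TRUE)
  pr <- promiscuity(fx$bin)
  orc <- oracle_promiscuity(fx$bits, fx$locus)
  expect_equal(sum(excl), sum(orc$excl_events_by_locus))
  # all-zero matrix still yields a valid file and (optionally) a plot
  zb <- make_bin(matrix(0L, 2, 2,
                        dimnames = list(c("DRB1*0101", "DQB1*0201"),
                                        c("p1", "p2"))),
                 c("DRB1*0101" = "DR", "DQB1*0201" = "DQ"))
  tf0 <- tempfile(fileext = ".tsv"); png0 <- tempfile(fileext = ".png")
  z <- heatmap_export(zb, tf0, file_plot = png0)
  expect_true(file.exists(tf0) && file.exists(png0))
  expect_equal(sum(z), 0)
  # dendrogram ordering permutes rows accordingly
  ad <- msboot_cluster(fx$bin, "jaccard", nboot = 20, seed = 2,
                       scales = c(0.8, 1, 1.2))
  tfo <- tempfile(fileext = ".tsv")
  ordd <- heatmap_export(fx$bin, tfo, ordering = ad)
  expect_equal(rownames(ordd), ad$hclust$labels[ad$hclust$order])
  expect_equal(ordd[rownames(fx$bits), ], fx$bin$bits)
})
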