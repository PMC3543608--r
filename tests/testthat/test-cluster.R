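test_that("jaccard and euclidean distances match hand-computed values", {
  bits <- rbind(u = c(1, 1, 0), v = c(1, 0, 1), w = c(1, 1, 0),
                z = c(0, 0, 0), z2 = c(0, 0, 0))
  colnames(bits) <- paste0("p", 1:3)
  D <- pairwise_distance(bits, "jaccard")
  expect_equal(D["u", "v"], 2 / 3)
  expect_equal(D["u", "w"], 0)
  expect_equal(D["z", "z2"], 0)      # all-zero convention: identical
  expect_equal(D["z", "u"], 1)
  expect_equal(unname(diag(D)), rep(0, 5))
  expect_equal(D, t(D))
  X <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(pairwise_distance(X, "euclidean")["a", "b"], 5)
  expect_error(pairwise_distance(X, "jaccard"), "binary")
})

test_that("agglomeration is forced by a closest pair and makes n-1 merges", {
  D <- matrix(c(0, 1, 9, 9,
                1, 0, 9, 9,
                9, 9, 0, 5,
                9, 9, 5, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  hc <- hierarchical_cluster(D)
  keys <- clade_keys_of(hc)
  expect_equal(keys[1], "a;b")
  expect_equal(length(keys), 3L)
  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("agglomeration equals the naive set-distance oracle on small instances", {
  set.seed(41)
  for (linkage in c("average", "complete", "single")) {
    for (rep in 1:12) {
      n <- sample(4:6, 1)
      M <- matrix(runif(n * n, 0.1, 2), n, n)
      D <- (M + t(M)) / 2; diag(D) <- 0
      dimnames(D) <- list(sample(LETTERS, n), NULL)
      colnames(D) <- rownames(D)
      hc <- hierarchical_cluster(D, linkage)
      orc <- oracle_agglomerate(D, linkage)
      expect_equal(clade_keys_of(hc), orc$keys)
      expect_equal(hc$height, orc$heights)
    }
  }
})

test_that("all-equal distances give a deterministic tie-broken tree", {
  D <- matrix(1, 5, 5); diag(D) <- 0
  dimnames(D) <- list(c("e", "c", "a", "d", "b"), c("e", "c", "a", "d", "b"))
  hc1 <- hierarchical_cluster(D)
  hc2 <- hierarchical_cluster(D[sample(5), sample(5)] * 0 + D)  # same input
  expect_equal(clade_keys_of(hc1), clade_keys_of(hc2))
  expect_equal(clade_keys_of(hc1), oracle_agglomerate(D)$keys)
  expect_equal(clade_keys_of(hc1)[1], "a;b")  # sorted-id tie-break
})

test_that("flat bootstrap proportions of one half give AU exactly one half", {
  scales <- seq(0.5, 1.4, by = 0.1)
  fit <- estimate_au(rep(0.5, 10), scales, 1000)
  expect_equal(fit$au, 0.5)
  expect_equal(fit$v, 0, tolerance = 1e-12)
  expect_equal(fit$c, 0, tolerance = 1e-12)
})

test_that("the signed-distance/curvature model is recovered from exact proportions", {
  scales <- seq(0.5, 1.4, by = 0.1)
  v <- 1; cc <- 0.2
  bp <- 1 - pnorm(v * sqrt(scales) + cc / sqrt(scales))
  fit <- estimate_au(bp, scales, 1000)
  expect_equal(fit$v, v, tolerance = 1e-9)
  expect_equal(fit$c, cc, tolerance = 1e-9)
  expect_equal(fit$au, 1 - pnorm(0.8), tolerance = 1e-9)
  # zero curvature: AU equals the model BP at scale 1
  bp0 <- 1 - pnorm(0.7 * sqrt(scales))
  fit0 <- estimate_au(bp0, scales, 1000)
  expect_equal(fit0$au, fit0$bp, tolerance = 1e-9)
})

test_that("degenerate all-0/1 proportions clamp with a flag instead of failing", {
  scales <- seq(0.5, 1.4, by = 0.1)
  hi <- estimate_au(rep(1, 10), scales, 100)
  lo <- estimate_au(rep(0, 10), scales, 100)
  expect_true(hi$flagged); expect_true(lo$flagged)
  expect_equal(hi$au, 1); expect_equal(lo$au, 0)
  expect_true(is.na(hi$se_au))
})

test_that("multiscale bootstrap supports planted blocks and is reproducible", {
  set.seed(50)
  proto <- rbind(matrix(rep(c(1, 0), c(30, 30)), 4, 60, byrow = TRUE),
                 matrix(rep(c(0, 1), c(30, 30)), 4, 60, byrow = TRUE))
  bits <- abs(proto - (matrix(runif(8 * 60), 8, 60) < 0.03))
  dimnames(bits) <- list(sprintf("A%02d", 1:8), sprintf("p%02d", 1:60))
  mb1 <- multiscale_bootstrap(bits, "jaccard", nboot = 200, seed = 99)
  block_edges <- which(vapply(strsplit(mb1$keys, ","), length, 0L) == 4)
  expect_true(all(mb1$bp_by_scale[block_edges, "r1.00"] >= 0.9))
  mb2 <- multiscale_bootstrap(bits, "jaccard", nboot = 200, seed = 99)
  expect_identical(mb1$bp_by_scale, mb2$bp_by_scale)
  expect_error(multiscale_bootstrap(bits, "jaccard", nboot = 0), "nboot")
  expect_error(multiscale_bootstrap(bits, "jaccard", scales = numeric(0)),
               "scales")
})

test_that("standard error of AU does not grow when B doubles", {
  set.seed(51)
  X <- simulate_null(12, 40, seed = 3)
  ad1 <- msboot_cluster(X, "euclidean", nboot = 100, seed = 7)
  ad2 <- msboot_cluster(X, "euclidean", nboot = 200, seed = 7)
  m1 <- median(ad1$edges$se_au, na.rm = TRUE)
  m2 <- median(ad2$edges$se_au, na.rm = TRUE)
  expect_lte(m2, m1 * 1.15)
})

test_that("cluster extraction honours the iterated AU cutoff schedule", {
  ad <- make_annotated(6, seed = 9)
  n_edges <- nrow(ad$edges)
  # single significant non-root edge -> one cluster at the first iteration
  ad$edges$au <- rep(0.5, n_edges)
  ad$edges$au[1] <- 0.99
  cs <- extract_clusters(ad)
  expect_length(cs$clusters, 1L)
  expect_equal(sort(cs$clusters[[1]]), sort(edge_members(ad, 1)))
  expect_equal(cs$alpha_trace[1], 0.95)
  # nested significant edges: only the maximal one is accepted
  ad$edges$au <- rep(0, n_edges)
  parent <- which(ad$edges$size > 2 & ad$edges$size < 6)[1]
  child <- which(vapply(seq_len(n_edges), function(i)
    all(edge_members(ad, i) %in% edge_members(ad, parent)) &&
      ad$edges$size[i] < ad$edges$size[parent], TRUE))[1]
  ad$edges$au[c(parent, child)] <- 0.99
  cs <- extract_clusters(ad)
  expect_length(cs$clusters, 1L)
  expect_equal(sort(cs$clusters[[1]]), sort(edge_members(ad, parent)))
  # all-zero AU -> empty cluster set; bad step errors
  ad$edges$au <- rep(0, n_edges)
  expect_length(extract_clusters(ad)$clusters, 0L)
  expect_error(extract_clusters(ad, alpha_step = 0), "alpha_step")
  # the root is never a cluster even at AU 1
  ad$edges$au <- rep(1, n_edges)
  cs <- extract_clusters(ad)
  expect_true(all(lengths(cs$clusters) < 6))
})
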