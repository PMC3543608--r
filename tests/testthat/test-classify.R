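sep_data <- function(n_per_class = 40, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * 2, 0, 0.5), ncol = 2),
             matrix(rnorm(n_per_class * 2, 4, 0.5), ncol = 2))
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

test_that("PPA is proportional to per-peptide event counts", {
  bits <- matrix(0L, 3, 3, dimnames = list(
    c("DRB1*0101", "DQB1*0201", "DPB1*0101"), c("a", "b", "c")))
  bits[, 1] <- c(1L, 1L, 1L); bits[1, 2] <- 1L
  # counts 3, 1, 0 -> ppa 100, 100/3, 0
  ppa <- compute_ppa(make_bin(bits, infer_locus(rownames(bits))))
  expect_equal(ppa$ppa, c(100, 100 / 3, 0))
  expect_equal(max(ppa$ppa), 100)
  one <- compute_ppa(make_bin(bits[, 1, drop = FALSE],
                              infer_locus(rownames(bits))))
  expect_equal(one$ppa, 100)
})

test_that("PPA equals the brute-force column-sum ratio on random fixtures", {
  for (seed in 1:10) {
    fx <- random_bin_fixture(seed)
    if (sum(fx$bits) == 0) next
    ppa <- compute_ppa(fx$bin)
    counts <- apply(fx$bits, 2, sum)
    expect_equal(ppa$event_counts, unname(counts))
    expect_equal(ppa$ppa, unname(100 * counts / max(counts)))
  }
  zb <- make_bin(matrix(0L, 2, 2, dimnames = list(
    c("DRB1*0101", "DQB1*0201"), c("p1", "p2"))),
    c("DRB1*0101" = "DR", "DQB1*0201" = "DQ"))
  expect_error(compute_ppa(zb), "no binding events")
})

test_that("activity labels use a strict threshold and are monotone in it", {
  fx <- random_bin_fixture(3, n_alleles = 10, n_peptides = 50)
  ppa <- compute_ppa(fx$bin)
  # boundary: a peptide exactly at the threshold is inactive
  thr <- ppa$ppa[which(ppa$ppa > 0 & ppa$ppa < 100)[1]]
  lab <- assign_activity(ppa, thr)
  expect_equal(lab$activity[match(thr, ppa$ppa)], 0L)
  # threshold 0 labels every peptide with >= 1 event positive
  lab0 <- assign_activity(ppa, 0)
  expect_equal(lab0$stats$n_pos, sum(ppa$event_counts >= 1))
  # monotonicity of the positive count across rising thresholds
  npos <- sapply(c(10, 20, 30, 40, 50), function(t)
    assign_activity(ppa, t)$stats$n_pos)
  expect_true(all(diff(npos) <= 0))
  expect_equal(lab0$stats$n_pos + lab0$stats$n_neg, length(ppa$peptide_ids))
  expect_error(assign_activity(ppa, 100), "threshold")
})

test_that("subsampling splits honour the 4:1 per-class ratio and the seed", {
  y <- rep(c(0L, 1L), each = 100)
  sp <- subsample_splits(y, n_splits = 3, seed = 11)
  for (s in sp) {
    expect_length(s$test, 40L)   # 20 per class
    expect_length(s$train, 160L)
    expect_equal(sort(c(s$train, s$test)), seq_along(y))
    expect_length(intersect(s$train, s$test), 0L)
    expect_equal(sum(y[s$test]), 20L)
  }
  expect_false(identical(sp[[1]]$test, sp[[2]]$test))
  sp2 <- subsample_splits(y, n_splits = 3, seed = 11)
  expect_identical(sp, sp2)
  expect_error(subsample_splits(rep(c(0L, 1L), c(4, 50))), "at least 5")
  expect_error(subsample_splits(rep(0L, 10)), "both classes")
})

test_that("confusion-matrix algebra matches hand-computed values", {
  m <- confusion_metrics(tp = 8, fn = 2, tn = 7, fp = 3)
  expect_equal(m$precision, 8 / 11)
  expect_equal(m$recall, 0.8)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$f_measure,
               2 * m$precision * m$recall / (m$precision + m$recall))
  expect_true(is.na(confusion_metrics(0, 0, 5, 5)$precision))
})

test_that("every algorithm separates well-separated classes", {
  d <- sep_data(40, seed = 2)
  sp <- subsample_splits(d$y, n_splits = 2, seed = 3)
  for (alg in c("svm_rbf", "random_forest", "naive_bayes", "ann", "knn")) {
    rep_ <- evaluate(d$x, d$y, sp, alg, seed = 4)
    expect_gte(rep_$average[["accuracy"]], 0.95)
    expect_gte(rep_$average[["auc"]], 0.95)
    expect_equal(rep_$average[["f_measure"]],
                 mean(sapply(seq_len(nrow(rep_$per_split)), function(i) {
                   p <- rep_$per_split$precision[i]
                   r <- rep_$per_split$recall[i]
                   2 * p * r / (p + r)
                 })))
  }
  expect_error(evaluate(d$x, d$y, sp, "boosted_stump"), "unknown algorithm")
})

test_that("SVM defaults carry the radial kernel parameters", {
  d <- sep_data(30, seed = 5)
  sp <- subsample_splits(d$y, n_splits = 1, seed = 5)
  rep_ <- evaluate(d$x, d$y, sp, "svm_rbf")
  expect_equal(rep_$params$gamma, 0.5)
  expect_equal(rep_$params$cost, 2.0)
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(6)
  x <- matrix(rnorm(240 * 4), ncol = 4)
  y <- rep(c(0L, 1L), each = 120)[sample(240)]
  sp <- subsample_splits(y, n_splits = 3, seed = 7)
  rep_ <- evaluate(x, y, sp, "svm_rbf", seed = 8)
  expect_lt(abs(rep_$average[["auc"]] - 0.5), 0.1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  y <- rep(c(0, 1), each = 30)
  s <- rnorm(60) + y
  a1 <- hlaSupertype:::auc_score(y, s)
  expect_equal(hlaSupertype:::auc_score(y, exp(s)), a1)
  expect_equal(hlaSupertype:::auc_score(y, rank(s)), a1)
})

test_that("LOOCV equals the naive leave-one-out loop and conserves counts", {
  d <- sep_data(10, seed = 10)  # n = 20
  set.seed(11)
  flip <- sample(20, 4)
  d$y[flip] <- 1L - d$y[flip]   # some class overlap so errors occur
  for (alg in c("naive_bayes", "knn")) {
    lo <- loocv_evaluate(d$x, d$y, alg, seed = 30)
    naive_splits <- lapply(seq_len(20), function(i)
      list(train = setdiff(seq_len(20), i), test = i))
    nv <- evaluate(d$x, d$y, naive_splits, alg, seed = 30)
    pooled <- colSums(nv$per_split[, c("tp", "fp", "tn", "fn")])
    expect_equal(unlist(lo$per_split[1, c("tp", "fp", "tn", "fn")]),
                 pooled)
    expect_equal(sum(pooled), 20)
  }
  tiny <- loocv_evaluate(sep_data(2, seed = 12)$x,
                         rep(c(0L, 1L), each = 2), "knn",
                         params = list(k = 1))
  expect_equal(tiny$average[["accuracy"]], 1.0)
  expect_error(loocv_evaluate(d$x[1:2, ], d$y[1:2], "knn"), "at least 3")
})
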