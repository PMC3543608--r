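as_item_matrix <- function(x) {
  if (inherits(x, "binary_binding_matrix")) return(x$bits)
  if (inherits(x, "affinity_matrix")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("expected a matrix, binary_binding_matrix or feature_matrix")
}

#' Pairwise distances between items (matrix rows)
#'
#' Jaccard binary distance `1 - |u AND v| / |u OR v|` for binary binding
#' profiles, or Euclidean distance for numeric descriptor vectors. Two
#' all-zero binary rows have an empty union and are defined to be at
#' distance 0 (identical profiles).
#'
#' @param x a `binary_binding_matrix`, `feature_matrix`, or plain matrix
#'   with items as rows.
#' @param metric `"jaccard"` (binary rows only) or `"euclidean"`.
#' @return symmetric numeric distance matrix with zero diagonal and item
#'   dimnames.
#' @export
pairwise_distance <- function(x, metric = c("jaccard", "euclidean")) {
  metric <- match.arg(metric)
  X <- as_item_matrix(x)
  if (metric == "jaccard") {
    if (!all(X %in% c(0, 1)))
      stop("jaccard distance requires a binary matrix")
    storage.mode(X) <- "double"
    A <- tcrossprod(X)
    s <- rowSums(X)
    U <- outer(s, s, "+") - A
    D <- 1 - A / U
    D[U == 0] <- 0
    diag(D) <- 0
  } else {
    D <- as.matrix(stats::dist(X, method = "euclidean"))
  }
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Deterministic agglomerative hierarchical clustering
#'
#' Standard Lance-Williams agglomeration (average, complete, single, or
#' Ward) with an explicit tie-break so results are identical across
#' platforms: items are first sorted by id; active clusters are ordered by
#' creation time (sorted singletons, then merged clusters in merge order);
#' at each step the candidate pair with minimal distance is merged, ties
#' broken by smallest (row, column) position in that ordering. Ward uses
#' the squared-distance (Ward.D2) update.
#'
#' @param d symmetric distance matrix (or `dist`) with item labels.
#' @param linkage one of `"average"` (default), `"complete"`, `"single"`,
#'   `"ward"`.
#' @return an object of class `hclust` (usable with [stats::cutree()],
#'   [ape::as.phylo()] etc.).
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete",
                                                "single", "ward")) {
  linkage <- match.arg(linkage)
  D <- if (inherits(d, "dist")) as.matrix(d) else d
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("'d' must be a square distance matrix")
  if (max(abs(D - t(D))) > 1e-8) stop("'d' must be symmetric")
  if (any(diag(D) != 0)) stop("'d' must have a zero diagonal")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 2L) stop("need at least two items")
  ord <- order(labels)
  D <- D[ord, ord, drop = FALSE]
  code <- -ord                 # hclust codes, in original input indexing
  size <- rep(1, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    k <- nrow(D)
    M <- D
    M[lower.tri(M, diag = TRUE)] <- Inf
    v <- min(M)
    cand <- which(M == v, arr.ind = TRUE)
    pick <- cand[order(cand[, 1], cand[, 2])[1], ]
    i <- pick[1]; j <- pick[2]
    a <- code[i]; b <- code[j]
    merge[m, ] <- if (a < 0 && b < 0) sort(c(a, b), decreasing = TRUE)
      else sort(c(a, b))
    height[m] <- v
    rest <- setdiff(seq_len(k), c(i, j))
    dn <- switch(linkage,
      average  = (size[i] * D[i, rest] + size[j] * D[j, rest]) /
                 (size[i] + size[j]),
      complete = pmax(D[i, rest], D[j, rest]),
      single   = pmin(D[i, rest], D[j, rest]),
      ward     = sqrt(pmax(0,
                 ((size[i] + size[rest]) * D[i, rest]^2 +
                  (size[j] + size[rest]) * D[j, rest]^2 -
                  size[rest] * D[i, j]^2) /
                 (size[i] + size[j] + size[rest]))))
    newsize <- size[i] + size[j]
    D <- rbind(cbind(D[rest, rest, drop = FALSE], dn),
               c(dn, 0))
    code <- c(code[rest], m)
    size <- c(size[rest], newsize)
  }
  leaf_order <- function(m) {
    if (m < 0) return(-m)
    c(leaf_order(merge[m, 1]), leaf_order(merge[m, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = leaf_order(n - 1L),
                 labels = labels,
                 method = linkage, dist.method = "user"),
            class = "hclust")
}

# leaf-index sets (original row indices) for each merge of an hclust tree
merge_leafsets <- function(merge) {
  n1 <- nrow(merge)
  sets <- vector("list", n1)
  for (m in seq_len(n1)) {
    get1 <- function(x) if (x < 0) -x else sets[[x]]
    sets[[m]] <- sort(c(get1(merge[m, 1]), get1(merge[m, 2])))
  }
  sets
}

merge_keys <- function(merge) {
  vapply(merge_leafsets(merge), paste, "", collapse = ",")
}

#' Multiscale bootstrap of a hierarchical clustering
#'
#' Resamples the feature columns (peptides for binding matrices,
#' descriptor columns for encoded motifs) with replacement at a range of
#' resample-size scales r, rebuilds the tree with the same metric and
#' linkage from each resample, and counts for every internal edge of the
#' observed tree how often its exact leaf set recurs as a clade. Distances
#' are always recomputed from the resampled columns, as the multiscale
#' scheme requires.
#'
#' @param x items-by-features input (`binary_binding_matrix`,
#'   `feature_matrix`, or matrix).
#' @param metric distance metric, see [pairwise_distance()].
#' @param linkage agglomeration rule, see [hierarchical_cluster()].
#' @param scales resample-size ratios r (default `seq(0.5, 1.4, 0.1)`);
#'   scale r draws `round(r * n_features)` columns.
#' @param nboot bootstrap replicates per scale (default 1000).
#' @param seed optional integer seed.
#' @return list with the observed `hclust` tree, per-edge `keys`,
#'   `bp_by_scale` (edges x scales proportions), `counts`, `scales`,
#'   `nboot`.
#' @export
multiscale_bootstrap <- function(x, metric = c("jaccard", "euclidean"),
                                 linkage = "average",
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 nboot = 1000, seed = NULL) {
  metric <- match.arg(metric)
  X <- as_item_matrix(x)
  p <- ncol(X)
  if (p < 2L) stop("need at least two feature columns")
  if (length(scales) == 0L || any(scales <= 0))
    stop("'scales' must be a non-empty vector of positive ratios")
  if (nboot < 1L) stop("'nboot' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- hierarchical_cluster(pairwise_distance(X, metric), linkage)
  keys <- merge_keys(obs$merge)
  counts <- matrix(0L, length(keys), length(scales),
                   dimnames = list(NULL, sprintf("r%.2f", scales)))
  for (s in seq_along(scales)) {
    nr <- max(1L, as.integer(round(scales[s] * p)))
    for (b in seq_len(nboot)) {
      cols <- sample.int(p, nr, replace = TRUE)
      tb <- tryCatch(
        hierarchical_cluster(pairwise_distance(X[, cols, drop = FALSE],
                                               metric), linkage),
        error = function(e) NULL)
      if (is.null(tb)) next
      counts[, s] <- counts[, s] + (keys %in% merge_keys(tb$merge))
    }
  }
  list(hclust = obs, keys = keys, counts = counts,
       bp_by_scale = counts / nboot, scales = scales, nboot = nboot)
}

#' Fit the multiscale-bootstrap model for one edge
#'
#' Given bootstrap proportions BP_r across resample-size scales r, fits
#' `qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)` by weighted least squares
#' (weights from the binomial variance of BP_r via the delta method) and
#' returns the approximately unbiased p-value `AU = 1 - pnorm(v - c)`, the
#' model bootstrap probability at scale 1 `BP = 1 - pnorm(v + c)`, the
#' signed distance `v`, curvature `c`, and the delta-method standard error
#' of AU. Scales with degenerate BP (0 or 1) are excluded from the fit; if
#' fewer than two informative scales remain, AU is clamped to 0 or 1
#' (majority of the degenerate values) and flagged with `se_au = NA`.
#'
#' @param bp numeric vector of bootstrap proportions, one per scale.
#' @param scales resample-size ratios matching `bp`.
#' @param nboot bootstrap replicates behind each proportion (scalar or
#'   per-scale vector).
#' @return list with `au`, `bp`, `v`, `c`, `se_au`, `flagged`.
#' @export
estimate_au <- function(bp, scales, nboot) {
  stopifnot(length(bp) == length(scales))
  nboot <- rep_len(nboot, length(bp))
  use <- bp > 0 & bp < 1
  if (sum(use) < 2L) {
    au <- ifelse(mean(bp) >= 0.5, 1, 0)
    return(list(au = au, bp = au, v = NA_real_, c = NA_real_,
                se_au = NA_real_, flagged = TRUE))
  }
  r <- scales[use]
  z <- stats::qnorm(1 - bp[use])
  w <- nboot[use] * stats::dnorm(z)^2 / (bp[use] * (1 - bp[use]))
  X <- cbind(sqrt(r), 1 / sqrt(r))
  XtW <- t(X * w)
  V <- solve(XtW %*% X)
  coefs <- drop(V %*% (XtW %*% z))
  v <- coefs[1]; cc <- coefs[2]
  au <- 1 - stats::pnorm(v - cc)
  bp1 <- 1 - stats::pnorm(v + cc)
  var_vmc <- V[1, 1] - 2 * V[1, 2] + V[2, 2]
  se_au <- stats::dnorm(v - cc) * sqrt(max(var_vmc, 0))
  list(au = unname(au), bp = unname(bp1), v = unname(v), c = unname(cc),
       se_au = unname(se_au), flagged = FALSE)
}

#' Hierarchical clustering with multiscale-bootstrap AU support values
#'
#' Runs [hierarchical_cluster()], [multiscale_bootstrap()] and
#' [estimate_au()] end to end and returns an annotated dendrogram whose
#' internal edges carry the raw scale-1 bootstrap probability, the fitted
#' AU p-value, the fit parameters (v, c) and the standard error of AU.
#'
#' @inheritParams multiscale_bootstrap
#' @return object of class `annotated_dendrogram`: list with `hclust`,
#'   `leaf_ids`, `edges` (data.frame: edge, key, size, bp_raw, au, bp, v,
#'   c, se_au, flagged), `bp_by_scale`, `scales`, `nboot`, `metric`,
#'   `linkage`.
#' @export
msboot_cluster <- function(x, metric = c("jaccard", "euclidean"),
                           linkage = "average",
                           scales = seq(0.5, 1.4, by = 0.1),
                           nboot = 1000, seed = NULL) {
  metric <- match.arg(metric)
  mb <- multiscale_bootstrap(x, metric, linkage, scales, nboot, seed)
  labels <- mb$hclust$labels
  sets <- merge_leafsets(mb$hclust$merge)
  fits <- apply(mb$bp_by_scale, 1, estimate_au, scales = mb$scales,
                nboot = mb$nboot)
  s1 <- which.min(abs(mb$scales - 1))
  edges <- data.frame(
    edge = seq_along(sets),
    key = vapply(sets, function(s) paste(sort(labels[s]), collapse = ";"), ""),
    size = lengths(sets),
    bp_raw = mb$bp_by_scale[, s1],
    au = vapply(fits, `[[`, 0, "au"),
    bp = vapply(fits, `[[`, 0, "bp"),
    v = vapply(fits, `[[`, 0, "v"),
    c = vapply(fits, `[[`, 0, "c"),
    se_au = vapply(fits, `[[`, 0, "se_au"),
    flagged = vapply(fits, `[[`, TRUE, "flagged"),
    stringsAsFactors = FALSE)
  structure(list(hclust = mb$hclust, leaf_ids = sort(labels),
                 edges = edges, bp_by_scale = mb$bp_by_scale,
                 scales = mb$scales, nboot = mb$nboot, metric = metric,
                 linkage = linkage, seed = seed),
            class = "annotated_dendrogram")
}

#' @export
print.annotated_dendrogram <- function(x, ...) {
  cat(sprintf("annotated_dendrogram: %d leaves, %s/%s, %d scales x %d boots\n",
              length(x$leaf_ids), x$metric, x$linkage, length(x$scales),
              x$nboot))
  n_sig <- sum(x$edges$au >= 0.95 & x$edges$edge < nrow(x$edges))
  cat(sprintf("  %d non-root edges with AU >= 0.95; max se_au %.4f\n",
              n_sig, max(x$edges$se_au, na.rm = TRUE)))
  invisible(x)
}

#' Members of one edge (clade) of an annotated dendrogram
#'
#' @param tree an `annotated_dendrogram`.
#' @param edge edge (merge) number.
#' @return character vector of leaf ids.
#' @export
edge_members <- function(tree, edge) {
  strsplit(tree$edges$key[edge], ";", fixed = TRUE)[[1]]
}

#' Extract significant clusters by iteratively relaxed AU cutoff
#'
#' Starting from `alpha_start`, the AU cutoff is lowered by `alpha_step`
#' per iteration. At each iteration the maximal edges (not nested in
#' another candidate and not inside an already accepted cluster) with
#' `AU >= alpha` and at least `min_size` leaves are accepted. The root
#' (the full leaf set) is never a cluster. Leaves not covered when the
#' iterations end remain unclustered.
#'
#' @param tree an `annotated_dendrogram`.
#' @param alpha_start initial AU cutoff (default 0.95).
#' @param alpha_step decrement per iteration (default 0.1); must be > 0.
#' @param min_size minimal cluster size (default 2).
#' @param max_iters number of iterations (default 5).
#' @return object of class `cluster_set`: list with `clusters` (list of
#'   leaf-id vectors), `au_of` (AU at extraction), `alpha_trace`,
#'   `universe`.
#' @export
extract_clusters <- function(tree, alpha_start = 0.95, alpha_step = 0.1,
                             min_size = 2L, max_iters = 5L) {
  stopifnot(inherits(tree, "annotated_dendrogram"))
  if (alpha_step <= 0) stop("'alpha_step' must be positive")
  ed <- tree$edges
  n <- length(tree$leaf_ids)
  sets <- lapply(ed$key, function(k) strsplit(k, ";", fixed = TRUE)[[1]])
  accepted <- list(); acc_au <- numeric(0)
  alphas <- numeric(0)
  covered <- character(0)
  for (it in seq_len(max_iters)) {
    a <- alpha_start - (it - 1) * alpha_step
    if (a <= 0) break
    alphas <- c(alphas, a)
    cand <- which(ed$au >= a & ed$size >= min_size & ed$size < n)
    cand <- cand[!vapply(cand, function(i)
      any(vapply(accepted, function(s) all(sets[[i]] %in% s), TRUE)), TRUE)]
    if (length(cand) > 0L) {
      maximal <- cand[!vapply(cand, function(i)
        any(vapply(cand, function(j)
          j != i && length(sets[[j]]) > length(sets[[i]]) &&
            all(sets[[i]] %in% sets[[j]]), TRUE)), TRUE)]
      for (i in maximal[order(-ed$size[maximal], ed$key[maximal])]) {
        if (!any(vapply(accepted, function(s) all(sets[[i]] %in% s), TRUE))) {
          accepted <- c(accepted, list(sets[[i]]))
          acc_au <- c(acc_au, ed$au[i])
        }
      }
      covered <- unique(unlist(accepted))
      if (length(covered) == n) break
    }
  }
  structure(list(clusters = accepted, au_of = acc_au, alpha_trace = alphas,
                 universe = tree$leaf_ids),
            class = "cluster_set")
}

#' Build a cluster set directly from known groups
#'
#' Convenience constructor used for consensus computations with externally
#' defined clusters.
#'
#' @param clusters list of character vectors of member ids.
#' @param universe all item ids (default: union of members).
#' @return a `cluster_set`.
#' @export
cluster_set <- function(clusters, universe = sort(unique(unlist(clusters)))) {
  stopifnot(is.list(clusters))
  if (any(lengths(clusters) < 1L)) stop("empty cluster")
  structure(list(clusters = lapply(clusters, sort),
                 au_of = rep(NA_real_, length(clusters)),
                 alpha_trace = numeric(0), universe = sort(universe)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d items\n",
              length(x$clusters), length(x$universe)))
  for (i in seq_along(x$clusters))
    cat(sprintf("  [%d]%s %s\n", i,
                if (is.na(x$au_of[i])) "" else sprintf(" AU=%.3f", x$au_of[i]),
                paste(x$clusters[[i]], collapse = ", ")))
  invisible(x)
}

#' Partition labels induced by a cluster set
#'
#' Cluster members get the cluster number; unclustered items get unique
#' singleton labels. Useful for comparing a recovered clustering with a
#' planted partition (e.g. adjusted Rand index).
#'
#' @param cs a `cluster_set`.
#' @param ids item ids to label (default: the cluster set's universe).
#' @return named integer vector of partition labels.
#' @export
cluster_partition <- function(cs, ids = cs$universe) {
  lab <- rep(NA_integer_, length(ids))
  names(lab) <- ids
  for (i in seq_along(cs$clusters)) lab[cs$clusters[[i]]] <- i
  nxt <- length(cs$clusters)
  for (j in which(is.na(lab))) { nxt <- nxt + 1L; lab[j] <- nxt }
  lab
}
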