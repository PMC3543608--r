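#' Configuration for the synthetic HLA II binding panel
#'
#' Describes a 27-allele, three-locus panel modelled on the classic
#' classic 27-allele HLA class II binding panel design: 15 DR, 6 DQ and 6 DP
#' beta-chain alleles measured against 636 peptides. Binder structure is
#' planted as cluster-level binder-prototype sets; every allele of a
#' cluster binds each prototype peptide with probability `retention` and
#' any other (reachable) peptide with probability `background`, and IC50
#' values are drawn log-normally around 50 nM for binders and 5000 nM for
#' non-binders, straddling the 500 nM cutoff symmetrically in log space.
#'
#' @param n_alleles_per_locus named integer vector (default
#'   `c(DR = 15, DQ = 6, DP = 6)`).
#' @param n_peptides number of peptides (default 636).
#' @param planted_clusters optional named list of allele-id vectors
#'   partitioning the panel; default: one cluster per locus.
#' @param binder_rate per-peptide probability of membership in a cluster
#'   prototype binder set (default 0.25).
#' @param retention probability that a cluster member binds a prototype
#'   peptide (default 0.7).
#' @param background per-locus (or scalar) probability of binding a
#'   non-prototype peptide (default 0.08); with the defaults the
#'   per-allele binder fraction is about 0.2.
#' @param ic50_noise log-scale standard deviation of the IC50 draw
#'   (default 0.8); 0 gives the exact 50/5000 nM centres.
#' @param promiscuity_mode `"promiscuous"` (prototypes drawn over the
#'   whole peptide panel, so loci share binders) or `"locus_pure"`
#'   (peptide panel partitioned among loci; no cross-locus binding).
#' @param motif_mutation_rate per-position substitution probability for
#'   [simulate_motifs()] (default 0.05).
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_alleles_per_locus = c(DR = 15L, DQ = 6L, DP = 6L),
                       n_peptides = 636L,
                       planted_clusters = NULL,
                       binder_rate = 0.25,
                       retention = 0.7,
                       background = 0.08,
                       ic50_noise = 0.8,
                       promiscuity_mode = c("promiscuous", "locus_pure"),
                       motif_mutation_rate = 0.05,
                       seed = 1L) {
  promiscuity_mode <- match.arg(promiscuity_mode)
  stopifnot(all(n_alleles_per_locus >= 1L), n_peptides >= 1L,
            binder_rate > 0, binder_rate <= 1,
            retention >= 0, retention <= 1,
            all(background >= 0), all(background <= 1),
            ic50_noise >= 0,
            motif_mutation_rate >= 0, motif_mutation_rate <= 1)
  loci <- names(n_alleles_per_locus)
  prefix <- c(DR = "DRB1*", DQ = "DQB1*", DP = "DPB1*")[loci]
  alleles <- unlist(lapply(seq_along(loci), function(i)
    sprintf("%s%02d01", prefix[i], seq_len(n_alleles_per_locus[i]))),
    use.names = FALSE)
  locus_of <- stats::setNames(rep(loci, n_alleles_per_locus), alleles)
  if (is.null(planted_clusters)) {
    planted_clusters <- split(alleles, locus_of)[loci]
  }
  all_members <- unlist(planted_clusters, use.names = FALSE)
  if (anyDuplicated(all_members) || !setequal(all_members, alleles))
    stop("'planted_clusters' must partition the allele panel")
  if (is.null(names(planted_clusters)))
    names(planted_clusters) <- sprintf("C%02d", seq_along(planted_clusters))
  bg <- if (length(background) == 1L)
    stats::setNames(rep(background, length(loci)), loci)
  else background[loci]
  structure(list(n_alleles_per_locus = n_alleles_per_locus,
                 n_peptides = as.integer(n_peptides),
                 alleles = alleles, locus_of = locus_of,
                 planted_clusters = planted_clusters,
                 binder_rate = binder_rate, retention = retention,
                 background = bg, ic50_noise = ic50_noise,
                 promiscuity_mode = promiscuity_mode,
                 motif_mutation_rate = motif_mutation_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an IC50 affinity panel with planted cluster structure
#'
#' Draws a binder bit for every allele x peptide cell from the planted
#' cluster prototypes (see [sim_config()]) and converts bits to IC50
#' values: binders log-normal around 50 nM, non-binders around 5000 nM,
#' log-sd `ic50_noise`. In `locus_pure` mode the peptide panel is split
#' into equal locus-specific segments and alleles can only bind peptides
#' of their own locus segment. Fully seeded and reproducible.
#'
#' @param config a `sim_config`.
#' @return list with `affinity` (an [affinity_matrix]), `truth` (list:
#'   `cluster_of` named cluster labels, `binder_matrix` the realized 0/1
#'   ground truth, `prototypes` cluster x peptide 0/1 matrix), and
#'   `config`.
#' @export
simulate_affinity <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  alleles <- config$alleles
  peptides <- sprintf("pep%04d", seq_len(config$n_peptides))
  loci <- names(config$n_alleles_per_locus)
  seg_of <- if (config$promiscuity_mode == "locus_pure") {
    sizes <- diff(floor(seq(0, config$n_peptides,
                            length.out = length(loci) + 1L)))
    stats::setNames(rep(loci, times = sizes), peptides)
  } else NULL
  clusters <- config$planted_clusters
  cluster_of <- stats::setNames(
    rep(names(clusters), lengths(clusters)), unlist(clusters))[alleles]
  proto <- matrix(0L, length(clusters), config$n_peptides,
                  dimnames = list(names(clusters), peptides))
  for (ci in seq_along(clusters)) {
    reach <- if (is.null(seg_of)) rep(TRUE, config$n_peptides)
    else seg_of == config$locus_of[clusters[[ci]][1]]
    proto[ci, reach] <- stats::rbinom(sum(reach), 1L, config$binder_rate)
  }
  bits <- matrix(0L, length(alleles), config$n_peptides,
                 dimnames = list(alleles, peptides))
  for (a in seq_along(alleles)) {
    pr <- proto[cluster_of[a], ]
    bg <- config$background[config$locus_of[a]]
    prob <- ifelse(pr == 1L, config$retention, bg)
    if (!is.null(seg_of))
      prob[seg_of != config$locus_of[a]] <- 0
    bits[a, ] <- stats::rbinom(config$n_peptides, 1L, prob)
  }
  centre <- ifelse(bits == 1L, log(50), log(5000))
  ic50 <- exp(centre + config$ic50_noise *
                matrix(stats::rnorm(length(bits)), nrow(bits), ncol(bits)))
  dimnames(ic50) <- dimnames(bits)
  list(affinity = affinity_matrix(ic50, locus = config$locus_of),
       truth = list(cluster_of = cluster_of, binder_matrix = bits,
                    prototypes = proto,
                    peptide_segment = seg_of),
       config = config)
}

#' Simulate 15-residue binding motifs with planted cluster structure
#'
#' Draws one random 15-mer prototype per planted cluster and derives each
#' allele's motif from its cluster prototype by independent per-position
#' substitution with probability `motif_mutation_rate`.
#'
#' @param config a `sim_config`.
#' @return list with `motifs` (named character vector of 15-mers),
#'   `truth` (`cluster_of`, `prototypes`), and `config`.
#' @export
simulate_motifs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  L <- 15L
  clusters <- config$planted_clusters
  proto <- vapply(seq_along(clusters), function(i)
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""), "")
  names(proto) <- names(clusters)
  cluster_of <- stats::setNames(
    rep(names(clusters), lengths(clusters)), unlist(clusters))[config$alleles]
  motifs <- vapply(config$alleles, function(a) {
    s <- strsplit(proto[cluster_of[a]], "")[[1]]
    mut <- stats::runif(L) < config$motif_mutation_rate
    if (any(mut))
      s[mut] <- vapply(s[mut], function(orig)
        sample(setdiff(AA_ALPHABET, orig), 1L), "")
    paste(s, collapse = "")
  }, "")
  list(motifs = motifs,
       truth = list(cluster_of = cluster_of, prototypes = proto),
       config = config)
}

#' Simulate an exchangeable null feature matrix
#'
#' Independent standard-normal entries: no cluster structure, items
#' exchangeable. Used to calibrate AU p-values.
#'
#' @param n_items,n_features positive dimensions.
#' @param seed integer seed.
#' @return numeric matrix with item rownames and feature colnames.
#' @export
simulate_null <- function(n_items, n_features, seed = 1L) {
  stopifnot(n_items >= 1L, n_features >= 1L)
  set.seed(seed)
  matrix(stats::rnorm(n_items * n_features), n_items, n_features,
         dimnames = list(sprintf("item%03d", seq_len(n_items)),
                         sprintf("f%05d", seq_len(n_features))))
}
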