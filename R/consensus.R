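#' Consensus (stable) clusters between two supertype classifications
#'
#' Intersects every cluster of the functional classification with every
#' cluster of the motif classification and keeps the intersections with at
#' least `min_size` alleles: these are the stable clusters on which the
#' two views agree. The operation is symmetric in its arguments.
#'
#' @param func_clusters,motif_clusters `cluster_set` objects over the same
#'   allele universe.
#' @param min_size minimal size of a reported intersection (default 2).
#' @return object of class `consensus_result`: list with `stable_pairs`
#'   (data.frame: functional cluster index, motif cluster index, members
#'   as `;`-joined string, size) and `consensus_clusters` (deduplicated
#'   list of member vectors).
#' @export
consensus <- function(func_clusters, motif_clusters, min_size = 2L) {
  stopifnot(inherits(func_clusters, "cluster_set"),
            inherits(motif_clusters, "cluster_set"))
  if (length(intersect(func_clusters$universe, motif_clusters$universe)) == 0L)
    stop("the two cluster sets share no alleles")
  pairs <- list()
  for (i in seq_along(func_clusters$clusters)) {
    for (j in seq_along(motif_clusters$clusters)) {
      ix <- sort(intersect(func_clusters$clusters[[i]],
                           motif_clusters$clusters[[j]]))
      if (length(ix) >= min_size)
        pairs[[length(pairs) + 1L]] <-
          list(functional = i, motif = j, members = ix)
    }
  }
  members <- lapply(pairs, `[[`, "members")
  keys <- vapply(members, paste, "", collapse = ";")
  stable_pairs <- data.frame(
    functional = vapply(pairs, `[[`, 0L, "functional"),
    motif = vapply(pairs, `[[`, 0L, "motif"),
    members = keys,
    size = lengths(members),
    stringsAsFactors = FALSE)
  structure(list(stable_pairs = stable_pairs,
                 consensus_clusters = members[!duplicated(keys)]),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d stable cluster(s)\n",
              length(x$consensus_clusters)))
  for (cl in x$consensus_clusters)
    cat("  ", paste(cl, collapse = ", "), "\n")
  invisible(x)
}

#' Peptide binding-promiscuity statistics
#'
#' Classifies every peptide with at least one binding event as
#' cross-locus (events in two or more loci) or locus-exclusive (all
#' events in one locus), and reports per-locus binding-event densities of
#' the locus-exclusive peptides relative to a maximum theoretical binding
#' denominator.
#'
#' @param binary a `binary_binding_matrix`.
#' @param density_denominator how the per-locus density denominator is
#'   formed: `"all_peptides"` (locus alleles x all peptides, default) or
#'   `"exclusive_peptides"` (locus alleles x total locus-exclusive
#'   peptides).
#' @return object of class `promiscuity_report`: counts and percentages
#'   of cross-locus and locus-exclusive peptides (percentages over
#'   peptides with >= 1 event), per-locus exclusive-event densities in
#'   percent, and `freq_by_locus`, the peptides x loci binding-event
#'   count matrix. With zero binding events all counts are 0 and
#'   percentages are `NA` with `undefined = TRUE`.
#' @export
promiscuity <- function(binary,
                        density_denominator = c("all_peptides",
                                                "exclusive_peptides")) {
  stopifnot(inherits(binary, "binary_binding_matrix"))
  density_denominator <- match.arg(density_denominator)
  bits <- binary$bits
  locus <- binary$locus[rownames(bits)]
  if (anyNA(locus)) stop("locus undefined for some alleles")
  loci <- sort(unique(locus))
  freq <- t(rowsum(bits, locus))          # peptides x loci event counts
  colnames(freq) <- sort(unique(locus))
  n_loci_hit <- rowSums(freq > 0)
  any_pep <- sum(n_loci_hit >= 1)
  cross <- sum(n_loci_hit >= 2)
  excl <- sum(n_loci_hit == 1)
  undefined <- any_pep == 0L
  excl_pep <- n_loci_hit == 1
  n_alleles <- table(locus)[loci]
  denom <- switch(density_denominator,
                  all_peptides = as.numeric(n_alleles) * ncol(bits),
                  exclusive_peptides = as.numeric(n_alleles) * max(excl, 1L))
  excl_events <- vapply(loci, function(L)
    sum(freq[excl_pep & freq[, L] > 0, L]), 0)
  structure(list(
    n_peptides = ncol(bits),
    n_peptides_binding_any = any_pep,
    cross_locus_count = cross,
    cross_locus_percent = if (undefined) NA_real_ else 100 * cross / any_pep,
    locus_exclusive_count = excl,
    locus_exclusive_percent = if (undefined) NA_real_ else
      100 * excl / any_pep,
    locus_density_percent = stats::setNames(100 * excl_events / denom, loci),
    density_denominator = density_denominator,
    freq_by_locus = freq,
    undefined = undefined), class = "promiscuity_report")
}

#' @export
print.promiscuity_report <- function(x, ...) {
  cat(sprintf("promiscuity_report: %d/%d peptides with >= 1 binding event\n",
              x$n_peptides_binding_any, x$n_peptides))
  if (x$undefined) { cat("  no binding events\n"); return(invisible(x)) }
  cat(sprintf("  cross-locus: %d (%.2f%%)  locus-exclusive: %d (%.2f%%)\n",
              x$cross_locus_count, x$cross_locus_percent,
              x$locus_exclusive_count, x$locus_exclusive_percent))
  cat("  locus-exclusive event density (%):",
      paste(sprintf("%s=%.3g", names(x$locus_density_percent),
                    x$locus_density_percent), collapse = " "), "\n")
  invisible(x)
}

#' Export a binding-event heat map
#'
#' Writes the binary binding matrix as TSV (full, or restricted to the
#' binding events of locus-exclusive peptides) and optionally renders a
#' PNG heat map with one mark per binding event. Rows can be reordered by
#' a dendrogram's leaf order.
#'
#' @param binary a `binary_binding_matrix`.
#' @param file_matrix TSV output path.
#' @param file_plot optional PNG output path.
#' @param ordering optional `annotated_dendrogram` or `hclust`; rows are
#'   permuted to its leaf order.
#' @param exclusive_only keep only binding events of locus-exclusive
#'   peptides (cross-locus peptides' columns are zeroed and dropped).
#' @return the exported 0/1 matrix, invisibly.
#' @export
heatmap_export <- function(binary, file_matrix, file_plot = NULL,
                           ordering = NULL, exclusive_only = FALSE) {
  stopifnot(inherits(binary, "binary_binding_matrix"))
  bits <- binary$bits
  if (exclusive_only) {
    rep_ <- promiscuity(binary)
    keep <- rowSums(rep_$freq_by_locus > 0) == 1
    bits <- bits[, keep, drop = FALSE]
  }
  if (!is.null(ordering)) {
    hc <- if (inherits(ordering, "annotated_dendrogram")) ordering$hclust
          else ordering
    bits <- bits[hc$labels[hc$order], , drop = FALSE]
  }
  utils::write.table(data.frame(allele = rownames(bits), bits,
                                check.names = FALSE),
                     file_matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(file_plot)) {
    grDevices::png(file_plot, width = 900, height = 500)
    op <- graphics::par(mar = c(2, 8, 2, 1))
    if (ncol(bits) > 0L && nrow(bits) > 0L) {
      graphics::image(seq_len(ncol(bits)), seq_len(nrow(bits)),
                      t(bits[rev(seq_len(nrow(bits))), , drop = FALSE]),
                      zlim = c(0, 1), col = c("black", "yellow"),
                      xlab = "", ylab = "", axes = FALSE)
      graphics::axis(2, at = seq_len(nrow(bits)),
                     labels = rev(rownames(bits)), las = 2, cex.axis = 0.6)
    } else {
      graphics::plot.new()
    }
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(bits)
}
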