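new_binary_binding_matrix <- function(bits, locus, rule, n_missing) {
  structure(list(bits = bits, locus = locus, rule = rule,
                 n_missing_zeroed = n_missing),
            class = "binary_binding_matrix")
}

#' @export
print.binary_binding_matrix <- function(x, ...) {
  cat(sprintf("binary_binding_matrix: %d alleles x %d peptides, %d binding events\n",
              nrow(x$bits), ncol(x$bits), sum(x$bits)))
  cat("  rule:", x$rule$type,
      if (x$rule$type == "quantile") sprintf("(fraction = %g)", x$rule$fraction)
      else sprintf("(cutoff = %g nM)", x$rule$cutoff_nM), "\n")
  if (x$n_missing_zeroed > 0)
    cat(sprintf("  %d missing affinities recorded as non-binding\n",
                x$n_missing_zeroed))
  invisible(x)
}

#' Binarize an affinity matrix by per-allele IC50 quantile
#'
#' For each allele, the `floor(fraction * n_present)` peptides with the
#' lowest IC50 among its present (non-missing) measurements are marked as
#' binders (1), all others as non-binders (0). Ties at the cut are broken
#' by ascending IC50 and then lexicographic peptide id, so the result is
#' deterministic. Missing affinities become 0 and are counted in
#' `n_missing_zeroed`.
#'
#' @param aff an [affinity_matrix].
#' @param fraction fraction of present values per allele taken as binders,
#'   in (0, 1); default 0.20 (the "smallest 20 percent" convention).
#' @return a `binary_binding_matrix` (elements `bits`, `locus`, `rule`,
#'   `n_missing_zeroed`).
#' @export
binarize_by_quantile <- function(aff, fraction = 0.20) {
  stopifnot(inherits(aff, "affinity_matrix"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("'fraction' must be a single number in (0, 1)")
  v <- aff$values
  bits <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  pep <- colnames(v)
  for (a in seq_len(nrow(v))) {
    present <- which(!is.na(v[a, ]))
    if (length(present) == 0L)
      stop("allele '", rownames(v)[a], "' has no measured affinities")
    k <- floor(fraction * length(present))
    if (k > 0L) {
      ord <- present[order(v[a, present], pep[present])]
      bits[a, ord[seq_len(k)]] <- 1L
    }
  }
  new_binary_binding_matrix(bits, aff$locus,
                            list(type = "quantile", fraction = fraction),
                            sum(is.na(v)))
}

#' Binarize an affinity matrix by a fixed IC50 cutoff
#'
#' A cell is a binding event (1) iff its IC50 is strictly below
#' `cutoff_nM`; the boundary value itself is a non-binder. Missing
#' affinities become 0 and are counted in `n_missing_zeroed`.
#'
#' @param aff an [affinity_matrix].
#' @param cutoff_nM positive IC50 cutoff in nM; default 500 (the stringent
#'   HLA II convention; 1000 nM is the looser one).
#' @return a `binary_binding_matrix`.
#' @export
binarize_by_threshold <- function(aff, cutoff_nM = 500) {
  stopifnot(inherits(aff, "affinity_matrix"))
  if (!is.numeric(cutoff_nM) || length(cutoff_nM) != 1L || cutoff_nM <= 0)
    stop("'cutoff_nM' must be a single positive number")
  v <- aff$values
  bits <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  bits[!is.na(v) & v < cutoff_nM] <- 1L
  new_binary_binding_matrix(bits, aff$locus,
                            list(type = "fixed", cutoff_nM = cutoff_nM),
                            sum(is.na(v)))
}
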