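#' Homogenize peptide lengths by trimming terminal residues
#'
#' Trims peptides longer than `target_len` down to exactly `target_len`
#' residues, removing only terminal residues. When a per-peptide
#' conservation profile is supplied (one numeric value per residue, higher
#' = more conserved, e.g. from an external multiple-sequence alignment of
#' the source proteins), the less conserved of the two current terminal
#' residues is removed first at each step (ties go to the C-terminus).
#' Without a profile the deterministic fallback applies: trim from the
#' C-terminus first, then the N-terminus, alternating.
#'
#' @param peptides character vector of amino-acid strings, all of length
#'   `>= target_len`.
#' @param target_len target length (default 15).
#' @param profiles optional list of numeric conservation vectors, one per
#'   peptide, each matching that peptide's length.
#' @return character vector of `target_len`-mers, names preserved.
#' @export
homogenize_length <- function(peptides, target_len = 15L, profiles = NULL) {
  stopifnot(is.character(peptides))
  if (!is.null(profiles) && length(profiles) != length(peptides))
    stop("'profiles' must have one entry per peptide")
  out <- character(length(peptides))
  for (i in seq_along(peptides)) {
    s <- strsplit(peptides[i], "")[[1]]
    if (length(s) < target_len)
      stop("peptide ", if (!is.null(names(peptides))) names(peptides)[i]
           else i, " is shorter than ", target_len, " residues")
    prof <- if (!is.null(profiles)) {
      p <- profiles[[i]]
      if (length(p) != length(s))
        stop("conservation profile length mismatch for peptide ", i)
      p
    } else NULL
    cut_c <- TRUE  # fallback: C-terminus first, then alternate
    while (length(s) > target_len) {
      drop_last <- if (!is.null(prof)) prof[length(s)] <= prof[1] else cut_c
      if (drop_last) {
        keep <- seq_len(length(s) - 1L)
      } else {
        keep <- seq.int(2L, length(s))
      }
      s <- s[keep]
      if (!is.null(prof)) prof <- prof[keep]
      cut_c <- !cut_c
    }
    out[i] <- paste(s, collapse = "")
  }
  names(out) <- names(peptides)
  out
}

#' Encode equal-length sequences as numeric feature vectors
#'
#' Each sequence of length L becomes a row of L x K features, where K is
#' the number of amino-acid indices in `table`: position-major layout, so
#' columns are named `p01_<index>`, ..., `pL_<index>`. Two identical
#' sequences encode to identical rows; changing one residue changes
#' exactly K features.
#'
#' @param sequences named character vector of equal-length amino-acid
#'   strings (motifs or homogenized peptides).
#' @param table an `index_table` from [load_index_table()].
#' @return numeric matrix (items x L*K) of class `feature_matrix`.
#' @export
encode_sequences <- function(sequences, table = load_index_table()) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%03d", seq_along(sequences))
  L <- unique(nchar(sequences))
  if (length(L) != 1L)
    stop("sequences must all have equal length (use homogenize_length())")
  K <- nrow(table)
  chars <- do.call(rbind, strsplit(sequences, ""))
  bad <- which(!(chars %in% colnames(table)))
  if (length(bad) > 0L) {
    r <- (bad[1] - 1L) %% nrow(chars) + 1L
    p <- (bad[1] - 1L) %/% nrow(chars) + 1L
    stop(sprintf("non-standard residue '%s' at position %d of sequence '%s'",
                 chars[r, p], p, names(sequences)[r]))
  }
  feat <- matrix(0, length(sequences), L * K)
  for (p in seq_len(L)) {
    feat[, ((p - 1L) * K + 1L):(p * K)] <- t(table[, chars[, p], drop = FALSE])
  }
  dimnames(feat) <- list(names(sequences),
                         paste0(rep(sprintf("p%02d", seq_len(L)), each = K),
                                "_", rep(rownames(table), L)))
  structure(feat, class = c("feature_matrix", "matrix", "array"),
            seq_length = L, n_indices = K)
}
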