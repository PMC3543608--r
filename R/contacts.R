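#' Find HLA-peptide contact residue pairs in a complex structure
#'
#' A residue pair is a contact when the minimal distance between any heavy
#' atom of the HLA residue and any heavy atom of the peptide residue is
#' less than or equal to `cutoff` Angstroms. Hydrogens, waters and
#' alternate locations other than the first are excluded; only the first
#' model of multi-model files is read.
#'
#' @param structure a `bio3d` pdb object (from [bio3d::read.pdb()]) or a
#'   path to a PDB file.
#' @param hla_chain,peptide_chain chain identifiers.
#' @param cutoff contact distance cutoff in Angstroms (default 4.0).
#' @return a `contact_set`: list with `structure_id` and `pairs`, a
#'   data.frame with columns `hla_chain`, `hla_resno`, `pep_resno`,
#'   `min_dist`.
#' @export
find_contact_residues <- function(structure, hla_chain, peptide_chain,
                                  cutoff = 4.0) {
  if (is.character(structure)) {
    structure_id <- basename(structure)
    structure <- bio3d::read.pdb(structure, multi = FALSE, verbose = FALSE)
  } else structure_id <- "structure"
  stopifnot(inherits(structure, "pdb"))
  atoms <- structure$atom
  keep <- (is.na(atoms$alt) | atoms$alt %in% c("", "A")) &
    !(atoms$resid %in% c("HOH", "WAT", "DOD")) &
    !(atoms$elesy %in% c("H", "D"))
  atoms <- atoms[keep, , drop = FALSE]
  pick <- function(ch, role) {
    sel <- atoms[atoms$chain == ch, , drop = FALSE]
    if (!ch %in% structure$atom$chain)
      stop("chain '", ch, "' (", role, ") not present in structure")
    if (nrow(sel) == 0L)
      stop("chain '", ch, "' (", role, ") has no usable heavy atoms")
    sel
  }
  ah <- pick(hla_chain, "HLA")
  ap <- pick(peptide_chain, "peptide")
  xh <- as.matrix(ah[, c("x", "y", "z")])
  xp <- as.matrix(ap[, c("x", "y", "z")])
  d2 <- outer(rowSums(xh^2), rowSums(xp^2), "+") - 2 * tcrossprod(xh, xp)
  d2[d2 < 0] <- 0
  dmin <- tapply(sqrt(d2),
                 list(hla = ah$resno[row(d2)], pep = ap$resno[col(d2)]), min)
  idx <- which(dmin <= cutoff, arr.ind = TRUE)
  pairs <- data.frame(
    hla_chain = rep(hla_chain, nrow(idx)),
    hla_resno = as.integer(rownames(dmin)[idx[, 1]]),
    pep_resno = as.integer(colnames(dmin)[idx[, 2]]),
    min_dist = dmin[idx])
  pairs <- pairs[order(pairs$hla_resno, pairs$pep_resno), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(structure_id = structure_id, cutoff = cutoff,
                 pairs = pairs), class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("contact_set: %d residue pairs within %.2f A (%s)\n",
              nrow(x$pairs), x$cutoff, x$structure_id))
  invisible(x)
}

#' Build a linear binding motif from a beta-chain sequence
#'
#' Concatenates the residues found at the requested beta-chain positions,
#' in the order given, into a linear binding motif (15 residues with the
#' default position set). Position numbering is explicit: `numbering[i]`
#' is the position number of the i-th sequence residue, defaulting to
#' 1-based mature-chain numbering `1..nchar(sequence)`.
#'
#' @param beta_sequence amino-acid string of the beta chain.
#' @param positions integer positions to extract, in motif order; defaults
#'   to [default_beta_positions()].
#' @param numbering optional integer vector, same length as the sequence,
#'   mapping sequence index to position number.
#' @param allele_id optional allele name, used in error messages and kept
#'   on the result.
#' @return a `binding_motif`: list with `allele_id`, `residues` (the motif
#'   string) and `positions`.
#' @export
build_motif <- function(beta_sequence, positions = default_beta_positions(),
                        numbering = NULL, allele_id = NA_character_) {
  stopifnot(is.character(beta_sequence), length(beta_sequence) == 1L)
  chars <- strsplit(beta_sequence, "")[[1]]
  if (!all(chars %in% AA_ALPHABET))
    stop("non-standard residue '", setdiff(chars, AA_ALPHABET)[1],
         "' in beta-chain sequence", if (!is.na(allele_id))
           paste0(" of ", allele_id) else "")
  if (is.null(numbering)) numbering <- seq_along(chars)
  if (length(numbering) != length(chars))
    stop("'numbering' must map every sequence residue")
  at <- match(positions, numbering)
  if (anyNA(at))
    stop("position ", positions[is.na(at)][1], " not resolvable in the ",
         "beta chain", if (!is.na(allele_id)) paste0(" of ", allele_id)
         else "")
  structure(list(allele_id = allele_id,
                 residues = paste(chars[at], collapse = ""),
                 positions = as.integer(positions)),
            class = "binding_motif")
}

#' @export
print.binding_motif <- function(x, ...) {
  cat(sprintf("binding_motif %s: %s (positions %s)\n",
              ifelse(is.na(x$allele_id), "", x$allele_id), x$residues,
              paste(x$positions, collapse = ",")))
  invisible(x)
}

#' Write binding motifs to a FASTA file
#'
#' @param motifs named character vector of motif strings, or a list of
#'   `binding_motif` objects.
#' @param path output FASTA path.
#' @export
write_motif_fasta <- function(motifs, path) {
  if (is.list(motifs) && all(vapply(motifs, inherits, TRUE, "binding_motif")))
    motifs <- stats::setNames(vapply(motifs, `[[`, "", "residues"),
                              vapply(motifs, `[[`, "", "allele_id"))
  stopifnot(is.character(motifs), !is.null(names(motifs)))
  writeLines(as.vector(rbind(paste0(">", names(motifs)), motifs)), path)
  invisible(path)
}

#' Read sequences from a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  stats::setNames(toupper(seqs), id)
}
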