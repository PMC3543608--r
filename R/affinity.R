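#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in alphabetical one-letter order.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Infer HLA class II locus from allele names
#'
#' Maps beta-chain allele name prefixes to loci: `DRB*` alleles (including
#' DRB1/DRB3/DRB4/DRB5) to `DR`, `DQB*` to `DQ`, `DPB*` to `DP`.
#'
#' @param alleles character vector of allele names, e.g. `"DRB1*0101"`.
#' @param locus_map optional named character vector (names = alleles) used
#'   for alleles whose prefix is not recognised.
#' @return named character vector of loci (`"DR"`, `"DQ"`, `"DP"`).
#' @export
infer_locus <- function(alleles, locus_map = NULL) {
  locus <- rep(NA_character_, length(alleles))
  locus[grepl("^DRB", alleles)] <- "DR"
  locus[grepl("^DQB", alleles)] <- "DQ"
  locus[grepl("^DPB", alleles)] <- "DP"
  if (!is.null(locus_map)) {
    hit <- alleles %in% names(locus_map)
    locus[hit] <- unname(locus_map[alleles[hit]])
  }
  if (anyNA(locus)) {
    stop("cannot infer locus for allele(s): ",
         paste(alleles[is.na(locus)], collapse = ", "),
         " (supply a locus map)")
  }
  names(locus) <- alleles
  locus
}

#' Construct an allele x peptide IC50 affinity matrix
#'
#' @param values numeric matrix of IC50 values in nM, alleles as rows and
#'   peptides as columns; `NA` marks a missing measurement. All present
#'   values must be strictly positive.
#' @param locus optional named character vector mapping every allele to its
#'   locus; inferred from allele-name prefixes when omitted.
#' @return object of class `affinity_matrix` with elements `values` and
#'   `locus`.
#' @export
affinity_matrix <- function(values, locus = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs allele rownames and peptide colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated allele ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicated peptide ids")
  if (any(values <= 0, na.rm = TRUE))
    stop("IC50 values must be strictly positive")
  if (is.null(locus)) {
    locus <- infer_locus(rownames(values))
  } else {
    if (!all(rownames(values) %in% names(locus)))
      stop("'locus' must cover every allele")
    locus <- locus[rownames(values)]
  }
  structure(list(values = values, locus = locus), class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("affinity_matrix: %d alleles x %d peptides (IC50, nM)\n",
              nrow(x$values), ncol(x$values)))
  cat("  loci:", paste(sprintf("%s=%d", names(table(x$locus)),
                               table(x$locus)), collapse = " "), "\n")
  cat(sprintf("  missing cells: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' Read an allele x peptide IC50 table from CSV/TSV
#'
#' The first column holds row ids and the header holds column ids.
#' Orientation is auto-detected: if the row ids look like HLA class II
#' beta-chain alleles the table is taken as alleles-in-rows (the default
#' layout); if instead the column ids do, it is transposed. Empty cells
#' and `NA` are recorded as missing, never as zero.
#'
#' @param path CSV (`.csv`) or TSV file.
#' @param locus_map optional path to a two-column (allele, locus) TSV, or a
#'   named character vector, for alleles with non-standard names.
#' @param orientation `"auto"` (default), `"alleles_rows"` or
#'   `"alleles_cols"`.
#' @return an [affinity_matrix].
#' @export
read_affinity_table <- function(path, locus_map = NULL,
                                orientation = c("auto", "alleles_rows",
                                                "alleles_cols")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("cannot parse '", path, "': file is empty")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) == 0L)
    stop("cannot parse '", path, "': no data rows/columns")
  m <- as.matrix(raw)
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m),
                                dimnames = dimnames(m)))
  bad <- which(is.na(num) & !(is.na(m) | m == "" | toupper(m) == "NA"),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                 colnames(m)[bad[1, 2]], path))
  }
  looks_hla <- function(ids) mean(grepl("^D[RQP]B", ids)) > 0.5
  if (orientation == "auto") {
    orientation <- if (looks_hla(rownames(num))) "alleles_rows"
    else if (looks_hla(colnames(num))) "alleles_cols"
    else stop("cannot auto-detect orientation of '", path,
              "': neither axis has HLA-like ids; pass 'orientation'")
  }
  if (orientation == "alleles_cols") num <- t(num)
  if (is.character(locus_map) && length(locus_map) == 1L &&
      file.exists(locus_map)) {
    lm <- utils::read.table(locus_map, sep = "\t", header = FALSE,
                            col.names = c("allele", "locus"),
                            colClasses = "character")
    locus_map <- stats::setNames(lm$locus, lm$allele)
  }
  affinity_matrix(num, locus = tryCatch(
    infer_locus(rownames(num), locus_map), error = function(e) stop(e)))
}

#' Write an affinity matrix to CSV/TSV
#'
#' Inverse of [read_affinity_table()]; missing values are written as `NA`.
#'
#' @param aff an [affinity_matrix].
#' @param path output file; `.csv` selects comma separation, otherwise tab.
#' @export
write_affinity_table <- function(aff, path) {
  stopifnot(inherits(aff, "affinity_matrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(allele = rownames(aff$values), aff$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an amino-acid index table
#'
#' Loads a K x 20 table of amino-acid physicochemical indices and (by
#' default) standardizes each index to zero mean and unit variance over the
#' 20 standard amino acids, so that no index dominates Euclidean distances
#' between encoded sequences by scale alone.
#'
#' The bundled `"hqi24-like"` table is a 24-index synthetic stand-in with
#' the dimensions and correlation structure of a curated high-quality index
#' set; substitute the real table via `path` when available.
#'
#' @param name_or_path `"hqi24-like"` for the bundled fixture, or a path to
#'   a TSV whose first column is the index name and remaining 20 columns
#'   are values for the amino acids.
#' @param standardize standardize each index over the 20 amino acids
#'   (default `TRUE`).
#' @return numeric matrix (indices x 20 amino acids) of class
#'   `index_table`, columns ordered as [AA_ALPHABET].
#' @export
load_index_table <- function(name_or_path = "hqi24-like",
                             standardize = TRUE) {
  path <- if (identical(name_or_path, "hqi24-like")) {
    system.file("extdata", "hqi24_synthetic.tsv", package = "hlaSupertype",
                mustWork = TRUE)
  } else name_or_path
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = c("character", rep("numeric", 20)))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  missing_aa <- setdiff(AA_ALPHABET, colnames(m))
  if (length(missing_aa) > 0L)
    stop("index table lacks amino acid(s): ",
         paste(missing_aa, collapse = ", "))
  m <- m[, AA_ALPHABET, drop = FALSE]
  if (anyNA(m)) {
    i <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("index '%s' has a missing value for amino acid '%s'",
                 rownames(m)[i[1]], colnames(m)[i[2]]))
  }
  if (standardize) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    if (any(sdv == 0)) stop("constant index cannot be standardized: ",
                            rownames(m)[sdv == 0][1])
    m <- (m - mu) / sdv
  }
  structure(m, class = c("index_table", "matrix"), standardized = standardize)
}

#' Default beta-chain binding-site positions
#'
#' The 15 HLA class II beta-chain positions whose residues contact bound
#' peptides within 4 Angstroms across reference HLA II-peptide complex
#' structures, distributed over the four classic binding pockets.
#'
#' @return integer vector of 15 mature beta-chain positions.
#' @export
default_beta_positions <- function() {
  as.integer(readLines(system.file("extdata", "beta_positions.txt",
                                   package = "hlaSupertype",
                                   mustWork = TRUE)))
}
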