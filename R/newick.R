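# map each internal node of a phylo object to its sorted tip-label set
phylo_clade_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  eo <- stats::reorder(phy, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    sets[[eo[k, 1]]] <- c(sets[[eo[k, 1]]], sets[[eo[k, 2]]])
  lapply(sets, sort)
}

#' Write an annotated dendrogram as a Newick tree
#'
#' Serializes the tree with per-edge support values as internal node
#' labels of the form `AU_BP` (e.g. `0.987_0.954`), readable by any
#' Newick parser and by [read_annotated_newick()]. The root carries no
#' label, so a binary tree with n leaves has n - 2 annotated internal
#' edges.
#'
#' @param tree an `annotated_dendrogram` from [msboot_cluster()].
#' @param path output file.
#' @param digits digits for the serialized support values (default 4).
#' @return the path, invisibly.
#' @export
write_annotated_newick <- function(tree, path, digits = 4) {
  stopifnot(inherits(tree, "annotated_dendrogram"))
  ed <- tree$edges
  n <- length(tree$leaf_ids)
  nonroot <- ed$size < n
  if (any(is.na(ed$au[nonroot])))
    stop("unannotated internal edge(s): ",
         paste(ed$edge[nonroot & is.na(ed$au)], collapse = ", "))
  phy <- ape::as.phylo(tree$hclust)
  sets <- phylo_clade_sets(phy)
  ntip <- length(phy$tip.label)
  keys <- vapply(sets[(ntip + 1):(ntip + phy$Nnode)],
                 paste, "", collapse = ";")
  hit <- match(keys, ed$key)
  lab <- sprintf(paste0("%.", digits, "f_%.", digits, "f"),
                 ed$au[hit], ed$bp_raw[hit])
  lab[is.na(hit) | lengths(sets[(ntip + 1):(ntip + phy$Nnode)]) == n] <- ""
  phy$node.label <- lab
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read an annotated Newick tree
#'
#' Parses a Newick file whose internal node labels follow the `AU_BP`
#' convention of [write_annotated_newick()].
#'
#' @param path Newick file.
#' @return list with `phylo` (the [ape] tree) and `edges`, a data.frame
#'   with one row per internal node: `key` (sorted member ids joined by
#'   `;`), `au`, `bp`.
#' @export
read_annotated_newick <- function(path) {
  phy <- ape::read.tree(path)
  sets <- phylo_clade_sets(phy)
  ntip <- length(phy$tip.label)
  keys <- vapply(sets[(ntip + 1):(ntip + phy$Nnode)],
                 paste, "", collapse = ";")
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", phy$Nnode)
  parts <- strsplit(lab, "_", fixed = TRUE)
  num <- function(i) vapply(parts, function(p)
    if (length(p) == 2L) as.numeric(p[i]) else NA_real_, 0)
  list(phylo = phy,
       edges = data.frame(key = keys, au = num(1), bp = num(2),
                          stringsAsFactors = FALSE))
}

#' Export per-edge support values as TSV
#'
#' @param tree an `annotated_dendrogram`.
#' @param path output TSV.
#' @export
write_edge_table <- function(tree, path) {
  stopifnot(inherits(tree, "annotated_dendrogram"))
  utils::write.table(tree$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
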