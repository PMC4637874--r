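# Tree input, validation and indexing. Parsing and surgery go through ape;
# the engine consumes a postorder index built by tree_index().

#' Read and validate a phylogenetic tree
#'
#' Parses a Newick string or file via [ape::read.tree()] and validates it for
#' use in likelihood computations: unique leaf names, finite non-negative
#' branch lengths, and a binary rooted topology. Polytomies are rejected
#' unless `resolve_polytomies = TRUE`, in which case they are resolved
#' arbitrarily with zero-length branches (recorded in an attribute).
#'
#' @param text A Newick string (used when `file` is `NULL`).
#' @param file Path to a Newick file.
#' @param resolve_polytomies Resolve multifurcations with zero-length
#'   branches instead of rejecting them.
#' @return An [ape::phylo] object, rooted and binary.
#' @examples
#' tr <- read_tree("((A:1,B:2):0.5,C:3);")
#' @export
read_tree <- function(text = NULL, file = NULL, resolve_polytomies = FALSE) {
  tr <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick input")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_tree(tr, resolve_polytomies = resolve_polytomies)
}

validate_tree <- function(tr, resolve_polytomies = FALSE) {
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup))
    stop("duplicate leaf name(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  if (anyNA(tr$edge.length) || any(!is.finite(tr$edge.length)))
    stop("tree has missing or non-finite branch lengths")
  if (any(tr$edge.length < 0))
    stop("tree has negative branch lengths")
  resolved <- FALSE
  if (!ape::is.binary.phylo(tr)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies; pass resolve_polytomies = TRUE to ",
           "resolve them arbitrarily with zero-length branches")
    tr <- ape::multi2di(tr, random = FALSE)
    tr$edge.length[is.na(tr$edge.length)] <- 0
    resolved <- TRUE
  }
  if (!ape::is.rooted(tr))
    stop("tree must be rooted")
  attr(tr, "polytomies_resolved") <- resolved
  tr
}

#' Write a tree to Newick
#'
#' @param tr An [ape::phylo] object.
#' @param file Optional output path; when `NULL` the Newick string is
#'   returned.
#' @param digits Branch-length precision.
#' @export
write_tree <- function(tr, file = NULL, digits = 10) {
  txt <- ape::write.tree(tr, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Postorder index used by the likelihood engine. Node numbering follows ape:
# tips 1..ntip, root ntip+1, internal nodes above. Edges are rows of the
# postorder edge matrix; einc[node] is the index of the edge leading into it.
tree_index <- function(tr) {
  tr2 <- stats::reorder(tr, "postorder")
  ntip <- length(tr2$tip.label)
  nnode <- tr2$Nnode
  nn <- ntip + nnode
  root <- ntip + 1L
  parent <- integer(nn)
  einc <- integer(nn)
  edge <- tr2$edge
  parent[edge[, 2L]] <- edge[, 1L]
  einc[edge[, 2L]] <- seq_len(nrow(edge))
  children <- vector("list", nn)
  for (i in seq_len(nrow(edge)))
    children[[edge[i, 1L]]] <- c(children[[edge[i, 1L]]], edge[i, 2L])
  # internal nodes in the order their last child edge appears = postorder
  int_post <- unique(edge[, 1L])
  list(tree = tr2, edge = edge, el = tr2$edge.length,
       ntip = ntip, nnode = nnode, nnodes_all = nn, root = root,
       parent = parent, einc = einc, children = children,
       int_postorder = int_post,
       int_preorder = rev(int_post),
       tip.label = tr2$tip.label)
}

# MRCA of a set of leaf labels (returns the leaf's node id for singletons).
mrca_node <- function(tr, leaves) {
  idx <- match(leaves, tr$tip.label)
  if (anyNA(idx))
    stop("leaves not in tree: ", paste(leaves[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tr, idx)
}

# Leaf labels below a node.
clade_leaves <- function(tr, node) {
  ntip <- length(tr$tip.label)
  if (node <= ntip) return(tr$tip.label[node])
  tr$tip.label[phangorn::Descendants(tr, node, type = "tips")[[1L]]]
}

# Edge indices (rows of tr$edge) on the path from each flagged node down,
# i.e. terminal edges of the given leaves plus internal edges of their clades.
clade_edges <- function(tr, node) {
  desc <- phangorn::Descendants(tr, node, type = "all")
  nodes <- c(node, desc)
  which(tr$edge[, 2L] %in% nodes)
}
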