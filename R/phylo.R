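#' Internal node feature ids
#'
#' Internal nodes are identified as `"n<k>"` where `k` is the node's index in
#' the tree's deterministic numbering (leaves `1..p`, internal nodes
#' `p+1..p+m`), so feature ids are stable across runs for the same Newick
#' input.
#'
#' @param tree an [ape::phylo] tree.
#' @return character vector of internal node ids, one per internal node.
#' @export
node_ids <- function(tree) {
  p <- length(tree$tip.label)
  paste0("n", seq(p + 1L, p + tree$Nnode))
}

# list over ALL node numbers (1..p+m): tip indices descending from each node,
# accumulated bottom-up over a postorder edge traversal
descendant_tips <- function(tree) {
  p <- length(tree$tip.label)
  n_all <- p + tree$Nnode
  desc <- vector("list", n_all)
  for (i in seq_len(p)) desc[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; child <- edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[child]])
  }
  lapply(desc, sort)
}

# parent lookup: parent[k] = parent node number of node k (0 for the root)
parent_vector <- function(tree) {
  p <- length(tree$tip.label)
  parent <- integer(p + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

#' Phylogenetic similarity matrix
#'
#' The Brownian-motion covariance on a rooted tree with branch lengths:
#' `Q[i, j]` is the shared root-to-path length of leaves `i` and `j`, i.e. the
#' depth of their most recent common ancestor, and `Q[i, i]` is the
#' root-to-leaf depth. A star tree with unit branches gives the identity.
#' This is the tree-structured prior covariance used by the generalized and
#' adaptive ordinations.
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @return symmetric positive semidefinite `p x p` matrix with leaf labels as
#'   dimnames, rows/columns in `tree$tip.label` order.
#' @export
tree_similarity <- function(tree) {
  validate_tree(tree)
  Q <- ape::vcv(tree)
  Q[tree$tip.label, tree$tip.label]
}

#' Expand a study into leaf and node features
#'
#' Builds the feature matrix for tree-based discriminant analysis: one column
#' per leaf holding the variance-stabilized abundance of that taxon, plus one
#' column per internal node holding the sum of the transformed abundances of
#' all leaves descending from it. Branch lengths are deliberately ignored:
#' node features are pure sums. Columns are not centered; centering is the
#' fitter's job.
#'
#' @param study a [study_table] whose taxa match the tree leaves.
#' @param tree an [ape::phylo] tree aligned with `study` (see
#'   [align_study()]).
#' @param transform `"log1p"` or `"asinh"`, applied to raw counts.
#' @return object of class `feature_matrix`: list with `values`
#'   (`n x (p + m)` matrix), `kind` (`"leaf"`/`"node"` per column) and
#'   `node_leaves` (named list mapping node ids to descendant leaf labels).
#' @export
expand_features <- function(study, tree, transform = c("log1p", "asinh")) {
  transform <- match.arg(transform)
  f <- transform_fun(transform)
  if (!setequal(colnames(study$counts), tree$tip.label)) {
    abort("study taxa and tree leaves differ; run align_study() first.")
  }
  leaf_vals <- f(study$counts[, tree$tip.label, drop = FALSE])
  p <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  inner <- seq(p + 1L, p + tree$Nnode)
  # p x m incidence: leaf i descends from node j
  incid <- vapply(inner, function(nd) {
    z <- numeric(p); z[desc[[nd]]] <- 1; z
  }, numeric(p))
  node_vals <- leaf_vals %*% incid
  ids <- node_ids(tree)
  colnames(node_vals) <- ids
  node_leaves <- lapply(desc[inner], function(i) tree$tip.label[i])
  names(node_leaves) <- ids
  structure(list(values = cbind(leaf_vals, node_vals),
                 kind = c(rep("leaf", p), rep("node", tree$Nnode)),
                 node_leaves = node_leaves,
                 transform = transform),
            class = "feature_matrix")
}

transform_fun <- function(name) {
  switch(name,
         log1p = log1p,
         asinh = asinh,
         abort(paste0("unknown transform: ", name)))
}

#' Back-map feature coefficients to leaves
#'
#' A coefficient on an internal-node feature acts additively on every leaf of
#' its clade (the node feature is the sum of those leaf features), so the
#' effective coefficient of a leaf is its own coefficient plus the sum of the
#' coefficients of all its ancestors. A leaf counts as selected when its
#' effective coefficient is non-zero.
#'
#' @param coefficients named numeric vector over leaf labels and/or node ids
#'   (`"n<k>"`).
#' @param tree the [ape::phylo] tree the features were built from.
#' @return named numeric vector of effective coefficients, one per leaf, in
#'   `tree$tip.label` order.
#' @export
leaf_coefficients <- function(coefficients, tree) {
  p <- length(tree$tip.label)
  valid <- c(tree$tip.label, node_ids(tree))
  bad <- setdiff(names(coefficients), valid)
  if (length(bad)) {
    abort(paste0("unknown feature id(s): ", paste(bad, collapse = ", ")))
  }
  full <- setNames(numeric(p + tree$Nnode), valid)
  full[names(coefficients)] <- coefficients
  parent <- parent_vector(tree)
  eff <- setNames(numeric(p), tree$tip.label)
  for (i in seq_len(p)) {
    v <- full[i]
    k <- parent[i]
    while (k != 0L) {
      v <- v + full[k]
      k <- parent[k]
    }
    eff[i] <- v
  }
  eff
}

#' Leaves of a clade
#'
#' @param tree an [ape::phylo] tree.
#' @param node_id a leaf label or an internal node id (`"n<k>"`).
#' @return character vector of leaf labels descending from the node (the
#'   singleton set for a leaf).
#' @export
clade_leaves <- function(tree, node_id) {
  p <- length(tree$tip.label)
  if (node_id %in% tree$tip.label) return(node_id)
  if (node_id %in% node_ids(tree)) {
    k <- as.integer(sub("^n", "", node_id))
    desc <- descendant_tips(tree)
    return(tree$tip.label[desc[[k]]])
  }
  abort(paste0("no such node: ", node_id))
}
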