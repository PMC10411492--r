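#' Read a Newick tree
#'
#' Internal-node labels are interpreted as support values (RAxML style).
#'
#' @param path path to a Newick file (or a file with one tree per line).
#' @return an `ape::phylo` object (or `multiPhylo` if several trees).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("parse error: no tree parsed from ", path)
  tr
}

#' Write trees as Newick
#'
#' Branch lengths are written with 12 significant digits so that
#' write-then-read round-trips preserve them.
#'
#' @param tree a `phylo` or `multiPhylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Node support values of a tree
#'
#' @param tree a `phylo` with supports stored as internal node labels.
#' @return numeric vector, one entry per internal node (NA when absent).
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[!nzchar(trimws(as.character(tree$node.label)))] <- NA_real_
  sup
}

# Descendant-tip sets per node, via one postorder pass over the edge matrix.
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(eo))) {
    p <- eo[r, 1L]; ch <- eo[r, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# Canonical key of a bipartition: the side not containing the reference
# taxon (the alphabetically first leaf), sorted and pipe-joined.
split_key <- function(side, all_taxa) {
  ref <- min(all_taxa)
  if (ref %in% side) side <- setdiff(all_taxa, side)
  paste(sort(side), collapse = "|")
}

#' Non-trivial splits of a tree
#'
#' Returns the bipartitions induced by internal edges, as a named numeric
#' vector: names are canonical split keys, values the corresponding branch
#' lengths (0 when the tree has none). Rooted trees are unrooted first, so
#' the redundant root edge contributes a single split.
#'
#' @param tree a `phylo`.
#' @return named numeric vector of split weights; attribute `taxa` carries
#'   the leaf set.
#' @export
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  taxa <- tree$tip.label
  ntip <- length(taxa)
  out <- numeric(0)
  if (ntip >= 4L) {
    desc <- descendant_tips(tree)
    el <- if (is.null(tree$edge.length)) rep(0, nrow(tree$edge)) else tree$edge.length
    keys <- character(0); wts <- numeric(0)
    for (r in seq_len(nrow(tree$edge))) {
      ch <- tree$edge[r, 2L]
      if (ch <= ntip) next
      side <- desc[[ch]]
      if (length(side) < 2L || length(side) > ntip - 2L) next
      keys <- c(keys, split_key(side, taxa))
      wts <- c(wts, el[r])
    }
    if (anyDuplicated(keys)) {
      wts <- tapply(wts, keys, sum)
      keys <- names(wts); wts <- as.numeric(wts)
    }
    out <- stats::setNames(wts, keys)
  }
  attr(out, "taxa") <- taxa
  out
}

#' Robinson-Foulds distance between two trees
#'
#' Trees are restricted to their shared leaf set before comparison. The
#' unweighted distance counts splits present in exactly one tree; the
#' weighted variant sums `|w1 - w2|` over the union of splits, with weight
#' zero for a split absent from a tree (internal edges only).
#'
#' @param t1,t2 `phylo` objects.
#' @param weighted logical.
#' @return non-negative numeric distance.
#' @export
rf_distance <- function(t1, t2, weighted = FALSE) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L)
    stop("input error: fewer than 4 shared taxa; RF distance undefined")
  t1 <- restrict_tree(t1, shared)
  t2 <- restrict_tree(t2, shared)
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  if (!weighted)
    return(sum(!(names(s1) %in% names(s2))) + sum(!(names(s2) %in% names(s1))))
  keys <- union(names(s1), names(s2))
  w1 <- ifelse(keys %in% names(s1), s1[keys], 0)
  w2 <- ifelse(keys %in% names(s2), s2[keys], 0)
  sum(abs(w1 - w2))
}

# Restrict a tree to a taxon subset (drop.tip sums branch lengths across
# suppressed degree-2 nodes).
restrict_tree <- function(tree, taxa) {
  drop <- setdiff(tree$tip.label, taxa)
  if (length(drop)) tree <- ape::drop.tip(tree, drop) else tree
}

#' Remove a taxon from a tree
#'
#' @param tree a `phylo`.
#' @param taxon leaf label(s) to remove.
#' @return the pruned tree; branch lengths across suppressed nodes are summed.
#' @export
prune_taxon <- function(tree, taxon) {
  miss <- setdiff(taxon, tree$tip.label)
  if (length(miss)) stop("input error: taxon not in tree: ",
                         paste(miss, collapse = ", "))
  ape::drop.tip(tree, taxon)
}

# Serialize an adjacency (children list + lengths + labels) back to a phylo
# via a Newick string; used by collapse/NNI edits.
adjacency_to_phylo <- function(children, lengths, labels, root) {
  fmt <- function(x) if (is.na(x)) "" else sprintf(":%.12g", x)
  rec <- function(v) {
    kids <- children[[v]]
    if (is.null(kids) || !length(kids))
      return(paste0(labels[[v]], fmt(lengths[[v]])))
    inner <- paste(vapply(kids, rec, ""), collapse = ",")
    lab <- if (is.null(labels[[v]]) || is.na(labels[[v]])) "" else labels[[v]]
    paste0("(", inner, ")", lab, fmt(lengths[[v]]))
  }
  ape::read.tree(text = paste0(rec(root), ";"))
}

phylo_adjacency <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  children <- vector("list", nn)
  lengths <- rep(NA_real_, nn)
  labels <- rep(NA_character_, nn)
  labels[seq_len(ntip)] <- tree$tip.label
  if (!is.null(tree$node.label))
    labels[ntip + seq_len(tree$Nnode)] <- tree$node.label
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1L]; ch <- tree$edge[r, 2L]
    children[[p]] <- c(children[[p]], ch)
    if (!is.null(tree$edge.length)) lengths[ch] <- tree$edge.length[r]
  }
  list(children = children, lengths = lengths, labels = labels,
       root = ntip + 1L, ntip = ntip)
}

#' Collapse poorly supported edges into polytomies
#'
#' Internal edges whose child-node support is strictly below `threshold`
#' are contracted; edges without a support value are retained. The leaf set
#' is unchanged and the total tree length decreases by exactly the lengths
#' of the contracted edges.
#'
#' @param tree a `phylo` with supports as internal node labels (percent).
#' @param threshold percent in `[0, 100]`; nodes with support `< threshold`
#'   are collapsed.
#' @return a `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 100)
    stop("input error: threshold must be in [0, 100]")
  sup <- node_supports(tree)
  ntip <- length(tree$tip.label)
  gone <- ntip + which(!is.na(sup) & sup < threshold)
  gone <- setdiff(gone, ntip + 1L)  # the root has no parent edge
  if (!length(gone)) return(tree)
  adj <- phylo_adjacency(tree)
  resolve <- function(v) { while (v %in% gone) v <- parent_of[v]; v }
  parent_of <- rep(NA_integer_, length(adj$children))
  for (p in seq_along(adj$children))
    for (ch in adj$children[[p]]) parent_of[ch] <- p
  newkids <- vector("list", length(adj$children))
  for (p in seq_along(adj$children)) {
    for (ch in adj$children[[p]]) {
      if (ch %in% gone) next
      tgt <- resolve(p)
      newkids[[tgt]] <- c(newkids[[tgt]], ch)
    }
  }
  adjacency_to_phylo(newkids, adj$lengths, adj$labels, adj$root)
}

# Internal-edge rows of an unrooted tree's edge matrix (child is an
# internal node inducing a non-trivial split).
internal_edge_rows <- function(tree) {
  ntip <- length(tree$tip.label)
  which(tree$edge[, 2L] > ntip)
}

#' Nearest-neighbor-interchange alternatives of an unrooted binary tree
#'
#' Each internal edge yields exactly two alternative topologies; with
#' `edge = NULL` all `2(n-3)` neighbors are returned.
#'
#' @param tree an unrooted binary `phylo`.
#' @param edge optional internal-edge row index (into `tree$edge`, after
#'   unrooting) restricting the result to that edge's two neighbors.
#' @return list of `phylo` objects.
#' @export
nni_neighbors <- function(tree, edge = NULL) {
  tree <- ape::unroot(tree)
  if (!ape::is.binary(tree))
    stop("input error: NNI requires a binary tree")
  rows <- internal_edge_rows(tree)
  if (!is.null(edge)) {
    if (!edge %in% rows) stop("input error: edge is not an internal edge")
    rows <- edge
  }
  out <- list()
  for (r in rows) out <- c(out, nni_at_edge(tree, r))
  out
}

# The two NNI rearrangements across edge row r = (u, v): swap one subtree
# attached at u with each of v's two children in turn.
nni_at_edge <- function(tree, r) {
  u <- tree$edge[r, 1L]; v <- tree$edge[r, 2L]
  kid_rows_u <- which(tree$edge[, 1L] == u & tree$edge[, 2L] != v)
  b_row <- kid_rows_u[1L]
  kid_rows_v <- which(tree$edge[, 1L] == v)
  lapply(kid_rows_v, function(c_row) {
    e <- tree
    b <- e$edge[b_row, 2L]; cc <- e$edge[c_row, 2L]
    e$edge[b_row, 2L] <- cc
    e$edge[c_row, 2L] <- b
    e$node.label <- NULL
    # normalize node bookkeeping through a serialization round-trip
    adj <- phylo_adjacency(e)
    adjacency_to_phylo(adj$children, adj$lengths, adj$labels, adj$root)
  })
}

#' Locate a tree edge by the bipartition it induces
#'
#' @param tree a `phylo` (unrooted internally).
#' @param side character vector of taxa forming one side of the split.
#' @return the edge row index in the unrooted tree, or `NA` if no internal
#'   edge induces the split.
#' @export
find_edge_by_split <- function(tree, side) {
  tree <- ape::unroot(tree)
  taxa <- tree$tip.label
  side <- intersect(side, taxa)
  if (length(side) < 2L || length(side) > length(taxa) - 2L) return(NA_integer_)
  want <- split_key(side, taxa)
  desc <- descendant_tips(tree)
  ntip <- length(taxa)
  for (r in internal_edge_rows(tree)) {
    ch <- tree$edge[r, 2L]
    s <- desc[[ch]]
    if (length(s) < 2L || length(s) > ntip - 2L) next
    if (split_key(s, taxa) == want) return(r)
  }
  NA_integer_
}

#' Total branch length of a tree
#' @param tree a `phylo`.
#' @export
tree_length <- function(tree) {
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length)
}

#' Re-graft a taxon as the sister of another taxon
#'
#' Detaches `taxon` and re-attaches it on `target`'s terminal edge with a
#' short stub branch — the topology a tree-estimation step would recover
#' when `taxon`'s sequence is a near-copy of `target`'s (as after
#' cross-contamination).
#'
#' @param tree a `phylo` with branch lengths.
#' @param taxon leaf to move.
#' @param target leaf to pair it with.
#' @param stub branch length of the moved leaf and of the new fork.
#' @return a `phylo`.
#' @export
graft_sister <- function(tree, taxon, target, stub = 1e-4) {
  if (!all(c(taxon, target) %in% tree$tip.label))
    stop("input error: taxon not in tree")
  tr <- ape::drop.tip(tree, taxon)
  tgt <- match(target, tr$tip.label)
  er <- which(tr$edge[, 2] == tgt)
  pos <- min(stub, tr$edge.length[er] / 2)
  newtip <- ape::read.tree(text = paste0("(", taxon, ":", format(stub), ");"))
  out <- ape::bind.tree(tr, newtip, where = tgt, position = pos)
  ape::reorder.phylo(out)
}
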