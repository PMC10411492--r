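# Independent oracles and small fixture builders shared across tests.

# Brute-force tree likelihood: per site, sum the joint probability over
# every assignment of states to internal nodes (and to ambiguous tips),
# averaged over gamma categories. Exponential in the node count -- only
# for tiny fixtures.
brute_force_lnl <- function(aln, tree, model) {
  tree <- ape::unroot(tree)
  m <- unclass(aln)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  gr <- model$gamma_rates
  k <- length(gr)
  state_sets <- lapply(seq_len(ncol(m)), function(s) {
    lapply(tree$tip.label, function(tx) {
      st <- match(m[tx, s], c("A", "C", "G", "T"))
      if (is.na(st)) 1:4 else st
    })
  })
  total <- 0
  for (s in seq_len(ncol(m))) {
    Ls <- 0
    for (cat in seq_len(k)) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(r)
        transition_matrix(model, tree$edge.length[r] * gr[cat]))
      free <- c(state_sets[[s]], rep(list(1:4), nint))
      grid <- do.call(expand.grid, free)
      Lc <- 0
      for (g in seq_len(nrow(grid))) {
        st <- as.integer(grid[g, ])
        pr <- model$pi[st[ntip + 1]]
        for (r in seq_len(nrow(tree$edge)))
          pr <- pr * Ps[[r]][st[tree$edge[r, 1]], st[tree$edge[r, 2]]]
        Lc <- Lc + pr
      }
      Ls <- Ls + Lc / k
    }
    total <- total + log(Ls)
  }
  total
}

# Split oracle: bipartitions found by deleting each internal edge of the
# tree graph and flood-filling the two components (a code path independent
# of tree_splits' descendant-set accumulation).
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  out <- character(0)
  for (r in seq_len(nrow(tree$edge))) {
    if (tree$edge[r, 2] <= ntip) next
    adj <- lapply(seq_len(nn), function(i) integer(0))
    for (q in seq_len(nrow(tree$edge))) {
      if (q == r) next
      a <- tree$edge[q, 1]; b <- tree$edge[q, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    comp <- integer(0)
    stack <- tree$edge[r, 2]
    seen <- logical(nn)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      if (v <= ntip) comp <- c(comp, v)
      stack <- c(stack, adj[[v]])
    }
    side <- tree$tip.label[comp]
    if (length(side) < 2 || length(side) > ntip - 2) next
    ref <- min(tree$tip.label)
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# All unrooted binary topologies on a taxon set, by sequential addition of
# each taxon to every edge (n = 6 gives the classic 105 topologies).
all_topologies <- function(taxa) {
  base <- ape::read.tree(text = sprintf("(%s,%s,%s);", taxa[1], taxa[2], taxa[3]))
  trees <- list(base)
  for (i in seq_along(taxa)[-(1:3)]) {
    nxt <- list()
    for (tr in trees) {
      tr$edge.length <- rep(1, nrow(tr$edge))
      for (e in seq_len(nrow(tr$edge))) {
        nt <- ape::bind.tree(tr, ape::read.tree(text = paste0("(", taxa[i], ":1);")),
                             where = tr$edge[e, 2], position = 0.5)
        nt$edge.length <- NULL
        nxt[[length(nxt) + 1L]] <- ape::unroot(nt)
      }
    }
    trees <- nxt
  }
  trees
}

rand_alignment <- function(taxa, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), length(taxa) * n, replace = TRUE),
              length(taxa), n, dimnames = list(taxa, NULL))
  new_alignment(m)
}

# small uneven GTR+Gamma model used across likelihood tests
test_model <- function(k = 4) {
  subst_model(pi = c(0.35, 0.15, 0.2, 0.3), rates = c(2, 4, 1.2, 0.8, 5, 1),
              alpha = 0.7, k = k)
}
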