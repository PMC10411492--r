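#' Simulate an alignment on a tree
#'
#' Root states are drawn from the model's stationary frequencies and
#' evolved edge-wise via [transition_matrix()]. Optional per-site rate
#' multipliers (recycled across sites, e.g. `c(1, 1, 20)` for codon
#' positions) scale every branch for that site; optionally a discrete
#' gamma rate is additionally drawn per site from the model.
#'
#' @param tree a `phylo` with branch lengths.
#' @param model a `subst_model`.
#' @param n_sites number of columns.
#' @param site_rate_multipliers numeric vector recycled over sites, or NULL.
#' @param gamma_sites draw an additional per-site discrete-gamma rate.
#' @param seed optional integer seed (deterministic output when set).
#' @return a `dna_alignment` of the tree's tips.
#' @export
simulate_alignment <- function(tree, model, n_sites,
                               site_rate_multipliers = NULL,
                               gamma_sites = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree$edge.length)) stop("input error: tree has no branch lengths")
  bases <- c("A", "C", "G", "T")
  rates <- rep(1, n_sites)
  if (!is.null(site_rate_multipliers))
    rates <- rates * rep_len(site_rate_multipliers, n_sites)
  if (gamma_sites && !is.null(model$alpha))
    rates <- rates * sample(model$gamma_rates, n_sites, replace = TRUE)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nn, n_sites)
  root <- ntip + 1L
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE, prob = model$pi)
  ur <- unique(rates)
  grp <- match(rates, ur)
  pre <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(pre$edge)))  # reverse postorder = parents first
  for (r in ord) {
    p <- pre$edge[r, 1L]; ch <- pre$edge[r, 2L]; t <- pre$edge.length[r]
    for (g in seq_along(ur)) {
      idx <- which(grp == g)
      if (!length(idx)) next
      P <- transition_matrix(model, t * ur[g])
      ps <- states[p, idx]
      out <- integer(length(idx))
      for (s in 1:4) {
        sel <- ps == s
        if (any(sel))
          out[sel] <- sample.int(4L, sum(sel), replace = TRUE, prob = P[s, ])
      }
      states[ch, idx] <- out
    }
  }
  m <- matrix(bases[states[seq_len(ntip), , drop = FALSE]], ntip, n_sites)
  rownames(m) <- tree$tip.label
  new_alignment(m, codon_frame = n_sites %% 3L == 0L)
}
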