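test_that("delta_lnl is antisymmetric and positive on the generating topology", {
  set.seed(80)
  sp <- ape::rphylo(8, 1, 0)
  sp$edge.length <- sp$edge.length / max(ape::node.depth.edgelength(sp)) * 0.4
  sp <- ape::unroot(sp)
  m <- subst_model()
  aln <- simulate_alignment(sp, m, 600, seed = 81)
  rec <- locus_record("L1", aln, tree = sp)
  fe <- focal_deep_edges(sp, 1)
  row <- delta_lnl(rec, sp, fe, model = m)
  expect_equal(nrow(row), 1L)
  expect_gt(row$delta, 0)
  expect_equal(row$delta_per_base * row$length_bp, row$delta, tolerance = 1e-9)
  # antisymmetry: score the data against the best alternative as reference
  er <- find_edge_by_split(ape::unroot(sp), fe[[1]])
  alts <- nni_neighbors(ape::unroot(sp), er)
  l_ref <- optimize_branch_lengths(aln, ape::unroot(sp), m)$log_likelihood
  l_alts <- vapply(alts, function(a)
    optimize_branch_lengths(aln, a, m)$log_likelihood, 0)
  d_fwd <- l_ref - max(l_alts)
  d_rev <- max(l_alts) - l_ref
  expect_equal(d_fwd, -d_rev)
  expect_equal(row$delta, d_fwd, tolerance = 0.05)
})

test_that("focal edges lost in taxon restriction are skipped", {
  set.seed(82)
  sp <- ape::unroot(ape::rtree(8))
  m <- subst_model()
  aln <- simulate_alignment(sp, m, 120, seed = 83)
  fe <- all_internal_splits(sp)
  small <- fe[[which.min(lengths(fe))]]  # a cherry
  aln2 <- prune_sequence(aln, small[1])  # break that cherry
  rec <- locus_record("L1", aln2, tree = prune_taxon(sp, small[1]))
  rows <- delta_lnl(rec, sp, fe[lengths(fe) == min(lengths(fe))], model = m)
  expect_lt(NROW(rows), sum(lengths(fe) == min(lengths(fe))))
})

test_that("bin_signal summarizes, classifies regimes, and is additive", {
  sig <- data.frame(
    locus = rep(sprintf("L%d", 1:6), each = 2),
    edge = rep(c("e1", "e2"), 6),
    lnl_ref = 0, lnl_best_alt = 0,
    delta = c(3, 1, 2.4, 0.8, 3.6, 1.2, -0.6, 2, -0.4, 1.6, -0.9, 1.8),
    delta_per_base = c(3, 1, 2.4, 0.8, 3.6, 1.2, -0.6, 2, -0.4, 1.6, -0.9, 1.8) / 100,
    length_bp = 100,
    linkage = rep(c("A", "X"), c(6, 6)))
  bs <- bin_signal(sig)
  expect_equal(sum(bs$bins$sum_delta), sum(sig$delta), tolerance = 1e-12)
  r <- bs$regimes
  expect_equal(r$regime[r$edge == "e1"], "discordant")    # A > 0, X < 0
  expect_equal(r$regime[r$edge == "e2"], "concordant_stronger")
  # single-bin input: no regime rows, bins present
  only_a <- sig[sig$linkage == "A", ]
  bs_a <- bin_signal(only_a)
  expect_true(all(bs_a$bins$linkage == "A"))
  expect_equal(NROW(bs_a$regimes), 0L)
})

test_that("NT12 correction strips third positions idempotently", {
  cfg <- sim_config(n_taxa = 8, n_autosomal = 3, n_x = 1, locus_length = 300,
                    seed = 84)
  sim <- simulate_locus_set(cfg)
  nt <- nt12_correction(sim$records)
  expect_true(all(vapply(nt$records, function(r) ncol(r$alignment), 0L) == 200L))
  # a non-codon locus is skipped with a flag
  odd <- sim$records[[1]]
  odd$alignment <- new_alignment(unclass(odd$alignment)[, 1:299, drop = FALSE],
                                 codon_frame = FALSE)
  nt2 <- nt12_correction(list(odd))
  expect_equal(nt2$skipped, odd$id)
  expect_equal(ncol(nt2$records[[1]]$alignment), 299L)
})

test_that("tree distance matrices are symmetric, zero-diagonal, collapse-aware", {
  set.seed(85)
  trees <- lapply(1:6, function(i) ape::rtree(10))
  d <- tree_distance_matrix(trees, support_collapse = NULL)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  ident <- tree_distance_matrix(rep(list(trees[[1]]), 4),
                                support_collapse = NULL)
  expect_true(all(ident == 0))
  # distance after collapsing weak edges cannot exceed the original
  # distance by more than the collapsed weight (here: decreases or equal)
  lab <- trees[[1]]
  lab$node.label <- c("", rep("30", lab$Nnode - 1))
  lab2 <- trees[[2]]
  lab2$node.label <- c("", rep("90", lab2$Nnode - 1))
  d_before <- rf_distance(lab, lab2, weighted = TRUE)
  d_after <- rf_distance(collapse_low_support(lab, 50), lab2, weighted = TRUE)
  collapsed_w <- tree_length(lab) - tree_length(collapse_low_support(lab, 50))
  expect_lte(d_after, d_before + collapsed_w + 1e-9)
})

test_that("PCoA reproduces Euclidean configurations exactly", {
  # three collinear points at 0, 1, 2
  d3 <- as.matrix(dist(c(0, 1, 2)))
  p3 <- pcoa(d3)
  expect_equal(sum(p3$eigenvalues > 1e-9), 1L)
  expect_equal(as.matrix(dist(p3$coords[, 1])), d3, ignore_attr = TRUE,
               tolerance = 1e-9)
  # a random planar configuration embeds exactly in two axes
  set.seed(86)
  xy <- matrix(rnorm(20), 10, 2)
  dd <- as.matrix(dist(xy))
  pp <- pcoa(dd)
  expect_equal(as.matrix(dist(pp$coords[, 1:2])), dd, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_true(all(diff(pp$eigenvalues) < 1e-9))
  z <- pcoa(matrix(0, 4, 4))
  expect_true(all(z$coords == 0))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("grove clustering recovers planted topology clusters", {
  set.seed(87)
  sp <- ape::rphylo(12, 1, 0)
  sp$edge.length <- sp$edge.length / max(ape::node.depth.edgelength(sp)) * 0.5
  topos <- list(ape::unroot(sp))
  for (g in 2:3) {  # planted topologies pairwise well-separated
    repeat {
      cand <- random_nni(topos[[1]], 4)
      if (all(vapply(topos, function(t) rf_distance(t, cand), 0) >= 6)) break
    }
    topos[[g]] <- cand
  }
  trees <- list(); truth <- integer(0)
  for (g in 1:3) for (i in 1:25) {
    tr <- topos[[g]]
    tr$edge.length <- tr$edge.length * exp(rnorm(length(tr$edge.length), 0, 0.15))
    trees[[length(trees) + 1L]] <- tr
    truth <- c(truth, g)
  }
  names(trees) <- sprintf("L%02d", seq_along(trees))
  d <- tree_distance_matrix(trees, support_collapse = NULL, weighted = TRUE)
  ord <- pcoa(d)
  asg <- cluster_groves(ord, k = 3, seed = 88)
  ari <- mclust::adjustedRandIndex(asg$cluster, truth)
  expect_gte(ari, 0.9)
  # determinism and the k = 1 degenerate case
  asg2 <- cluster_groves(ord, k = 3, seed = 88)
  expect_identical(asg$cluster, asg2$cluster)
  one <- cluster_groves(ord, k = 1, seed = 89)
  expect_true(all(one$cluster == 1))
  expect_error(cluster_groves(ord, k = 1000, seed = 1), "exceeds")
})

test_that("grove composition partitions the X count and rounds the rate", {
  cl <- stats::setNames(rep(1:3, c(5, 3, 2)), sprintf("L%02d", 1:10))
  link <- stats::setNames(rep(c("X", "A"), c(2, 8)), sprintf("L%02d", 1:10))
  comp <- grove_composition(cl, link)
  expect_equal(sum(comp$per_grove$n_X), 2L)
  expect_equal(sum(comp$per_grove$n_loci), 10L)
  expect_equal(comp$overall_pct_x, 20)
  # bookkeeping analogue: 145 X loci of 2,286 total reads as 6%
  big <- stats::setNames(rep(1L, 2286), sprintf("g%04d", 1:2286))
  blink <- stats::setNames(rep(c("X", "A"), c(145, 2141)), names(big))
  bc <- grove_composition(big, blink)
  expect_equal(bc$overall_pct_x_rounded, 6)
  expect_equal(bc$per_grove$pct_X[1], 100 * 145 / 2286)
})

test_that("topology space separates the discordant analysis tree", {
  set.seed(90)
  base <- ape::rtree(12)
  near1 <- random_nni(base, 1)
  near2 <- random_nni(base, 1)
  far <- ape::rtree(12)
  far$tip.label <- sample(base$tip.label)
  ts <- topology_space(list(nt = base, aa = near1, ast = near2, x = far))
  co <- ts$coords
  d1 <- as.matrix(dist(co[, 1]))
  expect_equal(rownames(co)[which.max(rowSums(d1))], "x")
  # duplicated analysis trees land on the same spot
  ts2 <- topology_space(list(a = base, b = base, c = far))
  expect_equal(ts2$coords["a", ], ts2$coords["b", ], tolerance = 1e-9,
               ignore_attr = TRUE)
})
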