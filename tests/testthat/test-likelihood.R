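test_that("pruning equals exhaustive state enumeration (4 and 5 taxa)", {
  set.seed(20)
  m <- test_model(k = 3)
  t4 <- ape::read.tree(text = "((A:0.1,B:0.25):0.07,C:0.3,D:0.12);")
  a4 <- simulate_alignment(t4, m, 25, seed = 21)
  expect_equal(tree_log_likelihood(a4, t4, m)$log_likelihood,
               brute_force_lnl(a4, t4, m), tolerance = 1e-8)
  t5 <- ape::unroot(ape::rtree(5))
  a5 <- simulate_alignment(t5, m, 15, seed = 22)
  expect_equal(tree_log_likelihood(a5, t5, m)$log_likelihood,
               brute_force_lnl(a5, t5, m), tolerance = 1e-8)
  # with gaps and N treated as fully ambiguous
  a4[1, 1:5] <- "-"; a4[2, 3:8] <- "N"
  expect_equal(tree_log_likelihood(a4, t4, m)$log_likelihood,
               brute_force_lnl(a4, t4, m), tolerance = 1e-8)
})

test_that("likelihood is invariant to root placement and leaf order", {
  m <- test_model()
  tr <- ape::unroot(ape::rtree(8))
  a <- simulate_alignment(tr, m, 120, seed = 23)
  base <- tree_log_likelihood(a, tr, m)$log_likelihood
  for (tip in c("t2", "t5", "t8")) {
    rr <- ape::root(tr, tip, resolve.root = TRUE)
    rr$edge.length[is.na(rr$edge.length)] <- 0
    expect_equal(tree_log_likelihood(a, rr, m)$log_likelihood, base,
                 tolerance = 1e-8)
  }
  perm <- a[rev(rownames(a)), , drop = FALSE]
  expect_equal(tree_log_likelihood(new_alignment(perm), tr, m)$log_likelihood,
               base, tolerance = 1e-10)
})

test_that("an all-missing taxon marginalizes out exactly", {
  m <- test_model()
  t4 <- ape::read.tree(text = "((A:0.1,B:0.2):0.08,C:0.15,D:0.3);")
  a <- simulate_alignment(t4, m, 60, seed = 24)
  a["D", ] <- "N"
  l_marg <- tree_log_likelihood(a, t4, m)$log_likelihood
  t3 <- prune_taxon(t4, "D")
  l_pruned <- tree_log_likelihood(prune_sequence(a, "D"), t3, m)$log_likelihood
  expect_equal(l_marg, l_pruned, tolerance = 1e-8)
})

test_that("per-site log-likelihoods sum to the total", {
  m <- test_model()
  tr <- ape::unroot(ape::rtree(6))
  a <- simulate_alignment(tr, m, 200, seed = 25)
  res <- tree_log_likelihood(a, tr, m)
  expect_length(res$per_site, 200L)
  expect_equal(sum(res$per_site), res$log_likelihood, tolerance = 1e-8)
})

test_that("pruning matches an independent implementation (phangorn)", {
  m <- test_model()
  tr <- ape::unroot(ape::rtree(9))
  a <- simulate_alignment(tr, m, 300, seed = 26)
  fit <- phangorn::pml(tr, phangorn::phyDat(unclass(a), type = "DNA"),
                       bf = m$pi, Q = m$rates, shape = m$alpha, k = m$k)
  expect_equal(tree_log_likelihood(a, tr, m)$log_likelihood, fit$logLik,
               tolerance = 1e-6)
})

test_that("edge-local likelihoods equal the global likelihood at every edge", {
  # the optimizer's edge-local objective must be the exact lnL
  m <- test_model()
  tr <- ape::unroot(ape::rtree(7))
  a <- simulate_alignment(tr, m, 150, seed = 27)
  pr <- phyloconflict:::prep_likelihood(a, tr, m)
  args <- list(pr$tree$edge, pr$tree$edge.length, length(pr$tree$tip.label),
               pr$pat$codes, pr$pat$weights, m$pi, m$U, m$Uinv, m$lambda,
               pr$gr)
  full <- do.call(phyloconflict:::.cpp_tree_loglik, args)$loglik
  per_edge <- do.call(phyloconflict:::.cpp_edge_lnl_check, args)
  expect_equal(per_edge, rep(full, nrow(pr$tree$edge)), tolerance = 1e-9)
})

test_that("branch-length optimization recovers generating lengths", {
  set.seed(27)
  tr <- ape::unroot(ape::rtree(8))
  tr$edge.length[] <- 0.1
  m <- subst_model()
  a <- simulate_alignment(tr, m, 10000, seed = 28)
  start <- tr; start$edge.length[] <- 0.02
  o <- optimize_branch_lengths(a, start, m)
  po <- ape::reorder.phylo(tr, "postorder")
  expect_lt(max(abs(o$tree$edge.length - po$edge.length)), 0.03)
  # optimized lnL is at least the generating-lengths lnL
  expect_gte(o$log_likelihood,
             tree_log_likelihood(a, tr, m)$log_likelihood - 1e-6)
})

test_that("optimized reference beats its NNI neighbors on simulated data", {
  set.seed(29)
  m <- subst_model()
  wins <- 0L
  n_rep <- 12L
  for (i in seq_len(n_rep)) {
    tr <- ape::unroot(ape::rtree(7))
    tr$edge.length <- pmax(tr$edge.length * 0.3, 0.03)
    a <- simulate_alignment(tr, m, 500)
    lref <- optimize_branch_lengths(a, tr, m)$log_likelihood
    lalt <- max(vapply(nni_neighbors(tr), function(x)
      optimize_branch_lengths(a, x, m)$log_likelihood, 0))
    if (lref >= lalt - 1e-6) wins <- wins + 1L
  }
  expect_gte(wins, round(0.9 * n_rep))
})

test_that("degenerate all-identical data drives lengths to the floor", {
  a <- new_alignment(rbind(A = rep("A", 30), B = rep("A", 30),
                           C = rep("A", 30), D = rep("A", 30)))
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,C:0.1,D:0.1);")
  o <- optimize_branch_lengths(a, tr, jc_model())
  expect_true(all(o$tree$edge.length < 1e-4))
})

test_that("pairwise distances: closed forms, saturation, recovery", {
  a <- new_alignment(rbind(A = rep(c("A", "C"), c(85, 15)), B = rep("A", 100)),
                     codon_frame = FALSE)
  expect_equal(pairwise_distance(a, "A", "B", "JC"), -0.75 * log(0.8),
               tolerance = 1e-5)
  expect_equal(pairwise_distance(a, "A", "A", "JC"), 0)
  expect_equal(pairwise_distance(a, "A", "A", "GTR"), 0)
  sat <- new_alignment(rbind(A = rep(c("A", "C", "G", "T"), 25),
                             B = rep(c("C", "G", "T", "A"), 25)),
                       codon_frame = FALSE)
  d <- pairwise_distance(sat, "A", "B", "JC")
  expect_true(is.infinite(d) && isTRUE(attr(d, "saturated")))
  # ML GTR distance recovers the simulation separation at 10 kb
  m <- subst_model(pi = c(0.3, 0.2, 0.2, 0.3), rates = c(1.5, 3, 1, 1, 3, 1))
  two <- ape::read.tree(text = "(A:0.1,B:0.1);")
  big <- simulate_alignment(two, m, 10000, seed = 30)
  expect_equal(pairwise_distance(big, "A", "B", "GTR"), 0.2, tolerance = 0.02)
})

test_that("distance estimation is consistent as sites grow", {
  m <- jc_model()
  two <- ape::read.tree(text = "(A:0.15,B:0.15);")
  err <- vapply(c(1000, 10000, 100000), function(n) {
    a <- simulate_alignment(two, m, n, seed = 31 + n)
    abs(pairwise_distance(a, "A", "B", "JC") - 0.3)
  }, 0)
  expect_lt(err[3], 0.01)
  expect_lt(err[3], err[1] + 0.01)
})

test_that("simulation: determinism, zero-length trees, expected p-distance", {
  m <- test_model()
  tr <- ape::unroot(ape::rtree(6))
  a1 <- simulate_alignment(tr, m, 100, seed = 32)
  a2 <- simulate_alignment(tr, m, 100, seed = 32)
  expect_identical(unclass(a1), unclass(a2))
  z <- tr; z$edge.length[] <- 0
  az <- simulate_alignment(z, m, 50, seed = 33)
  expect_true(all(apply(unclass(az), 2, function(col) length(unique(col)) == 1)))
  # expected JC p-distance at separation d, within 3 binomial SE at 10 kb
  d <- 0.4
  two <- ape::read.tree(text = sprintf("(A:%f,B:%f);", d / 2, d / 2))
  aj <- simulate_alignment(two, jc_model(), 10000, seed = 34)
  p_obs <- mean(unclass(aj)["A", ] != unclass(aj)["B", ])
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))
})

test_that("fitted models recover generating parameters approximately", {
  set.seed(35)
  m <- subst_model(pi = c(0.3, 0.2, 0.2, 0.3), rates = c(1, 4, 1, 1, 4, 1),
                   alpha = 0.5, k = 4)
  tr <- ape::unroot(ape::rtree(10))
  tr$edge.length <- pmax(tr$edge.length * 0.4, 0.02)
  a <- simulate_alignment(tr, m, 2000, gamma_sites = TRUE, seed = 36)
  f <- fit_model(a, tr)
  # transition/transversion structure recovered
  expect_gt(f$rates[2] / f$rates[1], 2)
  expect_gt(f$rates[5] / f$rates[4], 2)
  expect_lt(abs(f$alpha - 0.5) / 0.5, 1)
})
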