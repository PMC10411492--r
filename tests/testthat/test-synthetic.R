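test_that("species tree simulation is seeded, ultrametric, height 1", {
  cfg <- sim_config(seed = 100)
  t1 <- simulate_species_tree(cfg)
  t2 <- simulate_species_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), cfg$n_taxa)
  depths <- ape::node.depth.edgelength(t1)[seq_len(cfg$n_taxa)]
  expect_true(all(abs(depths - 1) < 1e-9))
  t3 <- simulate_species_tree(sim_config(seed = 101))
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
})

test_that("locus sets carry complete truth tables and planted artifacts", {
  cfg <- sim_config(n_taxa = 10, n_autosomal = 12, n_x = 3,
                    locus_length = 300, contamination_n = 2,
                    long_branch_n = 2, seed = 102)
  sim <- simulate_locus_set(cfg)
  expect_length(sim$records, 15L)
  expect_equal(nrow(sim$truth$linkage), 15L)
  expect_equal(sum(sim$truth$linkage$linkage == "X"), 3L)
  expect_equal(nrow(sim$truth$contaminants), 2L)
  expect_equal(nrow(sim$truth$long_branches), 2L)
  # contaminated alignments really contain the copied sequence
  for (i in seq_len(nrow(sim$truth$contaminants))) {
    tc <- sim$truth$contaminants[i, ]
    rec <- sim$records[[match(tc$locus, vapply(sim$records, `[[`, "", "id"))]]
    # identical up to missingness masking applied after the copy
    a <- unclass(rec$alignment)[tc$recipient, ]
    b <- unclass(rec$alignment)[tc$donor, ]
    ok <- a != "N" & b != "N"
    expect_identical(a[ok], b[ok])
    expect_gt(sum(ok), 0L)
    # and the gene tree shows them as sisters
    expect_equal(rf_distance(rec$tree, graft_sister(sim$species_tree,
                                                    tc$recipient, tc$donor)), 0)
  }
  # long-branch loci have the inflated terminal edge
  for (i in seq_len(nrow(sim$truth$long_branches))) {
    tl <- sim$truth$long_branches[i, ]
    rec <- sim$records[[match(tl$locus, vapply(sim$records, `[[`, "", "id"))]]
    er <- which(rec$tree$edge[, 2] == match(tl$taxon, rec$tree$tip.label))
    expect_gt(rec$tree$edge.length[er], 10 * mean(rec$tree$edge.length))
  }
  # determinism
  sim2 <- simulate_locus_set(cfg)
  expect_identical(unclass(sim2$records[[5]]$alignment),
                   unclass(sim$records[[5]]$alignment))
})

test_that("X loci evolve about x_rate times faster than autosomal loci", {
  cfg <- sim_config(n_taxa = 10, n_autosomal = 60, n_x = 40,
                    locus_length = 150, seed = 103)
  sim <- simulate_locus_set(cfg)
  tl <- vapply(sim$records, function(r) tree_length(r$tree), 0)
  lk <- vapply(sim$records, `[[`, "", "linkage")
  ratio <- mean(tl[lk == "X"]) / mean(tl[lk == "A"])
  expect_lt(abs(ratio - cfg$x_rate), 0.15 * cfg$x_rate)
})

test_that("zero topology noise with one grove gives identical gene trees", {
  cfg <- sim_config(n_taxa = 8, n_autosomal = 5, n_x = 0, locus_length = 150,
                    n_groves = 1, locus_nni = 0, seed = 104)
  sim <- simulate_locus_set(cfg)
  for (r in sim$records)
    expect_equal(rf_distance(r$tree, sim$species_tree), 0)
})

test_that("male X missingness is planted only where recorded", {
  cfg <- sim_config(n_taxa = 10, n_autosomal = 5, n_x = 10,
                    locus_length = 300, male_x_missing = 0.6, seed = 105)
  sim <- simulate_locus_set(cfg)
  expect_gt(nrow(sim$truth$missing), 0L)
  for (i in seq_len(nrow(sim$truth$missing))) {
    tm <- sim$truth$missing[i, ]
    rec <- sim$records[[match(tm$locus, vapply(sim$records, `[[`, "", "id"))]]
    expect_gt(mean(unclass(rec$alignment)[tm$taxon, ] == "N"), 0.4)
    expect_equal(sim$sex[[tm$taxon]], "male")
    expect_equal(rec$linkage, "X")
  }
})

test_that("coverage simulation halves male X depth in expectation", {
  cfg <- sim_config(n_taxa = 20, seed = 106)
  link <- stats::setNames(rep(c("A", "X"), c(30, 70)), sprintf("L%03d", 1:100))
  sex <- stats::setNames(rep(c("male", "female"), 10), sprintf("s%02d", 1:20))
  cov <- simulate_coverage(cfg, link, sex)
  mx <- cov$depth[link == "X", sex == "male"]      # 700 male-X cells
  exp_mean <- cfg$depth_mean * cfg$male_x_depth_ratio
  se <- sqrt(exp_mean * (1 + exp_mean / cfg$depth_dispersion) / length(mx))
  expect_lt(abs(mean(mx) - exp_mean), 3 * se)
  # female depths unaffected by X status
  fx <- mean(cov$depth[link == "X", sex == "female"])
  fa <- mean(cov$depth[link == "A", sex == "female"])
  expect_equal(fx / fa, 1, tolerance = 0.1)
  cov2 <- simulate_coverage(cfg, link, sex)
  expect_identical(cov$depth, cov2$depth)
})

test_that("fixture directories are complete and re-readable", {
  cfg <- sim_config(n_taxa = 6, n_autosomal = 3, n_x = 1, locus_length = 150,
                    seed = 107)
  sim <- simulate_locus_set(cfg)
  link <- stats::setNames(sim$truth$linkage$linkage, sim$truth$linkage$locus)
  cov <- simulate_coverage(cfg, link, sim$sex)
  dir <- withr::local_tempdir()
  write_fixture_dir(sim, dir, coverage = cov)
  expect_length(list.files(file.path(dir, "loci")), 4L)
  aln <- read_fasta(file.path(dir, "loci", "L0001.fasta"))
  expect_identical(unclass(aln), unclass(sim$records[[1]]$alignment))
  trees <- read_newick(file.path(dir, "genetrees.nwk"))
  expect_length(trees, 4L)
  sp <- read_newick(file.path(dir, "species_tree.nwk"))
  expect_equal(rf_distance(sp, sim$species_tree), 0)
  back <- read_coverage(file.path(dir, "coverage"))
  expect_equal(back$depth, cov$depth)
  cfg_back <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg_back$seed, 107)
  expect_true(file.exists(file.path(dir, "truth", "linkage.tsv")))
})

test_that("manifests capture seed, config, and checksums for reruns", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "out.tsv")
  writeLines("a\t1", f)
  mp <- file.path(dir, "manifest.json")
  write_manifest(mp, seed = 42, config = sim_config(seed = 42), files = f)
  m <- jsonlite::read_json(mp)
  expect_equal(m$seed, 42)
  expect_equal(m$config$n_taxa, 16)
  expect_equal(m$checksums[[f]], unname(as.character(tools::md5sum(f))))
})
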