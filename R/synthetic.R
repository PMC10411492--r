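#' Configuration for the synthetic faster-X data generator
#'
#' Defaults define the `faster_x_demo` preset: 16 taxa, 200 autosomal plus
#' 15 X-linked loci (about 7% X, matching the few-percent X fraction
#' typical of arthropod phylogenomic locus sets), 600 bp codon-structured
#' loci, X loci with a 3-fold overall rate elevation, fast third codon
#' positions (5-fold autosomal, 20-fold on X, where hemizygous exposure
#' and saturation are strongest), halved male X read depth, and male-X
#' missingness enrichment.
#'
#' @param n_taxa number of taxa (>= 4).
#' @param n_autosomal,n_x locus counts per linkage class.
#' @param locus_length locus length in bp (rounded up to a codon multiple).
#' @param birth,death birth-death rates for the species tree.
#' @param base_rate expected substitutions per site per unit tree height
#'   for autosomal loci (default 0.3, giving concatenation-scale pairwise
#'   distances of a few tenths, as in deep arthropod phylogenomic data).
#' @param x_rate overall branch-rate multiplier of X loci.
#' @param pos3_rate third-codon-position rate multiplier, named vector with
#'   entries `A` and `X`.
#' @param n_groves number of planted gene-tree clusters (grove 1 is the
#'   species tree itself).
#' @param grove_props mixing proportions over groves (sum to 1).
#' @param grove_nni NNI moves separating each non-reference grove topology
#'   from the species tree.
#' @param locus_nni per-locus NNI noise moves applied to the grove topology.
#' @param brlen_jitter lognormal sd of per-edge branch-length jitter.
#' @param contamination_n number of loci receiving an injected
#'   cross-contaminant (donor sequence copied over a distant recipient).
#' @param long_branch_n number of loci receiving a long-branch paralog
#'   (terminal branch multiplied by `long_branch_scale`).
#' @param long_branch_scale terminal-branch multiplier for paralog injection.
#' @param male_x_depth_ratio male:female depth ratio at X loci (0.5 for a
#'   hemizygous X).
#' @param depth_mean,depth_dispersion negative-binomial read-depth model
#'   (mean autosomal depth; `size` dispersion).
#' @param male_x_missing probability that a male sequence at an X locus is
#'   partially masked to `N`.
#' @param missing_frac fraction of sites masked when missingness fires.
#' @param model generation `subst_model` (default: uneven frequencies and
#'   transition-biased exchangeabilities).
#' @param seed integer seed (mandatory).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 16L, n_autosomal = 200L, n_x = 15L,
                       locus_length = 600L, birth = 1, death = 0,
                       base_rate = 0.3,
                       x_rate = 3, pos3_rate = c(A = 5, X = 20),
                       n_groves = 1L, grove_props = NULL, grove_nni = 3L,
                       locus_nni = 0L, brlen_jitter = 0.25,
                       contamination_n = 0L, long_branch_n = 0L,
                       long_branch_scale = 60,
                       male_x_depth_ratio = 0.5, depth_mean = 120,
                       depth_dispersion = 50, male_x_missing = 0.2,
                       missing_frac = 0.5,
                       model = subst_model(pi = c(0.3, 0.2, 0.2, 0.3),
                                           rates = c(1.5, 4, 1, 1, 4, 1)),
                       seed) {
  if (missing(seed)) stop("input error: seed is mandatory")
  if (is.null(grove_props)) grove_props <- rep(1 / n_groves, n_groves)
  if (length(grove_props) != n_groves || abs(sum(grove_props) - 1) > 1e-8)
    stop("input error: grove proportions must sum to 1")
  stopifnot(n_taxa >= 4L, x_rate > 0, all(pos3_rate > 0))
  locus_length <- as.integer(3L * ceiling(locus_length / 3L))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric species tree of height 1
#'
#' Birth-death tree rescaled so every root-to-tip path length is exactly 1
#' (tree height doubles as the time axis for informativeness epochs).
#'
#' @param config a `sim_config`.
#' @return ultrametric `phylo` with `config$n_taxa` tips `t1..tn`.
#' @export
simulate_species_tree <- function(config) {
  set.seed(config$seed)
  tr <- ape::rphylo(config$n_taxa, birth = config$birth, death = config$death)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("t%02d", seq_len(config$n_taxa))
  tr
}

#' Apply random NNI moves to a tree
#'
#' Each move picks an internal edge uniformly and one of its two
#' nearest-neighbor-interchange rearrangements; used to plant topology
#' noise and grove structure.
#'
#' @param tree an unrooted binary `phylo`.
#' @param n_moves number of successive moves.
#' @return a `phylo`.
#' @export
random_nni <- function(tree, n_moves = 1L) {
  for (i in seq_len(n_moves)) {
    tree <- ape::unroot(tree)
    rows <- internal_edge_rows(tree)
    if (!length(rows)) break
    nb <- nni_at_edge(tree, sample(rows, 1L))
    tree <- nb[[sample.int(2L, 1L)]]
  }
  tree
}

#' Simulate a full locus set with planted structure
#'
#' Per locus: a grove topology is drawn by the mixing proportions, NNI
#' noise and lognormal branch jitter are applied, branches are scaled by
#' the linkage rate multiplier, and a codon-structured alignment is
#' simulated with fast third positions. Configured artifacts
#' (cross-contaminants: a donor sequence copied over a distant recipient;
#' long-branch paralogs: an inflated terminal branch; male-X missingness)
#' are injected and recorded in truth tables.
#'
#' @param config a `sim_config`.
#' @return list with `records` (list of `locus_record`), `species_tree`,
#'   `sex` (named vector per taxon), `truth` (data frames: `linkage`,
#'   `grove`, `contaminants`, `long_branches`, `missing`), and `config`.
#' @export
simulate_locus_set <- function(config) {
  sp <- simulate_species_tree(config)
  set.seed(config$seed + 1L)
  n_loci <- config$n_autosomal + config$n_x
  ids <- sprintf("L%04d", seq_len(n_loci))
  linkage <- sample(rep(c("A", "X"), c(config$n_autosomal, config$n_x)))
  sex <- stats::setNames(rep(c("male", "female"), length.out = config$n_taxa),
                         sp$tip.label)
  groves <- list(ape::unroot(sp))
  if (config$n_groves > 1L)
    for (g in 2:config$n_groves)
      groves[[g]] <- random_nni(sp, config$grove_nni)
  grove_of <- sample.int(config$n_groves, n_loci, replace = TRUE,
                         prob = config$grove_props)
  contam_loci <- if (config$contamination_n > 0)
    sample(n_loci, min(config$contamination_n, n_loci)) else integer(0)
  lb_loci <- if (config$long_branch_n > 0)
    sample(setdiff(seq_len(n_loci), contam_loci),
           min(config$long_branch_n, n_loci)) else integer(0)
  contam <- lb <- miss <- NULL
  records <- vector("list", n_loci)
  males <- names(sex)[sex == "male"]
  for (i in seq_len(n_loci)) {
    tr <- groves[[grove_of[i]]]
    if (config$locus_nni > 0L) tr <- random_nni(tr, config$locus_nni)
    tr$edge.length <- tr$edge.length * config$base_rate *
      exp(stats::rnorm(length(tr$edge.length), 0, config$brlen_jitter))
    if (linkage[i] == "X") tr$edge.length <- tr$edge.length * config$x_rate
    lb_taxon <- NULL
    if (i %in% lb_loci) {
      lb_taxon <- sample(tr$tip.label, 1L)
      er <- which(tr$edge[, 2L] == match(lb_taxon, tr$tip.label))
      # a paralog diverges on the gene-family time scale, not the terminal
      # branch's: set the terminal to scale x the mean edge length
      tr$edge.length[er] <- config$long_branch_scale * mean(tr$edge.length)
      lb <- rbind(lb, data.frame(locus = ids[i], taxon = lb_taxon,
                                 scale = config$long_branch_scale))
    }
    pos3 <- unname(config$pos3_rate[linkage[i]])
    aln <- simulate_alignment(tr, config$model, config$locus_length,
                              site_rate_multipliers = c(1, 1, pos3))
    if (i %in% contam_loci) {
      cand <- distant_pair(sp)
      aln[cand["recipient"], ] <- unclass(aln)[cand["donor"], ]
      # the gene tree a tree-estimation step would see: the recipient's
      # copied sequence places it as the donor's sister
      tr <- graft_sister(tr, cand[["recipient"]], cand[["donor"]])
      contam <- rbind(contam, data.frame(locus = ids[i],
                                         donor = cand[["donor"]],
                                         recipient = cand[["recipient"]]))
    }
    if (linkage[i] == "X" && config$male_x_missing > 0) {
      for (tx in males) {
        if (stats::runif(1) < config$male_x_missing) {
          cols <- sample(ncol(aln), round(config$missing_frac * ncol(aln)))
          aln[tx, cols] <- "N"
          miss <- rbind(miss, data.frame(locus = ids[i], taxon = tx))
        }
      }
    }
    rec <- locus_record(ids[i], aln, tree = tr, linkage = linkage[i])
    rec$grove <- grove_of[i]
    records[[i]] <- rec
  }
  list(records = records, species_tree = sp, sex = sex,
       truth = list(
         linkage = data.frame(locus = ids, linkage = linkage),
         grove = data.frame(locus = ids, grove = grove_of),
         contaminants = contam, long_branches = lb, missing = miss),
       config = config)
}

# a taxon pair far apart on the species tree (top quartile of patristic
# distances): donor -> recipient contamination between relatives would be
# invisible to the concatenation screen, as in real cross-contamination
distant_pair <- function(species_tree) {
  pat <- ape::cophenetic.phylo(species_tree)
  thr <- stats::quantile(pat[upper.tri(pat)], 0.75)
  cand <- which(pat >= thr & upper.tri(pat), arr.ind = TRUE)
  pick <- cand[sample(nrow(cand), 1L), ]
  c(donor = rownames(pat)[pick[1]], recipient = colnames(pat)[pick[2]])
}

#' Simulate a read-depth coverage table
#'
#' Depth is negative binomial with mean `depth_mean`, halved (by
#' `male_x_depth_ratio`) for male samples at X loci.
#'
#' @param config a `sim_config`.
#' @param linkage named character vector of true linkage per locus.
#' @param sex named character vector per sample.
#' @return a `coverage_table`.
#' @export
simulate_coverage <- function(config, linkage, sex) {
  set.seed(config$seed + 2L)
  loci <- names(linkage)
  samples <- names(sex)
  mu <- outer(ifelse(linkage == "X", 1, 1), ifelse(sex == "male", 1, 1)) *
    config$depth_mean
  isx <- linkage == "X"
  ism <- sex == "male"
  mu[isx, ism] <- mu[isx, ism] * config$male_x_depth_ratio
  depth <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = config$depth_dispersion),
                  nrow = length(loci),
                  dimnames = list(loci, samples))
  coverage_table(depth, sex, linkage)
}

#' Write a simulated fixture directory
#'
#' Layout: `loci/*.fasta`, `genetrees.nwk`, `species_tree.nwk`,
#' `coverage.tsv` (+ `_sex`/`_linkage` companions), `truth/*.tsv`,
#' `config.json`.
#'
#' @param sim result of [simulate_locus_set()].
#' @param dir output directory (created).
#' @param coverage optional `coverage_table` to include.
#' @export
write_fixture_dir <- function(sim, dir, coverage = NULL) {
  dir.create(file.path(dir, "loci"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (r in sim$records)
    write_fasta(r$alignment, file.path(dir, "loci", paste0(r$id, ".fasta")))
  trees <- lapply(sim$records, `[[`, "tree")
  class(trees) <- "multiPhylo"
  names(trees) <- vapply(sim$records, `[[`, "", "id")
  ape::write.tree(trees, file.path(dir, "genetrees.nwk"), digits = 12,
                  tree.names = TRUE)
  write_newick(sim$species_tree, file.path(dir, "species_tree.nwk"))
  for (nm in names(sim$truth))
    if (!is.null(sim$truth[[nm]]))
      utils::write.table(sim$truth[[nm]], file.path(dir, "truth",
                                                    paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(coverage)) write_coverage(coverage, file.path(dir, "coverage"))
  cfg <- sim$config
  cfg$model <- list(pi = cfg$model$pi, rates = cfg$model$rates,
                    alpha = cfg$model$alpha, k = cfg$model$k)
  jsonlite::write_json(cfg[setdiff(names(cfg), "")],
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(dir)
}
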