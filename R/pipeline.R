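#' Deep, resolvable focal edges of a species tree
#'
#' Depth proxy: the size of the smaller side of the bipartition (deep
#' backbone edges split the taxon set most evenly). Among edges whose
#' smaller side holds at least `min_side_frac` of the taxa, edges are
#' ranked by branch length: a near-zero-length deep edge carries no
#' resolvable signal for any data subset, so the longest deep edges are
#' where conflict between subsets is measurable.
#'
#' @param species_tree a `phylo`.
#' @param n number of edges to return.
#' @param min_side_frac minimum fraction of taxa on the split's smaller
#'   side for an edge to count as deep (default 0.25).
#' @return named list of splits (one side each), best first.
#' @export
focal_deep_edges <- function(species_tree, n = 2L, min_side_frac = 0.25) {
  weights <- tree_splits(ape::unroot(species_tree))
  sp <- all_internal_splits(species_tree)
  ntax <- length(ape::unroot(species_tree)$tip.label)
  depth <- vapply(sp, function(s) min(length(s), ntax - length(s)), 0)
  deep <- depth >= max(2, ceiling(min_side_frac * ntax))
  if (!any(deep)) deep <- depth >= max(depth)
  cand <- sp[deep]
  w <- weights[names(cand)]
  cand[order(w, decreasing = TRUE)][seq_len(min(n, length(cand)))]
}

#' Signal analysis before and after third-position exclusion
#'
#' Runs the per-locus likelihood-signal analysis on the full nucleotide
#' data and again after NT12 correction (per-locus models refitted on the
#' corrected alignments), and returns the per-edge linkage-bin summaries
#' of both runs.
#'
#' @param records list of `locus_record`.
#' @param species_tree reference `phylo`.
#' @param focal_edges named list of splits (default: the two deepest edges).
#' @param ... passed to [signal_table()].
#' @return list with `pre` and `post` (each: `signal`, `bins`, `regimes`).
#' @export
signal_with_nt12 <- function(records, species_tree, focal_edges = NULL, ...) {
  if (is.null(focal_edges)) focal_edges <- focal_deep_edges(species_tree, 2L)
  pre_sig <- signal_table(records, species_tree, focal_edges, ...)
  pre <- bin_signal(pre_sig)
  nt12 <- nt12_correction(records)
  post_sig <- signal_table(nt12$records, species_tree, focal_edges, ...)
  post <- bin_signal(post_sig)
  list(pre = c(list(signal = pre_sig), pre),
       post = c(list(signal = post_sig), post),
       focal_edges = focal_edges, nt12_skipped = nt12$skipped)
}

#' Grove clustering of a locus set's gene trees
#'
#' Collapse at the support threshold, pairwise weighted RF, PCoA, k-means
#' groves, and linkage composition.
#'
#' @param records list of `locus_record` with gene trees.
#' @param k number of groves.
#' @param seed clustering seed.
#' @param support_collapse collapse threshold (percent; `NULL` to skip).
#' @param weighted weighted RF (default TRUE).
#' @return list with `assignment` (a `grove_assignment`), `composition`,
#'   `ordination`, and `dist` (the tree distance matrix).
#' @export
grove_analysis <- function(records, k, seed, support_collapse = 50,
                           weighted = TRUE) {
  trees <- lapply(records, `[[`, "tree")
  names(trees) <- vapply(records, `[[`, "", "id")
  keep <- !vapply(trees, is.null, TRUE)
  d <- tree_distance_matrix(trees[keep], support_collapse = support_collapse,
                            weighted = weighted)
  ord <- pcoa(d)
  asg <- cluster_groves(ord, k = k, seed = seed)
  linkage <- stats::setNames(vapply(records, `[[`, "", "linkage"),
                             vapply(records, `[[`, "", "id"))
  comp <- grove_composition(asg, linkage)
  list(assignment = asg, composition = comp, ordination = ord, dist = d)
}

#' Write a small reproducibility manifest
#'
#' Records the seed, the generator configuration, and md5 checksums of the
#' stage outputs, so a rerun can be checked for byte-identity.
#'
#' @param path output JSON path.
#' @param seed master seed.
#' @param config a `sim_config` (or any list; models are reduced to their
#'   parameters).
#' @param files character vector of produced files to checksum.
#' @export
write_manifest <- function(path, seed, config = NULL, files = character(0)) {
  cfg <- NULL
  if (!is.null(config)) {
    cfg <- unclass(config)
    if (!is.null(cfg$model))
      cfg$model <- list(pi = cfg$model$pi, rates = cfg$model$rates,
                        alpha = cfg$model$alpha, k = cfg$model$k)
  }
  files <- files[file.exists(files)]
  jsonlite::write_json(list(
    tool = "phyloconflict",
    version = as.character(utils::packageVersion("phyloconflict")),
    seed = seed, config = cfg,
    checksums = as.list(tools::md5sum(files))),
    path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Concatenation-wide GTR distance matrix for a locus set
#'
#' Concatenates the loci and computes pairwise GTR distances on the
#' supermatrix; the result feeds the contamination screen.
#'
#' @param records list of `locus_record`.
#' @return symmetric distance matrix over all taxa.
#' @export
concat_distances <- function(records) {
  cat_res <- concatenate_loci(stats::setNames(
    lapply(records, `[[`, "alignment"),
    vapply(records, `[[`, "", "id")))
  distance_matrix(cat_res$alignment, family = "GTR")
}
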