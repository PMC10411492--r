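#' Bundle one locus: alignment, gene tree, linkage label, QC history
#'
#' @param id locus identifier.
#' @param alignment a `dna_alignment`.
#' @param tree the locus gene tree (`phylo`), or `NULL`.
#' @param linkage `"A"` (autosomal), `"X"`, or `"unknown"`.
#' @return an object of class `locus_record`.
#' @export
locus_record <- function(id, alignment, tree = NULL,
                         linkage = c("unknown", "A", "X")) {
  linkage <- match.arg(linkage)
  structure(list(id = id, alignment = alignment, tree = tree,
                 linkage = linkage,
                 removed = empty_actions(), degenerate = FALSE),
            class = "locus_record")
}

#' @export
print.locus_record <- function(x, ...) {
  cat(sprintf("<locus_record> %s: %d taxa x %d bp, linkage %s, %d removals\n",
              x$id, nrow(x$alignment), ncol(x$alignment), x$linkage,
              nrow(x$removed)))
  invisible(x)
}

empty_actions <- function() {
  data.frame(locus = character(), taxon = character(), rule = character(),
              evidence = character(), stringsAsFactors = FALSE)
}

# Remove taxa from both the alignment and the gene tree, recording why.
apply_removals <- function(record, taxa, rule, evidence) {
  taxa <- intersect(taxa, rownames(record$alignment))
  if (!length(taxa)) return(record)
  record$alignment <- prune_sequence(record$alignment, taxa)
  if (!is.null(record$tree)) {
    keep <- setdiff(record$tree$tip.label, taxa)
    if (length(keep) < 3L) {
      record$degenerate <- TRUE
      record$tree <- NULL
    } else {
      record$tree <- prune_taxon(record$tree, intersect(record$tree$tip.label, taxa))
    }
  }
  if (!is.null(record$dist_cache)) {
    keep <- setdiff(rownames(record$dist_cache), taxa)
    record$dist_cache <- record$dist_cache[keep, keep, drop = FALSE]
  }
  if (nrow(record$alignment) < 4L) record$degenerate <- TRUE
  record$removed <- rbind(record$removed,
                          data.frame(locus = record$id, taxon = taxa,
                                     rule = rule, evidence = evidence,
                                     stringsAsFactors = FALSE))
  record
}

#' Remove excessively long terminal branches (likely paralogs)
#'
#' A terminal taxon is removed when its terminal branch exceeds
#' `factor` times the mean length over all edges of the gene tree (the
#' candidate edge included in the mean). Removal changes the mean, so the
#' rule is iterated to a fixed point.
#'
#' @param record a `locus_record` with a gene tree carrying branch lengths.
#' @param factor multiplier over the mean edge length (default 50).
#' @return the updated `locus_record`; removals appear in `$removed`.
#' @export
filter_long_branches <- function(record, factor = 50) {
  repeat {
    tr <- record$tree
    if (is.null(tr) || is.null(tr$edge.length) || record$degenerate) break
    ntip <- length(tr$tip.label)
    mean_edge <- mean(tr$edge.length)
    term <- tr$edge[, 2L] <= ntip
    bad <- which(term & tr$edge.length > factor * mean_edge)
    if (!length(bad)) break
    taxa <- tr$tip.label[tr$edge[bad, 2L]]
    ev <- sprintf("terminal=%.6g mean=%.6g factor=%g",
                  tr$edge.length[bad], mean_edge, factor)
    record <- apply_removals(record, taxa, "long_branch", ev)
  }
  record
}

#' Detect and remove cross-contaminant sequences
#'
#' Suspect pairs show an unexpectedly small within-locus GTR distance
#' (`< d_locus_max`) although their concatenation-wide distance is large
#' (`> d_concat_min`). For each suspect pair, each terminal is dropped in
#' turn and the RF distance of the reduced gene tree to the equally reduced
#' species tree is compared: the drop giving the strictly smaller RF
#' identifies the contaminant (removed; the donor is kept); equal RF
#' removes both. Multi-taxon suspect groups are handled pairwise in
#' alphabetical taxon order.
#'
#' @param record a `locus_record` with a gene tree.
#' @param concat_distances symmetric matrix of pairwise GTR distances on
#'   the concatenated supermatrix (taxon-named).
#' @param species_tree reference `phylo`.
#' @param d_locus_max within-locus distance threshold (default 0.01).
#' @param d_concat_min concatenation distance threshold (default 0.2).
#' @param locus_distances optional precomputed within-locus GTR distance
#'   matrix (computed when `NULL`).
#' @return updated `locus_record`.
#' @export
detect_contamination <- function(record, concat_distances, species_tree,
                                 d_locus_max = 0.01, d_concat_min = 0.2,
                                 locus_distances = NULL) {
  if (is.null(record$tree) || record$degenerate) return(record)
  if (is.null(locus_distances)) {
    if (is.null(record$dist_cache))
      record$dist_cache <- distance_matrix(record$alignment, family = "GTR")
    locus_distances <- record$dist_cache
  }
  taxa <- sort(rownames(record$alignment))
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (j <= i) next
    a <- taxa[i]; b <- taxa[j]
    if (!a %in% rownames(record$alignment) ||
        !b %in% rownames(record$alignment)) next
    if (!a %in% rownames(locus_distances) || !b %in% rownames(locus_distances)) next
    if (!a %in% rownames(concat_distances) || !b %in% rownames(concat_distances)) {
      warning("pair not in concatenation distance table: ", a, " / ", b)
      next
    }
    dl <- locus_distances[a, b]
    dc <- concat_distances[a, b]
    if (is.na(dl) || is.na(dc) || dl >= d_locus_max || dc <= d_concat_min) next
    if (!all(c(a, b) %in% record$tree$tip.label)) next
    rf_a <- tryCatch(rf_distance(prune_taxon(record$tree, a),
                                 species_tree), error = function(e) NA)
    rf_b <- tryCatch(rf_distance(prune_taxon(record$tree, b),
                                 species_tree), error = function(e) NA)
    if (is.na(rf_a) || is.na(rf_b)) next
    ev <- sprintf("d_locus=%.4g d_concat=%.4g rf_drop_a=%d rf_drop_b=%d",
                  dl, dc, rf_a, rf_b)
    if (rf_a < rf_b) {
      record <- apply_removals(record, a, "contamination", ev)
    } else if (rf_b < rf_a) {
      record <- apply_removals(record, b, "contamination", ev)
    } else {
      record <- apply_removals(record, c(a, b), "contamination", ev)
    }
  }
  record
}

#' Remove sequence-distance outliers
#'
#' A sequence is an outlier when its mean pairwise (Jukes-Cantor,
#' saturation-capped) distance to all other sequences exceeds, by more
#' than `k` standard deviations, the mean of that statistic over the
#' *other* sequences. The fence is leave-one-out because an inclusive
#' mean/SD caps the attainable z-score at \eqn{(n-1)/\sqrt{n}} and can
#' never flag anything at typical locus sizes. All decisions are taken on
#' the original statistics in a single pass.
#'
#' Because taxa on long terminal branches legitimately have elevated mean
#' distances, a flagged sequence must also exceed `fold` times the locus
#' median of the statistic — the filter targets catastrophic errors
#' (misassembly, non-homologous fragments), not ordinary rate variation.
#'
#' @param record a `locus_record` with at least 5 sequences.
#' @param k fence width in standard deviations (default 3; `Inf` disables).
#' @param fold practical-significance guard (default 1.5).
#' @return updated `locus_record`.
#' @export
filter_distance_outliers <- function(record, k = 3, fold = 1.5) {
  if (!is.finite(k)) return(record)
  n <- nrow(record$alignment)
  if (n < 5L) return(record)
  d <- distance_matrix(record$alignment, family = "JC")
  stat <- rowSums(d, na.rm = TRUE) / (n - 1L)
  thr <- pmax(vapply(seq_len(n), function(i)
    mean(stat[-i]) + k * stats::sd(stat[-i]), 0),
    fold * stats::median(stat))
  bad <- names(stat)[stat > thr]
  if (length(bad))
    record <- apply_removals(record, bad, "distance_outlier",
                             sprintf("mean_dist=%.4g threshold=%.4g",
                                     stat[stat > thr], thr[stat > thr]))
  record
}

#' Discard loci shorter than a minimum length
#'
#' Strictly-shorter comparison: a locus of exactly `min_bp` is retained.
#'
#' @param records list of `locus_record`.
#' @param min_bp minimum length in bp (default 150, i.e. 50 codons).
#' @return list with `records` (retained) and `drops` (data frame).
#' @export
filter_short_loci <- function(records, min_bp = 150L) {
  lens <- vapply(records, function(r) ncol(r$alignment), 0L)
  short <- lens < min_bp
  drops <- data.frame(locus = vapply(records[short], `[[`, "", "id"),
                      rule = rep("too_short", sum(short)),
                      evidence = sprintf("length_bp=%d min_bp=%d",
                                         lens[short], min_bp),
                      stringsAsFactors = FALSE)
  list(records = records[!short], drops = drops)
}

# Normalized weighted RF of a gene tree to the species tree: wRF divided by
# the summed internal branch lengths of both shared-taxon-restricted trees.
normalized_wrf <- function(tree, species_tree) {
  shared <- intersect(tree$tip.label, species_tree$tip.label)
  if (length(shared) < 4L) return(NA_real_)
  t1 <- restrict_tree(tree, shared)
  t2 <- restrict_tree(species_tree, shared)
  denom <- sum(tree_splits(t1)) + sum(tree_splits(t2))
  if (denom <= 0) return(0)
  rf_distance(t1, t2, weighted = TRUE) / denom
}

#' Drop loci whose gene trees are weighted-RF outliers
#'
#' The weighted RF distance of each gene tree to the species tree
#' (shared-taxon restriction, normalized by the summed internal branch
#' lengths of both trees) is screened with a Tukey fence: loci above
#' `Q3 + k * IQR` are dropped.
#'
#' @param records list of `locus_record` with gene trees.
#' @param species_tree reference `phylo`.
#' @param k Tukey fence multiplier (default 1.5; `Inf` disables).
#' @return list with `records`, `drops`, and the `threshold` used.
#' @export
filter_rf_outliers <- function(records, species_tree, k = 1.5) {
  nwrf <- vapply(records, function(r) {
    if (is.null(r$tree)) return(NA_real_)
    normalized_wrf(r$tree, species_tree)
  }, 0)
  if (sum(!is.na(nwrf)) < 8L) {
    warning("fewer than 8 loci with comparable trees; RF-outlier filter skipped")
    return(list(records = records, drops = empty_actions()[0, c(1, 3, 4)],
                threshold = NA_real_))
  }
  if (!is.finite(k)) {
    return(list(records = records, drops = empty_actions()[0, c(1, 3, 4)],
                threshold = Inf))
  }
  q <- stats::quantile(nwrf, c(0.25, 0.75), na.rm = TRUE)
  thr <- q[[2]] + k * (q[[2]] - q[[1]])
  bad <- !is.na(nwrf) & nwrf > thr
  drops <- data.frame(locus = vapply(records[bad], `[[`, "", "id"),
                      rule = rep("rf_outlier", sum(bad)),
                      evidence = sprintf("norm_wrf=%.4g threshold=%.4g",
                                         nwrf[bad], thr),
                      stringsAsFactors = FALSE)
  list(records = records[!bad], drops = drops, threshold = thr)
}

#' Run the full locus-hygiene cascade
#'
#' Order: long-branch removal, cross-contamination drop-tests (when a
#' concatenation distance table is supplied), sequence-distance outliers,
#' short-locus drop, weighted-RF outlier drop. The cascade is idempotent:
#' re-running it on its own output changes nothing.
#'
#' @param records list of `locus_record`.
#' @param species_tree reference `phylo` (for contamination and RF filters).
#' @param concat_distances optional concatenation GTR distance matrix;
#'   `NULL` skips the contamination step.
#' @param long_branch_factor,distance_k,min_bp,rf_k rule parameters.
#' @return list with `records` (surviving loci) and `report` (data frame of
#'   all removals and drops).
#' @export
run_qc_cascade <- function(records, species_tree, concat_distances = NULL,
                           long_branch_factor = 50, distance_k = 3,
                           min_bp = 150L, rf_k = 1.5, max_rounds = 10L) {
  n_removed <- function(rs) sum(vapply(rs, function(r) nrow(r$removed), 0L))
  n_prior <- vapply(records, function(r) nrow(r$removed), 0L)  # history
  # per-taxon rules, iterated until no rule fires (the fences move when
  # sequences are removed, so one pass is not a fixed point)
  for (round in seq_len(max_rounds)) {
    before <- n_removed(records)
    records <- lapply(records, filter_long_branches, factor = long_branch_factor)
    if (!is.null(concat_distances))
      records <- lapply(records, detect_contamination,
                        concat_distances = concat_distances,
                        species_tree = species_tree)
    records <- lapply(records, filter_distance_outliers, k = distance_k)
    if (n_removed(records) == before) break
  }
  # report only this run's actions, not removal history carried on records
  actions <- do.call(rbind, lapply(seq_along(records), function(i) {
    rem <- records[[i]]$removed
    if (nrow(rem) > n_prior[i]) rem[(n_prior[i] + 1L):nrow(rem), ] else NULL
  }))
  sl <- filter_short_loci(records, min_bp = min_bp)
  records <- sl$records
  rf_drops <- NULL
  thr <- NA_real_
  for (round in seq_len(max_rounds)) {  # Tukey fence re-estimated: iterate
    rf <- suppressWarnings(filter_rf_outliers(records, species_tree, k = rf_k))
    records <- rf$records
    thr <- rf$threshold
    if (!nrow(rf$drops)) break
    rf_drops <- rbind(rf_drops, rf$drops)
  }
  drops <- rbind(if (nrow(sl$drops)) cbind(sl$drops, taxon = NA_character_),
                 if (!is.null(rf_drops)) cbind(rf_drops, taxon = NA_character_))
  report <- rbind(actions,
                  if (!is.null(drops) && nrow(drops))
                    drops[, c("locus", "taxon", "rule", "evidence")])
  list(records = records,
       report = if (is.null(report)) empty_actions() else report,
       rf_threshold = thr)
}

#' Write a QC report as TSV
#' @param report data frame from [run_qc_cascade()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
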