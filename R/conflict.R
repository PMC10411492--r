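#' Per-locus log-likelihood signal around focal edges of a species tree
#'
#' For each focal edge of the species tree (restricted to the locus taxa),
#' the reference topology and its two nearest-neighbor-interchange
#' alternatives are scored with branch lengths re-optimized per topology
#' under a model held fixed for the locus. The signal is
#' `delta = lnL_ref - max(lnL_alt1, lnL_alt2)` (positive means the
#' reference resolution is favored), also rescaled per base so long loci
#' do not dominate.
#'
#' @param record a `locus_record`.
#' @param species_tree reference `phylo`.
#' @param focal_edges named list of character vectors; each vector is one
#'   side of the bipartition identifying a focal edge. `NULL` uses every
#'   internal edge of the species tree.
#' @param model a `subst_model` for the locus; `NULL` fits one with
#'   [fit_model()] on the restricted species tree.
#' @param tol,max_sweeps passed to [optimize_branch_lengths()].
#' @return data frame (one row per surviving focal edge): locus, edge,
#'   lnl_ref, lnl_best_alt, delta, delta_per_base, linkage. Focal edges
#'   lost in the taxon restriction are skipped.
#' @export
delta_lnl <- function(record, species_tree, focal_edges = NULL, model = NULL,
                      tol = 1e-2, max_sweeps = 20L) {
  aln <- record$alignment
  shared <- intersect(species_tree$tip.label, rownames(aln))
  if (length(shared) < 4L) return(NULL)
  ref <- ape::unroot(restrict_tree(species_tree, shared))
  ref$node.label <- NULL
  if (is.null(focal_edges)) focal_edges <- all_internal_splits(ref)
  if (is.null(model))  # fit on the gene tree: realistically scaled lengths
    model <- fit_model(aln, if (!is.null(record$tree)) record$tree else ref)
  if (!is.null(record$tree)) {
    # start optimization at the locus's own length scale, not the species
    # tree's: the gene tree's total length carries the locus rate
    gt <- restrict_tree(record$tree, intersect(record$tree$tip.label, shared))
    s <- tree_length(gt) / max(tree_length(ref), 1e-12)
    if (is.finite(s) && s > 0) ref$edge.length <- ref$edge.length * s
  }
  opt_ref <- optimize_branch_lengths(aln, ref, model, tol = tol,
                                     max_sweeps = max_sweeps)
  ref_tree <- opt_ref$tree
  rows <- lapply(seq_along(focal_edges), function(i) {
    side <- focal_edges[[i]]
    ename <- names(focal_edges)[i]
    if (is.null(ename) || !nzchar(ename))
      ename <- paste(sort(side), collapse = "|")
    er <- find_edge_by_split(ref_tree, side)
    if (is.na(er)) return(NULL)
    alts <- nni_neighbors(ref_tree, er)
    lnl_alt <- vapply(alts, function(at) {
      r <- tryCatch(optimize_branch_lengths(aln, at, model, tol = tol,
                                            max_sweeps = max_sweeps),
                    error = function(e) NULL)
      if (is.null(r)) NA_real_ else r$log_likelihood
    }, 0)
    if (all(is.na(lnl_alt))) return(NULL)
    best_alt <- max(lnl_alt, na.rm = TRUE)
    delta <- opt_ref$log_likelihood - best_alt
    data.frame(locus = record$id, edge = ename,
               lnl_ref = opt_ref$log_likelihood, lnl_best_alt = best_alt,
               delta = delta, delta_per_base = delta / ncol(aln),
               length_bp = ncol(aln), linkage = record$linkage,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' All internal-edge bipartitions of a tree, as a named split list
#' @param tree a `phylo`.
#' @return named list of character vectors (one side of each split).
#' @export
all_internal_splits <- function(tree) {
  tree <- ape::unroot(tree)
  sp <- tree_splits(tree)
  sides <- strsplit(names(sp), "|", fixed = TRUE)
  stats::setNames(sides, names(sp))
}

#' Signal table over a set of loci
#'
#' @param records list of `locus_record`.
#' @param species_tree reference `phylo`.
#' @inheritParams delta_lnl
#' @param models optional named list of per-locus `subst_model`s.
#' @return combined signal data frame (see [delta_lnl()]).
#' @export
signal_table <- function(records, species_tree, focal_edges = NULL,
                         models = NULL, tol = 1e-2, max_sweeps = 20L) {
  out <- lapply(records, function(r)
    delta_lnl(r, species_tree, focal_edges,
              model = if (!is.null(models)) models[[r$id]] else NULL,
              tol = tol, max_sweeps = max_sweeps))
  do.call(rbind, out)
}

#' Summarize per-edge signal by chromosomal linkage bin
#'
#' For each (focal edge, linkage bin): the summed delta, the median and
#' IQR of the per-base delta, and the locus count. Each edge with both an
#' autosomal and an X bin is classified into one of the conflict regimes:
#' `concordant_weaker` (both medians positive, X below A),
#' `concordant_stronger` (both positive, X at or above A), `discordant`
#' (medians of opposite sign), or `other`.
#'
#' @param signal data frame from [signal_table()].
#' @return list with `bins` (per edge x bin summary) and `regimes`
#'   (per-edge classification).
#' @export
bin_signal <- function(signal) {
  if (is.null(signal) || !nrow(signal)) stop("input error: empty signal table")
  bins <- do.call(rbind, lapply(split(signal, signal[c("edge", "linkage")]),
    function(d) {
      if (!nrow(d)) return(NULL)
      data.frame(edge = d$edge[1], linkage = d$linkage[1], n = nrow(d),
                 sum_delta = sum(d$delta),
                 median_delta_per_base = stats::median(d$delta_per_base),
                 iqr_delta_per_base = stats::IQR(d$delta_per_base),
                 stringsAsFactors = FALSE)
    }))
  rownames(bins) <- NULL
  regimes <- do.call(rbind, lapply(split(bins, bins$edge), function(d) {
    a <- d[d$linkage == "A", ]; x <- d[d$linkage == "X", ]
    if (!nrow(a) || !nrow(x)) return(NULL)
    ma <- a$median_delta_per_base; mx <- x$median_delta_per_base
    regime <-
      if (ma > 0 && mx > 0 && mx < ma) "concordant_weaker"
      else if (ma > 0 && mx > 0) "concordant_stronger"
      else if (ma * mx < 0) "discordant"
      else "other"
    data.frame(edge = d$edge[1], median_A = ma, median_X = mx,
               regime = regime, stringsAsFactors = FALSE)
  }))
  rownames(regimes) <- NULL
  list(bins = bins, regimes = regimes)
}

#' Remove third codon positions across loci (NT12 correction)
#'
#' Third positions are the most saturated; excluding them and re-running
#' the signal analysis tests whether apparent conflict is saturation-driven.
#' Non-codon-framed loci are skipped with a flag.
#'
#' @param records list of `locus_record`.
#' @return list with `records` (corrected; `nt12 = TRUE` attribute) and
#'   `skipped` (ids of non-codon loci, returned unchanged).
#' @export
nt12_correction <- function(records) {
  skipped <- character(0)
  out <- lapply(records, function(r) {
    if (ncol(r$alignment) %% 3L != 0L) {
      skipped <<- c(skipped, r$id)
      return(r)
    }
    r$alignment <- codon_subset(r$alignment, keep = c(1L, 2L))
    r$nt12 <- TRUE
    r
  })
  list(records = out, skipped = skipped)
}

#' Pairwise tree distance matrix over gene trees
#'
#' Trees are first collapsed at the support threshold, then compared by
#' (weighted) RF on their shared-taxon restrictions. Pairs with fewer than
#' 4 shared taxa receive the matrix maximum as a sentinel (logged).
#'
#' @param trees list of `phylo` (names become dimnames).
#' @param support_collapse collapse threshold in percent (`NULL` skips).
#' @param weighted use branch-length-weighted RF (default `TRUE`).
#' @return symmetric, zero-diagonal distance matrix.
#' @export
tree_distance_matrix <- function(trees, support_collapse = 50,
                                 weighted = TRUE) {
  n <- length(trees)
  if (n < 3L) stop("input error: need at least 3 trees")
  if (is.null(names(trees))) names(trees) <- sprintf("tree%d", seq_len(n))
  if (!is.null(support_collapse))
    trees <- lapply(trees, collapse_low_support, threshold = support_collapse)
  sp <- lapply(trees, tree_splits)
  d <- matrix(0, n, n, dimnames = list(names(trees), names(trees)))
  undef <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- intersect(attr(sp[[i]], "taxa"), attr(sp[[j]], "taxa"))
    if (length(shared) < 4L) {
      d[i, j] <- d[j, i] <- NA_real_
      undef <- undef + 1L
      next
    }
    full_i <- length(shared) == length(attr(sp[[i]], "taxa"))
    full_j <- length(shared) == length(attr(sp[[j]], "taxa"))
    if (full_i && full_j) {
      s1 <- sp[[i]]; s2 <- sp[[j]]
      keys <- union(names(s1), names(s2))
      if (weighted) {
        w1 <- ifelse(keys %in% names(s1), s1[keys], 0)
        w2 <- ifelse(keys %in% names(s2), s2[keys], 0)
        d[i, j] <- d[j, i] <- sum(abs(w1 - w2))
      } else {
        d[i, j] <- d[j, i] <- sum(!(names(s1) %in% names(s2))) +
          sum(!(names(s2) %in% names(s1)))
      }
    } else {
      d[i, j] <- d[j, i] <- rf_distance(trees[[i]], trees[[j]],
                                        weighted = weighted)
    }
  }
  if (undef > 0L) {
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- mx
    message(undef, " tree pair(s) had <4 shared taxa; set to matrix maximum")
  }
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: double-centering of the squared distances,
#' eigendecomposition, coordinates scaled by the square roots of the
#' positive eigenvalues. Negative eigenvalues are reported but their axes
#' dropped.
#'
#' @param d symmetric zero-diagonal distance matrix.
#' @param m maximum number of axes to return (default all positive).
#' @return list with `coords` (n x m matrix) and `eigenvalues` (all, in
#'   descending order).
#' @export
pcoa <- function(d, m = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (any(abs(d - t(d)) > 1e-8) || any(abs(diag(d)) > 1e-12))
    stop("input error: distance matrix must be symmetric with zero diagonal")
  if (all(d == 0))
    return(list(coords = matrix(0, n, 1, dimnames = list(rownames(d), NULL)),
                eigenvalues = rep(0, n)))
  cm <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- sort(cm$eig, decreasing = TRUE)
  pts <- cm$points
  # drop numerically-zero axes (relative to the leading eigenvalue)
  keep <- min(ncol(pts), sum(eig > max(eig) * 1e-8))
  pts <- pts[, seq_len(max(keep, 1L)), drop = FALSE]
  if (!is.null(m) && ncol(pts) > m) pts <- pts[, seq_len(m), drop = FALSE]
  rownames(pts) <- rownames(d)
  list(coords = pts, eigenvalues = eig)
}

#' Cluster loci into conflict groves
#'
#' Centroid-based (k-means) clustering of the PCoA coordinates, on the
#' leading axes jointly explaining at least `min_mass` of the positive
#' eigenvalue mass, with `nstart` restarts under a fixed seed.
#'
#' @param ord a [pcoa()] result (or a list with `coords`/`eigenvalues`).
#' @param k number of groves.
#' @param seed integer seed (mandatory for reproducibility).
#' @param min_mass minimum cumulative positive-eigenvalue mass (default 0.8).
#' @param nstart k-means restarts (default 50).
#' @return object of class `grove_assignment`: `cluster` (named integer),
#'   `coords`, `eigenvalues`, `axes_used`, `k`.
#' @export
cluster_groves <- function(ord, k, seed, min_mass = 0.8, nstart = 50L) {
  n <- nrow(ord$coords)
  if (k > n) stop("input error: k exceeds the number of loci")
  pos <- ord$eigenvalues[ord$eigenvalues > 0]
  mass <- cumsum(pos) / sum(pos)
  m <- min(which(mass >= min_mass))
  m <- min(m, ncol(ord$coords))
  co <- ord$coords[, seq_len(m), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(co, centers = k, nstart = nstart, iter.max = 100L)
  structure(list(cluster = stats::setNames(km$cluster, rownames(co)),
                 coords = ord$coords, eigenvalues = ord$eigenvalues,
                 axes_used = m, k = k),
            class = "grove_assignment")
}

#' @export
print.grove_assignment <- function(x, ...) {
  cat(sprintf("<grove_assignment> %d loci in %d groves (%d PCoA axes)\n",
              length(x$cluster), x$k, x$axes_used))
  print(table(grove = x$cluster))
  invisible(x)
}

#' Linkage composition of groves
#'
#' @param assignment a `grove_assignment` (or a named cluster vector).
#' @param linkage named character vector (`A`/`X`) per locus.
#' @return list with `per_grove` (grove, n_loci, n_X, pct_X) and
#'   `overall_pct_x` (raw and rounded to integer).
#' @export
grove_composition <- function(assignment, linkage) {
  cl <- if (inherits(assignment, "grove_assignment")) assignment$cluster
        else assignment
  if (anyNA(linkage[names(cl)]))
    stop("input error: linkage labels missing for some loci")
  lk <- linkage[names(cl)]
  per <- do.call(rbind, lapply(sort(unique(cl)), function(g) {
    in_g <- cl == g
    data.frame(grove = g, n_loci = sum(in_g), n_X = sum(lk[in_g] == "X"),
               pct_X = 100 * sum(lk[in_g] == "X") / sum(in_g))
  }))
  raw <- 100 * sum(lk == "X") / length(lk)
  list(per_grove = per,
       overall_pct_x = raw, overall_pct_x_rounded = round(raw))
}

#' Ordination of analysis topologies in RF tree space
#'
#' Unweighted RF distances between named analysis trees (e.g. the trees
#' from different data subsets), followed by PCoA; coordinates are labeled
#' by analysis name.
#'
#' @param trees named list of `phylo` on a common taxon set.
#' @return [pcoa()] result with named coordinate rows.
#' @export
topology_space <- function(trees) {
  if (length(trees) < 3L) stop("input error: need at least 3 trees")
  if (is.null(names(trees))) stop("input error: trees must be named")
  d <- tree_distance_matrix(trees, support_collapse = NULL, weighted = FALSE)
  pcoa(d)
}
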