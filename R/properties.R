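#' Per-locus property profile
#'
#' Computes the descriptive statistics used to compare autosomal and
#' X-linked loci: length, taxon count, missingness, proportion of
#' parsimony-informative sites, GC mean and across-taxon variance per codon
#' position, gene-tree length, mean branch length, mean node support, and
#' the saturation slope. Informativeness summaries are included when
#' per-site rates are supplied.
#'
#' @param record a `locus_record`.
#' @param site_rates optional per-site rates for the informativeness profile.
#' @return one-row data frame.
#' @export
locus_properties <- function(record, site_rates = NULL) {
  aln <- record$alignment
  m <- unclass(aln)
  n_taxa <- nrow(m)
  len <- ncol(m)
  missing_prop <- mean(m == "-" | m == "N")
  pis <- mean(apply(m, 2L, is_parsimony_informative))
  gc <- gc_by_codon_position(aln)
  tr <- record$tree
  sup <- if (!is.null(tr)) node_supports(tr) else NA_real_
  pi_prof <- if (!is.null(site_rates)) informativeness_profile(site_rates)
             else list(epoch_of_max = NA_real_, area = NA_real_)
  data.frame(
    id = record$id, linkage = record$linkage, length_bp = len,
    n_taxa = n_taxa, missing_prop = missing_prop, pis_prop = pis,
    gc1_mean = gc$mean[1], gc1_var = gc$var[1],
    gc2_mean = gc$mean[2], gc2_var = gc$var[2],
    gc3_mean = gc$mean[3], gc3_var = gc$var[3],
    tree_length = if (!is.null(tr)) tree_length(tr) else NA_real_,
    mean_brlen = if (!is.null(tr) && !is.null(tr$edge.length))
      mean(tr$edge.length) else NA_real_,
    mean_support = if (all(is.na(sup))) NA_real_ else mean(sup, na.rm = TRUE),
    sat_slope = if (!is.null(tr)) saturation_slope(record) else NA_real_,
    pi_epoch_max = pi_prof$epoch_of_max, pi_area = pi_prof$area,
    stringsAsFactors = FALSE)
}

# A column is parsimony-informative when at least two states are each
# carried by at least two taxa (gaps/N are not states).
is_parsimony_informative <- function(column) {
  tab <- table(column[column %in% c("A", "C", "G", "T")])
  sum(tab >= 2L) >= 2L
}

# GC proportion per taxon at each codon position; mean and variance taken
# across taxa (taxa with no called base at a position are skipped).
gc_by_codon_position <- function(aln) {
  pos <- codon_positions(aln)
  m <- unclass(aln)
  mean3 <- var3 <- rep(NA_real_, 3)
  for (p in 1:3) {
    sub <- m[, pos == p, drop = FALSE]
    gc <- apply(sub, 1L, function(row) {
      called <- row %in% c("A", "C", "G", "T")
      if (!any(called)) return(NA_real_)
      mean(row[called] %in% c("G", "C"))
    })
    mean3[p] <- mean(gc, na.rm = TRUE)
    var3[p] <- stats::var(gc, na.rm = TRUE)
  }
  list(mean = mean3, var = var3)
}

#' Substitution saturation slope of a locus
#'
#' Zero-intercept regression of uncorrected pairwise p-distance on
#' patristic (tree-path) distance across all taxon pairs. A slope near 1
#' indicates an unsaturated locus; the slope decreases toward 0 as repeat
#' substitutions accumulate (the p-distance is bounded by 3/4).
#'
#' @param record a `locus_record` with a gene tree carrying branch lengths.
#' @return slope, or `NA` when the patristic distances have no variance.
#' @export
saturation_slope <- function(record) {
  tr <- record$tree
  if (is.null(tr) || is.null(tr$edge.length) || length(tr$tip.label) < 4L)
    return(NA_real_)
  pat <- ape::cophenetic.phylo(tr)
  taxa <- intersect(rownames(record$alignment), rownames(pat))
  if (length(taxa) < 4L) return(NA_real_)
  codes <- encode_alignment(record$alignment)[taxa, , drop = FALSE]
  xs <- ys <- numeric(0)
  for (i in seq_along(taxa)[-1]) for (j in seq_len(i - 1L)) {
    a <- codes[i, ]; b <- codes[j, ]
    ok <- a < 4L & b < 4L
    if (sum(ok) < 10L) next
    xs <- c(xs, pat[taxa[i], taxa[j]])
    ys <- c(ys, mean(a[ok] != b[ok]))
  }
  if (!length(xs) || sum(xs^2) == 0) return(NA_real_)
  sum(xs * ys) / sum(xs^2)
}

#' Phylogenetic informativeness profile
#'
#' For per-site rates \eqn{r}, the informativeness at normalized epoch
#' \eqn{t} is \eqn{\sum_{sites} 16 r^2 t e^{-4 r t}}; it is sampled on a
#' regular grid over tree height normalized to 1. Reported are the full
#' curve, the epoch of maximum informativeness, and the area under the
#' curve (trapezoid rule).
#'
#' @param site_rates non-negative per-site rates.
#' @param epochs grid of normalized epochs (default 0 to 1 by 0.01).
#' @return list with `curve` (data frame epoch/informativeness),
#'   `epoch_of_max` (`NA` when all rates are 0), and `area`.
#' @export
informativeness_profile <- function(site_rates, epochs = seq(0, 1, by = 0.01)) {
  if (any(site_rates < 0)) stop("input error: negative site rates")
  inf <- vapply(epochs, function(t)
    sum(16 * site_rates^2 * t * exp(-4 * site_rates * t)), 0)
  area <- sum(diff(epochs) * (utils::head(inf, -1) + utils::tail(inf, -1)) / 2)
  epoch_max <- if (all(inf == 0)) NA_real_ else epochs[which.max(inf)]
  list(curve = data.frame(epoch = epochs, informativeness = inf),
       epoch_of_max = epoch_max, area = area)
}

# standard genetic code: codon string -> amino acid (stop = "*"),
# built once via seqinr
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      bases <- c("T", "C", "A", "G")
      codons <- as.vector(outer(outer(bases, bases, paste0), bases,
                                function(ab, c) paste0(ab, c)))
      aa <- vapply(codons, function(cd)
        seqinr::translate(strsplit(cd, "")[[1]]), "")
      tab <<- stats::setNames(aa, codons)
    }
    tab
  }
})

# synonymous fraction of the three possible changes at each codon position
# (changes to stop codons excluded from numerator and denominator)
ng86_site_counts <- function(codon, tab) {
  aa <- tab[[codon]]
  s <- 0
  for (p in 1:3) {
    alts <- vapply(setdiff(c("T", "C", "A", "G"), substr(codon, p, p)),
                   function(b) { x <- codon; substr(x, p, p) <- b; x }, "")
    aas <- tab[alts]
    valid <- aas != "*"
    if (!any(valid)) next
    s <- s + sum(aas[valid] == aa) / sum(valid)
  }
  c(S = s, N = 3 - s)
}

# pathway-averaged synonymous/nonsynonymous difference counts between two
# codons (pathways through stop codons excluded; if all pathways hit a
# stop, all are used)
ng86_diff_counts <- function(c1, c2, tab) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(Sd = 0, Nd = 0))
  paths <- if (nd == 1L) list(pos) else {
    perms <- if (nd == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(i) pos[i])
    }
    perms
  }
  score <- function(path) {
    cur <- c1; sd <- 0; ndiff <- 0; ok <- TRUE
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (tab[[nxt]] == "*") ok <- FALSE
      if (tab[[nxt]] == tab[[cur]]) sd <- sd + 1 else ndiff <- ndiff + 1
      cur <- nxt
    }
    c(sd, ndiff, ok)
  }
  sc <- vapply(paths, score, numeric(3))
  use <- sc[3, ] == 1
  if (!any(use)) use <- rep(TRUE, ncol(sc))
  c(Sd = mean(sc[1, use]), Nd = mean(sc[2, use]))
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) method
#'
#' Counts average synonymous and nonsynonymous sites per codon,
#' pathway-averaged difference counts, and applies the Jukes-Cantor
#' correction to the proportions. Codons containing gaps, `N`, or stop
#' codons in either sequence are skipped.
#'
#' @param aln a codon-framed `dna_alignment`.
#' @param taxon1,taxon2 taxon names.
#' @return list with `dN`, `dS`, `omega` (`NA` when `dS` is 0), raw counts,
#'   and a `saturated` flag when `pS` or `pN` reaches 3/4.
#' @export
dnds_pairwise <- function(aln, taxon1, taxon2) {
  if (ncol(aln) %% 3L != 0L) stop("input error: alignment not codon-framed")
  tab <- codon_table()
  s1 <- paste(unclass(aln)[taxon1, ], collapse = "")
  s2 <- paste(unclass(aln)[taxon2, ], collapse = "")
  n_codon <- nchar(s1) / 3L
  S <- N <- Sd <- Nd <- 0
  used <- 0L
  for (i in seq_len(n_codon)) {
    c1 <- substr(s1, 3 * i - 2, 3 * i)
    c2 <- substr(s2, 3 * i - 2, 3 * i)
    if (grepl("[^TCAG]", c1) || grepl("[^TCAG]", c2)) next
    if (tab[[c1]] == "*" || tab[[c2]] == "*") next
    used <- used + 1L
    sc1 <- ng86_site_counts(c1, tab)
    sc2 <- ng86_site_counts(c2, tab)
    S <- S + (sc1["S"] + sc2["S"]) / 2
    N <- N + (sc1["N"] + sc2["N"]) / 2
    dc <- ng86_diff_counts(c1, c2, tab)
    Sd <- Sd + dc["Sd"]
    Nd <- Nd + dc["Nd"]
  }
  if (used == 0L) stop("input error: no comparable codons")
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  saturated <- pS >= 0.75 || pN >= 0.75
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  list(dN = unname(dN), dS = unname(dS),
       omega = if (is.finite(dS) && dS > 0 && is.finite(dN)) dN / dS else NA_real_,
       S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
       n_codons = used, saturated = saturated)
}

#' Property table for a set of loci
#'
#' @param records list of `locus_record`.
#' @return data frame, one row per locus (see [locus_properties()]).
#' @export
properties_table <- function(records) {
  do.call(rbind, lapply(records, locus_properties))
}
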