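# Shared preparation for the C++ engine: restrict the alignment to the
# tree's tips, compress to site patterns, and reorder the tree postorder.
prep_likelihood <- function(aln, tree, model) {
  tree <- ape::unroot(tree)
  miss <- setdiff(tree$tip.label, rownames(aln))
  if (length(miss))
    stop("input error: tree tips absent from alignment: ",
         paste(miss, collapse = ", "))
  aln <- unclass(aln)[tree$tip.label, , drop = FALSE]
  codes <- matrix(4L, nrow(aln), ncol(aln), dimnames = dimnames(aln))
  bases <- c("A", "C", "G", "T")
  for (i in 1:4) codes[aln == bases[i]] <- i - 1L
  pat <- site_patterns(codes)
  po <- ape::reorder.phylo(tree, "postorder")
  if (is.null(po$edge.length)) po$edge.length <- rep(0.1, nrow(po$edge))
  gr <- model$gamma_rates
  list(tree = po, pat = pat, gr = as.numeric(gr))
}

# log-likelihood from a cached prep (avoids re-encoding the alignment when
# scoring many models on the same data/topology, as in fit_model)
lnl_from_prep <- function(pr, model) {
  .cpp_tree_loglik(pr$tree$edge, pr$tree$edge.length,
                   length(pr$tree$tip.label), pr$pat$codes, pr$pat$weights,
                   model$pi, model$U, model$Uinv, model$lambda,
                   as.numeric(model$gamma_rates))$loglik
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Gaps and `N` are treated as fully ambiguous. The likelihood is invariant
#' to root placement under the (reversible) GTR model. Tips of the tree must
#' all be present in the alignment; extra alignment rows are ignored.
#'
#' @param aln a `dna_alignment`.
#' @param tree a `phylo` with branch lengths.
#' @param model a `subst_model`.
#' @return a `likelihood_result`: list with `log_likelihood` (nats),
#'   `per_site` (per-column log-likelihoods), and `tree`.
#' @export
tree_log_likelihood <- function(aln, tree, model) {
  pr <- prep_likelihood(aln, tree, model)
  res <- .cpp_tree_loglik(pr$tree$edge, pr$tree$edge.length,
                          length(pr$tree$tip.label), pr$pat$codes,
                          pr$pat$weights, model$pi, model$U, model$Uinv,
                          model$lambda, pr$gr)
  structure(list(log_likelihood = res$loglik,
                 per_site = res$pattern_loglik[pr$pat$index],
                 tree = pr$tree),
            class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf("<likelihood_result> lnL = %.6f over %d sites\n",
              x$log_likelihood, length(x$per_site)))
  invisible(x)
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise Brent optimization of each branch against the exact
#' likelihood, swept until the total log-likelihood improves by less than
#' `tol` (or `max_sweeps` rounds). The log-likelihood never decreases
#' across sweeps.
#'
#' @param aln a `dna_alignment`.
#' @param tree a `phylo`; starting lengths are taken from the tree
#'   (0.1 per edge when absent).
#' @param model a `subst_model`.
#' @param tol stopping tolerance on the log-likelihood improvement per sweep.
#' @param max_sweeps maximum number of sweeps.
#' @return a `likelihood_result` whose `tree` carries optimized lengths.
#' @export
optimize_branch_lengths <- function(aln, tree, model, tol = 1e-4,
                                    max_sweeps = 20L) {
  pr <- prep_likelihood(aln, tree, model)
  res <- .cpp_optimize_bl(pr$tree$edge, pr$tree$edge.length,
                          length(pr$tree$tip.label), pr$pat$codes,
                          pr$pat$weights, model$pi, model$U, model$Uinv,
                          model$lambda, pr$gr, tol, as.integer(max_sweeps))
  out <- pr$tree
  out$edge.length <- res$edge_length
  structure(list(log_likelihood = res$loglik,
                 per_site = res$pattern_loglik[pr$pat$index],
                 tree = out, sweeps = res$sweeps),
            class = "likelihood_result")
}

#' Fit a GTR+Gamma model to one locus on a fixed tree
#'
#' Base frequencies are empirical counts; exchangeabilities and the gamma
#' shape are fitted by direct-search maximum likelihood with the tree and
#' its branch lengths held fixed: a one-dimensional search over the shape
#' starting from moment-estimated exchangeabilities, followed by a short
#' Nelder-Mead polish over all log parameters. The fitted model is meant
#' to be reused unchanged when rescoring alternative topologies of the
#' same locus.
#'
#' @param aln a `dna_alignment`.
#' @param tree a `phylo` with branch lengths (e.g. the locus gene tree).
#' @param fit_exchangeabilities if `FALSE`, only the gamma shape is fitted.
#' @param k discrete gamma categories.
#' @param maxit Nelder-Mead iteration cap for the polish stage.
#' @return a `subst_model`.
#' @export
fit_model <- function(aln, tree, fit_exchangeabilities = TRUE, k = 4L,
                      maxit = 60L) {
  pi <- base_frequencies(aln)
  pr <- prep_likelihood(aln, tree, subst_model(k = k))
  eng <- .cpp_make_engine(pr$tree$edge, pr$tree$edge.length,
                          length(pr$tree$tip.label), pr$pat$codes,
                          pr$pat$weights, as.integer(max(1L, k)))
  obj <- function(par) {
    r <- if (fit_exchangeabilities) c(exp(par[1:5]), 1) else rep(1, 6)
    a <- exp(par[length(par)])
    m <- tryCatch(subst_model(pi = pi, rates = r, alpha = a, k = k),
                  error = function(e) NULL)
    if (is.null(m)) return(1e10)
    ll <- tryCatch(.cpp_engine_loglik(eng, m$pi, m$U, m$Uinv, m$lambda,
                                      as.numeric(m$gamma_rates)),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  # stage 1: moment exchangeabilities, 1-D search over the gamma shape
  start_ex <- tryCatch(gtr_empirical(aln)$rates, error = function(e) rep(1, 6))
  lex <- log(pmin(pmax(start_ex[1:5], 1e-2), 1e2))
  a0 <- if (fit_exchangeabilities) {
    stats::optimize(function(la) obj(c(lex, la)), c(log(0.05), log(20)),
                    tol = 0.02)$minimum
  } else {
    stats::optimize(function(la) obj(la), c(log(0.05), log(20)),
                    tol = 0.02)$minimum
  }
  # stage 2: short simplex polish over all log parameters
  p0 <- if (fit_exchangeabilities) c(lex, a0) else a0
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-6))
  r <- if (fit_exchangeabilities) c(exp(fit$par[1:5]), 1) else rep(1, 6)
  subst_model(pi = pi, rates = pmin(pmax(r, 1e-3), 1e3),
              alpha = min(max(exp(fit$par[length(fit$par)]), 0.02), 100),
              k = k)
}

# Moment estimate of GTR parameters from an alignment: empirical base
# frequencies plus exchangeabilities from the pooled mismatch table over
# (at most max_pairs) sequence pairs.
gtr_empirical <- function(aln, max_pairs = 200L) {
  codes <- encode_alignment(aln)
  n <- nrow(codes)
  prs <- utils::combn(n, 2)
  if (ncol(prs) > max_pairs) prs <- prs[, seq_len(max_pairs), drop = FALSE]
  cnt <- matrix(0, 4, 4)
  for (j in seq_len(ncol(prs))) {
    a <- codes[prs[1, j], ]; b <- codes[prs[2, j], ]
    ok <- a < 4L & b < 4L
    if (!any(ok)) next
    tab <- tabulate(a[ok] * 4L + b[ok] + 1L, nbins = 16L)
    cnt <- cnt + matrix(tab, 4, 4, byrow = TRUE)
  }
  cnt <- cnt + t(cnt) + 0.5
  pi <- base_frequencies(aln)
  R <- cnt / (pi %o% pi)
  ex <- c(R[1, 2], R[1, 3], R[1, 4], R[2, 3], R[2, 4], R[3, 4])
  subst_model(pi = pi, rates = ex / ex[6])
}

#' Pairwise evolutionary distance between two aligned sequences
#'
#' Under `JC`, the closed form `-(3/4) log(1 - (4/3) p)` on shared ungapped
#' columns; proportions `p >= 3/4` saturate and return `Inf` flagged with a
#' `saturated` attribute. Under `GTR`, one-dimensional maximum-likelihood
#' optimization of the separation `t` of a two-leaf tree with empirical
#' alignment-wide frequencies and exchangeabilities (or a supplied model).
#'
#' @param aln a `dna_alignment`.
#' @param taxon1,taxon2 taxon names.
#' @param family `"JC"` or `"GTR"`.
#' @param model optional `subst_model` fixing pi/exchangeabilities for GTR.
#' @return distance in substitutions per site.
#' @export
pairwise_distance <- function(aln, taxon1, taxon2,
                              family = c("JC", "GTR"), model = NULL) {
  family <- match.arg(family)
  miss <- setdiff(c(taxon1, taxon2), rownames(aln))
  if (length(miss)) stop("input error: taxon not in alignment: ",
                         paste(miss, collapse = ", "))
  a <- encode_alignment(aln)[taxon1, ]
  b <- encode_alignment(aln)[taxon2, ]
  ok <- a < 4L & b < 4L
  if (!any(ok)) stop("input error: no shared ungapped columns")
  if (family == "JC") {
    p <- mean(a[ok] != b[ok])
    if (p >= 0.75) return(structure(Inf, saturated = TRUE))
    return(-0.75 * log(1 - 4 * p / 3))
  }
  if (is.null(model)) model <- gtr_empirical(aln)
  cnt <- matrix(tabulate(a[ok] * 4L + b[ok] + 1L, nbins = 16L), 4, 4,
                byrow = TRUE)
  if (sum(cnt[row(cnt) != col(cnt)]) == 0) return(0)
  nll <- function(t) {
    P <- transition_matrix(model, t)
    L <- model$pi * P
    -sum(cnt * log(pmax(L, 1e-300)))
  }
  opt <- stats::optimize(nll, c(1e-8, 20), tol = 1e-8)
  d <- opt$minimum
  if (d > 19) structure(d, saturated = TRUE) else d
}

#' All pairwise distances of an alignment
#'
#' @inheritParams pairwise_distance
#' @param cap value substituted for saturated (infinite) estimates.
#' @return symmetric matrix of distances.
#' @export
distance_matrix <- function(aln, family = c("JC", "GTR"), model = NULL,
                            cap = 5) {
  family <- match.arg(family)
  if (family == "GTR" && is.null(model)) model <- gtr_empirical(aln)
  taxa <- rownames(aln)
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- tryCatch(pairwise_distance(aln, taxa[i], taxa[j], family, model),
                  error = function(e) NA_real_)
    if (!is.na(v) && !is.finite(v)) v <- cap
    d[i, j] <- d[j, i] <- v
  }
  d
}
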