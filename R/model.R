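#' General time-reversible substitution model with discrete-gamma rates
#'
#' Builds a GTR rate matrix from base frequencies and six exchangeabilities
#' (order AC, AG, AT, CG, CT, GT; GT is fixed to 1), normalized to a mean
#' substitution rate of 1. Among-site rate variation uses `k` discrete
#' gamma categories whose rates are the means of equal-probability classes
#' of a mean-1 gamma with shape `alpha`.
#'
#' @param pi base frequencies (A, C, G, T), summing to 1.
#' @param rates six exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param alpha gamma shape (> 0), or `NULL` for rate homogeneity.
#' @param k number of discrete gamma categories.
#' @return an object of class `subst_model`.
#' @export
subst_model <- function(pi = rep(0.25, 4), rates = rep(1, 6), alpha = NULL,
                        k = 4L) {
  if (length(pi) != 4L || any(pi <= 0)) stop("input error: pi must be 4 positive values")
  pi <- pi / sum(pi)
  if (length(rates) != 6L || any(rates <= 0))
    stop("input error: need 6 positive exchangeabilities")
  rates <- rates / rates[6L]
  if (!is.null(alpha) && alpha <= 0) stop("input error: alpha must be > 0")
  R <- matrix(0, 4, 4)
  R[1, 2] <- rates[1]; R[1, 3] <- rates[2]; R[1, 4] <- rates[3]
  R[2, 3] <- rates[4]; R[2, 4] <- rates[5]; R[3, 4] <- rates[6]
  R <- R + t(R)
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  # reversibility: diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric
  sp <- sqrt(pi)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  structure(list(
    pi = pi, rates = rates, alpha = alpha, k = as.integer(k), Q = Q,
    U = diag(1 / sp) %*% e$vectors,
    Uinv = t(e$vectors) %*% diag(sp),
    lambda = e$values,
    gamma_rates = gamma_rates(alpha, k)
  ), class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("<subst_model> GTR",
      if (!is.null(x$alpha)) sprintf("+G%d (alpha = %.4g)", x$k, x$alpha),
      "\n  pi:", sprintf("%.4f", x$pi),
      "\n  exchangeabilities:", sprintf("%.4g", x$rates), "\n")
  invisible(x)
}

#' Jukes-Cantor model (equal frequencies and exchangeabilities)
#' @param alpha,k gamma parameters, see [subst_model()].
#' @export
jc_model <- function(alpha = NULL, k = 4L) subst_model(alpha = alpha, k = k)

#' Discrete-gamma category rates (means of equal-probability classes)
#'
#' @param alpha gamma shape; `NULL` gives a single rate of 1.
#' @param k number of categories.
#' @return numeric vector of `k` rates with mean 1.
#' @export
gamma_rates <- function(alpha, k = 4L) {
  if (is.null(alpha) || k == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  r <- k * diff(stats::pgamma(b, shape = alpha + 1, rate = alpha))
  r / mean(r) * 1  # guard tiny numeric drift; mean is 1 by construction
}

#' Transition probability matrix P(t)
#'
#' @param model a `subst_model`.
#' @param t branch length (expected substitutions per site, >= 0).
#' @return 4x4 row-stochastic matrix (rows/cols A, C, G, T).
#' @export
transition_matrix <- function(model, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("input error: branch length must be a single value >= 0")
  P <- model$U %*% diag(exp(model$lambda * t)) %*% model$Uinv
  P[P < 0] <- 0
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  P
}

#' Empirical base frequencies of an alignment
#' @param aln a `dna_alignment`.
#' @param pseudocount added to each base count.
#' @export
base_frequencies <- function(aln, pseudocount = 1) {
  n <- vapply(c("A", "C", "G", "T"), function(b) sum(unclass(aln) == b), 0)
  (n + pseudocount) / sum(n + 4 * pseudocount)
}

#' Serialize / restore model parameters
#'
#' @param model a `subst_model`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(pi = model$pi, rates = model$rates,
                            alpha = model$alpha, k = model$k),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  subst_model(pi = x$pi, rates = x$rates, alpha = x$alpha, k = x$k)
}
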