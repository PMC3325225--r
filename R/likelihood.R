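#' Discrete-gamma rate multipliers
#'
#' Equal-probability discretization of the gamma(shape, rate = shape) rate
#' distribution: category representatives are the conditional means of the
#' distribution between consecutive `1/ncat` quantiles, normalized to mean 1.
#' With `ncat = 1` rate heterogeneity is switched off.
#'
#' @param shape gamma shape `alpha > 0` (small values = strong heterogeneity).
#' @param ncat number of categories (default 4).
#' @return increasing numeric vector of `ncat` rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, ncat = 4L) {
  if (!is.numeric(shape) || shape <= 0) stop("shape must be > 0")
  stopifnot(ncat >= 1)
  if (ncat == 1L) return(1)
  q <- qgamma(seq(0, 1, length.out = ncat + 1L), shape = shape, rate = shape)
  # E[X; a<X<b] for gamma(a,a) via the incomplete-gamma shift property
  cum <- pgamma(q, shape = shape + 1, rate = shape)
  r <- ncat * diff(cum)
  r / mean(r) * 1  # already mean 1 up to rounding; renormalize exactly
}

#' GTR+I+G substitution model
#'
#' General time-reversible model with a proportion of invariable sites and
#' discrete-gamma rate heterogeneity.  The rate matrix `Q` is built from the
#' six exchangeabilities (order AC, AG, AT, CG, CT, GT) and the base
#' frequencies, then scaled so the expected substitution rate over the
#' variable fraction is 1 — branch lengths are therefore expected
#' substitutions per variable site, comparable with standard ML tools.
#'
#' @param rates six nonnegative exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param base_freq four base frequencies (A, C, G, T) summing to 1.
#' @param p_inv proportion of invariable sites in `[0, 1)`.
#' @param alpha gamma shape; `Inf` (or `ncat = 1`) disables heterogeneity.
#' @param ncat number of gamma categories.
#' @return an object of class `gtr_model` with the scaled `Q`, eigensystem,
#'   and the input parameters.
#' @export
gtr_model <- function(rates = rep(1, 6),
                      base_freq = rep(0.25, 4),
                      p_inv = 0, alpha = Inf, ncat = 4L) {
  stopifnot(length(rates) == 6, all(rates >= 0),
            length(base_freq) == 4, all(base_freq > 0))
  if (abs(sum(base_freq) - 1) > 1e-12) stop("base frequencies must sum to 1")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  if (!is.infinite(alpha) && alpha <= 0) stop("alpha must be > 0")
  S <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  S[upper.tri(S)] <- rates[c(1, 2, 4, 3, 5, 6)]  # fill col-major upper tri
  S <- S + t(S)
  Q <- S %*% diag(base_freq)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freq * diag(Q))
  Q <- Q / mu
  # symmetrized eigensystem for a stable, reversible exponential
  sp <- sqrt(base_freq)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(rates = rates, base_freq = base_freq, p_inv = p_inv,
                 alpha = alpha, ncat = as.integer(ncat), Q = Q,
                 eig_values = eig$values,
                 eig_right = diag(1 / sp) %*% eig$vectors,
                 eig_left = t(eig$vectors) %*% diag(sp)),
            class = "gtr_model")
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR+I+G model\n")
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      paste(format(x$rates, digits = 4), collapse = " "), "\n")
  cat("  base frequencies (A C G T):",
      paste(format(x$base_freq, digits = 4), collapse = " "), "\n")
  cat("  p_inv:", x$p_inv, "  alpha:", x$alpha,
      "  gamma categories:", x$ncat, "\n")
  invisible(x)
}

# Transition-probability matrix exp(Q * t) from the cached eigensystem.
gtr_pmatrix <- function(model, t) {
  P <- model$eig_right %*% (exp(model$eig_values * t) * model$eig_left)
  P[P < 0] <- 0
  P
}

.base_partials <- function(symbol) {
  switch(symbol,
         A = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
         G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
         c(1, 1, 1, 1))  # gap / ? / N: uninformative
}

#' GTR+I+G log-likelihood of an alignment on a fixed tree
#'
#' Felsenstein pruning, site by site (with site-pattern compression).  The
#' likelihood of a site is
#' `p_inv * I(site invariant-compatible) * sum_s pi_s prod_tips compat(tip,s)`
#' plus `(1 - p_inv)` times the mean over gamma categories of the pruned
#' likelihood with branch lengths scaled by the category rate.  Gaps and
#' ambiguities contribute all-ones partial likelihoods (and count as
#' compatible for the invariant term).  Because the model is reversible, the
#' value is invariant under rerooting.
#'
#' @param tree a `phylo` object with branch lengths; its tips must be a
#'   subset of the alignment taxa.
#' @param aln alignment character matrix.
#' @param model a [gtr_model()].
#' @return the total log-likelihood (sum over sites).
#' @export
tree_log_likelihood <- function(tree, aln, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "gtr_model"))
  if (is.null(tree$edge.length)) stop("missing branch lengths")
  .validate_alignment(aln)
  absent <- setdiff(tree$tip.label, rownames(aln))
  if (length(absent)) stop("tip absent from alignment: ",
                           paste(absent, collapse = ", "))
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  sub <- aln[tree$tip.label, , drop = FALSE]
  pat <- apply(sub, 2, paste, collapse = "\r")
  upat <- unique(pat)
  w <- as.vector(table(pat)[upat])
  cols <- match(upat, pat)
  S <- length(cols)
  tipP <- lapply(seq_len(ntip), function(i)
    vapply(sub[i, cols], .base_partials, numeric(4)))  # 4 x S
  rates <- if (model$ncat == 1L || is.infinite(model$alpha)) 1
           else discrete_gamma_rates(model$alpha, model$ncat)
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  elen <- po$edge.length
  pi4 <- model$base_freq
  site_var <- matrix(0, length(rates), S)
  for (ci in seq_along(rates)) {
    L <- vector("list", nn)
    L[seq_len(ntip)] <- tipP
    for (e in seq_len(nrow(E))) {
      p <- E[e, 1L]; ch <- E[e, 2L]
      P <- gtr_pmatrix(model, rates[ci] * elen[e])
      msg <- P %*% L[[ch]]
      L[[p]] <- if (is.null(L[[p]])) msg else L[[p]] * msg
    }
    site_var[ci, ] <- as.vector(pi4 %*% L[[ntip + 1L]])
  }
  var_lik <- colMeans(site_var)
  inv_lik <- if (model$p_inv > 0) {
    vapply(seq_len(S), function(s) {
      comp <- Reduce(`*`, lapply(tipP, function(m) m[, s]))
      sum(pi4 * comp)
    }, numeric(1))
  } else rep(0, S)
  site_lik <- model$p_inv * inv_lik + (1 - model$p_inv) * var_lik
  if (any(site_lik <= 0)) return(-Inf)
  sum(w * log(site_lik))
}
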