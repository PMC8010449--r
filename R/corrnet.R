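# Analytic shrinkage intensity toward the diagonal target on the
# correlation scale (Schafer-Strimmer style): lambda* =
# sum_ij Var(r_ij) / sum_ij r_ij^2 over off-diagonal entries, clipped to
# [0, 1]. Deterministic, no resampling.
shrinkage_intensity <- function(X) {
  n <- nrow(X)
  Xs <- scale(X)
  # w_kij are the per-observation products of standardized columns
  R <- stats::cor(X)
  p <- ncol(X)
  num <- 0; den <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      w <- Xs[, i] * Xs[, j]
      var_r <- n / (n - 1)^3 * sum((w - mean(w))^2)
      num <- num + var_r
      den <- den + R[i, j]^2
    }
  }
  if (den <= 0) return(1)
  max(0, min(1, num / den))
}

partial_from_correlation <- function(R) {
  Om <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular at the requested shrinkage; use a nonzero (or 'auto') shrinkage intensity")
  })
  d <- sqrt(diag(Om))
  P <- -Om / tcrossprod(d)
  diag(P) <- 1
  P
}

#' Statistically corrected pairwise abundance correlations
#'
#' Counts are log(1+x)-transformed, taxa occupying fewer than
#' `min_occupancy` of the levels are excluded as numerically rare, and (for
#' the default estimator) the correlation matrix is shrunk toward the
#' identity before inverting it to obtain partial correlations. Two-sided
#' p-values come from the Fisher z transform with effective sample size equal
#' to the number of levels; q-values are Benjamini-Hochberg adjusted over all
#' retained pairs.
#'
#' @param m An [abundance_matrix()].
#' @param min_occupancy Minimum fraction of levels a taxon must occur in
#'   (default 0.25); rarer taxa are reported in the `excluded` attribute.
#' @param shrinkage `"auto"` for the analytic intensity, or a number in
#'   `[0, 1]`. Ignored for the plain estimators.
#' @param estimator `"partial"` (shrunk partial correlation, default),
#'   `"pearson"` or `"spearman"` marginal correlation, kept switchable for
#'   sensitivity analysis.
#' @return A `correlation_set` data frame with one row per retained pair:
#'   `taxon_a`, `taxon_b`, `r`, `p`, `q`, `n_levels`, `co_occurrence`.
#'   Attributes: `nodes` (all taxa), `retained`, `excluded`, `lambda`.
#' @export
corrected_correlations <- function(m, min_occupancy = 0.25,
                                   shrinkage = "auto",
                                   estimator = c("partial", "pearson",
                                                 "spearman")) {
  estimator <- match.arg(estimator)
  n <- nrow(m$counts)
  if (n < 4) stop("need at least 4 levels for correlation analysis")
  occupancy <- colMeans(m$counts > 0)
  variable <- apply(m$counts, 2, function(x) stats::var(x) > 0)
  retained <- occupancy >= min_occupancy & variable
  excluded <- taxa_of(m)[!retained]
  empty_set <- function() {
    out <- data.frame(taxon_a = character(0), taxon_b = character(0),
                      r = numeric(0), p = numeric(0), q = numeric(0),
                      n_levels = integer(0), co_occurrence = integer(0))
    attr(out, "nodes") <- taxa_of(m)
    attr(out, "retained") <- character(0)
    attr(out, "excluded") <- excluded
    attr(out, "lambda") <- NA_real_
    class(out) <- c("correlation_set", "data.frame")
    out
  }
  if (sum(retained) < 2) {
    warning("fewer than 2 taxa pass the occupancy filter; empty correlation set")
    return(empty_set())
  }
  X <- log1p(m$counts[, retained, drop = FALSE])
  taxa <- colnames(X)

  lambda <- NA_real_
  if (estimator == "partial") {
    R0 <- stats::cor(X)
    lambda <- if (identical(shrinkage, "auto")) shrinkage_intensity(X)
              else as.numeric(shrinkage)
    if (lambda < 0 || lambda > 1) stop("shrinkage must lie in [0, 1]")
    Rs <- (1 - lambda) * R0
    diag(Rs) <- 1
    Rmat <- partial_from_correlation(Rs)
  } else if (estimator == "pearson") {
    Rmat <- stats::cor(X)
  } else {
    Rmat <- stats::cor(X, method = "spearman")
  }

  idx <- which(upper.tri(Rmat), arr.ind = TRUE)
  r <- Rmat[idx]
  r_c <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(r_c) * sqrt(max(n - 3, 1))
  p <- 2 * stats::pnorm(-abs(z))
  occ <- m$counts[, retained, drop = FALSE] > 0
  co <- crossprod(occ)
  out <- data.frame(
    taxon_a = taxa[idx[, 1]], taxon_b = taxa[idx[, 2]],
    r = r, p = p, q = stats::p.adjust(p, method = "BH"),
    n_levels = n, co_occurrence = as.integer(co[idx]),
    stringsAsFactors = FALSE
  )
  attr(out, "nodes") <- taxa_of(m)
  attr(out, "retained") <- taxa
  attr(out, "excluded") <- excluded
  attr(out, "lambda") <- lambda
  class(out) <- c("correlation_set", "data.frame")
  out
}

#' Build a significance-filtered correlation network
#'
#' Edges are the pairs of a [corrected_correlations()] set with BH-adjusted
#' q-value at or below `alpha`; weights keep the correlation's sign. All taxa
#' of the source matrix are carried as nodes, so rare taxa appear isolated.
#'
#' @param cs A `correlation_set`.
#' @param alpha FDR level in (0, 1), default 0.05.
#' @return A [corr_network()].
#' @export
build_network <- function(cs, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  keep <- cs$q <= alpha
  edges <- data.frame(taxon_a = cs$taxon_a[keep], taxon_b = cs$taxon_b[keep],
                      weight = cs$r[keep], q_value = cs$q[keep],
                      stringsAsFactors = FALSE)
  corr_network(attr(cs, "nodes"), edges)
}
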