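#' Fit a one-dimensional Gaussian mixture by maximum likelihood
#'
#' EM with multiple seeded initializations per candidate component count
#' (k-means++-style center seeding on the 1-D values); the component count
#' is selected by BIC. Component standard deviations are floored at
#' `sigma_floor` to prevent likelihood collapse onto single points.
#'
#' @param values Numeric vector (at least 10 values).
#' @param k_candidates Candidate component counts (subset of 1..8).
#' @param n_restarts EM initializations per K.
#' @param seed Integer seed.
#' @param sigma_floor Lower bound on component SD.
#' @return A `gmm_fit` list: `components` data frame (mean, sd, weight),
#'   `K`, `loglik`, `bic` (named per candidate K), `k_candidates`.
#' @export
fit_gmm_1d <- function(values, k_candidates = 1:6, n_restarts = 5, seed = 1,
                       sigma_floor = 1e-3) {
  values <- as.numeric(values[is.finite(values)])
  n <- length(values)
  if (n < 10) stop("need at least 10 values")
  if (any(k_candidates < 1 | k_candidates > 8)) {
    stop("k_candidates must lie in 1..8")
  }
  kmax_ok <- k_candidates[2 * k_candidates <= n]
  if (length(kmax_ok) < length(k_candidates)) {
    warning("candidate K truncated: too few values for the largest K")
    k_candidates <- kmax_ok
  }
  set.seed(seed)

  em_once <- function(K, centers) {
    mu <- centers
    sd_ <- rep(stats::sd(values), K)
    w <- rep(1 / K, K)
    ll_old <- -Inf
    for (it in 1:500) {
      dens <- vapply(seq_len(K), function(k) {
        w[k] * stats::dnorm(values, mu[k], sd_[k])
      }, numeric(n))
      if (K == 1) dens <- matrix(dens, ncol = 1)
      rowsum_ <- rowSums(dens)
      rowsum_[rowsum_ < 1e-300] <- 1e-300
      ll <- sum(log(rowsum_))
      # EM guarantee: the log-likelihood never decreases
      stopifnot(ll >= ll_old - 1e-8)
      if (ll - ll_old < 1e-8) break
      ll_old <- ll
      resp <- dens / rowsum_
      nk <- colSums(resp)
      w <- nk / n
      mu <- colSums(resp * values) / nk
      sd_ <- sqrt(colSums(resp * outer(values, mu, "-")^2) / nk)
      sd_ <- pmax(sd_, sigma_floor)
    }
    list(mu = mu, sd = sd_, w = w, ll = ll)
  }

  kmeanspp_centers <- function(K) {
    cen <- sample(values, 1)
    while (length(cen) < K) {
      d2 <- vapply(values, function(v) min((v - cen)^2), numeric(1))
      if (sum(d2) == 0) {
        cen <- c(cen, sample(values, K - length(cen), replace = TRUE))
      } else {
        cen <- c(cen, sample(values, 1, prob = d2))
      }
    }
    cen
  }

  fits <- list(); bics <- stats::setNames(numeric(0), character(0))
  for (K in k_candidates) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- em_once(K, kmeanspp_centers(K))
      if (is.null(best) || fit$ll > best$ll) best <- fit
    }
    npar <- 3 * K - 1
    bics[as.character(K)] <- -2 * best$ll + npar * log(n)
    fits[[as.character(K)]] <- best
  }
  kbest <- k_candidates[which.min(bics[as.character(k_candidates)])]
  bf <- fits[[as.character(kbest)]]
  o <- order(bf$mu)
  structure(list(
    components = data.frame(mean = bf$mu[o], sd = bf$sd[o],
                            weight = bf$w[o]),
    K = kbest, loglik = bf$ll, bic = bics, k_candidates = k_candidates
  ), class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: K = %d components (BIC-selected), means %s\n", x$K,
              paste(sprintf("%.3f", x$components$mean), collapse = ", ")))
  invisible(x)
}

#' Bhattacharyya coefficient between two Gaussian components
#'
#' `BC = exp(-D_B)` with
#' `D_B = (mu_a - mu_b)^2 / (4 (s_a^2 + s_b^2)) + log((s_a^2 + s_b^2) / (2 s_a s_b)) / 2`;
#' equals 1 iff the components are identical and decays to 0 as the means
#' separate.
#'
#' @param mean_a,sd_a,mean_b,sd_b Parameters of the two components
#'   (positive SDs).
#' @return A number in (0, 1].
#' @export
gaussian_similarity <- function(mean_a, sd_a, mean_b, sd_b) {
  if (any(c(sd_a, sd_b) <= 0)) stop("component SDs must be positive")
  v <- sd_a^2 + sd_b^2
  db <- (mean_a - mean_b)^2 / (4 * v) + 0.5 * log(v / (2 * sd_a * sd_b))
  exp(-db)
}

# spectral embedding of a similarity matrix: top eigenvectors of the
# symmetric normalized affinity, scaled by their eigenvalues (diffusion-map
# scaling), so noise directions with near-zero eigenvalues contribute
# nothing and one embedding serves every candidate cluster count
spectral_embedding <- function(S, dim) {
  d <- rowSums(S)
  d[d <= 0] <- 1e-12
  A <- S / sqrt(tcrossprod(d))
  ev <- eigen(A, symmetric = TRUE)
  U <- ev$vectors[, seq_len(dim), drop = FALSE]
  U %*% diag(pmax(ev$values[seq_len(dim)], 0), dim)
}

gap_wss <- function(X, C, seed) {
  if (C == 1) return(sum(scale(X, scale = FALSE)^2))
  set.seed(seed)
  km <- stats::kmeans(X, centers = C, nstart = 10, iter.max = 50)
  km$tot.withinss
}

#' Cluster Gaussian components into interaction categories
#'
#' A Bhattacharyya similarity matrix over all components is embedded
#' spectrally (symmetric normalized affinity, top eigenvectors,
#' row-normalized); k-means in the embedding gives candidate clusterings
#' and the Tibshirani gap statistic, with uniform reference draws over the
#' embedding's bounding box, selects the cluster count (smallest C with
#' `Gap(C) >= Gap(C+1) - s(C+1)`). Categories are ordered by ascending
#' cluster mean of the component means; each category's interval is the
#' range of its member means.
#'
#' @param components Data frame with columns `mean`, `sd` (weights
#'   optional), e.g. pooled from several [fit_gmm_1d()] fits.
#' @param c_candidates Candidate cluster counts.
#' @param n_ref Reference data sets for the gap statistic.
#' @param seed Integer seed.
#' @return A `category_scheme` list: `assignment` (category per component),
#'   `intervals` data frame (category, lower, upper, mean), `C`, `gap`
#'   table.
#' @export
cluster_components <- function(components, c_candidates = 1:6, n_ref = 50,
                               seed = 1) {
  n <- nrow(components)
  if (n < 4) stop("need at least 4 components")
  c_candidates <- c_candidates[c_candidates < n]
  S <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    gaussian_similarity(components$mean[i], components$sd[i],
                        components$mean[j], components$sd[j])
  }))

  if (max(abs(S[upper.tri(S)] - 1)) < 1e-10) {
    # all components indistinguishable
    return(new_category_scheme(components, rep(1L, n), NULL))
  }
  if (all(S[upper.tri(S)] < 1e-12)) {
    warning("similarity graph disconnected; each component its own cluster")
    return(new_category_scheme(components, seq_len(n), NULL))
  }

  cmax <- max(c_candidates)
  gaps <- data.frame(C = c_candidates, gap = NA_real_, s = NA_real_)
  assignments <- list()
  set.seed(seed)
  ref_seeds <- sample.int(1e6, n_ref)
  # one fixed embedding for all candidate counts, so the gap statistic
  # compares dispersions on the same data
  X <- spectral_embedding(S, min(cmax, n - 1))
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  for (ci in seq_along(c_candidates)) {
    C <- c_candidates[ci]
    w_obs <- gap_wss(X, C, seed)
    if (C == 1) {
      assignments[[ci]] <- rep(1L, n)
    } else {
      set.seed(seed)
      km <- stats::kmeans(X, centers = C, nstart = 10, iter.max = 50)
      assignments[[ci]] <- km$cluster
    }
    w_ref <- vapply(seq_len(n_ref), function(b) {
      set.seed(ref_seeds[b] + C)
      Xr <- vapply(seq_along(lo), function(j) {
        stats::runif(n, lo[j], hi[j])
      }, numeric(n))
      gap_wss(Xr, C, ref_seeds[b])
    }, numeric(1))
    lw <- log(pmax(w_ref, 1e-300))
    gaps$gap[ci] <- mean(lw) - log(max(w_obs, 1e-300))
    gaps$s[ci] <- stats::sd(lw) * sqrt(1 + 1 / n_ref)
  }
  # smallest C whose gap reaches within one reference-SE of the global
  # maximum (the firstSEmax convention): the plain one-SE first-crossing
  # rule stops at C = 1 whenever the curve dips before the true cluster
  # count, and the raw maximizer overfits once clusters are exhausted
  imax <- which.max(gaps$gap)
  Cbest <- gaps$C[which(gaps$gap >= gaps$gap[imax] - gaps$s[imax])[1]]
  new_category_scheme(components,
                      assignments[[match(Cbest, c_candidates)]], gaps)
}

new_category_scheme <- function(components, cluster, gap) {
  means_by <- tapply(components$mean, cluster, mean)
  ord <- order(means_by)
  relabel <- match(cluster, as.integer(names(means_by))[ord])
  iv <- do.call(rbind, lapply(sort(unique(relabel)), function(cat) {
    mu <- components$mean[relabel == cat]
    data.frame(category = cat, lower = min(mu), upper = max(mu),
               mean = mean(mu))
  }))
  structure(list(assignment = relabel, intervals = iv,
                 C = length(unique(relabel)), gap = gap,
                 components = components),
            class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat(sprintf("category_scheme: %d categories\n", x$C))
  for (i in seq_len(nrow(x$intervals))) {
    cat(sprintf("  category %d: means in [%.3f, %.3f]\n",
                x$intervals$category[i], x$intervals$lower[i],
                x$intervals$upper[i]))
  }
  invisible(x)
}

#' Assign a correlation value to a category interval
#'
#' Values between intervals are left unassigned (`NA`), mirroring the rule
#' that only correlations inside a category's band are categorized.
#'
#' @param r Numeric vector of correlations.
#' @param scheme A [cluster_components()] scheme.
#' @return Integer vector of categories, `NA` where outside all intervals.
#' @export
assign_category <- function(r, scheme) {
  out <- rep(NA_integer_, length(r))
  for (i in seq_len(nrow(scheme$intervals))) {
    inside <- r >= scheme$intervals$lower[i] & r <= scheme$intervals$upper[i]
    out[inside & is.na(out)] <- scheme$intervals$category[i]
  }
  out
}

#' Composition of interaction types across category intervals
#'
#' For each true interaction type of the labeled ABM correlations
#' (specialist, generalist, competition), the fraction of that type's
#' correlations falling in each category interval, plus the per-category
#' raw counts and the overall fraction of interaction-derived correlations
#' falling inside any interval.
#'
#' @param labeled Data frame with columns `label`, `r` (e.g. from
#'   [abm_correlations()] or [corpus_correlations()]); `none` pairs are not
#'   interactions and are ignored.
#' @param scheme A [cluster_components()] scheme.
#' @return List: `propensity` (type x category row-normalized matrix),
#'   `counts` (type x category), `in_interval_fraction`,
#'   `dominant_by_category` (type with the highest propensity per
#'   category).
#' @export
category_composition <- function(labeled, scheme) {
  if (is.null(scheme) || scheme$C < 1) stop("empty category scheme")
  lab <- labeled[labeled$label != "none", , drop = FALSE]
  cat_ <- assign_category(lab$r, scheme)
  types <- c("competition", "generalist", "specialist")
  cats <- scheme$intervals$category
  counts <- matrix(0L, length(types), length(cats),
                   dimnames = list(types, paste0("category_", cats)))
  for (i in seq_along(types)) {
    for (j in seq_along(cats)) {
      counts[i, j] <- sum(lab$label == types[i] & !is.na(cat_) &
                            cat_ == cats[j])
    }
  }
  n_type <- table(factor(lab$label, levels = types))
  prop <- sweep(counts, 1, pmax(as.integer(n_type), 1), "/")
  dominant <- apply(prop, 2, function(col) types[which.max(col)])
  list(propensity = prop, counts = counts,
       in_interval_fraction = mean(!is.na(cat_)),
       dominant_by_category = dominant)
}
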