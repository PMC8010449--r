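#' Normalized Hamming distance between two networks
#'
#' Fraction of unordered node pairs whose edge presence differs; the two
#' networks must share a node set. This is the graph-structural distance
#' used to express how strongly differential preservation rewires an
#' inferred network.
#'
#' @param g1,g2 [corr_network()] objects over the same node set.
#' @return A number in \[0, 1\].
#' @export
hamming_distance <- function(g1, g2) {
  if (!setequal(g1$nodes, g2$nodes) ||
      length(g1$nodes) != length(g2$nodes)) {
    stop("networks must share one node set")
  }
  n <- length(g1$nodes)
  if (n < 2) return(0)
  key <- function(g) paste(g$edges$taxon_a, g$edges$taxon_b, sep = "\r")
  k1 <- key(g1); k2 <- key(g2)
  diff <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  diff / choose(n, 2)
}

# dyad design matrix for the attribute terms of one categorical factor:
# per category, a homophily indicator (both endpoints in c) and an
# activity count (number of endpoints in c)
dyad_design <- function(nodes, labels) {
  cats <- sort(unique(labels))
  idx <- utils::combn(length(nodes), 2)
  la <- labels[idx[1, ]]; lb <- labels[idx[2, ]]
  X <- matrix(0, ncol(idx), 0)
  for (cc in cats) {
    X <- cbind(X, as.numeric(la == cc & lb == cc),
               (la == cc) + (lb == cc))
  }
  colnames(X) <- as.vector(rbind(paste0("match.", cats),
                                 paste0("count.", cats)))
  list(X = X, idx = idx, cats = cats)
}

#' Fit a dyad-independent ERGM by maximum pseudo-likelihood
#'
#' Logistic regression of edge presence over all dyads with an edges
#' (intercept) term plus, for each category of the node factor, a homophily
#' indicator (both endpoints in the category) and an activity count
#' (endpoints in the category). For these dyad-independent statistics the
#' MPLE is the exact MLE and is deterministic. The attribute effect
#' statistic `delta` is the fraction of the edges-only (null) deviance
#' explained by the attribute block, in \[0, 1\]: 0 when the categories
#' carry no information about edge placement, approaching 1 when edge
#' placement is fully category-determined.
#'
#' @param g A [corr_network()].
#' @param labels Named per-node category vector (names = node names), or an
#'   unnamed vector in node order.
#' @return An `ergm_fit` list: `coefficients`, `se`, `deviance_null`
#'   (edges-only), `deviance_fit`, `delta`, `degenerate`.
#' @export
fit_ergm <- function(g, labels) {
  nodes <- g$nodes
  if (length(nodes) < 5) stop("need at least 5 nodes")
  if (!is.null(names(labels))) {
    if (!all(nodes %in% names(labels))) {
      stop("labels missing for node(s): ",
           paste(setdiff(nodes, names(labels)), collapse = ", "))
    }
    labels <- labels[nodes]
  } else if (length(labels) != length(nodes)) {
    stop("labels must cover every node")
  }
  d <- dyad_design(nodes, as.character(labels))
  ia <- nodes[d$idx[1, ]]; ib <- nodes[d$idx[2, ]]
  ekey <- paste(g$edges$taxon_a, g$edges$taxon_b, sep = "\r")
  y <- as.numeric(paste(pmin(ia, ib), pmax(ia, ib), sep = "\r") %in% ekey)

  n_edge <- sum(y)
  if (n_edge == 0 || n_edge == length(y)) {
    return(structure(list(coefficients = c(edges = stats::qlogis(
      pmin(pmax(mean(y), 1e-12), 1 - 1e-12))),
      se = NA_real_, deviance_null = 0, deviance_fit = 0, delta = 0,
      degenerate = TRUE), class = "ergm_fit"))
  }
  null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  full_fit <- suppressWarnings(
    stats::glm(y ~ ., data = as.data.frame(d$X),
               family = stats::binomial())
  )
  dev_drop <- null_fit$deviance - full_fit$deviance
  structure(list(
    coefficients = stats::coef(full_fit),
    se = suppressWarnings(summary(full_fit)$coefficients[, "Std. Error"]),
    deviance_null = null_fit$deviance,
    deviance_fit = full_fit$deviance,
    delta = max(0, dev_drop) / max(null_fit$deviance, 1e-12),
    degenerate = FALSE
  ), class = "ergm_fit")
}

#' Default network builder used in bias scoring
#'
#' Builds a significance-filtered correlation network from a (census or
#' abundance) count matrix. The bias machinery defaults to plain Pearson
#' correlation networks: the Hamming distance between a degraded and a
#' perfect network is most informative when the network keeps all
#' marginally coupled pairs, and the same builder must be used for
#' calibration and for the windows being scored.
#'
#' @param min_occupancy,shrinkage,estimator,alpha Passed through to
#'   [corrected_correlations()] and [build_network()].
#' @return A function `matrix -> corr_network`.
#' @export
net_builder <- function(min_occupancy = 0.1, shrinkage = "auto",
                        estimator = "pearson", alpha = 0.05) {
  function(counts) {
    m <- abundance_matrix(counts, thickness_cm = 10)
    cs <- corrected_correlations(m, min_occupancy = min_occupancy,
                                 shrinkage = shrinkage,
                                 estimator = estimator)
    build_network(cs, alpha = alpha)
  }
}

#' Calibrate the preservation-bias coefficient on an ABM corpus
#'
#' For every (perfect, degraded) pair of the corpus, networks are built from
#' both census matrices; the normalized Hamming distance between them
#' measures how much differential preservation rewired the network, and the
#' ERGM attribute statistic of the degraded network with respect to the
#' preservation-category labels measures how much category structure is
#' visible in it. An isotonic regression of distance on statistic gives a
#' monotone map from the observable (the ERGM statistic on a single
#' network) to the expected structural alteration, which is the bias
#' coefficient scale.
#'
#' @param corpus An [run_abm_corpus()] result.
#' @param builder Network builder from [net_builder()].
#' @return A `bias_calibration` object: step-wise non-decreasing map with
#'   fields `delta` (sorted), `fitted` (isotonic d_H), plus the raw pairs.
#' @export
calibrate_bias <- function(corpus, builder = net_builder()) {
  deltas <- numeric(0); dh <- numeric(0)
  for (run in corpus$runs) {
    g_base <- builder(run$census)
    for (deg in run$degradations) {
      g_deg <- builder(deg$census)
      dh <- c(dh, hamming_distance(g_deg, g_base))
      fit <- fit_ergm(g_deg, deg$category)
      deltas <- c(deltas, fit$delta)
    }
  }
  if (all(dh == 0)) {
    warning("no degradation effect in corpus; calibration is flat at 0")
  }
  o <- order(deltas)
  iso <- stats::isoreg(deltas[o], dh[o])
  structure(list(delta = deltas[o], fitted = iso$yf,
                 raw = data.frame(delta = deltas, d_hamming = dh)),
            class = "bias_calibration")
}

#' @export
print.bias_calibration <- function(x, ...) {
  cat(sprintf("bias_calibration: %d corpus pairs, coefficient range [%.3f, %.3f]\n",
              length(x$delta), min(x$fitted), max(x$fitted)))
  invisible(x)
}

# evaluate the isotonic lookup at new delta values (piecewise-linear
# interpolation between the isotonic knots, flat extrapolation)
predict_calibration <- function(cal, delta) {
  f <- stats::approxfun(cal$delta, cal$fitted, method = "linear",
                        yleft = cal$fitted[1],
                        yright = cal$fitted[length(cal$fitted)],
                        ties = max)
  pmin(pmax(f(delta), 0), 1)
}

#' Preservation-bias coefficient of a network for one trait factor
#'
#' The ERGM attribute statistic of the network with respect to the factor's
#' per-node categories, passed through the ABM-fitted calibration: the
#' result estimates the expected normalized Hamming distance between the
#' observed network and the network that perfect preservation would have
#' produced, on a \[0, 1\] scale.
#'
#' @param g A [corr_network()].
#' @param labels Named per-node category vector.
#' @param cal A [calibrate_bias()] result.
#' @return A number in \[0, 1\].
#' @export
bias_coefficient <- function(g, labels, cal) {
  fit <- fit_ergm(g, labels)
  unname(predict_calibration(cal, fit$delta))
}

#' Bias coefficients across running windows, with stratum trimming
#'
#' Computes the bias coefficient of each window's network for each trait
#' factor (body type, size class, habitat), flags windows where any factor
#' exceeds the threshold, and reports contiguous flagged regions at the
#' section's ends as end trims (the high-bias margins excluded from
#' downstream analyses).
#'
#' @param windows A [make_windows()] data frame.
#' @param networks List of [corr_network()], one per window.
#' @param traits A [taxon_traits()] table covering the networks' nodes.
#' @param cal A [calibrate_bias()] result.
#' @param threshold Exclusion threshold on the coefficient (default 0.5).
#' @param factors Trait factors to score.
#' @return A `bias_series` list: `series` (window_id x factor coefficient
#'   data frame with `excluded` flag), `kept_windows`, `trim_start`,
#'   `trim_end` (window counts trimmed at each end).
#' @export
bias_series_and_trim <- function(windows, networks, traits, cal,
                                 threshold = 0.5,
                                 factors = c("body_type", "size_class",
                                             "habitat")) {
  if (length(networks) != nrow(windows)) {
    stop("need exactly one network per window")
  }
  rows <- list()
  for (i in seq_len(nrow(windows))) {
    g <- networks[[i]]
    coefs <- vapply(factors, function(f) {
      bias_coefficient(g, trait_labels(traits, g$nodes, f), cal)
    }, numeric(1))
    rows[[i]] <- data.frame(window_id = windows$window_id[i],
                            t(coefs), excluded = any(coefs > threshold))
  }
  series <- do.call(rbind, rows)
  excl <- series$excluded
  trim_start <- if (all(excl)) length(excl) else match(FALSE, excl) - 1L
  trim_end <- if (all(excl)) 0L else {
    length(excl) - max(which(!excl))
  }
  structure(list(series = series,
                 kept_windows = windows$window_id[!excl],
                 trim_start = trim_start, trim_end = trim_end,
                 threshold = threshold),
            class = "bias_series")
}

#' @export
print.bias_series <- function(x, ...) {
  cat(sprintf("bias_series: %d windows, %d excluded (threshold %.2f), end trims %d/%d\n",
              nrow(x$series), sum(x$series$excluded), x$threshold,
              x$trim_start, x$trim_end))
  invisible(x)
}
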