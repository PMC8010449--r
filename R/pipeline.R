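#' Run the full interaction-inference chain on an abundance data set
#'
#' Convenience wrapper: bins 10 cm levels into 20 cm levels, detects
#' sub-assemblages (SHEBI + ANOSIM consensus), computes corrected
#' correlations per sub-assemblage, decomposes each sub-assemblage's
#' correlation distribution into Gaussian components, clusters the pooled
#' components into interaction categories, categorizes significant pairs
#' per sub-assemblage and extracts consensus interactions.
#'
#' @param m An [abundance_matrix()] of 10 cm levels.
#' @param bin_cm Bin thickness (default 20).
#' @param min_occupancy,estimator,alpha Correlation/network settings, see
#'   [corrected_correlations()] and [build_network()].
#' @param k_candidates Candidate Gaussian component counts per stratum.
#' @param c_candidates Candidate interaction-category counts for the
#'   component clustering (default 1:4; few, broad categories keep the
#'   consensus rule stable across strata).
#' @param win_width,win_step Running-window width and step (in binned
#'   levels) for the finer-resolution analysis; the windows' Gaussian
#'   components are pooled with the sub-assemblage components before
#'   clustering, so every category's interval is spanned by many component
#'   means.
#' @param seed Integer seed.
#' @return A list: `partition`, `correlations` (per stratum), `gmm_fits`
#'   (per stratum), `scheme`, `per_stratum` categorizations, `records`
#'   (consensus interactions).
#' @export
infer_interactions <- function(m, bin_cm = 20, min_occupancy = 0.25,
                               estimator = "pearson", alpha = 0.05,
                               k_candidates = 1:6, c_candidates = 1:4,
                               win_width = 30, win_step = 10, seed = 1) {
  binned <- bin_levels(m, bin_cm)
  partition <- detect_subassemblages(binned, seed = seed)
  strata <- sort(unique(partition$labels))
  correlations <- list(); gmm_fits <- list(); per_stratum <- list()
  comp_pool <- list()
  for (s in strata) {
    idx <- which(partition$labels == s)
    sub <- abundance_matrix(binned$counts[idx, , drop = FALSE],
                            level_ids = binned$level_ids[idx],
                            thickness_cm = binned$thickness_cm[idx])
    cs <- corrected_correlations(sub, min_occupancy = min_occupancy,
                                 estimator = estimator)
    correlations[[s]] <- cs
    if (nrow(cs) >= 10) {
      fit <- fit_gmm_1d(cs$r, k_candidates = k_candidates, seed = seed)
      gmm_fits[[s]] <- fit
      comp <- fit$components
      comp$stratum <- s
      comp_pool[[s]] <- comp
    }
  }
  # finer-resolution running windows contribute components too
  if (win_width <= nrow(binned$counts)) {
    wins <- make_windows(binned, width = win_width, step = win_step)
    for (w in seq_len(nrow(wins))) {
      sub <- window_slice(binned, wins[w, ])
      cs <- tryCatch(
        corrected_correlations(sub, min_occupancy = min_occupancy,
                               estimator = estimator),
        warning = function(w_) NULL, error = function(e) NULL)
      if (is.null(cs) || nrow(cs) < 10) next
      fit <- fit_gmm_1d(cs$r, k_candidates = k_candidates, seed = seed + w)
      comp <- fit$components
      comp$stratum <- sprintf("window_%02d", w)
      comp_pool[[comp$stratum[1]]] <- comp
    }
  }
  pooled <- do.call(rbind, comp_pool)
  scheme <- if (!is.null(pooled) && nrow(pooled) >= 4) {
    cluster_components(pooled, c_candidates = c_candidates, seed = seed)
  } else NULL
  records <- NULL
  if (!is.null(scheme)) {
    for (s in strata) {
      cs <- correlations[[s]]
      per_stratum[[s]] <- list(
        categories = categorize_pairs(cs, scheme, alpha = alpha),
        taxa_present = attr(cs, "retained")
      )
    }
    records <- consensus_interactions(per_stratum)
  }
  list(partition = partition, correlations = correlations,
       gmm_fits = gmm_fits, scheme = scheme, per_stratum = per_stratum,
       records = records)
}
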