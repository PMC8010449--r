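#' Specify planted pairwise dependencies
#'
#' Helper building the edge specification consumed by
#' [generate_assemblage()]. Each planted pair carries an interaction class
#' and a latent correlation: specialist-like pairs are strongly positive,
#' generalist-like pairs weakly positive, competitive-like pairs negative.
#'
#' @param taxon_a,taxon_b Taxon indices or names.
#' @param class One of `"specialist"`, `"generalist"`, `"competitive"` per
#'   pair.
#' @param rho Latent correlation per pair; defaults by class to 0.8 / 0.4 /
#'   -0.5.
#' @return A data frame with columns `taxon_a`, `taxon_b`, `class`, `rho`.
#' @export
edge_spec <- function(taxon_a, taxon_b,
                      class = c("specialist", "generalist", "competitive"),
                      rho = NULL) {
  class <- match.arg(class, several.ok = TRUE)
  n <- max(length(taxon_a), length(taxon_b))
  class <- rep_len(class, n)
  if (is.null(rho)) {
    rho <- c(specialist = 0.8, generalist = 0.4, competitive = -0.5)[class]
  }
  if (any(abs(rho) > 1)) stop("|rho| must be <= 1")
  ok <- (class == "competitive") == (rho < 0)
  if (any(!ok)) stop("competitive pairs need rho < 0, trophic pairs rho > 0")
  data.frame(taxon_a = rep_len(taxon_a, n), taxon_b = rep_len(taxon_b, n),
             class = class, rho = as.numeric(rho), stringsAsFactors = FALSE)
}

latent_correlation_matrix <- function(n_taxa, edges) {
  R <- diag(n_taxa)
  if (!is.null(edges) && nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges$taxon_a[k]; j <- edges$taxon_b[k]
      if (i == j) stop("planted edge cannot be a self-pair")
      R[i, j] <- R[j, i] <- edges$rho[k]
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("planted correlation matrix is not positive semi-definite; thin the planted edges")
  }
  R
}

#' Generate a synthetic stratigraphic assemblage
#'
#' Counts are drawn as Poisson with log-mean equal to a per-facies baseline
#' plus a latent Gaussian field whose pairwise correlations equal the planted
#' values (a Gaussian copula construction), so the planted interaction
#' structure is recovered on the correlation scale downstream. Facies
#' segments delimited by `boundaries` draw independent baseline vectors from
#' a log-normal prior, planting compositional boundaries. Trait labels are
#' assigned at random; trait-dependent preservation is applied afterwards via
#' [apply_preservation()].
#'
#' @param n_taxa Number of taxa.
#' @param n_levels Number of 10 cm stratigraphic levels.
#' @param boundaries Interior level indices at which a new facies starts
#'   (level `b` is the first level of the new segment); empty for one facies.
#' @param edges Planted pair specification from [edge_spec()], with taxon
#'   indices in `1..n_taxa`; `NULL` for none.
#' @param baseline_meanlog,baseline_sdlog Log-normal prior for per-segment,
#'   per-taxon baseline mean abundance (defaults give typical level counts of
#'   a few to tens of specimens, as in densely sampled shale beds).
#' @param noise_sd Standard deviation of the latent log-abundance field.
#' @param facies_profiles Optional `n_segments x n_taxa` matrix of
#'   log-baseline abundances overriding the log-normal prior, for planting
#'   contrasts of controlled strength (e.g. disjoint dominant taxa).
#' @param seed Integer seed; the construction is deterministic given it.
#' @return A list of class `synthetic_assemblage` with fields `abundance`
#'   ([abundance_matrix()]), `traits` ([taxon_traits()]), `planted_edges`,
#'   `planted_boundaries`, `preservation_probs` and `latent_correlation`.
#' @export
generate_assemblage <- function(n_taxa, n_levels, boundaries = integer(0),
                                edges = NULL, baseline_meanlog = log(8),
                                baseline_sdlog = 0.8, noise_sd = 0.6,
                                facies_profiles = NULL, seed = 1) {
  stopifnot(n_taxa >= 2, n_levels >= 2)
  boundaries <- sort(unique(as.integer(boundaries)))
  if (length(boundaries) > 0 &&
      (min(boundaries) < 2 || max(boundaries) > n_levels)) {
    stop("boundaries must be interior level indices (2..n_levels)")
  }
  if (!is.null(edges) && nrow(edges) > 0) {
    if (!is.numeric(edges$taxon_a)) {
      stop("edge_spec for generation uses taxon indices")
    }
    if (max(edges$taxon_a, edges$taxon_b) > n_taxa) {
      stop("planted edge taxon index exceeds n_taxa")
    }
  }
  R <- latent_correlation_matrix(n_taxa, edges)
  set.seed(seed)
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))

  # facies segment of each level
  seg <- findInterval(seq_len(n_levels), c(1, boundaries))
  n_seg <- max(seg)
  baselines <- if (is.null(facies_profiles)) {
    matrix(stats::rnorm(n_seg * n_taxa, baseline_meanlog, baseline_sdlog),
           nrow = n_seg)
  } else {
    fp <- as.matrix(facies_profiles)
    if (!all(dim(fp) == c(n_seg, n_taxa))) {
      stop("facies_profiles must be n_segments x n_taxa")
    }
    fp
  }

  # latent Gaussian field with planted correlations (copula construction)
  ev <- eigen(R, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n_taxa) %*%
    t(ev$vectors)
  Z <- matrix(stats::rnorm(n_levels * n_taxa), n_levels) %*% rt

  log_mu <- baselines[seg, , drop = FALSE] + noise_sd * Z
  counts <- matrix(stats::rpois(n_levels * n_taxa, exp(log_mu)), n_levels,
                   dimnames = list(NULL, taxa))

  traits <- taxon_traits(
    taxa,
    body_type = sample(body_type_levels, n_taxa, replace = TRUE),
    size_class = sample(size_class_levels, n_taxa, replace = TRUE),
    habitat = sample(habitat_levels, n_taxa, replace = TRUE),
    motility = sample(c("motile", "sessile", "facultative"), n_taxa,
                      replace = TRUE)
  )

  planted <- if (is.null(edges) || nrow(edges) == 0) {
    data.frame(taxon_a = character(0), taxon_b = character(0),
               class = character(0), rho = numeric(0))
  } else {
    data.frame(taxon_a = taxa[edges$taxon_a], taxon_b = taxa[edges$taxon_b],
               class = edges$class, rho = edges$rho, stringsAsFactors = FALSE)
  }

  structure(
    list(abundance = abundance_matrix(counts,
                                      level_ids = seq_len(n_levels) * 10,
                                      thickness_cm = 10),
         traits = traits,
         planted_edges = planted,
         planted_boundaries = boundaries,
         preservation_probs = stats::setNames(rep(1, n_taxa), taxa),
         latent_correlation = R),
    class = "synthetic_assemblage"
  )
}

#' @export
print.synthetic_assemblage <- function(x, ...) {
  cat(sprintf("synthetic_assemblage: %d levels x %d taxa, %d planted edges, boundaries at {%s}\n",
              nrow(x$abundance$counts), ncol(x$abundance$counts),
              nrow(x$planted_edges),
              paste(x$planted_boundaries, collapse = ", ")))
  invisible(x)
}

#' Binomial preservation thinning
#'
#' Each cell count is replaced by a Binomial(count, p) draw with the taxon's
#' preservation probability, emulating taphonomic loss that acts
#' independently on specimens. `p = 1` leaves a taxon untouched.
#'
#' @param m An [abundance_matrix()].
#' @param probs Per-taxon preservation probability in (0, 1]; a single value
#'   is recycled; a named vector is matched by taxon name.
#' @param seed Optional integer seed.
#' @return The thinned [abundance_matrix()].
#' @export
apply_preservation <- function(m, probs, seed = NULL) {
  taxa <- taxa_of(m)
  if (!is.null(names(probs))) {
    idx <- match(taxa, names(probs))
    if (anyNA(idx)) {
      stop("preservation probability missing for taxon: ",
           paste(taxa[is.na(idx)], collapse = ", "))
    }
    probs <- probs[idx]
  } else {
    probs <- rep_len(probs, length(taxa))
  }
  if (any(probs <= 0 | probs > 1)) {
    stop("preservation probabilities must lie in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- m$counts
  for (j in seq_along(taxa)) {
    if (probs[j] < 1) {
      counts[, j] <- stats::rbinom(nrow(counts), counts[, j], probs[j])
    }
  }
  abundance_matrix(counts, level_ids = m$level_ids,
                   thickness_cm = m$thickness_cm)
}

#' Map a trait factor to per-taxon preservation probabilities
#'
#' @param traits A [taxon_traits()] table.
#' @param factor One of `"body_type"`, `"size_class"`, `"habitat"`.
#' @param probs_by_category Named vector of probabilities covering every
#'   category of the factor present in the table.
#' @return Named per-taxon probability vector.
#' @export
trait_preservation_map <- function(traits,
                                   factor = c("body_type", "size_class",
                                              "habitat"),
                                   probs_by_category) {
  factor <- match.arg(factor)
  labels <- traits[[factor]]
  missing_cat <- setdiff(unique(labels), names(probs_by_category))
  if (length(missing_cat) > 0) {
    stop("probs_by_category lacks categories: ",
         paste(missing_cat, collapse = ", "))
  }
  p <- probs_by_category[labels]
  if (any(p <= 0 | p > 1)) stop("preservation probabilities must lie in (0, 1]")
  stats::setNames(as.numeric(p), traits$taxon)
}
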