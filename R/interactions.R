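pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Categorize significant pairs of a correlation set
#'
#' Maps each pair with BH-adjusted q-value at or below `alpha` to the
#' category interval containing its correlation; correlations between
#' intervals stay uncategorized.
#'
#' @param cs A [corrected_correlations()] set.
#' @param scheme A [cluster_components()] scheme.
#' @param alpha Significance threshold on q (default 0.05).
#' @return Data frame `taxon_a`, `taxon_b`, `r`, `category` (NA if outside
#'   all intervals).
#' @export
categorize_pairs <- function(cs, scheme, alpha = 0.05) {
  if (is.null(scheme) || scheme$C < 1) stop("empty category scheme")
  sig <- cs[cs$q <= alpha, , drop = FALSE]
  data.frame(taxon_a = sig$taxon_a, taxon_b = sig$taxon_b, r = sig$r,
             category = assign_category(sig$r, scheme),
             stringsAsFactors = FALSE)
}

#' Consensus interactions across strata
#'
#' For every taxon pair, the modal category over the strata where the two
#' taxa co-occur; the pair obtains a consensus category only when the modal
#' category holds in strictly more than half of those strata (strata where
#' the co-occurring pair has no categorized edge count against consensus).
#'
#' @param per_stratum List with one element per stratum, each a list with
#'   `categories` (a [categorize_pairs()] data frame) and `taxa_present`
#'   (character vector of taxa occurring in the stratum).
#' @return An `interaction_records` data frame: `taxon_a`, `taxon_b`,
#'   `consensus_category` (NA if none), `consensus_fraction`,
#'   `n_cooccurring`.
#' @export
consensus_interactions <- function(per_stratum) {
  if (length(per_stratum) < 1) stop("need at least one stratum")
  votes <- list()    # pair -> vector of categories (NA = uncategorized)
  cooc <- list()
  for (st in per_stratum) {
    present <- st$taxa_present
    if (length(present) < 2) next
    pairs <- utils::combn(sort(present), 2)
    cat_df <- st$categories
    ck <- pair_key(cat_df$taxon_a, cat_df$taxon_b)
    for (j in seq_len(ncol(pairs))) {
      k <- pair_key(pairs[1, j], pairs[2, j])
      hit <- match(k, ck)
      v <- if (is.na(hit)) NA_integer_ else cat_df$category[hit]
      votes[[k]] <- c(votes[[k]], v)
    }
  }
  if (length(votes) == 0) {
    return(structure(data.frame(taxon_a = character(0),
                                taxon_b = character(0),
                                consensus_category = integer(0),
                                consensus_fraction = numeric(0),
                                n_cooccurring = integer(0)),
                     class = c("interaction_records", "data.frame")))
  }
  rows <- lapply(names(votes), function(k) {
    v <- votes[[k]]
    n <- length(v)
    tab <- table(v[!is.na(v)])
    taxa <- strsplit(k, "\r", fixed = TRUE)[[1]]
    if (length(tab) == 0) {
      return(data.frame(taxon_a = taxa[1], taxon_b = taxa[2],
                        consensus_category = NA_integer_,
                        consensus_fraction = 0, n_cooccurring = n))
    }
    best <- which.max(tab)
    frac <- as.numeric(tab[best]) / n
    data.frame(taxon_a = taxa[1], taxon_b = taxa[2],
               consensus_category = if (frac > 0.5)
                 as.integer(names(tab)[best]) else NA_integer_,
               consensus_fraction = frac, n_cooccurring = n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$taxon_a, out$taxon_b), ]
  rownames(out) <- NULL
  class(out) <- c("interaction_records", "data.frame")
  out
}

#' Compare consensus interactions with a literature list
#'
#' Categories above the lowest are treated as trophic, the lowest category
#' as competitive. Confirmed = literature pairs with a trophic consensus;
#' missing = analyzable literature pairs without one; proposed = trophic
#' consensus pairs absent from the literature, split by whether either
#' taxon appears in the literature at all; competitive consensus pairs are
#' counted separately (no literature reference set exists for them).
#'
#' @param records An [consensus_interactions()] data frame.
#' @param literature_pairs Data frame with columns `taxon_a`, `taxon_b`
#'   (undirected).
#' @param data_taxa Taxa analyzable in the data set (passing the occupancy
#'   filter); literature pairs touching other taxa are counted
#'   `rare_excluded` (or `out_of_data` when absent entirely).
#' @param competitive_category Category id treated as competitive
#'   (default 1).
#' @return A `comparison_summary` list of counts plus `accuracy` =
#'   confirmed / (confirmed + missing).
#' @export
compare_to_literature <- function(records, literature_pairs, data_taxa,
                                  competitive_category = 1) {
  lit_k <- unique(pair_key(as.character(literature_pairs$taxon_a),
                           as.character(literature_pairs$taxon_b)))
  lit_taxa <- unique(c(as.character(literature_pairs$taxon_a),
                       as.character(literature_pairs$taxon_b)))
  rec_k <- pair_key(records$taxon_a, records$taxon_b)
  trophic <- !is.na(records$consensus_category) &
    records$consensus_category != competitive_category
  competitive <- !is.na(records$consensus_category) &
    records$consensus_category == competitive_category
  trophic_k <- rec_k[trophic]

  analyzable <- vapply(strsplit(lit_k, "\r", fixed = TRUE), function(tx) {
    all(tx %in% data_taxa)
  }, logical(1))
  confirmed <- sum(lit_k[analyzable] %in% trophic_k)
  missing <- sum(analyzable) - confirmed
  rare_excluded <- sum(!analyzable)

  proposed_k <- setdiff(trophic_k, lit_k)
  prop_taxa <- strsplit(proposed_k, "\r", fixed = TRUE)
  partial <- vapply(prop_taxa, function(tx) any(tx %in% lit_taxa),
                    logical(1))
  structure(list(
    confirmed = confirmed, missing = missing,
    rare_excluded = rare_excluded,
    proposed = length(proposed_k),
    proposed_partial = sum(partial),
    proposed_new = sum(!partial),
    competitive = sum(competitive),
    accuracy = if (confirmed + missing > 0)
      confirmed / (confirmed + missing) else NA_real_
  ), class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf(
    "comparison_summary: %d confirmed / %d missing (accuracy %.1f%%), %d proposed (%d partial + %d new), %d competitive, %d rare-excluded\n",
    x$confirmed, x$missing, 100 * x$accuracy, x$proposed,
    x$proposed_partial, x$proposed_new, x$competitive, x$rare_excluded))
  invisible(x)
}

# profile log-likelihood of a Bernoulli SBM for a given block assignment
sbm_loglik <- function(adj, blocks) {
  bl <- sort(unique(blocks))
  ll <- 0
  for (i in seq_along(bl)) {
    for (j in i:length(bl)) {
      bi <- which(blocks == bl[i]); bj <- which(blocks == bl[j])
      if (i == j) {
        n_pairs <- length(bi) * (length(bi) - 1) / 2
        e <- sum(adj[bi, bi]) / 2
      } else {
        n_pairs <- length(bi) * length(bj)
        e <- sum(adj[bi, bj])
      }
      if (n_pairs == 0) next
      p <- e / n_pairs
      if (p > 0 && p < 1) {
        ll <- ll + e * log(p) + (n_pairs - e) * log(1 - p)
      }
    }
  }
  ll
}

fit_sbm <- function(adj, n_blocks_range) {
  n <- nrow(adj)
  blocks <- seq_len(n)
  best <- list(blocks = blocks, score = -Inf)
  n_pairs_tot <- n * (n - 1) / 2
  score_of <- function(blocks) {
    B <- length(unique(blocks))
    sbm_loglik(adj, blocks) - 0.5 * (B * (B + 1) / 2) * log(n_pairs_tot)
  }
  # agglomerative: merge the block pair that best improves the likelihood
  while (length(unique(blocks)) > min(n_blocks_range)) {
    bl <- sort(unique(blocks))
    if (length(bl) <= max(n_blocks_range)) {
      sc <- score_of(blocks)
      if (sc > best$score) best <- list(blocks = blocks, score = sc)
    }
    base_ll <- sbm_loglik(adj, blocks)
    gain_best <- -Inf; merge_best <- NULL
    for (i in seq_along(bl)) {
      for (j in seq_len(i - 1)) {
        bb <- blocks
        bb[bb == bl[i]] <- bl[j]
        g <- sbm_loglik(adj, bb) - base_ll
        if (g > gain_best) {
          gain_best <- g; merge_best <- c(bl[i], bl[j])
        }
      }
    }
    if (is.null(merge_best)) break
    blocks[blocks == merge_best[1]] <- merge_best[2]
  }
  if (length(unique(blocks)) >= min(n_blocks_range)) {
    sc <- score_of(blocks)
    if (sc > best$score) best <- list(blocks = blocks, score = sc)
  }
  match(best$blocks, sort(unique(best$blocks)))
}

#' Weighted Shannon equitability of trait labels across SBM blocks
#'
#' Fits a (non-degree-corrected) stochastic block model to the network by
#' agglomerative likelihood merging, then computes within each block the
#' Shannon equitability `H(label distribution) / ln(k)` of the node labels
#' (k = number of label types present in the network; single-node blocks
#' score 0) and averages over blocks weighted by block size. 1 means every
#' block mixes the label types evenly; 0 means each block is dominated by a
#' single type.
#'
#' @param g A [corr_network()].
#' @param labels Named per-node category vector (e.g. habitat or motility).
#' @param n_blocks_range Admissible block counts (default 1..6).
#' @param seed Unused placeholder for interface stability (fit is
#'   deterministic).
#' @return List with `equitability`, `blocks` (named assignment),
#'   `n_blocks`.
#' @export
sbm_equitability <- function(g, labels, n_blocks_range = 1:6, seed = 1) {
  nodes <- g$nodes
  if (length(nodes) < 4) stop("need at least 4 nodes")
  if (!is.null(names(labels))) labels <- labels[nodes]
  k <- length(unique(labels))
  if (k < 2) {
    warning("single label type; equitability 0")
    return(list(equitability = 0,
                blocks = stats::setNames(rep(1L, length(nodes)), nodes),
                n_blocks = 1L))
  }
  adj <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(g$edges) > 0) {
    adj[cbind(g$edges$taxon_a, g$edges$taxon_b)] <- 1L
    adj[cbind(g$edges$taxon_b, g$edges$taxon_a)] <- 1L
  }
  blocks <- fit_sbm(adj, n_blocks_range)
  eq <- vapply(sort(unique(blocks)), function(b) {
    lab <- labels[blocks == b]
    if (length(lab) < 2) return(0)
    p <- table(lab) / length(lab)
    -sum(p * log(p)) / log(k)
  }, numeric(1))
  sizes <- as.integer(table(blocks))
  list(equitability = sum(eq * sizes) / sum(sizes),
       blocks = stats::setNames(blocks, nodes),
       n_blocks = length(unique(blocks)))
}

#' Habitat-association test for signed edges
#'
#' Tests whether edges of the selected sign preferentially connect taxa of
#' the same (or different) habitat: a 2x2 table of edge sign membership
#' (selected sign vs the other) against habitat relation (same vs
#' different), with Yates-corrected Pearson chi-squared.
#'
#' @param cs A [corrected_correlations()] set.
#' @param habitats Named habitat label per taxon.
#' @param sign `"negative"` or `"positive"`: which edge sign to test.
#' @param alpha Significance threshold selecting edges (on q).
#' @return List with `chisq`, `p`, `table`, `degenerate`.
#' @export
habitat_chisq <- function(cs, habitats,
                          sign = c("negative", "positive"), alpha = 0.05) {
  sign <- match.arg(sign)
  sig <- cs[cs$q <= alpha, , drop = FALSE]
  if (nrow(sig) == 0) stop("no significant pairs to test")
  in_sign <- if (sign == "negative") sig$r < 0 else sig$r > 0
  if (!any(in_sign)) {
    stop(sprintf("no significant %s pairs to test", sign))
  }
  same_hab <- habitats[sig$taxon_a] == habitats[sig$taxon_b]
  tab <- table(factor(in_sign, levels = c(TRUE, FALSE)),
               factor(same_hab, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chisq = 0, p = 1, table = tab, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(chisq = unname(ct$statistic), p = unname(ct$p.value), table = tab,
       degenerate = FALSE)
}
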