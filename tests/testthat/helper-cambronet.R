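# shared fixture builders; everything is generated in code

# iid multinomial levels from one fixed community (homogeneous null)
multinomial_section <- function(seed, n_levels = 100, n_taxa = 15,
                                n_per_level = 80) {
  set.seed(seed)
  p <- stats::rexp(n_taxa) + 0.2
  p <- p / sum(p)
  counts <- t(vapply(seq_len(n_levels),
                     function(i) stats::rmultinom(1, n_per_level, p)[, 1],
                     integer(n_taxa)))
  abundance_matrix(counts)
}

# two facies with disjoint dominant taxa (hard composition change)
hard_profiles <- function(n_taxa = 16) {
  hi <- log(25); lo <- log(2)
  rbind(c(rep(hi, n_taxa / 2), rep(lo, n_taxa / 2)),
        c(rep(lo, n_taxa / 2), rep(hi, n_taxa / 2)))
}

# planted interaction structure used by the end-to-end checks: a
# specialist-like block (taxa 1-5 mutually 0.8), a generalist-like block
# (6-11 mutually 0.5), competitive pairs (12,13)...(22,23) at -0.55
planted_blocks <- function() {
  ta <- c(); tb <- c(); cls <- c(); rho <- c()
  p1 <- t(utils::combn(1:5, 2))
  ta <- c(ta, p1[, 1]); tb <- c(tb, p1[, 2])
  cls <- c(cls, rep("specialist", nrow(p1))); rho <- c(rho, rep(0.8, nrow(p1)))
  p2 <- t(utils::combn(6:11, 2))
  ta <- c(ta, p2[, 1]); tb <- c(tb, p2[, 2])
  cls <- c(cls, rep("generalist", nrow(p2))); rho <- c(rho, rep(0.5, nrow(p2)))
  ta <- c(ta, c(12, 14, 16, 18, 20, 22)); tb <- c(tb, c(13, 15, 17, 19, 21, 23))
  cls <- c(cls, rep("competitive", 6)); rho <- c(rho, rep(-0.55, 6))
  data.frame(taxon_a = ta, taxon_b = tb, class = cls, rho = rho)
}

# four facies, each with six stratum-specific dominant taxa
e2e_profiles <- function(n_seg = 4, n_taxa = 24, seed = 99) {
  set.seed(seed)
  base <- matrix(stats::rnorm(n_seg * n_taxa, log(12), 0.3), n_seg)
  for (k in seq_len(n_seg)) {
    dom <- ((k - 1) * 6 + 1):((k - 1) * 6 + 6)
    base[k, dom] <- base[k, dom] + 1.4
  }
  base
}

# dense-marginal assemblage with a category-orthogonal block structure,
# used by the preservation-bias recovery checks
bias_assemblage <- function(seed, n_levels = 300) {
  pairs <- t(utils::combn(24, 2))
  blocks <- rep(1:4, each = 6)
  inblk <- blocks[pairs[, 1]] == blocks[pairs[, 2]]
  es <- data.frame(taxon_a = pairs[, 1], taxon_b = pairs[, 2],
                   class = "generalist",
                   rho = ifelse(inblk, 0.75, 0.5))
  syn <- generate_assemblage(24, n_levels, edges = es,
                             baseline_meanlog = log(25), noise_sd = 0.8,
                             seed = seed)
  syn$traits$body_type <-
    rep(c("soft", "soft", "intermediate", "hard", "intermediate", "hard"), 4)
  syn
}

# small ABM corpus shared between bias tests (memoized per test run)
tiny_corpus_env <- new.env()
tiny_corpus <- function() {
  if (is.null(tiny_corpus_env$corpus)) {
    tiny_corpus_env$corpus <-
      run_abm_corpus(n_runs = 10, n_degradations = 4, seed = 5,
                     steps = 200, burn_in = 50)
  }
  tiny_corpus_env$corpus
}

# build a corr_network from an explicit edge list of node-name pairs
net_from_pairs <- function(nodes, pairs, weight = 0.8) {
  if (length(pairs) == 0 || is.null(nrow(pairs))) {
    return(corr_network(nodes))
  }
  corr_network(nodes, data.frame(taxon_a = pairs[, 1], taxon_b = pairs[, 2],
                                 weight = weight, q_value = 0.01))
}
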