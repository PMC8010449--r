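test_that("hamming distance matches pair enumeration and is a metric", {
  nodes <- c("A", "B", "C", "D")
  g1 <- net_from_pairs(nodes, rbind(c("A", "B"), c("B", "C")))
  g2 <- net_from_pairs(nodes, rbind(c("A", "B"), c("C", "D")))
  expect_equal(hamming_distance(g1, g1), 0)
  expect_equal(hamming_distance(g1, g2), 2 / 6)
  empty <- net_from_pairs(nodes, NULL)
  complete <- net_from_pairs(nodes, t(combn(nodes, 2)))
  expect_equal(hamming_distance(empty, complete), 1)
  expect_error(hamming_distance(g1, net_from_pairs(c("A", "B", "C"), NULL)),
               "node set")

  # independent oracle: mean of the XOR of adjacency matrices; plus the
  # metric axioms on random graph triples
  adj_of <- function(g) {
    a <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
    if (nrow(g$edges)) {
      a[cbind(g$edges$taxon_a, g$edges$taxon_b)] <- 1
      a[cbind(g$edges$taxon_b, g$edges$taxon_a)] <- 1
    }
    a
  }
  set.seed(1)
  rand_g <- function() {
    pr <- t(combn(nodes, 2))
    net_from_pairs(nodes, pr[runif(6) < 0.5, , drop = FALSE])
  }
  for (i in 1:20) {
    ga <- rand_g(); gb <- rand_g(); gc <- rand_g()
    oracle <- sum(abs(adj_of(ga) - adj_of(gb))) / 2 / 6
    expect_equal(hamming_distance(ga, gb), oracle)
    expect_equal(hamming_distance(ga, gb), hamming_distance(gb, ga))
    expect_lte(hamming_distance(ga, gc),
               hamming_distance(ga, gb) + hamming_distance(gb, gc) + 1e-12)
  }
})

test_that("ERGM MPLE separates category-structured from random networks", {
  set.seed(2)
  nodes <- sprintf("n%02d", 1:18)
  labs <- setNames(rep(c("hard", "soft", "intermediate"), 6), nodes)

  # perfect-separation construction: hard clique, soft isolated
  hard <- nodes[labs == "hard"]
  g_clique <- net_from_pairs(nodes, t(combn(hard, 2)))
  fit <- fit_ergm(g_clique, labs)
  expect_gt(fit$delta, 0.5)
  expect_gt(fit$coefficients[["match.hard"]], 0)

  # random graph, random labels: delta stays near 0
  deltas <- vapply(1:30, function(s) {
    set.seed(s + 100)
    pr <- t(combn(nodes, 2))
    g <- net_from_pairs(nodes, pr[runif(nrow(pr)) < 0.3, , drop = FALSE])
    fit_ergm(g, setNames(sample(labs), nodes))$delta
  }, numeric(1))
  expect_lt(median(deltas), 0.1)

  # degenerate graphs flag delta = 0
  expect_equal(fit_ergm(net_from_pairs(nodes, NULL), labs)$delta, 0)
  expect_true(fit_ergm(net_from_pairs(nodes, NULL), labs)$degenerate)

  # invariant to relabeling node order
  perm <- sample(nodes)
  expect_equal(fit_ergm(g_clique, labs[perm])$delta, fit$delta)

  expect_error(fit_ergm(g_clique, labs[1:5]), "missing")
  expect_error(fit_ergm(net_from_pairs(nodes[1:3], NULL), labs[1:3]),
               "5 nodes")
})

test_that("calibration is monotone and tracks degradation severity", {
  cal <- calibrate_bias(tiny_corpus(), net_builder())
  expect_true(all(diff(cal$fitted) >= -1e-12))
  expect_true(all(cal$fitted >= 0 & cal$fitted <= 1))
  expect_gt(cor(cal$raw$delta, cal$raw$d_hamming, method = "spearman"), 0)

  # all-perfect corpus: calibration flat near 0
  perfect <- run_abm_corpus(n_runs = 2, n_degradations = 2,
                            degradation_probs = c(1, 1, 1), seed = 4,
                            steps = 120, burn_in = 40)
  expect_warning(cal0 <- calibrate_bias(perfect, net_builder()),
                 "no degradation effect")
  expect_true(all(cal0$fitted == 0))
})

test_that("bias coefficient separates null from constructed bias", {
  cal <- calibrate_bias(tiny_corpus(), net_builder())
  nodes <- sprintf("n%02d", 1:30)
  labs <- setNames(rep(c("hard", "soft", "intermediate"), 10), nodes)
  hard <- nodes[labs == "hard"]
  g_clique <- net_from_pairs(nodes, t(combn(hard, 2)))
  co_clique <- bias_coefficient(g_clique, labs, cal)
  set.seed(3)
  co_null <- replicate(30, {
    pr <- t(combn(nodes, 2))
    g <- net_from_pairs(nodes, pr[runif(nrow(pr)) < 0.3, , drop = FALSE])
    bias_coefficient(g, setNames(sample(labs), nodes), cal)
  })
  expect_gt(co_clique, median(co_null))
  expect_true(all(co_null >= 0 & co_null <= 1))
  expect_error(bias_coefficient(g_clique, labs[1:4], cal), "missing")
})

test_that("window series flag and trim by threshold", {
  # synthetic calibration: identity-ish monotone map
  grid <- seq(0, 1, 0.05)
  cal <- structure(list(delta = grid, fitted = grid,
                        raw = data.frame(delta = grid, d_hamming = grid)),
                   class = "bias_calibration")
  nodes <- sprintf("n%02d", 1:18)
  labs3 <- rep(c("hard", "soft", "intermediate"), 6)
  traits <- taxon_traits(nodes, body_type = labs3,
                         size_class = rep(c("small", "medium", "large"), 6),
                         habitat = rep(habitat_levels, 6),
                         motility = "motile")
  m <- abundance_matrix(matrix(5L, 40, length(nodes),
                               dimnames = list(NULL, nodes)))
  wins <- make_windows(m, 10, 10)
  set.seed(4)
  pr <- t(combn(nodes, 2))
  g_rand <- net_from_pairs(nodes, pr[runif(nrow(pr)) < 0.3, , drop = FALSE])
  g_biased <- net_from_pairs(nodes, t(combn(nodes[labs3 == "hard"], 2)))
  nets <- list(g_biased, g_rand, g_rand, g_rand)

  bs <- bias_series_and_trim(wins, nets, traits, cal, threshold = 0.5)
  expect_equal(nrow(bs$series), 4)
  expect_true(bs$series$excluded[1])
  expect_false(any(bs$series$excluded[2:4]))
  expect_equal(bs$trim_start, 1L)
  expect_equal(bs$trim_end, 0L)

  bs0 <- bias_series_and_trim(wins, nets, traits, cal, threshold = 0)
  expect_true(all(bs0$series$excluded))

  # flat-zero calibration: nothing trimmed
  cal0 <- structure(list(delta = c(0, 1), fitted = c(0, 0),
                         raw = data.frame(delta = c(0, 1),
                                          d_hamming = c(0, 0))),
                    class = "bias_calibration")
  bsf <- bias_series_and_trim(wins, nets, traits, cal0, threshold = 0.5)
  expect_false(any(bsf$series$excluded))
  expect_error(bias_series_and_trim(wins, nets[1:2], traits, cal),
               "one network per window")
})
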