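test_that("near-duplicate columns give r near 1 and chains give small partials", {
  set.seed(1)
  base <- rpois(120, 30)
  jit <- pmax(base + sample(c(-1L, 0L, 1L), 120, replace = TRUE), 0L)
  m <- abundance_matrix(cbind(a = base, b = jit,
                              c = rpois(120, 10), d = rpois(120, 10)))
  cs <- corrected_correlations(m, shrinkage = 0)
  expect_gt(cs$r[cs$taxon_a == "a" & cs$taxon_b == "b"], 0.95)

  # latent chain X <- Y -> Z: marginal corr(X, Z) > 0, partial ~ 0;
  # oracle from the closed-form partial correlation of the constructed
  # covariance: r_xz|y = (r_xz - r_xy r_yz) / sqrt((1-r_xy^2)(1-r_yz^2))
  set.seed(2)
  n <- 600
  y <- rnorm(n)
  x <- 0.8 * y + rnorm(n, 0, 0.6)
  z <- 0.8 * y + rnorm(n, 0, 0.6)
  counts <- round(exp(2 + 0.5 * cbind(x = x, y = y, z = z)))
  m2 <- abundance_matrix(counts)
  cs2 <- corrected_correlations(m2, shrinkage = 0)
  X <- log1p(counts)
  r_xy <- cor(X[, "x"], X[, "y"]); r_yz <- cor(X[, "y"], X[, "z"])
  r_xz <- cor(X[, "x"], X[, "z"])
  oracle <- (r_xz - r_xy * r_yz) / sqrt((1 - r_xy^2) * (1 - r_yz^2))
  got <- cs2$r[cs2$taxon_a == "x" & cs2$taxon_b == "z"]
  expect_gt(r_xz, 0.3)
  expect_equal(got, oracle, tolerance = 1e-6)
  expect_lt(abs(got), 0.15)
})

test_that("type-I error is calibrated on independent columns", {
  fpr <- vapply(1:10, function(s) {
    set.seed(s)
    m <- abundance_matrix(matrix(rpois(500 * 10, 8), 500, 10))
    cs <- corrected_correlations(m, shrinkage = 0)
    mean(cs$p < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fpr) - 0.05), 0.02)
})

test_that("partial correlations are invariant to per-taxon scaling", {
  set.seed(3)
  counts <- matrix(rpois(200 * 6, 20), 200, 6)
  m1 <- abundance_matrix(counts)
  counts2 <- counts
  counts2[, 4] <- counts2[, 4] * 7L
  m2 <- abundance_matrix(counts2)
  cs1 <- corrected_correlations(m1, shrinkage = 0.1)
  cs2 <- corrected_correlations(m2, shrinkage = 0.1)
  # log(1+x) turns scaling into a near-additive shift at these counts
  expect_equal(cs1$r, cs2$r, tolerance = 0.02)
})

test_that("permutation destroys edges and planted edges are detected", {
  # permutation safety: independently shuffled levels leave few edges
  edge_counts <- vapply(1:10, function(s) {
    syn <- generate_assemblage(10, 150, edges = edge_spec(1, 2, rho = 0.9),
                               seed = s)
    counts <- apply(syn$abundance$counts, 2, sample)
    g <- build_network(corrected_correlations(abundance_matrix(counts)))
    nrow(g$edges)
  }, numeric(1))
  expect_lte(mean(edge_counts), 0.05 * choose(10, 2))

  # power: the planted strong edge is recovered
  hits <- vapply(1:20, function(s) {
    syn <- generate_assemblage(10, 200, edges = edge_spec(1, 2, rho = 0.9),
                               baseline_meanlog = log(15),
                               baseline_sdlog = 0.5, seed = s)
    g <- build_network(corrected_correlations(syn$abundance), alpha = 0.05)
    any(g$edges$taxon_a == "taxon_01" & g$edges$taxon_b == "taxon_02")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("build_network filters on q, keeps signs and all nodes", {
  set.seed(4)
  m <- abundance_matrix(matrix(rpois(300, 10), 50, 6))
  cs <- corrected_correlations(m)
  g <- build_network(cs, alpha = 0.05)
  expect_setequal(g$nodes, attr(cs, "nodes"))
  expect_true(all(g$edges$q_value <= 0.05))
  key_cs <- paste(cs$taxon_a, cs$taxon_b)
  expect_true(all(paste(g$edges$taxon_a, g$edges$taxon_b) %in% key_cs))
  expect_error(build_network(cs, alpha = 0), "alpha")
  g_none <- build_network(cs, alpha = 1e-12)
  expect_equal(nrow(g_none$edges), 0L)
})

test_that("degenerate inputs are rejected with guidance", {
  m3 <- abundance_matrix(matrix(rpois(9, 5), 3, 3))
  expect_error(corrected_correlations(m3), "4 levels")

  # rare taxa fall below the occupancy filter
  counts <- cbind(a = rpois(40, 10), b = rpois(40, 10),
                  c = c(rep(0L, 38), 1L, 1L))
  cs <- corrected_correlations(abundance_matrix(counts))
  expect_true("c" %in% attr(cs, "excluded"))
  expect_false("c" %in% cs$taxon_a | "c" %in% cs$taxon_b)

  expect_warning(
    corrected_correlations(abundance_matrix(
      cbind(a = rpois(20, 5), b = rep(0L, 20), c = rep(0L, 20)))),
    "occupancy")

  # more taxa than levels is singular without shrinkage
  set.seed(5)
  wide <- abundance_matrix(matrix(rpois(10 * 30, 10), 10, 30))
  expect_error(corrected_correlations(wide, shrinkage = 0), "shrinkage")
  cs_auto <- corrected_correlations(wide, shrinkage = "auto")
  expect_true(all(is.finite(cs_auto$r)))
})
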