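# small, fast configuration reused across ABM tests
small_cfg <- function(...) {
  abm_config(n_prey = 5, n_predators = 2, n_specialists = 1,
             generalist_diet_size = 3, grid_side = 14, init_prey = 25,
             init_predators = 10, steps = 150, burn_in = 50, ...)
}

test_that("simulations are bit-reproducible under a fixed seed", {
  r1 <- run_abm(small_cfg(seed = 42))
  r2 <- run_abm(small_cfg(seed = 42))
  expect_identical(r1$census, r2$census)
  r3 <- run_abm(small_cfg(seed = 43))
  expect_false(identical(r1$census, r3$census))
})

test_that("true pair labels partition all species pairs exactly once", {
  cfg <- abm_config()
  lab <- abm_pair_labels(cfg)
  expect_equal(nrow(lab), choose(25, 2))
  expect_false(any(duplicated(lab[, c("species_a", "species_b")])))
  expect_equal(sum(lab$label == "specialist"), cfg$n_specialists)
  # all prey-prey pairs compete through the shared resource
  prey_pairs <- lab$species_a <= 17 & lab$species_b <= 17
  expect_true(all(lab$label[prey_pairs] == "competition"))
  expect_setequal(unique(lab$label),
                  c("specialist", "generalist", "competition", "none"))
})

test_that("census bookkeeping balances births and deaths", {
  res <- run_abm(small_cfg(seed = 7))
  pop <- rowSums(res$census)
  n0 <- 5 * 25 + 2 * 10
  expect_equal(pop, n0 + cumsum(res$births) - cumsum(res$deaths))
  expect_true(all(res$census >= 0))
})

test_that("prey persist without predators and starve without resource", {
  # ample resource, no predators: positive quasi-stationary level
  surv <- vapply(1:20, function(s) {
    cfg <- abm_config(n_prey = 5, n_predators = 0, n_specialists = 0,
                      grid_side = 14, init_prey = 25, steps = 150,
                      burn_in = 50, resource_regrowth = 1, env_sd = 0.08,
                      seed = s)
    cen <- run_abm(cfg)$census
    all(colMeans(cen[101:150, , drop = FALSE]) > 0)
  }, logical(1))
  expect_gte(mean(surv), 0.9)

  # no regrowth, no immigration: energy runs out, everything dies
  cfg0 <- small_cfg(resource_regrowth = 0, immigration = 0, seed = 3)
  cen <- run_abm(cfg0)$census
  expect_true(all(cen[nrow(cen), ] == 0))
})

test_that("population explosions abort with a diagnostic", {
  cfg <- small_cfg(max_agents = 50, seed = 1)
  expect_error(run_abm(cfg), "max_agents")
})

test_that("specialist predators track their prey positively in most runs", {
  rs <- vapply(1:8, function(s) {
    res <- run_abm(abm_config(n_prey = 4, n_predators = 1,
                              n_specialists = 1, generalist_diet_size = 2,
                              grid_side = 18,
                              init_prey = 40, init_predators = 15,
                              steps = 400, burn_in = 100, seed = s))
    cc <- abm_correlations(res)
    r <- cc$r[cc$label == "specialist"]
    if (length(r) == 0) NA_real_ else r
  }, numeric(1))
  expect_gt(mean(rs > 0, na.rm = TRUE), 0.5)
})

test_that("abm_correlations handles duplicates, constants and labels", {
  res <- run_abm(small_cfg(seed = 11))
  # duplicated series correlate exactly 1
  res2 <- res
  res2$census[, 2] <- res2$census[, 1]
  cc <- abm_correlations(res2)
  expect_equal(cc$r[cc$species_a == 1 & cc$species_b == 2], 1)
  # constant series are dropped and counted
  res3 <- res
  res3$census[, 3] <- 5L
  cc3 <- abm_correlations(res3)
  expect_false(any(cc3$species_a == 3 | cc3$species_b == 3))
  expect_equal(attr(cc3, "dropped"),
               sum(res$labels$species_a == 3 | res$labels$species_b == 3))
  # every surviving pair appears exactly once
  expect_false(any(duplicated(cc[, c("species_a", "species_b")])))
  expect_error(abm_correlations(res, burn_in = 150), "burn_in")
})

test_that("corpus bookkeeping: counts and the perfect-preservation case", {
  corpus <- run_abm_corpus(n_runs = 3, n_degradations = 2,
                           degradation_probs = c(1, 1, 1), seed = 2,
                           steps = 120, burn_in = 40)
  expect_length(corpus$runs, 3)
  expect_true(all(vapply(corpus$runs,
                         function(r) length(r$degradations), 0L) == 2L))
  # all categories preserve perfectly: degraded census equals the base
  for (run in corpus$runs) {
    for (deg in run$degradations) {
      expect_identical(deg$census, run$census)
    }
  }
})

test_that("preference matrices are validated and renormalized over diets", {
  expect_error(abm_config(n_prey = 2, n_predators = 1, n_specialists = 0,
                          generalist_diet_size = 2,
                          preference = matrix(c(0.9, 0.1, 0.5), 1)),
               "n_predators x n_prey")
  cfg <- abm_config(n_prey = 2, n_predators = 1, n_specialists = 0,
                    generalist_diet_size = 2,
                    preference = matrix(c(9, 1), 1))
  expect_equal(cfg$preference[1, ], c(0.9, 0.1))
  expect_error(abm_config(n_prey = 2, n_predators = 1, n_specialists = 0,
                          generalist_diet_size = 2,
                          preference = matrix(c(-1, 1), 1)),
               "non-negative")
})
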