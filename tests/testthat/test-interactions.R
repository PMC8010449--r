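toy_scheme <- function() {
  cluster_components(
    data.frame(mean = c(-0.5, -0.48, -0.05, -0.03, 0.3, 0.32, 0.7, 0.72),
               sd = 0.05), seed = 1)
}

test_that("significant pairs map onto category intervals", {
  scheme <- toy_scheme()
  cs <- data.frame(taxon_a = c("a", "a", "b"), taxon_b = c("b", "c", "c"),
                   r = c(0.71, -0.9, -0.04),
                   p = c(0.001, 0.5, 0.01), q = c(0.003, 0.6, 0.02),
                   n_levels = 50, co_occurrence = 50)
  out <- categorize_pairs(cs, scheme, alpha = 0.05)
  expect_equal(nrow(out), 2)  # the q = 0.6 pair is not significant
  expect_equal(out$category[out$taxon_a == "a" & out$taxon_b == "b"], 4L)
  expect_equal(out$category[out$taxon_a == "b"], 2L)
})

test_that("consensus follows the strict majority rule over co-occurring strata", {
  mk <- function(cats) {
    lapply(cats, function(cc) list(
      categories = if (is.na(cc)) {
        data.frame(taxon_a = character(0), taxon_b = character(0),
                   r = numeric(0), category = integer(0))
      } else {
        data.frame(taxon_a = "a", taxon_b = "b", r = 0.7, category = cc)
      },
      taxa_present = c("a", "b")))
  }
  rec <- consensus_interactions(mk(c(4L, 4L, 4L, 2L)))
  expect_equal(rec$consensus_category, 4L)
  expect_equal(rec$consensus_fraction, 0.75)
  expect_equal(rec$n_cooccurring, 4L)

  # exactly 0.5 is not a majority
  rec2 <- consensus_interactions(mk(c(4L, 4L, 2L, 2L)))
  expect_true(is.na(rec2$consensus_category))

  # uncategorized strata count against the consensus
  rec3 <- consensus_interactions(mk(c(4L, NA, NA, 4L)))
  expect_true(is.na(rec3$consensus_category))
  expect_equal(rec3$consensus_fraction, 0.5)

  # strata order does not matter
  rec4 <- consensus_interactions(mk(c(2L, 4L, 4L, 4L)))
  expect_equal(rec4$consensus_category, rec$consensus_category)

  # a pair never co-occurring is absent from the records
  st <- list(
    list(categories = data.frame(taxon_a = "a", taxon_b = "b", r = 0.7,
                                 category = 4L),
         taxa_present = c("a", "b")),
    list(categories = data.frame(taxon_a = character(0),
                                 taxon_b = character(0), r = numeric(0),
                                 category = integer(0)),
         taxa_present = c("c", "d")))
  rec5 <- consensus_interactions(st)
  expect_false(any(rec5$taxon_a == "a" & rec5$taxon_b == "c"))
  expect_true(any(rec5$taxon_a == "c" & rec5$taxon_b == "d"))
})

test_that("literature comparison counts confirmed, missing and proposed", {
  rec <- structure(data.frame(
    taxon_a = c("A", "D", "E", "F"), taxon_b = c("B", "Eo", "F", "G"),
    consensus_category = c(3L, 4L, 1L, 2L),
    consensus_fraction = c(0.8, 1, 0.7, 0.6),
    n_cooccurring = 4L), class = c("interaction_records", "data.frame"))
  lit <- data.frame(taxon_a = c("A", "A"), taxon_b = c("B", "C"))
  cmp <- compare_to_literature(rec, lit,
                               data_taxa = c("A", "B", "C", "D", "Eo",
                                             "E", "F", "G"))
  expect_equal(cmp$confirmed, 1)
  expect_equal(cmp$missing, 1)
  expect_equal(cmp$accuracy, 0.5)
  # trophic consensus pairs absent from literature are proposed; the
  # category-1 (competitive) pair is counted separately
  expect_equal(cmp$proposed, 2)
  expect_equal(cmp$proposed_partial, 0)  # neither D-Eo nor F-G touches a literature taxon
  expect_equal(cmp$proposed_new, 2)
  expect_equal(cmp$competitive, 1)

  # empty literature: accuracy undefined, everything trophic is proposed
  cmp0 <- compare_to_literature(rec, lit[0, ], data_taxa = LETTERS)
  expect_true(is.na(cmp0$accuracy))
  expect_equal(cmp0$proposed, 3)

  # literature pairs with rare/absent taxa are excluded from the accuracy
  lit2 <- data.frame(taxon_a = c("A", "X"), taxon_b = c("B", "Y"))
  cmp2 <- compare_to_literature(rec, lit2, data_taxa = c("A", "B"))
  expect_equal(cmp2$rare_excluded, 1)
  expect_equal(cmp2$confirmed + cmp2$missing, 1)
})

test_that("block equitability hits its closed-form anchor cases", {
  # two planted blocks, labels 6:2 within each block of 8
  nodes <- sprintf("n%02d", 1:16)
  b1 <- nodes[1:8]; b2 <- nodes[9:16]
  dense <- rbind(t(combn(b1, 2)), t(combn(b2, 2)))
  g <- net_from_pairs(nodes, dense)
  labs <- setNames(c(rep("x", 6), rep("y", 2), rep("y", 6), rep("x", 2)),
                   nodes)
  res <- sbm_equitability(g, labs, n_blocks_range = 1:4)
  expect_equal(res$n_blocks, 2L)
  h <- -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(2)
  expect_equal(res$equitability, h, tolerance = 1e-9)
  expect_equal(round(res$equitability, 4), 0.8113)

  # uniform labels across blocks -> 1
  labs_u <- setNames(rep(c("x", "y"), 8), nodes)
  expect_equal(sbm_equitability(g, labs_u, 1:4)$equitability, 1)

  # single-label blocks -> 0
  labs_d <- setNames(c(rep("x", 8), rep("y", 8)), nodes)
  expect_equal(sbm_equitability(g, labs_d, 1:4)$equitability, 0)

  # invariant under renaming of label categories
  labs_r <- setNames(c("p", "q")[match(labs, c("x", "y"))], nodes)
  expect_equal(sbm_equitability(g, labs_r, 1:4)$equitability,
               res$equitability)

  expect_warning(r0 <- sbm_equitability(g, setNames(rep("x", 16), nodes)),
                 "single label")
  expect_equal(r0$equitability, 0)
})

test_that("Yates-corrected chi-squared matches the closed formula", {
  # the standard Yates formula as an independent oracle
  yates <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (abs(a * d - b * c) - n / 2)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
  }
  expect_equal(unname(chisq.test(matrix(c(20, 5, 5, 20), 2),
                                 correct = TRUE)$statistic),
               yates(20, 5, 5, 20))
  expect_equal(round(yates(20, 5, 5, 20), 2), 15.68)

  # craft a correlation set realizing the [[20,5],[5,20]] table:
  # 20 negative same-habitat, 5 negative different, 5 positive same,
  # 20 positive different
  taxa <- sprintf("t%03d", 1:100)
  habs <- setNames(rep("nektobenthic", 100), taxa)
  rows <- list()
  k <- 0
  add_pairs <- function(n, sign, same) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      k <<- k + 2
      a <- taxa[k - 1]; b <- taxa[k]
      if (!same) habs[b] <<- "nektonic/pelagic"
      out[[i]] <- data.frame(taxon_a = a, taxon_b = b,
                             r = if (sign == "neg") -0.5 else 0.5,
                             p = 0.001, q = 0.004, n_levels = 50,
                             co_occurrence = 50)
    }
    out
  }
  rows <- c(add_pairs(20, "neg", TRUE), add_pairs(5, "neg", FALSE),
            add_pairs(5, "pos", TRUE), add_pairs(20, "pos", FALSE))
  cs <- do.call(rbind, rows)
  res <- habitat_chisq(cs, habs, sign = "negative")
  expect_equal(res$chisq, yates(20, 5, 5, 20), tolerance = 1e-10)
  expect_lt(res$p, 1e-4)

  # no-association table gives chi-squared 0, p 1
  expect_equal(unname(chisq.test(matrix(c(10, 10, 10, 10), 2),
                                 correct = TRUE)$statistic), 0)
})

test_that("degenerate chi-squared tables are flagged, not crashed", {
  taxa <- c("a", "b", "c", "d")
  habs <- setNames(rep("nektobenthic", 4), taxa)
  cs <- data.frame(taxon_a = c("a", "c"), taxon_b = c("b", "d"),
                   r = c(-0.5, 0.5), p = 0.001, q = 0.004,
                   n_levels = 50, co_occurrence = 50)
  res <- habitat_chisq(cs, habs, sign = "negative")
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  expect_error(habitat_chisq(cs[cs$r > 0, ], habs, sign = "negative"),
               "negative")
})
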