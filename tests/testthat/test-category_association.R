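make_records <- function(up, down) {
  data.frame(protein_id = c(up, down),
             direction = factor(rep(c("up", "down"), c(length(up), length(down))),
                                levels = c("up", "down", "ns")))
}

test_that("contingency construction counts DEPs once per category", {
  rec <- make_records(c("a", "b"), "c")
  ann <- annotation_table(id = c("a", "b", "c", "a"),
                          ontology = c("GO-CC", "GO-CC", "GO-CC", "GO-CC"),
                          category = c("nucleus", "nucleus", "nucleus",
                                       "membrane"))
  tab <- build_contingency(rec, ann, "GO-CC")
  expect_equal(tab["nucleus", "up"], 2L)
  expect_equal(tab["nucleus", "down"], 1L)
  expect_equal(tab["membrane", "up"], 1L)   # second category of DEP 'a'
  expect_equal(attr(tab, "n_unannotated"), 0L)

  # a direction with zero DEPs still yields a valid (zero) column
  rec2 <- make_records(c("a", "b"), character(0))
  tab2 <- build_contingency(rec2, ann, "GO-CC")
  expect_equal(sum(tab2[, "down"]), 0L)
  expect_error(monte_carlo_chisq(tab2), NA)

  expect_error(build_contingency(make_records("zz", "zz2"), ann, "GO-CC"),
               "association error")
})

test_that("chi-squared statistic, residuals and MC p agree with exact oracles on a 2x2 table", {
  tab <- matrix(c(20, 10, 5, 15), nrow = 2,
                dimnames = list(c("r1", "r2"), c("up", "down")))
  res <- monte_carlo_chisq(tab, n_sim = 2000, seed = 99)
  expect_equal(res$chi2_statistic, 25 / 3, tolerance = 1e-12)

  pr <- pearson_residual_bands(tab)
  expect_equal(unname(pr$residuals),
               matrix(c(5 / sqrt(15), -5 / sqrt(15),
                        -5 / sqrt(10), 5 / sqrt(10)), nrow = 2),
               tolerance = 1e-12)
  expect_false(any(pr$significant))      # largest |r| = 1.581 < 2

  # exact fixed-margin null: cell (1,1) is hypergeometric; the statistic
  # exceeds 25/3 exactly when |a - 15| >= 5
  a <- 5:25
  chi2_a <- (a - 15)^2 / 3
  p_exact <- sum(dhyper(a[chi2_a >= 25 / 3], 30, 20, 25))
  expect_lt(abs(res$mc_p_value - p_exact), 0.0075)
  # and the asymptotic df = 1 tail is close by
  expect_lt(abs(p_exact - pchisq(25 / 3, 1, lower.tail = FALSE)), 0.01)

  # independent reference: R's own Monte-Carlo chi-squared test
  set.seed(1)
  ref <- suppressWarnings(chisq.test(tab, simulate.p.value = TRUE, B = 4000))
  expect_equal(res$chi2_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(res$mc_p_value - ref$p.value), 0.01)
})

test_that("residual identity, homogeneity null and band edges", {
  # sum of squared residuals equals the statistic on a bigger random table
  set.seed(3)
  tab <- matrix(rpois(8, 30), nrow = 4,
                dimnames = list(paste0("c", 1:4), c("up", "down")))
  chis <- monte_carlo_chisq(tab, seed = 1)
  pr <- pearson_residual_bands(tab)
  expect_equal(sum(pr$residuals^2), chis$chi2_statistic, tolerance = 1e-9)

  # perfectly homogeneous table: statistic 0, p 1, all residuals 0
  flat <- matrix(10, 2, 2, dimnames = list(c("a", "b"), c("up", "down")))
  resf <- monte_carlo_chisq(flat, seed = 1)
  expect_equal(resf$chi2_statistic, 0)
  expect_equal(resf$mc_p_value, 1)
  prf <- pearson_residual_bands(flat)
  expect_true(all(prf$residuals == 0))
  expect_true(all(prf$bands == "n.s."))

  # band thresholds at the standard-normal quantiles
  band_of <- function(r) dephub:::.residual_band(r)
  expect_equal(band_of(1.5), "n.s.")
  expect_equal(band_of(1.7), "•")
  expect_equal(band_of(-2.0), "*")
  expect_equal(band_of(2.3), "**")
  expect_equal(band_of(3.5), "**")

  expect_error(monte_carlo_chisq(matrix(0, 2, 2)), "test error")
  expect_error(monte_carlo_chisq(matrix(c(-1, 2, 3, 4), 2)), "test error")
})

test_that("MC p is invariant under row/column permutation and determinstic under seed", {
  tab <- matrix(c(12, 7, 30, 21, 9, 14), nrow = 3,
                dimnames = list(paste0("c", 1:3), c("up", "down")))
  r1 <- monte_carlo_chisq(tab, seed = 7)
  r2 <- monte_carlo_chisq(tab[c(3, 1, 2), c(2, 1)], seed = 7)
  expect_equal(r1$chi2_statistic, r2$chi2_statistic, tolerance = 1e-12)
  expect_equal(r1$mc_p_value, r2$mc_p_value)
  expect_identical(monte_carlo_chisq(tab, seed = 7)$mc_p_value,
                   r1$mc_p_value)
})

test_that("planted enrichment drives the designated cell's residual past 2", {
  # 200 planted DEPs, odds factor 5: the up-enriched cell should light up
  # in at least 95% of seeded runs
  up <- sprintf("U%03d", 1:120); down <- sprintf("D%03d", 1:80)
  rec <- make_records(up, down)
  hits <- 0L
  n_runs <- 200L
  for (s in seq_len(n_runs)) {
    ann <- generate_annotation_table(c(up, down), up, down,
                                     ontologies = "GO-BP",
                                     enrichment_factor = 5, seed = s)
    enriched <- attr(ann, "enriched")[["GO-BP"]]$up
    tab <- build_contingency(rec, ann, "GO-BP")
    pr <- pearson_residual_bands(tab)
    if (pr$residuals[enriched, "up"] > 2) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.95)
})
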