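test_that("Welch statistics match hand formulas and the reference implementation", {
  ds <- make_dataset(list(p = c(1:6, 3:8)))
  rec <- dep_statistics(ds)
  # hand-derived: fc = 2, sd both sqrt(3.5), pooled sd sqrt(3.5),
  # d = 2/sqrt(3.5), Welch t on 10 df, two-sided p ~ 0.0936
  expect_equal(rec$fc, 2)
  expect_equal(rec$pooled_sd, sqrt(3.5), tolerance = 1e-12)
  expect_equal(rec$cohen_d, 2 / sqrt(3.5), tolerance = 1e-12)
  ref <- t.test(3:8, 1:6, var.equal = FALSE)
  expect_equal(rec$t_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(rec$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(rec$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(rec$p_value, 0.0938, tolerance = 1e-3)

  # identical groups: perfect symmetry
  ds0 <- make_dataset(list(p = c(1, 2, 3, 4, 1, 2, 3, 4)))
  rec0 <- dep_statistics(ds0)
  expect_equal(rec0$fc, 0)
  expect_equal(rec0$cohen_d, 0)
  expect_equal(rec0$p_value, 1)

  # equal group SDs collapse the pooled SD to that SD
  expect_equal(rec$pooled_sd, rec[["sd_CONTROL"]], tolerance = 1e-12)
})

test_that("Welch and Student variants both agree with t.test on random data", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6, sd = runif(1, 0.3, 3))
    ds <- make_dataset(list(p = c(x, y)))
    for (variant in c("welch", "student")) {
      rec <- dep_statistics(ds, test = variant)
      ref <- t.test(y, x, var.equal = (variant == "student"))
      expect_equal(rec$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("zero-variance proteins are degenerate, never DEPs", {
  ds <- make_dataset(list(flat = c(rep(1, 6), rep(5, 6)),
                          ok = c(1, 2, 3, 1, 2, 3, 7, 8, 9, 7, 8, 9)))
  rec <- classify_deps(dep_statistics(ds))
  expect_true(rec$degenerate[1])
  expect_true(is.na(rec$cohen_d[1]))
  expect_true(is.na(rec$p_value[1]))
  expect_equal(as.character(rec$direction[1]), "ns")
  expect_equal(as.character(rec$direction[2]), "up")
})

test_that("DEP classification uses strict cut-offs on both p and d", {
  rec <- data.frame(protein_id = paste0("p", 1:5),
                    cohen_d = c(2.5, 2.5, -2.0, -2.4, 0.1),
                    p_value = c(0.01, 0.2, 0.01, 0.04, 0.001),
                    degenerate = FALSE)
  cl <- classify_deps(rec)
  expect_equal(as.character(cl$direction),
               c("up", "ns", "ns", "down", "ns"))
  expect_equal(sum(table(cl$direction)), nrow(rec))
})

test_that("label swap negates fc and d and preserves p", {
  sim <- generate_abundance_dataset(
    sim_params(n_proteins = 150, missing_rate = 0,
               n_exclusive_per_group = 0, seed = 21))
  ds <- sim$dataset
  swapped <- abundance_dataset(ds$values, ds$group_of,
                               group_levels = rev(ds$group_levels))
  a <- dep_statistics(ds); b <- dep_statistics(swapped)
  expect_equal(a$fc, -b$fc, tolerance = 1e-12)
  expect_equal(a$cohen_d, -b$cohen_d, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("outlier cutoff is mean + 2 SD of |LFC| with strict exceedance", {
  # arithmetic oracle on ten numbers: mean 3, sd sqrt(10), cutoff 9.3246
  fcs <- c(rep(2, 9), 12)
  rec <- data.frame(protein_id = paste0("p", 1:10), fc = fcs,
                    cohen_d = 3, p_value = 0.01, degenerate = FALSE)
  rec <- classify_deps(rec)
  out <- detect_outliers(rec)
  expect_equal(out$mean_abs_lfc, 3)
  expect_equal(out$sd_abs_lfc, sqrt(10), tolerance = 1e-12)
  expect_equal(out$cutoff, 3 + 2 * sqrt(10), tolerance = 1e-12)
  expect_equal(out$outliers_up, "p10")
  expect_length(out$outliers_down, 0)

  # all-equal |fc|: sd 0, cutoff = mean, strictly nothing exceeds it
  rec2 <- data.frame(protein_id = paste0("p", 1:4), fc = c(2, -2, 2, -2),
                     cohen_d = c(3, -3, 3, -3), p_value = 0.01,
                     degenerate = FALSE)
  out2 <- detect_outliers(classify_deps(rec2))
  expect_equal(out2$cutoff, 2)
  expect_length(c(out2$outliers_up, out2$outliers_down), 0)

  expect_error(detect_outliers(classify_deps(rec2[1, ])), "outlier error")
})

test_that("planted extreme effects surface as LFC outliers on synthetic data", {
  sim <- generate_abundance_dataset(
    sim_params(n_proteins = 2000, frac_dep = 0.025, missing_rate = 0,
               n_exclusive_per_group = 0, frac_outlier_dep = 0.02,
               seed = 31))
  imp <- impute_sample_mean(sim$dataset)
  rec <- classify_deps(dep_statistics(imp$dataset))
  out <- detect_outliers(rec)
  found <- c(out$outliers_up, out$outliers_down)
  expect_true(all(sim$truth$outlier_ids %in% found))
})

test_that("volcano table floors p at 1e-300 and mirrors the classification", {
  rec <- data.frame(protein_id = c("a", "b", "c"),
                    cohen_d = c(3, -3, 0),
                    p_value = c(0.01, 1e-320, 1),
                    degenerate = c(FALSE, FALSE, FALSE))
  v <- volcano_table(classify_deps(rec))
  expect_equal(v$neg_log10_p[1], 2)
  expect_equal(v$neg_log10_p[2], 300)
  expect_equal(v$neg_log10_p[3], 0)
  expect_true(all(is.finite(v$neg_log10_p)))
  expect_equal(as.character(v$direction), c("up", "down", "ns"))
})
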