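#' Per-protein differential statistics
#'
#' For every protein computes group means and sample standard deviations
#' (denominator n-1), the fold change `fc = mean_case - mean_reference`
#' (a difference of log abundances, i.e. a log fold change), the pooled SD
#' `sqrt((sd_ref^2 + sd_case^2) / 2)`, Cohen's effect size
#' `d = fc / pooled_sd`, and a two-sided two-sample t-test p-value (Welch by
#' default; Student's pooled-variance t optionally). Proteins where both
#' group SDs are zero admit no finite test statistic and are flagged
#' `degenerate` with `NA` for `cohen_d` and `p_value`; degenerate proteins
#' are never called differentially expressed.
#'
#' @param dataset an imputed [abundance_dataset()] with no missing values.
#' @param imputation_counts optional named vector from
#'   [impute_sample_mean()]; carried into the output as `n_imputed`.
#' @param test `"welch"` (default) or `"student"`.
#' @return data.frame with one row per protein: `protein_id`, `mean_<ref>`,
#'   `mean_<case>`, `sd_<ref>`, `sd_<case>`, `fc`, `pooled_sd`, `cohen_d`,
#'   `t_statistic`, `df`, `p_value`, `n_imputed`, `degenerate`.
#' @export
dep_statistics <- function(dataset, imputation_counts = NULL,
                           test = c("welch", "student")) {
  test <- match.arg(test)
  if (anyNA(dataset$values))
    stop("statistics error: dataset still contains missing values; ",
         "filter and impute first", call. = FALSE)
  cols <- group_columns(dataset)
  n1 <- length(cols[[1]]); n2 <- length(cols[[2]])
  if (n1 < 2L || n2 < 2L)
    stop("statistics error: each group needs at least 2 samples",
         call. = FALSE)
  x1 <- dataset$values[, cols[[1]], drop = FALSE]  # reference group
  x2 <- dataset$values[, cols[[2]], drop = FALSE]  # case group
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  fc <- m2 - m1
  pooled_sd <- sqrt((v1 + v2) / 2)
  degenerate <- v1 == 0 & v2 == 0
  cohen_d <- ifelse(degenerate, NA_real_, fc / pooled_sd)
  if (test == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- fc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- fc / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(fc))
  }
  tstat[degenerate] <- NA_real_
  df[degenerate] <- NA_real_
  p <- 2 * stats::pt(-abs(tstat), df)
  n_imputed <- if (is.null(imputation_counts)) rep(0L, length(fc))
               else as.integer(imputation_counts[dataset$protein_ids])
  out <- data.frame(
    protein_id = dataset$protein_ids,
    mean_ref = unname(m1), mean_case = unname(m2),
    sd_ref = unname(sqrt(v1)), sd_case = unname(sqrt(v2)),
    fc = unname(fc), pooled_sd = unname(pooled_sd),
    cohen_d = unname(cohen_d),
    t_statistic = unname(tstat), df = unname(df), p_value = unname(p),
    n_imputed = n_imputed, degenerate = unname(degenerate),
    stringsAsFactors = FALSE)
  names(out)[2:5] <- c(paste0("mean_", dataset$group_levels),
                       paste0("sd_", dataset$group_levels))
  attr(out, "group_levels") <- dataset$group_levels
  attr(out, "test") <- test
  out
}

#' Classify DEP records into up / down / non-significant
#'
#' A protein is up-regulated iff `p_value < p_cutoff` and
#' `cohen_d > d_cutoff`; down-regulated iff `p_value < p_cutoff` and
#' `cohen_d < -d_cutoff`; everything else (including degenerate records and
#' boundary ties, all inequalities strict) is non-significant.
#'
#' @param records output of [dep_statistics()].
#' @param p_cutoff p-value threshold (default 0.05).
#' @param d_cutoff Cohen's d threshold (default 2).
#' @return `records` with an added `direction` factor column in
#'   `c("up", "down", "ns")`.
#' @export
classify_deps <- function(records, p_cutoff = 0.05, d_cutoff = 2.0) {
  ok <- !records$degenerate & !is.na(records$p_value)
  up <- ok & records$p_value < p_cutoff & records$cohen_d > d_cutoff
  down <- ok & records$p_value < p_cutoff & records$cohen_d < -d_cutoff
  records$direction <- factor(ifelse(up, "up", ifelse(down, "down", "ns")),
                              levels = c("up", "down", "ns"))
  records
}

#' Parametric outlier detection on DEP log fold changes
#'
#' Over the absolute fold changes of the called DEPs only (up and down), the
#' cutoff is `mean(|fc|) + 2 * sd(|fc|)` (sample SD); a DEP is an outlier
#' when its `|fc|` strictly exceeds the cutoff.
#'
#' @param records classified records from [classify_deps()].
#' @param k number of SDs above the mean (default 2).
#' @return list with `cutoff`, `mean_abs_lfc`, `sd_abs_lfc`, `outliers_up`,
#'   `outliers_down` (protein id vectors) and `n_deps`.
#' @export
detect_outliers <- function(records, k = 2.0) {
  deps <- records[records$direction %in% c("up", "down"), , drop = FALSE]
  if (nrow(deps) < 2L)
    stop("outlier error: need at least 2 DEPs to fit a cutoff",
         call. = FALSE)
  abs_lfc <- abs(deps$fc)
  m <- mean(abs_lfc)
  s <- stats::sd(abs_lfc)
  cutoff <- m + k * s
  out <- abs_lfc > cutoff
  list(cutoff = cutoff, mean_abs_lfc = m, sd_abs_lfc = s,
       n_deps = nrow(deps),
       outliers_up = deps$protein_id[out & deps$direction == "up"],
       outliers_down = deps$protein_id[out & deps$direction == "down"])
}

#' Volcano-plot coordinates
#'
#' One row per non-degenerate protein: Cohen's effect size on the x axis and
#' `-log10(p)` on the y axis (p floored at 1e-300 so the coordinate stays
#' finite), with the [classify_deps()] direction for coloring.
#'
#' @param records classified records from [classify_deps()].
#' @return data.frame with columns `protein_id`, `cohen_d`, `neg_log10_p`,
#'   `direction`.
#' @export
volcano_table <- function(records) {
  rec <- records[!records$degenerate, , drop = FALSE]
  data.frame(protein_id = rec$protein_id,
             cohen_d = rec$cohen_d,
             neg_log10_p = -log10(pmax(rec$p_value, 1e-300)),
             direction = rec$direction,
             stringsAsFactors = FALSE)
}
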