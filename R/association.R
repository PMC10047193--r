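#' Build a category x direction contingency table
#'
#' Counts, for one ontology, how many up- and down-regulated DEPs are
#' annotated to each category. A DEP carrying several categories counts once
#' per category; DEPs without any annotation in the chosen ontology are
#' dropped (their number is reported as an attribute).
#'
#' @param records classified records from [classify_deps()] (only rows with
#'   direction `up` or `down` are used), or any data.frame with columns
#'   `protein_id` and `direction`.
#' @param annotations an annotation table ([read_annotation_table()]).
#' @param ontology one of `GO-CC`, `GO-BP`, `GO-MF`, `KOG`.
#' @return integer matrix, categories in rows, columns `up` and `down`;
#'   attribute `n_unannotated` counts the DEPs with no category.
#' @export
build_contingency <- function(records, annotations, ontology) {
  if (!ontology %in% .ONTOLOGIES)
    stop("value error: unknown ontology '", ontology, "'", call. = FALSE)
  deps <- records[records$direction %in% c("up", "down"), , drop = FALSE]
  ann <- annotations[annotations$ontology == ontology, , drop = FALSE]
  hit <- merge(deps[, c("protein_id", "direction")], ann,
               by.x = "protein_id", by.y = "id")
  if (nrow(hit) == 0L)
    stop("association error: no DEP has an annotation in ", ontology,
         call. = FALSE)
  tab <- table(category = hit$category,
               direction = factor(hit$direction, levels = c("up", "down")))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  attr(m, "n_unannotated") <-
    sum(!deps$protein_id %in% ann$id)
  m
}

# chi-squared statistic over cells with positive expected count
.chisq_stat <- function(obs, expected) {
  pos <- expected > 0
  sum((obs[pos] - expected[pos])^2 / expected[pos])
}

#' Monte-Carlo chi-squared test of a contingency table
#'
#' Computes the Pearson chi-squared statistic of the observed table against
#' expected counts from the row/column margins, then estimates the p-value
#' by sampling `n_sim` null tables with the same fixed margins
#' ([stats::r2dtable()]) and applying the add-one Monte-Carlo estimator
#' `p = (1 + #\{sim >= obs\}) / (n_sim + 1)`, which can never return zero.
#' Rows and columns whose margin is zero carry no information and are
#' dropped before testing.
#'
#' @param contingency non-negative integer matrix with positive grand total.
#' @param n_sim number of simulated null tables (default 2000).
#' @param seed integer RNG seed.
#' @return list with `chi2_statistic`, `mc_p_value`, `n_sim`, `seed`,
#'   `expected` (full-shape expected counts, `NA` where a margin is zero).
#' @export
monte_carlo_chisq <- function(contingency, n_sim = 2000L, seed = 1L) {
  x <- as.matrix(contingency)
  if (any(x < 0) || any(x != round(x)))
    stop("test error: contingency must hold non-negative integers",
         call. = FALSE)
  if (sum(x) == 0L)
    stop("test error: all-zero contingency table", call. = FALSE)
  rs <- rowSums(x); cs <- colSums(x)
  expected_full <- outer(rs, cs) / sum(x)
  keep_r <- rs > 0; keep_c <- cs > 0
  xr <- x[keep_r, keep_c, drop = FALSE]
  er <- outer(rs[keep_r], cs[keep_c]) / sum(x)
  stat <- .chisq_stat(xr, er)
  if (nrow(xr) < 2L || ncol(xr) < 2L) {
    # a single informative row or column is exactly its own margin:
    # the statistic is 0 and every null table reproduces it
    p <- 1
  } else {
    # simulate under sorted margins: the null statistic's law depends only
    # on the margin multisets, and sorting makes the p-value invariant to
    # row/column permutations of the input table
    rs_s <- sort(rowSums(xr), decreasing = TRUE)
    cs_s <- sort(colSums(xr), decreasing = TRUE)
    es <- outer(rs_s, cs_s) / sum(xr)
    set.seed(seed)
    sims <- stats::r2dtable(n_sim, rs_s, cs_s)
    simstat <- vapply(sims, .chisq_stat, numeric(1), expected = es)
    p <- (1 + sum(simstat >= stat)) / (n_sim + 1)
  }
  expected_full[!keep_r, ] <- NA_real_
  expected_full[, !keep_c] <- NA_real_
  list(chi2_statistic = stat, mc_p_value = p, n_sim = n_sim, seed = seed,
       expected = expected_full)
}

# confidence band of one |residual| against standard-normal quantiles:
# 90-95% "." (bullet), 95-97.5% "*", 97.5-99% "**"; >=99% also shown "**"
.residual_band <- function(r) {
  a <- abs(r)
  if (is.na(a)) NA_character_
  else if (a >= stats::qnorm(0.975 + 0.025 / 2)) "**"   # 2.241
  else if (a >= stats::qnorm(0.975)) "*"                # 1.960
  else if (a >= stats::qnorm(0.95)) "\u2022"            # 1.645
  else "n.s."
}

#' Pearson residuals and confidence bands of a contingency table
#'
#' Residual `(obs - exp) / sqrt(exp)` per cell; a cell marks a significant
#' association when its residual is above 2 or below -2 (strict). Display
#' bands follow standard-normal quantiles of |residual|: bullet for 90-95%
#' confidence, `*` for 95-97.5%, `**` for 97.5% and beyond (residuals past
#' the 99% quantile 2.576 are still shown `**`, with a note attribute).
#' Cells with zero expected count have undefined residuals and are reported
#' as `NA`.
#'
#' @param contingency non-negative integer matrix.
#' @return list with `residuals`, `bands` (character matrix), `significant`
#'   (logical matrix, |r| > 2), `expected`.
#' @export
pearson_residual_bands <- function(contingency) {
  x <- as.matrix(contingency)
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  res <- (x - expected) / sqrt(expected)
  res[expected == 0] <- NA_real_
  bands <- apply(res, c(1, 2), .residual_band)
  if (any(abs(res) >= stats::qnorm(0.995), na.rm = TRUE))
    attr(bands, "note") <-
      "cells beyond the 99% quantile (|r| >= 2.576) are displayed as '**'"
  list(residuals = res, bands = bands,
       significant = !is.na(res) & abs(res) > 2,
       expected = expected)
}

#' Full direction-vs-category association analysis for one ontology
#'
#' Convenience wrapper: [build_contingency()], [monte_carlo_chisq()] and
#' [pearson_residual_bands()] in one call.
#'
#' @inheritParams build_contingency
#' @inheritParams monte_carlo_chisq
#' @return list with `ontology`, `contingency`, the chi-squared results and
#'   the residual analysis. The algebraic identity
#'   `sum(residuals^2) = chi2_statistic` holds whenever no margin is zero.
#' @export
test_category_association <- function(records, annotations, ontology,
                                      n_sim = 2000L, seed = 1L) {
  tab <- build_contingency(records, annotations, ontology)
  chisq <- monte_carlo_chisq(tab, n_sim = n_sim, seed = seed)
  resid <- pearson_residual_bands(tab)
  c(list(ontology = ontology, contingency = tab), chisq, resid)
}
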