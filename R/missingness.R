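#' Detect group-exclusive proteins
#'
#' A protein is exclusive to a group when every value in the *other* group is
#' missing while at least `min_present` actual abundance values exist in the
#' group itself (for a 6 vs 6 design: all six missing on one side, three or
#' more present on the other). Exclusive detection is defined on the raw
#' matrix: these proteins can never survive the missingness filter, so this
#' stage must run before [filter_missingness()].
#'
#' @param dataset a raw (unfiltered, unimputed) [abundance_dataset()].
#' @param min_present minimum number of non-missing values required in the
#'   presenting group (default 3).
#' @return data.frame with columns `protein_id`, `present_group`,
#'   `n_present`, sorted by `protein_id`.
#' @export
detect_exclusive <- function(dataset, min_present = 3L) {
  cols <- group_columns(dataset)
  present <- !is.na(dataset$values)
  n1 <- rowSums(present[, cols[[1]], drop = FALSE])
  n2 <- rowSums(present[, cols[[2]], drop = FALSE])
  excl1 <- n2 == 0L & n1 >= min_present   # exclusive to group 1
  excl2 <- n1 == 0L & n2 >= min_present   # exclusive to group 2
  out <- data.frame(
    protein_id = c(dataset$protein_ids[excl1], dataset$protein_ids[excl2]),
    present_group = c(rep(dataset$group_levels[1], sum(excl1)),
                      rep(dataset$group_levels[2], sum(excl2))),
    n_present = c(n1[excl1], n2[excl2]),
    stringsAsFactors = FALSE)
  out[order(out$protein_id), , drop = FALSE]
}

#' Filter proteins by missing-value pattern
#'
#' Keeps a protein only if it has at least `min_present_per_group` actual
#' replicate values within *each* group and at most `max_total_na` missing
#' values in total.
#'
#' @param dataset an [abundance_dataset()].
#' @param min_present_per_group minimum non-missing values per group
#'   (default 4).
#' @param max_total_na maximum missing values per protein over all samples
#'   (default 3).
#' @return list with elements `dataset` (the filtered [abundance_dataset()])
#'   and `report`, a list holding `kept_ids`, `excluded_ids`, `per_protein`
#'   (NA counts by group and the keep decision) and `per_sample` (non-NA /
#'   NA protein counts per sample, computed on the input matrix).
#' @export
filter_missingness <- function(dataset, min_present_per_group = 4L,
                               max_total_na = 3L) {
  cols <- group_columns(dataset)
  sizes <- lengths(cols)
  if (min_present_per_group > min(sizes))
    stop("parameter error: min_present_per_group (", min_present_per_group,
         ") exceeds the smallest group size (", min(sizes), ")",
         call. = FALSE)
  miss <- is.na(dataset$values)
  na1 <- rowSums(miss[, cols[[1]], drop = FALSE])
  na2 <- rowSums(miss[, cols[[2]], drop = FALSE])
  keep <- (sizes[1] - na1) >= min_present_per_group &
          (sizes[2] - na2) >= min_present_per_group &
          (na1 + na2) <= max_total_na
  per_protein <- data.frame(
    protein_id = dataset$protein_ids,
    na_group1 = unname(na1), na_group2 = unname(na2),
    na_total = unname(na1 + na2), kept = unname(keep),
    stringsAsFactors = FALSE)
  names(per_protein)[2:3] <- paste0("na_", dataset$group_levels)
  per_sample <- data.frame(
    sample_id = dataset$sample_ids,
    group = unname(dataset$group_of),
    non_na_proteins = unname(colSums(!miss)),
    na_proteins = unname(colSums(miss)),
    stringsAsFactors = FALSE)
  filtered <- abundance_dataset(
    dataset$values[keep, , drop = FALSE], dataset$group_of,
    gene_symbols = if (!is.null(dataset$gene_symbols))
      dataset$gene_symbols[keep],
    group_levels = dataset$group_levels)
  list(dataset = filtered,
       report = list(kept_ids = dataset$protein_ids[keep],
                     excluded_ids = dataset$protein_ids[!keep],
                     n_kept = sum(keep), n_excluded = sum(!keep),
                     per_protein = per_protein,
                     per_sample = per_sample,
                     min_present_per_group = min_present_per_group,
                     max_total_na = max_total_na))
}

#' Impute remaining missing values with the sample (column) mean
#'
#' Each missing cell is replaced by the mean of the non-missing values of its
#' own sample column, computed on the pre-imputation matrix; observed cells
#' are untouched. Column means are therefore invariant under imputation.
#'
#' @param dataset an [abundance_dataset()] (typically the output of
#'   [filter_missingness()]).
#' @return list with `dataset` (imputed, no missing values) and
#'   `imputation_counts`, a named integer vector of imputed cells per
#'   protein.
#' @export
impute_sample_mean <- function(dataset) {
  vals <- dataset$values
  miss <- is.na(vals)
  if (any(colSums(!miss) == 0L))
    stop("imputation error: sample column(s) with no observed values: ",
         paste(dataset$sample_ids[colSums(!miss) == 0L], collapse = ", "),
         call. = FALSE)
  col_means <- colMeans(vals, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  if (nrow(idx) > 0L) vals[idx] <- col_means[idx[, "col"]]
  counts <- stats::setNames(as.integer(rowSums(miss)), dataset$protein_ids)
  out <- dataset
  out$values <- vals
  list(dataset = out, imputation_counts = counts)
}
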