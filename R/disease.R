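#' Filter gene-disease associations by confidence score
#'
#' Keeps records whose confidence score strictly exceeds `min_score`
#' (default 2) and summarizes the passing set: distinct genes (a gene
#' passing in any evidence channel counts), record counts per channel and
#' per disease id. Optionally restricts to one DOID first (literal match,
#' no ontology traversal).
#'
#' @param records validated records from [read_disease_table()] /
#'   [disease_table()].
#' @param min_score confidence threshold (default 2, strict).
#' @param doid optional disease id (e.g. `"DOID:1826"`) to restrict to.
#' @return list with `records` (passing rows, ordered by score descending
#'   then gene), `genes` (sorted distinct gene symbols), `n_genes`,
#'   `n_records`, `per_channel` (named counts over all three channels) and
#'   `per_disease`.
#' @export
filter_associations <- function(records, min_score = 2.0, doid = NULL) {
  if (!is.null(doid))
    records <- records[records$disease_id == doid, , drop = FALSE]
  pass <- records[records$score > min_score, , drop = FALSE]
  pass <- pass[order(-pass$score, pass$gene), , drop = FALSE]
  per_channel <- stats::setNames(integer(length(.CHANNELS)), .CHANNELS)
  tab <- table(pass$channel)
  per_channel[names(tab)] <- as.integer(tab)
  per_disease <- table(pass$disease_id)
  list(records = pass,
       genes = sort(unique(pass$gene)),
       n_genes = length(unique(pass$gene)),
       n_records = nrow(pass),
       per_channel = per_channel,
       per_disease = stats::setNames(as.integer(per_disease),
                                     names(per_disease)),
       min_score = min_score)
}
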