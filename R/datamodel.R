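#' Construct an abundance dataset
#'
#' The central container of the package: a protein x sample matrix of
#' log-abundance values (as produced by a DIA quantification pipeline such as
#' MSstats), a missing-value mask encoded as `NA`, and a two-group sample
#' design. Values are treated as opaque log units; no log base is assumed.
#'
#' @param values numeric matrix, proteins in rows, samples in columns. `NA`
#'   marks a missing quantification.
#' @param group_of named character vector mapping every sample id (column name)
#'   to one of exactly two group labels.
#' @param gene_symbols optional character vector of per-protein gene symbols,
#'   parallel to the rows of `values`.
#' @param group_levels length-2 character vector `c(reference, case)` fixing
#'   which group is the reference (control) and which the case; fold changes
#'   downstream are case minus reference. Defaults to the order in which the
#'   groups first appear in `group_of`.
#' @return an object of class `abundance_dataset`: a list with elements
#'   `values`, `protein_ids`, `gene_symbols`, `sample_ids`, `group_of`,
#'   `group_levels`.
#' @export
abundance_dataset <- function(values, group_of, gene_symbols = NULL,
                              group_levels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  protein_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(protein_ids) || anyDuplicated(protein_ids) || any(protein_ids == ""))
    stop("format error: protein ids (rownames) must be unique and non-empty",
         call. = FALSE)
  if (is.null(sample_ids) || anyDuplicated(sample_ids))
    stop("format error: sample ids (colnames) must be unique", call. = FALSE)
  if (!all(sample_ids %in% names(group_of)))
    stop("consistency error: samples in matrix missing from metadata: ",
         paste(setdiff(sample_ids, names(group_of)), collapse = ", "),
         call. = FALSE)
  if (!all(names(group_of) %in% sample_ids))
    stop("consistency error: samples in metadata missing from matrix: ",
         paste(setdiff(names(group_of), sample_ids), collapse = ", "),
         call. = FALSE)
  group_of <- group_of[sample_ids]
  lev <- unique(unname(group_of))
  if (length(lev) != 2L)
    stop("group error: exactly two groups required, found ", length(lev),
         call. = FALSE)
  if (is.null(group_levels)) group_levels <- lev
  if (!setequal(group_levels, lev) || length(group_levels) != 2L)
    stop("group error: `group_levels` must name the two groups in the metadata",
         call. = FALSE)
  if (any(table(group_of) < 2L))
    stop("group error: every group needs at least 2 samples", call. = FALSE)
  if (!is.null(gene_symbols) && length(gene_symbols) != nrow(values))
    stop("format error: `gene_symbols` must be parallel to rows", call. = FALSE)
  structure(
    list(values = values,
         protein_ids = protein_ids,
         gene_symbols = gene_symbols,
         sample_ids = sample_ids,
         group_of = group_of,
         group_levels = group_levels),
    class = "abundance_dataset")
}

#' @export
print.abundance_dataset <- function(x, ...) {
  tab <- table(x$group_of)[x$group_levels]
  cat("abundance_dataset: ", nrow(x$values), " proteins x ",
      ncol(x$values), " samples\n", sep = "")
  cat("  groups: ", paste(sprintf("%s (n=%d)", names(tab), tab),
                          collapse = ", "),
      "  [reference = ", x$group_levels[1], "]\n", sep = "")
  cat("  missing cells: ", sum(is.na(x$values)), " (",
      format(100 * mean(is.na(x$values)), digits = 3), "%)\n", sep = "")
  invisible(x)
}

# sample columns belonging to each group, in dataset order
group_columns <- function(dataset) {
  lapply(stats::setNames(dataset$group_levels, dataset$group_levels),
         function(g) which(dataset$group_of == g))
}

#' Read a log-abundance matrix and its sample metadata
#'
#' The matrix file is TSV with a header: a `protein_id` column, an optional
#' `gene_symbol` column, then one numeric column per sample. Missing values
#' are encoded as an empty cell or the literal `NA` (case-sensitive); any
#' other non-numeric cell is a parse error. The metadata file is TSV with
#' columns `sample_id` and `group`.
#'
#' @param matrix_path path to the matrix TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @param group_levels optional `c(reference, case)` ordering passed to
#'   [abundance_dataset()].
#' @return an [abundance_dataset()].
#' @export
read_abundance_matrix <- function(matrix_path, metadata_path,
                                  group_levels = NULL) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  if (ncol(raw) < 2L || names(raw)[1] != "protein_id")
    stop("format error: first column must be 'protein_id'", call. = FALSE)
  gene_symbols <- NULL
  first_sample <- 2L
  if (ncol(raw) >= 2L && names(raw)[2] == "gene_symbol") {
    gene_symbols <- raw[[2]]
    first_sample <- 3L
  }
  sample_cols <- names(raw)[first_sample:ncol(raw)]
  vals <- as.matrix(raw[, sample_cols, drop = FALSE])
  missing_mask <- vals == "" | vals == "NA"
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- !missing_mask & is.na(num)
  if (any(bad))
    stop("parse error: non-numeric non-missing cell(s), e.g. '",
         vals[which(bad)[1]], "'", call. = FALSE)
  num[missing_mask] <- NA_real_
  dimnames(num) <- list(raw$protein_id, sample_cols)

  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("format error: metadata needs columns 'sample_id' and 'group'",
         call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("format error: duplicate sample ids in metadata", call. = FALSE)
  group_of <- stats::setNames(meta$group, meta$sample_id)
  abundance_dataset(num, group_of, gene_symbols = gene_symbols,
                    group_levels = group_levels)
}

#' Write an abundance dataset to the TSV dialect read by
#' [read_abundance_matrix()]
#'
#' @param dataset an [abundance_dataset()].
#' @param matrix_path,metadata_path output paths.
#' @return invisibly, the dataset.
#' @export
write_abundance_matrix <- function(dataset, matrix_path, metadata_path) {
  vals <- dataset$values
  chr <- matrix(vapply(vals, function(v)
    if (is.na(v)) "NA" else format(v, digits = 17), ""), nrow = nrow(vals))
  df <- data.frame(protein_id = dataset$protein_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(dataset$gene_symbols)) df$gene_symbol <- dataset$gene_symbols
  df <- cbind(df, as.data.frame(chr, stringsAsFactors = FALSE))
  names(df)[(ncol(df) - ncol(vals) + 1L):ncol(df)] <- dataset$sample_ids
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = dataset$sample_ids,
                     group = unname(dataset$group_of))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dataset)
}

#' Read a scored protein-protein interaction edge list
#'
#' TSV with columns `node_a`, `node_b` and optionally `score` (confidence in
#' \[0,1\]; defaults to 1 when absent). The result is a simple undirected
#' igraph graph: self-loops are dropped with a warning and duplicate pairs
#' (in either order) are collapsed keeping the maximum score, in the spirit
#' of highest-confidence interaction selection.
#'
#' @param path path to the edge-list TSV.
#' @return an undirected simple `igraph` graph with edge attribute `score`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (nrow(df) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  if (!all(c("node_a", "node_b") %in% names(df)))
    stop("format error: edge list needs columns 'node_a' and 'node_b'",
         call. = FALSE)
  score <- if ("score" %in% names(df)) as.numeric(df$score)
           else rep(1.0, nrow(df))
  if (anyNA(score) || any(score < 0 | score > 1))
    stop("value error: edge scores must be numbers in [0, 1]", call. = FALSE)
  ppi_network(df$node_a, df$node_b, score)
}

#' Build a simple scored undirected network from edge endpoints
#'
#' @param node_a,node_b character vectors of edge endpoints.
#' @param score numeric confidence scores in \[0,1\].
#' @return an undirected simple `igraph` graph with edge attribute `score`.
#' @export
ppi_network <- function(node_a, node_b, score = rep(1.0, length(node_a))) {
  stopifnot(length(node_a) == length(node_b), length(score) == length(node_a))
  if (any(score < 0 | score > 1))
    stop("value error: edge scores must be in [0, 1]", call. = FALSE)
  nodes <- sort(unique(c(node_a, node_b)))
  loop <- node_a == node_b
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped", call. = FALSE)
    node_a <- node_a[!loop]; node_b <- node_b[!loop]; score <- score[!loop]
  }
  # canonical unordered pair, keep max score over duplicates
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(nodes)
  if (length(node_a) > 0L) {
    a <- pmin(node_a, node_b); b <- pmax(node_a, node_b)
    key <- paste(a, b, sep = "\r")
    keep <- tapply(score, key, max)
    pairs <- do.call(rbind, strsplit(names(keep), "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(pairs)), score = unname(keep))
  }
  g
}

.ONTOLOGIES <- c("GO-CC", "GO-BP", "GO-MF", "KOG")

#' Read a protein/gene ontology annotation table
#'
#' TSV with columns `id`, `ontology`, `category`. The ontology label must be
#' one of `GO-CC`, `GO-BP`, `GO-MF`, `KOG`. Exact duplicate rows are dropped.
#'
#' @param path path to the annotation TSV.
#' @return data.frame with columns `id`, `ontology`, `category`.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (nrow(df) == 0L)
    return(data.frame(id = character(), ontology = character(),
                      category = character()))
  if (!all(c("id", "ontology", "category") %in% names(df)))
    stop("format error: annotation table needs columns id/ontology/category",
         call. = FALSE)
  annotation_table(df$id, df$ontology, df$category)
}

#' Validate an annotation table held in memory
#'
#' @param id,ontology,category character vectors of equal length.
#' @return data.frame with duplicates dropped.
#' @export
annotation_table <- function(id, ontology, category) {
  bad <- setdiff(unique(ontology), .ONTOLOGIES)
  if (length(bad) > 0L)
    stop("value error: unknown ontology label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  df <- data.frame(id = id, ontology = ontology, category = category,
                   stringsAsFactors = FALSE)
  unique(df)
}

.CHANNELS <- c("knowledge", "experimental", "textmining")

#' Read a gene-disease association table
#'
#' TSV with columns `gene`, `disease_id` (a DOID such as `DOID:1826`),
#' `disease_name`, `channel` (one of `knowledge`, `experimental`,
#' `textmining`) and a non-negative confidence `score`.
#'
#' @param path path to the disease TSV.
#' @return data.frame of validated records, in file order.
#' @export
read_disease_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (nrow(df) == 0L)
    return(data.frame(gene = character(), disease_id = character(),
                      disease_name = character(), channel = character(),
                      score = numeric()))
  need <- c("gene", "disease_id", "disease_name", "channel", "score")
  if (!all(need %in% names(df)))
    stop("format error: disease table needs columns ",
         paste(need, collapse = "/"), call. = FALSE)
  disease_table(df$gene, df$disease_id, df$disease_name, df$channel,
                as.numeric(df$score))
}

#' Validate gene-disease association records
#'
#' @param gene,disease_id,disease_name,channel character vectors.
#' @param score numeric non-negative confidence scores.
#' @return data.frame of validated records.
#' @export
disease_table <- function(gene, disease_id, disease_name, channel, score) {
  if (!all(grepl("^DOID:[0-9]+$", disease_id)))
    stop("value error: malformed DOID identifier(s): ",
         paste(unique(disease_id[!grepl("^DOID:[0-9]+$", disease_id)]),
               collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(channel), .CHANNELS)
  if (length(bad) > 0L)
    stop("value error: unknown channel(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyNA(score) || any(score < 0))
    stop("value error: scores must be non-negative numbers", call. = FALSE)
  data.frame(gene = gene, disease_id = disease_id,
             disease_name = disease_name, channel = channel, score = score,
             stringsAsFactors = FALSE)
}
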