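#' Simulation parameters for the synthetic abundance generator
#'
#' Defaults emulate a two-group label-free DIA experiment of the size the
#' package targets: ~5000 proteins quantified over 6 replicates per group on
#' a log-abundance scale, a small fraction of proteins carrying a planted
#' group effect expressed in Cohen's-d units (the mean shift is
#' `d * within_sd`, so the planted d is directly comparable to the DEP
#' cut-off), a few extreme-effect outliers among them, sparse missingness
#' completely at random, and a handful of group-exclusive proteins per
#' group.
#'
#' @param n_proteins number of proteins (default 5000).
#' @param n_reps_per_group replicates per group (default 6).
#' @param baseline_mean,baseline_sd log-unit distribution of per-protein
#'   baseline abundance (defaults 20, 2).
#' @param within_sd within-group replicate SD in log units (default 0.5).
#' @param frac_dep fraction of proteins with a planted effect (default 0.03).
#' @param effect_size_range range of planted |d|, sampled uniformly with
#'   random sign (default `c(2, 5)`).
#' @param frac_outlier_dep fraction of planted DEPs given an extreme effect
#'   instead (default 0.02).
#' @param outlier_effect_range range of planted |d| for outliers
#'   (default `c(8, 12)`).
#' @param missing_rate MCAR missingness probability per cell (default 0.015).
#' @param n_exclusive_per_group planted group-exclusive proteins per group
#'   (default 10): all values missing in one group, at least 3 present in
#'   the other.
#' @param exclusive_min_present minimum present values planted on the
#'   presenting side (default 3).
#' @param group_labels the two group labels, reference first
#'   (default `c("CONTROL", "GASH")`).
#' @param seed integer RNG seed.
#' @return a list of validated parameters (class `sim_params`).
#' @export
sim_params <- function(n_proteins = 5000L, n_reps_per_group = 6L,
                       baseline_mean = 20, baseline_sd = 2,
                       within_sd = 0.5, frac_dep = 0.03,
                       effect_size_range = c(2, 5),
                       frac_outlier_dep = 0.02,
                       outlier_effect_range = c(8, 12),
                       missing_rate = 0.015,
                       n_exclusive_per_group = 10L,
                       exclusive_min_present = 3L,
                       group_labels = c("CONTROL", "GASH"),
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(n_proteins > 0, n_reps_per_group >= 2,
            frac_dep >= 0, frac_dep <= 1,
            frac_outlier_dep >= 0, frac_outlier_dep <= 1,
            missing_rate >= 0, missing_rate <= 1,
            n_exclusive_per_group >= 0, within_sd > 0,
            exclusive_min_present <= n_reps_per_group,
            length(group_labels) == 2)
  n_dep <- round(frac_dep * n_proteins)
  if (2 * n_exclusive_per_group + n_dep > n_proteins)
    stop("parameter error: exclusive + DEP allocation exceeds n_proteins",
         call. = FALSE)
  structure(p, class = "sim_params")
}

#' Generate a synthetic abundance dataset with planted ground truth
#'
#' Per protein, a baseline is drawn from
#' `Normal(baseline_mean, baseline_sd)`; replicate values are
#' `Normal(baseline, within_sd)` in the reference group and
#' `Normal(baseline + d * within_sd, within_sd)` in the case group for the
#' planted-effect proteins. MCAR missingness is applied everywhere except
#' over the planted exclusive patterns, which are constructed exactly
#' (all-missing on one side, a drawn number >= `exclusive_min_present` of
#' present values on the other). Identical parameters and seed give a
#' bit-identical dataset.
#'
#' @param params a [sim_params()] object.
#' @return list with `dataset` (an [abundance_dataset()]) and `truth`: a
#'   list holding `dep_ids`, `planted_d` (named, signed), `outlier_ids`,
#'   `exclusive_ids` (list per group), `params` and `seed`. The DEP and
#'   exclusive id sets are disjoint by construction.
#' @export
generate_abundance_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_proteins; r <- params$n_reps_per_group
  protein_ids <- sprintf("P%05d", seq_len(n))
  sample_ids <- c(paste0("C", seq_len(r)), paste0("G", seq_len(r)))
  group_of <- stats::setNames(rep(params$group_labels, each = r), sample_ids)

  n_dep <- round(params$frac_dep * n)
  dep_idx <- sort(sample.int(n, n_dep))
  n_out <- round(params$frac_outlier_dep * n_dep)
  out_idx <- if (n_out > 0) sort(sample(dep_idx, n_out)) else integer(0)
  d <- numeric(n)
  plain <- setdiff(dep_idx, out_idx)
  d[plain] <- stats::runif(length(plain), params$effect_size_range[1],
                           params$effect_size_range[2]) *
    sample(c(-1, 1), length(plain), replace = TRUE)
  d[out_idx] <- stats::runif(length(out_idx),
                             params$outlier_effect_range[1],
                             params$outlier_effect_range[2]) *
    sample(c(-1, 1), length(out_idx), replace = TRUE)

  baseline <- stats::rnorm(n, params$baseline_mean, params$baseline_sd)
  vals <- matrix(stats::rnorm(n * 2 * r, mean = baseline, sd = params$within_sd),
                 nrow = n, ncol = 2 * r)
  # case-group shift in Cohen's-d units of the within-group SD
  case_cols <- (r + 1):(2 * r)
  vals[, case_cols] <- vals[, case_cols] + d * params$within_sd
  dimnames(vals) <- list(protein_ids, sample_ids)

  # MCAR mask first, exclusive patterns stamped on top afterwards
  if (params$missing_rate > 0) {
    mask <- matrix(stats::runif(n * 2 * r) < params$missing_rate, nrow = n)
    vals[mask] <- NA_real_
  }
  nx <- params$n_exclusive_per_group
  exclusive_ids <- stats::setNames(list(character(0), character(0)),
                                   params$group_labels)
  if (nx > 0) {
    pool <- setdiff(seq_len(n), dep_idx)
    ex_idx <- sample(pool, 2 * nx)
    ex1 <- ex_idx[seq_len(nx)]          # present in group 1, absent in 2
    ex2 <- ex_idx[nx + seq_len(nx)]     # present in group 2, absent in 1
    ref_cols <- seq_len(r)
    stamp <- function(i, present_cols, absent_cols) {
      vals[i, ] <<- NA_real_
      npres <- sample(params$exclusive_min_present:r, 1)
      keep <- sample(present_cols, npres)
      vals[i, keep] <<- stats::rnorm(npres, baseline[i], params$within_sd)
    }
    for (i in ex1) stamp(i, ref_cols, case_cols)
    for (i in ex2) stamp(i, case_cols, ref_cols)
    exclusive_ids <- stats::setNames(
      list(protein_ids[sort(ex1)], protein_ids[sort(ex2)]),
      params$group_labels)
  }

  dataset <- abundance_dataset(vals, group_of,
                               group_levels = params$group_labels)
  truth <- list(dep_ids = protein_ids[dep_idx],
                planted_d = stats::setNames(d[dep_idx],
                                            protein_ids[dep_idx]),
                outlier_ids = protein_ids[out_idx],
                exclusive_ids = exclusive_ids,
                params = params, seed = params$seed)
  list(dataset = dataset, truth = truth)
}

#' Generate a PPI network with planted hub nodes
#'
#' A sparse Erdos-Renyi background graph plus `n_hubs` planted hubs, each
#' the shared member of `n_cliques_per_hub` otherwise-disjoint cliques of
#' size `clique_size`. Each planted hub therefore has degree
#' `n_cliques_per_hub * (clique_size - 1)`, MNC `clique_size - 1` and MCC
#' `n_cliques_per_hub * (clique_size - 1)!`, dominating the background on
#' all three local centralities. Edge confidence scores are drawn uniformly
#' in (0.9, 1].
#'
#' @param n_background background node count (default 40).
#' @param n_hubs planted hub count (default 3).
#' @param clique_size clique size around each hub (default 4).
#' @param n_cliques_per_hub cliques per hub (default 3).
#' @param p_background background edge probability (default 0.03).
#' @param seed integer RNG seed.
#' @return list with `network` (igraph with `score` edge attribute) and
#'   `truth` (list with `hub_ids`, `seed`).
#' @export
generate_ppi_network <- function(n_background = 40L, n_hubs = 3L,
                                 clique_size = 4L, n_cliques_per_hub = 3L,
                                 p_background = 0.03, seed = 1L) {
  stopifnot(n_background > 0, n_hubs >= 0, clique_size >= 2,
            n_cliques_per_hub >= 1)
  set.seed(seed)
  bg <- sprintf("B%03d", seq_len(n_background))
  ea <- character(0); eb <- character(0)
  pairs <- utils::combn(bg, 2)
  keep <- stats::runif(ncol(pairs)) < p_background
  ea <- pairs[1, keep]; eb <- pairs[2, keep]
  hubs <- if (n_hubs > 0) sprintf("HUB%02d", seq_len(n_hubs)) else character(0)
  for (h in seq_len(n_hubs)) {
    for (q in seq_len(n_cliques_per_hub)) {
      members <- c(hubs[h],
                   sprintf("H%02dQ%02dN%02d", h, q,
                           seq_len(clique_size - 1)))
      mp <- utils::combn(members, 2)
      ea <- c(ea, mp[1, ]); eb <- c(eb, mp[2, ])
    }
  }
  score <- 0.9 + 0.1 * stats::runif(length(ea))
  net <- ppi_network(ea, eb, score)
  # make sure isolated background nodes survive as vertices
  missing_nodes <- setdiff(c(bg, hubs), igraph::V(net)$name)
  if (length(missing_nodes) > 0)
    net <- igraph::add_vertices(net, length(missing_nodes),
                                name = missing_nodes)
  list(network = net, truth = list(hub_ids = hubs, seed = seed))
}

#' Generate an ontology annotation table with planted direction enrichment
#'
#' Every protein receives one category per ontology, drawn multinomially
#' from `n_categories` categories. For planted up- (down-) regulated
#' proteins the first (second) category's odds are multiplied by
#' `enrichment_factor` and the opposite direction's designated category is
#' depleted by the same factor, so `enrichment_factor = 1` is the exact
#' independence null.
#'
#' @param protein_ids all protein/gene ids to annotate.
#' @param up_ids,down_ids planted DEP ids by direction (subsets of
#'   `protein_ids`).
#' @param ontologies ontologies to annotate (default all four).
#' @param n_categories categories per ontology (default 6).
#' @param enrichment_factor odds multiplier >= 1 (default 1 = null).
#' @param seed integer RNG seed.
#' @return annotation data.frame (`id`, `ontology`, `category`) with
#'   attribute `enriched`, a list per ontology naming the up- and
#'   down-enriched categories.
#' @export
generate_annotation_table <- function(protein_ids, up_ids = character(0),
                                      down_ids = character(0),
                                      ontologies = .ONTOLOGIES,
                                      n_categories = 6L,
                                      enrichment_factor = 1,
                                      seed = 1L) {
  stopifnot(enrichment_factor >= 1, n_categories >= 2)
  set.seed(seed)
  out <- vector("list", length(ontologies))
  enriched <- list()
  for (k in seq_along(ontologies)) {
    ont <- ontologies[k]
    cats <- sprintf("%s_cat%02d", gsub("-", "", ont), seq_len(n_categories))
    w <- matrix(1, nrow = length(protein_ids), ncol = n_categories)
    rownames(w) <- protein_ids
    w[protein_ids %in% up_ids, 1] <- enrichment_factor
    w[protein_ids %in% up_ids, 2] <- 1 / enrichment_factor
    w[protein_ids %in% down_ids, 2] <- enrichment_factor
    w[protein_ids %in% down_ids, 1] <- 1 / enrichment_factor
    pick <- apply(w, 1, function(p) sample.int(n_categories, 1, prob = p))
    out[[k]] <- data.frame(id = protein_ids, ontology = ont,
                           category = cats[pick], stringsAsFactors = FALSE)
    enriched[[ont]] <- list(up = cats[1], down = cats[2])
  }
  tab <- do.call(rbind, out)
  tab <- annotation_table(tab$id, tab$ontology, tab$category)
  attr(tab, "enriched") <- enriched
  tab
}

#' Generate a gene-disease association table with planted high scorers
#'
#' Exactly `n_high` distinct genes receive one record with confidence score
#' strictly above `threshold`; every other gene receives one record at or
#' below it. Disease ids are drawn from a small epilepsy-flavored DOID pool
#' and channels from the knowledge/textmining channels.
#'
#' @param genes character vector of gene symbols.
#' @param n_high number of genes planted above the threshold.
#' @param threshold the downstream filter threshold (default 2).
#' @param seed integer RNG seed.
#' @return list with `records` (a validated disease table) and `truth`
#'   (list with `high_score_genes`, `seed`).
#' @export
generate_disease_table <- function(genes, n_high, threshold = 2.0,
                                   seed = 1L) {
  stopifnot(n_high <= length(genes), n_high >= 0)
  set.seed(seed)
  doids <- c("DOID:1826" = "Epilepsy",
             "DOID:3328" = "Temporal lobe epilepsy",
             "DOID:2234" = "Focal epilepsy")
  high <- if (n_high > 0) sort(sample(genes, n_high)) else character(0)
  score <- ifelse(genes %in% high,
                  threshold + stats::runif(length(genes), 0.1, 2),
                  stats::runif(length(genes), 0, threshold))
  ids <- sample(names(doids), length(genes), replace = TRUE)
  rec <- disease_table(
    gene = genes, disease_id = ids, disease_name = unname(doids[ids]),
    channel = sample(c("knowledge", "textmining"), length(genes),
                     replace = TRUE),
    score = round(score, 3))
  list(records = rec, truth = list(high_score_genes = high, seed = seed))
}
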