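# Independent brute-force oracles and tiny fixture builders shared by the
# test files. Everything here works from first principles (adjacency
# matrices, exhaustive enumeration) so it never reuses the code paths it
# checks.

# small two-group dataset from explicit row values; NA marks missing
make_dataset <- function(rows, n_per_group = NULL,
                         groups = c("CONTROL", "GASH")) {
  m <- do.call(rbind, rows)
  if (is.null(n_per_group)) n_per_group <- ncol(m) / 2
  rownames(m) <- names(rows)
  colnames(m) <- c(paste0("C", seq_len(n_per_group)),
                   paste0("G", seq_len(ncol(m) - n_per_group)))
  group_of <- stats::setNames(
    rep(groups, c(n_per_group, ncol(m) - n_per_group)), colnames(m))
  abundance_dataset(m, group_of, group_levels = groups)
}

# ---- graph oracles on a (0/1) adjacency matrix -----------------------------

adjacency_of <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  a[a > 1] <- 1
  diag(a) <- 0
  a
}

oracle_degree <- function(adj) rowSums(adj)

# connected components of the induced subgraph on `nodes` via BFS
oracle_components_max <- function(adj, nodes) {
  if (length(nodes) == 0) return(0)
  sub <- adj[nodes, nodes, drop = FALSE]
  seen <- rep(FALSE, length(nodes))
  best <- 0
  for (s in seq_along(nodes)) {
    if (seen[s]) next
    comp <- s
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier) > 0) {
      nxt <- which(colSums(sub[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    best <- max(best, length(comp))
  }
  best
}

oracle_mnc <- function(adj) {
  vapply(seq_len(nrow(adj)), function(v)
    oracle_components_max(adj, which(adj[v, ] == 1)), numeric(1))
}

# exhaustive maximal-clique enumeration by subset testing (n <= ~15)
oracle_maximal_cliques <- function(adj) {
  n <- nrow(adj)
  is_clique <- function(s) {
    if (length(s) < 2) return(TRUE)
    all(adj[s, s][upper.tri(diag(length(s)))] == 1)
  }
  out <- list()
  for (code in seq_len(2^n - 1)) {
    s <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (!is_clique(s)) next
    # maximal iff no outside vertex is adjacent to every member
    ext <- setdiff(seq_len(n), s)
    if (length(ext) == 0 ||
        !any(vapply(ext, function(v) all(adj[v, s] == 1), logical(1))))
      out[[length(out) + 1]] <- s
  }
  out
}

oracle_mcc <- function(adj) {
  cl <- oracle_maximal_cliques(adj)
  out <- numeric(nrow(adj))
  for (s in cl) {
    if (length(s) < 2) next  # isolated vertices score 0
    out[s] <- out[s] + factorial(length(s) - 1)
  }
  out
}

# ---- missingness-rule oracle ----------------------------------------------

# direct transcription of the keep rule for a 6+6 design
oracle_keep <- function(na_ctrl, na_case, min_present = 4, max_total = 3,
                        n = 6) {
  (n - na_ctrl) >= min_present && (n - na_case) >= min_present &&
    (na_ctrl + na_case) <= max_total
}

# dataset with one protein per (na_ctrl, na_case) pattern in {0..6}^2
all_na_pattern_dataset <- function() {
  rows <- list()
  for (a in 0:6) for (b in 0:6) {
    v <- c(11:16, 21:26) + stats::rnorm(12, 0, 0.01)
    if (a > 0) v[seq_len(a)] <- NA
    if (b > 0) v[6 + seq_len(b)] <- NA
    rows[[sprintf("NA_%d_%d", a, b)]] <- v
  }
  make_dataset(rows)
}

# ---- misc ------------------------------------------------------------------

extdata <- function(f) system.file("extdata", f, package = "dephub")
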