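test_that("edge filter keeps strictly higher-confidence edges and isolated nodes", {
  g <- ppi_network(c("A", "B", "C"), c("B", "C", "D"),
                   c(0.95, 0.90, 0.85))
  f <- filter_edges(g, 0.9)
  expect_equal(igraph::ecount(f), 1L)           # 0.90 boundary is dropped
  expect_equal(igraph::vcount(f), 4L)           # nodes all retained
  expect_equal(igraph::E(f)$score, 0.95)

  all_high <- ppi_network(c("A", "B"), c("B", "C"), c(1, 1))
  expect_equal(igraph::ecount(filter_edges(all_high)), 2L)

  empty <- ppi_network(character(0), character(0), numeric(0))
  expect_equal(igraph::ecount(filter_edges(empty)), 0L)
})

test_that("centralities match hand-derived values on canonical graphs", {
  # triangle: degree 2, MNC 2 (neighborhood is an edge), MCC 2! = 2
  tri <- ppi_network(c("a", "a", "b"), c("b", "c", "c"))
  expect_equal(unname(degree_centrality(tri)), rep(2L, 3))
  expect_equal(unname(mnc_centrality(tri)), rep(2L, 3))
  expect_equal(unname(mcc_centrality(tri)), rep(2, 3))

  # star K1,3: center degree 3, MNC 1 (no edges among leaves), MCC 3
  star <- ppi_network(rep("c", 3), c("l1", "l2", "l3"))
  expect_equal(degree_centrality(star)[["c"]], 3L)
  expect_equal(mnc_centrality(star)[["c"]], 1L)
  expect_equal(mcc_centrality(star)[["c"]], 3)  # = degree: leaves not adjacent
  expect_equal(degree_centrality(star)[["l1"]], 1L)

  # path a-b-c: MCC(b) = 1! + 1! = 2
  path <- ppi_network(c("a", "b"), c("b", "c"))
  expect_equal(mcc_centrality(path)[["b"]], 2)

  # two triangles sharing v: MCC(v) = 2! + 2! = 4
  bowtie <- ppi_network(c("v", "v", "a", "v", "v", "c"),
                        c("a", "b", "b", "c", "d", "d"))
  expect_equal(mcc_centrality(bowtie)[["v"]], 4)
  expect_equal(mnc_centrality(bowtie)[["v"]], 2L)

  # isolated node scores zero everywhere
  iso <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices("x")
  expect_equal(degree_centrality(iso)[["x"]], 0L)
  expect_equal(mnc_centrality(iso)[["x"]], 0L)
  expect_equal(mcc_centrality(iso)[["x"]], 0)
})

test_that("degree, MNC and MCC equal exhaustive oracles on 100 random graphs", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.15, 0.6))
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    adj <- adjacency_of(g)
    expect_equal(unname(degree_centrality(g)), unname(oracle_degree(adj)),
                 label = paste("degree graph", i))
    expect_equal(unname(mnc_centrality(g)), unname(oracle_mnc(adj)),
                 ignore_attr = TRUE, label = paste("mnc graph", i))
    expect_equal(unname(mcc_centrality(g)), unname(oracle_mcc(adj)),
                 label = paste("mcc graph", i))
  }
})

test_that("centralities are invariant under node relabeling", {
  set.seed(77)
  g <- igraph::sample_gnp(10, 0.4)
  igraph::V(g)$name <- letters[1:10]
  perm <- sample(10)
  h <- igraph::permute(g, perm)
  for (fn in list(degree_centrality, mnc_centrality, mcc_centrality)) {
    a <- fn(g); b <- fn(h)
    expect_equal(a[sort(names(a))], b[sort(names(b))])
  }
})

test_that("MCC equals degree exactly on edge-free neighborhoods (stars and trees)", {
  star <- ppi_network(rep("c", 5), paste0("l", 1:5))
  expect_equal(mcc_centrality(star), as.numeric(degree_centrality(star)),
               ignore_attr = TRUE)
  set.seed(5)
  tree <- igraph::sample_tree(12)
  igraph::V(tree)$name <- sprintf("t%02d", 1:12)
  expect_equal(unname(mcc_centrality(tree)),
               as.numeric(unname(degree_centrality(tree))))
})

test_that("consensus selection intersects the three score-thresholded sets", {
  scores <- data.frame(node = c("a", "b", "c", "d"),
                       degree = c(5L, 2L, 1L, 3L),
                       mnc = c(4L, 2L, 3L, 1L),
                       mcc = c(24, 2, 6, 1))
  sets <- consensus_hubs(scores, threshold = 2)
  expect_setequal(sets$degree, c("a", "b", "d"))
  expect_setequal(sets$mnc, c("a", "b", "c"))
  expect_setequal(sets$mcc, c("a", "b", "c"))
  expect_equal(sets$consensus, c("a", "b"))

  # one empty selection forces an empty consensus
  scores0 <- transform(scores, mnc = 0L)
  expect_length(consensus_hubs(scores0, 2)$consensus, 0)

  # identical sets pass through
  same <- data.frame(node = c("a", "b"), degree = c(3L, 2L),
                     mnc = c(3L, 2L), mcc = c(2, 2))
  expect_setequal(consensus_hubs(same, 2)$consensus, c("a", "b"))

  # rank mode takes the top-k per method instead
  expect_equal(consensus_hubs(scores, 1, mode = "rank")$consensus, "a")
})

test_that("planted hubs always enter the consensus on synthetic networks", {
  hits <- 0L
  for (s in 1:50) {
    gen <- generate_ppi_network(n_background = 30, n_hubs = 3,
                                clique_size = 4, seed = s)
    net <- filter_edges(gen$network, 0.9)
    sets <- consensus_hubs(hub_scores(net), 2)
    if (all(gen$truth$hub_ids %in% sets$consensus)) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})
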