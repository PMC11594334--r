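test_that("axes are assembled exactly on the enumerated toy instance", {
  inp <- toy_network_inputs()
  net <- build_axes(inp$pairs, inp$circ_mir, inp$mir_mrna, inp$expressed)
  expect_setequal(paste(net$axes$circ_id, net$axes$mirna_id, net$axes$gene_id),
                  c("c1 u1 m1", "c1 u2 m2", "c2 u1 m1"))
  # 6 distinct entities: c1, c2, u1, u2, m1, m2
  expect_equal(as.list(network_stats(net)),
               list(n_axes = 3L, n_nodes = 6L,
                    n_circ_mir_edges = 3L, n_mir_mrna_edges = 2L))
})

test_that("the miRNA expression gate and minimal/empty cases behave", {
  inp <- toy_network_inputs()
  none <- build_axes(inp$pairs, inp$circ_mir, inp$mir_mrna, character(0))
  expect_equal(network_stats(none)$n_axes, 0)
  expect_equal(as.list(network_stats(none)),
               list(n_axes = 0L, n_nodes = 0L,
                    n_circ_mir_edges = 0L, n_mir_mrna_edges = 0L))

  one <- build_axes(inp$pairs[1, ], inp$circ_mir[1, ], inp$mir_mrna[1, ], "u1")
  expect_equal(as.list(network_stats(one)),
               list(n_axes = 1L, n_nodes = 3L,
                    n_circ_mir_edges = 1L, n_mir_mrna_edges = 1L))

  # partial gate: dropping u2 removes exactly its axis
  part <- build_axes(inp$pairs, inp$circ_mir, inp$mir_mrna, "u1")
  expect_setequal(part$axes$mirna_id, "u1")
  expect_equal(nrow(part$axes), 2)
})

test_that("networks are strictly tripartite", {
  bad <- tibble::tibble(circ_id = "x", mirna_id = "u1", gene_id = "x")
  expect_error(cerna_network(bad), "tripartite")
  ok <- cerna_network(random_axes(0))
  expect_equal(network_stats(ok)$n_nodes, 0)
})

test_that("every edge is supported by at least one axis", {
  set.seed(14)
  for (i in 1:20) {
    net <- cerna_network(random_axes(sample(1:25, 1)))
    s <- network_stats(net)
    expect_gte(s$n_axes, max(s$n_circ_mir_edges, s$n_mir_mrna_edges))
  }
})

test_that("hub ranking: degree dominance, toy enumeration, ties, k overflow", {
  star <- cerna_network(tibble::tibble(
    circ_id = c(rep("cBig", 5), "cSmall"),
    mirna_id = paste0("u", c(1:5, 1)),
    gene_id = "g1"))
  for (meth in c("degree", "mcc")) {
    h <- rank_hubs(star, meth, k = 2)
    expect_equal(h$node[1], "cBig")
  }

  inp <- toy_network_inputs()
  net <- build_axes(inp$pairs, inp$circ_mir, inp$mir_mrna, inp$expressed)
  h <- rank_hubs(net, "degree", k = 2)
  expect_equal(h$node, c("c1", "c2"))
  expect_equal(h$score, c(2, 1))

  expect_warning(all_h <- rank_hubs(net, k = 10), "exceeds")
  expect_equal(nrow(all_h), 2)
  expect_error(rank_hubs(net, k = 0), ">= 1")

  # lexicographic tie-break
  tie <- cerna_network(tibble::tibble(circ_id = c("cb", "ca"),
                                      mirna_id = c("u1", "u2"),
                                      gene_id = c("g1", "g2")))
  expect_equal(rank_hubs(tie, k = 2)$node, c("ca", "cb"))
})

test_that("MCC equals degree on tripartite (triangle-free) networks", {
  set.seed(24)
  for (i in 1:30) {
    net <- cerna_network(random_axes(sample(1:30, 1)))
    if (nrow(net$axes) == 0) next
    k <- sum(net$nodes$type == "circRNA")
    d <- rank_hubs(net, "degree", k)
    m <- rank_hubs(net, "mcc", k)
    expect_equal(d$node, m$node)
    expect_equal(d$score, m$score)
  }
})

test_that("hub ranking is invariant under axis order permutation", {
  set.seed(34)
  ax <- random_axes(20)
  net1 <- cerna_network(ax)
  net2 <- cerna_network(ax[sample(nrow(ax)), ])
  expect_equal(rank_hubs(net1, k = 3), rank_hubs(net2, k = 3))
})

test_that("subnetwork extraction filters axes by hub circRNA", {
  inp <- toy_network_inputs()
  net <- build_axes(inp$pairs, inp$circ_mir, inp$mir_mrna, inp$expressed)
  sub <- extract_subnetwork(net, "c1")
  expect_equal(nrow(sub$axes), 2)
  expect_equal(length(unique(sub$axes$mirna_id)), 2)
  expect_equal(length(unique(sub$axes$gene_id)), 2)
  all_c <- extract_subnetwork(net, c("c1", "c2"))
  expect_equal(all_c$axes, net$axes)
  expect_equal(nrow(extract_subnetwork(net, character(0))$axes), 0)
  expect_error(extract_subnetwork(net, "nope"), "unknown hub")
})

test_that("exports write SIF/edge-TSV/GraphML with partition prefixes", {
  inp <- toy_network_inputs()
  net <- build_axes(inp$pairs, inp$circ_mir, inp$mir_mrna, inp$expressed)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 5)  # 3 sponge + 2 target edges
  expect_true(all(grepl("\t(sponges|targets)\t", lines)))
  expect_true(any(startsWith(lines, "circ:")))

  etsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, etsv, "edge_tsv")
  back <- read_edge_tsv(etsv)
  expect_setequal(paste(back$from, back$interaction, back$to, sep = "\t"), lines)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml",
                 node_attrs = tibble::tibble(id = c("c1", "c2"),
                                             log2_fc = c(1.5, -2)))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 5)
  expect_setequal(unique(igraph::V(g)$type), c("circRNA", "miRNA", "mRNA"))

  empty <- cerna_network(random_axes(0))
  sif0 <- withr::local_tempfile(fileext = ".sif")
  export_network(empty, sif0, "sif")
  expect_length(readLines(sif0), 0)  # valid empty file
})
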