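test_that("hypergraph construction counts hypernodes and hyperedges", {
  inst <- tibble::tibble(
    code = c("PPP", "PPP", "PPP", "rrr", "RP"),
    topo_type = c("COM", "COM", "COM", "FFL", "2FB"),
    n1 = c("a", "b", "c", "a", "x"),
    n2 = c("b", "c", "d", "b", "y"),
    n3 = c("c", "d", "e", "c", NA))
  h_com <- build_hypergraph(inst, "COM")
  expect_equal(nrow(h_com), 3L)
  expect_equal(length(unique(unlist(h_com$nodes))), 5L)
  h_all <- build_hypergraph(inst, "ALL")
  expect_equal(nrow(h_all), 5L)
  h_2fb <- build_hypergraph(inst, "2FB")
  expect_equal(lengths(h_2fb$nodes), 2L)
  expect_equal(nrow(build_hypergraph(inst, "CIR")), 0L)
})

test_that("cluster extraction reproduces the analytic toy optima", {
  # single hyperedge: the only candidate, ratio 1/3
  cl <- cluster_hypergraph(make_hypergraph(list(c("a", "b", "c"))))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$ratio, 1 / 3)
  expect_equal(cl$nodes[[1]], c("a", "b", "c"))

  # all triples of 4 nodes: the 4-node set at ratio 1 beats any triple's 1/3
  h <- make_hypergraph(utils::combn(letters[1:4], 3L, simplify = FALSE))
  cl2 <- cluster_hypergraph(h)
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$ratio, 1)
  expect_equal(lengths(cl2$nodes), 4L)

  # two dense components joined by one bridging hyperedge: the first
  # cluster attains the exhaustive-search optimum on this instance
  comp1 <- utils::combn(c("a", "b", "c", "d"), 3L, simplify = FALSE)
  comp2 <- utils::combn(c("w", "x", "y", "z"), 3L, simplify = FALSE)
  sets <- c(comp1, comp2, list(c("d", "w", "x")))
  cl3 <- cluster_hypergraph(make_hypergraph(sets))
  expect_equal(cl3$ratio[1],
               exhaustive_max_ratio(sets, sort(unique(unlist(sets)))))
})

test_that("first cluster attains the exhaustive optimum on random instances", {
  set.seed(5150)
  for (i in 1:30) {
    n <- sample(5:10, 1)
    nodes <- letters[seq_len(n)]
    sets <- unique(lapply(seq_len(sample(3:12, 1)),
                          function(j) sort(sample(nodes, sample(2:3, 1)))))
    cl <- suppressWarnings(cluster_hypergraph(make_hypergraph(sets)))
    expect_equal(cl$ratio[1],
                 exhaustive_max_ratio(sets, sort(unique(unlist(sets)))),
                 info = paste("instance", i))
  }
})

test_that("every hyperedge lands in exactly one cluster and output is deterministic", {
  set.seed(77)
  sets <- unique(lapply(1:15, function(j)
    sort(sample(letters[1:9], sample(2:3, 1)))))
  h <- make_hypergraph(sets)
  cl <- suppressWarnings(cluster_hypergraph(h))
  assigned <- sort(unlist(cl$hyperedges))
  expect_equal(assigned, h$id)
  cl2 <- suppressWarnings(cluster_hypergraph(h))
  expect_identical(cl, cl2)
})

test_that("module filtering applies size bounds and the strict homology rule", {
  layers <- layer_spec(c("R", "H", "P"), c(TRUE, FALSE, FALSE))
  # cluster of 4 nodes: below the 5-node minimum
  small <- tibble::tibble(cluster = 1L, nodes = list(letters[1:4]),
                          hyperedges = list(1L), ratio = 1)
  netA <- composite_network(tibble::tibble(from = "a", to = "b", layer = "P"),
                            layers)
  expect_equal(nrow(filter_modules(small, netA, "COM")), 0L)

  # 6 nodes, 10 internal edges all homologous: fraction 1.0 > 0.9, dropped
  nodes6 <- letters[1:6]
  h_edges <- tibble::tibble(from = utils::combn(nodes6, 2)[1, 1:10],
                            to = utils::combn(nodes6, 2)[2, 1:10],
                            layer = "H")
  netB <- composite_network(h_edges, layers)
  clB <- tibble::tibble(cluster = 1L, nodes = list(nodes6),
                        hyperedges = list(1L), ratio = 1)
  expect_equal(nrow(filter_modules(clB, netB, "COM")), 0L)

  # 9 H + 1 P: fraction exactly 0.9, kept under the strict > rule
  mixed <- h_edges
  mixed$layer[10] <- "P"
  netC <- composite_network(mixed, layers)
  kept <- filter_modules(clB, netC, "COM")
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$module, "COM_1")
  expect_equal(nrow(kept$internal_edges[[1]]), 10L)
})

test_that("module naming is 1-based in extraction order per pool", {
  layers <- layer_spec("P", FALSE)
  set.seed(2)
  # two clear cliques of different density
  cl6 <- utils::combn(paste0("a", 1:6), 3L, simplify = FALSE)
  cl5 <- utils::combn(paste0("b", 1:5), 3L, simplify = FALSE)
  edges <- purrr::map_dfr(c(cl6, cl5), function(tr) {
    p <- utils::combn(tr, 2L)
    tibble::tibble(from = p[1, ], to = p[2, ], layer = "P")
  })
  net <- composite_network(dplyr::distinct(edges), layers)
  mods <- detect_modules(net, pools = "COM")
  expect_equal(mods$module, paste0("COM_", seq_len(nrow(mods))))
  # the denser 6-clique is extracted first
  expect_equal(sort(mods$nodes[[1]]), paste0("a", 1:6))
})

test_that("tidy and glance summarise module sets", {
  layers <- layer_spec("P", FALSE)
  edges <- purrr::map_dfr(utils::combn(paste0("g", 1:6), 2L, simplify = FALSE),
                          function(p) tibble::tibble(from = p[1], to = p[2],
                                                     layer = "P"))
  net <- composite_network(edges, layers)
  mods <- detect_modules(net, pools = c("COM", "ALL"))
  long <- tidy(mods)
  expect_equal(nrow(long), sum(mods$n_nodes))
  cen <- glance(mods)
  expect_setequal(cen$topo_type, c("COM", "ALL"))
})
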