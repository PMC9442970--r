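test_that("shared-edge counting pools directions and ignores internal edges", {
  layers <- layer_spec(c("R", "P"), c(TRUE, FALSE))
  # x-u and y-v cross; x-y is internal to module a
  net <- composite_network(tibble::tibble(
    from = c("u", "v", "x"), to = c("x", "y", "y"), layer = "P"), layers)
  expect_equal(count_shared_edges(net, c("x", "y"), c("u", "v"), "P"), 2L)
  expect_equal(count_shared_edges(net, c("x", "y"), c("u", "v"), "R"), 0L)

  # directed layer: both directions pooled
  net2 <- composite_network(tibble::tibble(
    from = c("x", "u"), to = c("u", "y"), layer = "R"), layers)
  expect_equal(count_shared_edges(net2, c("x", "y"), "u", "R"), 2L)
})

test_that("sampling null matches analytic cases", {
  layers <- layer_spec("P", FALSE)
  # empty layer: degenerate null
  net0 <- composite_network(tibble::tibble(from = "a", to = "b", layer = "P"),
                            layer_spec(c("P", "C"), FALSE),
                            nodes = letters[1:6])
  nm0 <- motifmodules:::superview_null(net0, "C", 2, 2, B = 50, seed = 1)
  expect_equal(unname(nm0), c(0, 0))

  # complete undirected layer on 8 nodes: every cross pair is an edge
  nodes <- letters[1:8]
  pairs <- utils::combn(nodes, 2L)
  net <- composite_network(tibble::tibble(from = pairs[1, ], to = pairs[2, ],
                                          layer = "P"), layers)
  nm <- motifmodules:::superview_null(net, "P", 3, 2, B = 100, seed = 1)
  expect_equal(unname(nm), c(6, 0))

  # sparse random layer: mean within 3 standard errors of the analytic
  # expectation size_a * size_b * 2 * density_of_unordered_pairs
  set.seed(42)
  netr <- random_composite_network(20, layers, density = 0.3)
  m <- nrow(netr$edges)
  dens <- m / choose(20, 2)
  B <- 2000
  nm2 <- motifmodules:::superview_null(netr, "P", 5, 5, B = B, seed = 9)
  expected <- 25 * dens
  se <- nm2[["sigma"]] / sqrt(B)
  expect_lt(abs(nm2[["mu"]] - expected), 3 * se + 1e-9)
})

test_that("oversized module pairs fall back to independent null draws with a warning", {
  layers <- layer_spec("P", FALSE)
  set.seed(2)
  net <- random_composite_network(10, layers, density = 0.4)
  expect_warning(
    nm <- motifmodules:::superview_null(net, "P", 7, 7, B = 100, seed = 1),
    "independently")
  expect_true(is.finite(nm[["mu"]]) && nm[["mu"]] > 0)
})

test_that("z and p follow the zero-count and normal-tail rules", {
  expect_equal(superview_score(5, 5, 2), tibble::tibble(z = 0, p = 0.5))
  expect_equal(superview_score(0, 3, 1), tibble::tibble(z = 0, p = 1))
  sc <- superview_score(10 + 1.645 * 2, 10, 2)
  expect_equal(sc$p, 1 - stats::pnorm(1.645), tolerance = 1e-12)
  # degenerate null: capped surrogate z
  expect_equal(superview_score(3, 1, 0)$z, 1e6)
  expect_equal(superview_score(2, 2, 0)$z, 0)
})

test_that("superview emits one record per unordered pair per layer", {
  layers <- layer_spec(c("R", "P"), c(TRUE, FALSE))
  set.seed(12)
  net <- random_composite_network(20, layers, density = 0.25)
  mods <- tibble::tibble(module = c("A", "B", "C"),
                         nodes = list(net$nodes[1:5], net$nodes[6:10],
                                      net$nodes[11:14]))
  sv <- superview(mods, net, B = 200, seed = 5)
  expect_equal(nrow(sv), 3 * 2)
  expect_true(all(sv$p >= 0 & sv$p <= 1))
  expect_true(all(sv$z[sv$x == 0] == 0) && all(sv$p[sv$x == 0] == 1))
  # symmetric in the module arguments
  expect_equal(count_shared_edges(net, mods$nodes[[1]], mods$nodes[[2]], "P"),
               count_shared_edges(net, mods$nodes[[2]], mods$nodes[[1]], "P"))
  # identical across core counts
  sv2 <- superview(mods, net, B = 200, seed = 5, cores = 2)
  expect_identical(sv, sv2)
})

test_that("regulator-module strength is the targeted fraction", {
  layers <- layer_spec(c("R", "M", "P"), c(TRUE, TRUE, FALSE))
  net <- composite_network(tibble::tibble(
    from = c(rep("tf", 3), rep("mir", 5)),
    to = c(paste0("g", 1:3), paste0("h", 1:5)),
    layer = c(rep("R", 3), rep("M", 5))), layers)
  mods <- tibble::tibble(module = c("A", "B"),
                         nodes = list(c(paste0("g", 1:3), paste0("x", 1:3)),
                                      paste0("h", 1:5)))
  rl <- regulator_links(mods, net, "R")
  expect_equal(rl$strength[rl$module == "A"], 0.5)  # 3 of 6
  expect_equal(nrow(rl[rl$module == "B", ]), 0L)    # no R edge into B
  rm <- regulator_links(mods, net, "M")
  expect_equal(rm$strength[rm$module == "B"], 1.0)  # all 5 targeted
  expect_error(regulator_links(tibble::tibble(module = "E",
                                              nodes = list(character())),
                               net, "R"), "empty")
})

test_that("module and regulator specificities are the defined fractions", {
  layers <- layer_spec(c("R", "P"), c(TRUE, FALSE))
  # 4 TFs total; 2 target module A; regulator inside a module counts
  net <- composite_network(tibble::tibble(
    from = c("t1", "t2", "t3", "t4", "t1"),
    to = c("a1", "a2", "b1", "b2", "t2"),
    layer = "R"), layers)
  mods <- tibble::tibble(module = c("A", "B"),
                         nodes = list(c("a1", "a2", "t2"), c("b1", "b2")))
  ms <- module_regulator_specificity(mods, net, "R")
  expect_equal(ms$specificity[ms$module == "A"], 2 / 4)
  rs <- regulator_specificity(mods, net, "R")
  expect_equal(rs$specificity[rs$regulator == "t1"], 1 / 2)
  expect_equal(rs$specificity[rs$regulator == "t3"], 1 / 2)
  expect_equal(sum(rs$n_modules), 4L)
})

test_that("set-connectivity reconstruction reproduces printed-summary arithmetic", {
  # 95% CI on the mean of 1000 null sums with mean 1720 and sd 880
  row <- connectivity_fold_change(32038, 1720, 880, B = 1000)
  expect_equal(row$ci_upper, 1720 + 1.96 * 880 / sqrt(1000))
  expect_equal(round(row$ci_upper), 1775, tolerance = 1)
  expect_equal(row$fold_change, 32038 / row$ci_upper)
  expect_equal(round(row$fold_change), 18)
  # degenerate null
  expect_equal(connectivity_fold_change(0, 0, 0)$fold_change, 0)
  expect_true(is.infinite(connectivity_fold_change(5, 0, 0)$fold_change))
})

test_that("connectivity of the whole module universe concentrates at fold change 1", {
  layers <- layer_spec("P", FALSE)
  set.seed(31)
  net <- random_composite_network(30, layers, density = 0.3)
  mods <- tibble::tibble(module = paste0("M", 1:6),
                         nodes = split(net$nodes, rep(1:6, each = 5)))
  sv <- superview(mods, net, B = 100, seed = 2)
  res <- module_set_connectivity(sv, mods$module, B = 200, seed = 3)
  tot <- res[res$layer == "Total", ]
  # the null sets equal the selected set, so observed == every null draw
  expect_equal(tot$random_sd, 0)
  expect_equal(tot$observed / tot$random_mean, 1)
  # a set with no internal superview edges has fold change 0
  empty_pair <- mods$module[1:2]
  sv0 <- sv
  sv0$x[sv0$module_a %in% empty_pair & sv0$module_b %in% empty_pair] <- 0L
  res0 <- module_set_connectivity(sv0, empty_pair, B = 50, seed = 1)
  expect_equal(res0$observed[res0$layer == "Total"], 0)
  expect_equal(res0$fold_change[res0$layer == "Total"], 0)
})

test_that("DE enrichment matches direct hypergeometric tail computation", {
  # identical DE rates inside and out: fold change 1
  mods <- tibble::tibble(module = c("S", "O"),
                         nodes = list(paste0("s", 1:10), paste0("o", 1:10)))
  de_equal <- c(paste0("s", 1:2), paste0("o", 1:2))
  expect_equal(de_gene_set_enrichment(mods, "S", de_equal)$fold_change, 1)

  # 10 of 20 in-set DE vs 50 of 1000 outside: fold change 10, exact tail
  set_genes <- paste0("s", 1:20)
  out_genes <- paste0("o", 1:1000)
  mods2 <- tibble::tibble(module = c("S", "O"),
                          nodes = list(set_genes, out_genes))
  de <- c(set_genes[1:10], out_genes[1:50])
  res <- de_gene_set_enrichment(mods2, "S", de)
  expect_equal(res$fold_change, (10 / 20) / (50 / 1000))
  expect_equal(res$p, sum(stats::dhyper(10:20, 60, 960, 20)),
               tolerance = 1e-12)

  # maximal enrichment: all set genes DE, none outside
  res2 <- de_gene_set_enrichment(mods2, "S", set_genes)
  expect_true(is.infinite(res2$fold_change))
  expect_lt(res2$p, 1e-20)
})
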