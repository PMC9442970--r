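expr_matrix <- function(genes, samples, fill) {
  m <- matrix(fill, nrow = length(genes), ncol = samples,
              dimnames = list(genes, sprintf("s%02d", seq_len(samples))))
  m
}

mods_nodes <- function(...) {
  sets <- list(...)
  tibble::tibble(module = paste0("M", seq_along(sets)), topo_type = "COM",
                 nodes = sets, n_nodes = lengths(sets),
                 internal_edges = lapply(sets, function(s) {
                   p <- utils::combn(s, 2L)
                   tibble::tibble(from = p[1, ], to = p[2, ], layer = "P")
                 }))
}

test_that("nPCC hits its analytic extremes", {
  set.seed(1)
  base <- stats::rnorm(10)
  # shared vector plus tiny jitter: near-perfect correlation
  genes <- paste0("g", 1:5)
  m <- t(vapply(genes, function(g) base + stats::rnorm(10, sd = 1e-4),
                numeric(10)))
  colnames(m) <- sprintf("s%02d", 1:10)
  bgm <- matrix(stats::rnorm(40 * 10), nrow = 40,
                dimnames = list(paste0("b", 1:40), colnames(m)))
  expr <- rbind(m, bgm)
  res <- module_npcc(mods_nodes(genes), expr, B = 200, seed = 3)
  expect_gt(res$npcc, 0.999)
  expect_gt(res$z, 3)
  expect_equal(res$coverage, 1)

  # two genes with correlation -1
  m2 <- rbind(g1 = base, g2 = -base, bgm)
  res2 <- module_npcc(mods_nodes(c("g1", "g2")), m2, B = 100, seed = 2)
  expect_equal(res2$npcc, -1)

  # fewer than two expressed genes: NA scores, coverage still reported
  res3 <- module_npcc(mods_nodes(c("g1", "zz1", "zz2")), m2, B = 50, seed = 2)
  expect_true(is.na(res3$npcc))
  expect_equal(res3$coverage, 0)  # no internal edge fully covered
})

test_that("nPCC p-values are near-uniform for independent-noise modules", {
  set.seed(21)
  expr <- matrix(stats::rnorm(200 * 12), nrow = 200,
                 dimnames = list(paste0("g", 1:200), sprintf("s%02d", 1:12)))
  sets <- lapply(1:60, function(i) sample(rownames(expr), 8))
  mods <- tibble::tibble(module = paste0("M", 1:60), topo_type = "COM",
                         nodes = sets, n_nodes = 8L,
                         internal_edges = vector("list", 60))
  res <- module_npcc(mods, expr, B = 300, seed = 4)
  expect_lt(abs(mean(res$npcc)), 0.05)
  # z-scores roughly standard under the matched null
  expect_lt(abs(mean(res$z)), 0.35)
  expect_lt(abs(stats::sd(res$z) - 1), 0.45)
})

test_that("ECD equals the per-edge correlation differential average", {
  set.seed(5)
  samples <- sprintf("s%02d", 1:16)
  cond <- samples[1:8]; ctrl <- samples[9:16]
  # identical matrices in both conditions: ecd exactly 0
  genes <- paste0("g", 1:5)
  half <- matrix(stats::rnorm(5 * 8), nrow = 5,
                 dimnames = list(genes, cond))
  expr_same <- cbind(half, `colnames<-`(half, ctrl))
  res0 <- module_ecd(mods_nodes(genes), expr_same, cond, ctrl,
                     B = 50, seed = 1)
  expect_equal(res0$ecd, 0)

  # perfectly correlated in condition, anti-correlated in control: ecd = 2
  v <- stats::rnorm(8)
  expr2 <- rbind(a = c(v, v), b = c(v, -v))
  colnames(expr2) <- samples
  res2 <- module_ecd(mods_nodes(c("a", "b")), expr2, cond, ctrl,
                     B = 50, seed = 1)
  expect_equal(res2$ecd, 2)

  # one rewired edge among ten: hand-computed average over edges
  hub_genes <- paste0("h", 1:5)
  mat_c <- matrix(stats::rnorm(5 * 8), nrow = 5,
                  dimnames = list(hub_genes, cond))
  mat_x <- mat_c
  mat_x["h5", ] <- -mat_c["h5", ] + stats::rnorm(8, sd = 0.1)
  expr3 <- cbind(mat_c, `colnames<-`(mat_x, ctrl))
  mods3 <- mods_nodes(hub_genes)  # all 10 pairs are internal edges
  res3 <- module_ecd(mods3, expr3, cond, ctrl, B = 50, seed = 1)
  hand <- mean(vapply(utils::combn(hub_genes, 2, simplify = FALSE),
                      function(p) {
                        stats::cor(expr3[p[1], cond], expr3[p[2], cond]) -
                          stats::cor(expr3[p[1], ctrl], expr3[p[2], ctrl])
                      }, 0))
  expect_equal(res3$ecd, hand, tolerance = 1e-12)
  expect_true(all(abs(res3$ecd) <= 2))

  # no qualifying edge: NA
  res4 <- module_ecd(mods_nodes(c("q1", "q2")), expr3, cond, ctrl,
                     B = 10, seed = 1)
  expect_true(is.na(res4$ecd))
})

test_that("activity score follows the inverse-normal aggregation arithmetic", {
  mods <- mods_nodes(paste0("g", 1:4))
  filler <- tibble::tibble(gene = paste0("f", 1:96), contrast = "c1",
                           p = stats::runif(96))
  # all p = 0.5: every z_i = 0, z_a = 0
  pv0 <- dplyr::bind_rows(
    tibble::tibble(gene = paste0("g", 1:4), contrast = "c1", p = 0.5), filler)
  act0 <- module_activity(mods, pv0, B = 100, seed = 1)
  expect_equal(act0$z_a, 0)

  # k = 4, all z_i = 2: z_a = 4 * 2 / sqrt(4) = 4
  pv2 <- dplyr::bind_rows(
    tibble::tibble(gene = paste0("g", 1:4), contrast = "c1",
                   p = 1 - stats::pnorm(2)), filler)
  act2 <- module_activity(mods, pv2, B = 100, seed = 1)
  expect_equal(act2$z_a, 4, tolerance = 1e-12)
  expect_equal(act2$k, 4L)

  # p = 0 exports survive through clamping
  pv3 <- dplyr::bind_rows(
    tibble::tibble(gene = paste0("g", 1:4), contrast = "c1", p = 0), filler)
  act3 <- module_activity(mods, pv3, B = 100, seed = 1)
  expect_true(is.finite(act3$z_a))

  # module with no scored gene: NA
  mods_na <- mods_nodes(c("none1", "none2", "none3", "none4", "none5"))
  act4 <- module_activity(mods_na, pv2, B = 50, seed = 1)
  expect_true(is.na(act4$s_a))
})

test_that("active-module selection requires positivity in every contrast", {
  act <- tibble::tibble(
    module = rep(c("A", "B", "C"), each = 3),
    contrast = rep(c("c1", "c2", "c3"), 3),
    s_a = c(2.1, 0.3, 5.0, 1.0, -0.2, 3.0, NA, 1, 1))
  expect_equal(select_active_modules(act), "A")
})
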