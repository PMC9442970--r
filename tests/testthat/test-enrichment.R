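mods_of <- function(...) {
  sets <- list(...)
  tibble::tibble(module = paste0("M", seq_along(sets)),
                 topo_type = "COM", nodes = sets,
                 n_nodes = lengths(sets))
}

test_that("hypergeometric p, log2 fold change and rank follow the definitions", {
  # background of 1000 annotated genes; term T1 covers 50, of which the
  # 10-gene module holds 5 -> log2((5/10)/(50/1000)) = log2(10) = 3.32
  bg <- sprintf("g%04d", 1:1000)
  module <- bg[1:10]
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = bg, term = "T0", name = "root process"),
    tibble::tibble(gene = c(module[1:5], bg[11:55]), term = "T1",
                   name = "specific process"))
  res <- enrich_modules(mods_of(module), ann, background = "custom",
                        background_genes = bg)
  row <- res[res$term == "T1", ]
  expect_equal(row$study_count, 5L)
  expect_equal(row$study_n, 10L)
  expect_equal(row$pop_count, 50L)
  expect_equal(row$pop_n, 1000L)
  expect_equal(row$log2_fc, log2(10), tolerance = 1e-12)
  expect_equal(row$rank, 1L)
  # raw p equals the exhaustive hypergeometric tail sum
  expect_equal(row$p_raw, sum(stats::dhyper(5:10, 50, 950, 10)),
               tolerance = 1e-12)
  # T0 covers everything: p = 1, never significant
  expect_false("T0" %in% res$term)
})

test_that("BH adjustment is monotone and applied within module", {
  bg <- sprintf("g%03d", 1:200)
  module <- bg[1:10]
  set.seed(8)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = bg, term = "T0", name = "all"),
    purrr::map_dfr(1:6, function(i) {
      tibble::tibble(gene = c(sample(module, 4), sample(bg[-(1:10)], 6)),
                     term = paste0("T", i), name = paste("proc", i))
    }))
  res <- enrich_modules(mods_of(module), ann, background = "custom",
                        background_genes = bg, alpha = 1 - 1e-12)
  expect_false(is.unsorted(res$p_adj))
  expect_false(is.unsorted(res$rank))
  # p_adj non-decreasing along ascending p_raw
  srt <- res[order(res$p_raw), ]
  expect_false(is.unsorted(srt$p_adj))
})

test_that("terms absent from the background are not tested and unannotated padding changes nothing", {
  bg <- sprintf("g%03d", 1:100)
  module <- bg[1:8]
  ann <- tibble::tibble(gene = c(module[1:4], bg[9:20]), term = "T1",
                        name = "thing")
  res <- enrich_modules(mods_of(module), ann, background = "custom",
                        background_genes = bg, alpha = 1 - 1e-12)
  # enlarge the background with unannotated, non-module genes
  res2 <- enrich_modules(mods_of(module), ann, background = "custom",
                         background_genes = c(bg, sprintf("x%03d", 1:500)),
                         alpha = 1 - 1e-12)
  expect_equal(res$p_raw, res2$p_raw)
  expect_equal(res$study_count, res2$study_count)
  expect_equal(res$study_n, res2$study_n)
  # a term annotated only outside the background is not tested
  ann3 <- dplyr::bind_rows(ann, tibble::tibble(gene = "zzz", term = "T9",
                                               name = "elsewhere"))
  res3 <- enrich_modules(mods_of(module), ann3, background = "custom",
                         background_genes = bg, alpha = 1 - 1e-12)
  expect_false("T9" %in% res3$term)
})

test_that("modules without annotated genes warn and yield no rows", {
  ann <- tibble::tibble(gene = "g1", term = "T1", name = "x")
  expect_warning(
    res <- enrich_modules(mods_of(c("u1", "u2", "u3", "u4", "u5")), ann,
                          background = "custom", background_genes = "g1"),
    "no annotated gene")
  expect_equal(nrow(res), 0L)
})

test_that("is_a propagation credits ancestors when an ontology is supplied", {
  bg <- sprintf("g%03d", 1:60)
  module <- bg[1:6]
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = bg, term = "T0", name = "all annotated"),
    tibble::tibble(gene = module[1:4], term = "child", name = "leaf"))
  onto <- tibble::tibble(term = "child", parent = "parent")
  res <- enrich_modules(mods_of(module), ann, background = "custom",
                        background_genes = bg, ontology = onto)
  expect_setequal(res$term, c("child", "parent"))
  expect_equal(res$study_count[res$term == "parent"], 4L)
  expect_equal(res$pop_count[res$term == "parent"], 4L)
})

test_that("keyword selection is case-insensitive over retained term names", {
  enr <- tibble::tibble(
    module = c("COM_1", "COM_2", "FFL_1"),
    term = c("GO:1", "GO:2", "GO:3"),
    name = c("cellular response to hypoxia", "ribosome biogenesis", NA),
    p_adj = c(0.01, 0.02, 0.03))
  expect_equal(select_modules_by_keyword(enr, "hypoxia"), "COM_1")
  expect_equal(select_modules_by_keyword(enr, "HYPOXIA"), "COM_1")
  expect_equal(select_modules_by_keyword(enr, "proteasome"), character())
  # falls back to the term id when no name is available
  expect_equal(select_modules_by_keyword(enr, "GO:3"), "FFL_1")
})

test_that("annotation readers parse flat tables and OBO stanzas", {
  d <- withr::local_tempdir()
  flat <- file.path(d, "ann.tsv")
  writeLines(c("g1\tGO:1\talpha", "g2\tGO:2\tbeta"), flat)
  ann <- read_annotations(flat)
  expect_equal(ann$gene, c("g1", "g2"))
  expect_equal(ann$name, c("alpha", "beta"))

  obo <- file.path(d, "mini.obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:2",
               "name: beta", "is_a: GO:1 ! alpha", "", "[Term]",
               "id: GO:1", "name: alpha", "", "[Typedef]", "id: part_of"),
             obo)
  onto <- read_obo(obo)
  expect_equal(onto$parents$term, "GO:2")
  expect_equal(onto$parents$parent, "GO:1")
  expect_setequal(onto$terms$term, c("GO:1", "GO:2"))
})
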