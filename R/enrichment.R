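# Per-module GO over-representation analysis.

#' Read a gene-term annotation table
#'
#' Accepts either a two-or-more-column TSV (`gene<TAB>term[<TAB>name]`) or a
#' GAF 2.x file (detected by the `!gaf-version` header or a `.gaf`
#' extension; columns 2, 5 and 10 are used).
#'
#' @param path Annotation file path.
#' @return A tibble `gene`, `term`, `name` (`name` may be `NA`).
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^!gaf", first) || grepl("\\.gaf$", path)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    tibble::tibble(gene = vapply(parts, `[`, "", 3L),
                   term = vapply(parts, `[`, "", 5L),
                   name = NA_character_)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "", fill = TRUE)
    tibble::tibble(gene = tab[[1L]], term = tab[[2L]],
                   name = if (ncol(tab) >= 3L) tab[[3L]] else NA_character_)
  }
}

#' Read is_a parent links from an OBO ontology file
#'
#' Minimal OBO reader: extracts term ids, names and `is_a` links from
#' `[Term]` stanzas.
#'
#' @param path OBO file path.
#' @return A list with `terms` (tibble `term`, `name`) and `parents`
#'   (tibble `term`, `parent`).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  term_id <- NA_character_
  ids <- character(); names_ <- character()
  child <- character(); parent <- character()
  in_term <- FALSE
  for (ln in lines) {
    if (ln == "[Term]") { in_term <- TRUE; term_id <- NA_character_; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id: ")) {
      term_id <- sub("^id: ", "", ln)
      ids <- c(ids, term_id); names_ <- c(names_, NA_character_)
    } else if (startsWith(ln, "name: ") && length(ids)) {
      names_[length(ids)] <- sub("^name: ", "", ln)
    } else if (startsWith(ln, "is_a: ") && !is.na(term_id)) {
      p <- sub("^is_a: ", "", ln)
      p <- sub(" !.*$", "", p)
      child <- c(child, term_id); parent <- c(parent, p)
    }
  }
  list(terms = tibble::tibble(term = ids, name = names_),
       parents = tibble::tibble(term = child, parent = parent))
}

# Propagate gene-term annotations to all is_a ancestors.
propagate_annotations <- function(annotations, parents) {
  parent_map <- split(parents$parent, parents$term)
  closure_cache <- new.env(parent = emptyenv())
  ancestors <- function(term) {
    hit <- closure_cache[[term]]
    if (!is.null(hit)) return(hit)
    direct <- parent_map[[term]]
    res <- if (is.null(direct)) character() else
      unique(c(direct, unlist(lapply(direct, ancestors))))
    closure_cache[[term]] <- res
    res
  }
  extra <- purrr::map_dfr(unique(annotations$term), function(t) {
    anc <- ancestors(t)
    if (!length(anc)) return(NULL)
    genes <- annotations$gene[annotations$term == t]
    tidyr::expand_grid(gene = genes, term = anc)
  })
  if (nrow(extra)) extra$name <- NA_character_
  dplyr::distinct(dplyr::bind_rows(annotations, extra),
                  .data$gene, .data$term, .keep_all = TRUE)
}

#' GO over-representation analysis per module
#'
#' One-sided hypergeometric test of each term with at least one study hit,
#' per module, against a configurable background: `"type"` (all genes in
#' modules of the same topological type), `"network"` (all network nodes),
#' or `"custom"` (a user-supplied gene vector). The annotated background
#' defines the population; Benjamini-Hochberg correction is applied across
#' the tested terms of each module (or globally with `global = TRUE`); rows
#' with adjusted p-value below `alpha` are retained and given a 1-based
#' rank by ascending adjusted p-value and a log2 fold change
#' `log2((k/n)/(K/N))`.
#'
#' @param modules A module tibble.
#' @param annotations Tibble `gene`, `term` and optional `name`, as from
#'   [read_annotations()].
#' @param background One of `"type"`, `"network"`, `"custom"`.
#' @param network Needed for `background = "network"`.
#' @param background_genes Needed for `background = "custom"`.
#' @param alpha Significance cut-off on the adjusted p-value (default 0.05).
#' @param keep Comparator applied to the adjusted p-value, `"below"`
#'   (standard; keep `p_adj < alpha`) or `"above"`.
#' @param ontology Optional parent-link tibble (`term`, `parent`) from
#'   [read_obo()]; annotations are propagated to is_a ancestors.
#' @param global Apply BH across all modules jointly instead of per module.
#' @param cores Workers for the per-module tests (forked; deterministic
#'   across core counts).
#' @return A tibble with columns `module`, `term`, `name`, `study_count`,
#'   `study_n`, `pop_count`, `pop_n`, `p_raw`, `p_adj`, `rank`, `log2_fc`.
#' @export
enrich_modules <- function(modules, annotations,
                           background = c("type", "network", "custom"),
                           network = NULL, background_genes = NULL,
                           alpha = 0.05, keep = c("below", "above"),
                           ontology = NULL, global = FALSE, cores = 1L) {
  background <- match.arg(background)
  keep <- match.arg(keep)
  annotations <- tibble::as_tibble(annotations)
  if (!is.null(ontology)) {
    annotations <- propagate_annotations(annotations, ontology)
  }
  term_names <- annotations[!is.na(annotations$name),
                            c("term", "name"), drop = FALSE]
  term_names <- term_names[!duplicated(term_names$term), , drop = FALSE]
  bg_for <- function(i) {
    switch(background,
           type = sort_c(unique(unlist(
             modules$nodes[modules$topo_type == modules$topo_type[i]]))),
           network = {
             if (is.null(network)) stop("background = 'network' needs `network`",
                                        call. = FALSE)
             network$nodes
           },
           custom = {
             if (is.null(background_genes)) stop("background = 'custom' needs `background_genes`",
                                                 call. = FALSE)
             unique(as.character(background_genes))
           })
  }
  test_module <- function(i) {
    bg <- bg_for(i)
    ann_bg <- annotations[annotations$gene %in% bg, , drop = FALSE]
    pop_genes <- unique(ann_bg$gene)
    study <- intersect(modules$nodes[[i]], pop_genes)
    if (!length(study)) {
      warning("module ", modules$module[i], " has no annotated gene in the background",
              call. = FALSE)
      return(NULL)
    }
    counts <- dplyr::count(ann_bg, .data$term, name = "pop_count")
    study_counts <- dplyr::count(ann_bg[ann_bg$gene %in% study, , drop = FALSE],
                                 .data$term, name = "study_count")
    tab <- dplyr::inner_join(study_counts, counts, by = "term")
    if (!nrow(tab)) return(NULL)
    n <- length(study); N <- length(pop_genes)
    p_raw <- stats::phyper(tab$study_count - 1L, tab$pop_count,
                           N - tab$pop_count, n, lower.tail = FALSE)
    tibble::tibble(module = modules$module[i], term = tab$term,
                   study_count = tab$study_count, study_n = n,
                   pop_count = tab$pop_count, pop_n = N, p_raw = p_raw)
  }
  res <- if (cores > 1L) {
    dplyr::bind_rows(parallel::mclapply(seq_len(nrow(modules)), test_module,
                                        mc.cores = cores))
  } else {
    dplyr::bind_rows(lapply(seq_len(nrow(modules)), test_module))
  }
  if (!nrow(res)) {
    return(tibble::tibble(module = character(), term = character(),
                          name = character(), study_count = integer(),
                          study_n = integer(), pop_count = integer(),
                          pop_n = integer(), p_raw = numeric(),
                          p_adj = numeric(), rank = integer(),
                          log2_fc = numeric()))
  }
  if (global) {
    res$p_adj <- stats::p.adjust(res$p_raw, method = "BH")
  } else {
    res <- dplyr::mutate(dplyr::group_by(res, .data$module),
                         p_adj = stats::p.adjust(.data$p_raw, method = "BH"))
    res <- dplyr::ungroup(res)
  }
  res <- if (keep == "below") res[res$p_adj < alpha, , drop = FALSE] else
    res[res$p_adj > alpha, , drop = FALSE]
  if (!nrow(res)) {
    res$name <- character(); res$rank <- integer(); res$log2_fc <- numeric()
    return(res[, c("module", "term", "name", "study_count", "study_n",
                   "pop_count", "pop_n", "p_raw", "p_adj", "rank", "log2_fc")])
  }
  res <- dplyr::arrange(res, .data$module, .data$p_adj, .data$p_raw, .data$term)
  res <- dplyr::mutate(dplyr::group_by(res, .data$module),
                       rank = dplyr::row_number())
  res <- dplyr::ungroup(res)
  res$log2_fc <- log2((res$study_count / res$study_n) /
                        (res$pop_count / res$pop_n))
  res$name <- term_names$name[match(res$term, term_names$term)]
  res[, c("module", "term", "name", "study_count", "study_n", "pop_count",
          "pop_n", "p_raw", "p_adj", "rank", "log2_fc")]
}

#' Select modules by an enrichment keyword
#'
#' Modules with at least one retained enrichment whose term name (or term
#' id, when no name is available) contains the keyword, case-insensitively.
#'
#' @param enrichment Result of [enrich_modules()].
#' @param keyword Search string.
#' @return Sorted character vector of module names.
#' @export
select_modules_by_keyword <- function(enrichment, keyword) {
  label <- ifelse(is.na(enrichment$name), enrichment$term, enrichment$name)
  hits <- stringr::str_detect(stringr::str_to_lower(label),
                              stringr::fixed(stringr::str_to_lower(keyword)))
  sort_c(unique(enrichment$module[hits]))
}

#' Write one enrichment TSV per module
#'
#' @param enrichment Result of [enrich_modules()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_enrichment <- function(enrichment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in unique(enrichment$module)) {
    utils::write.table(enrichment[enrichment$module == m, , drop = FALSE],
                       file.path(dir, paste0(m, "_enrichment.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
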