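# Contextualization of modules with expression data: co-expression (nPCC),
# differential correlation (ECD) and module activity scores, each embedded
# in a size-matched random-gene-set null.

# Accept a genes-x-samples matrix with rownames, or a tibble with a `gene`
# column followed by sample columns.
as_expression_matrix <- function(expr) {
  if (is.matrix(expr)) {
    stopifnot(!is.null(rownames(expr)))
    if (anyDuplicated(rownames(expr))) stop("duplicate gene rows", call. = FALSE)
    return(expr)
  }
  expr <- tibble::as_tibble(expr)
  stopifnot("gene" %in% names(expr))
  m <- as.matrix(expr[, setdiff(names(expr), "gene"), drop = FALSE])
  rownames(m) <- expr$gene
  if (anyDuplicated(rownames(m))) stop("duplicate gene rows", call. = FALSE)
  m
}

mean_pairwise_cor <- function(mat) {
  # rows = genes
  cm <- suppressWarnings(stats::cor(t(mat)))
  mean(cm[upper.tri(cm)], na.rm = TRUE)
}

# Null moments of the mean pairwise correlation of random size-k gene sets.
npcc_null_moments <- function(mat, k, B, seed) {
  set.seed(seed)
  vals <- vapply(seq_len(B), function(b) {
    idx <- sample.int(nrow(mat), k)
    mean_pairwise_cor(mat[idx, , drop = FALSE])
  }, 0)
  c(mu = mean(vals), sigma = stats::sd(vals))
}

# Fraction of a module's internal edges with expression for both endpoints;
# falls back to node coverage when no internal edges are recorded.
edge_coverage <- function(module_row, expressed) {
  ie <- module_row$internal_edges[[1L]]
  if (!is.null(ie) && nrow(ie)) {
    pairs <- unique(pair_key(ie$from, ie$to))
    parts <- strsplit(pairs, "\r", fixed = TRUE)
    mean(vapply(parts, function(p) all(p %in% expressed), TRUE))
  } else {
    mean(module_row$nodes[[1L]] %in% expressed)
  }
}

#' Module co-expression score (nPCC)
#'
#' Mean pairwise Pearson correlation over the module genes with expression
#' data, z-scored against `B` random gene sets of the same effective size
#' drawn from all genes with expression; `p = 1 - pnorm(z)`. Null moments
#' are cached per distinct effective size.
#'
#' @param modules A module tibble.
#' @param expr Expression data, genes x samples (matrix with rownames or
#'   tibble with a `gene` column).
#' @param B Null sample size (default 1000).
#' @param seed Integer seed.
#' @return A tibble `module`, `k` (genes with data), `npcc`, `mu_k`,
#'   `sigma_k`, `z`, `p`, `coverage`. Modules with fewer than two expressed
#'   genes get `NA` scores but a coverage value.
#' @export
module_npcc <- function(modules, expr, B = 1000L, seed = 1L) {
  mat <- as_expression_matrix(expr)
  if (ncol(mat) < 3L) stop("need at least 3 samples for correlation scores",
                           call. = FALSE)
  cache <- new.env(parent = emptyenv())
  purrr::map_dfr(seq_len(nrow(modules)), function(i) {
    genes <- intersect(modules$nodes[[i]], rownames(mat))
    cov <- edge_coverage(modules[i, ], rownames(mat))
    if (length(genes) < 2L) {
      return(tibble::tibble(module = modules$module[i], k = length(genes),
                            npcc = NA_real_, mu_k = NA_real_,
                            sigma_k = NA_real_, z = NA_real_, p = NA_real_,
                            coverage = cov))
    }
    val <- mean_pairwise_cor(mat[genes, , drop = FALSE])
    key <- as.character(length(genes))
    nm <- cache[[key]]
    if (is.null(nm)) {
      nm <- npcc_null_moments(mat, length(genes), B,
                              new_seed_stream(seed, length(genes)))
      cache[[key]] <- nm
    }
    z <- if (nm[["sigma"]] > 0) (val - nm[["mu"]]) / nm[["sigma"]] else 0
    tibble::tibble(module = modules$module[i], k = length(genes), npcc = val,
                   mu_k = nm[["mu"]], sigma_k = nm[["sigma"]], z = z,
                   p = 1 - stats::pnorm(z), coverage = cov)
  })
}

# Mean over gene pairs of cor(condition) - cor(control).
mean_pair_delta_cor <- function(mat_cond, mat_ctrl, pairs_idx) {
  d <- vapply(pairs_idx, function(ij) {
    suppressWarnings(
      stats::cor(mat_cond[ij[1L], ], mat_cond[ij[2L], ]) -
        stats::cor(mat_ctrl[ij[1L], ], mat_ctrl[ij[2L], ]))
  }, 0)
  mean(d, na.rm = TRUE)
}

#' Expression correlation differential (ECD)
#'
#' For each internal module edge with expression for both endpoints,
#' subtracts the Pearson correlation in the control samples from the
#' correlation in the condition samples and averages over the qualifying
#' edges. The null re-draws `B` random node sets of the same size and
#' applies the same averaging over all their gene pairs.
#'
#' @param modules A module tibble with an `internal_edges` list-column.
#' @param expr Expression data (see [module_npcc()]).
#' @param samples_condition,samples_control Column names of the two sample
#'   groups (each of size >= 2).
#' @param B Null sample size.
#' @param seed Integer seed.
#' @return A tibble `module`, `n_edges`, `ecd`, `mu_k`, `sigma_k`, `z`,
#'   `p`, `coverage`.
#' @export
module_ecd <- function(modules, expr, samples_condition, samples_control,
                       B = 1000L, seed = 1L) {
  mat <- as_expression_matrix(expr)
  stopifnot(all(samples_condition %in% colnames(mat)),
            all(samples_control %in% colnames(mat)),
            length(samples_condition) >= 2L, length(samples_control) >= 2L)
  mc <- mat[, samples_condition, drop = FALSE]
  mx <- mat[, samples_control, drop = FALSE]
  cache <- new.env(parent = emptyenv())
  purrr::map_dfr(seq_len(nrow(modules)), function(i) {
    ie <- modules$internal_edges[[i]]
    cov <- edge_coverage(modules[i, ], rownames(mat))
    keep <- if (!is.null(ie) && nrow(ie)) {
      pr <- unique(pair_key(ie$from, ie$to))
      parts <- strsplit(pr, "\r", fixed = TRUE)
      Filter(function(p) all(p %in% rownames(mat)), parts)
    } else list()
    if (!length(keep)) {
      return(tibble::tibble(module = modules$module[i], n_edges = 0L,
                            ecd = NA_real_, mu_k = NA_real_, sigma_k = NA_real_,
                            z = NA_real_, p = NA_real_, coverage = cov))
    }
    pairs_idx <- lapply(keep, function(p) match(p, rownames(mat)))
    val <- mean_pair_delta_cor(mc, mx, pairs_idx)
    k <- length(intersect(modules$nodes[[i]], rownames(mat)))
    key <- as.character(k)
    nm <- cache[[key]]
    if (is.null(nm)) {
      set.seed(new_seed_stream(seed, k))
      vals <- vapply(seq_len(B), function(b) {
        idx <- sample.int(nrow(mat), k)
        cmb <- utils::combn(idx, 2L, simplify = FALSE)
        mean_pair_delta_cor(mc, mx, cmb)
      }, 0)
      nm <- c(mu = mean(vals), sigma = stats::sd(vals))
      cache[[key]] <- nm
    }
    z <- if (nm[["sigma"]] > 0) (val - nm[["mu"]]) / nm[["sigma"]] else 0
    tibble::tibble(module = modules$module[i], n_edges = length(keep),
                   ecd = val, mu_k = nm[["mu"]], sigma_k = nm[["sigma"]],
                   z = z, p = 1 - stats::pnorm(z), coverage = cov)
  })
}

#' Module activity score
#'
#' Aggregates per-gene p-values for a contrast into a module activity
#' score: `z_i = qnorm(1 - p_i)` (p-values clamped to `[1e-16, 1 - 1e-16]`),
#' `z_a = sum(z_i)/sqrt(k)` over the `k` module genes with a p-value, and
#' `s_a = (z_a - mu_k)/sigma_k` with `mu_k`, `sigma_k` estimated from `B`
#' random size-`k` sets of genes with p-values. High `s_a` flags a module
#' as an active subnetwork in the contrast's condition. Background moments
#' are cached per (contrast, k).
#'
#' @param modules A module tibble.
#' @param pvalues Tibble `gene`, `contrast`, `p` (one row per gene and
#'   contrast; p-values in (0, 1]).
#' @param B Null sample size.
#' @param seed Integer seed.
#' @return A tibble `module`, `contrast`, `k`, `z_a`, `mu_k`, `sigma_k`,
#'   `s_a` (class `module_activity`). Modules with no scored gene in a
#'   contrast get `NA`.
#' @export
module_activity <- function(modules, pvalues, B = 1000L, seed = 1L) {
  pvalues <- tibble::as_tibble(pvalues)
  stopifnot(all(c("gene", "contrast", "p") %in% names(pvalues)))
  cache <- new.env(parent = emptyenv())
  res <- purrr::map_dfr(unique(pvalues$contrast), function(ct) {
    tab <- pvalues[pvalues$contrast == ct, , drop = FALSE]
    tab <- tab[!duplicated(tab$gene), , drop = FALSE]
    zs <- stats::setNames(stats::qnorm(1 - clamp_p(tab$p)), tab$gene)
    purrr::map_dfr(seq_len(nrow(modules)), function(i) {
      genes <- intersect(modules$nodes[[i]], names(zs))
      k <- length(genes)
      if (k == 0L) {
        return(tibble::tibble(module = modules$module[i], contrast = ct,
                              k = 0L, z_a = NA_real_, mu_k = NA_real_,
                              sigma_k = NA_real_, s_a = NA_real_))
      }
      z_a <- sum(zs[genes]) / sqrt(k)
      key <- paste(ct, k)
      nm <- cache[[key]]
      if (is.null(nm)) {
        set.seed(new_seed_stream(seed, k + 7919L * match(ct, unique(pvalues$contrast))))
        draws <- vapply(seq_len(B), function(b) {
          sum(zs[sample.int(length(zs), k)]) / sqrt(k)
        }, 0)
        nm <- c(mu = mean(draws), sigma = stats::sd(draws))
        cache[[key]] <- nm
      }
      s_a <- if (nm[["sigma"]] > 0) (z_a - nm[["mu"]]) / nm[["sigma"]] else 0
      tibble::tibble(module = modules$module[i], contrast = ct, k = k,
                     z_a = z_a, mu_k = nm[["mu"]], sigma_k = nm[["sigma"]],
                     s_a = s_a)
    })
  })
  class(res) <- c("module_activity", class(res))
  res
}

#' Select modules active in every contrast
#'
#' @param activity Result of [module_activity()].
#' @param threshold Activity threshold (default 0: positive `s_a` required
#'   in every contrast; modules with missing scores are excluded).
#' @return Sorted character vector of module names.
#' @export
select_active_modules <- function(activity, threshold = 0) {
  ok <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(activity), .data$module),
                         active = all(!is.na(.data$s_a)) &
                           all(.data$s_a > threshold),
                         .groups = "drop")
  sort_c(ok$module[ok$active])
}
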