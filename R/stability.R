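# Edge-resampling stability harness: rerun module detection on partial
# networks and score the recovery of the full-network modules.

#' Subsample the pooled edge set of a composite network
#'
#' Draws `floor(fraction * total)` edges uniformly without replacement from
#' the pooled edge multiset across layers (layer membership preserved).
#' Nodes isolated by the sampling are retained in the node set.
#'
#' @param network A `composite_network`.
#' @param fraction Fraction of edges to keep, in (0, 1).
#' @param seed Integer seed (same seed, same sample).
#' @return A `composite_network` on the sampled edges.
#' @export
subsample_edges <- function(network, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  m <- nrow(network$edges)
  keep <- sort(sample.int(m, floor(fraction * m)))
  composite_network(network$edges[keep, , drop = FALSE], network$layers,
                    nodes = network$nodes)
}

#' Restrict full-network modules to a sampled network
#'
#' Ground-truth construction for the stability analysis: each module keeps
#' only the internal edges present in the sampled network; nodes left with
#' no internal edge are dropped; emptied modules are removed. Restriction
#' never re-splits a module (splitting, if any, shows up on the re-clustered
#' side).
#'
#' @param modules Full-network module tibble (with `internal_edges`).
#' @param sampled_network The subsampled `composite_network`.
#' @return A module tibble of the restricted modules.
#' @export
restrict_modules <- function(modules, sampled_network) {
  key_sub <- paste(sampled_network$edges$from, sampled_network$edges$to,
                   sampled_network$edges$layer)
  rows <- purrr::map(seq_len(nrow(modules)), function(i) {
    ie <- modules$internal_edges[[i]]
    ie <- ie[paste(ie$from, ie$to, ie$layer) %in% key_sub, , drop = FALSE]
    nodes <- sort_c(unique(c(ie$from, ie$to)))
    if (!length(nodes)) return(NULL)
    tibble::tibble(module = modules$module[i], topo_type = modules$topo_type[i],
                   nodes = list(nodes), n_nodes = length(nodes),
                   hyperedges = modules$hyperedges[i],
                   internal_edges = list(ie))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("motif_modules", class(out))
  out
}

#' Jaccard index of two node sets
#'
#' @param a,b Character vectors.
#' @return `|a intersect b| / |a union b|`.
#' @export
jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# 2x2 contingency over the universe for two node sets.
binary_contingency <- function(a, b, universe) {
  ina <- universe %in% a
  inb <- universe %in% b
  matrix(c(sum(ina & inb), sum(ina & !inb),
           sum(!ina & inb), sum(!ina & !inb)), nrow = 2L)
}

#' Adjusted Rand index of two node sets over a node universe
#'
#' Both sets are turned into binary in/out membership labelings over
#' `universe` and compared with the standard ARI formula.
#'
#' @param a,b Character vectors (subsets of `universe`).
#' @param universe Character vector defining the labeling domain.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand <- function(a, b, universe) {
  tab <- binary_contingency(a, b, universe)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / denom
}

#' Adjusted mutual information of two node sets over a node universe
#'
#' Binary-membership AMI with the hypergeometric expected-MI correction and
#' max-entropy normalisation: `AMI = (MI - E[MI]) / (max(H(a), H(b)) -
#' E[MI])`.
#'
#' @inheritParams adjusted_rand
#' @return AMI (1 for identical labelings, ~0 for independent ones).
#' @export
adjusted_mutual_information <- function(a, b, universe) {
  tab <- binary_contingency(a, b, universe)
  n <- sum(tab)
  ai <- rowSums(tab); bj <- colSums(tab)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / n * log(n * nij / (ai[i] * bj[j]))
  }
  h <- function(x) {
    p <- x[x > 0] / n
    -sum(p * log(p))
  }
  ha <- h(ai); hb <- h(bj)
  emi <- 0
  for (i in 1:2) for (j in 1:2) {
    lo <- max(ai[i] + bj[j] - n, 0L)
    hi <- min(ai[i], bj[j])
    if (hi < 1L) next
    for (nij in max(lo, 1L):hi) {
      term <- nij / n * log(n * nij / (ai[i] * bj[j]))
      lp <- lchoose(bj[j], nij) + lchoose(n - bj[j], ai[i] - nij) -
        lchoose(n, ai[i])
      emi <- emi + term * exp(lp)
    }
  }
  denom <- max(ha, hb) - emi
  if (denom == 0) return(ifelse(mi == emi, 1, 0))
  (mi - emi) / denom
}

#' Best-match recovery scores between two module sets
#'
#' For every module of the test set, the maximum similarity against the
#' ground-truth modules, for each requested metric. JI compares node sets
#' directly; ARI and AMI compare binary membership labelings over the given
#' node universe.
#'
#' @param test_modules,truth_modules Module tibbles (both nonempty).
#' @param universe Node universe for ARI/AMI (default: union of all module
#'   nodes on both sides).
#' @param metrics Subset of `c("JI", "ARI", "AMI")`.
#' @return A tibble `module`, `metric`, `best_score`.
#' @export
best_match_scores <- function(test_modules, truth_modules,
                              universe = NULL,
                              metrics = c("JI", "ARI", "AMI")) {
  stopifnot(nrow(test_modules) > 0L, nrow(truth_modules) > 0L)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (is.null(universe)) {
    universe <- sort_c(unique(c(unlist(test_modules$nodes),
                                unlist(truth_modules$nodes))))
  }
  score_fun <- list(
    JI = function(a, b) jaccard_index(a, b),
    ARI = function(a, b) adjusted_rand(a, b, universe),
    AMI = function(a, b) adjusted_mutual_information(a, b, universe))
  purrr::map_dfr(seq_len(nrow(test_modules)), function(i) {
    a <- test_modules$nodes[[i]]
    purrr::map_dfr(metrics, function(m) {
      best <- max(vapply(truth_modules$nodes,
                         function(b) score_fun[[m]](a, b), 0))
      tibble::tibble(module = test_modules$module[i], metric = m,
                     best_score = best)
    })
  })
}

#' Edge-resampling stability analysis
#'
#' For each sampling fraction and repetition: subsample the pooled edges,
#' restrict the full-network modules to the sample (ground truth), rerun
#' module detection on the sampled network, and record per-module
#' best-match scores against the truth. Repetition `r` at any fraction uses
#' seed `seed + r`.
#'
#' @param network The full `composite_network`.
#' @param modules Full-network modules from [detect_modules()].
#' @param fractions Sampling fractions (default `seq(0.9, 0.1, by = -0.1)`).
#' @param reps Repetitions per fraction (default 10).
#' @param seed Base integer seed.
#' @param metrics Metrics to report (default JI, ARI, AMI).
#' @param ... Passed on to [detect_modules()] for the re-clustering runs.
#' @return A long tibble (class `stability_result`): `fraction`, `rep`,
#'   `metric`, `module`, `best_score`. Repetitions where re-clustering
#'   recovers no module at all contribute a single zero-score row; reps
#'   where no ground-truth module survives the subsample are skipped.
#' @export
stability_analysis <- function(network, modules,
                               fractions = seq(0.9, 0.1, by = -0.1),
                               reps = 10L, seed = 1L,
                               metrics = c("JI", "ARI", "AMI"), ...) {
  res <- purrr::map_dfr(fractions, function(f) {
    purrr::map_dfr(seq_len(reps), function(r) {
      sub <- subsample_edges(network, f, seed = new_seed_stream(seed, r))
      truth <- restrict_modules(modules, sub)
      test <- detect_modules(sub, ...)
      if (!nrow(truth)) return(NULL)
      if (!nrow(test)) {
        # nothing recovered: score the repetition as complete failure
        return(tibble::tibble(fraction = f, rep = r, metric = metrics,
                              module = NA_character_, best_score = 0))
      }
      scores <- best_match_scores(test, truth, universe = network$nodes,
                                  metrics = metrics)
      dplyr::mutate(scores, fraction = f, rep = r, .before = 1L)
    })
  })
  class(res) <- c("stability_result", class(res))
  res
}

#' Summarise a stability result
#'
#' @param x A `stability_result`.
#' @param ... Unused.
#' @return Mean best-match score per fraction, repetition and metric.
#' @exportS3Method generics::glance
glance.stability_result <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$fraction,
                                   .data$rep, .data$metric),
                   mean_best_score = mean(.data$best_score),
                   n_modules = dplyr::n(), .groups = "drop")
}
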