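# Superview: module-module connectivity against a sampling null, and
# regulator-module statistics.

#' Count layer edges shared between two node sets
#'
#' Counts the edges of one layer with one endpoint in `nodes_a` and the
#' other in `nodes_b`. Directions are pooled for directed layers; each edge
#' is counted once even when the two sets overlap.
#'
#' @param network A `composite_network`.
#' @param nodes_a,nodes_b Character vectors of node identifiers.
#' @param layer Layer letter.
#' @return Integer count.
#' @export
count_shared_edges <- function(network, nodes_a, nodes_b, layer) {
  e <- layer_edges(network, layer)
  fa <- e$from %in% nodes_a; ta <- e$to %in% nodes_a
  fb <- e$from %in% nodes_b; tb <- e$to %in% nodes_b
  sum((fa & tb) | (fb & ta))
}

# Sampling null for the shared-edge count between two random disjoint node
# sets of given sizes. Returns c(mu, sigma). Vectorised over the B draws.
superview_null <- function(network, layer, size_a, size_b, B = 1000L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- network$nodes
  disjoint <- size_a + size_b <= length(nodes)
  if (!disjoint) {
    # two disjoint sets of these sizes cannot be drawn from this network;
    # fall back to independent (possibly overlapping) draws
    warning("sizes ", size_a, " + ", size_b, " exceed the ", length(nodes),
            "-node network; null sets drawn independently, not disjointly",
            call. = FALSE)
  }
  e <- layer_edges(network, layer)
  if (!nrow(e)) return(c(mu = 0, sigma = 0))
  idx_from <- match(e$from, nodes)
  idx_to <- match(e$to, nodes)
  counts <- numeric(B)
  memb <- integer(length(nodes))
  for (b in seq_len(B)) {
    memb[] <- 0L
    if (disjoint) {
      pick <- sample.int(length(nodes), size_a + size_b)
      memb[pick[seq_len(size_a)]] <- 1L
      memb[pick[size_a + seq_len(size_b)]] <- 2L
    } else {
      memb[sample.int(length(nodes), size_a)] <- 1L
      pb <- sample.int(length(nodes), size_b)
      memb[pb] <- memb[pb] + 2L
    }
    mf <- memb[idx_from]; mt <- memb[idx_to]
    counts[b] <- sum((mf %in% c(1L, 3L) & mt >= 2L) |
                       (mt %in% c(1L, 3L) & mf >= 2L))
  }
  c(mu = mean(counts), sigma = stats::sd(counts))
}

#' z-score and right-tail p-value for an observed shared-edge count
#'
#' `z = (x - mu)/sigma`, `p = 1 - pnorm(z)`. An observed count of zero
#' forces `(z, p) = (0, 1)`. When the null is degenerate (`sigma = 0`) the
#' z-score is 0 if `x = mu` and is capped at `1e6` in absolute value
#' otherwise (a serialisable stand-in for infinity).
#'
#' @param x Observed count(s).
#' @param mu,sigma Null moments.
#' @return A tibble with columns `z` and `p`.
#' @export
superview_score <- function(x, mu, sigma) {
  z <- ifelse(sigma > 0, (x - mu) / sigma,
              ifelse(x == mu, 0, sign(x - mu) * 1e6))
  p <- 1 - stats::pnorm(z)
  z <- ifelse(x == 0, 0, z)
  p <- ifelse(x == 0, 1, p)
  tibble::tibble(z = z, p = p)
}

#' Module-module connectivity statistics
#'
#' For every unordered module pair and every layer, counts the shared edges
#' and embeds the count in a sampling null: `B` draws of two random disjoint
#' node sets with the same sizes, drawn uniformly from all network nodes.
#' Null moments are cached per (layer, size pair), so the cost scales with
#' the number of distinct module sizes rather than module pairs.
#'
#' @param modules A `motif_modules` tibble (or any tibble with `module` and
#'   `nodes` list-column).
#' @param network A `composite_network`.
#' @param layers Layers to score (default: all).
#' @param B Null sample size (default 1000).
#' @param seed Integer seed for the null draws.
#' @param cores Workers for the null-moment computations (forked; results
#'   are identical across core counts because every null draw has its own
#'   derived seed).
#' @return A tibble with columns `module_a`, `module_b`, `layer`, `x`,
#'   `mu`, `sigma`, `z`, `p` (one row per unordered pair per layer).
#' @export
superview <- function(modules, network, layers = network$layers$letter,
                      B = 1000L, seed = 1L, cores = 1L) {
  n <- nrow(modules)
  if (n < 2L) {
    return(tibble::tibble(module_a = character(), module_b = character(),
                          layer = character(), x = integer(), mu = numeric(),
                          sigma = numeric(), z = numeric(), p = numeric()))
  }
  sizes <- vapply(modules$nodes, length, 0L)
  pairs <- utils::combn(n, 2L)
  size_a <- pmin(sizes[pairs[1L, ]], sizes[pairs[2L, ]])
  size_b <- pmax(sizes[pairs[1L, ]], sizes[pairs[2L, ]])
  # distinct (layer, size pair) nulls, computed once (in parallel if asked)
  jobs <- unique(do.call(rbind, lapply(seq_along(layers), function(li)
    data.frame(li = li, sa = size_a, sb = size_b))))
  null_for <- function(row) {
    superview_null(network, layers[row$li], row$sa, row$sb, B = B,
                   seed = new_seed_stream(seed, row$li * 131071L +
                                            row$sa * 353L + row$sb))
  }
  job_list <- split(jobs, seq_len(nrow(jobs)))
  nulls <- if (cores > 1L) {
    parallel::mclapply(job_list, null_for, mc.cores = cores)
  } else {
    lapply(job_list, null_for)
  }
  names(nulls) <- paste(layers[jobs$li], jobs$sa, jobs$sb)
  out <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    layer <- layers[li]
    x <- integer(ncol(pairs))
    mu <- numeric(ncol(pairs)); sg <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      x[j] <- count_shared_edges(network, modules$nodes[[pairs[1L, j]]],
                                 modules$nodes[[pairs[2L, j]]], layer)
      nm <- nulls[[paste(layer, size_a[j], size_b[j])]]
      mu[j] <- nm[["mu"]]; sg[j] <- nm[["sigma"]]
    }
    sc <- superview_score(x, mu, sg)
    out[[li]] <- tibble::tibble(module_a = modules$module[pairs[1L, ]],
                                module_b = modules$module[pairs[2L, ]],
                                layer = layer, x = x, mu = mu, sigma = sg,
                                z = sc$z, p = sc$p)
  }
  dplyr::bind_rows(out)
}

#' Regulator-module connection strength
#'
#' For each regulator of a directed layer and each module it touches, the
#' strength is the fraction of module nodes that receive an edge from the
#' regulator in that layer.
#'
#' @param modules A module tibble.
#' @param network A `composite_network`.
#' @param layer A directed layer letter.
#' @return A tibble `regulator`, `module`, `layer`, `n_targeted`,
#'   `module_size`, `strength` (only nonzero rows).
#' @export
regulator_links <- function(modules, network, layer) {
  if (!layer_directed(network, layer)) {
    stop("layer ", layer, " is undirected", call. = FALSE)
  }
  e <- layer_edges(network, layer)
  purrr::map_dfr(seq_len(nrow(modules)), function(i) {
    nodes <- modules$nodes[[i]]
    if (!length(nodes)) stop("module ", modules$module[i], " is empty", call. = FALSE)
    hits <- e[e$to %in% nodes, , drop = FALSE]
    if (!nrow(hits)) return(NULL)
    counts <- table(hits$from)
    tibble::tibble(regulator = names(counts), module = modules$module[i],
                   layer = layer, n_targeted = as.integer(counts),
                   module_size = length(nodes),
                   strength = as.integer(counts) / length(nodes))
  })
}

#' Module regulator-specificity
#'
#' Fraction of all regulators of a directed layer that target a given
#' module with at least one edge. Regulators that are themselves module
#' members count when they target a co-member.
#'
#' @param modules A module tibble.
#' @param network A `composite_network`.
#' @param layer A directed layer letter.
#' @return A tibble `module`, `layer`, `n_regulators`, `total_regulators`,
#'   `specificity`.
#' @export
module_regulator_specificity <- function(modules, network, layer) {
  regs <- regulators(network, layer)
  if (!length(regs)) stop("layer ", layer, " has no regulators", call. = FALSE)
  e <- layer_edges(network, layer)
  purrr::map_dfr(seq_len(nrow(modules)), function(i) {
    nodes <- modules$nodes[[i]]
    n_reg <- length(unique(e$from[e$to %in% nodes]))
    tibble::tibble(module = modules$module[i], layer = layer,
                   n_regulators = n_reg, total_regulators = length(regs),
                   specificity = n_reg / length(regs))
  })
}

#' Regulator specificity over the module set
#'
#' Fraction of all modules that receive at least one edge from a given
#' regulator in a directed layer; distinguishes master regulators from
#' module-specific ones.
#'
#' @param modules A module tibble (nonempty).
#' @param network A `composite_network`.
#' @param layer A directed layer letter.
#' @return A tibble `regulator`, `layer`, `n_modules`, `total_modules`,
#'   `specificity`, one row per regulator of the layer.
#' @export
regulator_specificity <- function(modules, network, layer) {
  if (!nrow(modules)) stop("module list is empty", call. = FALSE)
  regs <- regulators(network, layer)
  e <- layer_edges(network, layer)
  hit <- matrix(FALSE, nrow = length(regs), ncol = nrow(modules),
                dimnames = list(regs, modules$module))
  for (i in seq_len(nrow(modules))) {
    targeting <- unique(e$from[e$to %in% modules$nodes[[i]]])
    hit[match(targeting, regs), i] <- TRUE
  }
  n_mod <- unname(rowSums(hit))
  tibble::tibble(regulator = regs, layer = layer,
                 n_modules = n_mod, total_modules = nrow(modules),
                 specificity = n_mod / nrow(modules))
}

#' Connectivity test for a selected module set
#'
#' Sums the pairwise shared-edge counts inside a selected set of modules
#' (per layer and in total) and compares each sum against `B` random module
#' sets of the same size drawn from the module universe of the superview
#' table. Reports the null mean and sd, the 95% confidence interval on the
#' mean (`mean +- 1.96 sd/sqrt(B)`), and the fold change of the observed
#' sum over the upper CI bound.
#'
#' @param sv A superview tibble from [superview()].
#' @param selected Character vector of at least two module names.
#' @param B Number of random sets (default 1000).
#' @param seed Integer seed.
#' @return A tibble with one row per layer plus a `Total` row: `layer`,
#'   `observed`, `random_mean`, `random_sd`, `ci_lower`, `ci_upper`,
#'   `fold_change`. A zero upper bound yields an infinite fold change.
#' @export
module_set_connectivity <- function(sv, selected, B = 1000L, seed = 1L) {
  universe <- sort_c(unique(c(sv$module_a, sv$module_b)))
  stopifnot(length(selected) >= 2L, all(selected %in% universe))
  set.seed(seed)
  layers <- unique(sv$layer)
  in_sel <- sv$module_a %in% selected & sv$module_b %in% selected
  draws <- replicate(B, sample(universe, length(selected)), simplify = FALSE)
  per_layer <- purrr::map_dfr(c(layers, "Total"), function(ly) {
    rows <- if (ly == "Total") sv else sv[sv$layer == ly, , drop = FALSE]
    obs <- sum(rows$x[if (ly == "Total") in_sel else
      rows$module_a %in% selected & rows$module_b %in% selected])
    null_sums <- vapply(draws, function(s) {
      sum(rows$x[rows$module_a %in% s & rows$module_b %in% s])
    }, 0)
    connectivity_row(ly, obs, mean(null_sums), stats::sd(null_sums), B)
  })
  per_layer
}

connectivity_row <- function(layer, observed, random_mean, random_sd, B) {
  half <- 1.96 * random_sd / sqrt(B)
  upper <- random_mean + half
  fc <- if (upper > 0) observed / upper else if (observed > 0) Inf else 0
  tibble::tibble(layer = layer, observed = observed,
                 random_mean = random_mean, random_sd = random_sd,
                 ci_lower = random_mean - half, ci_upper = upper,
                 fold_change = fc)
}

#' Confidence interval and fold change from summary statistics
#'
#' Reconstructs the connectivity-test arithmetic from printed summary
#' values: the 95% CI on the mean of `B` null sums and the observed/upper
#' fold change.
#'
#' @param observed Observed edge sum.
#' @param random_mean,random_sd Null moments.
#' @param B Null sample size.
#' @return A one-row tibble as in [module_set_connectivity()].
#' @export
connectivity_fold_change <- function(observed, random_mean, random_sd,
                                     B = 1000L) {
  connectivity_row("Total", observed, random_mean, random_sd, B)
}

#' Differential-expression enrichment of a module set
#'
#' One-sided hypergeometric test comparing the differential-expression rate
#' among the genes of a selected module set against the genes of all other
#' modules, plus the corresponding fold change of the two DE fractions.
#'
#' @param modules A module tibble.
#' @param selected Character vector of selected module names.
#' @param de_genes Nonempty character vector of differentially expressed
#'   gene identifiers.
#' @return A one-row tibble: `n_set`, `de_set`, `n_out`, `de_out`,
#'   `fold_change`, `p`. An outside DE fraction of zero yields an infinite
#'   fold change.
#' @export
de_gene_set_enrichment <- function(modules, selected, de_genes) {
  stopifnot(length(de_genes) > 0L)
  set_genes <- sort_c(unique(unlist(modules$nodes[modules$module %in% selected])))
  other_genes <- setdiff(
    sort_c(unique(unlist(modules$nodes[!modules$module %in% selected]))),
    set_genes)
  k <- sum(set_genes %in% de_genes)
  k_out <- sum(other_genes %in% de_genes)
  n <- length(set_genes); n_out <- length(other_genes)
  K <- k + k_out; N <- n + n_out
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  rate_in <- k / n
  rate_out <- if (n_out > 0) k_out / n_out else 0
  fc <- if (rate_out > 0) rate_in / rate_out else if (rate_in > 0) Inf else 1
  tibble::tibble(n_set = n, de_set = k, n_out = n_out, de_out = k_out,
                 fold_change = fc, p = p)
}
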