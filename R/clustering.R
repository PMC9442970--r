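# Hypergraph clustering of subgraph instances.
#
# Each subgraph instance becomes one hyperedge over its 2 or 3 nodes;
# clusters are extracted iteratively by maximising the edge-to-node ratio
# (total weight of hyperedges fully inside a node set divided by the set
# size), with node scores from a nonlinear power iteration.

#' Build the clustering hypergraph for a subgraph pool
#'
#' One hyperedge (weight 1) per instance; hypernodes are the nodes occurring
#' in at least one instance. The `ALL` pool takes every instance (including
#' two-node DD/DU instances); a type pool takes the instances of that
#' topological type only.
#'
#' @param instances Instance tibble from [enumerate_subgraphs()].
#' @param pool One of the topological types present or `"ALL"`.
#' @return A tibble with columns `id`, `nodes` (list of character vectors),
#'   `weight`, `code`, `topo_type`.
#' @export
build_hypergraph <- function(instances, pool = "ALL") {
  sel <- if (identical(pool, "ALL")) instances else
    instances[instances$topo_type == pool, , drop = FALSE]
  nodes <- purrr::pmap(list(sel$n1, sel$n2, sel$n3),
                       function(a, b, c) {
                         v <- c(a, b, c)
                         v[!is.na(v)]
                       })
  tibble::tibble(id = seq_len(nrow(sel)), nodes = nodes,
                 weight = rep(1, nrow(sel)),
                 code = sel$code, topo_type = sel$topo_type)
}

# Nonlinear power iteration on the hypergraph restricted to `edge_nodes`
# (list of integer node indices) with weights w; returns a score per node.
hyper_power_iteration <- function(edge_nodes, w, n_nodes, p = 1,
                                  max_iter = 1000L, tol = 1e-9) {
  x <- rep(1 / n_nodes, n_nodes)
  for (iter in seq_len(max_iter)) {
    xnew <- numeric(n_nodes)
    xp <- if (p == 1) x else x^p
    for (e in seq_along(edge_nodes)) {
      idx <- edge_nodes[[e]]
      # leave-one-out products computed directly (sizes 2 and 3) to avoid
      # 0/0 when peripheral scores underflow
      contrib <- if (length(idx) == 2L) {
        w[e] * xp[idx[c(2L, 1L)]]
      } else {
        w[e] * c(xp[idx[2L]] * xp[idx[3L]],
                 xp[idx[1L]] * xp[idx[3L]],
                 xp[idx[1L]] * xp[idx[2L]])
      }
      xnew[idx] <- xnew[idx] + contrib
    }
    s <- sum(xnew)
    if (s == 0) return(list(x = x, converged = FALSE))
    # 0.5 damping: same fixed points, suppresses the period-2 oscillation
    # that undamped multiplicative updates show on asymmetric hypergraphs
    xnew <- (xnew / s + x) / 2
    delta <- max(abs(xnew - x))
    x <- xnew
    if (delta < tol) return(list(x = x, converged = TRUE))
  }
  list(x = x, converged = FALSE)
}

#' Cluster a hypergraph by edge-to-node ratio maximisation
#'
#' Iterative extraction: (i) node scores from a nonlinear power iteration
#' (`x_i <- sum over hyperedges e containing i of w_e * prod_{j in e, j != i}
#' x_j^p`, renormalised until the change drops below `tol`); (ii) nodes are
#' sorted by descending score (ties broken lexicographically by identifier)
#' and the prefix maximising the edge-to-node ratio is selected; (iii) the
#' cluster and its internal hyperedges are removed and the process repeats
#' until no hyperedges remain. Nodes can recur in later clusters through
#' their surviving hyperedges.
#'
#' @param hypergraph Tibble from [build_hypergraph()].
#' @param p Nonnegative score exponent (default 1, the reference setting).
#' @param max_iter,tol Power-iteration controls.
#' @return A tibble with one row per extracted cluster: `cluster` (integer,
#'   extraction order), `nodes` (list; union of the assigned hyperedges'
#'   nodes), `hyperedges` (list of hyperedge ids), `ratio` (achieved
#'   edge-to-node ratio of the selected prefix).
#' @export
cluster_hypergraph <- function(hypergraph, p = 1, max_iter = 1000L, tol = 1e-9) {
  stopifnot(p >= 0, tol > 0)
  remaining <- hypergraph
  out <- list()
  k <- 0L
  while (nrow(remaining) > 0L) {
    node_ids <- sort_c(unique(unlist(remaining$nodes)))
    edge_nodes <- lapply(remaining$nodes, function(v) match(v, node_ids))
    pi <- hyper_power_iteration(edge_nodes, remaining$weight,
                                length(node_ids), p = p,
                                max_iter = max_iter, tol = tol)
    if (!pi$converged) {
      warning("power iteration did not converge after ", max_iter,
              " iterations; using last iterate", call. = FALSE)
    }
    # descending score, lexicographic tie-break (node_ids already sorted)
    ord <- order(-pi$x, method = "radix")
    rank_of <- integer(length(node_ids))
    rank_of[ord] <- seq_along(ord)
    last_rank <- vapply(edge_nodes, function(idx) max(rank_of[idx]), 0L)
    inside_w <- numeric(length(node_ids))
    agg <- tapply(remaining$weight, last_rank, sum)
    inside_w[as.integer(names(agg))] <- agg
    ratio <- cumsum(inside_w) / seq_along(node_ids)
    best_k <- which.max(ratio)
    # refine the best prefix to the exact maximum-ratio subset (parametric
    # min-cut); the spectral prefix is the warm start and usual answer
    best_set <- densest_subset(edge_nodes, remaining$weight,
                               length(node_ids),
                               start_set = which(rank_of <= best_k),
                               start_ratio = ratio[best_k])
    members <- vapply(edge_nodes, function(idx) all(idx %in% best_set), TRUE)
    k <- k + 1L
    out[[k]] <- tibble::tibble(
      cluster = k,
      nodes = list(sort_c(unique(unlist(remaining$nodes[members])))),
      hyperedges = list(remaining$id[members]),
      ratio = sum(remaining$weight[members]) / length(best_set))
    remaining <- remaining[!members, , drop = FALSE]
  }
  if (!length(out)) {
    return(tibble::tibble(cluster = integer(), nodes = list(),
                          hyperedges = list(), ratio = numeric()))
  }
  dplyr::bind_rows(out)
}

# Exact maximum edge-to-node-ratio subset via parametric min-cut
# (densest-subgraph flow construction extended to hyperedges): a ratio g is
# attainable iff max over S of (w(S) - g|S|) > 0, decided by a min-cut on
# the bipartite source->hyperedge->node->sink network. Binary search on g,
# warm-started from a known feasible set.
densest_subset <- function(edge_nodes, w, n_nodes, start_set, start_ratio) {
  m <- length(edge_nodes)
  total_w <- sum(w)
  # vertices: 1 = source, 2..(m+1) = hyperedges, (m+2)..(m+1+n) = nodes,
  # m+n+2 = sink
  src <- 1L; snk <- m + n_nodes + 2L
  e_from <- c(rep(src, m), unlist(lapply(seq_len(m), function(e)
    rep(e + 1L, length(edge_nodes[[e]])))))
  e_to <- c(seq_len(m) + 1L, unlist(edge_nodes) + m + 1L)
  node_arcs_from <- seq_len(n_nodes) + m + 1L
  big <- total_w + 1
  feasible_set <- function(g) {
    caps <- c(w, rep(big, length(e_to) - m), rep(g, n_nodes))
    gr <- igraph::graph_from_edgelist(
      cbind(c(e_from, node_arcs_from), c(e_to, rep(snk, n_nodes))),
      directed = TRUE)
    fl <- igraph::max_flow(gr, source = src, target = snk, capacity = caps)
    excess <- total_w - fl$value
    if (excess <= 1e-9) return(NULL)
    side <- as.integer(fl$partition1)
    sort(side[side > m + 1L & side < snk] - (m + 1L))
  }
  lo <- start_ratio
  best <- start_set
  hi <- total_w
  tol <- max(1e-9, 1 / (2 * n_nodes^2 * max(1, total_w)))
  # strictly better than lo?
  repeat {
    if (hi - lo <= tol) break
    mid <- (lo + hi) / 2
    s <- feasible_set(mid)
    if (is.null(s)) hi <- mid else { lo <- mid; best <- s }
  }
  best
}

# Induced typed edges of a node set.
induced_edges <- function(network, nodes) {
  e <- network$edges
  e[e$from %in% nodes & e$to %in% nodes, , drop = FALSE]
}

#' Filter clusters into named modules
#'
#' Keeps clusters with between `min_size` and `max_size` nodes, drops
#' clusters whose induced internal edges are more than `max_h_fraction`
#' homologous (layer `h_layer`; the boundary itself is kept, i.e. the rule
#' is a strict `>` comparison), and names survivors `<TYPE>_<index>` in
#' extraction order, 1-based.
#'
#' @param clusters Tibble from [cluster_hypergraph()].
#' @param network The `composite_network` providing the layer of each
#'   internal edge.
#' @param type Pool tag used in module names (a topological type or "ALL").
#' @param min_size,max_size Node-count bounds (defaults 5 and 50).
#' @param max_h_fraction Maximum tolerated fraction of homologous internal
#'   edges (default 0.9).
#' @param h_layer Letter of the homology layer (default `"H"`; ignored if
#'   the network has no such layer).
#' @return A module tibble: `module`, `topo_type`, `nodes` (list),
#'   `n_nodes`, `hyperedges` (list), `internal_edges` (list of edge
#'   tibbles).
#' @export
filter_modules <- function(clusters, network, type = "ALL",
                           min_size = 5L, max_size = 50L,
                           max_h_fraction = 0.9, h_layer = "H") {
  sizes <- vapply(clusters$nodes, length, 0L)
  keep <- sizes >= min_size & sizes <= max_size
  internal <- lapply(clusters$nodes, induced_edges, network = network)
  if (h_layer %in% network$layers$letter) {
    h_frac <- vapply(internal, function(e) {
      if (!nrow(e)) return(0)
      mean(e$layer == h_layer)
    }, 0)
    keep <- keep & !(h_frac > max_h_fraction)
  }
  kept <- clusters[keep, , drop = FALSE]
  internal <- internal[keep]
  tibble::tibble(
    module = if (nrow(kept)) paste0(type, "_", seq_len(nrow(kept))) else character(),
    topo_type = rep(type, nrow(kept)),
    nodes = kept$nodes,
    n_nodes = vapply(kept$nodes, length, 0L),
    hyperedges = kept$hyperedges,
    internal_edges = internal)
}

#' Detect topological modules in a composite network
#'
#' End-to-end module inference: enumerate subgraph instances (unless
#' provided), cluster each topological type's instances separately plus all
#' instances jointly (`ALL`), and filter the clusters into named modules.
#'
#' @param network A `composite_network`.
#' @param instances Optional precomputed instance tibble.
#' @param pools Pools to cluster; default: every three-node/2FB type present
#'   plus `"ALL"`.
#' @param p,max_iter,tol Passed to [cluster_hypergraph()].
#' @param min_size,max_size,max_h_fraction,h_layer Passed to
#'   [filter_modules()].
#' @return A module tibble (class `motif_modules`) combining all pools.
#' @export
detect_modules <- function(network, instances = NULL, pools = NULL,
                           p = 1, max_iter = 1000L, tol = 1e-9,
                           min_size = 5L, max_size = 50L,
                           max_h_fraction = 0.9, h_layer = "H") {
  if (is.null(instances)) instances <- enumerate_subgraphs(network)
  if (is.null(pools)) {
    pools <- c(sort_c(setdiff(unique(instances$topo_type), "DD")), "ALL")
  }
  mods <- purrr::map_dfr(pools, function(pool) {
    h <- build_hypergraph(instances, pool)
    if (!nrow(h)) return(NULL)
    cl <- cluster_hypergraph(h, p = p, max_iter = max_iter, tol = tol)
    filter_modules(cl, network, type = pool, min_size = min_size,
                   max_size = max_size, max_h_fraction = max_h_fraction,
                   h_layer = h_layer)
  })
  class(mods) <- c("motif_modules", class(mods))
  mods
}

#' Long module-membership table
#'
#' @param x A `motif_modules` tibble.
#' @param ... Unused.
#' @return A tibble with one row per (module, node) pair.
#' @exportS3Method generics::tidy
tidy.motif_modules <- function(x, ...) {
  tibble::tibble(module = rep(x$module, x$n_nodes),
                 topo_type = rep(x$topo_type, x$n_nodes),
                 node = unlist(x$nodes))
}

#' Module census
#'
#' @param x A `motif_modules` tibble.
#' @param ... Unused.
#' @return One row per pool: module count, node-count summary.
#' @exportS3Method generics::glance
glance.motif_modules <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$topo_type),
                   n_modules = dplyr::n(),
                   median_size = stats::median(.data$n_nodes),
                   min_size = min(.data$n_nodes),
                   max_size = max(.data$n_nodes),
                   .groups = "drop")
}

#' Write module membership and subgraph-assignment files
#'
#' `<path_prefix>_nodes.tsv` holds one `module<TAB>node` line per membership;
#' `<path_prefix>_subgraphs.tsv` holds `module<TAB>code<TAB>n1,n2,n3` lines
#' when an instance table is supplied.
#'
#' @param modules A `motif_modules` tibble.
#' @param path_prefix Output path prefix.
#' @param instances Optional instance tibble used for the assignment file
#'   (`hyperedges` ids index into the corresponding pool's hypergraph).
#' @return `path_prefix`, invisibly.
#' @export
write_modules <- function(modules, path_prefix, instances = NULL) {
  memb <- tidy.motif_modules(modules)[, c("module", "node")]
  utils::write.table(memb, paste0(path_prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(instances)) {
    rows <- purrr::map_dfr(seq_len(nrow(modules)), function(i) {
      h <- build_hypergraph(instances, modules$topo_type[i])
      sel <- h[h$id %in% modules$hyperedges[[i]], , drop = FALSE]
      tibble::tibble(module = modules$module[i], code = sel$code,
                     nodes = vapply(sel$nodes, paste, "", collapse = ","))
    })
    utils::write.table(rows, paste0(path_prefix, "_subgraphs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path_prefix)
}
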