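# Independent oracles and fixture builders used across the test suite.
# These deliberately avoid the package's own enumeration/clustering code
# paths: the subgraph oracle matches code patterns over explicit node
# triples, and the clustering oracle enumerates all node subsets.

toy_layers <- function(letters = c("R", "M", "P", "C"),
                       directed = c(TRUE, TRUE, FALSE, FALSE)) {
  layer_spec(letters, directed)
}

# Brute-force 3-node instance counts per canonical code: for each ordered
# triple of distinct nodes, check each code's three edge slots directly
# against the edge table; deduplicate matched edge sets.
brute_force_three_node <- function(network, codes) {
  e <- network$edges
  directed_letters <- network$layers$letter[network$layers$directed]
  lookup <- new.env(parent = emptyenv(), size = max(16L, 2L * nrow(e)))
  for (i in seq_len(nrow(e))) {
    lookup[[paste(e$from[i], e$to[i], e$layer[i])]] <- TRUE
  }
  has_edge <- function(u, v, letter, directed) {
    key <- if (directed) paste(u, v, letter) else
      paste(min(u, v), max(u, v), letter)
    isTRUE(lookup[[key]])
  }
  slot_pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  nodes <- network$nodes
  counts <- stats::setNames(integer(length(codes)), codes)
  sigs <- lapply(codes, function(cd) character())
  names(sigs) <- codes
  if (length(nodes) < 3L) return(counts)
  triples <- utils::combn(nodes, 3L, simplify = FALSE)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  for (cd in codes) {
    chars <- strsplit(cd, "")[[1L]]
    upper <- toupper(chars)
    for (tr in triples) {
      for (pm in perms) {
        ordered <- tr[pm]
        sig_edges <- character(3L)
        ok <- TRUE
        for (s in 1:3) {
          ij <- slot_pairs[[s]]
          u <- ordered[ij[1L]]; v <- ordered[ij[2L]]
          letter <- upper[s]
          if (letter %in% directed_letters) {
            if (chars[s] != upper[s]) { tmp <- u; u <- v; v <- tmp }
            if (!has_edge(u, v, letter, TRUE)) { ok <- FALSE; break }
            sig_edges[s] <- paste(u, v, letter, "d")
          } else {
            if (!has_edge(u, v, letter, FALSE)) { ok <- FALSE; break }
            sig_edges[s] <- paste(min(u, v), max(u, v), letter, "u")
          }
        }
        if (ok) {
          sig <- paste(sort(sig_edges), collapse = ";")
          if (!sig %in% sigs[[cd]]) sigs[[cd]] <- c(sigs[[cd]], sig)
        }
      }
    }
    counts[cd] <- length(sigs[[cd]])
  }
  counts
}

# Brute-force 2-node counts: DD = antiparallel directed edge pairs,
# DU = directed + undirected edge combinations per node pair.
brute_force_two_node <- function(network) {
  e <- network$edges
  directed_letters <- network$layers$letter[network$layers$directed]
  nodes <- network$nodes
  dd <- 0L; du <- 0L
  if (length(nodes) >= 2L) {
    for (pair in utils::combn(nodes, 2L, simplify = FALSE)) {
      u <- pair[1L]; v <- pair[2L]
      fwd <- e$layer[e$from == u & e$to == v & e$layer %in% directed_letters]
      rev <- e$layer[e$from == v & e$to == u & e$layer %in% directed_letters]
      und <- e$layer[((e$from == u & e$to == v) | (e$from == v & e$to == u)) &
                       !e$layer %in% directed_letters]
      dd <- dd + length(fwd) * length(rev)
      du <- du + (length(fwd) + length(rev)) * length(und)
    }
  }
  c(DD = dd, DU = du)
}

# Random composite network on <= `n_nodes` nodes with the given layers.
random_composite_network <- function(n_nodes, layers, density = 0.15) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  edges <- purrr::map_dfr(seq_len(nrow(layers)), function(i) {
    pairs <- utils::combn(nodes, 2L)
    keep <- stats::runif(ncol(pairs)) < density
    e <- tibble::tibble(from = pairs[1L, keep], to = pairs[2L, keep],
                        layer = layers$letter[i])
    if (layers$directed[i] && nrow(e)) {
      flip <- stats::runif(nrow(e)) < 0.5
      tmp <- e$from[flip]; e$from[flip] <- e$to[flip]; e$to[flip] <- tmp
      # occasionally add the antiparallel edge so DD pairs exist
      extra <- stats::runif(nrow(e)) < 0.2
      e <- dplyr::bind_rows(e, tibble::tibble(from = e$to[extra],
                                              to = e$from[extra],
                                              layer = layers$letter[i]))
    }
    e
  })
  composite_network(edges, layers, nodes = nodes)
}

# Exhaustive maximum edge-to-node ratio over all node subsets.
exhaustive_max_ratio <- function(hyperedge_sets, nodes) {
  best <- 0
  n <- length(nodes)
  for (m in seq_len(2^n - 1L)) {
    S <- nodes[as.logical(bitwAnd(m, 2^(seq_len(n) - 1L)))]
    w <- sum(vapply(hyperedge_sets, function(e) all(e %in% S), TRUE))
    best <- max(best, w / length(S))
  }
  best
}

make_hypergraph <- function(sets, weight = 1) {
  tibble::tibble(id = seq_along(sets), nodes = sets,
                 weight = rep_len(weight, length(sets)),
                 code = "X", topo_type = "COM")
}

truth_as_modules <- function(truth) {
  tb <- dplyr::summarise(dplyr::group_by(truth, module),
                         topo_type = dplyr::first(topo_type),
                         nodes = list(node), .groups = "drop")
  tb$n_nodes <- vapply(tb$nodes, length, 0L)
  tb
}
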