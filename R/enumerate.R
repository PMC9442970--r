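# Enumeration of composite-subgraph instances.
#
# Matching is non-induced: a node triple carrying extra edges still matches
# every code its edges contain, and one triple can contribute instances to
# several codes (one instance per distinct choice of one concrete edge per
# node pair, deduplicated by node permutation through canonicalisation).

# Map pair_key -> list of c(letter, dir) where dir is relative to the sorted
# node pair: 0 undirected, +1 from smaller to larger node, -1 reversed.
pair_edge_options <- function(network) {
  env <- new.env(parent = emptyenv(), size = max(16L, nrow(network$edges)))
  directed <- network$layers$letter[network$layers$directed]
  e <- network$edges
  is_dir <- e$layer %in% directed
  key <- pair_key(e$from, e$to)
  dir <- ifelse(!is_dir, 0L, ifelse(str_lt(e$from, e$to), 1L, -1L))
  for (i in seq_len(nrow(e))) {
    k <- key[i]
    env[[k]] <- c(env[[k]], list(c(e$layer[i], dir[i])))
  }
  env
}

#' Enumerate two- and three-node composite subgraph instances
#'
#' Lists every occurrence of the catalogue's three-node codes (triangles
#' with one typed edge per node pair) plus the special two-node subgraphs:
#' DD (a pair of antiparallel directed edges, any layers) and DU (a pair
#' carrying one directed and one undirected edge, topological type 2FB).
#' Each instance is reported once up to motif automorphism; per-code counts
#' are exact.
#'
#' @param network A `composite_network`.
#' @param codes Optional character vector of canonical three-node codes to
#'   restrict the search to (default: the full catalogue for the network's
#'   layers, see [network_codes()]). Codes must be canonical.
#' @param two_node Include the DD/DU two-node search (default `TRUE`).
#' @return A tibble of instances with columns `code`, `topo_type`, `n1`,
#'   `n2`, `n3` (`n3` is `NA` for two-node instances), in a stable sort
#'   order. Node columns hold the canonical slot ordering of each instance.
#' @export
enumerate_subgraphs <- function(network, codes = NULL, two_node = TRUE) {
  stopifnot(inherits(network, "composite_network"))
  catalogue <- network_codes(network)
  if (is.null(codes)) {
    codes <- catalogue$code
  } else if (!all(codes %in% catalogue$code)) {
    stop("non-canonical or unknown code(s): ",
         paste(setdiff(codes, catalogue$code), collapse = ", "), call. = FALSE)
  }
  type_of <- stats::setNames(catalogue$topo_type, catalogue$code)
  opts <- pair_edge_options(network)
  tri <- support_triangles(network)
  memo <- new.env(parent = emptyenv())
  res_code <- character()
  res_nodes <- list()
  if (nrow(tri)) {
    for (t in seq_len(nrow(tri))) {
      a <- tri$a[t]; b <- tri$b[t]; c_ <- tri$c[t]
      o1 <- opts[[pair_key(a, b)]]
      o2 <- opts[[pair_key(a, c_)]]
      o3 <- opts[[pair_key(b, c_)]]
      for (e1 in o1) for (e2 in o2) for (e3 in o3) {
        key <- paste(e1[1L], e1[2L], e2[1L], e2[2L], e3[1L], e3[2L], sep = "|")
        hit <- memo[[key]]
        if (is.null(hit)) {
          hit <- canonical_motif(c(e1[1L], e2[1L], e3[1L]),
                                 as.integer(c(e1[2L], e2[2L], e3[2L])))
          memo[[key]] <- hit
        }
        if (!(hit$code %in% codes)) next
        old_nodes <- c(a, b, c_)
        new_nodes <- character(3L)
        new_nodes[hit$perm] <- old_nodes
        res_code <- c(res_code, hit$code)
        res_nodes <- c(res_nodes, list(new_nodes))
      }
    }
  }
  three <- if (length(res_code)) {
    m <- do.call(rbind, res_nodes)
    tibble::tibble(code = res_code, topo_type = unname(type_of[res_code]),
                   n1 = m[, 1L], n2 = m[, 2L], n3 = m[, 3L])
  } else {
    tibble::tibble(code = character(), topo_type = character(),
                   n1 = character(), n2 = character(), n3 = character())
  }
  out <- if (two_node) {
    dplyr::bind_rows(three, enumerate_two_node(network, opts))
  } else three
  dplyr::arrange(out, .data$code, .data$n1, .data$n2, .data$n3)
}

# Triangles of the layer-union support graph, as sorted node triples.
support_triangles <- function(network) {
  e <- network$edges
  if (!nrow(e)) return(tibble::tibble(a = character(), b = character(), c = character()))
  swap <- str_lt(e$to, e$from)
  u <- ifelse(swap, e$to, e$from)
  v <- ifelse(swap, e$from, e$to)
  pairs <- unique(paste(u, v, sep = "\r"))
  parts <- strsplit(pairs, "\r", fixed = TRUE)
  pu <- vapply(parts, `[`, "", 1L)
  pv <- vapply(parts, `[`, "", 2L)
  g <- igraph::graph_from_edgelist(cbind(pu, pv), directed = FALSE)
  tr <- igraph::triangles(g)
  if (!length(tr)) return(tibble::tibble(a = character(), b = character(), c = character()))
  nm <- igraph::V(g)$name[tr]
  m <- matrix(nm, ncol = 3L, byrow = TRUE)
  m <- t(apply(m, 1L, sort, method = "radix"))
  tibble::tibble(a = m[, 1L], b = m[, 2L], c = m[, 3L])
}

# Two-node instances: DD (antiparallel directed pair) and DU (directed +
# undirected). Each qualifying combination of two concrete edges is one
# instance.
enumerate_two_node <- function(network, opts = pair_edge_options(network)) {
  keys <- ls(opts)
  code <- character(); type <- character(); n1 <- character(); n2 <- character()
  for (k in keys) {
    entries <- opts[[k]]
    if (length(entries) < 2L) next
    nodes <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    letters <- vapply(entries, `[`, "", 1L)
    dirs <- as.integer(vapply(entries, `[`, "", 2L))
    fwd <- which(dirs == 1L)
    rev <- which(dirs == -1L)
    und <- which(dirs == 0L)
    for (i in fwd) for (j in rev) {
      cand1 <- paste0(letters[i], tolower(letters[j]))
      cand2 <- paste0(letters[j], tolower(letters[i]))
      code <- c(code, sort(c(cand1, cand2), method = "radix")[1L])
      type <- c(type, "DD")
      n1 <- c(n1, nodes[1L]); n2 <- c(n2, nodes[2L])
    }
    for (i in c(fwd, rev)) for (j in und) {
      lc <- if (dirs[i] == 1L) letters[i] else tolower(letters[i])
      code <- c(code, paste0(lc, letters[j])); type <- c(type, "2FB")
      n1 <- c(n1, nodes[1L]); n2 <- c(n2, nodes[2L])
    }
  }
  tibble::tibble(code = code, topo_type = type, n1 = n1, n2 = n2,
                 n3 = NA_character_)
}

#' Write an instance table to a flat file
#'
#' One line per instance, `code<TAB>n1<TAB>n2<TAB>n3` (third node field
#' empty for two-node instances), in the instance table's stable sort order
#' so diffs between runs are reproducible.
#'
#' @param instances Instance tibble from [enumerate_subgraphs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instances <- function(instances, path) {
  out <- instances[, c("code", "n1", "n2", "n3")]
  out$n3[is.na(out$n3)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
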