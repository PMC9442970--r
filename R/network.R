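#' Declare the layers of a composite network
#'
#' A composite (multi-layer) network carries edges of several interaction
#' types, each identified by a single uppercase letter and declared either
#' directed (e.g. TF-target, miRNA-mRNA) or undirected (e.g. protein-protein,
#' co-functional, homology). `layer_spec()` builds the layer table consumed by
#' [read_composite_network()] and [composite_network()].
#'
#' @param letter Character vector of single uppercase letters, unique.
#' @param directed Logical vector, recycled to the length of `letter`.
#' @param path Optional character vector of edge-list file paths
#'   (tab-separated `source<TAB>target` lines).
#' @return A tibble with columns `letter`, `directed`, `path`.
#' @examples
#' layer_spec(c("R", "P"), directed = c(TRUE, FALSE))
#' @export
layer_spec <- function(letter, directed, path = NA_character_) {
  spec <- tibble::tibble(letter = as.character(letter),
                         directed = vctrs_recycle(as.logical(directed), length(letter)),
                         path = vctrs_recycle(as.character(path), length(letter)))
  validate_layers(spec)
  spec
}

vctrs_recycle <- function(x, n) {
  if (length(x) == n) x else rep_len(x, n)
}

validate_layers <- function(layers) {
  if (nrow(layers) < 1L) stop("at least one layer is required", call. = FALSE)
  if (!all(grepl("^[A-Z]$", layers$letter))) {
    stop("layer letters must be single uppercase characters", call. = FALSE)
  }
  if (anyDuplicated(layers$letter)) {
    stop("layer letters must be unique", call. = FALSE)
  }
  invisible(layers)
}

#' Build a composite network from an in-memory edge table
#'
#' Canonicalises the edge table: self-loops are dropped (with a message
#' reporting the count), undirected edges are stored with the
#' lexicographically smaller node first so that `A-B` and `B-A` collapse,
#' and duplicate edges within a layer are merged. A node pair may carry
#' edges in several layers; layers are never merged.
#'
#' @param edges A data frame with columns `from`, `to`, `layer`.
#' @param layers A layer table from [layer_spec()].
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node identifiers to retain in the node set.
#' @return A `composite_network` object: a list with `edges` (canonical
#'   tibble), `layers`, and `nodes` (sorted union of endpoints).
#' @seealso [read_composite_network()], [regulators()]
#' @export
composite_network <- function(edges, layers, nodes = NULL) {
  validate_layers(layers)
  edges <- tibble::as_tibble(edges)[, c("from", "to", "layer")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$layer <- as.character(edges$layer)
  unknown <- setdiff(unique(edges$layer), layers$letter)
  if (length(unknown)) {
    stop("edges reference undeclared layer(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n_loops <- sum(edges$from == edges$to)
  if (n_loops > 0L) {
    message("dropped ", n_loops, " self-loop(s)")
    edges <- edges[edges$from != edges$to, , drop = FALSE]
  }
  undirected <- layers$letter[!layers$directed]
  flip <- edges$layer %in% undirected & str_lt(edges$to, edges$from)
  if (any(flip)) {
    tmp <- edges$from[flip]
    edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
  }
  edges <- dplyr::distinct(edges)
  edges <- dplyr::arrange(edges, .data$layer, .data$from, .data$to)
  all_nodes <- sort_c(unique(c(edges$from, edges$to, as.character(nodes %||% character()))))
  structure(list(edges = edges, layers = layers[, c("letter", "directed")],
                 nodes = all_nodes),
            class = "composite_network")
}

#' Read a composite network from per-layer edge-list files
#'
#' Each layer file is delimited text with at least two columns (source,
#' target); extra columns are ignored. Alternatively a single composite file
#' with three columns `source<TAB>target<TAB>letter` may be given via
#' `composite_file`, with `layers` supplying the directedness of each letter.
#' Empty files yield an empty layer with a warning.
#'
#' @param layers A layer table from [layer_spec()]; the `path` column names
#'   each layer's edge-list file unless `composite_file` is used.
#' @param composite_file Optional path to a three-column composite edge list.
#' @inherit composite_network return
#' @export
read_composite_network <- function(layers, composite_file = NULL) {
  validate_layers(layers)
  if (!is.null(composite_file)) {
    tab <- utils::read.table(composite_file, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "")
    if (ncol(tab) < 3L) stop("composite file needs 3 columns: source, target, letter",
                             call. = FALSE)
    edges <- tibble::tibble(from = tab[[1]], to = tab[[2]], layer = tab[[3]])
    return(composite_network(edges, layers))
  }
  parts <- lapply(seq_len(nrow(layers)), function(i) {
    path <- layers$path[i]
    if (is.na(path)) stop("layer ", layers$letter[i], " has no path", call. = FALSE)
    if (file.size(path) == 0L) {
      warning("layer ", layers$letter[i], " file is empty", call. = FALSE)
      return(tibble::tibble(from = character(), to = character(),
                            layer = character()))
    }
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "")
    tibble::tibble(from = tab[[1]], to = tab[[2]], layer = layers$letter[i])
  })
  composite_network(dplyr::bind_rows(parts), layers)
}

#' Write the canonical composite edge list
#'
#' @param network A `composite_network`.
#' @param path Output file; written as `source<TAB>target<TAB>letter` with no
#'   header, in canonical order, so a reload reproduces the network exactly.
#' @return `path`, invisibly.
#' @export
write_composite_network <- function(network, path) {
  stopifnot(inherits(network, "composite_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

layer_edges <- function(network, letter) {
  network$edges[network$edges$layer == letter, , drop = FALSE]
}

layer_directed <- function(network, letter) {
  i <- match(letter, network$layers$letter)
  if (is.na(i)) stop("unknown layer: ", letter, call. = FALSE)
  network$layers$directed[i]
}

#' Regulators of a directed layer
#'
#' The regulators of a directed layer are the nodes with at least one
#' outgoing edge in that layer (TFs in a TF-target layer, miRNAs in a
#' miRNA-mRNA layer).
#'
#' @param network A `composite_network`.
#' @param layer Single layer letter; must be a directed layer.
#' @return Sorted character vector of regulator node identifiers.
#' @export
regulators <- function(network, layer) {
  stopifnot(inherits(network, "composite_network"))
  if (!layer_directed(network, layer)) {
    stop("layer ", layer, " is undirected; regulators are defined for directed layers",
         call. = FALSE)
  }
  sort_c(unique(layer_edges(network, layer)$from))
}

#' @export
print.composite_network <- function(x, ...) {
  cat("Composite network: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges in ", nrow(x$layers), " layer(s)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Per-layer summary of a composite network
#'
#' One row per layer: letter, directedness, node and edge counts, and for
#' directed layers the number of regulators (out-nodes) and targets
#' (in-nodes).
#'
#' @param x A `composite_network`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::glance
glance.composite_network <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$layers)), function(i) {
    letter <- x$layers$letter[i]
    e <- layer_edges(x, letter)
    tibble::tibble(
      layer = letter,
      directed = x$layers$directed[i],
      n_nodes = length(unique(c(e$from, e$to))),
      n_edges = nrow(e),
      n_regulators = if (x$layers$directed[i]) length(unique(e$from)) else NA_integer_,
      n_targets = if (x$layers$directed[i]) length(unique(e$to)) else NA_integer_)
  })
}

#' Edge table of a composite network
#'
#' @param x A `composite_network`.
#' @param ... Unused.
#' @return The canonical edge tibble (`from`, `to`, `layer`, `directed`).
#' @exportS3Method generics::tidy
tidy.composite_network <- function(x, ...) {
  dplyr::mutate(x$edges,
                directed = x$layers$directed[match(.data$layer, x$layers$letter)])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
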