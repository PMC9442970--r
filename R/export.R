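# Cytoscape export: nested-network (NNF) module files, node attributes
# (NOA) and a vizmap style sheet.

#' Write modules in nested-network format (NNF)
#'
#' One line per internal module edge,
#' `module<TAB>source<TAB>layer-letter<TAB>target`; module nodes without a
#' surviving internal edge are emitted as single-member lines
#' (`module<TAB>node`). Output ordering is deterministic, so re-exporting a
#' reloaded file is byte-identical.
#'
#' @param modules A nonempty module tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nnf <- function(modules, path) {
  stopifnot(nrow(modules) > 0L)
  lines <- unlist(lapply(seq_len(nrow(modules)), function(i) {
    ie <- modules$internal_edges[[i]]
    ie <- ie[order(ie$layer, ie$from, ie$to, method = "radix"), , drop = FALSE]
    edge_lines <- sprintf("%s\t%s\t%s\t%s", modules$module[i], ie$from,
                          ie$layer, ie$to)
    isolated <- setdiff(modules$nodes[[i]], unique(c(ie$from, ie$to)))
    c(edge_lines, sprintf("%s\t%s", modules$module[i], sort_c(isolated)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read an NNF module file written by [write_nnf()]
#'
#' @param path NNF file path.
#' @return A tibble `module`, `from`, `layer`, `to` (single-member lines
#'   have `NA` layer/to).
#' @export
read_nnf <- function(path) {
  parts <- strsplit(readLines(path), "\t", fixed = TRUE)
  purrr::map_dfr(parts, function(p) {
    if (length(p) == 4L) {
      tibble::tibble(module = p[1L], from = p[2L], layer = p[3L], to = p[4L])
    } else {
      tibble::tibble(module = p[1L], from = p[2L], layer = NA_character_,
                     to = NA_character_)
    }
  })
}

#' Node category annotations for export
#'
#' Categories are inferred from the regulator layers: nodes with outgoing
#' miRNA-layer edges become `miRNA`, remaining nodes with outgoing TF-layer
#' edges become `TF`, everything else is `gene`.
#'
#' @param modules A module tibble.
#' @param network A `composite_network`.
#' @param tf_layer,mirna_layer Letters of the TF-target and miRNA-mRNA
#'   layers (skipped when absent from the network).
#' @param descriptions Optional tibble `node`, `name`, `description`.
#' @return A tibble `node`, `category`, `name`, `description`.
#' @export
node_annotations <- function(modules, network, tf_layer = "R",
                             mirna_layer = "M", descriptions = NULL) {
  nodes <- sort_c(unique(unlist(modules$nodes)))
  category <- rep("gene", length(nodes))
  if (tf_layer %in% network$layers$letter && layer_directed(network, tf_layer)) {
    category[nodes %in% regulators(network, tf_layer)] <- "TF"
  }
  if (mirna_layer %in% network$layers$letter &&
      layer_directed(network, mirna_layer)) {
    category[nodes %in% regulators(network, mirna_layer)] <- "miRNA"
  }
  out <- tibble::tibble(node = nodes, category = category,
                        name = nodes, description = NA_character_)
  if (!is.null(descriptions)) {
    descriptions <- tibble::as_tibble(descriptions)
    idx <- match(out$node, descriptions$node)
    if ("name" %in% names(descriptions)) {
      out$name <- dplyr::coalesce(descriptions$name[idx], out$name)
    }
    if ("description" %in% names(descriptions)) {
      out$description <- descriptions$description[idx]
    }
  }
  out
}

#' Write the node-attribute (NOA) file
#'
#' @param annotations Tibble from [node_annotations()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_noa <- function(annotations, path) {
  out <- annotations
  out$description[is.na(out$description)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Fixed, documented palette; overridable via the `colors` argument.
default_layer_colors <- function(letters) {
  palette <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
               "#A65628", "#F781BF", "#999999")
  stats::setNames(rep_len(palette, length(letters)), letters)
}

#' Write a Cytoscape vizmap style sheet
#'
#' Maps each layer letter to an edge colour (and arrow shape for directed
#' layers) and node categories to node shapes; the XML is well-formed and
#' importable as a Cytoscape style.
#'
#' @param layers Layer table (`letter`, `directed`).
#' @param path Output file.
#' @param colors Optional named vector of hex colours per layer letter.
#' @return `path`, invisibly.
#' @export
write_style_xml <- function(layers, path, colors = NULL) {
  colors <- colors %||% default_layer_colors(layers$letter)
  doc <- xml2::xml_new_root("vizmap",
                            documentVersion = "3.0",
                            id = "composite-modules")
  style <- xml2::xml_add_child(doc, "visualStyle", name = "composite-modules")
  edge <- xml2::xml_add_child(style, "edge")
  col_map <- xml2::xml_add_child(
    edge, "visualProperty", name = "EDGE_STROKE_UNSELECTED_PAINT",
    default = "#000000")
  dmap <- xml2::xml_add_child(col_map, "discreteMapping",
                              attributeName = "interaction",
                              attributeType = "string")
  for (i in seq_len(nrow(layers))) {
    xml2::xml_add_child(dmap, "discreteMappingEntry",
                        attributeValue = layers$letter[i],
                        value = unname(colors[layers$letter[i]]))
  }
  arrow <- xml2::xml_add_child(edge, "visualProperty",
                               name = "EDGE_TARGET_ARROW_SHAPE",
                               default = "NONE")
  amap <- xml2::xml_add_child(arrow, "discreteMapping",
                              attributeName = "interaction",
                              attributeType = "string")
  for (i in seq_len(nrow(layers))) {
    xml2::xml_add_child(amap, "discreteMappingEntry",
                        attributeValue = layers$letter[i],
                        value = if (layers$directed[i]) "DELTA" else "NONE")
  }
  node <- xml2::xml_add_child(style, "node")
  shape <- xml2::xml_add_child(node, "visualProperty", name = "NODE_SHAPE",
                               default = "ELLIPSE")
  smap <- xml2::xml_add_child(shape, "discreteMapping",
                              attributeName = "category",
                              attributeType = "string")
  for (entry in list(c("TF", "DIAMOND"), c("miRNA", "TRIANGLE"),
                     c("gene", "ELLIPSE"))) {
    xml2::xml_add_child(smap, "discreteMappingEntry",
                        attributeValue = entry[1L], value = entry[2L])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
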