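# Synthetic multi-layer networks with planted topological modules, plus
# module-correlated expression data. The generator exercises every pipeline
# stage without external downloads; it is a validation device, not a
# biological model.

#' Simulate a composite network with planted modules
#'
#' Plants dense node groups whose internal edges instantiate subgraphs of a
#' declared topological type, then sprinkles uniform background edges per
#' layer:
#' * `COM` modules draw an undirected (P-layer) edge for each node pair at
#'   the intra-module density, yielding complex triangles;
#' * `COR` modules pick one regulator wired to the targets by directed
#'   (R-layer) edges, with undirected (P) edges between target pairs, both
#'   at the intra density;
#' * `FFL` modules order their nodes and draw directed (R) edges from
#'   earlier to later nodes at the intra density, so closed ordered triples
#'   form feed-forward loops.
#'
#' @param n_modules Named integer vector of planted modules per type, e.g.
#'   `c(COM = 4, COR = 3, FFL = 3)` (the default plants 10 modules).
#' @param size_range Inclusive node-count range per module (default 6-12,
#'   within the 5-50 module filter).
#' @param intra_density Probability of each candidate intra-module edge
#'   (default 0.8).
#' @param background_density Per-pair probability of a background edge in
#'   each layer (default 0.02).
#' @param n_background_nodes Extra nodes outside any module (default 20).
#' @param layers Layer table (default: directed R and M, undirected P, C,
#'   H).
#' @param seed Integer seed.
#' @return A list with `network` (`composite_network`) and `truth` (tibble
#'   `module`, `topo_type`, `node`).
#' @export
simulate_composite_network <- function(n_modules = c(COM = 4L, COR = 3L, FFL = 3L),
                                       size_range = c(6L, 12L),
                                       intra_density = 0.8,
                                       background_density = 0.02,
                                       n_background_nodes = 20L,
                                       layers = layer_spec(
                                         c("R", "M", "H", "P", "C"),
                                         directed = c(TRUE, TRUE, FALSE,
                                                      FALSE, FALSE)),
                                       seed = 1L) {
  stopifnot(all(names(n_modules) %in% c("COM", "COR", "FFL")),
            intra_density >= 0, intra_density <= 1,
            background_density >= 0, background_density <= 1,
            size_range[1L] >= 3L, size_range[2L] >= size_range[1L])
  set.seed(seed)
  total_mod <- sum(n_modules)
  size_opts <- seq.int(size_range[1L], size_range[2L])
  sizes <- size_opts[sample.int(length(size_opts), total_mod, replace = TRUE)]
  n_nodes <- sum(sizes) + n_background_nodes
  nodes <- sprintf("g%04d", seq_len(n_nodes))
  types <- rep(names(n_modules), n_modules)
  edges <- list()
  truth <- list()
  offset <- 0L
  for (m in seq_len(total_mod)) {
    members <- nodes[offset + seq_len(sizes[m])]
    offset <- offset + sizes[m]
    truth[[m]] <- tibble::tibble(module = paste0("truth_", m),
                                 topo_type = types[m], node = members)
    edges[[length(edges) + 1L]] <- plant_module_edges(members, types[m],
                                                      intra_density)
  }
  bg <- simulate_background_edges(nodes, layers, background_density)
  net <- composite_network(dplyr::bind_rows(c(edges, list(bg))), layers,
                           nodes = nodes)
  list(network = net, truth = dplyr::bind_rows(truth))
}

plant_module_edges <- function(members, type, density) {
  k <- length(members)
  if (type == "COM") {
    pairs <- utils::combn(members, 2L)
    keep <- stats::runif(ncol(pairs)) < density
    return(tibble::tibble(from = pairs[1L, keep], to = pairs[2L, keep],
                          layer = "P"))
  }
  if (type == "COR") {
    reg <- members[1L]
    targets <- members[-1L]
    reg_edges <- tibble::tibble(
      from = reg, to = targets[stats::runif(length(targets)) < density],
      layer = "R")
    pairs <- utils::combn(targets, 2L)
    keep <- stats::runif(ncol(pairs)) < density
    return(dplyr::bind_rows(reg_edges,
                            tibble::tibble(from = pairs[1L, keep],
                                           to = pairs[2L, keep],
                                           layer = "P")))
  }
  # FFL: ordered directed edges i -> j (i earlier than j)
  pairs <- utils::combn(members, 2L)
  keep <- stats::runif(ncol(pairs)) < density
  tibble::tibble(from = pairs[1L, keep], to = pairs[2L, keep], layer = "R")
}

simulate_background_edges <- function(nodes, layers, density) {
  if (density <= 0) {
    return(tibble::tibble(from = character(), to = character(),
                          layer = character()))
  }
  purrr::map_dfr(seq_len(nrow(layers)), function(i) {
    pairs <- utils::combn(nodes, 2L)
    keep <- stats::runif(ncol(pairs)) < density
    e <- tibble::tibble(from = pairs[1L, keep], to = pairs[2L, keep],
                        layer = layers$letter[i])
    if (layers$directed[i] && nrow(e)) {
      flip <- stats::runif(nrow(e)) < 0.5
      tmp <- e$from[flip]; e$from[flip] <- e$to[flip]; e$to[flip] <- tmp
    }
    e
  })
}

#' Simulate module-correlated expression and per-gene p-values
#'
#' Latent-factor Gaussian model: genes of the same planted module share a
#' per-sample factor with the configured correlation strength
#' (`expr = sqrt(rho) * factor + sqrt(1 - rho) * noise`); genes of modules
#' declared active get a mean shift of `effect_size` (in noise-sd units) in
#' the condition samples. Per-gene p-values come from a two-sample Welch
#' t-test between the conditions, so activity-score recovery is testable.
#'
#' @param truth Truth tibble from [simulate_composite_network()].
#' @param n_samples Samples per condition (default 8).
#' @param correlation Within-module correlation strength `rho` in [0, 1]
#'   (default 0.8).
#' @param active_modules Character vector of truth module names receiving
#'   the condition effect (default none).
#' @param effect_size Mean shift for active modules, in sd units
#'   (default 2).
#' @param contrast Label for the p-value table (default
#'   `"condition_vs_control"`).
#' @param seed Integer seed.
#' @return A list with `expr` (tibble: `gene` + sample columns), `samples`
#'   (tibble `sample`, `condition`) and `pvalues` (tibble `gene`,
#'   `contrast`, `p`).
#' @export
simulate_expression <- function(truth, n_samples = 8L, correlation = 0.8,
                                active_modules = character(),
                                effect_size = 2, contrast = "condition_vs_control",
                                seed = 1L) {
  stopifnot(correlation >= 0, correlation <= 1, n_samples >= 2L)
  set.seed(seed)
  genes <- sort_c(unique(truth$node))
  n_total <- 2L * n_samples
  condition <- rep(c("condition", "control"), each = n_samples)
  sample_ids <- sprintf("s%02d", seq_len(n_total))
  mods <- split(truth$node, truth$module)
  mat <- matrix(stats::rnorm(length(genes) * n_total), nrow = length(genes),
                dimnames = list(genes, sample_ids))
  for (m in names(mods)) {
    f <- stats::rnorm(n_total)
    rows <- match(unique(mods[[m]]), genes)
    mat[rows, ] <- sqrt(correlation) * matrix(f, nrow = length(rows),
                                              ncol = n_total, byrow = TRUE) +
      sqrt(1 - correlation) * mat[rows, , drop = FALSE]
    if (m %in% active_modules) {
      mat[rows, condition == "condition"] <-
        mat[rows, condition == "condition"] + effect_size
    }
  }
  p <- apply(mat, 1L, function(v) {
    stats::t.test(v[condition == "condition"], v[condition == "control"])$p.value
  })
  list(expr = dplyr::bind_cols(tibble::tibble(gene = genes),
                               tibble::as_tibble(mat)),
       samples = tibble::tibble(sample = sample_ids, condition = condition),
       pvalues = tibble::tibble(gene = genes, contrast = contrast, p = p))
}
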