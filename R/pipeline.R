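# End-to-end pipeline orchestration with a config file.

#' Build a pipeline configuration
#'
#' Either pass a YAML file path (fields mirror the arguments) or the
#' arguments directly. Referenced files must exist at run start.
#'
#' @param layers Layer table from [layer_spec()] (with paths), or for YAML a
#'   list of `{letter, directed, path}` entries.
#' @param composite_file Optional three-column composite edge list used
#'   instead of per-layer files.
#' @param annotations Optional annotation file path (see
#'   [read_annotations()]).
#' @param code_blacklist Codes removed from the catalogue before
#'   enumeration.
#' @param min_size,max_size,max_h_fraction Module filter bounds (defaults
#'   5, 50, 0.9).
#' @param B Null sample size for the superview (default 1000).
#' @param background Enrichment background (`"type"`, `"network"`,
#'   `"custom"`).
#' @param background_file Gene list file for `background = "custom"`.
#' @param seed Integer seed.
#' @param cores Worker count for the per-module superview/enrichment loops
#'   (forked via the parallel package when > 1; results are identical
#'   across core counts).
#' @param output_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(layers = NULL, composite_file = NULL,
                            annotations = NULL, code_blacklist = character(),
                            min_size = 5L, max_size = 50L,
                            max_h_fraction = 0.9, B = 1000L,
                            background = "type", background_file = NULL,
                            seed = 1L, cores = 1L, output_dir = "modules_out") {
  cfg <- list(layers = layers, composite_file = composite_file,
              annotations = annotations, code_blacklist = code_blacklist,
              min_size = min_size, max_size = max_size,
              max_h_fraction = max_h_fraction, B = B,
              background = background, background_file = background_file,
              seed = seed, cores = cores, output_dir = output_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()]; `layers`
#'   is a list of `{letter, directed, path}` entries. Relative layer paths
#'   are resolved against the YAML file's directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(p)
    if (file.exists(p)) p else file.path(base, p)
  }
  layers <- NULL
  if (!is.null(raw$layers)) {
    layers <- layer_spec(
      vapply(raw$layers, `[[`, "", "letter"),
      vapply(raw$layers, `[[`, TRUE, "directed"),
      vapply(raw$layers, function(l) resolve(l$path) %||% NA_character_, ""))
  }
  args <- raw[setdiff(names(raw), "layers")]
  for (f in c("composite_file", "annotations", "background_file")) {
    if (!is.null(args[[f]])) args[[f]] <- resolve(args[[f]])
  }
  do.call(pipeline_config, c(list(layers = layers), args))
}

#' Run the module-detection pipeline end to end
#'
#' Stages, in order: load the composite network, generate the code
#' catalogue (minus the blacklist), enumerate subgraph instances, cluster
#' per type and jointly (ALL), filter to modules, compute the superview and
#' regulator statistics, run GO enrichment when annotations are provided,
#' and write Cytoscape exports. Every artifact lands in `output_dir`
#' together with a manifest recording package version, seed and
#' parameters. Rerunning with the same seed and inputs reproduces every
#' file bit for bit; stage failures halt with a stage-scoped error and
#' retain partial outputs.
#'
#' @param config A `pipeline_config` or path to a YAML config.
#' @return Invisibly, a list with the computed objects (`network`,
#'   `instances`, `modules`, `superview`, `regulators`, `enrichment`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  network <- stage("load", read_composite_network(config$layers,
                                                  config$composite_file))
  write_composite_network(network, file.path(out, "composite_network.tsv"))
  utils::write.table(glance(network), file.path(out, "network_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  codes <- stage("codes", {
    cat_ <- network_codes(network)
    cat_[!cat_$code %in% config$code_blacklist, , drop = FALSE]
  })
  utils::write.table(codes, file.path(out, "code_catalogue.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  instances <- stage("enumerate",
                     enumerate_subgraphs(network, codes = codes$code))
  write_instances(instances, file.path(out, "subgraph_instances.tsv"))
  modules <- stage("cluster",
                   detect_modules(network, instances = instances,
                                  min_size = config$min_size,
                                  max_size = config$max_size,
                                  max_h_fraction = config$max_h_fraction))
  write_modules(modules, file.path(out, "modules"), instances = instances)
  sv <- NULL; reg <- NULL
  if (nrow(modules) >= 2L) {
    sv <- stage("superview", superview(modules, network, B = config$B,
                                       seed = config$seed,
                                       cores = config$cores))
    for (tt in unique(modules$topo_type)) {
      rows <- sv[sv$module_a %in% modules$module[modules$topo_type == tt] |
                   sv$module_b %in% modules$module[modules$topo_type == tt], ]
      utils::write.table(rows, file.path(out, paste0("superview_", tt, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    directed <- network$layers$letter[network$layers$directed]
    reg <- stage("regulators", purrr::map_dfr(directed, function(ly) {
      if (!nrow(layer_edges(network, ly))) return(NULL)
      regulator_links(modules, network, ly)
    }))
    utils::write.table(reg, file.path(out, "regulator_strength.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    spec_rows <- purrr::map_dfr(directed, function(ly) {
      if (!nrow(layer_edges(network, ly))) return(NULL)
      module_regulator_specificity(modules, network, ly)
    })
    utils::write.table(spec_rows, file.path(out, "module_specificity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rspec <- purrr::map_dfr(directed, function(ly) {
      if (!nrow(layer_edges(network, ly))) return(NULL)
      regulator_specificity(modules, network, ly)
    })
    utils::write.table(rspec, file.path(out, "regulator_specificity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  enr <- NULL
  if (!is.null(config$annotations) && nrow(modules)) {
    ann <- read_annotations(config$annotations)
    bg_genes <- if (!is.null(config$background_file)) {
      readLines(config$background_file)
    } else NULL
    enr <- stage("enrich",
                 enrich_modules(modules, ann, background = config$background,
                                network = network,
                                background_genes = bg_genes,
                                cores = config$cores))
    write_enrichment(enr, file.path(out, "enrichment"))
  }
  if (nrow(modules)) {
    stage("export", {
      write_nnf(modules, file.path(out, "modules.nnf"))
      ann_nodes <- node_annotations(modules, network)
      write_noa(ann_nodes, file.path(out, "modules.noa"))
      write_style_xml(network$layers, file.path(out, "style.xml"))
    })
  }
  manifest <- list(
    package = "motifmodules",
    version = as.character(utils::packageVersion("motifmodules")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    parameters = config[c("min_size", "max_size", "max_h_fraction", "B",
                          "background", "code_blacklist", "cores")],
    n_nodes = length(network$nodes),
    n_edges = nrow(network$edges),
    n_instances = nrow(instances),
    n_modules = nrow(modules))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(network = network, instances = instances, modules = modules,
                 superview = sv, regulators = reg, enrichment = enr))
}
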