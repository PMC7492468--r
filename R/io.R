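#' Write a study dataset as long-format CSV tables
#'
#' One CSV per record type (the same schemas double as the import path for
#' real data) plus a JSON provenance sidecar holding the generating
#' configuration and seed.
#'
#' @param dataset a `study_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_study_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("animals", "creep_curves", "cyclic_traces",
              "filament_responses", "ct_records", "ivd_heights",
              "histology", "truth")
  paths <- character(0)
  for (tb in tables) {
    path <- file.path(dir, paste0(tb, ".csv"))
    write.csv(dataset[[tb]], path, row.names = FALSE)
    paths <- c(paths, path)
  }
  prov <- file.path(dir, "provenance.json")
  jsonlite::write_json(
    list(seed = dataset$provenance$seed,
         excluded = dataset$provenance$excluded,
         config_yaml = yaml::as.yaml(unclass(dataset$provenance$config))),
    prov, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, prov))
}

# rebuild a study_config from its serialized plain-list form
restore_study_config <- function(lst) {
  cfg <- study_config(
    n_per_group = lst$n_per_group,
    seed = lst$seed,
    exclusions = as.data.frame(lst$exclusions),
    filament_forces = unlist(lst$filament_forces),
    effects = lst$effects,
    noise = lst$noise,
    timepoints_weeks = unlist(lst$timepoints_weeks),
    n_raters = lst$n_raters
  )
  if (!is.null(lst$protocol)) cfg$protocol <- modifyList(cfg$protocol, lst$protocol)
  cfg
}

#' Read a study dataset from long-format CSV tables
#'
#' Inverse of [write_study_csv()]; also the entry point for real data laid
#' out in the same schemas (a `truth.csv` table is optional for real data).
#'
#' @param dir directory holding the CSV tables and `provenance.json`.
#' @return A `study_dataset`.
#' @export
read_study_csv <- function(dir) {
  rd <- function(tb) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) return(NULL)
    tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  }
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  cfg <- restore_study_config(yaml::yaml.load(prov$config_yaml))
  structure(list(
    animals = rd("animals"),
    creep_curves = rd("creep_curves"),
    cyclic_traces = rd("cyclic_traces"),
    filament_responses = rd("filament_responses"),
    ct_records = rd("ct_records"),
    ivd_heights = rd("ivd_heights"),
    histology = rd("histology"),
    truth = rd("truth"),
    provenance = list(config = cfg, seed = prov$seed,
                      excluded = unlist(prov$excluded))
  ), class = "study_dataset")
}

#' Write a correlation network as a TSV edge list
#'
#' Columns: trait_a, trait_b, rho, p, q, sign.
#'
#' @param net a `correlation_network`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_network_tsv <- function(net, path) {
  write.table(net$edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a correlation network as GraphML
#'
#' Nodes carry the variable-type class; edges carry rho, raw p, q and sign.
#'
#' @param net a `correlation_network`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(net, path) {
  nodes <- as.data.frame(net$nodes)
  nodes$class[is.na(nodes$class)] <- "unknown"
  edges <- as.data.frame(net$edges)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
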