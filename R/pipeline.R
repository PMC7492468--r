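#' Pipeline configuration
#'
#' Bundles the study generator configuration with the reduction and network
#' options into one serializable object (YAML round-trip safe).
#'
#' @param study a [study_config()].
#' @param reduction list: `cycle_index` (default 20), `window_frac` (0.2),
#'   `rout_q` (percent, 1).
#' @param network list: `alpha` (0.05), `min_pairwise_n` (4).
#' @param seed optional override of `study$seed`.
#' @param input_dir optional directory of long-format CSVs to analyze
#'   instead of simulating (see [read_study_csv()]).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(study = study_config(),
                            reduction = list(),
                            network = list(),
                            seed = NULL,
                            input_dir = NULL) {
  if (!is.null(seed)) study$seed <- as.integer(seed)
  cfg <- list(
    study = study,
    reduction = modifyList(list(cycle_index = 20L, window_frac = 0.2,
                                rout_q = 1), reduction),
    network = modifyList(list(alpha = 0.05, min_pairwise_n = 4L), network),
    input_dir = input_dir
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the restored `pipeline_config`
#'   (load-save-load is the identity).
#' @export
write_pipeline_config <- function(config, path) {
  plain <- list(study = unclass(config$study),
                reduction = config$reduction,
                network = config$network,
                input_dir = config$input_dir)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  plain <- yaml::read_yaml(path)
  pipeline_config(study = restore_study_config(plain$study),
                  reduction = plain$reduction,
                  network = plain$network,
                  input_dir = plain$input_dir)
}

.stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[%s] ", fmt),
                               format(Sys.time(), "%H:%M:%S"), ...))
}

# traits analyzed by injury x sex two-way ANOVA in the standard report
.anova_traits <- c("grade_total", "height_pct_punctured",
                   "tensile_stiffness", "compressive_stiffness", "axial_ROM",
                   "axial_hysteresis", "torsional_stiffness", "torque_range",
                   "torsional_hysteresis", "creep_k_e", "creep_k_f",
                   "creep_k_s", "creep_tau_f", "creep_tau_s",
                   "creep_total_displacement")

#' Run the full study pipeline
#'
#' Simulate (or import) -> reduce -> group statistics -> per-sex Spearman-FDR
#' networks -> network comparison, writing every artifact plus a manifest
#' with file checksums to `out_dir`. Outputs are bit-reproducible given the
#' configured seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print stage timings.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  stages <- character(0)
  manifest <- list(seed = config$study$seed,
                   package_version = as.character(utils::packageVersion("ivdnet")),
                   config_yaml = yaml::as.yaml(list(
                     study = unclass(config$study),
                     reduction = config$reduction,
                     network = config$network)))
  fail <- function(stage, e) {
    manifest$completed_stages <- stages
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  ## simulate / import
  dataset <- tryCatch({
    .stage_log(verbose, "generating study (seed %d)", config$study$seed)
    if (is.null(config$input_dir)) generate_study(config$study)
    else read_study_csv(config$input_dir)
  }, error = function(e) fail("simulate", e))
  stages <- c(stages, "simulate")

  ## reduce
  red <- tryCatch({
    .stage_log(verbose, "reducing raw signals")
    reduce_study(dataset,
                 cycle_index = config$reduction$cycle_index,
                 window_frac = config$reduction$window_frac,
                 rout_q = config$reduction$rout_q)
  }, error = function(e) fail("reduce", e))
  stages <- c(stages, "reduce")

  ## trait tables
  tabs <- tryCatch({
    .stage_log(verbose, "assembling trait tables")
    lapply(setNames(nm = c("female", "male")), function(sx)
      assemble_trait_table(dataset, sx, reductions = red))
  }, error = function(e) fail("traits", e))
  for (sx in names(tabs)) {
    write.csv(tabs[[sx]], file.path(out_dir, paste0("traits_", sx, ".csv")),
              row.names = FALSE)
  }
  stages <- c(stages, "traits")

  ## group statistics
  tryCatch({
    .stage_log(verbose, "group statistics")
    both <- dplyr::bind_rows(tabs)
    sexes <- rep(names(tabs), vapply(tabs, nrow, integer(1)))
    rows <- list(); cells <- list(); log_lines <- character(0)
    for (tr in intersect(.anova_traits, names(both))) {
      res <- two_way_anova(both[[tr]], both$injury, sexes,
                           factor_names = c("injury", "sex"))
      rows[[tr]] <- dplyr::mutate(res$table, trait = tr, .before = 1)
      cells[[tr]] <- dplyr::mutate(res$cells, trait = tr, .before = 1)
      log_lines <- c(log_lines, sprintf(
        "%s: injury F=%.3f p=%.4g | sex F=%.3f p=%.4g | interaction F=%.3f p=%.4g",
        tr, res$table$f[1], res$table$p[1], res$table$f[2], res$table$p[2],
        res$table$f[3], res$table$p[3]))
    }
    ## von Frey: injury x time, per sex
    for (sx in names(tabs)) {
      vf <- red$vonfrey[red$vonfrey$animal_id %in% tabs[[sx]]$animal_id, ]
      inj <- tabs[[sx]]$injury[match(vf$animal_id, tabs[[sx]]$animal_id)]
      res <- two_way_anova(vf$threshold_g, inj, vf$week,
                           factor_names = c("injury", "week"))
      key <- paste0("vonfrey_by_week_", sx)
      rows[[key]] <- dplyr::mutate(res$table, trait = key, .before = 1)
      log_lines <- c(log_lines, sprintf(
        "%s: injury F=%.3f p=%.4g", key, res$table$f[1], res$table$p[1]))
    }
    ## expression: injury x DRG level, per sex and gene
    for (sx in names(tabs)) {
      ex <- red$expression[red$expression$sex == sx & !red$expression$outlier, ]
      for (gn in unique(ex$gene)) {
        exg <- ex[ex$gene == gn, ]
        res <- two_way_anova(exg$relative_expression, exg$injury_group,
                             exg$drg_level, factor_names = c("injury", "level"))
        key <- paste0("expr_", gn, "_by_level_", sx)
        rows[[key]] <- dplyr::mutate(res$table, trait = key, .before = 1)
      }
    }
    write.csv(dplyr::bind_rows(rows), file.path(out_dir, "stats_anova.csv"),
              row.names = FALSE)
    write.csv(dplyr::bind_rows(cells), file.path(out_dir, "stats_groups.csv"),
              row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "stats_log.txt"))
  }, error = function(e) fail("stats", e))
  stages <- c(stages, "stats")

  ## networks
  nets <- tryCatch({
    .stage_log(verbose, "building correlation networks")
    lapply(tabs, function(tb) trait_network(
      tb, alpha = config$network$alpha, min_n = config$network$min_pairwise_n))
  }, error = function(e) fail("network", e))
  stages <- c(stages, "network")
  for (sx in names(nets)) {
    write_network_tsv(nets[[sx]], file.path(out_dir, paste0("network_", sx, ".tsv")))
    write_network_graphml(nets[[sx]],
                          file.path(out_dir, paste0("network_", sx, ".graphml")))
  }
  cmp <- compare_networks(nets$male, nets$female,
                          edges_of_interest = data.frame(
                            a = c("injury", "injury", "injury"),
                            b = c("vonfrey_w6", "grade_total",
                                  "height_pct_punctured")))
  jsonlite::write_json(
    list(jaccard = cmp$jaccard,
         n_shared_edges = length(cmp$shared_edges),
         n_unique_male = length(cmp$unique_a),
         n_unique_female = length(cmp$unique_b),
         shared_edges = cmp$shared_edges,
         edges_of_interest = cmp$edges_of_interest),
    file.path(out_dir, "network_comparison.json"),
    auto_unbox = TRUE, digits = NA)
  stages <- c(stages, "compare")

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest$completed_stages <- stages
  manifest$failed_stage <- NULL
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  manifest$files <- lapply(setNames(nm = basename(files)), function(f)
    unname(md5sum(file.path(out_dir, f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .stage_log(verbose, "done (%.1f s)", manifest$elapsed_s)
  invisible(manifest)
}
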