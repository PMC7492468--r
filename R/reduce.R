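#' Reduce a study dataset to endpoint traits
#'
#' Runs every reduction stage on the raw records of a [generate_study()]
#' dataset (or an imported one with the same schemas): 20th-cycle axial and
#' torsional properties and the 5-parameter creep fit per animal; per-week
#' paw withdrawal thresholds (averaged over paws, normalized to week 0);
#' delta-Ct relative expression with per-group ROUT outlier flags and fold
#' changes versus the same-sex sham mean; per-level and punctured-average
#' IVD height percent changes; and rater-aggregated degeneration grades.
#'
#' @param dataset a `study_dataset`.
#' @param cycle_index cycle used for axial/torsional properties (default 20).
#' @param window_frac end-range fit window fraction (default 0.2).
#' @param rout_q ROUT Q in percent for qPCR outlier removal (default 1).
#' @param fit_creep set `FALSE` to skip the (comparatively slow) creep fits.
#' @return A `study_reductions` list of tibbles: `biomech`, `vonfrey`,
#'   `expression`, `heights`, `histology`.
#' @export
reduce_study <- function(dataset, cycle_index = 20, window_frac = 0.2,
                         rout_q = 1, fit_creep = TRUE) {
  pro <- dataset$provenance$config$protocol
  animals <- dataset$animals

  ## ---- biomechanics -------------------------------------------------
  biomech <- dplyr::bind_rows(lapply(animals$animal_id, function(id) {
    res <- list(animal_id = id)
    for (kd in c("axial", "torsional")) {
      tr <- dataset$cyclic_traces[dataset$cyclic_traces$animal_id == id &
                                    dataset$cyclic_traces$kind == kd, ]
      trace <- structure(list(kind = kd, time_s = tr$time_s,
                              primary = tr$primary, conjugate = tr$conjugate,
                              frequency_hz = pro$cyclic_frequency_hz,
                              n_cycles = pro$cyclic_n_cycles),
                         class = "cyclic_trace")
      cyc <- extract_cycle(trace, cycle_index)
      props <- if (kd == "axial") axial_properties(cyc, window_frac)
      else torsional_properties(cyc, window_frac)
      res <- c(res, props)
    }
    if (fit_creep) {
      cc <- dataset$creep_curves[dataset$creep_curves$animal_id == id, ]
      fit <- fit_creep_model(list(time_s = cc$time_s,
                                  displacement_mm = cc$displacement_mm,
                                  applied_load_n = cc$applied_load_n[1]))
      if (!is.null(fit$params) && fit$converged) {
        res <- c(res, fit$params[c("k_e", "k_f", "k_s", "tau_f", "tau_s")],
                 list(total_displacement = fit$total_displacement))
      } else {
        res <- c(res, list(k_e = NA_real_, k_f = NA_real_, k_s = NA_real_,
                           tau_f = NA_real_, tau_s = NA_real_,
                           total_displacement = NA_real_))
      }
    }
    tibble::as_tibble(res)
  }))

  ## ---- von Frey -----------------------------------------------------
  fr <- dataset$filament_responses
  vonfrey <- dplyr::bind_rows(lapply(split(fr, list(fr$animal_id, fr$week),
                                           drop = TRUE), function(df) {
    thr <- von_frey_threshold(df)
    tibble::tibble(animal_id = df$animal_id[1], week = df$week[1],
                   left_g = thr$threshold_g[thr$paw == "left"],
                   right_g = thr$threshold_g[thr$paw == "right"])
  }))
  vonfrey <- vonfrey[order(vonfrey$animal_id, vonfrey$week), ]
  vonfrey <- dplyr::group_by(vonfrey, .data$animal_id)
  vonfrey <- dplyr::mutate(
    vonfrey,
    threshold_g = (.data$left_g + .data$right_g) / 2,
    normalized_threshold = .data$threshold_g /
      .data$threshold_g[.data$week == 0][1])
  vonfrey <- dplyr::ungroup(vonfrey)

  ## ---- qPCR expression ----------------------------------------------
  ct <- dataset$ct_records
  gapdh <- ct[ct$gene == "Gapdh", c("animal_id", "drg_level", "ct_value")]
  names(gapdh)[3] <- "ct_gapdh"
  expr <- dplyr::left_join(ct[ct$gene != "Gapdh", ], gapdh,
                           by = c("animal_id", "drg_level"))
  expr$relative_expression <- relative_expression(expr$ct_value, expr$ct_gapdh)
  expr <- dplyr::left_join(expr,
                           animals[, c("animal_id", "sex", "injury_group")],
                           by = "animal_id")
  expr <- dplyr::group_by(expr, .data$sex, .data$injury_group,
                          .data$gene, .data$drg_level)
  expr <- dplyr::mutate(expr, outlier = rout_outliers(
    .data$relative_expression, Q = rout_q))
  expr <- dplyr::ungroup(expr)
  sham_means <- dplyr::summarise(
    dplyr::group_by(expr[expr$injury_group == 0 & !expr$outlier, ],
                    .data$sex, .data$gene, .data$drg_level),
    sham_mean = mean(.data$relative_expression, na.rm = TRUE),
    .groups = "drop")
  expr <- dplyr::left_join(expr, sham_means, by = c("sex", "gene", "drg_level"))
  expr$fold_change <- expr$relative_expression / expr$sham_mean
  expression <- expr[, c("animal_id", "sex", "injury_group", "gene",
                         "drg_level", "ct_value", "ct_gapdh",
                         "relative_expression", "fold_change", "outlier")]

  ## ---- radiographic heights -----------------------------------------
  punct <- dataset$provenance$config$punctured_levels
  hh <- dataset$ivd_heights
  heights <- dplyr::bind_rows(lapply(split(hh, hh$animal_id), function(df) {
    pc <- height_percent_change(df, punctured_levels = punct)
    tibble::tibble(animal_id = df$animal_id[1],
                   level = c(names(pc$per_level), "punctured_average"),
                   pct_change = c(unname(pc$per_level), pc$punctured_average))
  }))

  ## ---- histology ----------------------------------------------------
  hs <- dataset$histology
  histology <- dplyr::bind_rows(lapply(split(hs, hs$animal_id), function(df) {
    g <- total_degeneration_grade(df)
    tibble::tibble(animal_id = df$animal_id[1],
                   measure = c(names(g$category_means), "total"),
                   grade = c(unname(g$category_means), g$total))
  }))

  structure(list(biomech = biomech, vonfrey = vonfrey,
                 expression = expression, heights = heights,
                 histology = histology),
            class = "study_reductions")
}
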