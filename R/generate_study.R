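#' Generate a complete synthetic annular-puncture study
#'
#' Simulates every raw record of the emulated study from a latent-variable
#' model: per-animal latent degeneration (injury-driven) and latent
#' nociceptive sensitivity (sex- and injury-driven) generate the creep and
#' cyclic biomechanical traces, von Frey filament response tables, DRG qPCR
#' Ct values, radiographic IVD heights, and rater histology subscores. The
#' result is fully reproducible given `config$seed`, and exclusions
#' (attrition) are applied by removing the sampled animals from every record
#' table after generation.
#'
#' @param config a [study_config()].
#' @return A `study_dataset`: list of tibbles `animals`, `creep_curves`,
#'   `cyclic_traces`, `filament_responses`, `ct_records`, `ivd_heights`,
#'   `histology`, plus `truth` (per-animal ground-truth biomechanical
#'   properties, for validation) and `provenance` (config and seed).
#' @examples
#' ds <- generate_study(study_config(seed = 1))
#' nrow(ds$animals)  # 46 after the two exclusions
#' @export
generate_study <- function(config) {
  validate_study_config(config)
  eff <- config$effects
  nz <- config$noise
  pro <- config$protocol
  set.seed(config$seed)

  ## ---- animals -------------------------------------------------------
  n_grp <- config$n_per_group
  grid <- expand.grid(injury_group = c(0L, 1L), sex = config$sex_levels,
                      stringsAsFactors = FALSE)[, 2:1]
  animals <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    tibble::tibble(sex = grid$sex[i], injury_group = grid$injury_group[i],
                   idx = seq_len(n_grp))
  }))
  animals$animal_id <- sprintf("%s%02d", toupper(substr(animals$sex, 1, 1)),
                               stats::ave(seq_len(nrow(animals)), animals$sex,
                                          FUN = seq_along))
  n_all <- nrow(animals)
  animals$surgery_date <- sample(rep_len(seq_len(config$n_cohorts), n_all))
  w_base <- ifelse(animals$sex == "male", eff$weight_male, eff$weight_female)
  w_gain <- ifelse(animals$sex == "male", eff$weight_gain_male, eff$weight_gain_female)
  animals$weight_preop <- w_base + rnorm(n_all, 0, nz$weight_sd)
  animals$weight_6wk <- animals$weight_preop + w_gain + rnorm(n_all, 0, nz$weight_gain_sd)
  animals$estrous_stage <- ifelse(
    animals$sex == "female",
    sample(c("proestrus", "estrus", "metestrus", "diestrus"), n_all, replace = TRUE),
    NA_character_)
  animals$latent_degeneration <-
    animals$injury_group * (1 + rnorm(n_all, 0, nz$latent_degeneration_sd))

  ## latent log paw-withdrawal threshold: baseline deviation shared across
  ## weeks, plus an injury shift (male) or extra injury-only dispersion
  ## (female) from week 2 onward
  z_base <- rnorm(n_all, 0, nz$vf_sd_log)
  ratio <- ifelse(animals$sex == "male", eff$vf_injury_ratio_male,
                  eff$vf_injury_ratio_female)
  extra_sd <- ifelse(animals$sex == "female" & animals$injury_group == 1,
                     nz$vf_sd_log * sqrt(max(eff$vf_female_injury_sd_mult^2 - 1, 0)),
                     0)
  z_injury <- rnorm(n_all, 0, 1) * extra_sd
  log_thr_pre <- log(eff$vf_baseline_g) + z_base
  log_thr_post <- log_thr_pre + animals$injury_group * (log(ratio) + z_injury)
  animals$latent_sensitivity <- log_thr_post
  animals <- animals[, c("animal_id", "sex", "injury_group", "surgery_date",
                         "weight_preop", "weight_6wk", "estrous_stage",
                         "latent_degeneration", "latent_sensitivity")]

  ## ---- ground-truth biomechanics ------------------------------------
  lnorm_var <- function(n, cv) exp(rnorm(n, 0, cv))
  ax_inj <- ifelse(animals$injury_group == 1, eff$axial_injury_ratio, 1)
  to_inj <- ifelse(animals$injury_group == 1, eff$torsion_injury_ratio, 1)
  cr_inj <- ifelse(animals$injury_group == 1, eff$creep_injury_ratio, 1)
  tors_base <- ifelse(animals$sex == "male", eff$torsional_stiffness_male,
                      eff$torsional_stiffness_female)
  truth <- tibble::tibble(
    animal_id = animals$animal_id,
    tensile_stiffness = eff$tensile_stiffness * ax_inj * lnorm_var(n_all, nz$biomech_cv),
    compressive_stiffness = eff$compressive_stiffness * ax_inj * lnorm_var(n_all, nz$biomech_cv),
    axial_hysteresis = eff$axial_hysteresis * lnorm_var(n_all, nz$biomech_cv),
    torsional_stiffness = tors_base * to_inj * lnorm_var(n_all, nz$biomech_cv),
    torsional_hysteresis = eff$torsional_hysteresis * lnorm_var(n_all, nz$biomech_cv),
    k_e = eff$creep_k_e * cr_inj * lnorm_var(n_all, nz$biomech_cv),
    k_f = eff$creep_k_f * cr_inj * lnorm_var(n_all, nz$biomech_cv),
    k_s = eff$creep_k_s * cr_inj * lnorm_var(n_all, nz$biomech_cv),
    tau_f = eff$creep_tau_f * lnorm_var(n_all, nz$creep_tau_cv),
    tau_s = eff$creep_tau_s * lnorm_var(n_all, nz$creep_tau_cv)
  )
  truth$axial_ROM <- pro$axial_amplitude_n / truth$tensile_stiffness +
    pro$axial_amplitude_n / truth$compressive_stiffness
  truth$torque_range <- 2 * pro$torsional_amplitude_deg * truth$torsional_stiffness
  truth$total_displacement <- abs(vapply(seq_len(n_all), function(i) {
    creep_displacement(pro$creep_duration_s, pro$creep_load_n,
                       creep_params(truth$k_e[i], truth$k_f[i], truth$k_s[i],
                                    truth$tau_f[i], truth$tau_s[i]))
  }, numeric(1)))

  ## ---- raw biomechanical traces -------------------------------------
  cyclic_traces <- dplyr::bind_rows(lapply(seq_len(n_all), function(i) {
    ax <- simulate_cyclic_trace(
      "axial",
      list(tensile_stiffness = truth$tensile_stiffness[i],
           compressive_stiffness = truth$compressive_stiffness[i]),
      n_cycles = pro$cyclic_n_cycles, frequency_hz = pro$cyclic_frequency_hz,
      sampling_hz = pro$cyclic_sampling_hz,
      hysteresis_area = truth$axial_hysteresis[i],
      noise_sd = nz$cyclic_noise_axial_mm, amplitude = pro$axial_amplitude_n)
    to <- simulate_cyclic_trace(
      "torsional",
      list(torsional_stiffness = truth$torsional_stiffness[i]),
      n_cycles = pro$cyclic_n_cycles, frequency_hz = pro$cyclic_frequency_hz,
      sampling_hz = pro$cyclic_sampling_hz,
      hysteresis_area = truth$torsional_hysteresis[i],
      noise_sd = nz$cyclic_noise_torsional_nmm,
      amplitude = pro$torsional_amplitude_deg)
    dplyr::bind_rows(
      tibble::tibble(animal_id = animals$animal_id[i], kind = "axial",
                     time_s = ax$time_s, primary = ax$primary,
                     conjugate = ax$conjugate),
      tibble::tibble(animal_id = animals$animal_id[i], kind = "torsional",
                     time_s = to$time_s, primary = to$primary,
                     conjugate = to$conjugate))
  }))

  creep_curves <- dplyr::bind_rows(lapply(seq_len(n_all), function(i) {
    cc <- simulate_creep_curve(
      creep_params(truth$k_e[i], truth$k_f[i], truth$k_s[i],
                   truth$tau_f[i], truth$tau_s[i]),
      load = pro$creep_load_n, duration_s = pro$creep_duration_s,
      sampling_hz = pro$creep_sampling_hz, noise_sd = nz$creep_noise_sd_mm)
    tibble::tibble(animal_id = animals$animal_id[i], time_s = cc$time_s,
                   displacement_mm = cc$displacement_mm,
                   applied_load_n = cc$applied_load_n)
  }))

  ## ---- von Frey filament response tables ----------------------------
  deterministic_vf <- nz$vf_response == 0
  filament_responses <- dplyr::bind_rows(lapply(seq_len(n_all), function(i) {
    dplyr::bind_rows(lapply(config$timepoints_weeks, function(wk) {
      log_thr <- if (wk == 0) log_thr_pre[i] else log_thr_post[i]
      thr <- exp(log_thr + rnorm(2, 0, nz$vf_week_sd_log))
      tab <- simulate_filament_responses(
        c(left = thr[1], right = thr[2]),
        filament_forces = config$filament_forces, slope = eff$vf_slope,
        n_applications = config$n_applications,
        deterministic = deterministic_vf)
      tab$animal_id <- animals$animal_id[i]
      tab$week <- wk
      tab[, c("animal_id", "week", "paw", "force_g", "response_count")]
    }))
  }))

  ## ---- DRG qPCR Ct values -------------------------------------------
  lvl_off <- setNames(seq(-0.25, 0.25, length.out = length(config$drg_levels)),
                      config$drg_levels)
  ct_grid <- expand.grid(animal_id = animals$animal_id,
                         drg_level = config$drg_levels,
                         gene = c("Calca", "Tac1", "Gapdh"),
                         stringsAsFactors = FALSE)
  ct_grid <- dplyr::left_join(ct_grid,
                              animals[, c("animal_id", "sex", "injury_group")],
                              by = "animal_id")
  base_ct <- c(Calca = 22, Tac1 = 24, Gapdh = 18)
  log2fc <- with(ct_grid, ifelse(
    sex == "male" & injury_group == 1 & gene == "Calca" & drg_level == "L2",
    eff$calca_l2_male_log2fc,
    ifelse(sex == "male" & injury_group == 1 & gene == "Tac1" & drg_level == "L5",
           eff$tac1_l5_male_log2fc, 0)))
  ct_grid$ct_value <- base_ct[ct_grid$gene] +
    ifelse(ct_grid$gene == "Gapdh", 0, lvl_off[ct_grid$drg_level]) -
    log2fc + rnorm(nrow(ct_grid), 0, nz$ct_sd)
  ct_records <- tibble::as_tibble(
    ct_grid[, c("animal_id", "drg_level", "gene", "ct_value")])

  ## ---- radiographic IVD heights -------------------------------------
  lvl_grad <- setNames(1 + 0.02 * (seq_along(config$ivd_levels) -
                                     ceiling(length(config$ivd_levels) / 2)),
                       config$ivd_levels)
  size_fac <- 1 + rnorm(n_all, 0, nz$height_size_cv)
  hgt_grid <- expand.grid(animal_id = animals$animal_id,
                          level = config$ivd_levels, stringsAsFactors = FALSE)
  hgt_grid <- dplyr::left_join(hgt_grid,
                               animals[, c("animal_id", "sex", "injury_group")],
                               by = "animal_id")
  idx <- match(hgt_grid$animal_id, animals$animal_id)
  sex_base <- ifelse(hgt_grid$sex == "male", eff$height_base_male,
                     eff$height_base_female)
  true_h0 <- sex_base * lvl_grad[hgt_grid$level] * size_fac[idx]
  punct <- hgt_grid$level %in% config$punctured_levels
  loss <- eff$height_loss_frac * hgt_grid$injury_group * punct *
    (1 + rnorm(nrow(hgt_grid), 0, nz$height_loss_cv))
  loss <- pmin(pmax(loss, 0), 0.9)
  true_h6 <- true_h0 * (1 - loss)
  ivd_heights <- tibble::as_tibble(dplyr::bind_rows(
    data.frame(hgt_grid[, c("animal_id", "level")], timepoint = "baseline",
               height_mm = true_h0 * (1 + rnorm(nrow(hgt_grid), 0, nz$height_meas_cv))),
    data.frame(hgt_grid[, c("animal_id", "level")], timepoint = "6wk",
               height_mm = true_h6 * (1 + rnorm(nrow(hgt_grid), 0, nz$height_meas_cv)))
  ))

  ## ---- histology subscores ------------------------------------------
  categories <- c("AF_integrity", "AF_NP_border", "NP_cellularity",
                  "NP_matrix", "endplate")
  hist_grid <- expand.grid(animal_id = animals$animal_id, category = categories,
                           stringsAsFactors = FALSE)
  idx <- match(hist_grid$animal_id, animals$animal_id)
  severity <- pmin(pmax(
    eff$grade_base_severity +
      eff$grade_injury_severity * animals$latent_degeneration[idx] +
      rnorm(nrow(hist_grid), 0, nz$grade_category_sd), 0), 2)
  histology <- dplyr::bind_rows(lapply(seq_len(config$n_raters), function(r) {
    tibble::tibble(animal_id = hist_grid$animal_id, rater = r,
                   category = hist_grid$category,
                   subscore = pmin(pmax(round(
                     severity + rnorm(nrow(hist_grid), 0, nz$grade_rater_sd)), 0), 2))
  }))

  ## ---- exclusions (attrition) ---------------------------------------
  excluded <- character(0)
  ex <- config$exclusions
  if (!is.null(ex) && nrow(ex) > 0) {
    for (j in seq_len(nrow(ex))) {
      pool <- animals$animal_id[animals$sex == ex$sex[j] &
                                  animals$injury_group == ex$injury_group[j]]
      pool <- setdiff(pool, excluded)
      excluded <- c(excluded, sample(pool, ex$n[j]))
    }
  }
  keep <- function(df) df[!(df$animal_id %in% excluded), , drop = FALSE]

  structure(list(
    animals = keep(animals),
    creep_curves = keep(creep_curves),
    cyclic_traces = keep(cyclic_traces),
    filament_responses = keep(filament_responses),
    ct_records = keep(ct_records),
    ivd_heights = keep(ivd_heights),
    histology = keep(histology),
    truth = keep(truth),
    provenance = list(config = config, seed = config$seed,
                      excluded = excluded)
  ), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Synthetic annular-puncture study: %d animals (%s)\n",
              nrow(x$animals),
              paste(sprintf("%s %s: %d",
                            rep(unique(x$animals$sex), each = 2),
                            rep(c("sham", "injury"), 2),
                            as.vector(table(x$animals$injury_group, x$animals$sex))),
                    collapse = "; ")))
  cat(sprintf("  excluded: %s; seed %d\n",
              paste(x$provenance$excluded, collapse = ", "),
              x$provenance$seed))
  invisible(x)
}
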