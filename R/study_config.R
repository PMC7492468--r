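#' Study configuration for the synthetic annular-puncture study
#'
#' Builds the configuration object that drives [generate_study()]. The
#' defaults encode the design of the in vivo rat study the package emulates:
#' a 2x2 (sex x injury) design with n = 12 per group, one male-injury and one
#' female-injury animal excluded, lumbar IVD puncture at L3/4-L5/6, von Frey
#' testing at weeks 0/2/4/6 with an ascending Touch-Test filament set
#' (0.4-26 g), DRG qPCR at levels T13-L5, radiographs of L1/2-L5/6 at
#' baseline and 6 weeks, and histology subscores from 3 blinded raters.
#'
#' The `effects` block encodes the sex-specific effect structure the
#' generator reproduces by default: injury lowers the paw withdrawal
#' threshold in males but not on average in females (whose between-animal
#' variability is inflated instead); injury raises the degeneration grade and
#' lowers punctured-level IVD height in both sexes; injury leaves axial,
#' torsional and creep biomechanics unchanged; Calca is up-shifted at the L2
#' DRG and Tac1 at the L5 DRG in injured males only; and males have greater
#' torsional stiffness and torque range than females.
#'
#' @param n_per_group animals per sex x injury cell (default 12).
#' @param seed integer seed; every downstream draw is reproducible given it.
#' @param exclusions data frame with columns `sex`, `injury_group`, `n`
#'   giving post-hoc attrition per cell. Default: 1 male injury, 1 female
#'   injury.
#' @param filament_forces strictly increasing von Frey forces in grams; must
#'   start at 0.4 and end at 26.0.
#' @param effects,noise named lists overriding entries of the default effect
#'   and noise blocks (see [default_effects()] and [default_noise()]).
#' @param timepoints_weeks von Frey measurement weeks.
#' @param n_raters number of histology raters.
#' @return A `study_config` object (a validated named list).
#' @examples
#' cfg <- study_config(seed = 1)
#' cfg$filament_forces
#' @export
study_config <- function(n_per_group = 12,
                         seed = 1,
                         exclusions = data.frame(
                           sex = c("male", "female"),
                           injury_group = c(1L, 1L),
                           n = c(1L, 1L)
                         ),
                         filament_forces = c(0.4, 0.6, 1, 1.4, 2, 4, 6, 8, 10, 15, 26),
                         effects = list(),
                         noise = list(),
                         timepoints_weeks = c(0, 2, 4, 6),
                         n_raters = 3) {
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    sex_levels = c("female", "male"),
    injury_levels = c("sham", "injury"),
    exclusions = exclusions,
    seed = as.integer(seed),
    filament_forces = as.numeric(filament_forces),
    drg_levels = c("T13", "L1", "L2", "L3", "L4", "L5"),
    ivd_levels = c("L1/2", "L2/3", "L3/4", "L4/5", "L5/6"),
    punctured_levels = c("L3/4", "L4/5", "L5/6"),
    timepoints_weeks = as.numeric(timepoints_weeks),
    n_raters = as.integer(n_raters),
    n_applications = 5L,
    n_cohorts = 6L,
    protocol = list(
      cyclic_n_cycles = 20L, cyclic_frequency_hz = 1, cyclic_sampling_hz = 100,
      axial_amplitude_n = 8, torsional_amplitude_deg = 10,
      creep_load_n = -8, creep_duration_s = 3600, creep_sampling_hz = 1
    ),
    effects = modifyList(default_effects(), effects),
    noise = modifyList(default_noise(), noise)
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

#' Default effect block
#'
#' Effect sizes for the synthetic generator. Multiplicative effects are
#' ratios (1 = no effect); expression shifts are log2 fold changes.
#'
#' @return Named list of effect parameters.
#' @export
default_effects <- function() {
  list(
    # von Frey: latent paw-withdrawal threshold model (grams, log scale)
    vf_baseline_g = 12,            # pre-op latent threshold, both sexes
    vf_injury_ratio_male = 0.35,   # male injury: threshold drops to 35%
    vf_injury_ratio_female = 1.0,  # female injury: no mean shift
    vf_female_injury_sd_mult = 3,  # ... but inflated between-animal SD
    vf_slope = 6,                  # logistic slope in log-force units

    # structural degeneration
    grade_base_severity = 0.4,     # per-category continuous severity, sham
    grade_injury_severity = 1.1,   # added severity per unit latent degeneration
    height_loss_frac = 0.15,       # fractional height loss at punctured levels

    # radiographic baseline heights (mm)
    height_base_female = 0.90,
    height_base_male = 0.95,

    # DRG expression: male-only site-specific up-shifts (log2 fold change)
    calca_l2_male_log2fc = 1.0,
    tac1_l5_male_log2fc = 1.0,

    # biomechanics ground truth (population medians)
    tensile_stiffness = 60,        # N/mm
    compressive_stiffness = 120,   # N/mm
    axial_hysteresis = 0.5,        # N*mm (loop must nest inside the stroke)
    torsional_stiffness_female = 2.4,  # N*mm/deg
    torsional_stiffness_male = 3.0,
    torsional_hysteresis = 30,     # N*mm*deg
    creep_k_e = 100, creep_k_f = 50, creep_k_s = 25,  # N/mm
    creep_tau_f = 10, creep_tau_s = 600,              # s
    # injury effects on biomechanics (ratios; 1 = none, as observed)
    axial_injury_ratio = 1,
    torsion_injury_ratio = 1,
    creep_injury_ratio = 1,

    # body weight (grams)
    weight_female = 280, weight_male = 450,
    weight_gain_female = 20, weight_gain_male = 40
  )
}

#' Default noise block
#'
#' Standard deviations / coefficients of variation for every stochastic
#' component of the generator. Setting all entries to zero makes the
#' generator fully deterministic (binomial filament responses degenerate to a
#' step at p = 0.5).
#'
#' @return Named list of noise parameters.
#' @export
default_noise <- function() {
  list(
    vf_sd_log = 0.18,        # between-animal SD of log threshold
    vf_week_sd_log = 0.08,   # per-week, per-paw jitter of log threshold
    vf_response = 1,         # 0 disables binomial response sampling
    latent_degeneration_sd = 0.2,
    grade_category_sd = 0.15,
    grade_rater_sd = 0.3,
    height_meas_cv = 0.03,   # radiographic measurement CV per reading
    height_size_cv = 0.05,   # per-animal anatomical size CV
    height_loss_cv = 0.3,    # relative SD of the injury height loss
    ct_sd = 0.25,            # qPCR Ct replicate SD (cycles)
    biomech_cv = 0.12,       # between-animal lognormal CV, stiffness-like
    creep_tau_cv = 0.15,     # between-animal CV of creep time constants
    creep_noise_sd_mm = 0.005,   # additive creep displacement noise
    cyclic_noise_axial_mm = 0.002,   # displacement channel noise
    cyclic_noise_torsional_nmm = 0.3,  # torque channel noise
    weight_sd = 20,
    weight_gain_sd = 10
  )
}

validate_study_config <- function(cfg) {
  ff <- cfg$filament_forces
  if (length(ff) < 2 || any(diff(ff) <= 0)) {
    stop("filament_forces must be strictly increasing", call. = FALSE)
  }
  if (ff[1] != 0.4 || ff[length(ff)] != 26.0) {
    stop("filament_forces must span 0.4 g to 26.0 g", call. = FALSE)
  }
  if (cfg$n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  noise_num <- unlist(cfg$noise)
  if (any(!is.finite(noise_num)) || any(noise_num < 0)) {
    stop("noise parameters must be finite and non-negative", call. = FALSE)
  }
  ex <- cfg$exclusions
  if (!is.null(ex) && nrow(ex) > 0) {
    stopifnot(all(c("sex", "injury_group", "n") %in% names(ex)))
    if (!all(ex$sex %in% cfg$sex_levels)) stop("unknown sex in exclusions", call. = FALSE)
  }
  with_pos <- c("vf_baseline_g", "height_base_female", "height_base_male",
                "tensile_stiffness", "compressive_stiffness",
                "creep_k_e", "creep_k_f", "creep_k_s",
                "creep_tau_f", "creep_tau_s")
  if (any(unlist(cfg$effects[with_pos]) <= 0)) {
    stop("baseline effect parameters must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Set every noise component of a configuration to zero
#'
#' Convenience for round-trip testing: the resulting generator is fully
#' deterministic (animals of the same sex and group produce identical
#' signals).
#'
#' @param cfg a `study_config`.
#' @return The modified configuration.
#' @export
zero_noise <- function(cfg) {
  cfg$noise <- lapply(cfg$noise, function(x) 0)
  validate_study_config(cfg)
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  n_total <- x$n_per_group * length(x$sex_levels) * length(x$injury_levels)
  n_excl <- if (is.null(x$exclusions)) 0L else sum(x$exclusions$n)
  cat("Annular-puncture study configuration\n")
  cat(sprintf("  %d animals (%d/group), %d excluded, seed %d\n",
              n_total, x$n_per_group, n_excl, x$seed))
  cat(sprintf("  filaments: %s g\n", paste(x$filament_forces, collapse = ", ")))
  cat(sprintf("  DRG levels: %s; IVD levels: %s\n",
              paste(x$drg_levels, collapse = ","),
              paste(x$ivd_levels, collapse = ",")))
  invisible(x)
}
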