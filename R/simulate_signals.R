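#' Five-parameter viscoelastic creep parameters
#'
#' Container for the creep model used throughout the package: an elastic
#' spring in series with two Kelvin-Voigt arms (fast and slow), so that the
#' displacement under a constant load F is
#' \deqn{d(t) = F [ 1/k_e + (1/k_f)(1 - e^{-t/\tau_f})
#'               + (1/k_s)(1 - e^{-t/\tau_s}) ].}
#'
#' @param k_e,k_f,k_s elastic, fast and slow response stiffnesses (N/mm).
#' @param tau_f,tau_s fast and slow time constants (s); `tau_f < tau_s` is
#'   enforced by relabeling.
#' @return A `creep_params` list.
#' @export
creep_params <- function(k_e, k_f, k_s, tau_f, tau_s) {
  p <- list(k_e = k_e, k_f = k_f, k_s = k_s, tau_f = tau_f, tau_s = tau_s)
  if (any(!is.finite(unlist(p))) || any(unlist(p) <= 0)) {
    stop("creep parameters must be positive and finite", call. = FALSE)
  }
  if (p$tau_f > p$tau_s) {  # canonical order: fast arm first
    p <- list(k_e = p$k_e, k_f = p$k_s, k_s = p$k_f,
              tau_f = p$tau_s, tau_s = p$tau_f)
  }
  class(p) <- "creep_params"
  p
}

#' Creep displacement model
#'
#' @param t time since load application (s).
#' @param load signed constant load (N); compressive loads are negative.
#' @param params a [creep_params()] object.
#' @return Displacement (mm), same sign as the load.
#' @export
creep_displacement <- function(t, load, params) {
  load * (1 / params$k_e +
            (1 / params$k_f) * (1 - exp(-t / params$tau_f)) +
            (1 / params$k_s) * (1 - exp(-t / params$tau_s)))
}

#' Simulate a compressive creep curve
#'
#' Generates the displacement-vs-time record of a creep test at constant
#' load (default 1 h at -8 N, the protocol emulated by the package) from the
#' five-parameter viscoelastic solid model, with optional additive Gaussian
#' measurement noise.
#'
#' @param params a [creep_params()] object.
#' @param load signed constant load in newtons (default -8).
#' @param duration_s test duration (default 3600).
#' @param sampling_hz sampling rate (default 1).
#' @param noise_sd additive displacement noise SD (mm).
#' @param seed optional integer; if given, the RNG is seeded locally.
#' @return A `creep_curve`: list with `time_s`, `displacement_mm`,
#'   `applied_load_n`.
#' @export
simulate_creep_curve <- function(params, load = -8, duration_s = 3600,
                                 sampling_hz = 1, noise_sd = 0, seed = NULL) {
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_s, by = 1 / sampling_hz)
  d <- creep_displacement(t, load, params)
  if (noise_sd > 0) d <- d + rnorm(length(t), 0, noise_sd)
  structure(list(time_s = t, displacement_mm = d, applied_load_n = load),
            class = "creep_curve")
}

# Smooth taper of the hysteresis lens: 1 inside r0, 0 beyond r1 of the
# normalized primary-channel excursion, cubic smoothstep between. Keeping the
# lens out of the outer 20% of the range leaves the end-range fit windows
# exactly branch-linear.
.lens_taper <- function(r, r0 = 0.5, r1 = 0.7) {
  w <- pmin(pmax((r1 - r) / (r1 - r0), 0), 1)
  w * w * (3 - 2 * w)
}

# Unit lag shape u(phi) and the per-cycle loop area integral
# I = int cos^2(phi) E(|sin phi|) dphi, so a lens c*u(phi) added to the
# non-driver channel encloses area c * amplitude * I per cycle.
.lens_unit <- function(phi) -cos(phi) * .lens_taper(abs(sin(phi)))

.lens_area_integral <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      phi <- seq(0, 2 * pi, length.out = 200001)
      f <- cos(phi)^2 * .lens_taper(abs(sin(phi)))
      cache <<- sum((f[-1] + f[-length(f)]) / 2) * diff(phi[1:2])
    }
    cache
  }
})

#' Simulate a cyclic biomechanical trace
#'
#' Generates a 20-cycle (by default) sinusoidal test record. Axial tests are
#' load-controlled (+/- 8 N force sinusoid; displacement derived from
#' branch-wise tensile/compressive stiffnesses); torsional tests are
#' rotation-controlled (+/- 10 deg; torque derived from a single torsional
#' stiffness). Hysteresis is produced by a smooth elliptic phase-lag lens
#' confined to the inner ~70% of the primary-channel range and calibrated so
#' the enclosed loop area per cycle equals `hysteresis_area` exactly; the
#' outer 20% of the range -- where end-range stiffnesses are fitted -- stays
#' exactly branch-linear.
#'
#' @param kind `"axial"` or `"torsional"`.
#' @param properties for axial: list with `tensile_stiffness` and
#'   `compressive_stiffness` (N/mm); for torsional: list with
#'   `torsional_stiffness` (N*mm/deg).
#' @param n_cycles number of cycles (default 20).
#' @param frequency_hz cycle frequency (default 1).
#' @param sampling_hz samples per second (default 100).
#' @param hysteresis_area per-cycle loop area (N*mm for axial, N*mm*deg for
#'   torsional); must be non-negative.
#' @param noise_sd additive Gaussian noise SD on the derived channel.
#' @param amplitude driver amplitude; defaults 8 N (axial) / 10 deg
#'   (torsional).
#' @param transient list(magnitude, tau_s): optional additive exponential
#'   settling term on the derived channel, decayed by cycle 20 (default
#'   magnitude 0).
#' @param seed optional local RNG seed.
#' @return A `cyclic_trace`: list with `kind`, `time_s`, `primary`
#'   (displacement mm or rotation deg), `conjugate` (force N or torque
#'   N*mm), `frequency_hz`, `n_cycles`.
#' @export
simulate_cyclic_trace <- function(kind = c("axial", "torsional"),
                                  properties,
                                  n_cycles = 20, frequency_hz = 1,
                                  sampling_hz = 100,
                                  hysteresis_area = 0, noise_sd = 0,
                                  amplitude = NULL,
                                  transient = list(magnitude = 0, tau_s = 2),
                                  seed = NULL) {
  kind <- match.arg(kind)
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  if (hysteresis_area < 0) stop("hysteresis_area must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(amplitude)) amplitude <- if (kind == "axial") 8 else 10

  n <- round(n_cycles * sampling_hz / frequency_hz)
  t <- (seq_len(n) - 1) / sampling_hz
  phi <- 2 * pi * frequency_hz * t
  driver <- amplitude * sin(phi)
  lens_c <- if (hysteresis_area > 0) {
    hysteresis_area / (amplitude * .lens_area_integral())
  } else 0
  lens <- lens_c * .lens_unit(phi)
  settle <- transient$magnitude * exp(-t / transient$tau_s)

  if (kind == "axial") {
    kt <- properties$tensile_stiffness
    kc <- properties$compressive_stiffness
    if (kt <= 0 || kc <= 0) stop("stiffnesses must be positive", call. = FALSE)
    disp <- ifelse(driver >= 0, driver / kt, driver / kc) + lens + settle
    if (noise_sd > 0) disp <- disp + rnorm(n, 0, noise_sd)
    primary <- disp; conjugate <- driver
  } else {
    k <- properties$torsional_stiffness
    if (k <= 0) stop("torsional stiffness must be positive", call. = FALSE)
    torque <- k * driver + lens + settle
    if (noise_sd > 0) torque <- torque + rnorm(n, 0, noise_sd)
    primary <- driver; conjugate <- torque
  }
  structure(list(kind = kind, time_s = t, primary = primary,
                 conjugate = conjugate, frequency_hz = frequency_hz,
                 n_cycles = as.integer(n_cycles)),
            class = "cyclic_trace")
}

#' Simulate von Frey filament response counts
#'
#' For each filament force f, the response probability follows a logistic
#' curve in log force centered on the animal's latent withdrawal threshold,
#' p(f) = plogis(slope * log(f / threshold)), and the observed count is
#' Binomial(n_applications, p). With `deterministic = TRUE` the binomial
#' sampling is replaced by its p >= 0.5 step (all-or-none responses), which
#' makes the downstream threshold call equal the smallest filament at or
#' above the latent threshold.
#'
#' @param threshold_g latent withdrawal threshold(s) in grams; a named
#'   vector gives one row set per name (e.g. `c(left = 4, right = 6)`).
#' @param filament_forces ascending filament forces (grams).
#' @param slope logistic slope in log-force units (larger = steeper).
#' @param n_applications applications per filament (default 5).
#' @param deterministic replace binomial draws by the p >= 0.5 step.
#' @param seed optional local RNG seed.
#' @return A tibble with columns `paw`, `force_g`, `response_count`.
#' @export
simulate_filament_responses <- function(threshold_g,
                                        filament_forces = c(0.4, 0.6, 1, 1.4, 2, 4, 6, 8, 10, 15, 26),
                                        slope = 6, n_applications = 5,
                                        deterministic = FALSE, seed = NULL) {
  if (any(diff(filament_forces) <= 0)) {
    stop("filament_forces must be strictly increasing", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  paws <- names(threshold_g)
  if (is.null(paws)) paws <- if (length(threshold_g) == 2) c("left", "right") else
    paste0("paw", seq_along(threshold_g))
  out <- lapply(seq_along(threshold_g), function(i) {
    p <- plogis(slope * log(filament_forces / threshold_g[[i]]))
    counts <- if (deterministic) {
      as.integer(n_applications * (p >= 0.5))
    } else {
      rbinom(length(p), n_applications, p)
    }
    tibble::tibble(paw = paws[i], force_g = filament_forces,
                   response_count = counts)
  })
  dplyr::bind_rows(out)
}
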