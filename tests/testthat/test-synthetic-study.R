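test_that("configuration validation rejects malformed inputs", {
  expect_error(study_config(filament_forces = c(0.4, 2, 1, 26)),
               "strictly increasing")
  expect_error(study_config(filament_forces = c(0.6, 1, 26)), "0.4")
  expect_error(study_config(noise = list(ct_sd = -1)), "non-negative")
  cfg <- study_config(seed = 3)
  expect_equal(cfg$filament_forces[1], 0.4)
  expect_equal(cfg$filament_forces[length(cfg$filament_forces)], 26.0)
})

test_that("default study has 46 animals after the two exclusions", {
  ds <- generate_study(study_config(seed = 1))
  expect_equal(nrow(ds$animals), 46)
  counts <- table(ds$animals$sex, ds$animals$injury_group)
  expect_equal(as.vector(counts["male", ]), c(12, 11))
  expect_equal(as.vector(counts["female", ]), c(12, 11))
  # estrous present iff female
  expect_true(all(!is.na(ds$animals$estrous_stage[ds$animals$sex == "female"])))
  expect_true(all(is.na(ds$animals$estrous_stage[ds$animals$sex == "male"])))
  # every animal has every record type
  for (tb in c("creep_curves", "cyclic_traces", "filament_responses",
               "ct_records", "ivd_heights", "histology")) {
    expect_setequal(unique(ds[[tb]]$animal_id), ds$animals$animal_id)
  }
  # torsional and axial traces both present for everyone
  kinds <- table(ds$cyclic_traces$animal_id, ds$cyclic_traces$kind)
  expect_true(all(kinds > 0))
})

test_that("identical config and seed give identical datasets", {
  cfg <- study_config(seed = 42)
  d1 <- generate_study(cfg)
  d2 <- generate_study(cfg)
  for (tb in c("animals", "creep_curves", "cyclic_traces",
               "filament_responses", "ct_records", "ivd_heights",
               "histology", "truth")) {
    expect_identical(d1[[tb]], d2[[tb]])
  }
})

test_that("all-zero effects and noise make sham and injury indistinguishable", {
  cfg <- zero_noise(study_config(seed = 5, effects = null_effects()))
  ds <- generate_study(cfg)
  an <- ds$animals
  ref <- an$animal_id[an$sex == "male"][1]
  for (id in an$animal_id[an$sex == "male"]) {
    expect_equal(ds$creep_curves$displacement_mm[ds$creep_curves$animal_id == id],
                 ds$creep_curves$displacement_mm[ds$creep_curves$animal_id == ref])
    expect_equal(ds$filament_responses$response_count[ds$filament_responses$animal_id == id],
                 ds$filament_responses$response_count[ds$filament_responses$animal_id == ref])
    expect_equal(ds$histology$subscore[ds$histology$animal_id == id],
                 ds$histology$subscore[ds$histology$animal_id == ref])
  }
})

test_that("creep model evaluates to its closed form", {
  p <- creep_params(100, 50, 25, 10, 600)
  expect_equal(creep_displacement(0, -8, p), -8 / 100)
  # asymptote: sum of compliances
  expect_equal(creep_displacement(1e9, -8, p), -8 * (1 / 100 + 1 / 50 + 1 / 25))
  # independent term-by-term evaluation at t = 3600 s
  t <- 3600
  d_oracle <- -8 / 100 +
    (-8 / 50) * (1 - exp(-t / 10)) +
    (-8 / 25) * (1 - exp(-t / 600))
  expect_equal(creep_displacement(t, -8, p), d_oracle, tolerance = 1e-12)
  cc <- simulate_creep_curve(p, load = -8, duration_s = 3600, sampling_hz = 1)
  expect_length(cc$time_s, 3601)
  expect_equal(cc$displacement_mm[length(cc$time_s)], d_oracle, tolerance = 1e-12)
  expect_error(creep_params(-1, 50, 25, 10, 600), "positive")
})

test_that("cyclic traces have the requested geometry and loop area", {
  # counting: 20 cycles at 1 Hz, 100 Hz sampling -> 2000 samples
  tr <- simulate_cyclic_trace("torsional", list(torsional_stiffness = 2),
                              hysteresis_area = 0)
  expect_length(tr$time_s, 2000)
  expect_length(tr$primary, 2000)
  # elastic line: T = k * theta exactly, loop area 0
  expect_equal(tr$conjugate, 2 * tr$primary)
  c20 <- extract_cycle(tr, 20)
  expect_lt(loop_area(c20$primary, c20$conjugate), 1e-10)
  # requested hysteresis area recovered by the shoelace within 1%
  for (A in c(5, 30, 80)) {
    trh <- simulate_cyclic_trace("torsional", list(torsional_stiffness = 2.5),
                                 hysteresis_area = A)
    c20 <- extract_cycle(trh, 20)
    expect_equal(loop_area(c20$primary, c20$conjugate), A, tolerance = 0.01)
  }
  ax <- simulate_cyclic_trace("axial", list(tensile_stiffness = 60,
                                            compressive_stiffness = 120),
                              hysteresis_area = 0.5)
  c20 <- extract_cycle(ax, 20)
  expect_equal(loop_area(c20$primary, c20$conjugate), 0.5, tolerance = 0.01)
  expect_error(simulate_cyclic_trace("axial",
                                     list(tensile_stiffness = 60,
                                          compressive_stiffness = 120),
                                     hysteresis_area = -1), "hysteresis")
})

test_that("filament response tables follow the logistic latent model", {
  ff <- c(0.4, 0.6, 1, 1.4, 2, 4, 6, 8, 10, 15, 26)
  # saturated responder
  low <- simulate_filament_responses(c(left = 0.01), ff, slope = 50, seed = 1)
  expect_true(all(low$response_count == 5))
  # non-responder
  high <- simulate_filament_responses(c(left = 1000), ff, slope = 50, seed = 1)
  expect_true(all(high$response_count == 0))
  # step-function limit at threshold 6 g
  step <- simulate_filament_responses(c(left = 6), ff, deterministic = TRUE)
  expect_equal(step$response_count, as.integer(5 * (ff >= 6)))
  thr <- von_frey_threshold(step)
  expect_equal(thr$threshold_g, 6)
})

test_that("generator recovers the configured male threshold effect (500/group)", {
  cfg <- study_config(seed = 202)
  eff <- cfg$effects; nz <- cfg$noise
  sdl <- sqrt(nz$vf_sd_log^2 + nz$vf_week_sd_log^2)
  oracle_sham <- expected_call_oracle(log(eff$vf_baseline_g), sdl,
                                      cfg$filament_forces, eff$vf_slope)
  oracle_inj <- expected_call_oracle(log(eff$vf_baseline_g * eff$vf_injury_ratio_male),
                                     sdl, cfg$filament_forces, eff$vf_slope)
  n <- 500
  set.seed(303)
  sim_group <- function(mu) {
    vapply(seq_len(n), function(i) {
      thr <- exp(mu + rnorm(1, 0, nz$vf_sd_log) + rnorm(2, 0, nz$vf_week_sd_log))
      tab <- simulate_filament_responses(c(left = thr[1], right = thr[2]),
                                         cfg$filament_forces, slope = eff$vf_slope)
      mean(von_frey_threshold(tab)$threshold_g)
    }, numeric(1))
  }
  sham <- sim_group(log(eff$vf_baseline_g))
  inj <- sim_group(log(eff$vf_baseline_g * eff$vf_injury_ratio_male))
  diff_sim <- mean(sham) - mean(inj)
  diff_oracle <- oracle_sham - oracle_inj
  se <- sqrt(var(sham) / n + var(inj) / n)
  expect_gt(diff_sim, 0)
  expect_lt(abs(diff_sim - diff_oracle), 3 * se)
})
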