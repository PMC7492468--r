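#' Shoelace area of a sampled closed loop
#'
#' Orientation-independent polygon area of a sampled hysteresis loop; the
#' loop is closed virtually if the first and last samples differ.
#'
#' @param x_channel,y_channel numeric vectors of equal length (>= 3 points).
#' @return The absolute enclosed area.
#' @examples
#' loop_area(c(0, 1, 1, 0), c(0, 0, 1, 1))  # unit square -> 1
#' @export
loop_area <- function(x_channel, y_channel) {
  if (length(x_channel) != length(y_channel)) {
    stop("channels must have equal length", call. = FALSE)
  }
  if (length(x_channel) < 3) stop("need at least 3 points", call. = FALSE)
  x <- c(x_channel, x_channel[1])
  y <- c(y_channel, y_channel[1])
  n <- length(x)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Extract one cycle from a cyclic trace
#'
#' Cycle boundaries are taken from the nominal frequency: cycle c covers
#' times in \[(c-1)/f, c/f). The protocol's endpoint properties are computed
#' from the 20th (last) loading cycle.
#'
#' @param trace a `cyclic_trace` (see [simulate_cyclic_trace()]).
#' @param cycle_index 1-based cycle number (default 20).
#' @return A `cyclic_trace` restricted to that cycle (`n_cycles = 1`).
#' @export
extract_cycle <- function(trace, cycle_index = 20) {
  if (cycle_index < 1 || cycle_index > trace$n_cycles) {
    stop(sprintf("cycle_index %d out of range (1..%d)",
                 cycle_index, trace$n_cycles), call. = FALSE)
  }
  f <- trace$frequency_hz
  t0 <- trace$time_s[1]
  sel <- trace$time_s - t0 >= (cycle_index - 1) / f &
    trace$time_s - t0 < cycle_index / f
  structure(list(kind = trace$kind, time_s = trace$time_s[sel],
                 primary = trace$primary[sel], conjugate = trace$conjugate[sel],
                 frequency_hz = f, n_cycles = 1L),
            class = "cyclic_trace")
}

# Loading-branch mask: samples whose primary channel is moving away from
# zero toward the requested extreme (sign of a central-difference slope).
.branch_slope <- function(x) {
  n <- length(x)
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
}

.window_fit <- function(x, y, sel, what) {
  if (sum(sel) < 3) {
    stop(sprintf("fewer than 3 samples in the %s fit window", what),
         call. = FALSE)
  }
  unname(coef(lm(y ~ x, data = data.frame(x = x[sel], y = y[sel])))[2])
}

#' Axial properties from one force-displacement cycle
#'
#' Reduces a single axial cycle to the four endpoint measures: tensile and
#' compressive end-range stiffnesses (least-squares slope of force on
#' displacement over the loading-branch samples in the outer
#' `window_frac` of the tensile / compressive force range), axial range of
#' motion, and hysteresis (shoelace loop area).
#'
#' @param cycle a single-cycle `cyclic_trace` with `kind = "axial"`
#'   (primary = displacement mm, conjugate = force N).
#' @param window_frac fraction of the force range used for each end-range
#'   stiffness fit (default 0.2).
#' @return List with `tensile_stiffness`, `compressive_stiffness` (N/mm),
#'   `axial_ROM` (mm), `axial_hysteresis` (N*mm).
#' @export
axial_properties <- function(cycle, window_frac = 0.2) {
  x <- cycle$primary; F <- cycle$conjugate
  dx <- .branch_slope(x)
  f_max <- max(F); f_min <- min(F)
  tens_sel <- F >= (1 - window_frac) * f_max & dx > 0
  comp_sel <- F <= (1 - window_frac) * f_min & dx < 0
  list(
    tensile_stiffness = .window_fit(x, F, tens_sel, "tensile"),
    compressive_stiffness = .window_fit(x, F, comp_sel, "compressive"),
    axial_ROM = max(x) - min(x),
    axial_hysteresis = loop_area(x, F)
  )
}

#' Torsional properties from one torque-rotation cycle
#'
#' Torsional stiffness is the least-squares slope of torque on rotation over
#' the loading-branch samples in the outer `window_frac` of each rotation
#' extreme, averaged over the two directions; torque range is max - min
#' torque; hysteresis is the shoelace loop area.
#'
#' @param cycle a single-cycle `cyclic_trace` with `kind = "torsional"`
#'   (primary = rotation deg, conjugate = torque N*mm).
#' @param window_frac fraction of the rotation range per end window.
#' @return List with `torsional_stiffness` (N*mm/deg), `torque_range`
#'   (N*mm), `torsional_hysteresis` (N*mm*deg).
#' @export
torsional_properties <- function(cycle, window_frac = 0.2) {
  th <- cycle$primary; tq <- cycle$conjugate
  dth <- .branch_slope(th)
  th_max <- max(th); th_min <- min(th)
  pos_sel <- th >= (1 - window_frac) * th_max & dth > 0
  neg_sel <- th <= (1 - window_frac) * th_min & dth < 0
  k_pos <- .window_fit(th, tq, pos_sel, "positive-rotation")
  k_neg <- .window_fit(th, tq, neg_sel, "negative-rotation")
  list(
    torsional_stiffness = (k_pos + k_neg) / 2,
    torque_range = max(tq) - min(tq),
    torsional_hysteresis = loop_area(th, tq)
  )
}

#' Fit the five-parameter viscoelastic solid model to a creep curve
#'
#' Nonlinear least squares of the creep displacement model (see
#' [creep_params()]) on a recorded displacement-vs-time curve. Because the
#' model is linear in the three compliances once the two time constants are
#' fixed, initial values come from a variable-projection sweep over a
#' log-spaced grid of (tau_f, tau_s) pairs (inner linear solve per pair);
#' the best grid start is polished with Levenberg-Marquardt under positivity
#' bounds, and tau_f < tau_s is enforced by relabeling.
#'
#' @param curve a `creep_curve` (see [simulate_creep_curve()]) or any list
#'   with `time_s`, `displacement_mm`, `applied_load_n`.
#' @param init optional [creep_params()] used as an additional start.
#' @param tau_f_grid,tau_s_grid log-spaced initial time constants (s).
#' @return A `creep_fit`: list with `params` ([creep_params()] or `NULL` if
#'   all starts failed), `total_displacement` (|model displacement| at the
#'   last sample), `rmse`, and `converged` flag.
#' @export
fit_creep_model <- function(curve, init = NULL,
                            tau_f_grid = c(2, 5, 10, 30, 60),
                            tau_s_grid = c(100, 300, 600, 1200, 2400)) {
  t <- curve$time_s; d <- curve$displacement_mm; load <- curve$applied_load_n
  ok <- is.finite(t) & is.finite(d)
  t <- t[ok]; d <- d[ok]
  if (length(t) < 50) stop("creep fit needs >= 50 samples", call. = FALSE)

  starts <- expand.grid(tf = tau_f_grid, ts = tau_s_grid)
  starts <- starts[starts$tf < starts$ts, ]
  proj <- lapply(seq_len(nrow(starts)), function(i) {
    tf <- starts$tf[i]; ts <- starts$ts[i]
    B <- load * cbind(1, 1 - exp(-t / tf), 1 - exp(-t / ts))
    fit <- stats::lm.fit(B, d)
    cf <- fit$coefficients
    list(tf = tf, ts = ts, ce = cf[1], cf_ = cf[2], cs = cf[3],
         rss = sum(fit$residuals^2),
         feasible = all(is.finite(cf)) && all(cf > 0))
  })
  feas <- Filter(function(p) p$feasible, proj)
  pool <- if (length(feas)) feas else proj
  best <- pool[[which.min(vapply(pool, `[[`, numeric(1), "rss"))]]
  start_list <- list(
    list(ce = max(best$ce, 1e-6), cf_ = max(best$cf_, 1e-6),
         cs = max(best$cs, 1e-6), tf = best$tf, ts = best$ts))
  if (!is.null(init)) {
    start_list <- c(start_list, list(list(
      ce = 1 / init$k_e, cf_ = 1 / init$k_f, cs = 1 / init$k_s,
      tf = init$tau_f, ts = init$tau_s)))
  }

  best_fit <- NULL
  for (st in start_list) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        d ~ load * (ce + cf_ * (1 - exp(-t / tf)) + cs * (1 - exp(-t / ts))),
        data = list(d = d, t = t, load = load),
        start = st,
        lower = c(ce = 1e-10, cf_ = 1e-10, cs = 1e-10, tf = 1e-3, ts = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(resid(fit)^2))
    if (is.null(best_fit) || rmse < best_fit$rmse) {
      best_fit <- list(fit = fit, rmse = rmse)
    }
  }

  if (is.null(best_fit)) {
    return(structure(list(params = NULL, total_displacement = NA_real_,
                          rmse = NA_real_, converged = FALSE),
                     class = "creep_fit"))
  }
  cf <- coef(best_fit$fit)
  params <- creep_params(1 / cf[["ce"]], 1 / cf[["cf_"]], 1 / cf[["cs"]],
                         cf[["tf"]], cf[["ts"]])
  conv <- isTRUE(best_fit$fit$convInfo$isConv)
  total <- abs(creep_displacement(max(t), load, params))
  structure(list(params = params, total_displacement = total,
                 rmse = best_fit$rmse, converged = conv),
            class = "creep_fit")
}

#' @export
print.creep_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("creep fit: FAILED (no start converged)\n")
    return(invisible(x))
  }
  with(x$params, cat(sprintf(
    "creep fit: k_e=%.3g k_f=%.3g k_s=%.3g N/mm, tau_f=%.3g tau_s=%.3g s\n",
    k_e, k_f, k_s, tau_f, tau_s)))
  cat(sprintf("  total displacement %.4g mm, RMSE %.3g, converged: %s\n",
              x$total_displacement, x$rmse, x$converged))
  invisible(x)
}
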