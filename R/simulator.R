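#' Calibrate the flow-noise model from cohort-median percent changes
#'
#' The generator models pump-harmonic power as flow-independent and broadband
#' noise standard deviation as \eqn{\sigma(Q) = \sigma_b (Q/Q_{ref})^e}.  Under
#' the linearized signal chain the in-band RMS obeys
#' \deqn{RMS(Q)^2 = P_h + N (Q/Q_{ref})^{2e},}
#' with \eqn{P_h} the in-band harmonic power and \eqn{N} the in-band noise
#' power at the reference flow.  Given the target median percent changes of
#' RMS at the medium and high pump levels, the two unknowns --- the exponent
#' `e` and the baseline noise fraction `u = N / (P_h + N)` --- are solved
#' exactly (one-dimensional root find on the ratio equation).
#'
#' @param drms_medium_pct,drms_high_pct target percent change of RMS at the
#'   medium / high pump level relative to the low (baseline) level.
#' @param flows flows at the three pump levels in L/min,
#'   `c(low, medium, high)`; the low flow is the reference \eqn{Q_{ref}}.
#' @return list with `exponent` (e) and `noise_frac` (u).
#' @export
calibrate_flow_noise <- function(drms_medium_pct, drms_high_pct,
                                 flows = c(3.5, 4.0, 4.5)) {
  gm <- (1 + drms_medium_pct / 100)^2 - 1
  gh <- (1 + drms_high_pct / 100)^2 - 1
  qm <- flows[2] / flows[1]; qh <- flows[3] / flows[1]
  f <- function(x) (qh^x - 1) / (qm^x - 1) - gh / gm
  x <- stats::uniroot(f, c(1e-6, 200), tol = 1e-12)$root
  u <- gm / (qm^x - 1)
  if (u <= 0 || u > 1) stop("calibration infeasible: noise fraction outside (0, 1]")
  list(exponent = x / 2, noise_frac = u)
}

#' Calibrate the thrombosis noise gain to a target percent RMS change
#'
#' Solves the plateau broadband gain \eqn{\gamma} such that, at the
#' post-onset flow `flow_t` (the flow typically dips after anticoagulation
#' reversal), the linearized RMS exceeds its pre-onset baseline (at
#' `flow_ref`) by `drms_target_pct` percent:
#' \deqn{(1+\delta)^2 = 1 - u + u\,\phi\,(1+\gamma)^2, \quad
#'       \phi = (Q_t/Q_{ref})^{2e}.}
#'
#' @param drms_target_pct target percent RMS increase at the plateau.
#' @param noise_frac,exponent from [calibrate_flow_noise()].
#' @param flow_ref,flow_t reference (pre-onset) and post-onset flows, L/min.
#' @return the gain \eqn{\gamma} (fractional increase of the broadband noise
#'   standard deviation at plateau).
#' @export
calibrate_thrombosis_gain <- function(drms_target_pct, noise_frac, exponent,
                                      flow_ref = 3.5, flow_t = 3.3) {
  phi <- (flow_t / flow_ref)^(2 * exponent)
  rhs <- ((1 + drms_target_pct / 100)^2 - 1 + noise_frac) / (noise_frac * phi)
  if (rhs <= 0) stop("calibration infeasible")
  sqrt(rhs) - 1
}

#' Thrombosis gain profile
#'
#' Phenomenological time course of the clot-related broadband-noise gain: a
#' logistic rise that is exactly zero before `onset_s` (the profile is the
#' logistic re-normalized to start at 0 at onset), reaches half of
#' `max_gain` at `onset_s + rise_time_s`, and saturates at `max_gain`
#' (monotone non-decreasing).
#'
#' @param t time vector (s, recording clock).
#' @param onset_s onset time (anticoagulation-reversal event).
#' @param rise_time_s time from onset to half-maximum (s).
#' @param max_gain plateau gain (>= 0).
#' @return gain values, same length as `t`.
#' @export
thrombosis_gain <- function(t, onset_s, rise_time_s, max_gain) {
  tau <- t - onset_s
  L <- stats::plogis((tau - rise_time_s) * 6 / rise_time_s)
  L0 <- stats::plogis(-6)
  g <- max_gain * (L - L0) / (1 - L0)
  g[tau < 0] <- 0
  pmax(g, 0)
}

# Quadratic flow -> transmembrane pressure map fitted through the low and
# high protocol operating points: dp(Q) = a_lin Q + a_quad Q^2.
.dp_coeffs <- function(flows = c(3.5, 4.5), dps = c(12, 26)) {
  A <- rbind(c(flows[1], flows[1]^2), c(flows[2], flows[2]^2))
  ab <- solve(A, dps)
  list(a_lin = ab[1], a_quad = ab[2])
}

#' Synthetic-cohort configuration
#'
#' Assembles the generative parameters for the two-phase protocol emulation
#' and derives the calibrated quantities (flow-noise exponent, harmonic
#' amplitudes, broadband noise floor, thrombosis plateau gain, pressure
#' coefficients).  Defaults encode the study conditions: a cohort of 7
#' subjects, 1000 Hz sampling, a pump-speed sweep at flows 3.5/4.0/4.5 L/min
#' followed by anticoagulation reversal with a 60-min observation window and
#' a flow dip 3.5 -> 3.3 -> 3.2 -> 3.3 L/min; effect sizes calibrated so the
#' expected median RMS percent change is 23.1% at medium speed, 135.0% at
#' high speed, and 6.4% fifteen minutes after reversal, around a baseline
#' RMS of 0.381 g.
#'
#' @param n_subjects cohort size (default 7).
#' @param fs_hz sampling rate (default 1000; must exceed twice `f_hi_hz`).
#' @param include which protocol phases to simulate: `"both"`, `"speed"`
#'   (pump sweep only) or `"reversal"` (anticoagulation phase only).
#' @param level_duration_s duration of each pump-speed level (default 300 s).
#' @param pre_reversal_s steady-state baseline before reversal (default 300 s).
#' @param post_reversal_s observation window after reversal (default 3600 s).
#' @param rpm pump speeds at the three levels (default 2800/3300/3800 rpm;
#'   fundamental vibration frequency = rpm/60 Hz).
#' @param flow_lpm flows at the three levels (default 3.5/4.0/4.5 L/min).
#' @param flow_post flow at 0/900/1800/3600 s after reversal (default
#'   3.5/3.3/3.2/3.3 L/min), linearly interpolated.
#' @param gravity_g static gravity vector per axis in g (default c(0, 0, 1)).
#' @param harmonic_rel relative amplitudes of the pump harmonics on the
#'   gravity-aligned axis (default `c(1, 0.3, 0.15)` for harmonics 1--3).
#' @param axis_rel relative magnitude of the transverse axes --- applied to
#'   both harmonic amplitudes and the broadband noise floor (default 0.25);
#'   vibration is dominantly along the gravity-aligned mount axis, which
#'   keeps the omnidirectional norm in its linear regime.
#' @param baseline_rms_g target in-band RMS at the low level (default 0.381 g).
#' @param drms_medium_pct,drms_high_pct,drms_t15_pct calibration targets for
#'   the expected percent RMS change at medium speed, high speed and 15 min
#'   after reversal (defaults 23.1, 135.0, 6.4).
#' @param rise_time_s thrombosis-gain half-rise time (default 300 s).
#' @param lag_s delay of the pressure response behind the vibration response
#'   (default 900 s).
#' @param dp_clot_frac plateau clot contribution to the transmembrane
#'   pressure, as a fraction of the pre-reversal baseline pressure
#'   (default 0.4).
#' @param dp_noise_sd_mmHg pressure channel noise (default 0.5 mmHg).
#' @param f_lo_hz,f_hi_hz passband assumed when calibrating the in-band noise
#'   fraction (defaults 10 and 375 Hz).
#' @param sdlog_harmonics,sdlog_noise,sdlog_gain between-subject log-normal
#'   spreads (sdlog) on harmonic amplitudes, noise floor and thrombosis gain
#'   (defaults 0.15, 0.15, 0.2).
#' @param drift_amp_g,drift_hz optional sub-passband drift component
#'   (default amplitude 0).
#' @param mains_amp_g,mains_hz optional mains-interference tone (default
#'   amplitude 0).
#' @param aux_rate_hz sampling rate of the sparse trend channels (default 1).
#' @param seed master seed; per-subject sub-seeds are derived as
#'   `seed + 1009 * subject_index`.
#' @return object of class `sim_config` (a list; derived block under
#'   `$derived`).
#' @export
sim_config <- function(n_subjects = 7, fs_hz = 1000,
                       include = c("both", "speed", "reversal"),
                       level_duration_s = 300, pre_reversal_s = 300,
                       post_reversal_s = 3600,
                       rpm = c(low = 2800, medium = 3300, high = 3800),
                       flow_lpm = c(low = 3.5, medium = 4.0, high = 4.5),
                       flow_post = c(t0 = 3.5, t15 = 3.3, t30 = 3.2, t60 = 3.3),
                       gravity_g = c(0, 0, 1),
                       harmonic_rel = c(1, 0.3, 0.15),
                       axis_rel = 0.25,
                       baseline_rms_g = 0.381,
                       drms_medium_pct = 23.1, drms_high_pct = 135.0,
                       drms_t15_pct = 6.4,
                       rise_time_s = 300, lag_s = 900,
                       dp_clot_frac = 0.4, dp_noise_sd_mmHg = 0.5,
                       f_lo_hz = 10, f_hi_hz = 375,
                       sdlog_harmonics = 0.15, sdlog_noise = 0.15,
                       sdlog_gain = 0.2,
                       drift_amp_g = 0, drift_hz = 0.5,
                       mains_amp_g = 0, mains_hz = 50,
                       aux_rate_hz = 1, seed = 1L) {
  include <- match.arg(include)
  if (fs_hz <= 2 * f_hi_hz)
    stop("fs_hz must exceed twice f_hi_hz (Nyquist)")
  f0_max <- max(rpm) / 60 * length(harmonic_rel)
  if (f0_max >= fs_hz / 2)
    stop("Nyquist violation: highest requested pump harmonic (", f0_max,
         " Hz) reaches fs/2")
  cal <- calibrate_flow_noise(drms_medium_pct, drms_high_pct, unname(flow_lpm))
  band_frac <- (f_hi_hz - f_lo_hz) / (fs_hz / 2)   # in-band share of white noise
  p_total <- baseline_rms_g^2
  p_harm <- (1 - cal$noise_frac) * p_total         # in-band harmonic power (gravity axis)
  n_band <- cal$noise_frac * p_total               # in-band noise power at Q_ref
  amp1 <- sqrt(2 * p_harm / sum(harmonic_rel^2))
  amplitudes <- amp1 * harmonic_rel                # gravity-axis harmonic amplitudes, g
  sigma_b <- sqrt(n_band / band_frac)              # white-noise sd per axis, g
  max_gain <- calibrate_thrombosis_gain(drms_t15_pct, cal$noise_frac,
                                        cal$exponent,
                                        flow_ref = unname(flow_lpm[1]),
                                        flow_t = unname(flow_post[2]))
  cfg <- list(n_subjects = as.integer(n_subjects), fs_hz = fs_hz,
              include = include,
              level_duration_s = level_duration_s,
              pre_reversal_s = pre_reversal_s,
              post_reversal_s = post_reversal_s,
              rpm = rpm, flow_lpm = flow_lpm, flow_post = flow_post,
              gravity_g = gravity_g, harmonic_rel = harmonic_rel,
              axis_rel = axis_rel, baseline_rms_g = baseline_rms_g,
              drms_medium_pct = drms_medium_pct,
              drms_high_pct = drms_high_pct, drms_t15_pct = drms_t15_pct,
              rise_time_s = rise_time_s, lag_s = lag_s,
              dp_clot_frac = dp_clot_frac,
              dp_noise_sd_mmHg = dp_noise_sd_mmHg,
              f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz,
              sdlog_harmonics = sdlog_harmonics, sdlog_noise = sdlog_noise,
              sdlog_gain = sdlog_gain,
              drift_amp_g = drift_amp_g, drift_hz = drift_hz,
              mains_amp_g = mains_amp_g, mains_hz = mains_hz,
              aux_rate_hz = aux_rate_hz, seed = as.integer(seed),
              derived = c(cal, list(band_frac = band_frac,
                                    harmonic_power = p_harm,
                                    noise_power_inband = n_band,
                                    amplitudes_g = amplitudes,
                                    sigma_broadband_g = sigma_b,
                                    max_gain = max_gain,
                                    dp = .dp_coeffs(unname(flow_lpm[c(1, 3)])))))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config: %d subjects, fs %g Hz, phases '%s', seed %d>\n",
              x$n_subjects, x$fs_hz, x$include, x$seed))
  d <- x$derived
  cat(sprintf("  calibration: exponent e=%.3f, noise_frac u=%.4f, max_gain=%.3f\n",
              d$exponent, d$noise_frac, d$max_gain))
  cat(sprintf("  amplitudes (g): %s; sigma_b=%.4f g\n",
              paste(signif(d$amplitudes_g, 3), collapse = ", "),
              d$sigma_broadband_g))
  invisible(x)
}

#' Protocol timeline implied by a simulator configuration
#'
#' @param config a [sim_config].
#' @return list with the [protocol_timeline], total `duration_s`, the
#'   reversal time `reversal_s` (`NA` when the reversal phase is not
#'   simulated) and the phase-boundary table used by the generator.
#' @export
sim_timeline <- function(config) {
  L <- config$level_duration_s
  ev_t <- numeric(0); ev_l <- character(0)
  t <- 0
  if (config$include %in% c("both", "speed")) {
    ev_t <- c(ev_t, 0, L, 2 * L); ev_l <- c(ev_l, "baseline_start",
                                            "pump_medium", "pump_high")
    t <- 3 * L
  }
  reversal_s <- NA_real_
  if (config$include %in% c("both", "reversal")) {
    ev_t <- c(ev_t, t); ev_l <- c(ev_l, "reversal_baseline")
    reversal_s <- t + config$pre_reversal_s
    ev_t <- c(ev_t, reversal_s); ev_l <- c(ev_l, "reversal")
    for (tp in c(t15 = 900, t30 = 1800, t60 = 3600)) {
      if (tp <= config$post_reversal_s) {
        ev_t <- c(ev_t, reversal_s + tp)
        ev_l <- c(ev_l, names(c(t15 = 900, t30 = 1800, t60 = 3600))[
          c(900, 1800, 3600) == tp])
      }
    }
    t <- reversal_s + config$post_reversal_s
  }
  if (t > ev_t[length(ev_t)]) {        # omit "end" if a timepoint closes it
    ev_t <- c(ev_t, t); ev_l <- c(ev_l, "end")
  }
  list(timeline = protocol_timeline(ev_t, ev_l), duration_s = t,
       reversal_s = reversal_s)
}

# Per-sample flow (L/min), rpm and thrombosis gain over the protocol.
.protocol_tracks <- function(config, t) {
  tl <- sim_timeline(config)
  L <- config$level_duration_s
  flow <- rep(unname(config$flow_lpm[1]), length(t))
  rpm <- rep(unname(config$rpm[1]), length(t))
  if (config$include %in% c("both", "speed")) {
    med <- t >= L & t < 2 * L
    high <- t >= 2 * L & t < 3 * L
    flow[med] <- unname(config$flow_lpm[2]); rpm[med] <- unname(config$rpm[2])
    flow[high] <- unname(config$flow_lpm[3]); rpm[high] <- unname(config$rpm[3])
  }
  gain <- numeric(length(t))
  burden <- numeric(length(t))
  if (!is.na(tl$reversal_s)) {
    tau <- t - tl$reversal_s
    post <- tau >= 0
    fp <- stats::approx(x = c(0, 900, 1800, 3600),
                        y = unname(config$flow_post),
                        xout = pmin(tau[post], 3600), rule = 2)$y
    flow[post] <- fp
    gain <- thrombosis_gain(t, tl$reversal_s, config$rise_time_s,
                            config$derived$max_gain)
    burden <- thrombosis_gain(t, tl$reversal_s + config$lag_s,
                              config$rise_time_s, 1)
  }
  list(flow = flow, rpm = rpm, gain = gain, burden = burden,
       reversal_s = tl$reversal_s, duration_s = tl$duration_s,
       timeline = tl$timeline)
}

# Default per-subject draw: multiplicative log-normal spreads and random
# harmonic phases.  Sub-seed rule: master seed + 1009 * subject index.
.draw_subject <- function(config, i) {
  sub_seed <- config$seed + 1009L * i
  set.seed(sub_seed)
  nh <- length(config$harmonic_rel)
  list(subject_id = sprintf("subj%02d", i),
       sub_seed = sub_seed,
       s_harm = stats::rlnorm(1, 0, config$sdlog_harmonics),
       s_noise = stats::rlnorm(1, 0, config$sdlog_noise),
       s_gain = stats::rlnorm(1, 0, config$sdlog_gain),
       # one phase per harmonic, shared across axes (coherent rigid mount)
       phases = stats::runif(nh, 0, 2 * pi),
       hr_base = stats::rnorm(1, 85, 8),
       map_base = stats::rnorm(1, 75, 5),
       cvp_base = stats::rnorm(1, 6.5, 1.5),
       mpap_base = stats::rnorm(1, 20, 1.5),
       act_scale = stats::rlnorm(1, 0, 0.05))
}

# Linearized expected in-band RMS for a subject at flow Q and gain g.
.expected_rms <- function(config, subj, flow, gain) {
  d <- config$derived
  P <- subj$s_harm^2 * d$harmonic_power
  N <- subj$s_noise^2 * d$noise_power_inband *
    (flow / unname(config$flow_lpm[1]))^(2 * d$exponent) * (1 + gain)^2
  sqrt(P + N)
}

#' Simulate one subject's recording
#'
#' Generates a triaxial accelerometer recording following the two-phase
#' protocol: per axis a static gravity offset, pump harmonics whose
#' fundamental `rpm/60` Hz steps with the pump level (phase-continuous
#' across steps), and white Gaussian broadband noise whose standard
#' deviation scales as \eqn{(Q/Q_{ref})^e} with flow and is multiplied by
#' `1 + gain(t)` after the anticoagulation-reversal onset.  Sparse 1-Hz
#' trend channels are attached: transmembrane pressure (quadratic in flow
#' plus a clot term lagged by `lag_s`), ECMO flow, heart rate, arterial /
#' venous / pulmonary pressures, oxygen saturation and ACT.
#'
#' @param config a [sim_config].
#' @param subject subject index (used for the sub-seed) or a pre-drawn
#'   subject parameter list from a previous call (field `params` of the
#'   result).
#' @return list with `recording` ([accel_recording]), `timeline`
#'   ([protocol_timeline]), `params` (drawn subject parameters) and `truth`
#'   (injected expected RMS / percent-change values from the linearized
#'   model).
#' @export
simulate_recording <- function(config, subject = 1L) {
  stopifnot(inherits(config, "sim_config"))
  subj <- if (is.list(subject)) subject else .draw_subject(config, subject)
  fs <- config$fs_hz
  tli <- sim_timeline(config)
  n <- as.integer(round(tli$duration_s * fs))
  d <- config$derived

  # flow, pump speed and thrombosis gain vary on the seconds scale; evaluate
  # them on a 0.1-s grid and expand to the sample clock
  step <- 0.1
  per <- as.integer(round(step * fs))
  tc <- seq(0, by = step, length.out = ceiling(n / per))
  trc <- .protocol_tracks(config, tc)
  expand <- function(v) rep(v, each = per)[seq_len(n)]
  tr <- list(reversal_s = trc$reversal_s, duration_s = trc$duration_s,
             timeline = trc$timeline)
  t <- (seq_len(n) - 1) / fs

  set.seed(subj$sub_seed + 499L)       # noise stream, distinct from the draw
  theta <- if (length(unique(trc$rpm)) == 1L) {
    2 * pi * (trc$rpm[1] / 60) * t
  } else {
    2 * pi * cumsum(expand(trc$rpm) / 60) / fs  # phase-continuous across steps
  }
  amps <- subj$s_harm * d$amplitudes_g
  sigma <- expand(subj$s_noise * d$sigma_broadband_g *
                    (trc$flow / unname(config$flow_lpm[1]))^d$exponent *
                    (1 + subj$s_gain * trc$gain))
  harm <- 0
  for (k in seq_along(amps))
    harm <- harm + amps[k] * sin(k * theta + subj$phases[k])
  if (config$drift_amp_g > 0)
    harm <- harm + config$drift_amp_g * sin(2 * pi * config$drift_hz * t)
  if (config$mains_amp_g > 0)
    harm <- harm + config$mains_amp_g * sin(2 * pi * config$mains_hz * t)
  axes <- list(x = NULL, y = NULL, z = NULL)
  rel <- c(x = config$axis_rel, y = config$axis_rel, z = 1)
  for (a in names(axes)) {
    # vibration (harmonics and broadband floor alike) is dominantly along
    # the mount axis; transverse axes are scaled by axis_rel
    axes[[a]] <- config$gravity_g[match(a, c("x", "y", "z"))] +
      rel[[a]] * (harm + stats::rnorm(n) * sigma)
  }

  # sparse trend channels on a coarse clock
  ta <- seq(0, tr$duration_s - 1 / config$aux_rate_hz,
            by = 1 / config$aux_rate_hz)
  tra <- .protocol_tracks(config, ta)
  dp_base <- d$dp$a_lin * tra$flow + d$dp$a_quad * tra$flow^2
  dp_ref <- d$dp$a_lin * unname(config$flow_lpm[1]) +
    d$dp$a_quad * unname(config$flow_lpm[1])^2
  dp <- dp_base + config$dp_clot_frac * dp_ref * tra$burden +
    stats::rnorm(length(ta), 0, config$dp_noise_sd_mmHg)
  flow_ch <- tra$flow + stats::rnorm(length(ta), 0, 0.02)
  post_tau <- if (is.na(tra$reversal_s)) rep(-1, length(ta)) else ta - tra$reversal_s
  hr <- subj$hr_base + 8 * (tra$rpm > unname(config$rpm[1])) +
    13 * pmax(0, (post_tau - 1800) / 1800) + stats::rnorm(length(ta), 0, 2)
  map <- subj$map_base - 1.5 * pmin(1, pmax(0, post_tau / 900)) +
    stats::rnorm(length(ta), 0, 1.5)
  cvp <- subj$cvp_base + stats::rnorm(length(ta), 0, 0.7)
  mpap <- subj$mpap_base + stats::rnorm(length(ta), 0, 0.7)
  spo2 <- pmin(100, 100 - abs(stats::rnorm(length(ta), 0, 0.4)))
  act <- subj$act_scale * if (is.na(tra$reversal_s)) rep(232, length(ta)) else
    stats::approx(x = c(-1e9, 0, 900, 1800, 3600, 1e9),
                  y = c(220, 220, 175, 125, 117, 117),
                  xout = post_tau)$y
  sparse <- function(v) data.frame(time_s = ta, value = v)
  rec <- accel_recording(fs, axes$x, axes$y, axes$z,
                         aux = list(delta_p_oxy = sparse(dp),
                                    ecmo_flow = sparse(flow_ch),
                                    heart_rate = sparse(hr),
                                    map = sparse(map),
                                    cvp = sparse(cvp),
                                    mpap = sparse(mpap),
                                    spo2 = sparse(spo2),
                                    act_s = sparse(act)),
                         subject_id = subj$subject_id)

  q1 <- unname(config$flow_lpm[1])
  truth <- list(
    rms_low = .expected_rms(config, subj, q1, 0),
    rms_medium = .expected_rms(config, subj, unname(config$flow_lpm[2]), 0),
    rms_high = .expected_rms(config, subj, unname(config$flow_lpm[3]), 0),
    rms_t15 = .expected_rms(config, subj, unname(config$flow_post[2]),
                            subj$s_gain * d$max_gain))
  if (truth$rms_low > 0) {
    truth$drms_medium_pct <- percent_change(truth$rms_low, truth$rms_medium)
    truth$drms_high_pct <- percent_change(truth$rms_low, truth$rms_high)
    truth$drms_t15_pct <- percent_change(truth$rms_low, truth$rms_t15)
  } else {
    truth[c("drms_medium_pct", "drms_high_pct", "drms_t15_pct")] <- NA_real_
  }
  list(recording = rec, timeline = tr$timeline, params = subj, truth = truth)
}

#' Simulate a cohort
#'
#' Draws per-subject parameters from the between-subject log-normal spreads
#' (deterministic sub-seeds `seed + 1009 * i`), simulates each recording,
#' and either returns everything in memory or writes the per-subject
#' recording / timeline CSVs, a manifest and a ground-truth file to `dir`.
#'
#' @param config a [sim_config].
#' @param dir output directory, or `NULL` (default) for in-memory results.
#' @return list with `subjects` (per-subject results of
#'   [simulate_recording()]), `manifest` (a [cohort_manifest] when `dir` is
#'   given, else `NULL`), `truth` (per-subject drawn parameters and injected
#'   expected values plus the calibration block) and `config`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- vector("list", config$n_subjects)
  truth <- list(calibration = config$derived[c("exponent", "noise_frac",
                                               "max_gain")],
                targets = list(drms_medium_pct = config$drms_medium_pct,
                               drms_high_pct = config$drms_high_pct,
                               drms_t15_pct = config$drms_t15_pct),
                subjects = list())
  entries <- NULL
  for (i in seq_len(config$n_subjects)) {
    res <- simulate_recording(config, i)
    subjects[[i]] <- res
    truth$subjects[[res$params$subject_id]] <-
      c(res$params[c("subject_id", "sub_seed", "s_harm", "s_noise", "s_gain")],
        res$truth)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      rp <- file.path(dir, paste0(res$params$subject_id, "_recording.csv"))
      tp <- file.path(dir, paste0(res$params$subject_id, "_timeline.csv"))
      write_recording(res$recording, rp)
      write_timeline(res$timeline, tp)
      entries <- rbind(entries,
                       data.frame(subject_id = res$params$subject_id,
                                  recording_path = basename(rp),
                                  timeline_path = basename(tp)))
    }
  }
  manifest <- NULL
  if (!is.null(dir)) {
    manifest <- cohort_manifest(entries$subject_id,
                                file.path(dir, entries$recording_path),
                                file.path(dir, entries$timeline_path))
    mf <- data.table::as.data.table(entries)
    data.table::fwrite(mf, file.path(dir, "manifest.csv"), sep = ",")
    yaml::write_yaml(truth, file.path(dir, "ground_truth.txt"))
  }
  list(subjects = subjects, manifest = manifest, truth = truth,
       config = config)
}

#' Detection lead time of vibration over transmembrane pressure
#'
#' Finds, for the vibration RMS series and the pressure channel of one
#' subject, the first 30-s window whose value exceeds the pre-onset baseline
#' (median of all complete windows before `onset_s`) by a fractional
#' threshold, and reports the lead of the vibration crossing over the
#' pressure crossing.  The sparse pressure channel is aggregated to the same
#' windows (mean of samples per window) before thresholding.
#'
#' @param rms an `rms_series` from [process_recording()].
#' @param dp pressure channel: a `data.frame(time_s, value)` (sparse) or a
#'   full-rate numeric vector with attribute-free sampling implied by `fs`.
#' @param onset_s onset (reversal) time on the recording clock; at least one
#'   complete window must precede it.
#' @param baseline_from_s start of the pre-onset steady-state period used for
#'   the baseline (default 0; set to the start of the pre-reversal phase when
#'   earlier protocol phases -- e.g. the pump-speed sweep -- precede it).
#' @param threshold_frac fractional increase over baseline that counts as a
#'   crossing for the vibration series (default 0.03).
#' @param dp_threshold_frac same for the pressure series (default: matched,
#'   i.e. equal to `threshold_frac`).
#' @param fs sampling rate of `dp` when it is a plain vector.
#' @return list with `t_rms_cross`, `t_dp_cross` (window start times,
#'   `NA_real_` when the series never crosses), `lead_s`
#'   (`t_dp_cross - t_rms_cross`; positive = vibration leads; `NA` if either
#'   crossing is absent), `crossed_rms`, `crossed_dp`, and the baseline
#'   levels used.
#' @export
detection_lead_time <- function(rms, dp, onset_s, threshold_frac = 0.03,
                                dp_threshold_frac = threshold_frac,
                                baseline_from_s = 0, fs = NULL) {
  stopifnot(inherits(rms, "rms_series"))
  w <- rms$window_s
  starts <- rms$window_start_s
  pre <- starts + w <= onset_s & starts >= baseline_from_s
  if (!any(pre)) stop("no pre-reversal baseline windows")
  if (is.data.frame(dp)) {
    idx <- findInterval(dp$time_s, c(starts, starts[length(starts)] + w))
    ok <- idx >= 1 & idx <= length(starts)
    dpw <- vapply(seq_along(starts),
                  function(i) mean(dp$value[ok & idx == i]), numeric(1))
  } else {
    if (is.null(fs)) stop("fs required for a full-rate pressure vector")
    dpw <- vapply(seq_along(starts), function(i) {
      i0 <- (i - 1) * round(w * fs); mean(dp[(i0 + 1):min(length(dp), i0 + round(w * fs))])
    }, numeric(1))
  }
  base_rms <- stats::median(rms$values[pre])
  base_dp <- stats::median(dpw[pre], na.rm = TRUE)
  post <- which(starts >= onset_s)
  first_cross <- function(vals, base, thr) {
    hit <- post[which(vals[post] > base * (1 + thr))]
    if (length(hit)) starts[hit[1]] else NA_real_
  }
  t_rms <- first_cross(rms$values, base_rms, threshold_frac)
  t_dp <- first_cross(dpw, base_dp, dp_threshold_frac)
  list(t_rms_cross = t_rms, t_dp_cross = t_dp,
       lead_s = if (is.na(t_rms) || is.na(t_dp)) NA_real_ else t_dp - t_rms,
       crossed_rms = !is.na(t_rms), crossed_dp = !is.na(t_dp),
       baseline_rms = base_rms, baseline_dp = base_dp)
}
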