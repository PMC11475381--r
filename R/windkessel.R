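#' Perfusion targets and total coronary resistance
#'
#' The total resistance of each coronary side is `Rcor = MAP / Qcor` with
#' the mean arterial pressure `MAP = (2 x diastolic + systolic) / 3` of an
#' idealised 80/120 mmHg subject.  `Qcor` defaults emulate hyperaemic mean
#' inflows (cFFR, like invasive FFR, is defined at maximal vasodilation):
#' 2.5 cm^3/s for the left and 1.2 cm^3/s for the right coronary tree.
#'
#' @param diastolic,systolic pressures in mmHg.
#' @param Qcor_left,Qcor_right mean coronary inflow per side, cm^3/s.
#' @return an object of class `perfusion_targets` with `MAP` (mmHg).
#' @export
perfusion_targets <- function(diastolic = 80, systolic = 120,
                              Qcor_left = 2.5, Qcor_right = 1.2) {
  stopifnot(diastolic > 0, systolic >= diastolic)
  structure(list(diastolic = diastolic, systolic = systolic,
                 MAP = (2 * diastolic + systolic) / 3,
                 Qcor_left = Qcor_left, Qcor_right = Qcor_right),
            class = "perfusion_targets")
}

#' Total coronary resistance of one side
#'
#' @param targets a [perfusion_targets()].
#' @param side `"left"` or `"right"`.
#' @return resistance in dyn s/cm^5 (CGS; mmHg converted at 1333.22).
#' @export
total_resistance <- function(targets, side = c("left", "right")) {
  side <- match.arg(side)
  Q <- if (side == "left") targets$Qcor_left else targets$Qcor_right
  if (Q <= 0) stop("coronary inflow must be positive")
  mmHg_to_dyn(targets$MAP) / Q
}

#' Distribute terminal resistance and compliance (Murray's power law)
#'
#' Terminal flow fractions follow a variant of Murray's law with power
#' 2.27: `f_i = r_i^2.27 / sum(r_j^2.27)` over the terminal reference
#' radii.  Each terminal's total bed resistance is `RTf_i = Rcor / f_i`;
#' the characteristic impedance is `R1 = rho c0 / A0_end`, and the
#' remainder is split `R2 = 0.79 (RTf - R1)`, `R3 = 0.21 (RTf - R1)`
#' between the arterial and venous micro-circulation, so `R1+R2+R3 = RTf`.
#' Bed compliances are distributed over terminals proportionally to the
#' same flow fractions.
#'
#' @param mesh a [mesh1d()] (one coronary side).
#' @param Rcor total side resistance, dyn s/cm^5.
#' @param power Murray exponent (default 2.27).
#' @param blood a [blood_properties()].
#' @param wall a [wall_law()].
#' @param C1_total,C2_total total arterial / intramyocardial bed
#'   compliance of the side, cm^5/dyn.
#' @param Pven venous pressure, mmHg (default 5).
#' @param PLV scaled ventricular pressure waveform: a function of time
#'   returning dyn/cm^2 (default constant 0, i.e. no external compression).
#' @return list of `windkessel_bed` objects, one per terminal vessel, each
#'   with `vessel`, `R1`, `R2`, `R3`, `C1`, `C2`, `RTf`, `Pven` (dyn/cm^2),
#'   `PLV`, `A0_end`, `fraction`.
#' @export
distribute_terminals <- function(mesh, Rcor, power = 2.27,
                                 blood = blood_properties(),
                                 wall = wall_law(),
                                 C1_total = 5e-7, C2_total = 5e-6,
                                 Pven = 5, PLV = NULL) {
  stopifnot(inherits(mesh, "mesh1d"), Rcor > 0)
  term <- which(vapply(mesh$vessels, `[[`, logical(1), "terminal"))
  if (!length(term)) stop("mesh has no terminal vessel")
  r_end <- vapply(term, function(i) {
    r <- mesh$vessels[[i]]$r0
    r[length(r)]
  }, numeric(1))
  f <- r_end^power / sum(r_end^power)
  if (is.null(PLV)) PLV <- function(t) 0 * t
  beds <- vector("list", length(term))
  for (k in seq_along(term)) {
    A0_end <- pi * r_end[k]^2
    c0 <- wave_speed(r_end[k], blood, wall)
    RTf <- Rcor / f[k]
    R1 <- blood$rho * c0 / A0_end
    if (RTf <= R1)
      stop(sprintf(paste0("characteristic impedance exceeds bed resistance at ",
                          "terminal %s (R1 = %.3g, RTf = %.3g): unphysical ",
                          "geometry/flow combination"),
                   mesh$vessels[[term[k]]]$id, R1, RTf))
    beds[[k]] <- structure(list(
      vessel = term[k], fraction = f[k], A0_end = A0_end,
      RTf = RTf, R1 = R1, R2 = 0.79 * (RTf - R1), R3 = 0.21 * (RTf - R1),
      C1 = C1_total * f[k], C2 = C2_total * f[k],
      Pven = mmHg_to_dyn(Pven), PLV = PLV), class = "windkessel_bed")
  }
  beds
}

#' Explicit coronary Windkessel bed
#'
#' Direct constructor for a single terminal bed, used when the resistances
#' and compliances are specified rather than distributed by Murray's law.
#'
#' @param vessel terminal vessel index in the mesh.
#' @param R1,R2,R3 resistances in dyn s/cm^5.
#' @param C1,C2 compliances in cm^5/dyn.
#' @param Pven venous pressure in mmHg.
#' @param PLV scaled ventricular pressure waveform, function of time
#'   returning dyn/cm^2.
#' @param fraction Murray flow fraction (1 for a single terminal).
#' @return a `windkessel_bed`.
#' @export
windkessel_bed <- function(vessel, R1, R2, R3, C1 = 5e-7, C2 = 5e-6,
                           Pven = 5, PLV = NULL, fraction = 1) {
  stopifnot(R1 > 0, R2 > 0, R3 > 0, C1 > 0, C2 > 0)
  if (is.null(PLV)) PLV <- function(t) 0 * t
  structure(list(vessel = vessel, fraction = fraction,
                 A0_end = NA_real_, RTf = R1 + R2 + R3,
                 R1 = R1, R2 = R2, R3 = R3, C1 = C1, C2 = C2,
                 Pven = mmHg_to_dyn(Pven), PLV = PLV),
            class = "windkessel_bed")
}

#' @export
print.windkessel_bed <- function(x, ...) {
  cat(sprintf("<windkessel_bed> vessel %d: RTf %.3g (R1 %.3g, R2 %.3g, R3 %.3g) dyn s/cm^5, C1 %.2g, C2 %.2g cm^5/dyn\n",
              x$vessel, x$RTf, x$R1, x$R2, x$R3, x$C1, x$C2))
  invisible(x)
}

#' One implicit time step of a coronary Windkessel bed
#'
#' Backward-Euler update of the two compliance states: `Pc1` at the node
#' between R1 and R2 (arterial compliance C1) and `Pc2` at the node
#' between R2 and R3 (intramyocardial compliance C2, referenced to the
#' scaled ventricular pressure `PLV(t)` as its external pressure, which
#' produces systolic impediment of coronary inflow).  With constant inflow
#' the steady state satisfies `P_in - Pven = Q (R1 + R2 + R3)`.
#'
#' @param bed a `windkessel_bed`.
#' @param state numeric `c(Pc1, Pc2)` in dyn/cm^2 (defaults to venous
#'   pressure at rest).
#' @param Q_in inflow from the 1D domain, cm^3/s.
#' @param dt time step, s.
#' @param t new time (s), used to evaluate `PLV`.
#' @param t_prev previous time (defaults to `t - dt`).
#' @return list with updated `state` and the coupling pressure
#'   `P_in = Pc1 + Q_in * R1` seen by the 1D terminal node.
#' @export
bed_step <- function(bed, state = NULL, Q_in, dt, t = 0, t_prev = t - dt) {
  stopifnot(dt > 0)
  if (is.null(state)) state <- c(bed$Pven, bed$Pven)
  dplv <- (bed$PLV(t) - bed$PLV(t_prev)) / dt
  # C1 dPc1/dt = Q_in - (Pc1 - Pc2)/R2
  # C2 dPc2/dt = C2 dPLV/dt + (Pc1 - Pc2)/R2 - (Pc2 - Pven)/R3
  a11 <- bed$C1 / dt + 1 / bed$R2
  a12 <- -1 / bed$R2
  a21 <- -1 / bed$R2
  a22 <- bed$C2 / dt + 1 / bed$R2 + 1 / bed$R3
  b1 <- bed$C1 / dt * state[1] + Q_in
  b2 <- bed$C2 / dt * state[2] + bed$C2 * dplv + bed$Pven / bed$R3
  det <- a11 * a22 - a12 * a21
  Pc1 <- (b1 * a22 - a12 * b2) / det
  Pc2 <- (a11 * b2 - a21 * b1) / det
  list(state = c(Pc1, Pc2), P_in = Pc1 + Q_in * bed$R1)
}

#' Inflow waveform
#'
#' A periodic volumetric inflow sampled as `(t, Q)` pairs over one period.
#' `Q(0)` and `Q(period)` must agree (the closing sample is appended when
#' missing).  Use [default_inflow_waveform()] for representative coronary
#' shapes.
#'
#' @param samples data frame or matrix with columns `t` (s) and `Q`
#'   (cm^3/s) covering one period.
#' @param period cycle duration in s.
#' @param side `"left"` or `"right"`.
#' @return an object of class `inflow_waveform`; callable via
#'   [inflow_function()].
#' @export
inflow_waveform <- function(samples, period, side = c("left", "right")) {
  side <- match.arg(side)
  samples <- as.data.frame(samples)
  stopifnot(all(c("t", "Q") %in% names(samples)), period > 0,
            all(is.finite(samples$Q)))
  samples <- samples[order(samples$t), ]
  if (abs(samples$t[1]) > 1e-12) stop("samples must start at t = 0")
  if (samples$t[nrow(samples)] < period) {
    samples <- rbind(samples, data.frame(t = period, Q = samples$Q[1]))
  }
  if (abs(samples$Q[nrow(samples)] - samples$Q[1]) > 1e-9 * max(abs(samples$Q)))
    stop("waveform not periodic: Q(0) != Q(period)")
  structure(list(samples = samples, period = period, side = side),
            class = "inflow_waveform")
}

#' Periodic interpolating function of an inflow waveform
#'
#' @param wf an [inflow_waveform()].
#' @return function `Q(t)` (linear interpolation, periodic extension).
#' @export
inflow_function <- function(wf) {
  stopifnot(inherits(wf, "inflow_waveform"))
  s <- wf$samples; Tp <- wf$period
  function(t) stats::approx(s$t, s$Q, xout = t %% Tp, rule = 2)$y
}

#' Representative coronary inflow waveforms
#'
#' Two-phase shapes with the configured mean flow: the left coronary
#' waveform is predominantly diastolic (flow dips during systole when
#' intramyocardial pressure compresses the septal vessels), the right is
#' more uniform over the cycle.  These are editable defaults standing in
#' for subject-specific inflow data, not measurements.
#'
#' @param side `"left"` or `"right"`.
#' @param mean_flow cycle-mean inflow, cm^3/s (defaults from
#'   [perfusion_targets()]).
#' @param period cycle duration in s.
#' @param n number of samples over one period.
#' @return an [inflow_waveform()].
#' @export
default_inflow_waveform <- function(side = c("left", "right"),
                                    mean_flow = NULL, period = 0.8, n = 81) {
  side <- match.arg(side)
  if (is.null(mean_flow)) {
    pt <- perfusion_targets()
    mean_flow <- if (side == "left") pt$Qcor_left else pt$Qcor_right
  }
  t <- seq(0, period, length.out = n)
  ts <- 0.35 * period              # systolic fraction
  phase_sys <- pmin(t / ts, 1)
  phase_dia <- pmax((t - ts) / (period - ts), 0)
  if (side == "left") {
    # systolic dip to ~40% of mean, diastolic dome to ~150%
    shape <- ifelse(t < ts,
                    1 - 0.6 * sin(pi * phase_sys),
                    1 + 0.55 * sin(pi * phase_dia))
  } else {
    shape <- ifelse(t < ts,
                    1 - 0.15 * sin(pi * phase_sys),
                    1 + 0.12 * sin(pi * phase_dia))
  }
  shape[n] <- shape[1]
  # normalise the discrete mean to the requested mean flow
  w <- rep(1, n); w[c(1, n)] <- 0.5     # trapezoid weights
  shape <- shape / (sum(shape * w) / sum(w))
  inflow_waveform(data.frame(t = t, Q = mean_flow * shape), period, side)
}

#' Default scaled ventricular pressure waveform
#'
#' A smooth systolic pressure pulse `P_sys * sin^2(pi t / Ts)` during
#' systole and zero in diastole, scaled per side (0.5 left, 0.2 right);
#' used as the external pressure of the intramyocardial compliance.  The
#' scaling is uncalibrated and configuration-exposed.
#'
#' @param side `"left"` or `"right"`.
#' @param scale multiplier applied to the ventricular pressure (defaults
#'   0.5 left, 0.2 right).
#' @param peak peak ventricular pressure in mmHg.
#' @param period cycle duration in s.
#' @param systole systolic fraction of the cycle.
#' @return function `PLV(t)` in dyn/cm^2.
#' @export
default_plv_waveform <- function(side = c("left", "right"), scale = NULL,
                                 peak = 120, period = 0.8, systole = 0.35) {
  side <- match.arg(side)
  if (is.null(scale)) scale <- if (side == "left") 0.5 else 0.2
  ts <- systole * period
  peak_dyn <- mmHg_to_dyn(peak)
  function(t) {
    tm <- t %% period
    ifelse(tm < ts, scale * peak_dyn * sin(pi * tm / ts)^2, 0)
  }
}
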