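#' Blood properties
#'
#' @param rho density in g/cm^3 (default 1.06).
#' @param mu dynamic viscosity in Poise (default 0.04).
#' @return an object of class `blood_properties`.
#' @export
blood_properties <- function(rho = 1.06, mu = 0.04) {
  stopifnot(rho > 0, mu >= 0)
  structure(list(rho = rho, mu = mu), class = "blood_properties")
}

#' Vessel wall constitutive law
#'
#' Non-linear (visco-)elastic tube law relating transmural pressure to
#' cross-sectional area,
#' \deqn{P - P_{ext} - P_0 = \frac{2\rho c_0^2}{b}\left[(A/A_0)^{b/2} - 1\right]
#'       + \frac{\Gamma}{A_0\sqrt{A_0}}\frac{\partial A}{\partial t},}
#' with the reference wave speed
#' \deqn{c_0 = \sqrt{\tfrac{2}{3\rho}\,(k_1 e^{k_2 r_0} + k_3)}.}
#' When `Pcollapse` is supplied the exponent is
#' `b = 2 rho c0^2 / (P0 - Pcollapse)` (radius-dependent); otherwise the
#' constant default `b = 2` gives the widely used square-root tube law.
#' `Gamma = 0` (purely elastic) by default: the steady pressure field that
#' determines cFFR is independent of the viscoelastic term.
#'
#' @param k1,k2,k3 wave-speed constants; `k1 = 2e7` g/(cm s^2),
#'   `k2 = -22.53` 1/cm, `k3 = 8.65e5` g/(cm s^2).
#' @param P0 reference pressure (dyn/cm^2) at which `A = A0`; default the
#'   mean arterial pressure of the idealised 80/120 mmHg subject.
#' @param Pext external pressure (dyn/cm^2).
#' @param b tube-law exponent used when `Pcollapse` is `NULL`.
#' @param Gamma viscoelastic coefficient (g/s, per `A0^{3/2}` scaling).
#' @param Pcollapse optional collapse pressure (dyn/cm^2).
#' @return an object of class `wall_law`.
#' @export
wall_law <- function(k1 = 2e7, k2 = -22.53, k3 = 8.65e5,
                     P0 = mmHg_to_dyn(280 / 3), Pext = 0,
                     b = 2, Gamma = 0, Pcollapse = NULL) {
  stopifnot(b > 0)
  structure(list(k1 = k1, k2 = k2, k3 = k3, P0 = P0, Pext = Pext,
                 b = b, Gamma = Gamma, Pcollapse = Pcollapse),
            class = "wall_law")
}

#' Reference pulse wave speed of a vessel
#'
#' @param r0 reference radius in cm.
#' @param blood a [blood_properties()].
#' @param wall a [wall_law()].
#' @return wave speed `c0` in cm/s (strictly decreasing in `r0`).
#' @export
wave_speed <- function(r0, blood = blood_properties(), wall = wall_law()) {
  stopifnot(all(r0 > 0))
  rad <- 2 / (3 * blood$rho) * (wall$k1 * exp(wall$k2 * r0) + wall$k3)
  if (any(rad <= 0))
    stop("invalid wall constants: non-positive radicand in wave speed")
  sqrt(rad)
}

# tube-law exponent at reference radius r0 (Pcollapse route or constant)
tube_exponent <- function(r0, blood, wall) {
  if (is.null(wall$Pcollapse)) return(rep(wall$b, length(r0)))
  c0 <- wave_speed(r0, blood, wall)
  bb <- 2 * blood$rho * c0^2 / (wall$P0 - wall$Pcollapse)
  if (any(bb <= 0)) stop("Pcollapse must lie below P0")
  bb
}

#' Pressure from the tube law
#'
#' @param A cross-sectional area (cm^2), must be positive.
#' @param A0 reference area (cm^2).
#' @param blood a [blood_properties()].
#' @param wall a [wall_law()].
#' @param dA_dt area rate of change (cm^2/s) for the viscoelastic term.
#' @return pressure in dyn/cm^2.
#' @export
tube_law <- function(A, A0, blood = blood_properties(), wall = wall_law(),
                     dA_dt = 0) {
  if (any(A <= 0)) stop("tube law: non-positive area")
  stopifnot(all(A0 > 0))
  r0 <- sqrt(A0 / pi)
  c0 <- wave_speed(r0, blood, wall)
  b <- tube_exponent(r0, blood, wall)
  wall$Pext + wall$P0 + 2 * blood$rho * c0^2 / b * ((A / A0)^(b / 2) - 1) +
    wall$Gamma / (A0 * sqrt(A0)) * dA_dt
}

# elastic pressure and dP/dA for solver internals (vectorised over nodes)
tube_law_terms <- function(A, A0, c0, b, rho, P0, Pext) {
  ratio <- A / A0
  p <- Pext + P0 + 2 * rho * c0^2 / b * (ratio^(b / 2) - 1)
  dpda <- rho * c0^2 / A0 * ratio^(b / 2 - 1)
  list(p = p, dpda = dpda)
}

# area from elastic pressure (inverse tube law)
tube_law_inverse <- function(P, A0, c0, b, rho, P0, Pext) {
  A0 * pmax(1 + b * (P - Pext - P0) / (2 * rho * c0^2), 1e-12)^(2 / b)
}
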