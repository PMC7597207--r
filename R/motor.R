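# Flagellar motor switching and motile output. Each flagellum is a bistable
# stochastic switch between CCW and CW rotation whose transition rates
# depend on CheY-P through a free-energy barrier; the cell-level motile
# state follows a veto rule (any CW flagellum forces a tumble), and thrust
# scales linearly with PMF and logarithmically with flagellum count.

#' Flagellar switch parameters
#'
#' Free-energy barrier model: `dG(Y) = g0/4 - (g1/2) * Y/(Y + K_M)` (kT),
#' with rates `k_plus = omega * exp(-dG)` (CCW to CW, increasing in CheY-P)
#' and `k_minus = omega * exp(+dG)` (CW to CCW, decreasing). The defaults
#' are calibrated at a baseline CheY-P of 2.5159 uM to give a mean run of
#' 1.0 s and a mean tumble of 0.7 s for a four-flagellum cell.
#'
#' @param omega Attempt frequency (1/s).
#' @param g0,g1 Free-energy coefficients (kT).
#' @param K_M CheY-P half-saturation (uM).
#' @return Parameter list.
#' @export
switch_params <- function(omega = 0.6633, g0 = 40, g1 = 40, K_M = 3.06) {
  list(omega = omega, g0 = g0, g1 = g1, K_M = K_M)
}

#' CCW->CW and CW->CCW switching rates at a CheY-P level
#'
#' @param cheY_P CheY-P concentration (uM).
#' @param params A [switch_params()].
#' @return c(k_plus, k_minus) in 1/s.
#' @export
switch_rates <- function(cheY_P, params = switch_params()) {
  dg <- params$g0 / 4 - (params$g1 / 2) * cheY_P / (cheY_P + params$K_M)
  c(k_plus = params$omega * exp(-dg), k_minus = params$omega * exp(dg))
}

#' Advance one flagellum's rotational state by one time-step
#'
#' Two-state Markov switch with per-step transition probability `rate * dt`.
#' The chemotaxis chain needs `dt <= 0.01 s` to track the environment; a
#' larger step is a configuration error.
#'
#' @param rotation Current state: `"CCW"` or `"CW"`.
#' @param cheY_P CheY-P concentration (uM).
#' @param dt Time-step (s, <= 0.01).
#' @param params A [switch_params()].
#' @return New rotation state.
#' @export
flagellum_switch_step <- function(rotation, cheY_P, dt,
                                  params = switch_params()) {
  if (dt > 0.01 + 1e-12) {
    stop("flagellar switching requires dt <= 0.01 s")
  }
  k <- switch_rates(cheY_P, params)
  if (rotation == "CCW") {
    if (stats::runif(1) < k[["k_plus"]] * dt) "CW" else "CCW"
  } else {
    if (stats::runif(1) < k[["k_minus"]] * dt) "CCW" else "CW"
  }
}

#' Logarithmic flagellar bundling law
#'
#' Individual contributions to propulsion diminish as flagella join the
#' bundle: `L(n) = 1 + a * ln(n)` with `a` fixed by the two calibration
#' anchors, 0.31 pN for one flagellum and 0.5 pN for four at the
#' baseline PMF.
#'
#' @param n Flagellum count (>= 1).
#' @return Multiplier of the single-flagellum thrust.
#' @export
bundling_law <- function(n) {
  a <- (0.5 / 0.31 - 1) / log(4)
  1 + a * log(n)
}

#' Aggregate motile output from flagellar states
#'
#' Veto model: with at least one flagellum all rotating CCW the cell runs;
#' any CW flagellum forces a tumble; with no flagella the cell is nonmotile.
#' Run thrust is `f0 * (|pmf| / pmf0) * L(n)` applied along the body axis at
#' the rear pole; a tumble applies the same thrust magnitude at a random
#' angle, whose off-axis lever arm reorients the cell. The returned torque is
#' the rear-pole lever-arm torque `-(len/2) * thrust * sin(angle)`.
#'
#' @param rotations Character vector of per-flagellum states ("CCW"/"CW").
#' @param pmf Proton-motive force (mV).
#' @param f0 Single-flagellum thrust at the baseline PMF (pN).
#' @param pmf0 Baseline PMF magnitude (mV).
#' @param body_length Body length (um) for the torque lever arm.
#' @param tumble_angle Optional fixed tumble angle (radians); default is a
#'   fresh uniform draw in (-pi, pi).
#' @return List: `state` ("run"/"tumble"/"nonmotile"), `thrust` (pN),
#'   `thrust_angle` (radians from the body axis), `torque` (pN um).
#' @export
motile_output <- function(rotations, pmf, f0 = 0.31, pmf0 = 140,
                          body_length = 2, tumble_angle = NULL) {
  stopifnot(is.finite(pmf))
  n <- length(rotations)
  if (n == 0) {
    return(list(state = "nonmotile", thrust = 0, thrust_angle = 0, torque = 0))
  }
  thrust <- f0 * (abs(pmf) / pmf0) * bundling_law(n)
  if (any(rotations == "CW")) {
    angle <- tumble_angle %||% stats::runif(1, -pi, pi)
    list(state = "tumble", thrust = thrust, thrust_angle = angle,
         torque = -(body_length / 2) * thrust * sin(angle))
  } else {
    list(state = "run", thrust = thrust, thrust_angle = 0, torque = 0)
  }
}

#' Analytic stationary CW fraction of the two-state switch
#'
#' For fixed CheY-P the long-run CW occupancy is
#' `k_plus / (k_plus + k_minus)`; used as the closed-form oracle for the
#' stochastic switch.
#'
#' @param cheY_P CheY-P concentration (uM).
#' @param params A [switch_params()].
#' @return Stationary CW probability.
#' @export
stationary_cw_fraction <- function(cheY_P, params = switch_params()) {
  k <- switch_rates(cheY_P, params)
  k[["k_plus"]] / (k[["k_plus"]] + k[["k_minus"]])
}
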