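# Proton-motive force: Goldman-Hodgkin-Katz membrane potential over K+, Na+
# and Cl- plus a constant pH term. Flagellar rotation moves 1200 protons per
# revolution; proton flux is assumed instantly restored by the cell's pumps,
# so the PMF is bookkept but not depleted.

#' Default ion/permeability state
#'
#' Cytoplasmic and periplasmic K+, Na+ and Cl- concentrations in the
#' physiological range, with relative permeabilities and a constant pH term
#' calibrated so that the default PMF is -134 mV.
#'
#' @param temperature Kelvin.
#' @return A `pmf_state` list with fields `inside`/`outside` (named mM),
#'   `permeability` (relative), `temperature`, `delta_pH_mV`.
#' @export
pmf_state <- function(temperature = 310) {
  structure(list(
    inside = c(K = 200, Na = 10, Cl = 10),
    outside = c(K = 5, Na = 100, Cl = 50),
    permeability = c(K = 1, Na = 0.05, Cl = 0.05),
    temperature = temperature,
    delta_pH_mV = -54.9), class = "pmf_state")
}

#' Goldman membrane potential and proton-motive force
#'
#' \deqn{V_m = \frac{RT}{F}\ln\frac{\sum_{cations} P C_{out} + \sum_{anions} P C_{in}}
#' {\sum_{cations} P C_{in} + \sum_{anions} P C_{out}}}
#'
#' PMF = membrane potential + the constant pH term.
#'
#' @param state A [pmf_state()].
#' @return List: `membrane_potential` (mV), `pmf` (mV).
#' @export
goldman_pmf <- function(state) {
  stopifnot(all(state$inside > 0), all(state$outside > 0))
  rt_f <- 1000 * 8.314462618 * state$temperature / 96485.33212  # mV
  cations <- c("K", "Na"); anions <- "Cl"
  p <- state$permeability
  num <- sum(p[cations] * state$outside[cations]) +
    sum(p[anions] * state$inside[anions])
  den <- sum(p[cations] * state$inside[cations]) +
    sum(p[anions] * state$outside[anions])
  if (den <= 0) stop("Goldman denominator is zero")
  v <- rt_f * log(num / den)
  list(membrane_potential = v, pmf = v + state$delta_pH_mV)
}

#' Protons moved by flagellar rotation
#'
#' 1200 protons cross the membrane per revolution; at the typical 100 Hz
#' this is 120,000 protons per flagellum-second. Bookkeeping only: the PMF is
#' restored instantly.
#'
#' @param revolutions Number of revolutions (may be fractional).
#' @return Protons moved.
#' @export
proton_accounting <- function(revolutions) 1200 * revolutions
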