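# Minimal agent: exponential mass growth with a mass-threshold division
# condition and phylogeny color tagging.

#' Exponential mass growth
#'
#' Cells double in mass once per doubling time:
#' `mass * 2^(dt / doubling_time)`.
#'
#' @param mass Current mass (fg).
#' @param doubling_time Doubling time (s); default 2400 s (40 min).
#' @param dt Interval (s, >= 0).
#' @return New mass (fg).
#' @export
grow_mass <- function(mass, doubling_time = 2400, dt) {
  stopifnot(dt >= 0, doubling_time > 0)
  mass * 2^(dt / doubling_time)
}

#' Mass-threshold division check
#'
#' When mass reaches the division threshold (by default double the 1000 fg
#' birth mass) a `divide` topology message is emitted; the halve divider then
#' gives each daughter half the mother's state. Each daughter's phylogeny
#' color is the mother's plus an isotropic Gaussian mutation step, applied by
#' the daughter's own growth process at instantiation.
#'
#' @param mass Current mass (fg).
#' @param threshold Division threshold (fg), default 2000.
#' @param agent_path Store path of the agent compartment.
#' @return A divide topology message, or `NULL` when below threshold.
#' @export
maybe_divide <- function(mass, threshold = 2000, agent_path) {
  # tiny relative slack so compounded per-step growth that lands on the
  # threshold analytically is not missed to floating-point drift
  if (mass >= threshold * (1 - 1e-9)) {
    list(type = "divide", path = agent_path)
  } else {
    NULL
  }
}

#' Growth/division process for one agent
#'
#' Ports: `boundary` (the agent's boundary store: `mass` in fg, divided by
#' halving; `color`, a 3-vector phylogeny tag copied to daughters after a
#' mutation step in color space).
#'
#' @param agent Agent name (process is named `"<agent>.growth"`).
#' @param agent_path Path of the agent compartment in the hierarchy.
#' @param doubling_time Doubling time (s).
#' @param threshold Division threshold (fg).
#' @param initial_mass Initial mass (fg).
#' @param color_sd Std. dev. of the per-division color mutation.
#' @param time_step Process time-step (s); division is checked once per step.
#' @return A [process()].
#' @export
growth_division_process <- function(agent, agent_path,
                                    doubling_time = 2400, threshold = 2000,
                                    initial_mass = 1000, color_sd = 0.08,
                                    time_step = 1) {
  force(agent_path)
  ports <- list(boundary = list(
    mass = var_schema(default = initial_mass, units = "fg",
                      updater = "set", divider = "halve", emit = TRUE),
    color = var_schema(default = c(0.5, 0.5, 0.5), units = "dimensionless",
                       updater = "set", divider = "copy")))
  update <- function(view, dt, params) {
    m <- grow_mass(view$boundary$mass, params$doubling_time, dt)
    upd <- list(boundary = list(mass = m))
    msg <- maybe_divide(m, params$threshold, params$agent_path)
    if (!is.null(msg)) upd$.topology <- list(msg)
    upd
  }
  process(name = paste0(agent, ".growth"), ports = ports, update = update,
          time_step = time_step,
          parameters = list(doubling_time = doubling_time,
                            threshold = threshold, agent_path = agent_path,
                            color_sd = color_sd))
}

#' Mutate a phylogeny color
#'
#' Isotropic Gaussian step in RGB color space, clamped to `[0, 1]`.
#'
#' @param color Numeric 3-vector.
#' @param sd Mutation standard deviation.
#' @return Mutated color.
#' @export
mutate_color <- function(color, sd = 0.08) {
  pmin(pmax(color + stats::rnorm(3, 0, sd), 0), 1)
}
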