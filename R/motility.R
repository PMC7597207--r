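# Trajectory analysis: segmentation of a motile-state series into runs and
# tumbles, speeds over run segments, and reorientation angles between
# consecutive runs.

#' Summarize a motility trajectory
#'
#' Segments the trajectory by motile state. The speed is the per-step
#' displacement divided by dt, averaged over run-labelled steps; run and
#' tumble durations are segment lengths times dt (the first and last,
#' possibly truncated, segments are dropped); the reorientation angle is the
#' angle between the net-displacement headings of consecutive run segments,
#' folded into [0, 180] degrees.
#'
#' @param trajectory Data frame with columns `x`, `y` (um) and `state`
#'   (1 = run, 2 = tumble, 0 = nonmotile), sampled at fixed `dt`. A step's
#'   displacement (from the previous sample) is attributed to its state
#'   label.
#' @param dt Sampling interval (s).
#' @return List of class `motility_summary`: `mean_speed` (um/s),
#'   `run_durations`, `tumble_durations` (s), `reorientation_angles`
#'   (degrees), and their means. Empty (with a warning) if there are no
#'   runs.
#' @export
summarize_motility <- function(trajectory, dt) {
  st <- trajectory$state
  n <- length(st)
  if (!any(st == 1)) {
    warning("trajectory contains no run segments")
    return(structure(list(mean_speed = NA_real_, run_durations = numeric(),
                          tumble_durations = numeric(),
                          reorientation_angles = numeric(),
                          mean_run = NA_real_, mean_tumble = NA_real_,
                          mean_reorientation = NA_real_),
                     class = "motility_summary"))
  }
  dx <- diff(trajectory$x); dy <- diff(trajectory$y)
  step_speed <- sqrt(dx^2 + dy^2) / dt
  run_steps <- st[-1] == 1
  mean_speed <- mean(step_speed[run_steps])

  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  interior <- seq_along(r$values)
  interior <- interior[interior > 1 & interior < length(r$values)]
  run_durations <- r$lengths[interior][r$values[interior] == 1] * dt
  tumble_durations <- r$lengths[interior][r$values[interior] == 2] * dt

  run_idx <- which(r$values == 1)
  headings <- vapply(run_idx, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    atan2(trajectory$y[i1] - trajectory$y[i0],
          trajectory$x[i1] - trajectory$x[i0])
  }, 0)
  angles <- numeric(0)
  if (length(headings) > 1) {
    d <- diff(headings)
    d <- (d + pi) %% (2 * pi) - pi
    angles <- abs(d) * 180 / pi
  }
  structure(list(mean_speed = mean_speed,
                 run_durations = run_durations,
                 tumble_durations = tumble_durations,
                 reorientation_angles = angles,
                 mean_run = mean(run_durations),
                 mean_tumble = mean(tumble_durations),
                 mean_reorientation = mean(angles)),
            class = "motility_summary")
}

#' Extract one agent's trajectory from an experiment result
#'
#' @param result A [run_experiment()] result.
#' @param agent Agent name (default the first).
#' @return Data frame with `time`, `x`, `y`, `state`.
#' @export
extract_trajectory <- function(result, agent = NULL) {
  em <- result$emitted
  cols <- names(em)
  if (is.null(agent)) {
    loc_cols <- grep("^agents/[^/]+/boundary/location1$", cols, value = TRUE)
    if (length(loc_cols) == 0) stop("no agent locations in emitted series")
    agent <- sub("^agents/([^/]+)/.*$", "\\1", loc_cols[1])
  }
  pref <- paste0("agents/", agent, "/boundary/")
  data.frame(time = em$time,
             x = em[[paste0(pref, "location1")]],
             y = em[[paste0(pref, "location2")]],
             state = em[[paste0(pref, "motile_state")]])
}

#' Simulate single-agent motility and summarize it
#'
#' Convenience wrapper: builds the chemotaxis composite with one
#' four-flagellum agent in a uniform attractant environment, runs it at
#' dt = 0.01 s, and summarizes the trajectory.
#'
#' @param total_time Simulated seconds (default 300).
#' @param seed RNG seed.
#' @param n_flagella Flagellum count.
#' @param ligand0 Uniform attractant concentration (mM).
#' @return List: `summary` (a `motility_summary`), `trajectory`, `result`.
#' @export
simulate_motility <- function(total_time = 300, seed = 0, n_flagella = 4,
                              ligand0 = 0.1) {
  built <- build_chemotaxis(n_agents = 1, total_time = total_time,
                            seed = seed, n_flagella = n_flagella,
                            ligand0 = ligand0)
  res <- run_built(built)
  traj <- extract_trajectory(res, "c0")
  list(summary = summarize_motility(traj, dt = 0.01), trajectory = traj,
       result = res)
}
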