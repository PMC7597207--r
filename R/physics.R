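# Overdamped rigid-body mechanics for capsule-shaped agents in a bounded 2D
# environment. At micron scale the Reynolds number is tiny, so inertia is
# irrelevant: velocity is force/damping at every instant, and thermal jitter
# enters as random forces applied at random points on the body.

#' Create a capsule agent body
#'
#' @param location Numeric (x, y) in micrometers.
#' @param orientation Heading in radians.
#' @param length,width Capsule dimensions (um); `length >= width > 0`.
#' @param mass Mass in femtograms.
#' @param thrust Motile thrust in piconewtons, applied at the rear pole.
#' @param torque Motile torque in pN um.
#' @param thrust_angle Angle (radians) of the thrust direction relative to the
#'   body axis; 0 during a run, random during a tumble.
#' @return An `agent_body` list; `volume` (um^3) is derived from the capsule
#'   geometry (cylinder plus hemispherical caps).
#' @export
agent_body <- function(location = c(0, 0), orientation = 0,
                       length = 2, width = 1, mass = 1000,
                       thrust = 0, torque = 0, thrust_angle = 0) {
  stopifnot(length >= width, width > 0)
  r <- width / 2
  volume <- pi * r^2 * (length - width) + (4 / 3) * pi * r^3
  structure(list(location = location, orientation = orientation,
                 length = length, width = width, mass = mass,
                 thrust = thrust, torque = torque,
                 thrust_angle = thrust_angle, volume = volume),
            class = "agent_body")
}

#' Physics configuration
#'
#' @param translational_damping Damping coefficient gamma (pN s / um); the
#'   steady swimming speed under thrust F is F/gamma.
#' @param rotational_damping Rotational damping (pN um s / rad).
#' @param jitter_force Magnitude of the random thermal force (pN) applied each
#'   step in a uniform random direction at a uniform random point on the body
#'   axis.
#' @param dt Physics time-step (s).
#' @param bounds Environment extent (x, y) in um; walls reflect.
#' @return A `physics_config` list.
#' @export
physics_config <- function(translational_damping = 0.034,
                           rotational_damping = 0.075,
                           jitter_force = 0.04,
                           dt = 0.01,
                           bounds = c(200, 200)) {
  stopifnot(translational_damping > 0, rotational_damping > 0, dt > 0)
  structure(list(translational_damping = translational_damping,
                 rotational_damping = rotational_damping,
                 jitter_force = jitter_force, dt = dt, bounds = bounds),
            class = "physics_config")
}

# closest-approach vector between two segments p1-q1 and p2-q2; returns
# list(d = distance, v = unit vector from segment 1 toward segment 2)
seg_seg_closest <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) { s <- 0; t <- 0 }
  else if (a <= eps) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    c1 <- sum(d1 * r)
    if (e <= eps) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
    else {
      b <- sum(d1 * d2)
      denom <- a * e - b * b
      s <- if (denom > eps) min(max((b * f - c1 * e) / denom, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c1) / a, 0), 1) }
    }
  }
  cp1 <- p1 + s * d1; cp2 <- p2 + t * d2
  v <- cp2 - cp1
  d <- sqrt(sum(v * v))
  list(d = d, v = if (d > eps) v / d else c(1, 0))
}

capsule_segment <- function(body) {
  half <- (body$length - body$width) / 2
  axis <- c(cos(body$orientation), sin(body$orientation))
  list(p = body$location - half * axis, q = body$location + half * axis)
}

#' Advance agent bodies by one physics step
#'
#' Each body moves under its motile thrust (applied at the rear pole at
#' `thrust_angle` from the body axis, so off-axis thrust also produces
#' torque), its explicit torque, and a thermal jitter force of fixed magnitude
#' applied in a uniform random direction at a uniform random point along the
#' body axis. Dynamics are fully overdamped: `v = F / gamma`,
#' `omega = tau / gamma_r`. Overlapping capsules are pushed apart along their
#' closest-approach vector (volume exclusion), and walls reflect.
#'
#' @param bodies List of [agent_body()] objects.
#' @param config A [physics_config()].
#' @param dt Time-step (s); defaults to `config$dt`.
#' @return The advanced list of bodies.
#' @export
step_multibody <- function(bodies, config, dt = config$dt) {
  stopifnot(dt > 0)
  n <- length(bodies)
  for (i in seq_len(n)) {
    b <- bodies[[i]]
    theta <- b$orientation
    # motile force at the rear pole, rotated thrust_angle off the body axis
    fdir <- theta + b$thrust_angle
    force <- b$thrust * c(cos(fdir), sin(fdir))
    torque <- b$torque - (b$length / 2) * b$thrust * sin(b$thrust_angle)
    if (config$jitter_force > 0) {
      jang <- stats::runif(1, 0, 2 * pi)
      jarm <- stats::runif(1, -b$length / 2, b$length / 2)
      jf <- config$jitter_force * c(cos(jang), sin(jang))
      force <- force + jf
      # torque from off-center application: arm along axis x force
      axis <- c(cos(theta), sin(theta))
      torque <- torque + jarm * (axis[1] * jf[2] - axis[2] * jf[1])
    }
    v <- force / config$translational_damping
    w <- torque / config$rotational_damping
    b$location <- b$location + v * dt
    b$orientation <- (theta + w * dt) %% (2 * pi)
    bodies[[i]] <- b
  }
  # volume exclusion: push overlapping capsules apart (few relaxation sweeps)
  if (n > 1) {
    for (sweep in 1:3) {
      moved <- FALSE
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        bi <- bodies[[i]]; bj <- bodies[[j]]
        si <- capsule_segment(bi); sj <- capsule_segment(bj)
        cc <- seg_seg_closest(si$p, si$q, sj$p, sj$q)
        contact <- (bi$width + bj$width) / 2
        if (cc$d < contact) {
          push <- (contact - cc$d) / 2 + 1e-6
          bodies[[i]]$location <- bi$location - push * cc$v
          bodies[[j]]$location <- bj$location + push * cc$v
          moved <- TRUE
        }
      }
      if (!moved) break
    }
  }
  # reflecting walls
  for (i in seq_len(n)) {
    loc <- bodies[[i]]$location
    for (k in 1:2) {
      if (loc[k] < 0) loc[k] <- -loc[k]
      if (loc[k] > config$bounds[k]) loc[k] <- 2 * config$bounds[k] - loc[k]
      loc[k] <- min(max(loc[k], 0), config$bounds[k])
    }
    bodies[[i]]$location <- loc
  }
  bodies
}
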