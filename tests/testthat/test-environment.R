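test_that("a body with no forces stays put; thrust gives F/gamma steady speed", {
  cfg <- physics_config(jitter_force = 0, dt = 0.01, bounds = c(100, 100))
  b <- agent_body(location = c(50, 50), orientation = 0)
  out <- step_multibody(list(b), cfg)[[1]]
  expect_equal(out$location, c(50, 50))

  b$thrust <- 0.5
  loc <- b$location
  for (k in 1:100) {
    out <- step_multibody(list(b), cfg)[[1]]
    b$location <- out$location
  }
  speed <- sqrt(sum((b$location - loc)^2)) / 1  # 100 steps x 0.01 s
  expect_equal(speed, 0.5 / cfg$translational_damping, tolerance = 0.01)
})

test_that("overlapping capsules are pushed to at least contact distance", {
  cfg <- physics_config(jitter_force = 0, dt = 0.01, bounds = c(100, 100))
  b1 <- agent_body(location = c(50, 50), orientation = 0)
  b2 <- agent_body(location = c(50.3, 50.1), orientation = 1)
  out <- step_multibody(list(b1, b2), cfg)
  # brute-force check: minimum distance between capsule core segments
  s1 <- cellscale:::capsule_segment(out[[1]])
  s2 <- cellscale:::capsule_segment(out[[2]])
  d <- cellscale:::seg_seg_closest(s1$p, s1$q, s2$p, s2$q)$d
  contact <- (out[[1]]$width + out[[2]]$width) / 2
  expect_gte(d, contact - 0.05)
})

test_that("jitter-only motion has diffusive mean-squared displacement", {
  cfg <- physics_config(jitter_force = 0.04, dt = 0.01, bounds = c(1000, 1000))
  set.seed(11)
  msd_at <- function(nsteps) {
    disp <- replicate(60, {
      b <- agent_body(location = c(500, 500))
      for (k in seq_len(nsteps)) b <- step_multibody(list(b), cfg)[[1]]
      sum((b$location - c(500, 500))^2)
    })
    mean(disp)
  }
  m1 <- msd_at(50); m2 <- msd_at(200)
  expect_gt(m2 / m1, 2)   # grows ~linearly (x4), not bounded
  expect_lt(m2 / m1, 8)   # and not ballistically (x16)
})

test_that("diffusion conserves mass, leaves uniform fields unchanged", {
  g <- matrix(2.5, 8, 8)
  f <- make_field(list(glc = g), bin_size = 10, diffusion = c(glc = 100))
  f2 <- diffuse_field(f, 0.1)
  expect_equal(f2$grids$glc, g)

  g[3, 4] <- 100
  f <- make_field(list(glc = g), bin_size = 10, diffusion = c(glc = 100))
  f2 <- diffuse_field(f, 0.1)
  expect_equal(sum(f2$grids$glc), sum(g))
  expect_false(identical(f2$grids$glc, g))
})

test_that("diffusion stability bound is enforced", {
  f <- make_field(list(glc = matrix(1, 4, 4)), bin_size = 1,
                  diffusion = c(glc = 100))
  expect_error(diffuse_field(f, 0.1), "unstable")
})

test_that("point-source spread matches the heat kernel variance 2 D t", {
  n <- 61; h <- 1; D <- 5
  g <- matrix(0, n, n); g[31, 31] <- 1
  f <- make_field(list(s = g), bin_size = h, diffusion = c(s = D))
  dt <- 0.04; total_t <- 4
  for (k in seq_len(total_t / dt)) f <- diffuse_field(f, dt)
  xc <- (seq_len(n) - 31) * h
  w <- f$grids$s / sum(f$grids$s)
  var_x <- sum(outer(xc^2, rep(1, n)) * w)
  expect_equal(var_x, 2 * D * total_t, tolerance = 0.05)
})

test_that("agent exchange converts amounts to concentrations and floors at 0", {
  f <- make_field(list(glc = matrix(1, 5, 5)), bin_size = 10,
                  diffusion = c(glc = 0))
  locs <- list(c(15, 15), c(45, 45))
  # zero exchange: field unchanged, locals equal bin values
  out <- agent_field_exchange(f, locs, list(c(glc = 0), c(glc = 0)))
  expect_equal(out$field$grids$glc, f$grids$glc)
  expect_equal(out$local[[1]][["glc"]], 1)

  # secretion of X raises concentration by X / bin volume
  out <- agent_field_exchange(f, locs, list(c(glc = 30), c(glc = 0)))
  expect_equal(out$local[[1]][["glc"]], 1 + 30 / bin_volume(f))

  # uptake beyond availability empties the bin, never negative
  out <- agent_field_exchange(f, locs, list(c(glc = -1e6), c(glc = 0)))
  expect_equal(out$local[[1]][["glc"]], 0)
  expect_true(all(out$field$grids$glc >= 0))
  expect_equal(out$granted[[1]][["glc"]], -bin_volume(f) * 1)

  expect_error(agent_field_exchange(f, list(c(500, 500))), "outside")
})

test_that("gradient fields: uniform, infinite length-scale limit, e-fold ratio", {
  fu <- make_gradient_field("uniform", nx = 5, ny = 5, bin_size = 10, c0 = 1)
  expect_true(all(fu$grids$ligand == 1))

  fi <- make_gradient_field("exponential", nx = 5, ny = 5, bin_size = 10,
                            c0 = 2, lambda = Inf)
  expect_true(all(fi$grids$ligand == 2))

  fe <- make_gradient_field("exponential", nx = 3, ny = 30, bin_size = 10,
                            c0 = 1, lambda = 100)
  # bins 10 apart along y are separated by lambda = 100 um
  expect_equal(fe$grids$ligand[1, 15] / fe$grids$ligand[1, 5], exp(1))
  expect_error(make_gradient_field("uniform", c0 = -1), "nonnegative")
})

test_that("colony area grows while agents grow and divide", {
  built <- build_grow_divide(n_agents = 1, total_time = 5000, seed = 3,
                             doubling_time = 1200)
  res <- run_built(built)
  agents <- names(res$state$agents)
  expect_gte(length(agents), 4)  # at least two divisions
  locs <- t(vapply(agents, function(a) {
    res$state$agents[[a]]$boundary$location$value
  }, c(0, 0)))
  # daughters pushed apart by volume exclusion: distinct positions
  expect_gt(max(dist(locs)), 1)
})
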