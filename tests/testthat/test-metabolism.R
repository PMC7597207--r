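test_that("FBA on a hand-solvable chain reaches the uptake-limited optimum", {
  # EX_A (<= 10) -> A -> B -> biomass: optimum = 10 by inspection
  net <- metabolic_network(
    reactions = list(EX_A = c(A = 1), R_AB = c(A = -1, B = 1)),
    bounds = list(EX_A = c(0, 10)),
    objective = c(B = 1),
    exchange_reactions = "EX_A",
    molecular_weights = c(A = 0.2, B = 0.2))
  sol <- solve_fba(net)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 10)

  # closing all exchanges shuts the objective to zero
  sol0 <- solve_fba(net, list(EX_A = c(0, 0)))
  expect_equal(sol0$objective, 0)

  # tightening a binding uptake bound never increases the optimum
  prev <- Inf
  for (ub in c(10, 6, 3, 1, 0.2)) {
    o <- solve_fba(net, list(EX_A = c(0, ub)))$objective
    expect_lte(o, prev + 1e-9)
    prev <- o
  }
})

test_that("toy glucose/lactose network is feasible and mass-balanced", {
  net <- toy_metabolism()
  sol <- solve_fba(net, list(EX_glc = c(2, 2), EX_lcts = c(0, 0)))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 2)
  # lactose route: 1 lcts -> 1.9 glc-equivalents, mass conserving
  sol2 <- solve_fba(net, list(EX_glc = c(0, 0), EX_lcts = c(1, 1)))
  expect_equal(sol2$objective, 1.9)
  mw <- net$molecular_weights
  expect_equal(unname(mw["lcts"]), unname(1.9 * mw["glc"]))
})

test_that("convenience kinetics reduces to Michaelis-Menten and handles inhibition", {
  rx <- kinetic_reaction("up", substrates = c(S = 0.5), enzyme = "E", kcat = 2)
  # half saturation at S = Km
  expect_equal(convenience_rate(rx, c(S = 0.5), 10), 2 * 10 / 2)
  expect_equal(convenience_rate(rx, c(S = 0), 10), 0)
  # exact MM equivalence across concentrations (single substrate, no inhibitor)
  for (s in c(0.01, 0.3, 2, 50)) {
    expect_equal(convenience_rate(rx, c(S = s), 3),
                 2 * 3 * s / (0.5 + s))
  }
  # competitor at I = Ki: direct evaluation of the convenience form
  rxi <- kinetic_reaction("up", substrates = c(S = 0.5),
                          competitors = c(I = 1), enzyme = "E", kcat = 2)
  s <- 500; i <- 1
  expected <- 2 * 7 * (s / 0.5) / (1 + s / 0.5 + i / 1)
  expect_equal(convenience_rate(rxi, c(S = s, I = i), 7), expected)
  expect_equal(convenience_rate(rxi, c(S = s, I = i), 7) / (2 * 7), 1,
               tolerance = 0.01)  # S >> Km: approaches kcat E
})

test_that("transport pins exchange fluxes, linearly in transporter count", {
  rxs <- toy_transport_kinetics()
  env <- c(glc_e = 1, lcts_e = 1)
  c0 <- transport_step(rxs, c(GlcT = 100, LacY = 0), env)
  expect_equal(c0$EX_lcts, c(0, 0))  # no LacY, no lactose uptake
  c1 <- transport_step(rxs, c(GlcT = 100, LacY = 50), c(glc_e = 0, lcts_e = 1))
  expect_equal(c1$EX_glc, c(0, 0))   # no external glucose
  c2 <- transport_step(rxs, c(GlcT = 100, LacY = 50), env)
  c3 <- transport_step(rxs, c(GlcT = 200, LacY = 100), env)
  expect_equal(c3$EX_glc, 2 * c2$EX_glc)
  expect_equal(c3$EX_lcts, 2 * c2$EX_lcts)
  expect_error(transport_step(rxs, c(GlcT = 1), env), "missing")
})

test_that("dFBA moves mass from environment to pools, conserving total", {
  net <- toy_metabolism()
  env <- c(glc_e = 1, lcts_e = 0)
  vol <- 1000
  step <- dfba_step(net, c(prec = 0), env, list(EX_glc = c(2, 2)), dt = 5,
                    env_volume = vol)
  expect_equal(step$status, "optimal")
  expect_gt(step$mass_delta, 0)
  env_mass_loss <- -sum(step$env_deltas * net$molecular_weights["glc"])
  expect_equal(step$mass_delta, env_mass_loss)

  # empty environment: no exchange, no growth
  s0 <- dfba_step(net, c(prec = 0), c(glc_e = 0, lcts_e = 0),
                  list(EX_glc = c(2, 2), EX_lcts = c(1, 1)), dt = 1,
                  env_volume = vol)
  expect_equal(s0$mass_delta, 0)

  # uptake capped by availability: cannot import more than the bin holds
  tiny <- dfba_step(net, c(prec = 0), c(glc_e = 0.001, lcts_e = 0),
                    list(EX_glc = c(10, 10)), dt = 10, env_volume = vol)
  expect_lte(-tiny$env_deltas[["glc_e"]], 0.001 * vol + 1e-9)

  # two half steps equal one full step under static constraints
  one <- dfba_step(net, c(prec = 0), env, list(EX_glc = c(2, 2)), dt = 2,
                   env_volume = 1e9)
  h1 <- dfba_step(net, c(prec = 0), env, list(EX_glc = c(2, 2)), dt = 1,
                  env_volume = 1e9)
  h2 <- dfba_step(net, c(prec = h1$pool_deltas[["prec"]]), env,
                  list(EX_glc = c(2, 2)), dt = 1, env_volume = 1e9)
  expect_equal(h1$pool_deltas + h2$pool_deltas, one$pool_deltas,
               tolerance = 1e-8)
})

test_that("biomass is the weight-weighted sum of pools", {
  expect_equal(biomass_from_pools(numeric(), c(a = 1)), 0)
  expect_equal(biomass_from_pools(c(a = 2), c(a = 0.5)), 1)
  expect_equal(biomass_from_pools(c(a = 4, b = 6), c(a = 0.5, b = 1)),
               2 * biomass_from_pools(c(a = 2, b = 3), c(a = 0.5, b = 1)))
  expect_error(biomass_from_pools(c(z = 1), c(a = 1)), "molecular weight")
})

test_that("LacY expression is repressed by glucose and rises without it", {
  set.seed(4)
  p <- lacY_params()
  # high glucose signal: production stays near basal (strong repression)
  s <- list(lacY_mRNA = 0, LacY_protein = 0)
  for (k in 1:200) {
    d <- lacY_expression_step(s, glucose_signal = 3, dt = 1, p)
    s$lacY_mRNA <- s$lacY_mRNA + d$lacY_mRNA
    s$LacY_protein <- s$LacY_protein + d$LacY_protein
  }
  repressed <- s$LacY_protein
  # no glucose: LacY rises toward a positive steady state
  s <- list(lacY_mRNA = 0, LacY_protein = 0)
  for (k in 1:200) {
    d <- lacY_expression_step(s, glucose_signal = 0, dt = 1, p)
    s$lacY_mRNA <- s$lacY_mRNA + d$lacY_mRNA
    s$LacY_protein <- s$LacY_protein + d$LacY_protein
  }
  expect_gt(s$LacY_protein, 10 * max(repressed, 1))

  # zero synthesis: monotone decay to zero
  p0 <- utils::modifyList(p, list(k_tx = 0, k_tl = 0, noise = 0))
  s <- list(lacY_mRNA = 50, LacY_protein = 100)
  prev_m <- s$lacY_mRNA
  for (k in 1:50) {
    d <- lacY_expression_step(s, 0, dt = 1, p0)
    s$lacY_mRNA <- s$lacY_mRNA + d$lacY_mRNA
    expect_lte(s$lacY_mRNA, prev_m)
    prev_m <- s$lacY_mRNA
  }
})

test_that("network fixture JSON round-trips through the loader", {
  dir <- withr::local_tempdir()
  path <- generate_fixtures("toy_metabolism", out_dir = dir)
  net <- load_metabolic_network(path)
  ref <- toy_metabolism()
  expect_equal(net$reactions, ref$reactions)
  expect_equal(net$objective, ref$objective)
  expect_equal(solve_fba(net, list(EX_glc = c(1, 1), EX_lcts = c(0, 0)))$objective, 1)
})
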