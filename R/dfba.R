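# Dynamic FBA: iteratively re-optimize biomass production under
# transport-imposed flux constraints, moving material between the local
# environment and the cell's internal metabolite pools. Includes the minimal
# stochastic-ODE LacY expression model used for integrative FBA coupling.

#' Total biomass of metabolite pools
#'
#' Pools are multiplied by their molecular weights and summed.
#'
#' @param pools Named numeric: metabolite -> amount (mM * um^3 units).
#' @param molecular_weights Named numeric: metabolite -> fg per amount unit.
#' @return Mass in fg.
#' @export
biomass_from_pools <- function(pools, molecular_weights) {
  if (length(pools) == 0) return(0)
  missing <- setdiff(names(pools), names(molecular_weights))
  if (length(missing)) {
    stop(sprintf("no molecular weight for: %s", paste(missing, collapse = ", ")))
  }
  sum(unlist(pools) * molecular_weights[names(pools)])
}

#' One dynamic-FBA step
#'
#' Solves the FBA problem under the given constraints (uptake additionally
#' capped by local availability over `dt`), then moves material: the biomass
#' flux times the objective composition is added to the internal pools, and
#' exchange fluxes are returned as environment deltas (uptake negative).
#' Because every network reaction is mass-balanced, the pool mass gain equals
#' the environment mass loss exactly. An infeasible LP yields a zero-growth
#' step.
#'
#' @param network A [metabolic_network()].
#' @param pools Named numeric internal pools (amount units).
#' @param local_env Named numeric external concentrations (mM).
#' @param constraints `FluxConstraints` from [transport_step()].
#' @param dt Time-step (s, > 0).
#' @param env_volume Volume (um^3) converting external mM to amounts.
#' @return List: `pool_deltas`, `env_deltas` (named amounts), `mass_delta`
#'   (fg), `fluxes`, `status`.
#' @export
dfba_step <- function(network, pools, local_env, constraints, dt,
                      env_volume = 1) {
  stopifnot(dt > 0)
  # cap uptake by what the local environment actually holds
  for (r in network$exchange_reactions) {
    st <- network$reactions[[r]]
    ext <- network$exchange_species[[r]]
    avail <- vget(local_env, ext) * env_volume / dt / abs(st[[1]])
    b <- constraints[[r]]
    if (is.null(b)) b <- c(network$bounds[[r]][1] %||% 0,
                           network$bounds[[r]][2] %||% network$default_ub)
    b[2] <- min(b[2], avail)
    b[1] <- min(b[1], b[2])
    constraints[[r]] <- b
  }
  sol <- solve_fba(network, constraints)
  if (sol$status != "optimal") {
    return(list(pool_deltas = numeric(), env_deltas = numeric(),
                mass_delta = 0, fluxes = NULL, status = sol$status))
  }
  growth <- sol$objective
  pool_deltas <- network$objective * growth * dt
  env_deltas <- numeric()
  for (r in network$exchange_reactions) {
    st <- network$reactions[[r]]
    ext <- network$exchange_species[[r]]
    env_deltas[ext] <- vget(env_deltas, ext) - st[[1]] * sol$fluxes[[r]] * dt
  }
  mass_delta <- sum(pool_deltas * network$molecular_weights[names(pool_deltas)])
  list(pool_deltas = pool_deltas, env_deltas = env_deltas,
       mass_delta = mass_delta, fluxes = sol$fluxes, status = "optimal")
}

#' Minimal stochastic-ODE LacY expression step
#'
#' Transcription of *lacY* is repressed by the internal glucose signal
#' (Hill repression), mRNA decays first-order, protein is synthesized
#' proportionally to mRNA and diluted by growth. Molecular noise enters the
#' synthesis terms scaled by sqrt(dt); counts are floored at zero.
#'
#' @param state List with `lacY_mRNA` and `LacY_protein` counts.
#' @param glucose_signal Internal glucose amount (repressing signal).
#' @param dt Time-step (s, > 0).
#' @param params List: `k_tx` (max mRNA/s), `K_rep` (repression half-point),
#'   `h` (Hill coefficient), `d_mrna` (1/s), `k_tl` (protein/s per mRNA),
#'   `dilution` (1/s), `noise` (noise scale).
#' @return List of deltas `lacY_mRNA`, `LacY_protein` (to apply with a
#'   nonnegative accumulator).
#' @export
lacY_expression_step <- function(state, glucose_signal, dt,
                                 params = lacY_params()) {
  stopifnot(dt > 0)
  p <- params
  repress <- 1 / (1 + (glucose_signal / p$K_rep)^p$h)
  synth <- p$k_tx * repress
  d_mrna <- synth * dt - p$d_mrna * state$lacY_mRNA * dt +
    p$noise * sqrt(synth * dt + 1e-12) * stats::rnorm(1)
  d_prot <- p$k_tl * state$lacY_mRNA * dt -
    p$dilution * state$LacY_protein * dt +
    p$noise * sqrt(max(p$k_tl * state$lacY_mRNA * dt, 0) + 1e-12) * stats::rnorm(1)
  d_mrna <- max(d_mrna, -state$lacY_mRNA)
  d_prot <- max(d_prot, -state$LacY_protein)
  list(lacY_mRNA = d_mrna, LacY_protein = d_prot)
}

#' Default LacY expression parameters
#'
#' Calibrated so the toy diauxie reproduces its three regimes: full
#' repression while internal glucose is abundant, a lag of a few hundred
#' seconds while LacY accumulates after glucose depletion, and resumed
#' growth on lactose.
#'
#' @return Parameter list for [lacY_expression_step()].
#' @export
lacY_params <- function() {
  list(k_tx = 0.25, K_rep = 0.5, h = 4, d_mrna = 0.01,
       k_tl = 0.05, dilution = 3e-4, noise = 1.0)
}

#' Default transport kinetics for the toy network
#'
#' Glucose uptake through a constitutive transporter (GLCpts), lactose
#' through LacY; glucose competitively inhibits lactose uptake. Rates are
#' fitted so a 1000 fg cell on replete glucose grows with roughly a 40-min
#' doubling time.
#'
#' @return List of [kinetic_reaction()].
#' @export
toy_transport_kinetics <- function() {
  list(
    kinetic_reaction("EX_glc", substrates = c(glc_e = 0.02),
                     enzyme = "GlcT", kcat = 3.2e-3),
    kinetic_reaction("EX_lcts", substrates = c(lcts_e = 0.05),
                     competitors = c(glc_e = 0.005),
                     enzyme = "LacY", kcat = 6e-3))
}
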