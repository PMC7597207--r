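# Engine process wrappers for coupled transport-metabolism (iFBA): kinetic
# transport pins exchange fluxes in a shared flux store, dynamic FBA
# consumes them as constraints, and the minimal stochastic-ODE LacY process
# closes the gene-regulation loop. All three run at the internal 1.0 s
# time-step.

#' Kinetic transport process
#'
#' Computes convenience-kinetics transport fluxes from transporter copy
#' numbers and the local environment, writing them to the flux store where
#' metabolism reads them as equality constraints.
#'
#' @param agent Agent name.
#' @param reactions List of [kinetic_reaction()] (default
#'   [toy_transport_kinetics()]).
#' @param time_step Seconds.
#' @return A [process()].
#' @export
transport_process <- function(agent, reactions = toy_transport_kinetics(),
                              time_step = 1) {
  flux_schema <- function() var_schema(0, units = "amount/s", updater = "set",
                                       divider = "copy")
  rids <- vapply(reactions, `[[`, "", "id")
  ports <- list(
    proteins = stats::setNames(
      lapply(reactions, function(r) var_schema(0, units = "counts",
                                               updater = "nonnegative_accumulate",
                                               divider = "binomial",
                                               emit = TRUE)),
      vapply(reactions, `[[`, "", "enzyme")),
    env = list(),
    flux = stats::setNames(lapply(rids, function(r) flux_schema()), rids))
  update <- function(view, dt, params) {
    constraints <- transport_step(params$reactions, view$proteins, view$env)
    list(flux = lapply(constraints, function(b) b[1]))
  }
  process(paste0(agent, ".transport"), ports, update, time_step,
          parameters = list(reactions = reactions))
}

#' Dynamic FBA metabolism process
#'
#' Each step re-solves the biomass-maximizing FBA problem under the flux
#' store's transport constraints and the local nutrient availability, adds
#' the objective composition to the internal pools, applies exchange deltas
#' to the environment, and grows the boundary mass by exactly the imported
#' material. Divides when mass reaches the threshold.
#'
#' @param agent Agent name.
#' @param agent_path Path of the agent compartment (for the division
#'   message).
#' @param network A [metabolic_network()] (default [toy_metabolism()]).
#' @param env_volume Environment volume (um^3) converting mM to amounts.
#' @param division_threshold Mass (fg) triggering division; `Inf` disables.
#' @param time_step Seconds.
#' @return A [process()].
#' @export
metabolism_process <- function(agent, agent_path, network = toy_metabolism(),
                               env_volume = 2000, division_threshold = Inf,
                               time_step = 1) {
  env_schema <- function() var_schema(0, units = "mM",
                                      updater = "nonnegative_accumulate",
                                      divider = "copy", emit = TRUE)
  exts <- unname(network$exchange_species)
  ports <- list(
    flux = stats::setNames(lapply(network$exchange_reactions, function(r) {
      var_schema(0, units = "amount/s", updater = "set", divider = "copy")
    }), network$exchange_reactions),
    env = stats::setNames(lapply(exts, function(e) env_schema()), exts),
    pools = stats::setNames(lapply(names(network$objective), function(m) {
      var_schema(0, units = "amount", updater = "nonnegative_accumulate",
                 divider = "halve", emit = TRUE)
    }), names(network$objective)),
    boundary = list(mass = var_schema(1000, units = "fg",
                                      updater = "accumulate",
                                      divider = "halve", emit = TRUE)))
  update <- function(view, dt, params) {
    net <- params$network
    constraints <- lapply(view$flux, function(v) c(v, v))
    step <- dfba_step(net, unlist(view$pools), view$env, constraints, dt,
                      env_volume = params$env_volume)
    upd <- list(env = as.list(step$env_deltas / params$env_volume),
                pools = as.list(step$pool_deltas),
                boundary = list(mass = step$mass_delta))
    new_mass <- view$boundary$mass + step$mass_delta
    if (new_mass >= params$division_threshold) {
      upd$.topology <- list(list(type = "divide", path = params$agent_path))
    }
    upd
  }
  process(paste0(agent, ".metabolism"), ports, update, time_step,
          parameters = list(network = network, env_volume = env_volume,
                            division_threshold = division_threshold,
                            agent_path = agent_path))
}

#' Minimal LacY expression process (stochastic ODE)
#'
#' lacY transcription is repressed while glucose is being imported (the
#' glucose uptake flux is the repressing signal); LacY protein follows the
#' mRNA. This is the coarse-grained expression model used in the iFBA
#' coupling before the sequence-based stochastic processes replace it.
#'
#' @param agent Agent name.
#' @param params [lacY_params()] overrides.
#' @param time_step Seconds.
#' @return A [process()].
#' @export
lacy_expression_process <- function(agent, params = lacY_params(),
                                    time_step = 1) {
  ports <- list(
    flux = list(EX_glc = var_schema(0, units = "amount/s", updater = "set",
                                    divider = "copy")),
    rna = list(lacY_mRNA = var_schema(0, units = "counts",
                                      updater = "nonnegative_accumulate",
                                      divider = "binomial", emit = TRUE)),
    proteins = list(LacY = var_schema(0, units = "counts",
                                      updater = "nonnegative_accumulate",
                                      divider = "binomial", emit = TRUE)))
  update <- function(view, dt, p) {
    d <- lacY_expression_step(
      list(lacY_mRNA = view$rna$lacY_mRNA,
           LacY_protein = view$proteins$LacY),
      glucose_signal = view$flux$EX_glc, dt, p)
    list(rna = list(lacY_mRNA = d$lacY_mRNA),
         proteins = list(LacY = d$LacY_protein))
  }
  process(paste0(agent, ".lacy"), ports, update, time_step,
          parameters = params)
}
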