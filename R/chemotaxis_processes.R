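# Engine process wrappers for the chemotaxis sensorimotor chain: receptor,
# motor (switching + veto + thrust), and proton-motive force. The receptor
# and motor run at dt = 0.01 s -- the chain must track the environment at
# that rate or the cell misses gradient information -- while the PMF updates
# at 1.0 s like other internal processes.

ROTATION_CCW <- 0
ROTATION_CW <- 1
MOTILE_NONMOTILE <- 0
MOTILE_RUN <- 1
MOTILE_TUMBLE <- 2
FLAGELLUM_HZ <- 100  # rotation rate, revolutions/s

#' Chemoreceptor process
#'
#' Reads the agent's local attractant concentration from its boundary store,
#' updates cluster activity and methylation, and writes the transduced
#' CheY-P level. A `defunct` receptor pins activity (and hence CheY-P) at
#' baseline regardless of ligand: such agents keep baseline run/tumble
#' motility but cannot climb gradients.
#'
#' @param agent Agent name.
#' @param agent_path Path of the agent compartment.
#' @param cluster A [receptor_cluster()] supplying the MWC constants.
#' @param cheY A [cheY_params()].
#' @param defunct Logical; disable ligand sensitivity.
#' @param time_step Seconds (default 0.01).
#' @return A [process()].
#' @export
receptor_process <- function(agent, agent_path, cluster = receptor_cluster(),
                             cheY = cheY_params(), defunct = FALSE,
                             time_step = 0.01) {
  ports <- list(
    boundary = list(external_ligand = var_schema(0.1, units = "mM",
                                                 updater = "set",
                                                 divider = "copy")),
    internal = list(
      methylation = var_schema(cluster$methylation, units = "dimensionless",
                               updater = "set", divider = "copy"),
      P_on = var_schema(cluster$a0, units = "dimensionless", updater = "set",
                        divider = "copy"),
      cheY_P = var_schema(cheY$Y0, units = "uM", updater = "set",
                          divider = "copy")))
  update <- function(view, dt, params) {
    if (params$defunct) {
      return(list(internal = list(P_on = params$cluster$a0,
                                  cheY_P = params$cheY$Y0)))
    }
    cl <- params$cluster
    cl$methylation <- view$internal$methylation
    cl <- receptor_update(cl, max(view$boundary$external_ligand, 0), dt)
    list(internal = list(methylation = cl$methylation, P_on = cl$P_on,
                         cheY_P = cheY_P_level(cl$P_on, params$cheY)))
  }
  process(paste0(agent, ".receptor"), ports, update, time_step,
          parameters = list(cluster = cluster, cheY = cheY, defunct = defunct))
}

#' Flagellar motor process
#'
#' Advances each flagellum sub-compartment's CCW/CW state from the CheY-P
#' level, aggregates them with the veto rule, and writes the motile state,
#' thrust and thrust angle to the boundary store for the physics process. A
#' tumble's random thrust angle is drawn once when the tumble starts and
#' held until the next run. Proton flow (1200 per revolution at 100 Hz per
#' rotating flagellum) is bookkept on the boundary.
#'
#' @param agent Agent name.
#' @param agent_path Path of the agent compartment.
#' @param switch A [switch_params()].
#' @param f0,pmf0 Thrust calibration (see [motile_output()]).
#' @param body_length Body length (um).
#' @param time_step Seconds (default 0.01; must be <= 0.01).
#' @return A [process()].
#' @export
motor_process <- function(agent, agent_path, switch = switch_params(),
                          f0 = 0.31, pmf0 = 140, body_length = 2,
                          time_step = 0.01) {
  ports <- list(
    internal = list(cheY_P = var_schema(cheY_params()$Y0, units = "uM",
                                        updater = "set", divider = "copy")),
    flagella = list(.divider = "split_list"),
    boundary = list(
      pmf = var_schema(-134, units = "mV", updater = "set", divider = "copy"),
      thrust = var_schema(0, units = "pN", updater = "set", divider = "copy"),
      thrust_angle = var_schema(0, units = "radians", updater = "set",
                                divider = "copy"),
      motile_state = var_schema(MOTILE_NONMOTILE, units = "dimensionless",
                                updater = "set", divider = "copy",
                                emit = TRUE),
      protons_moved = var_schema(0, units = "counts",
                                 updater = "accumulate", divider = "halve")))
  update <- function(view, dt, params) {
    y <- view$internal$cheY_P
    flagella <- view$flagella
    rot_upd <- list()
    rotations <- character(0)
    for (fl in names(flagella)) {
      state <- if (flagella[[fl]]$rotation == ROTATION_CW) "CW" else "CCW"
      state <- flagellum_switch_step(state, y, dt, params$switch)
      rotations <- c(rotations, state)
      rot_upd[[fl]] <- list(rotation = if (state == "CW") ROTATION_CW else ROTATION_CCW)
    }
    was_tumbling <- view$boundary$motile_state == MOTILE_TUMBLE
    held <- if (was_tumbling) view$boundary$thrust_angle else NULL
    out <- motile_output(rotations, view$boundary$pmf, params$f0, params$pmf0,
                         params$body_length, tumble_angle = held)
    state_code <- switch(out$state, nonmotile = MOTILE_NONMOTILE,
                         run = MOTILE_RUN, tumble = MOTILE_TUMBLE)
    upd <- list(
      internal = list(),
      boundary = list(thrust = out$thrust, thrust_angle = out$thrust_angle,
                      motile_state = state_code,
                      protons_moved = proton_accounting(
                        FLAGELLUM_HZ * dt * length(rotations))))
    if (length(rot_upd)) upd$flagella <- rot_upd
    upd
  }
  process(paste0(agent, ".motor"), ports, update, time_step,
          parameters = list(switch = switch, f0 = f0, pmf0 = pmf0,
                            body_length = body_length))
}

#' Proton-motive force process
#'
#' Recomputes the Goldman membrane potential and PMF from the ion state and
#' writes it to the boundary. Runs at the internal 1.0 s time-step; proton
#' flux through the motors is restored instantly, so the PMF is effectively
#' set by the ion state.
#'
#' @param agent Agent name.
#' @param ions A [pmf_state()].
#' @param time_step Seconds (default 1).
#' @return A [process()].
#' @export
pmf_process <- function(agent, ions = pmf_state(), time_step = 1) {
  ports <- list(boundary = list(
    pmf = var_schema(-134, units = "mV", updater = "set", divider = "copy"),
    membrane_potential = var_schema(-79, units = "mV", updater = "set",
                                    divider = "copy")))
  update <- function(view, dt, params) {
    g <- goldman_pmf(params$ions)
    list(boundary = list(pmf = g$pmf, membrane_potential = g$membrane_potential))
  }
  process(paste0(agent, ".pmf"), ports, update, time_step,
          parameters = list(ions = ions))
}

#' A flagellum sub-compartment store
#'
#' @param rotation Initial rotation (`ROTATION_CCW` = 0 or `ROTATION_CW` = 1).
#' @return Store subtree for one flagellum.
#' @export
flagellum_store <- function(rotation = ROTATION_CCW) {
  list(rotation = store_leaf(rotation,
                             var_schema(ROTATION_CCW, units = "dimensionless",
                                        updater = "set", divider = "copy")))
}

#' Flagellar assembly process
#'
#' Watches the agent's count of newly completed flagellum complexes and adds
#' a flagellum sub-compartment (with a fresh CCW rotational state) to the
#' hierarchy for each, consuming the count.
#'
#' @param agent Agent name.
#' @param agent_path Path of the agent compartment.
#' @param time_step Seconds.
#' @return A [process()].
#' @export
flagella_assembly_process <- function(agent, agent_path, time_step = 1) {
  force(agent_path)
  ports <- list(
    counts = list(new_flagella = var_schema(0, units = "counts",
                                            updater = "accumulate",
                                            divider = "binomial")),
    flagella = list(.divider = "split_list"))
  update <- function(view, dt, params) {
    n <- view$counts$new_flagella
    if (n < 1) return(NULL)
    existing <- length(view$flagella)
    msgs <- lapply(seq_len(n), function(i) {
      list(type = "add_subcompartment",
           path = c(params$agent_path, "flagella"),
           name = sprintf("flg_%d", existing + i),
           subtree = flagellum_store())
    })
    list(counts = list(new_flagella = -n), .topology = msgs)
  }
  process(paste0(agent, ".assembly"), ports, update, time_step,
          parameters = list(agent_path = agent_path))
}
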