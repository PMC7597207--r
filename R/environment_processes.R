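# Engine process wrappers for the environment compartment: multi-body
# physics over all agent bodies, and diffusion over the molecular fields
# with agent-local exchange.

#' Build an agent boundary store
#'
#' The boundary store is shared between the agent's internal processes and
#' the environment's physics/diffusion processes: it holds the body state
#' (location, orientation, dimensions, mass), the motile forces, and the
#' agent's local external concentrations.
#'
#' @param location,orientation Body pose.
#' @param length,width Capsule dimensions (um).
#' @param mass Mass (fg).
#' @param external_ligand Initial local attractant concentration (mM).
#' @return Store subtree for the boundary.
#' @export
make_agent_boundary <- function(location = c(0, 0), orientation = 0,
                                length = 2, width = 1, mass = 1000,
                                external_ligand = 0.1) {
  list(
    location = store_leaf(location, var_schema(c(0, 0), units = "um",
                                               updater = "set",
                                               divider = "copy", emit = TRUE)),
    orientation = store_leaf(orientation,
                             var_schema(0, units = "radians", updater = "set",
                                        divider = "copy")),
    length = store_leaf(length, var_schema(2, units = "um", updater = "set",
                                           divider = "copy")),
    width = store_leaf(width, var_schema(1, units = "um", updater = "set",
                                         divider = "copy")),
    mass = store_leaf(mass, var_schema(1000, units = "fg", updater = "set",
                                       divider = "halve", emit = TRUE)),
    external_ligand = store_leaf(external_ligand,
                                 var_schema(0.1, units = "mM",
                                            updater = "set", divider = "copy")))
}

#' Multi-body physics process
#'
#' Steps every agent body under its boundary-store thrust and thrust angle
#' plus thermal jitter, with volume exclusion and reflecting walls, then
#' writes the new poses back. When a field is present, each agent's local
#' attractant concentration is refreshed from the bin containing it.
#'
#' @param config A [physics_config()].
#' @param species Field species to sample into `external_ligand` (NULL to
#'   skip).
#' @param time_step Seconds.
#' @return A [process()].
#' @export
physics_process <- function(config = physics_config(), species = "ligand",
                            time_step = config$dt) {
  ports <- list(agents = list(), fields = list())
  update <- function(view, dt, params) {
    agents <- view$agents
    if (is.null(agents) || length(agents) == 0) return(NULL)
    nms <- names(agents)
    bodies <- lapply(nms, function(a) {
      b <- agents[[a]]$boundary
      agent_body(location = b$location, orientation = b$orientation,
                 length = b$length, width = b$width, mass = b$mass,
                 thrust = b$thrust %||% 0,
                 thrust_angle = b$thrust_angle %||% 0)
    })
    bodies <- step_multibody(bodies, params$config, dt)
    field <- view$fields$field
    upd <- list()
    for (i in seq_along(nms)) {
      b <- bodies[[i]]
      entry <- list(location = b$location, orientation = b$orientation)
      if (!is.null(field) && !is.null(params$species) &&
          !is.null(field$grids[[params$species]])) {
        ij <- field_bin(field, b$location)
        entry$external_ligand <- field$grids[[params$species]][ij[1], ij[2]]
      }
      upd[[nms[i]]] <- list(boundary = entry)
    }
    list(agents = upd)
  }
  process("env.physics", ports, update, time_step,
          parameters = list(config = config, species = species))
}

#' Field diffusion process
#'
#' Diffuses the environment's molecular fields, sub-stepping internally to
#' respect the explicit-scheme stability bound.
#'
#' @param time_step Seconds.
#' @return A [process()].
#' @export
diffusion_process <- function(time_step = 1) {
  ports <- list(fields = list())
  update <- function(view, dt, params) {
    field <- view$fields$field
    if (is.null(field)) return(NULL)
    maxD <- max(unlist(field$diffusion), 0)
    if (maxD > 0) {
      sub <- ceiling(maxD * dt / (0.2 * field$bin_size^2))
      for (k in seq_len(max(sub, 1L))) field <- diffuse_field(field, dt / max(sub, 1L))
    }
    list(fields = list(field = field))
  }
  process("env.diffusion", ports, update, time_step, parameters = list())
}

#' A field store leaf
#'
#' @param field A `cs_field`.
#' @return Store subtree holding the field under variable `field`.
#' @export
make_field_store <- function(field) {
  list(field = store_leaf(field, var_schema(field, units = "mM",
                                            updater = "set", divider = "copy")))
}
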