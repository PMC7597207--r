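# The simulation engine: processes, topology, hierarchy construction,
# multi-timescale scheduling, update application, topology updates, emission.

#' Define a process
#'
#' A process is a mechanistic sub-model that views part of the state through
#' named ports, runs for its own time-step, and returns an update.
#'
#' @param name Unique process name. Agent-owned processes follow the naming
#'   convention `"<agent>.<role>"` so that they can be retired and replaced
#'   when the agent divides.
#' @param ports Named list: port name -> named list of [var_schema()] for the
#'   variables the process reads/writes through that port. A port may contain
#'   the special entry `.divider = "split_list"` to mark the wired store as a
#'   sub-compartment store.
#' @param update Function `(view, dt, params)` returning an update: a named
#'   list `port -> (variable -> delta)` (deltas interpreted by each variable's
#'   updater), optionally with an element `.topology` holding a list of
#'   topology messages (see [apply_topology_update()]).
#' @param time_step Process time-step in seconds (> 0).
#' @param parameters Named list passed to `update` as `params`.
#' @return A `cs_process`.
#' @export
process <- function(name, ports, update, time_step = 1, parameters = list()) {
  stopifnot(is.character(name), length(name) == 1L, time_step > 0)
  structure(list(name = name, ports = ports, update = update,
                 time_step = time_step, parameters = parameters),
            class = "cs_process")
}

#' Build a store hierarchy from processes + topology
#'
#' Creates every store path referenced by the topology, installing each
#' variable's schema (first declaration wins; conflicting units are an
#' error), then overlays `initial_state` values.
#'
#' @param processes List of [process()] objects.
#' @param topology Named list: process name -> (port name -> character vector
#'   path into the hierarchy).
#' @param initial_state Nested list of initial values (optional).
#' @return A store tree.
#' @export
build_hierarchy <- function(processes, topology, initial_state = list()) {
  tree <- list()
  for (p in processes) {
    wiring <- topology[[p$name]]
    if (is.null(wiring)) stop(sprintf("process '%s' missing from topology", p$name))
    for (port in names(p$ports)) {
      path <- wiring[[port]]
      if (is.null(path)) stop(sprintf("port '%s' of '%s' not wired", port, p$name))
      schemas <- p$ports[[port]]
      for (v in names(schemas)) {
        if (v == ".divider") {
          node <- path_get(tree, path)
          if (is.null(node)) node <- list()
          attr(node, "divider") <- schemas[[v]]
          tree <- path_set(tree, path, node)
          next
        }
        s <- schemas[[v]]
        leaf_path <- c(path, v)
        existing <- path_get(tree, leaf_path)
        if (is.null(existing)) {
          tree <- path_set(tree, leaf_path, store_leaf(s$default, s))
        } else if (is_leaf(existing) &&
                   !identical(existing$schema$units, s$units)) {
          stop(sprintf("schema conflict at %s: units '%s' vs '%s'",
                       paste(leaf_path, collapse = "/"),
                       existing$schema$units, s$units))
        }
      }
    }
  }
  overlay_values(tree, initial_state)
}

# View the state through a process's ports: port -> nested raw values.
port_view <- function(tree, proc, wiring) {
  view <- vector("list", length(proc$ports))
  names(view) <- names(proc$ports)
  for (port in names(proc$ports)) {
    node <- path_get(tree, wiring[[port]])
    view[[port]] <- if (is.null(node)) NULL else store_values(node)
  }
  view
}

# Apply one process's update to the tree. Updates may only touch variables
# reachable through the process's declared ports (locality enforcement).
apply_process_update <- function(tree, proc, wiring, update) {
  for (port in names(update)) {
    if (port == ".topology") next
    if (!port %in% names(proc$ports)) {
      stop(sprintf("process '%s' attempted update through undeclared port '%s'",
                   proc$name, port))
    }
    path <- wiring[[port]]
    tree <- path_set(tree, path,
                     apply_node_update(path_get(tree, path), update[[port]],
                                       proc$name, port))
  }
  tree
}

apply_node_update <- function(node, upd, pname, where) {
  if (is_leaf(node)) return(store_leaf(apply_update(node$value, upd, node$schema),
                                       node$schema))
  if (!is.list(upd)) {
    stop(sprintf("process '%s' update at '%s' targets a store, not a variable",
                 pname, where))
  }
  for (nm in names(upd)) {
    child <- node[[nm]]
    if (is.null(child)) {
      stop(sprintf("process '%s' referenced unknown variable '%s' under '%s'",
                   pname, nm, where))
    }
    node[[nm]] <- apply_node_update(child, upd[[nm]], pname,
                                    paste(where, nm, sep = "/"))
  }
  node
}

#' Apply a topology message to a hierarchy
#'
#' Supported messages (named lists with a `type` field):
#' \describe{
#'   \item{divide}{`path` names an agent compartment; it is replaced under its
#'     parent by two daughters (suffixes "0"/"1") produced by
#'     [divide_state()].}
#'   \item{add_subcompartment}{Insert `subtree` as child `name` under `path`.}
#'   \item{delete}{Remove the compartment at `path`.}
#' }
#'
#' @param tree Store tree.
#' @param message Topology message.
#' @return List with elements `tree` (the updated hierarchy) and `daughters`
#'   (for divide: the two daughter paths, else NULL).
#' @export
apply_topology_update <- function(tree, message) {
  type <- message$type
  path <- message$path
  if (!type %in% c("divide", "add_subcompartment", "delete")) {
    stop(sprintf("unknown topology message '%s'", type))
  }
  if (type != "add_subcompartment" && is.null(path_get(tree, path))) {
    stop(sprintf("topology message references nonexistent compartment '%s'",
                 paste(path, collapse = "/")))
  }
  daughters <- NULL
  if (type == "divide") {
    mother <- path_get(tree, path)
    halves <- divide_state(mother)
    parent_path <- path[-length(path)]
    mother_name <- path[length(path)]
    d_names <- paste0(mother_name, c("0", "1"))
    parent <- if (length(parent_path)) path_get(tree, parent_path) else tree
    parent[[mother_name]] <- NULL
    parent[[d_names[1]]] <- halves[[1]]
    parent[[d_names[2]]] <- halves[[2]]
    if (length(parent_path)) tree <- path_set(tree, parent_path, parent) else tree <- parent
    daughters <- lapply(d_names, function(n) c(parent_path, n))
  } else if (type == "add_subcompartment") {
    tree <- path_set(tree, c(path, message$name), message$subtree)
  } else if (type == "delete") {
    parent_path <- path[-length(path)]
    name <- path[length(path)]
    parent <- if (length(parent_path)) path_get(tree, parent_path) else tree
    parent[[name]] <- NULL
    if (length(parent_path)) tree <- path_set(tree, parent_path, parent) else tree <- parent
  }
  list(tree = tree, daughters = daughters)
}

# Greatest common divisor of time-steps, on a 1-microsecond integer lattice.
# Fails fast for non-commensurate steps rather than allowing silent drift.
time_base_us <- function(dts) {
  us <- dts * 1e6
  if (any(abs(us - round(us)) > 1e-3)) {
    stop("non-commensurate time-steps: process time-steps must lie on a 1 microsecond lattice")
  }
  us <- as.numeric(round(us))
  g <- us[1]
  gcd2 <- function(a, b) { while (b > 0) { t <- a %% b; a <- b; b <- t }; a }
  for (x in us[-1]) g <- gcd2(g, x)
  g
}

#' Run an experiment
#'
#' Assembles the hierarchy (unless one is supplied), then advances a temporal
#' front: each process is invoked every `time_step` of its own, and its update
#' is applied immediately; processes due at the same front time run in sorted
#' name order, making multi-writer resolution deterministic. Emitted variables
#' are recorded every `emit_interval` seconds of simulated time.
#'
#' Each process draws randomness from its own L'Ecuyer-CMRG substream derived
#' from `seed`, so results are reproducible and independent of process count.
#'
#' @param processes List of [process()] objects.
#' @param topology Named list: process name -> (port -> path).
#' @param total_time Simulated seconds to run.
#' @param initial_state Nested list of initial values.
#' @param hierarchy Optional pre-built store tree (overrides
#'   `initial_state`).
#' @param emit_interval Emission interval, simulated seconds (default 1.0).
#' @param seed Integer seed for the experiment's RNG streams.
#' @param agent_template Optional function `(agent_name, agent_path)`
#'   returning `list(processes=, topology=)` used to instantiate processes for
#'   daughter agents after a division.
#' @return List with `emitted` (data.frame: time + one column per emitted
#'   variable path), `state` (final store tree), `processes`, `topology`.
#' @export
run_experiment <- function(processes, topology, total_time,
                           initial_state = list(), hierarchy = NULL,
                           emit_interval = 1.0, seed = 0L,
                           agent_template = NULL) {
  names(processes) <- vapply(processes, `[[`, "", "name")
  tree <- hierarchy %||% build_hierarchy(processes, topology, initial_state)

  base_us <- time_base_us(c(vapply(processes, `[[`, 0, "time_step"),
                            emit_interval, total_time))
  to_ticks <- function(s) round(s * 1e6 / base_us)
  total_ticks <- to_ticks(total_time)
  emit_ticks <- to_ticks(emit_interval)

  # per-process RNG substreams from one fountain
  old_kind <- RNGkind("L'Ecuyer-CMRG")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  fountain <- get(".Random.seed", globalenv())
  streams <- list()
  next_stream <- function() {
    fountain <<- parallel::nextRNGStream(fountain)
    fountain
  }
  for (nm in sort(names(processes))) streams[[nm]] <- next_stream()

  due <- vapply(processes, function(p) to_ticks(p$time_step), 0)
  dt_ticks <- due

  emitted <- vector("list", total_ticks %/% emit_ticks + 2L)
  n_emit <- 0L
  emit_now <- function(time_s) {
    rec <- store_flatten(tree, emit_only = TRUE)
    flat <- unlist(rec, use.names = TRUE)
    n_emit <<- n_emit + 1L
    emitted[[n_emit]] <<- c(time = time_s, flat)
  }
  emit_now(0)

  retire_agent_processes <- function(agent_name) {
    prefix <- paste0(agent_name, ".")
    drop <- names(processes)[startsWith(names(processes), prefix)]
    processes[drop] <- NULL
    topology[drop] <- NULL
    due <- due[!names(due) %in% drop]
    dt_ticks <- dt_ticks[!names(dt_ticks) %in% drop]
    list(processes = processes, topology = topology, due = due, dt = dt_ticks)
  }

  front <- 0
  next_emit <- emit_ticks
  while (front < total_ticks) {
    advance <- min(due)
    front <- advance
    ready <- sort(names(due)[due == advance])
    messages <- list()
    for (nm in ready) {
      p <- processes[[nm]]
      wiring <- topology[[nm]]
      view <- port_view(tree, p, wiring)
      assign(".Random.seed", streams[[nm]], globalenv())
      upd <- p$update(view, p$time_step, p$parameters)
      streams[[nm]] <- get(".Random.seed", globalenv())
      if (!is.null(upd)) {
        tree <- apply_process_update(tree, p, wiring, upd)
        if (!is.null(upd$.topology)) {
          for (m in upd$.topology) { m$.issuer <- nm; messages[[length(messages) + 1L]] <- m }
        }
      }
      due[nm] <- due[nm] + dt_ticks[nm]
    }
    for (m in messages) {
      assign(".Random.seed", streams[[m$.issuer]], globalenv())
      res <- apply_topology_update(tree, m)
      tree <- res$tree
      streams[[m$.issuer]] <- get(".Random.seed", globalenv())
      if (m$type == "divide" && !is.null(agent_template)) {
        mother <- m$path[length(m$path)]
        r <- retire_agent_processes(mother)
        processes <- r$processes; topology <- r$topology
        due <- r$due; dt_ticks <- r$dt
        for (di in seq_along(res$daughters)) {
          dp <- res$daughters[[di]]
          dname <- dp[length(dp)]
          inst <- agent_template(dname, dp)
          if (!is.null(inst$patch_state)) {
            tree <- path_set(tree, dp, inst$patch_state(path_get(tree, dp), di))
          }
          for (p in inst$processes) {
            processes[[p$name]] <- p
            topology[[p$name]] <- inst$topology[[p$name]]
            streams[[p$name]] <- next_stream()
            dt_ticks[p$name] <- to_ticks(p$time_step)
            due[p$name] <- front + dt_ticks[p$name]
          }
        }
      } else if (m$type == "divide" || m$type == "delete") {
        # retire processes of removed compartments even without a template
        gone <- m$path[length(m$path)]
        r <- retire_agent_processes(gone)
        processes <- r$processes; topology <- r$topology
        due <- r$due; dt_ticks <- r$dt
      }
      if (length(processes) == 0L) break
    }
    while (next_emit <= front) {
      emit_now(next_emit * base_us / 1e6)
      next_emit <- next_emit + emit_ticks
    }
    if (length(processes) == 0L) break
  }

  emitted <- emitted[seq_len(n_emit)]
  all_names <- unique(unlist(lapply(emitted, names)))
  mat <- matrix(NA_real_, nrow = length(emitted), ncol = length(all_names),
                dimnames = list(NULL, all_names))
  for (i in seq_along(emitted)) mat[i, names(emitted[[i]])] <- emitted[[i]]
  list(emitted = as.data.frame(mat, check.names = FALSE),
       state = tree, processes = processes, topology = topology)
}
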