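# Composite builders: the packaged experiments assembling processes, stores
# and topologies into runnable hierarchies -- colony growth/division,
# glucose-lactose diauxie (single compartment or spatial), flagellar gene
# expression, and chemotaxis in uniform or gradient environments.

# merge subtree into tree at path, keeping any existing leaves
graft <- function(tree, path, subtree) {
  node <- path_get(tree, path)
  if (is.null(node)) return(path_set(tree, path, subtree))
  for (nm in names(subtree)) {
    if (is.null(node[[nm]])) node[[nm]] <- subtree[[nm]]
  }
  for (a in setdiff(names(attributes(subtree)), "names")) {
    attr(node, a) <- attr(subtree, a)
  }
  path_set(tree, path, node)
}

#' Build a named experiment
#'
#' Assembles the compartment hierarchy, processes and topology for one of
#' the packaged composites:
#' \describe{
#'   \item{grow_divide}{Environment with multi-body physics and diffusion,
#'     plus minimal exponential-growth agents that divide at 2000 fg.}
#'   \item{diauxie}{Transport + dynamic FBA + LacY expression on the toy
#'     glucose/lactose network; single compartment, or spatial with several
#'     agents.}
#'   \item{flagella_expression}{Stochastic sequence-based expression of the
#'     flagellar regulon in a growing, dividing cell.}
#'   \item{chemotaxis}{Receptor + motor + PMF agents swimming in a uniform or
#'     exponential-gradient attractant field.}
#' }
#'
#' @param config List with `experiment` (name above), `seed`, `total_time`,
#'   and per-experiment options (see the builders' arguments).
#' @return A runnable experiment description: list with `processes`,
#'   `topology`, `hierarchy`, `agent_template`, `emit_interval`,
#'   `total_time`, `seed`. Run it with [run_built()].
#' @export
build_experiment <- function(config) {
  name <- config$experiment
  builder <- switch(name,
    grow_divide = build_grow_divide,
    diauxie = build_diauxie,
    flagella_expression = build_flagella_expression,
    chemotaxis = build_chemotaxis,
    stop(sprintf("unknown experiment '%s'", name)))
  built <- do.call(builder, config[setdiff(names(config), "experiment")])
  built$name <- name
  built
}

#' Run a built experiment
#'
#' @param built Output of [build_experiment()].
#' @return [run_experiment()] result.
#' @export
run_built <- function(built) {
  run_experiment(built$processes, built$topology,
                 total_time = built$total_time,
                 hierarchy = built$hierarchy,
                 emit_interval = built$emit_interval %||% 1,
                 seed = built$seed %||% 0L,
                 agent_template = built$agent_template)
}

#' @rdname build_experiment
#' @param n_agents Number of initial agents.
#' @param total_time Simulated seconds.
#' @param seed RNG seed.
#' @param bounds Environment extent (um).
#' @param doubling_time,threshold Growth parameters.
#' @param physics_dt Physics time-step (s); growth experiments use 1.0 s
#'   since nothing moves fast.
#' @export
build_grow_divide <- function(n_agents = 1, total_time = 3600, seed = 0,
                              bounds = c(60, 60), doubling_time = 2400,
                              threshold = 2000, physics_dt = 1, ...) {
  cfg <- physics_config(dt = physics_dt, bounds = bounds, jitter_force = 0.01)
  agent_names <- paste0("c", seq_len(n_agents) - 1)
  template <- function(agent, agent_path) {
    gp <- growth_division_process(agent, agent_path,
                                  doubling_time = doubling_time,
                                  threshold = threshold)
    list(processes = list(gp),
         topology = stats::setNames(
           list(list(boundary = c("agents", agent, "boundary"))), gp$name),
         patch_state = function(subtree, i) {
           b <- subtree$boundary
           b$color <- store_leaf(mutate_color(b$color$value), b$color$schema)
           if (!is.null(b$location)) {
             ang <- b$orientation$value %||% 0
             off <- (if (i == 1) -0.5 else 0.5) * c(cos(ang), sin(ang))
             b$location <- store_leaf(b$location$value + off,
                                      b$location$schema)
           }
           subtree$boundary <- b
           subtree
         })
  }
  processes <- list(physics_process(cfg, species = NULL,
                                    time_step = physics_dt),
                    diffusion_process(time_step = 1))
  topology <- list(env.physics = list(agents = "agents", fields = "fields"),
                   env.diffusion = list(fields = "fields"))
  for (a in agent_names) {
    inst <- template(a, c("agents", a))
    processes <- c(processes, inst$processes)
    topology <- c(topology, inst$topology)
  }
  tree <- build_hierarchy(processes, topology)
  field <- make_gradient_field("uniform", nx = 12, ny = 12,
                               bin_size = bounds[1] / 12, c0 = 1,
                               species = "glc", diffusion = 100)
  tree <- graft(tree, "fields", make_field_store(field))
  for (i in seq_along(agent_names)) {
    loc <- bounds / 2 + c(2.5 * (i - (n_agents + 1) / 2), 0)
    tree <- graft(tree, c("agents", agent_names[i], "boundary"),
                  make_agent_boundary(location = loc,
                                      orientation = (i * 0.7) %% (2 * pi)))
    # growth agents divide: move boundary color/mass under the growth schema
  }
  list(processes = processes, topology = topology, hierarchy = tree,
       agent_template = template, emit_interval = 10,
       total_time = total_time, seed = seed)
}

#' @rdname build_experiment
#' @param glc0,lcts0 Initial glucose / lactose concentrations (mM).
#' @param env_volume Shared environment volume (um^3); with several agents
#'   this is the population setup, all drawing on one well-mixed pool.
#' @param transporters Initial `GlcT` copy number.
#' @param division_threshold Mass (fg) at which agents divide (`Inf`
#'   disables division).
#' @export
build_diauxie <- function(n_agents = 1, total_time = 600, seed = 0,
                          glc0 = 0.1, lcts0 = 2, env_volume = 2000,
                          transporters = 500,
                          division_threshold = Inf, ...) {
  network <- toy_metabolism()
  agent_names <- paste0("c", seq_len(n_agents) - 1)
  env_path <- "environment"
  template <- function(agent, agent_path) {
    tp <- transport_process(agent)
    mp <- metabolism_process(agent, agent_path, network,
                             env_volume = env_volume,
                             division_threshold = division_threshold)
    lp <- lacy_expression_process(agent)
    base <- c("agents", agent)
    topo <- stats::setNames(list(
      list(proteins = c(base, "proteins"), env = env_path,
           flux = c(base, "flux")),
      list(flux = c(base, "flux"), env = env_path,
           pools = c(base, "pools"), boundary = c(base, "boundary")),
      list(flux = c(base, "flux"), rna = c(base, "rna"),
           proteins = c(base, "proteins"))),
      c(tp$name, mp$name, lp$name))
    list(processes = list(tp, mp, lp), topology = topo)
  }
  processes <- list(); topology <- list()
  for (a in agent_names) {
    inst <- template(a, c("agents", a))
    processes <- c(processes, inst$processes)
    topology <- c(topology, inst$topology)
  }
  tree <- build_hierarchy(
    processes, topology,
    initial_state = list(environment = list(glc_e = glc0, lcts_e = lcts0)))
  for (a in agent_names) {
    tree <- path_set(tree, c("agents", a, "proteins", "GlcT"),
                     store_leaf(transporters,
                                var_schema(0, units = "counts",
                                           updater = "nonnegative_accumulate",
                                           divider = "binomial")))
  }
  list(processes = processes, topology = topology, hierarchy = tree,
       agent_template = template, emit_interval = 1,
       total_time = total_time, seed = seed)
}

#' @rdname build_experiment
#' @param network Flagellar network fixture (default [flagellar_network()]).
#' @param endoRNAse EndoRNAse copy number.
#' @export
build_flagella_expression <- function(total_time = 1200, seed = 0,
                                      network = flagellar_network(),
                                      doubling_time = 2400,
                                      endoRNAse = 1, ...) {
  agent <- "c0"
  xp <- expression_composite_process(agent, c("agents", agent), network,
                                     endoRNAse = endoRNAse)
  gp <- growth_division_process(agent, c("agents", agent),
                                doubling_time = doubling_time)
  template <- function(a, agent_path) {
    xp2 <- expression_composite_process(a, agent_path, network,
                                        endoRNAse = endoRNAse)
    gp2 <- growth_division_process(a, agent_path,
                                   doubling_time = doubling_time)
    list(processes = list(xp2, gp2),
         topology = stats::setNames(
           list(list(expression = c(agent_path, "expression"),
                     boundary = c(agent_path, "boundary")),
                list(boundary = c(agent_path, "boundary"))),
           c(xp2$name, gp2$name)),
         patch_state = function(subtree, i) {
           # polymerases are not expressed: reset to fixture counts
           ex <- subtree$expression
           ex$free_rnap <- store_leaf(network$polymerases$rnap,
                                      ex$free_rnap$schema)
           ex$free_ribosomes <- store_leaf(network$polymerases$ribosomes,
                                           ex$free_ribosomes$schema)
           subtree$expression <- ex
           subtree
         })
  }
  inst <- template(agent, c("agents", agent))
  topology <- inst$topology
  tree <- build_hierarchy(inst$processes, topology)
  tree <- graft(tree, c("agents", agent, "boundary"), make_agent_boundary())
  list(processes = inst$processes, topology = topology, hierarchy = tree,
       agent_template = template, emit_interval = 10,
       total_time = total_time, seed = seed)
}

#' Integrated gene-expression process (transcription + translation +
#' complexation + degradation)
#'
#' Wraps the four sequence-based stochastic steps as a single engine process
#' operating on an `expression` store: free/bound polymerases, pools,
#' transcripts, proteins and complexes. Flagellum counts are divided
#' binomially at division while polymerase counts are reset by the composite
#' template (they are not expressed by the model).
#'
#' Polymerase positions along templates are private mechanism state held by
#' the process instance, so a built experiment containing this process is
#' single-run: rebuild (e.g. via [build_experiment()]) before running again.
#'
#' @param agent Agent name.
#' @param agent_path Agent compartment path.
#' @param network [flagellar_network()]-style fixture.
#' @param endoRNAse Copy number for degradation.
#' @param time_step Seconds.
#' @return A [process()].
#' @export
expression_composite_process <- function(agent, agent_path, network,
                                         endoRNAse = 1, time_step = 1) {
  chromosome <- network$chromosome
  ops <- names(chromosome$operons)
  genes <- unname(chromosome_gene_names(chromosome))
  cxs <- unique(unlist(lapply(network$complexation$reactions, function(r) {
    names(r$stoich)[r$stoich > 0]
  })))
  count_schema <- function(divider = "binomial", emit = FALSE) {
    var_schema(0, units = "counts", updater = "set", divider = divider,
               emit = emit)
  }
  ports <- list(
    expression = c(
      list(free_rnap = var_schema(network$polymerases$rnap, units = "counts",
                                  updater = "set", divider = "copy"),
           free_ribosomes = var_schema(network$polymerases$ribosomes,
                                       units = "counts", updater = "set",
                                       divider = "copy"),
           atp = var_schema(1e7, units = "counts", updater = "set",
                            divider = "halve"),
           adp = var_schema(0, units = "counts", updater = "set",
                            divider = "halve")),
      stats::setNames(lapply(ops, function(o) count_schema(emit = TRUE)),
                      paste0("mrna_", ops)),
      stats::setNames(lapply(genes, function(g) count_schema()),
                      paste0("prot_", genes)),
      stats::setNames(lapply(cxs, function(x) count_schema(emit = TRUE)),
                      paste0("cx_", cxs))),
    boundary = list(mass = var_schema(1000, units = "fg", updater = "set",
                                      divider = "halve")))
  # persistent polymerase positions live outside the store: they are private
  # mechanism state of this process, carried in a closure environment keyed
  # by agent (positions are discarded for daughters, a simplification).
  mech <- new.env(parent = emptyenv())
  mech$tsc <- list(free_rnap = NULL, bound = list())
  mech$trl <- list(free_ribosomes = NULL, bound = list())
  mech$pools <- NULL

  update <- function(view, dt, params) {
    ex <- view$expression
    pools <- mech$pools
    if (is.null(pools)) {
      pools <- expression_pools(
        nucleotides = c(A = 1e6, C = 1e6, G = 1e6, U = 1e6),
        amino_acids = stats::setNames(rep(1e6, 20),
                                      strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
        atp = ex$atp, adp = ex$adp)
    }
    pools$atp <- ex$atp; pools$adp <- ex$adp
    for (o in ops) pools$transcripts[o] <- ex[[paste0("mrna_", o)]]
    for (g in genes) pools$proteins[g] <- ex[[paste0("prot_", g)]]
    for (x in cxs) pools$complexes[x] <- ex[[paste0("cx_", x)]]
    tsc <- mech$tsc; trl <- mech$trl
    tsc$free_rnap <- ex$free_rnap
    trl$free_ribosomes <- ex$free_ribosomes

    counts <- c(pools$proteins, pools$complexes)
    tf <- c(FlhDC = vget(counts, "FlhDC"), FliA = vget(counts, "fliA"))
    ts <- transcription_step(params$network$chromosome, tsc, pools, tf, dt)
    tsc <- ts$state; pools <- ts$pools
    tl <- translation_step(params$network$chromosome, trl, pools, dt)
    trl <- tl$state; pools <- tl$pools
    counts <- c(pools$proteins, pools$complexes)
    d <- complexation_step(counts, params$network$complexation, dt)
    for (nm in names(d)) {
      if (nm %in% genes) {
        pools$proteins[nm] <- vget(pools$proteins, nm) + d[[nm]]
      } else {
        pools$complexes[nm] <- vget(pools$complexes, nm) + d[[nm]]
      }
    }
    d2 <- flgM_export_step(c(pools$proteins, pools$complexes))
    for (nm in names(d2)) {
      if (nm %in% genes) {
        pools$proteins[nm] <- vget(pools$proteins, nm) + d2[[nm]]
      } else {
        pools$complexes[nm] <- vget(pools$complexes, nm) + d2[[nm]]
      }
    }
    dg <- degradation_step(params$network$chromosome, pools,
                           params$endoRNAse, dt)
    pools <- dg$pools
    mech$tsc <- tsc; mech$trl <- trl; mech$pools <- pools

    ex_upd <- list(free_rnap = tsc$free_rnap,
                   free_ribosomes = trl$free_ribosomes,
                   atp = pools$atp, adp = pools$adp)
    for (o in ops) ex_upd[[paste0("mrna_", o)]] <- vget(pools$transcripts, o)
    for (g in genes) ex_upd[[paste0("prot_", g)]] <- vget(pools$proteins, g)
    for (x in cxs) ex_upd[[paste0("cx_", x)]] <- vget(pools$complexes, x)
    list(expression = ex_upd)
  }
  process(paste0(agent, ".expression"), ports, update, time_step,
          parameters = list(network = network, endoRNAse = endoRNAse))
}

#' @rdname build_experiment
#' @param n_receptorless Number of agents with defunct chemoreceptors
#'   (motor-only controls).
#' @param n_flagella Flagella per agent.
#' @param field `"uniform"` or `"exponential"`.
#' @param ligand0 Uniform / base ligand concentration (mM).
#' @param lambda Gradient length scale (um).
#' @param start Common start location (um), default the arena center (lower
#'   third for gradient runs).
#' @param dt Chemotaxis time-step (s), 0.01.
#' @param emit_interval Emission interval (s); defaults to `dt` so run and
#'   tumble segments are resolved.
#' @export
build_chemotaxis <- function(n_agents = 1, n_receptorless = 0,
                             total_time = 300, seed = 0, n_flagella = 4,
                             field = "uniform", ligand0 = 0.1, lambda = 100,
                             bounds = NULL, start = NULL, dt = 0.01,
                             emit_interval = dt, ...) {
  if (is.null(bounds)) {
    bounds <- if (field == "uniform") c(4000, 4000) else c(400, 1200)
  }
  if (is.null(start)) {
    start <- if (field == "uniform") bounds / 2 else c(bounds[1] / 2, bounds[2] / 6)
  }
  cfg <- physics_config(dt = dt, bounds = bounds)
  agent_names <- paste0("c", seq_len(n_agents) - 1)
  defunct <- c(rep(FALSE, n_agents - n_receptorless),
               rep(TRUE, n_receptorless))

  fld <- NULL
  if (field == "exponential") {
    nyb <- ceiling(bounds[2] / 20)
    fld <- make_gradient_field("exponential", nx = ceiling(bounds[1] / 20),
                               ny = nyb, bin_size = 20, c0 = ligand0,
                               lambda = lambda, y0 = 0, diffusion = 0)
  }

  processes <- list(physics_process(cfg,
                                    species = if (is.null(fld)) NULL else "ligand",
                                    time_step = dt))
  topology <- list(env.physics = list(agents = "agents", fields = "fields"))
  for (i in seq_along(agent_names)) {
    a <- agent_names[i]
    base <- c("agents", a)
    lig_init <- if (is.null(fld)) ligand0 else ligand0 * exp(start[2] / lambda)
    rp <- receptor_process(a, base,
                           cluster = receptor_cluster(ligand0 = lig_init),
                           defunct = defunct[i], time_step = dt)
    mp <- motor_process(a, base, time_step = dt)
    pp <- pmf_process(a)
    processes <- c(processes, list(rp, mp, pp))
    topology[[rp$name]] <- list(boundary = c(base, "boundary"),
                                internal = c(base, "internal"))
    topology[[mp$name]] <- list(internal = c(base, "internal"),
                                flagella = c(base, "flagella"),
                                boundary = c(base, "boundary"))
    topology[[pp$name]] <- list(boundary = c(base, "boundary"))
  }
  tree <- build_hierarchy(processes, topology)
  if (!is.null(fld)) tree <- graft(tree, "fields", make_field_store(fld))
  for (i in seq_along(agent_names)) {
    a <- agent_names[i]
    lig <- if (is.null(fld)) ligand0 else ligand0 * exp(start[2] / lambda)
    tree <- graft(tree, c("agents", a, "boundary"),
                  make_agent_boundary(location = start,
                                      orientation = (i - 1) * 2 * pi / max(n_agents, 1),
                                      external_ligand = lig))
    lig_path <- c("agents", a, "boundary", "external_ligand")
    tree <- path_set(tree, lig_path,
                     store_leaf(lig, path_get(tree, lig_path)$schema))
    flg <- stats::setNames(
      lapply(seq_len(n_flagella), function(k) flagellum_store()),
      sprintf("flg_%d", seq_len(n_flagella)))
    attr(flg, "divider") <- "split_list"
    tree <- graft(tree, c("agents", a, "flagella"), flg)
  }
  list(processes = processes, topology = topology, hierarchy = tree,
       agent_template = NULL, emit_interval = emit_interval,
       total_time = total_time, seed = seed)
}
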