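# small processes reused across engine tests

counting_process <- function(name = "count", delta = 1, dt = 1,
                             updater = "accumulate") {
  process(name,
          ports = list(s = list(x = var_schema(0, updater = updater,
                                               emit = TRUE))),
          update = function(view, dt, params) list(s = list(x = params$delta)),
          time_step = dt, parameters = list(delta = delta))
}

noop_process <- function(name = "noop", dt = 1) {
  process(name, ports = list(s = list(x = var_schema(5, emit = TRUE))),
          update = function(view, dt, params) NULL, time_step = dt)
}

# a minimal dividing-agent experiment: one agent, mass grows stepwise and
# divides at the threshold
divider_template <- function(step_mass = 300, threshold = 2000) {
  function(agent, agent_path) {
    p <- process(paste0(agent, ".grow"),
                 ports = list(boundary = list(
                   mass = var_schema(1000, units = "fg",
                                     updater = "accumulate",
                                     divider = "halve", emit = TRUE),
                   n_prot = var_schema(10, units = "counts",
                                       updater = "accumulate",
                                       divider = "binomial"))),
                 update = function(view, dt, params) {
                   upd <- list(boundary = list(mass = params$step_mass,
                                               n_prot = 0))
                   if (view$boundary$mass + params$step_mass >= params$threshold) {
                     upd$.topology <- list(list(type = "divide",
                                                path = params$agent_path))
                   }
                   upd
                 },
                 time_step = 1,
                 parameters = list(step_mass = step_mass,
                                   threshold = threshold,
                                   agent_path = agent_path))
    list(processes = list(p),
         topology = stats::setNames(
           list(list(boundary = c(agent_path, "boundary"))), p$name))
  }
}
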