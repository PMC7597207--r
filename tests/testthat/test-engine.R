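test_that("updaters apply accumulate, set and nonnegative semantics", {
  expect_equal(apply_update(10, 5, var_schema(updater = "accumulate")), 15)
  expect_equal(apply_update(10, 7, var_schema(updater = "set")), 7)
  expect_equal(apply_update(3, -5, var_schema(updater = "nonnegative_accumulate")), 0)
  expect_error(
    apply_update(1, list(value = 1, units = "mM"),
                 var_schema(units = "fg", updater = "accumulate")),
    "unit mismatch")
})

test_that("processes run at their own time-steps and counts accumulate", {
  fast <- counting_process("fast", dt = 0.01)
  slow <- process("slow",
                  ports = list(s = list(y = var_schema(0, updater = "accumulate"))),
                  update = function(v, dt, p) list(s = list(y = 1)),
                  time_step = 1)
  res <- run_experiment(list(fast, slow),
                        list(fast = list(s = "st"), slow = list(s = "st")),
                        total_time = 2)
  vals <- store_values(res$state)
  expect_equal(vals$st$x, 200)  # 0.01 s process invoked 200 times over 2 s
  expect_equal(vals$st$y, 2)    # 1.0 s process invoked twice
})

test_that("a no-op process leaves state identical to the initial state", {
  res <- run_experiment(list(noop_process()), list(noop = list(s = "st")),
                        total_time = 7)
  expect_equal(store_values(res$state), list(st = list(x = 5)))
})

test_that("one +1 accumulate process at dt=1 over 10 s yields 10", {
  res <- run_experiment(list(counting_process()),
                        list(count = list(s = "st")), total_time = 10)
  expect_equal(store_values(res$state)$st$x, 10)
})

test_that("non-commensurate time-steps fail fast at construction", {
  p1 <- counting_process("a", dt = 1)
  p2 <- counting_process("b", dt = 1 / 3e6)  # off the microsecond lattice
  expect_error(
    run_experiment(list(p1, p2), list(a = list(s = "st"), b = list(s = "st")),
                   total_time = 2),
    "non-commensurate")
})

test_that("scheduler is deterministic: same config and seed, identical series", {
  stoch <- process("noise",
                   ports = list(s = list(x = var_schema(0, updater = "accumulate",
                                                        emit = TRUE))),
                   update = function(v, dt, p) list(s = list(x = stats::rnorm(1))),
                   time_step = 0.5)
  topo <- list(noise = list(s = "st"))
  r1 <- run_experiment(list(stoch), topo, total_time = 5, seed = 42)
  r2 <- run_experiment(list(stoch), topo, total_time = 5, seed = 42)
  expect_identical(r1$emitted, r2$emitted)
  r3 <- run_experiment(list(stoch), topo, total_time = 5, seed = 43)
  expect_false(identical(r2$emitted, r3$emitted))
})

test_that("a process cannot modify variables outside its declared ports", {
  rogue <- process("rogue",
                   ports = list(s = list(x = var_schema(0))),
                   update = function(v, dt, p) list(hidden = list(z = 1)),
                   time_step = 1)
  expect_error(
    run_experiment(list(rogue), list(rogue = list(s = "st",
                                                  hidden = "secret")),
                   total_time = 1),
    "undeclared port|unknown variable")
  rogue2 <- process("rogue2",
                    ports = list(s = list(x = var_schema(0))),
                    update = function(v, dt, p) list(s = list(ghost = 1)),
                    time_step = 1)
  expect_error(
    run_experiment(list(rogue2), list(rogue2 = list(s = "st")),
                   total_time = 1),
    "unknown variable")
})

test_that("a process at dt and at dt/2 with halved deltas agree exactly", {
  full <- counting_process("p", delta = 2, dt = 1)
  half <- counting_process("p", delta = 1, dt = 0.5)
  r1 <- run_experiment(list(full), list(p = list(s = "st")), total_time = 8)
  r2 <- run_experiment(list(half), list(p = list(s = "st")), total_time = 8)
  expect_identical(store_values(r1$state), store_values(r2$state))
})

test_that("dividers partition values correctly", {
  leaf <- function(v, div) store_leaf(v, var_schema(divider = div))
  halves <- divide_state(leaf(2000, "halve"))
  expect_equal(c(halves[[1]]$value, halves[[2]]$value), c(1000, 1000))

  set.seed(1)
  for (n in c(0, 1, 10, 101)) {
    d <- divide_state(leaf(n, "binomial"))
    expect_equal(d[[1]]$value + d[[2]]$value, n)
    expect_gte(d[[1]]$value, 0)
  }

  d <- divide_state(leaf(3.7, "copy"))
  expect_equal(c(d[[1]]$value, d[[2]]$value), c(3.7, 3.7))

  flg <- stats::setNames(lapply(1:5, function(i) flagellum_store()),
                         paste0("flg_", 1:5))
  attr(flg, "divider") <- "split_list"
  d <- divide_state(flg)
  expect_equal(length(d[[1]]), 3)  # five sub-compartments split 3 and 2
  expect_equal(length(d[[2]]), 2)
  expect_equal(names(d[[1]]), c("flg_1", "flg_3", "flg_5"))
})

test_that("divide replaces one agent with two daughters, environment untouched", {
  tmpl <- divider_template()
  inst <- tmpl("c0", c("agents", "c0"))
  env_leaf <- list(glc = store_leaf(1.5, var_schema(1.5, units = "mM")))
  tree <- build_hierarchy(inst$processes, inst$topology)
  tree$fields <- env_leaf
  res <- run_experiment(inst$processes, inst$topology, total_time = 6,
                        hierarchy = tree, agent_template = tmpl, seed = 1)
  agents <- names(res$state$agents)
  expect_setequal(agents, c("c00", "c01"))
  expect_equal(res$state$fields$glc$value, 1.5)
  masses <- vapply(agents, function(a) res$state$agents[[a]]$boundary$mass$value, 0)
  expect_true(all(masses < 2000) && all(masses > 0))
})

test_that("add_subcompartment and delete update the hierarchy in place", {
  flg <- stats::setNames(lapply(1:2, function(i) flagellum_store()),
                         paste0("flg_", 1:2))
  attr(flg, "divider") <- "split_list"
  tree <- list(agents = list(c0 = list(flagella = flg)))
  out <- apply_topology_update(tree, list(type = "add_subcompartment",
                                          path = c("agents", "c0", "flagella"),
                                          name = "flg_3",
                                          subtree = flagellum_store()))
  expect_equal(length(out$tree$agents$c0$flagella), 3)
  expect_equal(out$tree$agents$c0$flagella$flg_3$rotation$value, 0)

  out2 <- apply_topology_update(out$tree, list(type = "delete",
                                               path = c("agents", "c0")))
  expect_equal(length(out2$tree$agents), 0)
  expect_error(
    apply_topology_update(out2$tree, list(type = "divide",
                                          path = c("agents", "nope"))),
    "nonexistent")
})
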