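test_that("build_experiment rejects unknown names and builds the composites", {
  expect_error(build_experiment(list(experiment = "nope")), "unknown experiment")

  gd <- build_experiment(list(experiment = "grow_divide", n_agents = 1,
                              total_time = 100, seed = 1))
  expect_setequal(names(gd$topology),
                  c("env.physics", "env.diffusion", "c0.growth"))
  expect_true(!is.null(gd$hierarchy$agents$c0$boundary$mass))

  dx <- build_experiment(list(experiment = "diauxie", n_agents = 3,
                              total_time = 10, seed = 1))
  expect_equal(length(names(dx$hierarchy$agents)), 3)
  expect_true(all(paste0("c", 0:2, ".metabolism") %in% names(dx$topology)))

  cx <- build_experiment(list(experiment = "chemotaxis", n_agents = 12,
                              n_receptorless = 6, field = "exponential",
                              total_time = 1, seed = 1))
  expect_equal(length(names(cx$hierarchy$agents)), 12)
  expect_equal(length(cx$hierarchy$agents$c0$flagella), 4)
  # all twelve start at the same point
  locs <- vapply(names(cx$hierarchy$agents), function(a) {
    cx$hierarchy$agents[[a]]$boundary$location$value
  }, c(0, 0))
  expect_equal(max(locs[1, ]) - min(locs[1, ]), 0)
})

test_that("fixture generation is deterministic and schema-valid", {
  dir <- withr::local_tempdir()
  p1 <- generate_fixtures("flagellar_network", out_dir = dir, seed = 7)
  txt1 <- readLines(p1)
  p2 <- generate_fixtures("flagellar_network", out_dir = dir, seed = 7)
  expect_identical(txt1, readLines(p2))

  fx <- load_chromosome(p1)
  expect_equal(length(fx$chromosome$operons), 7)
  expect_s3_class(fx$complexation, "complexation_network")
  expect_equal(fx$polymerases$rnap, 10)
  expect_equal(fx$polymerases$ribosomes, 20)

  pm <- generate_fixtures("toy_metabolism", out_dir = dir)
  net <- load_metabolic_network(pm)
  sol <- solve_fba(net, list(EX_glc = c(1, 1), EX_lcts = c(0.5, 0.5)))
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective, 0)

  pc <- generate_fixtures("toy_chromosome", out_dir = dir)
  chrom <- load_chromosome(pc)
  expect_s3_class(chrom, "chromosome_config")
  expect_true("lacY" %in% names(chrom$operons$lac$genes))
})

test_that("packaged fixtures in extdata match the generators", {
  pkg_fix <- system.file("extdata", "flagellar_network.json",
                         package = "cellscale")
  dir <- withr::local_tempdir()
  fresh <- generate_fixtures("flagellar_network", out_dir = dir, seed = 7)
  expect_identical(readLines(pkg_fix), readLines(fresh))
})

test_that("motility summary on constructed trajectories", {
  # straight-line run at 10 um/s: speed 10, no turns
  n <- 101
  traj <- data.frame(x = seq(0, 10, length.out = n), y = 0,
                     state = rep(1, n))
  s <- summarize_motility(traj, dt = 0.01)
  expect_equal(s$mean_speed, 10)
  expect_equal(length(s$reorientation_angles), 0)

  # alternating 1 s runs and 0.5 s tumbles
  st <- rep(c(rep(1, 100), rep(2, 50)), 5)
  traj <- data.frame(x = cumsum(rep(0.1, length(st))), y = 0, state = st)
  s <- summarize_motility(traj, dt = 0.01)
  expect_equal(unique(s$run_durations), 1.0)
  expect_equal(unique(s$tumble_durations), 0.5)

  # a 90 degree heading change between two constructed runs
  traj <- data.frame(
    x = c(seq(0, 1, length.out = 50), rep(1, 5), rep(1, 50)),
    y = c(rep(0, 50), rep(0, 5), seq(0, 1, length.out = 50)),
    state = c(rep(1, 50), rep(2, 5), rep(1, 50)))
  s <- summarize_motility(traj, dt = 0.01)
  expect_equal(s$reorientation_angles, 90)

  expect_warning(
    summarize_motility(data.frame(x = 0:5, y = 0, state = rep(2, 6)), 0.01),
    "no run")
})

test_that("emitted series export as JSONL and CSV", {
  res <- run_experiment(list(counting_process()),
                        list(count = list(s = "st")), total_time = 3)
  dir <- withr::local_tempdir()
  jp <- write_emitted_jsonl(res$emitted, file.path(dir, "out.jsonl"))
  lines <- readLines(jp)
  expect_equal(length(lines), 4)  # t = 0..3
  rec <- jsonlite::fromJSON(lines[4])
  expect_equal(rec[["st/x"]], 3)
  cp <- write_emitted_csv(res$emitted, file.path(dir, "out.csv"))
  df <- utils::read.csv(cp, check.names = FALSE)
  expect_equal(df[["st/x"]], 0:3)
})

test_that("experiment configs load from YAML and JSON", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("experiment: chemotaxis", "n_agents: 2", "total_time: 5"), yml)
  cfg <- load_experiment_config(yml)
  expect_equal(cfg$experiment, "chemotaxis")
  expect_equal(cfg$n_agents, 2)
  jsn <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(experiment = "diauxie", total_time = 10), jsn,
                       auto_unbox = TRUE)
  cfg2 <- load_experiment_config(jsn)
  expect_equal(cfg2$experiment, "diauxie")
})

test_that("each named experiment runs end-to-end at reduced scale", {
  for (cfg in list(
    list(experiment = "grow_divide", n_agents = 1, total_time = 50, seed = 1),
    list(experiment = "diauxie", n_agents = 1, total_time = 20, seed = 1),
    list(experiment = "flagella_expression", total_time = 30, seed = 1),
    list(experiment = "chemotaxis", n_agents = 1, total_time = 2, seed = 1))) {
    res <- run_built(build_experiment(cfg))
    expect_true(is.data.frame(res$emitted))
    expect_gt(nrow(res$emitted), 1)
    expect_true("time" %in% names(res$emitted))
  }
})
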