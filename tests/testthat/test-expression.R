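ample_pools <- function(atp = 1e6) {
  expression_pools(
    nucleotides = c(A = 1e5, C = 1e5, G = 1e5, U = 1e5),
    amino_acids = stats::setNames(rep(1e5, 20),
                                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
    atp = atp)
}

two_operon_chromosome <- function(len1 = 100, len2 = 200) {
  set.seed(99)
  chromosome_config(list(
    opA = list(sequence = cellscale:::synthetic_dna(len1),
               promoter = list(basal = 5, sites = list()),
               genes = list(gA = list(aa_seq = cellscale:::synthetic_protein(20),
                                      rbs_affinity = 0.5))),
    opB = list(sequence = cellscale:::synthetic_dna(len2),
               promoter = list(basal = 0,
                               sites = list(list(tf = "TF1", role = "activator",
                                                 threshold = 10, weight = 4),
                                            list(tf = "Rep1", role = "repressor",
                                                 threshold = 5, weight = 0))),
               genes = list(gB = list(aa_seq = cellscale:::synthetic_protein(100),
                                      rbs_affinity = 0.5)))))
}

test_that("gillespie draws match exponential waits and propensity ratios", {
  expect_identical(gillespie_draw(c(a = 0, b = 0))$reaction, NA_character_)
  expect_error(gillespie_draw(c(a = -1)), "nonnegative")
  set.seed(8)
  waits <- replicate(1e4, gillespie_draw(c(r = 2))$wait)
  expect_equal(mean(waits), 0.5, tolerance = 0.05)
  picks <- replicate(4e3, gillespie_draw(c(r1 = 1, r2 = 3))$reaction)
  expect_equal(mean(picks == "r2"), 0.75, tolerance = 0.05)
})

test_that("promoter propensities follow the binary-sum gate", {
  chrom <- two_operon_chromosome()
  # all activators below threshold: basal only
  p <- promoter_binding_propensities(chrom, c(TF1 = 0, Rep1 = 0))
  expect_equal(unname(p["opA"]), 5)
  expect_equal(unname(p["opB"]), 0)
  # activator above threshold: elevated
  p <- promoter_binding_propensities(chrom, c(TF1 = 50, Rep1 = 0))
  expect_equal(unname(p["opB"]), 4)
  # repressor occupied: zero (default floor)
  p <- promoter_binding_propensities(chrom, c(TF1 = 50, Rep1 = 50))
  expect_equal(unname(p["opB"]), 0)
  # configured basal floor under repression
  p <- promoter_binding_propensities(chrom, c(TF1 = 50, Rep1 = 50),
                                     repressor_floor = 0.25)
  expect_equal(unname(p["opB"]), 1)
  expect_error(promoter_binding_propensities(chrom, c(TF1 = 0)), "unknown")
})

test_that("RNAP elongates 50 bp/s, pays 1 ATP/nt, and stalls without ATP", {
  chrom <- two_operon_chromosome(len2 = 500)
  pools <- ample_pools()
  state <- list(free_rnap = 0,
                bound = list(list(operon = "opB", position = 0)))
  out <- transcription_step(chrom, state, pools, c(TF1 = 0, Rep1 = 0), dt = 1)
  expect_equal(out$state$bound[[1]]$position, 50)
  expect_equal(sum(pools$nucleotides) - sum(out$pools$nucleotides), 50)
  expect_equal(pools$atp - out$pools$atp, 50)
  expect_equal(out$pools$adp, 50)

  starved <- ample_pools(atp = 0)
  out2 <- transcription_step(chrom, state, starved, c(TF1 = 0, Rep1 = 0), dt = 1)
  expect_equal(out2$state$bound[[1]]$position, 0)  # stall in place
})

test_that("a 100 bp template completes in 2 s and frees the polymerase", {
  chrom <- two_operon_chromosome(len1 = 100)
  pools <- ample_pools()
  state <- list(free_rnap = 0,
                bound = list(list(operon = "opA", position = 0)))
  s1 <- transcription_step(chrom, state, pools, c(TF1 = 0, Rep1 = 0), dt = 1)
  expect_equal(length(s1$completed), 0)
  s2 <- transcription_step(chrom, s1$state, s1$pools, c(TF1 = 0, Rep1 = 0), dt = 1)
  expect_equal(unname(s2$completed["opA"]), 1)
  expect_equal(unname(s2$pools$transcripts[["opA"]]), 1)
  expect_equal(s2$state$free_rnap, 1)
})

test_that("promoter occlusion blocks binding until the RNAP is 30 bp away", {
  chrom <- two_operon_chromosome()
  pools <- ample_pools()
  set.seed(3)
  # an RNAP parked at position 10 occludes opA's strong promoter
  state <- list(free_rnap = 5,
                bound = list(list(operon = "opA", position = 10)))
  starved <- ample_pools(atp = 0)  # freeze elongation to isolate binding
  out <- transcription_step(chrom, state, starved, c(TF1 = 0, Rep1 = 0), dt = 5)
  expect_equal(length(out$state$bound), 1)
  # at 40 bp the promoter is free and binding resumes
  state$bound[[1]]$position <- 40
  out2 <- transcription_step(chrom, state, starved, c(TF1 = 0, Rep1 = 0), dt = 5)
  expect_gt(length(out2$state$bound), 1)
})

test_that("ribosomes elongate 22 aa/s and pay 2 ATP per amino acid", {
  chrom <- two_operon_chromosome()
  pools <- ample_pools()
  pools$transcripts <- c(opB = 1)
  state <- list(free_ribosomes = 0,
                bound = list(list(operon = "opB", gene = "gB", position = 0)))
  out <- translation_step(chrom, state, pools, dt = 1)
  expect_equal(out$state$bound[[1]]$position, 22)
  expect_equal(sum(pools$amino_acids) - sum(out$pools$amino_acids), 22)
  expect_equal(pools$atp - out$pools$atp, 44)

  # completing the 100-aa protein: composition and 200 ATP total
  st <- state; pl <- pools
  for (k in 1:5) {
    out <- translation_step(chrom, st, pl, dt = 1)
    st <- out$state; pl <- out$pools
  }
  expect_equal(unname(pl$proteins[["gB"]]), 1)
  expect_equal(pools$atp - pl$atp, 200)
  comp <- aa_composition(chrom$operons$opB$genes$gB$aa_seq)
  expect_equal(pools$amino_acids - pl$amino_acids, comp)
  expect_equal(st$free_ribosomes, 1)

  # no free ribosomes, no initiation
  set.seed(5)
  out0 <- translation_step(chrom, list(free_ribosomes = 0, bound = list()),
                           pools, dt = 10)
  expect_equal(length(out0$state$bound), 0)
})

test_that("complexation fires only with all reactants and conserves monomers", {
  net <- complexation_network(list(
    ab = list(stoich = c(A = -1, B = -1, AB = 1), rate = 1000)))
  set.seed(6)
  d <- complexation_step(c(A = 10, B = 0, AB = 0), net, dt = 1)
  expect_true(all(d == 0))  # missing B: never fires
  d <- complexation_step(c(A = 10, B = 10, AB = 0), net, dt = 1)
  expect_equal(unname(d["A"]), unname(d["B"]))
  expect_equal(unname(d["AB"]), -unname(d["A"]))
  expect_equal(unname(d["AB"]), 10)  # fast propensity exhausts the monomers

  # multi-stage chain reaches the terminal complex
  chain <- complexation_network(list(
    s1 = list(stoich = c(m1 = -2, inter = 1), rate = 1000),
    s2 = list(stoich = c(inter = -1, m2 = -1, flagellum = 1), rate = 1000)))
  d <- complexation_step(c(m1 = 4, m2 = 2, inter = 0, flagellum = 0),
                         chain, dt = 1)
  expect_equal(unname(d["flagellum"]), 2)
})

test_that("degradation returns bases at one ATP per nucleotide", {
  chrom <- two_operon_chromosome(len1 = 100)
  pools <- ample_pools(atp = 1000)
  pools$transcripts <- c(opA = 1)
  set.seed(2)
  # crank the hazard so the single transcript is degraded this step
  out <- degradation_step(chrom, pools, endoRNAse_count = 1e5, dt = 1,
                          kcat = 1, Km = 1)
  expect_equal(unname(out$degraded["opA"]), 1)
  expect_equal(sum(out$pools$nucleotides) - sum(pools$nucleotides), 100)
  expect_equal(pools$atp - out$pools$atp, 100)
  comp <- nt_composition(chrom$operons$opA$sequence)
  expect_equal(out$pools$nucleotides - pools$nucleotides, comp)

  out0 <- degradation_step(chrom, pools, endoRNAse_count = 0, dt = 1)
  expect_equal(length(out0$degraded), 0)
})

test_that("nucleotide and energy bookkeeping balance over a full run", {
  net <- flagellar_network()
  # monomer conservation holds with degradation active (bases are returned)
  res <- run_expression(net, total_time = 120, dt = 1, endoRNAse = 5)
  poly <- polymerized_nt(net$chromosome, res$pools, res$tsc_state)
  expect_equal(sum(res$pools$nucleotides) + sum(poly), 4e6)
  expect_equal(res$pools$atp + res$pools$adp, 1e7)

  # without degradation the energy ledger closes exactly:
  # ADP made = nt transcribed + 2 x aa translated
  res0 <- run_expression(net, total_time = 120, dt = 1, endoRNAse = 0)
  nt_used <- 4e6 - sum(res0$pools$nucleotides)
  aa_used <- 20e6 - sum(res0$pools$amino_acids)
  expect_equal(res0$pools$adp, nt_used + 2 * aa_used)
  expect_equal(res0$pools$atp, 1e7 - res0$pools$adp)
})

test_that("just-in-time ordering: early, middle, late transcript classes", {
  net <- flagellar_network()
  first_times <- replicate(20, {
    res <- run_expression(net, total_time = 400, dt = 1, endoRNAse = 0)
    ser <- res$transcript_series
    first <- function(op) {
      i <- which(ser[, op] > 0)[1]
      if (is.na(i)) Inf else i
    }
    c(early = first("flhDC"),
      middle = min(first("flgAMN"), first("fliAZY")),
      late = min(first("fliC"), first("motAB_cheAW")))
  })
  med <- apply(first_times, 1, stats::median)
  expect_lt(med[["early"]], med[["middle"]])
  expect_lt(med[["middle"]], med[["late"]])
})

test_that("the expressing, growing cell keeps nonzero flagella across divisions", {
  built <- build_flagella_expression(total_time = 2600, seed = 1,
                                     doubling_time = 1200)
  res <- run_built(built)
  agents <- names(res$state$agents)
  expect_gte(length(agents), 2)  # at least one division happened
  flg <- vapply(agents, function(a) {
    res$state$agents[[a]]$expression$cx_flagellum$value
  }, 0)
  expect_gt(sum(flg), 0)
})
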