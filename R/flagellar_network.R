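# The packaged flagellar regulatory-network fixture: seven operons under
# FlhDC / FliA control, a complexation chain to the assembled flagellum, and
# FlgM sequestration of FliA. Gene and protein sequences are synthetic
# placeholders of reduced, realistic-ordering lengths (the network topology,
# not the sequence content, carries the biology); they are generated
# deterministically from a fixed seed.

synthetic_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

synthetic_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

#' The flagellar expression network fixture
#'
#' Seven operons: the constitutive master regulator operon `flhDC`; four
#' middle (class 2) operons activated by the FlhDC complex with increasing
#' thresholds (`flgAMN`, `flgBCD`, `fliFGH`, `fliAZY`); and two late
#' (class 3) operons activated by free FliA (`fliC`, `motAB_cheAW`). FliA is
#' sequestered by FlgM until basal-body completion triggers FlgM export. The
#' increasing activation thresholds generate "just-in-time" transcript
#' ordering: early before middle before late.
#'
#' @param seed Seed for the synthetic sequences.
#' @return List with `chromosome` (a [chromosome_config()]), `complexation`
#'   (a [complexation_network()]), and `polymerases`
#'   (`list(rnap = 10, ribosomes = 20)`, the copy numbers estimated to
#'   support about four flagella).
#' @export
flagellar_network <- function(seed = 7) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  gene <- function(len, aff = 0.2) list(aa_seq = synthetic_protein(len),
                                        rbs_affinity = aff)
  site <- function(tf, threshold, weight = 0.05, role = "activator") {
    list(tf = tf, role = role, threshold = threshold, weight = weight)
  }
  op <- function(genes, basal = 0, sites = list()) {
    nt <- sum(vapply(genes, function(g) 3 * nchar(g$aa_seq), 0)) + 30
    list(sequence = synthetic_dna(nt),
         promoter = list(basal = basal, sites = sites),
         genes = genes)
  }

  operons <- list(
    flhDC = op(list(flhD = gene(40), flhC = gene(45)), basal = 0.02),
    flgAMN = op(list(flgM = gene(30), flgN = gene(35)),
                sites = list(site("FlhDC", 20))),
    flgBCD = op(list(flgB = gene(40), flgC = gene(40), flgD = gene(40)),
                sites = list(site("FlhDC", 35))),
    fliFGH = op(list(fliF = gene(50), fliG = gene(40), fliH = gene(30)),
                sites = list(site("FlhDC", 50))),
    fliAZY = op(list(fliA = gene(40), fliZ = gene(30)),
                sites = list(site("FlhDC", 65))),
    fliC = op(list(fliC = gene(60, aff = 0.3)),
              sites = list(site("FliA", 20, weight = 0.08))),
    motAB_cheAW = op(list(motA = gene(40), motB = gene(40),
                          cheA = gene(40), cheW = gene(30)),
                     sites = list(site("FliA", 20, weight = 0.08))))

  cxn <- complexation_network(list(
    cx_FlhDC = list(stoich = c(flhD = -1, flhC = -1, FlhDC = 1), rate = 1000),
    cx_FlgM_FliA = list(stoich = c(flgM = -1, fliA = -1, FlgM_FliA = 1),
                        rate = 1000),
    cx_basal_body = list(stoich = c(flgB = -1, flgC = -1, flgD = -1,
                                    fliF = -1, fliG = -1, fliH = -1,
                                    basal_body = 1), rate = 1000),
    cx_flagellum = list(stoich = c(basal_body = -1, fliC = -4, motA = -1,
                                   motB = -1, flagellum = 1), rate = 1000)))

  list(chromosome = chromosome_config(operons), complexation = cxn,
       polymerases = list(rnap = 10, ribosomes = 20))
}

#' Trigger FlgM export after basal-body completion
#'
#' Once at least one basal body (or complete flagellum) exists, free FlgM is
#' exported from the cell and FlgM-sequestered FliA is released. Returns
#' count deltas.
#'
#' @param counts Named protein/complex counts.
#' @return Named deltas (possibly empty).
#' @export
flgM_export_step <- function(counts) {
  done <- vget(counts, "basal_body") + vget(counts, "flagellum")
  deltas <- numeric()
  if (done >= 1) {
    seq_cx <- vget(counts, "FlgM_FliA")
    free_flgM <- vget(counts, "flgM")
    if (seq_cx > 0) {
      deltas["FlgM_FliA"] <- -seq_cx
      deltas["fliA"] <- seq_cx
    }
    if (free_flgM > 0) deltas["flgM"] <- -free_flgM
  }
  deltas
}

#' Run the integrated gene-expression processes
#'
#' Steps transcription, translation, complexation (with FlgM export), and
#' degradation at `dt` over `total_time`, with replete nucleotide/amino-acid
#' and ATP pools. TF inputs to the promoters are the FlhDC complex count and
#' the free FliA count.
#'
#' @param network A [flagellar_network()]-style list (chromosome,
#'   complexation, polymerases).
#' @param total_time Simulated seconds.
#' @param dt Time-step (s), default 1.
#' @param endoRNAse Copy number for degradation.
#' @param pools Optional starting [expression_pools()]; defaults to replete
#'   pools.
#' @param record Record per-step transcript counts.
#' @return List: `pools`, `tsc_state`, `trl_state`, and (if `record`)
#'   `transcript_series` (matrix time x operon).
#' @export
run_expression <- function(network, total_time, dt = 1, endoRNAse = 1,
                           pools = NULL, record = TRUE) {
  chromosome <- network$chromosome
  if (is.null(pools)) {
    pools <- expression_pools(
      nucleotides = c(A = 1e6, C = 1e6, G = 1e6, U = 1e6),
      amino_acids = stats::setNames(rep(1e6, 20),
                                    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
      atp = 1e7)
  }
  tsc <- list(free_rnap = network$polymerases$rnap, bound = list())
  trl <- list(free_ribosomes = network$polymerases$ribosomes, bound = list())
  ops <- names(chromosome$operons)
  n_steps <- round(total_time / dt)
  series <- if (record) matrix(0, n_steps, length(ops),
                               dimnames = list(NULL, ops))
  for (k in seq_len(n_steps)) {
    counts <- c(pools$proteins, pools$complexes)
    tf <- c(FlhDC = vget(counts, "FlhDC"), FliA = vget(counts, "fliA"))
    ts <- transcription_step(chromosome, tsc, pools, tf, dt)
    tsc <- ts$state; pools <- ts$pools
    tl <- translation_step(chromosome, trl, pools, dt)
    trl <- tl$state; pools <- tl$pools
    counts <- c(pools$proteins, pools$complexes)
    d <- complexation_step(counts, network$complexation, dt)
    for (nm in names(d)) {
      if (nm %in% names(pools$proteins) || nm %in% chromosome_gene_names(chromosome)) {
        pools$proteins[nm] <- vget(pools$proteins, nm) + d[[nm]]
      } else {
        pools$complexes[nm] <- vget(pools$complexes, nm) + d[[nm]]
      }
    }
    counts <- c(pools$proteins, pools$complexes)
    d2 <- flgM_export_step(counts)
    for (nm in names(d2)) {
      if (nm == "fliA" || nm == "flgM") {
        pools$proteins[nm] <- vget(pools$proteins, nm) + d2[[nm]]
      } else {
        pools$complexes[nm] <- vget(pools$complexes, nm) + d2[[nm]]
      }
    }
    dg <- degradation_step(chromosome, pools, endoRNAse, dt)
    pools <- dg$pools
    if (record) {
      for (opn in ops) series[k, opn] <- vget(pools$transcripts, opn)
    }
  }
  out <- list(pools = pools, tsc_state = tsc, trl_state = trl)
  if (record) out$transcript_series <- series
  out
}

chromosome_gene_names <- function(chromosome) {
  unlist(lapply(chromosome$operons, function(o) names(o$genes)))
}
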