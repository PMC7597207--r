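# Sequence-driven stochastic gene expression: Gillespie binding of
# polymerases to templates, deterministic elongation at fixed rates,
# complexation, and mRNA degradation, with explicit nucleotide, amino-acid
# and ATP accounting. Transcription elongates at 50 bp/s (1 ATP per
# nucleotide) and frees the promoter 30 bp downstream; translation at
# 22 aa/s (2 ATP per amino acid) with a 50 bp ribosome occlusion distance;
# degradation returns bases at 1 ATP per nucleotide. Proteins are not
# degraded; their loss is dilution by growth and division.

TSC_RATE_BP_S <- 50      # RNAP elongation, base pairs / s
TSC_OCCLUSION_BP <- 30   # promoter freed at this distance
TRL_RATE_AA_S <- 22      # ribosome elongation, amino acids / s
TRL_OCCLUSION_BP <- 50   # min spacing between ribosomes on one mRNA

#' One Gillespie draw
#'
#' Samples a waiting time from Exponential(sum of propensities) and picks a
#' reaction with probability proportional to its propensity.
#'
#' @param propensities Named numeric, all finite and >= 0.
#' @return List `wait` (s; `Inf` when all propensities are zero) and
#'   `reaction` (name or `NA`).
#' @export
gillespie_draw <- function(propensities) {
  if (any(propensities < 0) || any(!is.finite(propensities))) {
    stop("propensities must be finite and nonnegative")
  }
  a0 <- sum(propensities)
  if (a0 <= 0) return(list(wait = Inf, reaction = NA_character_))
  wait <- stats::rexp(1, a0)
  r <- sample(names(propensities), 1, prob = propensities)
  list(wait = wait, reaction = r)
}

#' Chromosome / regulatory network configuration
#'
#' @param operons Named list; each operon is a list with `sequence`
#'   (sense-strand nucleotide string; coordinates 0-based half-open),
#'   `promoter` (list: `basal` propensity in 1/s and `sites`, a list of
#'   `list(tf=, role="activator"|"repressor", threshold=, weight=)`),
#'   `terminator` (position, defaults to the sequence length), and `genes`
#'   (named list: gene -> `list(aa_seq=, rbs_affinity=)`).
#' @return A `chromosome_config`.
#' @export
chromosome_config <- function(operons) {
  for (op in names(operons)) {
    o <- operons[[op]]
    len <- nchar(o$sequence)
    term <- o$terminator %||% len
    if (term > len || term < 1) stop(sprintf("terminator outside sequence in '%s'", op))
    operons[[op]]$terminator <- term
    if (length(o$genes) == 0) stop(sprintf("operon '%s' has no genes", op))
    for (g in names(o$genes)) {
      if (is.null(o$genes[[g]]$aa_seq)) {
        stop(sprintf("gene '%s' lacks a protein sequence", g))
      }
    }
  }
  structure(list(operons = operons), class = "chromosome_config")
}

#' Nucleotide composition of a (DNA sense strand) segment, as transcript bases
#' @param seq Nucleotide string.
#' @return Named counts over A, C, G, U.
#' @export
nt_composition <- function(seq) {
  rna <- chartr("T", "U", seq)
  chars <- strsplit(rna, "")[[1]]
  counts <- c(A = 0, C = 0, G = 0, U = 0)
  tab <- table(chars)
  counts[names(tab)] <- as.numeric(tab)
  counts
}

#' Amino-acid composition of a protein segment
#' @param aa_seq One-letter amino-acid string.
#' @return Named counts over the 20 canonical letters.
#' @export
aa_composition <- function(aa_seq) {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  counts <- stats::setNames(numeric(20), letters20)
  tab <- table(strsplit(aa_seq, "")[[1]])
  counts[names(tab)] <- as.numeric(tab)
  counts
}

#' Create expression pools
#'
#' @param nucleotides Named counts (A, C, G, U).
#' @param amino_acids Named counts (20 one-letter codes).
#' @param atp,adp ATP/ADP counts.
#' @param transcripts Named mRNA counts per operon.
#' @param proteins Named monomer counts per gene.
#' @param complexes Named complex counts.
#' @return An `expression_pools` list.
#' @export
expression_pools <- function(nucleotides = c(A = 0, C = 0, G = 0, U = 0),
                             amino_acids = aa_composition(""),
                             atp = 0, adp = 0,
                             transcripts = numeric(),
                             proteins = numeric(),
                             complexes = numeric()) {
  structure(list(nucleotides = nucleotides, amino_acids = amino_acids,
                 atp = atp, adp = adp, transcripts = transcripts,
                 proteins = proteins, complexes = complexes),
            class = "expression_pools")
}

#' Promoter binding propensities under transcription-factor control
#'
#' Binary-sum gate: each site is occupied when its transcription factor's
#' concentration exceeds the site threshold. Occupied activator sites add
#' their weights to the basal propensity; an occupied repressor site
#' multiplies the result by `repressor_floor` (default 0).
#'
#' @param chromosome A [chromosome_config()].
#' @param tf_concentrations Named numeric of TF concentrations/counts.
#' @param repressor_floor Propensity fraction remaining under repression.
#' @return Named propensities (1/s) per operon.
#' @export
promoter_binding_propensities <- function(chromosome, tf_concentrations,
                                          repressor_floor = 0) {
  out <- numeric()
  for (op in names(chromosome$operons)) {
    pr <- chromosome$operons[[op]]$promoter
    prop <- pr$basal %||% 0
    repressed <- FALSE
    for (site in pr$sites %||% list()) {
      conc <- vget(tf_concentrations, site$tf, default = NULL)
      if (is.null(conc)) stop(sprintf("unknown transcription factor '%s'", site$tf))
      occupied <- conc > site$threshold
      if (occupied && site$role == "activator") prop <- prop + site$weight
      if (occupied && site$role == "repressor") repressed <- TRUE
    }
    if (repressed) prop <- prop * repressor_floor
    out[op] <- prop
  }
  out
}

#' Advance transcription by one time-step
#'
#' RNAP binding uses the Gillespie algorithm with promoter propensities from
#' [promoter_binding_propensities()]; a promoter is occluded while its last
#' bound RNAP is within 30 bp. Bound RNAPs then elongate 50 bp/s,
#' consuming one matching nucleotide and one ATP per base pair; elongation
#' stalls when pools run short. Reaching the terminator releases the RNAP and
#' increments the operon's transcript count.
#'
#' @param chromosome A [chromosome_config()].
#' @param state List: `free_rnap` count and `bound` (list of
#'   `list(operon=, position=)`).
#' @param pools An [expression_pools()].
#' @param tf_concentrations Named TF concentrations for the promoters.
#' @param dt Time-step (s, > 0).
#' @param repressor_floor Passed to [promoter_binding_propensities()].
#' @return List: `state`, `pools`, `completed` (named new transcript counts).
#' @export
transcription_step <- function(chromosome, state, pools, tf_concentrations,
                               dt, repressor_floor = 0) {
  stopifnot(dt > 0)
  props <- promoter_binding_propensities(chromosome, tf_concentrations,
                                         repressor_floor)
  occluded <- function() {
    occ <- stats::setNames(rep(FALSE, length(props)), names(props))
    for (b in state$bound) {
      if (b$position < TSC_OCCLUSION_BP) occ[b$operon] <- TRUE
    }
    occ
  }
  t <- 0
  repeat {
    if (state$free_rnap <= 0) break
    active <- props
    active[occluded()] <- 0
    draw <- gillespie_draw(active)
    if (!is.finite(draw$wait) || t + draw$wait > dt) break
    t <- t + draw$wait
    state$bound[[length(state$bound) + 1L]] <- list(operon = draw$reaction,
                                                    position = 0)
    state$free_rnap <- state$free_rnap - 1L
  }

  completed <- numeric()
  keep <- rep(TRUE, length(state$bound))
  adv_max <- round(TSC_RATE_BP_S * dt)
  for (i in seq_along(state$bound)) {
    b <- state$bound[[i]]
    op <- chromosome$operons[[b$operon]]
    target <- min(b$position + adv_max, op$terminator)
    n <- target - b$position
    if (n <= 0) next
    seg <- substr(op$sequence, b$position + 1, target)
    comp <- nt_composition(seg)
    if (pools$atp >= n && all(pools$nucleotides >= comp)) {
      pools$nucleotides <- pools$nucleotides - comp
      pools$atp <- pools$atp - n
      pools$adp <- pools$adp + n
      b$position <- target
    }  # else stall in place until pools recover
    if (b$position >= op$terminator) {
      completed[b$operon] <- vget(completed, b$operon) + 1
      pools$transcripts[b$operon] <- vget(pools$transcripts, b$operon) + 1
      state$free_rnap <- state$free_rnap + 1L
      keep[i] <- FALSE
    } else {
      state$bound[[i]] <- b
    }
  }
  state$bound <- state$bound[keep]
  list(state = state, pools = pools, completed = completed)
}

#' Advance translation by one time-step
#'
#' Ribosomes bind gene products on available transcripts with per-gene
#' binding affinities (propensity = affinity x transcript count, capped by
#' the 50 bp occlusion spacing), then elongate 22 aa/s, consuming
#' matching amino acids and two ATP per amino acid. Completion releases the
#' protein and the ribosome.
#'
#' @param chromosome A [chromosome_config()].
#' @param state List: `free_ribosomes` count and `bound` (list of
#'   `list(operon=, gene=, position=)`, position in amino acids).
#' @param pools An [expression_pools()].
#' @param dt Time-step (s, > 0).
#' @return List: `state`, `pools`, `completed` (named new protein counts).
#' @export
translation_step <- function(chromosome, state, pools, dt) {
  stopifnot(dt > 0)
  gene_ids <- list()
  props <- numeric()
  for (op in names(chromosome$operons)) {
    genes <- chromosome$operons[[op]]$genes
    m <- vget(pools$transcripts, op)
    for (g in names(genes)) {
      cap <- m * max(1, floor(3 * nchar(genes[[g]]$aa_seq) / TRL_OCCLUSION_BP))
      n_bound <- sum(vapply(state$bound, function(b) b$gene == g, TRUE))
      key <- paste(op, g, sep = ":")
      gene_ids[[key]] <- list(operon = op, gene = g)
      props[key] <- if (m > 0 && n_bound < cap) {
        (genes[[g]]$rbs_affinity %||% 0.1) * m
      } else 0
    }
  }
  t <- 0
  repeat {
    if (state$free_ribosomes <= 0 || sum(props) <= 0) break
    draw <- gillespie_draw(props)
    if (!is.finite(draw$wait) || t + draw$wait > dt) break
    t <- t + draw$wait
    id <- gene_ids[[draw$reaction]]
    state$bound[[length(state$bound) + 1L]] <- list(operon = id$operon,
                                                    gene = id$gene, position = 0)
    state$free_ribosomes <- state$free_ribosomes - 1L
  }

  completed <- numeric()
  keep <- rep(TRUE, length(state$bound))
  adv_max <- round(TRL_RATE_AA_S * dt)
  for (i in seq_along(state$bound)) {
    b <- state$bound[[i]]
    aa_seq <- chromosome$operons[[b$operon]]$genes[[b$gene]]$aa_seq
    len <- nchar(aa_seq)
    target <- min(b$position + adv_max, len)
    n <- target - b$position
    if (n <= 0) next
    seg <- substr(aa_seq, b$position + 1, target)
    comp <- aa_composition(seg)
    if (pools$atp >= 2 * n && all(pools$amino_acids >= comp)) {
      pools$amino_acids <- pools$amino_acids - comp
      pools$atp <- pools$atp - 2 * n
      pools$adp <- pools$adp + 2 * n
      b$position <- target
    }
    if (b$position >= len) {
      completed[b$gene] <- vget(completed, b$gene) + 1
      pools$proteins[b$gene] <- vget(pools$proteins, b$gene) + 1
      state$free_ribosomes <- state$free_ribosomes + 1L
      keep[i] <- FALSE
    } else {
      state$bound[[i]] <- b
    }
  }
  state$bound <- state$bound[keep]
  list(state = state, pools = pools, completed = completed)
}

#' Define a complexation network
#'
#' @param reactions Named list: reaction id -> `list(stoich = named integer
#'   vector (reactants negative, products positive), rate = propensity in
#'   1/s)`. The default propensity of 1000/s is an order-of-magnitude
#'   estimate for fast association.
#' @return A `complexation_network`.
#' @export
complexation_network <- function(reactions) {
  for (r in names(reactions)) {
    st <- reactions[[r]]$stoich
    if (any(st != round(st))) stop("complexation stoichiometry must be integer")
    if ((reactions[[r]]$rate %||% 1000) < 0) stop("propensity must be >= 0")
    reactions[[r]]$rate <- reactions[[r]]$rate %||% 1000
  }
  structure(list(reactions = reactions), class = "complexation_network")
}

#' Advance complexation by one time-step
#'
#' Gillespie over the reactions whose reactants are all available; each
#' firing consumes stoichiometric reactants and produces the complex, so
#' monomer mass is conserved into complexes.
#'
#' @param counts Named counts of monomers and complexes.
#' @param network A [complexation_network()].
#' @param dt Time-step (s, > 0).
#' @return Named deltas to apply to `counts`.
#' @export
complexation_step <- function(counts, network, dt) {
  stopifnot(dt > 0)
  deltas <- stats::setNames(numeric(length(counts)), names(counts))
  avail <- unlist(counts)
  feasible <- function() {
    vapply(network$reactions, function(r) {
      st <- r$stoich
      need <- -st[st < 0]
      have <- avail[names(need)]
      if (!anyNA(have) && all(have >= need)) r$rate else 0
    }, 0)
  }
  t <- 0
  repeat {
    props <- feasible()
    draw <- gillespie_draw(props)
    if (!is.finite(draw$wait) || t + draw$wait > dt) break
    t <- t + draw$wait
    st <- network$reactions[[draw$reaction]]$stoich
    for (sp in names(st)) {
      avail[sp] <- vget(avail, sp) + st[[sp]]
      deltas[sp] <- vget(deltas, sp) + st[[sp]]
    }
  }
  deltas
}

#' Advance mRNA degradation by one time-step
#'
#' EndoRNAse-driven Michaelis-Menten kinetics over the total transcript
#' pool; each transcript is degraded independently with the per-transcript
#' hazard. A degraded transcript returns its nucleotides (by composition) to
#' the pools at a cost of one ATP per nucleotide. Proteins are never
#' degraded.
#'
#' @param chromosome A [chromosome_config()] (for transcript compositions).
#' @param pools An [expression_pools()].
#' @param endoRNAse_count Enzyme copy number.
#' @param dt Time-step (s, > 0).
#' @param kcat Transcripts per second per endoRNAse at saturation.
#' @param Km Michaelis constant (transcript counts).
#' @return List: `pools`, `degraded` (named counts).
#' @export
degradation_step <- function(chromosome, pools, endoRNAse_count, dt,
                             kcat = 0.002, Km = 5) {
  stopifnot(dt > 0)
  degraded <- numeric()
  total <- sum(unlist(pools$transcripts))
  if (total <= 0 || endoRNAse_count <= 0) {
    return(list(pools = pools, degraded = degraded))
  }
  hazard <- kcat * endoRNAse_count / (Km + total)
  p <- min(1, hazard * dt)
  for (op in names(pools$transcripts)) {
    m <- pools$transcripts[[op]]
    if (m <= 0) next
    n <- stats::rbinom(1, m, p)
    if (n == 0) next
    len <- chromosome$operons[[op]]$terminator
    comp <- nt_composition(substr(chromosome$operons[[op]]$sequence, 1, len))
    # ATP-limited: degrade as many whole transcripts as energy allows
    n <- min(n, floor(pools$atp / len))
    if (n == 0) next
    pools$transcripts[[op]] <- m - n
    pools$nucleotides <- pools$nucleotides + comp * n
    pools$atp <- pools$atp - len * n
    pools$adp <- pools$adp + len * n
    degraded[op] <- n
  }
  list(pools = pools, degraded = degraded)
}

#' Nucleotides currently polymerized in transcripts and partial transcripts
#'
#' Used by conservation checks: free + polymerized nucleotides are constant
#' through transcription/degradation.
#'
#' @param chromosome A [chromosome_config()].
#' @param pools An [expression_pools()].
#' @param tsc_state Transcription state (for partial transcripts).
#' @return Named counts over A, C, G, U.
#' @export
polymerized_nt <- function(chromosome, pools, tsc_state = NULL) {
  tot <- c(A = 0, C = 0, G = 0, U = 0)
  for (op in names(pools$transcripts)) {
    m <- pools$transcripts[[op]]
    if (m > 0) {
      o <- chromosome$operons[[op]]
      tot <- tot + m * nt_composition(substr(o$sequence, 1, o$terminator))
    }
  }
  for (b in tsc_state$bound %||% list()) {
    if (b$position > 0) {
      tot <- tot + nt_composition(substr(chromosome$operons[[b$operon]]$sequence,
                                         1, b$position))
    }
  }
  tot
}
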