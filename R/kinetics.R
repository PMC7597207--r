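# Convenience kinetics: a generalized Michaelis-Menten rate law handling any
# number of substrates, cofactors, and competitive inhibitors, used for the
# membrane transport reactions that constrain the FBA problem.

#' Define a kinetic reaction
#'
#' @param id Reaction id (must match a reaction in the metabolic network when
#'   used to build flux constraints).
#' @param substrates Named numeric: substrate metabolite -> Km (mM, > 0).
#' @param cofactors Named numeric: cofactor metabolite -> Km (mM); treated as
#'   additional saturating factors.
#' @param competitors Named numeric: inhibitor metabolite -> Ki (mM);
#'   competitive terms added to every substrate denominator.
#' @param enzyme Protein id whose copy number scales the rate.
#' @param kcat Catalytic rate per enzyme (amount units/s per enzyme, >= 0).
#' @return A `kinetic_reaction`.
#' @export
kinetic_reaction <- function(id, substrates, cofactors = numeric(),
                             competitors = numeric(), enzyme, kcat) {
  stopifnot(all(substrates > 0), all(cofactors > 0), all(competitors > 0),
            kcat >= 0)
  structure(list(id = id, substrates = substrates, cofactors = cofactors,
                 competitors = competitors, enzyme = enzyme, kcat = kcat),
            class = "kinetic_reaction")
}

#' Convenience-kinetics rate
#'
#' \deqn{rate = kcat \cdot E \cdot \prod_s \frac{s/K_s}{1 + s/K_s + \sum_i I_i/K_{I,i}}}
#'
#' over substrates and cofactors s, with competitive inhibitors I in every
#' denominator. With one substrate and no inhibitors this is exactly
#' Michaelis-Menten: `kcat * E * S / (Km + S)`.
#'
#' @param reaction A [kinetic_reaction()].
#' @param concentrations Named numeric of metabolite concentrations (mM,
#'   >= 0); missing species are treated as 0.
#' @param enzyme_count Enzyme copy number.
#' @return Flux (amount units/s).
#' @export
convenience_rate <- function(reaction, concentrations, enzyme_count) {
  conc <- function(m) {
    v <- concentrations[[m]]
    if (is.null(v) || is.na(v)) 0 else v
  }
  inhib <- 0
  for (m in names(reaction$competitors)) {
    inhib <- inhib + conc(m) / reaction$competitors[[m]]
  }
  sat <- 1
  for (set in list(reaction$substrates, reaction$cofactors)) {
    for (m in names(set)) {
      x <- conc(m) / set[[m]]
      sat <- sat * x / (1 + x + inhib)
    }
  }
  reaction$kcat * enzyme_count * sat
}

#' Build flux constraints from transport kinetics
#'
#' Computes each transport flux with [convenience_rate()] from the local
#' environment and the transporter copy numbers, and pins it as an equality
#' bound `(flux, flux)` on the matching exchange reaction, so that metabolism
#' is limited to exactly what transport supplies.
#'
#' @param reactions List of [kinetic_reaction()].
#' @param proteins Named numeric of transporter copy numbers.
#' @param local_env Named numeric of external concentrations (mM).
#' @return Named list of `c(lb, ub)` equality constraints, a `FluxConstraints`
#'   map for [solve_fba()]/[dfba_step()].
#' @export
transport_step <- function(reactions, proteins, local_env) {
  constraints <- list()
  for (rx in reactions) {
    e <- vget(proteins, rx$enzyme, default = NULL)
    if (is.null(e)) stop(sprintf("transporter '%s' missing from protein store",
                                 rx$enzyme))
    flux <- convenience_rate(rx, local_env, e)
    constraints[[rx$id]] <- c(flux, flux)
  }
  constraints
}
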