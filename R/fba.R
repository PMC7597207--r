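# Flux balance analysis: stoichiometric LP with a biomass objective.
#
# Reaction fluxes v satisfy S v = 0 (steady state for every internal
# metabolite) subject to per-reaction bounds; the objective ("BIOMASS")
# column drains the biomass-composition metabolites out of the steady-state
# network and into the cell's internal pools. Exchange reactions carry
# material across the compartment boundary with positive flux = uptake.

#' Define a metabolic network
#'
#' @param reactions Named list: reaction id -> named numeric stoichiometry
#'   (metabolite -> coefficient; negative consumed, positive produced).
#' @param bounds Named list: reaction id -> c(lower, upper) flux bounds.
#'   Reactions without bounds default to `c(0, default_ub)`.
#' @param objective Named numeric: biomass composition, metabolite ->
#'   coefficient. The implicit `BIOMASS` reaction consumes these metabolites
#'   from the network; its flux times these coefficients is delivered to the
#'   internal pools by [dfba_step()].
#' @param exchange_reactions Character vector of reaction ids that cross the
#'   compartment boundary (uptake positive).
#' @param exchange_species Named character: exchange reaction id -> external
#'   species name; defaults to the drained metabolite's name with an `_e`
#'   suffix.
#' @param molecular_weights Named numeric: metabolite -> fg per amount unit
#'   (1 amount unit = 1 mM * um^3 ~ 602,000 molecules; numerically Da / 1000).
#' @param default_ub Default upper bound for unbounded reactions.
#' @return A `metabolic_network`.
#' @export
metabolic_network <- function(reactions, bounds = list(), objective,
                              exchange_reactions = character(),
                              molecular_weights = numeric(),
                              exchange_species = NULL,
                              default_ub = 1000) {
  mets <- unique(unlist(lapply(reactions, names)))
  if (length(objective) == 0) stop("objective must be nonempty")
  if (!all(names(objective) %in% mets)) {
    stop("objective references metabolites absent from the network")
  }
  if (is.null(exchange_species)) {
    exchange_species <- vapply(exchange_reactions, function(r) {
      paste0(names(reactions[[r]])[1], "_e")
    }, "")
  }
  structure(list(reactions = reactions, bounds = bounds,
                 objective = objective,
                 exchange_reactions = exchange_reactions,
                 exchange_species = exchange_species,
                 molecular_weights = molecular_weights,
                 metabolites = mets, default_ub = default_ub),
            class = "metabolic_network")
}

#' Solve the FBA linear program
#'
#' Maximizes the biomass flux subject to `S v = 0` and flux bounds. Transport
#' constraints pin exchange fluxes as equality bounds, making supply
#' authoritative over demand.
#'
#' @param network A [metabolic_network()].
#' @param constraints Named list: reaction id -> c(lower, upper) imposed
#'   bounds (typically equality bounds from [transport_step()]). Must lie
#'   within the structural bounds' sign convention.
#' @return List: `fluxes` (named, including `BIOMASS`), `objective` (biomass
#'   flux at optimum), `status` (`"optimal"` or `"infeasible"`).
#' @export
solve_fba <- function(network, constraints = list()) {
  rids <- c(names(network$reactions), "BIOMASS")
  mets <- network$metabolites
  S <- matrix(0, nrow = length(mets), ncol = length(rids),
              dimnames = list(mets, rids))
  for (r in names(network$reactions)) {
    st <- network$reactions[[r]]
    S[names(st), r] <- st
  }
  S[names(network$objective), "BIOMASS"] <- -network$objective

  lb <- rep(0, length(rids)); ub <- rep(network$default_ub, length(rids))
  names(lb) <- names(ub) <- rids
  for (r in names(network$bounds)) {
    lb[r] <- network$bounds[[r]][1]; ub[r] <- network$bounds[[r]][2]
  }
  for (r in names(constraints)) {
    if (!r %in% rids) stop(sprintf("constraint on unknown reaction '%s'", r))
    lb[r] <- constraints[[r]][1]; ub[r] <- constraints[[r]][2]
  }
  if (any(lb > ub + 1e-12)) return(list(fluxes = NULL, objective = 0,
                                        status = "infeasible"))

  # shift to w = v - lb >= 0; equality rows signed so rhs >= 0 for simplex
  beq <- as.numeric(-S %*% lb)
  Aeq <- S
  neg <- beq < 0
  Aeq[neg, ] <- -Aeq[neg, ]
  beq[neg] <- -beq[neg]
  obj <- as.numeric(rids == "BIOMASS")
  res <- tryCatch(
    boot::simplex(a = obj, A1 = diag(length(rids)), b1 = ub - lb,
                  A3 = Aeq, b3 = beq, maxi = TRUE,
                  n.iter = 50 * length(rids) + 200),
    error = function(e) NULL)
  if (is.null(res) || res$solved != 1) {
    return(list(fluxes = NULL, objective = 0, status = "infeasible"))
  }
  v <- as.numeric(res$soln) + lb
  names(v) <- rids
  list(fluxes = v, objective = unname(v["BIOMASS"]), status = "optimal")
}

#' Load a metabolic network from the package JSON format
#'
#' The JSON has fields `reactions` (id -> metabolite coefficients), `bounds`
#' (id -> [lb, ub]), `objective`, `exchange_reactions`,
#' `molecular_weights`.
#'
#' @param path JSON file path.
#' @return A [metabolic_network()].
#' @export
load_metabolic_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  metabolic_network(
    reactions = lapply(j$reactions, unlist),
    bounds = lapply(j$bounds, unlist),
    objective = unlist(j$objective),
    exchange_reactions = j$exchange_reactions %||% character(),
    molecular_weights = unlist(j$molecular_weights) %||% numeric(),
    exchange_species = if (!is.null(j$exchange_species)) unlist(j$exchange_species))
}

#' Load a BiGG-style genome-scale model JSON
#'
#' Adapter for the BiGG model database JSON schema (`metabolites`,
#' `reactions` with `metabolites` stoichiometries, `lower_bound`,
#' `upper_bound`, `objective_coefficient`). BiGG uses negative flux for
#' uptake on `EX_` reactions; this adapter keeps that convention in the
#' bounds and marks `EX_` reactions as exchanges. Intended for optional,
#' offline-downloaded models; the packaged toy network is the default test
#' substrate.
#'
#' @param path BiGG JSON file path.
#' @return A [metabolic_network()]. The BiGG biomass reaction is kept as an
#'   ordinary column and its products form the objective.
#' @export
load_bigg_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  reactions <- list(); bounds <- list(); objective <- numeric()
  for (r in j$reactions) {
    st <- unlist(r$metabolites)
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      objective <- st[st > 0]
      next
    }
    reactions[[r$id]] <- st
    bounds[[r$id]] <- c(r$lower_bound %||% -1000, r$upper_bound %||% 1000)
  }
  mw <- vapply(j$metabolites, function(m) (m$formula_weight %||% 0) / 1000, 0)
  names(mw) <- vapply(j$metabolites, `[[`, "", "id")
  if (length(objective) == 0) stop("BiGG model has no objective reaction")
  metabolic_network(reactions, bounds, objective,
                    exchange_reactions = grep("^EX_", names(reactions),
                                              value = TRUE),
                    molecular_weights = mw)
}

#' The packaged toy glucose/lactose network
#'
#' An eight-column network (glucose uptake, lactose uptake, lactose
#' hydrolysis, glycolytic conversion to biomass precursor, maintenance drain,
#' and the implicit biomass objective) that mass-balances: every reaction
#' conserves femtograms via the molecular weights. Glucose enters at 0.18
#' fg/amount, lactose at 0.342, and lactose hydrolyses to 1.9 glucose
#' equivalents.
#'
#' @return A [metabolic_network()].
#' @export
toy_metabolism <- function() {
  metabolic_network(
    reactions = list(
      EX_glc  = c(glc = 1),
      EX_lcts = c(lcts = 1),
      LCTShyd = c(lcts = -1, glc = 1.9),
      GLYC    = c(glc = -1, prec = 1)),
    bounds = list(EX_glc = c(0, 10), EX_lcts = c(0, 10)),
    objective = c(prec = 1),
    exchange_reactions = c("EX_glc", "EX_lcts"),
    molecular_weights = c(glc = 0.180, lcts = 0.342, prec = 0.180))
}
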