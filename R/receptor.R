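# Monod-Wyman-Changeux chemoreceptor cluster: Tar and Tsr homodimers in a
# 1:2 ratio acting as a single allosteric two-state unit, with methylation
# providing slow negative-feedback adaptation toward a baseline activity.

#' Create a receptor cluster
#'
#' Cluster free energy (kT units):
#' \deqn{F = \sum_{type} n_{type}\left[\epsilon(m) +
#'   \ln\frac{1 + c/K_{off}}{1 + c/K_{on}}\right]}
#' with per-dimer methylation offset `epsilon(m) = e0 - e1 * m` and activity
#' `P_on = 1/(1 + exp(F))`. Attractant binding (K_off < K_on) raises F and so
#' favors the off state; methylation lowers F and favors on.
#'
#' Methylation integrates `dm/dt = k_meth * (a0 - P_on)`, which restores
#' activity to the `a0` baseline after any sustained step within the
#' methylation range (perfect adaptation); larger steps need a larger
#' methylation change and hence a longer adaptation time.
#'
#' Ligand dissociation constants default to MeAsp sensing: Tar is sensitive
#' in the 0.02-0.5 mM window, Tsr nearly insensitive.
#'
#' @param n_tar Tar dimer count; Tsr is fixed at twice this (1:2 ratio).
#' @param methylation Initial methylation level, in `[0, m_max]`; by default
#'   the adapted level at `ligand0`.
#' @param ligand0 Ambient ligand concentration (mM) the cluster starts
#'   adapted to.
#' @param a0 Baseline (adapted) activity.
#' @param k_meth Methylation rate constant (m-units/s).
#' @param K_off,K_on Named c(Tar=, Tsr=) dissociation constants (mM) for the
#'   inactive/active conformations.
#' @param e0,e1 Methylation offset parameters (kT; `epsilon = e0 - e1 * m`).
#' @param m_max Methylation upper bound.
#' @return A `receptor_cluster` list.
#' @export
receptor_cluster <- function(n_tar = 6, methylation = NULL, a0 = 1 / 3,
                             k_meth = 0.1, ligand0 = 0,
                             K_off = c(Tar = 0.02, Tsr = 100),
                             K_on = c(Tar = 0.5, Tsr = 1e6),
                             e0 = 1.0, e1 = 0.5, m_max = 8) {
  cl <- structure(list(n_tar = n_tar, n_tsr = 2 * n_tar, a0 = a0,
                       k_meth = k_meth, K_off = K_off, K_on = K_on,
                       e0 = e0, e1 = e1, m_max = m_max, methylation = 0,
                       P_on = a0), class = "receptor_cluster")
  if (is.null(methylation)) methylation <- adapted_methylation(cl, ligand0)
  cl$methylation <- min(max(methylation, 0), m_max)
  cl$P_on <- receptor_activity(cl, ligand0)
  cl
}

#' Adapted methylation level at a ligand concentration
#'
#' The methylation level at which the cluster's activity equals its `a0`
#' baseline for a sustained ligand concentration (the fixed point of the
#' methylation feedback).
#'
#' @param cluster A [receptor_cluster()].
#' @param ligand Ligand concentration (mM).
#' @return Methylation level (unbounded; callers clamp to `[0, m_max]`).
#' @export
adapted_methylation <- function(cluster, ligand) {
  n <- cluster$n_tar + cluster$n_tsr
  f0 <- log(1 / cluster$a0 - 1)
  f_lig <- (cluster$n_tar * log((1 + ligand / cluster$K_off[["Tar"]]) /
                                (1 + ligand / cluster$K_on[["Tar"]])) +
            cluster$n_tsr * log((1 + ligand / cluster$K_off[["Tsr"]]) /
                                (1 + ligand / cluster$K_on[["Tsr"]]))) / n
  (cluster$e0 + f_lig - f0 / n) / cluster$e1
}

#' Instantaneous cluster activity at a ligand concentration
#'
#' @param cluster A [receptor_cluster()].
#' @param ligand Attractant concentration (mM, >= 0).
#' @return `P_on` in `[0, 1]`.
#' @export
receptor_activity <- function(cluster, ligand) {
  stopifnot(ligand >= 0)
  eps <- cluster$e0 - cluster$e1 * cluster$methylation
  f_type <- function(type) {
    log((1 + ligand / cluster$K_off[[type]]) /
        (1 + ligand / cluster$K_on[[type]]))
  }
  f <- cluster$n_tar * (eps + f_type("Tar")) +
    cluster$n_tsr * (eps + f_type("Tsr"))
  1 / (1 + exp(f))
}

#' Advance the receptor cluster by one time-step
#'
#' Computes activity at the current ligand concentration, then integrates the
#' methylation feedback (bounded to its valid range).
#'
#' @param cluster A [receptor_cluster()].
#' @param ligand Attractant concentration (mM).
#' @param dt Time-step (s, > 0).
#' @return The cluster with updated `P_on` and `methylation`.
#' @export
receptor_update <- function(cluster, ligand, dt) {
  stopifnot(dt > 0)
  a <- receptor_activity(cluster, ligand)
  m <- cluster$methylation + cluster$k_meth * (cluster$a0 - a) * dt
  cluster$methylation <- min(max(m, 0), cluster$m_max)
  cluster$P_on <- receptor_activity(cluster, ligand)
  cluster
}

#' CheY-P parameters
#'
#' Steady-state CheY-P follows a Michaelis-type balance between CheA
#' autophosphorylation (proportional to cluster activity) and CheZ
#' dephosphorylation: `Y_P = Y_max * a / (a + K_a)`, normalized so the
#' baseline activity maps to the baseline CheY-P concentration used by the
#' flagellar switch.
#'
#' @param Y0 Baseline CheY-P (uM) at baseline activity `a0`.
#' @param a0 Baseline activity.
#' @param K_a Half-saturation activity.
#' @return Parameter list.
#' @export
cheY_params <- function(Y0 = 2.5159, a0 = 1 / 3, K_a = 0.5) {
  list(Y0 = Y0, a0 = a0, K_a = K_a, Y_max = Y0 * (a0 + K_a) / a0)
}

#' Steady-state CheY-P from cluster activity
#'
#' Monotone increasing in activity; `cheY_P_level(a0) = Y0`.
#'
#' @param activity Cluster activity in `[0, 1]`.
#' @param params A [cheY_params()].
#' @return CheY-P concentration (uM).
#' @export
cheY_P_level <- function(activity, params = cheY_params()) {
  stopifnot(activity >= 0, activity <= 1)
  params$Y_max * activity / (activity + params$K_a)
}
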