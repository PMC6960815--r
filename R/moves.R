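# Reference (plain-R) implementations of the elementary Monte Carlo moves.
# These operate on an explicit microstate and evaluate the energy change by
# full recomputation; the compiled kernel performs the same moves with
# incremental updates.  They exist as the transparent, testable definition
# of the move set and for detailed-balance spot checks on tiny chains.

#' Microstate of the chain
#'
#' Bundles a protonation vector and a conformation (SGCMC mode), or a
#' smeared charge and a conformation (ccMC mode).
#'
#' @param topology A [chain_topology()].
#' @param settings A [simulation_settings()].
#' @param protonation Binary vector (defaults to all-deprotonated in sgcmc
#'   mode; ignored in ccmc mode).
#' @param conformation A [conformation()] (defaults to relaxed all-trans).
#' @return An object of class `system_state` with fields `protonation`,
#'   `conformation` and the cached total `energy` (kBT).
#' @export
system_state <- function(topology, settings, protonation = NULL,
                         conformation = NULL) {
  if (is.null(conformation)) conformation <- conformation(topology)
  if (settings$mode == "sgcmc" && is.null(protonation))
    protonation <- rep(0L, topology$n_ionizable)
  e <- total_free_energy(topology, conformation, protonation, settings)
  structure(list(protonation = protonation, conformation = conformation,
                 energy = as.numeric(e), energy_terms = attr(e, "terms")),
            class = "system_state")
}

new_candidate <- function(topology, settings, state, protonation, conformation) {
  e <- total_free_energy(topology, conformation, protonation, settings)
  list(state = structure(list(protonation = protonation,
                              conformation = conformation,
                              energy = as.numeric(e),
                              energy_terms = attr(e, "terms")),
                         class = "system_state"),
       delta_energy = as.numeric(e) - state$energy)
}

#' Propose a protonation flip (semi-grand canonical exchange)
#'
#' Toggles one uniformly chosen ionizable site; geometry is unchanged, so
#' only the proton-binding, short-range and long-range terms contribute to
#' the energy change.
#'
#' @param state A [system_state()].
#' @param topology A [chain_topology()].
#' @param settings A [simulation_settings()] in `sgcmc` mode.
#' @param site Site to flip (default: drawn uniformly with R's RNG).
#' @return List with the candidate `state` and `delta_energy` (kBT).
#' @export
propose_protonation_flip <- function(state, topology, settings, site = NULL) {
  if (settings$mode != "sgcmc")
    stop("protonation flips are only defined in sgcmc mode")
  if (is.null(site)) site <- sample.int(topology$n_ionizable, 1L)
  s <- state$protonation
  s[site] <- 1L - s[site]
  new_candidate(topology, settings, state, s, state$conformation)
}

#' Propose a rotational (trans/gauche pivot) move
#'
#' Assigns a uniformly chosen rotatable bond one of its two alternative
#' states; the downstream chain segment pivots rigidly.
#'
#' @param state A [system_state()].
#' @param topology A [chain_topology()].
#' @param settings A [simulation_settings()].
#' @param bond Index into the rotatable-bond list (default: uniform draw).
#' @param new_state New dihedral state (default: uniform over the two
#'   alternatives).
#' @return List with the candidate `state` and `delta_energy` (kBT;
#'   `+Inf` if the excluded-volume test fails).
#' @export
propose_rotation <- function(state, topology, settings, bond = NULL,
                             new_state = NULL) {
  n_rot <- length(topology$rotatable_bonds)
  if (n_rot < 1L) stop("no rotatable bonds")
  if (is.null(bond)) bond <- sample.int(n_rot, 1L)
  conf <- state$conformation
  if (is.null(new_state))
    new_state <- sample(setdiff(DIHEDRAL_STATES, conf$dihedral_states[bond]), 1L)
  conf$dihedral_states[bond] <- new_state
  new_candidate(topology, settings, state, state$protonation, conf)
}

#' Propose an elastic (bond length or angle) perturbation
#'
#' Perturbs one bond length or one bond angle by a Gaussian step; the
#' downstream segment translates or pivots accordingly.
#'
#' @param state A [system_state()].
#' @param topology A [chain_topology()].
#' @param settings A [simulation_settings()] with `elastic_sampling = TRUE`.
#' @param which `"length"` or `"angle"` (default: proportional draw over
#'   all internal coordinates).
#' @param index Bond or interior-angle index (default: uniform draw).
#' @return List with the candidate `state` and `delta_energy` (kBT).
#' @export
propose_elastic_perturbation <- function(state, topology, settings,
                                         which = NULL, index = NULL) {
  if (!settings$elastic_sampling)
    stop("elastic moves require elastic_sampling = TRUE")
  M <- topology$n_bonds
  if (is.null(which))
    which <- if (sample.int(2L * M - 1L, 1L) <= M) "length" else "angle"
  conf <- state$conformation
  if (which == "length") {
    if (is.null(index)) index <- sample.int(M, 1L)
    conf$bond_lengths[index] <- conf$bond_lengths[index] +
      stats::rnorm(1L, sd = settings$sigma_length)
    if (conf$bond_lengths[index] <= 0)
      return(list(state = state, delta_energy = Inf))
  } else {
    if (is.null(index)) index <- sample.int(M - 1L, 1L)
    conf$bond_angles[index] <- conf$bond_angles[index] +
      stats::rnorm(1L, sd = settings$sigma_angle)
    if (conf$bond_angles[index] <= 0 || conf$bond_angles[index] >= 180)
      return(list(state = state, delta_energy = Inf))
  }
  new_candidate(topology, settings, state, state$protonation, conf)
}
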