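# SBRIS free-energy terms in units of kBT.  This layer is a direct, plain-R
# transcription of the model used by the exact enumeration oracle and as a
# reference for the compiled sampler; it is deliberately independent of the
# C++ code path.

LN10 <- log(10)

#' Intrinsic rotational (torsional) free energy
#'
#' Sum of the per-state torsional energies over the rotatable bonds,
#' \eqn{\beta F_{rot} = \sum_j \epsilon_{rot}(\phi_j)}.
#'
#' @param conformation A [conformation()].
#' @param eps_rot Named vector `c(t=, gp=, gm=)` of state energies in kBT;
#'   the symmetric chain requires `gp == gm`.
#' @return Energy in kBT.
#' @export
rotational_energy <- function(conformation, eps_rot = c(t = 0, gp = 0, gm = 0)) {
  eps_rot <- check_state_energies(eps_rot, "eps_rot")
  if (length(conformation$dihedral_states) == 0L) return(0)
  key <- c(t = "t", `g+` = "gp", `g-` = "gm")[conformation$dihedral_states]
  sum(eps_rot[key])
}

#' Proton-binding free energy
#'
#' \eqn{\beta F_p = \ln 10 \, (pH - pK) \sum_i s_i}: the semi-grand
#' canonical one-body term coupling the chain to the proton bath.  It only
#' contributes in fluctuating-charge (constant-pH) mode.
#'
#' @param state Binary protonation vector (1 = protonated).
#' @param pH Solution pH.
#' @param pK Intrinsic site pK (scalar or per-site vector).
#' @return Energy in kBT.
#' @examples
#' protonation_energy(c(1, 1), pH = 10, pK = 9)  # 2 ln 10
#' @export
protonation_energy <- function(state, pH, pK) {
  stopifnot(all(state %in% c(0, 1)))
  LN10 * sum((pH - pK) * state)
}

#' Long-range Debye-Hueckel electrostatic energy
#'
#' Screened Coulomb energy over all ionizable-site pairs separated by at
#' least two sites along the chain,
#' \eqn{\beta F_{LR} = \sum_{j \ge i+2} (\ell_B / d_{ij}) e^{-\kappa d_{ij}} q_i q_j}.
#' Nearest-neighbour site pairs are excluded here because their interaction
#' is carried by the chemically specific short-range term.
#'
#' @param charges Per-site charge values: the binary protonation vector in
#'   fluctuating mode or the smeared value `theta` per site in
#'   constant-charge mode.
#' @param coords Node coordinate matrix (nm).
#' @param env An [electrostatic_environment()].
#' @param topology A [chain_topology()] locating the ionizable sites.
#' @return Energy in kBT.
#' @export
long_range_energy <- function(charges, coords, env, topology) {
  stopifnot(inherits(env, "electrostatic_environment"),
            inherits(topology, "chain_topology"),
            length(charges) == topology$n_ionizable)
  if (env$bjerrum_length == 0 || all(charges == 0)) return(0)
  pos <- coords[topology$site_nodes, , drop = FALSE]
  N <- nrow(pos)
  if (N < 3L) return(0)
  e <- 0
  for (i in seq_len(N - 2L)) {
    if (charges[i] == 0) next
    for (j in (i + 2L):N) {
      if (charges[j] == 0) next
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d == 0) stop("singularity: coincident charged sites")
      e <- e + env$bjerrum_length / d * exp(-env$kappa * d) * charges[i] * charges[j]
    }
  }
  e
}

#' Short-range interaction energy between consecutive ionizable sites
#'
#' \eqn{\beta F_{SR} = \ln 10 \sum_i \epsilon_{int}(\phi_{3i-1}) q_i q_{i+1}},
#' where \eqn{\phi_{3i-1}} is the rotational state of the middle bond
#' between sites i and i+1.  `eps_int` is given in log10 (pK-shift) units;
#' the ln 10 prefactor makes a protonated pair across a trans bond with
#' `eps_int = 1` cost one pK unit.
#'
#' @param charges Per-site charges (binary `s` or smeared `theta`).
#' @param conformation A [conformation()] (one rotatable bond per
#'   consecutive site pair).
#' @param eps_int Named vector `c(t=, gp=, gm=)` in log10 units.
#' @return Energy in kBT.
#' @export
short_range_energy <- function(charges, conformation,
                               eps_int = c(t = 1, gp = 3, gm = 3)) {
  eps_int <- check_state_energies(eps_int, "eps_int")
  n_pairs <- length(conformation$dihedral_states)
  stopifnot(length(charges) == n_pairs + 1L)
  if (n_pairs == 0L) return(0)
  key <- c(t = "t", `g+` = "gp", `g-` = "gm")[conformation$dihedral_states]
  LN10 * sum(eps_int[key] * charges[-length(charges)] * charges[-1L])
}

#' Harmonic bond stretching and bending energy
#'
#' \eqn{\sum_j k_l/2 (l_j - l_0)^2 + \sum_j k_\alpha/2 (\alpha_j - \alpha_0)^2}
#' over all bonds and interior angles, with the force constants of the
#' topology converted to kBT at 298.15 K.
#'
#' @param conformation A [conformation()].
#' @param topology A [chain_topology()].
#' @return Energy in kBT.
#' @export
elastic_energy <- function(conformation, topology) {
  dl <- conformation$bond_lengths - topology$l0
  da <- (conformation$bond_angles - topology$alpha0) * pi / 180
  topology$k_length_int / 2 * sum(dl * dl) +
    topology$k_angle_int / 2 * sum(da * da)
}

#' Mechanical work of the applied stretching force
#'
#' \eqn{\beta W = -F r_z / k_B T} for a force F (pN) applied between the
#' chain ends along the laboratory z axis, with kBT = 4.1164 pN nm.
#'
#' @param coords Node coordinate matrix (nm).
#' @param force Applied force in pN.
#' @return Energy in kBT.
#' @export
mechanical_work <- function(coords, force) {
  if (force == 0) return(0)
  -force * end_to_end_vector(coords)[3L] / sbris_constants$kBT_pN_nm
}

#' Hard-sphere excluded-volume overlap test
#'
#' Checks all node pairs separated by at least four bonds along the chain
#' for hard-sphere overlap (`d <= Ri + Rj`); closer pairs are controlled by
#' the bonded terms.  An overlap corresponds to infinite energy, i.e. move
#' rejection.  With excluded volume disabled all radii are zero and the
#' result is always `FALSE`.
#'
#' @param coords Node coordinate matrix (nm).
#' @param topology A [chain_topology()].
#' @param enabled If `FALSE`, the chain is treated as point sites.
#' @return `TRUE` if any checked pair overlaps.
#' @export
sev_overlap <- function(coords, topology, enabled = TRUE) {
  if (!enabled) return(FALSE)
  radii <- topology$node_radii
  if (all(radii == 0)) return(FALSE)
  n <- nrow(coords)
  if (n < 5L) return(FALSE)
  for (i in seq_len(n - 4L)) {
    for (j in (i + 4L):n) {
      d2 <- sum((coords[i, ] - coords[j, ])^2)
      rs <- radii[i] + radii[j]
      if (d2 <= rs * rs) return(TRUE)
    }
  }
  FALSE
}

#' Total SBRIS free energy of a microstate
#'
#' Sum of the torsional, proton-binding, short-range, long-range, elastic
#' and mechanical-work terms, with `+Inf` returned when the hard-sphere
#' excluded-volume test fails.  In constant-charge (`ccmc`) mode every site
#' carries the smeared charge `theta` and the proton-binding term is
#' dropped.
#'
#' @param topology A [chain_topology()].
#' @param conformation A [conformation()].
#' @param protonation Binary protonation vector (required in `sgcmc` mode).
#' @param settings A [simulation_settings()] providing the mode, pH or
#'   theta, ionic strength, force and feature flags.
#' @return Energy in kBT, with a `"terms"` attribute holding the breakdown.
#' @export
total_free_energy <- function(topology, conformation, protonation = NULL,
                              settings) {
  stopifnot(inherits(settings, "simulation_settings"))
  env <- electrostatic_environment(settings$ionic_strength, settings$bjerrum_length)
  coords <- build_coordinates(topology, conformation)
  if (settings$mode == "sgcmc") {
    stopifnot(!is.null(protonation), length(protonation) == topology$n_ionizable)
    q <- as.numeric(protonation)
    fp <- protonation_energy(protonation, settings$pH, topology$pK)
  } else {
    q <- rep(settings$theta, topology$n_ionizable)
    fp <- 0
  }
  terms <- c(
    rotational  = rotational_energy(conformation, topology$eps_rot),
    protonation = fp,
    short_range = short_range_energy(q, conformation, topology$eps_int),
    long_range  = long_range_energy(q, coords, env, topology),
    elastic     = elastic_energy(conformation, topology),
    work        = mechanical_work(coords, settings$force),
    sev         = if (sev_overlap(coords, topology, settings$sev_enabled)) Inf else 0
  )
  structure(sum(terms), terms = terms)
}
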