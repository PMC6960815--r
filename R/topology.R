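#' Build the topology of a weak polyelectrolyte chain
#'
#' Constructs the static description of a linear chain with `n_ionizable`
#' titratable sites placed every third chain position (positions 1, 4, ...,
#' 3N-2), the pattern of linear poly(ethylene imine).  The chain then has
#' `3N - 2` nodes and `M = 3N - 3` bonds.  Only the middle bond between two
#' consecutive ionizable sites (bond `3i - 1`, the bond carrying the pendant
#' site) is rotatable between the trans, gauche+ and gauche- states; all
#' other bonds are frozen in trans.
#'
#' Default parameters are the reference set used throughout the package:
#' `pK = 9`, equilibrium bond length `l0 = 0.15` nm, bond angle
#' `alpha0 = 120` degrees, stretching constant 300 kcal/mol/A^2, bending
#' constant 0.01 kcal/mol/deg^2, hard-sphere radii 1.55 A (ionizable) and
#' 1.7 A (inert), nearest-neighbour interaction energies
#' `eps_int = c(t = 1, gp = 3, gm = 3)` (log10 units, i.e. pK-shift-like)
#' and zero intrinsic rotational energies.
#'
#' @param n_ionizable Number of titratable sites N (>= 2).
#' @param pK Intrinsic protonation constant (common to all sites).
#' @param l0 Equilibrium bond length in nm.
#' @param alpha0 Equilibrium bond angle in degrees.
#' @param k_length Bond stretching constant in kcal mol^-1 A^-2.
#' @param k_angle Bond bending constant in kcal mol^-1 deg^-2.
#' @param radius_ionizable,radius_inert Hard-sphere radii in nm (used only
#'   when excluded volume is enabled).
#' @param eps_int Named numeric vector `c(t=, gp=, gm=)`: short-range
#'   interaction energy between consecutive protonated sites as a function
#'   of the rotational state of the middle bond, in log10 (pK-shift) units.
#'   Symmetry requires `gp == gm`.
#' @param eps_rot Named numeric vector `c(t=, gp=, gm=)`: intrinsic
#'   torsional energy of each rotational state in kBT.  Symmetry requires
#'   `gp == gm`.
#' @return An object of class `chain_topology`.
#' @examples
#' topo <- chain_topology(50)
#' topo$n_nodes    # 148
#' topo$n_bonds    # 147
#' length(topo$rotatable_bonds)  # 49
#' @export
chain_topology <- function(n_ionizable,
                           pK = 9,
                           l0 = 0.15,
                           alpha0 = 120,
                           k_length = 300,
                           k_angle = 0.01,
                           radius_ionizable = 0.155,
                           radius_inert = 0.17,
                           eps_int = c(t = 1, gp = 3, gm = 3),
                           eps_rot = c(t = 0, gp = 0, gm = 0)) {
  if (!is.numeric(n_ionizable) || length(n_ionizable) != 1L ||
      n_ionizable != round(n_ionizable) || n_ionizable < 2)
    stop("invalid topology: 'n_ionizable' must be an integer >= 2")
  n_ionizable <- as.integer(n_ionizable)
  stopifnot(l0 > 0, alpha0 > 0, alpha0 <= 180, k_length >= 0, k_angle >= 0,
            radius_ionizable >= 0, radius_inert >= 0)
  eps_int <- check_state_energies(eps_int, "eps_int")
  eps_rot <- check_state_energies(eps_rot, "eps_rot")

  N <- n_ionizable
  n_nodes <- 3L * N - 2L
  M <- n_nodes - 1L
  site_nodes <- 3L * seq_len(N) - 2L
  node_kinds <- rep("inert", n_nodes)
  node_kinds[site_nodes] <- "ionizable"
  rotatable <- 3L * seq_len(N - 1L) - 1L

  structure(list(
    n_ionizable = N,
    n_nodes = n_nodes,
    n_bonds = M,
    node_kinds = node_kinds,
    site_nodes = site_nodes,
    rotatable_bonds = rotatable,
    pK = pK,
    l0 = l0,
    alpha0 = alpha0,
    k_length = k_length,
    k_angle = k_angle,
    radius_ionizable = radius_ionizable,
    radius_inert = radius_inert,
    eps_int = eps_int,
    eps_rot = eps_rot,
    # internal-unit conversions (kBT, nm, rad)
    k_length_int = k_length * sbris_constants$kcal_mol_to_kBT * 100,  # kBT/nm^2
    k_angle_int  = k_angle * sbris_constants$kcal_mol_to_kBT * (180 / pi)^2, # kBT/rad^2
    node_radii   = ifelse(node_kinds == "ionizable", radius_ionizable, radius_inert)
  ), class = "chain_topology")
}

check_state_energies <- function(x, name) {
  if (is.null(names(x)) || !all(c("t", "gp", "gm") %in% names(x)))
    stop(sprintf("'%s' must be a named vector with entries t, gp, gm", name))
  x <- x[c("t", "gp", "gm")]
  if (x[["gp"]] != x[["gm"]])
    stop(sprintf("'%s': the chain is symmetric, gauche+ and gauche- energies must be equal",
                 name))
  x
}

#' @export
print.chain_topology <- function(x, ...) {
  cat("SBRIS chain topology\n")
  cat(sprintf("  %d ionizable sites (pK = %g), %d nodes, %d bonds (%d rotatable)\n",
              x$n_ionizable, x$pK, x$n_nodes, x$n_bonds, length(x$rotatable_bonds)))
  cat(sprintf("  l0 = %g nm, alpha0 = %g deg, k_length = %g kcal/mol/A^2, k_angle = %g kcal/mol/deg^2\n",
              x$l0, x$alpha0, x$k_length, x$k_angle))
  cat(sprintf("  eps_int(t, g) = (%g, %g) log10 units; radii %g / %g nm\n",
              x$eps_int[["t"]], x$eps_int[["gp"]],
              x$radius_ionizable, x$radius_inert))
  invisible(x)
}

#' Contour length of the chain
#'
#' Normalisation constant for extension curves.  Two conventions are
#' available: the geometric all-trans end-to-end projection built from all
#' `M` bonds, \eqn{M l_0 \cos((\pi-\alpha_0)/2)} (the default), and the
#' site-based form \eqn{N l_0 \cos((\pi-\alpha_0)/2)} built from the number
#' of ionizable sites.  The geometric form is the physical maximum extension
#' of the zig-zag chain; the site form is retained because published
#' extension curves are sometimes normalised per ionizable site.
#'
#' @param topology A [chain_topology()].
#' @param form `"geometric"` (M bonds, default) or `"sites"` (N sites).
#' @return Contour length in nm.
#' @examples
#' topo <- chain_topology(50)
#' contour_length(topo)            # ~19.09 nm
#' contour_length(topo, "sites")   # ~6.50 nm
#' @export
contour_length <- function(topology, form = c("geometric", "sites")) {
  stopifnot(inherits(topology, "chain_topology"))
  form <- match.arg(form)
  half <- (pi - topology$alpha0 * pi / 180) / 2
  n <- if (form == "geometric") topology$n_bonds else topology$n_ionizable
  n * topology$l0 * cos(half)
}
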