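# Internal-coordinate description of a chain microstate and its conversion
# to Cartesian node positions.  Model dihedral convention: trans = 0,
# gauche+ = +120 deg, gauche- = -120 deg (right-handed torsion); the fully
# extended planar zig-zag has all dihedrals at trans.

DIHEDRAL_STATES <- c("t", "g+", "g-")
DIHEDRAL_ANGLES <- c(t = 0, `g+` = 2 * pi / 3, `g-` = -2 * pi / 3)

#' Chain conformation in internal coordinates
#'
#' A conformation holds one rotational state per rotatable bond plus the
#' continuous bond lengths and bond angles.  Frozen (non-rotatable) bonds
#' are always in trans.
#'
#' @param topology A [chain_topology()].
#' @param dihedral_states Character vector over `"t"`, `"g+"`, `"g-"`, one
#'   per rotatable bond (recycled if length 1).
#' @param bond_lengths Bond lengths in nm, one per bond (default: all `l0`).
#' @param bond_angles Interior bond angles in degrees, one per interior node
#'   (default: all `alpha0`).
#' @return An object of class `chain_conformation`.
#' @examples
#' topo <- chain_topology(3)
#' conformation(topo)                       # all-trans, relaxed
#' conformation(topo, c("g+", "t"))
#' @export
conformation <- function(topology, dihedral_states = "t",
                         bond_lengths = NULL, bond_angles = NULL) {
  stopifnot(inherits(topology, "chain_topology"))
  n_rot <- length(topology$rotatable_bonds)
  if (length(dihedral_states) == 1L)
    dihedral_states <- rep(dihedral_states, n_rot)
  if (length(dihedral_states) != n_rot)
    stop("dimension mismatch: need one dihedral state per rotatable bond")
  if (!all(dihedral_states %in% DIHEDRAL_STATES))
    stop("dihedral states must be one of 't', 'g+', 'g-'")
  if (is.null(bond_lengths)) bond_lengths <- rep(topology$l0, topology$n_bonds)
  if (is.null(bond_angles)) bond_angles <- rep(topology$alpha0, topology$n_bonds - 1L)
  if (length(bond_lengths) != topology$n_bonds)
    stop("dimension mismatch: need one bond length per bond")
  if (length(bond_angles) != topology$n_bonds - 1L)
    stop("dimension mismatch: need one bond angle per interior node")
  if (any(bond_lengths <= 0)) stop("bond lengths must be positive")
  if (any(bond_angles <= 0 | bond_angles > 180))
    stop("bond angles must lie in (0, 180] degrees")
  structure(list(
    dihedral_states = dihedral_states,
    bond_lengths = bond_lengths,
    bond_angles = bond_angles
  ), class = "chain_conformation")
}

# Full per-bond dihedral vector (rad) for bonds 2..M-1; frozen bonds at trans.
full_dihedrals <- function(topology, conf) {
  M <- topology$n_bonds
  phi <- rep(0, max(M - 2L, 0L))            # indexed by bond j = 2..M-1
  idx <- topology$rotatable_bonds - 1L      # position of bond j in this vector
  phi[idx] <- DIHEDRAL_ANGLES[conf$dihedral_states]
  phi
}

#' Convert a conformation to Cartesian node positions
#'
#' Places node 1 at the origin, the first bond along the z axis and the
#' second bond in the x-z plane, then grows the chain bond by bond from the
#' bond lengths, bond angles and dihedral states (natural extension
#' reference frame).  Frozen bonds are placed in trans.
#'
#' @param topology A [chain_topology()].
#' @param conformation A [conformation()] consistent with the topology.
#' @return A numeric matrix with `n_nodes` rows and columns x, y, z (nm).
#' @examples
#' topo <- chain_topology(2)
#' xyz <- build_coordinates(topo, conformation(topo))
#' sqrt(sum((xyz[4, ] - xyz[1, ])^2))   # all-trans end-to-end distance
#' @export
build_coordinates <- function(topology, conformation) {
  stopifnot(inherits(topology, "chain_topology"),
            inherits(conformation, "chain_conformation"))
  M <- topology$n_bonds
  l <- conformation$bond_lengths
  alpha <- conformation$bond_angles * pi / 180
  if (length(l) != M || length(alpha) != M - 1L)
    stop("dimension mismatch between conformation and topology")
  phi <- full_dihedrals(topology, conformation)
  r <- matrix(0, M + 1L, 3L, dimnames = list(NULL, c("x", "y", "z")))
  r[2L, 3L] <- l[1L]
  if (M >= 2L) {
    th <- pi - alpha[1L]
    r[3L, ] <- r[2L, ] + l[2L] * c(sin(th), 0, cos(th))
  }
  if (M >= 3L) for (k in 3L:M) {
    a <- r[k, ] - r[k - 1L, ]; a <- a / sqrt(sum(a * a))
    b <- r[k - 1L, ] - r[k - 2L, ]; b <- b / sqrt(sum(b * b))
    n <- cross3(b, a)
    if (sum(n * n) < 1e-24) {
      # collinear previous bonds (straight rod): reference plane arbitrary
      e <- numeric(3L); e[which.min(abs(a))] <- 1
      n <- cross3(e, a)
    }
    n <- n / sqrt(sum(n * n))
    m <- cross3(n, a)
    th <- pi - alpha[k - 1L]
    ph <- phi[k - 2L]   # dihedral of bond k-1 (vector starts at bond 2)
    u <- cos(th) * a + sin(th) * (-cos(ph) * m + sin(ph) * n)
    r[k + 1L, ] <- r[k, ] + l[k] * u
  }
  r
}

cross3 <- function(p, q) {
  c(p[2L] * q[3L] - p[3L] * q[2L],
    p[3L] * q[1L] - p[1L] * q[3L],
    p[1L] * q[2L] - p[2L] * q[1L])
}

#' End-to-end vector of a chain
#'
#' @param coords Coordinate matrix from [build_coordinates()] (or any matrix
#'   of chain node positions, one row per node).
#' @return Numeric length-3 vector from the first to the last node (nm).
#' @export
end_to_end_vector <- function(coords) {
  stopifnot(is.matrix(coords), nrow(coords) >= 2L, ncol(coords) == 3L)
  unname(coords[nrow(coords), ] - coords[1L, ])
}

# Measured model dihedral (rad, trans = 0) of bond j from coordinates.
measure_dihedral <- function(coords, j) {
  b1 <- coords[j, ] - coords[j - 1L, ]
  b2 <- coords[j + 1L, ] - coords[j, ]
  b3 <- coords[j + 2L, ] - coords[j + 1L, ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2 * b2)))
  std <- atan2(sum(m1 * n2), sum(n1 * n2))
  ((std + pi + pi) %% (2 * pi)) - pi     # model convention: trans = 0
}

# Interior bond angle (deg) at node k from coordinates.
measure_angle <- function(coords, k) {
  a <- coords[k - 1L, ] - coords[k, ]
  b <- coords[k + 1L, ] - coords[k, ]
  acos(sum(a * b) / sqrt(sum(a * a) * sum(b * b))) * 180 / pi
}

# Recover internal coordinates from Cartesian positions (round-trip support).
coords_to_internal <- function(topology, coords) {
  M <- topology$n_bonds
  d <- coords[-1L, , drop = FALSE] - coords[-nrow(coords), , drop = FALSE]
  lengths <- sqrt(rowSums(d * d))
  angles <- vapply(2L:M, function(k) measure_angle(coords, k), numeric(1))
  states <- vapply(topology$rotatable_bonds, function(j) {
    phi <- measure_dihedral(coords, j)
    DIHEDRAL_STATES[which.min(abs(c(phi, phi - 2 * pi / 3, phi + 2 * pi / 3)))]
  }, character(1))
  conformation(topology, states, lengths, angles)
}

#' Write chain coordinates as an XYZ snapshot
#'
#' Writes a standard XYZ file with one pseudo-element per node kind
#' (`N` for ionizable nodes, `C` for inert nodes) for visual inspection in
#' any molecular viewer.  Coordinates are written in Angstrom as usual for
#' the format.
#'
#' @param coords Coordinate matrix (nm).
#' @param topology A [chain_topology()].
#' @param file Path of the file to write.
#' @param comment Comment line for the snapshot.
#' @return The file path, invisibly.
#' @export
write_xyz <- function(coords, topology, file, comment = "sbris chain snapshot") {
  stopifnot(nrow(coords) == topology$n_nodes)
  elem <- ifelse(topology$node_kinds == "ionizable", "N", "C")
  lines <- c(
    as.character(nrow(coords)),
    comment,
    sprintf("%s %12.6f %12.6f %12.6f", elem,
            coords[, 1L] * 10, coords[, 2L] * 10, coords[, 3L] * 10)
  )
  writeLines(lines, file)
  invisible(file)
}
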