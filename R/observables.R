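# Thermal-average observables and their uncertainties.

#' Degree of protonation from sampled proton counts
#'
#' \eqn{\theta = \langle N_+ \rangle / N} with a standard error from block
#' averaging.
#'
#' @param nplus Sampled numbers of protonated sites.
#' @param n_sites Number of ionizable sites N.
#' @param n_blocks Number of blocks for the SE estimate.
#' @return Named vector `c(value=, se=)`.
#' @export
degree_of_protonation <- function(nplus, n_sites, n_blocks = 32L) {
  c(value = mean(nplus) / n_sites,
    se = block_standard_error(nplus / n_sites, n_blocks))
}

#' Binding capacitance from sampled proton counts
#'
#' The variance of the number of bound protons,
#' \eqn{C = \langle (N_+ - N\theta)^2 \rangle}; it equals
#' \eqn{N \partial\theta/\partial\mu}, which [capacitance_from_titration()]
#' exploits as an independent cross-check by finite differences over pH.
#' Undefined for constant-charge samples, where the charge is frozen.
#'
#' @param nplus Sampled numbers of protonated sites.
#' @param mode Sampling mode that produced the samples.
#' @return The capacitance (dimensionless variance).
#' @export
binding_capacitance <- function(nplus, mode = "sgcmc") {
  if (mode != "sgcmc")
    stop("capacitance is undefined for constant-charge (ccmc) samples")
  mean((nplus - mean(nplus))^2)
}

#' Capacitance from the slope of the titration curve
#'
#' Finite-difference evaluation of \eqn{C = N \partial\theta/\partial\mu}
#' with \eqn{\mu = \ln 10\,(pH - pK)}, i.e.
#' \eqn{C = -N \Delta\theta / (\ln 10\, \Delta pH)}... note \eqn{\theta}
#' decreases with pH, so the slope against \eqn{\mu = \ln 10 (pH - pK)}
#' enters with its sign: \eqn{C = N\, d\theta/d(-\mu)}.
#'
#' @param theta_lo,theta_hi Degrees of protonation at `pH - dpH/2` and
#'   `pH + dpH/2`.
#' @param dpH pH step of the central difference.
#' @param n_sites Number of ionizable sites N.
#' @return Capacitance estimate.
#' @export
capacitance_from_titration <- function(theta_lo, theta_hi, dpH, n_sites) {
  -n_sites * (theta_hi - theta_lo) / (log(10) * dpH)
}

#' Gauche-state probability
#'
#' \eqn{P(g) = \langle M_g \rangle / M_{rot}} where \eqn{M_g} is the number
#' of bonds in either gauche state.  The denominator is the number of
#' rotatable bonds: the frozen bonds are always trans by construction, and
#' the free-chain limit of 2/3 (three isoenergetic states) only holds with
#' this convention.  Dividing by all M bonds is available for comparison.
#'
#' @param mg Sampled gauche-bond counts.
#' @param topology A [chain_topology()].
#' @param denominator `"rotatable"` (default) or `"all"` bonds.
#' @return The gauche fraction.
#' @export
gauche_probability <- function(mg, topology,
                               denominator = c("rotatable", "all")) {
  denominator <- match.arg(denominator)
  m <- if (denominator == "rotatable") length(topology$rotatable_bonds)
       else topology$n_bonds
  mean(mg) / m
}

#' Persistence length from the mean square end-to-end distance
#'
#' \eqn{l_p = \langle r^2 \rangle / (2 M l_0) + l_0 / 2}.  The lower bound
#' \eqn{l_0/2} is attained at \eqn{\langle r^2\rangle = 0}; a rigid rod of
#' M bonds gives \eqn{M l_0/2 + l_0/2}.
#'
#' @param mean_sq_end_to_end \eqn{\langle r^2 \rangle} in nm^2.
#' @param topology A [chain_topology()].
#' @return Persistence length in nm.
#' @export
persistence_length_from_r2 <- function(mean_sq_end_to_end, topology) {
  stopifnot(mean_sq_end_to_end >= 0)
  mean_sq_end_to_end / (2 * topology$n_bonds * topology$l0) + topology$l0 / 2
}

#' Persistence length from bond-direction correlations
#'
#' Sum of the average projections of all bonds \eqn{j \ge i} onto the
#' direction of a central reference bond i,
#' \eqn{l_p = \sum_{j \ge i} \langle \vec{u}_j \cdot \hat{u}_i \rangle}.
#' The central bond is used to reduce end effects.  For long uncharged
#' chains this estimator agrees with [persistence_length_from_r2()].
#'
#' @param coords_samples List of coordinate matrices (snapshots), or a
#'   single matrix.
#' @param reference_bond Reference bond index (default: central bond).
#' @return Persistence length in nm.
#' @export
persistence_length_projection <- function(coords_samples, reference_bond = NULL) {
  if (is.matrix(coords_samples)) coords_samples <- list(coords_samples)
  M <- nrow(coords_samples[[1L]]) - 1L
  if (is.null(reference_bond)) reference_bond <- max(1L, M %/% 2L)
  proj <- vapply(coords_samples, function(r) {
    u <- r[-1L, , drop = FALSE] - r[-nrow(r), , drop = FALSE]
    uc <- u[reference_bond, ]
    uc <- uc / sqrt(sum(uc * uc))
    sum(u[reference_bond:M, , drop = FALSE] %*% uc)
  }, numeric(1))
  mean(proj)
}

#' Kirkwood-Shumaker interaction between two charge-regulating bodies
#'
#' Leading-order interaction free energy of two identical macromolecules
#' with mean charge Q and binding capacitance C at separation R (no
#' counterions):
#' \eqn{\beta U = \ell_B Q^2/R - (\ell_B^2/R^2) Q C - (\ell_B^2/2R^2) C^2}.
#' The fluctuation terms are attractive even for net-neutral regulators.
#'
#' @param Q Mean charge (elementary charges).
#' @param C Binding capacitance.
#' @param R Separation in nm (> 0).
#' @param env An [electrostatic_environment()] (only the Bjerrum length is
#'   used).
#' @return Energy in kBT.
#' @examples
#' kirkwood_shumaker_energy(1, 1, 0.7, electrostatic_environment(0.1))  # -0.5
#' @export
kirkwood_shumaker_energy <- function(Q, C, R, env = electrostatic_environment(0.1)) {
  if (any(R <= 0)) stop("separation R must be positive")
  lB <- env$bjerrum_length
  lB * Q^2 / R - lB^2 / R^2 * Q * C - lB^2 / (2 * R^2) * C^2
}

#' Standard error over independent replicates
#'
#' @param values Per-replicate observable values (>= 2).
#' @return Standard error of the replicate mean; `NA` with a warning for a
#'   single replicate.
#' @export
replicate_standard_error <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    warning("standard error unavailable with fewer than 2 replicates")
    return(NA_real_)
  }
  stats::sd(values) / sqrt(length(values))
}

#' Block-averaged standard error of a correlated series
#'
#' Splits the series into `n_blocks` contiguous blocks and uses the spread
#' of the block means, which accounts for autocorrelation when the blocks
#' are longer than the correlation time.
#'
#' @param x Sampled series.
#' @param n_blocks Number of blocks.
#' @return Standard error of the series mean.
#' @export
block_standard_error <- function(x, n_blocks = 32L) {
  n <- length(x)
  if (n < 2L * n_blocks) n_blocks <- max(2L, n %/% 2L)
  size <- n %/% n_blocks
  if (size < 1L) return(NA_real_)
  means <- vapply(seq_len(n_blocks), function(b)
    mean(x[((b - 1L) * size + 1L):(b * size)]), numeric(1))
  stats::sd(means) / sqrt(n_blocks)
}
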