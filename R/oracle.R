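# Exact statistical mechanics for tiny rigid chains by brute-force
# enumeration of the protonation x rotational state space.  This is the
# primary ground truth for the Monte Carlo sampler.

#' Exact enumeration of the SBRIS state space (tiny rigid chains)
#'
#' Enumerates every combination of protonation pattern (SGCMC mode) and
#' rotational states, evaluates the Boltzmann weight of each microstate
#' with the plain-R energy functions, and returns exact thermal averages.
#' The geometry must be rigid (no elastic sampling): bonds at `l0`, angles
#' at `alpha0`.
#'
#' An applied force is handled exactly by averaging each conformation over
#' the global orientations of its end-to-end vector: a conformation with
#' end-to-end distance r acquires the weight factor
#' \eqn{\sinh(x)/x} with \eqn{x = \beta F r}, and its mean extension along
#' the force is \eqn{r\,L(x)} with the Langevin function
#' \eqn{L(x) = \coth x - 1/x}.
#'
#' @param topology A [chain_topology()].
#' @param settings A [simulation_settings()] (rigid: `elastic_sampling`
#'   must be `FALSE`).
#' @param max_states Refuse state spaces larger than this.
#' @return An object of class `sbris_enumeration` with fields
#'   `partition_function`, `theta`, `capacitance`, `p_gauche`,
#'   `mean_sq_end_to_end`, `extension_z` and `persistence_length`.
#' @examples
#' topo <- chain_topology(2, eps_int = c(t = 0, gp = 0, gm = 0))
#' st <- simulation_settings("sgcmc", pH = 9, ionic_strength = 1,
#'                           bjerrum_length = 0, n_steps = 10,
#'                           n_equilibration = 0)
#' enumerate_states(topo, st)   # theta = 1/2, P(g) = 2/3
#' @export
enumerate_states <- function(topology, settings, max_states = 1e6) {
  stopifnot(inherits(topology, "chain_topology"),
            inherits(settings, "simulation_settings"))
  if (settings$elastic_sampling)
    stop("exact enumeration requires a rigid chain (elastic_sampling = FALSE)")
  N <- topology$n_ionizable
  n_rot <- length(topology$rotatable_bonds)
  n_conf <- 3^n_rot
  n_prot <- if (settings$mode == "sgcmc") 2^N else 1
  if (n_conf * n_prot > max_states)
    stop(sprintf("state space too large: %g states (max %g)",
                 n_conf * n_prot, max_states))
  env <- electrostatic_environment(settings$ionic_strength, settings$bjerrum_length)
  f_int <- settings$force / sbris_constants$kBT_pN_nm

  # protonation patterns and their one-body term
  if (settings$mode == "sgcmc") {
    smat <- as.matrix(expand.grid(rep(list(0:1), N)))
    fp <- LN10 * (settings$pH - topology$pK) * rowSums(smat)
  } else {
    smat <- matrix(settings$theta, 1L, N)
    fp <- 0
  }
  nplus <- rowSums(smat == 1)

  Z <- 0; s_np <- 0; s_np2 <- 0; s_mg <- 0; s_r2 <- 0; s_rz <- 0
  states <- DIHEDRAL_STATES
  digits <- integer(max(n_rot, 1L))
  for (ic in seq_len(n_conf)) {
    v <- ic - 1L
    for (k in seq_len(n_rot)) { digits[k] <- v %% 3L; v <- v %/% 3L }
    conf <- conformation(topology, states[digits[seq_len(n_rot)] + 1L])
    coords <- build_coordinates(topology, conf)
    if (sev_overlap(coords, topology, settings$sev_enabled)) next
    mg <- sum(digits[seq_len(n_rot)] != 0L)
    erot <- rotational_energy(conf, topology$eps_rot)
    r <- end_to_end_vector(coords)
    rlen <- sqrt(sum(r * r))
    x <- f_int * rlen
    if (x > 1e-8) {
      w_or <- sinh(x) / x
      rz_mean <- rlen * (1 / tanh(x) - 1 / x)
    } else {
      w_or <- 1 + x^2 / 6
      rz_mean <- rlen * x / 3
    }
    # interaction energies per protonation pattern
    for (ip in seq_len(nrow(smat))) {
      q <- smat[ip, ]
      e <- erot + fp[ip] +
        short_range_energy(q, conf, topology$eps_int) +
        long_range_energy(q, coords, env, topology)
      w <- exp(-e) * w_or
      Z <- Z + w
      np <- if (settings$mode == "sgcmc") nplus[ip] else N * settings$theta
      s_np <- s_np + w * np
      s_np2 <- s_np2 + w * np^2
      s_mg <- s_mg + w * mg
      s_r2 <- s_r2 + w * rlen^2
      s_rz <- s_rz + w * rz_mean
    }
  }
  if (Z <= 0) stop("partition function vanished: no accessible states")
  mean_np <- unname(s_np / Z)
  r2 <- unname(s_r2 / Z)
  s_np2 <- unname(s_np2); s_mg <- unname(s_mg); s_rz <- unname(s_rz)
  Z <- unname(Z)
  structure(list(
    partition_function = Z,
    theta = mean_np / N,
    capacitance = if (settings$mode == "sgcmc") s_np2 / Z - mean_np^2 else NA_real_,
    p_gauche = (s_mg / Z) / n_rot,
    mean_sq_end_to_end = r2,
    extension_z = s_rz / Z,
    persistence_length = persistence_length_from_r2(r2, topology),
    n_states = n_conf * n_prot,
    mode = settings$mode
  ), class = "sbris_enumeration")
}

#' @export
print.sbris_enumeration <- function(x, ...) {
  cat(sprintf("Exact enumeration (%s, %g microstates)\n", x$mode, x$n_states))
  cat(sprintf("  theta = %.6g   C = %.6g   P(g) = %.6g\n",
              x$theta, x$capacitance, x$p_gauche))
  cat(sprintf("  <r2> = %.6g nm^2   <rz> = %.6g nm   lp = %.6g nm\n",
              x$mean_sq_end_to_end, x$extension_z, x$persistence_length))
  invisible(x)
}

#' Ideal (non-interacting) titration curve
#'
#' Langmuir / Henderson-Hasselbalch limit for identical independent sites:
#' \eqn{\theta = 1 / (1 + 10^{pH - pK})}.
#'
#' @param pH Solution pH (vectorised).
#' @param pK Site pK.
#' @return Degree of protonation.
#' @examples
#' ideal_titration(9, 9)   # 0.5
#' @export
ideal_titration <- function(pH, pK) {
  1 / (1 + 10^(pH - pK))
}
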