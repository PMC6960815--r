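#' Monte Carlo simulation settings
#'
#' Control variables for [run_simulation()].  Two sampling modes are
#' supported: `"sgcmc"` (semi-grand canonical, constant pH, fluctuating
#' protonation; requires `pH`) and `"ccmc"` (constant smeared charge;
#' requires `theta`, protonation moves disabled, the proton-binding term is
#' dropped).
#'
#' Step counts refer to elementary move attempts.  `n_equilibration`
#' attempts are discarded before `n_steps` production attempts are
#' accumulated.  The `"desk"` preset (1e6 equilibration + 1e7 production, 8
#' replicates) is sized for interactive work and the test bench; the
#' `"full"` preset (5e7 + 1e9, 12 replicates) matches the full production
#' conditions of the reference study.
#'
#' @param mode `"sgcmc"` or `"ccmc"`.
#' @param pH Solution pH (sgcmc only).
#' @param theta Smeared charge per site in `[0, 1]` (ccmc only).
#' @param ionic_strength Ionic strength in mol/L.
#' @param force Applied stretching force in pN (along the laboratory z axis).
#' @param sev_enabled Enable hard-sphere excluded volume.
#' @param elastic_sampling Sample the continuous bond lengths and angles; if
#'   `FALSE` the chain is rigid at `l0`, `alpha0`.
#' @param n_steps Production move attempts per replicate.
#' @param n_equilibration Discarded attempts per replicate
#'   (`< n_steps`).
#' @param n_replicates Number of independent replicate chains.
#' @param move_mix Named probabilities over
#'   `c(flip=, rotation=, elastic=)`; must sum to 1, `flip` must be 0 in
#'   ccmc mode and `elastic` must be 0 when `elastic_sampling` is off.
#'   Defaults: 0.25/0.75/0 (sgcmc, rigid), 0.2/0.6/0.2 (sgcmc, elastic),
#'   0/1/0 (ccmc, rigid), 0/0.75/0.25 (ccmc, elastic).
#' @param p_reorient Probability that an attempt is a rigid-body
#'   reorientation of the whole chain (random axis, uniform angle) instead
#'   of one of the `move_mix` moves.  Single-arm pivots conserve the
#'   laboratory direction of the central bond, so these moves are what
#'   makes the global orientation ergodic; they only couple to the
#'   mechanical work term.  The remaining probability is shared among the
#'   `move_mix` moves in their given proportions.
#' @param seed Master seed (integer); replicate sub-seeds are derived from
#'   it by a fixed splitting rule, so a run is fully reproducible.
#' @param sample_every Record observables every this many attempts.
#' @param sigma_length,sigma_angle Gaussian step widths for elastic moves
#'   (nm and degrees).  Defaults are one thermal standard deviation of the
#'   corresponding harmonic term for the reference force constants.
#' @param bjerrum_length Bjerrum length in nm (0.7 for water at 298.15 K;
#'   0 switches long-range electrostatics off).
#' @param check_every Recompute the total energy from scratch every this
#'   many attempts and track the worst drift of the incremental energy
#'   (0 = never; a diagnostic, not needed in production).
#' @param preset `"desk"`, `"full"`, or `NULL` to use `n_steps`,
#'   `n_equilibration` and `n_replicates` as given.
#' @return An object of class `simulation_settings`.
#' @examples
#' simulation_settings("sgcmc", pH = 7, ionic_strength = 0.1, seed = 1,
#'                     n_steps = 1e5, n_equilibration = 1e4, n_replicates = 2)
#' @export
simulation_settings <- function(mode = c("sgcmc", "ccmc"),
                                pH = NULL,
                                theta = NULL,
                                ionic_strength = 0.1,
                                force = 0,
                                sev_enabled = FALSE,
                                elastic_sampling = FALSE,
                                n_steps = 1e7,
                                n_equilibration = 1e6,
                                n_replicates = 8L,
                                move_mix = NULL,
                                p_reorient = 0.05,
                                seed = 1L,
                                sample_every = 100L,
                                sigma_length = 0.0044,
                                sigma_angle = 7.7,
                                bjerrum_length = sbris_constants$bjerrum_nm,
                                check_every = 0L,
                                preset = NULL) {
  mode <- match.arg(mode)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "full"))
    if (preset == "desk") {
      n_equilibration <- 1e6; n_steps <- 1e7; n_replicates <- 8L
    } else {
      n_equilibration <- 5e7; n_steps <- 1e9; n_replicates <- 12L
    }
  }
  if (mode == "sgcmc") {
    if (is.null(pH)) stop("sgcmc mode requires 'pH'")
    if (!is.null(theta)) stop("'theta' is an output of sgcmc, not an input")
  } else {
    if (is.null(theta)) stop("ccmc mode requires 'theta'")
    stopifnot(theta >= 0, theta <= 1)
    if (!is.null(pH)) stop("'pH' is not a control variable in ccmc mode")
  }
  stopifnot(ionic_strength >= 0, n_steps >= 1, n_equilibration >= 0,
            n_equilibration < n_steps, n_replicates >= 1,
            sample_every >= 1, sigma_length > 0, sigma_angle > 0,
            p_reorient >= 0, p_reorient < 1,
            bjerrum_length >= 0, check_every >= 0)
  if (is.null(move_mix)) {
    move_mix <- if (mode == "sgcmc") {
      if (elastic_sampling) c(flip = 0.2, rotation = 0.6, elastic = 0.2)
      else c(flip = 0.25, rotation = 0.75, elastic = 0)
    } else {
      if (elastic_sampling) c(flip = 0, rotation = 0.75, elastic = 0.25)
      else c(flip = 0, rotation = 1, elastic = 0)
    }
  }
  if (is.null(names(move_mix)) || !all(c("flip", "rotation", "elastic") %in% names(move_mix)))
    stop("'move_mix' must be named with entries flip, rotation, elastic")
  move_mix <- move_mix[c("flip", "rotation", "elastic")]
  if (abs(sum(move_mix) - 1) > 1e-12) stop("'move_mix' must sum to 1")
  if (any(move_mix < 0)) stop("'move_mix' probabilities must be non-negative")
  if (mode == "ccmc" && move_mix[["flip"]] > 0)
    stop("protonation flips are not available in ccmc mode")
  if (!elastic_sampling && move_mix[["elastic"]] > 0)
    stop("elastic moves require elastic_sampling = TRUE")
  structure(list(
    mode = mode, pH = pH, theta = theta,
    ionic_strength = ionic_strength, force = force,
    sev_enabled = isTRUE(sev_enabled),
    elastic_sampling = isTRUE(elastic_sampling),
    n_steps = n_steps, n_equilibration = n_equilibration,
    n_replicates = as.integer(n_replicates),
    move_mix = move_mix, p_reorient = p_reorient, seed = as.integer(seed),
    sample_every = as.integer(sample_every),
    sigma_length = sigma_length, sigma_angle = sigma_angle,
    bjerrum_length = bjerrum_length,
    check_every = as.integer(check_every)
  ), class = "simulation_settings")
}

#' @export
print.simulation_settings <- function(x, ...) {
  cond <- if (x$mode == "sgcmc") sprintf("pH = %g", x$pH)
          else sprintf("theta = %g", x$theta)
  cat(sprintf("%s settings: %s, I = %g M, F = %g pN\n",
              toupper(x$mode), cond, x$ionic_strength, x$force))
  cat(sprintf("  %g equilibration + %g production attempts x %d replicates (seed %d)\n",
              x$n_equilibration, x$n_steps, x$n_replicates, x$seed))
  cat(sprintf("  moves (flip/rotation/elastic): %g/%g/%g; SEV %s; elastic %s\n",
              x$move_mix[["flip"]], x$move_mix[["rotation"]], x$move_mix[["elastic"]],
              if (x$sev_enabled) "on" else "off",
              if (x$elastic_sampling) "on" else "off"))
  invisible(x)
}
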