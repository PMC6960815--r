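# R-side driver for the compiled Metropolis kernel.

kernel_topology <- function(topology) {
  c(topology[c("n_ionizable", "n_nodes", "n_bonds", "site_nodes",
               "rotatable_bonds", "l0", "alpha0", "k_length_int",
               "k_angle_int", "node_radii", "pK")],
    list(eps_int_vec = unname(topology$eps_int[c("t", "gp", "gm")]),
         eps_rot_vec = unname(topology$eps_rot[c("t", "gp", "gm")])))
}

kernel_ctrl <- function(settings, replicate = 1L) {
  env <- electrostatic_environment(settings$ionic_strength, settings$bjerrum_length)
  list(
    mode = if (settings$mode == "sgcmc") 0L else 1L,
    pH = if (is.null(settings$pH)) 0 else settings$pH,
    theta = if (is.null(settings$theta)) 0 else settings$theta,
    bjerrum = settings$bjerrum_length,
    kappa = env$kappa,
    force_pN = settings$force,
    sev = as.integer(settings$sev_enabled),
    elastic = as.integer(settings$elastic_sampling),
    n_equil = as.double(settings$n_equilibration),
    n_steps = as.double(settings$n_steps),
    p_flip = settings$move_mix[["flip"]],
    p_rot = settings$move_mix[["rotation"]],
    p_orient = settings$p_reorient,
    sample_every = settings$sample_every,
    check_every = settings$check_every,
    sigma_l = settings$sigma_length,
    sigma_a = settings$sigma_angle * pi / 180,
    seed = as.double(settings$seed),
    replicate = as.integer(replicate)
  )
}

#' Metropolis acceptance rule
#'
#' Accepts a proposed move of energy change `delta_energy` (kBT) with
#' probability \eqn{\min(1, e^{-\Delta E})}.  Uses R's random number stream.
#'
#' @param delta_energy Energy change(s) in kBT; `+Inf` (e.g. a hard-sphere
#'   clash) is always rejected.
#' @return Logical vector of accept decisions.
#' @export
metropolis_accept <- function(delta_energy) {
  p <- exp(pmin(-delta_energy, 0))
  p[is.nan(p)] <- 0          # -Inf - Inf guards
  stats::runif(length(delta_energy)) < p
}

#' Run a Monte Carlo simulation of the SBRIS chain
#'
#' Runs `n_replicates` independent Metropolis chains (sub-seeded from the
#' master seed by a fixed splitting rule), discards the equilibration
#' attempts, and accumulates thermal averages of the degree of protonation,
#' binding capacitance, gauche-state probability, end-to-end statistics and
#' persistence length.  Uncertainties are standard errors over replicates.
#'
#' @param settings A [simulation_settings()].
#' @param topology A [chain_topology()].
#' @return An object of class `sbris_result` with print and summary methods.
#'   Key fields: `theta`, `capacitance`, `p_gauche`, `extension_z`,
#'   `mean_sq_end_to_end`, `persistence_length` (all with `*_se`
#'   companions), `persistence_length_projection`, the per-replicate table
#'   `replicates`, per-move acceptance rates and the worst incremental
#'   energy drift seen by the consistency check (if enabled).
#' @examples
#' topo <- chain_topology(4)
#' st <- simulation_settings("sgcmc", pH = 9, ionic_strength = 1, seed = 42,
#'                           n_steps = 2e4, n_equilibration = 2e3,
#'                           n_replicates = 2)
#' run_simulation(st, topo)
#' @export
run_simulation <- function(settings, topology) {
  stopifnot(inherits(settings, "simulation_settings"),
            inherits(topology, "chain_topology"))
  topo <- kernel_topology(topology)
  N <- topology$n_ionizable
  n_rot <- length(topology$rotatable_bonds)
  M <- topology$n_bonds
  l0 <- topology$l0

  reps <- vector("list", settings$n_replicates)
  for (r in seq_len(settings$n_replicates)) {
    out <- run_chain_cpp(topo, kernel_ctrl(settings, r))
    if (length(out$nplus) == 0L)
      stop("no samples recorded: increase n_steps or decrease sample_every")
    theta_r <- if (settings$mode == "sgcmc") mean(out$nplus) / N else settings$theta
    cap_r <- if (settings$mode == "sgcmc") mean((out$nplus - mean(out$nplus))^2) else NA_real_
    r2_r <- mean(out$r2)
    reps[[r]] <- list(
      theta = theta_r,
      capacitance = cap_r,
      p_gauche = mean(out$mg) / n_rot,
      p_gauche_plus = mean(out$mg_plus) / n_rot,
      p_gauche_minus = (mean(out$mg) - mean(out$mg_plus)) / n_rot,
      extension_z = mean(out$rz),
      mean_sq_end_to_end = r2_r,
      persistence_length = persistence_length_from_r2(r2_r, topology),
      persistence_length_projection = mean(out$proj),
      n_samples = length(out$nplus),
      attempts = out$attempts,
      accepts = out$accepts,
      max_energy_drift = out$max_energy_drift
    )
  }
  rep_tab <- data.frame(
    replicate = seq_along(reps),
    theta = vapply(reps, `[[`, 0, "theta"),
    capacitance = vapply(reps, `[[`, 0, "capacitance"),
    p_gauche = vapply(reps, `[[`, 0, "p_gauche"),
    p_gauche_plus = vapply(reps, `[[`, 0, "p_gauche_plus"),
    p_gauche_minus = vapply(reps, `[[`, 0, "p_gauche_minus"),
    extension_z = vapply(reps, `[[`, 0, "extension_z"),
    mean_sq_end_to_end = vapply(reps, `[[`, 0, "mean_sq_end_to_end"),
    persistence_length = vapply(reps, `[[`, 0, "persistence_length"),
    persistence_length_projection =
      vapply(reps, `[[`, 0, "persistence_length_projection")
  )
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(c(NA_real_, NA_real_))
    c(mean(v), if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }
  obs <- lapply(rep_tab[-1L], agg)
  attempts <- Reduce(`+`, lapply(reps, `[[`, "attempts"))
  accepts <- Reduce(`+`, lapply(reps, `[[`, "accepts"))
  acc_rate <- ifelse(attempts > 0, accepts / attempts, NA_real_)
  names(acc_rate) <- c("flip", "rotation", "elastic", "reorientation")

  structure(list(
    mode = settings$mode,
    theta = obs$theta[1], theta_se = obs$theta[2],
    capacitance = obs$capacitance[1], capacitance_se = obs$capacitance[2],
    p_gauche = obs$p_gauche[1], p_gauche_se = obs$p_gauche[2],
    extension_z = obs$extension_z[1], extension_z_se = obs$extension_z[2],
    mean_sq_end_to_end = obs$mean_sq_end_to_end[1],
    mean_sq_end_to_end_se = obs$mean_sq_end_to_end[2],
    persistence_length = obs$persistence_length[1],
    persistence_length_se = obs$persistence_length[2],
    persistence_length_projection = obs$persistence_length_projection[1],
    persistence_length_projection_se = obs$persistence_length_projection[2],
    replicates = rep_tab,
    acceptance_rates = acc_rate,
    max_energy_drift = max(vapply(reps, `[[`, 0, "max_energy_drift")),
    n_samples_per_replicate = reps[[1L]]$n_samples,
    settings = settings,
    n_ionizable = N,
    contour_length = contour_length(topology)
  ), class = "sbris_result")
}

#' @export
print.sbris_result <- function(x, ...) {
  fmt <- function(v, se) {
    if (is.na(v)) return("  NA")
    if (is.na(se)) sprintf("%.5g", v) else sprintf("%.5g +/- %.2g", v, se)
  }
  cond <- if (x$mode == "sgcmc") sprintf("pH = %g", x$settings$pH)
          else sprintf("theta = %g (fixed)", x$settings$theta)
  cat(sprintf("%s simulation, %s, I = %g M, F = %g pN (%d replicates)\n",
              toupper(x$mode), cond, x$settings$ionic_strength,
              x$settings$force, x$settings$n_replicates))
  cat("  degree of protonation  theta =", fmt(x$theta, x$theta_se), "\n")
  cat("  binding capacitance    C     =", fmt(x$capacitance, x$capacitance_se), "\n")
  cat("  gauche probability     P(g)  =", fmt(x$p_gauche, x$p_gauche_se), "\n")
  cat("  persistence length     lp    =", fmt(x$persistence_length, x$persistence_length_se), "nm\n")
  cat("  extension along force  Lz    =", fmt(x$extension_z, x$extension_z_se), "nm\n")
  cat("  mean square end-to-end <r2>  =", fmt(x$mean_sq_end_to_end, x$mean_sq_end_to_end_se), "nm^2\n")
  invisible(x)
}

#' @export
summary.sbris_result <- function(object, ...) {
  print(object)
  cat("  acceptance rates:",
      paste(names(object$acceptance_rates),
            signif(object$acceptance_rates, 3), collapse = ", "), "\n")
  if (object$max_energy_drift > 0)
    cat("  max incremental-energy drift:", object$max_energy_drift, "kBT\n")
  invisible(object)
}

#' @export
as.data.frame.sbris_result <- function(x, ...) {
  s <- x$settings
  data.frame(
    mode = x$mode,
    pH = if (is.null(s$pH)) NA_real_ else s$pH,
    theta_input = if (is.null(s$theta)) NA_real_ else s$theta,
    ionic_strength = s$ionic_strength,
    force = s$force,
    theta = x$theta, theta_se = x$theta_se,
    capacitance = x$capacitance, capacitance_se = x$capacitance_se,
    p_gauche = x$p_gauche, p_gauche_se = x$p_gauche_se,
    lp = x$persistence_length, lp_se = x$persistence_length_se,
    Lz = x$extension_z, Lz_se = x$extension_z_se,
    r2 = x$mean_sq_end_to_end, r2_se = x$mean_sq_end_to_end_se,
    n_replicates = s$n_replicates,
    n_steps = s$n_steps,
    seed = s$seed,
    stringsAsFactors = FALSE
  )
}
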