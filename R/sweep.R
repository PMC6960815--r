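# Reproducible experiment sweeps: grids over pH / ionic strength / force,
# SGCMC -> ccMC chaining, and CSV result tables.

#' Define an experiment sweep
#'
#' The Cartesian product of the given axes defines the conditions; each
#' condition becomes one [simulation_settings()] built on top of
#' `base_settings` overrides.
#'
#' @param pH pH values (sgcmc conditions) or `NA` for ccmc-only plans.
#' @param ionic_strength Ionic strengths in mol/L.
#' @param force Applied forces in pN.
#' @param mode `"sgcmc"`, `"ccmc"` or `"both"` (ccmc conditions take their
#'   theta from the paired sgcmc run at zero force, see [run_plan()]).
#' @param base_settings Named list of [simulation_settings()] arguments
#'   applied to every condition (step counts, seed, flags...).
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(pH, ionic_strength, force = 0,
                            mode = c("sgcmc", "ccmc", "both"),
                            base_settings = list()) {
  mode <- match.arg(mode)
  if (length(pH) == 0L || length(ionic_strength) == 0L || length(force) == 0L)
    stop("empty plan: every axis needs at least one value")
  grid <- expand.grid(pH = pH, ionic_strength = ionic_strength, force = force,
                      KEEP.OUT.ATTRS = FALSE)
  structure(list(grid = grid, mode = mode, base_settings = base_settings),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("Experiment plan: %d conditions (%s)\n", nrow(x$grid), x$mode))
  invisible(x)
}

condition_settings <- function(plan, pH = NULL, theta = NULL, I, F,
                               mode, condition_index) {
  args <- modifyList(list(mode = mode, ionic_strength = I, force = F),
                     plan$base_settings)
  if (mode == "sgcmc") args$pH <- pH else args$theta <- theta
  # decorrelate conditions deterministically from the master seed
  base_seed <- if (is.null(args$seed)) 1L else args$seed
  args$seed <- as.integer((base_seed + 7919L * condition_index) %% .Machine$integer.max)
  do.call(simulation_settings, args)
}

#' Execute an experiment plan
#'
#' Runs every condition of the plan and collects one result row per run
#' (via the as.data.frame method of `sbris_result`).  With `mode = "both"`, each sgcmc
#' condition is followed by the paired constant-charge run at the same
#' ionic strength and force, with `theta` fixed to the sgcmc zero-force
#' average for that (pH, I) — the titrate-then-freeze protocol.
#'
#' @param plan An [experiment_plan()].
#' @param topology A [chain_topology()].
#' @param out_dir Optional directory: results are written to
#'   `results.csv` and the full settings of every condition to
#'   `metadata.csv` there.
#' @return Data frame of per-condition results.
#' @export
run_plan <- function(plan, topology, out_dir = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(plan$grid))) {
    g <- plan$grid[i, ]
    if (plan$mode %in% c("sgcmc", "both")) {
      idx <- idx + 1L
      st <- condition_settings(plan, pH = g$pH, I = g$ionic_strength,
                               F = g$force, mode = "sgcmc",
                               condition_index = idx)
      res <- run_simulation(st, topology)
      rows[[length(rows) + 1L]] <- as.data.frame(res)
      if (plan$mode == "both") {
        idx <- idx + 1L
        rows[[length(rows) + 1L]] <-
          as.data.frame(paired_ccmc(plan, topology, g, res, idx))
      }
    } else {
      stop("ccmc-only plans need an explicit theta: use run_pair() or ",
           "simulation_settings() directly")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(out, file.path(out_dir, "results.csv"))
    meta <- cbind(out[c("mode", "pH", "theta_input", "ionic_strength",
                        "force", "n_replicates", "n_steps", "seed")],
                  package_version = as.character(utils::packageVersion("sbris")))
    write.csv(meta, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  }
  out
}

paired_ccmc <- function(plan, topology, g, sgc_result, condition_index) {
  theta0 <- if (g$force == 0) sgc_result$theta else {
    st0 <- condition_settings(plan, pH = g$pH, I = g$ionic_strength, F = 0,
                              mode = "sgcmc", condition_index = condition_index)
    run_simulation(st0, topology)$theta
  }
  st <- condition_settings(plan, theta = theta0, I = g$ionic_strength,
                           F = g$force, mode = "ccmc",
                           condition_index = condition_index)
  run_simulation(st, topology)
}

#' Paired SGCMC and constant-charge runs (titrate then freeze)
#'
#' Runs the SGCMC condition at zero force to obtain the mean degree of
#' protonation, then launches the constant-charge run with `theta` fixed to
#' that value at the requested force.  This isolates the effect of charge
#' fluctuations at identical mean charge.
#'
#' @param pH Solution pH of the sgcmc leg.
#' @param ionic_strength Ionic strength in mol/L.
#' @param topology A [chain_topology()].
#' @param force Force (pN) applied in both legs.
#' @param ... Further arguments passed to [simulation_settings()] for both
#'   legs (step counts, seed, ...).
#' @return List with elements `sgcmc` and `ccmc` (both `sbris_result`) and
#'   `theta` (the shared mean charge, from the zero-force sgcmc leg).
#' @export
run_pair <- function(pH, ionic_strength, topology, force = 0, ...) {
  st_sg <- simulation_settings(mode = "sgcmc", pH = pH,
                               ionic_strength = ionic_strength,
                               force = force, ...)
  res_sg <- run_simulation(st_sg, topology)
  theta0 <- if (force == 0) res_sg$theta else {
    st0 <- simulation_settings(mode = "sgcmc", pH = pH,
                               ionic_strength = ionic_strength, force = 0, ...)
    run_simulation(st0, topology)$theta
  }
  st_cc <- simulation_settings(mode = "ccmc", theta = theta0,
                               ionic_strength = ionic_strength,
                               force = force, ...)
  res_cc <- run_simulation(st_cc, topology)
  list(sgcmc = res_sg, ccmc = res_cc, theta = theta0)
}

#' Force-extension scan at fixed solution conditions
#'
#' Runs the same condition over a grid of forces and assembles a
#' [force_extension()] curve from the mean extensions.
#'
#' @param forces Forces in pN (strictly increasing).
#' @param topology A [chain_topology()].
#' @param mode,pH,theta,ionic_strength Condition (see
#'   [simulation_settings()]).
#' @param ... Further [simulation_settings()] arguments.
#' @return A [force_extension()] curve; the per-force `sbris_result`
#'   objects are attached as attribute `"results"`.
#' @export
force_extension_scan <- function(forces, topology, mode = "sgcmc",
                                 pH = NULL, theta = NULL,
                                 ionic_strength = 0.1, ...) {
  results <- lapply(forces, function(f)
    run_simulation(simulation_settings(mode = mode, pH = pH, theta = theta,
                                       ionic_strength = ionic_strength,
                                       force = f, ...), topology))
  curve <- force_extension(
    force = forces,
    extension = vapply(results, `[[`, 0, "extension_z"),
    se = vapply(results, `[[`, 0, "extension_z_se"),
    mode = mode, pH = pH, theta = theta, ionic_strength = ionic_strength
  )
  attr(curve, "results") <- results
  curve
}

#' Write / read a result table as CSV
#'
#' @param results Data frame of results (from [run_plan()] or
#'   `as.data.frame()` on results).
#' @param file CSV path.
#' @return `write_results` the path invisibly; `read_results` the data
#'   frame.
#' @export
write_results <- function(results, file) {
  write.csv(results, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_results
#' @export
read_results <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}
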