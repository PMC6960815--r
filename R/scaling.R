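# Low-force scaling analysis of force-extension curves: linear
# (fluctuation-dissipation) regime, Pincus power-law regime, and the
# linear dependence of the Pincus exponent on the degree of protonation.

#' Force-extension curve container
#'
#' @param force Applied forces in pN (strictly increasing).
#' @param extension Mean extensions along the force, nm.
#' @param se Standard errors of the extensions (optional; used as fit
#'   weights 1/se^2).
#' @param ... Condition metadata stored as attributes (e.g. `pH`, `theta`,
#'   `ionic_strength`, `mode`).
#' @return A `force_extension` data frame.
#' @export
force_extension <- function(force, extension, se = NULL, ...) {
  stopifnot(length(force) == length(extension), !is.unsorted(force, strictly = TRUE))
  if (is.null(se)) se <- rep(NA_real_, length(force))
  out <- data.frame(force = force, extension = extension, se = se)
  meta <- list(...)
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  class(out) <- c("force_extension", "data.frame")
  out
}

fit_weights <- function(se) {
  if (all(is.na(se)) || any(se == 0, na.rm = TRUE)) return(NULL)
  1 / se^2
}

#' Fit the very-low-force linear response
#'
#' In the linear regime (forces below ~0.3 pN) the extension obeys
#' \eqn{L_z/(M l_0) = \beta F l_K / 3}, a direct consequence of the
#' fluctuation-dissipation theorem, with the Kuhn length
#' \eqn{l_K = 2 l_p - l_0}.  A zero-intercept weighted least-squares fit
#' over the points with `force < f_max` returns the Kuhn length and the
#' implied persistence length.
#'
#' @param curve A [force_extension()] curve.
#' @param topology A [chain_topology()].
#' @param f_max Upper force bound of the window (pN).
#' @return A `scaling_fit` object with `kuhn_length` and
#'   `persistence_length` (nm).
#' @export
fit_linear_regime <- function(curve, topology, f_max = 0.3) {
  pts <- curve[curve$force < f_max & curve$force > 0, ]
  if (nrow(pts) < 2L)
    stop("insufficient data: need at least 2 points below f_max")
  beta_f <- pts$force / sbris_constants$kBT_pN_nm        # 1/nm
  y <- pts$extension / (topology$n_bonds * topology$l0)  # dimensionless
  w <- fit_weights(pts$se / (topology$n_bonds * topology$l0))
  fit <- if (is.null(w)) stats::lm(y ~ 0 + beta_f) else stats::lm(y ~ 0 + beta_f, weights = w)
  slope <- unname(coef(fit)[1L])            # lK / 3
  lK <- 3 * slope
  structure(list(
    type = "linear",
    kuhn_length = lK,
    persistence_length = (lK + topology$l0) / 2,
    amplitude = slope,
    nu = 0.5,
    fit_window = c(0, f_max),
    n_points = nrow(pts),
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    fit = fit
  ), class = "scaling_fit")
}

#' Fit the Pincus power-law regime
#'
#' For intermediate low forces the extension of a self-avoiding
#' (electrostatically swollen) chain follows the Pincus law
#' \eqn{L_z \propto F^{1/\nu - 1}}.  A weighted least-squares fit of
#' \eqn{\log L_z} against \eqn{\log F} inside the window returns the slope
#' \eqn{1/\nu - 1} and hence the exponent \eqn{\nu}.
#'
#' @param curve A [force_extension()] curve.
#' @param window Force window in pN (default 0.3 to 1, the validity range
#'   of the power law for the reference chain; shorter chains shift the
#'   regime boundaries by roughly kBT/lp).
#' @param sanity Exponent range outside which a warning is raised
#'   (fits are still returned).
#' @param weighted Weight the log-log fit by the inverse squared relative
#'   errors.  Off by default: near the upper end of the window the power
#'   law bends towards saturation while the extensions are most precise,
#'   so error weighting concentrates the fit exactly where the law is
#'   weakest and biases the exponent upward; equal weighting across the
#'   window is the robust choice.
#' @return A `scaling_fit` with `nu`, `nu_se` and `amplitude`.
#' @export
fit_pincus <- function(curve, window = c(0.3, 1), sanity = c(0.45, 0.8),
                       weighted = FALSE) {
  pts <- curve[curve$force >= window[1L] & curve$force <= window[2L], ]
  if (nrow(pts) < 3L) stop("insufficient data: need >= 3 points in the window")
  if (any(pts$extension <= 0))
    stop("non-positive extensions in the fit window")
  lx <- log(pts$force); ly <- log(pts$extension)
  w <- if (weighted) fit_weights(pts$se / pts$extension) else NULL  # delta(log y) = se/y
  fit <- if (is.null(w)) stats::lm(ly ~ lx) else stats::lm(ly ~ lx, weights = w)
  slope <- unname(coef(fit)[2L])             # 1/nu - 1
  slope_se <- tryCatch(suppressWarnings(summary(fit)$coefficients[2L, 2L]), error = function(e) NA_real_)
  nu <- 1 / (slope + 1)
  nu_se <- if (is.na(slope_se)) NA_real_ else nu^2 * slope_se
  if (!is.na(nu) && (nu < sanity[1L] || nu > sanity[2L]))
    warning(sprintf("fitted exponent nu = %.3f outside the sanity envelope [%g, %g]",
                    nu, sanity[1L], sanity[2L]))
  structure(list(
    type = "pincus",
    nu = nu,
    nu_se = nu_se,
    amplitude = exp(unname(coef(fit)[1L])),
    fit_window = window,
    n_points = nrow(pts),
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    fit = fit
  ), class = "scaling_fit")
}

#' Fit the linear dependence of the Pincus exponent on protonation
#'
#' Ordinary (optionally weighted) least squares of \eqn{\nu = m\theta + n}
#' over conditions spanning the protonation range, with coefficient
#' standard errors.
#'
#' @param theta Degrees of protonation (>= 3 distinct values, or exactly 2
#'   for an exact line through two points).
#' @param nu Fitted Pincus exponents at those conditions.
#' @param se Optional standard errors of `nu` (weights 1/se^2).
#' @return A `scaling_fit` with `m`, `n`, `m_se`, `n_se`.
#' @export
fit_nu_vs_theta <- function(theta, nu, se = NULL) {
  stopifnot(length(theta) == length(nu))
  if (length(unique(theta)) < 2L)
    stop("degenerate theta values: cannot fit a line")
  if (length(theta) < 2L) stop("need at least 2 points")
  w <- if (!is.null(se)) fit_weights(se) else NULL
  fit <- if (is.null(w)) stats::lm(nu ~ theta) else stats::lm(nu ~ theta, weights = w)
  cf <- coef(fit)
  ses <- tryCatch(suppressWarnings(summary(fit)$coefficients[, 2L]),
                  error = function(e) c(NA_real_, NA_real_))
  structure(list(
    type = "nu_vs_theta",
    m = unname(cf[2L]), n = unname(cf[1L]),
    m_se = unname(ses[2L]), n_se = unname(ses[1L]),
    n_points = length(theta),
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    fit = fit
  ), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  switch(x$type,
    linear = cat(sprintf(
      "Linear-regime fit (F < %g pN, %d points): lK = %.4g nm, lp = %.4g nm\n",
      x$fit_window[2L], x$n_points, x$kuhn_length, x$persistence_length)),
    pincus = cat(sprintf(
      "Pincus fit (%g-%g pN, %d points): nu = %.4g%s\n",
      x$fit_window[1L], x$fit_window[2L], x$n_points, x$nu,
      if (is.na(x$nu_se)) "" else sprintf(" +/- %.2g", x$nu_se))),
    nu_vs_theta = cat(sprintf(
      "nu(theta) fit (%d points): nu = %.4g theta + %.4g  (m se %.2g, n se %.2g)\n",
      x$n_points, x$m, x$n, x$m_se, x$n_se))
  )
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  switch(object$type,
    linear = c(kuhn_length = object$kuhn_length,
               persistence_length = object$persistence_length),
    pincus = c(nu = object$nu, amplitude = object$amplitude),
    nu_vs_theta = c(m = object$m, n = object$n)
  )
}
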