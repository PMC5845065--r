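# Differential viscoelastic material models (Maxwell, Zener) and their stress
# response to an imposed strain history. SI units throughout.

#' Maxwell viscoelastic material
#'
#' A spring of modulus `E1` in series with a dashpot of viscosity `eta`.
#' The model relaxes stress completely under constant strain and shows
#' permanent deformation, with relaxation time `tau = eta / E1`.
#' Exactly one of `eta`, `tau` may be omitted; if both are given they must
#' agree to relative 1e-12.
#'
#' @param E1 Elastic modulus, Pa (> 0).
#' @param eta Viscous factor, Pa s (> 0).
#' @param tau Relaxation time, s (> 0), `tau = eta / E1`.
#' @return An object of class `maxwell_material` with fields `E1`, `eta`,
#'   `tau`.
#' @examples
#' m <- maxwell_material(E1 = 2.827e6, tau = 13.38)
#' m$eta
#' @export
maxwell_material <- function(E1, eta = NULL, tau = NULL) {
  stopifnot(is.numeric(E1), length(E1) == 1, is.finite(E1), E1 > 0)
  if (is.null(eta) && is.null(tau))
    stop("supply at least one of `eta` or `tau`")
  if (is.null(eta)) eta <- tau * E1
  if (is.null(tau)) tau <- eta / E1
  stopifnot(eta > 0, tau > 0)
  if (abs(tau - eta / E1) > 1e-12 * tau)
    stop("`tau` and `eta`/`E1` disagree beyond relative 1e-12")
  structure(list(E1 = E1, eta = eta, tau = tau), class = "maxwell_material")
}

#' Zener (standard linear solid) viscoelastic material
#'
#' A Maxwell branch (`E1`, dashpot `eta = tau * E1`) in parallel with a spring
#' `E0`. Instantaneous modulus `E0 + E1`, equilibrium modulus `E0`.
#' `E0 = 0` is admitted as the degenerate case in which the model reduces
#' exactly to the Maxwell model.
#'
#' @param E0 Parallel (equilibrium) elastic modulus, Pa (>= 0).
#' @param E1 Series elastic modulus, Pa (> 0).
#' @param tau Relaxation time of the Maxwell branch, s (> 0).
#' @return An object of class `zener_material` with fields `E0`, `E1`, `tau`
#'   and the derived `eta = tau * E1`.
#' @examples
#' pdms <- zener_material(E0 = 2.114e6, E1 = 0.9365e6, tau = 0.2611)
#' @export
zener_material <- function(E0, E1, tau) {
  stopifnot(is.numeric(E0), length(E0) == 1, is.finite(E0), E0 >= 0,
            is.numeric(E1), length(E1) == 1, is.finite(E1), E1 > 0,
            is.numeric(tau), length(tau) == 1, is.finite(tau), tau > 0)
  structure(list(E0 = E0, E1 = E1, tau = tau, eta = tau * E1),
            class = "zener_material")
}

#' @export
print.maxwell_material <- function(x, ...) {
  cat(sprintf("Maxwell material: E1 = %g Pa, eta = %g Pa.s, tau = %g s\n",
              x$E1, x$eta, x$tau))
  invisible(x)
}

#' @export
print.zener_material <- function(x, ...) {
  cat(sprintf(
    "Zener material: E0 = %g Pa, E1 = %g Pa, tau = %g s (eta = %g Pa.s)\n",
    x$E0, x$E1, x$tau, x$eta))
  invisible(x)
}

#' Strain history on a time grid
#'
#' Tabulated strain samples driving a constitutive model. Between samples the
#' strain is taken piecewise linear, so its rate is exact per segment. An
#' analytic strain can be supplied instead through `deriv_fun` (with `eps`
#' still tabulated on `t`) to avoid differentiation noise.
#'
#' @param t Time samples, s; strictly increasing, length >= 2.
#' @param eps Strain samples (dimensionless), same length as `t`.
#' @param deriv_fun Optional function of time returning the analytic strain
#'   rate, 1/s.
#' @return An object of class `strain_history`.
#' @export
strain_history <- function(t, eps, deriv_fun = NULL) {
  stopifnot(is.numeric(t), is.numeric(eps), length(t) == length(eps),
            length(t) >= 2, all(is.finite(t)), all(is.finite(eps)))
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing")
  if (!is.null(deriv_fun)) stopifnot(is.function(deriv_fun))
  structure(list(t = as.numeric(t), eps = as.numeric(eps),
                 deriv_fun = deriv_fun),
            class = "strain_history")
}

# Piecewise strain-rate lookup: slope of the segment containing each time.
strain_rate_fun <- function(strain) {
  if (!is.null(strain$deriv_fun)) return(strain$deriv_fun)
  t <- strain$t
  k <- diff(strain$eps) / diff(t)
  function(tt) {
    i <- findInterval(tt, t, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(k))
    k[i]
  }
}

strain_value_fun <- function(strain) {
  stats::approxfun(strain$t, strain$eps, rule = 2)
}

#' Stress response of a viscoelastic material to a strain history
#'
#' Integrates the constitutive ordinary differential equation along the strain
#' history's time grid and returns the stress at the same sample times.
#' For the Maxwell model the ODE is
#' `dsigma/dt = E1 * deps/dt - sigma / tau`;
#' for the Zener model
#' `dsigma/dt + sigma / tau = (E0 + E1) * deps/dt + (E0 / tau) * eps`.
#'
#' Two integration paths are available. `method = "rk45"` (default) uses an
#' adaptive embedded Dormand-Prince Runge-Kutta pair (via [deSolve::ode()]) at
#' relative tolerance `rtol` (default 1e-8). `method = "exact"` exploits the
#' linearity of the ODE: for piecewise-linear strain the solution is
#' closed-form per segment (integrating factor), evaluated by a fast linear
#' recursion — it is exact up to round-off on any grid and is what the fitting
#' objective uses.
#'
#' @param material A `maxwell_material` or `zener_material`.
#' @param strain A [strain_history()].
#' @param sigma0 Initial stress, Pa, at `strain$t[1]`. Default 0 (virgin
#'   sample).
#' @param method `"rk45"` or `"exact"`.
#' @param rtol,atol Solver tolerances for `method = "rk45"`.
#' @return A `stress_history`: list with `t` (s) and `sigma` (Pa) on the
#'   strain grid.
#' @examples
#' m <- maxwell_material(E1 = 1e6, tau = 0.5)
#' s <- strain_history(t = seq(0, 2, by = 0.01), eps = rep(0.01, 201))
#' # pure relaxation from sigma0
#' r <- stress_response(m, s, sigma0 = 1e4)
#' @export
stress_response <- function(material, strain, sigma0 = 0,
                            method = c("rk45", "exact"),
                            rtol = 1e-8, atol = 1e-12) {
  UseMethod("stress_response")
}

#' @export
stress_response.maxwell_material <- function(material, strain, sigma0 = 0,
                                             method = c("rk45", "exact"),
                                             rtol = 1e-8, atol = 1e-12) {
  method <- match.arg(method)
  constitutive_solve(E0 = 0, E1 = material$E1, tau = material$tau,
                     strain = strain, sigma0 = sigma0, method = method,
                     rtol = rtol, atol = atol)
}

#' @export
stress_response.zener_material <- function(material, strain, sigma0 = 0,
                                           method = c("rk45", "exact"),
                                           rtol = 1e-8, atol = 1e-12) {
  method <- match.arg(method)
  constitutive_solve(E0 = material$E0, E1 = material$E1, tau = material$tau,
                     strain = strain, sigma0 = sigma0, method = method,
                     rtol = rtol, atol = atol)
}

#' @rdname stress_response
#' @export
maxwell_stress_response <- function(material, strain, sigma0 = 0, ...) {
  stopifnot(inherits(material, "maxwell_material"))
  stress_response(material, strain, sigma0 = sigma0, ...)
}

#' @rdname stress_response
#' @export
zener_stress_response <- function(material, strain, sigma0 = 0, ...) {
  stopifnot(inherits(material, "zener_material"))
  stress_response(material, strain, sigma0 = sigma0, ...)
}

# Shared solver: the Zener ODE with E0 = 0 is exactly the Maxwell ODE.
constitutive_solve <- function(E0, E1, tau, strain, sigma0, method,
                               rtol, atol) {
  stopifnot(inherits(strain, "strain_history"),
            is.numeric(sigma0), length(sigma0) == 1, is.finite(sigma0))
  if (method == "exact" && is.null(strain$deriv_fun)) {
    sigma <- constitutive_exact(E0, E1, tau, strain$t, strain$eps, sigma0)
  } else if (method == "exact") {
    # analytic strain rate: fall back to RK (the per-segment closed form
    # assumes piecewise-linear strain)
    sigma <- constitutive_rk(E0, E1, tau, strain, sigma0, rtol, atol)
  } else {
    sigma <- constitutive_rk(E0, E1, tau, strain, sigma0, rtol, atol)
  }
  structure(list(t = strain$t, sigma = sigma), class = "stress_history")
}

constitutive_rk <- function(E0, E1, tau, strain, sigma0, rtol, atol) {
  rate <- strain_rate_fun(strain)
  val <- strain_value_fun(strain)
  rhs <- function(t, y, parms) {
    list((E0 + E1) * rate(t) + (E0 / tau) * val(t) - y / tau)
  }
  sol <- deSolve::ode(y = c(sigma = sigma0), times = strain$t, func = rhs,
                      parms = NULL, method = "ode45",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("constitutive RK integration failed to meet tolerance")
  as.numeric(sol[, 2])
}

# Closed-form per-segment propagation for piecewise-linear strain.
# On [t_i, t_i + D] with rate k and start strain e_i the forcing is
# g(s) = alpha + beta * s, alpha = (E0+E1) k + (E0/tau) e_i,
# beta = (E0/tau) k, and
# sigma(t_i + D) = r sigma_i + alpha tau (1 - r) + beta tau (D - tau (1 - r)),
# r = exp(-D/tau). Uniform grids use a stats::filter recursion.
constitutive_exact <- function(E0, E1, tau, t, eps, sigma0) {
  n <- length(t)
  D <- diff(t)
  k <- diff(eps) / D
  r <- exp(-D / tau)
  alpha <- (E0 + E1) * k + (E0 / tau) * eps[-n]
  beta <- (E0 / tau) * k
  P <- alpha * tau * (1 - r) + beta * tau * (D - tau * (1 - r))
  if (diff(range(D)) <= 1e-12 * max(D)) {
    # uniform grid: sigma_{i+1} = r sigma_i + P_i  -> recursive filter
    s <- stats::filter(c(sigma0 * r[1] + P[1], P[-1]), r[1],
                       method = "recursive",
                       init = 0)
    c(sigma0, as.numeric(s))
  } else {
    sigma <- numeric(n)
    sigma[1] <- sigma0
    for (i in seq_len(n - 1)) sigma[i + 1] <- r[i] * sigma[i] + P[i]
    sigma
  }
}

#' Complex modulus of a viscoelastic model
#'
#' Closed-form dynamic modulus `E*(omega)` at angular frequency `omega`:
#' `E* = E0 + E1 * (i omega tau) / (1 + i omega tau)` for the Zener model and
#' the same with `E0 = 0` for Maxwell. `Re(E*)` is the storage modulus,
#' `Im(E*)` the loss modulus.
#'
#' @param material A `maxwell_material` or `zener_material`.
#' @param omega Angular frequency, rad/s.
#' @return Complex vector, Pa.
#' @export
complex_modulus <- function(material, omega) {
  E0 <- if (inherits(material, "zener_material")) material$E0 else 0
  iwt <- 1i * omega * material$tau
  E0 + material$E1 * iwt / (1 + iwt)
}
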