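# Analytic decay-rate machinery: Moens-Korteweg-type wave speeds, Maxwell
# modal spectrum, Zener cubic characteristic roots (Cardano/trigonometric with
# a companion-matrix cross-check), essential spectrum, equivalent time
# constants, attenuation and required-length formulae.

#' Thin-walled tube geometry
#'
#' Geometry and fluid density defining the wave speeds and modal wavenumbers
#' of a fluid-filled viscoelastic tube. Thin-wall membrane equilibrium
#' (`p r = sigma e`) underlies the whole model, so the thickness-to-diameter
#' ratio `e/(2r)` must stay small: a warning is issued above 0.2 and an error
#' above 0.25.
#'
#' @param r Inner radius, m.
#' @param e Wall thickness, m.
#' @param L Tube length, m.
#' @param rho Fluid density, kg/m^3. Default 1000 (blood-like).
#' @return An object of class `tube_geometry`.
#' @examples
#' carotid <- tube_geometry(r = 0.004, e = 0.0005, L = 1, rho = 1000)
#' @export
tube_geometry <- function(r, e, L, rho = 1000) {
  stopifnot(is.numeric(r), r > 0, is.numeric(e), e > 0,
            is.numeric(L), L > 0, is.numeric(rho), rho > 0)
  ratio <- e / (2 * r)
  if (ratio > 0.25)
    stop(sprintf("thickness-to-diameter ratio %.3f exceeds 0.25: outside the thin-wall regime", ratio))
  if (ratio > 0.2)
    warning(sprintf("thickness-to-diameter ratio %.3f > 0.2: thin-wall assumption is marginal", ratio))
  structure(list(r = r, e = e, L = L, rho = rho), class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("Tube: r = %g m, e = %g m, L = %g m, rho = %g kg/m^3\n",
              x$r, x$e, x$L, x$rho))
  invisible(x)
}

#' Pulse wave speeds in a viscoelastic tube
#'
#' Moens-Korteweg-type speeds `c^2 = e E /(2 rho r)`. For a Maxwell wall there
#' is a single speed from `E1`; for a Zener wall the equilibrium branch gives
#' `c0` (from `E0`), the series branch `c1` (from `E1`), and the pulse speed
#' is `c = sqrt(c0^2 + c1^2)`.
#'
#' @param material A `maxwell_material` or `zener_material`.
#' @param geom A [tube_geometry()].
#' @return An object of class `wave_speeds`: list with `c0` (NA for Maxwell),
#'   `c1` and `c`, m/s.
#' @examples
#' pdms <- zener_material(E0 = 2.114e6, E1 = 0.9365e6, tau = 0.2611)
#' wave_speeds(pdms, tube_geometry(0.004, 0.0005, 1))$c  # 13.808 m/s
#' @export
wave_speeds <- function(material, geom) UseMethod("wave_speeds")

#' @export
wave_speeds.maxwell_material <- function(material, geom) {
  stopifnot(inherits(geom, "tube_geometry"))
  c1 <- sqrt(geom$e * material$E1 / (2 * geom$rho * geom$r))
  structure(list(c0 = NA_real_, c1 = c1, c = c1), class = "wave_speeds")
}

#' @export
wave_speeds.zener_material <- function(material, geom) {
  stopifnot(inherits(geom, "tube_geometry"))
  c0 <- sqrt(geom$e * material$E0 / (2 * geom$rho * geom$r))
  c1 <- sqrt(geom$e * material$E1 / (2 * geom$rho * geom$r))
  structure(list(c0 = c0, c1 = c1, c = sqrt(c0^2 + c1^2)),
            class = "wave_speeds")
}

#' @rdname wave_speeds
#' @export
wave_speed_maxwell <- function(material, geom) {
  stopifnot(inherits(material, "maxwell_material"))
  wave_speeds(material, geom)
}

#' @rdname wave_speeds
#' @export
wave_speeds_zener <- function(material, geom) {
  stopifnot(inherits(material, "zener_material"))
  wave_speeds(material, geom)
}

#' Build a material from target wave speeds
#'
#' Convenience inverses of the Moens-Korteweg relation: given the branch
#' speeds a tube should exhibit, return the material whose moduli produce
#' them (`E = 2 rho r c^2 / e`). Useful for reproducing validation cases
#' stated in terms of (tau, c) rather than moduli.
#'
#' @param c0,c1 Branch wave speeds, m/s (`c0` equilibrium/parallel spring,
#'   `c1` Maxwell branch).
#' @param cs Pulse speed for the Maxwell variant, m/s.
#' @param geom A [tube_geometry()].
#' @param tau Relaxation time, s.
#' @return A `zener_material` or `maxwell_material`.
#' @export
zener_from_speeds <- function(c0, c1, geom, tau) {
  stopifnot(inherits(geom, "tube_geometry"), c0 > 0, c1 > 0)
  f <- 2 * geom$rho * geom$r / geom$e
  zener_material(E0 = f * c0^2, E1 = f * c1^2, tau = tau)
}

#' @rdname zener_from_speeds
#' @export
maxwell_from_speed <- function(cs, geom, tau) {
  stopifnot(inherits(geom, "tube_geometry"), cs > 0)
  maxwell_material(E1 = 2 * geom$rho * geom$r * cs^2 / geom$e, tau = tau)
}

# Spatial eigenvalue of mode n on [0, L] with pinned ends.
lambda_n <- function(n, L) (n * pi / L)^2

#' Modal decay spectrum of the Maxwell damped wave equation
#'
#' For the damped wave equation `p_tt + p_t / tau = c^2 p_xx` on a tube of
#' length `L` with pinned ends, mode `n` (spatial eigenvalue
#' `lambda_n = (n pi / L)^2`) has temporal exponents
#' `mu_{1n,2n} = -1/(2 tau) +/- sqrt(Delta_n)` with discriminant
#' `Delta_n = 1/(4 tau^2) - lambda_n c^2`. Modes with `Delta_n > 0` are
#' overdamped (two real negative rates), `Delta_n < 0` underdamped (decaying
#' oscillation at `omega_n = sqrt(-Delta_n)` with envelope `exp(-t/(2 tau))`),
#' `Delta_n = 0` critically damped. Overdamped modes exist for mode indices
#' up to `k_critical = floor(L / (2 c pi tau))`.
#'
#' @param material A [maxwell_material()].
#' @param geom A [tube_geometry()].
#' @param n_max Number of modes to tabulate. Default 200.
#' @return An object of class `decay_spectrum`: list with `model`, `modes`
#'   (data.frame: `n`, `lambda_n`, `rate1`, `rate2` (complex, 1/s), `omega_n`,
#'   `regime`), `k_critical`, `tau_eq`, `validity_m2`, `valid`, and the
#'   speeds/geometry used.
#' @examples
#' g <- tube_geometry(r = 0.01, e = 0.001, L = 10, rho = 1000)
#' m <- maxwell_from_speed(5, g, tau = 0.2)
#' sp <- maxwell_spectrum(m, g, n_max = 10)
#' Re(sp$modes$rate1[1])  # -0.555 1/s, the dominant overdamped rate
#' @export
maxwell_spectrum <- function(material, geom, n_max = 200) {
  stopifnot(inherits(material, "maxwell_material"),
            inherits(geom, "tube_geometry"), n_max >= 1)
  tau <- material$tau
  cs <- wave_speeds(material, geom)$c
  L <- geom$L
  n <- seq_len(n_max)
  lam <- lambda_n(n, L)
  Delta <- 1 / (4 * tau^2) - lam * cs^2
  # classification window for exact critical damping in floating point
  crit_tol <- 1e-12 / (4 * tau^2)
  regime <- ifelse(Delta > crit_tol, "overdamped",
                   ifelse(Delta < -crit_tol, "underdamped", "critical"))
  sq <- sqrt(as.complex(Delta))
  rate1 <- -1 / (2 * tau) + sq   # slow branch when overdamped
  rate2 <- -1 / (2 * tau) - sq
  omega <- ifelse(regime == "underdamped", sqrt(pmax(-Delta, 0)), NA_real_)
  modes <- data.frame(n = n, lambda_n = lam, omega_n = omega,
                      regime = regime, stringsAsFactors = FALSE)
  modes$rate1 <- rate1
  modes$rate2 <- rate2
  structure(list(model = "maxwell",
                 modes = modes,
                 k_critical = floor(L / (2 * cs * pi * tau)),
                 tau_eq = maxwell_tau_eq(material, geom),
                 tau_inf = NA_real_,
                 validity_m2 = tau^2 * cs^2,
                 valid = tau^2 * cs^2 >= 1,
                 c = cs, tau = tau, L = L),
            class = "decay_spectrum")
}

#' @export
print.decay_spectrum <- function(x, ...) {
  cat(sprintf("%s decay spectrum: %d modes, c = %g m/s, L = %g m\n",
              x$model, nrow(x$modes), x$c, x$L))
  cat(sprintf("  tau_eq = %g s; tau^2 c^2 = %g m^2 (%s)\n",
              x$tau_eq, x$validity_m2,
              if (x$valid) "envelope prediction valid" else "outside validity"))
  if (x$model == "maxwell")
    cat(sprintf("  overdamped modes: n <= %d\n", x$k_critical))
  if (x$model == "zener")
    cat(sprintf("  essential spectrum tau_inf = %g s\n", x$tau_inf))
  invisible(x)
}

#' Equivalent decay time of the Maxwell model
#'
#' Single time constant summarizing the spatial envelope
#' `exp(-x / (c tau_eq))` of a pulse. When all modes are underdamped
#' (`4 tau^2 pi^2 c^2 / L^2 >= 1`) the envelope decays as `exp(-t/(2 tau))`
#' so `tau_eq = 2 tau`; otherwise the slowest overdamped rate `mu_11`
#' dominates and `tau_eq = 2 tau / (1 - sqrt(1 - 4 tau^2 pi^2 c^2 / L^2))`,
#' which equals `-1/mu_11`.
#'
#' @inheritParams maxwell_spectrum
#' @return Equivalent decay time, s.
#' @export
maxwell_tau_eq <- function(material, geom) {
  stopifnot(inherits(material, "maxwell_material"),
            inherits(geom, "tube_geometry"))
  tau <- material$tau
  cs <- wave_speeds(material, geom)$c
  q <- 4 * tau^2 * pi^2 * cs^2 / geom$L^2
  if (q >= 1) 2 * tau else 2 * tau / (1 - sqrt(1 - q))
}

#' Characteristic roots of a Zener mode
#'
#' For the third-order (Moore-Gibson-Thompson-type) pressure equation of a
#' Zener-walled tube, mode `n` decays as `exp(-t / tau_n)` where `1/tau_n`
#' solves the cubic
#' `x^3 - x^2/tau + lambda_n (c0^2 + c1^2) x - lambda_n c0^2 / tau = 0`.
#' The three roots are computed twice: by the Cardano closed form
#' (`S1, S2` from `R`, `Q`, switching to the trigonometric three-real-root
#' form when `R^2 + Q^3 < 0`, the casus irreducibilis) and by the
#' companion-matrix root finder [polyroot()]. The two must agree to relative
#' 1e-9 (scaled by the spectral radius) or an internal consistency error is
#' raised. All roots have non-negative real part.
#'
#' @param material A [zener_material()].
#' @param geom A [tube_geometry()].
#' @param n Mode index (>= 1).
#' @return Complex vector of the three roots `1/tau_{n,1..3}`, 1/s, real root
#'   first.
#' @examples
#' g <- tube_geometry(r = 0.01, e = 0.001, L = 10, rho = 1000)
#' z <- zener_from_speeds(4, 3, g, tau = 2)
#' zener_mode_roots(z, g, n = 1)
#' @export
zener_mode_roots <- function(material, geom, n) {
  stopifnot(inherits(material, "zener_material"),
            inherits(geom, "tube_geometry"),
            is.numeric(n), length(n) == 1, n >= 1, n == floor(n))
  sp <- wave_speeds(material, geom)
  zener_cubic_roots(material$tau, sp$c0^2, sp$c1^2, lambda_n(n, geom$L))
}

# Cardano / trigonometric roots of
#   x^3 - x^2/tau + lam*(c0s+c1s)*x - lam*c0s/tau = 0
# with a polyroot cross-check. R and Q are the scaled resolvent quantities
# (27 tau^3 and 9 tau^2 scalings of the standard -q/2 and p/3).
zener_cubic_roots <- function(tau, c0s, c1s, lam, tol = 1e-9) {
  R <- 9 / 2 * tau^2 * lam * (2 * c0s - c1s) + 1
  Q <- 3 * tau^2 * lam * (c0s + c1s) - 1
  disc <- R^2 + Q^3
  if (disc >= 0) {
    rt <- sqrt(disc)
    S1 <- cbrt(R + rt) / (3 * tau)
    S2 <- cbrt(R - rt) / (3 * tau)
    roots <- c(1 / (3 * tau) + S1 + S2,
               1 / (3 * tau) - (S1 + S2) / 2 + sqrt(3) / 2 * 1i * (S2 - S1),
               1 / (3 * tau) - (S1 + S2) / 2 - sqrt(3) / 2 * 1i * (S2 - S1))
    roots <- as.complex(roots)
  } else {
    # three real roots: trigonometric form, immune to the complex cube
    # roots the literal Cardano formula would need
    theta <- acos(max(-1, min(1, R / sqrt(-Q^3))))
    m <- 2 * sqrt(-Q) / (3 * tau)
    roots <- as.complex(1 / (3 * tau) + m * cos((theta - 2 * pi * (0:2)) / 3))
  }
  check <- polyroot(c(-lam * c0s / tau, lam * (c0s + c1s), -1 / tau, 1))
  scale <- max(Mod(check), 1 / tau)
  # nearest-neighbour (symmetric Hausdorff) matching: conjugate pairs make
  # lexicographic sorting unstable in floating point
  dmat <- abs(outer(roots, check, "-"))
  if (max(apply(dmat, 1, min), apply(dmat, 2, min)) > tol * scale)
    stop("internal consistency error: Cardano and companion-matrix roots disagree")
  if (any(Re(roots) < -tol * scale))
    stop("internal consistency error: characteristic root with negative real part")
  roots
}

# real cube root
cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Decay time constant of a Zener mode
#'
#' `tau_n = 1 / min(Re(roots))` over the three characteristic roots of
#' [zener_mode_roots()]: the slowest-decaying exponent controls the mode's
#' persistence.
#'
#' @inheritParams zener_mode_roots
#' @return Decay time constant, s.
#' @export
zener_decay_constant <- function(material, geom, n) {
  1 / min(Re(zener_mode_roots(material, geom, n)))
}

#' Essential spectrum of the Zener pressure equation
#'
#' Limiting decay time of the modal spectrum as the mode index grows:
#' `1/tau_inf = min( (1/tau) E0/(E0+E1), (1/(2 tau)) E1/(E0+E1) )`.
#' For sharp pulses (rich in high modes) this is the dominant attenuation
#' rate.
#'
#' @param material A [zener_material()].
#' @return Limiting decay time `tau_inf`, s.
#' @export
zener_essential_spectrum <- function(material) {
  stopifnot(inherits(material, "zener_material"))
  E0 <- material$E0; E1 <- material$E1; tau <- material$tau
  # E0 = 0 (pure Maxwell limit): zero equilibrium stiffness, no decay floor
  1 / min(E0 / (tau * (E0 + E1)), E1 / (2 * tau * (E0 + E1)))
}

#' Equivalent decay time of the Zener model
#'
#' `tau_eq = max( tau (E0+E1)/E0, 2 tau (E0+E1)/E1 )`, the reciprocal of the
#' essential-spectrum rate: the first branch applies when `E1 >= 2 E0`
#' (`tau_eq >= 3 tau`), the second when `E1 < 2 E0`
#' (`tau_eq` in `(2 tau, 3 tau]` scaled by the modulus ratio). Trustworthy as
#' a single-exponential envelope only when `tau^2 c^2 >= 1 m^2`
#' (see [validity_condition()]).
#'
#' @param material A [zener_material()].
#' @return Equivalent decay time, s.
#' @export
zener_tau_eq <- function(material) {
  stopifnot(inherits(material, "zener_material"))
  E0 <- material$E0; E1 <- material$E1; tau <- material$tau
  if (E0 == 0) return(Inf)
  teq <- max(tau * (E0 + E1) / E0, 2 * tau * (E0 + E1) / E1)
  # max/min duality with the essential spectrum: identical by construction
  stopifnot(abs(teq - zener_essential_spectrum(material)) <= 1e-12 * teq)
  teq
}

#' Validity of the single-exponential envelope approximation
#'
#' The equivalent-time-constant envelope is trusted when `tau^2 c^2` is large
#' compared to 1 m^2; operationally the flag is `tau^2 c^2 >= 1 m^2` and the
#' raw value is returned so callers can apply stricter margins.
#'
#' @param material A [zener_material()].
#' @param geom A [tube_geometry()].
#' @return List with `value_m2` (`tau^2 c^2`, m^2) and logical `valid`.
#' @export
validity_condition <- function(material, geom) {
  v <- material$tau^2 * wave_speeds(material, geom)$c^2
  list(value_m2 = v, valid = v >= 1)
}

#' Zener modal decay spectrum
#'
#' Tabulates the characteristic roots, per-mode decay constants and damping
#' regimes of the Zener third-order pressure equation, together with the
#' essential spectrum, equivalent decay time and validity flag.
#'
#' @inheritParams zener_mode_roots
#' @param n_max Number of modes. Default 200.
#' @return A `decay_spectrum` (see [maxwell_spectrum()]); `modes` has the
#'   three complex roots `rate1..rate3` (as `-1/tau_{n,k}`, decay exponents),
#'   `tau_n`, `omega_n` and `regime`.
#' @export
zener_spectrum <- function(material, geom, n_max = 200) {
  stopifnot(inherits(material, "zener_material"),
            inherits(geom, "tube_geometry"), n_max >= 1)
  sp <- wave_speeds(material, geom)
  n <- seq_len(n_max)
  rts <- vapply(n, function(k)
    zener_cubic_roots(material$tau, sp$c0^2, sp$c1^2,
                      lambda_n(k, geom$L)),
    complex(3))
  tau_n <- 1 / apply(Re(rts), 2, min)
  imax <- apply(abs(Im(rts)), 2, max)
  regime <- ifelse(imax > 1e-9 / material$tau, "underdamped", "overdamped")
  omega <- ifelse(regime == "underdamped", imax, NA_real_)
  modes <- data.frame(n = n, lambda_n = lambda_n(n, geom$L),
                      tau_n = tau_n, omega_n = omega, regime = regime,
                      stringsAsFactors = FALSE)
  modes$rate1 <- -rts[1, ]
  modes$rate2 <- -rts[2, ]
  modes$rate3 <- -rts[3, ]
  vc <- validity_condition(material, geom)
  structure(list(model = "zener", modes = modes,
                 k_critical = NA_integer_,
                 tau_eq = zener_tau_eq(material),
                 tau_inf = zener_essential_spectrum(material),
                 validity_m2 = vc$value_m2, valid = vc$valid,
                 c = sp$c, tau = material$tau, L = geom$L),
            class = "decay_spectrum")
}

#' Predicted attenuation of a pulse over a tube length
#'
#' With the single-exponential envelope `p(x) = p0 exp(-x / (c tau_eq))`, the
#' fractional peak-pressure loss between inlet and outlet of a tube of length
#' `L` is `a = 1 - exp(-L / (c tau_eq))`.
#'
#' @param tau_eq Equivalent decay time, s ([maxwell_tau_eq()] or
#'   [zener_tau_eq()]).
#' @param c Pulse wave speed, m/s.
#' @param L Tube length, m.
#' @return An `attenuation_prediction`: list with `a` (fraction in `[0,1)`),
#'   `p_ratio` (`p_out/p_in`) and the inputs.
#' @examples
#' pdms <- zener_material(2.114e6, 0.9365e6, 0.2611)
#' g <- tube_geometry(0.004, 0.0005, 1)
#' attenuation(zener_tau_eq(pdms), wave_speeds(pdms, g)$c, 1)$a  # ~0.042
#' @export
attenuation <- function(tau_eq, c, L) {
  stopifnot(tau_eq > 0, c > 0, L >= 0)
  p_ratio <- exp(-L / (c * tau_eq))
  structure(list(a = 1 - p_ratio, p_ratio = p_ratio,
                 tau_eq = tau_eq, c = c, L = L),
            class = "attenuation_prediction")
}

#' @export
print.attenuation_prediction <- function(x, ...) {
  cat(sprintf("attenuation over %g m: %.3f%% (p_out/p_in = %.5f)\n",
              x$L, 100 * x$a, x$p_ratio))
  invisible(x)
}

#' Tube length required for a target attenuation
#'
#' Inverse of [attenuation()]: `L = c tau_eq ln(1/(1-a))`.
#'
#' @inheritParams attenuation
#' @param a Target attenuation fraction, strictly in (0, 1).
#' @return Required length, m.
#' @export
required_length <- function(tau_eq, c, a) {
  stopifnot(tau_eq > 0, c > 0)
  if (!is.numeric(a) || any(a <= 0) || any(a >= 1))
    stop("target attenuation `a` must lie strictly in (0, 1)")
  c * tau_eq * log(1 / (1 - a))
}
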