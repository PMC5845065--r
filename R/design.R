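# Inverse design: for a conduit geometry and a target attenuation over a
# device length, map (E0, E1) grids to the relaxation time tau the wall
# material must have, with feasibility masking by the envelope-validity
# condition tau^2 c^2 >= 1 m^2.

#' Relaxation time required for a target attenuation
#'
#' Inverts the attenuation formula for the Zener model: with the pulse speed
#' `c` from the moduli and geometry, and the equivalent-time ratio
#' `kappa = tau_eq / tau` (`2 (E0 + E1)/E1` when `E1 < 2 E0`, else
#' `(E0 + E1)/E0`), the required relaxation time is
#' `tau = L_device / (c kappa ln(1/(1 - a)))`. Vectorized over `E0`, `E1`.
#'
#' @param E0,E1 Zener moduli, Pa (vectorized, recycled).
#' @param geom A [tube_geometry()] (its `L` is not used; the device length is
#'   explicit).
#' @param a Target attenuation fraction in (0, 1).
#' @param L_device Device length, m.
#' @return Required `tau`, s (always finite and positive; whether the
#'   resulting material satisfies the validity condition is a separate
#'   question, see [build_design_map()]).
#' @export
required_tau <- function(E0, E1, geom, a, L_device) {
  stopifnot(inherits(geom, "tube_geometry"), all(E0 > 0), all(E1 > 0),
            length(a) == 1, a > 0, a < 1, L_device > 0)
  cs <- sqrt(geom$e * (E0 + E1) / (2 * geom$rho * geom$r))
  kappa <- ifelse(E1 < 2 * E0, 2 * (E0 + E1) / E1, (E0 + E1) / E0)
  L_device / (cs * kappa * log(1 / (1 - a)))
}

#' Design query for an attenuating conduit
#'
#' @param geom A [tube_geometry()].
#' @param a Target attenuation fraction in (0, 1).
#' @param L_device Device length, m.
#' @param E0_grid,E1_grid Modulus grids, Pa, positive and sorted. Default
#'   100 points log-spaced over 0.01 to 10 MPa.
#' @return An object of class `design_query`.
#' @export
design_query <- function(geom, a, L_device,
                         E0_grid = mpa_grid(), E1_grid = mpa_grid()) {
  stopifnot(inherits(geom, "tube_geometry"), a > 0, a < 1, L_device > 0,
            all(E0_grid > 0), all(E1_grid > 0),
            !is.unsorted(E0_grid, strictly = TRUE),
            !is.unsorted(E1_grid, strictly = TRUE))
  structure(list(geom = geom, a = a, L_device = L_device,
                 E0_grid = E0_grid, E1_grid = E1_grid),
            class = "design_query")
}

#' @rdname design_query
#' @param n Grid resolution.
#' @param from,to Grid limits, Pa.
#' @export
mpa_grid <- function(n = 100, from = 0.01e6, to = 10e6) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Material-property design map
#'
#' Evaluates [required_tau()] and the validity product `tau^2 c^2` over the
#' `(E0, E1)` grid. A grid point is feasible when the required `tau` is
#' finite and `tau^2 c^2 >= 1 m^2`, i.e. when the single-exponential
#' envelope on which the inversion rests is trustworthy there.
#'
#' @param query A [design_query()].
#' @return A `design_map`: list with the grids, matrices `tau_required` (s),
#'   `validity_m2` (m^2), `c` (m/s) and logical `feasible`
#'   (rows index `E0_grid`, columns `E1_grid`), plus the query.
#' @examples
#' g <- tube_geometry(r = 0.004, e = 0.0005, L = 0.2)
#' m <- build_design_map(design_query(g, a = 0.05, L_device = 0.2,
#'                                    E0_grid = mpa_grid(25),
#'                                    E1_grid = mpa_grid(25)))
#' sum(m$feasible)
#' @export
build_design_map <- function(query) {
  stopifnot(inherits(query, "design_query"))
  E0 <- matrix(query$E0_grid, nrow = length(query$E0_grid),
               ncol = length(query$E1_grid))
  E1 <- matrix(query$E1_grid, nrow = length(query$E0_grid),
               ncol = length(query$E1_grid), byrow = TRUE)
  tau <- required_tau(E0, E1, query$geom, query$a, query$L_device)
  cs <- sqrt(query$geom$e * (E0 + E1) / (2 * query$geom$rho * query$geom$r))
  validity <- tau^2 * cs^2
  structure(list(E0_grid = query$E0_grid, E1_grid = query$E1_grid,
                 tau_required = tau, validity_m2 = validity, c = cs,
                 feasible = is.finite(tau) & validity >= 1,
                 query = query),
            class = "design_map")
}

#' @export
print.design_map <- function(x, ...) {
  q <- x$query
  cat(sprintf(
    "design map: a = %g%% over %g mm, %d x %d grid, %d/%d feasible points\n",
    100 * q$a, 1000 * q$L_device, length(x$E0_grid), length(x$E1_grid),
    sum(x$feasible), length(x$feasible)))
  invisible(x)
}
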