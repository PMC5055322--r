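#' Tension-dependent calcium-troponin equilibrium constant
#'
#' The dissociation equilibrium constant of calcium binding to an in-register
#' troponin pair decays exponentially with the local thin-filament tension:
#' `K(S) = k_tnca0 * exp(-c_s * S)`. Mechanical tension raises the energy
#' needed to detach calcium, so the bound state is favoured where the filament
#' is loaded.
#'
#' @param params A [mechchem_params()] object.
#' @param s Thin-filament tension, S units (>= 0). Vectorised.
#' @return Equilibrium constant(s), uM.
#' @examples
#' p <- mechchem_params(1.85, 9.27, 10.09)
#' equilibrium_constant(p, 0)    # k_tnca0, untensioned
#' equilibrium_constant(p, 0.1)
#' @export
equilibrium_constant <- function(params, s) {
  stopifnot(inherits(params, "mechchem_params"), is.numeric(s))
  if (any(s < 0)) stop("tension s must be >= 0")
  params$k_tnca0 * exp(-params$c_s * s)
}

#' Fraction of activated troponin
#'
#' Proportion of in-register troponin pairs with calcium bound (and hence with
#' nearby cross-bridge binding sites unblocked) at a given calcium
#' concentration and local tension:
#' `P = 1 / (1 + exp(n * (-c_s*S - log(ca / k_tnca0))))`.
#' Evaluated through the numerically stable logistic so large exponents do not
#' overflow.
#'
#' @param params A [mechchem_params()] object.
#' @param ca Calcium concentration, uM (> 0). Vectorised (recycled against
#'   `s`).
#' @param s Local thin-filament tension, S (>= 0).
#' @return Activation fraction(s) in (0, 1).
#' @examples
#' p <- mechchem_params(1.85, 9.27, 10.09)
#' activation_fraction(p, ca = 10.09, s = 0) # exactly 1/2
#' @export
activation_fraction <- function(params, ca, s) {
  stopifnot(inherits(params, "mechchem_params"), is.numeric(ca), is.numeric(s))
  if (any(ca <= 0)) stop("calcium concentration must be > 0 (log undefined)")
  if (any(s < 0)) stop("tension s must be >= 0")
  stats::plogis(params$n * (params$c_s * s + log(ca / params$k_tnca0)))
}

# Right-hand side dS/dx = c_f * P(S; ca) for a vector of independent calcium
# levels sharing one x-axis. State y is the tension at each ca.
.tension_rhs <- function(x, y, parms) {
  p <- parms$params
  list(p$c_f * stats::plogis(p$n * (p$c_s * y + parms$log_ca_ratio)))
}

# Integrate the tension ODE for all ca at once. Returns a matrix
# [length(x_out) x length(ca)] of tensions; x_out must start at 0.
.solve_tension <- function(params, ca, x_out, rtol = 1e-8, atol = 1e-12) {
  parms <- list(params = params, log_ca_ratio = log(ca / params$k_tnca0))
  sol <- deSolve::ode(y = numeric(length(ca)), times = x_out,
                      func = .tension_rhs, parms = parms,
                      method = "ode45", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("tension ODE solver failed to converge (c_f=", params$c_f,
         ", c_s=", params$c_s, ", k_tnca0=", params$k_tnca0,
         ", n=", params$n, ", ca range [", min(ca), ", ", max(ca), "] uM)")
  m <- unname(sol[, -1L, drop = FALSE])
  # clip the solver's atol-scale negative wobble at zero tension
  m[m < 0] <- 0
  m
}

#' Integrate the thin-filament tension profile
#'
#' Solves `dS/dx = c_f * P(S(x); ca)` with `S(0) = 0` from the mid-line end of
#' the single-overlap region (x = 0) to the Z-disk end (x = x_max), using an
#' adaptive Runge-Kutta scheme (Dormand-Prince 4(5), relative tolerance 1e-8,
#' absolute 1e-12) with dense output on a uniform grid. Because tension feeds
#' back into the activation fraction, the profile steepens toward the Z-disk
#' and the activation may saturate before the end of the overlap region.
#'
#' @param params A [mechchem_params()] object.
#' @param ca Calcium concentration, uM (scalar > 0).
#' @param x_max Single-overlap length, um (> 0); see
#'   [single_overlap_length()].
#' @param n_grid Number of output grid points (uniform in x).
#' @param sl Optional sarcomere length, um, recorded in the result for
#'   provenance.
#' @return An object of class `"tension_profile"`: a data frame with columns
#'   `x` (um), `tension` (S) and `activation` (the troponin activation
#'   fraction at each position), with the calcium level, parameters and
#'   sarcomere length stored as attributes.
#' @examples
#' p <- mechchem_params(1.97, 7.32, 8.63)
#' prof <- integrate_tension(p, ca = 5, x_max = 0.65)
#' head(prof)
#' @export
integrate_tension <- function(params, ca, x_max, n_grid = 512, sl = NA_real_) {
  stopifnot(inherits(params, "mechchem_params"),
            is.numeric(ca), length(ca) == 1L,
            is.numeric(x_max), length(x_max) == 1L)
  if (ca <= 0) stop("calcium concentration must be > 0")
  if (x_max <= 0) stop("x_max must be > 0")
  x <- seq(0, x_max, length.out = n_grid)
  s <- .solve_tension(params, ca, x)[, 1L]
  out <- data.frame(x = x, tension = s,
                    activation = activation_fraction(params, ca, s))
  structure(out, class = c("tension_profile", "data.frame"),
            ca = ca, sl = sl, params = params)
}

#' @export
print.tension_profile <- function(x, ...) {
  cat(sprintf(
    "Thin-filament tension profile: [Ca2+] = %g uM, x_max = %.4g um, S(x_max) = %.4g S\n",
    attr(x, "ca"), max(x$x), x$tension[nrow(x)]))
  NextMethod()
}

#' @export
plot.tension_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$x, x$tension, type = "l", xlab = "x (um)",
                 ylab = "tension S(x) (S)", ...)
  graphics::plot(x$x, x$activation, type = "l", ylim = c(0, 1),
                 xlab = "x (um)", ylab = "activation P(x)", ...)
  invisible(x)
}

#' Total thin-filament tension
#'
#' Tension at the Z-disk end of the single-overlap region, `S(x_max)` --- the
#' summed force of every cross-bridge along the thin filament and therefore
#' the tension the filament transmits to the Z-disk.
#'
#' @param params A [mechchem_params()] object.
#' @param ca Calcium concentration(s), uM (> 0). Vectorised.
#' @param geom A [sarcomere_geometry()] object.
#' @return Total tension(s), S.
#' @examples
#' p <- mechchem_params(1.85, 9.27, 10.09)
#' total_tension(p, ca = 10, geom = sarcomere_geometry(1.85))
#' @export
total_tension <- function(params, ca, geom) {
  stopifnot(inherits(params, "mechchem_params"), is.numeric(ca))
  if (any(ca <= 0)) stop("calcium concentration must be > 0")
  x_max <- single_overlap_length(geom)
  if (x_max <= 0) return(rep(0, length(ca)))
  .solve_tension(params, ca, c(0, x_max))[2L, ]
}

#' Discrete cross-bridge ladder
#'
#' The discrete picture underlying the continuum model: `n_sites` equally
#' spaced cross-bridge locations along the overlap region, each adding a force
#' `F_XB = c_f * dx * P(S)` where `P` is evaluated at the tension accumulated
#' strictly before the site (left-Riemann convention). The staircase converges
#' to the ODE solution at first order in `dx`, and serves as an independent
#' check on the integrator.
#'
#' @param params A [mechchem_params()] object.
#' @param ca Calcium concentration, uM (scalar > 0).
#' @param x_max Single-overlap length, um (> 0).
#' @param n_sites Number of cross-bridge sites (>= 1).
#' @param sl Optional sarcomere length recorded for provenance.
#' @return A `"tension_profile"` data frame with `n_sites + 1` rows (x = 0
#'   plus one row just distal to each site).
#' @examples
#' p <- mechchem_params(1.97, 7.32, 8.63)
#' discrete_ladder(p, ca = 5, x_max = 0.65, n_sites = 8)
#' @export
discrete_ladder <- function(params, ca, x_max, n_sites, sl = NA_real_) {
  stopifnot(inherits(params, "mechchem_params"),
            is.numeric(ca), length(ca) == 1L, ca > 0,
            is.numeric(x_max), length(x_max) == 1L, x_max > 0)
  n_sites <- as.integer(n_sites)
  if (n_sites < 1L) stop("n_sites must be >= 1")
  dx <- x_max / n_sites
  s <- numeric(n_sites + 1L)
  for (j in seq_len(n_sites))
    s[j + 1L] <- s[j] + params$c_f * dx * activation_fraction(params, ca, s[j])
  x <- seq(0, x_max, length.out = n_sites + 1L)
  out <- data.frame(x = x, tension = s,
                    activation = activation_fraction(params, ca, s))
  structure(out, class = c("tension_profile", "data.frame"),
            ca = ca, sl = sl, params = params)
}

#' Steady-state calcium-tension curve
#'
#' Total thin-filament tension as a function of calcium concentration at a
#' fixed sarcomere length. With mechanochemical coupling active (`c_s > 0`)
#' the curve is asymmetric: a sharp upward bend at low calcium followed by a
#' gentle approach to saturation, steeper overall than the intrinsic
#' cooperativity alone would produce.
#'
#' @param params A [mechchem_params()] object.
#' @param geom A [sarcomere_geometry()] object.
#' @param ca_grid Ascending vector of calcium concentrations, uM. Defaults to
#'   [default_ca_grid()].
#' @return An object of class `"ca_tension_curve"`: a data frame with columns
#'   `ca` (uM) and `tension` (S), with `sl`, `params` and the overlap length
#'   as attributes.
#' @examples
#' p <- mechchem_params(1.97, 7.32, 8.63)
#' cur <- ca_tension_curve(p, sarcomere_geometry(2.05))
#' ec50(cur)
#' @export
ca_tension_curve <- function(params, geom, ca_grid = default_ca_grid()) {
  stopifnot(inherits(params, "mechchem_params"),
            inherits(geom, "sarcomere_geometry"),
            is.numeric(ca_grid), length(ca_grid) >= 2L)
  if (any(ca_grid <= 0)) stop("ca_grid must be strictly positive")
  if (is.unsorted(ca_grid, strictly = TRUE)) stop("ca_grid must be ascending")
  tension <- total_tension(params, ca_grid, geom)
  out <- data.frame(ca = ca_grid, tension = tension)
  structure(out, class = c("ca_tension_curve", "data.frame"),
            sl = geom$sl, params = params,
            x_max = single_overlap_length(geom))
}

#' @export
print.ca_tension_curve <- function(x, ...) {
  cat(sprintf(
    "Calcium-tension curve: SL = %g um, %d Ca points in [%g, %g] uM, peak %.4g S\n",
    attr(x, "sl"), nrow(x), min(x$ca), max(x$ca), x$tension[nrow(x)]))
  invisible(x)
}

#' @export
plot.ca_tension_curve <- function(x, ..., log = "x") {
  graphics::plot(x$ca, x$tension, type = "l", log = log,
                 xlab = "[Ca2+] (uM)", ylab = "tension (S)", ...)
  invisible(x)
}
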