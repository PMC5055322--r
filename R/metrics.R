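#' Half-maximal calcium concentration (EC50)
#'
#' Calcium concentration at which the curve reaches half of its peak tension,
#' where "peak" is the tension at the largest grid concentration (10 uM under
#' the default protocol) -- the convention of a bounded experimental protocol,
#' not the `c_f * x_max` asymptote. The crossing is located by monotone
#' piecewise-cubic interpolation in (log ca, tension).
#'
#' @param curve A `"ca_tension_curve"`, or a data frame with columns `ca` and
#'   `tension`.
#' @return EC50, uM.
#' @examples
#' p <- mechchem_params(1.97, 7.32, 8.63)
#' ec50(ca_tension_curve(p, sarcomere_geometry(2.05)))
#' @export
ec50 <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("ca", "tension") %in% names(curve)))
  ca <- curve$ca
  s <- curve$tension
  if (is.unsorted(ca, strictly = TRUE)) stop("curve must have ascending ca")
  half <- s[length(s)] / 2
  if (half <= 0 || max(s) < half)
    stop("curve never reaches half of its peak tension; EC50 undefined")
  lca <- log(ca)
  f <- if (!is.unsorted(s)) {
    stats::splinefun(lca, s, method = "hyman")
  } else {
    # noisy curves: monotonize by isotonic regression, interpolate linearly
    iso <- stats::isoreg(lca, s)
    stats::approxfun(lca, iso$yf, rule = 2)
  }
  root <- stats::uniroot(function(l) f(l) - half,
                         interval = range(lca), tol = 1e-12)
  exp(root$root)
}

#' Percent change in peak tension between two curves
#'
#' `100 * (peak_b - peak_a) / peak_a`, with peaks taken at the top of the
#' shared calcium grid.
#'
#' @param curve_a,curve_b Curves on the same calcium grid (`curve_a` is the
#'   reference).
#' @return Percent change.
#' @export
peak_tension_change <- function(curve_a, curve_b) {
  stopifnot(is.data.frame(curve_a), is.data.frame(curve_b))
  if (nrow(curve_a) != nrow(curve_b) ||
      max(abs(log(curve_a$ca / curve_b$ca))) > 1e-9)
    stop("curves must share the same calcium grid")
  pa <- curve_a$tension[nrow(curve_a)]
  pb <- curve_b$tension[nrow(curve_b)]
  if (pa <= 0) stop("reference curve has zero peak tension")
  100 * (pb - pa) / pa
}

#' Parameter variation across sarcomere lengths
#'
#' Summarises how the three model constants move across an ordered set of
#' per-sarcomere-length parameter fits: the maximal relative variation of
#' `c_f` (`(max - min)/min`), and the relative decreases of `k_tnca0` and
#' `c_s` from the first (shortest) to the last (longest) sarcomere length.
#'
#' @param table Data frame with columns `sl`, `c_f`, `c_s`, `k_tnca0`
#'   (>= 2 rows, ordered by `sl`), e.g. `reference_params("percurve")` or the
#'   `params` element of a [mechchem()] fit.
#' @return Named vector, in percent: `c_f_variation`, `k_tnca0_decrease`,
#'   `c_s_decrease`.
#' @examples
#' param_variation(reference_params("percurve"))
#' @export
param_variation <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("sl", "c_f", "c_s", "k_tnca0") %in% names(table)))
  if (nrow(table) < 2L) stop("need at least two sarcomere lengths")
  if (is.unsorted(table$sl)) stop("rows must be ordered by sl")
  last <- nrow(table)
  c(c_f_variation = 100 * (max(table$c_f) - min(table$c_f)) / min(table$c_f),
    k_tnca0_decrease = 100 * (table$k_tnca0[1L] - table$k_tnca0[last]) /
      table$k_tnca0[1L],
    c_s_decrease = 100 * (table$c_s[1L] - table$c_s[last]) / table$c_s[1L])
}

#' Apparent Hill coefficient of a calcium-tension curve
#'
#' The `n_h` of the best three-parameter Hill fit to the curve (see
#' [fit_hill()]). For the mechanochemical model with `c_s > 0` this exceeds
#' the intrinsic cooperativity `n`, quantifying the boost contributed by
#' tension; with `c_s = 0` it returns `n` exactly (up to grid conventions).
#'
#' @param curve A `"ca_tension_curve"` or data frame with `ca`, `tension`.
#' @return Apparent Hill coefficient (dimensionless).
#' @export
apparent_hill_coefficient <- function(curve) {
  unname(coef(fit_hill(curve$ca, curve$tension))["n_h"])
}

#' Summary metrics for one calcium-tension curve
#'
#' @param curve A `"ca_tension_curve"`.
#' @return One-row data frame: `sl`, `ec50` (uM), `peak_tension` (S, at the
#'   top of the grid), `apparent_n_h`.
#' @export
curve_summary <- function(curve) {
  data.frame(sl = if (!is.null(attr(curve, "sl"))) attr(curve, "sl") else NA_real_,
             ec50 = ec50(curve),
             peak_tension = curve$tension[nrow(curve)],
             apparent_n_h = apparent_hill_coefficient(curve))
}
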