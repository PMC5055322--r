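#' Mechanochemical model parameters
#'
#' A parameter set for the tension-coupled calcium-troponin model. Internal
#' units are um (length), uM (concentration) and S, the arbitrary sarcomere
#' tension unit of the skinned-muscle measurements the model was built
#' against. `c_f` is stored in S per um; published values quoted in
#' 10^6 m^-1 S are numerically identical (1.85e6 m^-1 S == 1.85 S um^-1).
#'
#' @param c_f Force density at full troponin activation, S um^-1 (> 0).
#' @param c_s Tension sensitivity of the calcium-troponin equilibrium,
#'   S^-1 (>= 0). `c_s = 0` decouples chemistry from mechanics and the model
#'   collapses to a Hill curve with coefficient `n`.
#' @param k_tnca0 Calcium-troponin equilibrium constant at zero tension,
#'   uM (> 0).
#' @param n Intrinsic cooperativity coefficient of calcium binding to an
#'   in-register troponin pair, dimensionless (>= 1). Default 3, the value
#'   measured in tension-free trabeculae.
#'
#' @return An object of class `"mechchem_params"`.
#' @examples
#' mechchem_params(c_f = 1.97, c_s = 7.32, k_tnca0 = 8.63)
#' @export
mechchem_params <- function(c_f, c_s, k_tnca0, n = 3) {
  stopifnot(is.numeric(c_f), is.numeric(c_s), is.numeric(k_tnca0),
            is.numeric(n),
            length(c_f) == 1L, length(c_s) == 1L, length(k_tnca0) == 1L,
            length(n) == 1L)
  if (!is.finite(c_f) || c_f <= 0) stop("c_f must be > 0")
  if (!is.finite(c_s) || c_s < 0) stop("c_s must be >= 0")
  if (!is.finite(k_tnca0) || k_tnca0 <= 0) stop("k_tnca0 must be > 0")
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  structure(list(c_f = c_f, c_s = c_s, k_tnca0 = k_tnca0, n = n),
            class = "mechchem_params")
}

#' @export
print.mechchem_params <- function(x, ...) {
  cat(sprintf(
    "MechChem parameters: Cf = %.4g S/um, Cs = %.4g 1/S, KTnCa0 = %.4g uM, n = %g\n",
    x$c_f, x$c_s, x$k_tnca0, x$n))
  invisible(x)
}

#' Hill comparator parameters
#'
#' @param s_max Saturating tension, S (> 0).
#' @param ec50 Calcium concentration at half-maximal tension, uM (> 0).
#' @param n_h Hill coefficient, dimensionless (> 0).
#' @return An object of class `"hill_params"`.
#' @examples
#' hill_params(s_max = 0.90, ec50 = 4.28, n_h = 7.3)
#' @export
hill_params <- function(s_max, ec50, n_h) {
  stopifnot(is.numeric(s_max), is.numeric(ec50), is.numeric(n_h),
            length(s_max) == 1L, length(ec50) == 1L, length(n_h) == 1L)
  if (!all(is.finite(c(s_max, ec50, n_h))) || s_max <= 0 || ec50 <= 0 || n_h <= 0)
    stop("all Hill parameters must be strictly positive and finite")
  structure(list(s_max = s_max, ec50 = ec50, n_h = n_h),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill parameters: Smax = %.4g S, EC50 = %.4g uM, nH = %.4g\n",
              x$s_max, x$ec50, x$n_h))
  invisible(x)
}

#' Published reference parameter sets
#'
#' Parameter values obtained by fitting the mechanochemical and Hill models to
#' the skinned cardiac muscle calcium-tension measurements of Dobesh et al.
#' (2002) at five sarcomere lengths. Three blocks are available:
#' \describe{
#'   \item{`"percurve"`}{all three mechanochemical parameters fitted to each
#'     sarcomere-length curve independently (intrinsic cooperativity n = 3);}
#'   \item{`"shared"`}{`c_f = 1.93` S/um and `c_s = 6.5` 1/S held fixed across
#'     sarcomere lengths with only `k_tnca0` refitted per length;}
#'   \item{`"hill"`}{three-parameter Hill fits to the same data.}
#' }
#'
#' @param block One of `"percurve"`, `"shared"`, `"hill"`.
#' @return A data frame with one row per sarcomere length. Columns depend on
#'   the block: `sl` plus (`k_tnca0`, `c_f`, `c_s`, `rmse`) for the
#'   mechanochemical blocks or (`s_max`, `ec50`, `n_h`, `rmse`) for the Hill
#'   block. `rmse` is the published root-mean-square misfit, in S.
#' @examples
#' reference_params("percurve")
#' @export
reference_params <- function(block = c("percurve", "shared", "hill")) {
  block <- match.arg(block)
  sl <- c(1.85, 1.95, 2.05, 2.15, 2.25)
  switch(block,
    percurve = data.frame(
      sl = sl,
      k_tnca0 = c(10.09, 9.46, 8.63, 7.14, 5.73),
      c_f = c(1.85, 1.95, 1.97, 1.96, 1.95),
      c_s = c(9.27, 8.66, 7.32, 4.61, 2.73),
      n = 3,
      rmse = c(0.017, 0.013, 0.012, 0.017, 0.040)),
    shared = data.frame(
      sl = sl,
      k_tnca0 = c(9.26, 8.56, 8.18, 7.91, 7.48),
      c_f = 1.93,
      c_s = 6.5,
      n = 3,
      rmse = c(0.024, 0.018, 0.019, 0.021, 0.053)),
    hill = data.frame(
      sl = sl,
      ec50 = c(4.28, 3.9, 3.6, 3.4, 3.16),
      n_h = c(7.3, 7.5, 7.5, 7.2, 6.9),
      s_max = c(0.90, 1.04, 1.14, 1.22, 1.32),
      rmse = c(0.028, 0.037, 0.033, 0.032, 0.033))
  )
}

# row of a mechanochemical reference block -> mechchem_params
.params_from_row <- function(row) {
  mechchem_params(c_f = row$c_f, c_s = row$c_s, k_tnca0 = row$k_tnca0,
                  n = if (!is.null(row$n)) row$n else 3)
}

#' Default log-spaced calcium grid
#'
#' 200 logarithmically spaced concentrations spanning 0.001 to 10 uM, the
#' calcium range of the simulation protocol the model was developed under.
#'
#' @param n Number of grid points.
#' @param ca_min,ca_max Grid end points, uM.
#' @return Ascending numeric vector, uM.
#' @export
default_ca_grid <- function(n = 200, ca_min = 0.001, ca_max = 10) {
  stopifnot(n >= 2, ca_min > 0, ca_max > ca_min)
  exp(seq(log(ca_min), log(ca_max), length.out = n))
}
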