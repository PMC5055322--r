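#' Hill-equation tension
#'
#' The classical sigmoid comparator:
#' `S_H(ca) = s_max * ca^n_h / (ec50^n_h + ca^n_h)`.
#'
#' @param hp A [hill_params()] object.
#' @param ca Calcium concentration(s), uM (>= 0).
#' @return Tension(s), S, in `[0, s_max)`.
#' @examples
#' hill_tension(hill_params(0.90, 4.28, 7.3), ca = 4.28) # s_max / 2
#' @export
hill_tension <- function(hp, ca) {
  stopifnot(inherits(hp, "hill_params"), is.numeric(ca))
  if (any(ca < 0)) stop("calcium concentration must be >= 0")
  # evaluate via the ratio (ec50/ca)^n_h for stability at large n_h
  out <- numeric(length(ca))
  pos <- ca > 0
  out[pos] <- hp$s_max / (1 + (hp$ec50 / ca[pos])^hp$n_h)
  out
}

# deterministic multistart grid for the Hill fit: multiplicative nudges on
# (s_max, ec50) plus a spread of Hill coefficients
.hill_starts <- function(ca, tension) {
  s0 <- max(tension)
  half <- s0 / 2
  i <- which(tension >= half)[1L]
  e0 <- if (is.na(i)) stats::median(ca) else ca[max(i, 1L)]
  list(c(s0, e0, 4), c(s0 * 1.1, e0 * 0.8, 7), c(s0 * 1.05, e0 * 1.2, 2.5),
       c(s0 * 1.3, e0, 10), c(s0, e0 * 1.5, 5.5))
}

#' Fit the Hill equation to calcium-tension data
#'
#' Three-parameter bounded nonlinear least squares in linear tension space
#' (Levenberg-Marquardt with five deterministic starting points; the narrow
#' valley around steep Hill coefficients makes a single start unreliable).
#'
#' @param ca Calcium concentrations, uM (> 0).
#' @param tension Measured or simulated tensions, S. Alternatively pass a
#'   `"ca_tension_curve"` as `ca` and leave `tension` missing.
#' @param lower,upper Parameter bounds in the order (s_max, ec50, n_h).
#' @return An object of class `"hillfit"`: a list with elements `params` (a
#'   [hill_params()]), `fitted`, `residuals` (fitted - observed), `rmse`,
#'   `converged`, `n_evals` and the data. Methods: `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' ca <- default_ca_grid(40, 0.5, 10)
#' fit <- fit_hill(ca, hill_tension(hill_params(1, 3.5, 7), ca))
#' coef(fit)
#' @export
fit_hill <- function(ca, tension, lower = c(1e-6, 1e-4, 0.2),
                     upper = c(Inf, 1e4, 50)) {
  if (inherits(ca, "ca_tension_curve") && missing(tension)) {
    tension <- ca$tension
    ca <- ca$ca
  }
  stopifnot(is.numeric(ca), is.numeric(tension),
            length(ca) == length(tension))
  if (length(ca) < 4L)
    stop("need at least 4 (ca, tension) points to fit the three-parameter Hill model")
  if (any(ca <= 0)) stop("calcium concentrations must be > 0")
  if (diff(range(tension)) <= 0)
    stop("degenerate data: all tension values are identical; Hill fit is undefined")

  resid_fun <- function(theta)
    theta[1L] / (1 + (theta[2L] / ca)^theta[3L]) - tension

  best <- NULL
  n_evals <- 0L
  for (start in .hill_starts(ca, tension)) {
    start <- pmin(pmax(start, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_evals <- n_evals + fit$niter
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("Hill fit failed to converge from every starting point")

  theta <- best$par
  fitted <- theta[1L] / (1 + (theta[2L] / ca)^theta[3L])
  res <- fitted - tension
  structure(list(
    params = hill_params(theta[1L], theta[2L], theta[3L]),
    fitted = fitted, residuals = res,
    rmse = rmse(fitted, tension),
    converged = best$info %in% 1:4,
    n_evals = n_evals,
    data = data.frame(ca = ca, tension = tension)),
    class = "hillfit")
}

#' @export
coef.hillfit <- function(object, ...) {
  with(object$params, c(s_max = s_max, ec50 = ec50, n_h = n_h))
}

#' @export
print.hillfit <- function(x, ...) {
  cat("Hill fit to", nrow(x$data), "calcium-tension points\n")
  print(x$params)
  cat(sprintf("  RMSE %.4g S; converged: %s\n", x$rmse, x$converged))
  invisible(x)
}

#' @export
summary.hillfit <- function(object, ...) {
  cat("Hill-equation fit\n")
  print(object$params)
  cat(sprintf("  n points: %d\n  RMSE: %.4g S\n  residual range: [%.4g, %.4g] S\n",
              nrow(object$data), object$rmse,
              min(object$residuals), max(object$residuals)))
  invisible(object)
}

#' @export
predict.hillfit <- function(object, ca = NULL, ...) {
  if (is.null(ca)) return(object$fitted)
  hill_tension(object$params, ca)
}

#' @export
residuals.hillfit <- function(object, ...) object$residuals

#' @export
plot.hillfit <- function(x, ...) {
  graphics::plot(x$data$ca, x$data$tension, log = "x",
                 xlab = "[Ca2+] (uM)", ylab = "tension (S)", ...)
  ca_line <- exp(seq(log(min(x$data$ca)), log(max(x$data$ca)), length.out = 200))
  graphics::lines(ca_line, hill_tension(x$params, ca_line))
  invisible(x)
}
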