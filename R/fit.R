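#' Root-mean-square error between model and data tensions
#'
#' `sqrt(mean((model - data)^2))`, the unweighted misfit criterion used for
#' every fit in this package.
#'
#' @param model_tensions,data_tensions Numeric vectors of equal length (>= 1),
#'   S units.
#' @return RMSE, S (scalar >= 0).
#' @examples
#' rmse(c(1, 1), c(0, 2)) # 1
#' @export
rmse <- function(model_tensions, data_tensions) {
  stopifnot(is.numeric(model_tensions), is.numeric(data_tensions))
  if (length(model_tensions) != length(data_tensions))
    stop("length mismatch: ", length(model_tensions), " model vs ",
         length(data_tensions), " data tensions")
  if (length(model_tensions) < 1L) stop("need at least one point")
  sqrt(mean((model_tensions - data_tensions)^2))
}

# parameter bounds for the mechanochemical fit, order (c_f, c_s, k_tnca0).
# Wide enough for the low-cooperativity regime (n = 1 fits push k_tnca0 into
# the hundreds of uM).
.mc_lower <- c(0.5, 0, 0.5)
.mc_upper <- c(5, 200, 1000)

# model tensions at the data's ca values for one sarcomere-length group
.mc_model <- function(theta, n, ca, x_max) {
  p <- mechchem_params(theta[1L], theta[2L], theta[3L], n)
  .solve_tension(p, ca, c(0, x_max))[2L, ]
}

# deterministic multistart set for one group
.mc_starts <- function(ca, tension, x_max) {
  peak <- max(tension)
  cf0 <- min(max(peak / x_max, .mc_lower[1L]), .mc_upper[1L])
  half <- peak / 2
  i <- which(tension >= half)[1L]
  e0 <- if (is.na(i)) stats::median(ca) else ca[max(i, 1L)]
  list(c(cf0, 7, 2.4 * e0), c(cf0, 0.1, 1.0 * e0), c(cf0, 3, 1.8 * e0),
       c(cf0 * 1.2, 15, 3.0 * e0), c(cf0, 40, 4.0 * e0))
}

.fit_one_group <- function(ca, tension, x_max, n) {
  resid_fun <- function(theta) .mc_model(theta, n, ca, x_max) - tension
  best <- NULL
  n_evals <- 0L
  for (start in .mc_starts(ca, tension, x_max)) {
    start <- pmin(pmax(start, .mc_lower), .mc_upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = .mc_lower, upper = .mc_upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-15, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_evals <- n_evals + fit$niter
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("mechanochemical fit failed from every starting point")
  list(theta = best$par, deviance = best$deviance,
       converged = best$info %in% 1:4, n_evals = n_evals)
}

# parse `tension ~ ca | group`; group term optional
.parse_mc_formula <- function(formula, data) {
  if (length(formula) != 3L) stop("formula must have the form tension ~ ca | group")
  lhs <- formula[[2L]]
  rhs <- formula[[3L]]
  if (is.call(rhs) && identical(rhs[[1L]], as.name("|"))) {
    ca_expr <- rhs[[2L]]
    grp_expr <- rhs[[3L]]
  } else {
    ca_expr <- rhs
    grp_expr <- NULL
  }
  tension <- eval(lhs, data, parent.frame(2L))
  ca <- eval(ca_expr, data, parent.frame(2L))
  group <- if (is.null(grp_expr)) rep(NA_real_, length(ca))
           else eval(grp_expr, data, parent.frame(2L))
  if (!is.numeric(tension) || !is.numeric(ca))
    stop("tension and calcium must be numeric columns")
  if (any(ca <= 0)) stop("calcium concentrations must be > 0")
  data.frame(sl = group, ca = ca, tension = tension)
}

#' Fit the mechanochemical model to calcium-tension data
#'
#' Estimates the model constants by bounded nonlinear least squares on the
#' tensions (Levenberg-Marquardt, five deterministic starting points per
#' group; the strong interdependency between `k_tnca0` and `c_s` makes the
#' objective flat along one direction, so multistart matters). Two modes:
#' \describe{
#'   \item{`"percurve"`}{`c_f`, `c_s` and `k_tnca0` fitted independently for
#'     each sarcomere-length group;}
#'   \item{`"shared"`}{one `(c_f, c_s)` pair common to all groups with a
#'     per-group `k_tnca0`, seeded from the mean of the per-curve fits and
#'     then jointly re-optimised.}
#' }
#' The intrinsic cooperativity `n` is held fixed (default 3); it is a
#' property of the chemistry, not a free constant of the fit.
#'
#' @param formula A formula `tension ~ ca | sl` naming the tension column
#'   (S), the calcium column (uM) and the grouping sarcomere-length column
#'   (um). The group term may be omitted for single-curve data, in which case
#'   `sl` must be given.
#' @param data Data frame holding the columns named in `formula`.
#' @param mode `"percurve"` or `"shared"`.
#' @param n Intrinsic cooperativity coefficient (fixed during the fit).
#' @param sl Sarcomere length, um, when the formula has no group term.
#' @param thick_len,thin_len,bare_zone_len Filament geometry passed to
#'   [sarcomere_geometry()].
#' @return An object of class `"mechchem"`: a list with elements
#'   `params` (data frame, one row per group: `sl`, `c_f`, `c_s`, `k_tnca0`,
#'   `n`, `rmse`, `n_points`), `mode`, `data` (with fitted values and
#'   residuals), `objective` (total sum of squares), `converged`, `n_evals`
#'   and the geometry constants. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' ds <- generate_dataset("mechchem", reference_params("shared"),
#'                        noise_sigma = 0.02, seed = 1)
#' fit <- mechchem(tension_S ~ calcium_uM | sarcomere_length_um,
#'                 data = ds, mode = "shared")
#' coef(fit)
#' }
#' @export
mechchem <- function(formula = tension_S ~ calcium_uM | sarcomere_length_um,
                     data, mode = c("percurve", "shared"), n = 3,
                     sl = NULL, thick_len = 1.65, thin_len = 1.2,
                     bare_zone_len = 0.1) {
  mode <- match.arg(mode)
  d <- .parse_mc_formula(formula, data)
  if (all(is.na(d$sl))) {
    if (is.null(sl)) stop("formula has no group term; supply the sarcomere length via `sl =`")
    d$sl <- sl
  }
  groups <- sort(unique(d$sl))
  if (mode == "shared" && length(groups) < 1L) stop("no data groups found")
  geoms <- lapply(groups, sarcomere_geometry, thick_len = thick_len,
                  thin_len = thin_len, bare_zone_len = bare_zone_len)
  x_maxs <- vapply(geoms, single_overlap_length, numeric(1))
  idx <- lapply(groups, function(g) which(d$sl == g))
  for (i in seq_along(groups))
    if (length(idx[[i]]) < 5L)
      stop("group sl = ", groups[i], " has fewer than 5 points")

  # stage 1: independent per-curve fits (also the seed for the shared fit)
  per <- lapply(seq_along(groups), function(i) {
    rows <- idx[[i]]
    .fit_one_group(d$ca[rows], d$tension[rows], x_maxs[i], n)
  })
  n_evals <- sum(vapply(per, `[[`, numeric(1), "n_evals"))
  theta_mat <- do.call(rbind, lapply(per, `[[`, "theta"))
  converged <- all(vapply(per, `[[`, logical(1), "converged"))

  if (mode == "shared" && length(groups) > 1L) {
    # stage 2: joint fit with (c_f, c_s) shared and k_tnca0 free per group
    resid_fun <- function(theta) {
      out <- numeric(nrow(d))
      for (i in seq_along(groups)) {
        rows <- idx[[i]]
        th <- c(theta[1L], theta[2L], theta[2L + i])
        out[rows] <- .mc_model(th, n, d$ca[rows], x_maxs[i]) - d$tension[rows]
      }
      out
    }
    lower <- c(.mc_lower[1:2], rep(.mc_lower[3L], length(groups)))
    upper <- c(.mc_upper[1:2], rep(.mc_upper[3L], length(groups)))
    start0 <- c(mean(theta_mat[, 1L]), mean(theta_mat[, 2L]), theta_mat[, 3L])
    starts <- list(start0,
                   start0 * c(1.1, 1.3, rep(1, length(groups))),
                   start0 * c(0.9, 0.7, rep(1.1, length(groups))))
    best <- NULL
    for (start in starts) {
      start <- pmin(pmax(start, lower), upper)
      fit <- tryCatch(
        minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                           fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 400, ftol = 1e-15, ptol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit)) next
      n_evals <- n_evals + fit$niter
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    if (is.null(best)) stop("shared-parameter fit failed from every starting point")
    converged <- best$info %in% 1:4
    theta_mat <- cbind(rep(best$par[1L], length(groups)),
                       rep(best$par[2L], length(groups)),
                       best$par[2L + seq_along(groups)])
  }

  # assemble fitted values, residuals and per-group rmse
  d$fitted <- NA_real_
  grp_rmse <- numeric(length(groups))
  for (i in seq_along(groups)) {
    rows <- idx[[i]]
    d$fitted[rows] <- .mc_model(theta_mat[i, ], n, d$ca[rows], x_maxs[i])
    grp_rmse[i] <- rmse(d$fitted[rows], d$tension[rows])
  }
  d$residual <- d$fitted - d$tension

  params <- data.frame(sl = groups,
                       c_f = theta_mat[, 1L], c_s = theta_mat[, 2L],
                       k_tnca0 = theta_mat[, 3L], n = n,
                       rmse = grp_rmse,
                       n_points = lengths(idx))
  structure(list(params = params, mode = mode, n = n, data = d,
                 objective = sum(d$residual^2), converged = converged,
                 n_evals = n_evals,
                 geometry = list(thick_len = thick_len, thin_len = thin_len,
                                 bare_zone_len = bare_zone_len)),
            class = "mechchem")
}

#' @export
coef.mechchem <- function(object, ...) {
  p <- object$params
  m <- as.matrix(p[, c("c_f", "c_s", "k_tnca0")])
  rownames(m) <- format(p$sl)
  m
}

#' @export
print.mechchem <- function(x, ...) {
  cat("Mechanochemical model fit (mode:", x$mode, ", n =", x$n, ")\n")
  print(x$params, row.names = FALSE, digits = 4)
  cat(sprintf("Total SSQ %.4g S^2 over %d points; converged: %s\n",
              x$objective, nrow(x$data), x$converged))
  invisible(x)
}

#' @export
summary.mechchem <- function(object, ...) {
  print(object)
  cat("Residual summary (fitted - observed, S):\n")
  print(summary(object$data$residual))
  invisible(object)
}

#' @export
fitted.mechchem <- function(object, ...) object$data$fitted

#' @export
residuals.mechchem <- function(object, ...) object$data$residual

# resolve (sl, ca) columns in newdata under either naming convention
.newdata_cols <- function(newdata) {
  sl <- if ("sl" %in% names(newdata)) newdata$sl
        else newdata$sarcomere_length_um
  ca <- if ("ca" %in% names(newdata)) newdata$ca else newdata$calcium_uM
  if (is.null(sl) || is.null(ca))
    stop("newdata needs columns (sl, ca) or (sarcomere_length_um, calcium_uM)")
  data.frame(sl = sl, ca = ca)
}

#' Predict tension from a fitted mechanochemical model
#'
#' @param object A `"mechchem"` fit.
#' @param newdata Optional data frame with columns `sl` and `ca` (or
#'   `sarcomere_length_um` and `calcium_uM`). Sarcomere lengths must be among
#'   the fitted groups. Defaults to the training points.
#' @param ... Unused.
#' @return Numeric vector of tensions, S.
#' @export
predict.mechchem <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$data$fitted)
  nd <- .newdata_cols(newdata)
  out <- numeric(nrow(nd))
  for (g in unique(nd$sl)) {
    row <- match(g, object$params$sl)
    if (is.na(row)) stop("sarcomere length ", g, " was not among the fitted groups")
    p <- .params_from_row(object$params[row, ])
    geom <- sarcomere_geometry(g, object$geometry$thick_len,
                               object$geometry$thin_len,
                               object$geometry$bare_zone_len)
    sel <- nd$sl == g
    out[sel] <- total_tension(p, nd$ca[sel], geom)
  }
  out
}

#' Simulate datasets from a fitted mechanochemical model
#'
#' Draws new noisy datasets at the fitted parameters using the same
#' (sl, ca) design as the training data.
#'
#' @param object A `"mechchem"` fit.
#' @param nsim Number of datasets.
#' @param seed Seed passed to the generator (each replicate uses
#'   `seed + i - 1`).
#' @param noise_sigma Gaussian tension noise, S.
#' @param ... Unused.
#' @return A list of `nsim` dataset data frames (see [generate_dataset()]).
#' @export
simulate.mechchem <- function(object, nsim = 1, seed = 1,
                              noise_sigma = 0.02, ...) {
  lapply(seq_len(nsim), function(i)
    generate_dataset("mechchem", object$params,
                     ca_design = object$data$ca[object$data$sl == object$params$sl[1L]],
                     noise_sigma = noise_sigma, seed = seed + i - 1L,
                     thick_len = object$geometry$thick_len,
                     thin_len = object$geometry$thin_len,
                     bare_zone_len = object$geometry$bare_zone_len))
}

#' @export
plot.mechchem <- function(x, ...) {
  d <- x$data
  graphics::plot(d$ca, d$tension, log = "x", col = factor(d$sl),
                 xlab = "[Ca2+] (uM)", ylab = "tension (S)", ...)
  ca_line <- exp(seq(log(min(d$ca)), log(max(d$ca)), length.out = 150))
  for (i in seq_len(nrow(x$params))) {
    p <- .params_from_row(x$params[i, ])
    geom <- sarcomere_geometry(x$params$sl[i], x$geometry$thick_len,
                               x$geometry$thin_len, x$geometry$bare_zone_len)
    graphics::lines(ca_line, total_tension(p, ca_line, geom), col = i)
  }
  invisible(x)
}

#' Scan the K_TnCa0 / C_s compensation ridge
#'
#' The zero-tension equilibrium constant and the tension-coupling constant
#' trade off against one another: scaling `k_tnca0` by a factor `a` can be
#' compensated almost exactly by adjusting `c_s`, leaving the calcium-tension
#' curve nearly unchanged. For each `a` this scan finds the `c_s` minimising
#' the RMSE distance to the reference curve (on the standard log calcium
#' grid) and reports that distance, plus the power-law exponent
#' `log(c_s_opt / c_s) / log(a)` implied by the compensation.
#'
#' @param params Reference [mechchem_params()].
#' @param geom A [sarcomere_geometry()].
#' @param a_values Positive scale factors applied to `k_tnca0`.
#' @param ca_grid Calcium grid for the curve distance.
#' @return Data frame with columns `a`, `c_s_opt`, `distance` (RMSE, S) and
#'   `exponent` (NA at `a = 1`).
#' @examples
#' \donttest{
#' p <- mechchem_params(1.97, 7.32, 8.63)
#' ridge_scan(p, sarcomere_geometry(2.05), a_values = c(1, 1.2))
#' }
#' @export
ridge_scan <- function(params, geom, a_values,
                       ca_grid = default_ca_grid(60)) {
  stopifnot(inherits(params, "mechchem_params"),
            inherits(geom, "sarcomere_geometry"),
            is.numeric(a_values), all(a_values > 0))
  ref <- ca_tension_curve(params, geom, ca_grid)$tension
  out <- lapply(a_values, function(a) {
    if (abs(a - 1) < 1e-12)
      return(data.frame(a = a, c_s_opt = params$c_s, distance = 0,
                        exponent = NA_real_))
    dist_of <- function(cs) {
      p2 <- mechchem_params(params$c_f, cs, params$k_tnca0 * a, params$n)
      rmse(ca_tension_curve(p2, geom, ca_grid)$tension, ref)
    }
    opt <- stats::optimize(dist_of, interval = c(0, .mc_upper[2L]),
                           tol = 1e-6)
    data.frame(a = a, c_s_opt = opt$minimum, distance = opt$objective,
               exponent = log(opt$minimum / params$c_s) / log(a))
  })
  do.call(rbind, out)
}
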