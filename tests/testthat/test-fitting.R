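test_that("rmse is the root mean squared difference", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 1), c(0, 2)), 1)
  expect_error(rmse(1:3, 1:4), "length mismatch")
  # stored per-group rmse is recomputable from residuals
  ds <- generate_dataset("mechchem", reference_params("percurve")[3, ],
                         noise_sigma = 0.01, seed = 5)
  fit <- mechchem(data = ds, mode = "percurve")
  expect_equal(fit$params$rmse,
               rmse(fit$data$fitted, fit$data$tension), tolerance = 1e-12)
})

test_that("per-curve fit recovers a noiseless generating curve exactly", {
  ds <- generate_dataset("mechchem", reference_params("percurve")[3, ],
                         noise_sigma = 0)
  fit <- mechchem(data = ds, mode = "percurve")
  expect_lt(fit$params$rmse, 1e-6)
  # curve-space recovery on the full grid (parameters may slide along the
  # k_tnca0/c_s ridge; the curve itself is the identified object)
  geom <- sarcomere_geometry(2.05)
  gen <- ca_tension_curve(mechchem_params(1.97, 7.32, 8.63), geom)
  fitted_curve <- ca_tension_curve(.row_params(fit, 1), geom)
  expect_lt(max(abs(gen$tension - fitted_curve$tension)), 1e-3)
})

test_that("per-curve fit on noisy data reaches the noise floor", {
  ds <- generate_dataset("mechchem", reference_params("percurve")[2, ],
                         noise_sigma = 0.02, seed = 17)
  fit <- mechchem(data = ds, mode = "percurve")
  expect_lt(fit$params$rmse, 2 * 0.02)
  expect_true(fit$converged)
})

test_that("data from a pure Hill curve needs no mechanochemical coupling", {
  ds <- generate_dataset("hill", data.frame(sl = 2.05, s_max = 1.2,
                                            ec50 = 8, n_h = 3),
                         noise_sigma = 0)
  fit <- mechchem(data = ds, mode = "percurve")
  expect_lt(fit$params$c_s, 0.05)
  expect_equal(fit$params$k_tnca0, 8, tolerance = 1e-3)
  expect_equal(fit$params$c_f, 1.2 / single_overlap_length(sarcomere_geometry(2.05)),
               tolerance = 1e-3)
})

test_that("shared fit recovers the generating curves and parameter structure", {
  truth <- reference_params("shared")
  ds <- generate_dataset("mechchem", truth, noise_sigma = 0.02, seed = 11)
  fit <- mechchem(data = ds, mode = "shared")
  expect_true(fit$converged)
  # one (c_f, c_s) pair across groups
  expect_equal(length(unique(fit$params$c_f)), 1L)
  expect_equal(length(unique(fit$params$c_s)), 1L)
  # force-density constant is well identified; the coupling constant only
  # jointly with k_tnca0 (ridge), so it gets a wider band
  expect_equal(fit$params$c_f[1L], 1.93, tolerance = 0.05)
  expect_equal(fit$params$c_s[1L], 6.5, tolerance = 0.3)
  # calcium sensitivity at zero tension falls monotonically with SL
  expect_true(all(diff(fit$params$k_tnca0) < 0))
  # curve-space recovery everywhere on the standard grid
  for (i in seq_len(nrow(truth))) {
    geom <- sarcomere_geometry(truth$sl[i])
    gen <- ca_tension_curve(
      mechchem_params(truth$c_f[i], truth$c_s[i], truth$k_tnca0[i]), geom)
    fc <- ca_tension_curve(.row_params(fit, i), geom)
    expect_lt(max(abs(gen$tension - fc$tension)), 0.05)
  }
})

test_that("shared fit cannot beat the per-curve fits it nests in", {
  ds <- generate_dataset("mechchem", reference_params("shared")[c(1, 3, 5), ],
                         noise_sigma = 0.03, seed = 23)
  per <- mechchem(data = ds, mode = "percurve")
  shared <- mechchem(data = ds, mode = "shared")
  expect_gte(shared$objective, per$objective - 1e-10)
})

test_that("single-group shared fit degenerates to the per-curve fit", {
  ds <- generate_dataset("mechchem", reference_params("percurve")[3, ],
                         noise_sigma = 0.02, seed = 31)
  per <- mechchem(data = ds, mode = "percurve")
  shared <- mechchem(data = ds, mode = "shared")
  expect_equal(shared$params, per$params, tolerance = 1e-8)
})

test_that("formula interface checks its inputs", {
  ds <- generate_dataset("mechchem", reference_params("percurve")[3, ],
                         noise_sigma = 0)
  # ungrouped formula requires an explicit sarcomere length
  expect_error(mechchem(tension_S ~ calcium_uM, data = ds), "sl")
  fit <- mechchem(tension_S ~ calcium_uM, data = ds, sl = 2.05)
  expect_equal(fit$params$sl, 2.05)
  expect_error(mechchem(data = ds[1:3, ]), "fewer than 5")
})

test_that("ridge scan finds compensating coupling constants", {
  p <- mechchem_params(1.97, 7.32, 8.63)
  geom <- sarcomere_geometry(2.05)
  tab <- ridge_scan(p, geom, a_values = c(1, 1.2))
  expect_equal(tab$c_s_opt[1L], 7.32)
  expect_identical(tab$distance[1L], 0)
  # scaling k_tnca0 by 1.2 is nearly neutral at the compensating c_s
  peak <- ca_tension_curve(p, geom)$tension[200L]
  expect_lt(tab$distance[2L], 0.03 * peak)
  expect_gt(tab$c_s_opt[2L], 7.32)  # larger k0 needs stronger coupling
})

test_that("predict and simulate round-trip through the fitted model", {
  ds <- generate_dataset("mechchem", reference_params("percurve")[c(1, 5), ],
                         noise_sigma = 0.02, seed = 3)
  fit <- mechchem(data = ds, mode = "percurve")
  pr <- predict(fit, newdata = data.frame(sl = 1.85, ca = c(2, 4, 8)))
  expect_true(all(diff(pr) > 0))
  expect_error(predict(fit, newdata = data.frame(sl = 2.05, ca = 4)),
               "not among the fitted groups")
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  expect_false(identical(sims[[1]]$tension_S, sims[[2]]$tension_S))
})
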