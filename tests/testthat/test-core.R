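p205 <- mechchem_params(c_f = 1.97, c_s = 7.32, k_tnca0 = 8.63)
p185 <- mechchem_params(c_f = 1.85, c_s = 9.27, k_tnca0 = 10.09)

test_that("equilibrium constant decays exponentially with tension", {
  expect_equal(equilibrium_constant(mechchem_params(1, 5, 10), 0), 10)
  expect_equal(equilibrium_constant(p185, 0.1), 10.09 * exp(-0.927),
               tolerance = 1e-12)
  # c_s = 0 decouples the constant from tension entirely
  p0 <- mechchem_params(1, 0, 10)
  expect_equal(equilibrium_constant(p0, c(0, 0.5, 2)), rep(10, 3))
  # strictly decreasing in s when c_s > 0
  s <- seq(0, 1, by = 0.1)
  expect_true(all(diff(equilibrium_constant(p185, s)) < 0))
  expect_error(equilibrium_constant(p185, -0.1), ">= 0")
})

test_that("activation fraction has the logistic closed form and limits", {
  expect_equal(activation_fraction(p185, ca = 10.09, s = 0), 0.5)
  ca <- c(0.5, 2, 5, 20)
  expect_equal(activation_fraction(p185, ca, s = 0),
               1 / (1 + (10.09 / ca)^3), tolerance = 1e-12)
  expect_equal(activation_fraction(p185, ca = 1e12, s = 0), 1, tolerance = 1e-9)
  expect_equal(activation_fraction(p185, ca = 1e-12, s = 0), 0, tolerance = 1e-9)
  # extreme exponents stay finite (stable logistic)
  expect_true(is.finite(activation_fraction(p185, ca = 1e-300, s = 0)))
  # increasing in ca and in s; steeper in ca for larger n
  expect_true(all(diff(activation_fraction(p185, ca, s = 0)) > 0))
  expect_true(all(diff(activation_fraction(p185, ca = 5, s = c(0, .2, .5))) > 0))
  p_n6 <- mechchem_params(1.85, 9.27, 10.09, n = 6)
  slope3 <- activation_fraction(p185, 10.09 * 1.01, 0) -
    activation_fraction(p185, 10.09 * 0.99, 0)
  slope6 <- activation_fraction(p_n6, 10.09 * 1.01, 0) -
    activation_fraction(p_n6, 10.09 * 0.99, 0)
  expect_gt(slope6, slope3)
  expect_error(activation_fraction(p185, ca = 0, s = 0), "> 0")
})

test_that("decoupled (c_s = 0) tension profile is exactly linear", {
  p0 <- mechchem_params(c_f = 2, c_s = 0, k_tnca0 = 8)
  prof <- integrate_tension(p0, ca = 4, x_max = 0.6)
  expect_equal(prof$tension, 2 * prof$x / (1 + (8 / 4)^3), tolerance = 1e-8)
})

test_that("profiles satisfy their structural invariants", {
  for (ca in c(0.5, 3, 5, 10)) {
    prof <- integrate_tension(p205, ca, x_max = 0.65)
    expect_identical(prof$tension[1L], 0)
    expect_true(all(diff(prof$tension) >= -1e-12))
    expect_true(all(prof$activation >= 0 & prof$activation <= 1))
    # force density bounded by c_f
    dx <- diff(prof$x)
    expect_true(all(diff(prof$tension) <= 1.97 * dx + 1e-9))
  }
})

test_that("adaptive solution matches an independent fixed-step RK4 oracle", {
  tab <- reference_params("percurve")
  ca <- c(0.5, 2, 3.5, 6, 10)
  n_checked <- 0L
  for (i in seq_len(nrow(tab))) {
    geom <- sarcomere_geometry(tab$sl[i])
    x_max <- single_overlap_length(geom)
    p <- mechchem_params(tab$c_f[i], tab$c_s[i], tab$k_tnca0[i])
    got <- total_tension(p, ca, geom)
    want <- rk4_total_tension(tab$c_f[i], tab$c_s[i], tab$k_tnca0[i], 3,
                              ca, x_max, dx = 1e-4)
    expect_equal(got, want, tolerance = 1e-5)
    n_checked <- n_checked + length(ca)
  }
  expect_gte(n_checked, 20L)
})

test_that("discrete cross-bridge ladder converges to the ODE at first order", {
  x_max <- 0.65
  ode_end <- integrate_tension(p205, ca = 4, x_max)$tension[512L]
  single <- discrete_ladder(p205, ca = 4, x_max, n_sites = 1)
  expect_equal(single$tension[2L],
               1.97 * x_max * activation_fraction(p205, 4, 0))
  n_sites <- 2^(5:12)
  errs <- vapply(n_sites, function(ns) {
    lad <- discrete_ladder(p205, ca = 4, x_max, n_sites = ns)
    expect_true(all(diff(lad$tension) >= 0))
    abs(lad$tension[ns + 1L] - ode_end)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # halving dx roughly halves the error once asymptotic
  ratios <- errs[-1] / errs[-length(errs)]
  expect_true(all(ratios[4:7] > 0.35 & ratios[4:7] < 0.65))
})

test_that("calcium-tension curves are monotone, bounded and linear in c_f", {
  geom <- sarcomere_geometry(2.05)
  cur <- ca_tension_curve(p205, geom)
  expect_true(all(diff(cur$tension) >= -1e-12))
  expect_true(all(cur$tension < 1.97 * single_overlap_length(geom)))
  # doubling c_f at c_s = 0 doubles every tension value
  pA <- mechchem_params(1, 0, 8); pB <- mechchem_params(2, 0, 8)
  expect_equal(ca_tension_curve(pB, geom)$tension,
               2 * ca_tension_curve(pA, geom)$tension, tolerance = 1e-9)
  # c_s = 0 curve is the Hill closed form with coefficient n, EC50 = k0
  expect_equal(ca_tension_curve(pA, geom)$tension,
               closed_form_tension_cs0(1, 8, 3, cur$ca,
                                       single_overlap_length(geom)),
               tolerance = 1e-8)
})

test_that("total tension rises with ca, c_f, c_s and overlap length", {
  geom <- sarcomere_geometry(2.05)
  base <- total_tension(p205, 3.5, geom)
  expect_gt(total_tension(p205, 3.5 * 1.05, geom), base)
  expect_gt(total_tension(mechchem_params(1.97 * 1.05, 7.32, 8.63), 3.5, geom),
            base)
  expect_gt(total_tension(mechchem_params(1.97, 7.32 * 1.05, 8.63), 3.5, geom),
            base)
  expect_gt(total_tension(p205, 3.5, sarcomere_geometry(2.15)), base)
  # vanishing calcium gives vanishing tension
  expect_lt(total_tension(p205, 1e-3, geom), 1e-6)
})

test_that("half-activation decoupled total tension is c_f * x_max / 2", {
  p0 <- mechchem_params(c_f = 1.85, c_s = 0, k_tnca0 = 10.09)
  geom <- sarcomere_geometry(1.85)
  expect_equal(total_tension(p0, ca = 10.09, geom), 1.85 * 0.55 / 2,
               tolerance = 1e-8)
})
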