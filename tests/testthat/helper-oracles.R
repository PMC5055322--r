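# Independent oracles used across tests. These deliberately avoid the
# package's solver path: a hand-rolled fixed-step classical RK4 for the
# tension ODE and closed forms for the decoupled (c_s = 0) limit.

# fixed-step RK4 for dS/dx = c_f / (1 + exp(n*(-c_s*S - log(ca/k0)))),
# vectorised over ca; returns final tension S(x_max)
rk4_total_tension <- function(c_f, c_s, k0, n, ca, x_max, dx = 1e-4) {
  nstep <- ceiling(x_max / dx)
  h <- x_max / nstep
  lr <- log(ca / k0)
  f <- function(S) c_f / (1 + exp(n * (-c_s * S - lr)))
  S <- numeric(length(ca))
  for (i in seq_len(nstep)) {
    k1 <- f(S); k2 <- f(S + h / 2 * k1); k3 <- f(S + h / 2 * k2); k4 <- f(S + h * k3)
    S <- S + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  S
}

# closed-form total tension when c_s = 0 (ODE right side independent of S)
closed_form_tension_cs0 <- function(c_f, k0, n, ca, x_max) {
  c_f * x_max / (1 + (k0 / ca)^n)
}

# closed-form EC50 under the grid-peak convention (peak at ca_max) for c_s = 0
closed_form_ec50_cs0 <- function(k0, n, ca_max = 10) {
  k0 / (1 + 2 * (k0 / ca_max)^n)^(1 / n)
}

# parameters of group i of a mechchem() fit, as a mechchem_params object
.row_params <- function(fit, i) {
  r <- fit$params[i, ]
  mechchem_params(r$c_f, r$c_s, r$k_tnca0, r$n)
}

# per-curve reference parameter sets as mechchem_params objects
ref_param_list <- function(block = "percurve") {
  tab <- reference_params(block)
  lapply(seq_len(nrow(tab)), function(i)
    mechchem_params(tab$c_f[i], tab$c_s[i], tab$k_tnca0[i], tab$n[i]))
}
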