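# shared fixtures: all synthetic, generated in code at test time

# ideal (unregularized) Herschel-Bulkley stress, used as the independent
# reference the regularized law must approach
hb_ideal_stress <- function(gamma_dot, tau_y, K, n) tau_y + K * gamma_dot^n

# synthetic rheometer flow curve from known parameters
synth_flow_curve <- function(tau_y, K, n, n_pts = 30, noise_sd = 0,
                             range = c(1e-2, 1e2), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- exp(seq(log(range[1]), log(range[2]), length.out = n_pts))
  tau <- hb_ideal_stress(g, tau_y, K, n)
  if (noise_sd > 0) tau <- tau * exp(stats::rnorm(n_pts, 0, noise_sd))
  flow_curve(g, stresses = tau)
}

# two-pass tearing trace with start-up transient and plateau ratio
synth_tearing_trace <- function(ratio, n = 200, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, 10, length.out = n)
  shape <- 1 - exp(-t / 0.5)         # rise to plateau
  noise <- function() if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  tearing_trace(t, 2e-3 * shape * (1 + noise()),
                2e-3 * ratio * shape * (1 + noise()))
}

# quiescent periodic test bed
small_grid <- function(n = 32, dx = 1e-4, bc = "periodic") grid_spec(n, n, dx, bc = bc)

newtonian_props <- function(mu = 1) fluid_properties(gel_hb = hb_params(0, mu, 1))
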