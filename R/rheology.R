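#' Herschel-Bulkley parameter set
#'
#' Bundles the constitutive parameters of a (regularized) Herschel-Bulkley
#' yield-stress fluid: \eqn{\tau = \tau_y + K \dot\gamma^n} above yield.
#' The stress singularity at zero shear is removed by Papanastasiou
#' exponential regularization with time scale \code{m_reg}, so the
#' unyielded material behaves as a very viscous fluid rather than a rigid
#' solid.
#'
#' @param tau_y yield stress, Pa (>= 0)
#' @param K consistency index, Pa s^n (> 0)
#' @param n flow index, dimensionless (> 0); n < 1 is shear thinning
#' @param m_reg regularization time scale, s (> 0); larger values approach
#'   the ideal (unregularized) law
#' @param mu_max cap on the effective viscosity, Pa s; bounds the
#'   zero-shear divergence of the power-law term when n < 1 and the
#'   regularized plateau \code{tau_y * m_reg}
#' @return object of class \code{hb_params}
#' @examples
#' hb <- hb_params(tau_y = 50, K = 20, n = 0.4)
#' effective_viscosity(c(0.01, 1, 100), hb)
#' @export
hb_params <- function(tau_y, K, n, m_reg = 1000, mu_max = 1e6) {
  stopifnot(is.finite(tau_y), is.finite(K), is.finite(n), is.finite(m_reg))
  if (tau_y < 0) stop("tau_y must be >= 0")
  if (K <= 0) stop("K must be > 0")
  if (n <= 0) stop("n must be > 0")
  if (m_reg <= 0) stop("m_reg must be > 0")
  if (mu_max <= 0) stop("mu_max must be > 0")
  structure(list(tau_y = tau_y, K = K, n = n, m_reg = m_reg, mu_max = mu_max),
            class = "hb_params")
}

#' @export
print.hb_params <- function(x, ...) {
  cat(sprintf(
    "Herschel-Bulkley: tau_y = %g Pa, K = %g Pa.s^n, n = %g (m_reg = %g s, mu_max = %g Pa.s)\n",
    x$tau_y, x$K, x$n, x$m_reg, x$mu_max))
  invisible(x)
}

#' Effective viscosity of a regularized Herschel-Bulkley fluid
#'
#' Papanastasiou-regularized effective viscosity
#' \deqn{\mu(\dot\gamma) = K \dot\gamma^{n-1} +
#'       \frac{\tau_y}{\dot\gamma}\left(1 - e^{-m\dot\gamma}\right),}
#' continuous in \eqn{\dot\gamma} with the analytic limit
#' \eqn{\mu(0^+) = \tau_y m + \lim K\dot\gamma^{n-1}} and capped at
#' \code{hb$mu_max}.
#'
#' @param gamma_dot shear rate(s), 1/s, >= 0 (vector or matrix)
#' @param hb \code{\link{hb_params}}
#' @return effective viscosity, Pa s, same shape as \code{gamma_dot}
#' @export
effective_viscosity <- function(gamma_dot, hb) {
  stopifnot(inherits(hb, "hb_params"))
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0))
    stop("gamma_dot must be finite and >= 0")
  g <- gamma_dot
  mu <- numeric(length(g))
  pos <- g > 0
  gp <- g[pos]
  mu[pos] <- hb$K * gp^(hb$n - 1) + hb$tau_y / gp * (1 - exp(-hb$m_reg * gp))
  # analytic gamma_dot -> 0 limit: yield term -> tau_y*m_reg; power-law term
  # -> 0 (n > 1), K (n = 1) or +Inf (n < 1, taken up by the cap)
  pl0 <- if (hb$n > 1) 0 else if (hb$n == 1) hb$K else Inf
  mu[!pos] <- hb$tau_y * hb$m_reg + pl0
  mu <- pmin(mu, hb$mu_max)
  if (is.matrix(gamma_dot)) dim(mu) <- dim(gamma_dot)
  mu
}

#' Shear stress of a regularized Herschel-Bulkley fluid
#'
#' \eqn{\tau = \mu_{\mathrm{eff}}(\dot\gamma)\,\dot\gamma}; zero at zero
#' shear rate and converging to the ideal law
#' \eqn{\tau_y + K\dot\gamma^n} once \eqn{m\dot\gamma \gg 1}.
#'
#' @inheritParams effective_viscosity
#' @return shear stress, Pa
#' @export
shear_stress <- function(gamma_dot, hb) {
  effective_viscosity(gamma_dot, hb) * gamma_dot
}

#' Material formulation for a support bath
#'
#' A named gel recipe: Herschel-Bulkley parameters plus density, surface
#' tension against air and optional small-strain storage modulus. The
#' M1/M2/M3 names follow the field's support-bath taxonomy: M1 low yield
#' stress (injected air breaks into bubbles), M2 intermediate (stable
#' channels), M3 elastic-dominated (the gel tears and recovers poorly).
#'
#' @param name label, e.g. "M1", "M1A", "M2", "M3" or user-defined
#' @param hb \code{\link{hb_params}}
#' @param density kg/m^3
#' @param surface_tension_vs_air N/m
#' @param storage_modulus Pa, optional
#' @param chemistry free-text tag ("silicone", "gelatin", "GelMA", ...)
#' @return object of class \code{ap_material}
#' @export
ap_material <- function(name, hb, density = 1000, surface_tension_vs_air = 0.025,
                        storage_modulus = NA_real_, chemistry = "") {
  stopifnot(inherits(hb, "hb_params"), is.character(name), nzchar(name))
  if (density <= 0) stop("density must be > 0")
  if (surface_tension_vs_air <= 0) stop("surface_tension_vs_air must be > 0")
  structure(list(name = name, hb = hb, density = density,
                 surface_tension_vs_air = surface_tension_vs_air,
                 storage_modulus = storage_modulus, chemistry = chemistry),
            class = "ap_material")
}

#' @export
print.ap_material <- function(x, ...) {
  cat(sprintf("Material %s (%s): rho = %g kg/m^3, sigma = %g N/m\n  ",
              x$name, ifelse(nzchar(x$chemistry), x$chemistry, "unspecified"),
              x$density, x$surface_tension_vs_air))
  print(x$hb)
  invisible(x)
}

#' Built-in materials catalog
#'
#' Named formulations spanning the M1 -> M3 regime taxonomy, with four
#' intermediate recipes (M1A..M1D) between the bubble-forming M1 and the
#' channel-stable M2, plus a stiffer M2-family member (M2B) for studies
#' that need a pre-printed channel comfortably inside the stable regime.
#' Yield stress and consistency rise monotonically from M1 to M3; M3
#' additionally carries a high storage modulus (elasticity dominated).
#' Values are representative of silicone/gelatin support baths used for
#' embedded printing; see the methods vignette for the rationale.
#'
#' @param path optional YAML catalog file (see \code{\link{write_materials_catalog}});
#'   when missing the built-in catalog is returned
#' @return named list of \code{\link{ap_material}}
#' @export
materials_catalog <- function(path = NULL) {
  if (!is.null(path)) return(read_materials_catalog(path))
  spec <- list(
    #      tau_y    K     n   G'      chem
    M1  = c(2,     5,   0.60,  30),
    M1A = c(6,     8,   0.55,  60),
    M1B = c(15,   12,   0.50, 120),
    M1C = c(30,   15,   0.45, 250),
    M1D = c(60,   18,   0.42, 450),
    M2  = c(100,  20,   0.40, 800),
    M2B = c(250,  30,   0.40, 1500),
    M3  = c(400,  60,   0.35, 8000))
  out <- lapply(names(spec), function(nm) {
    v <- spec[[nm]]
    ap_material(nm, hb_params(v[1], v[2], v[3]),
                density = 1000, surface_tension_vs_air = 0.025,
                storage_modulus = v[4], chemistry = "silicone")
  })
  names(out) <- names(spec)
  out
}

#' Write / read a materials catalog as YAML
#'
#' @param catalog named list of \code{\link{ap_material}}
#' @param path file path
#' @return \code{read_materials_catalog} returns a named list of materials.
#' @export
write_materials_catalog <- function(catalog, path) {
  stopifnot(all(vapply(catalog, inherits, TRUE, "ap_material")))
  lst <- lapply(catalog, function(m)
    list(hb = m$hb[c("tau_y", "K", "n", "m_reg", "mu_max")],
         density = m$density, surface_tension_vs_air = m$surface_tension_vs_air,
         storage_modulus = m$storage_modulus, chemistry = m$chemistry))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_materials_catalog
#' @export
read_materials_catalog <- function(path) {
  lst <- yaml::read_yaml(path)
  if (anyDuplicated(names(lst))) stop("material names must be unique")
  out <- lapply(names(lst), function(nm) {
    e <- lst[[nm]]
    ap_material(nm, do.call(hb_params, e$hb), density = e$density,
                surface_tension_vs_air = e$surface_tension_vs_air,
                storage_modulus = if (is.null(e$storage_modulus)) NA_real_ else e$storage_modulus,
                chemistry = if (is.null(e$chemistry)) "" else e$chemistry)
  })
  names(out) <- names(lst)
  out
}

#' Rheometer flow curve
#'
#' Shear rate versus stress (or viscosity) table, as produced by a
#' rate-controlled flow sweep. At least 4 strictly ascending positive
#' shear rates are required.
#'
#' @param shear_rates 1/s, strictly positive ascending
#' @param stresses Pa (exclusive with \code{viscosities})
#' @param viscosities Pa s (converted internally via \eqn{\tau = \mu\dot\gamma})
#' @return object of class \code{flow_curve} with fields
#'   \code{shear_rates}, \code{stresses}
#' @export
flow_curve <- function(shear_rates, stresses = NULL, viscosities = NULL) {
  if (is.null(stresses) == is.null(viscosities))
    stop("supply exactly one of stresses or viscosities")
  if (!is.null(viscosities)) stresses <- viscosities * shear_rates
  if (length(shear_rates) < 4) stop("need >= 4 points")
  if (length(stresses) != length(shear_rates)) stop("length mismatch")
  if (any(!is.finite(shear_rates)) || any(!is.finite(stresses)) ||
      any(shear_rates <= 0) || any(stresses <= 0))
    stop("values must be finite and positive")
  if (any(diff(shear_rates) <= 0)) stop("shear_rates must be strictly ascending")
  structure(list(shear_rates = as.numeric(shear_rates),
                 stresses = as.numeric(stresses)), class = "flow_curve")
}

#' Read / write flow curves as CSV
#'
#' Columns: \code{shear_rate_per_s} and one of \code{stress_Pa} /
#' \code{viscosity_Pa_s}.
#' @param curve \code{\link{flow_curve}}
#' @param path file path
#' @export
write_flow_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(shear_rate_per_s = curve$shear_rates,
                              stress_Pa = curve$stresses),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_curve_csv
#' @export
read_flow_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"shear_rate_per_s" %in% names(df)) stop("missing shear_rate_per_s column")
  if ("stress_Pa" %in% names(df))
    flow_curve(df$shear_rate_per_s, stresses = df$stress_Pa)
  else if ("viscosity_Pa_s" %in% names(df))
    flow_curve(df$shear_rate_per_s, viscosities = df$viscosity_Pa_s)
  else stop("need stress_Pa or viscosity_Pa_s column")
}

#' Fit Herschel-Bulkley parameters to a flow curve
#'
#' Least-squares fit of the ideal law \eqn{\tau = \tau_y + K\dot\gamma^n}
#' on log-stress. The yield stress is profiled out: for fixed
#' \eqn{\tau_y}, \eqn{\log(\tau - \tau_y)} is linear in
#' \eqn{\log\dot\gamma}, so the inner (K, n) problem is an ordinary
#' regression and a 1-D search over \eqn{\tau_y \in [0, \min\tau)} does
#' the rest. Robust to the usual rheometer log-spaced grids.
#'
#' @param curve \code{\link{flow_curve}}
#' @return object of class \code{hb_fit}: \code{params}
#'   (\code{\link{hb_params}}), \code{residual_rms_log} (RMS of log-stress
#'   residuals), \code{converged}
#' @export
fit_flow_curve <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  g <- curve$shear_rates; tau <- curve$stresses
  lg <- log(g)
  rss_of <- function(ty) {
    y <- tau - ty
    if (any(y <= 0)) return(Inf)
    fit <- stats::lm.fit(cbind(1, lg), log(y))
    # residuals of log-total-stress, not log-excess-stress
    pred <- ty + exp(fit$fitted.values)
    sum((log(pred) - log(tau))^2)
  }
  upper <- min(tau) * (1 - 1e-9)
  opt <- stats::optimize(rss_of, c(0, upper), tol = upper * 1e-9 + 1e-12)
  # compare against the tau_y = 0 boundary (power-law fluid)
  ty <- if (rss_of(0) <= opt$objective) 0 else opt$minimum
  fit <- stats::lm.fit(cbind(1, lg), log(tau - ty))
  K <- exp(fit$coefficients[[1]]); n <- fit$coefficients[[2]]
  pred <- ty + K * g^n
  rms <- sqrt(mean((log(pred) - log(tau))^2))
  converged <- is.finite(rms) && n > 0 && K > 0
  if (!converged) warning("flow-curve fit did not converge")
  structure(list(params = hb_params(max(ty, 0), K, max(n, 1e-6)),
                 residual_rms_log = rms, converged = converged,
                 curve = curve), class = "hb_fit")
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("Herschel-Bulkley flow-curve fit",
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(x$params)
  cat(sprintf("  RMS log-stress residual: %.3g\n", x$residual_rms_log))
  invisible(x)
}

#' @export
coef.hb_fit <- function(object, ...) {
  with(object$params, c(tau_y = tau_y, K = K, n = n))
}

#' @export
predict.hb_fit <- function(object, gamma_dot = object$curve$shear_rates, ...) {
  with(object$params, tau_y + K * gamma_dot^n)
}

#' Gel tearing trace
#'
#' Torque record of the two-pass gel tearing test: a nozzle is translated
#' twice along the same path with a rest gap, and the resisting torque of
#' each pass is logged.
#'
#' @param time s, common time base within a pass
#' @param torque_first,torque_second N m, >= 0
#' @param pass_gap s, rest time between passes
#' @return object of class \code{tearing_trace}
#' @export
tearing_trace <- function(time, torque_first, torque_second, pass_gap = 5) {
  if (!length(torque_first) || !length(torque_second)) stop("passes must be nonempty")
  if (any(torque_first < 0) || any(torque_second < 0)) stop("torque must be >= 0")
  if (length(time) != length(torque_first) || length(time) != length(torque_second))
    stop("length mismatch")
  structure(list(time = as.numeric(time), torque_first = as.numeric(torque_first),
                 torque_second = as.numeric(torque_second), pass_gap = pass_gap),
            class = "tearing_trace")
}

#' @rdname tearing_trace
#' @param trace \code{tearing_trace}
#' @param path file path; CSV columns \code{time_s}, \code{torque_Nm}, \code{pass}
#' @export
write_tearing_trace_csv <- function(trace, path) {
  df <- data.frame(
    time_s = c(trace$time, trace$time),
    torque_Nm = c(trace$torque_first, trace$torque_second),
    pass = rep(1:2, each = length(trace$time)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tearing_trace
#' @export
read_tearing_trace_csv <- function(path, pass_gap = 5) {
  df <- utils::read.csv(path)
  need <- c("time_s", "torque_Nm", "pass")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  p1 <- df[df$pass == 1, ]; p2 <- df[df$pass == 2, ]
  tearing_trace(p1$time_s, p1$torque_Nm, p2$torque_Nm, pass_gap = pass_gap)
}

#' Recovery percentage from a gel tearing trace
#'
#' Ratio of the steady-torque plateaus of the two passes,
#' \eqn{100 \times \bar T_2 / \bar T_1}, each plateau estimated as the
#' mean of the final half of the samples (robust to start-up transients).
#' A well-recovering gel resists the second pass as strongly as the first
#' (about 100 percent); a torn gel shows a much lower second-pass torque.
#'
#' @param trace \code{\link{tearing_trace}}
#' @param plateau_fraction final fraction of each pass used for the
#'   plateau mean (default 0.5)
#' @return recovery, percent, clamped to [0, 100 + 5]
#' @export
recovery_percent <- function(trace, plateau_fraction = 0.5) {
  stopifnot(inherits(trace, "tearing_trace"))
  n <- length(trace$time)
  idx <- seq.int(max(1L, n - ceiling(n * plateau_fraction) + 1L), n)
  p1 <- mean(trace$torque_first[idx]); p2 <- mean(trace$torque_second[idx])
  if (p1 <= 0 || p1 < 1e-12 * max(trace$torque_first, 1e-300))
    stop("first-pass plateau is ~0; recovery undefined")
  min(max(100 * p2 / p1, 0), 105)
}

#' Yield-capillary (plastocapillary) number
#'
#' \eqn{Y = \tau_y R / \sigma}: yield stress against the capillary stress
#' \eqn{\sigma/R} on a channel of radius R. When Y is large the gel's
#' yield stress can hold a non-spherical air body against surface
#' tension; when Y is small, surface tension wins and channels collapse
#' into bubbles.
#'
#' @param tau_y yield stress, Pa (> 0)
#' @param sigma surface tension, N/m (> 0)
#' @param R channel radius, m (> 0)
#' @return dimensionless Y > 0
#' @examples
#' yield_capillary_number(100, 0.025, 250e-6)  # 1
#' @export
yield_capillary_number <- function(tau_y, sigma, R) {
  if (any(tau_y <= 0) || any(sigma <= 0) || any(R <= 0))
    stop("all arguments must be positive")
  tau_y * R / sigma
}

#' Classify the printing regime of a material
#'
#' Three-way taxonomy driven by the gel-tearing recovery and the
#' yield-capillary number: poor recovery marks the tearing regime (M3);
#' otherwise a plastocapillary number above \code{Y_crit} marks
#' channel-stable M2 and below it bubble-forming M1.
#'
#' @param mat \code{\link{ap_material}}
#' @param R channel radius, m
#' @param recovery percent in [0, 100]
#' @param recovery_threshold percent below which the material is M3
#'   (default 80)
#' @param Y_crit plastocapillary stability threshold (default 0.1)
#' @return one of \code{"M1"}, \code{"M2"}, \code{"M3"}
#' @export
classify_regime <- function(mat, R, recovery, recovery_threshold = 80, Y_crit = 0.1) {
  stopifnot(inherits(mat, "ap_material"))
  if (recovery < 0 || recovery > 100) stop("recovery must be in [0, 100]")
  if (recovery < recovery_threshold) return("M3")
  Y <- if (mat$hb$tau_y > 0)
    yield_capillary_number(mat$hb$tau_y, mat$surface_tension_vs_air, R) else 0
  if (Y >= Y_crit) "M2" else "M1"
}
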