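#' Phase-field parameters
#'
#' Parameters of the conserved (Cahn-Hilliard) order parameter
#' \eqn{\phi \in [-1, 1]} tracking the air/gel interface. The mixing
#' energy density is calibrated to the physical surface tension by the
#' sharp-interface relation \eqn{\lambda = (3/\sqrt 8)\,\sigma\,
#' \epsilon_{pf}}, and the interface mobility is
#' \eqn{M = \chi\,\lambda/\epsilon_{pf}^2} with tuning parameter
#' \eqn{\chi} (m^3 s/kg).
#'
#' @param sigma surface tension, N/m (> 0)
#' @param eps_pf capillary width (interface thickness scale), m (> 0);
#'   resolve with at least 1.5 cells per \code{eps_pf}
#' @param chi_mob mobility tuning parameter, m^3 s/kg (> 0)
#' @return object of class \code{pf_params} with derived
#'   \code{lambda_mix} (N) and \code{mobility} (m^2/s)
#' @export
pf_params <- function(sigma, eps_pf, chi_mob = 1) {
  if (sigma <= 0 || eps_pf <= 0 || chi_mob <= 0)
    stop("sigma, eps_pf, chi_mob must be > 0")
  lambda <- 3 / sqrt(8) * sigma * eps_pf
  structure(list(sigma = sigma, eps_pf = eps_pf, chi_mob = chi_mob,
                 lambda_mix = lambda, mobility = chi_mob * lambda / eps_pf^2),
            class = "pf_params")
}

#' @export
print.pf_params <- function(x, ...) {
  cat(sprintf(
    "phase field: sigma = %g N/m, eps_pf = %g m, chi_mob = %g\n  lambda = %g N, mobility = %g m^2/s\n",
    x$sigma, x$eps_pf, x$chi_mob, x$lambda_mix, x$mobility))
  invisible(x)
}

#' Phase-field state
#'
#' Order parameter \eqn{\phi} on a grid, with time stamp. \eqn{\phi} is
#' never hard-clamped during evolution; a small overshoot (|phi| up to
#' 1.05) is tolerated and clamping applies only inside
#' \code{\link{volume_fractions}}.
#'
#' @param phi matrix \code{nx x ny}, dimensionless
#' @param grid \code{\link{grid_spec}}
#' @param time s
#' @return object of class \code{pf_state}
#' @export
pf_state <- function(phi, grid, time = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(phi) || nrow(phi) != grid$nx || ncol(phi) != grid$ny)
    stop("phi must be an nx x ny matrix")
  if (any(!is.finite(phi))) stop("phi must be finite")
  if (max(abs(phi)) > 1.05)
    warning("phi exceeds [-1.05, 1.05]; interface may be under-resolved")
  structure(list(phi = phi, grid = grid, time = time), class = "pf_state")
}

#' @export
print.pf_state <- function(x, ...) {
  cat(sprintf("phase field state at t = %g s, phi in [%.3f, %.3f], air fraction %.3f\n",
              x$time, min(x$phi), max(x$phi),
              mean(volume_fractions(x$phi)$f_air)))
  invisible(x)
}

#' Chemical potential of the Cahn-Hilliard double well
#'
#' \deqn{\psi = -\nabla\cdot(\epsilon_{pf}^2 \nabla\phi) +
#'       (\phi^2 - 1)\phi,}
#' the dimensionless chemical potential whose gradient drives interfacial
#' relaxation. Discretized spectrally (periodic) or in the cosine basis
#' (no-flux), both self-adjoint.
#'
#' @param phi matrix, order parameter
#' @param grid \code{\link{grid_spec}}
#' @param eps_pf capillary width, m
#' @return matrix \code{psi}
#' @export
chemical_potential <- function(phi, grid, eps_pf) {
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(phi) != grid$nx || ncol(phi) != grid$ny) stop("phi/grid mismatch")
  if (all(grid$bc == "periodic")) {
    kg <- .kgrid(grid$nx, grid$ny, grid$dx, grid$dy)
    lap <- .ifft2(-kg$K2 * .fft2(phi))
  } else {
    e <- .ext_even(phi)
    kg <- .kgrid(2 * grid$nx, 2 * grid$ny, grid$dx, grid$dy)
    lap <- .quadrant(.ifft2(-kg$K2 * .fft2(e)), grid$nx, grid$ny)
  }
  -eps_pf^2 * lap + (phi^2 - 1) * phi
}

#' Equilibrium (planar) interface profile
#'
#' Stationary 1D solution of the double-well chemical potential:
#' \eqn{\phi(x) = \tanh\!\big(x / (\sqrt 2\, \epsilon_{pf})\big)}, odd in
#' the signed distance x and approaching air (+1) / gel (-1) away from
#' the interface.
#'
#' @param x signed distance from the interface, m
#' @param eps_pf capillary width, m
#' @return phi value(s)
#' @export
equilibrium_profile <- function(x, eps_pf) tanh(x / (sqrt(2) * eps_pf))

#' Volume fractions of air and gel
#'
#' Within the diffuse interface the mixture volume fractions are
#' \eqn{(1 \pm \phi)/2}; \code{phi} is clamped to [-1, 1] first so the
#' two fractions are in [0, 1] and sum to one exactly.
#'
#' @param phi order parameter (any shape)
#' @return list with \code{f_air} and \code{f_gel}
#' @export
volume_fractions <- function(phi) {
  p <- pmin(pmax(phi, -1), 1)
  if (!is.null(dim(phi))) dim(p) <- dim(phi)
  list(f_air = (1 + p) / 2, f_gel = (1 - p) / 2)
}

#' Mixing free energy of a phase-field state
#'
#' \deqn{F = \int \frac{\lambda}{\epsilon_{pf}^2}\left[
#'   \frac{\epsilon_{pf}^2}{2}|\nabla\phi|^2 +
#'   \frac{(\phi^2-1)^2}{4}\right] dV,}
#' non-negative, zero only for uniform pure phases. For a relaxed planar
#' interface the energy per unit interface length tends to the surface
#' tension \eqn{\sigma}, which is what calibrates
#' \eqn{\lambda = (3/\sqrt 8)\sigma\epsilon_{pf}}.
#'
#' @param state \code{\link{pf_state}}
#' @param params \code{\link{pf_params}}
#' @return free energy, J per unit depth (2D)
#' @export
free_energy <- function(state, params) {
  stopifnot(inherits(state, "pf_state"), inherits(params, "pf_params"))
  g <- state$grid; phi <- state$phi
  if (all(g$bc == "periodic")) {
    kg <- .kgrid(g$nx, g$ny, g$dx, g$dy)
    gr <- .grad_spec(phi, kg)
    gx <- gr$gx; gy <- gr$gy
  } else {
    e <- .ext_even(phi)
    kg <- .kgrid(2 * g$nx, 2 * g$ny, g$dx, g$dy)
    gr <- .grad_spec(e, kg)
    gx <- .quadrant(gr$gx, g$nx, g$ny); gy <- .quadrant(gr$gy, g$nx, g$ny)
  }
  dens <- params$lambda_mix / params$eps_pf^2 *
    (params$eps_pf^2 / 2 * (gx^2 + gy^2) + (phi^2 - 1)^2 / 4)
  sum(dens) * g$dx * g$dy
}

#' Advance the Cahn-Hilliard equation one time step
#'
#' Semi-implicit (linearly stabilized) spectral step for
#' \deqn{\partial_t\phi + \nabla\cdot(u\,\phi) =
#'   \nabla\cdot\big(M \nabla\psi\big) + s_\phi,}
#' with \eqn{M = \chi\lambda/\epsilon_{pf}^2}. The biharmonic part is
#' implicit, the double-well nonlinearity explicit with stabilization
#' constant \code{stab} (Eyre-type splitting), so the stiff interfacial
#' terms impose no time-step restriction; only the advective CFL limit
#' applies and is enforced with an error naming the admissible dt. The
#' k = 0 mode is untouched by transport, so total \eqn{\sum\phi} is
#' conserved to machine precision up to explicit sources.
#'
#' @param state \code{\link{pf_state}}
#' @param velocity \code{NULL} (quiescent) or list with cell-centered
#'   matrices \code{uc}, \code{vc} (m/s); if the velocity field has
#'   nonzero divergence (injection), pass it as \code{div_source}
#' @param params \code{\link{pf_params}}
#' @param dt time step, s (> 0)
#' @param source optional matrix, explicit \eqn{\partial_t\phi} source
#'   (1/s), e.g. air injection at the nozzle tip
#' @param div_source optional matrix, local velocity divergence (1/s);
#'   the advective term is corrected by \eqn{+\phi\,\nabla\cdot u} so
#'   pure injection does not spuriously create or destroy \eqn{\phi}
#' @param stab stabilization constant (default 2)
#' @return updated \code{pf_state}
#' @export
cahn_hilliard_step <- function(state, velocity = NULL, params, dt,
                               source = NULL, div_source = NULL, stab = 2) {
  stopifnot(inherits(state, "pf_state"), inherits(params, "pf_params"))
  if (dt <= 0) stop("dt must be > 0")
  g <- state$grid; phi <- state$phi
  periodic <- all(g$bc == "periodic")
  if (!periodic && !is.null(velocity))
    stop("advected Cahn-Hilliard requires periodic boundaries")
  M <- params$mobility; eps2 <- params$eps_pf^2

  if (periodic) {
    kg <- .kgrid(g$nx, g$ny, g$dx, g$dy)
    rhs <- .fft2(phi)
    if (!is.null(velocity)) {
      umax <- max(abs(velocity$uc)); vmax <- max(abs(velocity$vc))
      dt_adm <- 0.5 / max(umax / g$dx + vmax / g$dy, 1e-300)
      if (dt > dt_adm)
        stop(sprintf("advective CFL violated: dt = %g > admissible %g s", dt, dt_adm))
      adv <- 1i * kg$KXd * .fft2(velocity$uc * phi) +
             1i * kg$KYd * .fft2(velocity$vc * phi)
      if (!is.null(div_source)) adv <- adv - .fft2(phi * div_source)
      rhs <- rhs - dt * adv
    }
    f_exp <- phi^3 - phi - stab * phi
    rhs <- rhs - dt * M * kg$K2 * .fft2(f_exp)
    if (!is.null(source)) rhs <- rhs + dt * .fft2(source)
    denom <- 1 + dt * M * (eps2 * kg$K2^2 + stab * kg$K2)
    phi_new <- .ifft2(rhs / denom)
  } else {
    e <- .ext_even(phi)
    kg <- .kgrid(2 * g$nx, 2 * g$ny, g$dx, g$dy)
    rhs <- .fft2(e)
    f_exp <- e^3 - e - stab * e
    rhs <- rhs - dt * M * kg$K2 * .fft2(f_exp)
    if (!is.null(source)) rhs <- rhs + dt * .fft2(.ext_even(source))
    denom <- 1 + dt * M * (eps2 * kg$K2^2 + stab * kg$K2)
    phi_new <- .quadrant(.ifft2(rhs / denom), g$nx, g$ny)
  }
  pf_state(phi_new, g, time = state$time + dt)
}

#' Default Cahn-Hilliard time step
#'
#' Accuracy-motivated step \eqn{dt = c\,\epsilon_{pf}^2 / M}: the inverse
#' of the fastest linear growth rate of the spinodal spectrum is
#' \eqn{4\epsilon_{pf}^2/M}, and \code{c = 0.2} resolves it comfortably.
#' The scheme itself is stable for larger steps; this default preserves
#' the fidelity of interface relaxation.
#'
#' @param params \code{\link{pf_params}}
#' @param c safety factor
#' @return dt, s
#' @export
ch_default_dt <- function(params, c = 0.2) {
  c * params$eps_pf^2 / params$mobility
}

#' Total air area (2D volume per unit depth) of a phase field
#' @param state \code{\link{pf_state}} (or a phi matrix plus grid)
#' @param grid required when \code{state} is a bare matrix
#' @return air area, m^2
#' @export
air_volume <- function(state, grid = NULL) {
  if (inherits(state, "pf_state")) { phi <- state$phi; grid <- state$grid }
  else phi <- state
  sum(volume_fractions(phi)$f_air) * grid$dx * grid$dy
}
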