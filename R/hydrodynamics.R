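#' Fluid properties of the air/gel pair
#'
#' @param rho_air air density, kg/m^3
#' @param mu_air air dynamic viscosity, Pa s
#' @param rho_gel gel density, kg/m^3
#' @param gel_hb \code{\link{hb_params}} of the gel
#' @return object of class \code{fluid_properties}
#' @export
fluid_properties <- function(rho_air = 1.2, mu_air = 1.8e-5, rho_gel = 1000,
                             gel_hb = hb_params(100, 20, 0.4)) {
  stopifnot(inherits(gel_hb, "hb_params"))
  if (rho_air <= 0 || mu_air <= 0 || rho_gel <= 0) stop("properties must be positive")
  mu_gel0 <- effective_viscosity(0, gel_hb)
  if (mu_air > 0.01 * mu_gel0)
    warning("mu_air is not small compared to the gel zero-shear viscosity")
  structure(list(rho_air = rho_air, mu_air = mu_air, rho_gel = rho_gel,
                 gel_hb = gel_hb), class = "fluid_properties")
}

#' Flow state on a staggered (MAC) grid
#'
#' \code{u[i, j]} lives on the left x-face of cell (i, j), \code{v[i, j]}
#' on the bottom y-face, \code{p[i, j]} at the cell center; all arrays
#' are \code{nx x ny} with periodic wrap.
#'
#' @param u,v face velocities, m/s
#' @param p pressure, Pa
#' @param grid \code{\link{grid_spec}}
#' @param time s
#' @return object of class \code{flow_state}
#' @export
flow_state <- function(u = NULL, v = NULL, p = NULL, grid, time = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  z <- function(m) if (is.null(m)) matrix(0, grid$nx, grid$ny) else m
  u <- z(u); v <- z(v); p <- z(p)
  if (any(dim(u) != c(grid$nx, grid$ny)) || any(dim(v) != c(grid$nx, grid$ny)) ||
      any(dim(p) != c(grid$nx, grid$ny))) stop("field/grid mismatch")
  if (any(!is.finite(u)) || any(!is.finite(v)) || any(!is.finite(p)))
    stop("fields must be finite")
  structure(list(u = u, v = v, p = p, grid = grid, time = time),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("flow state at t = %g s, max|u| = %.3g m/s, max|div| = %.3g 1/s\n",
              x$time, max(abs(x$u), abs(x$v)), max(abs(divergence(x)))))
  invisible(x)
}

# periodic shift helpers: ip = index + 1 with wrap, im = index - 1
.shift <- function(m, di = 0, dj = 0) {
  nx <- nrow(m); ny <- ncol(m)
  i <- ((seq_len(nx) - 1 + di) %% nx) + 1
  j <- ((seq_len(ny) - 1 + dj) %% ny) + 1
  m[i, j, drop = FALSE]
}

#' Discrete divergence of a MAC flow state
#' @param flow \code{\link{flow_state}}
#' @return matrix (1/s) at cell centers
#' @export
divergence <- function(flow) {
  g <- flow$grid
  (.shift(flow$u, 1) - flow$u) / g$dx + (.shift(flow$v, 0, 1) - flow$v) / g$dy
}

#' Shear-rate magnitude of a flow field
#'
#' \eqn{\dot\gamma = \sqrt{2\,D:D}} with D the rate-of-strain tensor,
#' evaluated at cell centers (corner-averaged cross terms). Zero for
#' rigid translation; equal to the imposed rate for simple shear.
#'
#' @param flow \code{\link{flow_state}}
#' @return matrix, 1/s, >= 0
#' @export
shear_rate_magnitude <- function(flow) {
  g <- flow$grid
  ux <- (.shift(flow$u, 1) - flow$u) / g$dx            # centers
  vy <- (.shift(flow$v, 0, 1) - flow$v) / g$dy
  uy_c <- (flow$u - .shift(flow$u, 0, -1)) / g$dy      # corners (i, j)
  vx_c <- (flow$v - .shift(flow$v, -1)) / g$dx
  s_c <- uy_c + vx_c
  # average the squared corner term to centers (corners i,j / i+1,j / i,j+1 / i+1,j+1)
  s2 <- (s_c^2 + .shift(s_c, 1)^2 + .shift(s_c, 0, 1)^2 + .shift(s_c, 1, 1)^2) / 4
  sqrt(2 * ux^2 + 2 * vy^2 + s2)
}

#' Mixture viscosity field
#'
#' Arithmetic volume-fraction blend of air and (regularized
#' Herschel-Bulkley) gel viscosity:
#' \eqn{\mu = f_{air}\mu_{air} + f_{gel}\,\mu_{HB}(\dot\gamma)}.
#'
#' @param phi order parameter matrix
#' @param gamma_dot shear-rate magnitude matrix, 1/s
#' @param props \code{\link{fluid_properties}}
#' @return viscosity matrix, Pa s
#' @export
mixture_viscosity <- function(phi, gamma_dot, props) {
  stopifnot(inherits(props, "fluid_properties"))
  f <- volume_fractions(phi)
  f$f_air * props$mu_air + f$f_gel * effective_viscosity(gamma_dot, props$gel_hb)
}

#' Phase-field surface-tension body force
#'
#' Potential-form continuum surface force \eqn{f = G\,\nabla\phi} with
#' \eqn{G = (\lambda/\epsilon_{pf}^2)\,\psi}, localized at the diffuse
#' interface and vanishing in the bulk phases. Returned on the staggered
#' faces so the force and the pressure gradient are discretely balanced
#' (small spurious currents).
#'
#' @param state \code{\link{pf_state}} (periodic grid)
#' @param params \code{\link{pf_params}}
#' @return list of face matrices \code{fx}, \code{fy} (N/m^3)
#' @export
surface_tension_force <- function(state, params) {
  stopifnot(inherits(state, "pf_state"), inherits(params, "pf_params"))
  g <- state$grid
  psi <- chemical_potential(state$phi, g, params$eps_pf)
  G <- params$lambda_mix / params$eps_pf^2 * psi
  phi <- state$phi
  fx <- 0.5 * (G + .shift(G, -1)) * (phi - .shift(phi, -1)) / g$dx
  fy <- 0.5 * (G + .shift(G, 0, -1)) * (phi - .shift(phi, 0, -1)) / g$dy
  list(fx = fx, fy = fy)
}

#' Nozzle model
#'
#' A moving rigid nozzle realized as a Brinkman-penalized disc mask plus
#' an air source in a tip disc behind the direction of motion (the bent
#' nozzle exudes air opposite to its travel). The dispense speed is
#' \eqn{Q / (\pi d^2/4)}; in the 2D planar sections the injected
#' area rate is \code{dispense speed * d} unless overridden.
#'
#' @param diameter nozzle diameter, m (> 0)
#' @param position numeric(2), m
#' @param velocity numeric(2), m/s
#' @param air_flow_rate Q, m^3/s (>= 0; negative aspirates)
#' @param shape one of "bent-horizontal-segment", "ball", "straight"
#' @param ball_diameter m, ball nozzles only
#' @param penalization_strength 1/s; velocity inside the mask is driven
#'   to the nozzle velocity at this (implicitly treated) rate
#' @param area_rate_2d optional override of the 2D injected area rate,
#'   m^2/s
#' @return object of class \code{nozzle_model} with derived
#'   \code{dispense_speed}
#' @export
nozzle_model <- function(diameter, position, velocity = c(0, 0),
                         air_flow_rate = 0, shape = "bent-horizontal-segment",
                         ball_diameter = NULL, penalization_strength = 1e5,
                         area_rate_2d = NULL) {
  shape <- match.arg(shape, c("bent-horizontal-segment", "ball", "straight"))
  if (diameter <= 0) stop("diameter must be > 0")
  if (penalization_strength <= 0) stop("penalization_strength must be > 0")
  dispense <- air_flow_rate / (pi * diameter^2 / 4)
  if (is.null(area_rate_2d)) area_rate_2d <- dispense * diameter
  structure(list(shape = shape, diameter = diameter,
                 ball_diameter = ball_diameter, position = position,
                 velocity = velocity, air_flow_rate = air_flow_rate,
                 penalization_strength = penalization_strength,
                 dispense_speed = dispense, area_rate_2d = area_rate_2d),
            class = "nozzle_model")
}

#' Nozzle forcing fields
#'
#' Builds the Brinkman mask on the staggered faces, the phase-field
#' injection source (rate of \eqn{\partial_t\phi}) and the matching
#' velocity-divergence source for a nozzle on a periodic grid. Injection
#' is weighted toward gel-occupied cells of the tip disc so \eqn{\phi}
#' stays bounded; total injected air area rate equals
#' \code{nozzle$area_rate_2d} exactly. Aspiration (negative rate)
#' weights air-occupied cells instead.
#'
#' @param nozzle \code{\link{nozzle_model}}
#' @param grid \code{\link{grid_spec}}
#' @param phi current order parameter (for source weighting)
#' @return list: \code{mask_u}, \code{mask_v} (0/1 face masks),
#'   \code{mask_c} (center mask), \code{src_phi} (1/s),
#'   \code{src_div} (1/s)
#' @export
nozzle_forcing <- function(nozzle, grid, phi) {
  stopifnot(inherits(nozzle, "nozzle_model"), inherits(grid, "grid_spec"))
  pos <- nozzle$position
  if (pos[1] < 0 || pos[1] > grid$Lx || pos[2] < 0 || pos[2] > grid$Ly)
    stop("nozzle left the domain at position (",
         pos[1], ", ", pos[2], ") m")
  r <- nozzle$diameter / 2
  if (nozzle$shape == "ball" && !is.null(nozzle$ball_diameter))
    r <- nozzle$ball_diameter / 2
  # periodic squared distance from (x0, y0) to arbitrary points
  pdist2 <- function(px, py, x0, y0) {
    dxp <- abs(px - x0); dxp <- pmin(dxp, grid$Lx - dxp)
    dyp <- abs(py - y0); dyp <- pmin(dyp, grid$Ly - dyp)
    outer(dxp^2, dyp^2, "+")
  }
  cc <- grid_centers(grid)
  xf <- (seq_len(grid$nx) - 1) * grid$dx   # u-face x
  yf <- (seq_len(grid$ny) - 1) * grid$dy   # v-face y
  if (nozzle$shape == "straight") {
    # a straight (vertical) nozzle seen in the 2D section: injection only,
    # no in-plane solid body
    mask_c <- mask_u <- mask_v <- matrix(FALSE, grid$nx, grid$ny)
  } else {
    mask_c <- pdist2(cc$x, cc$y, pos[1], pos[2]) <= r^2
    mask_u <- pdist2(xf, cc$y, pos[1], pos[2]) <= r^2
    mask_v <- pdist2(cc$x, yf, pos[1], pos[2]) <= r^2
  }
  storage.mode(mask_c) <- storage.mode(mask_u) <- storage.mode(mask_v) <- "double"

  src_phi <- src_div <- matrix(0, grid$nx, grid$ny)
  A <- nozzle$area_rate_2d
  if (A != 0) {
    sp <- sqrt(sum(nozzle$velocity^2))
    dir <- if (sp > 0) nozzle$velocity / sp else c(-1, 0)
    r_src <- nozzle$diameter / 2
    # source sits in the wake void just behind the mask (the bent nozzle's
    # orifice); an isotropic kernel weighted toward the receiving phase: as
    # the deposit saturates (phi -> +1) the weight migrates to its rim, so
    # air inflates the deposit without driving phi past its bounds. The
    # morphology (trail vs. blob) is decided by the bath rheology, not by
    # the source shape.
    sig_k <- max(4 * max(grid$dx, grid$dy), r_src / 3)
    ctr <- if (nozzle$shape == "straight") pos
           else pos - dir * (r + sig_k)
    ctr[1] <- ctr[1] %% grid$Lx; ctr[2] <- ctr[2] %% grid$Ly
    kern <- exp(-0.5 * pdist2(cc$x, cc$y, ctr[1], ctr[2]) / sig_k^2)
    w <- if (A > 0) pmax(1 - phi, 0) else pmax(1 + phi, 0)
    w <- w * kern
    if (sum(w) < 1e-12) w <- kern
    dA <- grid$dx * grid$dy
    wsum <- sum(w) * dA
    src_phi <- 2 * A * w / wsum
    src_div <- A * w / wsum
  }
  list(mask_u = mask_u, mask_v = mask_v, mask_c = mask_c,
       src_phi = src_phi, src_div = src_div)
}

#' Transverse capillary pressure (quasi-3D closure)
#'
#' A strictly planar 2D model misses the out-of-plane curvature of a
#' printed feature: a straight channel has flat walls in the plane, so
#' nothing drives the varicose (Plateau-Rayleigh) dynamics that decide
#' bubble versus channel in three dimensions. Treating the deposit as
#' locally an x-aligned cylinder whose cross-section radius is its local
#' half-width h(x), the air carries the extra capillary pressure
#' \eqn{\sigma/h(x)}; narrow necks are pressurized above wide bulges, so
#' air drains from necks unless the bath's yield stress resists — the
#' plastocapillary competition \eqn{\tau_y} vs \eqn{\sigma/h}.
#'
#' @param phi order parameter matrix
#' @param grid \code{\link{grid_spec}}
#' @param sigma surface tension, N/m
#' @return pressure field matrix (Pa), tapered by the air fraction
#' @export
transverse_capillary_pressure <- function(phi, grid, sigma) {
  f_air <- (1 + pmin(pmax(phi, -1), 1)) / 2
  w <- .rowSums(f_air, grid$nx, grid$ny) * grid$dy   # air width per x-station
  h <- pmax(w / 2, grid$dx)                          # cap the neck blow-up
  pt <- ifelse(w > 0.1 * grid$dy, sigma / h, 0)
  # mild smoothing along x to avoid jagged forcing at body ends
  pts <- (c(pt[grid$nx], pt[-grid$nx]) + 2 * pt + c(pt[-1], pt[1])) / 4
  matrix(pts, grid$nx, grid$ny) * f_air
}

#' Flow-solver control settings
#'
#' @param stokes drop the inertial advection term (creeping-flow default)
#' @param mu_floor numeric viscosity floor applied inside the momentum
#'   solve, Pa s; raising the air viscosity numerically tames spurious
#'   currents without affecting the gel side
#' @param refactor_every rebuild the viscous operator (and its Cholesky
#'   factor) every this many steps; between rebuilds the viscosity field
#'   is Picard-lagged
#' @param gravity numeric(2), m/s^2 (off by default; the printed bodies
#'   are drag-stabilized)
#' @param div_tol relative divergence tolerance asserted after projection
#' @param transverse_capillarity include the quasi-3D out-of-plane
#'   capillary pressure of \code{\link{transverse_capillary_pressure}}
#'   (used by the planar printing scenarios; off for transverse-slice
#'   and purely 2D studies)
#' @param zero_mean_flow remove the k = 0 (mean) velocity mode after each
#'   projection: the zero-total-flux gauge representing a bath anchored
#'   by distant walls, without which a net nozzle force would accelerate
#'   the whole periodic box
#' @param injection_flow when TRUE, air injection also drives an explicit
#'   displacement (divergence) flow at the source, balanced by a uniform
#'   compensation on the closed box; by default injection is a pure
#'   conversion source and the flow stays strictly divergence-free,
#'   which keeps the air bookkeeping exact
#' @return list of class \code{flow_control}
#' @export
flow_control <- function(stokes = TRUE, mu_floor = 0, refactor_every = 1,
                         gravity = c(0, 0), div_tol = 1e-8,
                         injection_flow = FALSE, zero_mean_flow = TRUE,
                         transverse_capillarity = FALSE) {
  structure(list(stokes = stokes, mu_floor = mu_floor,
                 refactor_every = as.integer(refactor_every),
                 gravity = gravity, div_tol = div_tol,
                 injection_flow = injection_flow,
                 zero_mean_flow = zero_mean_flow,
                 transverse_capillarity = transverse_capillarity),
            class = "flow_control")
}

#' Create a reusable flow-solver cache
#'
#' Holds wavenumber tables, assembly index maps and Cholesky factors
#' between calls to \code{\link{flow_step}}. One cache per grid.
#' @param grid \code{\link{grid_spec}}
#' @return environment of class \code{flow_cache}
#' @export
new_flow_cache <- function(grid) {
  e <- new.env(parent = emptyenv())
  e$grid <- grid
  e$kg <- .kgrid(grid$nx, grid$ny, grid$dx, grid$dy)
  e$count <- 0L
  class(e) <- "flow_cache"
  e
}

# assemble the SPD viscous-implicit operator for one velocity component.
# diag_extra: rho/dt + rho*beta*mask on the component's faces.
# muW/muE: viscosity on the +-x neighbours of each face; muS/muN likewise in y.
.assemble_visc <- function(nx, ny, dx, dy, muW, muE, muS, muN, diag_extra) {
  n <- nx * ny
  idx <- matrix(seq_len(n), nx, ny)
  iE <- as.vector(.shift(idx, 1));  iW <- as.vector(.shift(idx, -1))
  iN <- as.vector(.shift(idx, 0, 1)); iS <- as.vector(.shift(idx, 0, -1))
  aE <- as.vector(muE) / dx^2; aW <- as.vector(muW) / dx^2
  aN <- as.vector(muN) / dy^2; aS <- as.vector(muS) / dy^2
  d <- as.vector(diag_extra) + aE + aW + aN + aS
  ii <- c(seq_len(n), seq_len(n), seq_len(n), seq_len(n), seq_len(n))
  jj <- c(seq_len(n), iE, iW, iN, iS)
  xx <- c(d, -aE, -aW, -aN, -aS)
  keep <- ii <= jj
  Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                       dims = c(n, n), symmetric = TRUE)
}

# corner viscosity (harmonic mean of the 4 adjacent cell centers)
.mu_corner <- function(mu) {
  s <- 1 / mu
  4 / (s + .shift(s, -1) + .shift(s, 0, -1) + .shift(s, -1, -1))
}

#' Advance the flow one time step
#'
#' Incremental pressure-correction projection step for incompressible
#' variable-viscosity flow on a periodic MAC grid:
#' component-wise implicit viscous solve
#' \eqn{(\rho/\Delta t + \rho\beta\chi - \nabla\cdot\mu\nabla)u^* = rhs}
#' (sparse Cholesky), then an FFT Poisson projection that renders the
#' discrete divergence equal to the prescribed injection source to
#' machine precision. Surface tension enters as the phase-field CSF
#' force; the nozzle as implicit Brinkman drag toward its velocity. The
#' steady states of the scheme satisfy the variable-viscosity Stokes
#' system exactly, so with a persistent cache the step doubles as a
#' relaxation iteration toward creeping flow.
#'
#' @param flow \code{\link{flow_state}}
#' @param phi_state \code{\link{pf_state}} sharing the grid
#' @param props \code{\link{fluid_properties}}
#' @param params \code{\link{pf_params}}
#' @param nozzle optional \code{\link{nozzle_model}}
#' @param dt time step, s
#' @param control \code{\link{flow_control}}
#' @param cache optional \code{\link{new_flow_cache}} environment; reuse
#'   it across steps to amortize factorization
#' @return updated \code{flow_state}; attribute \code{"diagnostics"}
#'   holds max divergence residual, the advective dt bound and the
#'   viscosity range
#' @export
flow_step <- function(flow, phi_state, props, params, nozzle = NULL, dt,
                      control = flow_control(), cache = NULL, forcing = NULL) {
  stopifnot(inherits(flow, "flow_state"), inherits(phi_state, "pf_state"),
            inherits(props, "fluid_properties"), inherits(params, "pf_params"))
  g <- flow$grid
  if (!all(g$bc == "periodic")) stop("flow solver requires periodic boundaries")
  if (dt <= 0) stop("dt must be > 0")
  if (is.null(cache)) cache <- new_flow_cache(g)
  rho <- props$rho_gel  # uniform solver density (creeping regime; see vignette)

  nf <- if (!is.null(forcing)) forcing
        else if (!is.null(nozzle)) nozzle_forcing(nozzle, g, phi_state$phi)
        else NULL

  refactor <- is.null(cache$chol_u) || cache$count %% control$refactor_every == 0L
  if (refactor) {
    gam <- shear_rate_magnitude(flow)
    mu <- mixture_viscosity(phi_state$phi, gam, props)
    mu <- pmax(mu, control$mu_floor)
    cache$mu <- mu
    muc <- .mu_corner(mu)
    beta_u <- if (is.null(nf)) 0 else nozzle$penalization_strength * nf$mask_u
    beta_v <- if (is.null(nf)) 0 else nozzle$penalization_strength * nf$mask_v
    de_u <- rho / dt + rho * beta_u
    de_v <- rho / dt + rho * beta_v
    # u faces: x-neighbours are cell centers i-1 (W) and i (E);
    #          y-neighbours are corners (i, j) (S) and (i, j+1) (N)
    Au <- .assemble_visc(g$nx, g$ny, g$dx, g$dy,
                         muW = .shift(mu, -1), muE = mu,
                         muS = muc, muN = .shift(muc, 0, 1),
                         diag_extra = de_u)
    Av <- .assemble_visc(g$nx, g$ny, g$dx, g$dy,
                         muW = muc, muE = .shift(muc, 1),
                         muS = .shift(mu, 0, -1), muN = mu,
                         diag_extra = de_v)
    if (is.null(cache$chol_u)) {
      cache$chol_u <- Matrix::Cholesky(Au, LDL = FALSE)
      cache$chol_v <- Matrix::Cholesky(Av, LDL = FALSE)
    } else {
      cache$chol_u <- Matrix::update(cache$chol_u, Au)
      cache$chol_v <- Matrix::update(cache$chol_v, Av)
    }
    cache$beta_u <- beta_u; cache$beta_v <- beta_v
  }
  cache$count <- cache$count + 1L

  fst <- surface_tension_force(phi_state, params)
  rhs_u <- rho / dt * flow$u + fst$fx + rho * control$gravity[1]
  rhs_v <- rho / dt * flow$v + fst$fy + rho * control$gravity[2]
  if (isTRUE(control$transverse_capillarity)) {
    pt <- transverse_capillary_pressure(phi_state$phi, g, params$sigma)
    rhs_u <- rhs_u - (pt - .shift(pt, -1)) / g$dx
    rhs_v <- rhs_v - (pt - .shift(pt, 0, -1)) / g$dy
  }
  if (!is.null(nf)) {
    rhs_u <- rhs_u + rho * cache$beta_u * nozzle$velocity[1]
    rhs_v <- rhs_v + rho * cache$beta_v * nozzle$velocity[2]
  }
  dt_adv <- Inf
  if (!control$stokes) {
    umax <- max(abs(flow$u)); vmax <- max(abs(flow$v))
    dt_adv <- 0.5 / max(umax / g$dx + vmax / g$dy, 1e-300)
    if (dt > dt_adv)
      stop(sprintf("advective CFL violated: dt = %g > admissible %g s", dt, dt_adv))
    adv <- .mac_advection(flow, g)
    rhs_u <- rhs_u - rho * adv$au
    rhs_v <- rhs_v - rho * adv$av
  }
  # lagged pressure gradient (incremental projection)
  rhs_u <- rhs_u - (flow$p - .shift(flow$p, -1)) / g$dx
  rhs_v <- rhs_v - (flow$p - .shift(flow$p, 0, -1)) / g$dy

  us <- matrix(as.numeric(Matrix::solve(cache$chol_u, as.vector(rhs_u))), g$nx, g$ny)
  vs <- matrix(as.numeric(Matrix::solve(cache$chol_v, as.vector(rhs_v))), g$nx, g$ny)

  # projection: div u is driven to zero (default) or to the injection
  # source when an explicit displacement flow is requested; on a closed
  # periodic box the source is balanced by a uniform compensation
  src <- if (is.null(nf) || !isTRUE(control$injection_flow)) 0
         else nf$src_div - mean(nf$src_div)
  div <- (.shift(us, 1) - us) / g$dx + (.shift(vs, 0, 1) - vs) / g$dy
  rhs_p <- rho / dt * (div - src)
  rp <- .fft2(rhs_p)
  dph <- rp / (-cache$kg$KH2)
  dph[1, 1] <- 0
  dp <- .ifft2(dph)
  un <- us - dt / rho * (dp - .shift(dp, -1)) / g$dx
  vn <- vs - dt / rho * (dp - .shift(dp, 0, -1)) / g$dy
  if (isTRUE(control$zero_mean_flow)) {
    # zero-total-flux gauge: a periodic box has no walls to anchor the
    # bath, so the net nozzle force would accelerate the k = 0 velocity
    # mode without bound; removing it models a bath held by distant walls
    un <- un - mean(un)
    vn <- vn - mean(vn)
  }
  pn <- flow$p + dp

  out <- flow_state(un, vn, pn, g, time = flow$time + dt)
  divres <- (.shift(un, 1) - un) / g$dx + (.shift(vn, 0, 1) - vn) / g$dy - src
  uscale <- max(max(abs(un)), max(abs(vn)), 1e-300)
  attr(out, "diagnostics") <- list(
    max_div_residual = max(abs(divres)),
    div_rel = max(abs(divres)) / (uscale / g$dx),
    dt_advective_bound = dt_adv,
    mu_range = range(cache$mu),
    refactored = refactor)
  out
}

# simple centered MAC advection terms (u.grad u) on faces
.mac_advection <- function(flow, g) {
  u <- flow$u; v <- flow$v
  # at u faces: du/dx centered with cell-centered u; du/dy with corner v
  uc <- 0.5 * (u + .shift(u, 1))                      # centers
  dudx_c <- (.shift(u, 1) - u) / g$dx                 # centers
  au1 <- 0.5 * (uc * dudx_c + .shift(uc * dudx_c, -1))
  v_at_u <- 0.25 * (v + .shift(v, -1) + .shift(v, 0, 1) + .shift(v, -1, 1))
  dudy <- (.shift(u, 0, 1) - .shift(u, 0, -1)) / (2 * g$dy)
  au <- au1 + v_at_u * dudy
  vc <- 0.5 * (v + .shift(v, 0, 1))
  dvdy_c <- (.shift(v, 0, 1) - v) / g$dy
  av1 <- 0.5 * (vc * dvdy_c + .shift(vc * dvdy_c, 0, -1))
  u_at_v <- 0.25 * (u + .shift(u, 0, -1) + .shift(u, 1, 0) + .shift(u, 1, -1))
  dvdx <- (.shift(v, 1) - .shift(v, -1)) / (2 * g$dx)
  av <- av1 + u_at_v * dvdx
  list(au = au, av = av)
}

#' Steady channel (Poiseuille) profile of a regularized HB fluid
#'
#' Solves \eqn{\frac{d}{dy}\big(\mu(|u'|)\,u'\big) = -G} between no-slip
#' walls at y = 0 and y = H by damped Picard iteration on a
#' finite-volume tridiagonal system. For a Bingham-like gel (n = 1) the
#' profile exhibits the classical central plug where the local stress
#' falls below the yield stress.
#'
#' @param hb \code{\link{hb_params}}
#' @param G driving pressure gradient (body force), Pa/m
#' @param H channel height, m
#' @param ny number of cells across
#' @param tol relative convergence tolerance
#' @param max_iter Picard iteration cap
#' @return list: \code{y} (cell centers), \code{u} (m/s), \code{mu}
#'   (face viscosities), \code{iterations}, \code{converged}
#' @export
channel_flow_profile <- function(hb, G, H, ny = 128, tol = 1e-9,
                                 max_iter = 400) {
  stopifnot(inherits(hb, "hb_params"))
  dy <- H / ny
  y <- (seq_len(ny) - 0.5) * dy
  u <- rep(0, ny)
  mu_f <- rep(effective_viscosity(abs(G) * H / (8 * hb$K) + 1e-12, hb), ny + 1)
  conv <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    # faces 1..ny+1 at y = 0, dy, ..., H; ghost no-slip via half-cell
    aS <- mu_f[1:ny] / dy^2
    aN <- mu_f[2:(ny + 1)] / dy^2
    # walls: face 1 and ny+1 connect to u = 0 at distance dy/2
    aS[1] <- 2 * mu_f[1] / dy^2
    aN[ny] <- 2 * mu_f[ny + 1] / dy^2
    diag_v <- aS + aN
    low <- -aS[-1]; up <- -aN[-ny]
    A <- Matrix::bandSparse(ny, k = c(-1, 0, 1),
                            diagonals = list(low, diag_v, up))
    unew <- as.numeric(Matrix::solve(A, rep(G, ny)))
    uprev <- u
    u <- 0.5 * u + 0.5 * unew
    rel <- max(abs(u - uprev)) / max(max(abs(u)), 1e-300)
    gdot_f <- abs(c(2 * u[1] / dy, diff(u) / dy, -2 * u[ny] / dy))
    mu_new <- effective_viscosity(gdot_f, hb)
    mu_f <- 0.5 * mu_f + 0.5 * mu_new
    if (rel < tol) { conv <- TRUE; break }
  }
  list(y = y, u = u, mu = mu_f, iterations = it, converged = conv)
}
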