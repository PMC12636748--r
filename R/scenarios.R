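#' Printability number
#'
#' Ratio of the air dispense speed \eqn{Q/(\pi d^2/4)} to the nozzle
#' translation speed. PN = 1 deposits air exactly as fast as the nozzle
#' advances; larger PN inflates wider channels.
#'
#' @param Q air flow rate, m^3/s (> 0)
#' @param nozzle_diameter m (> 0)
#' @param nozzle_speed m/s (> 0)
#' @return dimensionless PN > 0
#' @examples
#' printability_number(1.667e-8, 1e-3, 0.02122)  # ~1
#' @export
printability_number <- function(Q, nozzle_diameter, nozzle_speed) {
  if (any(Q <= 0) || any(nozzle_diameter <= 0) || any(nozzle_speed <= 0))
    stop("all arguments must be positive")
  (Q / (pi * nozzle_diameter^2 / 4)) / nozzle_speed
}

#' Theoretical channel diameter
#'
#' Volume conservation for a cylindrical channel inflated at flow rate Q
#' while the nozzle travels at speed v:
#' \eqn{\pi D^2/4 \cdot v = Q}, i.e. \eqn{D = \sqrt{4Q/(\pi v)}},
#' equivalently \eqn{D = d\sqrt{PN}}.
#'
#' @param Q air flow rate, m^3/s (> 0)
#' @param nozzle_speed m/s (> 0)
#' @return channel diameter D, m
#' @export
theoretical_channel_diameter <- function(Q, nozzle_speed) {
  if (any(Q <= 0) || any(nozzle_speed <= 0)) stop("all arguments must be positive")
  sqrt(4 * Q / (pi * nozzle_speed))
}

#' Channel stability criterion
#'
#' A printed channel of radius R survives when the plastocapillary
#' number \eqn{Y = \tau_y R/\sigma} exceeds \code{Y_crit}; otherwise
#' surface tension defeats the yield stress and the channel collapses
#' into bubbles.
#'
#' @param mat \code{\link{ap_material}}
#' @param R channel radius, m
#' @param Y_crit stability threshold (default 0.1)
#' @return \code{"stable-channel"} or \code{"collapses-to-bubbles"}
#' @export
channel_stability_criterion <- function(mat, R, Y_crit = 0.1) {
  stopifnot(inherits(mat, "ap_material"))
  if (mat$hb$tau_y <= 0) return("collapses-to-bubbles")
  Y <- yield_capillary_number(mat$hb$tau_y, mat$surface_tension_vs_air, R)
  if (Y >= Y_crit) "stable-channel" else "collapses-to-bubbles"
}

#' Define a virtual printing experiment
#'
#' Bundles material, nozzle kinematics, grid and numerical policy for
#' one embedded air-printing run. Defaults define the reference desk
#' scale: a 1 mm nozzle traversing a 20 x 10 nozzle-diameter periodic
#' domain at 20 mm/s with PN = 1, the channel resolved by ~13 cells.
#'
#' @param material \code{\link{ap_material}}
#' @param nozzle_diameter m
#' @param nozzle_speed m/s (> 0)
#' @param pn printability number (sets Q unless \code{Q} given)
#' @param Q air flow rate, m^3/s; overrides \code{pn}
#' @param nx,ny grid cells
#' @param domain_x domain length in x, m (y is scaled by ny/nx)
#' @param path_x numeric(2): start/end x of the measured path, m; the
#'   nozzle actually starts \code{lead_in} earlier so the deposition has
#'   reached its steady state when it enters the measured window
#' @param path_y nozzle path height, m
#' @param relax_time extra quiescent time after the pass, s
#' @param lead_in run-in distance before the measured path, m
#' @param injection_noise relative amplitude of the seeded AR(1)
#'   dispensing-rate fluctuation (correlation time: one nozzle passage);
#'   0.2 emulates a real air supply and seeds the capillary dynamics
#'   that break weak-bath deposits into bubbles
#' @param eps_factor capillary width in cells (eps_pf = eps_factor * dx)
#' @param chi_mob phase-field mobility tuning; \code{NULL} picks
#'   \eqn{\chi = v\,\epsilon_{pf}^3/\lambda} so interfacial relaxation
#'   keeps pace with advection (see vignette)
#' @param cfl advective CFL factor for the time step
#' @param mu_floor solver viscosity floor, Pa s
#' @param refactor_every viscous-operator refactorization cadence
#' @param seed integer; runs are deterministic, the seed is recorded and
#'   applied for any randomized initialization
#' @param record_every record the diagnostic series every this many steps
#' @return object of class \code{print_job}
#' @export
print_job <- function(material, nozzle_diameter = 1e-3, nozzle_speed = 0.02,
                      pn = 1, Q = NULL, nx = 256, ny = 128,
                      domain_x = 20 * nozzle_diameter,
                      path_x = NULL, path_y = NULL, relax_time = NULL,
                      lead_in = 4 * nozzle_diameter,
                      injection_noise = 0.2,
                      eps_factor = 2, chi_mob = NULL, cfl = 0.15,
                      mu_floor = 0.01, refactor_every = 4, seed = 1L,
                      record_every = 25) {
  stopifnot(inherits(material, "ap_material"))
  if (nozzle_speed <= 0) stop("nozzle_speed must be > 0")
  if (is.null(Q)) Q <- pn * nozzle_speed * pi * nozzle_diameter^2 / 4
  dx <- domain_x / nx
  grid <- grid_spec(nx, ny, dx)
  if (is.null(path_x)) path_x <- c(7, 17) * nozzle_diameter
  if (is.null(path_y)) path_y <- grid$Ly / 2
  if (min(path_x) - lead_in < 2 * nozzle_diameter ||
      max(path_x) > grid$Lx - 2 * nozzle_diameter)
    stop("path (with its lead-in) must keep a margin of >= 2 nozzle diameters")
  eps <- eps_factor * dx
  sig <- material$surface_tension_vs_air
  lambda <- 3 / sqrt(8) * sig * eps
  if (is.null(chi_mob)) chi_mob <- nozzle_speed * eps^3 / lambda
  params <- pf_params(sig, eps, chi_mob)
  dispense <- Q / (pi * nozzle_diameter^2 / 4)
  u_char <- max(nozzle_speed, dispense)
  dt <- cfl * dx / u_char
  if (is.null(relax_time)) relax_time <- 2 * nozzle_diameter / nozzle_speed
  structure(list(material = material, nozzle_diameter = nozzle_diameter,
                 nozzle_speed = nozzle_speed, Q = Q,
                 pn = printability_number(Q, nozzle_diameter, nozzle_speed),
                 grid = grid, params = params,
                 props = fluid_properties(gel_hb = material$hb,
                                          rho_gel = material$density),
                 path_x = path_x, path_y = path_y, relax_time = relax_time,
                 lead_in = lead_in, dt = dt,
                 injection_noise = injection_noise,
                 control = flow_control(mu_floor = mu_floor,
                                        refactor_every = refactor_every,
                                        injection_flow = TRUE,
                                        transverse_capillarity = TRUE),
                 seed = as.integer(seed), record_every = record_every),
            class = "print_job")
}

#' @export
print.print_job <- function(x, ...) {
  cat(sprintf(
    "print job: %s, d = %g mm, v = %g mm/s, Q = %.3g mL/min (PN = %.3g)\n",
    x$material$name, 1e3 * x$nozzle_diameter, 1e3 * x$nozzle_speed,
    x$Q * 6e7, x$pn))
  print(x$grid)
  invisible(x)
}

# width statistics of the largest body inside the measured path window:
# mean width, CV and coverage (filled fraction of the window)
.window_stats <- function(bodies, job) {
  if (!length(bodies))
    return(list(mean_width = NA_real_, cv = NA_real_, coverage = 0))
  b <- bodies[[1]]
  w <- b$diameter_profile
  xs <- seq(b$bbox[1], b$bbox[2], length.out = length(w))
  inside <- xs >= job$path_x[1] & xs <= job$path_x[2]
  if (!any(inside))
    return(list(mean_width = NA_real_, cv = NA_real_, coverage = 0))
  ww <- w[inside]
  dxp <- if (length(xs) > 1) xs[2] - xs[1] else job$grid$dx
  coverage <- sum(inside & w > 0) * dxp / (job$path_x[2] - job$path_x[1])
  list(mean_width = mean(ww), cv = stats::sd(ww) / mean(ww),
       coverage = min(coverage, 1))
}

# coupled phase-field / flow time stepping shared by all scenarios.
# nozzle_at: function(t) -> nozzle_model or NULL.
.run_coupled <- function(phi0, job, nsteps, nozzle_at, dt = job$dt,
                         record_every = job$record_every, cache = NULL) {
  g <- job$grid
  ps <- pf_state(phi0, g)
  fl <- flow_state(grid = g)
  if (is.null(cache)) cache <- new_flow_cache(g)
  rows <- list(); injected <- 0
  # dispensing noise: seeded AR(1) modulation of the air supply rate,
  # emulating the flow-rate fluctuations of a real dispenser; this seeds
  # the capillary (dripping / varicose) dynamics in weak baths while a
  # yield-stress bath simply freezes the ripples into a small width CV
  amp <- if (is.null(job$injection_noise)) 0 else job$injection_noise
  z <- 0
  for (k in seq_len(nsteps)) {
    t <- (k - 1) * dt
    noz <- nozzle_at(t)
    if (!is.null(noz) && amp > 0 && noz$area_rate_2d != 0) {
      tau_c <- noz$diameter / max(abs(noz$dispense_speed),
                                  sqrt(sum(noz$velocity^2)), 1e-12)
      rho_ar <- exp(-dt / tau_c)
      z <- rho_ar * z + sqrt(1 - rho_ar^2) * stats::rnorm(1)
      noz$area_rate_2d <- noz$area_rate_2d * max(0, 1 + amp * z)
    }
    nf <- if (!is.null(noz)) nozzle_forcing(noz, g, ps$phi) else NULL
    fl <- flow_step(fl, ps, job$props, job$params, nozzle = noz, dt = dt,
                    control = job$control, cache = cache, forcing = nf)
    uc <- list(uc = 0.5 * (fl$u + .shift(fl$u, 1)),
               vc = 0.5 * (fl$v + .shift(fl$v, 0, 1)))
    # Exact air bookkeeping: with the displacement flow on, the total-phi
    # budget gains sum(phi * div u) from the transport terms; that quantity
    # is computable before the step, so the conversion source is rescaled
    # each step to make the injected air area exactly area_rate * dt.
    src_phi <- NULL; div_src <- NULL
    if (!is.null(nf) && !is.null(noz) && noz$area_rate_2d != 0) {
      src_phi <- nf$src_phi
      if (isTRUE(job$control$injection_flow)) {
        div_src <- nf$src_div - mean(nf$src_div)
        corr <- sum(ps$phi * div_src) * g$dx * g$dy
        src_phi <- nf$src_phi *
          ((2 * noz$area_rate_2d - corr) / (2 * noz$area_rate_2d))
      }
    }
    # Velocity transients (mask edges, injection onset) can exceed the
    # nominal CFL; sub-step the explicit advection when they do.
    bound <- 0.5 / max(max(abs(uc$uc)) / g$dx + max(abs(uc$vc)) / g$dy, 1e-300)
    nsub <- max(1L, ceiling(dt / (0.8 * bound)))
    for (s in seq_len(nsub))
      ps <- cahn_hilliard_step(ps, uc, job$params, dt / nsub,
                               source = src_phi, div_source = div_src)
    if (!is.null(noz)) injected <- injected + noz$area_rate_2d * dt
    if (k %% record_every == 0 || k == nsteps) {
      rows[[length(rows) + 1]] <- data.frame(
        time_s = k * dt, air_area_m2 = air_volume(ps),
        injected_area_m2 = injected,
        max_speed_m_s = max(abs(fl$u), abs(fl$v)),
        max_div_residual = attr(fl, "diagnostics")$max_div_residual)
    }
  }
  list(phi_state = ps, flow = fl, series = do.call(rbind, rows),
       injected = injected, cache = cache)
}

#' Simulate a planar embedded air print
#'
#' Runs the coupled Cahn-Hilliard / variable-viscosity flow model for a
#' bent nozzle traversing the bath while exuding air behind it, then
#' lets the bath relax with the nozzle withdrawn. In low plastocapillary
#' materials (M1-like) the trailing air pinches into discrete bubbles;
#' in high-Y materials (M2-like) a uniform channel survives.
#'
#' @param job \code{\link{print_job}}
#' @return object of class \code{ap_sim}: final \code{phi_state},
#'   \code{flow}, extracted \code{bodies}, \code{metrics} data frame,
#'   diagnostic \code{series}, injected air area, and the job
#' @export
simulate_print <- function(job) {
  stopifnot(inherits(job, "print_job"))
  set.seed(job$seed)
  g <- job$grid
  d <- job$nozzle_diameter
  x_start <- job$path_x[1] - job$lead_in
  pass_T <- (job$path_x[2] - x_start) / job$nozzle_speed
  n_pass <- ceiling(pass_T / job$dt)
  n_relax <- ceiling(job$relax_time / job$dt)
  nozzle_at <- function(t) {
    if (t >= pass_T) return(NULL)
    nozzle_model(d, c(x_start + job$nozzle_speed * t, job$path_y),
                 velocity = c(job$nozzle_speed, 0), air_flow_rate = job$Q)
  }
  run <- .run_coupled(matrix(-1, g$nx, g$ny), job, n_pass + n_relax, nozzle_at)
  bodies <- extract_air_bodies(run$phi_state$phi, g)
  metrics <- body_metrics(bodies, time = run$phi_state$time)
  # channel quality judged inside the measured window
  win <- .window_stats(bodies, job)
  sweep_row <- data.frame(
    pn = job$pn, Q_m3_s = job$Q, nozzle_speed_m_s = job$nozzle_speed,
    body_count = length(bodies),
    channel_diameter_m = win$mean_width,
    uniformity_cv = win$cv,
    stable = length(bodies) == 1 && win$coverage >= 0.8 &&
      !is.na(win$cv) && win$cv <= 0.2)
  structure(list(job = job, phi_state = run$phi_state, flow = run$flow,
                 bodies = bodies, metrics = metrics, series = run$series,
                 injected = run$injected, sweep_row = sweep_row),
            class = "ap_sim")
}

#' @export
print.ap_sim <- function(x, ...) {
  cat(sprintf("air-print simulation (%s, PN = %.3g): %d air bod%s at t = %.3g s\n",
              x$job$material$name, x$job$pn, length(x$bodies),
              if (length(x$bodies) == 1) "y" else "ies", x$phi_state$time))
  if (nrow(x$sweep_row))
    cat(sprintf("  channel diameter %.3g mm, uniformity CV %.3g, stable: %s\n",
                1e3 * x$sweep_row$channel_diameter_m, x$sweep_row$uniformity_cv,
                x$sweep_row$stable))
  invisible(x)
}

#' Relax an initial air shape in a quiescent bath
#'
#' Evolves a given air configuration under surface tension and the
#' material's (regularized) yield-stress rheology with no nozzle,
#' recording shape metrics over time. Low plastocapillary shapes round
#' up toward discs; high-Y shapes arrest.
#'
#' @param phi0 initial order parameter matrix (use the \code{phi_*}
#'   initializers)
#' @param material \code{\link{ap_material}}
#' @param T total time, s
#' @param grid \code{\link{grid_spec}}
#' @param n_record number of metric snapshots
#' @param eps_factor,chi_mob,mu_floor,refactor_every,dt numerics; as in
#'   \code{\link{print_job}}, with \code{dt} defaulting to a capillary
#'   scale
#' @return data frame time series: time, circularity, major/minor axes,
#'   area of the largest body, body count
#' @export
run_relaxation <- function(phi0, material, T, grid, n_record = 10,
                           eps_factor = 2, chi_mob = NULL, mu_floor = 0.01,
                           refactor_every = 4, dt = NULL) {
  stopifnot(inherits(material, "ap_material"), inherits(grid, "grid_spec"))
  eps <- eps_factor * grid$dx
  sig <- material$surface_tension_vs_air
  lambda <- 3 / sqrt(8) * sig * eps
  # capillary velocity against the gel viscosity at the capillary shear rate
  mu_ref <- effective_viscosity(1, material$hb)
  u_cap <- sig / mu_ref
  if (is.null(chi_mob)) chi_mob <- max(u_cap, 1e-6) * eps^3 / lambda
  params <- pf_params(sig, eps, chi_mob)
  props <- fluid_properties(gel_hb = material$hb, rho_gel = material$density)
  if (is.null(dt)) dt <- 0.3 * grid$dx / max(u_cap, 1e-6)
  nsteps <- max(ceiling(T / dt), n_record)
  job <- structure(list(grid = grid, params = params, props = props, dt = dt,
                        control = flow_control(mu_floor = mu_floor,
                                               refactor_every = refactor_every),
                        record_every = max(1L, nsteps %/% n_record)),
                   class = "print_job")
  ps <- pf_state(phi0, grid)
  fl <- flow_state(grid = grid)
  cache <- new_flow_cache(grid)
  every <- max(1L, nsteps %/% n_record)
  rows <- list()
  measure <- function(ps) {
    b <- extract_air_bodies(ps$phi, grid)
    if (!length(b)) return(data.frame(time_s = ps$time, circularity = NA_real_,
                                      major_m = NA_real_, minor_m = NA_real_,
                                      area_m2 = 0, body_count = 0L))
    data.frame(time_s = ps$time, circularity = circularity(b[[1]]),
               major_m = b[[1]]$major_axis, minor_m = b[[1]]$minor_axis,
               area_m2 = b[[1]]$area, body_count = length(b))
  }
  rows[[1]] <- measure(ps)
  for (k in seq_len(nsteps)) {
    fl <- flow_step(fl, ps, props, params, dt = dt, control = job$control,
                    cache = cache)
    uc <- list(uc = 0.5 * (fl$u + .shift(fl$u, 1)),
               vc = 0.5 * (fl$v + .shift(fl$v, 0, 1)))
    ps <- cahn_hilliard_step(ps, uc, params, dt)
    if (k %% every == 0 || k == nsteps) rows[[length(rows) + 1]] <- measure(ps)
  }
  do.call(rbind, rows)
}

#' Printability-number sweep
#'
#' Runs the deposition-slice scenario over a set of printability
#' numbers: in the plane transverse to nozzle motion, the nozzle passage
#' deposits air area \eqn{Q/v} per unit path length, which inflates and
#' relaxes into a body whose measured diameter is compared with the
#' volume-conservation prediction \eqn{D = \sqrt{4Q/(\pi v)} = d\sqrt{PN}}.
#' PN can be varied through the flow rate (fixed speed) or through the
#' nozzle speed (fixed flow rate).
#'
#' @param pn_values printability numbers (>= 2 values, ascending)
#' @param material \code{\link{ap_material}}
#' @param nozzle_diameter m
#' @param nozzle_speed m/s (reference speed)
#' @param vary \code{"Q"} or \code{"v"}
#' @param nx slice grid cells per side
#' @param domain slice extent, m (default 8 nozzle diameters)
#' @param seed integer
#' @return \code{sweep_result}: data frame with PN, Q, v, measured and
#'   theoretical diameter, body count, uniformity proxy and stability
#' @export
run_pn_sweep <- function(pn_values, material, nozzle_diameter = 1e-3,
                         nozzle_speed = 0.02, vary = c("Q", "v"), nx = 192,
                         domain = 6 * nozzle_diameter, seed = 1L) {
  vary <- match.arg(vary)
  if (length(pn_values) < 2 || any(diff(pn_values) <= 0))
    stop("pn_values must be >= 2 ascending values")
  rows <- lapply(pn_values, function(pn) {
    if (vary == "Q") {
      v <- nozzle_speed
      Q <- pn * v * pi * nozzle_diameter^2 / 4
    } else {
      # fixed flow rate (PN = 1 at the reference speed), speed varied
      Q <- nozzle_speed * pi * nozzle_diameter^2 / 4
      v <- (Q / (pi * nozzle_diameter^2 / 4)) / pn
    }
    sl <- simulate_deposition_slice(material, nozzle_diameter, v, Q,
                                    nx = nx, domain = domain, seed = seed)
    D_th <- theoretical_channel_diameter(Q, v)
    data.frame(pn = pn, Q_m3_s = Q, nozzle_speed_m_s = v,
               diameter_m = sl$diameter, diameter_theory_m = D_th,
               rel_err = sl$diameter / D_th - 1,
               body_count = sl$body_count, circularity = sl$circularity,
               stable = sl$body_count == 1)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Deposition-slice simulation of channel inflation
#'
#' The 2D section transverse to the nozzle path: during the passage time
#' \eqn{d/v} air is injected at the section's deposition rate
#' \eqn{Q/d}, totalling the conserved per-length volume \eqn{Q/v};
#' the body then relaxes (or arrests) under surface tension and yield
#' stress. Returns the measured body diameter (mean of the principal
#' axes of the largest body) among shape diagnostics.
#'
#' @inheritParams run_pn_sweep
#' @param v nozzle speed, m/s
#' @param Q air flow rate, m^3/s
#' @param relax_factor relaxation time as a multiple of the passage time
#' @return list: \code{diameter} (m), \code{body_count},
#'   \code{circularity}, \code{area} (m^2), \code{phi_state}
#' @export
simulate_deposition_slice <- function(material, nozzle_diameter, v, Q,
                                      nx = 192, domain = 6 * nozzle_diameter,
                                      relax_factor = 2, seed = 1L) {
  stopifnot(inherits(material, "ap_material"))
  set.seed(seed)
  g <- grid_spec(nx, nx, domain / nx)
  d <- nozzle_diameter
  pass_T <- d / v
  rate <- Q / d                       # slice area rate during passage
  job <- print_job(material, nozzle_diameter = d, nozzle_speed = v, Q = Q,
                   nx = nx, ny = nx, domain_x = domain,
                   path_x = c(2 * d, domain - 2 * d), lead_in = 0,
                   seed = seed)
  # slice time step: resolve the injection inflow speed
  u_inj <- rate / d
  dt <- 0.2 * g$dx / max(u_inj, v, 1e-9)
  n_pass <- ceiling(pass_T / dt)
  n_relax <- ceiling(relax_factor * pass_T / dt)
  ctr <- c(g$Lx / 2, g$Ly / 2)
  nozzle_at <- function(t) {
    if (t >= pass_T) return(NULL)
    nozzle_model(d, ctr, velocity = c(0, 0), air_flow_rate = Q,
                 shape = "straight", area_rate_2d = rate)
  }
  job$grid <- g
  job$dt <- dt
  # in the transverse slice the in-plane curvature IS the channel's
  # cross-section curvature; no quasi-3D augmentation on top of it, and
  # the slice integrates the passage, so the supply is taken as smooth
  job$control$transverse_capillarity <- FALSE
  job$injection_noise <- 0
  run <- .run_coupled(matrix(-1, g$nx, g$ny), job, n_pass + n_relax, nozzle_at,
                      dt = dt, record_every = max(1L, (n_pass + n_relax) %/% 10))
  bodies <- extract_air_bodies(run$phi_state$phi, g)
  if (!length(bodies))
    return(list(diameter = NA_real_, body_count = 0L, circularity = NA_real_,
                area = 0, phi_state = run$phi_state, series = run$series))
  b <- bodies[[1]]
  list(diameter = (b$major_axis + b$minor_axis) / 2,
       body_count = length(bodies), circularity = circularity(b),
       area = b$area, phi_state = run$phi_state, series = run$series)
}

#' Neighbor-channel disturbance
#'
#' Pre-lays a straight air channel, translates a nozzle along a parallel
#' path at a given centerline gap (no injection), lets the bath relax
#' with the nozzle withdrawn, and reports the permanent deformation
#' ratio of the channel: minimum local width inside the disturbed window
#' over the mean width of the undisturbed far segments of the same
#' snapshot (self-controlled, so slow common-mode width drift cancels).
#'
#' @param material \code{\link{ap_material}}
#' @param gap centerline distance between channel and nozzle path, m
#' @param nozzle_diameter m
#' @param nozzle_speed m/s
#' @param channel_width pre-printed channel width, m
#' @param nx,ny grid
#' @param domain_x domain length, m
#' @param relax_factor post-pass relaxation time in viscous relaxation
#'   times (permanence check)
#' @param seed integer
#' @return list: \code{deformation_ratio}, \code{nominal_width},
#'   \code{min_width}, \code{transient_ratio} (minimum during the pass
#'   window, before relaxation), \code{phi_state}
#' @export
run_neighbor_disturbance <- function(material, gap, nozzle_diameter = 5e-4,
                                     nozzle_speed = 0.1,
                                     channel_width = 5e-4, nx = 256, ny = 128,
                                     domain_x = 16e-3, relax_factor = 5,
                                     seed = 1L) {
  stopifnot(inherits(material, "ap_material"))
  if (gap <= nozzle_diameter / 2)
    stop("gap <= nozzle radius: nozzle would collide with the channel")
  set.seed(seed)
  d <- nozzle_diameter
  job <- print_job(material, nozzle_diameter = d, nozzle_speed = nozzle_speed,
                   pn = 1, nx = nx, ny = ny, domain_x = domain_x,
                   path_x = c(0.3, 0.7) * domain_x, seed = seed)
  # this scenario isolates the mechanical nozzle-channel interaction: the
  # quasi-3D capillary term is disabled so the pre-laid channel is a
  # stationary baseline (its stability is the dichotomy scenario's job)
  job$control$transverse_capillarity <- FALSE
  job$control$refactor_every <- 6L   # slowly varying viscosity field
  job$injection_noise <- 0
  # the channel interface only ever moves at the squeeze-flow scale (a
  # few percent of the nozzle speed), and the fast flow near the mask
  # carries no interface; tying the mobility to the interface-transport
  # speed keeps Cahn-Hilliard diffusion from eroding the channel
  eps <- job$params$eps_pf
  lambda <- job$params$lambda_mix
  job$params <- pf_params(material$surface_tension_vs_air, eps,
                          chi_mob = 0.05 * nozzle_speed * eps^3 / lambda)
  g <- job$grid
  y0 <- 0.3 * g$Ly
  y_noz <- y0 + gap
  if (y_noz > g$Ly - 2 * d) stop("gap too large for the domain")
  # channel much longer than the pass window so its (slowly eroding) end
  # caps stay far from both the window and the far reference segments
  phi0 <- phi_stripe(g, y0, channel_width, job$params$eps_pf,
                     x_range = c(0.04, 0.96) * g$Lx)
  # equilibrate the channel briefly, then measure the nominal width
  pre <- .run_coupled(phi0, job, 40, function(t) NULL)
  pass_T <- diff(job$path_x) / nozzle_speed
  nozzle_at <- function(t) {
    if (t >= pass_T) return(NULL)
    nozzle_model(d, c(job$path_x[1] + nozzle_speed * t, y_noz),
                 velocity = c(nozzle_speed, 0), air_flow_rate = 0)
  }
  n_pass <- ceiling(pass_T / job$dt)
  # viscous relaxation time of the channel against capillary stress
  gdot_ref <- nozzle_speed / d
  t_visc <- channel_width * effective_viscosity(gdot_ref, material$hb) /
    material$surface_tension_vs_air
  n_relax <- ceiling(relax_factor * t_visc / job$dt)
  mid <- .run_coupled(pre$phi_state$phi, job, n_pass, nozzle_at,
                      cache = pre$cache)
  # self-controlled measurement: the constricted width inside the pass
  # window against the undisturbed far segments of the SAME snapshot,
  # so slow common-mode width drift of the whole channel cancels
  measure <- function(ps) {
    bodies <- extract_air_bodies(ps$phi, g)
    if (!length(bodies)) return(c(win = NA_real_, far = NA_real_))
    b <- bodies[[which.max(vapply(bodies, function(x) x$area, 0))]]
    w <- b$diameter_profile
    xs <- seq(b$bbox[1], b$bbox[2], length.out = length(w))
    win <- xs >= job$path_x[1] + 2 * d & xs <= job$path_x[2] - 2 * d
    ends <- 3 * channel_width
    far <- (xs > b$bbox[1] + ends & xs < job$path_x[1] - 2 * d) |
      (xs > job$path_x[2] + 2 * d & xs < b$bbox[2] - ends)
    if (!any(win) || !any(far))
      return(c(win = min(w), far = stats::median(w)))
    c(win = min(w[win]), far = stats::median(w[far]))
  }
  tr <- measure(mid$phi_state)
  # the nozzle is withdrawn: velocities are small, the advective limit is
  # far away, and the implicit solver allows a larger relaxation step
  dt_relax <- 3 * job$dt
  post <- .run_coupled(mid$phi_state$phi, job,
                       max(ceiling(n_relax / 3), 40),
                       function(t) NULL, dt = dt_relax, cache = mid$cache)
  fin <- measure(post$phi_state)
  list(deformation_ratio = unname(deformation_ratio(fin["win"], fin["far"])),
       transient_ratio = unname(deformation_ratio(tr["win"], tr["far"])),
       nominal_width = unname(fin["far"]), min_width = unname(fin["win"]),
       phi_state = post$phi_state, gap = gap)
}

# ---- phase-field shape initializers ----------------------------------------

#' Initial air shapes
#'
#' Diffuse (tanh-profiled) indicator fields for common initial
#' configurations: a disc, an axis-aligned rectangle and a horizontal
#' channel stripe with rounded ends.
#'
#' @param grid \code{\link{grid_spec}}
#' @param center numeric(2), m
#' @param R disc radius, m
#' @param eps_pf capillary width, m
#' @return phi matrix
#' @export
phi_disc <- function(grid, center, R, eps_pf) {
  cc <- grid_centers(grid)
  r <- sqrt(outer((cc$x - center[1])^2, (cc$y - center[2])^2, "+"))
  equilibrium_profile(R - r, eps_pf)
}

#' @rdname phi_disc
#' @param width,height rectangle extents, m
#' @export
phi_rect <- function(grid, center, width, height, eps_pf) {
  cc <- grid_centers(grid)
  ddx <- abs(outer(cc$x - center[1], rep(1, grid$ny))) - width / 2
  ddy <- abs(outer(rep(1, grid$nx), cc$y - center[2])) - height / 2
  # signed distance to the box boundary (negative inside)
  sd_out <- sqrt(pmax(ddx, 0)^2 + pmax(ddy, 0)^2)
  sd_in <- pmin(pmax(ddx, ddy), 0)
  equilibrium_profile(-(sd_out + sd_in), eps_pf)
}

#' @rdname phi_disc
#' @param y0 stripe centerline height, m
#' @param x_range numeric(2): stripe extent in x, m
#' @export
phi_stripe <- function(grid, y0, width, eps_pf, x_range = NULL) {
  if (is.null(x_range)) x_range <- c(0.1, 0.9) * grid$Lx
  cc <- grid_centers(grid)
  # capsule signed distance: segment from (x1, y0) to (x2, y0), radius w/2
  px <- pmin(pmax(cc$x, x_range[1]), x_range[2])
  dmat <- sqrt(outer((cc$x - px)^2, rep(1, grid$ny)) +
               outer(rep(1, grid$nx), (cc$y - y0)^2))
  equilibrium_profile(width / 2 - dmat, eps_pf)
}

#' Write simulation metrics and snapshots
#'
#' Metrics go to a deterministic CSV (fixed-format numbers, one row per
#' body); field snapshots to RDS (phi, u, v, p, time and the full
#' parameter set) with an optional plain-CSV dump of phi.
#'
#' @param sim \code{ap_sim}
#' @param dir output directory (created)
#' @param fields also dump phi as CSV
#' @return paths written, invisibly
#' @export
write_sim_outputs <- function(sim, dir, fields = FALSE) {
  stopifnot(inherits(sim, "ap_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, "metrics.csv")
  body_metrics(sim$bodies, mpath, time = sim$phi_state$time)
  spath <- file.path(dir, "series.csv")
  utils::write.csv(format(sim$series, digits = 12), spath, row.names = FALSE)
  rpath <- file.path(dir, "snapshot.rds")
  saveRDS(list(phi = sim$phi_state$phi, u = sim$flow$u, v = sim$flow$v,
               p = sim$flow$p, time = sim$phi_state$time, job = sim$job), rpath)
  paths <- c(mpath, spath, rpath)
  if (fields) {
    fpath <- file.path(dir, "phi.csv")
    utils::write.table(format(sim$phi_state$phi, digits = 8), fpath,
                       sep = ",", row.names = FALSE, col.names = FALSE)
    paths <- c(paths, fpath)
  }
  invisible(paths)
}
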