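#' Uniform Cartesian grid specification
#'
#' 2D cell-centered grid with per-axis boundary tag. Periodic boundaries
#' use spectral operators; \code{"no-flux"} boundaries are realized by an
#' even mirror extension (cosine basis), which imposes zero normal flux
#' of both the order parameter and the chemical potential.
#'
#' @param nx,ny number of cells (>= 16)
#' @param dx,dy cell size, m (> 0)
#' @param bc character(2), per-axis boundary tag, \code{"periodic"} or
#'   \code{"no-flux"}
#' @return object of class \code{grid_spec} with derived extents
#'   \code{Lx}, \code{Ly}
#' @export
grid_spec <- function(nx, ny, dx, dy = dx, bc = c("periodic", "periodic")) {
  if (nx < 16 || ny < 16) stop("nx, ny must be >= 16")
  if (dx <= 0 || dy <= 0) stop("dx, dy must be > 0")
  bc <- match.arg(bc, c("periodic", "no-flux"), several.ok = TRUE)
  if (length(bc) == 1) bc <- rep(bc, 2)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, dy = dy,
                 bc = bc, Lx = nx * dx, Ly = ny * dy), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid %d x %d, dx = %g m, dy = %g m, bc = [%s, %s]\n",
              x$nx, x$ny, x$dx, x$dy, x$bc[1], x$bc[2]))
  invisible(x)
}

#' Cell-center coordinates of a grid
#' @param grid \code{\link{grid_spec}}
#' @return list with vectors \code{x}, \code{y} (m)
#' @export
grid_centers <- function(grid) {
  list(x = (seq_len(grid$nx) - 0.5) * grid$dx,
       y = (seq_len(grid$ny) - 0.5) * grid$dy)
}

# ---- internal spectral helpers (periodic, cell-centered) --------------------

# angular wavenumber matrices and Laplacian symbols for an nx x ny grid
.kgrid <- function(nx, ny, dx, dy) {
  kx <- 2 * pi / (nx * dx) * c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1))
  ky <- 2 * pi / (ny * dy) * c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1))
  if (nx %% 2 == 0) kx[nx %/% 2 + 1] <- pi / dx  # Nyquist sign convention
  if (ny %% 2 == 0) ky[ny %/% 2 + 1] <- pi / dy
  KX <- matrix(kx, nx, ny)
  KY <- matrix(ky, nx, ny, byrow = TRUE)
  # first-derivative symbols: Nyquist mode zeroed (odd operator)
  kxd <- kx; kyd <- ky
  if (nx %% 2 == 0) kxd[nx %/% 2 + 1] <- 0
  if (ny %% 2 == 0) kyd[ny %/% 2 + 1] <- 0
  KXd <- matrix(kxd, nx, ny)
  KYd <- matrix(kyd, nx, ny, byrow = TRUE)
  # discrete (5-point) Laplacian symbol, used by the staggered projection
  LH <- (2 * cos(kx * dx) - 2) / dx^2
  LHy <- (2 * cos(ky * dy) - 2) / dy^2
  KH2 <- -(matrix(LH, nx, ny) + matrix(LHy, nx, ny, byrow = TRUE))  # >= 0
  list(KX = KX, KY = KY, KXd = KXd, KYd = KYd, K2 = KX^2 + KY^2, KH2 = KH2)
}

.fft2 <- function(x) stats::fft(x)
.ifft2 <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

# even (mirror) extension to 2nx x 2ny; restriction back to the quadrant
.ext_even <- function(phi) {
  nx <- nrow(phi); ny <- ncol(phi)
  e <- matrix(0, 2 * nx, 2 * ny)
  e[1:nx, 1:ny] <- phi
  e[(nx + 1):(2 * nx), 1:ny] <- phi[nx:1, ]
  e[, (ny + 1):(2 * ny)] <- e[, ny:1]
  e
}
.quadrant <- function(e, nx, ny) e[1:nx, 1:ny]

# spectral gradient of a periodic field
.grad_spec <- function(phi, kg) {
  ph <- .fft2(phi)
  list(gx = .ifft2(1i * kg$KXd * ph), gy = .ifft2(1i * kg$KYd * ph))
}
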