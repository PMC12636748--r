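#' Extract connected air bodies from a phase field
#'
#' Thresholds the order parameter (air where \eqn{\phi >} threshold),
#' labels 4-connected components (diagonal contact does not merge
#' near-touching bubbles) and measures each body: area, centroid,
#' principal axes, perimeter and a local-width (diameter) profile along
#' the major axis. Widths integrate the air volume fraction
#' \eqn{(1+\phi)/2} across the body, which locates the interface at the
#' \eqn{\phi = 0} level with subcell precision; binary masks (0/1
#' images) are handled by the same route after mapping to \eqn{\pm 1}.
#'
#' Bodies are returned in deterministic order: descending area, ties
#' broken by the lower centroid x.
#'
#' @param field matrix: order parameter in [-1, 1] or a binary 0/1 mask
#' @param grid \code{\link{grid_spec}}
#' @param threshold level defining the interface (default 0)
#' @return list of \code{air_body} objects (empty if no air)
#' @export
extract_air_bodies <- function(field, grid, threshold = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  binary <- all(field %in% c(0, 1))
  phi <- if (binary) 2 * field - 1 else field
  mask <- phi > threshold
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  cc <- grid_centers(grid)
  bodies <- lapply(seq_len(nlab), function(id) {
    phi_k <- phi
    phi_k[lab > 0 & lab != id] <- -1   # suppress sibling bodies only;
                                       # the body's own diffuse skirt counts
    .measure_body(lab == id, phi_k, grid, cc, id, threshold)
  })
  areas <- vapply(bodies, function(b) b$area, 0)
  cx <- vapply(bodies, function(b) b$centroid[1], 0)
  ord <- order(-areas, cx)
  bodies <- bodies[ord]
  for (k in seq_along(bodies)) bodies[[k]]$id <- k
  bodies
}

.measure_body <- function(bm, phi, grid, cc, id, threshold) {
  idx <- which(bm, arr.ind = TRUE)
  n <- nrow(idx)
  xs <- cc$x[idx[, 1]]; ys <- cc$y[idx[, 2]]
  dA <- grid$dx * grid$dy
  area <- n * dA
  ctr <- c(mean(xs), mean(ys))
  # second moments -> principal axes (full lengths, ellipse convention)
  mxx <- mean((xs - ctr[1])^2) + grid$dx^2 / 12
  myy <- mean((ys - ctr[2])^2) + grid$dy^2 / 12
  mxy <- mean((xs - ctr[1]) * (ys - ctr[2]))
  tr <- (mxx + myy) / 2; dd <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr + dd; l2 <- max(tr - dd, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  theta <- 0.5 * atan2(2 * mxy, mxx - myy)
  perim <- .body_perimeter(bm, phi, grid, threshold)
  prof <- .width_profile(bm, phi, grid, theta)
  structure(list(id = id, cell_count = n, area = area, volume = area * 1,
                 centroid = ctr,
                 bbox = c(min(xs) - grid$dx / 2, max(xs) + grid$dx / 2,
                          min(ys) - grid$dy / 2, max(ys) + grid$dy / 2),
                 major_axis = major, minor_axis = minor, orientation = theta,
                 perimeter = perim, diameter_profile = prof),
            class = "air_body")
}

#' @export
print.air_body <- function(x, ...) {
  cat(sprintf(
    "air body %d: area %.4g m^2, centroid (%.4g, %.4g) m,\n  axes %.4g x %.4g m, circularity %.3f, mean width %.4g m (%d cells)\n",
    x$id, x$area, x$centroid[1], x$centroid[2], x$major_axis, x$minor_axis,
    circularity(x), mean(x$diameter_profile), x$cell_count))
  invisible(x)
}

# perimeter: marching-squares contour length of the body's field at the
# interface level; binary bodies are smoothed first to tame the staircase
.body_perimeter <- function(bm, phi, grid, threshold) {
  f <- ifelse(bm, phi, -1)
  binaryish <- max(abs(abs(f[bm]) - 1)) < 1e-9
  if (binaryish) {
    f <- ifelse(bm, 1, -1)
    for (k in 1:2) {
      fx <- 0.25 * (.shift_z(f, -1) + 2 * f + .shift_z(f, 1))
      f <- 0.25 * (.shift_z(fx, 0, -1) + 2 * fx + .shift_z(fx, 0, 1))
    }
  }
  cc <- grid_centers(grid)
  cl <- grDevices::contourLines(cc$x, cc$y, f, levels = threshold)
  if (!length(cl)) return(4 * sqrt(sum(bm)) * sqrt(grid$dx * grid$dy))  # sub-cell body
  sum(vapply(cl, function(s) sum(sqrt(diff(s$x)^2 + diff(s$y)^2)), 0))
}

# zero-padded shift (non-periodic), for smoothing near edges
.shift_z <- function(m, di = 0, dj = 0) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(-1, nx, ny)
  si <- max(1, 1 - di):min(nx, nx - di)
  sj <- max(1, 1 - dj):min(ny, ny - dj)
  out[si + di, sj + dj] <- m[si, sj]
  out
}

# local width profile along the major axis: distance between the outer
# phi = 0 crossings of each cross-section, located by linear (subcell)
# interpolation. Crossing-based widths ignore any weak far-field phi
# drift, unlike volume-fraction integrals.
.width_profile <- function(bm, phi, grid, theta) {
  along_x <- abs(cos(theta)) >= cos(pi / 4)
  if (!along_x) { bm <- t(bm); phi <- t(phi) }
  h <- if (along_x) grid$dy else grid$dx
  n2 <- ncol(bm)
  cols <- which(apply(bm, 1, any))
  w <- vapply(cols, function(i) {
    j <- which(bm[i, ])
    j1 <- min(j); j2 <- max(j)
    lo <- j1 - 0.5; hi <- j2 + 0.5
    if (j1 > 1 && phi[i, j1 - 1] < phi[i, j1])
      lo <- j1 - phi[i, j1] / (phi[i, j1] - phi[i, j1 - 1])
    if (j2 < n2 && phi[i, j2 + 1] < phi[i, j2])
      hi <- j2 + phi[i, j2] / (phi[i, j2] - phi[i, j2 + 1])
    (hi - lo) * h
  }, 0)
  w[w > 0]
}

#' Aspect ratio
#'
#' Length over diameter of a channel (or any elongated body); e.g. a
#' 20 m serpentine channel of 500 um diameter has aspect ratio 4e4.
#'
#' @param length m (> 0)
#' @param diameter m (> 0)
#' @return dimensionless ratio
#' @examples
#' aspect_ratio(20, 500e-6)  # 40000
#' @export
aspect_ratio <- function(length, diameter) {
  if (any(length <= 0) || any(diameter <= 0)) stop("arguments must be > 0")
  length / diameter
}

#' Aspect ratio of an extracted air body
#' @param body \code{air_body}
#' @return major over minor principal axis length
#' @export
body_aspect_ratio <- function(body) {
  stopifnot(inherits(body, "air_body"))
  if (body$minor_axis <= 0) stop("degenerate body")
  body$major_axis / body$minor_axis
}

#' Circularity of an air body
#'
#' \eqn{4\pi A / P^2}: 1 for a perfect disc, \eqn{\pi/4} for a square,
#' smaller for elongated or ragged bodies.
#'
#' @param body \code{air_body}
#' @return dimensionless in (0, 1] up to discretization tolerance
#' @export
circularity <- function(body) {
  stopifnot(inherits(body, "air_body"))
  if (body$cell_count < 4) warning("circularity of a near-degenerate body")
  4 * pi * body$area / body$perimeter^2
}

#' Channel uniformity (coefficient of variation of local width)
#'
#' CV of the diameter profile of an elongated body, with half a mean
#' width trimmed from each end so the end caps do not inflate the
#' spread. Small CV means a uniform channel; beads-on-string morphology
#' raises it.
#'
#' @param body \code{air_body} with aspect ratio >= 2
#' @return CV >= 0
#' @export
channel_uniformity <- function(body) {
  stopifnot(inherits(body, "air_body"))
  if (body_aspect_ratio(body) < 2) stop("body is not elongated (aspect < 2)")
  w <- body$diameter_profile
  if (length(w) < 8) stop("body too short for a width profile")
  ntrim <- ceiling(0.5 * mean(w) / (body$major_axis / length(w)))
  ntrim <- min(ntrim, (length(w) - 4) %/% 2)
  if (ntrim > 0) w <- w[(1 + ntrim):(length(w) - ntrim)]
  stats::sd(w) / mean(w)
}

#' Deformation ratio of a disturbed channel
#'
#' Constricted over nominal diameter; 1 for an unperturbed channel,
#' approaching 0 for a full pinch.
#'
#' @param diameter_constricted m (> 0)
#' @param diameter_nominal m (> 0)
#' @return dimensionless ratio
#' @export
deformation_ratio <- function(diameter_constricted, diameter_nominal) {
  if (any(diameter_constricted <= 0) || any(diameter_nominal <= 0))
    stop("diameters must be > 0")
  diameter_constricted / diameter_nominal
}

#' Write body metrics to CSV
#'
#' One row per body: id, cell count, area, centroid, axes, perimeter,
#' circularity, mean/min width, uniformity where defined.
#' @param bodies list of \code{air_body}
#' @param path file; when missing, the data frame is returned only
#' @param time snapshot time stamp, s
#' @return data frame (invisibly when written)
#' @export
body_metrics <- function(bodies, path = NULL, time = NA_real_) {
  df <- do.call(rbind, lapply(bodies, function(b) {
    cv <- tryCatch(channel_uniformity(b), error = function(e) NA_real_)
    data.frame(time_s = time, id = b$id, cell_count = b$cell_count,
               area_m2 = b$area, centroid_x_m = b$centroid[1],
               centroid_y_m = b$centroid[2], major_axis_m = b$major_axis,
               minor_axis_m = b$minor_axis, perimeter_m = b$perimeter,
               circularity = circularity(b),
               mean_width_m = mean(b$diameter_profile),
               min_width_m = min(b$diameter_profile),
               uniformity_cv = cv)
  }))
  if (is.null(df)) df <- data.frame()
  if (!is.null(path)) {
    utils::write.csv(format(df, digits = 12), path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
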