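# Low-level 3D array numerics used by the thickness solvers.
# All functions operate on plain 3D double arrays; voxel coordinates are
# 0-based (i.e. voxel [1,1,1] in R has coordinate (0,0,0)), matching the
# NIfTI affine convention.

#' Shift a 3D array by an integer offset
#'
#' Returns an array of the same shape where element `x` holds the value of
#' `a` at `x - offset`. Out-of-range positions are filled with `fill`
#' (`"zero"`) or with the nearest edge value (`"edge"`).
#'
#' @param a 3D array.
#' @param offset integer vector of length 3.
#' @param fill `"zero"` or `"edge"`.
#' @return shifted 3D array.
#' @keywords internal
#' @noRd
shift3d <- function(a, offset, fill = c("zero", "edge")) {
  fill <- match.arg(fill)
  d <- dim(a)
  idx <- vector("list", 3L)
  for (ax in 1:3) {
    src <- seq_len(d[ax]) - offset[ax]
    if (fill == "edge") {
      src <- pmin(pmax(src, 1L), d[ax])
    }
    idx[[ax]] <- src
  }
  if (fill == "edge") {
    return(a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  out <- array(0, dim = d)
  keep <- lapply(1:3, function(ax) which(idx[[ax]] >= 1L & idx[[ax]] <= d[ax]))
  if (any(vapply(keep, length, 1L) == 0L)) return(out)
  out[keep[[1]], keep[[2]], keep[[3]]] <-
    a[idx[[1]][keep[[1]]], idx[[2]][keep[[2]]], idx[[3]][keep[[3]]], drop = FALSE]
  out
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Truncated at 3 sigma; kernel normalised to unit sum. Values beyond the
#' array border are treated as zero, which is appropriate for the indicator
#' and velocity fields this is applied to (they vanish near the border).
#'
#' @param a 3D array.
#' @param sigma kernel standard deviation in voxels; `<= 0` returns `a`.
#' @return smoothed array.
#' @keywords internal
#' @noRd
smooth_gaussian <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  taps <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  taps <- taps / sum(taps)
  for (ax in 1:3) {
    acc <- array(0, dim = dim(a))
    for (t in seq_along(taps)) {
      off <- c(0L, 0L, 0L)
      off[ax] <- t - r - 1L
      acc <- acc + taps[t] * shift3d(a, off, fill = "zero")
    }
    a <- acc
  }
  a
}

#' Central-difference gradient of a 3D scalar field
#'
#' Differences are taken per voxel index (unit spacing); borders use edge
#' replication, i.e. one-sided differences of half magnitude there.
#'
#' @param a 3D array.
#' @return list of three arrays (d/di, d/dj, d/dk).
#' @keywords internal
#' @noRd
gradient3d <- function(a) {
  g <- vector("list", 3L)
  for (ax in 1:3) {
    plus <- c(0L, 0L, 0L); plus[ax] <- -1L   # value at x+1
    minus <- c(0L, 0L, 0L); minus[ax] <- 1L  # value at x-1
    g[[ax]] <- (shift3d(a, plus, fill = "edge") -
                shift3d(a, minus, fill = "edge")) / 2
  }
  names(g) <- c("x", "y", "z")
  g
}

#' Trilinear interpolation of a 3D array at fractional voxel coordinates
#'
#' @param a 3D array.
#' @param pts n x 3 matrix of 0-based voxel coordinates; coordinates are
#'   clamped to the valid range, so queries slightly outside the grid take
#'   border values.
#' @return numeric vector of length n.
#' @keywords internal
#' @noRd
interp_trilinear <- function(a, pts) {
  d <- dim(a)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  x <- pmin(pmax(pts[, 1], 0), d[1] - 1)
  y <- pmin(pmax(pts[, 2], 0), d[2] - 1)
  z <- pmin(pmax(pts[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(x), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(z), d[3] - 2); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # linear index of the (x0, y0, z0) corner, 1-based
  base <- 1 + x0 + d[1] * (y0 + d[2] * z0)
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  a <- as.vector(a)
  v000 <- a[base]
  v100 <- a[base + sx]
  v010 <- a[base + sy]
  v110 <- a[base + sx + sy]
  v001 <- a[base + sz]
  v101 <- a[base + sx + sz]
  v011 <- a[base + sy + sz]
  v111 <- a[base + sx + sy + sz]
  w000 <- (1 - fx) * (1 - fy) * (1 - fz)
  w100 <- fx * (1 - fy) * (1 - fz)
  w010 <- (1 - fx) * fy * (1 - fz)
  w110 <- fx * fy * (1 - fz)
  w001 <- (1 - fx) * (1 - fy) * fz
  w101 <- fx * (1 - fy) * fz
  w011 <- (1 - fx) * fy * fz
  w111 <- fx * fy * fz
  v000 * w000 + v100 * w100 + v010 * w010 + v110 * w110 +
    v001 * w001 + v101 * w101 + v011 * w011 + v111 * w111
}

#' Jacobian determinant of the map identity + displacement
#'
#' The displacement field is given in voxel units as three arrays (one per
#' component). The Jacobian of `x + u(x)` is computed by central differences
#' (edge replication at borders) and its determinant returned per voxel. A
#' zero field and any uniform translation give exactly 1 everywhere.
#'
#' @param field list of three 3D arrays (`x`, `y`, `z` displacement
#'   components, voxel units).
#' @return 3D array of determinants.
#' @export
#' @examples
#' z <- array(0, dim = c(4, 4, 4))
#' range(jacobian_determinant(list(x = z, y = z, z = z)))  # 1 1
jacobian_determinant <- function(field) {
  stopifnot(is.list(field), length(field) == 3L)
  g <- lapply(field, gradient3d)
  # J[r][c] = d(x_r + u_r)/d x_c
  j11 <- 1 + g[[1]][[1]]; j12 <- g[[1]][[2]]; j13 <- g[[1]][[3]]
  j21 <- g[[2]][[1]]; j22 <- 1 + g[[2]][[2]]; j23 <- g[[2]][[3]]
  j31 <- g[[3]][[1]]; j32 <- g[[3]][[2]]; j33 <- 1 + g[[3]][[3]]
  j11 * (j22 * j33 - j23 * j32) -
    j12 * (j21 * j33 - j23 * j31) +
    j13 * (j21 * j32 - j22 * j31)
}
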