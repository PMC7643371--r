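# Registration-based cortical thickness (DiReCT-style core).
#
# The WM/GM interface is propagated diffeomorphically toward the GM/CSF
# interface; the thickness at a boundary point is the arc length of its
# trajectory, in mm. The scheme is a greedy composed-displacement flow: a
# smooth, static velocity field points "outward" across the GM band (from a
# multiscale boundary-propagation potential), each iteration's update field
# is Gaussian-smoothed and clamped below half a voxel before being composed
# with the accumulated displacement, and the Jacobian determinant of the
# accumulated map is verified positive after every iteration. Boundary
# points freeze when they cross the pial boundary (sub-voxel, by linear
# interpolation of the sharpened GM map) or when their path length reaches
# the thickness prior.

#' Parameters of the thickness propagation
#'
#' @param max_iterations maximum number of propagation iterations.
#' @param gradient_step nominal per-iteration step length in voxels; values
#'   are clamped to 0.45 voxels so no single update can approach half a
#'   voxel (a sufficient margin for diffeomorphic composition).
#' @param field_smoothing_sigma Gaussian smoothing of each update field, in
#'   voxels.
#' @param max_thickness_prior upper bound on thickness, mm; points freeze
#'   when their path reaches it.
#' @param convergence_window,convergence_threshold propagation stops early
#'   when the relative change of the front energy (summed step lengths of
#'   active points) over `convergence_window` iterations falls below
#'   `convergence_threshold`.
#' @return object of class `direct_params`.
#' @export
direct_params <- function(max_iterations = 45L,
                          gradient_step = 0.25,
                          field_smoothing_sigma = 1.0,
                          max_thickness_prior = 10,
                          convergence_window = 10L,
                          convergence_threshold = 1e-6) {
  p <- list(max_iterations = as.integer(max_iterations),
            gradient_step = gradient_step,
            field_smoothing_sigma = field_smoothing_sigma,
            max_thickness_prior = max_thickness_prior,
            convergence_window = as.integer(convergence_window),
            convergence_threshold = convergence_threshold)
  if (any(vapply(p, function(v) v <= 0, TRUE)))
    stop("all direct_params must be positive")
  structure(p, class = "direct_params")
}

# voxels (n x 3, 1-based) -> 1-based linear indices
lin_index <- function(vox, shape) {
  1 + (vox[, 1] - 1) + shape[1] * ((vox[, 2] - 1) + shape[2] * (vox[, 3] - 1))
}

FACE_OFFSETS <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L),
                      c(0L, 1L, 0L), c(0L, -1L, 0L),
                      c(0L, 0L, 1L), c(0L, 0L, -1L))

# TRUE where mask has >= 1 face-adjacent TRUE neighbor; voxels beyond the
# grid border count as `oob`
face_neighbor_any <- function(mask, oob = FALSE) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (r in seq_len(nrow(FACE_OFFSETS))) {
    e <- FACE_OFFSETS[r, ]
    nb <- shift3d(mask * 1, -e, fill = "zero") > 0  # value at x + e
    if (oob) {
      ax <- which(e != 0L)
      if (e[ax] > 0L) {
        if (ax == 1L) nb[d[1], , ] <- TRUE
        if (ax == 2L) nb[, d[2], ] <- TRUE
        if (ax == 3L) nb[, , d[3]] <- TRUE
      } else {
        if (ax == 1L) nb[1, , ] <- TRUE
        if (ax == 2L) nb[, 1, ] <- TRUE
        if (ax == 3L) nb[, , 1] <- TRUE
      }
    }
    out <- out | nb
  }
  out
}

#' Extract the WM/GM and GM/CSF interfaces
#'
#' The WM/GM interface is the set of GM voxels with at least one
#' face-adjacent (6-connectivity) WM voxel; the GM/CSF interface the set of
#' GM voxels with at least one face-adjacent background voxel (voxels beyond
#' the grid border count as background).
#'
#' @param d a `direct_input` from [prepare_direct_input()].
#' @return list with `wm_gm` and `gm_csf`, each an n x 3 integer matrix of
#'   1-based voxel indices.
#' @export
extract_interfaces <- function(d) {
  ifc <- interfaces_raw(d)
  if (nrow(ifc$wm_gm) == 0L)
    stop("no cortex found: no GM voxel has a face-adjacent WM voxel")
  ifc
}

interfaces_raw <- function(d) {
  stopifnot(inherits(d, "direct_input"))
  seg <- d$p_seg$values
  gm <- seg == 2L
  if (!any(gm)) stop("no cortex found: segmentation contains no GM voxels")
  wm_adj <- face_neighbor_any(seg == 3L, oob = FALSE)
  csf_adj <- face_neighbor_any(seg == 0L, oob = TRUE)
  list(wm_gm = which(gm & wm_adj, arr.ind = TRUE),
       gm_csf = which(gm & csf_adj, arr.ind = TRUE))
}

# start positions: face midpoint between each interface GM voxel and its
# WM neighbors (0-based fractional voxel coordinates)
interface_start_points <- function(wm_gm, seg) {
  shape <- dim(seg)
  wm <- seg == 3L
  n <- nrow(wm_gm)
  dir <- matrix(0, n, 3)
  for (r in seq_len(nrow(FACE_OFFSETS))) {
    e <- FACE_OFFSETS[r, ]
    nb <- sweep(wm_gm, 2, e, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
          nb[, 2] >= 1 & nb[, 2] <= shape[2] &
          nb[, 3] >= 1 & nb[, 3] <= shape[3]
    hit <- rep(FALSE, n)
    hit[ok] <- wm[lin_index(nb[ok, , drop = FALSE], shape)]
    if (any(hit))
      dir[hit, ] <- dir[hit, , drop = FALSE] +
        matrix(e, sum(hit), 3, byrow = TRUE)
  }
  nrm <- sqrt(rowSums(dir^2))
  nrm[nrm == 0] <- 1
  (wm_gm - 1) + 0.5 * dir / nrm
}

#' Estimate a voxel-wise thickness map by diffeomorphic boundary propagation
#'
#' One boundary point is seeded per WM/GM interface voxel, at the face
#' midpoint toward its WM neighbours. A static velocity field of magnitude
#' `gradient_step * P_g'` follows the outward direction of a multiscale
#' boundary-propagation potential (smoothed WM indicator minus smoothed
#' background indicator, summed over scales 1, 2 and 4 voxels). The velocity
#' field is Gaussian-smoothed once and each iteration composes the
#' accumulated displacement with this one fixed, small, invertible update
#' map (evaluated at the warped positions), so the accumulated map is a
#' composition of diffeomorphisms; the Jacobian determinant is nevertheless
#' re-verified after every iteration and a non-positive value aborts the
#' run. Points accumulate Euclidean arc length in mm and freeze on
#' crossing the pial surface of the segmentation (the interpolated GM
#' indicator falls below 0.5, crossing refined linearly — the same surface
#' convention [laplacian_thickness()] uses) or on reaching
#' `max_thickness_prior`. Finally each
#' point's total arc length is scattered to the GM voxels its trajectory
#' crossed; GM voxels missed by every trajectory take the value of the
#' nearest assigned GM voxel within 2 voxels, else 0.
#'
#' @param d a `direct_input` from [prepare_direct_input()].
#' @param params a [direct_params()] object.
#' @return a [thickness_map]; its `diagnostics` element records iterations
#'   run, the minimum Jacobian determinant observed, the number of boundary
#'   points and the energy history.
#' @export
estimate_thickness <- function(d, params = direct_params()) {
  stopifnot(inherits(d, "direct_input"), inherits(params, "direct_params"))
  seg <- d$p_seg$values
  grid <- d$p_seg$grid
  shape <- grid$shape
  spacing <- grid$spacing
  ifc <- interfaces_raw(d)
  if (nrow(ifc$wm_gm) == 0L) {
    warning("no GM voxel is adjacent to WM; nothing to propagate")
    return(thickness_map(array(0, shape), grid))
  }

  gmp <- d$p_g_prime$values
  step <- min(params$gradient_step, 0.45)

  # static velocity field: outward direction x speed weight
  chi_wm <- (seg == 3L) * 1
  chi_bg <- (seg == 0L) * 1
  psi <- 0
  for (s in c(1, 2, 4))
    psi <- psi + smooth_gaussian(chi_wm, s) - smooth_gaussian(chi_bg, s)
  g <- gradient3d(psi)
  gn <- sqrt(g$x^2 + g$y^2 + g$z^2)
  gn[gn < 1e-9] <- Inf
  rho <- pmin(pmax(gmp, 0), 1)
  # the per-iteration update map is the SAME smoothed static field, so every
  # iteration composes the accumulated map with one fixed small invertible
  # map and the Jacobian determinant stays positive by construction
  vel <- lapply(list(x = -g$x / gn * step * rho,
                     y = -g$y / gn * step * rho,
                     z = -g$z / gn * step * rho),
                smooth_gaussian, sigma = params$field_smoothing_sigma)

  # boundary points (Lagrangian probes of the displacement field)
  pts0 <- interface_start_points(ifc$wm_gm, seg)
  npts <- nrow(pts0)
  ell <- numeric(npts)
  armed <- rep(FALSE, npts)
  active <- rep(TRUE, npts)
  pos <- pts0
  # freeze on the segmentation's own GM surface: crossing of the
  # interpolated hard GM indicator, the same convention the Laplacian
  # solver uses, so both methods measure between the same surfaces
  stopfield <- (seg == 2L) * 1
  g_here <- interp_trilinear(stopfield, pos)

  # accumulated displacement on the grid, voxel units
  u <- list(x = array(0, shape), y = array(0, shape), z = array(0, shape))
  coords <- list(
    x = array(rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3]), shape),
    y = array(rep(rep(seq_len(shape[2]) - 1, each = shape[1]), times = shape[3]), shape),
    z = array(rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2]), shape))

  samples_pos <- list(pos, ifc$wm_gm - 1)  # trajectory samples (0-based)
  samples_id <- list(seq_len(npts), seq_len(npts))
  energy <- numeric(0)
  min_jac <- Inf
  iterations <- 0L

  for (k in seq_len(params$max_iterations)) {
    iterations <- k
    warped <- cbind(as.vector(coords$x + u$x),
                    as.vector(coords$y + u$y),
                    as.vector(coords$z + u$z))
    delta <- lapply(vel, function(vc) array(interp_trilinear(vc, warped), shape))
    u <- list(x = u$x + delta$x, y = u$y + delta$y, z = u$z + delta$z)
    jmin <- min(jacobian_determinant(u))
    min_jac <- min(min_jac, jmin)
    if (jmin <= 0)
      stop(sprintf(
        "diffeomorphism violated at iteration %d: min Jacobian determinant %.4g",
        k, jmin))

    if (any(active)) {
      ai <- which(active)
      dmove <- cbind(interp_trilinear(delta$x, pts0[ai, , drop = FALSE]),
                     interp_trilinear(delta$y, pts0[ai, , drop = FALSE]),
                     interp_trilinear(delta$z, pts0[ai, , drop = FALSE]))
      step_mm <- sqrt((dmove[, 1] * spacing[1])^2 +
                      (dmove[, 2] * spacing[2])^2 +
                      (dmove[, 3] * spacing[3])^2)
      new_pos <- pos[ai, , drop = FALSE] + dmove
      g_new <- interp_trilinear(stopfield, new_pos)
      g_old <- g_here[ai]
      armed[ai] <- armed[ai] | g_new >= 0.6

      crossed <- armed[ai] & g_new < 0.5 & g_old >= 0.5
      frac <- rep(1, length(ai))
      frac[crossed] <- (g_old[crossed] - 0.5) /
        pmax(g_old[crossed] - g_new[crossed], 1e-12)
      ell[ai] <- ell[ai] + frac * step_mm
      pos[ai, ] <- pos[ai, , drop = FALSE] + frac * dmove
      g_here[ai] <- ifelse(crossed, 0.5, g_new)

      capped <- ell[ai] >= params$max_thickness_prior
      ell[ai[capped]] <- params$max_thickness_prior
      active[ai[crossed | capped]] <- FALSE

      moved <- ai[!(crossed | capped)]
      if (length(moved)) {
        samples_pos[[length(samples_pos) + 1L]] <- pos[moved, , drop = FALSE]
        samples_id[[length(samples_id) + 1L]] <- moved
      }
      energy[k] <- sum(step_mm)
    } else {
      energy[k] <- 0
    }

    if (!any(active)) break
    w <- params$convergence_window
    if (k > w) {
      e_ref <- energy[k - w]
      if (abs(energy[k] - e_ref) / max(e_ref, 1e-12) < params$convergence_threshold)
        break
    }
  }

  # final positions are part of the trajectories too
  samples_pos[[length(samples_pos) + 1L]] <- pos
  samples_id[[length(samples_id) + 1L]] <- seq_len(npts)

  vals <- scatter_trajectories(samples_pos, samples_id, ell, seg, shape)
  out <- thickness_map(vals, grid)
  out$diagnostics <- list(iterations = iterations, min_jacobian = min_jac,
                          n_points = npts, energy = energy,
                          params = params)
  out
}

# assign each point's final arc length to the GM voxels its trajectory
# crossed (nearest trajectory sample wins), then fill unassigned GM voxels
# from the nearest assigned GM voxel within 2 voxels
scatter_trajectories <- function(samples_pos, samples_id, ell, seg, shape) {
  pos <- do.call(rbind, samples_pos)
  id <- unlist(samples_id)
  vox <- round(pos)
  inb <- vox[, 1] >= 0 & vox[, 1] <= shape[1] - 1 &
         vox[, 2] >= 0 & vox[, 2] <= shape[2] - 1 &
         vox[, 3] >= 0 & vox[, 3] <= shape[3] - 1
  pos <- pos[inb, , drop = FALSE]; vox <- vox[inb, , drop = FALSE]
  id <- id[inb]
  lin <- lin_index(vox + 1, shape)
  is_gm <- seg[lin] == 2L
  pos <- pos[is_gm, , drop = FALSE]; vox <- vox[is_gm, , drop = FALSE]
  id <- id[is_gm]; lin <- lin[is_gm]

  vals <- array(0, shape)
  assigned <- array(FALSE, shape)
  if (length(lin)) {
    d2 <- rowSums((pos - vox)^2)
    ord <- order(d2)
    lin_o <- lin[ord]
    first <- !duplicated(lin_o)
    vals[lin_o[first]] <- ell[id[ord][first]]
    assigned[lin_o[first]] <- TRUE
  }

  todo <- which(seg == 2L & !assigned)
  if (length(todo)) {
    tv <- which(seg == 2L & !assigned, arr.ind = TRUE)
    offs <- as.matrix(expand.grid(dx = -2:2, dy = -2:2, dz = -2:2))
    nrm2 <- rowSums(offs^2)
    offs <- offs[nrm2 > 0 & nrm2 <= 4, , drop = FALSE]
    offs <- offs[order(rowSums(offs^2)), , drop = FALSE]
    filled <- rep(FALSE, nrow(tv))
    for (r in seq_len(nrow(offs))) {
      if (all(filled)) break
      nb <- sweep(tv, 2, offs[r, ], "+")
      ok <- !filled &
        nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
      if (!any(ok)) next
      nlin <- lin_index(nb[ok, , drop = FALSE], shape)
      hit <- assigned[nlin]
      if (any(hit)) {
        tgt <- which(ok)[hit]
        vals[lin_index(tv[tgt, , drop = FALSE], shape)] <- vals[nlin[hit]]
        filled[tgt] <- TRUE
      }
    }
  }
  vals
}

#' Laplacian cortical thickness (independent oracle)
#'
#' Solves Laplace's equation on the GM domain with Dirichlet values 0 on WM
#' and 1 on background/CSF (Jacobi iteration, Neumann condition at the grid
#' border), then integrates a streamline through the normalized gradient
#' field from every GM voxel in both directions; thickness is the summed
#' streamline length in mm, with the end points refined to the sub-voxel
#' crossing of the GM indicator. This construction is independent of the
#' propagation scheme in [estimate_thickness()] and is near-exact on
#' parallel-plate and concentric-sphere geometries.
#'
#' @param d a `direct_input` from [prepare_direct_input()].
#' @param tol relative residual below which the Laplace solve is accepted.
#' @param max_sweeps maximum Jacobi sweeps; exceeding this is an error.
#' @param step_voxels streamline integration step, voxels.
#' @param max_path_mm streamlines longer than this are treated as undefined
#'   (their voxels get thickness 0 with a warning).
#' @return a [thickness_map].
#' @export
laplacian_thickness <- function(d, tol = 1e-5, max_sweeps = 20000L,
                                step_voxels = 0.25, max_path_mm = 30) {
  stopifnot(inherits(d, "direct_input"))
  seg <- d$p_seg$values
  grid <- d$p_seg$grid
  shape <- grid$shape
  spacing <- grid$spacing
  gm <- seg == 2L
  if (!any(gm)) stop("no cortex found: segmentation contains no GM voxels")

  phi <- array(0, shape)
  phi[seg == 0L] <- 1
  phi[gm] <- 0.5
  gm_idx <- which(gm)
  nb_mean <- function(a) {
    acc <- array(0, dim = dim(a))
    for (r in seq_len(nrow(FACE_OFFSETS)))
      acc <- acc + shift3d(a, -FACE_OFFSETS[r, ], fill = "edge")
    acc / 6
  }
  residual <- Inf
  for (sweep_i in seq_len(max_sweeps)) {
    m <- nb_mean(phi)
    if (sweep_i %% 10L == 0L || sweep_i == 1L)
      residual <- max(abs(phi[gm_idx] - m[gm_idx]))
    phi[gm_idx] <- m[gm_idx]
    if (residual <= tol) break
  }
  if (residual > tol)
    stop(sprintf("Laplace solve did not converge: relative residual %.3g > %g after %d sweeps",
                 residual, tol, max_sweeps))

  gphi <- gradient3d(phi)
  gm_ind <- gm * 1
  starts <- which(gm, arr.ind = TRUE) - 1  # 0-based centers
  step_mm <- step_voxels * min(spacing)
  max_steps <- as.integer(ceiling(max_path_mm / step_mm))

  trace_side <- function(sgn) {
    n <- nrow(starts)
    posn <- starts
    len <- numeric(n)
    active <- rep(TRUE, n)
    bad <- rep(FALSE, n)
    gprev <- interp_trilinear(gm_ind, posn)
    for (s in seq_len(max_steps)) {
      if (!any(active)) break
      ai <- which(active)
      p <- posn[ai, , drop = FALSE]
      gx <- interp_trilinear(gphi$x, p) / spacing[1]
      gy <- interp_trilinear(gphi$y, p) / spacing[2]
      gz <- interp_trilinear(gphi$z, p) / spacing[3]
      mag <- sqrt(gx^2 + gy^2 + gz^2)
      stalled <- mag < 1e-8
      bad[ai[stalled]] <- TRUE
      active[ai[stalled]] <- FALSE
      mv <- which(!stalled)
      if (!length(mv)) next
      aj <- ai[mv]
      ux <- sgn * gx[mv] / mag[mv]; uy <- sgn * gy[mv] / mag[mv]
      uz <- sgn * gz[mv] / mag[mv]
      dp <- cbind(ux * step_mm / spacing[1],
                  uy * step_mm / spacing[2],
                  uz * step_mm / spacing[3])
      newp <- posn[aj, , drop = FALSE] + dp
      gnew <- interp_trilinear(gm_ind, newp)
      crossed <- gnew < 0.5 & gprev[aj] >= 0.5
      frac <- rep(1, length(aj))
      frac[crossed] <- (gprev[aj][crossed] - 0.5) /
        pmax(gprev[aj][crossed] - gnew[crossed], 1e-12)
      len[aj] <- len[aj] + frac * step_mm
      posn[aj, ] <- posn[aj, , drop = FALSE] + frac * dp
      gprev[aj] <- ifelse(crossed, 0.5, gnew)
      active[aj[crossed]] <- FALSE
    }
    bad[active] <- TRUE  # ran out of path budget
    list(len = len, bad = bad)
  }

  up <- trace_side(+1)
  down <- trace_side(-1)
  thick <- up$len + down$len
  bad <- up$bad | down$bad
  if (any(bad)) {
    warning(sprintf(
      "%d GM voxel(s) have no streamline connecting WM to CSF; thickness set to 0",
      sum(bad)))
    thick[bad] <- 0
  }
  vals <- array(0, shape)
  vals[gm_idx] <- thick
  thickness_map(vals, grid)
}
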