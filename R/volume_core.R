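# Grid-aware volume containers and NIfTI-1 I/O.
#
# Every downstream stage operates on validated, aligned 3D arrays. Three
# volume kinds exist: probability volumes (values in [0,1]), label volumes
# (non-negative integer codes with a legend) and thickness maps (mm, >= 0).
# Volumes carry a voxel grid: shape, spacing and a 4x4 affine mapping
# 0-based voxel indices to world mm coordinates (RAS).

GRID_TOL <- 1e-5
PROB_TOL <- 1e-6

#' Voxel grid
#'
#' Describes the sampling lattice of a volume: array shape, voxel spacing in
#' mm, and the 4x4 affine mapping 0-based voxel indices to world (RAS) mm
#' coordinates. Two volumes are considered aligned iff their shapes match and
#' their affines agree within `1e-5`.
#'
#' @param shape integer vector of 3 positive extents.
#' @param spacing voxel edge lengths in mm (default 1 mm isotropic).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   RAS affine with the grid centre at the world origin.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be 3 positive integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("all voxel spacings must be > 0")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
    affine[1:3, 4] <- -spacing * (shape - 1) / 2
  } else {
    # voxel edge lengths are encoded in the affine columns
    spacing <- sqrt(colSums(as.matrix(affine)[1:3, 1:3]^2))
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(shape = shape, spacing = spacing, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s, spacing %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

grids_aligned <- function(g1, g2, tol = GRID_TOL) {
  identical(g1$shape, g2$shape) && max(abs(g1$affine - g2$affine)) <= tol
}

#' Check that volumes share a grid
#'
#' Returns invisibly iff all volumes have identical shapes and affines
#' (within tolerance `1e-5`); otherwise stops, naming the first mismatching
#' pair. Every multi-volume operation in the package calls this: there is no
#' silent resampling anywhere.
#'
#' @param volumes list of volumes (or objects with a `$grid`).
#' @return invisible `TRUE`.
#' @export
assert_aligned <- function(volumes) {
  if (length(volumes) < 2L) return(invisible(TRUE))
  g1 <- volumes[[1]]$grid
  for (i in seq_along(volumes)[-1]) {
    gi <- volumes[[i]]$grid
    if (!identical(g1$shape, gi$shape))
      stop(sprintf("volumes 1 and %d are not aligned: shape %s vs %s",
                   i, paste(g1$shape, collapse = "x"),
                   paste(gi$shape, collapse = "x")))
    if (max(abs(g1$affine - gi$affine)) > GRID_TOL)
      stop(sprintf("volumes 1 and %d are not aligned: affines differ by %.3g",
                   i, max(abs(g1$affine - gi$affine))))
  }
  invisible(TRUE)
}

new_volume <- function(values, grid, class) {
  if (!identical(dim(values), NULL) && !identical(as.integer(dim(values)), grid$shape))
    stop("values dimensions do not match the grid shape")
  dim(values) <- grid$shape
  structure(list(values = values, grid = grid),
            class = c(class, "brain_volume"))
}

#' Probability volume
#'
#' A per-voxel tissue probability in `[0,1]` on a voxel grid. Values beyond
#' the range by at most `1e-6` (float32 I/O noise) are clipped with a
#' warning; larger deviations are an error.
#'
#' @param values 3D numeric array.
#' @param grid a [voxel_grid].
#' @return object of class `probability_volume`.
#' @export
probability_volume <- function(values, grid) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("probability volume contains missing values")
  lo <- values < 0; hi <- values > 1
  if (any(lo) || any(hi)) {
    worst <- max(c(0 - values[lo], values[hi] - 1, 0))
    n_off <- sum(lo) + sum(hi)
    if (worst > PROB_TOL)
      stop(sprintf(
        "%d voxel(s) outside [0,1] by up to %.3g (tolerance %g)",
        n_off, worst, PROB_TOL))
    warning(sprintf("clipped %d voxel(s) to [0,1] (max deviation %.2g)",
                    n_off, worst))
    values <- pmin(pmax(values, 0), 1)
  }
  new_volume(values, grid, "probability_volume")
}

default_legend <- function(codes) {
  codes <- sort(unique(codes[codes != 0L]))
  data.frame(code = as.integer(codes),
             region = sprintf("region_%d", codes),
             hemisphere = rep("none", length(codes)),
             stringsAsFactors = FALSE)
}

#' Label volume
#'
#' Non-negative integer region codes per voxel plus a legend mapping each
#' nonzero code to a region name and hemisphere (`left`, `right`, `none`).
#' When no legend is supplied a placeholder legend is generated so the
#' "every nonzero code has a legend entry" invariant always holds.
#'
#' @param values 3D array of non-negative integers (integer-valued numerics
#'   are accepted).
#' @param grid a [voxel_grid].
#' @param legend data frame with columns `code`, `region`, `hemisphere`.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(values, grid, legend = NULL) {
  v <- as.numeric(values)
  if (anyNA(v)) stop("label volume contains missing values")
  if (max(abs(v - round(v))) > 0)
    stop("label volume contains non-integer values")
  if (any(v < 0)) stop("label codes must be non-negative")
  iv <- as.integer(round(v))
  if (is.null(legend)) legend <- default_legend(iv)
  legend$code <- as.integer(legend$code)
  missing_codes <- setdiff(unique(iv[iv != 0L]), legend$code)
  if (length(missing_codes))
    stop("codes missing from legend: ", paste(missing_codes, collapse = ", "))
  vol <- new_volume(iv, grid, "label_volume")
  vol$legend <- legend
  vol
}

#' Thickness map
#'
#' Per-voxel cortical thickness in mm: finite, non-negative, and zero outside
#' the gray matter it was computed on.
#'
#' @param values 3D numeric array of thickness in mm.
#' @param grid a [voxel_grid].
#' @return object of class `thickness_map`.
#' @export
thickness_map <- function(values, grid) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("thickness map contains missing or non-finite values")
  if (any(values < 0)) stop("thickness map contains negative values")
  new_volume(values, grid, "thickness_map")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("<%s %s, spacing %s mm, values in [%.4g, %.4g]>\n",
              class(x)[1], paste(x$grid$shape, collapse = "x"),
              paste(signif(x$grid$spacing, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

grid_from_nifti <- function(img) {
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  attributes(aff) <- list(dim = dim(aff))
  voxel_grid(dim(img)[1:3], spacing = RNifti::pixdim(img)[1:3], affine = aff)
}

#' Read a volume from a NIfTI-1 file
#'
#' Values are validated against the invariants of the requested kind:
#' probabilities must lie in `[0,1]` (excess up to `1e-6` is clipped with a
#' warning), labels must be integer-valued, thickness must be non-negative.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param kind one of `"probability"`, `"label"`, `"thickness"`.
#' @param lut optional path to a label look-up table (see [read_lut]); only
#'   used for `kind = "label"`.
#' @return a [probability_volume], [label_volume] or [thickness_map].
#' @export
read_volume <- function(path, kind = c("probability", "label", "thickness"),
                        lut = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D volume: ", path)
  grid <- grid_from_nifti(img)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  switch(kind,
    probability = probability_volume(vals, grid),
    label = label_volume(vals, grid,
                         legend = if (!is.null(lut)) read_lut(lut) else NULL),
    thickness = thickness_map(vals, grid))
}

#' Write a volume to a NIfTI-1 file
#'
#' Labels are written as int32 (codes round-trip exactly); probabilities and
#' thickness as float32. The affine is stored in both the sform and qform.
#'
#' @param volume a volume created by this package.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "brain_volume"))
  # re-validate so an invalid object (e.g. negative thickness) is refused
  if (inherits(volume, "thickness_map") && any(volume$values < 0))
    stop("refusing to write a thickness map with negative values")
  if (inherits(volume, "probability_volume") &&
      (min(volume$values) < 0 || max(volume$values) > 1))
    stop("refusing to write a probability volume outside [0,1]")
  vals <- volume$values
  datatype <- if (inherits(volume, "label_volume")) "int32" else "float"
  img <- RNifti::asNifti(vals)
  RNifti::`pixdim<-`(img, volume$grid$spacing) -> img
  aff <- structure(volume$grid$affine, code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path, datatype = datatype)
  if (!file.exists(path)) stop("could not write ", path)
  invisible(path)
}

#' Read a label look-up table
#'
#' Accepts either the package's 3-column tab-separated format
#' (`code<TAB>region<TAB>hemisphere`) or the FreeSurfer LUT dialect
#' (whitespace-separated `code name R G B A`, `#` comments); in the latter
#' case the hemisphere is inferred from `lh`/`rh`/`ctx-lh`/`ctx-rh`/`Left`/
#' `Right` name prefixes.
#'
#' @param path LUT file path.
#' @return data frame with columns `code`, `region`, `hemisphere`.
#' @export
read_lut <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty LUT: ", path)
  parts <- strsplit(lines, "[ \t]+")
  has_header <- !grepl("^[0-9]+$", vapply(parts, `[`, "", 1L))
  if (has_header[1]) { parts <- parts[-1] }
  code <- as.integer(vapply(parts, `[`, "", 1L))
  region <- vapply(parts, `[`, "", 2L)
  third <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA_character_, "")
  if (all(!is.na(third)) && all(third %in% c("left", "right", "none"))) {
    hemisphere <- third
  } else {
    hemisphere <- rep("none", length(region))
    hemisphere[grepl("^(lh[-_.]|ctx-lh|Left[-_])", region)] <- "left"
    hemisphere[grepl("^(rh[-_.]|ctx-rh|Right[-_])", region)] <- "right"
  }
  if (anyNA(code)) stop("malformed LUT line in ", path)
  data.frame(code = code, region = region, hemisphere = hemisphere,
             stringsAsFactors = FALSE)
}

#' Write a label look-up table
#'
#' @param legend data frame with columns `code`, `region`, `hemisphere`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lut <- function(legend, path) {
  stopifnot(all(c("code", "region", "hemisphere") %in% names(legend)))
  utils::write.table(legend[, c("code", "region", "hemisphere")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
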