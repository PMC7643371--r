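# Synthetic data with analytically known ground truth.
#
# Geometric phantoms (slab, spherical shell, gyrified shell) emulate soft
# segmenter outputs: tissue probabilities are logistic functions of the
# signed distance to the analytic interfaces, with edge softness sigma_edge
# mimicking partial-volume decay. Cohort and re-scan simulators emulate the
# statistical structure of a morphometry study: age slope, brain-size
# covariate, group effect on dementia, subject-level random effects and
# measurement noise. Every generator returns its generative parameters so
# recovery can be tested.

#' Phantom specification
#'
#' @param kind `"shell"`, `"slab"` or `"gyrified-shell"`.
#' @param shape grid extents (default 48^3).
#' @param spacing voxel size in mm (default 1 mm isotropic).
#' @param inner_radius,outer_radius shell radii in mm; true thickness is
#'   their difference.
#' @param gm_width slab GM band width in mm (slab true thickness).
#' @param sigma_edge logistic softness of the interfaces in mm.
#' @param gyr_amplitude,gyr_frequency sinusoidal modulation of the outer
#'   radius for the gyrified shell (amplitude in mm, <= 1).
#' @param seed random seed (only used when `noise_sd > 0`).
#' @param noise_sd optional additive probability noise (default 0: phantoms
#'   are purely geometric).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("shell", "slab", "gyrified-shell"),
                         shape = c(48, 48, 48), spacing = c(1, 1, 1),
                         inner_radius = 8, outer_radius = 11,
                         gm_width = 5, sigma_edge = 0.5,
                         gyr_amplitude = 0.8, gyr_frequency = 4,
                         seed = 1L, noise_sd = 0) {
  kind <- match.arg(kind)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (sigma_edge <= 0) stop("sigma_edge must be > 0")
  if (kind != "slab" && !(outer_radius > inner_radius && inner_radius > 0))
    stop("need outer_radius > inner_radius > 0")
  if (kind == "slab" && gm_width <= 0) stop("gm_width must be > 0")
  if (kind == "gyrified-shell" && gyr_amplitude > 1)
    stop("gyrification amplitude must be <= 1 mm")
  structure(list(kind = kind, shape = as.integer(shape), spacing = spacing,
                 inner_radius = inner_radius, outer_radius = outer_radius,
                 gm_width = gm_width, sigma_edge = sigma_edge,
                 gyr_amplitude = gyr_amplitude, gyr_frequency = gyr_frequency,
                 seed = as.integer(seed), noise_sd = noise_sd),
            class = "phantom_spec")
}

#' Generate a geometric phantom
#'
#' Builds soft WM and GM probability maps as logistic functions of the
#' signed distance to the analytic interfaces:
#' `P_w = 1/(1 + exp(s_in / sigma))` with `s_in` the signed distance to the
#' inner (WM/GM) interface, and `P_g = (1 - P_w) / (1 + exp(s_out / sigma))`
#' with `s_out` the distance to the outer (GM/CSF) interface, which
#' guarantees `P_g + P_w <= 1` everywhere. Slab interfaces are placed on
#' voxel faces (as a voxelized tissue map would have them); shell interfaces
#' are spheres around the grid center. The parcellation labels the
#' hard-thresholded GM band: octants for shells (hemispheres split at the
#' x = center plane), stripes for slabs.
#'
#' @param spec a [phantom_spec()].
#' @return list with `p_g`, `p_w` ([probability_volume]s), `parc`
#'   ([label_volume]) and `truth` (generative parameters, including
#'   `thickness_mm` and, for shells, the analytic GM volume).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape; sp <- spec$spacing
  grid <- voxel_grid(shape, spacing = sp)
  # world coordinates of voxel centers, grid centered at the origin
  cx <- (seq_len(shape[1]) - 1 - (shape[1] - 1) / 2) * sp[1]
  cy <- (seq_len(shape[2]) - 1 - (shape[2] - 1) / 2) * sp[2]
  cz <- (seq_len(shape[3]) - 1 - (shape[3] - 1) / 2) * sp[3]
  X <- array(rep(cx, times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(cy, each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(cz, each = shape[1] * shape[2]), shape)

  if (spec$kind == "slab") {
    # interfaces on voxel faces: outer face just above the grid middle
    mid <- floor(shape[1] / 2)
    x_outer <- cx[mid] + sp[1] / 2
    x_inner <- x_outer - spec$gm_width
    if (x_inner < cx[1] + 2 * sp[1] || x_outer > cx[shape[1]] - 2 * sp[1])
      stop("grid too small for the slab geometry (+2 voxel margin)")
    s_in <- X - x_inner
    s_out <- X - x_outer
    truth_mm <- spec$gm_width
    gm_analytic_mm3 <- spec$gm_width * diff(range(cy)) * diff(range(cz))
  } else {
    r <- sqrt(X^2 + Y^2 + Z^2)
    r_out <- spec$outer_radius
    if (spec$kind == "gyrified-shell") {
      az <- atan2(Y, X)
      pol <- acos(ifelse(r > 0, Z / pmax(r, 1e-9), 1))
      r_out <- r_out + spec$gyr_amplitude *
        sin(spec$gyr_frequency * az) * sin(2 * spec$gyr_frequency * pol)
    }
    max_extent <- min((shape - 1) / 2 * sp)
    if (spec$outer_radius + (spec$kind == "gyrified-shell") * spec$gyr_amplitude >
        max_extent - 2 * min(sp))
      stop("grid too small for the shell geometry (+2 voxel margin)")
    s_in <- r - spec$inner_radius
    s_out <- r - r_out
    truth_mm <- spec$outer_radius - spec$inner_radius
    gm_analytic_mm3 <- 4 / 3 * pi * (spec$outer_radius^3 - spec$inner_radius^3)
  }

  p_w <- 1 / (1 + exp(s_in / spec$sigma_edge))
  p_g <- (1 - p_w) / (1 + exp(s_out / spec$sigma_edge))
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    p_w <- pmin(pmax(p_w + stats::rnorm(length(p_w), 0, spec$noise_sd), 0), 1)
    p_g <- pmin(pmax(p_g + stats::rnorm(length(p_g), 0, spec$noise_sd), 0), 1)
    p_g <- pmin(p_g, 1 - p_w)
  }

  gm_band <- p_g > 0.5
  parc_vals <- array(0L, shape)
  if (spec$kind == "slab") {
    n_stripes <- 4L
    stripe <- pmin(floor((Y - min(cy)) / (diff(range(cy)) + 1e-9) * n_stripes),
                   n_stripes - 1)
    hemi_right <- Z >= 0
    parc_vals[gm_band] <- 1L + as.integer(stripe[gm_band]) +
      n_stripes * as.integer(hemi_right[gm_band])
    legend <- data.frame(
      code = 1:(2L * n_stripes),
      region = sprintf("stripe_%d", rep(1:n_stripes, 2)),
      hemisphere = rep(c("left", "right"), each = n_stripes),
      stringsAsFactors = FALSE)
  } else {
    oct <- 1L + (X >= 0) * 4L + (Y >= 0) * 2L + (Z >= 0) * 1L
    parc_vals[gm_band] <- oct[gm_band]
    legend <- data.frame(
      code = 1:8,
      region = sprintf("octant_%s%s",
                       rep(c("a", "p"), each = 2), rep(c("i", "s"), 2)),
      hemisphere = rep(c("left", "right"), each = 4),
      stringsAsFactors = FALSE)
    legend$region <- paste0(legend$region, "_", rep(1:4, 2))
  }
  legend <- legend[legend$code %in% unique(parc_vals[parc_vals != 0L]), ]

  list(p_g = probability_volume(p_g, grid),
       p_w = probability_volume(p_w, grid),
       parc = label_volume(parc_vals, grid, legend = legend),
       truth = list(kind = spec$kind, thickness_mm = truth_mm,
                    gm_volume_mm3 = gm_analytic_mm3, spec = spec))
}

#' Cohort specification
#'
#' Defaults emulate an elderly dementia-study cohort: mean cortical thickness
#' 2.5 mm, ages 45-90, a small negative age slope, an eTIV covariate effect,
#' between-subject SD 0.1 mm and scan noise 0.03 mm.
#'
#' @param n_hc,n_questionable,n_dementia subjects per group (CDR 0 / 0.5 /
#'   >= 1).
#' @param baseline_mm mean global thickness of a HC at the age-range
#'   midpoint.
#' @param age_range uniform age range in years.
#' @param age_slope thickness change per year of age, mm (applies within and
#'   across subjects).
#' @param etiv_mean,etiv_sd eTIV distribution, mm^3.
#' @param etiv_effect thickness change per SD of eTIV, mm.
#' @param group_effect_d true standardized (Cohen's d) thickness deficit of
#'   the dementia group relative to HC; the questionable group gets half the
#'   deficit.
#' @param sigma_between between-subject SD, mm.
#' @param sigma_noise per-scan measurement noise SD, mm.
#' @param n_visits scans per subject (longitudinal when > 1).
#' @param visit_spacing_years time between visits.
#' @param scanners scanner model labels sampled uniformly.
#' @param seed random seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 100L, n_questionable = 0L, n_dementia = 0L,
                        baseline_mm = 2.5, age_range = c(45, 90),
                        age_slope = -0.005,
                        etiv_mean = 1.5e6, etiv_sd = 1.5e5, etiv_effect = 0.02,
                        group_effect_d = 0, sigma_between = 0.1,
                        sigma_noise = 0.03, n_visits = 1L,
                        visit_spacing_years = 1,
                        scanners = c("scanner_a", "scanner_b"), seed = 1L) {
  stopifnot(sigma_between >= 0, sigma_noise >= 0, etiv_sd > 0,
            n_visits >= 1L, diff(age_range) >= 0)
  structure(list(n_hc = n_hc, n_questionable = n_questionable,
                 n_dementia = n_dementia, baseline_mm = baseline_mm,
                 age_range = age_range, age_slope = age_slope,
                 etiv_mean = etiv_mean, etiv_sd = etiv_sd,
                 etiv_effect = etiv_effect, group_effect_d = group_effect_d,
                 sigma_between = sigma_between, sigma_noise = sigma_noise,
                 n_visits = as.integer(n_visits),
                 visit_spacing_years = visit_spacing_years,
                 scanners = scanners, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of global-mean thickness measurements
#'
#' Thickness of scan t of subject s:
#' `baseline + age_slope * (age_st - mid_age) + etiv_effect * z_etiv_s +
#' shift(group_s) + b_s + e_st`, with `b_s ~ N(0, sigma_between^2)`,
#' `e_st ~ N(0, sigma_noise^2)`, and the dementia shift
#' `-group_effect_d * sqrt(sigma_between^2 + sigma_noise^2)` (half of that
#' for the questionable group), so `group_effect_d` is the true standardized
#' HC-minus-dementia difference. CDR is constant within subject. Ages
#' advance by `visit_spacing_years` per visit, so the within-subject rate
#' equals `age_slope`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `thickness` (thickness-table records, region
#'   `global_mean`), `cohort` (per-scan metadata: subject, session, scan,
#'   age, sex, scanner, cdr, etiv, time_years) and `truth` (the spec plus
#'   the absolute group shift).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- c(rep("HC", spec$n_hc),
              rep("questionable", spec$n_questionable),
              rep("dementia", spec$n_dementia))
  n <- length(groups)
  if (!n) stop("empty cohort")
  sigma_within_total <- sqrt(spec$sigma_between^2 + spec$sigma_noise^2)
  shift_dem <- -spec$group_effect_d * sigma_within_total
  shifts <- c(HC = 0, questionable = shift_dem / 2, dementia = shift_dem)
  cdrs <- c(HC = 0, questionable = 0.5, dementia = 1)

  subject <- sprintf("sub-%04d", seq_len(n))
  age0 <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  sex <- sample(c("F", "M"), n, replace = TRUE)
  scanner <- sample(spec$scanners, n, replace = TRUE)
  etiv <- stats::rnorm(n, spec$etiv_mean, spec$etiv_sd)
  b_s <- stats::rnorm(n, 0, spec$sigma_between)
  mid_age <- mean(spec$age_range)

  i <- rep(seq_len(n), each = spec$n_visits)
  v <- rep(seq_len(spec$n_visits), times = n)
  t_years <- (v - 1) * spec$visit_spacing_years
  age <- age0[i] + t_years
  thick <- spec$baseline_mm +
    spec$age_slope * (age - mid_age) +
    spec$etiv_effect * (etiv[i] - spec$etiv_mean) / spec$etiv_sd +
    shifts[groups[i]] + b_s[i] +
    stats::rnorm(length(i), 0, spec$sigma_noise)
  df <- data.frame(
    subject = subject[i], session = sprintf("ses-%02d", v),
    scan = sprintf("%s_ses-%02d_scan-01", subject[i], v),
    age = age, sex = sex[i], scanner = scanner[i],
    cdr = unname(cdrs[groups[i]]), etiv = etiv[i], time_years = t_years,
    group = groups[i], thickness = unname(thick),
    stringsAsFactors = FALSE)
  thickness <- data.frame(
    subject = df$subject, session = df$session, scan = df$scan,
    method = "simulated", region = "global_mean", hemisphere = "none",
    mean_thickness_mm = df$thickness, n_voxels = NA_integer_,
    stringsAsFactors = FALSE)
  cohort <- df[, c("subject", "session", "scan", "age", "sex", "scanner",
                   "cdr", "etiv", "time_years", "group")]
  list(thickness = thickness, cohort = cohort,
       truth = c(unclass(spec), list(shift_dementia_mm = shift_dem)))
}

#' Simulate same-session re-scans with multiplicative noise
#'
#' Measurement t of session i is `m(i,t) = mu_i * (1 + e_t)` with
#' `e_t ~ N(0, sigma_rescan^2)`. Under this model the expected
#' reproducibility error for two re-scans is `100 * sigma / sqrt(pi)`
#' percent.
#'
#' @param session_means vector of true session means `mu_i` (> 0).
#' @param sigma_rescan relative noise SD (>= 0).
#' @param n_rescans measures per session (default 2).
#' @param seed random seed.
#' @return data frame with columns `session`, `rescan`, `value`.
#' @export
simulate_rescans <- function(session_means, sigma_rescan, n_rescans = 2L,
                             seed = 1L) {
  stopifnot(sigma_rescan >= 0, n_rescans >= 2L, all(session_means > 0))
  set.seed(seed)
  n <- length(session_means)
  e <- stats::rnorm(n * n_rescans, 0, sigma_rescan)
  data.frame(session = rep(seq_len(n), each = n_rescans),
             rescan = rep(seq_len(n_rescans), times = n),
             value = rep(session_means, each = n_rescans) * (1 + e))
}
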