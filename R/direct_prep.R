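# Preparation of DiReCT inputs from raw tissue probability maps.
#
# Registration-based thickness needs inputs that look like a hard
# segmentation with a well-defined WM/GM boundary. Raw segmenter outputs are
# hardened in three steps: a hard segmentation (codes 0 background, 2 GM,
# 3 WM), a binary WM map (the moving image of the registration does not
# change topology, so a binary WM is appropriate), and a boundary-sharpened
# GM map that keeps partial-volume information only on the outer (pial)
# side. All thresholds are strict comparisons; no epsilon.

#' Merge gray-matter probability maps
#'
#' Elementwise maximum over one or more aligned probability volumes. Cortical
#' GM is typically merged with amygdala and hippocampus probabilities this
#' way. Because the sigmoid is monotone, the elementwise maximum of
#' probabilities equals the sigmoid of the maximum logit, so this can be done
#' in probability space.
#'
#' @param maps list of [probability_volume] objects (length >= 1).
#' @return a [probability_volume] with the voxel-wise maximum.
#' @export
combine_gm_probability <- function(maps) {
  if (!length(maps)) stop("need at least one probability map")
  lapply(maps, function(m) stopifnot(inherits(m, "probability_volume")))
  assert_aligned(maps)
  vals <- maps[[1]]$values
  for (m in maps[-1]) vals <- pmax(vals, m$values)
  probability_volume(vals, maps[[1]]$grid)
}

#' Hard segmentation from GM and WM probabilities
#'
#' Per voxel, evaluated strictly in this order:
#' if `P_g + P_w > 0.7` the label is `argmax(P_g, P_w) + 2` (ties resolve to
#' the first position, i.e. GM); else if `P_g > 0.5` the label is 2 (GM);
#' else if `P_w > 0.5` the label is 3 (WM); else 0 (background/CSF).
#'
#' @param p_g,p_w aligned [probability_volume] objects.
#' @return a [label_volume] with codes 0, 2, 3.
#' @export
hard_segmentation <- function(p_g, p_w) {
  stopifnot(inherits(p_g, "probability_volume"),
            inherits(p_w, "probability_volume"))
  assert_aligned(list(p_g, p_w))
  g <- p_g$values; w <- p_w$values
  lab <- array(0L, dim = dim(g))
  b1 <- (g + w) > 0.7
  lab[b1] <- ifelse(g[b1] >= w[b1], 2L, 3L)
  b2 <- !b1 & g > 0.5
  lab[b2] <- 2L
  b3 <- !b1 & !b2 & w > 0.5
  lab[b3] <- 3L
  label_volume(lab, p_g$grid,
               legend = data.frame(code = c(2L, 3L),
                                   region = c("gray_matter", "white_matter"),
                                   hemisphere = c("none", "none"),
                                   stringsAsFactors = FALSE))
}

#' Binary white-matter map
#'
#' 1 where `P_w > P_g` and the hard segmentation is foreground
#' (`P_seg > 0`), else 0. Ties `P_w == P_g` give 0 (the inequality is
#' strict).
#'
#' @param p_g,p_w aligned [probability_volume] objects.
#' @param p_seg the hard segmentation from [hard_segmentation()].
#' @return a binary-valued [probability_volume].
#' @export
wm_prime <- function(p_g, p_w, p_seg) {
  stopifnot(inherits(p_seg, "label_volume"))
  assert_aligned(list(p_g, p_w, p_seg))
  vals <- as.numeric(p_w$values > p_g$values & p_seg$values > 0L)
  probability_volume(vals, p_g$grid)
}

#' Boundary-sharpened gray-matter map
#'
#' Per voxel, in order: 1 if `P_g > 0.5`; else `P_g` if `P_g > P_w`; else 0.
#' Saturating the GM interior to 1 gives a sharp WM/GM boundary while the
#' outer (pial) side keeps its partial-volume decay.
#'
#' @param p_g,p_w aligned [probability_volume] objects.
#' @return a [probability_volume].
#' @export
gm_prime <- function(p_g, p_w) {
  assert_aligned(list(p_g, p_w))
  g <- p_g$values; w <- p_w$values
  vals <- ifelse(g > 0.5, 1, ifelse(g > w, g, 0))
  probability_volume(vals, p_g$grid)
}

#' Assemble the full DiReCT input triple
#'
#' Runs [combine_gm_probability()] (when extra GM maps are given),
#' [hard_segmentation()], [wm_prime()] and [gm_prime()], and verifies the
#' internal-consistency theorem that `P_w' = 1` exactly where `P_seg = 3`
#' (provable by case analysis of the hardening rules). A violation indicates
#' an implementation bug, not bad data, and is a hard error.
#'
#' @param p_g a [probability_volume] of (cortical) GM probability, or a list
#'   of probability volumes to be merged by elementwise maximum.
#' @param p_w a [probability_volume] of WM probability.
#' @return an object of class `direct_input`: list with `p_seg`
#'   ([label_volume]), `p_w_prime` and `p_g_prime`
#'   ([probability_volume]s).
#' @export
prepare_direct_input <- function(p_g, p_w) {
  if (inherits(p_g, "probability_volume")) p_g <- list(p_g)
  p_g <- combine_gm_probability(p_g)
  assert_aligned(list(p_g, p_w))
  p_seg <- hard_segmentation(p_g, p_w)
  p_w_p <- wm_prime(p_g, p_w, p_seg)
  p_g_p <- gm_prime(p_g, p_w)
  if (!all((p_w_p$values == 1) == (p_seg$values == 3L)))
    stop("internal consistency violated: P_w' = 1 does not coincide with P_seg = 3")
  structure(list(p_seg = p_seg, p_w_prime = p_w_p, p_g_prime = p_g_p),
            class = "direct_input")
}

#' @export
print.direct_input <- function(x, ...) {
  n_gm <- sum(x$p_seg$values == 2L)
  n_wm <- sum(x$p_seg$values == 3L)
  cat(sprintf("<direct_input %s: %d GM, %d WM voxels>\n",
              paste(x$p_seg$grid$shape, collapse = "x"), n_gm, n_wm))
  invisible(x)
}
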