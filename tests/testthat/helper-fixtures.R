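# Shared fixtures: tiny direct inputs built from hard segmentations, and
# small phantoms. Everything is generated in code; no stored data.

grid_for <- function(shape, spacing = 1) {
  voxel_grid(shape, spacing = rep(spacing, 3L))
}

# direct_input from a hard segmentation array (codes 0/2/3): probabilities
# are the tissue indicators, which the hardening rules map back to `seg`
toy_input <- function(seg, spacing = 1) {
  g <- grid_for(dim(seg), spacing)
  p_g <- probability_volume((seg == 2L) * 1, g)
  p_w <- probability_volume((seg == 3L) * 1, g)
  prepare_direct_input(p_g, p_w)
}

# segmentation array: WM | GM | background slab along x (counts in voxels)
slab_seg <- function(nx_wm, nx_gm, nx_bg, ny = 8L, nz = 8L) {
  seg <- array(0L, dim = c(nx_wm + nx_gm + nx_bg, ny, nz))
  seg[seq_len(nx_wm), , ] <- 3L
  seg[nx_wm + seq_len(nx_gm), , ] <- 2L
  seg
}

small_shell_input <- function(thickness = 3, shape = 40L, inner = 7) {
  ph <- make_phantom(phantom_spec(kind = "shell", shape = rep(shape, 3L),
                                  inner_radius = inner,
                                  outer_radius = inner + thickness))
  list(phantom = ph, input = prepare_direct_input(ph$p_g, ph$p_w))
}
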