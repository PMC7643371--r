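# dlthick

Registration-based cortical thickness from tissue probability maps, in R.

The cerebral cortex is a gray-matter (GM) ribbon about 2.5 mm thick whose
thinning tracks aging and neurodegeneration, so reliable thickness measures
from MRI are a biomarker of wide interest. Surface-based pipelines measure
it from reconstructed meshes; the registration-based alternative (DiReCT:
diffeomorphic registration-based cortical thickness) works directly on
volumetric tissue maps: assuming the white-matter/GM and GM/CSF interfaces
share a topology, the inner interface is deformed onto the outer one by a
diffeomorphic flow and thickness is the distance each boundary point
travels. `dlthick` implements everything downstream of the tissue
segmenter, for anyone who has WM/GM probability volumes (from a deep
segmentation network, an atlas-based segmenter, or a phantom generator) and
wants thickness maps, regional statistics and cohort-level evaluation.

The package provides:

* **Input hardening.** Per voxel, with branches evaluated in order and the
  argmax starting at index 0 (ties to GM):

  $$P_{seg} = \begin{cases} \arg\max(P_g, P_w) + 2 & P_g + P_w > 0.7 \\ 2 & P_g > 0.5 \\ 3 & P_w > 0.5 \\ 0 & \text{otherwise,} \end{cases} \qquad
  P_w' = \begin{cases} 1 & P_w > P_g \text{ and } P_{seg} > 0 \\ 0 & \text{otherwise,} \end{cases} \qquad
  P_g' = \begin{cases} 1 & P_g > 0.5 \\ P_g & P_g > P_w \\ 0 & \text{otherwise,} \end{cases}$$

  yielding a hard segmentation (2 = GM, 3 = WM), a binary WM moving image
  and a GM map with a sharp inner boundary.
* **Thickness core.** Greedy composed-displacement propagation of the WM/GM
  interface toward the pial surface; per-point arc length in mm becomes the
  voxel-wise thickness map. The accumulated map is a composition of small
  invertible updates and its Jacobian determinant is verified positive at
  every iteration. An independent Laplacian solver (potential flow between
  the interfaces, streamline lengths) cross-checks the estimates.
* **ROI statistics.** Inner-boundary voxels are labeled by the nearest
  parcellation voxel (masked beyond 3.0 voxel units), averaged per region
  over nonzero thickness, then reduced to hemisphere and global means —
  with a 34-region-per-hemisphere atlas, the usual 70 measures per image.
* **Evaluation statistics.** Scan–rescan reproducibility error
  $\varepsilon_\mu = \frac{100}{N}\sum_i \frac{1}{n(i)} \sum_t |m_{i,t}-\mu_i|/\mu_i$ (%),
  covariate correction `lm(thick ~ eTIV + age)` fitted on healthy controls,
  Cohen's *d* with large-sample CI, longitudinal and cross-sectional atrophy
  rates with paired-t comparisons, and Bland–Altman method agreement.
* **Phantoms.** Slab / shell / gyrified-shell probability maps with
  analytically known thickness, plus cohort and re-scan simulators with
  known generative parameters, so the entire pipeline is testable without
  any imaging data.

## Worked example

Build a spherical-shell phantom with true thickness 3 mm, harden it,
estimate thickness and reduce it to ROI statistics:

```r
library(dlthick)

ph <- make_phantom(phantom_spec(kind = "shell", shape = c(48, 48, 48),
                                inner_radius = 8, outer_radius = 11))
d <- prepare_direct_input(ph$p_g, ph$p_w)
print(d)
#> <direct_input 48x48x48: 3440 GM, 2176 WM voxels>

thick <- estimate_thickness(d)
cat(sprintf("mean thickness in GM: %.3f mm (truth %.1f mm)\n",
            mean(thick$values[thick$values > 0]), ph$truth$thickness_mm))
#> mean thickness in GM: 3.024 mm (truth 3.0 mm)
cat(sprintf("min Jacobian determinant: %.3f\n", thick$diagnostics$min_jacobian))
#> min Jacobian determinant: 0.291

tab <- roi_thickness_table(thick, d$p_seg, ph$parc)
tab[, c("region", "hemisphere", "mean_thickness_mm", "n_voxels")]
#>             region hemisphere mean_thickness_mm n_voxels
#> 1      octant_ai_1       left             2.978       93
#> ...8 octant rows, all 2.978...
#> 9  hemisphere_mean       left             2.978      372
#> 10 hemisphere_mean      right             2.978      372
#> 11     global_mean       none             2.978      744
```

The propagated mean (3.024 mm) recovers the analytic truth within 1%; the
positive Jacobian minimum certifies the deformation never folded; the ROI
table shows the 8 octant regions, both hemisphere means and the global mean
all at 2.978 mm (boundary-voxel averages sit marginally below the GM-wide
mean because the inner boundary is sampled on the voxel lattice).

The same steps are scriptable from a shell via the thin CLI in
`inst/cli/dlth`:

```sh
dlth phantom shell --out-dir ph && dlth prep --gm ph/p_gm.nii.gz --wm ph/p_wm.nii.gz --out-dir direct
dlth thickness --seg direct/seg.nii.gz --wm-prime direct/wm_prime.nii.gz \
  --gm-prime direct/gm_prime.nii.gz --out thick.nii.gz
dlth roistats --thickness thick.nii.gz --seg direct/seg.nii.gz \
  --parc ph/parc.nii.gz --lut ph/parc_lut.tsv --out stats.csv
```

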