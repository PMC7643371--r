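---
title: "Methods: registration-based cortical thickness from probability maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registration-based cortical thickness from probability maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dlthick` estimates cortical thickness from soft white-matter (WM) and
gray-matter (GM) probability volumes, the typical output of a modern tissue
segmenter. The cortex is a thin GM ribbon, on average about 2.5 mm thick,
bounded by the WM/GM interface on the inside and the pial (GM/CSF) interface
on the outside. Under the assumption that the two interfaces share a common
topology, thickness can be measured by deforming the inner interface onto
the outer one with a diffeomorphic registration and recording the distance
each boundary point travels — the idea behind DiReCT-style
(diffeomorphic registration-based cortical thickness) pipelines. This
vignette documents the model, the numerical choices, and what the synthetic
tests do and do not demonstrate.

## Input hardening

Registration-based thickness works poorly on raw probability maps; the input
should resemble a hard segmentation with a crisp WM/GM boundary. Given GM
probability $P_g$ (the voxel-wise maximum over cortical GM, amygdala and
hippocampus probabilities — the elementwise maximum of probabilities equals
the sigmoid of the maximum logit because the sigmoid is monotone) and WM
probability $P_w$, three volumes are derived per voxel, with branches
evaluated strictly in order and all comparisons strict:

* **Hard segmentation** $P_{seg}$: if $P_g + P_w > 0.7$, the label is
  $\arg\max(P_g, P_w) + 2$ with the argmax starting at index 0 (so ties go
  to GM, label 2; WM is 3); else 2 if $P_g > 0.5$; else 3 if $P_w > 0.5$;
  else 0 (background/CSF).
* **Binary WM map** $P_w'$: 1 where $P_w > P_g$ and $P_{seg} > 0$, else 0.
  A binary moving image is appropriate because the WM region does not change
  topology during the registration.
* **Sharpened GM map** $P_g'$: 1 if $P_g > 0.5$; else $P_g$ if $P_g > P_w$;
  else 0. The GM interior saturates to 1 (sharp inner boundary) while the
  pial side keeps its partial-volume decay.

A provable consequence, checked at assembly time and under test on random
volumes, is that $P_w' = 1$ exactly where $P_{seg} = 3$: label 3 is only
reachable with $P_w > P_g$ (first branch) or $P_w > 0.5 \ge P_g$ (third
branch), and conversely every GM branch implies $P_w \le P_g$ or
$P_g > 0.5$ with $P_g + P_w \le 0.7$. The thresholds 0.7 and 0.5 are fixed
constants of the method.

## Thickness by diffeomorphic boundary propagation

`estimate_thickness()` seeds one boundary point per WM/GM interface voxel
(a GM voxel with a face-adjacent WM voxel, 6-connectivity). Points start at
the face midpoint toward their WM neighbours — the best sub-voxel estimate
of the interface available from a hard segmentation.

The outward direction comes from a *multiscale boundary-propagation
potential* $\psi = \sum_{s \in \{1,2,4\}} G_s * \chi_{WM} - G_s * \chi_{CSF}$
(Gaussian-smoothed WM indicator minus smoothed background indicator):
$\psi$ decreases monotonically from the WM side to the CSF side of the
band at every cortical width up to the thickness prior, so
$-\nabla\psi / |\nabla\psi|$ is a well-defined outward field across the whole
ribbon, where the gradient of any single-scale smoothing would vanish
mid-band. The velocity is this direction scaled by `gradient_step` and by
the local $P_g'$ (motion stops outside the ribbon), then Gaussian-smoothed
once with `field_smoothing_sigma`.

Each iteration composes the accumulated displacement with this one fixed,
small update map: $u_{k+1}(x) = u_k(x) + \tilde v(x + u_k(x))$. Because
every increment is the same smooth field with magnitude clamped below half
a voxel, each incremental map is invertible and the accumulated map is a
composition of diffeomorphisms; its Jacobian determinant is nonetheless
recomputed after every iteration (central differences of $\mathrm{id} + u$)
and the run aborts rather than return a folded field. An earlier design that
re-smoothed each iteration's update in material coordinates was discarded
because it let moving material pile up against the pial rim and produced
non-positive Jacobians on a plain 5 mm slab; the fixed-update composition is
the standard remedy and costs one smoothing pass total.

Boundary points are Lagrangian probes of the same field
($p_k = x_0 + u_k(x_0)$), accumulating Euclidean arc length in mm. A point
freezes when it crosses the pial surface of the segmentation — the
0.5-level of the interpolated hard GM indicator, with the crossing fraction
refined linearly. This is deliberately the same surface convention the
Laplacian solver uses, so the two methods measure between identical
surfaces; freezing on the 0.5-level of $P_g'$ instead is biased about +0.2
voxel outward, because $P_g'$ saturates to 1 inside GM and its interpolated
crossing overshoots the interface. The crossing test is "armed" only after
the point has been strictly inside GM (indicator $\ge 0.6$), which prevents
spurious freezing at the partial-volume inner interface where the
interpolated indicator starts near 0.5. Points also freeze when their path
length reaches `max_thickness_prior`.

Finally each point's total arc length is scattered to the GM voxels its
trajectory crossed (the nearest trajectory sample wins a voxel); GM voxels
crossed by no trajectory take the value of the nearest assigned GM voxel
within 2 voxels, else 0. The fill rule makes the map dense over the GM
ribbon, which downstream ROI averaging expects; whether a production
pipeline assigns values along trajectories only or over the full ribbon is
a convention, and this package's choice is explicit and tested.

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `max_iterations` | 45 | iterations | enough for 10 mm at the default step |
| `gradient_step` | 0.25 | voxels/iteration | per-iteration displacement; clamped at 0.45 so no update approaches half a voxel. Public DiReCT implementations quote a "gradient step" of 0.025 in their own energy parameterization; in this greedy scheme the step is literally the displacement per iteration, and 0.025 could not traverse a cortex within 45 iterations, so the default is set by the displacement budget instead. |
| `field_smoothing_sigma` | 1.0 | voxels | regularizes the update field; standard for ~1 mm grids |
| `max_thickness_prior` | 10 | mm | generous anatomical upper bound |
| `convergence_window` / `convergence_threshold` | 10 / 1e-6 | — | stop when front energy (summed active step lengths) is stationary |

The core contains no randomness: identical inputs and parameters give
bit-identical maps.

## Laplacian thickness (independent oracle)

`laplacian_thickness()` solves Laplace's equation on the GM domain with
Dirichlet boundary values 0 on WM and 1 on CSF (Jacobi iteration, Neumann
condition at the grid border, accepted at relative residual $10^{-5}$,
error if 20 000 sweeps do not converge), then integrates a streamline
through the normalized gradient field from every GM voxel in both
directions, stopping at the interpolated GM-indicator crossing. Thickness
is the summed streamline length. On parallel plates the potential is linear
and the method is exact to interpolation error; on concentric spheres the
streamlines are radial. GM voxels with no streamline connection to CSF
(e.g. GM fully enclosed by WM) get thickness 0 with a warning. The solver
shares only low-level array utilities with the propagation core and no
algorithmic machinery, so agreement between the two is a meaningful
cross-check: on the test phantoms the mean absolute difference is well
under 0.5 mm (0.07 mm measured across slab and shells).

## ROI statistics

The paper-style reduction to "70 measures per image" (34 regions per
hemisphere plus hemisphere means) is implemented as:

1. **Inner boundary**: all GM voxels with a face-adjacent WM voxel.
2. **Label assignment**: each boundary voxel takes the code of the nearest
   nonzero parcellation voxel (Euclidean distance in *voxel units*, as the
   masking rule is specified in voxel dimensions); voxels farther than
   `max_dist = 3.0` from every parcel are masked out, which excludes deep
   gray-matter structures whose boundary is not cortex. The search
   enumerates all integer offsets within the masking radius in increasing
   distance — exact within the radius — and distance ties resolve to the
   lower numeric code, making the assignment deterministic.
3. **Region means**: arithmetic mean of the *nonzero* thickness values per
   region; a region with no nonzero voxel is reported as missing (`NA`),
   never as 0. Averaging is over the labeled boundary voxels: whether a
   production pipeline averages boundary voxels or the full parcel ribbon
   is ambiguous, and the boundary reading is implemented because the ROI is
   *defined* from boundary voxels.
4. **Hemisphere and global means**: hemisphere means are voxel-count
   weighted by default (closest to a surface-wide mean; an unweighted
   variant is available via `weighted = FALSE`); the global mean is the
   unweighted average of the two hemisphere means and is missing when
   either hemisphere has no usable record.

## Evaluation statistics

* **Reproducibility error**: for sessions with $n(i) \ge 2$ same-session
  re-scans, $\varepsilon_\mu = \frac{100}{N}\sum_i \frac{1}{n(i)}\sum_t
  |m_{i,t} - \mu_i| / \mu_i$ with $\mu_i$ the within-session mean —
  scale-invariant, zero iff all re-scans agree. Under multiplicative noise
  $m = \mu(1+e)$, $e \sim N(0, \sigma^2)$, two re-scans give
  $E[\varepsilon_\mu] = 100\,\sigma/\sqrt{\pi}$, the closed form the test
  suite checks at $\sigma = 1\%$ (0.564%).
* **Covariate correction**: OLS of thickness on standardized eTIV and age,
  fitted on healthy controls only (standardization parameters from the HC
  sample are stored and reused), then applied to all scans by subtracting
  the covariate terms. The intercept is retained so corrected values stay
  on the mm scale and the corrected HC mean equals the observed HC mean.
  Sex and scanner can be added as dummy-coded covariates but are off by
  default, since both are typically eliminated in covariate screening.
* **Cohen's d**: pooled-SD standardized mean difference, with the
  large-sample CI $d \pm z_{97.5}\sqrt{(n_a+n_b)/(n_a n_b) +
  d^2/(2(n_a+n_b-2))}$. Dedicated effect-size packages use slight variants
  of this interval; differences are negligible at the cohort sizes involved.
* **Atrophy rates**: per-subject OLS slope of the measure against time in
  years over all timepoints (an endpoint-difference variant is available;
  identical for two timepoints), including only subjects whose scans span
  at least one year and whose CDR-derived group is constant. Rates of two
  methods are compared with a two-sided *paired* t-test; an all-zero
  difference vector is reported as p = 1 rather than an error.
* **Method agreement**: per region, Pearson r across matched scans plus the
  Bland–Altman bias and limits of agreement (bias ± 1.96 SD of the paired
  differences).

## Synthetic data

`make_phantom()` builds slab, spherical-shell and gyrified-shell phantoms
whose true thickness is known exactly (band width, or outer minus inner
radius). Probabilities are logistic in the signed distance to the analytic
interfaces with softness `sigma_edge` (default 0.5 mm), emulating the
partial-volume softness the hardening rules were designed for;
$P_g = (1 - P_w)\,\mathrm{logistic}(-s_{out}/\sigma)$ guarantees
$P_g + P_w \le 1$. Slab interfaces are placed on voxel faces, as a
voxelized tissue map would have them; shell interfaces cannot be
face-aligned, so shell recoveries also exercise sub-voxel averaging.
Parcellations label the hard GM band: 8 octants for shells (hemispheres
split at the x = center plane — the smallest scheme exercising region,
hemisphere and global reductions), 4 stripes × 2 hemispheres for slabs.
The gyrified shell modulates the outer radius sinusoidally (≤ 1 mm) to
stress non-convex geometry; it participates in invariant checks
(diffeomorphism, caps) but not tight-tolerance recovery, since its true
mean thickness is not a closed form.

`simulate_cohort()` emulates the statistical structure of a dementia
cohort study: thickness = baseline 2.5 mm + age slope × (age − mid-age) +
eTIV effect × standardized eTIV + group shift + subject effect + scan
noise. Defaults (ages 45–90, slope −0.005 mm/year, eTIV effect 0.02 mm/SD,
between-subject SD 0.1 mm, scan noise 0.03 mm, dementia shift expressed as
a true Cohen's d against the within-group SD, the questionable group at
half the dementia shift) were chosen once as representative of elderly
cohort studies and are not tuned per test; recovery tests override only
the parameters their scenario prescribes (sample sizes, slopes, noise).
`simulate_rescans()` adds multiplicative session noise with the closed-form
reproducibility expectation above. All generators are pure functions of
(spec, seed).

What the phantoms do **not** emulate: MRI intensities, bias fields, scanner
artifacts, realistic cortical folding, topological defects in the
segmentation, or segmenter errors correlated with anatomy. Passing the
phantom suite therefore demonstrates that the geometry and statistics
machinery is correct — not that thickness estimates on real MRI are
accurate, which additionally depends on segmentation quality.

## Numerical conventions and degenerate inputs

* Voxel indices are 0-based in all geometry code; world coordinates come
  from the NIfTI affine; distances for the ROI masking rule are in voxel
  units, arc lengths in mm via the voxel spacing.
* Volumes are float32 on disk (labels int32); probabilities may exceed
  [0, 1] by at most 1e-6 (float I/O noise) and are clipped with a warning;
  larger deviations are errors. Grids are "aligned" when shapes match and
  affines agree within 1e-5; nothing is ever silently resampled.
* Face (6-)connectivity defines all interfaces; out-of-grid neighbours
  count as background for the pial interface.
* An all-GM volume has no WM/GM interface and is an error for interface
  extraction; a segmentation whose GM never touches WM yields an all-zero
  thickness map with a warning (there is nothing to propagate).
* Test problem sizes: the slab recovery runs on a 64³ grid at 1 mm with a
  5 mm band; shell recoveries on 48³ grids with 2/3/4 mm shells; the
  resolution-consistency check compares 1 mm and 0.5 mm samplings of the
  same 4 mm slab. These sizes give a few thousand boundary points per
  phantom, enough that voxelization noise averages out (recovered means
  within ~2% of truth) while the full suite stays fast.

## Known limitations

* The propagation's energy and parameterization are not numerically
  identical to any particular production DiReCT implementation; agreement
  is validated against analytic phantoms and the independent Laplacian
  solver instead.
* Thickness is only measured where the WM/GM interface exists; GM with no
  WM contact (e.g. after severe segmentation failure) is reported as zero,
  and regions whose boundary voxels all lack thickness are reported
  missing.
* The boundary-voxel count underestimates the analytic interface area by
  roughly 10% on spheres (a voxel adjacent to several WM faces counts
  once); this affects diagnostics only, not thickness averages.
* Hemisphere assignment comes entirely from the parcellation legend; a
  parcellation without left/right information yields hemisphere means of
  `NA` and no global mean.
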