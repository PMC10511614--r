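# aaastrain

Local wall-strain analysis for 4D ultrasound imaging of abdominal aortic
aneurysms (AAAs).

Time-resolved 3D ("4D") ultrasound with speckle tracking measures the motion
of the aneurysm wall over the cardiac cycle as a structured grid of material
points (rings of 36 circumferential points along the vessel).  A single
manual segmentation of such an acquisition carries a considerable random
error, so strain maps from one segmentation support group comparisons but
not conclusions about an individual patient.  `aaastrain` implements the
workflow that addresses this:

1. **Averaged wall-motion models.**  Several segmentations of *one*
   acquisition are unwrapped into cylindrical coordinates, re-meshed onto a
   common homogeneous grid in the end-diastolic reference frame, and each
   homogeneous point is anchored inside its host quadrilateral element at
   local isoparametric coordinates (r, s).  The point is then carried
   through the cycle by the element's bilinear shape functions,
   `H^t = sum_a N_a(r, s) x_a^t` with `N_a(r, s) = (1 + r r_a)(1 + s s_a)/4`,
   and the K segmentations are averaged point-wise per frame.  Averaging
   suppresses the random segmentation error roughly like 1/sqrt(K) while
   the homogeneous re-mesh keeps the element shapes regular.
2. **In-plane Biot strain.**  Per element and frame, the in-plane
   deformation gradient `F` is evaluated at the element centroid from the
   shape-function derivatives, in local element frames (axis 1
   longitudinal, axis 2 circumferential) that are re-derived in every
   configuration so rigid body motion drops out.  The strain is
   `eps = U - I`, with `U = sqrt(F^T F)` the right stretch tensor
   (closed-form 2x2 square root).  Per element, the peak-to-peak amplitude
   `max_t eps - min_t eps` of each component summarises the cycle.
3. **Registration to CT.**  The ultrasound geometry is aligned to a
   CT-derived wall point cloud with a bounded iterative-closest-point
   scheme (k-d tree correspondences, Levenberg–Marquardt updates with box
   constraints): rigid (`R_x R_y R_z` + translation) for geometry
   comparison, affine (`M_s M_r M_h`, scale–rotation–shear) for mapping
   calcifications onto wall elements.  Because the cardiac phase of the CT
   scan is unknown, every ultrasound frame is registered and the frame with
   the smallest RMSE is kept; RMSE and (symmetric and directed) Hausdorff
   distances quantify the agreement.
4. **Regional statistics.**  Elements are classified as calcified when at
   least half of their area (sampled on a 10x10 lattice through the shape
   functions) lies within a capture radius of the registered calcification
   cloud.  Amplitude distributions per region are summarised by
   distribution indices — mean strain, maximum strain, local strain ratio
   (max/mean) and heterogeneity index (sd/mean) — and compared with a
   left-tailed Mann–Whitney U test of the hypothesis that calcified wall
   regions strain less.
5. **Synthetic phantom.**  A pulsating fusiform aneurysm generator with
   known per-element ground truth (radius profile, compliance map with
   calcified patches at factor kappa, noisy segmentations, CT-like clouds
   under a known transform) makes the whole pipeline testable without
   patient data.

## Worked example

```r
library(aaastrain)

spec  <- phantom_spec()                 # 50 mm AAA, 14 x 36 grid, 20 frames
truth <- generate_phantom(spec)
segs  <- make_segmentations(truth, K = 10, seed = 7)   # noisy segmentations
avg   <- average_segmentations(segs)

amps  <- strain_amplitudes(strain_series(avg$model))
amps0 <- strain_amplitudes(strain_series(truth$grid))  # noise-free reference
lab   <- truth$elements$calcified
round(100 * c(mean_noisefree = mean(amps0$amp22),
              calc  = mean(amps0$amp22[lab]),
              nocalc = mean(amps0$amp22[!lab])), 3)
#> mean_noisefree           calc         nocalc
#>          1.141          0.900          1.178
mannwhitney_left(amps0$amp22[lab], amps0$amp22[!lab])$p_value
#> [1] 2.421887e-38
```

On the noise-free phantom the mean circumferential amplitude is 1.14 %
(inside the 0.5–3 % band typical for AAA walls), calcified elements strain
0.90 % versus 1.18 % elsewhere — a 23.6 % reduction by construction
(kappa = 0.75 with part-covered border elements) — and the left-tailed
Mann–Whitney test separates the regions decisively.  With the default
segmentation noise (sd 0.3 mm per node and frame) the amplitudes of noisy
segmentations are noise-dominated; see the methods vignette
(`vignettes/methods.Rmd`) for what averaging does and does not recover
under that model.

Registration of the simulated CT clouds works the same way:

```r
ct  <- make_ct_clouds(truth, frame = 6, transform = rigid_params(
         angles = c(5, -3, 6) * pi / 180, t = c(4, -2, 3)), seed = 1)
sel <- select_best_frame(avg$model, ct$wall)    # rigid, all frames
sel$best_frame; sel$best$final_rmse
```

A thin command-line front end with `simulate / average / strain / register /
classify / report / run` subcommands is installed at
`inst/cli/aaastrain.R`.

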