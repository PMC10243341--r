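# perfct

Simulation and reconstruction toolkit for **low-dose dynamic
contrast-enhanced CT (DCE-CT) cerebral perfusion** studies, for
researchers studying how spatiotemporal regularization affects
perfusion quantification under photon starvation.

Repeatedly scanning a brain slice during contrast passage (50 frames,
1 s apart) forces a low tube current, and the resulting Poisson
counting noise corrupts the time-attenuation curves from which
cerebral blood flow (CBF), blood volume (CBV) and mean transit time
(MTT) are computed. `perfct` implements the full chain needed to study
this quantitatively, with no external data dependencies:

* **Digital brain-perfusion phantom** — skull, gray/white matter, CSF,
  vessel, optional penumbra + ischemic-core lesion; every pixel has
  analytic ground-truth CBF/CBV/MTT, and tissue enhancement follows
  the indicator-dilution model
  `C(t) = (rho/kH) CBF (C_AIF * R)(t)` with a mono-exponential residue.
* **Fan-beam projector** — equiangular geometry (1000 views × 377
  detector bins at full scale), Siddon ray tracing as a cached sparse
  system matrix (back projection is the exact adjoint), Beer-Lambert
  counting noise `I = I0 exp(-P)` with Poisson + Gaussian readout
  noise and unity clamping.
* **FBP** — Ram-Lak and Shepp-Logan filters for the equiangular fan
  geometry; the noise-free Ram-Lak series ("REF") is the evaluation
  reference.
* **Regularized reconstruction** — four objectives solved by a
  Chambolle-Pock primal-dual iteration:

  | method | objective |
  |--------|-----------|
  | TV   | ½‖Ax−b‖² + α‖∇₃x‖₁ |
  | TGV  | ½‖Ax−b‖² + min_v α₁‖∇₃x−v‖₁ + α₀‖Ev‖₁ |
  | LTV  | ½‖A(L+S)−b‖² + α‖∇₃S‖₁ + β‖L‖\* |
  | LTGV | ½‖A(L+S)−b‖² + TGV²(S) + β‖L‖\* |

  with ∇₃ the spatiotemporal forward-difference gradient, E the
  symmetrized gradient, ‖·‖\* the nuclear norm of the Casorati
  (pixels × frames) matrix, and x̂ = L̂ + Ŝ for the low-rank variants.
* **Perfusion quantification** — baseline-subtracted contrast
  enhancement, arterial input extraction by fuzzy c-means on a vessel
  ROI, block-circulant SVD deconvolution (delay-insensitive,
  truncated-SVD regularized), CBF from the residue peak, CBV from the
  area ratio, MTT = 60·CBV/CBF.
* **Evaluation** — PSNR, frame-averaged SSIM (Wang defaults), linear
  regression of maps against REF, ROI mean/SD analysis, and tidy
  parameter sweeps over the regularization weight.

## Worked example

```r
library(perfct)

spec <- phantom_spec(grid_size = 64, n_frames = 32, dt = 1,
                     pixel_spacing = 4, lesion = list())
geom <- scan_geometry(n_views = 180, n_detectors = 128,
                      grid_size = 64, pixel_spacing = 4)
lm     <- build_phantom(spec)
series <- render_dynamic_hu(lm, spec)           # dynamic HU series
sino   <- lowdose_from_series(series, geom,     # noisy line integrals
                              noise_model(I0 = 2.5e5, seed = 1))

rec <- reconstruct(sino, geom,
                   regularizer_config("ltgv", alpha = 0.0025,
                                      n_max = 150))
rec$report
#> primal-dual solve: 150 iterations, iteration cap reached
#>   final relative change 0.000114, steps sigma = 0.25 tau = 0.25

ce   <- contrast_enhancement(rec$series, 1:8)
aif  <- extract_aif(ce, lm$rois$ica)
maps <- compute_maps(ce, aif, lm$brain_mask)
print(maps)
#> perfusion maps (2056 perfused px): CBF 53.1, CBV 4.35, MTT 5.65 (means)
```

The printed summary is the mean over perfused brain pixels: mixed
gray/white tissue averaging between the gray-matter truth
(60 mL/100 g/min, 4 mL/100 g) and white-matter truth (25, 2), with
the bias of reconstruction smoothing and the 10% SVD truncation of
the deconvolution; MTT is pulled above the tissue truths of 4 s (GM)
and 4.8 s (WM) by the truncation's CBF underestimation. On the
*noise-free rendered* series with negligible SVD truncation the same
pipeline recovers per-tissue CBV within 2% and CBF within 5%.

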