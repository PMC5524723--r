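# msrbeta

Adaptive contrast enhancement for low-contrast, unevenly illuminated
greyscale images — the kind produced by near-infrared cameras over
recirculating-aquaculture fish tanks, where a single overhead lamp leaves
frames dim at the edges and the grey histogram concentrated in a narrow
band. The package is for image-analysis pipelines (fish detection, counting,
segmentation) that need a contrast-rich, evenly lit input without hand-tuned
per-image parameters.

## Method

Two stages, with the second's parameters selected automatically per image:

1. **Multi-Scale Retinex (MSR)** removes the smooth illumination field in
   the log domain:

   R(x,y) = Σₖ ωₖ { log[I(x,y)+ε] − log[(F_cₖ ∗ I)(x,y)+ε] },
   F_c(x,y) ∝ exp(−(x²+y²)/c²),

   with unit-sum Gaussian surrounds at scales c = 15, 80, 250 and weights
   1/3.

2. **Incomplete-Beta grey transform**: the MSR output is normalized to
   [0, 1] by its own min/max and passed through the regularized incomplete
   Beta function F(u; α, β) — the Beta CDF, a monotone [0,1] → [0,1] curve
   family spanning dark-stretching, bright-stretching, S and inverse-S
   shapes for 0 < α, β < 10 — then mapped back to [0, 255].

   The shape pair (α, β) is chosen by **particle swarm optimization**
   (10 particles, 100 iterations, c₁ = c₂ = 2, inertia 0.9 → 0.4, v_max = 5)
   maximizing the output's grey-value variance

   Fitness = (1/NM) Σ f‴² − [(1/NM) Σ f‴]²,

   which is also the "contrast" metric the package reports.

Also included: the contrast/MSE/PSNR/entropy quality-metric suite,
linear-stretch and histogram-equalization baselines, a seeded synthetic
tank-scene generator with ground-truth illumination, PNG/BMP/TIFF greyscale
I/O, and a command-line front end (`inst/cli/msrbeta`).

## Worked example

```r
library(msrbeta)

# a seeded synthetic tank scene: dark fish blobs, radial lamp field, noise
scene <- synth_scene(scene_config(seed = 42))
img_contrast(scene$image)   # 627.9947  — low-contrast input
img_entropy(scene$image)    # 6.474285 bits

res <- enhance(scene$image, pso_config = pso_config(seed = 0))
res
#> <enhancement_result> MSR + adaptive Beta transform
#>   selected (alpha, beta): (9.9000, 2.5189)
#>   PSO best fitness: 5123.2292 after 100 iterations (seed 0)
#> <quality_report>
#>   contrast: 5123.0061
#>   MSE:      6042.6537
#>   PSNR:     10.3185 dB
#>   entropy:  7.6261 bits

img_contrast(msr_rescaled(scene$image))  # 1380.642 — MSR alone, linear stretch
write_gray(res$enhanced, "enhanced.png")
```

Reading the numbers: the adaptive pipeline lifts the grey-value variance
from 628 (original) past 1381 (MSR + plain linear stretch) to 5123, an
~8-fold contrast gain, while entropy rises from 6.47 to 7.63 bits — the
histogram both widens and fills in. The selected S-curve (α = 9.9, β = 2.5)
is steepest where the normalized MSR histogram is densest. MSE/PSNR are
computed against the original frame, so for an enhancement this aggressive
they mainly quantify how far the image moved.

The same run from the shell:

```sh
Rscript inst/cli/msrbeta enhance tank.png enhanced.png \
    --seed 0 --report report.json --trace trace.csv
```

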