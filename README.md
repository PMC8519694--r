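# smbft

Superpixel segmentation by spatially regularized fuzzy c-means (SMBFT),
with the standard evaluation metrics and a seeded phantom generator.

## Why fuzzy superpixels

Superpixels are small, connected, homogeneous regions used as atomic units
in image analysis. Classical superpixel methods commit each pixel to a
single region at every step; on images with genuinely fuzzy boundaries —
brain MR slices, where partial-volume effects blur the tissue interfaces —
that hard commitment misclassifies boundary pixels and single superpixels
end up containing several tissues. SMBFT keeps the assignment fuzzy until
the end: it minimizes

```
J = Σ_i Σ_k u_ik^p [ ‖y_k − v_i‖² + α((X_k − X_i)² + (Y_k − Y_i)²)
                     + (β/N_R) Σ_{r∈N_k} ‖y_r − v_i‖² ]
```

over memberships `u_ik` (each pixel's memberships sum to 1), intensity
centers `v_i` and coordinate centers `(X_i, Y_i)`. The coordinate term
(weight `α`) keeps clusters compact and non-crossing — it is what turns a
fuzzy c-means intensity clustering into a superpixel method — and the
8-neighborhood term (weight `β`, normalizer `N_R = 8`) scores each pixel's
neighbors against the candidate center so that isolated noisy pixels
cannot flip an assignment. All three blocks have closed-form updates
(Lagrange multipliers for the constrained membership block), which are
alternated until the centers stop moving; hard labels are the membership
argmax, then connectivity is enforced and undersized regions are merged
into their closest-mean neighbor. Color images run through the identical
pipeline in CIE L\*a\*b\*.

The package also implements the usual segmentation criteria:
undersegmentation error `UE`, boundary recall `BR(ε)`, the composite
average accuracy rate `AAR = μ(1 − UE) + (1 − μ)BR`, and per-superpixel
intensity entropy for gray images without a ground truth. A phantom
generator (piecewise-constant templates + Gaussian noise + a smooth
multiplicative bias field, with exact ground truth) makes the whole
pipeline testable at desk scale.

## Worked example

Segment a noisy, bias-shaded three-tissue phantom into 100 superpixels and
score the result against the known truth:

```r
library(smbft)

ph <- generate_phantom(phantom_spec(shape = c(128, 128), template = "brain",
                                    intensities = c(20, 120, 200),
                                    noise_pct = 5, bias_pct = 40, rng_seed = 42))
seg <- superpixels(ph$image, k = 100, alpha = 2, beta = 1)
seg$fit
#> SMBFT fit: 100 clusters on a 128 x 128 image
#>   100 iteration(s), iteration cap reached (final center shift 0.0185)
#>   objective 1.08441e+06 -> 999246

evaluate_segmentation(seg$labels, ph$gt, image = ph$image)
#> Segmentation metrics
#>   superpixels:  100
#>   UE:           0.0000
#>   BR:           1.0000
#>   AAR:          1.0000
#>   mean entropy: 3.4399
```

The objective decreases monotonically across iterations (each update is
the exact minimizer of its block). `UE = 0` means no superpixel straddles
a tissue boundary; `BR = 1` means every true boundary pixel lies within 2
pixels of a superpixel boundary; `AAR` combines the two with equal weight
and reaches its maximum of 1 exactly at that ideal. The mean entropy is
the average Shannon entropy of the superpixels' intensity histograms —
noise inside otherwise homogeneous regions keeps it above zero.

## Command line

A thin wrapper in `inst/scripts/smbft` drives the same functions from a
shell:

```sh
smbft phantom --template brain --noise 5 --bias 40 --seed 42 \
      --out-image ph.png --out-gt gt.tif
smbft segment --input ph.png --output labels.tif --k 100 --alpha 2 --beta 1
smbft eval    --labels labels.tif --gt gt.tif --image ph.png --eps 2 --mu 0.5
smbft sweep   --input ph.png --gt gt.tif --k 50,100,200 --out sweep.csv
```

`--config file.yaml` supplies defaults that flags override; `segment` logs
the objective trace so convergence can be audited afterwards.

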