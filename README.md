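# scribseg

Minimally interactive segmentation of sparse, motion-corrupted 3D MRI —
built for structures like the placenta in fetal MRI, where slices are sharp
but thick (0.74 mm in-plane vs 3–4 mm between slices), inter-slice motion
corrupts the stack, and the organ's shape varies too much between subjects
for atlas priors. The intended users are medical-image-analysis researchers
and tool builders who need accurate volumetric masks from minimal
interaction: **scribbles in one start slice per volume**.

## Method

Two phases:

1. **Single-volume propagation.** An online random forest (N = 20 trees,
   depth ≤ 10) learns foreground probability from the scribbled pixels'
   patch features — intensity mean/sd, GLCM texture and Haar wavelet
   statistics of each pixel's 9×9 neighborhood. Streaming updates use
   online bagging (each sample replicated Pois(λ = 1) times per tree). The
   posterior is regularized per slice by a conditional random field

       E(C) = Σᵢ −log p(cᵢ) + λ₁ Σ_{(i,j)∈N₁} B_ij · [cᵢ ≠ cⱼ],
       B_ij = exp(−(Iᵢ−Iⱼ)² / 2σ₁²) / dist(i,j)

   solved *exactly* by max-flow/min-cut. The labeling propagates
   slice-by-slice in both directions; after each slice, the foreground
   skeleton and the 10-px-eroded background are harvested as new training
   data, so the forest tracks appearance drift across slices.

2. **4D probability-based co-segmentation.** Volumes of the same subject in
   different views are fused by one joint graph cut adding inter-slice
   terms (λ₂ = 10, σ₂ = 0.005, on the phase-1 probabilities) and
   inter-volume terms over nearest-voxel correspondences (λ₃ = 3,
   σ₃ = 0.08, no distance factor), refining all views simultaneously.

A synthetic phantom generator (sparse slicing, per-slice gain drift,
1-mm inter-slice motion, textured background, crescent- or
ellipsoid-shaped object) makes every stage testable without any data
download, and `dice()`, `assd()`, `fleiss_kappa()` implement the standard
evaluation metrics. See `vignettes/methods.Rmd` for the full model,
parameter table and design rationale.

## Worked example

```r
library(scribseg)

# a two-view phantom study: axial-like 0.74x0.74x3 mm and a rotated
# 1.48x1.48x4 mm view of the same crescent-shaped object
study <- generate_study(phantom_spec(seed = 5), n_views = 2)

# "user" scribbles: 100 mm foreground + 100 mm background per view,
# drawn inside the eroded truth of the middle object slice
scribbles <- lapply(1:2, function(k)
  auto_scribbles(study$truths[[k]],
                 middle_object_slice(study$truths[[k]]),
                 fg_len_mm = 100, bg_len_mm = 100, seed = k))

res <- run_study(study, scribbles, seg_config())

for (k in 1:2)
  cat(sprintf("view %d: initial Dice %.4f -> refined Dice %.4f (ASSD %.2f mm)\n",
              k, dice(res$initial[[k]]$label_volume, study$truths[[k]]),
              dice(res$refined[[k]], study$truths[[k]]),
              assd(res$refined[[k]], study$truths[[k]])))
```

```
view 1: initial Dice 0.9967 -> refined Dice 0.9969 (ASSD 0.01 mm)
view 2: initial Dice 0.9534 -> refined Dice 0.9846 (ASSD 0.22 mm)
```

Phase 1 alone already recovers each volume well from 200 mm of scribbles;
the joint 4D refinement then fuses the views' complementary resolution —
the weaker view gains the most. `res$initial[[k]]$per_slice_log`
records per-slice training-set sizes, foreground areas and CRF energies.

A thin command-line wrapper ships in `inst/scripts/scribseg`
(`phantom`, `segment`, `coseg`, `evaluate` subcommands over NIfTI + JSON
files); `read_config()` loads a YAML file mirroring `seg_config()`.

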