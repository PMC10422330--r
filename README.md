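# reef3d

Fine-grained, three-dimensional monitoring of coral-reef habitats from
photogrammetric survey products.

Reef monitoring has traditionally reduced to two-dimensional cover
percentages, but the ecological value of a reef lives in its 3D structure:
branching corals create the rugosity that shelters fish and invertebrates,
and bleaching events change that structure faster than cover statistics
reveal. Underwater photogrammetry now delivers millimeter-resolution
orthomosaics, digital surface models (DSMs), dense point clouds and meshes
of fixed reef plots across repeat surveys. `reef3d` turns those products
into class-aware structural change measurements:

1. **Multi-modal semantic segmentation** of co-registered orthomosaic +
   DSM patches into background / live coral / dead coral, with an
   encoder-decoder network (ASPP, decoder with separable convolutions)
   whose backbone uses **shape-aware convolutions**: each K x K window is
   split per channel into its spatial mean (*base*) and the residual
   (*shape*), reweighted with learnable weights and recombined before the
   convolution, so the network exploits local relief rather than absolute
   depth. Training uses the hybrid loss

   L = L_CE + mu * L_IoU,  mu = 0.4,

   cross entropy for smooth per-pixel gradients plus a soft
   intersection-over-union term that scores whole regions. Evaluation uses
   mean pixel accuracy (mPA) and mean intersection-over-union (mIoU) with
   five-fold cross-validation support.
2. **Structural change analysis** stratified by the predicted classes:
   pixel-wise DSM differencing (reported in mm, median-based summaries),
   multi-scale **Vector Ruggedness Measure** (VRM: one minus the
   normalized resultant of per-cell unit normals in a moving window, 0 =
   flat, 1 = maximally rugged) from Horn slope/aspect, multi-scale 3D
   **point-cloud roughness** (distance of each point to the total
   least-squares plane of its radius neighbors), and projection of masks
   and change maps onto triangle meshes for 3D inspection.

Because no public dataset exists at this scale, the package includes a
first-class synthetic scene generator producing two-epoch reef scenes with
*known* growth, mortality and colony removal; the entire pipeline is
validated end-to-end against that ground truth.

## Worked example

Two synthetic epochs with prescribed change — 10 mm of growth on surviving
live colonies and 25% live-coral mortality — analyzed exactly as a real
survey pair would be:

```r
library(reef3d)

p <- scene_params(extent_px = c(256, 256), n_colonies = 6, seed = 1,
                  colony_radius_range = c(0.025, 0.04),
                  colony_height_range = c(0.03, 0.06))
s2018 <- generate_scene(p)
s2019 <- evolve_scene(s2018, epoch_delta(growth_mm = 10,
                                         mortality_fraction = 0.25, seed = 2))

change <- dsm_difference(s2019$dsm, s2018$dsm)   # mm
change_summary(change)$stats$median                          # scene-wide
change_summary(change, s2019$labels, class_id = 1)$stats$median  # live coral

v <- vrm(s2019$dsm, 21)                           # 21 mm window
stratify_by_class(v$vrm, s2019$labels, scale = 21)

cloud <- sample_point_cloud(s2019, 1, jitter = FALSE)
cloud <- roughness(transfer_labels(cloud, s2019$labels), 0.02)
stratify_by_class(cloud, scale = 0.02, scalar_name = "roughness_r20")
```

Output:

```
scene median change (mm): 0
live-coral median change (mm): 10

  class scale     n     median       mean      # VRM, 21 mm window
1     0    21 34908 0.05486452 0.09888169
2     1    21 15054 0.21515984 0.22758238
3     2    21  4794 0.23359707 0.24079617

  class     n       median                      # 3D roughness, r = 20 mm
1     0 45326 0.0005127935
2     1 15294 0.0024906116
3     2  4916 0.0029816150
```

Reading the numbers: the scene-wide median height change is 0 mm (most
cells are static sand) while the live-coral median recovers the prescribed
10 mm exactly — the same scene-median < class-median relationship seen in
real two-epoch surveys, where growth concentrates on the living colonies.
At the 21 mm window, coral-class VRM (~0.22) is roughly four times the
sandy-background VRM (~0.05), and point roughness at r = 20 mm shows the
same contrast (~2.5 mm vs ~0.5 mm): structural complexity metrics separate
coral from substrate at fine scales. Dead colonies score slightly *higher*
than live ones here because their intact skeletons keep full ridge relief.

Model training follows the classic fitting idiom:

```r
patches <- extract_patches(s2019$ortho, s2019$dsm, s2019$labels,
                           window = 64, stride = 32)
model <- mmcs_fit(patches, mmcs_config("tiny"), epochs = 10, seed = 1)
summary(model)            # per-run validation mPA / mIoU
pred <- predict(model, s2019$ortho, s2019$dsm)
seg_eval(pred$label, s2019$labels)
```

A command-line interface wraps the same functions
(`inst/scripts/reef3d`): `synth`, `tile`, `split`, `train`, `predict`,
`eval`, `vrm`, `heightchange`, `roughness`, `project-mesh`, and `demo`,
which runs the full two-epoch workflow and writes a `summary.json`. Every
command records a JSON sidecar with its inputs, parameters and seed.

See `vignettes/reef3d-methods.Rmd` for the model, the measurement
definitions, parameter defaults and their rationale, and known
limitations.

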