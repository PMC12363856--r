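# labelmorph

Anatomy-aware, label-informed deformable image registration and the
volumetric morphometrics built on top of it, for 3D (and 2D) scalar
volumes such as contrast-enhanced microCT of mouse embryos.

Overt phenotypes — severe scoliosis, displaced or resized organs — make
subjects fail to register to a normative template with intensity-only
methods, which silently invalidates every downstream voxel statistic.
`labelmorph` lets anatomical label maps (segmentations from any source)
drive the registration: label centers of mass initialise the linear
alignment, a masked diffeomorphic engine refines it on intensities, and an
optional stage refines on a label-similarity metric. The package also
implements the downstream analyses in the standard notation of the field:

* **Tensor-based morphometry (TBM)**: per voxel, the log-Jacobian
  determinant `log J(x)` of the forward (template-to-subject) transform is
  compared across groups with the pooled two-sample t-test (equivalently,
  OLS on a group indicator), with Benjamini–Hochberg FDR control and
  significance heatmaps of the group difference in mean `log J`
  (`log J < 0` = local volume reduction).
* **Deformation PCA (morphospace)**: PCA of the combined inverse
  displacement fields sampled on the template grid within the body mask;
  PC-extreme warps of the template visualise each mode.
* **Label volume statistics**: physical volumes in mm^3 and per-organ
  Welch t-tests, from per-subject tables or directly from published
  mean/sd/n summaries.
* **Synthetic phantoms**: a seeded generator of multi-organ phantoms with
  known ground-truth diffeomorphic deformations (scoliosis-like quadratic
  bends with analytic Jacobian 1, per-organ volume scalings with core
  `log J = ln f`, random elastic individuality), so every stage is
  testable against analytic truth with no external data.

Minimal NIfTI-1 I/O (.nii/.nii.gz, including vector displacement fields)
and a CLI are included.

## Worked example

```r
library(labelmorph)

# template phantom with 8 organs + a severely bent, organ-scaled subject
tpl <- make_template_phantom(phantom_spec(shape = 48, spacing = 0.08,
                                          noise_sd = 4, seed = 11))
sub <- make_subject(tpl, subject_spec(bend_amplitude = 0.3,
                                      organ_scale = c("4" = 0.5, "5" = 0.5,
                                                      "3" = 1.3),
                                      seed = 501))

# label-informed vs intensity-only registration of subject to template
rl <- label_image_registration(tpl$intensity, tpl$labels,
                               sub$intensity, sub$labels, mask = tpl$mask)
ri <- intensity_only_registration(tpl$intensity, sub$intensity,
                                  mask = tpl$mask)
g <- tpl$intensity$grid
epe <- c(label = endpoint_error(rl$forward, sub$true_forward, g, tpl$mask),
         intensity = endpoint_error(ri$forward, sub$true_forward, g,
                                    tpl$mask)) / min(g$spacing)
round(epe, 2)
#>     label intensity
#>      1.55      2.06
```

The recovered transform from the label-informed arm is ~25% closer to the
known ground-truth deformation (mean endpoint error in voxels inside the
body mask) than the intensity-only arm on this severely bent subject; on
unbent subjects the two arms perform comparably. Jacobians, TBM and PCA
then run on the composite transforms:

```r
jac <- jacobian_image(rl$forward, g)          # log J on the template grid
mean(jac$values[tpl$labels$values == 4])      # ~ log(0.5) over a halved lung
w <- welch_t_from_summary(0.445, 0.054, 9, 0.314, 0.105, 9)
round(w$p, 3)
#> [1] 0.006
```

The last line reproduces a published bladder-volume p-value from its
printed group summaries.

## Command line

```sh
Rscript inst/cli/labelmorph phantom  --out-prefix out/ph_ --shape 64 --subject --bend 0.3
Rscript inst/cli/labelmorph register --arm label --fixed out/ph_template.nii.gz \
    --moving out/ph_subject.nii.gz --fixed-labels out/ph_template_labels.nii.gz \
    --moving-labels out/ph_subject_labels.nii.gz --mask out/ph_template_mask.nii.gz \
    --out-prefix out/reg_
Rscript inst/cli/labelmorph tbm --group-a a1.nii.gz,a2.nii.gz --group-b b1.nii.gz,b2.nii.gz \
    --mask mask.nii.gz --alpha 0.05 --out-prefix out/tbm_
```

Subcommands: `phantom`, `register`, `template`, `jacobian`, `tbm`, `pca`,
`volumes`, `volume-test`. Every run writes a JSON manifest of its resolved
configuration; `--config file.json|yaml` mirrors all flags (command line
wins).

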