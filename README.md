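# sparsewmh

Cross-modality, cross-resolution training of white-matter-lesion segmenters,
in R.

## The problem

White-matter lesions (hyperintense on T2-FLAIR, gray-matter-like on T1) are
a standard imaging biomarker of brain aging. Hospital FLAIR is typically a
stack of 18-24 thick (~6 mm) axial slices, while T1-weighted images are ~1 mm
isotropic and acquired in essentially every cohort. This package implements
a training framework in which a 3D convolutional network segments lesions
*on the high-resolution T1 grid* while being supervised only by binary masks
that live on the thick-slice FLAIR grid — without ever interpolating those
masks.

The core device is a **spatially sparse loss**. Every FLAIR voxel center is
mapped through the rigid FLAIR-to-T1 registration (composed with the
training-time augmentation transform) to its nearest T1 voxel, and the loss
is a plain sum of squared differences over exactly those pairs, plus a
weighted dense auxiliary term for the cortical ribbon:

    L = sum_FLAIR ( out1[S(v)] - FLAIR_wmh[v] )^2
        + 0.001 * sum_T1 ( out2 - T1_ribbon )^2

T1 voxels that no FLAIR center maps to receive no training signal and an
exactly zero gradient — they are never given an interpolated surrogate.
Because the sampled planes sit at different axial phases in different
subjects (and shift with every augmentation draw), the whole output grid is
covered across a training set, and the model learns to place lesion
boundaries where the high-resolution image puts them rather than where
interpolation smears them.

The package provides:

- voxel-grid geometry, rigid/affine transforms, the FLAIR-to-T1 sampling
  map, and grid-to-grid resampling (`grid()`, `build_sampling_map()`,
  `resample()`);
- the sparse loss, the auxiliary ribbon loss, their weighted sum, and the
  dense interpolating baseline (`sparse_lesion_loss()`, `joint_loss()`,
  `dense_interpolating_loss()`);
- the three published U-shaped topologies with skip *sums*, index-preserving
  unpooling and instance normalization, at scalable width
  (`build_t1_wmh_net()`, `build_t1_roi_net()`, `build_flair_net()`), backed
  by a compact BLAS-based conv-net engine (no external deep-learning
  framework);
- the training loop (batch size 1, ADAM) and the two-step curation workflow
  — mimic, rank by loss, correct, retrain with 10x oversampling
  (`train()`, `rank_by_loss()`, `two_step_flair_workflow()`,
  `train_t1_from_flair()`);
- periventricular / deep / juxtacortical white-matter partitioning with a
  9 mm ventricle expansion, and ROI-net distillation with simulated lacunes
  (`partition_wm()`, `regional_volumes()`, `train_roi_net_with_lacunes()`);
- DICE evaluation in the target FLAIR space, volume-binned summaries, and
  paired comparisons (`dice_in_flair_space()`, `paired_compare()`);
- a synthetic paired-resolution phantom generator with known ground truth
  (`make_phantom()`, `render()`, `lesion_mask_flair()`, `corrupt_target()`),
  which is what the entire test suite runs on;
- NIfTI-1 I/O, CSV manifests, and a CLI (`inst/cli/sparsewmh`) with
  `simulate`, `train-flair`, `curate`, `train-t1`, `train-roi`, `segment`,
  `evaluate`.

## A worked example

```r
library(sparsewmh)

# a paired-resolution phantom: 64x64x48 @ 1 mm truth, 8 slabs of 6 mm FLAIR
truth <- make_phantom(seed = 1, shape = c(64, 64, 48),
                      n_lesions_by_class = c(2, 1, 1))
t1   <- render(truth, acquisition_spec("t1", noise_sd = 0.02, seed = 1))
fl   <- render(truth, acquisition_spec("flair", slice_thickness_mm = 6,
                                       noise_sd = 0.02, seed = 1))
mask <- lesion_mask_flair(truth, acquisition_spec("flair",
                                                  slice_thickness_mm = 6))
fl$grid
#> <grid 64x64x8 @ 1x1x6 mm>

map <- build_sampling_map(mask$grid, t1$grid, fl$rigid)
map
#> <sampling_map: 32768 pairs, 0 dropped>
```

All 64x64x8 FLAIR centers pair with a T1 voxel; the other 5/6 of the T1
grid receives no training signal. An all-zero prediction pays one unit per
positive FLAIR voxel, while the true high-resolution lesion field comes far
closer (the residual is the partial-volume disagreement between the
continuous field and the thresholded slab average — at its minimum a
well-trained net can dip below the field itself on these positions):

```r
zero <- volume(array(0, truth$grid$shape), truth$grid)
pred <- volume(truth$lesion_field$data, truth$grid)
sparse_lesion_loss(zero, mask, map)
#> [1] 205
sparse_lesion_loss(pred, mask, map)
#> [1] 56.5618

dice_in_flair_space(pred, mask, fl$rigid, id = "phantom-1", method = "truth")
#>          id method      dice lesion_volume_mm3
#> 1 phantom-1  truth 0.9624413              1230

part <- partition_wm(
  volume(array(as.numeric(truth_mask(truth, "wm")), truth$grid$shape), truth$grid),
  volume(array(as.numeric(truth_mask(truth, "ventricle")), truth$grid$shape), truth$grid),
  volume(array(as.numeric(truth_mask(truth, "ribbon")), truth$grid$shape), truth$grid))
regional_volumes(pred, part)
#>  pv_mm3 deep_mm3   jc_mm3
#>     897      278      281
```

So the phantom carries 1230 mm^3 of lesions on the FLAIR reference grid,
distributed 897 / 278 / 281 mm^3 over the periventricular / deep /
juxtacortical white matter, and the ground-truth field scores DICE 0.96
against its own thresholded slab average — the ceiling any T1 model can
reach in target space on this subject.

Training end to end on simulated data, via the CLI:

```sh
Rscript inst/cli/sparsewmh simulate --out data --n 16 --seed 7
Rscript inst/cli/sparsewmh train-flair --manifest data/manifest.csv --out fl
Rscript inst/cli/sparsewmh curate --model fl/flair_model.rds \
        --manifest data/manifest.csv --out report.csv
Rscript inst/cli/sparsewmh train-t1 --manifest data/manifest.csv --out t1m
Rscript inst/cli/sparsewmh segment --t1 data/sub-013/t1.nii.gz \
        --model t1m/t1_model.rds --out seg --assume-aligned
```

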