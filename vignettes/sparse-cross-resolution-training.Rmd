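---
title: "Training a high-resolution T1 lesion segmenter from thick-slice FLAIR masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training a high-resolution T1 lesion segmenter from thick-slice FLAIR masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

White-matter lesions are conspicuous on T2-FLAIR MRI, where they appear as
hyperintensities, but typical hospital FLAIR acquisitions are stacks of 18-24
thick (~6 mm) axial slices. T1-weighted images are acquired at ~1 mm
isotropic resolution in almost every cohort, and the same lesions are visible
there — at nearly the same signal intensity as cortical gray matter, which
is what makes them hard to extract from T1 by thresholds or atlases.

`sparsewmh` implements a cross-modality, cross-resolution training scheme:
a 3D convolutional network that reads the high-resolution T1 volume and
outputs a lesion probability map on the T1 grid is *supervised from the
FLAIR-space masks*, without ever interpolating those masks to the T1 grid.

## The spatially sparse loss

Each FLAIR voxel center is mapped through the rigid FLAIR-to-T1 registration
(composed with the training-time augmentation transform, when one is drawn)
into the T1 grid and rounded to its nearest voxel. The loss is

```
L = sum_FLAIR (out1[S(v)] - FLAIR_wmh[v])^2 + w * sum_T1 (out2 - T1_ribbon)^2
```

where `S` is that voxel-center sampling map, `out1`/`out2` are the lesion and
cortical-ribbon output channels, and `w = 0.001` weights the auxiliary dense
ribbon task. Both terms are plain squared errors (interpretable as
independent per-voxel probabilities) and both are *sums*, following the
equation; `normalize_loss` in `train_config()` offers mean normalization but
defaults to off.

T1 voxels that no FLAIR center maps to are simply absent from the first sum:
they contribute nothing and their gradient is exactly zero. They are never
given an interpolated surrogate value — this is the difference from the
`dense_interpolating_loss()` baseline, which resamples the FLAIR mask
trilinearly onto the T1 grid and penalizes everywhere. A model trained
against interpolated targets is rewarded for reproducing interpolation
artifacts; a model trained sparsely is free to place the lesion boundary
where the *image* puts it.

Why this recovers resolution at all: the sampled planes sit at different
z-phases in different subjects (scanner table position, head pose, and the
random affine augmentation all shift them), so across a training set every
axial phase of the output grid receives supervision. The augmentation
transform enters *only* through the sampling map — targets are never
interpolated, matching the design.

Rounding ties (a continuous index at exactly .5) round toward the lower
index, deterministically. If two FLAIR centers land on the same T1 voxel
(possible under in-plane downscaling), both pairs are kept, so that voxel is
counted twice — the loss is a sum over FLAIR voxels, not over T1 voxels.
Out-of-bounds centers are dropped and counted (`n_dropped`); how the original
work handled them is not documented, so dropping is this package's explicit
choice.

## Networks

`build_t1_wmh_net()`, `build_t1_roi_net()` and `build_flair_net()` construct
the three published U-shaped topologies: skip connections are *sums* (never
concatenations), max-pooling records argmax indices that the decoder's
unpooling restores exactly, and all normalization is instance normalization
(per-volume, per-channel, epsilon 1e-5, learned affine) because the
mini-batch size is fixed at 1. At `width_scale = 1` the channel counts are
the published ones (24/64/128 for the T1 lesion net; 12/16 for the ROI and
FLAIR nets). The FLAIR net halves the slice axis only at its first pooling
level; all deeper pools act in-plane only, so 18-24-slice native stacks pass
through five levels and the output slice count always equals the input's.

Two transcription choices are documented here deliberately: the printed T1
decoder lists one Unpool too few for its five MaxPools (we restore all five
— the shape contract demands it, and skip-sums come from encoder blocks 0-3
exactly as printed, with no skip from block 4); and the ROI net's final
"Softmask" is implemented as a per-voxel softmax over the four label maps.
The FLAIR net's three output channels are assigned as channel 1 = lesion
mask, the rest auxiliary.

Inputs whose dimensions are not divisible by the pooling factors are
symmetrically zero-padded on the way in and cropped on the way out, so the
spatial output shape always equals the input shape. Inputs below half the
pooling divisor per axis are rejected with the required minimum named.

One numerical choice matters a great deal at small scale: the bias of the
final pre-sigmoid convolution is initialized to -3 (a ~5% positive prior).
With a plain squared-error loss on rare-positive targets, a zero-initialized
output layer first collapses into saturated all-zero predictions and then
cannot recover through the flat sigmoid tails; starting near the class prior
removes that failure mode entirely. This affects initialization only, not
the model family.

## Training loop and the two-step curation workflow

`train()` iterates samples singly (batch size 1, ADAM), drawing *fresh*
augmentation at every visit; everything derives from one seed, so identical
configs give bit-identical loss histories. The published stopping criterion
("a slower convergence regime") was a visual judgment; here it is formalized
as: stop when the moving-average loss over the last `stop_patience` epochs
has decreased relative to the previous window by less than `stop_slope`
(default 0 = disabled, i.e. run to `max_epochs`).

The curation workflow (`two_step_flair_workflow()`) follows the two-step
scheme: train a FLAIR net to mimic the provided (imperfect) masks; rank all
samples by evaluation-mode loss (`rank_by_loss()`) — networks learn the
dataset's main trends before its particular deviations, so mis-segmented
targets surface at the top; apply external corrections or drops
(`build_curated_dataset()`); retrain with corrected samples visited 10 times
per epoch (`oversample_factor`, each visit with fresh augmentation — ten
live visits rather than ten frozen augmented copies, which would freeze the
augmentation distribution); and emit model-generated reference masks for the
whole set. Those masks are the targets of `train_t1_from_flair()`.

Augmentation defaults (±10° rotations — axial-only in FLAIR space, to avoid
inter-slice resampling — ±5 mm translations, monotone histogram warps with 5
knots) are configuration values, not claims from the source; its exact
magnitudes are unpublished. The histogram warp is a random monotone Hyman
spline through jittered knots of the intensity range: monotone so tissue
ordering is never inverted, smooth so no new edges are created.

## Regions of interest

`partition_wm()` splits white matter into periventricular (within a 9 mm
Euclidean expansion of the ventricles — the published radius), juxtacortical
(within `jc_radius_mm` of the cortical ribbon; **4 mm by default, a value
this package had to choose** because the class is named but never
quantified), and deep (the rest), with periventricular winning overlaps.
The three classes partition the white matter exactly — no holes — which is
the property the lesion load summaries rely on. `expand_mask()` is an exact
Euclidean-distance-transform dilation honoring anisotropic voxels.

`train_roi_net_with_lacunes()` distills this geometric partition into the
ROI network, scattering simulated lacunes (small smooth dark patches,
attenuated toward the CSF level) over the white matter of the *input* image
only, so the network learns to keep its region labels over dark cavities
instead of carving holes the way intensity-driven tissue classifiers do.

## The phantom generator: what it emulates, and what it does not

`make_phantom()` builds a small head: an ellipsoidal brain whose outer ~2
voxels form the cortical ribbon, two central ventricles, white matter in
between, and super-Gaussian lesion blobs placed by class (periventricular /
deep / juxtacortical) with centers kept away from zone borders. Semi-axes,
ventricle size and head position vary across subjects — deliberate cohort
heterogeneity; without it a desk-scale network can memorize anatomy by
position and never needs to read the image, which would invalidate every
robustness experiment. Rendering reproduces the contrast facts the method
stands on: on T1, lesions take gray-matter intensity (so *no global
intensity window separates lesion from ribbon* — asserted as a test), on
FLAIR they are frankly hyperintense; the FLAIR volume is slab-averaged from
the high-resolution signal (slice-profile integration, not nearest-slice
sampling), and `z_offset_mm` shifts the slab stack to emulate table
position. `corrupt_target()` reproduces the documented failure taxonomy of
automatic FLAIR segmenters (missed small components, bright-artifact false
positives, motion ghosting).

The default geometry downscales the real resolution ratio (1 mm isotropic T1
against ~6 mm FLAIR slabs) to a 64×64×48 grid — the 6:1 anisotropy is kept,
which is the property the super-resolution experiments need; the heavy
training experiments run at 32-scale for time, again with 6:1 anisotropy.
What the phantom does **not** emulate: MRI physics (no k-space, no bias
fields beyond the histogram augmentation, no partial-volume model beyond the
smooth blob edges), real lesion morphology, and any pathology other than WM
blobs and simulated lacunes. A green test on phantoms establishes that the
machinery implements the intended mathematics and that the comparative
claims hold in a controlled world — not clinical performance.

At 32-scale the 9 mm periventricular radius covers nearly all white matter,
so only periventricular (and sometimes juxtacortical) lesion classes are
feasible there; experiments needing all three classes use the 64-scale
default. This is geometry, not a bug: the 9 mm radius is held fixed because
it is the published value.

## Evaluation

`dice_in_flair_space()` resamples the T1-space probability map into the
reference FLAIR grid (trilinear — probabilities interpolate smoothly, hard
masks do not, so resampling precedes the 50% threshold; the order is a
documented config default), thresholds, and computes DICE. Empty-vs-empty
masks score 1 by default (perfect agreement on absence; configurable)
and empty-vs-nonempty scores 0. `volume_binned_summary()` reports per-bin
mean/SD and a 5th-95th percentile envelope over quantile bins of reference
lesion volume (the exact binning of the published figure is unspecified;
quantile bins are used). `paired_compare()` is the classical paired t
written in closed form, with the zero-variance case flagged explicitly
rather than propagated as NaN.

## Desk-scale experiment design in the acceptance suite

The acceptance tests reproduce the framework's comparative claims at a scale
a single CPU can run in minutes, with these frozen choices:

- training phantoms 32×32×18..24 at 1 mm with 6 mm slabs (6:1 anisotropy
  preserved), 2-3 periventricular lesions of 4-8 mm radius;
- per-subject random slab z-offsets and ±3 mm translation augmentation —
  the mechanism that lets sparse supervision cover every axial phase;
- T1 nets at `width_scale = 0.125`, FLAIR nets at 0.5, 2 pooling levels,
  ADAM at 2e-3: the smallest configurations that converged reliably in
  design runs (narrower nets left some seeds at the all-zero solution);
- random restarts on ignition failure (`restart_patience = 3`,
  `max_restarts = 2` in the T1 driver): with a squared-error loss and rare
  positives, an occasional initialization never leaves the constant-output
  regime; a restart with a shifted init seed is the classical cure and is
  applied identically to both arms of every comparison;
- the "reconstruction error along the slice axis" of the loss comparison is
  the mean squared error against the binarized high-resolution truth
  restricted to T1 voxels that receive no FLAIR training signal — exactly
  the voxels where only super-resolution generalization can help;
- epoch counts (4-16) sized to the 1-CPU test-time budget.

Known limitations: the conv-net engine is deliberately minimal (CPU only,
double precision, no threading guarantees beyond BLAS); full-width training
at the canonical 184×202×72 workspace is out of desk-scale reach, though
construction, forward passes and all shape contracts are exercised at full
width; and the loss-vs-loss comparison is run at one desk scale, not across
scales.
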