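---
title: "Clustering time-activity curves: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering time-activity curves: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacclust)
```

## The problem

A dynamic acquisition — dynamic PET with a radiotracer, or DCE-MRI with a
contrast bolus — is a temporal sequence of 3D volumes. Each voxel carries a
time-activity curve (TAC): its intensity across the frames. Tissues with
different kinetics (a ventricle filling early, myocardium accumulating
tracer, lung background) trace differently shaped curves, so grouping
voxels by TAC similarity segments the image into kinetic regions and yields
low-noise mean curves for compartmental modelling, without hand-drawn
regions of interest.

`tacclust` treats this as a generic clustering problem over the
voxels-by-frames matrix, with three pluggable pieces: the 4D container, the
TAC distance metric, and the clustering technique. Anything satisfying the
metric or technique contract can be dropped in through the registry
(`register_metric()`, `register_technique()`).

## The image model

A `dynamic_image` wraps a numeric `(x, y, z, t)` array. Inputs with a
single time point are rejected as static: there is nothing kinetic to
cluster. Coordinates follow the hyperstack convention: in-plane `x`, `y`
are 0-based, the axial `slice` is 1-based (`slice = z + 1`), and a 4D
stack of `n_slices` slices and `F` frames flattens plane `(frame, slice)`
to linear position `(frame - 1) * n_slices + slice` (`hyperstack_index()`;
20 slices and 20 frames give a 400-plane stack).

Voxel iteration order is fixed to x fastest, then y, then slice. Nothing
scientific hangs on this choice; what matters is that it is deterministic,
because the leader-follower technique is order-sensitive and tests need
reproducible streams. `tac_matrix()` rows, `voxel_grid()` rows and
`iterate_voxels()` all share the order.

TACs are dense numeric vectors; there is no masking or NaN support.
Background (air) voxels are clustered like any others — they typically form
their own flat-kinetics cluster. Under the Pearson metric a constant TAC is
defined to be maximally distant (distance 2), so flat voxels never dilute a
kinetic cluster.

## Metrics

For TACs $a(t)$, $b(t)$:

* **Pearson distance** $1 - r_{ab}$, with $r$ the sample correlation. Range
  $[0, 2]$: 0 for identical shape regardless of scale, 2 for perfect
  anticorrelation. The population-vs-sample variance convention cancels in
  $r$. Zero-variance TACs have undefined $r$; we return 2 (0 when both
  arguments are the identical constant curve, preserving $d(a,a) = 0$)
  rather than raising, so flat background never errors a run.
* **p-norm** $\left(\sum_t |a(t) - b(t)|^p\right)^{1/p}$, default $p = 2$
  (Euclidean); $p = 1$ is Manhattan. $p$ must be positive.
* **Mahalanobis** $\sqrt{(a-b)^\top S^{-1} (a-b)}$, where $S$ is the
  frames-by-frames sample covariance of the whole image (voxels as
  observations, unbiased $n-1$ denominator). $S$ is computed once in the
  metric's `init()` pass and its inverse cached; techniques guarantee the
  init pass runs exactly once, before any distance call. Image frames are
  often nearly collinear, making $S$ ill-conditioned, so a singular $S$ is
  inverted after Tikhonov regularization $S + \varepsilon I$ with
  $\varepsilon = 10^{-6}\,\mathrm{tr}(S)/T$ — negligible for
  well-conditioned $S$, finite for rank-deficient ones.

## Techniques

**k-means** (`tac_kmeans`) is Lloyd alternation under any of the metrics:
assign each voxel to its nearest centroid, recompute each centroid as the
arithmetic member mean, stop when no assignment changes or after
`max_iter = 100` sweeps. Assignments are the observable output, so the
stopping rule is zero reassignments, not a centroid-shift tolerance. The
centroid stays the arithmetic mean whatever the assignment metric; the
mean is not redefined per metric. A cluster emptied by a sweep is reseeded
with the voxel farthest from its current centroid, so exactly `k` clusters
always come back. Initialization is `"plusplus"` (default) — k-means++
D-squared seeding, each new seed drawn with probability proportional to
the squared metric distance to its nearest chosen seed — or `"random"`
(uniform over distinct TACs). Both are reproducible from the `seed`
argument (default 1 everywhere, for reproducible command-line runs).

The per-sweep objective (sum of member-to-centroid distances) is recorded
in the result. With mean updates the unsquared-distance objective is not
mathematically guaranteed monotone — the mean minimizes squared distance —
but it decreases in practice on kinetic data and the suite asserts it on
the phantom with a 1e-8 slack.

**Leader-follower** (`leader_follower`) is a single deterministic streaming
pass: a voxel joins the most-similar existing cluster if the Pearson
correlation with its centroid reaches `threshold`, else founds a new
cluster; centroids are running means. The default `threshold = 0.3` is a
conservative default for bolus kinetics inherited from the method's
antecedents rather than fixed by any analysis here; expect to tune it per
study. With `max_clusters` set, an overflowing voxel joins its best cluster
anyway and the event is logged in `extra_info`. Output clusters are sorted
by size, descending.

**PCA / SVD / ICA** produce component score maps rather than a partition.
PCA centers the frame columns and computes all `n_frames` components of the
TAC covariance; SVD factors the uncentered matrix (right singular vectors
as temporal factors, scores $XV$); ICA whitens the centered matrix and runs
symmetric fixed-point FastICA with the logcosh contrast (convergence when
directions change less than `tol = 1e-6`, warning and a flag in
`extra_info` otherwise — on data with no non-Gaussian structure, e.g. white
noise, non-convergence is expected and the returned estimate is still
orthogonal in whitened space). One 3D score map per component is attached
as `extra_images`.

These three also return a hard labeling, formed by assigning each voxel to
the component with the largest absolute score. That mapping is this
package's convention, chosen so every technique satisfies the same result
contract; component images remain the primary output, and the labeling
should be read as a view of them.

Every technique returns a `cluster_result`: an ordered cluster list
(1-based numbering), a composite label volume (0 = unassigned), optional
extra images and info lines. The partition is hard — fuzzy membership is
out of scope — and `cluster_result()` rejects any voxel claimed twice.

## The phantom generator

`generate_phantom()` produces the ground-truth-labeled inputs for all
tests: the voxel grid is split into contiguous near-equal slabs (axis-
aligned blocks — ground-truth clarity over anatomical realism), each slab
carries one class TAC drawn from a gamma-variate bolus model
$A (t - t_0)^\alpha e^{-(t - t_0)/\beta}$ (amplitudes 2–10, delay 0–2,
shape 0.5–3, decay 1–5; frame times $0, 1, \dots$) or a biexponential
washout, and i.i.d. Gaussian noise of SD `noise_sigma` is added. Gaussian
rather than Poisson noise is the default because it is sufficient for
exercising clustering behavior; a frame-duration-weighted Poisson mode
exists for count-statistics realism but is not used by the shipped checks.

Study conditions are generator inputs: `min_separation` redraws the class
TACs (advancing a deterministic attempt counter) until the minimum pairwise
Euclidean distance is reached, and `max_class_correlation` does the same
for shape decorrelation. Amplitude separation is what Euclidean k-means
needs; decorrelation is what the correlation-based routes (Pearson k-means,
leader-follower) need — gamma-variate boluses on a short time axis are
naturally highly correlated, so correlation-based tests state an explicit
cap (0.8 in the recovery checks, with a 0.9 joining threshold above it).

What passing phantom tests shows — and does not. The phantom has
piecewise-constant kinetics, spatially independent noise and no partial-
volume mixing, scatter, motion or reconstruction correlations. Recovery of
its classes validates the algorithmic machinery (distances, seeding,
update rules, output conventions), not segmentation accuracy on scanner
data, where class boundaries are gradual and noise is structured.

## I/O conventions

Images load from NIfTI-1 (`.nii`/`.nii.gz`) and Analyze 7.5 (`.hdr`/
`.img`) via RNifti. DICOM series are not read; convert to NIfTI first.
Frame timing is never mined from image metadata: the two-column text
timing file (start, end in seconds; tabs or spaces; `#` comments) is the
sole source, and times are written back as given, without unit conversion.

Results are written as (i) the pseudo-dynamic label image — `n + 1`
frames, frame `k` showing cluster `k`'s voxels at value `k`, the last
frame the composite labeling, stored as 16-bit unsigned integers to allow
more than 255 clusters — and (ii) a TAC table with one row per frame,
frame start/end in the first two columns (frame indices `0..n-1`/`1..n`
as the documented fallback when no timing file is given) and one column
per cluster mean TAC. Dialects: CSV, TSV, and a PMOD-style `.tac` table
(tab-separated, header `start[seconds]  end[seconds]  cluster1 ...`).
The PMOD header is a documented best effort at that suite's convention,
fixed by the round-trip tests. Values are printed with 17 significant
digits so every writer round-trips at float64 precision. Technique info
lines land in a sibling `*_info.txt`.

## Problem sizes in the shipped checks

The test suite and the acceptance script run phantoms of 16×16×4 voxels
with 10–25 frames (1024 TACs), tiny 8-voxel instances for the
exhaustive-enumeration k-means oracle (all 2-partitions of 8 voxels), and
10^4-draw frequency checks for the k-means++ seeding law. These sizes make
every oracle exactly computable and the whole suite rerunnable in well
under a minute per check; the implementation itself is vectorized over
voxels and has no intrinsic size limit beyond memory.

## Known limitations

* Hard partitions only; no fuzzy or probabilistic membership.
* No spatial regularization — neighboring voxels are clustered
  independently.
* No intensity calibration (SUV), masking, or motion handling.
* The leader-follower threshold and the component-to-cluster argmax
  mapping are conventions to be read as such, not estimated quantities.
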