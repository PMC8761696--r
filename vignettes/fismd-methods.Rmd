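---
title: "Methods: organoid swelling quantification and structure-geometry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organoid swelling quantification and structure-geometry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fismd)
```

# Scope

`fismd` implements two families of analysis that are routinely run in-house
and rarely published as reusable code:

1. **Forskolin-induced swelling (FIS) quantification** — segmenting round
   intestinal organoids in brightfield time-lapse stacks with a
   gradient-orientation pixel classifier, converting per-frame areas into
   normalized swelling curves and an area-under-curve (AUC) response, plus
   the derived treatment metrics (baseline correction, fold change,
   synergy).
2. **Structure and trajectory geometry** — least-squares superposition,
   global and residue-wise RMSD, RMSF, minimum-distance series, salt-bridge
   contact fractions, a minimum C-alpha distance between a residue and a
   helix, and a sliding-window scan that ranks candidate sequence registers
   for an unresolved protein segment by backbone-RMSD stability.

Both families are exercised end-to-end on synthetic data with known ground
truth, generated by the package itself.

# The FIS readout

Organoids expressing functional CFTR swell when stimulated with forskolin;
the swelling magnitude over one hour is a quantitative readout of channel
activity.  Images are acquired at 10-minute intervals for 60 minutes
(7 frames).  The total organoid-covered area $A(t)$ per frame is normalized
to baseline,

$$N(t) = 100 \cdot A(t) / A(0),$$

so $N(0) = 100$ exactly, and the response is the trapezoidal integral of the
deviation above the 100 % baseline:

$$\mathrm{AUC} = \int_0^{60} \big(N(t) - 100\big)\, dt \quad [\%\cdot\min].$$

Integrating the *deviation* rather than the absolute normalized area is
forced by the magnitudes of typical reported responses (hundreds of
%·min over 60 min; integrating absolute area would never drop below 6000).
A flat series yields 0 and shrinkage yields negative AUC, which we report
rather than clip.  The trapezoid rule is exact for piecewise-linear input,
so a linear ramp from 100 % to 200 % gives exactly
$\tfrac12 \cdot 100 \cdot 60 = 3000$ %·min — one of the package's fixed
acceptance checks.

Treatment metrics operate on AUC values: `baseline_correct()` subtracts the
matched untreated response at the same forskolin concentration,
`fold_change()` forms the ratio of two group means (rounded to an integer,
matching the "n-fold" convention), and `synergy_score()` compares a
combination response to the sum of its single-agent responses, positive
values flagging synergy.  `summarize_condition()` reports mean ± sample SD
(n − 1) per condition; single-well groups report SD 0 with a flag, and
degenerate wells (zero baseline area) are excluded and counted.

# Segmentation model

Brightfield organoids appear as a dark rim (out-of-focus cell layer)
enclosing a bright lumen on a mid-gray background.  The classifier follows
a ridge/valley scheme driven by the local gradient orientation:

1. **Blur.** Gaussian blur with $\sigma = 1.3$ px (separable convolution,
   reflecting boundaries; kernel sampled to $\pm\lceil 4\sigma\rceil$ and
   normalized, so constants are preserved).
2. **Gradient.** Central differences on the blurred image (Sobel available
   behind `gradient_operator = "sobel"`); direction
   $\theta = \operatorname{atan2}(\partial I/\partial y, \partial I/\partial x)$.
3. **Classification.** For each pixel the blurred intensity is sampled by
   bilinear interpolation at $\pm s$ pixels along $\theta$
   (`neighbor_step`, default 1).  With backward/center/forward samples
   $b, c, f$: center above both neighbours → *Ridge*; below both →
   *Valley*; monotone increase along the direction → *Rising*; decrease →
   *Falling*.  Ties within $10^{-9}$ defer to the one strict difference; a
   fully flat profile is *Background*.
4. **Background test.** A pixel is Background when the gradient magnitude
   is below threshold at the pixel *and* at both of its $\pm s$ samples.
   The flank condition matters: ridge crests and valley troughs have
   near-zero central gradient by definition, and a purely central magnitude
   test would discard exactly the pixels the method is named after.  The
   default threshold is Otsu's method on the magnitude histogram
   (`"auto"`); degenerate (constant) images threshold to infinity, i.e.
   all Background.
5. **Clean-up.** (i) Ridge/Valley connected components that touch only
   Background are noise and are removed; (ii) Rising/Falling bands are
   eroded (3×3 cross, `erosion_iterations = 1`) so edge bands hug object
   boundaries; (iii) holes enclosed by the combined boundary map are
   filled, turning closed outlines into object interiors; (iv) the filled
   mask is eroded once more (`boundary_erosion_iterations = 1`, see below);
   (v) components smaller than `min_area = 500` px² are removed as debris.

## Numerical choices and their rationale

* **Post-fill boundary erosion.** The blur widens every edge band, so the
  filled outline sits systematically ~1.5 px outside the true boundary
  (about +13 % area on the synthetic wells).  Eroding the thin class bands
  harder instead breaks ring closure — a 3-px rasterized annulus does not
  survive two cross erosions — and collapses the segmentation.  One erosion
  of the *filled* mask is connectivity-safe and brings total area within
  ~5 % of ground truth.  Both counts are configurable.
* **Tie handling** uses an absolute $10^{-9}$ intensity tolerance; images
  are in [0, 1] so this is far below any real contrast.
* **min_area = 500 px²** corresponds to a disk of radius ~12.6 px; the
  synthetic debris model stays below it by construction, and the validation
  asserts that no ground-truth debris pixel survives.
* **Rotation robustness** is approximate, not exact: direction quantization
  and border handling break perfect 90° symmetry; the test budget is 2 %
  area agreement.

# Synthetic wells

`generate_organoid_stack()` draws 25–30 (default; configurable) round
organoids per 512×512 well as a dark annulus (`rim_width` 4 px,
intensity 0.15) around a bright lumen (0.85) on a 0.5 background, placed
without overlap by rejection sampling with a margin reserved for the final
frame's radius.  Area grows linearly in time,
$A(t) = A_0 (1 + g\,t/60)$ with `growth_rate` $g$ per hour (default 0.5,
a mid-range swelling response; $g = 1$ doubles the area by $t = 60$,
i.e. radius × √2).  Small debris disks (radius 2–6 px, below the size
exclusion) and additive Gaussian noise (σ = 0.01 grayscale, clipped to
[0, 1]) complete the image.  All randomness comes from R's Mersenne-Twister
generator with a recorded seed, so identical specs produce bit-identical
stacks.

What the generator does **not** emulate: optical point-spread functions,
uneven illumination, organoid shape irregularity, touching/merging
organoids, and focus drift.  A green end-to-end test therefore establishes
that the pipeline recovers areas from images *of this appearance model* —
it does not validate performance on real microscope data.

# Trajectory geometry

Superposition uses the Kabsch algorithm (SVD of the cross-covariance with a
determinant correction, so reflections are never returned); fewer than
three fit atoms or collinear geometry is an error.  RMSD per frame is

$$\mathrm{RMSD}(t) = \sqrt{\tfrac1n \sum_i |x_i(t) - x_i^{\mathrm{ref}}|^2},$$

after (by default) superposing each frame onto the reference, fit on the
C-alphas of the analysis selection.  Residue-wise RMSD superposes globally,
then averages each residue's squared deviation over the frame window
(reported as the square root of the mean square, so the RMS over residues
of the profile equals the quadratic mean of the global series under the
same fit — an identity the tests verify numerically).

RMSF is provided in two modes because two definitions circulate:
`"reference"` measures fluctuation about the reference coordinates,
$\sqrt{\langle |x_i - x_i^{\mathrm{ref}}|^2 \rangle}$, and `"mean"` the
conventional fluctuation about the time-mean position.  They differ
whenever the ensemble average is displaced from the reference (a constant
1 Å offset gives 1.0 vs 0.0).  The default is `"reference"`.  For pure
isotropic per-coordinate noise of SD σ both converge to $\sigma\sqrt3$ —
the basis of the parameter-recovery test (σ = 0.5 Å → 0.866 Å within 2 %
at 20 000 frames, fit disabled since fitting on a small atom set absorbs
part of the noise).

Salt-bridge contacts use the minimum distance between the basic residue's
side-chain nitrogens (LYS NZ; ARG NE/NH1/NH2; HIS ND1/NE2) and the acidic
residue's side-chain oxygens (ASP OD1/OD2; GLU OE1/OE2), with direct
contact defined *strictly* below 4 Å — a frame at exactly 4.0 Å does not
count.  Periodic boundary conditions are **not** applied; inputs are
assumed whole and unwrapped.

Residue spans are 1-based and inclusive throughout: 818–834 is 17 residues
and 630–856 is 227, the span conventions the acceptance checks pin down.

# The sliding-window register scan

When a cryo-EM map resolves only the backbone of a segment (here: 17
residues — an 8-residue coil followed by a 9-residue helix — in an
otherwise disordered regulatory domain), the residue *register* is unknown.
The scan enumerates every candidate register by sliding a 17-residue window
backwards one residue at a time from an anchor (default residue 842,
chosen for its proximity to the next resolved residue), producing 24
candidates by default with window ends 842 down to 819.  The stopping rule
behind "24" is not derivable from structure alone, so `n_windows` is an
explicit parameter rather than a hidden heuristic.

Each candidate is scored by the mean backbone C-alpha RMSD of the modeled
segment to the reference over a trailing frame window, with the global fit
on the *rest* of the protein so the score isolates the segment's own
motion.  `rank_by_stability()` sorts ascending; rank 1 is the most stable.
Ties (not observed in practice) break toward the smaller start residue — a
declared, arbitrary rule that keeps the ranking a deterministic total
order.  On synthetic ensembles where one segment is generated with the
smallest programmed fluctuation, that segment ranks first; this is a
parameter-recovery check of the scoring machinery, not a re-derivation of
any particular biological assignment, which would require the original
microsecond-scale simulations.

The bundled sequence fixture (`inst/extdata/rdomain_synthetic.fasta`, also
available as `synthetic_rdomain_sequence()`) is a **synthetic stand-in**:
only the residue identities the span conventions depend on (F630, L818,
E826, F834, T842, H856) are fixed; everything else is arbitrary but
deterministic.  It exercises coordinates and bookkeeping, not biology.

# File formats

No TIFF or PDB reader is available in the supported dependency set, so the
package implements the minimal subsets it needs: uncompressed little-endian
baseline TIFF (8/16-bit grayscale, multi-page) and fixed-column PDB
(ATOM/HETATM, MODEL/ENDMDL).  Both are round-trip tested, and the writers
were cross-checked against independent readers (`tifffile`, `biotite`)
during development.  16-bit TIFF quantizes intensities to 1/65535 — below
any tolerance used in the analyses.

# Known limitations

* The segmentation measures **total** organoid area per frame; individual
  organoids are not tracked across frames.
* The classifier's free parameters (threshold rule, neighbour step, erosion
  counts) are declared defaults validated on the synthetic appearance
  model, not values recovered from any original unpublished script.
* Microsecond-scale trajectory statistics (multi-Å residue-wise RMSD shifts
  between genotypes, RMSF doubling at elevated temperature) are out of
  reach of desk-scale synthetic data; the package validates the measuring
  instruments, not those empirical outcomes.
* PBC-wrapped trajectories must be unwrapped upstream.
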