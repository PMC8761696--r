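# fismd

Quantification of forskolin-induced swelling (FIS) of intestinal organoids
from brightfield time-lapse imaging, and structure/trajectory geometry
analysis for CFTR-style structural biology — with seeded synthetic-data
generators so every stage is testable against known ground truth.

## Who this is for

Labs using the FIS assay read out CFTR channel function as organoid
swelling: organoids are imaged at 10-min intervals for 60 min after
forskolin stimulation, the organoid-covered area is segmented per frame,
normalized to baseline, and summarized as an area-under-curve (AUC)
response. The segmentation scripts behind published FIS datasets are
typically custom and unpublished; this package provides a documented,
tested implementation of that pipeline, plus the geometry analyses used to
interpret channel mutations structurally (RMSD/RMSF, salt-bridge contacts,
minimum C-alpha distances, and a sliding-window register scan for
unresolved cryo-EM segments).

## The core quantities

* Normalized swelling: `N(t) = 100 · A(t)/A(0)` (% of baseline area).
* FIS response: `AUC = ∫₀⁶⁰ (N(t) − 100) dt` in %·min (trapezoid on the
  10-min grid; baseline = 100 %).
* Treatment metrics: baseline-corrected AUC (treated − untreated),
  integer-rounded fold changes of group means, and a synergy score
  `AUC_combo − (AUC_a + AUC_b)`.
* Geometry: Kabsch superposition; `RMSD(t) = √(1/n Σᵢ |xᵢ(t) − xᵢ_ref|²)`;
  RMSF about the reference (default) or the time-mean position; salt-bridge
  direct contact = side-chain N–O minimum distance strictly < 4 Å;
  1-based inclusive residue spans (818–834 = 17 residues).

Segmentation follows a gradient-orientation pixel classification: Gaussian
blur (σ = 1.3 px), local gradient magnitude/direction, per-pixel
classification into Background / Ridge / Valley / Rising / Falling by
comparing bilinear samples along the gradient direction, then clean-up
(drop boundary fragments touching only background, erode edge bands, fill
closed outlines, size-exclude debris < 500 px²). See the methods vignette
(`vignettes/fismd-methods.Rmd`) for every numerical choice.

## Worked example

```r
library(fismd)

# a synthetic 512x512 well: 27 organoids, 7 frames, 50%/h area growth
well <- generate_organoid_stack(well_spec(n_organoids = 27L,
                                          noise_sigma = 0.01, seed = 1L))
q <- quantify_fis(well$stack)
round(q$series$normalized, 1)
#> [1] 100.0 108.2 116.4 124.5 132.4 140.5 148.4
round(q$auc, 1)
#> [1] 1462.6       # ground truth: 1497.9 (within 2.4%)

fold_change(655.8, 210.4)   # potentiator efficacy ratio of group means
#> [1] 3

# RMSF parameter recovery: 0.5 A per-coordinate noise -> sigma*sqrt(3)
ref <- generate_reference_structure(10)
tr  <- generate_trajectory(ref, fluctuation_spec(5000, rep(0.5, 10), seed = 1L))
round(mean(rmsf(tr, ref, fit = FALSE)$value), 3)
#> [1] 0.869       # expected 0.866

# sliding-window register scan: 24 candidates anchored at residue 842
w <- enumerate_windows(synthetic_rdomain_sequence(), seq_start_res = 630L)
w[w$start_res == 818, c("start_res", "end_res", "helix_start", "helix_end")]
#>   start_res end_res helix_start helix_end
#> 9       818     834         826       834
```

The measured series sits ~1 % below truth (the segmented boundary is
conservative by design); normalization cancels most of the bias, so the
AUC lands within a few percent.

## Command line

A single entry point wraps the main operations:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/fismd.R", package = "fismd"))')
Rscript $CLI simulate-well --seed 3 --out well/          # stack + ground truth
Rscript $CLI segment --in well/stack.tif --out seg/      # masks + areas CSV
Rscript $CLI rmsd --traj traj.pdb --ref ref.pdb --out rmsd.csv
Rscript $CLI scan-rdomain --seq inst/extdata/rdomain_synthetic.fasta \
        --offset 630 --out ranked.csv
```

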