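---
title: "Building DIA-experiment-specific spectral libraries from chimeric spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building DIA-experiment-specific spectral libraries from chimeric spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dialibrarian)
```

## The problem

Peptide-centric DIA search engines need a spectral library: for every
candidate precursor, the m/z and relative intensity of its strongest
fragment ions and its expected retention time. Libraries predicted by
models pretrained on DDA data transfer imperfectly to a given DIA
experiment, because fragmentation depends on instrument, collision energy
and acquisition scheme. The alternative — learning the models from the DIA
experiment itself — faces an obstacle: wide isolation windows co-fragment
many precursors at once, so the MS2 spectra are chimeric and many fragment
peaks carry intensity from more than one analyte. A model trained naively
on such spectra learns contaminated intensities.

`dialibrarian` implements the full workflow around that obstacle:

1. mine training data directly from the chimeric DIA run, labeling each
   matched fragment peak as *shared* (interfered) or not via two
   complementary detectors;
2. train a fragment-ion-intensity model and a retention-time model with a
   masked L1 loss, so shared peaks contribute nothing to the objective;
3. digest a protein database in silico and predict a filtered,
   search-engine-compatible library table.

A deterministic simulator generates DIA runs with known interference so
every stage is testable against ground truth without external data.

## Shared-peak determination

For each detected precursor (a q-value-filtered row of a DIA-NN-style
report) the matched MS2 spectrum at the apex time point is annotated with
all theoretical b/y ions (charges 1-2 for multiply charged precursors;
additional -98 Da phosphoric-acid-loss ions in phospho mode) at a
configurable tolerance (10 ppm by default, 30 ppm for TOF-like data).
Matching takes the nearest peak within tolerance; the fragment table is a
fixed-shape matrix whose rows are cleavage sites and whose columns are ion
types, with a mask distinguishing usable cells from shared and
out-of-scan-range cells.

Three routes mark a cell shared; the final label is their union.

* **Spectrum-centric**: a peak also matched by a fragment of *another
  detected peptide* in the same spectrum. This is exact but blind to
  peptides the search did not report.
* **Peptide-centric**: each matched fragment's XIC is extracted between the
  precursor's peak boundaries and smoothed (Savitzky-Golay, window 5,
  order 2 by default; a triangular weighted moving average is available).
  Every fragment gets an aggregate score — the sum of its Pearson
  correlations to all other fragments — and the top scorer defines the
  reference elution shape. A fragment whose correlation to the top scorer
  falls below 0.8 is shared. A fragment that correlates well but whose
  *peak shape score* is 2 — its smoothed trace stays above both the median
  of all fragments and 10% of its own apex (25% for fragments weaker than
  half the strongest) at *both* boundary time points, i.e. it never
  returns to baseline — is shared too.
* **Ambiguous**: one spectrum peak claimed by two different fragment ions
  of the same peptide.

Design choices where the procedure is underdetermined: correlations are
computed on smoothed XICs restricted to the reported boundaries; the
boundary-median comparison uses smoothed values; nearest-peak (not
summed-peak) matching; zero-variance XICs carry no shape evidence and are
conservatively labeled shared; chromatograms with fewer than three points
are non-scorable and left unlabeled; reported peak boundaries are taken
verbatim (no boundary refinement).

## Training data

Matched intensities are normalized so the highest matched peak is 1.
Unmatched in-range cells are zero; cells whose theoretical m/z falls
outside the acquired scan range are masked rather than zeroed, because the
instrument could not have observed them. A spectrum is rejected when its
highest matched peak is shared or when more than 50% of its matched peaks
are shared (out-of-range cells count in neither numerator nor
denominator). For retention time, each peptidoform contributes one example
— the apex RT of its lowest-q-value charge state — normalized by the run's
maximum RT (or a user-supplied factor). Splits are at the peptidoform
level (default 10% test), so no sequence leaks across partitions.

## Models

The intensity model is a transformer encoder: one-hot residues,
per-position modification mass deltas, a sinusoidal positional encoding
and separately encoded metadata (charge, NCE, instrument category) are
concatenated and projected to the model width; four self-attention +
feed-forward blocks (with residual connections) and two fully-connected
layers map each cleavage-site position to its row of the fragment matrix.
The RT model is a width-3 convolution followed by a bidirectional LSTM
with mask-aware mean pooling and a two-layer head. Both train with Adam
under a linear learning-rate warmup (10 epochs by default) and the masked
L1 loss — masked cells contribute exactly nothing to loss or gradient.
Default schedules are 20 epochs / batch 512 (intensity) and 40 epochs /
batch 1024 (RT) at learning rate 1e-4, the settings appropriate for
fine-tuning at scale.

Both networks and their backpropagation are implemented directly on R
matrices; the test suite verifies every gradient against finite
differences, and training is bit-reproducible for a fixed config seed on
one thread. The package ships no pretrained weights: `init_weights` lets a
caller resume from exported tensors (the checkpoint stores parameters
under stable names), and everything in the tests trains from scratch at
reduced width. Desk-scale runs use a scaled-down configuration — 1-2
transformer layers, width 24-32, 60-200 epochs at learning rate 2-3e-3 on
a few hundred examples — which trains in well under a minute per model;
hidden sizes are not load-bearing for the synthetic rules and are exposed
in the config. Sequences are capped at 35 residues with padding masked out
of attention, pooling and the loss. Prediction applies no masking, clips
negatives to zero and renormalizes each matrix to maximum 1.

## Library generation

`digest_fasta()` cleaves after K/R without proline suppression (Trypsin/P),
allows one missed cleavage, keeps lengths 7-35 and maps peptides to all
source proteins; N-terminal methionine excision is deliberately not
applied. `expand_precursors()` applies fixed carbamidomethyl-C, optional
variable phospho-STY (max 1 by default) and charges 2-4.
`build_library()` drops precursors and fragment ions outside the training
run's m/z scan range, keeps the top 20 fragments by predicted intensity —
the range filter runs *before* top-n selection, a documented ordering
choice that matters when more than 20 candidates are in range —
renormalizes the kept set, and converts normalized RTs back to minutes
with the training normalization factor. Output is a row-per-fragment TSV
(ModifiedPeptide, PrecursorCharge, PrecursorMz, NormalizedRetentionTime,
FragmentType, FragmentSeriesNumber, FragmentCharge, FragmentLossType,
FragmentMz, RelativeIntensity, ProteinId).

## Evaluation machinery

* `spearman_unmasked()`: rank correlation between predicted and observed
  intensities over non-interfered cells only.
* `build_entrapment_db()` / `estimate_fdp()` / `fdp_sweep()`: paired
  entrapment analysis. Targets are I-to-L normalized; each gets a shuffled
  partner with the C-terminal residue fixed. At a score cutoff *s*, with
  N_T and N_E the target and entrapment discovery counts, the bounds are
  lower = N_E / (N_T + N_E) and upper = (N_E + N_{E>=s>T} + 2 N_{E>T>=s})
  / (N_T + N_E).
* `spectral_entropy_similarity()` / `calibrate_nce()`: unweighted spectral
  entropy similarity (1 − (2H(mix) − H(A) − H(B)) / ln 4 after sum
  normalization; peaks aligned by a ppm-tolerance merge, unmatched peaks
  kept as distinct dimensions). NCE calibration scans 20-40, takes the
  median similarity between predictions and the observed unshared peaks
  per NCE, and picks the argmax (ties to the lowest NCE). Passing the
  acquired scan range excludes theoretically predicted but unobservable
  fragments from the comparison.

## The simulator and what it does (not) capture

`sim_config()` defaults describe the simulated study conditions: 24 m/z
isolation windows tiling 400-1000 m/z, fragment scan range 150-1800 m/z, a
30 min gradient at 3 s cycle time, Gaussian elution with 18 s FWHM, 5%
multiplicative intensity noise, acquisition at NCE 30. The ground-truth
model is a smooth deterministic rule: fragment intensities depend on the
basicity/hydropathy of the residues flanking each cleavage site, fragment
position, charge and NCE (each site has its own NCE optimum near 28-33, so
spectra are injective in NCE around the acquisition value); retention time
is a residue-additive hydropathy sum squashed into the gradient span —
learnable by construction, which is what lets small models reach high
accuracy in the tests.

Interference is injected two ways. With probability `interference_rate`
a fragment peak receives a contaminant trace whose apex is offset by
1.4-2.6 peak sigmas and whose magnitude is drawn from an *independent*
co-isolated analyte (abundance on the peptides' own lognormal scale times
a U(0.05, 1) relative fragment intensity). The independence matters: a
contaminant proportional to the corrupted fragment's own intensity would
perturb spectra multiplicatively and leave intensity *ranks* intact in
expectation, making masking pointless by construction. Additionally, a
fraction of peptides get a co-eluting partner with two adjacent residues
swapped — same composition, same additive RT, identical fragment masses
outside the swapped region — which is what gives the spectrum-centric
route true positives. Reported peak boundaries sit one cycle beyond the 5%
-of-apex crossing, where a peak picker operating on the sampled
chromatogram would place them; placing them exactly at the crossing makes
the first in-boundary sample land at up to ~12% of apex through cycle
quantization and trips the 10% shape criterion on clean peaks.

Truth tables record, per fragment cell, whether injected interference
touches the matched peak at the apex (`shared`) and whether an unrelated
detected peptide coincidentally contributes at the same m/z inside the
integration window (`collision`, e.g. the identical y1 of two co-eluting
R-ending peptides). Collisions are genuine interference but not injected,
so detector scoring excludes them rather than counting them as errors.

What the simulator does not emulate: isotope envelopes, MS1 spectra,
staggered windows, ion mobility, profile-mode peaks, peak tailing,
missed or mis-assigned detections, and real fragmentation chemistry.
Passing tests therefore demonstrate that the machinery — annotation,
interference labeling, masked training, filtering, calibration — is
correct and self-consistent, not that the trained models transfer to real
instruments.

## Numerical choices

Monoisotopic residue masses; proton 1.007276466 Da; water 18.010565 Da;
phospho neutral loss 97.976896 Da. Isolation windows are half-open
[low, high). RTs are minutes everywhere. Ties in nearest-peak matching go
to the smaller m/z distance; apex-spectrum ties to the earlier spectrum;
NCE-calibration ties to the lowest NCE. Degenerate inputs fail loudly:
empty FASTA, profile-mode or isolation-metadata-free mzML, reports with
missing columns, apex RTs outside their boundaries, RT factors that do not
cover the observed RTs.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data:
300 precursors for interference recovery, 200 intensity examples and 500
RT peptides for model quality, three simulation seeds for the
masking-benefit comparison, and a few-hundred-precursor library build.
These sizes were chosen so the full suite exercises every stage in a few
minutes on one CPU. The detector operating point and model learnability
are stable across seeds; the masking-benefit comparison is decided by
majority over three simulation seeds because at a few hundred training
spectra the per-seed effect is small relative to training noise — the
benefit of masking grows with the interference burden and the training-set
size, and at desk scale it is a directional check, not a large margin.

## Known limitations

* The masking-benefit comparison disables the spectrum-rejection rules
  (via `reject = FALSE`) so both arms train on identical examples; with
  rejection active at high interference rates, most spectra are discarded
  (the observed top peak is usually contaminated) and the comparison
  confounds masking with training-set size.
* The Skyline report dialect is a documented column mapping, not a tested
  integration against Skyline output.
* Peak-boundary refinement is not implemented; boundaries come from the
  report verbatim.
* The weighted-moving-average smoother is exposed but Savitzky-Golay is
  the default and the tested path.
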