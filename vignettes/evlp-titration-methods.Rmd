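---
title: "Methods: titrating BE-eVLP preparations and monitoring transduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: titrating BE-eVLP preparations and monitoring transduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evlptiter)
```

Engineered virus-like particles carrying base-editor ribonucleoproteins
(BE-eVLPs) are produced in batches that vary in particle content, so
dosing by volume alone is not reproducible. This package implements two
titration routes — absolute sgRNA copy number by RT-qPCR, and relative
VSV-G abundance by a split NanoBiT (HiBiT/LgBiT) luciferase assay — the
dose adjustment that standardizes batches against a reference preparation,
the analysis of live-cell transduction kinetics in an LgBiT reporter line,
and a motif scan that looks for HiBiT-like peptides hidden in the plasmids
used for particle production. This vignette explains the models, the
tunable parameters, and the design decisions, in the order a user meets
them.

## Absolute sgRNA quantification

### The standard curve

A synthetic standard oligonucleotide (the cDNA sequence of a full sgRNA)
is serially diluted 10-fold, each step run in triplicate, and an ordinary
least-squares line is fitted in slope-intercept form with the log
quantity as the response:

$$y = m\,x + b, \qquad y = \log_{10}(\text{ng of standard}),\; x = \mathrm{Ct}.$$

This orientation — quantity regressed on Ct rather than the instrument
convention of Ct on quantity — is kept deliberately so that extrapolating
a test sample is a single antilog, `ng = 10^(m·Ct + b)`, with no algebraic
inversion. The amplification efficiency follows from the slope as
$E = 10^{-m} - 1$: a perfect assay doubles template each cycle
($m = -\log_{10} 2 \approx -0.301$, $E = 1$). `fit_standard_curve()`
reports $m$, $b$, $R^2$, $E$, and the number of surviving dilution points;
a well-behaved dilution series yields efficiencies in the 90–100% range
with $R^2$ very close to 1, and the fit refuses to proceed with fewer
than three valid points.

### Replicate quality control

Triplicate Ct values whose standard deviation exceeds 0.5 cycles contain
at least one outlier. The rule as stated leaves open which value to
discard and how many; `filter_replicates()` operationalizes it as: remove
the single value farthest from the median, re-test, and if the SD still
exceeds the threshold mark the whole group invalid. At most one value is
ever removed, every removal is recorded in the flags, and non-detects are
treated as missing rather than imputed at the cycle ceiling. Lowering the
threshold can only shrink the kept set (a tested monotonicity property).

### From ng to copies per µL of preparation

Mass converts to molecules with the standard single-stranded DNA
approximation:

$$\text{copies} = \frac{\text{ng} \times 6.022\times10^{23}\ \text{mol}^{-1}}
{L \times 330\ \text{g/mol} \times 10^{9}\ \text{ng/g}},$$

where $L$ is the amplicon length in bp (69 for the bundled scaffold
assay). Reaction-level copies then scale to the preparation through four
bookkeeping steps (`copies_per_ul_prep()`): × cDNA dilution factor (10 or
100), × cDNA synthesis volume (20 µL), ÷ RNA volume used in the synthesis
(sample-specific, default 4 µL), × RNA elution volume (30 µL), ÷ prep
volume extracted (5 µL). The workflow description mentions the cDNA
dilution both when defining the extrapolated ng and as step one of the
chain; applying it twice would inflate titers 100-fold, so the package
applies it exactly once, in the chain. Every factor lives in
`workflow_params()` and is validated strictly positive. The whole mapping
is degree-1 homogeneous: doubling input ng doubles the titer at every
stage, which the tests assert exactly.

For plasmid-carryover monitoring, `plasmid_load_per_genome()` quantifies a
plasmid target and an internal control gene (e.g. RPLP0) against their own
curves and amplicon lengths, converts control copies to genome equivalents
(default 2 control copies per diploid genome, overridable), and reports
plasmid copies per 100 genomes.

## Batch standardization

`adjust_doses()` solves the one-line proportionality
$v_i = v_{\mathrm{ref}} \cdot M_{\mathrm{ref}} / M_i$ for each prep, where
$M$ is the chosen metric (sgRNA copies/µL or lytic RLU/µL) on a common
undiluted basis — metrics measured at a dilution are first multiplied by
the dilution factor. The invariants are what make it trustworthy: the
delivered amount $v_i M_i$ is identical across preps by construction,
volumes are invariant to rescaling all metrics by a constant, and changing
the reference rescales all volumes by one factor. Volumes above an
optional cap are truncated with an explicit flag (never silently), and a
prep with zero metric is excluded as non-normalizable. Display rounds to
0.01 µL — pipettable precision — while full precision is kept internally.
Whether to equalize plate-measured or undiluted-basis RLUs is not fixed by
the protocol; the dilution-rescaled basis is the default and passing
`dilution = 1` reproduces the raw basis.

## Luminescence analyses

### Lytic titration

`lytic_titer()` summarizes replicate readings as mean and SD of log10 RLU,
subtracts the plate background (e.g. PBS wells) in linear space before any
log transform, floors negative differences at zero with a flag, and scales
by the measurement dilution for cross-prep comparison. Because it is not
stated whether published log10 RLU values are background-subtracted, both
the raw and subtracted values are returned.

### Live-cell kinetics

Each well is normalized by its own pre-treatment reading (time −1 h;
treatment at 0 h), which cancels well-to-well scale factors exactly —
proportional wells give identical normalized curves, and normalizing an
already-normalized course is the identity. The plateau of the mean curve
is defined operationally, since "plateaued" is qualitative: the plateau
level is the mean over the final `window` hours (default 1 h), and the
plateau time is the earliest time point from which every later value stays
within ±`plateau_tolerance` (default 5%) of that level, with the extra
requirement that the band be sustained for at least the final window — a
monotone ramp that only touches the band inside its own final window is
censored, not called a plateau. On noiseless logistic curves
$L/(1+e^{-k(t-t_{50})})$ the detector agrees with the closed-form band
crossing within one sampling interval for rates $k$ between 1 and 6 per
hour (a tested property). With noisy replicate means the 5% band is
intentionally strict: a single 3σ time point censors the call, and the
analysis drivers widen the band to match the simulated noise (15% at a
10% per-reading CV over triplicate wells) rather than weakening the
default.

Treatment effects are reported by `fold_change()` as control/treated at a
requested time (nearest recorded point within half the local sampling
interval; no interpolation), so a 4-fold inhibition by an
endosomal-acidification blocker reads as 4.0; SD is propagated from both
courses, and a zero treated mean yields a flagged infinite ratio rather
than an error. `dose_linearity()` compares signal ratios with volume
ratios against a ±30% default tolerance and flags saturation when the
signal falls short — the regime where cellular uptake capacity, not dose,
limits transduction. `correlate_editing()` regresses editing % (response)
on log10 RLU (predictor), matching how luminescence is used to predict
editing outcome; replicate-level points are used when available.

## Sequence analyses

### Six-frame scan for HiBiT-like peptides

A non-specific luminescent signal from untagged particles motivates asking
whether any plasmid-encoded protein region resembles the 11-residue HiBiT
peptide VSGWRLFKKIS (average mass 1.32 kDa). `translate_six_frames()`
translates whole frames — not ORFs — because cross-reactive peptides need
not start at a methionine: stops are kept as `*`, codons containing
ambiguity codes become `X`, and every residue carries a 0-based
forward-strand codon start so reverse-frame hits report consistent
coordinates. Windows containing `*` or `X` are excluded from matching (a
peptide interrupted by a stop is not translatable); `X` counts as a
mismatch where distances are computed.

Three comparators run over all 11-residue windows: exact identity;
Hamming distance (default reporting threshold 3, chosen as roughly a
quarter of the window — the full distance is always recorded so any
threshold can be re-applied); and a property comparator that maps residues
through a five-class biochemical alphabet (hydrophobic AVLIMFWY, special
GPC, polar STNQ, positive KRH, negative DE) and counts class differences.
The class grouping is a package default, shipped as an overridable named
map — residue identity implies class identity, so exact ⊆ Hamming ⊆
property hits at matched thresholds (a tested containment property).
Ordering and per-source ranking tie-break deterministically by distance,
then frame in the order +1,+2,+3,−1,−2,−3, then offset. All three
scanners are verified hit-for-hit against a naive all-windows brute force
on random 2-kb sequences.

### In-silico PCR

`insilico_pcr()` requires exact, full-length primer matches: one primer on
the template's forward strand and the other's reverse complement
downstream, the product spanning both matches inclusively. Both
orientations are tried; with several possible products the shortest is
returned with a multiplicity flag. Circular templates (plasmids) are
handled, off by default, by also scanning the origin junction extended by
primer-length−1 bases. On the three bundled standard oligonucleotides the
scaffold primer pair predicts one identical 69-bp product — the design is
spacer-agnostic, which is what makes a single standard curve serve any
guide.

## The synthetic-data generators

Every generator emits the exact tabular/FASTA dialects the analysis
functions read, plus a truth table, and is byte-reproducible under a seed
(restoring the caller's RNG state). The defaults are the study
conditions: 7-point 10-fold dilution series in triplicate; Gaussian Ct
noise with SD 0.15 cycles; prep titers in the 10⁶ copies/µL range; no-RT
signal 20–26-fold below the test signal; logistic ("sigmoidal")
transduction kinetics with rate 3/h and midpoint 1 h over a small
pre-treatment baseline, sampled every 5 min for the first hour and every
30 min to 5 h; lognormal well scale factors (SD 0.2 on the log scale) and
10% multiplicative measurement noise; dose-proportional plateaus capped
above 5 µL to emulate saturation of endocytic capacity. Noise magnitudes
are not published quantities — they are package assumptions calibrated to
the visual spread of typical replicate bars and stated here as such.

What the generators deliberately do not model: amplification-efficiency
drift across a dilution series, inter-plate batch effects, substrate
depletion kinetics, Sanger trace noise in the editing percentages, or any
immune-response dynamics. Passing the recovery tests therefore shows the
estimators are correct for data that satisfy the stated model, not that
real plates are free of these artifacts.

## Numerical and scope notes

Problem sizes in the test suite are chosen to exercise the statistics at
realistic scale: 200 simulated preps for parameter recovery (median
absolute relative titer error below 10% at Ct SD 0.15), 50 random 2-kb
sequences for scanner-oracle equivalence, and noiseless limits checked to
10⁻⁹ relative. Degenerate inputs are explicit: all-ND replicate groups
and zero control signals flag rather than throw; empty scan results are
empty data frames; a missing primer site is a no-product result, not an
error. The package does not call Cts from raw fluorescence, analyze melt
curves, quantify editing from traces, align with gaps, or use
substitution matrices; those sit outside its scope.
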