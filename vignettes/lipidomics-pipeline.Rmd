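---
title: "Processing untargeted lipidomics data with lipidproc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing untargeted lipidomics data with lipidproc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidproc)
```

# Scope and model

`lipidproc` processes untargeted high-resolution LC-MS lipidomics feature
tables — as produced by upstream peak picking — into per-species molar
abundances and group-level statistics. The motivating application is the
lipidome of ether-lipid biosynthesis defects: deficiencies of
CTP:phosphoethanolamine cytidylyltransferase (ET, the rate-limiting enzyme of
the CDP-ethanolamine pathway) reshape the phospholipid and neutral-lipid
profile of patient fibroblasts and plasma, with accumulation of ether-PC,
DG/TG and their ether analogues, reduction of PC/PE and their lyso and ether
analogues, and appearance of plasmanyl-PS in patients only.

The pipeline runs four stages:

1. **Annotation.** Observed m/z values are matched against a species
   database within a ppm tolerance (default 3 ppm, the routine accuracy of
   an externally calibrated Orbitrap).
2. **Isotope correction.** Natural-abundance isotopologue patterns are
   computed from elemental formulas and species whose patterns are
   unresolvable at the instrument resolution are deconvoluted jointly.
3. **Quantitation.** Intensities are converted to nmol per mg protein
   against class internal standards and summed per class.
4. **Statistics.** Student's t-test, one-way ANOVA with Bonferroni
   correction, optional Dunnett comparisons versus control, and PLS-DA with
   VIP ranking.

A ground-truthed synthetic-study generator reproduces the statistical
structure this analysis assumes, so every stage can be validated by
parameter recovery.

# Lipid chemistry

A species is identified as `class(carbons:double_bonds)`, e.g. `PC(34:1)`.
Each class carries a construction rule — a base formula plus one C and two H
per side-chain carbon, minus two H per double bond — shipped as a versioned
table (`class_rules()`), validated against reference compositions of the
di-14:0 standards. Ether (`[O]`) species are the diacyl counterpart minus O
plus 2 H (an alkyl sn-1 linkage). Plasmenyl (vinyl-ether, plasmalogen)
species are stored as alkyl species with the vinyl-ether double bond counted
in `double_bonds` (`P-n:m` is `O-n:m+1`), which makes the formula rule
unambiguous; mass spectrometry cannot distinguish the two anyway, only the
acid-hydrolysis assay can (see below).

Isotopologue distributions are computed by element-wise convolution of
per-element isotope patterns (IUPAC masses and abundances, bundled and
versioned). Patterns are truncated at M+3 by default: the retained fraction
exceeds 99% for all in-scope species and is recorded per distribution. The
exact mass shift reported for each nominal shift is the abundance-weighted
mean over contributing isotopic combinations.

The default database (`default_class_config()`) enumerates roughly 270
species over the classes named by the internal-standard panel plus the ether
variants relevant here (including plasmanyl-PS), one primary adduct per
class in the class's routine polarity (protonated/deprotonated
glycerophospholipids, ammoniated neutral lipids). The adduct choice per
class is a documented default, not a reconstruction of any particular
instrument method; it is fully user-overridable. Endogenous carbon ranges
start above the short-chain standards so the spiked species never collide
with an enumerated endogenous species.

# Annotation and overlap groups

A feature is matched to every database isotopologue peak within the ppm
tolerance, in its own ion mode; the accepted candidate minimizes the
absolute ppm error (ties: fewer double bonds, then lexical class order).
All candidates are kept with an `accepted` flag so ambiguity remains
auditable. Retention time is carried but not used for matching; an optional
RT window exists and is off by default, since identification here is
mass-based.

Overlap groups are built from a resolution model: full width at half maximum
FWHM(m/z) = m/z^1.5 / (R sqrt(m0)) with resolving power R = 280,000
referenced at m0 = 200 (Orbitrap-type scaling), and two theoretical peaks
are considered unresolvable when closer than 2 FWHM. The archetype is a TG
pair one double bond apart: the M+2 of the more unsaturated species lands
about 9 mDa below the other's monoisotopic peak. Each annotated species'
predicted isotopologues are assigned to the nearest feature within that
threshold; species sharing a feature form one connected component, which is
one linear system.

# Isotope correction

Per group and per sample the pipeline solves `y = A x`, where `y` holds
feature intensities and column `s` of `A` holds species `s`'s isotopologue
fractions at the features they map to. The solution `x` is the species'
full-pattern intensity. Square non-singular systems (the usual triangular
double-bond chains) are solved exactly — equivalent to the classic
sequential peel-off subtraction — and otherwise, or whenever noise pushes an
exact solution negative, non-negative least squares is used. Rank-deficient
systems are flagged and their species reported `NA` (unresolved), never
silently zeroed. Missing features enter as zero intensity, consistent with
the "low/absent in controls" semantics needed for patients-only species.

# Quantitation

For classes with an internal standard, abundance = (species intensity / IS
intensity) x spiked nmol / protein mg, in nmol per mg protein. Ether classes
are normalized on the diacyl-class standard. Classes without a standard are
protein-scaled only and unit-tagged `intensity_per_mg`. Protein scaling and
IS normalization commute under this formula, so their order is immaterial.
Class totals are arithmetic sums over member species, standards excluded.
They rest on the equal-response assumption within a class, so totals are
comparable between sample groups within a class, never across classes; the
output carries that caveat as metadata. Fold changes are ratios of group
means; a zero control mean with positive patient mean is reported as a
`patients_only` sentinel rather than an infinite ratio. Species with at
least 38 side-chain carbons and at least 5 double bonds are flagged as
PUFA-rich.

The deuterated CE standard is modeled as unlabeled CE(16:0): the label only
shifts the standard's own m/z and plays no role in any in-scope computation.

## Plasmalogen discrimination

Hydrochloric acid hydrolyses the plasmenyl (vinyl-ether) but not the
plasmanyl (alkyl) sn-1 linkage. Given paired untreated/treated runs, the
fraction of each ether species surviving treatment classifies it: below 0.5
is plasmenyl, at or above is plasmanyl, and species undetected before
treatment are indeterminate. The 0.5 threshold sits halfway between the
ideal outcomes (0 and 1) and tolerates partial hydrolysis and measurement
noise symmetrically.

## Enzyme activity

ET activity is quantified by stable-isotope dilution: the measured response
is product peak area over internal-standard area times the 87 pmol IS
amount, inverted through an unweighted ordinary-least-squares calibration
line (with intercept by default; through-origin optional) and divided by
protein (40 µg per assay) and incubation time (1 h), giving pmol h^-1 mg^-1
— units chosen to match the assay scale since none are dictated by the
readout itself.

# Statistics

The t-test defaults to the pooled-variance (Student's) form; Welch is
available. The ANOVA spans all group levels. Bonferroni multiplies by the
number of species tested in the run — the natural family for one
matrix/polarity analysis. Degenerate species (zero variance everywhere) get
p = 1 when means agree, p = 0 when they differ, and are flagged.

Dunnett's test versus control is computed by Monte Carlo: group means and a
shared pooled variance are drawn under the joint null and the family-wise p
is P(max |T| >= |t_obs|). With 10^5 draws the Monte-Carlo error is well
under 0.005, and with a single comparison group the procedure reduces to the
two-sided t-test, which is verified in the tests (as is agreement with the
closed-form implementation in `multcomp`).

PLS-DA uses sequential NIPALS extraction against centered one-hot group
indicators, with autoscaling (the metabolomics default; center-only and
Pareto are available) and deflation after each component; two components by
default. The fit is deterministic. VIP scores use the standard
explained-response-variance weighting, so mean squared VIP is exactly 1.
The VIP ranking targets the patient-versus-control discrimination, so
subject-level subgroups are collapsed to a binary response for this stage —
with the subgroup response the leading components chase within-patient
differences that are pure noise under the study design. Heat-map matrices
take the top-30 VIP-ranked species, log-transform with a pseudo-count of
half the smallest nonzero value, and center each row, so color encodes log
relative abundance versus the per-species mean.

# The synthetic-data generator

`simulate_study()` emulates the target study design: 3 control and 2
patient fibroblast lines, each measured in quadruplicate. Species baselines
are log-normal (median 0.5 nmol/mg, log-SD 0.7); patient abundances are
baseline times a class multiplier — defaults x4 PC[O], x3 LPC[O], x2 DG/TG,
x3 DG[O], x4 TG[O], x0.5 for PC, LPC, PE, LPE, PE[O], LPE[O] — with
plasmanyl-PS appearing in patients only (true zero in controls). The fold
differences are synthetic defaults chosen to be of the magnitude seen in
ether-lipid deficiency; they are not measured values. Each species carries a
fixed per-species effect drawn around its class multiplier (log-SD 0.25),
reflecting that class-level effects in real lipidomes are heterogeneous
across species. Intensity noise is multiplicative log-normal (CV 15%,
mean 1); mass error is Gaussian (SD 1 ppm) — standard figures for an
Orbitrap-class instrument. Internal standards are spiked at the panel
amounts per extraction. Isotopologue peaks are emitted to M+3, peaks within
the resolution-model merge threshold are summed into one observed feature
(creating true overlap groups), and the observed feature m/z is the
position of the strongest contributing peak plus ppm error, emulating apex
centroiding of partially fused peaks.

Two seeds separate biology from measurement: `seed` fixes baselines,
per-species folds and patients-only species; `noise_seed` (default derived
from `seed`) fixes the noise realization, so the same biology can be
re-measured. The generator records ground truth — per-sample species
amounts, per-species sn-1 linkage, the feature that holds each species'
monoisotopic peak and whether that peak is its cluster's apex — enabling
honest recovery denominators: a monoisotopic peak buried under a stronger
neighboring isotopologue is undetectable at the instrument resolution, which
is physics, not an annotation failure.

`simulate_hydrolysis_pairs()` renders the same extracts untreated and
treated, scaling plasmenyl species by 1 - efficiency. The default linkage
truth encodes the pattern characteristic of ET deficiency: PC-ether species
plasmanyl, PE-ether species plasmenyl. `simulate_enzyme_assay()` generates
assay records and calibration points under one instrument-response model,
and `simulate_null_matrix()` produces species-level null matrices for
calibration checks (under the null the class structure is irrelevant and
only the noise model matters).

What the generator does **not** emulate: chromatographic peak shapes and
co-elution, adduct multiplicity per species, in-source fragmentation,
intensity-dependent mass error, detector saturation, and batch effects.
Passing recovery tests therefore demonstrates the correctness of the
computations under the stated noise model, not robustness to every artifact
of real acquisitions.

# Numerical choices

* Isotope patterns are convolved exactly and truncated last; binary
  exponentiation keeps C100-scale formulas cheap.
* NNLS per group per sample; exact triangular solve as a special case.
  Residual norms are reported per group and sample.
* The Dunnett null is sampled once per design and reused across species.
* Degenerate inputs are handled by convention and flagged: zero-variance
  tests, zero IS intensity (class invalid in that sample), zero control
  means (sentinel), zero abundances in log heat maps (pseudo-count).
* NIPALS converges on weight-vector change below 1e-10; constant columns
  are given zero weight rather than dropped, preserving indexing.

# Problem sizes used in validation

The bundled tests and the acceptance script validate at desk scale: the
default ~270-species panel with 20 samples end to end; 200 random formulas
against a brute-force isotopologue enumeration; triangular chains of 2-6
species and 100 random systems against grid-refinement search; 10-seed
annotation-recovery and plasmalogen runs; 2000 null species for t-test
calibration; 192 replicate enzyme assays at 5% area noise. These sizes give
stable estimates of every reported rate while keeping a full run in minutes.

# Known limitations

* Identification is by accurate mass only; isomeric species (same class,
  carbons, double bonds) are indistinguishable, and sn-positional isomers
  are out of scope.
* Quantitation inherits the equal-response assumption of class internal
  standards; values are relative molar abundances, not absolute
  concentrations, and ether classes borrow the diacyl standard.
* The VIP *ranking order* among strongly perturbed species is intrinsically
  unstable when the group discrimination saturates (many species separating
  the groups almost perfectly): the membership of the extreme top of the
  list then varies between noise realizations even at fixed biology. The
  reliable statement is that the top of the ranking is dominated by truly
  perturbed species, which is what the validation asserts.
* Cross-sample joint deconvolution and isotope-tracer correction are not
  implemented; correction is per sample and assumes natural abundance.
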