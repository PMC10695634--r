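---
title: "Methods: linking secreted extracellular DNA to yeast metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking secreted extracellular DNA to yeast metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exdna)
```

## The problem

Growing *Saccharomyces cerevisiae* in fed-batch reactors releases DNA
fragments into the culture medium. The amount and genomic identity of this
extracellular DNA (exDNA) depend on the active metabolism — fermentative
under unrestricted exponential feeding, respiratory when the feed is
limited — and the accumulating exDNA behaves like a growth self-inhibitor.
`exdna` re-implements the computational side of that analysis as a reusable,
fully testable pipeline: descriptive metrics for genome-mapped fragment
sets, similarity of exDNA against intracellular extrachromosomal circular
DNA (eccDNA), gene-set and pathway coverage, an NMR correlation
fingerprint of the medium, and a fed-batch feeding/growth model. A
synthetic-data module generates every input type, so each stage can be
exercised end to end without any external download.

All genomic intervals in the package are 0-based and half-open, the BED
convention; GFF3 input is converted on read. Strand is ignored throughout:
the fragment and eccDNA comparisons are strand-agnostic. The bundled
reference is the S288C r64 assembly layout — 16 nuclear chromosomes plus
the mitochondrial chromosome, 12,157,105 bp in total — and it supplies the
denominator for genome-fraction and density computations. The eccDNA
coordinates used as a comparison reference are assumed to be on the same
assembly; the loaders do not lift over between assembly versions.

## Fragment metrics

`stratify_metrics()` cross-tabulates a fragment set by length class
(shorter or longer than 100 bp) and FPKM class (`<10`, `10-100`,
`100-1000`, `>1000`). Class boundaries are half-open — `[0,10)`, `[10,100)`,
`[100,1000)`, `[1000,Inf)`, and `[100,Inf)` bp for the long class — because
range labels like "10-to-100" do not state boundary ownership and the
half-open choice is the only self-consistent partition. Roll-ups are exact
stratum aggregates: counts and total lengths are additive, means are
length-sums over counts. kbp totals are rounded half-to-even to integers
for display and kept unrounded internally; percentage-type quantities use
half-away-from-zero rounding (`round_half_away()`), the convention that
reproduces published coverage-percentage tables cell by cell.

`genome_fraction()` defaults to sum-of-lengths mode (fragment lengths
summed, overlaps counted every time) rather than a merged-footprint union,
because published per-sample Mbp figures equal the plain total contig
lengths, showing no overlap-merging was done upstream. Union mode is
available and is never larger, with equality exactly for disjoint sets.
`chromosome_density()` reports fragments per Mbp per chromosome, the
unweighted mean ± sample SD over nuclear chromosomes, and the
mitochondrial chromosome separately, since mitochondrial representation is
where fermentative and respiratory media differ most.

## Overlap similarity

The comparative engine asks how much of a reference fragment set (usually
eccDNA) is recovered in a query set (exDNA from one medium), with three
reference-normalized metrics:

* **fragment-based** — the percentage of reference fragments overlapped by
  at least 1 bp by any query fragment;
* **bp-based** — the percentage of total reference length covered by the
  query footprint; the query is merged (union) first so shared base pairs
  are never double-counted, while the reference side is deliberately not
  merged, keeping the denominator equal to the plain total reference
  length;
* **gene-based** — genes overlapped completely *or partially* (≥ 1 bp) by
  fragments of both sets, with Venn partitioning for two or three sets.

The overlap predicate is ≥ 1 shared bp on the same chromosome; no minimum
overlap fraction or reciprocal-overlap threshold is applied, since the
definition being mirrored gives none. Overlap queries go through
Bioconductor `IRanges`/`GenomicRanges` index structures; the test-suite
checks the index against an independent brute-force scan on a thousand
random set pairs. All percentages are reported to one decimal. Metrics are
directional: swapping query and reference changes the value unless the
sets coincide.

## Pathway coverage

`coverage_table()` counts, for each sample gene set, the members of each
pathway present, as a count and as an integer percentage of pathway size
(half-away-from-zero). The default synthetic pathway collection mirrors
the five KEGG pathways used to separate respiratory from fermentative
signatures — TCA cycle (31 genes), pentose phosphate (28), oxidative
phosphorylation (76), glycolysis/gluconeogenesis (55), cell cycle (130).
No enrichment statistic is computed: coverage is reported raw, and a gene
belongs to a sample by the same partial-overlap rule as the Venn analysis.

## NMR fingerprint

Proton NMR spectra of the culture medium are reduced to 1000 bins of 0.01
ppm over 0–10 ppm (`bin_spectrum()`; bins are left-closed right-open, the
1000th closing at exactly 10.00). `normalize_permille()` masks a residual
solvent window — default 4.60–4.80 ppm around the D2O resonance at 4.70
ppm; the window width is configurable because it is not standardized — and
rescales the remaining bins to sum to exactly 1000.

`correlate_growth()` computes a Pearson correlation between every bin and
the culture growth rate, defined as the backward difference Δmass/Δt
carried to the interval's right endpoint; the spectrum at time *t_i* pairs
with the rate over (*t*<sub>i-1</sub>, *t_i*], so the first spectrum drops
out. With 9–10 observation times the sample is small, so p-values come
from the exact t distribution with n−2 degrees of freedom, not a normal
approximation. Two significance classes are kept, strong (p < 0.001) and
weak (p < 0.05), with strict inequalities and the sign carried by r. No
multiple-testing correction is applied — deliberately, to mirror the
original procedure — and the profile records the expected false-positive
count (0.05 × bins tested) so a reader can weigh isolated weak hits.
`annotate_regions()` labels significant bins with diagnostic
chemical-shift regions (deoxyribose protons at 3.40–4.40 and 2.30–2.80
ppm, anomeric protons at 5.60–6.30 ppm, nitrogen-base protons between 5.9
and 8.4 ppm, amino-acid signals at 0.60–0.75, 1.80–2.20 and 6.50–7.30
ppm); overlapping regions are all reported.

Whether correlation should run on raw or per-mille-normalized bins is not
fixed by the procedure being mirrored; the pipeline normalizes first (the
order the processing description implies) but `correlate_growth()` accepts
either. Note one consequence used by our own calibration tests: per-mille
normalization divides every bin by the total signal, which couples bins
together and lets strongly rate-associated signal regions induce spurious
(anti-)correlations in otherwise null bins. Statistical-calibration checks
(type-I error, sensitivity) therefore run on raw synthetic intensities,
where null bins are genuinely independent; on normalized data the
false-positive rate among null bins can exceed the nominal level when a
large share of the spectrum carries signal.

## Feeding and growth model

`exponential_feed()` implements F(t) = F0·exp(SFR·t) with the specific
feed rate SFR defaulting to 0.16 h⁻¹. The limited regime
(`limited_feed_profile()`, and `simulate_fedbatch(mode = "lfc")`) holds
SFR at its initial value until a switch time, then scales it by
μ(t)/μ(switch), clipped to [0, SFR₀]. A feed that is progressively
reduced to track the culture's declining specific growth rate admits
several functional forms and no exact one is standardized; this μ-tracking
rule is one admissible reading, and it is flagged as such. OD590 and biomass
interconvert by the calibration factor 2.30 OD590 per g L⁻¹.

`simulate_fedbatch()` integrates a deliberately minimal
growth-with-inhibitor model (it is *not* a reimplementation of the full
published systems-dynamics model, which is out of scope):

dX/dt = μX, dS/dt = F·s_in/V − μX/Y, dI/dt = k·μX,
μ = μ_max · S/(K_s+S) · max(0, 1 − I/I_cap).

Inhibitor secretion is growth-linked (proportional to μX) by default, with
a switch to biomass-linked (∝ X) secretion, since extracellular DNA keeps
accumulating after the growth plateau in respiratory cultures. Defaults
(μ_max = 0.45 h⁻¹, K_s = 0.2 g L⁻¹, Y = 0.5 g g⁻¹, s_in = 300 g L⁻¹,
X₀ = 1 g L⁻¹, k = 0.1, I_cap = 3) are typical aerobic-glucose values
chosen so that the inhibitor ceiling X₀ + I_cap/k ≈ 31 g L⁻¹ binds before
substrate does: that makes matched exponential and limited runs converge
to the same final biomass (≈ 30 g L⁻¹), the qualitative behaviour of the
real cultures, even though the limited run ends with a feed rate several
times lower. The batch phase is not simulated; time zero is feed onset,
and the feeding phase lasts 30 h by default. Volume change from feeding is
ignored (constant-volume approximation).

Integration is fixed-step RK4 at dt = 0.01 h — the system is non-stiff and
a fixed step keeps runs bit-reproducible for testing; halving the step
changes final biomass by well under 0.1%. The feed rate is held constant
within a step and advanced geometrically between steps. A non-finite state
aborts with the failing time step named. F0 is a free parameter (its
numeric value is not published); the default matches the initial substrate
demand of X₀ growing at SFR.

## Synthetic data: what it emulates, and what it does not

`make_fragments()` draws fragment lengths log-normal (default meanlog 5.2,
sdlog 1.3: mean ≈ 420 bp, range tens of bp to tens of kbp, floor 11 bp)
and FPKM log-normal (meanlog 1, sdlog 2), giving the heavy tail in which a
handful of contigs exceed FPKM 1000 while thousands sit below 10. Only
class counts, not raw abundance distributions, are published for real
samples, so these defaults are calibrated to reproduce the *shape* — four
occupied FPKM classes with the observed ordering — not any exact class
proportions. Similarity targeting places one query fragment inside each of
a randomly chosen fraction *s* of reference intervals and the rest in
reference-free gaps, so the fragment-based similarity is controlled
directly (recovered within a couple of percentage points; exactly *s* when
the reference intervals are disjoint). Generated sets are pure functions
of (parameters, seed).

`make_nmr_series()` builds spectra in which labeled bins move with the
standardized growth rate — intensity = baseline ± effect·z(rate) + Gaussian
noise truncated at zero, defaults effect 2, noise SD 1, baseline 10 — and
null bins are baseline plus noise. The default label map marks the
DNA-constituent regions negative and nutrient regions positive, emulating
the structure of a respiratory-culture fingerprint. A pre-build power
calculation fixed the default effect-to-noise ratio at 2: with 9
observation times (8 paired rates) the population correlation is
2/√5 ≈ 0.89 and the weak-threshold power ≈ 0.89, comfortably above the
80% sensitivity the calibration tests require.

What the generators do *not* emulate: sequencing reads, mismatch
accumulation, amplification bias, assembly artifacts, real FPKM class
proportions, chemical peak shapes or multiplets, and the metabolic
(fermentative/respiratory) switch itself. Passing synthetic tests
therefore demonstrates that the arithmetic, the interval algebra and the
statistical machinery are correct under controlled conditions — not that
biological conclusions transfer to any particular real dataset.

## Numerical choices and degenerate inputs

* Percentages to one decimal; integer percentages half-away-from-zero;
  display kbp half-to-even. Internal values are never rounded.
* Empty fragment sets give zero counts and NA means; an empty *reference*
  set makes similarity undefined and errors.
* Zero-variance spectral bins are flagged undefined and can never be
  significant; all-zero spectra refuse to normalize.
* Validation rejects exactly the fragments violating
  0 ≤ start < end ≤ chromosome length, naming the first offender.
* Problem sizes in the shipped tests — e.g. 1000 random set pairs of up to
  200 fragments for the oracle-equality checks, 1000 seeds × 200 null bins
  for the type-I calibration, 100 seeds for sensitivity — were chosen to
  make Monte-Carlo error small relative to the tested tolerances.

## Known limitations

* The package consumes mapped fragment tables; read mapping, assembly and
  FPKM computation happen upstream.
* Published headline similarities between real exDNA and eccDNA (83.6% /
  91.2% for the respiratory culture) require the original supplemental
  datasets, which are not redistributed here; the engine reproduces them
  only given those inputs. The shipped tests substitute exhaustive
  oracle-equality and generator-recovery properties.
* Two published gene-universe sizes for eccDNA (1957 vs 1861) are
  inconsistent with each other; the engine carries whichever universe it
  is given and never reconciles the two.
* The growth simulator is a minimal caricature intended for generating
  plausible trajectories, not for fitting real reactor data.
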