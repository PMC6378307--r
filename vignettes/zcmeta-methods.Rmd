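---
title: "Methods: carbon oxidation state of sequence pools and the redox-affinity model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon oxidation state of sequence pools and the redox-affinity model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zcmeta)
```

## The oxidation-state metric

For a formula $\mathrm{C}_c\mathrm{H}_h\mathrm{N}_n\mathrm{O}_o\mathrm{S}_s$
the average oxidation state of carbon is

$$Z_\mathrm{C} = \frac{-h + 3n + 2o + 2s}{c},$$

implemented in `zc()`. It assigns the usual oxidation numbers (H +1, N −3,
O −2, S −2) to the heteroatoms and attributes the remainder to carbon, so it
runs from −4 in methane to +4 in CO~2~. The generalized form `nosc()`,

$$\mathrm{NOSC} = \frac{z - h + 3n + 2o + 2s - 5p}{c},$$

adds the formal charge $z$ and phosphorus (+5) terms. The two coincide for
neutral phosphorus-free molecules. The distinction matters for exactly one
reason here: protonation changes $h$ and $z$ together, and phosphate
condensation (+HPO~3~: $h{+}1, o{+}3, p{+}1$) changes three terms at once, and
only the NOSC form is invariant under both. That invariance is why the
oxidation state of a DNA or RNA strand — charged sugar-phosphate backbone and
all — equals that of its constituent nucleosides, and why the package can
compute nucleic-acid $Z_\mathrm{C}$ from nucleoside formulas while the
thermodynamic layer uses phosphate-bearing nucleotide ions. The test suite
asserts these invariances by direct recomputation on randomized compositions.

Element counts are stored as reals, not integers: the average per-monomer
formula of a hypothetical 50 % Ala / 50 % Gly protein is
C~2.5~H~6~NO~2~ ($Z_\mathrm{C} = 0.4$), and such fractional formulas are the
central objects of the thermodynamic model. `combine_compositions()`
implements the weighted element-wise sum; the $Z_\mathrm{C}$ of any
combination is the carbon-weighted mean of the members' values, which the
tests verify against a brute-force oracle.

## From sequence files to pooled compositions

Unassembled reads are cleaned in two steps before pooling. The ambiguity rule
removes reads with more than 5 non-ACGT characters (all IUPAC ambiguity
codes count; composition is never assigned to an ambiguous base). The length
rule removes reads outside mean ± 2 SD of the set's lengths (population SD,
inclusive boundaries). A single pass of the length rule is not a well-defined
selection: truncating a distribution shrinks its SD, so reapplication removes
further boundary reads. `length_filter()` therefore iterates the rule to a
fixed point, making the operation idempotent (an explicitly tested property);
`iterate = FALSE` recovers the strict single-pass behaviour of the upstream
preprocessing scripts this convention comes from. Contig inputs skip both
cleaning stages, as well as dereplication.

`dereplicate()` removes artificial duplicate reads by exact identity of the
leading 50-base prefix (full-sequence identity for shorter reads), keeping
the first occurrence — the deterministic tie-break. The 50-base default
follows the common preprocessing convention for amplification duplicates and
is configurable.

`pool_dsdna()` counts unambiguous bases and base-pairs them: A–T pairs =
A + T, G–C pairs = G + C. Working on the double-stranded composition makes
pooled $Z_\mathrm{C}$ invariant to which strand was sequenced and to GC skew
(both tested). Since the only compositional degree of freedom left is the GC
fraction $f$, dsDNA $Z_\mathrm{C}$ follows the closed form
$(10 + 4f)/(20 - f)$; the implementation nevertheless sums full nucleoside
compositions, and the closed form serves as the independent oracle (and as
the generator's truth function). mRNA pools count positive-sense coding
sequences as ribonucleosides (negative-sense genes are reverse-complemented
first by `orient_cds()`); protein pools count residues as free amino acids.

Per-taxon pools keep only taxa with ≥ 1 % of classified reads *and* ≥ 20,000
unambiguous bases — both thresholds are needed because a taxon can clear the
fraction test on a handful of short reads whose composition would be
unstable.

## Subsampling uncertainty

`subsample_zc()` includes each sequence independently with probability
$p = \mathrm{target}/\mathrm{total}$, so the expected subsample size equals
the target in *units* (bases or amino acids) even though reads have variable
lengths — the only interpretation of "subsamples averaging 50,000 bases"
that is well-defined per read. Sampling is without replacement within a
replicate; replicates that draw zero units are redrawn (and counted), keeping
the number of scored replicates fixed. Defaults: 50,000 units × 100
replicates for whole-sample estimates; 10,000 × 100 for species-level
estimates, whose smaller classified-read pools force a smaller target at the
cost of a larger SD (the SD ordering is tested). Every estimate is
reproducible from one integer seed; the pipeline derives independent
per-sample, per-stage substreams from its configured seed, so reruns write
byte-identical tables.

The subsample mean converges to the whole-pool value as the target grows
(unbiasedness within sampling error is tested against a
$3\,\mathrm{SD}/\sqrt{\mathrm{reps}}$ bound), and the SD scales roughly as
$1/\sqrt{\mathrm{target}}$ for i.i.d. reads (tested within a factor of two).

## The thermodynamic model

`average_monomer()` collapses a sample to one average monomer — for DNA the
mole-weighted mean of the two nucleotide-monophosphate base pairs
(dAMP²⁻ + dTMP²⁻ and dGMP²⁻ + dCMP²⁻), for protein the mole-weighted mean
amino acid — with a matching mole-weighted mean standard Gibbs energy.
Averaging normalizes molecule size away so that the energetics compare
compositions; scaling a sample's counts by any constant changes nothing
(tested). The NMP ions are taken as the fully deprotonated −2 species of the
standard compilation; the loss of one H~2~O per monomer on polymerization is
ignored because it is identical for every sample and cancels from relative
affinities (and cannot affect $Z_\mathrm{C}$ at all).

`balance_reaction()` solves the 7 × 7 linear system (C, H, N, O, S, P,
charge) for the unique basis-species coefficients forming one mole of
product from H~2~O, HCO~3~⁻, H~2~PO~4~⁻, NH~4~⁺, HS⁻, H⁺ and e⁻. The solve
is refused if the residual exceeds 10⁻⁹ (it is at machine precision for all
tested inputs). With carbon supplied fully oxidized (+4) and N and S at
their basis oxidation states (−3, −2), the electron coefficient obeys

$$n_{e^-} = c\,(4 - Z_\mathrm{C}),$$

e.g. 12 for alanine, 6 for glycine — the hand-balanced oracle of the test
suite, and the mechanism linking oxidation state to redox sensitivity.

`affinity_curve()` evaluates $A/(2.303RT) = \log K - \log Q$ on an Eh grid
at 25 °C, 1 bar, with fixed basis log activities (0, −3, −5, −7, −9, −7)
and the electron activity driven by Eh:
$\log a_{e^-} = -F\,E_h/(2.303RT)$, i.e. −16.90 per volt at 25 °C. The
product activity is fixed at 1; any common choice cancels from relative
affinities, which are the reported quantity. Affinity is affine in Eh with
slope $-n_{e^-} F/(2.303RT)$ (tested analytically), so the absolute curves
of different samples in a dataset are nearly indistinguishable — the
electron term dominates. `relative_affinity()` subtracts the per-Eh mean
across samples (zero-sum at every grid point, by construction and by test),
exposing the compositional differences.

The default Eh window is −0.35 V to +0.05 V in 128 steps. No single window
suits every environment; the window is configuration, and its endpoints
define the quadrant evaluation: `quadrant_classify()` requires the
designated most-reducing samples to have strictly positive relative
affinities for *both* DNA and protein at the low-Eh endpoint, and the
most-oxidizing samples at the high-Eh endpoint. Degenerate datasets
(identical compositions) put endpoints on the axes and classify as negative.
Temperature is fixed at 25 °C even for hot-spring-like gradients —
per-sample temperature correction of Gibbs energies (HKF-style equations of
state) is out of scope, as are activity coefficients and speciation.

The bundled monomer table ships formulas and standard Gibbs energies
(kJ/mol, aqueous, 25 °C) for amino acids, nucleobases, sugars, nucleosides,
NMP ions and basis species, with explicit unit tags and per-row source
notes. The Gibbs energies are approximate transcriptions of the standard
geochemical compilations (several nucleoside/NMP values are additive
estimates, flagged as such). Every tested thermodynamic claim —
conservation residuals, the electron-count identity, slopes, zero sums,
orderings, quadrant logic — is structural and independent of these absolute
values; absolute affinities inherit their uncertainty and should be read as
indicative.

## The synthetic-data generator

`gen_reads()` draws i.i.d. bases at $P(G) = P(C) = \mathrm{gc}/2$ with
normal read lengths (default mean 250, SD 50 — typical of the classified
read lengths in the environmental datasets this workflow targets), optional
uniform N contamination, and injected exact-copy duplicates whose count is
recorded, so dereplication can be checked against truth. An optional GC-skew
knob redistributes G/C on the sequenced strand without changing GC fraction,
to exercise the strand invariance. `gen_cds()` draws genes codon-by-codon
from per-amino-acid frequencies (synonymous codons uniform under the
standard genetic code) and emits a random half negative-sense with strand
labels. `gen_gradient()` arranges samples along a gradient — default five
samples, GC 0.30 → 0.60 (the bulk-genomic GC range), 1,500 reads each,
0.2 % N rate, 5 % duplicate rate, 85 % coding fraction — with protein
composition interpolating between a reduced (aliphatic-rich) and an
oxidized (Gly/Ser/Asp/Asn/Thr-rich) endmember, so DNA and protein oxidation
states co-vary as they do along natural redox gradients. Truth tables carry
the closed-form DNA $Z_\mathrm{C}$ and the frequency-derived protein
$Z_\mathrm{C}$.

What the generator does *not* emulate: dinucleotide and codon-position
structure (irrelevant to any statistic that depends only on composition),
sequencing error and quality scores, genome-level organization of named
taxa, read-coverage structure from real communities, and rRNA content.
Passing tests therefore demonstrate correctness of the compositional and
thermodynamic machinery under known truth — not robustness to classifier
error or to the ecological complexities of real metagenomes, which enter
the package only through its input interfaces.

Test and example problem sizes (hundreds to a couple of thousand reads per
sample, 8,000–50,000-unit subsampling targets, 16–128-point Eh grids) are
chosen so the full suite exercises every stage, including five-sample
end-to-end runs, in about a minute and a half; all defaults scale to
realistically sized inputs unchanged.

## Known limitations

- Energies are 25 °C/1 bar only; no temperature/pressure extrapolation, no
  ionization-state speciation of amino-acid side chains (the simplified
  additive monomer model is used deliberately).
- Absolute affinities depend on the approximate bundled Gibbs energies;
  relative affinities and all tested structure do not.
- Single-stranded DNA/RNA $Z_\mathrm{C}$ depends on all four base
  frequencies, not just GC; only the dsDNA pool enjoys the closed form.
- External preprocessing (adapter trimming, rRNA removal, gene calling,
  taxonomic classification) is trusted as given; the package neither
  validates nor re-performs it.
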