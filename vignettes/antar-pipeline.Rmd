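---
title: "Dissecting NIT-ANTAR autoinhibition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting NIT-ANTAR autoinhibition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antartools)
```

## The biological question

ANTAR domains are small three-helix RNA-binding modules that promote
transcription antitermination: when an ANTAR protein binds a tandem
two-hairpin motif in a nascent leader RNA, the terminator hairpin cannot
form and RNA polymerase reads through into the downstream genes. In
one-component regulators such as *Klebsiella oxytoca* NasR, the ANTAR
domain is fused to a nitrate/nitrite-sensing NIT domain, and RNA binding is
observed only when the signal ligand is present. The mechanistic hypothesis
this package's analyses support is **autoinhibition**: in the signal-free
state, residues of the NIT domain pair with RNA-binding residues of the
ANTAR domain across an interdomain interface and sequester them; ligand
binding releases the interface and unmasks the RNA-binding surface.

Five computational stages probe that model, each implemented as a module
with a seeded synthetic-data generator so the whole pipeline is testable at
desk scale:

1. **Conservation** -- which ANTAR residues are universally conserved
   (candidate RNA-binding or core residues), and which positions are
   *differentially* conserved in sensor-fused (NIT-ANTAR) proteins relative
   to the rest of the family (candidate interface residues)?
2. **Structure interface** -- which residue pairs actually face each other
   across the NIT-ANTAR interface in the crystallographic model?
3. **SELEX** -- does in-vitro selection against the protein enrich the
   tandem two-hairpin RNA motif, and what consensus does the selected pool
   show?
4. **Binding** -- what is the equilibrium affinity of protein for RNA,
   how does it change with mutations and ionic conditions?
5. **Attenuation** -- how much transcriptional readthrough does the protein
   cause with and without its signal?

## Conservation scoring

Per-column residue distributions are estimated with an additive
pseudocount, `freq = (count + alpha) / (n_eff + 20 * alpha)`. Gaps never
enter the denominator; they are reported as a per-column `gap_fraction`.
The default `alpha = 0.5` is a Jeffreys-style choice: small enough not to
wash out strong columns in family-scale alignments, large enough to keep
the differential statistic finite. All scores are in bits (log base 2).

Two scores are computed:

* **Relative entropy against a background** (`informationContent`),
  `IC = sum_a p(a) log2(p(a)/q(a))`, the classical sequence-logo height.
  With a uniform background it is bounded by `log2(20) ~ 4.32` bits,
  attained only at a point mass.
* **Group-versus-rest differential KL divergence** (`differentialKL`),
  `D = sum_a p_grp(a) log2(p_grp(a)/p_rest(a))`. This is the differential
  logo statistic: columns where the sensor-fused group prefers different
  residues than the rest of the family. KL divergence is asymmetric; the
  group-to-rest direction is used because the question is "what is special
  about the group", and the identity case is the only guaranteed zero.
  The rest profile must be pseudocounted (`alpha > 0`); the function
  refuses zero-frequency denominators with an instructive error rather
  than returning infinities.

**Letter heights.** The figure convention encoded here makes the *total*
column height equal the divergence; letters are drawn from the positive
per-letter terms only, rescaled to sum to the total. Negative terms
(residues depleted in the group) are tabulated in the score object but not
drawn. This is one of several defensible conventions; it is applied
uniformly to both score types so logos are comparable.

**Conserved-position calling** (`conservedPositions`) uses *raw*
frequencies, not pseudocounted ones, because the rule is stated on
fractions of sequences: `single_residue` at >= 40% identity, otherwise
`chemical_class` when one class exceeds a majority. The classes
(hydrophobic, aromatic, positive, negative, polar -- see
`chemicalClasses`) overlap deliberately; the largest passing sum wins,
ties broken by table order. Columns with more than 50% gaps are masked:
ragged alignment edges otherwise produce spurious calls. Because the
call count depends on the alignment supplied, no fixed "number of
conserved positions" is asserted anywhere; the caller is validated on
constructed columns with known answers instead.

## Interface contact detection

`interdomainContacts` is a purely geometric scan: every residue pair with
one member in each declared domain is reported when the minimum side-chain
heavy-atom distance is within 4.0 A. Classification follows standard
contact-analysis practice: opposite formal charges with a donor/acceptor
pair within 3.5 A is a salt-bridge candidate; any donor/acceptor pair
within 3.5 A is a hydrogen-bond candidate; two aromatic rings with
centroids within 5.5 A stack; everything else is a van der Waals contact.
The cutoffs are exposed as arguments. Deliberate simplifications:

* backbone atoms are excluded (the hypothesis concerns side-chain
  pairing); glycine is represented by CA so it can still register;
* histidine is excluded from salt bridges (protonation unknown);
* there is no energy model, dielectric, or angle term -- candidates are
  meant to be inspected, not trusted blindly;
* author residue numbering is authoritative and never rewritten, so
  published residue identifiers can be used directly in `domainSpec`
  ranges (e.g. ANTAR 328-397 against NIT 1-327 for a deposited NasR
  model).

`annotateContacts` closes the loop with stage 1: through a user-supplied
residue-to-column map it attaches each contact residue's differential KL,
its compositional-bias delta and its conservation call, so interface pairs
that are also group-biased stand out. Unmapped residues keep their row
with NA annotations.

## SELEX simulation and motif analysis

The analyzer is defined from the selected-pool consensus: two consecutive
stem-loops, each with a terminal C:G closing pair (strand-specific, C on
the 5' arm) and a hexanucleotide loop preferring A at position 1 and G at
position 4. `foldTandemHairpins` enumerates *all* stem placements (stem
3-7 bp, Watson-Crick plus G:U wobble, loop fixed at 6 nt by default) and
scores each hairpin `stem_len + 2*[C:G close] + 1*[loop A1] + 1*[loop G4]`;
the best non-overlapping pair within a 10-nt spacer wins. The 2/1/1
weights are package choices, exposed only through the scoring definition
and validated against an independent exhaustive enumeration in the tests.
Thermodynamic folding engines are intentionally not used: the motif is
defined combinatorially, and an energy model would import assumptions the
consensus description does not make.

`simulateSelex` emulates rounds of selection and amplification: retention
probability `eps + (1 - eps) * logistic(beta * (score - s0))` followed by
multinomial resampling back to pool size. The pivot `s0 = 8` sits halfway
to the score of a canonical planted tandem motif (16), so background
sequences (score 0, retention ~ `eps`) and planted binders (retention ~ 1)
separate cleanly at `beta = 2`. Sequencing and RT-PCR errors are not
modelled. The preset pool (1,000 molecules, 30-mers, four rounds, 1%
planted motif) is deliberately small; enrichment dynamics depend on the
retention ratio, not the absolute pool size, and the property suites run
hundreds of simulations.

## Binding-curve fitting

The model is the specific-binding Hill equation
`dA = Bmax * x^n / (Kd^n + x^n)` on the anisotropy change relative to the
zero-titrant reference; the x axis is protein *dimer* concentration in
binding mode or ion concentration in ion-response mode. All replicate
points are fitted with equal weights (the experimental design is four
replicate wells per concentration) by bounded Levenberg-Marquardt
(`minpack.lm::nlsLM`), with `Kd` bounded in `[x_min/100, 100 x_max]`,
`n` in `[0.3, 6]` and `Bmax` in `(0, 3 max dA]`. Initialisation is from
the data: `Bmax` at the maximal mean response, `Kd` log-interpolated at
half of it, `n = 1`.

Two outcomes other than a clean fit are first-class:

* **Refusal.** When the maximal mean response does not exceed three pooled
  replicate standard deviations, the fit is refused -- that is the
  operational definition of "no detectable binding", and it is what
  flat control curves (unrelated RNA, no signal ligand) should produce.
* **Non-convergence.** An optimum on a `Kd` bound is returned but flagged,
  and `classifyVariant` treats it as negligible binding.

`classifyVariant` encodes the three-way mutant rule: negligible
(refused/non-converged), reduced (Kd more than 2-fold above reference),
else comparable-or-better. Hill coefficients are reported but never
compared to a reference value, since the emulated study reports none.

## Readthrough quantification

`readthroughFraction` computes `f = I_RO / (I_RO + I_T)` per lane. The
default is the raw intensity ratio. Because the radiolabel enters through
UTP, band signal scales with each species' uridine content; passing
`normalizeByU = TRUE` divides each intensity by its transcript's U count
first, converting to molar signal. The gel presets use equal U counts for
the two species so that the raw ratio directly estimates the molecular
fraction the presets plant (52% with nitrate, 5% without); the
unequal-label case is exercised separately in the tests, where the raw
ratio is provably biased and the normalized one is not. Background
subtraction and densitometry are upstream of this package.

## Synthetic-data generators and what they do not show

Every generator returns its dataset plus a `truth` list (seed, parameters,
planted structure), and is byte-reproducible given a seed. Presets encode
the emulated study conditions in one auditable table (`listPresets()`,
`presetParams()`): tandem-hairpin affinity 1 uM, single-hairpin 12 uM,
nitrate half-response 0.3 mM, nitrite 0.1 uM, readthrough fractions
0.52/0.05. Amplitudes (`Bmax = 0.12-0.15` anisotropy units), 5%
multiplicative lognormal noise, a 0.002-unit additive well-noise floor,
and the binomial molecule counts are calibration choices made once to
resemble replicate scatter in published anisotropy and gel data.

The generators emulate *statistical* structure, not biology: alignment
columns are independent (no phylogenetic correlation, no indel process
beyond gaps in real inputs), SELEX pools have no sequencing error or
amplification bias, titration noise is homoscedastic on the relative
scale, and toy structures are schematic geometries rather than real
stereochemistry. Passing recovery tests therefore demonstrates that the
estimators are correct and calibrated on data satisfying their own
assumptions -- not that real alignments or gels are free of the
confounders the generators omit.

Problem sizes used by the test and acceptance suites (chosen so the whole
pipeline exercises comfortably on a laptop): alignments of 200 group +
1,000 rest sequences by 30 columns for bias recovery; SELEX pools of 500
molecules over 4 rounds for the enrichment property; 12 concentrations by
4 replicates for titrations; 10,000 molecules per gel lane; 100 seeded
repetitions for each recovery-rate property.

## Numerical and interface choices

* Log base 2 everywhere; divergences are reported in bits.
* Zero-probability terms contribute zero to divergences (`0 log 0 = 0`);
  denominator zeros are errors, not infinities.
* All-gap columns at `alpha = 0` fall back to a uniform distribution
  rather than NaN; they are also masked by the caller.
* Tandem-motif ties are broken deterministically (leftmost first hairpin,
  then leftmost second), so equal-scoring calls are reproducible.
* Alignment columns are 1-based in every report; coordinate residue
  numbers are author numbering.
* The ambiguity code X is masked to gap on input (with a count in the
  warning); other non-standard letters are rejected.
* Generators seed the RNG locally and restore the caller's stream.
* The package's functions are the interface, exercised from R; the
  acceptance script under `scripts/` is the only command-line entry point.

## Known limitations

* Sequence weighting (e.g. phylogenetic down-weighting) is not applied;
  heavily sampled clades inflate both conservation scores, as they do in
  any unweighted logo.
* The differential statistic is one-directional KL; a symmetrised variant
  would rank some columns differently.
* Contact classification has no geometry beyond distances; bifurcated or
  water-mediated hydrogen bonds are invisible.
* The Hill fit assumes trace labeled RNA (no ligand depletion); quadratic
  binding models are out of scope.
* The hairpin scan's fixed loop length (relaxable to 5-7 via `loopLen`)
  and maximum stem of 7 bp bound the motif space it can describe.
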