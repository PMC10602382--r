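---
title: "Methods: detecting, scoring and tracing highly charged protein regions"
author: "ChargedRegions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting, scoring and tracing highly charged protein regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChargedRegions)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter
and why they default as they do, what the synthetic generator does and
does not emulate, and where the numerical edges are.

## 1. What counts as charged

Every charge-based quantity is parameterized by a `ChargeModel`. The
default treats K and R as positive and D and E as negative. Histidine
is excluded on purpose: its imidazole pKa sits near physiological pH,
so its charge state is context-dependent, and including it would blur
the contrast between robustly charged regions and conditionally charged
ones. Users studying acidic compartments can opt back in with
`chargeModel(positive = c("K", "R", "H"))`. The same reasoning excludes
phosphomimetic or pH-shifted charge assignments entirely: conditional
charge is out of scope here.

## 2. Region detection

`detectEnrichedRegions()` slides a 12-residue window with triangular
weights over each protein and scores, per residue, the weighted
fraction of target-set membership.

Parameters, defaults, and rationale:

| parameter | default | meaning |
|---|---|---|
| `windowLen` | 12 residues | averaging span; even length gives a two-position central plateau `(1,2,3,4,5,6,6,5,4,3,2,1)/42` |
| `threshold` | 0.40 | enrichment a position must reach to seed/extend a region |
| `tolerance` | 10 residues | longest below-threshold run absorbed inside a region |
| `minLen` | 30 residues | minimum pre-trim region length (inclusive: "at least 30") |
| `targetSet` | D, E, K, R | the residue set being scored; any set works (the drift scan exploits this) |

Three conventions were genuinely open and are fixed as follows:

- **Per-residue scores with renormalized terminal windows.** Scores are
  centered on residues (even windows cover offsets −5..+6), and windows
  truncated at the termini are renormalized over their in-bounds
  weights. The alternative — scoring only full windows — would leave
  the first and last five or six residues unscored, making a tolerance
  "counted in residues" ill-defined at the ends.
- **Per-run tolerance.** A region terminates at the last above-threshold
  position before a below-threshold run longer than the tolerance;
  shorter dips are absorbed, and the counter effectively resets at each
  above-threshold position. The package tests this contract by
  exhaustive comparison with a brute-force enumeration of all maximal
  qualifying intervals. A consequence worth knowing: a genuine charge
  clump in the background that lies within the tolerance of a region's
  edge is *merged into* the region. On an i.i.d. background with 20%
  charge this merges roughly one region in ten with a neighboring
  clump, which is the main source of boundary disagreement in the
  synthetic recovery benchmark (section 7).
- **Length filter before trimming.** Trimming uncharged termini can
  drop a region below `minLen`; such regions are kept and flagged
  (`belowMinLen`), with `strict = TRUE` available to drop them, because
  the filter is defined on the detector's output, not the trimmed one.

Coordinates are 1-based and closed throughout the package (the
IRanges/GRanges convention); only the BED-like export
(`writeRegionsBed()`) translates to 0-based half-open.

## 3. Charge patterning (kappa)

κ asks how *segregated* the positive and negative charges are, given
the composition. For blob sizes 5 and 6, each overlapping blob gets an
asymmetry σ = (f₊ − f₋)²/(f₊ + f₋); δ is the mean squared deviation of
blob σ from the whole-sequence σ; and κ averages δ/δmax over the two
blob sizes, where δmax belongs to the maximally segregated
rearrangement of the identical composition.

δmax is computed deterministically: the positive residues form one
block, the negatives another, and the neutral residues are split into
three blocks (before, between, after), with δ maximized over all
integer splits. δ is invariant under sequence reversal and under a
global charge flip, so the positive-first orientation covers all
arrangements of this family. The construction reproduces the nine
packaged worked-example κ values to within ±0.002, which is how the
package validates it.

Definedness follows the mathematics rather than a blanket rule: κ is
reported whenever δmax > 0 for both blob sizes. That includes
*single-species* charged sequences with neutral residues — σ degrades
gracefully to the charged fraction — which is required because strongly
acidic regions with no basic residues at all (the COP1 example) are
real and carry a meaningful patterning value. κ is `NA` (with a stated
reason) for sequences with no charges, charged homopolymers (δmax = 0),
and sequences shorter than the largest blob.

One mathematical footnote: a strictly alternating (EK)n sequence does
*not* have κ exactly 0. Blobs of odd size over an even-period repeat
are always one residue out of balance, so δ₅ > 0 while δ₆ = 0; the
resulting κ is ~0.0009. The package reports the true value rather than
rounding it away.

## 4. Hydropathy, complexity, and the charge/hydropathy heuristic

Hydropathy is per-residue Kyte–Doolittle, linearly mapped so the scale
minimum (R) is 0 and the maximum (I) is 1, with no smoothing window —
regions are short enough that windowing would only blur their already
extreme means.

Complexity is the compositional Shannon entropy K₂ = −Σᵢ (nᵢ/L)
log(nᵢ/L) divided by the entropy of a reference "language". Two
references are packaged: the proteome's own composition, and a
charged-enriched hypothetical proteome (D, E, K, R at 0.125 each, the
remaining 0.5 spread evenly) whose entropy is exactly 4 bits. The
second corrects for selection bias: regions found *because* they are
charge-enriched are trivially low-complexity against the proteome, so
the interesting question is whether they are low-complexity even
against a reference that expects them to be half charged. The ratio is
base-invariant; natural logs are used internally. Ratios above 1 are
possible against non-maximum-entropy references and are reported
unclamped.

The charge/hydropathy rule (`uverskyClassify()`) places |NCPR| against
normalized hydropathy relative to the line R = 2.785·H − 1.151. The
coefficients are configuration, not code: they come from the cited
boundary and can be replaced. Boundary points are assigned to *folded*
(documented tie rule). The signed NCPR is reported in metrics tables;
only this classifier takes the absolute value.

The codon-product null (`expectedAAFreqs()`) pools nucleotide
frequencies over all ORFs, multiplies them per codon, and sums per
amino acid; stop codons are excluded and the sense-renormalized vector
(summing to 1) is the default for comparison against observed usage,
with the raw vector also returned.

## 5. Structural annotation

Structure is consumed, never computed. Tracks merge a 3-class secondary
structure call (8-class DSSP codes collapse as H/G/I → helix, E/B →
sheet, rest → coil) with a per-residue confidence having pLDDT
semantics, read either directly or from the B-factor column of
AlphaFold-style PDB files (atoms within a residue should agree; if not,
the package warns and averages).

Residue classification is confidence-gated: helix/sheet require their
call *and* confidence ≥ 70 (the upstream predictor's own
"confident" boundary); disordered is confident coil *or* any residue
below 50; everything else is "other". Two boundary conventions were
open and are fixed as: confidence exactly 70 counts as confident (≥),
and exactly 50 as not-low. Coil in the ambiguous [50, 70) band is
"other" rather than dropped — dropping would silently change region
denominators; both choices are configurable via `structureConfig()`.
Region labels use a strict >60% dominance rule (exactly 60% is
"intermediate").

## 6. The composition classifier

Training regions are maximal single-class runs of helix or disordered
residues strictly longer than 25. Features are the 20 composition
fractions — not counts, and deliberately unstandardized, so that
coefficients are directly comparable across amino acids and can be read
as per-residue log-odds shifts. The fit is ridge-regularized logistic
regression (glmnet, α = 0) with a fixed, mild λ = 10⁻³: enough to keep
the solver stable on near-separable corpora, small enough not to
materially shrink coefficients; the value is recorded in the model
metadata. The split is region-level, stratified by label, and seeded;
fitting is deterministic given data and seed. Helical is the positive
class.

"Using only the top five coefficients" is ambiguous between truncating
the coefficient vector and refitting on the top-five features; the
package refits by default (dropping features shifts the optimal weights
of those kept) and offers truncation for comparison. The k = 1 variant
falls back to an unregularized `glm`, which may emit a
perfect-separation warning on cleanly separable data.

## 7. The synthetic generator, and what passing tests do not show

The generator exists so that detection, classification and conservation
can be tested against known truth with no downloads. Its defaults *are*
the benchmark conditions: uniform background composition (charged
residues jointly 0.20), implanted regions of length 60 at FCR 0.55,
structure tracks with helical truth at confidence 85–95 and disordered
truth at 20–45 against a mixed background, and star-phylogeny families.

Design choices that matter:

- **Sustained enrichment in implants.** Charged positions inside an
  implanted segment are placed by systematic sampling (even spacing,
  random phase), not an i.i.d. shuffle. A region whose *defining
  property* is enrichment should be enriched throughout; an i.i.d.
  arrangement at FCR 0.55 frequently contains local dips longer than
  the detector's tolerance, so recovery failures would measure the
  arrangement, not the detector. κ-targeted implants are subsequently
  rearranged by a seeded swap search (composition fixed, so δmax is
  computed once), reporting the achieved κ and erroring on infeasible
  targets instead of clamping.
- **Ground-truth alignments.** Families are evolved with per-site
  substitution and indel probabilities, and the alignment comes from
  the generator's own bookkeeping, never realignment. Insertions by
  different species at the same junction get separate columns: on a
  star phylogeny they are independent events, not homologous, and
  stacking them would fabricate column-level divergence.
- **Composition-preserving evolution.** Inside designated regions,
  substitutions resample within the target set (or within its
  complement), so enrichment is exactly invariant while sequence
  identity decays — the "conserved composition, divergent sequence"
  regime the drift scan is meant to detect.

What the generator does **not** emulate: real amino-acid backgrounds
(no di-residue correlation, no compositional heterogeneity across
proteins), rate heterogeneity or phylogenetic tree structure, length
variation of the implanted regions, or structure-prediction error
modes. Passing the synthetic benchmarks therefore shows the pipeline's
*internal* correctness — that each stage recovers what the generator
planted — not that the published full-proteome counts would be
reproduced; those require the external reference proteome, predicted
structures and ortholog alignments, which are out of scope.

A quantitative caveat from the recovery benchmark: with an i.i.d.
20%-charged background, about one implant in ten is merged by the
tolerance automaton with a genuine neighboring charge clump, dropping
its boundary Jaccard below 0.8. The measured recovery rate at the
default conditions is ~0.90–0.93. This is a property of the stated
background and the per-run tolerance contract jointly, not a detector
bug: the same automaton is verified interval-identical to a brute-force
oracle on a thousand random tracks.

## 8. Evolutionary statistics

Alignment trimming removes exactly one longest and one shortest row (by
ungapped length, first-occurrence tie-break, always two distinct rows)
and then drops all-gap columns. Gap frequency is the global "-"
fraction. Divergence is mean column entropy with gaps *excluded* from
the column distributions by default — an indel is one event already
measured by gap frequency, and counting its whole span again as column
"diversity" would double-book it — with `includeGaps = TRUE` available
to treat the gap as a 21st symbol. Entropies are in nats.

Regions map into alignments as the contiguous column span bounded by
the columns of their first and last reference residues, so insertions
in other species inside the region are counted in those species'
enrichment. Per-species enrichment normalizes by the species' *non-gap*
residue count in the span (a half-gapped species is scored on what it
actually has), and a species must hold at least 30 non-gap residues
there to count as retaining the region.

The drift score for a residue set is the mean over its detected regions
of the alignment-mean enrichment, scaled between the set's proteome
frequency (0) and the central enrichment of the detected hits
themselves (1). The center statistic is the **median** by default: the
two natural candidates (mean and median of the hit enrichments)
disagree only through a handful of extreme hits, and the median keeps
the 1-anchor stable across candidate sets with few regions; the mean is
available via `centerStat = "mean"`. Candidate sets are the C(16, 4)
four-residue combinations of non-charged amino acids filtered to a
combined frequency within ±0.01 of the charged set's (0.233 by
default — the yeast value, configurable in `driftConfig()`), scanned
with the relaxed detector (threshold 0.35, tolerance 15, minimum 30)
that matches charged-set hit statistics.

## 9. Numerical edges and degenerate inputs

- Empty sequences, non-ACGT ORF characters, and unknown DSSP codes are
  errors; non-standard residues (X, U, B) are rejected by default or
  dropped (from counts *and* length) under `invalid = "ignore"`.
- δmax enumeration is O(n²) in the neutral-residue count per blob size;
  regions are short (tens to low hundreds of residues), so this stays
  in milliseconds.
- `driftScore()` refuses a degenerate scale (center equal to the
  proteome average) rather than returning an infinity.
- The swap search for κ targets is seeded, capped (4000 iterations,
  3 restarts), and warns if it ends outside ±0.05 of the target,
  reporting the achieved value either way.
- Problem sizes in the test suite (1000 oracle tracks of length 60, 200
  recovery proteins of length 400, 4000 classifier regions, a 12-set
  drift scenario with 8 families each) were chosen as the smallest
  sizes at which the binomial noise on each benchmark statistic is well
  inside its decision margin.

## 10. Known limitations

- κ's δmax uses the three-block family; it reduces to the classic
  diblock for neutral-free compositions and matched all worked
  examples, but exotic compositions could in principle admit a higher-δ
  arrangement outside the family, which would bias κ slightly upward.
- The Uversky line coefficients, the hydropathy normalization, and the
  DSSP collapse are conventions taken from the cited sources and kept
  in configuration; other conventions exist in the literature.
- The classifier is trained on biological sequences; nothing about its
  coefficients transfers to arbitrary points of composition space.
- Detection boundary precision is limited by window bleed (±3–6
  residues) and clump-merging (section 7); downstream per-region
  statistics inherit that blur.
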