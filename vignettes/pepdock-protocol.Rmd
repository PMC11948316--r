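---
title: "The pepdock docking protocol: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pepdock docking protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdock)
```

## The protocol

Single-chain structure predictors accept one amino-acid sequence and emit
one chain of coordinates with a per-residue confidence (pLDDT, 0–100).
`pepdock` turns such a predictor into a protein–peptide docking engine in
five stages:

1. **Fusion.** Receptor and peptide are concatenated with a flexible
   polyglycine linker so the predictor sees a single chain. The linker is
   pure scaffold: long and glycine-flexible enough not to constrain the
   peptide's placement, and excised after prediction. A segment map (0-based
   half-open intervals) travels with the fused sequence — in code and in the
   FASTA description line — so the fusion is always invertible.
2. **Sampling by masking.** Deterministic predictors return near-identical
   models across seeds, so diversity must be injected at the input: each of
   `n_variants` copies replaces a fixed fraction of residues with a mask
   token before prediction.
3. **Prediction**, optionally with adaptive recycling (below).
4. **Post-processing.** The linker residues are discarded; receptor residues
   become chain A and peptide residues chain B, each renumbered from 1.
   pLDDT is carried per residue and written to the PDB B-factor column.
5. **Ranking, filtering, evaluation.** Candidates are ranked by a
   pLDDT-based scheme; models whose peptide sits more than 8 Å (minimum
   heavy-atom distance) from the receptor are discarded as misdocked; when a
   native complex is available, every model is scored with DockQ.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| linker length | 30 | residues | long enough to reach any face of a typical receptor; longer (100, 200) or N-terminal linkers are supported for protocol comparisons but did not prove superior |
| linker placement | peptide at C-terminus | — | receptor first keeps receptor numbering stable |
| mask rate | 0.25 | fraction of eligible residues | strong enough to perturb the fold without destroying it |
| variants per target | 8 | count | the pool size the ranking schemes are designed for |
| mask eligibility | receptor + peptide | — | the linker is scaffold; masking it cannot diversify the interface |
| recycles | 3 (base) → 12 (max), step 3 | count | adaptive schedule; see below |
| misdock cutoff | 8 | Å | minimum heavy-atom distance above which a peptide is considered not in contact |
| contact/interface cutoff (scoring) | 5 | Å | residues relevant to interface confidence |
| FNAT contact cutoff | 5 | Å | community-standard native-contact definition |
| iRMSD interface cutoff | 10 | Å | community-standard interface definition |
| high-confidence threshold | pLDDT > 70 (strict) | — | conventional cutoff for trusting a predicted structure |

The 5 Å and 8 Å cutoffs play different roles deliberately: 5 Å defines
which residues *score* (interface confidence), 8 Å defines which models
*survive* (misdock filter).

### Adaptive recycling

The predictor is first run at 3 recycles. If the peptide ends more than
8 Å from the receptor, the prediction is rerun with 3 more recycles, up to
12. Whether a real predictor should rerun from scratch or continue its
internal recycling state is an implementation detail of the backend; the
package's contract is rerun-with-incremented-recycles, which bounds the
work at `1 + (maximum − base)/step` backend calls (4 under the defaults)
and is what the mock backend implements.

### Ranking schemes

With `p` the vector of peptide per-residue pLDDT and `C` the set of peptide
residues within 5 Å of the receptor:

- `mean_peptide` = mean(p)
- `interface_only` = mean(p[C]), defined as 0 when `C` is empty
- `contact_weighted` = sum(p[C]) / length(p) = interface mean × contact
  fraction (the default)

All three default to *maximize*. A minimize direction is exposed because
selecting the *lowest* mean peptide pLDDT has been reported as a workable
heuristic for masked pools; we regard that as counterintuitive and possibly
an artifact, so it is an option, not a default. Defining the interface-only
score as 0 with no contacts (rather than NA) makes misdocked models sort
last under maximization, consistent with the weighted scheme's intent.

Ties are broken by higher `mean_peptide`, then by lower variant index; the
selected model is always exactly one and attains the extremal score.

## The synthetic backend and fixtures

The mock backend and the fixture generator share one geometric vocabulary:
the receptor is an ideal α-helix (rise 1.5 Å/residue, twist 100°/residue,
backbone N/CA/C/O plus CB), the peptide an extended segment placed at a
controllable minimum heavy-atom distance from the receptor midsection, the
linker a connecting path. Placement uses a fixed-point iteration that
converges to the requested distance within 0.02 Å.

What this emulates well: every *bookkeeping and geometry* property of the
protocol — span arithmetic, excision, renumbering, distances, contacts,
superpositions, ranking, filtering, DockQ — at exactly controlled ground
truth (decoys record their true transform and true distance in provenance).
pLDDT can be made uniform, correlated with docking correctness
(docked peptides draw 75–95, misdocked 20–50), or anticorrelated, so
ranking schemes can be both validated and stress-tested.

What it does not emulate: real folds, side-chain chemistry, energetics, or
the error modes of a trained network (partial interfaces, hallucinated
helices, confidence miscalibration at domain boundaries). A passing test
suite therefore certifies the protocol around the predictor, not the
predictor itself.

Masked positions keep their geometry in the mock (the mask is an input
token, not a deletion) and have their pLDDT damped by 0.8, mimicking
reduced information content. After prediction the pipeline restores the
original residues, since the emitted model corresponds to the real
molecule — this also guarantees model/native residue identity downstream.

## Numerical and boundary conventions

- **Rounding** is half-up everywhere a count or printed rate is derived
  from a fraction (`round_half_up()`): mask counts, integer-percent
  effective success rates, one-decimal overall rates. Banker's rounding
  would silently disagree with hand arithmetic on exact halves.
- **Mask count** is the fixed number `round(rate × n_eligible)` sampled
  without replacement, not per-position Bernoulli draws: variant size is
  then reproducible and exactly testable. Per-variant seeds are
  `seed + variant index`.
- **Cutoffs are inclusive** (≤) on the "in contact" side: a peptide at
  exactly 8 Å is docked, since "more than 8 Å" defines the discarded side
  strictly.
- **DockQ bins are left-closed**: acceptable is [0.23, 0.5), medium
  [0.5, 0.8), high [0.8, 1].
- **"Receptor surface"** is operationalized as minimum heavy-atom
  interatomic distance — no molecular-surface computation. Which atom
  subset a contact decision should use is genuinely ambiguous; heavy atoms
  are the default and a backbone-only policy is exposed.
- **Superposition** is Kabsch via SVD with the reflection corrected to a
  proper rotation; fewer than 3 points or collinear sets raise a
  degeneracy error rather than returning an arbitrary axis. The test suite
  checks it against an independent quaternion (Horn) implementation to
  1e-6 Å.
- **Missing backbone atoms**: a residue missing any of N/CA/C/O is dropped
  from RMSD atom sets with a warning; evaluation fails if more than 10% of
  residues are dropped. Hydrogens are excluded from heavy-atom policies;
  alternate locations keep the first conformer; HETATM records are skipped.
- **Correspondence** between model and native is by chain id + residue
  number, which the post-processing renumbering guarantees; mismatched
  residue identities are an error, not a warning.
- **Effective success rate with zero viable models** is undefined (NA), not
  0% — an empty denominator is not a failure rate.

## Benchmark bookkeeping

`summarize_benchmark()` counts quality bins among viable (docked) targets;
the effective success rate divides acceptable-or-better by viable targets,
the overall rate divides by all targets. Undocked targets therefore count
against the overall rate but not the effective rate — one bookkeeping that
reproduces both styles of headline number from the same table.
`compare_methods()` joins two result sets on target id and counts, in both
directions, targets where one method is acceptable-or-better and the other
incorrect ("rescues").

## Problem sizes used in the tests

The suite exercises toys of up to 50 residues for oracle-equivalence
checks (exhaustive all-pairs scans, brute-force contact enumeration,
quaternion superposition), 30+8-residue complexes for 50-pool ranking
statistics, and a full 240+12 = 252-residue run — the median complex size
the protocol targets — for the end-to-end check. These sizes keep the whole
suite under a minute of CPU while covering every code path; all quantities
scale linearly or quadratically in atom count, so nothing qualitative
changes at larger sizes.

## Known limitations

- Single peptide per receptor; no mixed-composition linkers; no nucleotide
  input.
- DockQ here is the two-chain formula; multi-interface generalizations,
  fnonnat/clash analysis and NMR-ensemble references are out of scope.
- Numerical parity with any specific external DockQ executable is not
  claimed — the formula and its standard constants (1.5 Å, 8.5 Å scales,
  5 Å contacts, 10 Å interface, N/CA/C/O backbone) are.
- The adapter for real predictors is a documented contract
  (sequence in, PDB + B-factor confidence out, deterministic per seed),
  not a shipped integration.
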