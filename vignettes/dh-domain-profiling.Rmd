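---
title: "Profiling variable substrate-binding regions in PKS dehydratase domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling variable substrate-binding regions in PKS dehydratase domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhprof)
```

## The analysis

Dehydratase (DH) domains of modular type I polyketide synthases eliminate
water from a C-3 hydroxyacyl intermediate delivered on the acyl carrier
protein's phosphopantetheine (PPant) arm.  Their catalytic core — a His/Asp
dyad inside a double-hotdog fold, with the His anchored by the HxxxGxxxxP
motif and a conserved Arg near the PPant entrance — is nearly invariant
across pathways.  What differs between pathways is the acyl moiety past the
C-3 position, and the working hypothesis this package operationalizes is
that substrate selection is carried by a small number of *variable, flexible
loops* lining the acyl-binding cavity.  Three independent observables
triangulate those loops:

1. **Sequence variability.**  Per-column Shannon entropy
   $H_j = -\sum_{i=1}^{20} p_{ij} \log_2 p_{ij}$ over a deep DH alignment,
   after discarding sparsely occupied columns (occupancy $\ge$ 10%,
   inclusive).  Conserved catalytic/structural positions sit near 0 bits;
   unconstrained positions approach $\log_2 20 \approx 4.32$ bits.
2. **Crystallographic flexibility.**  Per-residue mean B-factor, z-scored
   within the chain, plus residues entirely absent from the model
   (REMARK 465 or author-numbering gaps) — missing density being the
   strongest disorder signal.
3. **Structural deviation.**  Sequence-guided iterative Kabsch Cα
   superposition between domains, with per-cycle batch rejection of pairs
   deviating beyond a cutoff, reproducing the "RMSD of $x$ Å within $N$
   residues" protocol used in comparative structure papers.

A residue is called part of a *variable substrate-binding region* when its
mapped column entropy is high **and** it is either flexible or unmodeled;
flagged residues are merged into segments.  On DH domains this yields the
characteristic two-loop answer (the loops between α3–β11 and β7–α2), with
one loop typically evidenced by missing density and the other by elevated
B-factors.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_occupancy` | 0.10 (inclusive) | fraction | standard refinement before column-wise conservation scoring |
| `entropy_base` | 2 | — | entropies reported in bits; `base = exp(1)` available for cross-checking nat-based toolchains |
| `cutoff` | 2.0 | Å | per-cycle Cα rejection threshold of the iterative superposition |
| `max_cycles` | 5 | — | rejection cycles; convergence is usually earlier |
| `atom_selection` | CA | — | Cα B-factors; `backbone`/`all` available |
| `z_threshold` | 1.0 | σ | B-factor z-score calling a residue flexible |
| `h_percentile` | 0.75 | — | entropy percentile for the high-entropy gate |
| `h_floor` | 1.0 | bits | absolute lower bound of the high-entropy gate (below) |
| `min_length` | 3 | residues | shortest reportable segment |
| `merge_gap` | 1 | residues | numbering gap bridged when merging flagged residues |
| `max_dyad_distance` | 4.0 | Å | dyad acceptance; observed dyads average under 3.8 Å, the looser cutoff avoids false negatives while the measured value is always reported |
| `matrix`, `gap_open`, `gap_extend` | BLOSUM62, 10, 0.5 | — | alignment defaults; a length-L gap costs `gap_open + L*gap_extend` |

Percent identity depends more on the *denominator convention* than on gap
penalties; `percent_identity()` exposes `aligned_pairs` (default,
gap-excluded), `shorter_seq` and `alignment_length` so published figures
computed under unstated conventions can be chased.

### Why an absolute entropy floor

The high-entropy gate is primarily a percentile of the domain's own entropy
track (`h_percentile`).  On a uniformly conserved domain, however, the track
is nearly constant and *any* percentile flags a quarter of the chain for
free; `h_floor` (1 bit) prevents that degenerate case.  One bit corresponds
to a 50/50 two-state column — positions below it are conserved by any
reasonable reading, positions carrying real loop variability sit several
bits higher.

### Numerical conventions

* B-factor z-scores use the population (1/n) standard deviation, so the
  "z-scores have mean 0, sd 1" invariant is exact; normalization is per
  chain, not per structure, because absolute B scales differ between
  crystal forms.
* Alternate locations collapse to the highest-occupancy copy; ties go to
  the alphabetically first altloc tag.
* Kabsch fits correct reflections (determinant forced to +1) and flag
  collinear/coincident inputs as `degenerate` rather than erroring;
  outlier rejection is per-cycle batch (all pairs beyond the cutoff at
  once) for determinism.
* Ambiguous letters (B, J, Z, X, U, O) count toward column occupancy but
  are excluded from entropy frequencies — they are residues, but have no
  unambiguous frequency bin.
* Where the aligner can place a deletion at several score-equivalent
  positions (identical boundary letters), `map_to_reference()` re-anchors
  the mapping to agree with the chain's author numbering whenever the
  reassigned letters still match and the map stays injective.  Without
  this, the residue just downstream of an unmodeled loop occasionally
  inherits the wrong column.
* Residues missing from the model inherit the entropy of their
  interpolated column only when the flanking mapped columns bracket the
  gap with an offset equal to the residue-number offset (exact when the
  reference alignment row is gapless across the stretch); otherwise they
  carry `NA` entropy and cannot contribute high-entropy evidence.
* Canonical loop names (e.g. "α3–β11") are user configuration — a
  residue-range-to-label map — not inferred; secondary structure, when
  reported, comes from HELIX/SHEET records with a backbone-dihedral
  fallback (helix: φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°], runs ≥ 4; strand:
  φ ∈ [−180°, −40°], ψ ∈ [90°, 180°] ∪ [−180°, −170°], runs ≥ 3).

## What the synthetic generators emulate

Every input class has a deterministic generator, so the full pipeline is
testable with no downloads:

* `synth_structure()` — an idealized Cα trace (3.8 Å virtual bonds along a
  persistent random walk) with His/Asp side-chain stub atoms, a planted
  B-factor profile (background mean 20 Å², sd 2 Å²), planted unmodeled
  segments, and optionally exact active-site geometry (dyad at 2.8 Å,
  Arg–His Cα at 17.8 Å, a two-atom PPant-like ligand spanning 16.4 Å —
  the distances characteristic of DH active sites).
* `synth_structure_pair()` — a rigidly transformed copy with Gaussian
  coordinate noise and planted 6 Å displacements.  `noise` is the RMS 3-D
  displacement per atom (per-coordinate sd `noise/sqrt(3)`), so a 0.3 Å
  pair superposes at ≈ 0.3 Å core RMSD.
* `synth_msa()` — column-independent sampling: conserved columns carry a
  5% substitution rate by default in bundles (≈ 0.5 bits at depth 330),
  variable columns draw a composition once from a symmetric Dirichlet
  (α = 20: near-uniform, ≈ 4.2 bits).  Expected per-column entropies are
  stored as ground truth via direct simulation (10⁵ draws), so tests never
  share code with the entropy implementation.
* `synth_domain_bundle()` — couples the two: an MSA whose ungapped
  reference row *is* the structure's chain sequence, with regions planted
  simultaneously high-entropy and flexible/unmodeled.  Defaults emulate the
  study conditions: a 220-residue domain against a 330-sequence alignment,
  one 11-residue unmodeled high-entropy loop and one 8-residue
  high-B high-entropy loop.

The fixtures are statistical, not physical: no stereochemistry, no packing,
side chains are stubs, and MSA columns are independent.  Passing tests
therefore demonstrate that the *measurements and calling logic* are correct
under known truth — not that real crystal structures obey the model.  In
particular, real B-factors absorb TLS/refinement artifacts the generator
does not emulate, real alignments have correlated columns and phylogenetic
redundancy (no sequence weighting is applied), and selenomethionine
recorded as HETATM within a polymer chain is not folded back into the
one-letter sequence.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
100 random Kabsch instances (N ∈ [3, 200]) against an independent
quaternion-method oracle; 20 superposition pairs of 200 residues at
σ = 0.3 Å with 10% residues displaced 6 Å; 100 coupled bundles of
120 sequences × 120 residues for residue-level precision/recall of the
region caller; 50 random structures for brute-force dyad enumeration; and
one paper-scale bundle (330 × 220) for the two-loop emulation.  These sizes
give tight Monte-Carlo bands while keeping a full run in the low minutes on
one core.

## Known limitations

* mmCIF unobserved-residue metadata is not parsed; missing residues in
  mmCIF inputs are inferred from author-numbering gaps only.
* No sequence weighting or background-corrected relative entropy; the
  entropy is the plain plug-in estimator.
* No TLS/ANISOU handling — isotropic B only.
* Sequence-independent structural alignment (DALI/TM-align class) and
  docking are out of scope; superposition is always sequence-guided.
* Numbering-gap inference assumes monotone author numbering; non-monotone
  chains fall back to declared missing residues with a warning.
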