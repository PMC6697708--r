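# dhprof

Comparative sequence–structure profiling of **dehydratase (DH) domains**
from modular type I polyketide synthases (PKSs), for structural biologists
and PKS engineers asking: *which parts of a DH domain pick the substrate?*

DH domains eliminate water from a C-3 hydroxyacyl intermediate tethered to
the acyl carrier protein's phosphopantetheine (PPant) arm.  Their catalytic
machinery — the His/Asp dyad in the double-hotdog fold, the His anchored by
the HxxxGxxxxP motif, a conserved Arg at the PPant entrance — is invariant.
Substrate selection past the C-3 position instead maps to a small number of
variable, flexible loops lining the acyl-binding cavity.  `dhprof`
quantifies that contrast with three tracks and an integrative caller:

* **Conservation** — per-column Shannon entropy over a DH alignment,
  `H_j = -Σ_i p_ij log2 p_ij` (bits), after occupancy refinement
  (columns with ≥ 10% non-gap characters retained), mapped onto a
  reference chain.
* **Flexibility** — per-residue mean B-factor z-scored within the chain,
  plus unmodeled residues (REMARK 465 / numbering gaps) as the strongest
  disorder evidence.
* **Structural deviation** — sequence-guided iterative Kabsch Cα
  superposition with per-cycle outlier rejection, reporting RMSD over the
  retained residue pairs, and global Needleman–Wunsch percent identity
  under explicit denominator conventions.
* **Active-site geometry** — motif scanning (HxxxGxxxxP, GYxYGPxF, LPFxW,
  HPLL, LxLxR), dyad N–O distance, Arg–His Cα distance, and ligand atom
  spans.
* **Region calling** — residues that are simultaneously high-entropy and
  flexible/unmodeled, merged into segments: the variable substrate-binding
  loops (canonically α3–β11 and β7–α2 in DH domains).

Deterministic synthetic generators (`synth_structure()`, `synth_msa()`,
`synth_domain_bundle()`) produce every input class with known ground truth,
so the whole pipeline is testable offline.

## Worked example

Profile a synthetic DH-like bundle (220-residue domain, 330-sequence
alignment, two planted variable loops) end to end:

```r
library(dhprof)

b <- synth_domain_bundle(seed = 42)
prof <- profile_domain(b$structure, "A", b$msa, "reference",
  config = dh_config(region_labels = tibble::tibble(
    start = b$truth$regions$start, end = b$truth$regions$end,
    label = c("beta7-alpha2", "alpha3-beta11"))))

tidy(prof)
#> # A tibble: 2 × 8
#>   chain start   end length label         evidence                  mean_H mean_z
#>   <chr> <int> <int>  <int> <chr>         <chr>                      <dbl>  <dbl>
#> 1 A        70    77      8 beta7-alpha2  high_entropy,high_bfactor   4.24   4.95
#> 2 A       121   131     11 alpha3-beta11 high_entropy,unmodeled      4.25  NA

prof$active_site
#> <dh_activesite> chain A: His33 / Asp116 dyad 2.80 A
#>   conserved Arg219, Arg-His Ca 17.80 A
```

Two regions are called, exactly the planted loops: one evidenced by high
entropy plus elevated B-factors (mean z ≈ 5), one by high entropy plus an
11-residue stretch of missing density (no B-factors to average, hence
`mean_z = NA`).  Mean entropies ≈ 4.2 bits sit near the 4.32-bit maximum —
essentially unconstrained positions — against a conserved background of
≈ 0.5 bits.  The active-site report recovers the planted geometry: dyad
N–O distance 2.80 Å, Arg–His Cα distance 17.80 Å.

The same stages are exposed individually (`bfactor_profile()`,
`entropy_profile()`, `map_to_reference()`, `iterative_superpose()`,
`global_align()`, `find_catalytic_dyad()`, …), return tibbles or objects
with `tidy()`/`glance()`/`autoplot()` methods, and are scriptable from the
shell via `inst/scripts/dhprof.R`
(subcommands `identity`, `superpose`, `flex`, `entropy`, `activesite`,
`profile`, `synth`).

Real coordinate files work the same way: `read_structure("x.pdb")` (or
mmCIF) then any of the stages; `read_msa()` accepts gapped FASTA, Clustal
and Stockholm alignments.

## Method notes

See the methods vignette (`vignettes/dh-domain-profiling.Rmd`) for the
model, parameter defaults and units, the generators' scope and
limitations, and the numerical conventions (population-sd z-scores,
inclusive occupancy boundary, gap-placement canonicalization in the
column-to-residue map, degenerate-input handling).
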