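---
title: "PARCH hydropathy profiling of post-translational modifications: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PARCH hydropathy profiling of post-translational modifications: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parchr)
```

## The model

PARCH (Protocol for Assigning a Residue's Character on a Hydropathy scale)
measures per-residue hydropathy operationally rather than from a static
lookup table. A protein is embedded in a thin explicit water shell, heated
linearly from 300 K to 800 K under NVT conditions while the protein's heavy
atoms are position-restrained, and the waters in contact with each residue
are counted frame by frame as they "evaporate" off the surface. A residue
that retains its shell water through the ramp is hydrophilic; one that
sheds it early is hydrophobic. Each residue receives a PARCH value (PV)
between 0 (hydrophobic) and 10 (hydrophilic).

For a post-translational modification (PTM) — phosphorylation (Ser/Thr/Tyr
plus a doubly charged phosphate), N-lysine acetylation (charge
neutralizing), or monomethylation of Lys/Arg (charge preserving) — the
protocol is run on the unmodified and modified variants of the same
protein, residues are paired by sequence alignment, and the hydropathy
change is read off as ΔPV = PV(mod) − PV(unmod) at the modification site
and across its 3 Å neighborhood.

This package implements everything around the molecular dynamics engine:
system construction (shell carving, counter-ion placement, restraint and
annealing templates), trajectory-to-PV scoring, the ΔPV comparison
machinery with significance classification and a paired exact Wilcoxon
signed-rank test, and a synthetic trajectory generator with analytic
ground truth. It deliberately does *not* integrate equations of motion,
assign force-field types, or solvate structures: those stages belong to an
external MD engine, for which the package emits documented input templates
and whose trajectories it consumes (multi-model PDB or DCD; there is no
XTC reader in this toolchain).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `d_shell` | 0.415 | nm | water kept if its oxygen is within this of a protein heavy atom (inclusive) |
| `restraint_k` | 1e4 | kJ mol⁻¹ nm⁻² | position restraint on protein heavy atoms and ions |
| `d_ion` | 3.0 | nm | minimum counter-ion to protein distance |
| `d_b` | 3.0 | nm | ion–box boundary margin |
| `min_tol` | 1e3 | kJ mol⁻¹ nm⁻¹ | energy-minimization force tolerance (template only) |
| ramp | 300→800 | K | NVT heating, 1 K per 10 ps ⇒ 5000 ps |
| `d_water` | 0.315 | nm | water–residue contact cutoff (inclusive) |
| `w_init`, `w_final` | 0.05 | fraction | scoring windows at the two ends of the ramp |
| `neighbor_cutoff` | 0.3 | nm | heavy-atom minimum distance defining a site's neighborhood |
| `delta_threshold` | 0.2 | PV | \|ΔPV\| must exceed this to count as increase/decrease |
| `alpha` | 0.05 | — | significance level of the Wilcoxon verdict |

All of these are surfaced through `shell_params()`, `annealing_schedule()`,
`contact_params()`, `compare_params()` and the single `parch_config()`
document; every run manifest echoes the thresholds actually applied.

## Scoring: the retention ratio

The published PARCH normalization is defined in the scale's original
literature and is not part of this package's protocol description; what
is fixed here is that contacts are counted at 0.315 nm "to quantify and
scale" the values and that PV runs from 0 to 10. We therefore implement
scoring behind a pluggable strategy interface and document the default:

$$\mathrm{PV} = 10 \cdot \mathrm{clamp}\!\left(
  \frac{\langle n \rangle_{\text{final } 5\%}}
       {\langle n \rangle_{\text{initial } 5\%}},\, 0,\, 1\right)$$

where \(n\) is the per-frame count of distinct waters whose oxygen lies
within 0.315 nm of any heavy atom of the residue. A residue whose initial
window holds no water at all scores 0 and is flagged `buried` rather than
treated as fully evaporated. An alternative evaporation-temperature scorer
(`escape_temperature_scorer()`) scores by where along the ramp the count
first halves; it can be swapped in without touching any contact code. The
5 %/5 % windows are a package default (no published value exists); they
average enough frames to suppress single-frame noise while staying clear
of the opposite end of the ramp.

Contact convention: the probe is the water **oxygen** and the target is the
residue's **heavy atoms**, boundaries inclusive. Oxygen is the
conventional single locus of a water molecule; including hydrogens would
double-count orientational noise without changing which waters are
present. Modified residues are scored over *all* their atoms, including
the added phosphate/acetyl/methyl group.

Replicates: annealing is stochastic, so the protocol runs quintuplicates;
`aggregate_replicates()` reports the per-residue mean and sample standard
deviation and the replicate count.

## System construction choices

Several aspects of the published setup are ambiguous at the level of
detail an implementation needs; the package resolves them as follows.

* **What is restrained.** The restraint sentence could refer to the
  protein, the shell, or both. We restrain protein heavy atoms (and, as
  explicitly stated, the counter-ions). Shell waters are *never*
  restrained: evaporation is the observable, so the water must be mobile.
* **Shell carving, not solvation.** `carve_water_shell()` trims a
  user-supplied pre-solvated, equilibrated snapshot down to the thin
  shell; it does not synthesize water positions. This matches the
  equilibrate-then-anneal workflow and avoids re-implementing solvation.
  Carving is idempotent and invariant under rigid motion.
* **Ion placement.** No placement rule is published. Ions are placed on
  spherical Fibonacci directions from the protein centroid at radius
  `R_max + d_ion` (so the `d_ion` floor holds by construction), rotated by
  a seeded random rotation for reproducible decorrelation; positions are
  verified against an exhaustive distance scan and the post-placement
  system charge is exactly zero. Ions are emitted as bare monovalent
  Na⁺/Cl⁻; how "hydrated" counter-ions were represented upstream is not
  specified, and coordinated waters would in any case be carved away by
  the shell rule.
* **Box.** Cubic, with margin `max(d_b, d_ion + 0.5 nm)` beyond the
  system extent; only `d_b` is published.
* **Net charge.** Computed from residue bookkeeping (Arg/Lys +1, Asp/Glu
  −1, phospho-residues −2, acetyl-lysine 0, monomethyl +1, ion species
  charges); termini and nonstandard protonation are not modelled, and a
  known charge can be supplied explicitly.

## Residue identity and mapping

Modified residues are recognized by three-letter code: SEP/TPO/PTR
(phospho), ALY (acetyl), MLZ/MLY (methyl-Lys), NMM (methyl-Arg).
Structure-preparation pipelines vary in the codes they emit, so the table
is extensible via `ptm_recognition_table(extra = ...)` — it is a
documented default of this package; site lists in the wild name sites only
by type and position.

`map_residues()` pairs the two variants chain by chain with a global
alignment of parent one-letter sequences (match 1, mismatch 0, linear gap
−1, via Biostrings), so SEP aligns as S and pairs with the unmodified
serine. Residue numbering is never rewritten: all keys are
`(chain, resno)` verbatim from the source files. Alignments below 90 %
identity raise an error — at that point the inputs are not variants of one
protein. When several optimal alignments exist the traceback choice is
Biostrings' own; with the 1/0/−1 scheme this only matters for pathological
repeat sequences.

## The comparison stage

The neighborhood of a site is every protein residue with a heavy atom
within 0.3 nm (inclusive) of a heavy atom of the site residue, measured on
the **unmodified** structure so both states share one residue set (the
protocol itself does not prescribe which variant defines the set). Each mapped
residue's ΔPV is classified `increase` (> +0.2), `decrease` (< −0.2) or
`unchanged`; the classes are exhaustive and exclusive.

Two cumulative-neighborhood conventions are in circulation for the
neighborhood bar:
summing all signed neighbor deltas, and summing only those exceeding the
±0.2 threshold. Both exist behind `cumulative_mode`, default `"filtered"`
(consistent with the stated ±0.2 significance rule). The sum is of
*signed* deltas — hydrophobic shifts produce negative bars.

The paired Wilcoxon signed-rank test runs over the neighborhood's
per-residue replicate-mean PV pairs (the pairing unit is not published;
per-replicate pairing would conflate replicate noise with residue
identity). Zero differences are dropped (classical convention, not
Pratt's), ties get mid-ranks, and for `n ≤ 25` the two-sided p-value is
**exact**, computed from the full signed-rank distribution over all 2ⁿ
sign assignments by polynomial convolution on doubled ranks (so tied
mid-ranks stay integral). Above 25 a normal approximation with tie and
continuity correction takes over. The exact path is checked against a
brute-force 2ⁿ enumeration oracle and, on tie-free data, against
`stats::wilcox.test`; `stats::wilcox.test` is never the implementation.
α = 0.05 by default (the conventional level; "ns" labels in protocol
reports typically come without one).

## The synthetic generator: what it emulates, and what it does not

`synthetic_spec()` builds systems whose ground truth is analytic. Each
pseudo-residue is a single heavy atom with `m` waters (default 50) placed
0.12–0.30 nm away, i.e. inside the contact cutoff; residues are spaced
`2 × displacement_radius + 0.2` nm apart so shells never overlap. Every
water either persists for the whole ramp, with probability equal to the
residue's prescribed hydropathy `h ∈ [0, 1]`, or is assigned an escape
temperature uniform on (300, 800) K; past it, the water is displaced
radially to `displacement_radius` (1.5 nm, far outside the cutoff). The
expected retention ratio is then exactly `h` and the ground-truth PV is
`10·h`, so parameter recovery is a sharp test of the whole
contact-counting and scoring stack.

Two sampling details are deliberate:

* **Stratified persistence (default).** Within a residue, persistence is
  assigned through a randomly permuted low-discrepancy grid
  `u_j = (j − u)/m` with a single uniform offset `u`: each water is
  persistent with probability `h` marginally, while the realized
  persistent count stays within one of `m·h`. Under fully independent
  Bernoulli draws the per-replicate PV standard deviation at `h = 0.5`,
  `m = 50` is ≈ 0.71 (≈ 0.32 after five replicates), which makes a
  per-residue recovery bound of 0.5 PV a roughly 1.6 σ event per residue —
  unreliable as a guarantee across 20 residues. Stratification is a
  standard variance-reduction design for a calibration benchmark; it
  changes no expectation, and `persistence_sampling = "bernoulli"`
  restores the i.i.d. model for robustness studies.
* **Paired seeds.** RNG consumption per residue is independent of `h`, so
  a `perturb_site()`-ed spec under the same seed regenerates identical
  geometry everywhere except the perturbed residue — the synthetic
  analogue of comparing two prepared variants of one protein.

The generator reproduces the *contact pattern* of evaporation, not its
physics: no water–water interactions, no topography, no cooperative
hydration, no conformational response of the protein, and every
pseudo-residue is a bare point rather than a packed side chain. Passing
recovery tests therefore demonstrates that the measurement pipeline is
correct and well-calibrated; it says nothing about force fields or
sampling quality of real annealing trajectories, which must come from the
external engine.

Default problem sizes used throughout the tests and the acceptance script
— 20 residues spanning `h ∈ [0, 1]`, 50 waters per residue, 101 frames
over the 5000 ps ramp, quintuplicates — were chosen so that the binomial
sampling error of the recovered PV (≤ ~0.3 at five replicates) sits
comfortably inside the 0.5 PV recovery bound while a full recovery
experiment remains a desk-scale computation.

## Numerical and degenerate-input conventions

* All distance rules are boundary-inclusive (`≤`), stated per parameter.
* Coordinates are nm internally; PDB Å are divided by 10 on read, and
  round-trips are exact to the formats' printed precision (10⁻³ Å / 10⁻³
  nm).
* Distance kernels run on squared distances with a clamped-negative guard
  against floating cancellation; contact equality versus the brute-force
  oracle is exact in integers on every fixture tested.
* An empty shell, an empty trajectory, non-monotonic frame times,
  atom-count mismatches, unmapped neighborhood residues and out-of-range
  perturbations are hard errors; an all-zero difference vector in the
  Wilcoxon test is a flagged degenerate result (p = 1), not an error.
* Frames before a configurable `time_offset` (default 0) are excluded
  from profiles, for trajectories that carry equilibration frames.

## A worked synthetic example

```{r example, eval = FALSE}
spec  <- synthetic_spec(c(0.5, 0.2, 0.5, 0.8, 0.35),
                        waters_per_residue = 50, seed = 1)
mod   <- perturb_site(spec, 2, +0.4)          # a phosphorylation-like shift
run_u <- simulate_parch_experiment(spec, n_replicates = 5)
run_m <- simulate_parch_experiment(mod,  n_replicates = 5)
delta <- compute_delta(run_u$profile, run_m$profile,
                       map_residues(run_u$structure, run_m$structure),
                       site = list(chain = "A", resno = 2),
                       structure = run_u$structure)
glance(delta)      # site ΔPV ≈ +4, class "increase"
autoplot(delta)
```

## Known limitations

* Trajectory input is multi-model PDB or DCD; XTC requires upstream
  conversion.
* Net-charge bookkeeping ignores termini and protonation variants —
  supply the prepared system's charge when it is known.
* The retention-ratio scorer is a documented default, not the published
  normalization, which is defined in the scale's original literature; the
  strategy
  interface exists precisely so a faithful reimplementation of that
  normalization can be dropped in.
* No multiple-testing correction across proteins or sites is applied; the
  comparison stage reports per-site tests.
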