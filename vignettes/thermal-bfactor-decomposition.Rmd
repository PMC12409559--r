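---
title: "Decomposing B-factors in temperature-resolved crystal series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing B-factors in temperature-resolved crystal series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermalB)
```

## The model

An atom's crystallographic B-factor aggregates every source of
positional spread the diffraction experiment averages over: zero-point
fluctuation, local conformational vibration, static heterogeneity
across the lattice, rigid-body vibration of the whole molecule, and
lattice disorder. The Debye–Waller relation converts between B and
the mean-square displacement,

$$ B = 8\pi^2 \langle x^2 \rangle , $$

implemented by `b_to_msd()` / `msd_to_b()`.

When one crystal form is solved repeatedly across a temperature
series, the temperature-dependent part of B can be separated from its
zero-Kelvin remainder by fitting, per atom, residue or channel,

$$ B(T) = B_0 \, e^{kT} , $$

with $B_0$ in Å² the amplitude extrapolated to zero Kelvin and $k$ in
K⁻¹ the thermal constant. `fit_exponential()` minimises untransformed
residuals with Levenberg–Marquardt, seeded by ordinary least squares
on $(T, \log y)$; the log fit is only the initialiser, because the
quantity of interest is the B value itself, not its logarithm.
Conformational change is quantified independently: structures are
superposed onto a reference by the closed-form Kabsch solution
restricted to proper rotations (`kabsch_fit()`, `align_series()`), and
per-residue displacement profiles (`displacement_profile()`) are
regressed on temperature linearly ($\delta = \delta_0 + kT$,
`fit_linear()`) or exponentially. Pearson correlations between the
B-side parameters ($B_0$, $^{B}k$) and the displacement constants
($^{\delta}k$), with Fisher-z intervals and two-tailed p-values on
$n-2$ degrees of freedom, form the final cross-correlation stage
(`pearson_cor()`, `b_vs_plasticity()`); the $B_0$ axis is
log10-transformed there, matching how such wide-ranged amplitudes are
plotted.

Normalization divides each profile by its own average,
$B_\mathrm{norm} = B_\mathrm{obs} / B_\mathrm{avg}$ (`normalize_b()`),
within one selection of one structure — a side-chain profile is
normalized by the side-chain average, and so on — so that profiles
from different crystals, instruments and refinement scales become
comparable. Two consequences are load-bearing for the analysis. First,
$\mathrm{mean}(B_\mathrm{norm}) = 1$ identically and the profile is
invariant under $B \to cB$. Second, if every residue shares one
thermal constant and the spatial $B_0$ profile is
temperature-invariant, the exponential factor cancels in the ratio and
per-residue fits of $B_\mathrm{norm}(T)$ return $k \approx 0$: a flat
normalized-$k$ profile is exactly what a uniform (rigid-body-like)
thermal response looks like in this representation.

## Selections and conventions

Atoms are classified deterministically from residue name, atom name
and element (`classify_atoms()`): amino-acid N/C/O/OXT are backbone
and CA is the Cα selection; all other amino-acid heavy atoms are side
chain (glycine contributes none); HOH/WAT oxygens are waters; known
monoatomic het residues (CA, ZN, MG, ...) are ions; any other het
group is a ligand. Hydrogens are classified but excluded from every
downstream selection — at the 1.5 Å resolutions this workflow targets
they are effectively absent anyway. OXT is counted as backbone; the
partition between main chain and side chain is otherwise the
conventional one.

Author residue numbering plus insertion code is the residue key
throughout, and atoms are matched across structures by
(chain, residue, insertion code, atom name) with identical residue
names required; mutated or renamed residues are skipped. Alternate
locations are resolved before any analysis: the highest-occupancy
conformer wins, with occupancy ties broken by the lexicographically
smallest altloc identifier so the choice is reproducible. B-factor
averages are unweighted by occupancy (zero-occupancy atoms are
excluded entirely); this mirrors the plain per-selection means of the
classic Baverage-style summaries and is deliberately simple to reason
about. Waters, ions and ligands aggregate per atom rather than per
residue. Superposition fits on Cα atoms by default (whole-chain
alignment; backbone is available), unweighted, and the side-chain
displacement of a residue is the mean of its per-atom distances
rather than a centroid distance — robust to partially modelled side
chains.

## Tunable parameters

| parameter | default | where | meaning |
|---|---|---|---|
| `altloc_policy` | highest_occupancy | `read_structure()` | conformer selection |
| `fit_selection` | calpha | `align_series()` | superposition atom set |
| water match `cutoff` | 1.0 Å | `match_waters()` | below bond lengths, avoids identity swaps between adjacent waters; conserved-water counts are monotone in it |
| `conserved_frac` | 1.0 | `water_match_table()` | fraction of structures a water must appear in ("conserved in all" by default; 0.9 relaxes it) |
| `min_coverage` | 2/3 | `fit_profile_series()` | minimum fraction of structures a residue needs before it is fitted |
| `maxit`, `ftol` | 200, 1e-10 | `thermal_control()` | Levenberg–Marquardt iteration cap and relative loss tolerance |

Replicates enter every regression as individual points rather than
pre-averaged means: this preserves the true n for confidence
intervals and mirrors a triplicate design's scatter. For nonlinear
fits the reported Pearson r is between observed and fitted values
(`pearson_r_ty` additionally carries r between temperature and the
response, since either convention appears in practice; neither is used
as a hard acceptance quantity). Responses that reach zero or below —
possible for displacement series at the reference temperature — are
dropped from the log seed only and retained in the nonlinear
objective. A constant response reports $k = 0$ with
`converged = FALSE` and r set to 0, since the correlation is
undefined there.

## The synthetic generator

`generate_base_structure()` builds an idealized poly-alanine-like
chain on a serpentine lattice (one-atom CB side chains except at
glycine positions, ~10% of residues), a four-atom ligand group, one
calcium ion, and waters placed at least 2.4 Å from any atom. The
geometry is deliberately schematic — atoms are kept ≥ 2 Å apart
rather than at covalent bond lengths — because nothing downstream
depends on chemistry, only on matchable atom identities and sane
spatial separations for water matching.

`generate_ensemble()` then emulates a 9-temperature (100–300 K, 25 K
steps) × 3-replicate design with ground truth recorded per stage:

* per-residue $B_{0,i}$ log-normal, median 6 Å², sdlog 0.4 — the
  scale of low-temperature protein B-factors at ~1.5 Å resolution;
* thermal constant fixed at $k = 0.005$ K⁻¹ (`k_mode = "uniform"`,
  the uniform all-atom response the analysis is designed to detect) or
  per-residue uniform in [0.004, 0.006] K⁻¹ (`"varying"`);
* displacement coefficients $\delta_i$ half-normal with sd
  0.0015 Å K⁻¹, applied as $\delta_i (T - T_{\min})$ along a fixed
  random unit vector per residue — chain-averaged slopes land around
  $10^{-3}$ Å K⁻¹, the magnitude of real global drifts; drawn
  independently of $B_{0,i}$ by default, or coupled to
  $\log_{10} B_{0,i}$ (`delta_mode = "coupled"`, slope 0.01 Å K⁻¹ per
  log10 unit) to plant a strong, detectable correlation for
  validation;
* multiplicative B noise of 5% and isotropic coordinate noise of
  0.05 Å, typical refinement reproducibility at this resolution;
* one random proper rigid transform per replicate (replicate 1 keeps
  the base frame so the reference structure is untransformed);
* water retention falling linearly from 1.0 at 100 K to 0.5 at 300 K,
  realised through a persistent per-water rank $u \sim U(0,1)$ with a
  water present when $u \le p(T)$. Marginally the count at each
  temperature is Binomial$(n, p(T))$, while the best-ordered waters
  persist across the entire series — as conserved crystallographic
  waters do. Independent per-structure deletion would leave
  essentially no water surviving all 27 structures, which would make
  the conserved-water analysis vacuous;
* a stand-in Wilson B per structure (the average protein-atom B),
  written as a REMARK 3 header line, so the model-free channel of the
  global fits is exercised.

Everything is deterministic given (config, seed); written ensembles
are byte-identical across runs, and the truth table round-trips
through JSON at 17 significant digits, which reproduces IEEE doubles
exactly.

What the generator does *not* emulate: anisotropic displacement,
TLS-like correlated motion, the ~210 K dynamical (glass) transition,
crystal-contact effects, occupancy refinement, and real side-chain
geometry. Passing tests therefore demonstrate that the pipeline's
estimators recover planted parameters under realistic noise — not
that real crystals obey a single-exponential law; that judgement
needs deposited data.

## Numerical choices and degenerate inputs

PDB fixed-width fields quantize coordinates to $10^{-3}$ Å and B to
$10^{-2}$ Å², which bounds achievable recovery through files;
file-based tests use tolerances derived from that quantization
(e.g. $|\Delta k| < 10^{-4}$ K⁻¹ on noiseless ensembles), not machine
epsilon. The Kabsch solution forces $\det R = +1$ via the standard
sign correction on the smallest singular value. Water matching is
mutual-nearest-neighbour with conflicts resolved greedily in
ascending distance (deterministic and symmetric). Confidence
intervals for r require $n \ge 4$ (Fisher z) and are clamped at
$|r| = 1$; p-values are reported raw, with no multiple-testing
correction, as is conventional for these per-panel correlations.

Chain-averaged displacement slopes are mildly attenuated relative to
the planted mean $\delta$: least-squares superposition absorbs
whatever part of the displacement field looks like a rigid motion of
the whole chain, so the profile measures displacement *relative to
the best-fit frame*. This is a property of any
superposition-based analysis, not of this implementation; the
per-residue field itself is recovered exactly in the reference frame.

## Problem sizes

The test suite validates estimators at 8–60 residues and the
independence/planted correlation analyses at 220 residues over 100
seeded repeats; the acceptance script runs the full file-based
pipeline at 223 residues × 27 structures × 450 waters. These sizes
were chosen so every distributional claim is backed by enough
replication while a full run stays comfortably interactive.

## Known limitations

* Single-exponential only: no two-regime (glass-transition) or
  multi-exponential models, and no TLS decomposition.
* Wilson B is read from headers, never recomputed from intensities;
  structure factors are out of scope.
* PDB format only (no mmCIF), first MODEL only, no symmetry
  expansion; waters are recognised by residue name HOH/WAT only.
* The deposited-data reproduction requires the coordinate files
  locally; the library performs no network retrieval, by design, so
  results on deposited series are only as available as the files.
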