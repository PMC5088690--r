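---
title: "Genomic dimensionality, APY core sizes, and effective population size"
author: "apydim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic dimensionality, APY core sizes, and effective population size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genomic prediction by GBLUP needs the inverse of a genomic relationship
matrix (GRM). Direct inversion is cubic in the number of genotyped animals
and becomes prohibitive beyond roughly 10^5 animals, while commercial
cattle, pig and poultry populations now genotype far more. The Algorithm
for Proven and Young (APY) sidesteps this by treating the breeding values of
a small *core* subset as a basis: every non-core animal's breeding value is
written as a linear function of the core's, plus an independent residual.
The resulting inverse is cubic only in the core size and linear in the
non-core count.

How large must the core be? Additive information in a population is carried
by a limited number of effectively independent chromosome segments, a
number governed by the effective population size `Ne` and genome length `L`
(in Morgan). That dimensionality can be *measured*: it is tracked by the
number of largest eigenvalues of the GRM that explain a given fraction of
its variation. This package implements the full chain — GRM construction,
eigenvalue profiling, APY inversion at eigenvalue-derived core sizes,
mixed-model evaluation with either inverse, and Ne estimation from
eigenvalue counts — together with a forward-in-time simulator that supplies
populations with a controlled `Ne`.

## Models

**GRM.** With gene contents `M` (0/1/2) and observed allele frequencies
`p_j`, the centered matrix is `Z = M − 2p_j` and

    G0 = Z Z' / (2 Σ p_j (1 − p_j)).

Missing calls are imputed with the column mean `2 p_j` (they contribute
zero after centering); monomorphic columns contribute zero to numerator and
denominator and are kept, with a warning, because dropping them changes
nothing. `G0` has rank at most `min(n animals, n SNPs)` and is typically
singular, so the working matrix is the blend `G = w G0 + (1 − w) A22` with
the pedigree relationships `A22` of the genotyped animals and `w = 0.95`
by default (0.90–0.95 being the usual range).

**Eigenvalue profile.** The full symmetric spectrum of `G0` (LAPACK) is
clamped at zero — `G0` can have small negative noise eigenvalues, and the
clamped sum equals the trace for PSD input — and the profile records the
smallest `k` whose leading eigenvalues reach 90, 95, 98 and 99% of the
total. For large problems the same counts come from the singular values of
`Z` (`svdCounts()`), since the squared singular values are the `G0`
eigenvalues times the scalar denominator; the two routes agree to integer
identity and this equivalence is tested.

**APY.** Partitioning `G` into core (c) and non-core (n) blocks,

    Gapy^-1 = [Gcc^-1 0; 0 0] + [−Gcc^-1 Gcn; I] Mnn^-1 [−Gnc Gcc^-1  I],
    Mnn = diag{ g_ii − g_ic Gcc^-1 g_ci }.

`apyInverse()` stores only `Gcc^-1`, `Gcn` and `diag(Mnn^-1)` and exposes a
matrix-vector product; dense assembly exists for testing. The inverse it
represents is the exact inverse of the *implied* matrix
`[Gcc Gcn; Gnc Gnc Gcc^-1 Gcn + Mnn]`, which matches `G` exactly on every
block involving the core. A conditional variance `m_nn,i ≤ 1e-8 · g_ii`
(relative, since no absolute scale is guaranteed) means a non-core animal
lies numerically in the core span — a clone, effectively — and is an error
rather than a silent near-singularity.

**Evaluation.** `solveMME()` solves the single-trait animal model
`[X'X X'W; W'X W'W + λ Kinv][b; u] = [X'y; W'y]`, with
`λ = σe²/σu²` supplied (variance components are inputs, not estimated; the
default derives from the simulated h²). `Kinv` is a dense inverse, the
factored APY operator, or a single-step H-inverse
`Ainv + [0 0; 0 Ginv − A22inv]` with τ = ω = 1. Systems of at most 5000
equations are solved directly; larger ones use conjugate gradients with a
Jacobi preconditioner to a relative residual of 1e-8 (the diagonal of the
factored APY inverse is available in closed form for the preconditioner).
The direct and iterative paths agree to 1e-6 on every reported metric,
which is tested. A22 and A are inverted densely (Cholesky): at the desk
scale this package targets (≤ ~10,000 genotyped animals) sparse
Henderson-rule assembly of `Ainv` buys nothing.

**Validation.** Records are truncated at a time label; genotyped animals
whose records all fall after the cutoff form the validation set. Metrics:
predictive ability (correlation of GEBV with phenotypes adjusted by the
full-data fixed-effect estimates), validation R² (regression of a realized
dependent variable on GEBV), realized accuracy against true breeding
values (simulation only), and the correlation between GEBV from the
regular and APY inverses. Dairy-style daughter deviations require progeny,
which last-generation validation animals lack by construction; the
exported `progenyDeviation()` (mate-adjusted progeny means, expectation
`tbv/2`) serves that role for animals that do have progeny.

**Ne estimation.** Reference curves of the 90% eigenvalue count versus
`Ne` are regenerated by simulation at a matched design (the 90% count is
the least distorted by limited SNP and animal numbers; counts at higher
thresholds flatten when `n SNPs < 12 × count`, the diagnostic
`snpSufficiencyWarning()` flags this). Interpolation is piecewise linear
in log(count) vs log(Ne) — the curves are nearly linear on a log scale —
with linear extrapolation on the outer segments, flagged. Because
`Ne ~ 1/L` at constant segment count, an estimate made against curves at
one genome length transfers to another species' length by
`adjustNeForGenomeLength()`.

## The simulator

`simulatePopulation()` emulates the classical two-phase design used in
simulation studies of APY core sizes: a burn-in at constant census size
`ne` builds linkage disequilibrium by drift alone, then an expansion phase
produces discrete non-overlapping generations under random mating with no
selection, mutation or migration.

Design choices, made once:

* **Base population.** Founder haplotypes start in linkage equilibrium
  with allele frequencies uniform on (0.05, 0.95); LD is generated
  entirely by the burn-in (default `4·ne` generations), after which the
  frequency spectrum is drift-flattened and heterozygosity has decayed by
  `(1 − 1/(2ne))^t` — a property the test suite checks against the closed
  form.
* **Locus padding.** Drift fixes most founder loci over a `4·ne` burn-in
  (only ~15% segregate at the end), so the simulator initialises 8× the
  requested `nSnp + nQtl` loci and prunes fixed loci every 10 generations
  — exact, since a fixed locus can never re-segregate without mutation. A
  remaining shortfall is an error, not a silent reduction.
* **Recombination.** Poisson crossover counts per chromosome (mean = map
  length in Morgan), uniform positions, no interference (Haldane),
  independent assortment. Chromosomes are equal-length with evenly spaced
  loci.
* **Mating and Ne.** Hermaphroditic random mating with distinct parents;
  under random mating at constant census size the effective size equals
  the census size, so `ne` is controlled directly rather than through sex
  ratios.
* **Markers.** Loci fixed *during expansion* are retained (they carry zero
  information and keep the marker count constant across generations); only
  end-of-burn-in fixation excludes a locus.
* **Trait.** QTL are sampled from segregating loci disjoint from the
  markers; standard-normal substitution effects are rescaled so
  `var(TBV) = h²` in the first expansion generation and the residual
  variance is `1 − h²`, giving unit phenotypic variance and the requested
  h² there. The generation label doubles as the fixed-effect class and the
  truncation time axis. No canonical QTL count or heritability attaches to
  this design; the defaults (500 QTL, h² = 0.3) are ordinary values for a
  moderately polygenic production trait.

What the simulator does **not** emulate: selection (and the resulting
Bulmer effect and generation-specific information decay), overlapping
generations, migration, mutation, sex chromosomes, genotyping error and
imputation, multi-trait records. Passing tests therefore demonstrate the
method's behaviour under drift-only LD with clean genotypes; real
populations add distortions (notably imputation artifacts, which field
data suggest can flatten or dent accuracy curves) that this package
measures but does not model.

## Study scale and numerical choices

The packaged study design — used by the acceptance script and the heavy
tests — is `Ne = 40`, 10 Morgan over 10 chromosomes, 5000 SNPs, 500 QTL,
6 generations of 1000 with the last three genotyped (3000 animals),
h² = 0.3, truncation after generation 5. This is a deliberate desk-scale
analogue of national-evaluation studies (tens of thousands genotyped,
~40–60k SNPs): it keeps a full replicate (simulation, 3000×3000
eigendecomposition, three MME solves) in the low minutes on one CPU while
preserving the quantities of interest. One consequence of the scale is
worth knowing: the measured 98% count sits near 460–500 here, well below
the `3·Ne·L ≈ 1200` seen at national scale, because `12 × k98` exceeds the
5000 available SNPs — the 98% count is exactly in the regime the 12× rule
flags as compressed. The spectrum is therefore flatter than at full scale
(`k98/k90 ≈ 2.1` versus ≈ 3 in large populations), and *halving* the 98%
core lands at the 90% count, where accuracy visibly degrades (a mean loss
of ≈ 0.025–0.03 in the packaged experiments, versus the sub-0.01 plateau
loss reported for national-scale populations; the same holds in
single-step mode). The APY-versus-regular GEBV correlation at the 98% core
is ≥ 0.99 at this scale, as at full scale. The Ne-estimation checks use a
smaller design (1 Morgan, 400 SNPs, 300 genotyped) with curves at
Ne ∈ {20, 40, 80} and 5 replicates per grid point.

Numerical conventions collected in one place: symmetry is enforced (and
checked at 1e-8) before eigendecomposition; negative eigenvalues are
clamped to zero for explained-variation accounting; `m_nn` positivity uses
a 1e-8 relative tolerance; threshold counts use a 1e-12 slack so an exact
cumulative fraction (e.g. 0.9 at the identity matrix) is not missed to
rounding; core animals keep genotype-file order within blocks and the
factored inverse is permutation-consistent (tested); all randomness flows
through explicit seeds, sub-seeds being derived from a master seed by a
seeded integer draw, and every simulation is bit-reproducible from its
seed.

## Known limitations

* Dense, in-memory matrices throughout: the implementation is faithful to
  the algorithmic structure (factored APY storage, SVD route, CG solver)
  but is not an out-of-core national-evaluation engine.
* Variance components are inputs; no REML/Gibbs estimation.
* Random core selection only (plus user-supplied id lists); no optimised
  core-choice strategies.
* Ne estimates inherit the reference curves' design: a mismatch in genome
  length, SNP count or sample size between query and curves biases the
  estimate, which is why curve provenance is stored and checked.
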