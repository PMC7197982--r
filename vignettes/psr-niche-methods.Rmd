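---
title: "Methods: PSR curves for haplotype-level niche conservatism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSR curves for haplotype-level niche conservatism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psrniche)
```

# The model

`psrniche` asks whether bioclimatic niche variables are evolutionarily
constrained across the haplotypes of co-distributed plant lineages. The
chain of models is:

1. **Evolutionary units.** Individuals sharing identical nucleotide states
   (at unmasked, unambiguous columns) and identical indel-event presence
   are one haplotype. A contiguous gap run is one mutational event
   regardless of length, because a single replication slippage or
   deletion creates the whole block; two runs are the same event only when
   their column spans match exactly, the only reading under which
   "one event" is unambiguous.
2. **Genetic distances.** The Tajima–Nei (equal-input) distance
   d = −b·ln(1 − p/b) corrects the mismatch proportion p for unequal base
   composition (g~i~) and mismatch-pattern heterogeneity (h). It is a
   substitution model, so coded indel events do not enter the distance by
   default (`indelDistance = "add-events"` exists for sensitivity
   analysis). When composition is uniform and mismatch pairs are
   equidistributed it collapses exactly to Jukes–Cantor,
   −¾·ln(1 − 4p/3), which the test suite asserts to 1e−12.
3. **Eigenvector basis.** PCoA of the distance matrix gives orthogonal
   axes ordered by eigenvalue: the leading axes separate deep haplogroups,
   trailing axes recent tip structure.
4. **PSR curve and area.** For each niche variable (the per-haplotype mean
   over its carriers), OLS on the first k eigenvectors yields cumulative
   R²~k~, plotted against cumulative relative eigenvalues x~k~. Under
   Brownian motion trait variance accrues in proportion to the
   eigenvalues, so the curve tracks the diagonal; the signed trapezoidal
   area between curve and diagonal (|area| ≤ ½ by construction)
   summarizes constraint (negative, Ornstein–Uhlenbeck-like) versus burst
   (positive). Significance uses permutation of trait values across
   haplotypes — the standard operationalization of "no phylogenetic
   signal" — with a two-tailed p on |area| and the +1 small-sample
   correction; areas can deviate in either direction a priori, hence
   two-tailed.
5. **Networks.** A median-joining network over the haplotype character
   matrix (substitution columns plus event columns) visualizes the
   genealogy; nodes are shaded by exact 1-D K-means ranks of the
   eigenvector with the largest R² increment, connecting the statistical
   signal back to identifiable haplogroups.

# The PCoA scale convention

Standard PCoA double-centers **squared** distances. For PSR the relevant
quantity is the Brownian covariance among tips, and for an ultrametric
genealogy that covariance is (up to centering) −½ J D J applied to the
**unsquared** patristic distance matrix: C~ij~ = T − d~ij~/2. Genetic
distances are likewise linear in divergence time in expectation. The PSR
workflow therefore treats its distance input as already being on the
squared-Euclidean scale (`pcoaBasis(..., inputIsSquared = TRUE)`, the
default inside `runPSRPipeline`); `inputIsSquared = FALSE` gives textbook
PCoA and is the default of the standalone function. This is the single
choice that makes PSR curves straight, on average, under neutral
evolution; with literal re-squaring of tree distances the Brownian
baseline bows visibly below the diagonal.

Non-Euclidean inputs (Tajima–Nei matrices especially) produce negative
eigenvalues. These are dropped and counted (`droppedNonpositive`), with a
warning when the dropped mass exceeds 5% of the absolute spectrum — no
Cailliez/Lingoes correction, matching the observation that fewer
eigenvectors than n−1 are typically usable. Axes are retained above
1e−10·λ~max~ (the numerical floor of symmetric eigensolvers), signs fixed
so each axis's largest-magnitude entry is positive.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `minRun` | 6 | consensus poly-A/T run length masked; typical microsatellite-like hypervariability threshold, configurable to replicate other dialects |
| `deletion` | complete | drop gap/N columns alignment-wide before distances (pairwise available) |
| `strict` | FALSE | keep N-containing columns in haplotype identity (default maps them out, so sequencing artifacts do not inflate haplotype counts) |
| `nRand` | 999 | trait permutations per variable |
| `epsilon` | 0 | weight tolerance of the spanning network (0 = most parsimonious) |
| `groups` | 4 | K-means rank classes for overlays; a display choice, exposed prominently |
| `tol` | 1e-10 | relative eigenvalue floor |

Curve fitting exploits that double-centered eigenvectors are centered,
orthogonal and unit-norm: cumulative R² is a cumulative sum of squared
projections, identical to refitting the normal equations at each k (the
tests verify equality to 1e−10 against a brute-force OLS oracle). ΔR²~1~
is defined as R²~1~ so increments total R²~K~. Displayed class means are
rounded half-away-from-zero to two decimals; files keep full precision.
K-means ties in 1-D are resolved toward the earlier boundary; peak ties
toward smaller k. All alignment columns are reported 1-based inclusive.

# The synthetic-data generator

The generator emulates the study inputs without downloads: a Kingman
coalescent genealogy (successive Exp(C(j,2)) waiting times, uniformly
random pair merges; expected depth 2(1−1/n)), infinite-sites sequences
(Poisson(θ/2·branch length) substitutions at fresh columns, optional
geometric-length gap blocks coded as events), and traits evolved by exact
root-to-tip transition sampling under BM, OU (stationary root,
σ²/(2α) stationary variance) or an early burst (rate σ²e^(−λt)).
Individuals per haplotype are 1 + Poisson(3); each of the 20 niche
variables is the haplotype's trait value plus a per-variable offset, plus
Gaussian within-haplotype noise (SD 0.5 by default), coordinates jittered
around per-haplotype centers in a subtropical-grassland window. Defaults
(n = 64 haplotypes, 600 columns, θ = 8, indel rate 0.5, σ² = 1, α = 5,
decay 1.5) were fixed once as field-realistic magnitudes: θ of a few units
matches chloroplast spacer diversity at this sampling depth, α·depth ≈ 10
is unambiguously strong attraction, decay 1.5 quenches the early-burst
rate to ~5% of its initial value by the tips.

Datasets are conditioned on distinctness: a tip whose simulated sequence
duplicates another receives one private substitution, so an alignment
always collapses back to exactly n haplotypes. Everything is
bit-reproducible from the seed.

What the generator does **not** emulate: recombination, migration and
population structure, selection on the sequences, realistic WorldClim
magnitudes or inter-variable correlation structure (all 20 variables
derive from one latent trait plus offsets), and the original sampling
scale (thousands of individuals). Passing calibration tests therefore
shows the statistic behaves as designed under its own assumptions — not
that any particular empirical dataset satisfies those assumptions.

# Calibration behaviour and a known bias

On synthetic data with patristic distances, strong OU attraction yields
negative PSR areas in essentially all replicates and early bursts positive
areas in a majority — the sign conventions behave as designed
(`scripts/acceptance.R` recomputes both fractions). Under Brownian motion
every curve is monotone and ends at (1, 1) to 1e−8, but the **mean**
signed area over replicates is slightly negative rather than zero (the
acceptance script reports it). The reason is that R² is a ratio statistic:
the trait component on eigenvector k is λ~k~·χ²₁, and on coalescent
genealogies — whose deep splits put much eigenvalue mass on one or two
heavily skewed components — the heavy left tail of χ²₁ depresses E[R²~k~]
below the eigenvalue share. The effect shrinks for more balanced trees and
is a property of the statistic, not of this implementation; single-trait
PSR areas on genealogies with dominant deep splits should be read against
a simulated Brownian baseline rather than against zero.

# Degenerate inputs and errors

Empty alignments, alphabet violations (named per record), constant traits,
saturated distances (p/b ≥ 1, named per pair), pairs with zero comparable
sites, sub-3-point configurations, all-dropped spectra, out-of-range
eigenvector indices and over-clustered K-means (g exceeding distinct
scores) all fail fast with specific messages; pipeline stages prefix
errors with the stage name. Median-vector tie expansion is capped
(default 1000 candidates) to bound quasi-median blowup on heterogeneous
triplets.

# Problem sizes in the shipped tests

The suite exercises calibration at 200 replicates of 64-haplotype
genealogies (the acceptance checks), moment checks at 2000–5000 replicates
of 6–16 tips, oracle equivalences on 100 random bases of 5–10 points,
exhaustive permutation nulls at n = 4–5, and exhaustive network/K-means
enumerations up to 12 haplotypes. These sizes make the whole suite run in
well under a minute while keeping every Monte-Carlo tolerance at least
several standard errors wide.

# Limitations

- The retention rule for eigenvectors reproduces the qualitative
  behaviour of the original analyses (fewer than n−1 axes usable), not
  any specific software's axis count.
- The permutation null destroys all phylogenetic structure at once; it
  does not test against intermediate signal strengths.
- Median-joining is a heuristic: the network contains a minimum-spanning
  skeleton and never increases total cost when adding medians, but global
  Steiner optimality is only guaranteed (and tested) on small fixtures.
- Whether to average niche values over individuals or over unique
  localities is ambiguous in the field; the package averages over
  individuals, literally "all individuals that carried each haplotype".
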