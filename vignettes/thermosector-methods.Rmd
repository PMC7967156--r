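---
title: "Sector-based thermostability design: models, parameters and validation"
author: "thermosector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sector-based thermostability design: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermosector)
```

## The problem

Enzymes from mesophilic organisms denature at the elevated temperatures
where industrial biocatalysis would like to run them. Thermophilic
homologs demonstrate that the same fold can be stabilized by a modest
set of residue substitutions, and a family alignment that contains both
thermal classes records those substitutions — diluted by phylogeny,
functional constraints and noise. This package implements a purely
sequence-based route from such an alignment to a short, ranked list of
candidate stabilizing point mutations: no structure, no energy function,
no simulation.

The route combines two signals that are individually insufficient.
Coevolution analysis finds groups of residues that change together
("protein sectors"), but not which group is about stability.
Thermophile/mesophile profile divergence finds positions used
differently by the two classes, but scattered single positions are weak
and redundant candidates. The design rule is their intersection: find
the sector whose members are collectively the most divergent between
thermal classes, and mutate its most divergent positions toward the
thermophilic consensus.

## Models and procedure

### Residue correlation analysis

For an MSA with $M$ sequences and $N$ reference positions, the
substitution event between sequences $k<l$ at position $i$ is scored as
$X_i^{kl}$: BLOSUM50 between two amino acids, $-8$ when exactly one is a
gap, $0$ for two gaps. The gap scores are model constants, not tunables:
$-8$ is a conventional strong gap penalty on the BLOSUM50 half-bit
scale, and $0$ for gap–gap encodes "no event observed". Coevolution
between positions $i$ and $j$ is the Pearson correlation of
$\{X_i^{kl}\}$ and $\{X_j^{kl}\}$ over all $\binom{M}{2}$ unordered
pairs. Positions with zero substitution-score variance (a single residue
throughout) have no defined correlation; they are flagged and their
rows, columns and diagonal set to zero so the matrix keeps the reference
shape.

Two implementations are shipped. `rcaMatrixBruteforce()` enumerates the
pairs literally and is quadratic in $M$; it exists as the reference
semantics. `rcaMatrix()` collapses the pair sums into joint symbol-pair
counts — for each position pair a $21\times21$ contingency table $C$
gives the ordered-pair score sum as $\sum C \odot (S C S)$, from which
self-pairs are subtracted — reducing the cost to
$O(N^2(M + A^3))$. The two agree to $10^{-9}$ per entry by test, on
alignments with and without gaps. Pearson normalization uses the
population convention (divide by the pair count); since the same
constant enters numerator and denominator, the choice cannot affect
$r$, and it is fixed only so the equivalence contract is exact.

### Sectors from the eigen-spectrum

The correlation matrix is eigen-decomposed with eigenvalues descending.
Each eigenvector's sign is arbitrary, so it is fixed by making the
largest-magnitude component positive; without this, boundaries and
clustering would not be reproducible across LAPACK builds. Mode 1 is
treated as phylogenetic ("historical") covariation and excluded; modes
2–4 are the default signal space. No explicit phylogenetic correction is
attempted — dropping the dominant mode is the whole treatment, and the
synthetic benchmark (below) plants a clade structure precisely so that
this treatment is exercised.

Significance of a position is judged against a column-shuffling null:
each column's residues are permuted independently (10 trials by
default), which preserves every single-column frequency profile exactly
while destroying all between-column correlation. The RCA and
eigen-decomposition are recomputed per trial and the selected-mode
eigenvector components pooled (pooled-then-fit; fitting per trial and
averaging was considered and not implemented, as the pooled fit uses
the same $N\times\text{trials}$ samples with fewer moving parts). A
Gaussian fit (sample mean, ML standard deviation) gives the boundary:
position $i$ is retained iff $|v_k(i)-\mu_k| > n_\sigma \sigma_k$ for at
least one selected mode $k$ — the complement of "all mode weights
within the boundaries". Centered absolute deviation is used because the
sign-fixed eigenvectors of the null are symmetric around a mean that is
only approximately zero.

The multiplier $n_\sigma$ deserves a paragraph, because the literature
that popularized the Gaussian-fit boundary does not state one. With
three modes tested two-sided, the expected fraction of null positions
retained is approximately $6\,\Phi(-n_\sigma)$: a traditional
$2\sigma$ boundary would retain $\sim9\%$ of pure-noise positions in
expectation — and measurably more, since the extreme components of
noise-matrix eigenvectors are heavier-tailed than Gaussian. We
therefore set the default at the family-wise 5% point,
$n_\sigma = \Phi^{-1}(1 - 0.05/6) \approx 2.39$, the Bonferroni-style
correction for three two-sided tests. Measured retention on fully
shuffled alignments is ~5%, within the ≤10% calibration contract the
package tests enforce. The multiplier is exposed (`nullSigma`,
`--null-sigma`) for users who prefer a looser or stricter screen.

Retained positions are clustered by k-means on their raw
$(v_2, v_3, v_4)$ coordinates (eigenvalue-weighted coordinates are
available behind `weightModes`, but raw components match the mode-space
scatter convention in the sector literature). k-means++ seeding with 100
restarts keeps the best within-cluster sum of squares; cluster labels
are then relabeled by descending size with ties broken by smallest
member position, making the assignment deterministic given
`(seed, nRestarts)`. The number of sectors `k` defaults to 4 and is not
chosen automatically. A per-sector contiguity score — the median gap
between consecutive member positions — is reported because
sequence-contiguous sectors tend to be domain cores with functional
roles; the score is advisory only and never excludes a sector
automatically.

### The relative-entropy angle

For each thermal class, each position's frequency profile $f$ over the
21 symbols (gap is a first-class state) is compared with a shared
background $q$ through the componentwise binary relative entropy

$$D^a = f_a \log\frac{f_a}{q_a} + (1-f_a)\log\frac{1-f_a}{1-q_a},$$

the large-$M$ limit of the log-binomial surprise. The exact
log-binomial form is available behind `exact = TRUE` for comparison,
but it scales with the sub-alignment depth $M$, and the thermophilic
subset is typically an order of magnitude shallower than the mesophilic
one; the $M$-free KL form keeps the two vectors on one scale. Natural
logarithm is used; the choice is immaterial to the angle (a common
positive scale factor cancels) and fixed only for reproducibility of
the $D$ values themselves.

The background $q$ is computed from the full projected MSA: the gap
component is the overall gap fraction, the amino-acid components are
frequencies among non-gap cells scaled by $1-q_{gap}$. Sequences of
unknown thermal class contribute to $q$ but to neither class profile. A
fixed literature background can be supplied instead (`background`
argument); the MSA-derived default reflects the family actually
analyzed. All entries are floored at $10^{-4}$ and renormalized so no
$D$ component can diverge when a residue is absent from the family.

The divergence angle at a position is
$\theta = \arccos\!\big(D_{thermo}\cdot D_{meso} / \lVert D_{thermo}\rVert\,\lVert D_{meso}\rVert\big) \in [0, \pi/2]$,
with the cosine clamped to $[-1,1]$ against rounding. If either vector
has zero norm the position sits exactly at background in that class —
no divergence evidence — and $\theta$ is defined as 0 so such positions
cannot rank as design candidates. $\theta$ is invariant to log base and
to positive rescaling of either vector, symmetric in its arguments, and
exactly 0 when the two class profiles coincide.

### Mutation design

The target is the sector with the largest mean $\theta$ over its
members; a tie (within $10^{-12}$) aborts with a request for a manual
choice, because everything downstream hangs on this selection. Member
positions with $\theta$ above the site threshold (default 0.5 rad,
`--theta-threshold`) become mutation sites, ranked by descending
$\theta$.

At each site the candidate list is the amino acids present in the
thermophilic profile, by descending frequency, ties alphabetical,
excluding gap and the wild type. One rule modifies the order: if the
thermophilic and mesophilic consensus residues coincide (and are not
the wild type), that residue is demoted below the second-ranked
candidate and annotated `shared-consensus demotion` — a residue that
both classes prefer carries no thermoadaptive information. Gaps are
excluded from both consensus determinations. The full ranked list is
always emitted, not just the top choice: the intended workflow is
iterative, with experimentally unsuccessful mutations walked down to
the next candidate, which a program cannot do for you. Each candidate
is annotated with whether its side-chain class (hydrophobic / polar /
positive / negative / special) differs from the wild type's; this
mirrors the empirical observation that successful stabilizing
substitutions often change side-chain character, but it is an
annotation, never a filter. Double mutants pair an anchor — by default
the first-choice single at the highest-$\theta$ site — with every other
single.

## The synthetic benchmark

Real curated families with trustworthy thermal labels cannot ship with
a package, and published analyses depend on database versions and
curation details that are not reproducible from a desk. The generator
(`generateFamily()`) therefore produces labeled alignments with planted
ground truth, and its defaults are the package's study conditions:

* 150 thermophilic, 150 mesophilic, 100 unlabeled sequences, 60
  positions, 5% uniform gaps, plus a gap-free reference row (`REF`,
  labeled unknown, excluded from all statistics) so projection is the
  identity.
* **Clade structure.** Every sequence belongs to one of 3 clades;
  background columns draw from clade-conditional profiles (consensus
  weight 0.65). This is what makes mode 1 a dominant, sector-free
  "phylogenetic" mode, as in real families — without it, the strongest
  planted sector would occupy mode 1 and be discarded by the modes-2–4
  rule. It is deliberately not a tree simulation; a single categorical
  lineage factor is the minimal structure that reproduces the
  mode-1 phenomenon.
* **Sectors.** Per-sequence latent states (2 per sector) drive
  state-conditional sharp profiles across each sector's member
  positions, planting positive pairwise correlation. Two states per
  sector, not more, so each planted group occupies a single eigen-mode
  and three groups fit the three signal modes. The two
  sequence-contiguous sectors (positions 11–16 and 25–30) have
  concentrations 0.95 and 0.90: planted groups of equal strength would
  have nearly degenerate eigenvalues whose eigenvectors mix, which
  defeats any component-wise boundary — distinct strengths keep the
  modes separated, as distinct biological sectors' eigenvalues are.
* **Divergent sites.** A dispersed 6-position sector (35, 39, 44, 48,
  52, 56) whose sites carry a thermophilic consensus in thermophilic
  rows and a mesophilic consensus in mesophilic and unknown rows with
  weight 0.7 (the remaining 30% follows the sector's latent state).
  The planted consensus pairs are biochemically dissimilar (BLOSUM50
  ≤ −2, different side-chain classes). This is a property of the
  method worth knowing: a thermoadaptive substitution between similar
  residues (say R↔K, BLOSUM50 +3) produces substitution events that
  barely distinguish the classes and is nearly invisible to
  BLOSUM-scored correlation, while class-switching substitutions — the
  kind observed among effective stabilizing mutations — light up.

What passing the benchmark does and does not show: it shows the
pipeline recovers planted covariation groups (ARI ≥ 0.8 in ≥ 9/10
seeds), ranks planted divergent sites at the top of $\theta$ (all
within the top $m+2$), proposes the planted thermophilic consensus at
≥ 90% of sites, and calibrates its null (≤ 10% retention on shuffled
data). It does not show that real families have this structure: real
phylogeny is a tree, not three clades; real sectors overlap functional
constraints; real thermal labels are noisy; and real stabilizing
substitutions are validated only by melting curves.

## Numerical choices and degenerate inputs

* Degenerate (zero-variance) positions: zeroed rows/columns including
  the diagonal, excluded from significance selection; detected at
  `ssq ≤ 1e-6 × pair count`, far below the minimum variance any
  genuinely variable integer-scored column can have.
* Eigen ties: the symmetric LAPACK solver's stable order is kept, then
  the sign rule applied; reconstruction and trace are verified to
  $10^{-8}$ at decomposition time.
* k-means: duplicate k-means++ centers are collapsed before Lloyd
  iterations; an improvement must exceed $10^{-12}$ to replace the
  incumbent, so restart order cannot flip results by rounding.
* All randomness (shuffles, generator, k-means) flows through seeds and
  restores the caller's RNG state; identical seeded runs are
  byte-identical, which the test suite asserts on every TSV artifact.
* Problem sizes in the shipped tests — 200 random alignments up to
  30×12 for the equivalence contract, ten 401×60 end-to-end runs shared
  between the recovery checks — were chosen so the whole suite
  exercises every contract at full depth in about a minute.

## Known limitations

* No statistical-coupling-analysis weighting, no direct-coupling /
  Potts model, no average-product correction: the coevolution statistic
  is exactly the BLOSUM-scored pair correlation, with mode-1 removal as
  the only phylogeny treatment.
* Sequence redundancy is not reweighted; heavily oversampled clades
  pull both the correlation and the background. Curating redundancy
  belongs upstream.
* `k` is user-chosen; nothing prevents splitting one biological sector
  in two (the relabeling keeps this deterministic, not correct).
* $\theta$ ranks candidate positions, but says nothing about effect
  size in degrees Celsius; only experiments order the survivors.
* The conservation co-criterion sometimes mentioned alongside
  divergence-based site selection is not implemented as a filter; the
  $\theta$ threshold alone gates sites.
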