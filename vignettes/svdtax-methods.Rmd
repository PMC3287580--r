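---
title: "Methods: trigram SVD clustering of proteomes against Linnaean taxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trigram SVD clustering of proteomes against Linnaean taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdtax)
```

## The model

svdtax asks a simple question: how much of a species' taxonomic placement
can be read off the *composition* of its proteome, with no sequence
alignment at all? Each species is represented by the concatenation of its
protein sequences (in the motivating application, 13 mitochondrial gene
families per vertebrate species). That sequence is summarized by the counts
of its overlapping amino-acid trigrams: there are $20^3 = 8000$ possible
words of length 3 over the 20-letter alphabet, so a dataset of $n$ species
becomes a non-negative integer matrix $A \in \mathbb{N}^{8000 \times n}$,
column $j$ summing to $L_j - 2$ for a cleaned sequence of length $L_j$.

This is the document-term matrix of latent semantic indexing with species
as documents and trigrams as terms. As in LSI, the thin singular value
decomposition $A = U \Sigma V^\top$ is truncated to its $k$ leading
components, and each species is represented by its $k$ latent coordinates

$$D_k = \Sigma_k V_k^\top \in \mathbb{R}^{k \times n},$$

i.e. the projection of its trigram profile onto the $k$ dominant
directions of compositional variation. Euclidean distances between the
columns of $D_k$ drive all downstream clustering. At $k = \mathrm{rank}(A)$
these distances equal the raw column distances exactly (orthogonal
invariance), and they are monotone non-decreasing in $k$, so the rank acts
purely as a noise filter: small $k$ discards low-variance directions.
Cosine distance is deliberately not offered; overall profile magnitude
carries sequence-length signal that the method intends to keep.

### Raw counts versus frequencies

Columns are raw counts by default, not relative frequencies. Sequence
length then contributes to distances, which is intentional: species with
sharply shorter proteomes (missing gene families) really are harder to
place, and the search is designed to shed them into singleton clusters
rather than let normalization hide the deficit. An optional L1
normalization flag exists on `build_trigram_matrix()` for users who want
pure composition.

## ASAP clustering

The clusterer is deliberately minimal ("as simple as possible"): order the
species, take the first remaining one as pivot, gather every remaining
species at distance strictly below a threshold $d$ into its cluster,
remove them, repeat. Unlike single linkage, a formed cluster is never
re-inserted into the distance matrix. Two boundary laws pin the behaviour:
$d = 0$ yields $n$ singletons (strict inequality) and any $d$ above the
maximum pairwise distance yields one cluster.

The pivot order is the alphabetical species order by default, making every
run reproducible; a seeded random order is available, since random pivots
are equally valid for the algorithm. The pivot order only matters for
borderline thresholds.

Because membership decisions are comparisons with $d$, the resulting
partition is piecewise constant in $d$: it can only change when $d$
crosses one of the $\binom{n}{2}$ pairwise distances. Evaluating at zero,
at midpoints between consecutive sorted unique distances, and just above
the maximum therefore enumerates *every* achievable partition — the
profile grid is exhaustive, which the tests verify against brute-force
threshold sweeps.

## Scoring against Linnaean taxonomy

Every species carries an ordered 14-rank lineage (Superregnum first,
Species last). For a cluster $C$, the shared depth is the longest common
prefix of its members' lineages; distinct species can share at most rank
13 (genus), and a singleton is scored at that cap of 13 by convention. The
cluster's score is

$$\mathrm{cLtlf}(C) = |C| \times \mathrm{shared\_levels}(C),$$

the "common Linnaean taxonomy level frequency": how many species agree,
weighted by how deep their agreement goes. Ten avian species sharing their
lineage through Subclassis (rank 10) score $10 \times 10 = 100$; a
singleton scores $1 \times 13 = 13$, the minimum for a complete lineage.

A partition is summarized by the per-cluster cLtlf values: their sum,
mean, sample standard deviation ($n-1$ denominator — the bundled example
statistics only reproduce with the sample form), the quality ratio
$\mathrm{Lcq} = \Sigma \mathrm{cLtlf} / \sigma$ (undefined when
$\sigma = 0$, e.g. all-singleton partitions), and the median (even counts:
mean of the two central order statistics).

## The kdc search

The tunable parameters form a triad: the SVD rank $k$, the distance
threshold $d$, and the resulting cluster count $c$, with $c = f(d)$ and
$d$ depending on the rank-$k$ geometry. `kdc_search()` sweeps them
systematically:

* **Grids.** EDRD ("empirical dimensional range division") is
  $\max(1, \mathrm{round}(n/25))$ — step 3 for 76 species. Ranks default
  to $3, 3+\mathrm{EDRD}, \dots, n$ and target counts to multiples of
  EDRD below $n$. A dense sweep is available by passing explicit grids.
* **Threshold selection.** For each $(k, c)$ the search picks, among all
  plateaus of $d$ on which ASAP returns exactly $c$ clusters, the *widest*
  plateau, and the largest $d$ inside it. Width is measured on the
  partition, not the count: a count can persist across a composition
  change (one cluster absorbs a foreign member while another splits), and
  those accidental bands are narrow. The widest plateau is the partition
  most stable to perturbation of the distances, which is the property a
  calibration parameter should have. Selecting the globally largest
  realizing $d$ instead (available as `rule = "largest"`) tends to land in
  the narrow band just below a merge event, where clusters are already
  contaminated.
* **Control gate.** A configuration is valid only if some cluster equals
  the positive-control species set exactly ("integrally and isolatedly").
  The control group encodes the resolution the user wants: clusters as
  fine as the control clade.
* **Recursion.** If no configuration isolates the control, the best
  available result (largest control-cluster cLtlf, then fewest
  singletons) identifies species stuck in singleton clusters; those carry
  no grouping signal (frequently species with incomplete proteomes) and
  are dropped, and the sweep repeats on the remainder. Control members are
  never dropped — removing one would make isolation unattainable at every
  later depth. Depth is capped (default 3) to guarantee termination.
* **Finalize.** Valid configurations are ranked by the median of their
  per-cluster cLtlf values, descending. Lcq is deliberately *not* used
  here: once many configurations isolate the control, singleton-heavy
  partitions can post large Lcq while being uninformative; the median
  (dragged to 13 by singletons) penalizes them naturally. Ties are broken
  by fewer singletons, secondary-control isolation, larger mean cLtlf,
  then smaller $k$. The mean tie-break is needed because the median is
  blind to one specific failure mode: merging two unrelated groups keeps
  the other clusters' scores (and the median) intact while collapsing
  total agreement — e.g. planted-clade scores $\{50,50,50,50\}$ versus
  $\{50,50,20\}$ both have median 50, but means 50 versus 40. The full
  ranking table is always returned so a user can apply their own
  resolution preference instead of the automated ordering.

## The synthetic generator

`simulate_dataset()` emulates the structure the method targets: a root
protein is drawn uniformly over the 20 residues; each of `n_clades` clade
ancestors derives from it by an independent per-site substitution with
probability `between_clade_subst`; each leaf derives from its clade
ancestor with probability `within_clade_subst`. Substitutions are uniform
over the 19 alternative residues — the method is purely compositional, so
no empirical exchangeability matrix is needed to create the relevant
structure. Lineages are synthesized to match: clade members agree through
rank 10 (the depth of the avian control group in the motivating data) and
diverge below; optional outliers each descend from their *own* independent
random root and diverge from everything at rank 2, emulating the
construction of a negative-control set from unrelated phyla. Clade 1 is
the positive control.

Defaults are 4 clades × 5 species, 2000-residue sequences, 2% within- and
35% between-clade substitution, no outliers. Under these conditions the
mean between-clade trigram distance exceeds the mean within-clade distance
by a factor of about 2.8–2.9 across seeds. That ratio has a ceiling:
two essentially unrelated 2000-residue profiles sit roughly
$\sqrt{2(L-2)} \approx 63$ apart (independent multinomial counts), while
2% substitution keeps clade mates about
$\sqrt{2 \times 3 \times q L} \approx 21$ apart (each differing site
perturbs up to three trigram windows, pairwise site-difference rate
$q \approx 2 \times 0.02$), so no between-clade rate can push the ratio
much past 3 — separation saturates once profiles decorrelate.

What the generator does **not** model: indels, rate heterogeneity across
sites, codon structure, gene content differences, or compositional bias.
Passing the recovery tests therefore demonstrates that the search
machinery recovers planted compositional structure at realistic
signal-to-noise, not that real proteomes meet the generator's assumptions.

## Numerical choices and degenerate inputs

* Cleaning: residues outside the 20-letter alphabet (`B J O U X Z`, stops,
  gaps) are removed, not errors, and counted per species in the run
  report; removal keeps the trigram space exactly $20^3$. A species with
  nothing left after cleaning is a hard error.
* Numerical rank: singular values above $10^{-10} \sigma_1$; requesting
  $k$ beyond it is a parameter error. An all-zero matrix is a
  degenerate-input error.
* Singular-vector signs are unconstrained; every consumer uses distances,
  which are sign-invariant.
* ASAP threshold comparisons are strict (`< d`), fixing the $d = 0$
  boundary law.
* ASAP ties (equal distances) are resolved by the deterministic pivot
  order.
* Neighbor joining (via the classic Saitou–Nei agglomeration) can
  estimate negative branch lengths on non-additive matrices; these are
  clamped to zero with the deficit shifted to the sister branch,
  preserving path lengths through the joined pair, matching the common
  NEIGHBOR convention. Newick output fixes branch lengths at 6 decimals,
  so a path of $e$ edges re-parses within $5 \times 10^{-7} e$.
* k-means is seeded from `c` distinct species coordinates drawn under an
  explicit seed; duplicated coordinates are collapsed before drawing so
  initial centers are always distinct, and requesting more clusters than
  distinct points is an error.

## Problem sizes used by the test-suite and acceptance runs

The packaged checks run entirely on synthetic data and the bundled
example score sets: property tests use 4–20 species; the end-to-end
recovery study uses 20 replicates of the default 4 × 5-species, 2000-residue
condition, chosen because one replicate sweeps the full rank and count
grids in about 1.5 s, keeping the whole study near half a minute while
still exercising every stage of the recursion and ranking.

## Known limitations

* The 14-rank lineage is fixed-arity; ragged taxonomies must be completed
  before import, and shared depth uses prefix semantics only.
* cLtlf favours large clusters at equal depth by construction; comparing
  partitions of very different cluster counts by ΣcLtlf alone is not
  meaningful, which is why the search reports the full statistics table.
* The method is compositional: convergent amino-acid composition (e.g.
  extreme GC-driven proteome bias) can look like relatedness.
* With raw counts, grossly unequal sequence lengths dominate distances;
  use the normalization flag when that is not wanted.
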