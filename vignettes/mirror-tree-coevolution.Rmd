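---
title: "Mirror-tree coevolution analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirror-tree coevolution analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorcoev)
```

## The method

Two proteins that physically interact are expected to coevolve: a mutation in
one creates selective pressure for a compensating mutation in the other, so
their evolutionary histories should look alike. The mirror-tree method turns
this into a statistic without reconstructing any trees. For two protein
families A and B sharing $N$ species, each family yields an $N \times N$
matrix of pairwise evolutionary distances; the strict upper triangles
($n = (N^2 - N)/2$ entries each) are unrolled into two vectors in the same
fixed species-pair order, and their Pearson correlation $r_{AB}$ is the
mirror-tree statistic. If lineages in which family A evolved fast are also
the lineages in which family B evolved fast, $r_{AB}$ approaches 1.

The distance used is the uncorrected p-distance: substitutions divided by
compared sites. No Poisson or empirical-matrix correction is applied — the
statistic correlates *relative* rate variation across lineages, and the
monotone saturation shared by both families largely cancels in a rank sense;
more importantly, the p-distance is the definition under which the reference
panel correlations shipped with the package were produced, so using it keeps
the package's numbers commensurable with them. A `--model`-style hook exists
in the API surface but only `"p"` is implemented.

### Gaps and ambiguity

Sites are compared under **pairwise deletion**: a column contributes to a
pair's distance only when both sequences carry one of the 20 canonical
residues there (gaps and `X` — to which the rare ambiguity codes B/Z/U/O are
collapsed — are skipped for that pair alone). Pairwise deletion preserves
species with partial sequences, at the price of different pairs being
estimated from different site sets; `gap_policy = "complete"` is available
when uniform site support matters more. A per-pair floor of usable sites
(`min_sites`, default 50 — roughly a tenth of a short P-type-ATPase domain)
refuses distances estimated from near-empty overlaps; unit-scale examples
set it to 1 explicitly.

### Species handling

Species labels are normalized to lowercase `genus_species` (subspecies and
strain tokens dropped) before any intersection, and all derived orderings —
matrix labels, triangle vectorization, common-species lists — are
lexicographic, so results are invariant to the storage order of input
records and byte-reproducible across runs. When one family carries several
sequences for one species, the record with the longest ungapped sequence
wins, ties broken by smallest identifier: deterministic, and biased toward
complete entries. Distances for the common species are computed from the
full family alignment restricted to those rows; the columns are not
re-aligned, since alignment itself is upstream of this package.

## Significance machinery

The significance of a single $r$ uses the exact t-statistic
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, two-tailed. Two
correlations are compared on the Fisher scale, $z = \operatorname{atanh} r$,
with $z_{\text{stat}} = (z_1 - z_2)\big/\sqrt{1/(n_1-3) + 1/(n_2-3)}$
referred to the standard normal, two-tailed, with no continuity correction.

**The sample-size convention matters and is a deliberate choice.** Both
tests take the pairing count $n = (N^2-N)/2$, not the organism count $N$, as
the sample size. This is the convention under which the reference panels'
published comparisons reproduce (e.g. the PKC theta-vs-eta comparison gives
p = 0.002 with pairing counts, but p = 0.55 with organism counts). It is
statistically anti-conservative: the $n$ triangle entries are derived from
only $N$ sequences and are strongly dependent, so these p-values overstate
certainty and should be read as ranking devices, not literal error rates.
`sample_size = "organisms"` exposes the conservative alternative.

`rank_partners()` sorts candidates by $r$ and compares the leader against
every other candidate; a comparison with $p > 0.05$ (strict) flags a
statistical tie. The strictness shows at boundaries: the shipped Src-family
panel's leader-vs-runner-up comparison computes $p = 0.0497$, which rounds
to 0.05 but does not trip the strict flag. No multiple-testing correction
is applied across a panel, matching how such screens are conventionally
read; with 6–8 comparisons per panel, Bonferroni-minded readers can divide.

### Controls and the shared-phylogeny confound

All mirror-tree correlations are inflated by the species phylogeny common to
both families: even two functionally unrelated families produce large
$r_{AB}$ because both sets of distances grow with divergence time. The
package therefore treats control pairs as first-class: `control_banding()`
takes a positive-control correlation (a pair known to interact) and one or
more negative controls (pairs with no plausible interaction) and flags a
candidate only when its $r$ strictly exceeds every negative control. In the
shipped reference panels the negative controls reach $r = 0.9172$ — a
concrete illustration that a raw correlation above 0.9 is, by itself, not
evidence of coevolution. The same confound is reproduced in silico: the test
suite simulates two families with *uncorrelated* branch rates on one shared
tree and shows their $r_{AB}$ still far exceeds that of families evolved on
two unrelated trees.

## Conservation and kinase-context profiling

The conservation module reproduces the standard N-terminal alignment
analysis for candidate regulatory phosphosites. Positions are numbered by a
reference species (reference-gap columns are unnumbered), and a position's
conservation is the frequency of its modal non-gap residue — species gapped
at a column leave the denominator, and the gap count is reported alongside.
"Conserved" defaults to a threshold of 1.0 (every non-gapped species
agrees); class-level breakdowns (placental mammals, marsupials, reptiles,
amphibians, bony fish, cartilaginous fish, or any user grouping supplied as
a named vector or YAML file) use the same modal-fraction definition within
each class.

`kinase_context()` inspects the sequence neighbourhood of a candidate
tyrosine or serine/threonine in each species' *own ungapped coordinates* —
alignment columns would mis-measure physical proximity across indels. The
verdict rules operationalize two well-known kinase preferences without
claiming a trained predictor: Src-family tyrosine kinases favour nearby
acidic residues, so a tyrosine with at least one D/E within ±3 residues is
tagged `src-context`; protein kinase C favours basic flanks, so an S/T with
a K/R on each side, or at least two in total, within ±5 residues is tagged
`pkc-context`. Windows truncated by a sequence end are flagged rather than
padded.

## The synthetic-data generator

Real inputs to this analysis are database retrievals that cannot be
reproduced offline, so the package generates its own ground truth with the
exact statistical structure the method assumes:

* **Phylogeny** — a Yule (pure-birth) topology with exponential waiting
  times, rescaled so the mean root-to-tip path is 1.0 expected substitutions
  per site; 20–100 tips covers the common-species counts typical of such
  screens.
* **Rate heterogeneity** — each branch receives an independent lognormal
  rate multiplier $e^g$, $g \sim \mathcal N(-\sigma^2/2, \sigma^2)$, giving
  unit mean at every $\sigma$. The default $\sigma = 0.5$ produces the
  several-fold lineage rate variation familiar from real protein families.
* **Coevolution** — family B's log-rates are
  $g_B = \rho\, g_A + \sqrt{1-\rho^2}\,\varepsilon$ with $\varepsilon$
  normal and mean-shifted to keep unit-mean multipliers, so
  $\operatorname{corr}(g_A, g_B) = \rho$ by construction; $\rho = 1$ copies
  the rates exactly, $\rho = 0$ draws an independent set.
* **Sequences** — root drawn uniform over the 20 residues, evolved under the
  uniform 20-state exchange (Poisson) model using its exact finite-time
  transition probability per branch. This model was chosen over empirical
  matrices (JTT/WAG) precisely because it has a closed-form expected
  p-distance, $\mathbb E[p] = \tfrac{19}{20}\bigl(1 -
  e^{-\tfrac{20}{19} b}\bigr)$ for total path length $b$, which serves as an
  analytic oracle for the evolver. No indels and no among-site rate
  variation: the output is exactly aligned by construction, keeping external
  aligners out of the test loop.

A master seed is split into named substreams (tree, rates A, rates B,
sequences A, sequences B), so any one component can be varied while the
others stay fixed; every generator function is a pure function of its
parameters and seed.

```{r example, eval = TRUE}
pair <- make_coevolving_pair(n_species = 20, length = 800,
                             sigma = 0.5, rho = 1, seed = 11)
twin <- make_coevolving_pair(n_species = 20, length = 800,
                             sigma = 0.5, rho = 0, seed = 11)
c(coevolved = mirror_tree(pair$alignment_a, pair$alignment_b)$r_ab,
  independent_rates = mirror_tree(twin$alignment_a, twin$alignment_b)$r_ab)
```

What passing these tests shows — and does not show — about real data: the
simulator validates that the pipeline recovers correlated rate variation
when it exists and is well-calibrated under its own model. Real alignments
add indels and alignment error, among-site rate variation, non-uniform
exchangeabilities, database mislabelling, and taxon sampling that is far
from a Yule draw; none of these are emulated, and the published reference
panels are shipped as fixed inputs rather than recomputed, because the
underlying retrievals are not distributable.

## Numerical and design notes

* Triangle vectorization is strict-upper, row-major, over sorted labels —
  Pearson is order-invariant, but a fixed order makes outputs diffable.
* `pearson_r()` uses the centered two-pass form; tests pin it against an
  independent sums-based oracle and `stats::cor` to 1e-12 at length $10^4$.
* Distance-matrix text round trips are written at 17 significant digits
  (lossless for doubles); matrix reads reject asymmetry beyond 1e-9 and
  symmetrize what remains.
* Degenerate inputs fail loudly and early: ragged alignments name the
  offending record, constant distance vectors make the correlation an error
  rather than an `NA`, zero usable sites for a pair names the pair, and a
  species overlap below 5 ($n < 10$) refuses to produce a vacuous p-value.
* Problem sizes in the test suite — 20 paired replicates at 40 species ×
  2000 sites for recovery, $10^5$ sites for the analytic distance check,
  $10^5$ permutations for the Monte-Carlo check of the t-based p-value —
  were chosen so each check resolves its target to ~3 standard errors while
  the whole suite stays quick enough to run on every change.

## Limitations

The mirror-tree statistic here is the raw matrix correlation: no projection
of the underlying species-tree signal, no tree reconstruction, and no
correction for the dependence structure of distance-matrix entries. These
are the method's standard weaknesses and the reason controls and
rank-comparisons — not absolute correlations or their p-values — carry the
interpretive weight.
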