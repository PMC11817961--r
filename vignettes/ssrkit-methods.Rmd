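---
title: "Methods and design notes for ssrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ssrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrkit)
```

ssrkit implements the computational spine of an SSR marker study: mining
microsatellites from genome sequence, evaluating and virtually amplifying
primer pairs, computing diversity and identity statistics from
fragment-size genotypes, inferring admixture with an EM fit of the
admixture likelihood, and building DNA fingerprints. This vignette records
the models, the parameters that matter, and the design decisions taken
where the methodology was genuinely open.

## SSR mining

A locus is a maximal perfect tandem run of a *primitive* unit (one that is
not itself a tandem repetition of a shorter unit) of length 1–6 bp whose
count of complete units meets a per-unit-length threshold. Defaults are the
widely used MISA plant-genome setting — 10 for mononucleotides, 6 for
dinucleotides, 5 for tri- to hexanucleotides (`ssr_search_params()`).

Three conventions make the mining rule exactly testable:

* **Full units only.** A locus covers complete repeat units; a trailing
  partial unit neither extends the locus nor blocks adjacent detection, so
  `length_bp = unit_length * n_repeats` holds identically.
* **Primitivity as nested-type suppression.** A poly-A run is reported once
  at unit length 1, never again as "AA" or "AAA": any non-primitive unit is
  discarded, which is also what prevents double counting across unit
  lengths.
* **Ambiguity breaks runs.** `N` terminates runs and no locus spans one;
  lowercase input is upper-cased; any other character is a parse error that
  names its position.

The scanner works per unit length `k` on the boolean profile
`s[i] == s[i+k]`: maximal true runs are exactly the period-`k` regions, the
locus starts at the region start (leftmost alignment) and keeps
`floor(region/k)` units. The test suite checks equivalence against an
exhaustive position-by-position oracle on random sequence (15–20 kb per
seed, all unit lengths) — chosen large enough to contain dozens of loci yet
keep the quadratic oracle affordable.

Motifs are grouped under cyclic rotation plus reverse complementation; the
class representative is the lexicographic minimum over both orbit halves,
which reproduces the conventional A/T, AG/CT, AAG/CTT, AGAT/ATCT labels.
Brute-force enumeration over all `4^k` strings gives 2, 4, 10, 33, 102 and
350 classes for k = 1..6. A finite genome need not realise every class for
k ≥ 5, so observed class counts in any scan are a subset of these.

Length classes use an inclusive middle band — III below 20 nt, II from 20
to 30 nt inclusive, I above 30 nt — because the conventional "< 20" and
"> 30" boundaries force both endpoints into class II.

Compound SSRs (neighbours separated by at most 100 intervening bases, the
common "minimum spacing" convention) are *annotated*, not removed: summary
totals count loci individually, and callers who want spacing-filtered panels
can drop annotated rows (`--exclude-compound` in the CLI). Window densities
assign each locus to the window containing its start; with 100-kb windows
and loci of tens of bases the choice is immaterial but deterministic.
Degenerate inputs are kept composable: an empty locus table summarises to
zeros (mean length 0 rather than NaN) instead of erroring.

## Primer evaluation and in-silico PCR

`check_primer_pair()` evaluates length, GC, melting temperature, Tm
difference and product size against windows of 18–27 bp, 40–60 %,
55–65 °C, < 3 °C and 100–280 bp, and reports *every* violated criterion
rather than failing fast. M13 universal tails (TGTAAAACGACGGCCAGT) are
synthesis metadata: they are stripped before any computation.

Two Tm estimators are provided. The Wallace rule `2(A+T) + 4(G+C)` is
hand-checkable and used in tests. The default is nearest-neighbour
thermodynamics with the Allawi & SantaLucia 1997 unified parameter table,
terminal initiation terms, and the entropy salt correction
`ΔS += 0.368 (N−1) ln[Na+]`, at 50 mM monovalent salt and 250 nM total
strand — standard PCR-primer conditions. The test suite freezes values from
an independent implementation of the same parameter table.

Virtual PCR reports every site where the forward primer matches one strand
and the reverse primer matches the opposite strand in convergent
orientation, binding sites non-overlapping, product at most `max_product`
(default 5000 bp). Matching is exact by default — the reproducible choice
when the original electronic-PCR settings are unknown — and when mismatches
are allowed the 3′-terminal three bases of each primer must still match
exactly, mirroring the polymerase-extension requirement. Hit counts
classify markers: 0 = null, 1 = monomorphic (single locus),
≥ 2 = polymorphic (multiple loci).

## Diversity and identity statistics

Genotype tables are long tibbles of up to four recorded fragment sizes per
individual and locus. All statistics use a *diploid view* — the first two
recorded sizes, one size meaning a homozygote — because Ho/He/PIC presuppose
diploid scoring even in polyploids genotyped by fragment size; all four
recorded sizes are used only by the bin fingerprint encoding.

With allele frequencies `p` at a locus (two draws per non-missing
individual):

* `Na = |{p > 0}|`, `Ne = 1/Σp²`, `He = 1 − Σp²` (Nei gene diversity,
  no small-sample correction, matching PowerMarker-style reporting; an
  unbiased multiplier `2n/(2n−1)` is available as a toggle),
* `I = −Σ p ln p`, `PIC = 1 − Σp² − (Σp²)² + Σp⁴`
  (algebraically equal to the textbook double sum `1 − Σp² − Σ_{i<j} 2p_i²p_j²`),
* `PI = 2(Σp²)² − Σp⁴` and
  `PIsibs = 0.25 + 0.5Σp² + 0.5(Σp²)² − 0.25Σp⁴`.

Panel summaries are unweighted arithmetic means over loci. Cumulative PI
products run over loci sorted by ascending PI — most informative first, the
order used in "increasing marker combinations" plots — and the input order
is available as an option.

Similarity uses band presence/absence: each locus-allele is a band, a pair
of individuals is compared over the bands of loci typed in both, and either
simple matching `(a+d)/(a+b+c+d)` or Dice `2a/(2a+b+c)` is returned.
Which coefficient a given legacy study used is often unstated, so both are
first-class and neither is claimed to reproduce any particular published
mean. Genetic distance is `1 − GS`.

The Mantel test correlates lower triangles, permutes one matrix's order,
and reports the one-sided upper p-value with the `+1` correction,
`p = (1 + #{r* ≥ r}) / (n_perm + 1)`, 9999 permutations by default, seeded
explicitly. Geographic distances are haversine on a 6371-km sphere — the
usual choice when a study does not state its metric.

PCoA applies Gower centering to `−D²/2` and eigendecomposes. Axes with
positive eigenvalues are kept; percent variance divides by the sum of
positive eigenvalues only (a Lingoes correction flag exists for strongly
non-Euclidean matrices). Axis signs — arbitrary in any eigendecomposition —
are fixed by making the largest-magnitude score on each axis positive.

Trees: fragment-size data do not admit a defensible likelihood model for
phylogenetic ML, so the package builds UPGMA (average linkage) and
neighbour-joining trees from `1 − GS` distances instead; this is an
explicit methodological substitution, documented here. Ties are made
deterministic by pre-sorting labels lexicographically.

## Admixture EM and Evanno ΔK

The model is the standard admixture likelihood: allele copy `c` of
individual `i` at locus `l` comes from cluster `k` with probability
`q_ik`, then is allele `a` with probability `f_kl(a)`;
`L = Σ_{i,l,c} log Σ_k q_ik f_kl(a)`. Rather than MCMC sampling — which is
slow and non-deterministic at desk scale — the likelihood is maximised by
EM: responsibilities per allele copy, then closed-form updates of `Q` and
`F`. EM guarantees a non-decreasing log-likelihood, which the tests assert
at every iteration. Missing copies simply drop out of the sums. Defaults:
convergence when the log-likelihood improves by less than `1e-6`, at most
2000 iterations, 5 random restarts (Dirichlet-ish random initialisation)
keeping the best optimum. `K = 1` is solved in closed form.

Label switching is handled at comparison time: `match_clusters()` finds the
column permutation minimising mean absolute difference (exhaustively for
K ≤ 8).

`lnp_replicates()` records the maximised log-likelihood per (K, replicate)
with derived seeds. This is *not* the harmonic-mean marginal-likelihood
estimate that MCMC software prints; the Evanno statistic only needs a
consistent per-K score with replicate spread, which a maximised likelihood
under random restarts provides. `evanno()` computes replicate-wise second
differences: `ΔK = mean |L(K+1) − 2L(K) + L(K−1)| / sd(L(K))`, defined only
for interior K with positive replicate spread (a zero sd raises an error
advising more replicates); ties in the argmax break toward smaller K for
parsimony, and an everywhere-zero ΔK (exactly linear LnP) yields no flagged
optimum rather than an arbitrary one.

## Fingerprint encodings

Two encodings are implemented. The zygosity code writes one digit per
locus: 9 missing, 0 heterozygous, 1 homozygous — the reading convention of
silver-stained gels. The bin code cuts each locus's fragment-size range
into 10-bp bins numbered 1–9, anchored at the minimum observed size per
locus (an explicit anchor can be supplied; anchoring at the observed
minimum is the only self-contained reading when amplification ranges are
not published), with overflow folding into bin 9 and missing records coded
0. Each locus contributes exactly four digits — the four possible recorded
fragment sizes in an allotetraploid — in ascending size order, padded with
0; fixed widths make codes comparable across individuals by construction.

`min_discriminating_set()` reduces a panel: greedy adds the locus that
maximally increases the number of distinct code groups (ties by panel
order); exhaustive searches subset sizes breadth-first and is restricted to
12 loci, past which the subset lattice is too large. The greedy result is
always verified to discriminate; the exhaustive result is provably minimal
and serves as the optimality oracle in tests. A panel that cannot
distinguish some pair even in full raises an error listing the irreducible
groups rather than looping.

## What the simulators emulate — and what they do not

`simulate_genome()` builds i.i.d. background at 46 % GC (a typical grass
genome), scrubbed of accidental above-threshold SSRs by a bounded
rejection loop, then plants SSRs at a default density of 124 loci/Mb with
motif-length weights 43.3/35.1/20.2/0.9/0.2/0.3 % and repeat counts a few
units above threshold — the aggregate profile of a large temperate-grass
genome scan at desk scale (two 100-kb chromosomes by default). Planted
positions can be biased toward chromosome ends (`end_bias`, density
`∝ 1 + bias · proximity`), reproducing the telomeric enrichment seen in
real chromosomes. Flanking bases are chosen so a planted run cannot extend
leftward by a full period, and a final verification re-mines every
chromosome and re-scrubs until the miner reproduces the truth table
exactly; the tests assert perfect precision and recall. The background is
*not* a realistic genome: no genes, no GC isochores, no interrupted or
compound repeat structure unless requested.

`simulate_panel()` emulates a germplasm diversity panel: by default 105
individuals, 20 loci, K = 4 ancestral clusters. Cluster allele-frequency
profiles are Dirichlet(0.3) over a 25-allele ladder (base size uniform in
100–240 bp, 2-bp steps — dinucleotide markers sized on capillary
electrophoresis); admixture rows are Dirichlet(0.2), so most individuals
are dominated by one cluster with visible admixture; genotypes go missing
completely at random at 2 %. These defaults give panels whose mean He and
PIC (≈ 0.9) and allele counts sit in the range reported for highly
polymorphic outcrossing grasses. With isolation by distance on,
individuals sit near their dominant cluster's geographic centre (1° noise
over a 40–50° N, 105–125° E window), which produces a positive Mantel
correlation; the generator does not model continuous clines, stepwise
mutation, linkage or selection, so passing tests demonstrate algorithmic
correctness, not realism of any particular biological inference.

## Numerical choices and limitations

* Frequencies are exact rational tallies; no pseudo-counts are added.
  Cluster frequency estimates in EM can reach 0 for alleles absent from a
  cluster; the log-likelihood stays finite because responsibilities vanish
  with them, and the M-step guards division by an effectively zero column
  mass.
* All randomised routines (Mantel, simulators, EM initialisation,
  replicate grids) take explicit integer seeds and derive per-task seeds
  deterministically; nothing depends on ambient RNG state.
* Problem sizes in the test suite — 15–50 kb oracle sequences, panels of
  30–150 individuals, EM at K ≤ 3 with 20 loci — were chosen so the whole
  suite runs in about a minute while still exercising every code path at
  sizes where the statistics are stable.
* Known limitations: no interrupted/imperfect SSR model; no primer
  *design* (candidate generation is delegated to external tools — the
  package verifies and classifies); no thermodynamic dimer/hairpin
  screening; EM fits the uncorrelated-frequencies admixture model only;
  exhaustive marker-subset search caps at 12 loci.
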