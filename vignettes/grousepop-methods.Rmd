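---
title: "Methods: conservation-genetic assessment of captive and reintroduced grouse populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation-genetic assessment of captive and reintroduced grouse populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`grousepop` implements the analysis chain used to assess a captive grouse
breeding flock and the wild population reintroduced from it: non-invasive
genotype consolidation, per-locus microsatellite diversity statistics, a
sex-linkage screen, admixture-model clustering with Evanno ΔK model
choice, and mitochondrial control-region diversity. This vignette is the
package's account of the underlying models, the parameters that matter,
and the design choices taken where the methodology left room.

## The study design the package targets

Two populations are analysed together. A captive breeding flock is typed
from blood samples: wild-born founders drawn from two source lineages
(one of which is internally substructured, so three genetic clusters in
total) plus flock-born offspring. The reintroduced wild population is
known only through faecal (non-invasive) samples: low-quantity DNA typed
in replicate, with redundant samples of the same birds. Birds are ZZ/ZW:
males are the homogametic sex, so a microsatellite that happens to sit on
the Z chromosome is an ordinary diploid locus in males but hemizygous in
females — and fragment-analysis software records a female's single allele
as a *homozygous diploid call*. That scoring artefact, invisible without
sex metadata, is one of the package's central concerns.

## Synthetic data generator

Every stage is validated against `simulate_individuals()` /
`simulate_noninvasive_replicates()`, which emulate exactly this design.

* **Cluster divergence.** Ancestral per-locus allele frequencies are
  drawn flat-Dirichlet over each locus alphabet; each cluster's
  frequencies are drawn from the F-model, `Dirichlet(p · (1−F)/F)`, so
  the mean stays ancestral and `F` (default 0.15 per cluster) controls
  divergence.
* **Genotypes.** Each gene copy picks a cluster by the individual's
  membership proportions, then an allele from that cluster's frequencies;
  admixed individuals therefore mix *within* a genotype, matching the
  admixture clustering model's own assumption. At Z-linked loci (default:
  loci 1–2 of 9) males receive two copies, females one, recorded as a
  homozygous call; the truth object keeps the hemizygosity flag.
* **Populations.** Defaults mirror the study shape: captive 42 (sex ratio
  1:2.2 male:female, i.e. male proportion 1/3.2) and wild 62 individuals
  observed through 81 faecal field samples genotyped twice. The wild sex
  ratio is not known in the field; it is a free parameter defaulting
  to 0.5. Hybrid fractions default to 0.12 (captive) and 0.16 (wild),
  implemented as 50/50 two-cluster memberships.
* **Faecal noise.** Per replicate and locus: a true heterozygote loses a
  random allele with probability `dropout_rate` (default 0.07); each
  surviving allele is replaced by a random other allele with
  `false_allele_rate` (default 0, the blood-benchmarked value); the whole
  call goes missing with `missing_rate` (default 0.1, a realistic faecal
  per-locus failure). Dropout is modelled per heterozygous genotype, not
  per allele size class, because a single rate is what replicate
  comparisons can estimate.
* **mtDNA.** Haplotypes are drawn from per-population pools (default:
  nine haplotypes, four shared, three captive-only, two wild-only);
  offspring inherit their mother's haplotype in the packaged fixture.
* **Reproducibility.** One global seed feeds fixed substreams
  (`seed + 1000003·k mod 2³¹−19` per component), so adding a component
  does not perturb earlier draws, and equal seeds give bit-identical
  outputs.

What the generator does *not* emulate: multi-generation pedigrees,
mutation, allele-size homoplasy, size-biased dropout, spatial structure,
and real cross-contamination patterns. Tests passing on generator output
therefore demonstrate estimator correctness under the stated model, not
robustness to every pathology of real faecal data.

## Non-invasive QC

* **Completeness filter:** a sample passes with ≥ `min_loci` (default 7
  of 9) typed loci.
* **Probability of identity.** Per locus, unrelated:
  \(P_{ID} = \sum_i p_i^4 + \sum_{i<j}(2p_ip_j)^2\); full siblings:
  \(0.25 + 0.5\sum p_i^2 + 0.5(\sum p_i^2)^2 - 0.25\sum p_i^4\);
  multilocus products across loci. These justify collapsing identical
  genotypes into one individual.
* **Matching** is exact by default (`max_mismatch = 0`); loci missing in
  either sample are not comparisons (the completeness filter bounds the
  information loss). Groups are connected components; each is checked for
  shared mtDNA haplotype and locality as corroboration. A
  dropout-tolerant mode (`max_mismatch = 1`) exists, off by default.
* **Consensus:** an allele is confirmed by ≥ 2 replicates (or the sole
  replicate, flagged low-confidence). The two-replicate `{AB} vs {AA}`
  tie resolves to the heterozygote because dropout, not false alleles,
  dominates faecal error; with ≥ 3 replicates singleton alleles are
  demoted. Conflicting singletons leave the locus missing.
* **Error rates** are defined per replicate observation against the
  consensus: dropout = share of observations of consensus-heterozygous
  loci showing exactly one consensus allele; false-allele = share of all
  observations containing an allele absent from the consensus. Means are
  unweighted over loci, and an undefined rate (no heterozygous consensus)
  is reported `NA`, never silently 0.

## Per-locus diversity statistics

For each locus and population: allele number, observed heterozygosity,
unbiased expected heterozygosity
\(H_E = \frac{2n}{2n-1}(1-\sum p_i^2)\), and \(F_{IS} = 1 - H_O/H_E\)
(Nei's form; the simple ratio is what classic microsatellite toolkits
report, and a Weir–Cockerham variant would change only the estimator, not
the diagnostics built on it).

**Exact Hardy–Weinberg test.** Conditional on allele counts, a genotype
table has probability
\(P = n!\,\prod_a m_a!\,2^h / \big((2n)!\,\prod_g n_g!\big)\); the
p-value sums \(P\) over tables no more probable than the observed one.
Tables are enumerated completely up to 10⁶ tables (a compiled recursion;
equality of probabilities is compared with a relative tolerance of 1e−9
on the log scale); beyond that the null is sampled by randomly re-pairing
the 2n gene copies (10⁵ tables, add-one p-value, seeded). Monomorphic
loci return p = 1 by convention, flagged.

**Null-allele frequency** is the ML fit of the standard one-null-allele
model (visible homozygote \(p_i^2 + 2p_ir\), heterozygote \(2p_ip_j\),
blank \(\beta + (1-\beta)r^2\)) by EM (tolerance 1e−10 on `r`, cap 5000
iterations). By default the non-genetic failure rate β is estimated
jointly, which makes the blank class uninformative about `r` and drives
the estimate from homozygote excess — otherwise every technical dropout
would masquerade as a null homozygote. Fixing `beta = 0` recovers the
strict blank-scored variant. A caveat surfaced by the sex-linkage work:
an all-homozygote table (e.g. hemizygous females) is best explained by
`r → 1`; that degenerate value is itself a diagnostic.

**Multiple testing** uses Benjamini–Hochberg at `q = 0.05` across the
loci of one population table.

## Sex-linkage screen

Statistics are recomputed on male-only and female-only sub-tables. A
locus is flagged Z-linked when the female sub-table shows observed
heterozygosity ≤ ε (default 1e−9 — exact scoring makes female
heterozygotes impossible) while female expected heterozygosity is ≥ 0.3
and male NAF is ≤ 0.1 (males must look like a clean diploid locus,
ruling out a true null allele, which would depress both sexes). The
`h_min` floor denies power claims at near-monomorphic loci. Thresholds
are configurable; the defaults formalise the observed diagnostic pattern
(female H_E around 0.69 with H_O = 0; male NAF below 0.1). The
heterogametic convention defaults to ZW females and can be flipped for
XY systems. Two honest limitations: with few males (the captive flock
has ~13) a Wahlund-structured flock can push male NAF above 0.1 and cost
sensitivity — perfect recovery is only promised at ≥ 100 birds per sex
and locus heterozygosity ≥ 0.3 — and a near-monomorphic Z locus is
undetectable by design. Flagged loci are excluded from the starred
averages and from clustering input.

## Admixture clustering and model choice

The Gibbs sampler implements the admixture model with uncorrelated
cluster frequencies: gene-copy origins, cluster frequencies `P`
(Dirichlet prior, λ = 1) and memberships `Q` (Dirichlet prior, α) are
updated from conjugate conditionals; missing calls are skipped; `Q` and
`P` are reported as post-burn-in means. Desk-scale chain defaults are
2,000 burn-in + 8,000 sweeps (production studies run orders of magnitude
longer; both are plain parameters). Chains start `P` at Dirichlet-jittered
empirical allele frequencies: over-dispersed prior starts can strand
short replicate chains in different modes, inflating the replicate
spread that ΔK divides by. The correlated-frequencies model and
sampling-location priors are deliberately omitted: at the simulated
divergence levels they add hierarchy without changing what the scan must
deliver.

`L(K)` is estimated as mean − var/2 of the log-likelihood trace, and
\(\Delta K(k) = |\bar L(k+1) - 2\bar L(k) + \bar L(k-1)| / \mathrm{sd}\,L(k)\)
over replicate runs; the chosen K is the interior arg-max (ties to the
smaller K, with a warning; zero spread excludes a K; fewer than three
consecutive K values fall back to max mean `L(K)`).

Two α values appear deliberately. `gibbs_admixture()` keeps a flat fixed
α = 1 (no α updating — simpler, and adequate for single runs). The scan
`run_structure_scan()` defaults to α = 0.1: reference tools infer α from
the data and land near small values for distinct populations, and with a
flat prior the posterior-mean memberships of pure individuals saturate
around 0.85–0.9 at nine loci, which depresses the evidence gain at the
true K and biases ΔK toward smaller K. Label switching across replicate
runs is undone by exact permutation search (K ≤ 8; greedy above) against
an incrementally built consensus; individuals are assigned to a cluster
at membership ≥ 0.8 (the community convention — studies rarely print
their cutoff) and called hybrids below it. Recorded lineages are checked
against genetic clusters by mapping each cluster to its modal lineage, so
a lineage may legitimately span several clusters.

A known property worth restating: when the drift realisation is
hierarchical (one cluster pair much farther apart than the other), ΔK
prefers the top-level split — choosing K = 2 on three-cluster data — and
no amount of chain length changes that; it is a property of the
statistic, not a convergence failure.

## mtDNA diversity

Alignment columns carrying a gap or ambiguity in any sequence are
excluded alignment-wide (complete deletion, the classic toolkit default;
a pairwise-deletion option exists). Haplotypes are equivalence classes of
exact identity on included sites, labelled deterministically by
frequency then first occurrence. Haplotype diversity uses the unbiased
\(H_D = \frac{n}{n-1}(1-\sum p_i^2)\); nucleotide diversity is the mean
per-site pairwise difference; polymorphic sites are included sites with
≥ 2 states. Standard errors of `H_D`/`N_D` are not computed. Only
founders are expected to be sequenced in the captive population;
offspring share their mother's haplotype and the fixture propagates it
through its one-generation pedigree.

## Problem sizes used by the tests

The suite validates at sizes chosen to make Monte-Carlo tolerances
honest while staying desk-scale: parameter-recovery runs use 500–2,000
individuals or 1,000+ replicate observations; the clustering acceptance
check uses three populations of 30 at nine loci with K = 1..6 × 5
replicate chains of 2,000 + 8,000 sweeps; the full-pipeline smoke test
runs a reduced K range. `scripts/acceptance.R` re-runs the three
headline checks from scratch under a caller-supplied seed.

## Known limitations

Beyond the generator's idealisations listed above: the exact-test
enumeration bound makes large multi-allelic tables fall back to Monte
Carlo; the null-allele model assumes a single null allele and HWE within
the (possibly structured) table it is given; the clustering scan fixes α
rather than inferring it; and the lineage-concordance mapping needs each
cluster to have a modal lineage, which degenerates if priors are few.
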