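---
title: "Methods: population structure and connectivity inference in kelpconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure and connectivity inference in kelpconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpconn)
```

# Scope and data model

`kelpconn` implements an inference chain for population connectivity in a
kelp (sea belt) system sampled at roughly nine northwest-European
locations with two marker types: a 623 bp haploid mitochondrial COI
fragment (a `HaplotypeAlignment`, collapsed to a per-population
`HaplotypeFreqTable`) and a panel of ten diploid microsatellite loci
(a `GenotypeMatrix` of integer allele sizes with `NA` as the single
missing-data token). All downstream statistics operate on these two
containers, so field data and the package's own simulations flow through
identical code paths.

# Diversity statistics

Haplotype (gene) diversity uses the unbiased estimator
$h = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$ with Nei's sampling
variance
$V(h) = \frac{2}{n(n-1)}\Bigl\{2(n-2)\bigl[\sum p^3 - (\sum p^2)^2\bigr] +
\sum p^2 - (\sum p^2)^2\Bigr\}$.
Nucleotide diversity per site is
$\pi = \frac{n}{n-1} \sum_{i<j} 2 p_i p_j d_{ij} / L$ with $d_{ij}$ the
substitution count between haplotypes and $L$ the locus length; its
standard error combines Nei's stochastic and sampling terms
$V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2$.
For a sample of three sequences carrying two haplotypes (counts
necessarily $\{2,1\}$) these give $h = 0.6667 \pm 0.3143$; the estimators
reproduce the published diversity table of the study system at all four
printed decimals. Distances exclude unresolved characters (N, -)
pairwise; two sequences are distinct haplotypes only if they differ at a
mutually resolved site.

# Minimum spanning network

The haplotype network is a minimum spanning tree over observed
haplotypes weighted by substitution steps, built with Kruskal's
algorithm under a deterministic tie-break (weight, then lexicographic
label pair). Non-tree edges whose weight equals the largest weight on
the tree path between their endpoints are reported as `alternativeEdges`
— equally optimal links that a different tie-break would have chosen —
rather than resolved arbitrarily. Exhaustive enumeration over all
spanning trees of small instances backs the construction in the test
suite.

# AMOVA

Variance components follow the standard distance-based
sums-of-squared-deviations decomposition (method of moments). For
haplotypic data the analysis is two-level (among/within populations)
with squared distances taken as pairwise substitution counts, giving
$\Phi_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)$. For diploid
microsatellites it is three-level (among populations / among individuals
within populations / within individuals) on 0/1 allele mismatches,
summed over loci with per-locus handling of missing individuals;
$F_{ST}$, $F_{IS}$ and $F_{IT}$ are the usual component ratios, and the
identity $(1-F_{IT}) = (1-F_{IS})(1-F_{ST})$ holds by construction.
Negative component estimates are retained, not truncated, matching
common practice in distance-based AMOVA software.

Permutation tests use the schemes appropriate to each index (individuals
among populations for $F_{ST}$ and $\Phi_{ST}$; allele copies among
individuals within populations for $F_{IS}$; allele copies globally for
$F_{IT}$), with the $+1$-corrected p-value
$p = (\#\{\text{permuted} \ge \text{observed}\} + 1)/(B + 1)$ and a
default of $B = 9999$. Because the statistic depends on the data only
through count configurations, permutation ties make $p$ slightly
conservative on very small, few-haplotype samples; the uniformity test
in the suite therefore uses samples large enough (60 per population, ten
haplotype classes, generic distances) that ties are rare. Pairwise
analyses are run independently per population pair and use a Bonferroni
threshold of $\alpha$ divided by the number of pairs. Principal
coordinates analysis is classical scaling (`stats::cmdscale`) of the
squared-allele-mismatch individual distance; negative eigenvalues are
dropped from coordinates and reported separately.

# Structured-coalescent simulator

The isolation-with-migration simulator (C++ core) runs a structured
coalescent backward in time for any number of extant demes: within-deme
coalescence at rate $\binom{k}{2}/(2N)$ per generation for nuclear loci
and $\binom{k}{2}/N$ for the haploid organelle locus (the organelle
effective size is taken equal to $N$ — the study system does not resolve
a separate maternal effective size); backward migration of a lineage in
deme $i$ to deme $j$ at rate $m_{ji} N_j / N_i$, where the user-facing
parameters are forward-in-time migration fractions; and a merge of all
demes into a single ancestral pool of size $N_{anc}$ at the split time.
Sequence mutations are finite-sites Jukes–Cantor (Poisson on branches,
uniform site choice); with at most a handful of variable sites per 623 bp
at study scale the substitution model is immaterial. Microsatellites
follow an unbounded single-step model at a default rate of 0.001564 per
locus per generation, the cross-taxon average used for kelp; one locus
can carry a rate multiplier (default 10×) to emulate the panel's single
hypervariable marker. Generation time defaults to one year so years and
generations coincide; all randomness flows through R's RNG, so results
are bit-reproducible under `set.seed()`.

Calibration checks: a single population's mean pairwise sequence
difference matches $\theta = 2N\mu$ within Monte-Carlo error over 1,000
replicate loci; a symmetric two-deme system run far beyond its
equilibration time agrees with the forward island simulator.

# Forward island model and the approach to equilibrium

`simulateIslandForward()` is a biallelic Wright–Fisher island model
($d$ demes of $N$ diploids, symmetric mutation to keep variation
segregating) started from identical copies of a founding population so
that $F_{ST}(0)=0$. Its `m` is the immigration fraction from *other*
demes (migrant pool excluding self), the convention under which the
equilibrium expectation $F_{ST} \approx 1/(1 + 4Nm(d/(d-1))^2)$ holds
for the multi-locus ratio-of-sums estimator $1 - \sum H_S / \sum H_T$
used on the trajectory. The equilibrium estimate is the final-quarter
mean; the run is flagged unresolved when the third- and fourth-quarter
means still differ by more than 10% of the tail mean (a still-rising
ramp differs by ~29%, a plateau only by Monte-Carlo noise). The observed
half-time — the first generation at which the smoothed trajectory
reaches half the equilibrium estimate — matches the theoretical
$\ln 2/(2m + 1/(2N_e))$ within a few percent at $N=100$, $m=0.005$,
$d=10$.

# ABC inference of IM parameters

Demographic parameters are inferred by rejection ABC: draw from uniform
priors (aggregate priors `N`, `m`, `M = 2Nm` keep the dimension low when
symmetry is assumed), simulate, summarize, and accept the smallest
`toleranceQuantile` fraction by Euclidean distance on summaries
standardized by their median absolute deviation over the simulation
pool. Summaries per population are the haplotype count, haplotype
diversity and nucleotide diversity (sequence locus) and the mean allele
count, expected heterozygosity and allele-size variance over loci
(microsatellites); between populations they are the shared-haplotype
count, $\Phi_{ST}$, $F_{ST}$, Goldstein's $(\delta\mu)^2$ and the mean
shared-allele count. Summaries with zero variance across the pool are
dropped with a warning; when none remain (e.g. zero mutation rates) the
acceptance set is a plain prior sample, so the posterior correctly
collapses to the prior. Point estimates are marginal weighted-KDE modes
(Epanechnikov weights in distance); intervals are 90% highest-density
intervals of the accepted draws; an optional local-linear regression
adjustment is available but off by default. A fast C++ path computes the
same summaries inside the ABC loop; a test asserts bit-level agreement
with the R-level `summarizeDataset()`.

In a recovery experiment at study-like scale (8 microsatellite loci, 15
diploids per population, true $N=50$, $T=500$ generations, $M=0.5$,
20,000 simulations, 1% acceptance), the true $N$, $T$ and $M$ fall
inside their 90% HPD intervals in well over 80% of repetitions.

A known limitation, documented deliberately: from summary statistics a
*young split with no migration* is nearly indistinguishable from an *old
split at migration–drift equilibrium* — the two regimes produce matching
summary vectors once the equilibrium deme size is adjusted, and the
equilibrium ridge in $(T, M)$ carries most of the prior volume. The
marginal posterior mode of $M$ therefore tends to the ridge value, which
by construction equals the island-model inversion of the same $F_{ST}$.
Full-genealogy samplers exploit allele-configuration information that
these summaries do not carry and can separate the regimes; summary-based
ABC at this scale cannot, so the package's end-to-end reproduction of
the "all pairs below unity" signature is only partial (most, not all,
young-split pairs fall below the line). The converse diagnostic is
robust and tested: for young splits the island-model inversion
overestimates the *true* migrant numbers by an order of magnitude, while
data simulated at equilibrium cluster on the line of unity.

# Molecular-clock arithmetic and demographic scaling

A calibration point is a pairwise p-distance between two reference taxa
and a divergence-time window. The pairwise divergence rate is
$100\,p/t$ percent per million years; halving it (two lineages
accumulate the divergence) and multiplying by the locus length gives the
per-lineage locus substitution rate, e.g. $7.13\times10^{-7}$ and
$2.98\times10^{-6}$ substitutions per year per 623 bp locus for the two
calibrations of the study system, with their midpoint
$1.85\times10^{-6}$ used as the working clock. Scaled coalescent
parameters convert to demographic units via
$N = \theta/(2\mu_g)$ (haploid locus) or $\theta/(4\mu_g)$ (diploid),
$T_{\text{years}} = \tau/\mu_{\text{yr}}$ and $m = m^{*}\mu_g$; the
conversion round-trips exactly and reproduces the published magnitudes
(e.g. $\theta = 0.001$ at the mean clock gives $N \approx 270$;
$\tau = 0.322$ gives $T \approx 1.74\times10^{5}$ years).

# Equilibrium versus nonequilibrium connectivity

For every population pair, the equilibrium estimate inverts Wright's
island model, $Nm = (1-F_{ST})/(4F_{ST})$ (a finite-deme corrected
variant dividing by $(d/(d-1))^2$ is available behind `nDemes`), and the
nonequilibrium estimate is the mean of the two directional coalescent
migration estimates $(M_{a\to b}+M_{b\to a})/2$. The comparison reports
the Pearson correlation of the untransformed estimates with the
two-tailed p-value from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ (on 21 pairs,
$r = 0.5129$ gives $p = 0.0174$, matching the published pair), the
fraction of pairs whose coalescent estimate falls below the equilibrium
one, and the least-squares line for the scatter plot with its dashed
line of unity. Correlation on raw values is the default; since Pearson
$r$ is affine-invariant (tested), the choice of $Nm$ versus $2Nm$ units
does not affect it. The published per-pair coalescent estimates for the
21 intra-European comparisons ship in
`inst/extdata/im_pair_estimates.tsv`.

# Synthetic study-shaped data

`studyDesign()` mirrors the study's sampling layout: nine populations
with the published per-population sample sizes (191 sequences, 213
genotyped individuals), ten microsatellite loci with one hypervariable
marker, and per-population selfing probabilities. Its demography is a
nine-deme radiation from a common ancestral pool with near-zero
migration, calibrated once to the study's structure regime: deme size
$N = N_{anc} = 700$, $m = 10^{-6}$, and a split
$T = 6/(d\mu) \approx 3.6\times10^{5}$ generations placing about six
expected mutations on the deme branches of the sequence locus. Across
seeds this yields overall $\Phi_{ST} \approx 0.95$, microsatellite
$F_{ST} \approx 0.27$ and overall $F_{IS} \approx 0.11$ — the study's
regime of strong mitochondrial structure with moderate nuclear
differentiation and positive inbreeding.

Inbreeding is modeled as partial selfing at diploid formation: a selfed
individual's two gene copies are identical by descent with probability
1/2 independently per locus, so a single generation of selfing at
probability $s$ gives $F_{IS} \approx s/2$; the per-population defaults
are twice the published inbreeding coefficients (zero where those are
negative). What the generator deliberately does *not* emulate: the exact
published haplotype frequencies (supplementary-only data) and the exact
allele-count spectrum — a single-demography model with this divergence
depth yields 3–4 sequence haplotypes rather than seven, and more
microsatellite alleles per locus than the published 2–7, because the
published panel's allele counts reflect ascertainment during marker
development. The deterministic `fixtureHaplotypes()` object carries the
exact seven-haplotype, six-variable-site shape with a known
six-edge network for tests that need it. Passing tests on generated data
therefore demonstrate correctness of the estimators under a realistic
divergence/inbreeding regime, not a reproduction of the study's exact
marker panel.

# Pipeline

`runFullAnalysis()` orchestrates the full chain (diversity table,
network, AMOVA and Bonferroni-corrected pairwise structure, PCoA,
per-pair ABC-IM, equilibrium comparison) from a `runConfig()` or a YAML
file, writing plain-text artifacts and a JSON run log that records the
seed. Populations whose smallest marker sample size falls below `minN`
(default 4, the study's handling of its three-individual sample) are
excluded from all structure analyses but kept in the diversity table.
Per-pair IM analyses are pairwise only — no joint population tree is
assumed. Default pipeline ABC settings (2,000 simulations per pair) are
sized for interactive use; raise `abc$nSims` toward $2\times10^{4}$ for
final analyses. This package is a library: the exported functions and
configuration files are the operational interface, and no shell
executable is installed.

# Numerical and testing choices

Problem sizes in the test suite are chosen to keep the default run
within minutes while leaving Monte-Carlo slack around every stochastic
assertion: 1,000 replicate loci for the $\theta$ calibration (relative
standard error ~2%), four or five replicate forward runs for
equilibrium and half-time checks, 20 ABC repetitions at 20,000
simulations for recovery coverage, and 200 null datasets at 199
permutations for p-value uniformity. Degenerate inputs follow explicit
contracts: monomorphic data flag indices as undefined rather than
erroring, zero-information summaries reduce ABC to prior sampling, and
too-short forward runs flag the half-time as unresolved.
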