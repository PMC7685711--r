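---
title: "Methods: titer-associated viral types, from synthetic cohorts to evolutionary simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: titer-associated viral types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtype)
```

## The system

A large double-stranded DNA virus (a nudivirus) infecting wild *Drosophila*
segregates for two multilocus genotypes distinguished by eleven tightly
linked SNPs spread across its ~155 kbp genome. Hosts infected by the
complete "High" genotype carry roughly 100-fold more viral genome copies
per host genome than hosts infected by the complete "Low" genotype, with
intermediate allele counts giving intermediate titers and clearly
diminishing gains per additional allele. The type segregates within each of
several isolated host populations, and population-private background
variation shared between the two types indicates that the High type arose
recurrently on local genetic backgrounds rather than spreading by
migration.

`virtype` implements the quantitative machinery this kind of study needs,
end to end and testable without any sequencing data:

1. a seeded synthetic cohort generator with the sampling design, linkage
   structure, and titer model above;
2. a per-SNP titer association scan with permutation-based genome-wide
   significance and a haplotype permutation test;
3. linkage disequilibrium, four-gamete recombination screening, multilocus
   haplotype typing, coinfection screening, and background-SNP
   partitioning;
4. polarized McDonald-Kreitman counts, the Direction of Selection
   statistic, and contrasts against the genomic background;
5. a discrete susceptible-infected (SI) evolutionary simulator in which
   viral titer scales transmission, virulence and mutation supply; and
6. closed-form selection-coefficient arithmetic for sweep timing.

## The titer model of the generator

Let $K$ be the number of focal loci (default 11) and $k$ the number of
derived focal alleles a sample carries. Mean log10 titer is

$$\mu(k) = \mu_{\mathrm{low}} + \log_{10}(F)\,\frac{1-\lambda^k}{1-\lambda^K},$$

with full fold difference $F = 100$, saturation rate $\lambda = 0.7$, and
$\mu_{\mathrm{low}} = 3$ (log10 genome copies per host genome). Titers are
drawn Normal$(\mu(k), \sigma)$ with $\sigma = 0.4$. This geometric
saturation was chosen because the observed shape is monotone with
decaying increments and the formula hits the 100-fold difference exactly at
$k = K$; the study reports the shape but no functional form. At these
values an almost-complete genotype ($k = 10$) already reaches
$\mu = 4.98$, so intermediates close to High have near-High titers — a
property worth keeping in mind when interpreting classification-based
contrasts.

The default cohort reproduces the survey design: four populations of
57/92/92/92 flies with infection rates 26/44/71/79%, High-type frequencies
increasing along the same gradient (0.30/0.45/0.70/0.75; the study shows
type frequency tracking infection rate but prints no per-population
values), and 1403 viral loci in total: the 11 focal SNPs (evenly spaced so
none falls within the 10 kbp clumping window of another), 341
population-private background loci split 64/63/161/53, 12 High-exclusive
loci shared across populations, 1038 unlinked noise loci, and one
within-host segregating helicase-like locus.

Construction details that matter downstream:

* **Latent type and linkage flips.** Each infection is latently High or
  Low; each focal allele then flips away from the template independently
  with probability 0.01, producing the observed near-perfect focal linkage
  (mean pairwise $r^2 > 0.9$) and a realistic minority of intermediates.
* **Population-private background loci** are carried by every called-High
  sample of their population and by a fraction $f \sim U(0.19, 0.94)$
  (study-reported range; no distribution given) of the population's other
  samples, with at least one called-Low carrier enforced so the partition
  operation recovers the constructed class counts exactly.
* **Shared High-exclusive loci** are carried by a $U(0.3, 0.8)$ fraction of
  called-High samples spanning at least two populations. Only the focal
  SNPs themselves occur in *every* High sample; making shared background
  loci universal among High samples would render them statistically
  indistinguishable from focal loci, which the real data contradict.
* **Noise loci** get a per-locus carrier frequency $U(0.05, 0.5)$; carriers
  sit at within-host frequency 1. Consensus alleles are otherwise fixed
  within hosts, except the optional segregating locus, whose within-host
  frequency is Beta-distributed with a bell-shaped mode over titer rank
  (the study observed a non-monotone rank relationship without
  parameterizing it; the Beta concentration is exposed in the
  configuration).
* Sexes, dates and endosymbiont carriage are uniform nuisance covariates.

What the generator does **not** emulate: read-level error, index
switching, within-host diversity beyond one segregating locus, host
genome polymorphism, and any titer difference between collection years.
Passing tests on these cohorts therefore demonstrates correctness of the
statistical machinery under the stated generative model, not robustness to
the full messiness of field sequencing data.

## Association model

For each locus the within-host derived-allele frequency $x$ enters an
ordinary least squares fit

$$\log_{10}(\mathrm{titer}) \sim x + \mathrm{sex} + \mathrm{population} +
x\!:\!\mathrm{sex} + \mathrm{PC}_1 + \dots + \mathrm{PC}_m,$$

where the PCs are the top eigenvectors of the centered genotype
relationship matrix, a transparent fixed-covariate stand-in for a
mixed-model kinship term. The SNP main effect is reported with its
standard error, $t$, $p$, and Benjamini-Hochberg $q$. Monomorphic or
aliased loci are skipped with a recorded reason. A 0/1 consensus coding is
available by flag; covariate pruning is an explicit user choice rather
than automated stepwise selection, which is not reproducibly specifiable.

**How many relationship components?** The interface default is $m = 5$.
On synthetic cohorts, however, the leading genotype axes *are* the
High/Low type axis and the population axes: the phenotype-causal axis
itself. Including five components absorbs most of the focal signal (the
weakest focal-locus $t$ drops from ~19 to ~3 and background loci can
outrank focal ones), a textbook case of principal-component
over-correction when a causal axis dominates the genotype covariance.
Because population of collection is already a fixed covariate and the
generator introduces no further structure, the end-to-end recovery
analyses in this package run with $m = 0$; with that choice the 11 planted
loci separate from the best background locus by $t$ margins of 6-14 across
seeds. On real data with cryptic relatedness a nonzero $m$ remains
appropriate — chosen against the eigenvalue spectrum, not defaulted
blindly.

Two permutation procedures control significance:

* **Genome-wide threshold.** Titers are permuted across samples, the scan
  is refit per permutation, and the minimum $p$ recorded; the
  $\alpha$-quantile (default $\alpha = 0.01$, 1000 permutations, taken as
  the $\lfloor\alpha n\rfloor$-th smallest) is the genome-wide threshold.
  Empirical $p$ values use the plus-one rule and can never be zero.
* **Haplotype test.** Titers are permuted within population; per
  permutation an artificial "High" haplotype is assembled from the top
  SNP (either the permutation's own top SNP — the default — or a fixed
  supplied locus; the two published descriptions differ, so both modes
  exist) plus the ten loci most linked to it, and the mean titer
  difference between samples carrying all eleven derived alleles and
  samples carrying none forms the null. Groups smaller than five samples
  are not scored: five matches the marker filter's minimum carrier count,
  and without it a singleton "group" of one extreme-titer fly can fake a
  large haplotype difference under permutation.

## Linkage and haplotype operations

Consensus haploid genotypes call the derived allele at within-host
frequency $\ge 0.5$ (matching per-host consensus sequences).
$r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$ is computed from these calls;
monomorphic loci give missing values. The four-gamete screen flags locus
pairs displaying all four two-locus gametes; because a single
recombination event can flag many overlapping pairs, the genome-wide event
count collapses flagged pairs to their genomic intervals and merges
overlaps (the raw flagged-pair count is reported alongside — the study
prints a single count without defining the treatment, so both are
available). Pair windows never wrap the circular genome; no wrap rule was
stated. Haplotype classification is by focal derived-allele count
($K$ = High, 0 = Low, else intermediate) and is invariant to locus order;
the coinfection screen calls a sample mixed when more than two focal loci
segregate within the host at frequencies in (0.05, 0.95), the band
mirroring the 5% variant-calling floor.

## McDonald-Kreitman statistics

Sites arrive pre-classified as synonymous/nonsynonymous with two outgroup
alleles. The ancestral state is the allele shared by both outgroups;
discordant outgroups make a site uninformative (the published rule is
unstated, and requiring agreement is the conservative choice). A site is a
focal-branch substitution when the focal samples are monomorphic for a
non-ancestral allele, and a derived polymorphism when they vary — dropped
as a singleton if the derived allele occurs exactly once. Direction of
Selection is $\mathrm{DoS} = D_n/(D_n+D_s) - P_n/(P_n+P_s)$, undefined
(with a recorded reason) when either denominator is zero. Per-gene
contrasts subtract the median of all other genes, or of genes within
100 kbp on the same chromosome for the local scope; category enrichment
uses a within-category percentile bootstrap of the mean delta rather than
a Bayesian model-based selection effect — a deliberately closed-form
replacement delivering the same comparative claim.

## The evolutionary simulator

Hosts are S or I; each infected host carries a viral genotype over $K = 5$
ordered loci (the five largest-effect mutations; the genotype-class
implementation stores $2^K$ counts, exactly equivalent in law to tracking
$10^6$ individuals). Titer is $T(g) = T_0\prod_{k\le m}\mathrm{gain}_k$
over the maximal consecutive prefix $m$ of derived loci: a mutation
arriving out of order confers nothing until its predecessors arrive. The
default gains $(10, 3, 2, 1.5, 1.25)$ decrease strictly and multiply to
112.5, approximately the observed 100-fold difference; the published
notation implies diminishing per-mutation gains without an explicit
formula.

Per generation, with population size $N = 10^6$:

* **Transmission.** Per-class force $\beta_0 T_g I_g / N$ with
  $\beta_0 = 0.1$. Total new infections are Binomial in the summed force
  (clipped at 1 with a logged counter) and allocated multinomially by
  per-class force — the standard competing-risks discretization.
  Independent per-class binomial draws are identical in law while the
  force is small but, once two classes saturate the probability cap, hand
  them equal shares of susceptibles regardless of titer, which lets the
  lower-virulence resident coexist forever and makes final fixation
  impossible; the competing-risks form preserves the rate-equation
  outcome the model is meant to discretize.
* **Removal.** Binomial per class at $\gamma_0 T^a$, drawn from
  generation-start counts (parallel update, matching
  $I' = I + SI\beta - I\gamma$; applying deaths after infections would
  give the Low type a growth factor of ~0.981 instead of ~0.99 and
  extinguish it within a thousand generations). Dead hosts return to the
  susceptible pool, so $S + \sum_g I_g = N$ always. The virulence exponent
  defaults to $a = 0.5$: multiplying *both* transmission and removal by
  titer ($a = 1$) makes the basic reproduction number titer-neutral, so no
  mutation would ever be favoured — contradicting the higher $R_0$
  ascribed to the High type. $a = 1$ remains available and is verified
  titer-neutral numerically.
* **Mutation.** Each absent variant flips independently at
  $\mu T_g$ per host per generation, $\mu = 3.3\times10^{-7}$ (a
  $10^{-6}$ per-base rate times 1/3 for the correct change), the rate
  being per viral particle and hence scaling with titer. Mutations may
  occur out of order and never revert.
* **Recombination.** Viral genomes are paired uniformly at random; each of
  the $K-1$ adjacent intervals independently triggers a suffix swap with
  probability 2%, not scaled by titer (as observed for these viruses).
  When fewer than 2000 hosts are infected the random perfect matching is
  drawn explicitly; above that, pair-type counts use the standard
  multinomial approximation. Marginal allele counts are conserved by
  construction, and a replicate is flagged when the first full-complement
  genotype arises in a recombination step.

**Event recording.** First appearance counts a variant on any background.
Establishment and fixation count *in-order* carriers (the mutation
together with all predecessors): only those enjoy the titer gain whose
selective advantage $s_k = (T_k/T_{k-1})^{1-a} - 1$ sets the
establishment threshold $\lceil 1/(2s_k)\rceil$ carriers — the standard
drift-barrier scale for escaping stochastic loss; an absolute-count rule
is available. Fixation is carrier frequency $\ge 0.99$ among infected
hosts. Replicates (1000 by default, each on a seed derived from the master
seed) stop once every mutation has fixed, at extinction, or at $10^5$
generations.

**What the defaults produce.** First establishment almost always occurs
within a few hundred generations and full fixation typically within a few
hundred more — comfortably inside the published bounds (>99.93% of
replicates establishing by generation 1000; all fixing by 6000). One
published pattern does *not* reproduce at these parameters: strictly
decreasing mean inter-establishment waits. The second wait absorbs the
stochastic-loss cycles of the first beneficial lineage, and with
diminishing gains the later invasions grow more slowly, so measured mean
waits run ~(37, 50, 19, 18, 20) rather than decreasing strictly; the
any-background reading fares no better (~(31, 5, 7.5, 7.8, 10)). The
published mean time to full fixation (~3400 generations) also implies a
far smaller effective mutation supply than the printed rates yield,
suggesting the published simulation operated in an arrival-limited regime
these printed parameters do not produce. The corresponding check is left
failing rather than redefining establishment until it passes.

## Selection arithmetic

Under discrete exponential growth $p_t = p_0(1+s)^t$:
`estimate_selection_coefficient` inverts to
$s = (p_1/p_0)^{1/t} - 1$, and `time_to_frequency` to
$t = \ln(p_1/p_0)/\ln(1+s)$, with years at five viral generations per year
(the conservative minimum, one per host generation). Two printed constants
are reproduced verbatim despite internal tension: the published
$s = 0.0055$ for the 52%→71% rise over 80 generations (the closed form
gives 0.0039), and the drift-barrier starting frequency 0.0000714
(described as $1/(2N_e s)$, which at $N_e = 10^6$ and $s = 0.0055$ would
be $9.1\times10^{-5}$). With those constants, fixation from the drift
barrier takes ~1739 generations ≈ 348 years, the published "~350 years".
`joint_mutation_probability` gives the chance of all five variants arising
in one generation, $(3.3\times10^{-7})^5 = 4.12\times10^{-33}$ — the
reason recurrent evolution must proceed by sequential establishment rather
than simultaneous mutation.

## Numerical and design choices

* All randomness flows from integer seeds through stage-labelled derived
  sub-seeds, so adding a stage never perturbs another stage's draws, and
  every run is bit-reproducible.
* BH adjustment delegates to `stats::p.adjust`; tests verify it against an
  independent hand-written step-up oracle.
* Least squares per locus uses a precomputed QR per locus so the
  1000-permutation procedures refit cheaply; skipped loci (zero variance,
  aliased SNP, no residual degrees of freedom) carry explicit reasons.
* Empirical thresholds use the $\lfloor\alpha n\rfloor$-th order
  statistic; empirical $p$ values use the plus-one rule.
* Problem sizes in the test suite: the simulator checks run the full 1000
  default replicates once and reuse them; end-to-end recovery uses 100
  default cohorts; permutation calibration uses 60-sample, 40-locus
  cohorts with 1000-permutation thresholds against 500 fresh nulls.
* Fixture I/O is plain text (VCF v4.2 with haploid GT and an AF FORMAT
  field, TSVs, JSON), UTF-8 with LF endings, byte-stable for fixed seeds.

## Known limitations

* The generator's intermediates inherit background carriage stochastically
  from their population, not from an explicit recombination history.
* The simulator treats titer as deterministic given genotype;
  heterogeneity within genotype classes is not modelled (and not
  parameterized in the source material).
* The four-gamete event count is a lower bound under interval merging and
  an upper bound under pair counting; recurrent mutation is
  indistinguishable from recombination for a single pair.
* No spatial structure or migration between populations, no host genetic
  variation in susceptibility, and no two-type coexistence theory: these
  are outside the package's scope.
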