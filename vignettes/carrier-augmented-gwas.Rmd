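---
title: "Carrier-augmented GWAS in closed breeding populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carrier-augmented GWAS in closed breeding populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(carriergwas)
```

This vignette is the package's account of its science: the models it fits,
the assumptions behind them, the defaults and why they were chosen, the
numerical choices that matter, and what the simulated-data tests do and do
not establish about real data.

## The problem

Disease mapping in a purebred dog population differs from a human GWAS in
two linked ways. First, the sample is small and deeply related: every dog
descends from a modest founder set through a studbook pedigree, a minority
of popular sires contribute disproportionately, and background genomic
relatedness is far above zero. Second, the pedigree itself is informative.
If a disease segregates as an autosomal recessive, the parents and
offspring of an affected dog are (near-)obligate heterozygotes, and an
ancestor of several affected descendants is very likely one too.

The carrier-augmented design exploits this: instead of discarding the
relatives of cases, it codes them as an intermediate phenotype class. The
analysed trait is

* `y = 2` for confirmed cases,
* `y = 1` for pedigree-inferred carriers,
* `y = 0` for controls,

with dogs of *uncertain* carrier status removed rather than miscoded. A
conventional binary (case = 1 / control = 0) analysis is run alongside as
the comparison.

## Carrier classification

`classify_cohort()` applies fixed, ordered rules. Ambiguous diagnoses are
excluded first, then (optionally) cases of the minority immunophenotype.
Among genotyped non-cases:

1. **Carrier** — parent of at least one case, offspring of at least one
   case, or grandparent/great-grandparent of at least two cases.
2. **Excluded relative** — full or half sibling, grandchild or aunt/uncle
   of a case; grandparent/great-grandparent of exactly one case; or
   genome-wide IBD `PIHAT > 0.25` with any genotyped case. These dogs may
   or may not be heterozygous, so both labels would be guesses.
3. **Control** — everyone else.

The carrier rule takes precedence over exclusion: a dog that is both a
parent of one case and a sibling of another is a carrier. This precedence
is not optional — without it the rules would contradict each other on
exactly the informative dogs. Ungenotyped cases participate fully in the
relative rules (carrier status is a property of the pedigree, not of the
genotyping), but only genotyped dogs receive a label. One consequence
worth knowing: the single-immunophenotype exclusion removes a dog from the
*analysis*, but the dog remains a case for the relative rules, because its
relatives' germline exposure does not depend on our analysis choices.

## The mixed linear model

Both designs are analysed with the same linear mixed model,
$y = \mu + b\,x + g + e$ with $g \sim N(0, A\sigma^2_g)$ and
$e \sim N(0, I\sigma^2_e)$, where $A$ is the genomic relationship matrix
computed from all retained SNPs: off-diagonals
$\frac{1}{M}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}$ and the
homozygosity-based diagonal
$1 + \frac{1}{M}\sum_i \frac{x^2_{ij}-(1+2p_i)x_{ij}+2p_i^2}{2p_i(1-p_i)}$.
The variance components are estimated once under the null (no SNP) and
held fixed for the per-SNP generalized-least-squares fits; the candidate
SNP stays in the GRM (the non-LOCO convention). Each SNP gets a Wald test
$(b/\mathrm{SE})^2$ against $\chi^2_1$. The binary design is analysed with
the same *linear* mixed model, not logistic regression: at these sample
sizes the linear mixed model on a 0/1 outcome is the standard
quantitative-genetics treatment, and it keeps the two designs directly
comparable. Known approximations, accepted deliberately: no
leave-one-chromosome-out correction (slightly conservative near a true
signal) and no saddlepoint correction for case-control imbalance.

## False-discovery control

`qvalues()` implements the Storey procedure: $\hat\pi_0$ estimated on a
$\lambda$ grid from 0.05 to 0.95 in steps of 0.05, smoothed with a cubic
spline (3 df) and read off at $\lambda = 0.95$, then step-up q-values
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. With $\hat\pi_0 = 1$
this is exactly Benjamini–Hochberg, and any stratum with fewer than 100
p-values uses $\pi_0 = 1$ because the grid estimate is hopeless there.
Q-values are computed twice: genome-wide, and independently within each
chromosome ("chromosome-wise"), the latter being the more sensitive
screen when a signal is confined to one chromosome. The default reporting
threshold is q < 0.1.

## Relatedness

`pihat()` is the method-of-moments IBD estimator: observed counts of
IBS states 0/1/2 over shared non-missing SNPs are inverted against their
expectations given IBD state 0/1/2, computed from cohort allele
frequencies. We use unbiased product-moment estimators of $p^aq^b$ from
the allele counts (e.g. $\widehat{2p^2q^2} =
2X(X{-}1)Y(Y{-}1)/[N(N{-}1)(N{-}2)(N{-}3)]$ for $X$ minor and $Y$ major
alleles among $N$ chromosomes). Without this finite-sample correction the
estimator is noticeably inflated for unrelated pairs in small cohorts.
Two residual biases remain and are visible in tests: truncating negative
$Z$ components at zero inflates the mean PIHAT of unrelated pairs
slightly, and linkage disequilibrium reduces the effective number of
independent SNPs, widening the sampling distribution. Between-panel
differences aside, this is the behaviour of the classic `--genome`
estimator, which is why the exclusion threshold (0.25) targets first- and
second-degree relatives rather than anything finer.

Relationship networks use the allele-sharing distance
$1 - \overline{\mathrm{IBS}}/2$ and a mutual k-nearest-neighbour graph
(default k = 10): an edge exists only when each sample is within the
other's k nearest. Ties are broken by sample id for reproducibility.
Community detection beyond connected components is out of scope.

## Haplotype analysis

Block detection is Gabriel-style. For each SNP pair we profile the
likelihood of the unphased two-locus genotype table over a grid of
$|D'| \in [0,1]$ with the haplotype margins fixed at the sample allele
frequencies and the sign of $D$ taken from the EM point estimate; the
central 90% of the normalized grid likelihood gives the interval. A pair
is "strong LD" when the interval lower bound is at least 0.70 and the
upper at least 0.98, "recombination" when the upper bound is below 0.90;
a span is a block when at least 95% of its informative pairs are strong,
and blocks are accepted greedily, longest first, without overlap, within a
200 kb span cap and a 0.05 MAF floor — the familiar defaults, used because
the block-building tool is conventionally run without changing them.

Within a block, `em_hap_freqs()` runs EM over the diplotypes compatible
with each sample's multilocus genotype (heterozygous sites phase both
ways, missing sites take any allele pair; blocks are capped at 20 SNPs and
a sample's enumeration at $2^{16}$ states). Initialization is the
linkage-equilibrium product of single-SNP frequencies; convergence is a
maximum frequency change below $10^{-6}$ or 1000 iterations; haplotypes
below $10^{-4}$ are pruned. The log-likelihood is non-decreasing by
construction and the tests assert it. One documented degeneracy: a block
in which every sample is doubly heterozygous leaves EM at its symmetric
stationary point (all four haplotypes at 0.25) because the data genuinely
cannot break the tie.

Association uses **expected** haplotype dosages (posterior-weighted copy
numbers), one haplotype versus all others, linear for the 2/1/0 code and
logistic (reporting an odds ratio) for case/control; complete separation
is flagged and the p-value withheld. The per-group homozygosity tables
instead use the **best** (maximum-posterior) diplotype with a strict
argmax — a posterior tie counts as not homozygous — because a frequency
table built from fractional dogs would be unreadable. Haplotypes below a
1% frequency floor are not tested.

## Heritability and the liability scale

`ai_reml()` estimates $(\sigma^2_g, \sigma^2_e)$ by average-information
REML, with the first step an EM-REML step and an AI update thereafter.
Everything is computed in the GRM's eigenbasis, where the covariance is
diagonal; this makes each iteration cheap and makes feasibility explicit:
the homozygosity-based GRM diagonal admits negative eigenvalues, so
$V = \sigma^2_g A + \sigma^2_e I$ is only positive definite on part of the
parameter space, and proposals that leave it are step-halved back.
Components are floored at $10^{-6} V_p$; a component driven past zero by
an AI step is clamped at the floor (the boundary estimate) rather than
retreating to EM, which crawls geometrically near the boundary.
Convergence is a restricted log-likelihood change below $10^{-4}$, with a
300-iteration cap. The null (residual-only) restricted likelihood is
closed-form, and the test is the boundary-mixture LRT:
$p = \tfrac12 P(\chi^2_1 > \mathrm{LRT})$, so LRT = 0 gives p = 0.5. The
plain $\chi^2_1$ version is available as an option. The SE of
$V_G/V_p$ comes from the inverse AI matrix by the delta method.

Case-control samples ascertain cases far above their population
frequency, so the observed-scale estimate is transformed to the liability
scale with the standard threshold-model correction,
$$ h^2_L \;=\; h^2_{obs}\;\frac{K(1-K)}{z^2}\,\frac{K(1-K)}{P(1-P)}, $$
where $K$ is the assumed population prevalence, $P$ the sample case
proportion, and $z$ the standard-normal density at the $1-K$ quantile.
The SE transforms by the same factor. Because breed-specific prevalence
is rarely known, the report carries a grid of assumed prevalences
(defaults 0.1, 0.05, 0.025). Note the transform is linear in $h^2_{obs}$:
an observed-scale estimate pushed to the boundary (100%) converts to a
liability-scale value above 100%, which should be read as "uninformatively
large", not as a proportion.

## The synthetic cohort generator

`simulate_cohort()` exists so that every downstream stage has planted
truth. What it emulates, and how:

* **Pedigree** — discrete non-overlapping generations; a configurable
  fraction of males used at stud with long-tailed (exponential, optional
  power) usage weights, giving the popular-sire skew of real breeds;
  Poisson litter sizes. Defaults (300 founders, 5 generations, half of
  males at stud, mean litter 2.5) produce a breed-like closed population
  of some 1500 dogs with strong background relatedness.
* **Founder haplotypes** — each chromosome is partitioned into latent
  blocks of geometric length (mean 8 SNPs); within a block 2–6 haplotype
  variants segregate at Dirichlet(1) frequencies and founders draw
  blockwise-independently. This exchangeable-block model is deliberately
  *not* coalescent: it is cheap, gives exactly known block boundaries for
  the block-detection tests, and produces strong within-block and absent
  between-block LD. Real LD decays smoothly; conclusions about block
  detection on real data should not be over-read from these tests.
* **Transmission** — Mendelian gene dropping with Haldane (Poisson,
  no-interference) crossovers on a 1 cM/Mb map.
* **Disease** — one planted biallelic risk locus; dogs with two risk
  alleles are affected with probability `penetrance_aa`, all others with
  the sporadic (phenocopy) rate. Affected dogs draw an age at onset from
  Normal(8.7, 3.3²) years truncated to (0, 16] — a truncated normal, not
  a Weibull, because only a mean and SD are being matched — and a B-cell
  immunophenotype with probability 0.85, with a configurable fraction
  relabelled untyped.
* **Genotyping** — optionally case-ascertained: all affected dogs plus a
  sample of unaffected dogs from the most recent generations, mirroring a
  case series with biobank controls. Missingness is completely at random;
  panel merging and imputation are out of scope, so simulated data are
  complete unless a missing rate is requested.

Identical configurations (including the seed) reproduce cohorts and all
pipeline outputs byte for byte.

One scale caveat is worth stating plainly. In a real registry the
pedigree spans tens of thousands of dogs and the few dozen known cases sit
far from most controls, so the relative-exclusion rules remove only a
handful of dogs. A desk-scale simulated population is hundreds of dogs,
every one of them close to some case; the same rules therefore exclude a
much larger *fraction* here than in a real study. The simulator's
genotyping window and control-sampling options keep the analysed cohort
composition (a few dozen cases, a dozen-odd carriers, and a control
majority) in the realistic range, but the exclusion counts themselves are
a property of population size and should not be compared to a registry
study's.

## Problem sizes used in the tests

The bundled checks run at sizes chosen to exercise the statistics, not to
flatter them: variance-component recovery uses 20 cohorts of 300 dogs by
5000 SNPs with a true $h^2$ of 0.5; the design comparison uses 20 cohorts
of roughly 150–250 genotyped dogs by 10,000 SNPs with a planted recessive
locus at founder frequency 0.20 and penetrance 0.7; block recovery uses
founder-only panels with 2–3 variants per planted block, where exact
boundary recovery is a fair target; the demonstration pipeline runs the
full analysis twice on a 10,000-SNP cohort to assert byte-identical
reruns. Monte-Carlo tolerances are set from binomial/normal sampling error
at those sizes (roughly four standard errors), not tuned to outcomes.

## Known limitations

* The exchangeable-block LD model and MCAR missingness are idealizations;
  no imputation, no genotyping-batch structure, no allele-frequency
  mismatch between panels.
* Single-component REML only: a region's variance is estimated alone, not
  jointly with the rest of the genome, so regional estimates absorb some
  genome-wide signal through relatedness.
* The per-SNP scan holds variance components fixed at their null REML
  values (standard, slightly anticonservative near very strong signals).
* Logistic haplotype tests at these case counts meet separation often;
  flagged rows should be treated as "large effect, unquantified".
* `PIHAT` is a genome-wide average; it cannot distinguish a half-sib from
  an avuncular pair, which is precisely why the pedigree rules take
  precedence over it in classification.
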