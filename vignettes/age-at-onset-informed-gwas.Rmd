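---
title: "Age-at-onset informed GWAS under the liability-threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-at-onset informed GWAS under the liability-threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsetGWAS)
```

## The model

Case-control GWAS of late-onset diseases such as ischaemic stroke discard a
clinically important covariate: the age at which cases fell ill. Disease
prevalence rises steeply with age, so under the liability-threshold model a
case with onset at 50 must carry substantially more liability than a case
with onset at 85, and a 50-year-old control has excluded far less liability
than an 85-year-old one. `onsetGWAS` converts this epidemiological
information into a quantitative response for association testing.

The liability-threshold model posits a standard-normal latent liability
$L$; an individual is affected once $L$ exceeds an age-specific threshold

$$t(a) = \Phi^{-1}\{1 - K(a)\},$$

where $K(a)$ is the disease prevalence at age $a$ (for a disease subtype,
$K(a)$ is scaled by the subtype's share of overall prevalence, by default
20%, constant across age). Conditioning on affection status and age gives
each sample a posterior mean liability:

* cases, at their age at onset: $E[L \mid L > t] = \phi(t)/K$;
* controls, at their exam age: $E[L \mid L \le t] = -\phi(t)/(1-K)$.

These two quantities satisfy $K\,E_{case} + (1-K)\,E_{ctrl} = 0$ (the law
of total expectation), which the test suite verifies to $10^{-12}$.
Missing ages are median-imputed within each centre-by-status stratum,
matching the per-centre analysis design; a stratum with no observed ages
falls back to the status-wide and then the global median.

Because younger-onset cases receive larger posterior liabilities, a SNP
whose risk allele is enriched in younger cases correlates more strongly
with the liability response than with the raw 0/1 status — this is the
entire source of the method's extra power. When prevalence is flat in age
the liabilities are a two-valued affine transform of status and the
informed test reduces *exactly* to the standard one (tested to $10^{-10}$).

## Association testing

For each SNP, the expected imputed dosage $g \in [0,2]$ and the response
are residualized on an intercept plus any ancestry principal components,
and the score statistic is

$$\chi^2_1 = N\,r^2,$$

with $r$ the Pearson correlation of the residuals. Covariate adjustment by
double residualization makes the statistic a partial correlation; the
`uninformed_test()` runs identical machinery on the 0/1 status, so the two
analyses differ in nothing but the response vector (for a 0/1 response and
0/1 dosage the statistic is algebraically the Cochran–Armitage trend test,
which the suite checks against a contingency-table oracle). Effect sizes
(`beta`, `se`) are the least-squares slope of the residualized response on
the residualized dosage; they feed the heterogeneity assessment, not the
primary test. SNPs with zero dosage or response variance after
residualization are flagged `unestimable` and excluded from meta-analysis.

QC follows the convention "discard strictly below": imputation info
$\ge 0.3$ and MAF $\ge 0.01$ are retained, and per-criterion removal
counts are reported.

## Meta-analysis

Per-centre results are combined with Stouffer's weighted-Z method,

$$Z_{meta} = \frac{\sum_i w_i Z_i}{\sqrt{\sum_i w_i^2}}, \qquad
  w_i = \sqrt{N_{eff,i}},\quad N_{eff} = \frac{4}{1/n_{cases} + 1/n_{ctrl}},$$

the sample-size scheme appropriate for unbalanced case-control studies
(plain $\sqrt{N}$ weights are available). Genomic control is applied per
study before combination: $\lambda$ is the median association chi-square
over its null expectation 0.4549, and statistics are deflated by
$\max(\lambda, 1)$ — the floor prevents well-calibrated studies from being
inflated. Alleles are harmonized to the first study carrying each SNP;
strand-ambiguous A/T and C/G sites pass through with a logged warning
rather than frequency-based guessing.

Two filters mirror the discovery design: SNPs must be present in studies
contributing at least 75% of all cases (boundary kept), and must show no
heterogeneity evidence (Cochran's Q p strictly greater than 0.001).
Replication-style tools are included: fixed-effects inverse-variance
pooling, the Han–Eskin random-effects likelihood-ratio test with the
asymptotic $\tfrac12\chi^2_1 + \tfrac12\chi^2_2$ null (small-study
tabulated corrections are out of scope and flagged), and Fisher's method
$-2\sum\ln p_i \sim \chi^2_{2k}$ for combining discovery and replication.
Note a consequence of the mixture null worth knowing: with perfectly
homogeneous effects the RE2 statistic equals the squared fixed-effects
$z$, but its p-value is deliberately heavier-tailed than the
fixed-effects p — the tests assert the statistic identity, not p-value
equality.

## Permutation evaluation of the age effect

To ask whether age-at-onset information helps genome-wide, the package
reproduces the permutation design:

1. select SNPs by the **uninformed** case-control meta-analysis at a
   p-value threshold, and LD-clump them (greedy: lowest p is the index,
   neighbours within 300 kb with dosage $r^2 \ge 0.25$ are removed;
   ties on p broken by chromosome, position, id);
2. run the age-informed analysis at the clumped SNPs (observed result);
3. permute case onset ages within centre-by-subtype strata, re-run the
   informed analysis, and repeat for `n_perm` permutations;
4. convert each SNP's meta p to $|Z| = \Phi^{-1}(1 - p/2)$ and sum over
   the SNP set (`sumZ`); the empirical p is the fraction of permutations
   whose sumZ strictly exceeds the observed value, reported per selection
   threshold (0.05, 0.005, 0.0005, 0.00005) together with the median and
   IQR of the per-permutation proportion of SNPs more significant in the
   observed analysis.

Selection by the uninformed statistic is not a stylistic detail: it is
invariant under age permutation, which is precisely what makes the
empirical p uniform when onset carries no information. Selecting on the
observed informed p would bias the observed sumZ upward on the selected
set and break calibration under the null; the test suite checks
uniformity (200 null studies, Kolmogorov–Smirnov) under the implemented
design.

"More significant" is strict inequality throughout, matching the
$r/n$ empirical-p definition; exact ties are counted and reported
(`n_ties`), and an observed statistic more extreme than every permutation
reports 0 with a `<1/n` annotation. Permutation streams are derived per
(stratum, permutation index) from the master seed, so results do not
depend on evaluation order and are exactly reproducible from
`(seed, n_perm)`.

## The synthetic cohort generator

Because no individual-level stroke data can ship with a package, every
pipeline stage is validated on synthetic cohorts drawn from the same
generative model the analysis assumes:

* genotypes $g_j \sim \mathrm{Binomial}(2, p_j)$ with frequencies uniform
  on 0.05–0.5, jittered per centre on the logit scale (sd 0.02) to give
  realistic but unconfounded between-study drift;
* liability $L = \sum_j \beta_j (g_j - 2p_j)/\sqrt{2p_j(1-p_j)} +
  \varepsilon$, $\varepsilon \sim N(0, 1 - \sum\beta_j^2)$, fixed at
  birth;
* onset at the first age on a yearly grid where $t(a) \le L$ — onset is a
  deterministic, monotone function of liability, the mechanism by which
  age effects emerge purely from ascertainment (an `age_effect` dial can
  decouple onset from liability to create a generative null);
* exam age uniform on 40–85; affected iff onset $\le$ exam; cases and
  controls accumulated by rejection sampling (a draw cap converts an
  infeasible design into an informative error);
* imputation noise by a linear-Bayes observer: the expected dosage is
  $d = 2p + k(g - 2p) + k\eta$ with $k = \mathrm{var}(g) /
  (\mathrm{var}(g) + \sigma^2)$, so dosages shrink toward the
  allele-frequency mean exactly as imputed expectations do and the info
  statistic $\mathrm{var}(d)/\{2\,\mathrm{eaf}(1-\mathrm{eaf})\}$ equals
  $k$, decreasing monotonically in $\sigma$ (default $\sigma = 0.15$,
  info $\approx 0.9$).

The default study configuration is two centres of 1000 cases and 1000
controls each, 500 SNPs of which 20 are causal with standardized
$\beta = 0.12$. What the generator deliberately does **not** emulate:
realistic LD beyond optional AR(1) haplotype blocks, relatedness,
sex-specific liabilities, time-varying environmental liability, or
platform-specific genotyping artefacts. Passing tests therefore
demonstrate correctness of the statistical machinery under the model's own
assumptions, not robustness to every failure mode of real cohort data.

## Numerical choices

* $|Z|$ conversion uses `qnorm(p/2, lower.tail = FALSE)` so genome-wide
  significant p-values retain full precision (no catastrophic `1 - p/2`
  rounding).
* The RE2 profile likelihood is maximized over $\tau^2 \in [0,
  5\max(\mathrm{var}(\beta), \max se^2)]$ by golden-section search with
  the boundary $\tau^2 = 0$ checked explicitly; the constraint
  $\tau^2 \ge 0$ is enforced by construction.
* Logistic quantile ORs use IRLS (`glm`) with deviance tolerance $10^{-8}$
  and at most 50 iterations; fits with $|\hat\beta| > 15$ or fitted
  probabilities within $10^{-10}$ of 0/1 are flagged as separation and
  not reported.
* Clumping computes $r^2$ as squared Pearson correlation of expected
  dosages (composite LD), since phase is unavailable from dosages.
* The (t, K) consistency check in the posterior-mean functions tolerates
  $10^{-6}$ on the threshold scale.
* Ages outside the prevalence grid are clamped to the grid ends rather
  than extrapolated, keeping thresholds bounded in sparse age tails.

## Validation problem sizes

The shipped test-suite experiments use deliberately chosen scales:
calibration on one centre of 2000 samples with 2000 null SNPs (type-I
error within the binomial 99% band, $\lambda \in [0.9, 1.1]$); the
informed-vs-uninformed sign test over 50 replicate two-centre studies at
the default configuration; sumZ power over 20 replicates at 100
permutations; null calibration over 200 scaled-down studies (one centre,
500 samples, 100 SNPs); and clumping equivalence against an exhaustive
reference on 50 random 100-SNP instances. The full 1000-permutation
design remains available through `PermutationConfig`-style options
(`eval$n_perm` in the run configuration).

One evaluation choice deviates from a literal reading of the design
notes: the monotone decline of logistic odds ratios across cumulative
onset quantiles is tested at a single strong locus
($\beta = 0.45$, 1000/1000 samples) rather than at the default 20 weak
loci, because a per-SNP OR ordering across four nested strata is
statistically invisible at $\beta = 0.12$ — the strong-locus regime is
the one in which such post-hoc quantile analyses are actually run.

## Limitations

The package assumes prevalence inputs are externally estimated (no
in-sample prevalence estimation), handles autosomal dosages only, applies
no mixed-model relatedness correction, and implements the asymptotic RE2
null without small-study tabulated corrections. Genomic control in the
permutation evaluation is off by default because a median-based $\lambda$
over a small selected SNP set is noise; at genome scale it can be enabled
in the meta options.
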