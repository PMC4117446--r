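# onsetGWAS

Age-at-onset informed genome-wide association analysis for case-control
studies of diseases whose prevalence rises steeply with age — ischaemic
stroke and its aetiological subtypes (cardioembolic, large-artery
atherosclerotic, small-vessel) being the motivating case. The package is
aimed at statistical geneticists running multi-centre GWAS who have
age-at-onset (cases) and exam age (controls) on file and want to use them
instead of discarding them.

## The method

Under the liability-threshold model an unobserved standard-normal
liability *L* causes disease when it exceeds the age-specific threshold
*t(a) = Φ⁻¹{1 − K(a)}*, with *K(a)* the prevalence at age *a* (scaled by a
subtype fraction, default 20%, for subtype analyses). Conditioning on
affection status and age gives each sample a posterior mean liability

- cases (at onset age): **E[L | L > t] = φ(t)/K**
- controls (at exam age): **E[L | L ≤ t] = −φ(t)/(1−K)**

so a case with onset at 50 contributes a much larger response than one
with onset at 85. Each SNP's imputed dosage is then tested against these
liabilities with the score statistic **χ²₁ = N·r²** (r = correlation of
covariate-residualized dosage and liability); per-centre results are
combined by sample-size-weighted Stouffer meta-analysis with per-study
genomic control, Cochran's Q heterogeneity assessment, and
case-coverage (≥75%) / heterogeneity (Q p > 0.001) filters. A permutation
framework (onset ages shuffled within centre and subtype) quantifies
genome-wide age-at-onset effects through the summed-|Z| statistic, and
Fisher's method combines discovery with replication evidence. A
synthetic-cohort generator draws multi-centre case-control studies from
the identical generative model, so the whole pipeline is testable without
access to patient data.

## Worked example

```r
library(onsetGWAS)

cfg <- sim_config(seed = 42, n_centres = 2, n_cases = 500, n_controls = 500,
                  m_snps = 200, n_causal = 10, beta = 0.15)
cohort <- simulate_cohort(cfg)

inf <- informed_meta_scan(cohort$panels, cohort$phenotype, cohort$model, "IS")
uni <- uninformed_meta_scan(cohort$panels, cohort$phenotype, cohort$model, "IS")
head(inf[order(inf$p_meta), c("snp","chr","pos","z_meta","p_meta","q_p","direction")], 5)
#>       snp chr     pos z_meta   p_meta     q_p direction
#>  snp00152   1 7550001   9.07 1.17e-19 0.71870        ++
#>  snp00190   1 9450001   8.90 5.65e-19 0.21832        ++
#>  snp00025   1 1200001   8.50 1.95e-17 0.70644        ++
#>  snp00014   1  650001   8.19 2.61e-16 0.00201        ++
#>  snp00092   1 4550001   8.16 3.47e-16 0.89185        ++
```

All five top hits are true causal SNPs of the simulation
(`cohort$truth$causal`), and in this replicate the age-informed analysis
gives a smaller meta-analysis p than the uninformed analysis at 10 of the
10 causal SNPs — the power gain purchased by conditioning on onset age.
Combining a discovery p-value with an independent replication:

```r
cmd_combine(c(2.5e-7, 0.0048))
#> Fisher's method: combined p = 2.58e-08 (from 2.5e-07, 0.0048)
```

A command-line front end wrapping the same functions ships in
`inst/cli/onsetgwas` (`simulate`, `assoc`, `meta`, `evaluate`, `combine`),
driven by a single YAML run configuration (see `?read_run_config`).
Dosage input is either a tab-separated SNP-by-sample matrix with info
scores or a VCF with per-genotype `DS` dosages.

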