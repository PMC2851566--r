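---
title: "Mapping cis-acting regulatory variation from allelic expression ratios"
author: "aeqtlmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cis-acting regulatory variation from allelic expression ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A sequence variant that modulates a gene's expression *in cis* acts on
the allele that carries it, on its own chromosome.  In an individual
heterozygous for a transcribed SNP, the two alleles' transcripts can be
distinguished and quantified, and their ratio — the allelic expression
ratio (AER) — responds to cis-acting variation only: trans influences
(age, environment, cell composition, diffusible regulators) act on both
alleles equally and cancel within the individual.  This makes allelic
expression far more sensitive for mapping cis-regulatory SNPs than the
conventional comparison of total expression across genotype classes
(eQTL mapping), where trans variation inflates the residual.

`aeqtlmap` implements both arms — the allelic (aeQTL) likelihood model
and the total-expression regression — together with the measurement
plumbing (gDNA normalization, replicate aggregation, delta-Ct
quantification), haplotype-phase machinery, multiple-testing and
variance-decomposition summaries, and a synthetic two-cohort generator
that provides fully controlled data with a known truth record.

## The allelic-ratio likelihood

Code one allele of every biallelic site as 0 and the other as 1 (the
*coded* allele; for VCF input this is ALT).  For individual $j$,
heterozygous at transcribed markers $k = 1, \dots, m$ of a gene, let
$I_{jk}$ be the natural log of the measured allelic ratio at marker
$k$, oriented so the numerator is the marker's coded allele.  Allele-
level expression is taken as lognormal with a variance that does not
depend on the allele, so $I_{jk}$ is normal.  Its mean is modelled as a
linear combination of the mapping SNPs $i = 1, \dots, p$ under study:

$$\mu_{k}(g) = \sum_i \beta_i \, X_{ik}(g), \qquad
X_{ik}(g) \in \{-1, 0, +1\},$$

where the phase indicator $X_{ik}(g)$ is $+1$ if, in phased genotype
$g$, the coded allele of SNP $i$ lies on the haplotype carrying the
numerator allele of marker $k$; $-1$ if it lies on the other
haplotype; and $0$ if the individual is homozygous at $i$.  So
$\beta_i$ is the log allelic fold attributable to one copy of the
coded allele of SNP $i$, and `exp(beta)` is both the heterozygote
allelic ratio and the expression of coded-allele homozygotes relative
to the other homozygotes (no dominance, no interactions).

Phase is not observed.  Genotyping yields the unphased genotype $T_j$;
the compatible phased configurations $g$ receive posterior
probabilities $P(g \mid T_j)$ from cohort-specific haplotype
frequencies (below).  With ratios at different markers conditionally
independent given $g$, each with marker-specific variance
$\sigma^2_k$, the likelihood is the phase mixture

$$L = \prod_j \sum_{g} P(g \mid T_j) \prod_{k}
\mathcal{N}\!\left(I_{jk};\, \mu_k(g),\, \sigma^2_k\right),$$

evaluated with log-sum-exp for stability (`aer_loglik()`).  Maximising
over $(\beta, \sigma^2)$ gives the fit (`fit_aeqtl()`); the effect of a
SNP, adjusted for any set of other SNPs, is tested by the
likelihood-ratio statistic between nested fits on the identical
individual set, referred to $\chi^2_1$ (`lrt()`, `scan_snps()`).

Both transcribed markers of a gene enter one likelihood.  This is what
makes the approach efficient: an individual heterozygous at either
marker contributes, so the set of *informative heterozygotes* for a
tested SNP (heterozygous at the SNP and at $\ge 1$ measured marker) is
the union over markers.  SNPs with fewer than 8 informative
heterozygotes are excluded from scans by default — below that the
likelihood comparison is too unstable to interpret.

## Phase: EM haplotype frequencies and posteriors

Haplotype frequencies for the small SNP subset relevant to a fit (the
gene's transcribed markers plus the modelled SNPs) are estimated per
cohort by EM under Hardy-Weinberg equilibrium (`em_haplotype_freqs()`):
a diplotype $(h_1, h_2)$ has prior $f_{h_1} f_{h_2}$ (doubled when
heterokaryotypic), and each E step distributes every individual over
the compatible diplotypes.  The phasing subset is deliberately
restricted: only the relative phase between modelled SNPs and the
transcribed markers enters $X$, so phasing the whole region would add
computation and missing-data exposure without changing the quantity
that matters.  This is an approximation to phasing the complete panel;
with the strong local LD typical of such regions the difference is
negligible for posterior phase between nearby sites.

Numerical contracts: uniform initialisation (deterministic; random
multi-starts behind a flag), convergence when the largest frequency
change drops below $10^{-8}$ (cap 10,000 iterations, error with the
log-likelihood trace on failure), and the log-likelihood is asserted
non-decreasing at every iteration.  Individuals missing any subset
genotype contribute nothing to that fit and are listed in the model
object.  Double heterozygotes get a two-point phase posterior
$P(\text{coupling}) = f_{AB}f_{ab} / (f_{AB}f_{ab} + f_{Ab}f_{aB})$;
everyone else is phase-certain.  `ld_stats()` reports signed
$D' = D/D_{\max}$ and $r^2$ from the same machinery.

## Measurement model and normalization

The assay reads out the ratio of the two alleles' signals.  Because
amplification and detection are not perfectly symmetric between
alleles, each assay has a multiplicative bias, estimated from genomic
DNA of heterozygotes, where the true ratio is exactly 1:1.  The default
normalization divides by the assay's *population-mean* gDNA ratio; a
per-individual strategy (each person's cDNA by their own gDNA) is
available by flag.  The two agree in expectation, and on real data of
this design were reported indistinguishable; the population mean is the
default because it does not propagate one individual's gDNA measurement
noise into their cDNA ratio.  Applying the population strategy to the
gDNA measurements themselves returns mean ratio 1 by construction —
a wiring check used in the tests.

Replicates (four by default) are averaged on the ratio scale — the
scale on which the instrument reports — before the log transform.
Averaging logs instead would differ at second order in the replicate
CV (about $\mathrm{CV}^2/2 \approx 0.1\%$ at 5% CV), far below marker
dispersion; the choice is a convention, recorded here.

Total expression comes from real-time PCR by the comparative-Ct
method: $\Delta C_t$ = mean target Ct − mean of three reference genes,
and log relative expression $= -\Delta C_t \cdot \ln 2$ under 100%
amplification efficiency (configurable).  Adding a constant to all of
an individual's Ct values (loading differences) cancels exactly.

Per-individual measurement standard errors are *not* propagated into
the mixture likelihood — the model carries a single dispersion
$\sigma^2_k$ per marker, which absorbs measurement error and unmodelled
cis variation together.  This is a known limitation; it matches the
model the scan statistics assume.

## The eQTL arm

`eqtl_scan()` regresses log relative expression on additive genotype
(0/1/2) with age, sex and ethnicity covariates.  Ethnicity is
categorical with a closed category set and single-member categories
merged into "other" to keep the design nonsingular.  Outliers are
screened per gene by |z| > 3 on log expression before fitting — an
explicit, reproducible surrogate for the by-eye exclusion such
datasets usually get; the threshold is configurable and the exclusions
are logged.  Fold change is reported per two allele copies
(`exp(2 * slope)`), directly comparable with the allelic `exp(beta)`.

## Multiple testing and summaries

Family-wise error rates are Bonferroni over the mapping panel:
`FWER = min(1, m p)` with $m = 56$ for the full panel, giving the
0.05-level nominal threshold $0.05/56 = 8.9\times10^{-4}$
($-\log_{10} P = 3.05$; $-\log_{10}\text{FWER} = 1.3$).  Reported
$-\log_{10}$ values are rounded to 2 decimals in output tables.

The share of expression variance attributable to cis variation is
estimated from marker heterozygotes as
$\hat\sigma^2_{cis} = \frac{1}{2n}\sum_i I_i^2$ — under independent
alleles and zero-mean $I$, $\mathrm{Var}(I) = 2\,\mathrm{Var}(c)$ where
$c$ is one allele's cis contribution — divided by the sample variance
of log total expression.  An alternative $\frac{1}{4n}$ factor
(cis variance expressed on the log-total scale, using
$\log(e^{c_1} + e^{c_2}) \approx \text{const} + (c_1+c_2)/2$) is
available via `scale = "log-total"`; both are validated against the
generator's analytic truth record.  The per-allele form is the
default.  Two upward biases are worth knowing.  First, measurement:
$E[\hat\sigma^2_{cis}]$ includes half the marker's dispersion
$\sigma^2_k$; with assay noise well below the cis signal this stays
within the tolerance the recovery experiments demand.  Second,
ascertainment: the estimate conditions on heterozygosity at the
transcribed marker, and when the marker is in strong LD with the
causal site, marker heterozygotes are enriched for causal
heterozygotes, so $\overline{I^2}$ overstates the population cis
variance — visibly so for the simulated strong-LD gene in the
analysis scripts, where the estimated fraction runs well above the
truth record.  The recovery experiment therefore uses a marker
independent of the causal SNP; on real data the estimate should be
read as an upper bound for markers in tight LD with the signal.

`compare_scans()` (Pearson r of effects and of $-\log_{10} P$ over
shared SNPs) serves both the aeQTL-vs-eQTL and the cohort-vs-cohort
comparisons; `direction_concordance()` counts same- vs opposite-sign
effects among SNPs significant for two genes — the pattern that
distinguishes co-regulation from antisense-style repression.

## The synthetic-data generator

`default_sim_config()` encodes the study conditions: cohorts of 310
(SA-like) and 177 (Caucasian-like) individuals; 56 mapping SNPs with
two transcribed markers for each of three genes interleaved at their
genomic positions; cohort-specific founder-haplotype pools (8 founders
for the Caucasian-like cohort, 16 including recombinants for the
SA-like one, so the SA-like cohort has lower LD and generally higher
minor-allele frequencies — the property that makes an African-ancestry
cohort valuable for fine-mapping); per-gene cis effects of roughly
1.4-, 1.33- and 1.9-fold at chosen SNPs, the third gene carrying a
second, weaker effect and the second and third genes sharing one
causal SNP with opposite signs (the antisense-style pattern of a
transcript pair repressed and driven by the same site); marker
dispersions 0.15/0.15/0.25 (the
low-expressed third gene's assay is noisiest); assay biases between
0.85 and 1.25; four replicates at 5% lognormal CV (the assay's noise
distribution is not documented; lognormal is the natural choice for a
positive ratio and is stated as an assumption); a trans model (age,
sex, ethnicity plus residual SD 0.55) sized so that cis effects explain
roughly 5–25% of log-expression variance; 2% genotype missingness; and
Ct tables with 0.1-cycle replicate noise around reference-gene levels.
One strong-LD marker pair (D' near 1) is built into the third gene's
pool, reproducing the situation where two transcribed SNPs are almost
always co-inherited.

Trans effects enter both alleles' log expression equally, so simulated
AERs are trans-free by construction — exactly the property the allelic
method exploits.  The truth record carries the haplotypes, the true
$\beta$, and analytic values of the per-allele cis variance
($\mathrm{Var}(c)$ over the pool), of $\mathrm{Var}(\log T)$
(trans variance plus the exactly enumerated variance of
$\log(e^{c_1}+e^{c_2})$ over diplotypes), and of their ratio, so
recovery tests compare against closed-form truth, not against another
simulation.

What the generator does *not* emulate: genotyping error, spectra-level
artefacts, PCR-efficiency curvature, allele dropout, multi-allelic cis
architecture, imprinting, and cell-composition structure in trans
effects.  Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
failure mode of the assay.

## Numerical choices

* Mixture MLE by BFGS on $(\beta, \log\sigma^2)$ with 5 seeded starts
  (scans use fewer: the per-SNP likelihood is well-behaved); the
  objective is kept finite under extreme variance excursions so line
  searches can recover; convergence failures and $\sigma^2 \to 0$
  boundary collapses are errors, not silent results.
* With no modelled SNPs the MLE is closed-form
  ($\hat\sigma^2_k = \overline{I_k^2}$, or mean/central moment with
  marker intercepts), which both speeds nested tests and anchors the
  optimizer tests.
* Standard errors from the observed information (numerical Hessian),
  delta method for $\sigma^2$.
* Marker intercepts default off: gDNA normalization is assumed to
  remove assay bias, and a free intercept costs power; enable
  `marker_intercepts = TRUE` to absorb residual bias.
* Scan rows are ordered by genomic position (deterministic
  tie-breaking); re-running any stage with the same seed is
  reproducible, and every stochastic helper restores the caller's RNG
  state.
* Experiment sizes used by the validation suite: likelihood oracles on
  3–5 individuals; EM grid-search oracle at n = 50; parameter recovery
  100 replicates at n = 300; null calibration 1000 simulations at
  n = 300 each; cis-fraction recovery 100 replicates at n = 500;
  adjustment logic on the full two-cohort design.
* The LRT is an asymptotic test and is mildly anticonservative at
  realistic cohort sizes: across several thousand null simulations of
  the single-marker/single-SNP design at n = 300 (roughly 90
  informative heterozygotes) the rejection rate at nominal 0.05 is
  about 0.06.  Part of this is the usual $\chi^2$-vs-F effect of an
  estimated variance; the remainder traces to the phase-mixture terms
  of ambiguous double heterozygotes, whose likelihood contributions
  are bimodal in $\beta$.  It shrinks with sample size and with
  sharper phase posteriors (stronger LD), and is well within the
  tolerance of the calibration experiment, but P values near a
  threshold deserve the usual caution.

## Known limitations

* Bonferroni is conservative under the strong LD of a dense panel; the
  FWER values are upper bounds on family-wise significance.
* The likelihood treats the phase posteriors as known, ignoring
  haplotype-frequency estimation error; with cohort sizes in the
  hundreds and small subsets this is second-order.
* Combined-cohort fits pool the likelihood with shared $\beta$ and
  $\sigma^2_k$ but cohort-specific phase posteriors; cohort-by-effect
  heterogeneity is not modelled (compare cohorts with
  `compare_scans()` instead).
* No dominance, interactions, or multi-allelic cis sites — patterns
  such as a heterozygote class with stronger imbalance than either
  homozygote class (see `stratified_aer()`) are diagnosed, not
  modelled.
* The *sign* of a SNP effect is identified through the phase
  posterior, i.e. through LD between the tested SNP and the
  transcribed markers.  For a SNP in linkage equilibrium with the
  markers the phase posterior of every double heterozygote is near
  1/2, the likelihood is nearly symmetric in $\beta$, and the sign of
  the estimate is essentially arbitrary even though the magnitude (and
  the LRT) remain informative.  Cross-cohort or cross-method effect
  comparisons are therefore meaningful for SNPs with nontrivial
  marker LD — in practice the situation of any SNP close enough to a
  gene to be a cis candidate.
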