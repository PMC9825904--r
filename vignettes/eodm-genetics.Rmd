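---
title: "Methods: genetic risk scores and rare-variant prioritization for EODM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic risk scores and rare-variant prioritization for EODM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eodmtools)
```

## Background

Early-onset drusen maculopathy (EODM) is an AMD-like maculopathy diagnosed at
a young age (any sign of age-related maculopathy at 55 or younger, or severe
signs between 56 and 65). Because it appears decades before typical AMD, its
aetiology is expected to be more strongly genetic: a combination of the common
AMD-associated risk alleles — dominated by the complement pathway — and rare,
highly penetrant variants. `eodmtools` implements the analysis pipeline for
this setting: common-variant genetic risk scores (GRS), a rare-variant
prioritization cascade over candidate gene lists, a screen of inherited
retinal dystrophy (IRD) genes whose phenotypes can mimic AMD (Stargardt
disease, Sorsby fundus dystrophy), and the stage-stratified group statistics
used to report such cohorts.

Patient-level genomes for this kind of study are not public, so the package
pairs every analysis stage with a fully seeded synthetic cohort generator and
ships the published summary tables it can be validated against.

## Genetic risk scores

For a panel of $m$ variants the score of a sample is

$$\mathrm{GRS} = \sum_{i=1}^{m} G_i \,\beta_i,$$

where $G_i \in \{0,1,2\}$ counts the effect (minor) alleles and $\beta_i$ is
the natural logarithm of the variant's fully conditioned odds ratio — the
per-variant effect estimated jointly with all other panel variants in the
source GWAS. The default panel layout carries 52 variants, of which 19 are
tagged `complement` and 7 `lipid`; the overall GRS uses all variants and the
pathway GRS the tagged subsets. Because the tags partition the panel,

$$\mathrm{GRS}_\text{overall} =
  \mathrm{GRS}_\text{complement} + \mathrm{GRS}_\text{lipid} +
  \mathrm{GRS}_\text{other}$$

holds exactly for every sample, and the test suite asserts it on random
panels.

Design choices:

* **Effect sizes are configuration, not constants.** Published panels ship
  with their own effect sizes; the package's `default_risk_panel()` is a
  clearly labelled synthetic demonstration panel with literal, deterministic
  values. Real analyses must supply the panel file.
* **Allele coding.** The effect allele is whichever panel allele is declared,
  even if its observed cohort frequency exceeds 0.5 — the coding is fixed to
  the GWAS reference, not re-estimated locally. If the effect allele is the
  VCF reference allele, dosage flips to $2 - G$; scores are bit-identical
  under re-expression of a locus with swapped ref/alt.
* **Missing genotypes** default to mean imputation, $G = 2f$ with $f$ the
  configured panel frequency, which keeps scores comparable across samples
  with different missingness; a strict exclusion mode is available
  (`missing_policy = "exclude"`). When no frequency is configured the term is
  dropped either way and the missing count is reported per sample.

```{r grs-demo}
cfg <- simulation_config(n_controls = 300, n_cases = 49, seed = 1)
g <- simulate_common_genotypes(cfg)
prof <- grs_profiles(g, cfg$panel)
head(prof[, 1:4], 3)
c(simulated_control_mean = mean(prof$grs_overall[grepl("^ctrl_", prof$sample_id)]),
  analytic_control_mean = expected_mean_grs(cfg, "control"))
```

## Rare-variant prioritization cascade

The cascade mirrors the multi-step filtering used in WGS studies of EODM:

1. **Frequency:** keep variants with minor allele frequency below 1% in
   *both* an internal reference database and gnomAD; a missing frequency
   counts as rare (population databases not having seen a variant is
   evidence of rarity, not of commonness).
2. **Candidate genes:** intersect with the configured gene lists (complement
   pathway, lipid pathway, genes whose mouse models develop drusen-like
   phenotypes, and genes in AMD-associated loci). Multi-list membership is
   preserved and reported.
3. **Deleteriousness**, a disjunction of three rules with full reason codes:
   * *variant type*: nonsense, frameshift, stop-loss, or canonical
     splice-site (intronic offset ±1/±2);
   * *in silico*: PhyloP > 2.7 **and** CADD > 15 **and** Grantham > 80 — all
     three simultaneously, with strict inequalities, and a missing score
     failing its own comparison;
   * *ClinVar*: classification pathogenic, likely pathogenic, or the
     combined pathogenic/likely-pathogenic category.
4. **Recurrence:** a gene is reported when its rare variants are carried by
   at least two distinct patients (carrier union, not variant count).

Decisions that were genuinely open, and how they were settled:

* **Canonical splice is strict ±1/2.** Upstream annotation sometimes labels
  deeper intronic changes "splice-site"; a +6 donor-region variant is
  classified `splice_region` here and can only qualify through ClinVar. This
  keeps the type rule aligned with its biological rationale (obligatory
  splice positions).
* **ClinVar is rescue-only.** A benign or likely-benign ClinVar entry does
  not veto the type or in-silico rules. Reference results include
  ClinVar-benign variants retained by the in-silico rule, which is only
  consistent with rescue-only behaviour.
* **Grantham sentinels.** Variant tables conventionally print 1000 for stop
  gain/loss and 0 for frameshift and splice changes. The package reproduces
  that convention in `variant_grantham()`, but sentinels never drive
  classification: the type rule fires first for those classes. (Published
  tables are not always internally consistent here — one frameshift row
  prints 1000 — and the package deliberately emits 0 for frameshifts.)
* **Protein notation beats the consequence term** when the two conflict,
  because curated tables treat the protein change as authoritative.
* **Strict thresholds.** "Above the threshold" is implemented as `>`;
  the smallest passing Grantham value seen in reference data (81) is
  consistent with `> 80`.

The embedded Grantham matrix is the complete 1974 physicochemical distance
table (190 pairs, symmetric, zero diagonal), exported as `grantham_matrix`.

## IRD mimic screen

Eighteen genes causing macular dystrophies that can be mistaken for AMD are
screened with inheritance-aware carrier rules: autosomal dominant genes flag
on a single rare qualifying variant (nonsense, frameshift, protein-altering
or splice-site); autosomal recessive genes flag only on a biallelic state —
one homozygous variant or at least two distinct rare variants. Phase is
unknowable from unphased genotypes, so two heterozygous variants are assumed
in trans; this is deliberately conservative in the flagging direction.
Known pathogenic deep-intronic and structural events, which annotation-based
rules cannot classify, are matched by exact (gene, description) lookup from
the registry. The shipped 18-gene registry (12 AD, 6 AR) is a demonstration
reconstruction and is fully editable YAML.

## Group statistics

Cohort descriptives follow the reporting conventions of the field:
categorical fields as n (%) rounded to one decimal, continuous fields as
mean (SD) when normally distributed and median (IQR) otherwise. Score
comparisons use one-way ANOVA for normal data and Kruskal–Wallis for skewed
data. The normality decision was unspecified in the emulated workflow; the
package adopts per-group Shapiro–Wilk at $\alpha = 0.05$ (ANOVA only when no
group rejects), with `force_kw` / `force_anova` overrides so either test can
be forced. Stage-trend analyses are reported as the omnibus k-group test
across stages, not as an ordered trend test.

One numerical choice deserves emphasis: the chi-square approximation to the
Kruskal–Wallis null distribution is poor at very small samples, so for total
$n \le 8$ (configurable) the p-value is computed from the exact permutation
distribution — all distinct assignments of the pooled observations to the
observed group sizes, with midranks handling ties. The suite checks this
against an independent brute-force enumeration over all $n!$ orderings, and
checks the chi-square path's type-I error (0.05 ± 0.01 over 10,000 null
datasets of three groups of 30).

Degenerate inputs are errors, not silent results: all-tied observations
(rank test undefined), single groups, and zero within-group variance
everywhere (F undefined).

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
sequence-level data:

* **Controls** draw Hardy–Weinberg genotypes at each panel frequency $p$.
* **Cases** reweight genotype $g$ by $\mathrm{OR}^g$ (per-allele
  multiplicative odds). This retrospective reweighting matches the
  per-allele odds-ratio parameterization of the GRS weights directly and is
  again Hardy–Weinberg at $p' = p\,\mathrm{OR}/(1 - p + p\,\mathrm{OR})$,
  giving the closed form $E[\mathrm{GRS}] = \sum_i 2 p_i' \beta_i$ used as a
  convergence oracle (`expected_mean_grs()`).
* **Stage assignment is independent of genotype by default** (clean null);
  an optional severity-gradient mode inflates case betas by 25%/50% for
  stage-3/stage-4 cases to emulate a risk gradient over disease stages.
* **Rare variants** are planted in candidate genes with truth labels
  recorded out of band. Deleterious-class variants are engineered to fire
  exactly one named rule; benign-class variants to fire none. The in-silico
  score distributions are invented (no public reference provides them) and
  chosen to straddle the thresholds with a margin: benign CADD
  ~ N(8, 3) truncated below 14.5, deleterious CADD ~ N(25, 4) truncated
  above 15.5, and analogously for PhyloP and Grantham (deleterious missense
  changes draw a residue pair whose matrix distance exceeds 80, so the
  printed Grantham is consistent with the printed protein change).

Default group sizes are 925 controls and 49 cases with the case stage
distribution 10 : 17 : 22 over stage 1–2, stage 3 and stage 4 (stage 4 split
13 GA / 8 CNV / 1 mixed), i.e. the composition of the reference cohort. The
seed fully determines all output files byte-for-byte.

What passing tests on synthetic data do **not** show: the generator models
panel loci as independent (no linkage disequilibrium), plants rare variants
at user-set rates rather than from a mutation model, draws in-silico scores
from parametric distributions rather than real tool output, and contains no
genotyping error or relatedness. Results on synthetic cohorts validate the
pipeline's correctness, not biological effect sizes.

## Validation against published results

Three published anchors are reproduced exactly by the test suite and the
acceptance script, using only data bundled with the package:

* running the cascade on the bundled reference rare-variant table flags
  every row, spanning 19 genes with 16 complement-tagged rows;
* the embedded Grantham matrix returns the printed distance for every
  missense row of that table (e.g. Leu→Pro 98, Asp→Gly 94, Cys→Phe 205);
* the reference cohort composition yields 44.9% advanced-stage disease and
  67.3% female.

Cohort-scale quantities (mean GRS of 925 real controls, genome-wide variant
counts) require the original genomes and are replaced by the property checks
described above: the exact pathway-partition identity, closed-form recovery
of the simulated control mean within three Monte-Carlo standard errors at
n = 5000, planted-variant recovery with sensitivity 1.0 and zero benign
false positives, and the rank-test calibration checks. Problem sizes in the
suite (5000-control GRS recovery, 10,000 null datasets for calibration,
twenty 500-sample cohorts for the stage-gradient power check) were chosen so
the Monte-Carlo error is well inside each asserted tolerance.

## Known limitations

* The HGVS parser covers the clinical reporting subset (substitutions, stop
  gain/loss with extension, frameshifts, simple inframe indels, synonymous);
  inversions and delins with sequence payloads are out of scope.
* Annotation is one row per variant (canonical transcript); multi-transcript
  collapse is assumed to have happened upstream.
* No burden testing: cohorts of this size cannot establish rare-variant
  association, and the package deliberately stops at prioritization.
* ClinVar/gnomAD values are consumed as static annotation snapshots; no
  live queries.
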