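---
title: "eQTL-integrated GWAS discovery for SLE: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eQTL-integrated GWAS discovery for SLE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slepipe)
```

# The analysis

`slepipe` re-implements, as a tested pipeline over synthetic data, a staged
case-control discovery design for systemic lupus erythematosus (SLE) in
which cis-eQTL evidence is used to rescue sub-threshold GWAS signals. The
chain is:

1. **Quality control** — per-sample call rate, per-group SNP call rate and
   minor allele frequency, exact Hardy-Weinberg test in controls,
   relatedness by identity-by-descent, PCA ancestry outliers, and the
   genomic-control inflation factor $\lambda_{GC}$.
2. **Association** — the Cochran-Armitage trend test per SNP, allelic odds
   ratios with Woolf confidence intervals, and Mantel-Haenszel fixed-effect
   combination across stages.
3. **cis-eQTL screen** — OLS regression of rank-normalized probe expression
   on genotype dose (0/1/2) for probes within ±300 kb of each SNP, one
   global Benjamini-Hochberg family, and an "eQTL positive" flag at
   $Q < 0.2$.
4. **Prioritization** — candidates require GWAS $P < 10^{-4}$, or
   $10^{-4} \le P < 10^{-3}$ together with eQTL positivity; the best SNP
   per locus is kept, known susceptibility loci are excluded, and a
   pooled-DNA scan must support the candidate (a pooled SNP with rank-based
   $P < 0.01$ within ±100 kb or in LD at $r^2 > 0.5$).
5. **Replication gating** — Mantel-Haenszel combination of discovery +
   replication 1 gated at $P < 10^{-6}$; all three stages combined and
   declared significant at $P < 5\times10^{-8}$.
6. **ASTQ** — allele-specific transcript quantification: a genomic-DNA
   mixture standard curve converts TaqMan Ct differences into allelic
   ratios; cDNA/DNA ratio pairs per heterozygous cell line are tested for
   allelic imbalance by a paired t-test on the log2 scale.

All inputs are produced by the package's own synthetic-data generator, so
every stage is testable end to end without external data. The numbered
drivers under `analysis/` run the stages in sequence and write their tables
under `results/`.

# The synthetic-data generator

The generator defines the study conditions; its defaults are the emulated
design's sample sizes (discovery 891/3,384; replications 562/653 and
825/27,911; expression panel 90, matching an East-Asian lymphoblastoid
reference panel).

**Genotypes.** SNPs are partitioned into LD blocks, each on its own
synthetic chromosome (SNP spacing 25 kb). Within a block all SNPs share one
allele frequency drawn from `maf_range` and haplotypes follow a first-order
Markov copy process: allele $j$ equals allele $j-1$ with probability
$\rho$ (`block_ld_rho`), otherwise it is redrawn. With equal frequencies
the adjacent-SNP haplotype correlation is exactly $\rho$, which makes the
haplotype-counting LD oracle in the tests exact. A finite per-block
haplotype pool is available (`pool_size`), but the default draws each
haplotype fresh: a finite pool of size $K$ inflates null LD to
$E[r^2] \approx 1/K$, which would contaminate independence checks.

**Phenotypes.** Disease follows an additive liability-logit model,
$\mathrm{logit}\,P(\text{case}) = \beta_0 + \sum_k \log(\mathrm{OR}_k)
g_k$. The baseline $\beta_0$ is solved by 1-D root finding (tolerance
$10^{-8}$) so the population prevalence matches the configuration; cases
and controls are then ascertained by rejection sampling to the exact
quotas. Prevalence defaults to 0.01 — within the rare-disease regime where
the allelic odds ratio approximates the per-allele liability odds ratio,
yet dense enough that rejection sampling is tractable. When every odds
ratio is 1, status is independent of genotype and the generator draws the
quotas directly; this is an exact identity of the null model, not an
approximation. Missingness is completely at random; QC-violating fixtures
(low call rate, Hardy-Weinberg violations, ancestry outliers) come from
dedicated corruption helpers, never from the base model.

**Expression.** Each configured cis-eQTL SNP receives one probe inside its
±300 kb window with expression $\beta \cdot g + N(0, \sigma)$; the other
probes of that region, and all probes of randomly chosen decoy regions,
are pure noise. Probe coordinates are emitted 0-based half-open (BED).

**Pooled scan.** Each SNP gets an absolute standard-normal score; SNPs
within 100 kb of a causal SNP get a configurable mean shift (default 4),
and scores are converted to rank-based P-values ($p_i = \mathrm{rank}_i /
N$, average ranks for ties), uniform by construction under the null. The
score model is a stand-in: the pooled-array statistic it emulates is
consumed by the pipeline as a summary table, never recomputed, so only the
rank distribution and its spatial enrichment matter here.

**qPCR plates.** Ct values obey $Ct = Ct_0 - \log_2(\text{allele amount})
+ \text{channel offset} + N(0, \sigma_{Ct})$. A sample of total amount 1
with VIC:FAM ratio $r$ has allele amounts $r/(1+r)$ and $1/(1+r)$, hence
$\Delta Ct = -\log_2 r + \text{offset}$ — the standard curve's slope is
$-1$ at perfect efficiency, and the 2:8 mixture sits exactly
$+2$ cycles from the 5:5 mixture. The default plate is the 2:8 … 8:2
mixture series plus quadruplicate genomic-DNA (ratio 1) and cDNA pairs per
line.

**What the generator does not emulate:** genotyping-intensity artifacts
and cluster-plot failures, population admixture beyond a single
outlier-injection helper, X-chromosome inheritance, imputation
uncertainty, batch effects in expression, and qPCR efficiency differences
between alleles. Passing tests therefore demonstrate the statistical
machinery and decision logic under the assumed models, not robustness to
those real-data pathologies.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `sample_call_rate_min` | 0.98 | sample retained iff call rate ≥ 0.98 (strictly-below excluded) |
| `snp_call_rate_min` | 0.99 | per group (cases, controls) separately |
| `maf_min` | 0.01 | minor allele defined within each group separately |
| `hwe_p_min` | 1e-6 | exact test, controls only |
| `pihat_relatedness_min` | 0.1875 | midpoint between 2nd- and 3rd-degree expectations |
| `pca_outlier_sd` | 6 | distance from target-cluster centroid on PCs 1–2 |
| `p_select_strong` / `p_select_eqtl` | 1e-4 / 1e-3 | compound selection band |
| cis window | ±300 kb | probe interval intersection, boundaries inclusive |
| `q_threshold` | 0.2 | eQTL positivity, strict `<` |
| `pooled_rank_p` / `pooled_ld_r2` / distance | 0.01 / 0.5 / 100 kb | pooled-scan support |
| `p_stage_gate` / `p_genomewide` | 1e-6 / 5e-8 | replication gates |
| `locus_window_bp` | 500 kb | clumping radius (analysis choice) |
| `exclusion_window_bp` | 200 kb | known-locus exclusion radius (analysis choice) |

Band boundaries follow the quoted rules exactly: the strong-selection
clause is strict (`p < 1e-4`), so a SNP at exactly $10^{-4}$ needs eQTL
positivity; the cis window includes a probe starting exactly 300,000 bp
away; pooled support includes a signal at exactly 100,000 bp.

# Numerical and design choices

**Hardy-Weinberg exact test.** Two-sided by the standard convention: the
P-value sums the conditional probabilities of all heterozygote counts (at
the observed allele totals) no more probable than the observed one,
computed by the stable mid-out recurrence. The test suite checks identity
with a full log-factorial enumeration to $10^{-12}$ for tables up to 200
alleles.

**Trend vs χ² calibration.** The trend statistic's exact null departs from
$\chi^2_1$ by a finite-sample margin that a Kolmogorov-Smirnov test over
10,000 SNPs can detect at small cohorts (500/500: KS $P \approx
3\times10^{-4}$) even though calibration is fine (type-I error 0.048,
$\lambda_{GC}$ 0.99). The uniformity check therefore runs at 2,000/2,000
with MAF ≥ 0.2, where the approximation error is below KS detectability;
the type-I-error and $\lambda_{GC}$ checks stay at 500/500.

**Confidence intervals.** Woolf (log-OR normal) for single 2×2 tables,
Robins-Breslow-Greenland for the Mantel-Haenszel estimate; both reproduce
the published CI widths at printed precision on the worked examples. Zero
cells get the 0.5 continuity correction and a flag. The combined P-value
is the 1-df Mantel-Haenszel χ² without continuity correction; whether the
original combined analysis used a stratified trend test instead is not
determinable from the description, and the MH reading follows its naming.

**Reconstructing counts from printed frequencies.** Allele counts are
$2nf$ rounded half away from zero — published tables round half up, while
base R rounds half to even; the difference changes reconstructed odds
ratios in the second decimal, so the convention is pinned and exported
(`round_half_up`).

**BH q-values** are computed by `stats::p.adjust(method = "BH")` behind
the `bh_fdr()` surface and verified against a literal step-up
implementation on 1,000 random vectors. The FDR family is one global
family over all cis pairs — the conservative reading of a study-wide
screen; a per-SNP family is available via `fdr_family = "per_snp"`.

**EM haplotype LD.** Two-SNP haplotype frequencies are estimated by EM
over unphased genotypes (only the double heterozygote is phase-ambiguous),
convergence $|\Delta| < 10^{-10}$ within 1,000 iterations. On fixtures
where each SNP pair carries at most three haplotypes ($D' = 1$), phase is
identifiable and the EM optimum coincides with direct phased counting —
the identity the tests assert to $10^{-8}$. With all four haplotypes
present the EM maximum-likelihood estimate and the phased counts are
different estimators and agree only asymptotically.

**IBD.** Method-of-moments from the identity-by-state distribution given
sample allele frequencies, with (z0, z1, z2) truncated to [0, 1] and
renormalized; no small-sample bias correction is applied (at the SNP
counts used here its effect is far below the 0.1875 decision threshold).
Which member of a related pair is dropped is unspecified in such designs;
the rule here — lower call rate, ties to the lexicographically larger id —
is deterministic.

**PCA outliers.** The centroid is the coordinate-wise *median* of the
study samples on PCs 1–2, so a single outlier cannot drag it; the cluster
SD is the RMS distance. The 6-SD rule is a reconstruction (the emulated
protocol names software, not a criterion) and is configurable. LD pruning
before PCA/IBD uses the conventional 50-SNP window, step 5, $r^2 > 0.2$.

**QC iteration.** Sample call-rate and SNP filters interact (removing SNPs
changes sample call rates), so they are iterated to a fixed point. This
makes QC idempotent by construction: re-running QC on its own output
excludes nothing.

**Candidate-set comparison.** The compound rule's candidate set is by
construction a superset of the strict rule's ($p < 10^{-4}$) and a subset
of the loose rule's ($p < 10^{-3}$). The end-to-end property asserted is
therefore: strictly more frequent recovery of a mid-band causal eQTL SNP
than the strict rule, at an average candidate-set size no larger than the
loose rule that would be needed to match that recovery by P-value alone.

**Replication-stage simulation.** Replication cohorts genotype only the
candidate SNPs, so they are simulated as independent loci under HWE at the
discovery allele frequencies with the same liability model — LD structure
is irrelevant to single-SNP association there. Allele orientation across
stages is reconciled by allele-letter matching with strand-flip detection;
A/T and G/C SNPs with mismatched orientation are an error, since no
non-experimental information can resolve them.

**Determinism.** One master seed; every component (genotypes, phenotypes,
expression, pooled scan, plates, replication stages) derives its own
stream from the master seed and a component label, so adding a component
never perturbs another. The run manifest records a canonical hash of the
configuration and all stage outputs; identical config + seed reproduces
identical files byte for byte.

# Problem sizes used by the tests and the acceptance script

Simulation-based checks run at the following sizes, chosen to give the
asserted properties comfortable margins while keeping a laptop-scale
runtime: type-I error and $\lambda_{GC}$ over 10,000 null SNPs at 500/500;
KS uniformity over 10,000 SNPs at 2,000/2,000; CI coverage over 100 seeds
at 891/3,384; the prioritization comparison over 200 seeds (tests) or 60
seeds (acceptance script) at 891/3,384 with 100 SNPs in 20 blocks; ASTQ
recovery over 100 seeds at 17 lines. The full-scale study quantities
(430,797 SNPs × 4,275 subjects, genome-wide eQTL-positivity rates, the
1,207 → 57 → 8 selection funnel, and the wet-lab measurements) require the
original data and are outside what synthetic desk-scale runs can
reproduce; the pipeline reports such counts, it does not assert them.

# Known limitations

- The pooled-scan score model is a parameterized stand-in; only its rank
  distribution and spatial enrichment are meaningful.
- The liability model is additive on the logit scale with independent risk
  SNPs; no epistasis, dominance, or polygenic background.
- Expression noise is Gaussian and homoscedastic; the rank-based inverse
  normal transform makes the regression insensitive to monotone
  distortions but not to genotype-dependent variance.
- ASTQ assumes equal amplification efficiency for both alleles; the
  mixture curve absorbs a constant channel offset but not
  efficiency-by-allele interactions.
- The IBD estimator assumes homogeneous ancestry; in stratified samples
  π̂ is biased upward.
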