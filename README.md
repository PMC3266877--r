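# slepipe

An R implementation of an eQTL-integrated, multi-stage GWAS discovery
pipeline for systemic lupus erythematosus (SLE), exercised end to end on
synthetic data. It is written for statistical geneticists who want a
tested, reproducible reference implementation of the full decision chain —
quality control, staged case-control association, cis-eQTL prioritization,
pooled-scan cross-referencing, replication gating, and allele-specific
transcript quantification (ASTQ) — rather than a wrapper around existing
GWAS tooling.

## The statistical core

Per SNP, case-control association uses the Cochran-Armitage trend test
with dose weights (0, 1, 2),

χ² = N·(N·Σwᵢrᵢ − R·Σwᵢnᵢ)² / [R(N−R)·(N·Σwᵢ²nᵢ − (Σwᵢnᵢ)²)],

with the allelic odds ratio OR = ad/bc and Woolf 95% CI. Stages are
combined by the Mantel-Haenszel estimator OR_MH = Σ(aᵢdᵢ/Nᵢ) / Σ(bᵢcᵢ/Nᵢ)
with the Robins-Breslow-Greenland variance and the 1-df MH χ².

Candidate SNPs for replication are selected by a compound rule: GWAS
P < 10⁻⁴ outright, or 10⁻⁴ ≤ P < 10⁻³ together with an "eQTL positive"
flag — at least one expression probe within ±300 kb whose additive
regression on genotype dose passes a global Benjamini-Hochberg FDR of
Q < 0.2. Candidates must then be supported by a pooled-DNA scan (a signal
with rank-based P < 0.01 within ±100 kb or in LD at r² > 0.5, with LD from
EM-estimated haplotype frequencies), pass a combined P < 10⁻⁶ gate after
the first replication, and reach P < 5×10⁻⁸ over all stages.

ASTQ converts TaqMan Ct pairs into allelic ratios through a genomic-DNA
mixture standard curve (ΔCt regressed on log₂ ratio; slope −1 at perfect
efficiency), normalizes each cell line's cDNA ratio by its own DNA ratio,
and tests allelic imbalance by a paired t-test on log₂ ratios.

QC implements the exact Hardy-Weinberg test (mid-out recurrence over
heterozygote counts), per-group call-rate and MAF filters, identity-by-
descent relatedness by method of moments, PCA ancestry outliers, and the
genomic-control factor λ_GC.

A first-class synthetic-data module generates every input the pipeline
consumes — LD-blocked genotypes, case-control status under an additive
liability model, probe expression with cis effects, pooled-scan tables,
and qPCR plates — so all of the above is testable without external data.

## Worked example

The numbered drivers under `analysis/` run the whole synthetic study
(`Rscript analysis/01_simulate_cohort.R` … `07_astq.R`), writing tables
under `results/`. Driver 06 reworks the published association tables; it
prints:

```
rs340630 Mantel-Haenszel combination of the three stages:
  OR = 1.2034 (95% CI 1.127-1.285), P = 3.3e-08  [published: 1.21, P = 8.3e-9]

known-locus replication at alpha = 0.01: 17 of 26
  Asian-identified loci:    8 of 10 (80%)
  European-identified loci: 9 of 16 (56.3%)
eQTL-positive among the 26 loci: 8 (30.8%)
```

i.e. reconstructing allele counts from the printed stage frequencies and
sample sizes and pooling them by Mantel-Haenszel lands within 0.01 of the
published combined odds ratio, and 17 of the 26 previously reported SLE
loci replicate at α = 0.01, with the Asian-discovered subset replicating
at a higher rate (80%) than the European-discovered one (56.3%).

Driver 05 runs the full synthetic discovery chain; with the shared
configuration (891/3,384 discovery cohort, one causal cis-eQTL SNP with
allelic OR 1.2) it prints, for example:

```
surviving candidates:
  snp_id       stage supporting_pooled_snp   p_gwas p_combined12 p_combined_all or_mh
 snp0250 rep1_passed               snp0248 1.52e-05     7.44e-07       6.17e-08   1.2
```

— the causal SNP (true OR 1.2) is the only candidate to clear selection,
clumping and pooled support, passes the stage gate, and its three-stage
combined P of 6.2×10⁻⁸ falls just short of genome-wide significance in
this particular run, which is the expected behaviour for a modest-effect
locus at these sample sizes.

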