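#!/usr/bin/env Rscript

# Stage 1 of the analysis: simulate the discovery cohort.
#
# Generates a case-control panel at the discovery-stage sample sizes
# (891 cases, 3,384 controls) with LD-blocked genotypes, one causal
# cis-eQTL SNP of modest effect (allelic OR 1.2, expression beta 0.8), and
# writes the genotype/phenotype/truth tables under results/.

suppressPackageStartupMessages(library(slepipe))

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE)[1])),
                 "00_config.R"))

outdir <- "results/01_cohort"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cohort <- simulate_cohort(config)
write_genotype_tsv(cohort$genotypes, file.path(outdir, "genotypes.tsv"))
write_phenotypes(cohort$genotypes$samples, file.path(outdir, "phenotypes.tsv"))
utils::write.table(cohort$truth, file.path(outdir, "truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

maf <- colMeans(cohort$genotypes$geno, na.rm = TRUE) / 2
cat(sprintf("simulated %d samples x %d SNPs; causal SNP %s (OR %.2f)\n",
            nrow(cohort$genotypes$geno), ncol(cohort$genotypes$geno),
            cohort$truth$snp_id, cohort$truth$allele_or))
cat(sprintf("realized MAF range: %.3f - %.3f; missingness %.3f%%\n",
            min(pmin(maf, 1 - maf)), max(pmin(maf, 1 - maf)),
            100 * mean(is.na(cohort$genotypes$geno))))
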