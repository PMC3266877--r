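#!/usr/bin/env Rscript

# Stage 4: cis-eQTL screen.
#
# Simulates the expression reference panel for the QC-passed genotypes,
# regresses rank-normalized probe expression on genotype dose within
# +/- 300 kb cis windows, adjusts all pairs by one global Benjamini-Hochberg
# family, and flags eQTL-positive SNPs at Q < 0.2.

suppressPackageStartupMessages(library(slepipe))
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE)[1])),
                 "00_config.R"))

outdir <- "results/04_eqtl"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

g <- read_genotypes("results/02_qc/genotypes_qc.tsv", "tsv")
g$samples <- read_phenotypes("results/02_qc/phenotypes_qc.tsv")

ex <- simulate_expression(g, config)
write_expression_tsv(ex$expr, file.path(outdir, "expression.tsv"))
write_probe_bed(ex$probes, file.path(outdir, "probes.bed"))

scan <- eqtl_scan(g, ex$expr, ex$probes)
utils::write.table(scan$tests, file.path(outdir, "eqtl_tests.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(scan$flags, file.path(outdir, "eqtl_flags.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d cis SNP-probe pairs tested (%.2f probes per SNP with pairs)\n",
            nrow(scan$tests),
            nrow(scan$tests) / length(unique(scan$tests$snp_id))))
cat(sprintf("%d of %d SNPs eQTL positive (Q < 0.2): %.1f%%\n",
            sum(scan$flags$positive), nrow(scan$flags),
            100 * mean(scan$flags$positive)))
best <- scan$tests[which.min(scan$tests$q), ]
cat(sprintf("strongest pair: %s x %s, beta = %.2f, R^2 = %.3f, Q = %.2g\n",
            best$snp_id, best$probe_id, best$beta, best$r_squared, best$q))
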