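test_that("genotype simulation is deterministic given config and seed", {
  cfg <- sim_config(n_cases = 50, n_controls = 100, n_snps = 40, n_blocks = 4,
                    seed = 11)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
})

test_that("realized allele frequencies stay inside maf_range up to binomial error", {
  cfg <- sim_config(n_cases = 500, n_controls = 500, n_snps = 50, n_blocks = 5,
                    maf_range = c(0.1, 0.4), missing_rate = 0, seed = 7)
  g <- simulate_genotypes(cfg)
  freq <- colMeans(g$geno) / 2
  maf <- pmin(freq, 1 - freq)
  se <- sqrt(0.4 * 0.6 / (2 * nrow(g$geno)))
  expect_true(all(maf > 0.1 - 4 * se - 0.01))
  expect_true(all(maf < 0.4 + 4 * se + 0.01))
})

test_that("rho = 0 gives independent adjacent SNPs; duplicated columns give r2 = D' = 1", {
  cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_snps = 20,
                    n_blocks = 2, block_ld_rho = 0, missing_rate = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  r2 <- vapply(seq_len(9), function(j) {
    suppressWarnings(stats::cor(g$geno[, j], g$geno[, j + 1]))^2
  }, numeric(1))
  expect_true(all(r2 < 0.05))
  ## forced duplicate pair (rho -> 1 limit)
  g$geno <- cbind(g$geno, dup = g$geno[, 1])
  g$map <- rbind(g$map, data.frame(snp_id = "dup", chrom = g$map$chrom[1],
                                   pos = g$map$pos[1] + 5L, allele1 = "A",
                                   allele2 = "G", block = g$map$block[1],
                                   maf = g$map$maf[1]))
  ld <- ld_r2_dprime(g, g$map$snp_id[1], "dup")
  expect_equal(ld$r_squared, 1, tolerance = 1e-8)
  expect_equal(ld$d_prime, 1, tolerance = 1e-8)
})

test_that("within-block LD matches a haplotype-counting oracle", {
  cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_snps = 100,
                    n_blocks = 10, block_ld_rho = 0.8, missing_rate = 0, seed = 1)
  g <- simulate_genotypes(cfg, return_haplotypes = TRUE)
  H <- attr(g, "haplotypes")
  ## empirical genotype-correlation r2 between adjacent in-block SNPs vs the
  ## exact haplotype-count r2 of the same emitted haplotypes
  blocks <- split(seq_len(ncol(H)), g$map$block)
  diffs <- unlist(lapply(blocks, function(cols) {
    vapply(seq_len(length(cols) - 1L), function(k) {
      i <- cols[k]; j <- cols[k + 1L]
      emp <- suppressWarnings(stats::cor(g$geno[, i], g$geno[, j]))^2
      emp - hap_ld_oracle(H, i, j)$r_squared
    }, numeric(1))
  }))
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("null phenotype model leaves case/control frequencies compatible", {
  cfg <- sim_config(n_cases = 400, n_controls = 400, n_snps = 30, n_blocks = 3,
                    missing_rate = 0, seed = 9)
  co <- simulate_cohort(cfg)
  st <- co$genotypes$samples$status
  fc <- colMeans(co$genotypes$geno[st == 2, ]) / 2
  fk <- colMeans(co$genotypes$geno[st == 1, ]) / 2
  se <- sqrt(fc * (1 - fc) / (2 * 400) + fk * (1 - fk) / (2 * 400))
  expect_true(all(abs(fc - fk) < 3.5 * se + 1e-9))
  expect_equal(nrow(co$truth), 0L)
})

test_that("invalid configurations fail naming the field", {
  expect_error(sim_config(n_cases = 0), "n_cases")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(block_ld_rho = 1), "block_ld_rho")
  expect_error(sim_config(risk_snps = data.frame(snp_index = 999, allele_or = 1.2),
                          n_snps = 10, n_blocks = 2), "risk_snps")
  expect_error(sim_config(risk_snps = data.frame(snp_index = 1, allele_or = -1),
                          n_snps = 10, n_blocks = 2), "risk_snps")
})

test_that("truth table covers exactly the configured risk SNPs", {
  cfg <- sim_config(n_cases = 50, n_controls = 50, n_snps = 30, n_blocks = 3,
                    risk_snps = data.frame(snp_index = c(5, 20),
                                           allele_or = c(1.4, 1.2),
                                           eqtl_beta = c(0.5, NA)),
                    seed = 2)
  co <- simulate_cohort(cfg)
  expect_setequal(co$truth$snp_id, c("snp0005", "snp0020"))
  expect_true(all(co$genotypes$geno %in% c(0L, 1L, 2L) |
                  is.na(co$genotypes$geno)))
})

test_that("noiseless expression recovers the simulated effect exactly", {
  cfg <- sim_config(n_cases = 50, n_controls = 100, n_snps = 20, n_blocks = 2,
                    n_expr_samples = 60, expr_noise_sd = 0, missing_rate = 0,
                    probes_per_region = 1,
                    risk_snps = data.frame(snp_index = 3, allele_or = 1,
                                           eqtl_beta = 1),
                    seed = 4)
  co <- simulate_cohort(cfg)
  ex <- simulate_expression(co$genotypes, cfg)
  target <- ex$probes$probe_id[grepl("^target", ex$probes$gene_label)]
  expect_length(target, 1L)
  samp <- colnames(ex$expr)
  fit <- eqtl_regression(co$genotypes$geno[samp, "snp0003"],
                         ex$expr[target, ])
  expect_equal(fit$beta, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("null expression keeps the type-I error of the cis screen near nominal", {
  cfg <- sim_config(n_cases = 300, n_controls = 300, n_snps = 250,
                    n_blocks = 250, block_ld_rho = 0, n_expr_samples = 90,
                    expr_noise_sd = 1, missing_rate = 0,
                    probes_per_region = 4, n_decoy_regions = 250, seed = 21)
  co <- simulate_cohort(cfg)
  ex <- simulate_expression(co$genotypes, cfg)
  sc <- eqtl_scan(co$genotypes, ex$expr, ex$probes)
  expect_gte(nrow(sc$tests), 900)
  rate <- mean(sc$tests$p < 0.05)
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("expression-effect estimates are unbiased at the cell-line panel scale", {
  ## beta = 0.6, sd = 1, n = 62 heterozygosity-rich panel, 200 seeds
  betas <- vapply(1:200, function(s) {
    set.seed(s)
    g <- stats::rbinom(62, 2, 0.4)
    y <- 0.6 * g + stats::rnorm(62)
    eqtl_regression(g, y)$beta
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.6), 0.05)
})

test_that("pooled scan is uniform under the null and powered at causal loci", {
  cfg <- sim_config(n_cases = 50, n_controls = 50, n_snps = 1000,
                    n_blocks = 100, seed = 3)
  map <- slepipe:::block_layout(cfg)
  empty_truth <- data.frame(snp_id = character(), chrom = character(),
                            pos = integer(), allele_or = numeric(),
                            eqtl_beta = numeric(), causal = logical())
  ps <- simulate_pooled_scan(map, empty_truth, cfg)
  expect_equal(nrow(ps), 1000L)
  ks <- suppressWarnings(stats::ks.test(ps$rank_p, "punif"))
  expect_gt(ks$p.value, 0.01)
  ## strong enrichment pushes the causal SNP into the top percentile
  truth <- data.frame(snp_id = "snp0500", chrom = map$chrom[500],
                      pos = map$pos[500], allele_or = 1.5, eqtl_beta = NA,
                      causal = TRUE)
  hits <- vapply(1:50, function(s) {
    cfg2 <- sim_config(n_cases = 50, n_controls = 50, n_snps = 1000,
                       n_blocks = 100, seed = s, pooled_enrichment = 4)
    ps2 <- simulate_pooled_scan(map, truth, cfg2)
    ps2$rank_p[ps2$snp_id == "snp0500"] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("ASTQ plate obeys the exact log2 amount-Ct law when noiseless", {
  plate <- simulate_astq_plate(true_ratio = 1, n_lines = 2, noise_sd_ct = 0,
                               seed = 1, vic_offset = 0)
  dna <- plate[plate$material == "genomic_dna" & plate$sample_id == "line01", ]
  cdna <- plate[plate$material == "cdna" & plate$sample_id == "line01", ]
  expect_equal(mean(dna$ct_vic - dna$ct_fam), mean(cdna$ct_vic - cdna$ct_fam),
               tolerance = 1e-12)
  mix <- plate[plate$material == "mixture", ]
  dct <- tapply(mix$ct_vic - mix$ct_fam, mix$mixture_ratio, mean)
  ## 2:8 vs 5:5: dCt difference is -log2(0.25) - (-log2(1)) = +2 cycles
  expect_equal(unname(dct[as.character(2 / 8)] - dct["1"]), 2,
               tolerance = 1e-12)
})
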