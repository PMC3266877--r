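make_gwas <- function(snp_id, chrom, pos, p) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos, p = p,
             stringsAsFactors = FALSE)
}

test_that("EM haplotype LD equals phased-count oracle on phased fixtures", {
  ## 10-SNP phased fixtures with a ladder haplotype pool (columns monotone
  ## within a haplotype), so every SNP pair carries at most three of the four
  ## haplotypes (D' = 1) and the EM maximum coincides with the phased counts;
  ## phase of double heterozygotes is then identifiable and the identity is
  ## exact up to EM tolerance.
  set.seed(14)
  worst_f <- 0; worst_r2 <- 0; checked <- 0
  for (rep in 1:10) {
    lens <- sample(0:10, 8, replace = TRUE)
    pool <- t(vapply(lens, function(L) as.integer(seq_len(10) <= L), integer(10)))
    H <- pool[sample.int(8, 2 * 400, replace = TRUE), ]
    G <- H[seq(1, nrow(H), 2), ] + H[seq(2, nrow(H), 2), ]
    g <- wrap_geno(G)
    for (k in 1:5) {
      cols <- sample.int(10, 2)
      orc <- hap_ld_oracle(H, cols[1], cols[2])
      if (is.na(orc$r_squared)) next
      mine <- tryCatch(ld_r2_dprime(g, cols[1], cols[2]), error = function(e) NULL)
      if (is.null(mine)) next
      checked <- checked + 1
      worst_r2 <- max(worst_r2, abs(mine$r_squared - orc$r_squared))
      worst_f <- max(worst_f, max(abs(sort(mine$haplotype_freqs) -
                                      sort(unname(orc$freqs)))))
    }
  }
  expect_gt(checked, 20)
  expect_lt(worst_f, 1e-8)
  expect_lt(worst_r2, 1e-8)
})

test_that("LD of independent SNPs is near zero; identical columns are perfect LD", {
  set.seed(15)
  G <- cbind(a = stats::rbinom(2000, 2, 0.3), b = stats::rbinom(2000, 2, 0.4))
  g <- wrap_geno(G)
  ld <- ld_r2_dprime(g, "a", "b")
  expect_lt(ld$r_squared, 0.05)
  g2 <- wrap_geno(cbind(a = G[, 1], b = G[, 1]))
  ld2 <- ld_r2_dprime(g2, "a", "b")
  expect_equal(ld2$r_squared, 1, tolerance = 1e-8)
  expect_equal(ld2$d_prime, 1, tolerance = 1e-8)
  expect_error(ld_r2_dprime(g2, "a", "zz"), "not found")
  expect_error(ld_r2_dprime(wrap_geno(cbind(a = rep(1L, 10), b = 0:1)), "a", "b"),
               "polymorphic")
})

test_that("rank-based P-values follow the rank/N rule with average ties", {
  sc <- c(10, 5, 1)
  expect_equal(rank_based_p(sc), c(1, 2, 3) / 3)
  expect_equal(rank_based_p(rep(2, 10)), rep(11 / 20, 10))
  s <- c(rep(0, 98), 100, 50)
  expect_equal(rank_based_p(s)[99], 1 / 100)
  expect_error(rank_based_p(numeric(0)), "empty")
  expect_error(rank_based_p(c(1, Inf)), "finite")
  set.seed(16)
  ks <- suppressWarnings(stats::ks.test(rank_based_p(stats::rnorm(10000)), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("compound selection applies the exact band boundaries", {
  gwas <- make_gwas(paste0("s", 1:5), "chr1", (1:5) * 1e6,
                    c(5e-5, 5e-4, 5e-4, 1e-4, 2e-3))
  flags <- data.frame(snp_id = paste0("s", 1:5),
                      positive = c(FALSE, TRUE, FALSE, FALSE, TRUE))
  dec <- select_candidates(gwas, flags)
  expect_identical(dec$selected, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(dec$reason_codes[3], "eqtl_negative_midband")
  expect_identical(dec$reason_codes[4], "eqtl_negative_midband")
  expect_identical(dec$reason_codes[5], "p_above_selection")
  ## p = 1e-4 exactly with positivity is selected via the second clause
  dec2 <- select_candidates(make_gwas("x", "chr1", 1e6, 1e-4),
                            data.frame(snp_id = "x", positive = TRUE))
  expect_true(dec2$selected)
})

test_that("locus clumping keeps the best SNP and matches an interval oracle", {
  gwas <- make_gwas(paste0("s", 1:2), "chr1", c(1e6, 1.01e6), c(1e-6, 1e-5))
  dec <- select_candidates(gwas, data.frame(snp_id = paste0("s", 1:2),
                                            positive = FALSE))
  dec <- clump_best_per_locus(dec, gwas)
  expect_identical(dec$selected, c(TRUE, FALSE))
  expect_match(dec$reason_codes[2], "clumped")
  ## tie in P: smaller position kept
  gwas2 <- make_gwas(paste0("t", 1:2), "chr1", c(2e6, 1.9e6), c(1e-6, 1e-6))
  dec2 <- clump_best_per_locus(
    select_candidates(gwas2, data.frame(snp_id = paste0("t", 1:2), positive = FALSE)),
    gwas2)
  expect_identical(dec2$selected, c(FALSE, TRUE))
  ## random fixture vs brute-force greedy oracle
  set.seed(17)
  n <- 60
  gwas3 <- make_gwas(sprintf("r%02d", 1:n),
                     sample(c("chr1", "chr2"), n, replace = TRUE),
                     sample.int(2000000L, n), stats::runif(n, 1e-8, 9e-5))
  dec3 <- clump_best_per_locus(
    select_candidates(gwas3, data.frame(snp_id = gwas3$snp_id, positive = FALSE)),
    gwas3)
  kept <- dec3$snp_id[dec3$selected]
  ## oracle: iterate over P-sorted SNPs, keep if no kept neighbor yet
  ord <- order(gwas3$p, gwas3$pos, gwas3$snp_id)
  kept_oracle <- character(0)
  for (i in ord) {
    near <- gwas3$snp_id %in% kept_oracle &
            gwas3$chrom == gwas3$chrom[i] &
            abs(gwas3$pos - gwas3$pos[i]) <= 500000L
    if (!any(near)) kept_oracle <- c(kept_oracle, gwas3$snp_id[i])
  }
  expect_setequal(kept, kept_oracle)
  ## kept set pairwise separated
  kg <- gwas3[gwas3$snp_id %in% kept, ]
  for (i in seq_len(nrow(kg))) for (j in seq_len(nrow(kg))) {
    if (i < j && kg$chrom[i] == kg$chrom[j])
      expect_gt(abs(kg$pos[i] - kg$pos[j]), 500000L)
  }
})

test_that("known-locus exclusion removes candidates within the window", {
  gwas <- make_gwas(c("a", "b"), "chr1", c(1e6, 5e6), c(1e-5, 1e-5))
  dec <- select_candidates(gwas, data.frame(snp_id = c("a", "b"), positive = FALSE))
  known <- data.frame(chrom = "chr1", pos = 1.05e6)
  dec2 <- exclude_known_loci(dec, gwas, known)
  expect_identical(dec2$selected, c(FALSE, TRUE))
  expect_match(dec2$reason_codes[1], "known_locus")
  expect_identical(exclude_known_loci(dec, gwas, known[0, ]), dec)
})

test_that("pooled-scan support honours distance and LD criteria", {
  gwas <- make_gwas("cand", "chr1", 1e6, 1e-5)
  dec <- select_candidates(gwas, data.frame(snp_id = "cand", positive = FALSE))
  g <- wrap_geno(matrix(stats::rbinom(400, 2, 0.3), 200, 2,
                        dimnames = list(NULL, c("cand", "far_ld"))))
  ## distance support at exactly 99,999 bp
  pooled <- data.frame(snp_id = "pool1", chrom = "chr1", pos = 1e6 + 99999,
                       rank_p = 0.005)
  d1 <- pooled_support(dec, gwas, pooled, g)
  expect_identical(d1$stage, "pooled_supported")
  expect_identical(d1$supporting_pooled_snp, "pool1")
  ## adjacent but non-significant pooled SNP does not support
  pooled2 <- data.frame(snp_id = "pool1", chrom = "chr1", pos = 1e6 + 1000,
                        rank_p = 0.02)
  d2 <- pooled_support(dec, gwas, pooled2, g)
  expect_false(d2$selected)
  expect_match(d2$reason_codes, "no_pooled_support")
  ## LD support beyond the distance window: duplicate genotypes -> r2 = 1
  g2 <- wrap_geno(matrix(rep(stats::rbinom(200, 2, 0.3), 2), 200, 2,
                         dimnames = list(NULL, c("cand", "far_ld"))))
  pooled3 <- data.frame(snp_id = "far_ld", chrom = "chr1", pos = 5e6,
                        rank_p = 0.001)
  d3 <- pooled_support(dec, gwas, pooled3, g2)
  expect_identical(d3$stage, "pooled_supported")
  expect_identical(d3$supporting_pooled_snp, "far_ld")
  expect_error(pooled_support(dec, gwas, pooled[0, ], g), "empty")
})

test_that("replication gates enforce ordering and error on missing stages", {
  gwas <- data.frame(snp_id = "s1", chrom = "chr1", pos = 1e6,
                     allele1 = "A", allele2 = "G",
                     case_allele1 = 998, case_allele2 = 784,
                     control_allele1 = 3451, control_allele2 = 3315,
                     p = 1.5e-4, stringsAsFactors = FALSE)
  dec <- select_candidates(make_gwas("s1", "chr1", 1e6, 1.5e-4),
                           data.frame(snp_id = "s1", positive = TRUE))
  expect_true(dec$selected)
  rep1 <- data.frame(snp_id = "s1", allele1 = "A", allele2 = "G",
                     case_allele1 = 627, case_allele2 = 473,
                     control_allele1 = 633, control_allele2 = 659,
                     stringsAsFactors = FALSE)
  rep2 <- data.frame(snp_id = "s1", allele1 = "A", allele2 = "G",
                     case_allele1 = 918, case_allele2 = 722,
                     control_allele1 = 29586, control_allele2 = 26236,
                     stringsAsFactors = FALSE)
  out <- replication_gates(dec, gwas, rep1, rep2)
  expect_identical(out$stage, "final_significant")
  expect_lt(out$p_combined_all, 5e-8)
  expect_equal(out$or_mh, 1.2034, tolerance = 1e-3)
  ## missing replication-1 entry is an error, not a silent skip
  expect_error(replication_gates(dec, gwas, rep1[0, ], rep2), "missing")
  ## swapped alleles in rep1 are reconciled by flipping the table
  rep1_swap <- data.frame(snp_id = "s1", allele1 = "G", allele2 = "A",
                          case_allele1 = 473, case_allele2 = 627,
                          control_allele1 = 659, control_allele2 = 633,
                          stringsAsFactors = FALSE)
  out2 <- replication_gates(dec, gwas, rep1_swap, rep2)
  expect_equal(out2$or_mh, out$or_mh, tolerance = 1e-12)
  ## ambiguous A/T SNP with mismatched orientation errors
  gwas_at <- gwas; gwas_at$allele1 <- "A"; gwas_at$allele2 <- "T"
  rep1_at <- rep1; rep1_at$allele1 <- "T"; rep1_at$allele2 <- "A"
  expect_error(replication_gates(dec, gwas_at, rep1_at, rep2), "orientation")
})

test_that("gate ordering: a SNP failing the stage gate never reaches final", {
  gwas <- data.frame(snp_id = "s1", chrom = "chr1", pos = 1e6,
                     allele1 = "A", allele2 = "G",
                     case_allele1 = 500, case_allele2 = 500,
                     control_allele1 = 1500, control_allele2 = 1500,
                     p = 5e-5, stringsAsFactors = FALSE)
  dec <- select_candidates(make_gwas("s1", "chr1", 1e6, 5e-5),
                           data.frame(snp_id = "s1", positive = FALSE))
  rep1 <- data.frame(snp_id = "s1", allele1 = "A", allele2 = "G",
                     case_allele1 = 300, case_allele2 = 300,
                     control_allele1 = 400, control_allele2 = 400,
                     stringsAsFactors = FALSE)
  out <- replication_gates(dec, gwas, rep1, rep1)
  expect_identical(out$stage, "rejected")
  expect_match(out$reason_codes, "stage_gate")
  expect_true(is.na(out$p_combined_all))
})

test_that("every SNP ends with one terminal stage and a reconstructible reason chain", {
  cfg <- sim_config(n_cases = 150, n_controls = 300, n_snps = 80, n_blocks = 8,
                    seed = 29,
                    risk_snps = data.frame(snp_index = 12, allele_or = 1.6,
                                           eqtl_beta = 0.8),
                    n_expr_samples = 90)
  res <- run_sle_pipeline(cfg)
  dec <- res$decisions
  expect_equal(nrow(dec), ncol(res$qc_report$retained$geno))
  expect_true(all(dec$stage %in% c("rejected", "gwas_selected",
                                   "pooled_supported", "rep1_passed",
                                   "final_significant")))
  expect_true(all(dec$reason_codes[dec$stage == "rejected"] != ""))
  ## thresholds are pure configuration: statistics identical under a change,
  ## only decisions move
  th2 <- selection_thresholds(p_select_strong = 0.5, p_select_eqtl = 0.9)
  res2 <- run_sle_pipeline(cfg, thresholds = th2)
  expect_identical(res$gwas$p, res2$gwas$p)
  expect_identical(res$eqtl$tests$q, res2$eqtl$tests$q)
  sel1 <- select_candidates(res$gwas, res$eqtl$flags)
  sel2 <- select_candidates(res$gwas, res$eqtl$flags, th2)
  expect_false(identical(sel1$selected, sel2$selected))
})
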