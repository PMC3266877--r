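test_that("sample call-rate filter is strict below threshold and order-stable", {
  G <- matrix(1L, nrow = 4, ncol = 100,
              dimnames = list(paste0("s", 1:4), sprintf("snp%03d", 1:100)))
  G[2, 1:2] <- NA_integer_   # call rate 0.98 exactly -> retained
  G[3, 1:3] <- NA_integer_   # 0.97 -> excluded
  g <- wrap_geno(G)
  rep <- filter_samples_by_call_rate(g)
  expect_identical(rep$sample_id, paste0("s", 1:4))
  expect_identical(rep$excluded, c(FALSE, FALSE, TRUE, FALSE))
  empty <- structure(list(geno = matrix(integer(0), 0, 0)),
                     class = "genotype_matrix")
  expect_error(filter_samples_by_call_rate(empty), "empty")
})

test_that("corrupted low-call samples are exactly the flagged ones", {
  cfg <- sim_config(n_cases = 20, n_controls = 30, n_snps = 200, n_blocks = 20,
                    missing_rate = 0, seed = 13)
  co <- simulate_cohort(cfg)
  bad <- c(4L, 17L, 40L)
  g <- corrupt_genotypes(co$genotypes, low_call_samples = bad,
                         sample_miss_rate = 0.2, seed = 13)
  rep <- filter_samples_by_call_rate(g)
  expect_identical(which(rep$excluded), bad)
})

test_that("HWE exact test equals the enumeration oracle", {
  cases <- list(c(25, 50, 25), c(0, 100, 0), c(200, 0, 200), c(3, 1, 7),
                c(57, 14, 50), c(0, 1, 99), c(10, 10, 1), c(68, 28, 4))
  for (cc in cases) {
    expect_equal(hwe_exact_test(cc[1], cc[2], cc[3]),
                 hwe_enum_oracle(cc[1], cc[2], cc[3]), tolerance = 1e-12,
                 info = paste(cc, collapse = ","))
  }
  expect_equal(hwe_exact_test(0, 0, 50), 1.0)
  expect_lt(hwe_exact_test(0, 100, 0), 1e-6)
  expect_lt(hwe_exact_test(200, 0, 200), 1e-6)
  expect_error(hwe_exact_test(0, 0, 0), "missing")
})

test_that("HWE exact test matches the oracle for all tables with <= 200 alleles", {
  set.seed(1)
  worst <- 0
  for (rep in 1:400) {
    n <- sample(1:100, 1)           # up to 200 alleles
    na <- sample(0:(2 * n), 1)
    h_max <- min(na, 2 * n - na)
    if (h_max < 0) next
    hs <- seq(na %% 2, h_max, by = 2)
    h <- sample(hs, 1)
    n0 <- (na - h) / 2; n2 <- (2 * n - na - h) / 2
    if (n0 < 0 || n2 < 0) next
    worst <- max(worst, abs(hwe_exact_test(n0, h, n2) - hwe_enum_oracle(n0, h, n2)))
  }
  expect_lt(worst, 1e-12)
})

test_that("SNP filter applies reason codes in fixed order", {
  set.seed(2)
  n_case <- 100; n_ctrl <- 200
  mono <- rep(0L, n_case + n_ctrl)                      # maf 0 -> "maf"
  good <- stats::rbinom(n_case + n_ctrl, 2, 0.3)
  hwe_bad <- c(rep(0L, 100), rep(2L, 100), stats::rbinom(n_case, 2, 0.5))
  hwe_bad <- c(stats::rbinom(n_case, 2, 0.5), rep(c(0L, 2L), n_ctrl / 2))
  lowcall <- good; lowcall[sample(seq_len(n_ctrl), 30) + n_case] <- NA_integer_
  G <- cbind(mono = mono, good = good, hwe_bad = hwe_bad, lowcall = lowcall)
  rownames(G) <- sprintf("s%03d", seq_len(n_case + n_ctrl))
  g <- wrap_geno(G, status = c(rep(2L, n_case), rep(1L, n_ctrl)))
  rep <- filter_snps(g)
  expect_identical(rep$reason[rep$snp_id == "mono"], "maf")
  expect_identical(rep$reason[rep$snp_id == "good"], "")
  expect_identical(rep$reason[rep$snp_id == "hwe_bad"], "hwe")
  expect_identical(rep$reason[rep$snp_id == "lowcall"], "call_rate")
  ## perfect HWE proportions are not flagged for HWE
  perfect <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
  g2 <- wrap_geno(cbind(perfect = c(perfect, perfect, perfect)),
                  status = c(rep(2L, 100), rep(1L, 200)))
  expect_identical(filter_snps(g2)$reason, "")
  ## the (200, 0, 200) control table fails HWE below 1e-6
  expect_lt(hwe_exact_test(200, 0, 200), 1e-6)
  ## non-autosomal and unlabeled-sample contracts
  g3 <- wrap_geno(cbind(x = good), chrom = "chrX",
                  status = c(rep(2L, n_case), rep(1L, n_ctrl)))
  expect_identical(filter_snps(g3)$reason, "non_autosomal")
  g4 <- wrap_geno(cbind(x = good))
  expect_error(filter_snps(g4), "labeled")
})

test_that("IBD estimates separate duplicates, relatives and unrelated pairs", {
  set.seed(3)
  n_snp <- 5000
  p <- stats::runif(n_snp, 0.1, 0.5)
  hap <- function() as.integer(stats::runif(n_snp) < p)
  a1 <- hap(); a2 <- hap(); b1 <- hap(); b2 <- hap()
  child1 <- a1                      # inherits one haplotype from parent A
  child2 <- hap()
  G <- rbind(A = a1 + a2, Adup = a1 + a2, B = b1 + b2, child = child1 + child2)
  ## background samples so allele frequencies are estimable
  bg <- t(replicate(40, hap() + hap()))
  rownames(bg) <- sprintf("bg%02d", 1:40)
  g <- wrap_geno(rbind(G, bg))
  expect_gte(estimate_ibd(g, c("A", "Adup"))$pi_hat, 0.95)
  expect_lte(estimate_ibd(g, c("A", "B"))$pi_hat, 0.1)
  po <- estimate_ibd(g, c("A", "child"))$pi_hat
  expect_gte(po, 0.4); expect_lte(po, 0.6)
  expect_true(estimate_ibd(g, c("A", "B"), min_informative = 1e6)$low_confidence)
})

test_that("related-pair resolution excludes one member per pair and clears chains", {
  est <- data.frame(sample1 = c("A", "B", "C"), sample2 = c("B", "C", "D"),
                    pi_hat = c(0.6, 0.55, 0.05), stringsAsFactors = FALSE)
  cr <- c(A = 0.99, B = 0.95, C = 0.99, D = 0.99)
  out <- flag_related_pairs(est, cr)
  ## B has the lowest call rate in A~B; removing B also resolves B~C
  expect_identical(out, "B")
  ## residual flagged pairs after exclusion: none
  left <- est[est$pi_hat >= 0.1875 &
              !(est$sample1 %in% out) & !(est$sample2 %in% out), ]
  expect_equal(nrow(left), 0L)
  ## tie on call rate: lexicographically larger id dropped
  est2 <- data.frame(sample1 = "A", sample2 = "B", pi_hat = 0.9)
  expect_identical(flag_related_pairs(est2, c(A = 0.99, B = 0.99)), "B")
  expect_identical(flag_related_pairs(est2[0, ], cr), character(0))
})

test_that("PCA flags an injected divergent-ancestry sample and no one else", {
  cfg <- sim_config(n_cases = 60, n_controls = 140, n_snps = 400,
                    n_blocks = 400, block_ld_rho = 0, missing_rate = 0,
                    seed = 17)
  co <- simulate_cohort(cfg)
  expect_warning(res0 <- pca_ancestry_outliers(co$genotypes), "reference")
  expect_length(res0$outliers, 0L)
  g2 <- corrupt_genotypes(co$genotypes, ancestry_outlier_samples = 7L,
                          outlier_freq_shift = 0.4, seed = 17)
  expect_warning(res1 <- pca_ancestry_outliers(g2), "reference")
  expect_identical(res1$outliers, rownames(g2$geno)[7])
})

test_that("lambda_gc has the null median property and scale equivariance", {
  med <- stats::qchisq(0.5, 1)
  expect_equal(lambda_gc(c(med, med, med)), 1.0)
  x <- stats::rchisq(1000, 1)
  expect_equal(lambda_gc(2 * x), 2 * lambda_gc(x), tolerance = 1e-12)
  set.seed(4)
  expect_lt(abs(lambda_gc(stats::rchisq(10000, 1)) - 1), 0.05)
  expect_error(lambda_gc(numeric(0)), "chi-square")
})

test_that("QC is idempotent and exclusion counts partition the input", {
  cfg <- sim_config(n_cases = 80, n_controls = 120, n_snps = 100,
                    n_blocks = 10, missing_rate = 0.01, seed = 19,
                    maf_range = c(0.02, 0.5))
  co <- simulate_cohort(cfg)
  g <- corrupt_genotypes(co$genotypes, low_call_samples = 3L,
                         sample_miss_rate = 0.2, hwe_violation_snps = 10L,
                         seed = 19)
  q1 <- run_genotype_qc(g)
  expect_equal(nrow(q1$retained$geno) + nrow(q1$excluded_samples), nrow(g$geno))
  expect_equal(ncol(q1$retained$geno) + nrow(q1$excluded_snps), ncol(g$geno))
  expect_true(all(table(q1$excluded_samples$sample_id) == 1))
  q2 <- run_genotype_qc(q1$retained)
  expect_equal(nrow(q2$excluded_samples), 0L)
  expect_equal(nrow(q2$excluded_snps), 0L)
})
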