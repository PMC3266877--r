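#' Quality-control thresholds
#'
#' Defaults follow a stringent GWAS QC protocol: samples with call rate below
#' 0.98 are dropped; SNPs require call rate at least 0.99 and minor allele
#' frequency at least 0.01 in cases and in controls separately, and an exact
#' Hardy-Weinberg P of at least 1e-6 in controls. Relatedness is cut at
#' pi-hat 0.1875, the midpoint between the 2nd- and 3rd-degree expectations;
#' ancestry outliers are samples more than 6 cluster SDs from the target
#' cluster centroid on the first two principal components.
#'
#' @param sample_call_rate_min,snp_call_rate_min,maf_min,hwe_p_min,pihat_relatedness_min,pca_outlier_sd
#'   numeric thresholds as described above.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.98,
                          snp_call_rate_min = 0.99,
                          maf_min = 0.01,
                          hwe_p_min = 1e-6,
                          pihat_relatedness_min = 0.1875,
                          pca_outlier_sd = 6) {
  th <- list(sample_call_rate_min = sample_call_rate_min,
             snp_call_rate_min = snp_call_rate_min,
             maf_min = maf_min, hwe_p_min = hwe_p_min,
             pihat_relatedness_min = pihat_relatedness_min,
             pca_outlier_sd = pca_outlier_sd)
  for (f in names(th))
    if (!is.numeric(th[[f]]) || length(th[[f]]) != 1L || th[[f]] <= 0)
      config_error(f, "must be a positive number")
  for (f in c("sample_call_rate_min", "snp_call_rate_min", "maf_min", "hwe_p_min"))
    if (th[[f]] > 1) config_error(f, "must be in (0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Flag samples by genotype call rate
#'
#' A sample is excluded when its fraction of non-missing genotypes is
#' strictly below `sample_call_rate_min`; a call rate exactly at the
#' threshold is retained. Input order is preserved.
#'
#' @param genotypes a `genotype_matrix`.
#' @param thresholds a [qc_thresholds()].
#' @return data frame `sample_id`, `call_rate`, `excluded`, `reason`.
#' @export
filter_samples_by_call_rate <- function(genotypes, thresholds = qc_thresholds()) {
  G <- genotypes$geno
  if (is.null(G) || nrow(G) == 0L || ncol(G) == 0L)
    stop("empty genotype matrix", call. = FALSE)
  cr <- rowMeans(!is.na(G))
  excluded <- cr < thresholds$sample_call_rate_min
  data.frame(sample_id = rownames(G), call_rate = cr, excluded = excluded,
             reason = ifelse(excluded, "sample_call_rate", ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genotype counts for one SNP
#'
#' @param g integer vector of genotypes (0/1/2/NA).
#' @return list `n_hom_ref`, `n_het`, `n_hom_alt`, `n_missing`.
#' @export
genotype_counts <- function(g) {
  list(n_hom_ref = sum(g == 0L, na.rm = TRUE),
       n_het = sum(g == 1L, na.rm = TRUE),
       n_hom_alt = sum(g == 2L, na.rm = TRUE),
       n_missing = sum(is.na(g)))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the allele counts: the P-value is the
#' sum of the probabilities of all heterozygote counts (with the observed
#' allele totals) whose conditional probability does not exceed that of the
#' observed table. Probabilities follow the standard conditional distribution
#' of the heterozygote count and are computed by the stable mid-out
#' recurrence.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts; the first
#'   argument may also be the list returned by [genotype_counts()].
#' @return the exact P-value; monomorphic tables return 1.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het = NULL, n_hom_alt = NULL) {
  if (is.list(n_hom_ref)) {
    cts <- n_hom_ref
    n_het <- cts$n_het; n_hom_alt <- cts$n_hom_alt; n_hom_ref <- cts$n_hom_ref
  }
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0) ||
      any(c(n_hom_ref, n_het, n_hom_alt) != round(c(n_hom_ref, n_het, n_hom_alt))))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) stop("all genotypes missing", call. = FALSE)
  n_rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het   # rare allele count
  if (n_rare == 0L) return(1.0)
  ## possible heterozygote counts share the parity of the rare-allele count
  h_obs <- n_het
  h_max <- if (n_rare <= n) n_rare else 2L * n - n_rare
  h_min <- n_rare %% 2L
  hs <- seq.int(h_min, h_max, by = 2L)
  probs <- numeric(length(hs))
  ## start at the mode-ish midpoint and recurse both ways:
  ## P(h+2)/P(h) = ((nr-h)(2n-nr-h)) / ((h+2)(h+1)) with nr = rare count
  mid_i <- which.min(abs(hs - n_rare * (2 * n - n_rare) / (2 * n)))
  probs[mid_i] <- 1
  if (mid_i < length(hs)) for (i in mid_i:(length(hs) - 1L)) {
    h <- hs[i]
    probs[i + 1L] <- probs[i] * ((n_rare - h) * (2 * n - n_rare - h)) /
                                ((h + 2) * (h + 1))
  }
  if (mid_i > 1L) for (i in mid_i:2L) {
    h <- hs[i]
    probs[i - 1L] <- probs[i] * (h * (h - 1)) /
                                ((n_rare - h + 2) * (2 * n - n_rare - h + 2))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(h_obs, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

## Per-group SNP summaries used by filter_snps (vectorized over SNPs).
group_snp_stats <- function(G) {
  n0 <- colSums(G == 0L, na.rm = TRUE)
  n1 <- colSums(G == 1L, na.rm = TRUE)
  n2 <- colSums(G == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  freq1 <- ifelse(n > 0, (2 * n2 + n1) / (2 * n), NA_real_)
  list(n0 = n0, n1 = n1, n2 = n2, n = n,
       call_rate = n / nrow(G),
       maf = pmin(freq1, 1 - freq1))
}

#' Flag SNPs failing marker-level QC
#'
#' Rules, applied in fixed order with the first failure recorded as the
#' primary reason: call rate below `snp_call_rate_min` in cases or in
#' controls; minor allele frequency (evaluated within each group separately)
#' below `maf_min` in cases or in controls; exact Hardy-Weinberg P in
#' controls below `hwe_p_min`; non-autosomal chromosome; SNP not typed
#' (all-missing) in one of the two panels.
#'
#' @param genotypes a `genotype_matrix` whose `samples$status` labels every
#'   sample 2 (case) or 1 (control).
#' @param thresholds a [qc_thresholds()].
#' @return data frame `snp_id`, `excluded`, `reason`, plus the per-group
#'   diagnostics the decision was based on.
#' @export
filter_snps <- function(genotypes, thresholds = qc_thresholds()) {
  st <- genotypes$samples$status
  if (any(is.na(st)) || !all(st %in% c(1L, 2L)))
    stop("every sample must be labeled case (2) or control (1)", call. = FALSE)
  Gca <- genotypes$geno[st == 2L, , drop = FALSE]
  Gco <- genotypes$geno[st == 1L, , drop = FALSE]
  ca <- group_snp_stats(Gca); co <- group_snp_stats(Gco)
  hwe_co <- vapply(seq_len(ncol(Gco)), function(j) {
    if (co$n[j] == 0L) return(NA_real_)
    hwe_exact_test(co$n0[j], co$n1[j], co$n2[j])
  }, numeric(1))
  autosomal <- !grepl("^(chr)?(X|Y|MT|M)$", genotypes$map$chrom, ignore.case = TRUE)
  reason <- character(ncol(genotypes$geno))
  fail <- function(cond, code) reason <<- ifelse(reason == "" & cond, code, reason)
  fail(ca$call_rate < thresholds$snp_call_rate_min |
       co$call_rate < thresholds$snp_call_rate_min, "call_rate")
  fail(is.na(ca$maf) | is.na(co$maf) |
       ca$maf < thresholds$maf_min | co$maf < thresholds$maf_min, "maf")
  fail(!is.na(hwe_co) & hwe_co < thresholds$hwe_p_min, "hwe")
  fail(!autosomal, "non_autosomal")
  fail(ca$n == 0L | co$n == 0L, "not_shared")
  data.frame(snp_id = genotypes$map$snp_id,
             excluded = reason != "", reason = reason,
             call_rate_case = ca$call_rate, call_rate_control = co$call_rate,
             maf_case = ca$maf, maf_control = co$maf, hwe_p_control = hwe_co,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Method-of-moments identity-by-descent estimate for one sample pair
#'
#' Estimates the probabilities (z0, z1, z2) of sharing 0/1/2 alleles
#' identical by descent from the identity-by-state distribution across SNPs,
#' given sample allele frequencies, then truncates each to `[0, 1]` and
#' renormalizes. `pi_hat = z1/2 + z2`.
#'
#' @param genotypes a `genotype_matrix` (allele frequencies are estimated
#'   from all samples).
#' @param pair character or integer vector of length 2 naming the samples.
#' @param min_informative minimum complete, polymorphic SNPs before the
#'   estimate is flagged as low-confidence.
#' @return list `sample_pair`, `z0`, `z1`, `z2`, `pi_hat`, `n_snps`,
#'   `low_confidence`.
#' @export
estimate_ibd <- function(genotypes, pair, min_informative = 100L) {
  G <- genotypes$geno
  if (is.character(pair)) pair <- match(pair, rownames(G))
  if (length(pair) != 2L || any(is.na(pair)))
    stop("pair must name two samples present in the matrix", call. = FALSE)
  g1 <- G[pair[1], ]; g2 <- G[pair[2], ]
  p <- colMeans(G, na.rm = TRUE) / 2
  ok <- !is.na(g1) & !is.na(g2) & is.finite(p) & p > 0 & p < 1
  g1 <- g1[ok]; g2 <- g2[ok]; p <- p[ok]; q <- 1 - p
  n_inf <- length(p)
  if (n_inf == 0L) stop("no informative SNPs for IBD estimation", call. = FALSE)
  ibs <- 2L - abs(g1 - g2)
  ## treat het/het as IBS 2 only when both are het; abs-diff already does:
  ## |1-1| = 0 -> IBS 2. (0,2) -> IBS 0; (0,1),(1,2) -> IBS 1.
  N0 <- sum(ibs == 0L); N1 <- sum(ibs == 1L); N2 <- sum(ibs == 2L)
  ## expected IBS class probabilities given IBD state, summed over SNPs
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_ibd0 <- sum(p^4 + 4 * p^2 * q^2 + q^4)
  e1_ibd1 <- sum(2 * p * q)          # 2p^2 q + 2 p q^2
  e2_ibd1 <- sum(p^2 + q^2)          # p^3 + p^2 q + p q^2 + q^3
  z0 <- N0 / e0_ibd0
  z1 <- (N1 - z0 * e1_ibd0) / e1_ibd1
  z2 <- (N2 - z0 * e2_ibd0 - z1 * e2_ibd1) / n_inf
  z <- pmin(pmax(c(z0, z1, z2), 0), 1)
  z <- z / sum(z)
  list(sample_pair = rownames(G)[pair], z0 = z[1], z1 = z[2], z2 = z[3],
       pi_hat = z[2] / 2 + z[3], n_snps = n_inf,
       low_confidence = n_inf < min_informative)
}

#' Estimate IBD for every pair of the given samples
#'
#' @param genotypes a `genotype_matrix`.
#' @param sample_ids samples to compare (default all).
#' @param min_informative passed to [estimate_ibd()].
#' @return data frame `sample1`, `sample2`, `z0`, `z1`, `z2`, `pi_hat`,
#'   `n_snps`, `low_confidence`.
#' @export
estimate_ibd_pairs <- function(genotypes, sample_ids = NULL,
                               min_informative = 100L) {
  ids <- sample_ids %||% rownames(genotypes$geno)
  if (length(ids) < 2L) stop("need at least two samples", call. = FALSE)
  combs <- utils::combn(ids, 2L)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    e <- estimate_ibd(genotypes, combs[, k], min_informative)
    data.frame(sample1 = e$sample_pair[1], sample2 = e$sample_pair[2],
               z0 = e$z0, z1 = e$z1, z2 = e$z2, pi_hat = e$pi_hat,
               n_snps = e$n_snps, low_confidence = e$low_confidence,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Resolve related sample pairs into an exclusion list
#'
#' Pairs at or above `pihat_relatedness_min` are flagged; flagged pairs are
#' processed greedily by descending pi-hat, excluding from each the member
#' with the lower call rate (ties broken by excluding the lexicographically
#' larger id). Pairs already resolved by an earlier exclusion are skipped, so
#' chains (A~B, B~C) leave no flagged pair unresolved.
#'
#' @param estimates output of [estimate_ibd_pairs()].
#' @param call_rates named numeric vector of per-sample call rates (e.g. from
#'   [filter_samples_by_call_rate()]).
#' @param thresholds a [qc_thresholds()].
#' @return character vector of excluded sample ids (possibly empty).
#' @export
flag_related_pairs <- function(estimates, call_rates,
                               thresholds = qc_thresholds()) {
  flagged <- estimates[estimates$pi_hat >= thresholds$pihat_relatedness_min, ,
                       drop = FALSE]
  if (nrow(flagged) == 0L) return(character(0))
  flagged <- flagged[order(-flagged$pi_hat, flagged$sample1, flagged$sample2), ,
                     drop = FALSE]
  excluded <- character(0)
  for (i in seq_len(nrow(flagged))) {
    a <- flagged$sample1[i]; b <- flagged$sample2[i]
    if (a %in% excluded || b %in% excluded) next
    ca <- call_rates[[a]] %||% NA_real_; cb <- call_rates[[b]] %||% NA_real_
    drop <- if (isTRUE(ca < cb)) a
            else if (isTRUE(cb < ca)) b
            else max(a, b)
    excluded <- c(excluded, drop)
  }
  excluded
}

#' LD-prune SNPs by pairwise genotype correlation
#'
#' Conventional sliding-window pruning ahead of PCA/IBD: within windows of
#' `window` SNPs advanced by `step`, one SNP of every pair with genotype
#' r-squared above `r2_max` is removed (the later one in map order).
#'
#' @param genotypes a `genotype_matrix`.
#' @param window,step,r2_max pruning parameters.
#' @return character vector of retained SNP ids.
#' @export
ld_prune <- function(genotypes, window = 50L, step = 5L, r2_max = 0.2) {
  G <- genotypes$geno
  keep <- rep(TRUE, ncol(G))
  m <- ncol(G)
  starts <- seq(1L, max(1L, m - 1L), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1L, m)
    idx <- idx[keep[idx]]
    if (length(idx) < 2L) next
    cc <- suppressWarnings(stats::cor(G[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b > a && keep[idx[a]] && keep[idx[b]] && cc[a, b]^2 > r2_max)
        keep[idx[b]] <- FALSE
    }
  }
  genotypes$map$snp_id[keep]
}

#' Principal-component ancestry outlier detection
#'
#' Computes principal components of the standardized genotype matrix (study
#' samples plus an optional reference panel sharing the SNP map, after LD
#' pruning) and flags study samples whose Euclidean distance from the
#' target-cluster centroid on PCs 1-2 exceeds `pca_outlier_sd` times the
#' cluster's root-mean-square distance. The centroid is the coordinate-wise
#' median of the study samples, so a single outlier cannot drag it.
#'
#' @param genotypes study `genotype_matrix`.
#' @param reference_panel optional `genotype_matrix` on the same SNPs; when
#'   absent the analysis runs on the study samples alone with a warning.
#' @param thresholds a [qc_thresholds()].
#' @param prune apply [ld_prune()] first.
#' @return list `pca_coordinates` (sample, panel, PC1, PC2, distance,
#'   outlier) and `outliers` (study sample ids).
#' @export
pca_ancestry_outliers <- function(genotypes, reference_panel = NULL,
                                  thresholds = qc_thresholds(), prune = TRUE) {
  if (is.null(reference_panel)) {
    warning("no reference panel supplied; PCA runs on study samples alone")
    G <- genotypes$geno
    panel <- rep("study", nrow(G))
  } else {
    common <- intersect(genotypes$map$snp_id, reference_panel$map$snp_id)
    if (length(common) < 1000L)
      stop(sprintf("insufficient SNP overlap with reference panel (%d < 1000)",
                   length(common)), call. = FALSE)
    G <- rbind(genotypes$geno[, common, drop = FALSE],
               reference_panel$geno[, common, drop = FALSE])
    panel <- c(rep("study", nrow(genotypes$geno)),
               rep("reference", nrow(reference_panel$geno)))
  }
  if (prune) {
    tmp <- genotypes; tmp$geno <- G[panel == "study", , drop = FALSE]
    tmp$map <- genotypes$map[match(colnames(G), genotypes$map$snp_id), ]
    kept <- ld_prune(tmp)
    G <- G[, colnames(G) %in% kept, drop = FALSE]
  }
  p <- colMeans(G, na.rm = TRUE) / 2
  ok <- is.finite(p) & p > 0 & p < 1
  G <- G[, ok, drop = FALSE]; p <- p[ok]
  Z <- sweep(G, 2L, 2 * p, `-`)
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), `/`)
  Z[is.na(Z)] <- 0
  sv <- svd(Z, nu = 2L, nv = 0L)
  pcs <- sv$u %*% diag(sv$d[1:2], 2L, 2L)
  study <- panel == "study"
  centroid <- apply(pcs[study, , drop = FALSE], 2L, stats::median)
  d <- sqrt((pcs[, 1] - centroid[1])^2 + (pcs[, 2] - centroid[2])^2)
  cluster_sd <- sqrt(mean(d[study]^2))
  outlier <- study & d > thresholds$pca_outlier_sd * cluster_sd
  ids <- c(rownames(genotypes$geno),
           if (!is.null(reference_panel)) rownames(reference_panel$geno))
  list(
    pca_coordinates = data.frame(sample_id = ids, panel = panel,
                                 PC1 = pcs[, 1], PC2 = pcs[, 2],
                                 distance = d, outlier = outlier,
                                 stringsAsFactors = FALSE),
    outliers = ids[outlier]
  )
}

#' Genomic-control inflation factor
#'
#' Ratio of the median observed 1-df chi-square statistic to the null median
#' of the chi-square(1) distribution (0.4549364...).
#'
#' @param chi2_values numeric vector of association chi-square statistics.
#' @return lambda, a positive scalar.
#' @export
lambda_gc <- function(chi2_values) {
  chi2_values <- chi2_values[is.finite(chi2_values)]
  if (length(chi2_values) == 0L)
    stop("no finite chi-square values", call. = FALSE)
  stats::median(chi2_values) / stats::qchisq(0.5, df = 1)
}

#' Run full sample- and SNP-level QC
#'
#' Applies, in order: sample call-rate filtering, relatedness exclusion among
#' cases (greedy, lower call rate dropped), optional PCA ancestry outlier
#' removal, then SNP filtering on the retained samples. Because removing SNPs
#' changes sample call rates (and vice versa), the call-rate/SNP filters are
#' iterated to a fixed point, which makes the whole procedure idempotent:
#' re-running QC on its own output excludes nothing. Exclusions carry one
#' primary reason code each and the report reconciles with the input
#' dimensions.
#'
#' @param genotypes labeled `genotype_matrix`.
#' @param thresholds a [qc_thresholds()].
#' @param check_relatedness,check_ancestry toggle the heavier steps.
#' @param reference_panel optional panel for [pca_ancestry_outliers()].
#' @return list of class `qc_report`: `excluded_samples`, `excluded_snps`,
#'   `retained` (filtered `genotype_matrix`), `sample_report`, `snp_report`,
#'   `pca_coordinates`.
#' @export
run_genotype_qc <- function(genotypes, thresholds = qc_thresholds(),
                            check_relatedness = FALSE, check_ancestry = FALSE,
                            reference_panel = NULL) {
  samp_rep <- filter_samples_by_call_rate(genotypes, thresholds)
  ex0 <- samp_rep$sample_id[samp_rep$excluded]
  excluded_samples <- data.frame(sample_id = ex0,
                                 reason = rep("sample_call_rate", length(ex0)),
                                 stringsAsFactors = FALSE)
  keep <- !samp_rep$excluded
  g <- genotypes
  g$geno <- g$geno[keep, , drop = FALSE]
  g$samples <- g$samples[keep, , drop = FALSE]

  if (check_relatedness && nrow(g$geno) >= 2L) {
    cases <- g$samples$sample_id[g$samples$status == 2L]
    if (length(cases) >= 2L) {
      est <- estimate_ibd_pairs(g, cases)
      cr <- stats::setNames(samp_rep$call_rate, samp_rep$sample_id)
      rel <- flag_related_pairs(est, cr, thresholds)
      if (length(rel)) {
        excluded_samples <- rbind(excluded_samples,
          data.frame(sample_id = rel, reason = "relatedness",
                     stringsAsFactors = FALSE))
        keep2 <- !(g$samples$sample_id %in% rel)
        g$geno <- g$geno[keep2, , drop = FALSE]
        g$samples <- g$samples[keep2, , drop = FALSE]
      }
    }
  }
  pca_coords <- NULL
  if (check_ancestry) {
    pca <- pca_ancestry_outliers(g, reference_panel, thresholds)
    pca_coords <- pca$pca_coordinates
    if (length(pca$outliers)) {
      excluded_samples <- rbind(excluded_samples,
        data.frame(sample_id = pca$outliers, reason = "pca_ancestry",
                   stringsAsFactors = FALSE))
      keep3 <- !(g$samples$sample_id %in% pca$outliers)
      g$geno <- g$geno[keep3, , drop = FALSE]
      g$samples <- g$samples[keep3, , drop = FALSE]
    }
  }
  ## iterate SNP and sample call-rate filters to a fixed point
  excluded_snps <- data.frame(snp_id = character(), reason = character(),
                              stringsAsFactors = FALSE)
  snp_rep <- NULL
  repeat {
    sr <- filter_snps(g, thresholds)
    if (is.null(snp_rep)) snp_rep <- sr
    changed <- FALSE
    if (any(sr$excluded)) {
      changed <- TRUE
      excluded_snps <- rbind(excluded_snps,
        data.frame(snp_id = sr$snp_id[sr$excluded],
                   reason = sr$reason[sr$excluded], stringsAsFactors = FALSE))
      keep_snp <- !sr$excluded
      g$geno <- g$geno[, keep_snp, drop = FALSE]
      g$map <- g$map[keep_snp, , drop = FALSE]
    }
    sr2 <- filter_samples_by_call_rate(g, thresholds)
    if (any(sr2$excluded)) {
      changed <- TRUE
      excluded_samples <- rbind(excluded_samples,
        data.frame(sample_id = sr2$sample_id[sr2$excluded],
                   reason = "sample_call_rate", stringsAsFactors = FALSE))
      keep_s <- !sr2$excluded
      g$geno <- g$geno[keep_s, , drop = FALSE]
      g$samples <- g$samples[keep_s, , drop = FALSE]
    }
    if (!changed) break
  }
  structure(list(excluded_samples = excluded_samples,
                 excluded_snps = excluded_snps,
                 retained = g, sample_report = samp_rep, snp_report = snp_rep,
                 pca_coordinates = pca_coords),
            class = "qc_report")
}
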