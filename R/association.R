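#' Cochran-Armitage trend test for a 2x3 case-control genotype table
#'
#' Score test for a linear trend of case proportion across genotype dose with
#' weights (0, 1, 2). The statistic is
#' `N (N sum(w r) - R sum(w n))^2 / (R (N - R) (N sum(w^2 n) - sum(w n)^2))`
#' with `r` case counts, `n` column totals, `R` total cases; the P-value is
#' the chi-square(1) upper tail. A monomorphic table (zero score variance)
#' returns chi2 = 0, p = 1.
#'
#' @param case_counts,control_counts length-3 genotype counts
#'   (hom-ref, het, hom-alt).
#' @return list `chi2`, `p`.
#' @export
cochran_armitage_trend <- function(case_counts, control_counts) {
  r <- as.numeric(case_counts); s <- as.numeric(control_counts)
  if (length(r) != 3L || length(s) != 3L || any(c(r, s) < 0))
    stop("counts must be two non-negative length-3 vectors", call. = FALSE)
  if (sum(r) == 0 || sum(s) == 0)
    stop("both case and control rows must be non-empty", call. = FALSE)
  res <- trend_test_counts(matrix(r, 3L), matrix(s, 3L))
  list(chi2 = res$chi2[1], p = res$p[1])
}

## Vectorized trend test: 3 x M matrices of case and control genotype counts.
trend_test_counts <- function(R3, S3) {
  w <- c(0, 1, 2)
  n3 <- R3 + S3
  N <- colSums(n3); R <- colSums(R3)
  swr <- colSums(R3 * w); swn <- colSums(n3 * w); sw2n <- colSums(n3 * w^2)
  num <- N * (N * swr - R * swn)^2
  den <- R * (N - R) * (N * sw2n - swn^2)
  chi2 <- ifelse(den > 0, num / den, 0)
  list(chi2 = chi2, p = ifelse(den > 0, chisq_p(chi2), 1))
}

## Woolf (log-OR normal approximation) odds ratio with 95% CI from a 2x2
## allele table; zero cells get the 0.5 continuity correction and a flag.
or_from_counts <- function(a, b, c, d, conf = 0.95) {
  flagged <- any(c(a, b, c, d) == 0)
  if (flagged) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se),
       se_log = se, continuity_corrected = flagged)
}

#' Allelic odds ratio from published allele frequencies
#'
#' Reconstructs integer allele counts from frequencies and sample sizes
#' (counts = `2 n freq`, rounded half away from zero, as printed tables are),
#' then computes the allele-1 odds ratio with a Woolf 95% confidence
#' interval. A zero cell triggers the 0.5 continuity correction and a flag.
#'
#' @param freq_case,freq_control allele-1 frequencies in (0, 1).
#' @param n_case,n_control numbers of subjects (diploid).
#' @return list `or`, `ci_low`, `ci_high`, `table` (a, b, c, d),
#'   `continuity_corrected`.
#' @export
allelic_odds_ratio <- function(freq_case, freq_control, n_case, n_control) {
  if (any(c(freq_case, freq_control) <= 0) || any(c(freq_case, freq_control) >= 1))
    stop("frequencies must lie in (0, 1)", call. = FALSE)
  if (n_case <= 0 || n_control <= 0)
    stop("sample sizes must be positive", call. = FALSE)
  a <- round_half_up(2 * n_case * freq_case)
  b <- 2 * n_case - a
  c <- round_half_up(2 * n_control * freq_control)
  d <- 2 * n_control - c
  res <- or_from_counts(a, b, c, d)
  res$table <- c(a = a, b = b, c = c, d = d)
  res
}

#' Build a 2x2 allele table
#'
#' @param case_allele1,case_allele2,control_allele1,control_allele2
#'   non-negative allele counts.
#' @param stage_label optional stage name.
#' @return list of class `allele_table`.
#' @export
allele_table <- function(case_allele1, case_allele2,
                         control_allele1, control_allele2,
                         stage_label = "") {
  x <- c(case_allele1, case_allele2, control_allele1, control_allele2)
  if (any(x < 0)) stop("allele counts must be non-negative", call. = FALSE)
  if (case_allele1 + case_allele2 <= 0 || control_allele1 + control_allele2 <= 0)
    stop("row totals must be positive", call. = FALSE)
  structure(list(a = case_allele1, b = case_allele2,
                 c = control_allele1, d = control_allele2,
                 stage_label = stage_label), class = "allele_table")
}

#' Mantel-Haenszel combination of stratified 2x2 allele tables
#'
#' Fixed-effect pooled odds ratio
#' `OR_MH = sum(a_i d_i / N_i) / sum(b_i c_i / N_i)`, with a 95% confidence
#' interval from the Robins-Breslow-Greenland variance of `log OR_MH` and a
#' P-value from the 1-df Mantel-Haenszel chi-square (no continuity
#' correction). With a single stratum the estimate reduces exactly to the
#' crude odds ratio.
#'
#' @param strata list of [allele_table()]s (or of lists with `a`,`b`,`c`,`d`).
#' @return list `or_mh`, `ci_low`, `ci_high`, `chi2`, `p_combined`,
#'   `n_strata`.
#' @export
mantel_haenszel <- function(strata) {
  if (length(strata) < 1L) stop("need at least one stratum", call. = FALSE)
  a <- vapply(strata, function(t) t$a, numeric(1))
  b <- vapply(strata, function(t) t$b, numeric(1))
  c <- vapply(strata, function(t) t$c, numeric(1))
  d <- vapply(strata, function(t) t$d, numeric(1))
  N <- a + b + c + d
  usable <- N > 0 & (a + b) > 0 & (c + d) > 0
  if (!any(usable)) stop("all strata degenerate", call. = FALSE)
  a <- a[usable]; b <- b[usable]; c <- c[usable]; d <- d[usable]; N <- N[usable]
  Rs <- a * d / N; Ss <- b * c / N
  if (sum(Rs) == 0 || sum(Ss) == 0)
    stop("Mantel-Haenszel odds ratio undefined (zero margin); add a continuity correction upstream",
         call. = FALSE)
  or_mh <- sum(Rs) / sum(Ss)
  ## Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (a + d) / N; Q <- (b + c) / N
  var_log <- sum(P * Rs) / (2 * sum(Rs)^2) +
             sum(P * Ss + Q * Rs) / (2 * sum(Rs) * sum(Ss)) +
             sum(Q * Ss) / (2 * sum(Ss)^2)
  z <- stats::qnorm(0.975)
  ## Mantel-Haenszel chi-square on the allele-1 case cell
  Ea <- (a + b) * (a + c) / N
  Va <- (a + b) * (c + d) * (a + c) * (b + d) / (N^2 * (N - 1))
  Va[!is.finite(Va)] <- 0
  chi2 <- if (sum(Va) > 0) (sum(a) - sum(Ea))^2 / sum(Va) else 0
  list(or_mh = or_mh,
       ci_low = or_mh * exp(-z * sqrt(var_log)),
       ci_high = or_mh * exp(z * sqrt(var_log)),
       chi2 = chi2, p_combined = chisq_p(chi2),
       n_strata = sum(usable))
}

#' Per-SNP case-control association scan
#'
#' For every SNP: complete-case genotype counts by disease status, the
#' Cochran-Armitage trend test, allele-1 frequencies, and the allelic odds
#' ratio with Woolf 95% CI computed from the observed allele counts. SNPs
#' with `p < alpha_genomewide` are flagged genome-wide significant.
#'
#' @param genotypes labeled `genotype_matrix` (status 2 = case, 1 = control).
#' @param alpha_genomewide genome-wide significance threshold.
#' @param stage_label recorded in the output.
#' @return data frame, one row per SNP: counts, frequencies, `or`, `ci_low`,
#'   `ci_high`, `chi2`, `p`, `significant`.
#' @export
stage_association_scan <- function(genotypes, alpha_genomewide = 5e-8,
                                   stage_label = "gwas") {
  st <- genotypes$samples$status
  if (any(is.na(st)) || !all(st %in% c(1L, 2L)))
    stop("every sample must be labeled case (2) or control (1)", call. = FALSE)
  Gca <- genotypes$geno[st == 2L, , drop = FALSE]
  Gco <- genotypes$geno[st == 1L, , drop = FALSE]
  R3 <- rbind(colSums(Gca == 0L, na.rm = TRUE),
              colSums(Gca == 1L, na.rm = TRUE),
              colSums(Gca == 2L, na.rm = TRUE))
  S3 <- rbind(colSums(Gco == 0L, na.rm = TRUE),
              colSums(Gco == 1L, na.rm = TRUE),
              colSums(Gco == 2L, na.rm = TRUE))
  tt <- trend_test_counts(R3, S3)
  n_case <- colSums(R3); n_control <- colSums(S3)
  a <- colSums(R3 * c(0, 1, 2)); b <- 2 * n_case - a
  c_ <- colSums(S3 * c(0, 1, 2)); d <- 2 * n_control - c_
  ors <- t(vapply(seq_along(a), function(j) {
    o <- or_from_counts(a[j], b[j], c_[j], d[j])
    c(o$or, o$ci_low, o$ci_high)
  }, numeric(3)))
  data.frame(
    snp_id = genotypes$map$snp_id, chrom = genotypes$map$chrom,
    pos = genotypes$map$pos, stage = stage_label,
    n_case = n_case, n_control = n_control,
    freq_case = ifelse(n_case > 0, a / (2 * n_case), NA_real_),
    freq_control = ifelse(n_control > 0, c_ / (2 * n_control), NA_real_),
    case_allele1 = a, case_allele2 = b,
    control_allele1 = c_, control_allele2 = d,
    or = ors[, 1], ci_low = ors[, 2], ci_high = ors[, 3],
    chi2 = tt$chi2, p = tt$p,
    significant = tt$p < alpha_genomewide,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Count replicated known loci at a significance level
#'
#' @param results data frame with one P-value per locus (column `p`) and
#'   optional logical category columns (e.g. `discovered_asian`).
#' @param alpha significance level (default 0.01).
#' @param categories names of logical columns to compute per-category
#'   replication proportions for.
#' @return list `n_replicated`, `n_total`, and per-category
#'   `list(n_replicated, n_total, proportion)`.
#' @export
replication_count <- function(results, alpha = 0.01, categories = character(0)) {
  p <- results$p
  skip <- is.na(p)
  if (any(skip)) warning(sprintf("%d loci without P-values skipped", sum(skip)))
  rep_flag <- !skip & p < alpha
  out <- list(n_replicated = sum(rep_flag), n_total = sum(!skip))
  for (cat in categories) {
    inc <- isTRUE_vec(results[[cat]]) & !skip
    out[[cat]] <- list(n_replicated = sum(rep_flag & inc), n_total = sum(inc),
                       proportion = if (sum(inc) > 0) sum(rep_flag & inc) / sum(inc)
                                    else NA_real_)
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
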