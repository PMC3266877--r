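# Independent oracle implementations used to cross-check the package.
# These deliberately use brute-force formulations (full enumeration, direct
# counting, closed forms) rather than the algorithms under test.

# Exact Hardy-Weinberg P by full enumeration over heterozygote counts with
# the observed allele totals, using the log-factorial probability formula.
hwe_enum_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * n0 + n1   # allele "a" count
  nb <- 2 * n2 + n1
  if (na == 0 || nb == 0) return(1.0)
  hs <- seq(na %% 2, min(na, nb), by = 2)
  logp <- vapply(hs, function(h) {
    nh0 <- (na - h) / 2; nh2 <- (nb - h) / 2
    h * log(2) + lfactorial(n) - lfactorial(nh0) - lfactorial(h) -
      lfactorial(nh2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(n1, hs)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Benjamini-Hochberg q-values by the literal step-up definition.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n); q[o] <- pmin(q_sorted, 1)
  q
}

# r^2 and D' by direct haplotype counting from a phased 0/1 haplotype matrix.
hap_ld_oracle <- function(H, i, j) {
  p11 <- mean(H[, i] == 1 & H[, j] == 1)
  pA <- mean(H[, i]); pB <- mean(H[, j])
  D <- p11 - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) D^2 / denom else NA_real_
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(r_squared = r2, d_prime = if (dmax > 0) abs(D) / dmax else NA_real_,
       freqs = c(p11 = p11,
                 p10 = mean(H[, i] == 1 & H[, j] == 0),
                 p01 = mean(H[, i] == 0 & H[, j] == 1),
                 p00 = mean(H[, i] == 0 & H[, j] == 0)))
}

# Quadratic all-pairs scan for cis SNP-probe mapping (boundaries inclusive,
# probe interval 0-based half-open).
cis_pairs_oracle <- function(map, probes, window_bp) {
  out <- list()
  for (i in seq_len(nrow(map))) for (k in seq_len(nrow(probes))) {
    if (map$chrom[i] != probes$chrom[k]) next
    first_base <- probes$start[k] + 1L
    last_base <- probes$end[k]
    if (first_base <= map$pos[i] + window_bp && last_base >= map$pos[i] - window_bp)
      out[[length(out) + 1L]] <- c(map$snp_id[i], probes$probe_id[k])
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, character(1), collapse = "|"))
}

# Grid-search inversion of a standard curve: the ratio whose predicted dCt
# is closest to the observed mean dCt.
curve_inversion_oracle <- function(dct, curve, lo = -8, hi = 8, n_grid = 2e6) {
  grid <- seq(lo, hi, length.out = n_grid)
  pred <- curve$intercept + curve$slope * grid
  2^grid[which.min(abs(pred - dct))]
}

# Simple Cochran-Armitage oracle via the generic score-test formulation in
# stats (prop.trend.test is an independent implementation of the same test).
trend_oracle <- function(case_counts, control_counts) {
  n <- case_counts + control_counts
  keep <- n > 0  # an absent genotype column does not contribute
  st <- suppressWarnings(stats::prop.trend.test(case_counts[keep], n[keep],
                                                score = (c(0, 1, 2))[keep]))
  list(chi2 = unname(st$statistic), p = st$p.value)
}

# A tiny labeled genotype fixture built directly from counts.
geno_from_counts <- function(case_counts, control_counts, snp_id = "snpX") {
  g_case <- rep(0:2, case_counts)
  g_ctrl <- rep(0:2, control_counts)
  G <- matrix(c(g_case, g_ctrl), ncol = 1,
              dimnames = list(sprintf("s%03d", seq_len(length(g_case) + length(g_ctrl))),
                              snp_id))
  structure(list(
    geno = G,
    map = data.frame(snp_id = snp_id, chrom = "chr1", pos = 1000000L,
                     allele1 = "A", allele2 = "G", stringsAsFactors = FALSE),
    samples = data.frame(sample_id = rownames(G),
                         status = c(rep(2L, length(g_case)), rep(1L, length(g_ctrl))),
                         stage = "gwas", stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
}

# Wrap a plain genotype dose matrix as a genotype_matrix with a simple map.
wrap_geno <- function(G, chrom = "chr1", spacing = 10000L, status = NULL) {
  m <- ncol(G)
  if (is.null(colnames(G))) colnames(G) <- sprintf("snp%04d", seq_len(m))
  if (is.null(rownames(G))) rownames(G) <- sprintf("s%05d", seq_len(nrow(G)))
  structure(list(
    geno = G,
    map = data.frame(snp_id = colnames(G), chrom = chrom,
                     pos = 1000000L + (seq_len(m) - 1L) * spacing,
                     allele1 = "A", allele2 = "G",
                     maf = colMeans(G, na.rm = TRUE) / 2,
                     stringsAsFactors = FALSE),
    samples = data.frame(sample_id = rownames(G),
                         status = status %||% rep(NA_integer_, nrow(G)),
                         stage = NA_character_, stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
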