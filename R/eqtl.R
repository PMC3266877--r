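#' Enumerate cis SNP-probe pairs
#'
#' A pair is included when the probe interval (0-based half-open) intersects
#' the window `[snp_pos - window_bp, snp_pos + window_bp]` on the same
#' chromosome, boundaries inclusive. Chromosome mismatches are excluded, not
#' errors.
#'
#' @param map SNP map with `snp_id`, `chrom`, `pos` (1-based).
#' @param probes probe annotation with `probe_id`, `chrom`, `start`, `end`.
#' @param window_bp half-width of the cis window (default 300 kb).
#' @return data frame `snp_id`, `probe_id`, `distance` (0 when the probe
#'   overlaps the SNP).
#' @export
map_cis_pairs <- function(map, probes, window_bp = 300000L) {
  if (window_bp <= 0) config_error("window_bp", "must be > 0")
  out <- list()
  for (ch in intersect(unique(map$chrom), unique(probes$chrom))) {
    s <- map[map$chrom == ch, , drop = FALSE]
    pr <- probes[probes$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0L || nrow(pr) == 0L) next
    ## probe covers 1-based bases (start+1)..end
    lo <- outer(s$pos, pr$end, function(pos, end) end >= pos - window_bp)
    hi <- outer(s$pos, pr$start, function(pos, st) st + 1L <= pos + window_bp)
    hit <- which(lo & hi, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    d1 <- pr$start[hit[, 2]] + 1L - s$pos[hit[, 1]]  # probe right of SNP
    d2 <- s$pos[hit[, 1]] - pr$end[hit[, 2]]         # probe left of SNP
    out[[ch]] <- data.frame(snp_id = s$snp_id[hit[, 1]],
                            probe_id = pr$probe_id[hit[, 2]],
                            distance = pmax(d1, d2, 0L),
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(snp_id = character(), probe_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$snp_id, map$snp_id), res$probe_id), , drop = FALSE]
}

#' Rank-based inverse-normal transformation of expression
#'
#' Normalizes each probe across individuals: values are replaced by
#' `qnorm((rank - 0.5) / n)` with ties given average ranks, so every probe
#' has mean approximately 0 and variance approximately 1. Constant probes
#' cannot be ranked and become all zeros; their ids are attached as attribute
#' `constant_probes`.
#'
#' @param raw probes x samples expression matrix.
#' @return transformed matrix of the same shape.
#' @export
normalize_expression <- function(raw) {
  if (ncol(raw) < 2L) stop("need at least two samples", call. = FALSE)
  flagged <- character(0)
  out <- raw
  for (i in seq_len(nrow(raw))) {
    x <- raw[i, ]
    ok <- !is.na(x)
    if (sum(ok) < 2L || stats::sd(x[ok]) == 0) {
      out[i, ok] <- 0
      flagged <- c(flagged, rownames(raw)[i] %||% as.character(i))
      next
    }
    r <- rank(x[ok], ties.method = "average")
    out[i, ok] <- stats::qnorm((r - 0.5) / sum(ok))
  }
  attr(out, "constant_probes") <- flagged
  out
}

#' Additive-model eQTL regression for one SNP-probe pair
#'
#' Ordinary least squares of expression on genotype dose (0/1/2), complete
#' cases only: slope, standard error, two-sided t-test P-value, and
#' r-squared (the squared sample correlation).
#'
#' @param genotype_vector genotype doses.
#' @param expression_vector expression values, same length.
#' @return list `beta`, `se`, `r_squared`, `p`, `n`.
#' @export
eqtl_regression <- function(genotype_vector, expression_vector) {
  ok <- !is.na(genotype_vector) & !is.na(expression_vector)
  g <- as.numeric(genotype_vector[ok]); y <- as.numeric(expression_vector[ok])
  n <- length(g)
  if (n < 3L) stop("need at least 3 complete genotype-expression pairs", call. = FALSE)
  sgg <- sum((g - mean(g))^2)
  if (sgg == 0) stop("monomorphic in expression panel", call. = FALSE)
  beta <- sum((g - mean(g)) * (y - mean(y))) / sgg
  resid <- y - mean(y) - beta * (g - mean(g))
  rss <- sum(resid^2)
  syy <- sum((y - mean(y))^2)
  se <- sqrt(rss / (n - 2) / sgg)
  r2 <- if (syy > 0) 1 - rss / syy else 0
  tstat <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(beta = beta, se = se, r_squared = r2, p = max(p, .Machine$double.xmin),
       n = n)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement; the
#' input order is preserved in the output.
#'
#' @param p_values numeric vector of P-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Run the cis-eQTL screen
#'
#' Maps cis pairs, optionally applies the rank-based inverse-normal
#' transform, regresses each probe on genotype dose, and adjusts all pair
#' P-values in one global Benjamini-Hochberg family (the `per_snp` option
#' adjusts within each SNP's probe set instead). Pairs whose SNP is
#' monomorphic in the expression panel are dropped with a note.
#'
#' @param genotypes `genotype_matrix` covering the expression samples.
#' @param expr probes x samples expression matrix (columns matched to sample
#'   ids by name).
#' @param probes probe annotation (see [map_cis_pairs()]).
#' @param window_bp cis window half-width.
#' @param q_threshold FDR threshold for eQTL positivity.
#' @param normalize apply [normalize_expression()] first.
#' @param fdr_family `"global"` (default) or `"per_snp"`.
#' @return list `tests` (pair-level data frame with `beta`, `se`,
#'   `r_squared`, `p`, `q`), `flags` (see [flag_eqtl_positive()]),
#'   `n_monomorphic_dropped`.
#' @export
eqtl_scan <- function(genotypes, expr, probes, window_bp = 300000L,
                      q_threshold = 0.2, normalize = TRUE,
                      fdr_family = c("global", "per_snp")) {
  fdr_family <- match.arg(fdr_family)
  pairs <- map_cis_pairs(genotypes$map, probes, window_bp)
  common <- intersect(colnames(expr), rownames(genotypes$geno))
  if (length(common) < 3L)
    stop("fewer than 3 samples shared between genotype and expression panels",
         call. = FALSE)
  E <- expr[, common, drop = FALSE]
  if (normalize) E <- normalize_expression(E)
  G <- genotypes$geno[common, , drop = FALSE]
  res <- vector("list", nrow(pairs)); dropped <- 0L
  for (k in seq_len(nrow(pairs))) {
    g <- G[, pairs$snp_id[k]]
    y <- E[pairs$probe_id[k], ]
    fit <- tryCatch(eqtl_regression(g, y), error = function(e) NULL)
    if (is.null(fit)) { dropped <- dropped + 1L; next }
    res[[k]] <- data.frame(snp_id = pairs$snp_id[k], probe_id = pairs$probe_id[k],
                           beta = fit$beta, se = fit$se,
                           r_squared = fit$r_squared, p = fit$p, n = fit$n,
                           stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(tests))
    tests <- data.frame(snp_id = character(), probe_id = character(),
                        beta = numeric(), se = numeric(), r_squared = numeric(),
                        p = numeric(), n = integer(), q = numeric(),
                        stringsAsFactors = FALSE)
  if (nrow(tests) > 0L) {
    tests$q <- if (fdr_family == "global") bh_fdr(tests$p)
               else stats::ave(tests$p, tests$snp_id, FUN = bh_fdr)
  }
  list(tests = tests,
       flags = flag_eqtl_positive(tests, genotypes$map$snp_id, q_threshold),
       n_monomorphic_dropped = dropped)
}

#' eQTL positivity flags per SNP
#'
#' A SNP is eQTL positive when the minimum q-value over its cis probes is
#' strictly below `q_threshold`; the probe attaining it is recorded. SNPs
#' with no cis probe (or none testable) are negative with no best probe.
#'
#' @param tests pair-level test table with `snp_id`, `probe_id`, `q`.
#' @param snp_ids all SNP ids to emit a flag for.
#' @param q_threshold FDR threshold (default 0.2).
#' @return data frame `snp_id`, `positive`, `best_probe`, `best_q`.
#' @export
flag_eqtl_positive <- function(tests, snp_ids, q_threshold = 0.2) {
  out <- data.frame(snp_id = snp_ids, positive = FALSE,
                    best_probe = NA_character_, best_q = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(tests) > 0L) {
    sp <- split(seq_len(nrow(tests)), tests$snp_id)
    for (id in names(sp)) {
      i <- out$snp_id == id
      if (!any(i)) next
      rows <- sp[[id]]
      best <- rows[which.min(tests$q[rows])]
      out$best_q[i] <- tests$q[best]
      out$best_probe[i] <- tests$probe_id[best]
      out$positive[i] <- tests$q[best] < q_threshold
    }
  }
  out
}

#' eQTL-positivity enrichment between two SNP sets
#'
#' Positivity rates in a focal and a background SNP set, with a two-sided
#' Fisher exact P-value on the 2x2 table as a supplementary diagnostic.
#'
#' @param flags output of [flag_eqtl_positive()].
#' @param focal_snp_set,background_snp_set character vectors of SNP ids, both
#'   nonempty and covered by `flags`.
#' @return list `rate_focal`, `rate_background`, `n_focal_positive`,
#'   `n_focal`, `n_background_positive`, `n_background`, `fisher_p`.
#' @export
positivity_enrichment <- function(flags, focal_snp_set, background_snp_set) {
  if (length(focal_snp_set) == 0L || length(background_snp_set) == 0L)
    stop("SNP sets must be nonempty", call. = FALSE)
  if (!all(focal_snp_set %in% flags$snp_id) ||
      !all(background_snp_set %in% flags$snp_id))
    stop("every SNP in both sets must carry an eQTL flag", call. = FALSE)
  pos <- stats::setNames(flags$positive, flags$snp_id)
  fp <- sum(pos[focal_snp_set]); fn <- length(focal_snp_set) - fp
  bp <- sum(pos[background_snp_set]); bn <- length(background_snp_set) - bp
  ft <- stats::fisher.test(matrix(c(fp, fn, bp, bn), 2L), alternative = "two.sided")
  list(rate_focal = fp / length(focal_snp_set),
       rate_background = bp / length(background_snp_set),
       n_focal_positive = fp, n_focal = length(focal_snp_set),
       n_background_positive = bp, n_background = length(background_snp_set),
       fisher_p = ft$p.value)
}
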