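#' Simulation configuration for a synthetic case-control eQTL cohort
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate the
#' first (GWAS) stage of a Japanese SLE case-control study: 891 cases and
#' 3,384 controls, biallelic autosomal SNPs organised in LD blocks, additive
#' logistic disease risk, probe expression with additive cis-genotype effects,
#' a pooled-DNA scan emitting rank-based P-values, and qPCR plates obeying the
#' log2 amount-Ct relationship.
#'
#' @param n_cases,n_controls sample sizes of the simulated case-control panel.
#' @param n_snps,n_blocks number of biallelic SNPs and of LD blocks they are
#'   partitioned into. Each block is placed on its own chromosome.
#' @param block_ld_rho haplotype correlation between adjacent SNPs within a
#'   block, in `[0, 1)`.
#' @param maf_range range the per-block minor allele frequency is drawn from,
#'   within `(0, 0.5]`.
#' @param risk_snps `NULL` or a data frame with columns `snp_index`,
#'   `allele_or` (per-allele odds ratio, > 0) and optionally `eqtl_beta`
#'   (expression change per allele copy; `NA` for no cis effect).
#' @param prevalence population disease probability used to anchor the
#'   baseline of the liability model.
#' @param n_expr_samples number of individuals carried into the expression
#'   panel. Default 90 emulates an East-Asian lymphoblastoid reference panel.
#' @param probes_per_region expression probes placed in each annotated cis
#'   region (one carries the genotype effect in risk regions, the rest are
#'   decoys).
#' @param expr_noise_sd standard deviation of Gaussian expression noise.
#' @param missing_rate completely-at-random genotype missingness rate.
#' @param seed master integer seed; all component streams derive from it.
#' @param pool_size finite haplotype-pool size per block, or `Inf` (default)
#'   to draw every haplotype fresh from the block's Markov chain.
#' @param snp_spacing_bp distance between adjacent simulated SNPs.
#' @param n_decoy_regions number of non-risk SNPs that also receive a probe
#'   cluster, so the eQTL screen has a realistic null background.
#' @param pooled_enrichment mean shift added to the pooled-scan score of SNPs
#'   within `pooled_window_bp` of a causal SNP (0 disables the signal).
#' @param pooled_window_bp window around causal SNPs receiving pooled-scan
#'   enrichment.
#' @param n_rep1_cases,n_rep1_controls,n_rep2_cases,n_rep2_controls sample
#'   sizes of the two replication stages (defaults follow the emulated study
#'   design: 562/653 and 825/27,911).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 891L, n_controls = 3384L,
                       n_snps = 500L, n_blocks = 50L,
                       block_ld_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       risk_snps = NULL,
                       prevalence = 0.01,
                       n_expr_samples = 90L,
                       probes_per_region = 5L,
                       expr_noise_sd = 1,
                       missing_rate = 0.002,
                       seed = 1L,
                       pool_size = Inf,
                       snp_spacing_bp = 25000L,
                       n_decoy_regions = 20L,
                       pooled_enrichment = 4,
                       pooled_window_bp = 100000L,
                       n_rep1_cases = 562L, n_rep1_controls = 653L,
                       n_rep2_cases = 825L, n_rep2_controls = 27911L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_snps = as.integer(n_snps), n_blocks = as.integer(n_blocks),
    block_ld_rho = block_ld_rho, maf_range = as.numeric(maf_range),
    risk_snps = risk_snps, prevalence = prevalence,
    n_expr_samples = as.integer(n_expr_samples),
    probes_per_region = as.integer(probes_per_region),
    expr_noise_sd = expr_noise_sd, missing_rate = missing_rate,
    seed = as.integer(seed), pool_size = pool_size,
    snp_spacing_bp = as.integer(snp_spacing_bp),
    n_decoy_regions = as.integer(n_decoy_regions),
    pooled_enrichment = pooled_enrichment,
    pooled_window_bp = as.integer(pooled_window_bp),
    n_rep1_cases = as.integer(n_rep1_cases),
    n_rep1_controls = as.integer(n_rep1_controls),
    n_rep2_cases = as.integer(n_rep2_cases),
    n_rep2_controls = as.integer(n_rep2_controls)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      config_error(field, "must be a positive count")
  }
  for (f in c("n_cases", "n_controls", "n_snps", "n_blocks",
              "n_expr_samples", "probes_per_region")) pos_count(f)
  if (cfg$n_blocks > cfg$n_snps)
    config_error("n_blocks", "cannot exceed n_snps")
  if (!is.numeric(cfg$block_ld_rho) || cfg$block_ld_rho < 0 || cfg$block_ld_rho >= 1)
    config_error("block_ld_rho", "must lie in [0, 1)")
  mr <- cfg$maf_range
  if (length(mr) != 2L || any(!is.finite(mr)) || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    config_error("maf_range", "must be (low, high) within (0, 0.5]")
  if (!is.numeric(cfg$prevalence) || cfg$prevalence <= 0 || cfg$prevalence >= 1)
    config_error("prevalence", "must be a probability in (0, 1)")
  if (!is.numeric(cfg$expr_noise_sd) || cfg$expr_noise_sd < 0)
    config_error("expr_noise_sd", "must be non-negative")
  if (!is.numeric(cfg$missing_rate) || cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    config_error("missing_rate", "must lie in [0, 1)")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    config_error("seed", "must be a single integer")
  rs <- cfg$risk_snps
  if (!is.null(rs)) {
    if (!is.data.frame(rs) || !all(c("snp_index", "allele_or") %in% names(rs)))
      config_error("risk_snps", "needs columns snp_index and allele_or")
    if (any(rs$snp_index < 1 | rs$snp_index > cfg$n_snps))
      config_error("risk_snps", "snp_index out of range")
    if (any(!is.finite(rs$allele_or)) || any(rs$allele_or <= 0))
      config_error("risk_snps", "allele_or must be > 0")
    if (anyDuplicated(rs$snp_index))
      config_error("risk_snps", "duplicate snp_index")
  }
  invisible(cfg)
}

## Block bookkeeping: which block each SNP belongs to, and its genomic map.
## Each block sits on its own synthetic chromosome so that cis windows and
## pooled-scan distance rules never leak across blocks.
block_layout <- function(cfg) {
  block <- sort(rep_len(seq_len(cfg$n_blocks), cfg$n_snps))
  idx_in_block <- stats::ave(seq_along(block), block, FUN = seq_along)
  data.frame(
    snp_id = sprintf("snp%04d", seq_len(cfg$n_snps)),
    chrom = paste0("chr", block),
    pos = 1000000L + (idx_in_block - 1L) * cfg$snp_spacing_bp,
    allele1 = "A", allele2 = "G",
    block = block,
    stringsAsFactors = FALSE
  )
}

## Markov-chain haplotypes for one block: n_hap x m 0/1 matrix with
## cor(h[,j-1], h[,j]) = rho (all SNPs in a block share allele frequency p).
markov_haplotypes <- function(n_hap, m, p, rho) {
  h <- matrix(0L, nrow = n_hap, ncol = m)
  h[, 1] <- as.integer(stats::runif(n_hap) < p)
  if (m > 1L) for (j in 2:m) {
    copy <- stats::runif(n_hap) < rho
    fresh <- as.integer(stats::runif(n_hap) < p)
    h[, j] <- ifelse(copy, h[, j - 1L], fresh)
  }
  h
}

## Haplotypes for every block, stacked column-wise; optionally routed through
## a finite per-block pool (pool_size haplotypes generated, then resampled).
simulate_haplotypes <- function(cfg, n_hap, map, block_maf) {
  H <- matrix(0L, nrow = n_hap, ncol = cfg$n_snps)
  for (b in seq_len(cfg$n_blocks)) {
    cols <- which(map$block == b)
    if (is.finite(cfg$pool_size)) {
      pool <- markov_haplotypes(as.integer(cfg$pool_size), length(cols),
                                block_maf[b], cfg$block_ld_rho)
      H[, cols] <- pool[sample.int(nrow(pool), n_hap, replace = TRUE), , drop = FALSE]
    } else {
      H[, cols] <- markov_haplotypes(n_hap, length(cols), block_maf[b], cfg$block_ld_rho)
    }
  }
  H
}

#' Simulate a genotype matrix with block LD structure
#'
#' Haplotypes are generated per LD block by a first-order Markov copy process:
#' within a block all SNPs share one allele frequency drawn from `maf_range`,
#' and each haplotype allele is copied from the previous SNP with probability
#' `block_ld_rho` (otherwise redrawn), giving adjacent-SNP haplotype
#' correlation equal to `block_ld_rho`. Genotypes are the sum of two
#' haplotypes; missing entries are masked completely at random at
#' `missing_rate`.
#'
#' @param config a [sim_config()].
#' @param n_samples number of individuals (default `n_cases + n_controls`).
#' @param return_haplotypes keep the underlying haplotypes as attribute
#'   `haplotypes` (2 rows per sample), e.g. for exact LD oracles.
#' @param seed_stream label used to derive this component's RNG stream.
#' @return a `genotype_matrix`: list with integer matrix `geno` (samples x
#'   SNPs, values 0/1/2/NA counting copies of `allele1`), SNP `map`, and
#'   `samples` table.
#' @export
simulate_genotypes <- function(config, n_samples = NULL,
                               return_haplotypes = FALSE,
                               seed_stream = "genotypes") {
  validate_sim_config(config)
  n <- as.integer(n_samples %||% (config$n_cases + config$n_controls))
  if (n <= 0) config_error("n_samples", "must be positive")
  set.seed(derive_seed(config$seed, seed_stream))
  map <- block_layout(config)
  block_maf <- stats::runif(config$n_blocks, config$maf_range[1], config$maf_range[2])
  map$maf <- block_maf[map$block]
  H <- simulate_haplotypes(config, 2L * n, map, block_maf)
  G <- H[seq(1, 2L * n, by = 2L), , drop = FALSE] +
       H[seq(2, 2L * n, by = 2L), , drop = FALSE]
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(G)) < config$missing_rate
    G[mask] <- NA_integer_
  }
  dimnames(G) <- list(sprintf("s%05d", seq_len(n)), map$snp_id)
  out <- structure(list(
    geno = G,
    map = map,
    samples = data.frame(sample_id = rownames(G), status = NA_integer_,
                         stage = NA_character_, stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
  if (return_haplotypes) attr(out, "haplotypes") <- H
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d blocks), %.2f%% missing\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$block)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

## Truth table for the configured risk SNPs.
risk_truth <- function(config, map) {
  rs <- config$risk_snps
  if (is.null(rs) || nrow(rs) == 0L) {
    return(data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), allele_or = numeric(),
                      eqtl_beta = numeric(), causal = logical(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    snp_id = map$snp_id[rs$snp_index],
    chrom = map$chrom[rs$snp_index],
    pos = map$pos[rs$snp_index],
    allele_or = rs$allele_or,
    eqtl_beta = if ("eqtl_beta" %in% names(rs)) rs$eqtl_beta else NA_real_,
    causal = TRUE,
    stringsAsFactors = FALSE
  )
}

## Solve the liability-model baseline logit so the population prevalence under
## HWE at the realized risk-SNP allele frequencies equals config$prevalence.
## Exact enumeration over the 3^k risk-genotype distribution (k risk SNPs sit
## in distinct blocks and are treated as independent).
solve_baseline <- function(config, map) {
  rs <- config$risk_snps
  if (is.null(rs) || nrow(rs) == 0L || all(rs$allele_or == 1))
    return(stats::qlogis(config$prevalence))
  solve_baseline_core(map$maf[rs$snp_index], log(rs$allele_or), config$prevalence)
}

## Core 1-D root find: p and lor are the risk-SNP allele frequencies and
## per-allele log odds ratios; returns the baseline logit (tolerance 1e-8).
solve_baseline_core <- function(p, lor, prevalence) {
  keep <- lor != 0
  if (!any(keep)) return(stats::qlogis(prevalence))
  p <- p[keep]; lor <- lor[keep]
  ## genotype dose distributions under HWE, combined over SNPs
  scores <- 0; probs <- 1
  for (i in seq_along(p)) {
    gp <- c((1 - p[i])^2, 2 * p[i] * (1 - p[i]), p[i]^2)
    scores <- as.vector(outer(scores, lor[i] * 0:2, `+`))
    probs <- as.vector(outer(probs, gp, `*`))
    if (length(scores) > 200000L) { # collapse near-duplicates to bound growth
      o <- order(scores)
      scores <- scores[o]; probs <- probs[o]
      grp <- cumsum(c(TRUE, diff(scores) > 1e-9))
      probs <- as.vector(tapply(probs, grp, sum))
      scores <- as.vector(tapply(scores, grp, min))
    }
  }
  f <- function(b0) sum(probs * stats::plogis(b0 + scores)) - prevalence
  lo <- stats::qlogis(prevalence) - abs(sum(lor)) * 2 - 10
  hi <- stats::qlogis(prevalence) + 10
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

## Case probability per sample under the additive liability logit. Missing
## risk genotypes contribute their HWE-expected dose.
case_probability <- function(geno, map, config, baseline) {
  eta <- rep(baseline, nrow(geno))
  rs <- config$risk_snps
  if (!is.null(rs) && nrow(rs) > 0L) {
    for (i in seq_len(nrow(rs))) {
      g <- geno[, rs$snp_index[i]]
      g[is.na(g)] <- 2 * map$maf[rs$snp_index[i]]
      eta <- eta + log(rs$allele_or[i]) * g
    }
  }
  stats::plogis(eta)
}

#' Label a simulated genotype panel with case/control status
#'
#' Applies the additive logistic liability model (baseline solved by 1-D root
#' finding so the population prevalence matches the configuration, tolerance
#' 1e-8) and draws disease status per sample. Exactly `n_cases` cases and
#' `n_controls` controls are then retained, in input order; if the panel does
#' not contain enough of either, an error suggests [simulate_cohort()], which
#' keeps generating batches until the quotas are met.
#'
#' @param genotypes a `genotype_matrix`.
#' @param config the [sim_config()] used to generate it.
#' @return a `synthetic_cohort`: list with `genotypes` (cases first, status 2
#'   = case / 1 = control), and `truth` table of simulated effects.
#' @export
assign_phenotypes <- function(genotypes, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "phenotypes"))
  baseline <- solve_baseline(config, genotypes$map)
  pr <- case_probability(genotypes$geno, genotypes$map, config, baseline)
  is_case <- stats::runif(length(pr)) < pr
  case_idx <- which(is_case)[seq_len(min(sum(is_case), config$n_cases))]
  ctrl_idx <- which(!is_case)[seq_len(min(sum(!is_case), config$n_controls))]
  if (length(case_idx) < config$n_cases || length(ctrl_idx) < config$n_controls)
    stop(sprintf(paste0("panel yielded %d cases / %d controls but %d / %d were",
                        " requested; use simulate_cohort() for rejection sampling"),
                 length(case_idx), length(ctrl_idx),
                 config$n_cases, config$n_controls), call. = FALSE)
  keep <- c(case_idx, ctrl_idx)
  g <- genotypes
  g$geno <- g$geno[keep, , drop = FALSE]
  g$samples <- data.frame(
    sample_id = rownames(g$geno),
    status = c(rep(2L, length(case_idx)), rep(1L, length(ctrl_idx))),
    stage = "gwas", stringsAsFactors = FALSE
  )
  structure(list(genotypes = g, truth = risk_truth(config, genotypes$map)),
            class = "synthetic_cohort")
}

#' Simulate a case-control cohort by rejection sampling
#'
#' Generates genotype batches from the block-LD haplotype model, labels them
#' through the liability model, and accumulates cases and controls until the
#' configured quotas are reached exactly. Sample ids are reassigned
#' sequentially (cases first) after ascertainment.
#'
#' @param config a [sim_config()].
#' @param max_batches safety cap on rejection-sampling batches.
#' @param seed_stream RNG stream label (vary to obtain independent cohorts,
#'   e.g. replication stages, from one master seed).
#' @return a `synthetic_cohort` (see [assign_phenotypes()]).
#' @export
simulate_cohort <- function(config, max_batches = 200L, seed_stream = "cohort") {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, seed_stream))
  map <- block_layout(config)
  block_maf <- stats::runif(config$n_blocks, config$maf_range[1], config$maf_range[2])
  map$maf <- block_maf[map$block]
  baseline <- solve_baseline_with_map(config, map)
  need_case <- config$n_cases; need_ctrl <- config$n_controls
  null_model <- is.null(config$risk_snps) || nrow(config$risk_snps) == 0L ||
                all(config$risk_snps$allele_or == 1)
  if (null_model) {
    ## disease status is independent of genotype: draw the quotas directly
    n <- need_case + need_ctrl
    H <- simulate_haplotypes(config, 2L * n, map, block_maf)
    G <- H[seq(1, 2L * n, by = 2L), , drop = FALSE] +
         H[seq(2, 2L * n, by = 2L), , drop = FALSE]
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(G)) < config$missing_rate
      G[mask] <- NA_integer_
    }
    dimnames(G) <- list(sprintf("s%05d", seq_len(n)), map$snp_id)
    g <- structure(list(
      geno = G, map = map,
      samples = data.frame(sample_id = rownames(G),
                           status = c(rep(2L, need_case), rep(1L, need_ctrl)),
                           stage = "gwas", stringsAsFactors = FALSE)
    ), class = "genotype_matrix")
    return(structure(list(genotypes = g, truth = risk_truth(config, map)),
                     class = "synthetic_cohort"))
  }
  ## batch size targets filling the scarcer quota in a handful of batches
  ## while keeping each batch's genotype block at a bounded cell count
  exp_case_rate <- max(config$prevalence / 2, 1e-4)
  batch_n <- as.integer(min(60000, max(2000, ceiling(need_case / exp_case_rate / 3),
                                       need_ctrl / 2),
                            max(2000, floor(2e7 / config$n_snps))))
  cases <- list(); ctrls <- list(); got_case <- 0L; got_ctrl <- 0L
  for (b in seq_len(max_batches)) {
    H <- simulate_haplotypes(config, 2L * batch_n, map, block_maf)
    G <- H[seq(1, 2L * batch_n, by = 2L), , drop = FALSE] +
         H[seq(2, 2L * batch_n, by = 2L), , drop = FALSE]
    pr <- case_probability(G, map, config, baseline)
    is_case <- stats::runif(batch_n) < pr
    if (got_case < need_case && any(is_case)) {
      take <- which(is_case)[seq_len(min(sum(is_case), need_case - got_case))]
      cases[[length(cases) + 1L]] <- G[take, , drop = FALSE]
      got_case <- got_case + length(take)
    }
    if (got_ctrl < need_ctrl && any(!is_case)) {
      take <- which(!is_case)[seq_len(min(sum(!is_case), need_ctrl - got_ctrl))]
      ctrls[[length(ctrls) + 1L]] <- G[take, , drop = FALSE]
      got_ctrl <- got_ctrl + length(take)
    }
    if (got_case >= need_case && got_ctrl >= need_ctrl) break
  }
  if (got_case < need_case || got_ctrl < need_ctrl)
    stop(sprintf("prevalence %.4g unattainable: %d/%d cases after %d batches",
                 config$prevalence, got_case, need_case, max_batches), call. = FALSE)
  G <- rbind(do.call(rbind, cases), do.call(rbind, ctrls))
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(G)) < config$missing_rate
    G[mask] <- NA_integer_
  }
  dimnames(G) <- list(sprintf("s%05d", seq_len(nrow(G))), map$snp_id)
  g <- structure(list(
    geno = G, map = map,
    samples = data.frame(sample_id = rownames(G),
                         status = c(rep(2L, need_case), rep(1L, need_ctrl)),
                         stage = "gwas", stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
  structure(list(genotypes = g, truth = risk_truth(config, map)),
            class = "synthetic_cohort")
}

## solve_baseline against an explicit map (used when the map is built inline).
solve_baseline_with_map <- function(config, map) solve_baseline(config, map)

#' Simulate probe expression with additive cis-genotype effects
#'
#' The first `n_expr_samples` individuals of the genotype panel form the
#' expression panel. Every risk SNP with a non-missing `eqtl_beta` receives
#' one probe inside its cis window whose expression is
#' `eqtl_beta * genotype + N(0, expr_noise_sd)`; the remaining
#' `probes_per_region - 1` probes of that region, and all probes of
#' `n_decoy_regions` randomly chosen non-risk regions, carry pure noise.
#' Probe coordinates are emitted 0-based half-open.
#'
#' @param genotypes a `genotype_matrix`.
#' @param config a [sim_config()].
#' @return list with `expr` (probes x samples matrix) and `probes` annotation
#'   (`probe_id`, `chrom`, `start`, `end`, `gene_label`).
#' @export
simulate_expression <- function(genotypes, config) {
  validate_sim_config(config)
  if (config$n_expr_samples > nrow(genotypes$geno))
    config_error("n_expr_samples", "exceeds available samples")
  set.seed(derive_seed(config$seed, "expression"))
  map <- genotypes$map
  rs <- config$risk_snps
  ## risk SNPs are matched by id so the panel may already be QC-filtered
  eqtl_idx <- integer(0); eqtl_beta <- numeric(0)
  if (!is.null(rs) && nrow(rs) > 0L && "eqtl_beta" %in% names(rs)) {
    keep <- which(!is.na(rs$eqtl_beta))
    idx <- match(sprintf("snp%04d", rs$snp_index[keep]), map$snp_id)
    eqtl_idx <- idx[!is.na(idx)]; eqtl_beta <- rs$eqtl_beta[keep][!is.na(idx)]
  }
  decoy_pool <- setdiff(seq_len(nrow(map)), eqtl_idx)
  decoy_idx <- sort(sample(decoy_pool, min(config$n_decoy_regions, length(decoy_pool))))
  region_idx <- c(eqtl_idx, decoy_idx)
  region_true <- c(rep(TRUE, length(eqtl_idx)), rep(FALSE, length(decoy_idx)))
  region_beta <- c(eqtl_beta, rep(NA_real_, length(decoy_idx)))

  ## prefer control samples for the expression panel (it emulates a healthy
  ## reference panel); fall back to any samples when labels are absent
  st <- genotypes$samples$status
  ctrl <- which(!is.na(st) & st == 1L)
  samp <- if (length(ctrl) >= config$n_expr_samples)
    ctrl[seq_len(config$n_expr_samples)]
  else seq_len(config$n_expr_samples)
  Ge <- genotypes$geno[samp, , drop = FALSE]
  probes <- list(); exprs <- list(); pid <- 0L
  probe_len <- 50L
  for (r in seq_along(region_idx)) {
    s <- region_idx[r]
    n_probe <- config$probes_per_region
    offsets <- seq(-200000L, 200000L, length.out = max(n_probe, 2L))[seq_len(n_probe)]
    offsets <- as.integer(round(offsets))
    for (k in seq_len(n_probe)) {
      pid <- pid + 1L
      start0 <- map$pos[s] + offsets[k] - 1L  # 0-based
      if (start0 < 0L || start0 + probe_len < 1L)
        stop(sprintf("probe placement outside chromosome bounds for %s",
                     map$snp_id[s]), call. = FALSE)
      is_true <- region_true[r] && k == ((n_probe %/% 2) + 1L)
      y <- stats::rnorm(length(samp), 0, config$expr_noise_sd)
      if (is_true) {
        dose <- Ge[, s]
        dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
        y <- y + region_beta[r] * dose
      }
      probes[[pid]] <- data.frame(
        probe_id = sprintf("probe%05d", pid),
        chrom = map$chrom[s], start = start0, end = start0 + probe_len,
        gene_label = sprintf("%s_%s", if (is_true) "target" else "decoy", map$snp_id[s]),
        stringsAsFactors = FALSE
      )
      exprs[[pid]] <- y
    }
  }
  probes <- do.call(rbind, probes)
  expr <- do.call(rbind, exprs)
  dimnames(expr) <- list(probes$probe_id, rownames(Ge))
  list(expr = expr, probes = probes)
}

#' Simulate a pooled-DNA scan summary table
#'
#' Emits one rank-based P-value per SNP. Each SNP receives a standard-normal
#' score; SNPs within `pooled_window_bp` of a causal SNP in `truth` get a mean
#' shift of `pooled_enrichment`. Absolute scores are ranked (rank 1 = most
#' extreme) and converted with [rank_based_p()], so under the null the
#' P-values are uniform by construction. The score-generation model is a
#' stand-in for a pooled-array statistic, not a reconstruction of one.
#'
#' @param map SNP map (`snp_id`, `chrom`, `pos`).
#' @param truth truth table from a `synthetic_cohort` (may have zero rows).
#' @param config a [sim_config()].
#' @return data frame `snp_id`, `chrom`, `pos`, `score`, `rank_p`.
#' @export
simulate_pooled_scan <- function(map, truth, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "pooled_scan"))
  score <- stats::rnorm(nrow(map))
  if (nrow(truth) > 0L && config$pooled_enrichment != 0) {
    for (i in seq_len(nrow(truth))) {
      near <- map$chrom == truth$chrom[i] &
              abs(map$pos - truth$pos[i]) <= config$pooled_window_bp
      score[near] <- score[near] + config$pooled_enrichment
    }
  }
  data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
             score = abs(score), rank_p = rank_based_p(abs(score)),
             stringsAsFactors = FALSE)
}

#' Simulate an allele-specific qPCR plate
#'
#' Emits Ct pairs for the genomic-DNA mixture series used to build the
#' standard curve plus, per cell line, quadruplicate genomic-DNA (allelic
#' ratio 1, heterozygote) and cDNA (allelic ratio `true_ratio`) measurements.
#' Each Ct obeys `Ct = base_ct - log2(allele amount) + channel offset +
#' N(0, noise_sd_ct)`; the two allele amounts in a sample of total amount 1
#' with VIC:FAM ratio r are r/(1+r) and 1/(1+r).
#'
#' @param true_ratio cDNA allelic ratio (VIC over FAM allele) common to all
#'   lines.
#' @param n_lines number of heterozygous cell lines.
#' @param noise_sd_ct replicate Ct noise standard deviation.
#' @param seed integer seed.
#' @param mixtures VIC:FAM ratios of the genomic-DNA mixture series (default
#'   the 2:8 ... 8:2 series).
#' @param n_replicates replicates per sample and channel.
#' @param vic_offset probe-specific Ct shift of the VIC channel.
#' @param base_ct Ct of one unit of template.
#' @return data frame `sample_id`, `material` (`mixture`/`genomic_dna`/
#'   `cdna`), `mixture_ratio`, `replicate`, `ct_vic`, `ct_fam`.
#' @export
simulate_astq_plate <- function(true_ratio, n_lines, noise_sd_ct, seed = 1L,
                                mixtures = c(2/8, 3/7, 4/6, 1, 6/4, 7/3, 8/2),
                                n_replicates = 4L, vic_offset = 0,
                                base_ct = 24) {
  if (!is.numeric(true_ratio) || true_ratio <= 0)
    config_error("true_ratio", "must be > 0")
  if (n_lines < 1) config_error("n_lines", "must be a positive count")
  if (noise_sd_ct < 0) config_error("noise_sd_ct", "must be non-negative")
  set.seed(derive_seed(seed, "astq_plate"))
  ct_pair <- function(ratio) {
    amount_vic <- ratio / (1 + ratio); amount_fam <- 1 / (1 + ratio)
    list(vic = base_ct - log2(amount_vic) + vic_offset +
               stats::rnorm(n_replicates, 0, noise_sd_ct),
         fam = base_ct - log2(amount_fam) +
               stats::rnorm(n_replicates, 0, noise_sd_ct))
  }
  rows <- list()
  add <- function(id, material, ratio) {
    p <- ct_pair(ratio)
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = id, material = material,
      mixture_ratio = if (material == "mixture") ratio else NA_real_,
      replicate = seq_len(n_replicates), ct_vic = p$vic, ct_fam = p$fam,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(mixtures))
    add(sprintf("mix_%d", i), "mixture", mixtures[i])
  for (l in seq_len(n_lines)) {
    add(sprintf("line%02d", l), "genomic_dna", 1)
    add(sprintf("line%02d", l), "cdna", true_ratio)
  }
  do.call(rbind, rows)
}

#' Corrupt a genotype panel for QC fixtures
#'
#' Deliberately degrades a simulated panel so that QC rules have something to
#' catch: extra missingness in chosen samples or SNPs, a forced
#' heterozygote-free SNP (gross Hardy-Weinberg violation), or an injected
#' ancestry outlier whose allele frequencies are shifted away from the panel.
#'
#' @param genotypes a `genotype_matrix`.
#' @param low_call_samples,sample_miss_rate sample indices to degrade and
#'   their missingness rate.
#' @param low_call_snps,snp_miss_rate SNP indices to degrade and rate.
#' @param hwe_violation_snps SNP indices whose heterozygotes are pushed to
#'   homozygotes (het -> hom alternating), destroying HWE.
#' @param ancestry_outlier_samples sample indices regenerated from allele
#'   frequencies shifted by `outlier_freq_shift`.
#' @param outlier_freq_shift frequency displacement of the outlier population.
#' @param seed integer seed.
#' @return the corrupted `genotype_matrix`.
#' @export
corrupt_genotypes <- function(genotypes,
                              low_call_samples = integer(0), sample_miss_rate = 0.1,
                              low_call_snps = integer(0), snp_miss_rate = 0.05,
                              hwe_violation_snps = integer(0),
                              ancestry_outlier_samples = integer(0),
                              outlier_freq_shift = 0.35,
                              seed = 1L) {
  set.seed(derive_seed(seed, "corrupt"))
  G <- genotypes$geno
  for (s in low_call_samples) {
    mask <- stats::runif(ncol(G)) < sample_miss_rate
    G[s, mask] <- NA_integer_
  }
  for (j in low_call_snps) {
    mask <- stats::runif(nrow(G)) < snp_miss_rate
    G[mask, j] <- NA_integer_
  }
  for (j in hwe_violation_snps) {
    het <- which(!is.na(G[, j]) & G[, j] == 1L)
    if (length(het)) G[het, j] <- rep(c(0L, 2L), length.out = length(het))
  }
  for (s in ancestry_outlier_samples) {
    p <- pmin(pmax(genotypes$map$maf + outlier_freq_shift, 0.01), 0.99)
    G[s, ] <- stats::rbinom(ncol(G), 2L, p)
  }
  genotypes$geno <- G
  genotypes
}
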