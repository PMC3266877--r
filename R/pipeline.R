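#' Simulate a replication-stage cohort at a subset of SNPs
#'
#' Replication stages genotype only the candidate SNPs, so they are sampled
#' here as independent loci under Hardy-Weinberg at the allele frequencies of
#' the discovery map, with the same additive liability model and rejection
#' sampling to the exact stage quotas.
#'
#' @param map_sub SNP map rows for the genotyped subset (needs `maf`).
#' @param truth truth table (provides `allele_or` for causal SNPs; all other
#'   SNPs are null).
#' @param n_case,n_control stage quotas.
#' @param prevalence population disease probability.
#' @param seed integer seed for this stage.
#' @param stage_label stage name recorded in the samples table.
#' @return a labeled `genotype_matrix`.
#' @export
simulate_stage_cohort <- function(map_sub, truth, n_case, n_control,
                                  prevalence, seed, stage_label = "rep") {
  set.seed(seed)
  m <- nrow(map_sub)
  if (m == 0L) stop("empty SNP subset", call. = FALSE)
  lor <- rep(0, m)
  hit <- match(map_sub$snp_id, truth$snp_id)
  lor[!is.na(hit)] <- log(truth$allele_or[hit[!is.na(hit)]])
  baseline <- solve_baseline_core(map_sub$maf, lor, prevalence)
  need_case <- n_case; need_ctrl <- n_control
  batch_n <- as.integer(min(60000, max(2000, ceiling(need_case / (prevalence / 2) / 3),
                                       need_ctrl / 2)))
  cases <- list(); ctrls <- list(); got_case <- 0L; got_ctrl <- 0L
  for (b in seq_len(400L)) {
    G <- matrix(stats::rbinom(batch_n * m, 2L, rep(map_sub$maf, each = batch_n)),
                nrow = batch_n, ncol = m)
    eta <- baseline + as.vector(G %*% lor)
    is_case <- stats::runif(batch_n) < stats::plogis(eta)
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
    stop(sprintf("prevalence %.4g unattainable for stage '%s'",
                 prevalence, stage_label), call. = FALSE)
  G <- rbind(do.call(rbind, cases), do.call(rbind, ctrls))
  storage.mode(G) <- "integer"
  dimnames(G) <- list(sprintf("%s_s%05d", stage_label, seq_len(nrow(G))),
                      map_sub$snp_id)
  structure(list(
    geno = G, map = map_sub,
    samples = data.frame(sample_id = rownames(G),
                         status = c(rep(2L, need_case), rep(1L, need_ctrl)),
                         stage = stage_label, stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
}

#' Run the full synthetic discovery pipeline
#'
#' One call executes the whole staged analysis on synthetic data: cohort
#' simulation, QC, the GWAS trend-test scan, the cis-eQTL screen, the
#' pooled-DNA scan, compound candidate selection (strong-P or mid-band +
#' eQTL positive), locus clumping, known-locus exclusion, pooled-scan
#' support, simulation of the two replication stages at the surviving SNPs,
#' and Mantel-Haenszel replication gating. When `outdir` is given all stage
#' tables plus a run manifest are written via [write_report()].
#'
#' @param config a [sim_config()].
#' @param thresholds a [selection_thresholds()].
#' @param qc a [qc_thresholds()].
#' @param known_loci optional known-locus table (`chrom`, `pos`).
#' @param outdir optional report directory.
#' @param check_relatedness,check_ancestry heavier QC toggles (off by
#'   default; both are exercised by their own unit tests).
#' @return list with `cohort`, `qc_report`, `gwas`, `eqtl`, `pooled`,
#'   `decisions`, `rep1`, `rep2`, `lambda_gc`, `manifest`.
#' @export
run_sle_pipeline <- function(config,
                             thresholds = selection_thresholds(),
                             qc = qc_thresholds(),
                             known_loci = NULL,
                             outdir = NULL,
                             check_relatedness = FALSE,
                             check_ancestry = FALSE) {
  cohort <- simulate_cohort(config)
  qc_rep <- run_genotype_qc(cohort$genotypes, qc,
                            check_relatedness = check_relatedness,
                            check_ancestry = check_ancestry)
  gwas <- stage_association_scan(qc_rep$retained,
                                 alpha_genomewide = thresholds$p_genomewide)
  lam <- lambda_gc(gwas$chi2)
  exprs <- simulate_expression(qc_rep$retained, config)
  eqtl <- eqtl_scan(qc_rep$retained, exprs$expr, exprs$probes)
  pooled <- simulate_pooled_scan(qc_rep$retained$map, cohort$truth, config)
  dec <- select_candidates(gwas, eqtl$flags, thresholds)
  dec <- clump_best_per_locus(dec, gwas, thresholds)
  dec <- exclude_known_loci(dec, gwas, known_loci, thresholds)
  dec <- pooled_support(dec, gwas, pooled, qc_rep$retained, thresholds)
  rep1 <- NULL; rep2 <- NULL
  cand <- dec$snp_id[dec$selected]
  if (length(cand) > 0L) {
    map_sub <- qc_rep$retained$map[qc_rep$retained$map$snp_id %in% cand, ,
                                   drop = FALSE]
    g1 <- simulate_stage_cohort(map_sub, cohort$truth,
                                config$n_rep1_cases, config$n_rep1_controls,
                                config$prevalence,
                                derive_seed(config$seed, "rep1"), "rep1")
    g2 <- simulate_stage_cohort(map_sub, cohort$truth,
                                config$n_rep2_cases, config$n_rep2_controls,
                                config$prevalence,
                                derive_seed(config$seed, "rep2"), "rep2")
    rep1 <- stage_association_scan(g1, thresholds$p_genomewide, "rep1")
    rep2 <- stage_association_scan(g2, thresholds$p_genomewide, "rep2")
    dec <- replication_gates(dec, gwas, rep1, rep2, thresholds)
  }
  manifest <- NULL
  if (!is.null(outdir)) {
    manifest <- write_report(
      list(gwas = gwas, eqtl_tests = eqtl$tests, eqtl_flags = eqtl$flags,
           pooled_scan = pooled, decisions = dec,
           rep1 = rep1, rep2 = rep2,
           excluded_samples = qc_rep$excluded_samples,
           excluded_snps = qc_rep$excluded_snps),
      outdir, unclass(config), config$seed)
  }
  list(cohort = cohort, qc_report = qc_rep, gwas = gwas, eqtl = eqtl,
       pooled = pooled, decisions = dec, rep1 = rep1, rep2 = rep2,
       lambda_gc = lam, manifest = manifest)
}
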