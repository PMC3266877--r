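#' Selection thresholds for the staged discovery pipeline
#'
#' Defaults encode the compound discovery rule: candidates need GWAS
#' `p < 1e-4` outright, or `1e-4 <= p < 1e-3` together with an eQTL-positive
#' flag; pooled-scan support requires a pooled SNP with rank-based `p < 0.01`
#' within 100 kb or in LD at `r^2 > 0.5`; the stage-2 gate is combined
#' `p < 1e-6` and final significance `p < 5e-8`. Locus clumping and
#' known-locus exclusion radii are analysis choices (500 kb / 200 kb).
#'
#' @param p_select_strong,p_select_eqtl,pooled_rank_p,pooled_ld_r2,pooled_distance_bp,p_stage_gate,p_genomewide,locus_window_bp,exclusion_window_bp
#'   numeric thresholds as described.
#' @return object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(p_select_strong = 1e-4,
                                 p_select_eqtl = 1e-3,
                                 pooled_rank_p = 0.01,
                                 pooled_ld_r2 = 0.5,
                                 pooled_distance_bp = 100000L,
                                 p_stage_gate = 1e-6,
                                 p_genomewide = 5e-8,
                                 locus_window_bp = 500000L,
                                 exclusion_window_bp = 200000L) {
  th <- list(p_select_strong = p_select_strong, p_select_eqtl = p_select_eqtl,
             pooled_rank_p = pooled_rank_p, pooled_ld_r2 = pooled_ld_r2,
             pooled_distance_bp = pooled_distance_bp,
             p_stage_gate = p_stage_gate, p_genomewide = p_genomewide,
             locus_window_bp = locus_window_bp,
             exclusion_window_bp = exclusion_window_bp)
  for (f in c("p_select_strong", "p_select_eqtl", "pooled_rank_p",
              "p_stage_gate", "p_genomewide"))
    if (th[[f]] <= 0 || th[[f]] >= 1) config_error(f, "must be in (0, 1)")
  if (th$p_select_strong >= th$p_select_eqtl)
    config_error("p_select_strong", "must be below p_select_eqtl")
  if (th$pooled_ld_r2 < 0 || th$pooled_ld_r2 > 1)
    config_error("pooled_ld_r2", "must be in [0, 1]")
  structure(th, class = "selection_thresholds")
}

#' Haplotype-based LD between two SNPs (EM from unphased genotypes)
#'
#' Estimates the four two-SNP haplotype frequencies by
#' expectation-maximization over complete-case unphased genotypes (only the
#' double heterozygote is phase-ambiguous), then derives `r^2` and `D'`.
#' Convergence requires the largest frequency change below `tol` within
#' `max_iter` iterations.
#'
#' @param genotypes a `genotype_matrix`.
#' @param snp_a,snp_b SNP ids or column indices.
#' @param tol,max_iter EM convergence controls.
#' @return list `r_squared`, `d_prime`, `haplotype_freqs` (p11, p10, p01,
#'   p00 for allele-1 carriage at each SNP), `iterations`, `n`.
#' @export
ld_r2_dprime <- function(genotypes, snp_a, snp_b, tol = 1e-10,
                         max_iter = 1000L) {
  G <- genotypes$geno
  if (is.character(snp_a)) snp_a <- match(snp_a, colnames(G))
  if (is.character(snp_b)) snp_b <- match(snp_b, colnames(G))
  if (any(is.na(c(snp_a, snp_b)))) stop("SNP not found", call. = FALSE)
  ga <- G[, snp_a]; gb <- G[, snp_b]
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  n <- length(ga)
  if (n == 0L || stats::var(ga) == 0 || stats::var(gb) == 0)
    stop("both SNPs must be polymorphic among complete cases", call. = FALSE)
  ## 3x3 genotype cell counts
  cell <- table(factor(ga, 0:2), factor(gb, 0:2))
  pA <- mean(ga) / 2; pB <- mean(gb) / 2
  ## haplotype freqs: h11 carries allele1 at both SNPs, etc.
  h <- c(h11 = pA * pB, h10 = pA * (1 - pB), h01 = (1 - pA) * pB,
         h00 = (1 - pA) * (1 - pB))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ## E-step: expected haplotype counts; the double het (1,1) splits between
    ## (11/00) and (10/01) phases by their relative likelihoods.
    denom <- h["h11"] * h["h00"] + h["h10"] * h["h01"]
    w_cis <- if (denom > 0) h["h11"] * h["h00"] / denom else 0.5
    n11 <- 2 * cell["2", "2"] + cell["2", "1"] + cell["1", "2"] +
           w_cis * cell["1", "1"]
    n10 <- 2 * cell["2", "0"] + cell["2", "1"] + cell["1", "0"] +
           (1 - w_cis) * cell["1", "1"]
    n01 <- 2 * cell["0", "2"] + cell["1", "2"] + cell["0", "1"] +
           (1 - w_cis) * cell["1", "1"]
    n00 <- 2 * cell["0", "0"] + cell["0", "1"] + cell["1", "0"] +
           w_cis * cell["1", "1"]
    h_new <- c(n11, n10, n01, n00) / (2 * n)
    names(h_new) <- names(h)
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) break
    if (iter >= max_iter)
      stop(sprintf("EM did not converge in %d iterations (delta %.2e)",
                   iter, delta), call. = FALSE)
  }
  pA <- h["h11"] + h["h10"]; pB <- h["h11"] + h["h01"]
  D <- h["h11"] - pA * pB
  denom_r2 <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom_r2 > 0) unname(D^2 / denom_r2) else NA_real_
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax > 0) unname(abs(D) / dmax) else NA_real_
  list(r_squared = min(r2, 1), d_prime = min(dprime, 1),
       haplotype_freqs = h, iterations = iter, n = n)
}

#' Rank-based P-values from association scores
#'
#' `p_i = rank_i / N` with rank 1 assigned to the most extreme (largest)
#' score and ties given average ranks.
#'
#' @param scores finite numeric scores.
#' @return probabilities in (0, 1].
#' @export
rank_based_p <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  rank(-scores, ties.method = "average") / length(scores)
}

new_decisions <- function(snp_ids) {
  data.frame(snp_id = snp_ids, stage = "rejected", selected = FALSE,
             reason_codes = "", supporting_pooled_snp = NA_character_,
             p_gwas = NA_real_, p_combined12 = NA_real_,
             p_combined_all = NA_real_, or_mh = NA_real_,
             stringsAsFactors = FALSE)
}

add_reason <- function(dec, idx, code) {
  dec$reason_codes[idx] <- ifelse(dec$reason_codes[idx] == "", code,
                                  paste(dec$reason_codes[idx], code, sep = ";"))
  dec
}

#' Compound GWAS + eQTL candidate selection
#'
#' A SNP is selected when its GWAS P is strictly below `p_select_strong`, or
#' when `p_select_strong <= p < p_select_eqtl` and the SNP is eQTL positive.
#' Mid-band SNPs without eQTL support are rejected with reason
#' `eqtl_negative_midband`; SNPs above the mid band with `p_above_selection`.
#'
#' @param gwas_results output of [stage_association_scan()].
#' @param eqtl_flags output of [flag_eqtl_positive()] covering every GWAS SNP
#'   (unevaluated SNPs count as negative).
#' @param thresholds a [selection_thresholds()].
#' @return a decisions data frame (`snp_id`, `stage`, `selected`,
#'   `reason_codes`, `p_gwas`, ...).
#' @export
select_candidates <- function(gwas_results, eqtl_flags,
                              thresholds = selection_thresholds()) {
  dec <- new_decisions(gwas_results$snp_id)
  dec$p_gwas <- gwas_results$p
  pos <- stats::setNames(rep(FALSE, nrow(dec)), dec$snp_id)
  hit <- match(eqtl_flags$snp_id, dec$snp_id)
  pos[hit[!is.na(hit)]] <- eqtl_flags$positive[!is.na(hit)]
  strong <- dec$p_gwas < thresholds$p_select_strong
  midband <- dec$p_gwas >= thresholds$p_select_strong &
             dec$p_gwas < thresholds$p_select_eqtl
  sel <- strong | (midband & pos)
  dec$selected <- sel
  dec$stage[sel] <- "gwas_selected"
  dec <- add_reason(dec, midband & !pos, "eqtl_negative_midband")
  dec <- add_reason(dec, !strong & !midband, "p_above_selection")
  dec
}

#' Keep the most significant SNP per genomic locus
#'
#' Greedy clumping of the selected set by ascending GWAS P (ties broken by
#' smaller genomic position, then id): each kept SNP suppresses all other
#' selected SNPs within `locus_window_bp` on the same chromosome; suppressed
#' SNPs are rejected with reason `clumped`.
#'
#' @param decisions decisions data frame.
#' @param gwas_results matching scan results (for `chrom`, `pos`, `p`).
#' @param thresholds a [selection_thresholds()].
#' @return updated decisions.
#' @export
clump_best_per_locus <- function(decisions, gwas_results,
                                 thresholds = selection_thresholds()) {
  m <- match(decisions$snp_id, gwas_results$snp_id)
  chrom <- gwas_results$chrom[m]; pos <- gwas_results$pos[m]
  p <- gwas_results$p[m]
  active <- which(decisions$selected)
  ord <- active[order(p[active], pos[active], decisions$snp_id[active])]
  kept <- logical(nrow(decisions))
  suppressed <- logical(nrow(decisions))
  for (i in ord) {
    if (suppressed[i]) next
    kept[i] <- TRUE
    nearby <- decisions$selected &
              chrom == chrom[i] & abs(pos - pos[i]) <= thresholds$locus_window_bp
    nearby[i] <- FALSE
    suppressed <- suppressed | nearby
  }
  drop <- which(suppressed & decisions$selected)
  decisions$selected[drop] <- FALSE
  decisions$stage[drop] <- "rejected"
  decisions <- add_reason(decisions, seq_len(nrow(decisions)) %in% drop, "clumped")
  decisions
}

#' Exclude candidates inside known susceptibility loci
#'
#' Candidates within `exclusion_window_bp` of a known-locus SNP on the same
#' chromosome are rejected with reason `known_locus`.
#'
#' @param decisions decisions data frame.
#' @param gwas_results matching scan results.
#' @param known_loci data frame with `chrom` and `pos` of known loci (may be
#'   empty).
#' @param thresholds a [selection_thresholds()].
#' @return updated decisions.
#' @export
exclude_known_loci <- function(decisions, gwas_results, known_loci,
                               thresholds = selection_thresholds()) {
  if (is.null(known_loci) || nrow(known_loci) == 0L) return(decisions)
  m <- match(decisions$snp_id, gwas_results$snp_id)
  chrom <- gwas_results$chrom[m]; pos <- gwas_results$pos[m]
  near_known <- rep(FALSE, nrow(decisions))
  for (k in seq_len(nrow(known_loci))) {
    near_known <- near_known |
      (chrom == known_loci$chrom[k] &
       abs(pos - known_loci$pos[k]) <= thresholds$exclusion_window_bp)
  }
  drop <- which(decisions$selected & near_known)
  decisions$selected[drop] <- FALSE
  decisions$stage[drop] <- "rejected"
  decisions <- add_reason(decisions, seq_len(nrow(decisions)) %in% drop,
                          "known_locus")
  decisions
}

#' Cross-reference candidates against a pooled-DNA scan
#'
#' A candidate is retained when some pooled-scan SNP with rank-based
#' `p < pooled_rank_p` lies within `pooled_distance_bp` (inclusive) on the
#' same chromosome, or is in LD with the candidate at
#' `r^2 > pooled_ld_r2`. The nearest supporting pooled SNP is recorded. When
#' a pooled SNP is absent from the genotype panel its LD cannot be computed
#' and the distance criterion alone applies (flagged `ld_uncomputable`).
#'
#' @param decisions decisions data frame.
#' @param gwas_results matching scan results.
#' @param pooled_table pooled-scan table (`snp_id`, `chrom`, `pos`,
#'   `rank_p`).
#' @param genotypes `genotype_matrix` for LD computation.
#' @param thresholds a [selection_thresholds()].
#' @return updated decisions (`pooled_supported` stage for survivors).
#' @export
pooled_support <- function(decisions, gwas_results, pooled_table, genotypes,
                           thresholds = selection_thresholds()) {
  if (is.null(pooled_table) || nrow(pooled_table) == 0L)
    stop("pooled-scan table is empty", call. = FALSE)
  sig <- pooled_table[pooled_table$rank_p < thresholds$pooled_rank_p, ,
                      drop = FALSE]
  m <- match(decisions$snp_id, gwas_results$snp_id)
  chrom <- gwas_results$chrom[m]; pos <- gwas_results$pos[m]
  for (i in which(decisions$selected)) {
    support <- NA_character_
    if (nrow(sig) > 0L) {
      same <- which(sig$chrom == chrom[i] & sig$snp_id != decisions$snp_id[i])
      dists <- abs(sig$pos[same] - pos[i])
      near <- same[dists <= thresholds$pooled_distance_bp]
      ## a pooled signal at the candidate itself also counts as support
      self <- which(sig$snp_id == decisions$snp_id[i])
      if (length(self)) {
        support <- decisions$snp_id[i]
      } else if (length(near)) {
        support <- sig$snp_id[near[which.min(abs(sig$pos[near] - pos[i]))]]
      } else {
        for (j in same[order(dists)]) {
          if (!(sig$snp_id[j] %in% colnames(genotypes$geno))) {
            decisions <- add_reason(decisions, i, "ld_uncomputable")
            next
          }
          ld <- tryCatch(
            ld_r2_dprime(genotypes, decisions$snp_id[i], sig$snp_id[j]),
            error = function(e) NULL)
          if (!is.null(ld) && !is.na(ld$r_squared) &&
              ld$r_squared > thresholds$pooled_ld_r2) {
            support <- sig$snp_id[j]; break
          }
        }
      }
    }
    if (is.na(support)) {
      decisions$selected[i] <- FALSE
      decisions$stage[i] <- "rejected"
      decisions <- add_reason(decisions, i, "no_pooled_support")
    } else {
      decisions$stage[i] <- "pooled_supported"
      decisions$supporting_pooled_snp[i] <- support
    }
  }
  decisions
}

## Reconcile allele orientation of a later-stage table against stage-1
## alleles. Returns the (possibly flipped) table or errors for an
## irreconcilable or strand-ambiguous mismatch.
reconcile_alleles <- function(snp_id, ref_alleles, stage_alleles, tab) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  same <- identical(ref_alleles, stage_alleles)
  swapped <- identical(ref_alleles, rev(stage_alleles))
  flipped <- identical(ref_alleles, unname(comp[stage_alleles]))
  flipped_swapped <- identical(ref_alleles, unname(rev(comp[stage_alleles])))
  ambiguous <- identical(sort(stage_alleles),
                         sort(unname(comp[stage_alleles])))
  if (same) return(tab)
  if (ambiguous)
    stop(sprintf("allele mismatch for %s: A/T or G/C SNP needs explicit orientation metadata",
                 snp_id), call. = FALSE)
  if (swapped || flipped_swapped)
    return(allele_table(tab$b, tab$a, tab$d, tab$c, tab$stage_label))
  if (flipped) return(tab)
  stop(sprintf("allele mismatch between stages for %s", snp_id), call. = FALSE)
}

#' Staged replication gates with Mantel-Haenszel combination
#'
#' For every candidate: combine the GWAS and replication-1 allele tables by
#' Mantel-Haenszel; candidates with combined `p < p_stage_gate` pass to the
#' second replication, where all three stages are combined and
#' `final_significant` requires `p < p_genomewide`. A candidate missing its
#' replication-1 table is an error, not a silent skip; allele orientations
#' are reconciled against the GWAS stage (strand flips resolved for
#' non-ambiguous SNPs).
#'
#' @param decisions decisions data frame (candidates = `selected`).
#' @param gwas_results stage-1 scan results (provides allele tables and
#'   alleles per SNP).
#' @param rep1_results,rep2_results replication-stage tables with the same
#'   columns (`snp_id`, `case_allele1`, `case_allele2`, `control_allele1`,
#'   `control_allele2`, optional `allele1`, `allele2`).
#' @param thresholds a [selection_thresholds()].
#' @return updated decisions with `p_combined12`, `p_combined_all`, `or_mh`
#'   and terminal stages (`rep1_passed`, `final_significant`, or `rejected`).
#' @export
replication_gates <- function(decisions, gwas_results, rep1_results,
                              rep2_results, thresholds = selection_thresholds()) {
  stage_table <- function(res, snp_id, stage_label) {
    i <- match(snp_id, res$snp_id)
    if (is.na(i)) return(NULL)
    allele_table(res$case_allele1[i], res$case_allele2[i],
                 res$control_allele1[i], res$control_allele2[i], stage_label)
  }
  stage_alleles <- function(res, snp_id) {
    i <- match(snp_id, res$snp_id)
    if ("allele1" %in% names(res)) c(res$allele1[i], res$allele2[i]) else NULL
  }
  for (i in which(decisions$selected)) {
    id <- decisions$snp_id[i]
    t1 <- stage_table(gwas_results, id, "gwas")
    t2 <- stage_table(rep1_results, id, "rep1")
    if (is.null(t2))
      stop(sprintf("replication study 1 results missing for %s", id),
           call. = FALSE)
    ref_al <- stage_alleles(gwas_results, id)
    al2 <- stage_alleles(rep1_results, id)
    if (!is.null(ref_al) && !is.null(al2))
      t2 <- reconcile_alleles(id, ref_al, al2, t2)
    mh12 <- mantel_haenszel(list(t1, t2))
    decisions$p_combined12[i] <- mh12$p_combined
    if (mh12$p_combined >= thresholds$p_stage_gate) {
      decisions$selected[i] <- FALSE
      decisions$stage[i] <- "rejected"
      decisions <- add_reason(decisions, i, "stage_gate")
      decisions$or_mh[i] <- mh12$or_mh
      next
    }
    decisions$stage[i] <- "rep1_passed"
    t3 <- stage_table(rep2_results, id, "rep2")
    if (is.null(t3))
      stop(sprintf("replication study 2 results missing for gated SNP %s", id),
           call. = FALSE)
    al3 <- stage_alleles(rep2_results, id)
    if (!is.null(ref_al) && !is.null(al3))
      t3 <- reconcile_alleles(id, ref_al, al3, t3)
    mh <- mantel_haenszel(list(t1, t2, t3))
    decisions$p_combined_all[i] <- mh$p_combined
    decisions$or_mh[i] <- mh$or_mh
    if (mh$p_combined < thresholds$p_genomewide) {
      decisions$stage[i] <- "final_significant"
    } else {
      decisions <- add_reason(decisions, i, "not_genomewide")
    }
  }
  decisions
}
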