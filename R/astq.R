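#' Fit the genomic-DNA mixture standard curve
#'
#' Least-squares line of the replicate-averaged Ct difference
#' (`mean(Ct_vic) - mean(Ct_fam)`) on `log2(mixture ratio)` over the
#' genomic-DNA mixture series. Under perfect amplification efficiency the
#' slope is -1 (one Ct cycle per two-fold amount change) and the intercept
#' absorbs any probe-specific channel offset.
#'
#' @param mixtures plate rows with `material == "mixture"` (a plate data
#'   frame from [simulate_astq_plate()] or read from TSV).
#' @return object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
build_standard_curve <- function(mixtures) {
  mixtures <- mixtures[mixtures$material == "mixture", , drop = FALSE]
  if (nrow(mixtures) == 0L) stop("no mixture rows", call. = FALSE)
  ratios <- sort(unique(mixtures$mixture_ratio))
  if (length(ratios) < 3L)
    stop("need at least 3 distinct mixture ratios", call. = FALSE)
  dct <- vapply(ratios, function(r) {
    rows <- mixtures[mixtures$mixture_ratio == r, , drop = FALSE]
    mean(rows$ct_vic) - mean(rows$ct_fam)
  }, numeric(1))
  x <- log2(ratios)
  fit <- stats::lm(dct ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((dct - mean(dct))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_points = length(ratios)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: dCt = %.4f * log2(ratio) + %.4f (R^2 = %.4f, %d points)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Convert a sample's Ct pair to an allelic ratio via the standard curve
#'
#' Inverts the fitted line: `ratio = 2^((mean dCt - intercept) / slope)`.
#' Replicate variability is propagated to a first-order standard error of
#' the ratio.
#'
#' @param sample_rows plate rows of one sample and material.
#' @param curve a [build_standard_curve()] fit.
#' @return list `ratio`, `se`, `dct`, `n_replicates`.
#' @export
quantify_allelic_ratio <- function(sample_rows, curve) {
  if (abs(curve$slope) < 0.2)
    stop("uninformative curve: |slope| < 0.2", call. = FALSE)
  if (nrow(sample_rows) == 0L) stop("no replicate rows", call. = FALSE)
  dct <- mean(sample_rows$ct_vic) - mean(sample_rows$ct_fam)
  nrep <- nrow(sample_rows)
  var_dct <- (stats::var(sample_rows$ct_vic) %||% 0) / nrep +
             (stats::var(sample_rows$ct_fam) %||% 0) / nrep
  if (is.na(var_dct)) var_dct <- 0
  log2_ratio <- (dct - curve$intercept) / curve$slope
  ratio <- 2^log2_ratio
  se_log2 <- sqrt(var_dct) / abs(curve$slope)
  list(ratio = ratio, se = ratio * log(2) * se_log2, dct = dct,
       n_replicates = nrep)
}

#' Quantify per-line DNA and cDNA allelic ratios
#'
#' Applies [quantify_allelic_ratio()] to each cell line's genomic-DNA and
#' cDNA quadruplicates and normalizes the transcript ratio by the same
#' line's DNA ratio (per-line pairing). Lines missing either material are
#' excluded with a warning.
#'
#' @param plate full plate data frame.
#' @param curve a [build_standard_curve()] fit.
#' @return data frame `sample_id`, `ratio_dna`, `ratio_cdna`,
#'   `ratio_normalized`.
#' @export
astq_quantify_lines <- function(plate, curve) {
  lines <- unique(plate$sample_id[plate$material %in% c("genomic_dna", "cdna")])
  rows <- list(); skipped <- character(0)
  for (id in lines) {
    dna <- plate[plate$sample_id == id & plate$material == "genomic_dna", ,
                 drop = FALSE]
    cdna <- plate[plate$sample_id == id & plate$material == "cdna", ,
                  drop = FALSE]
    if (nrow(dna) == 0L || nrow(cdna) == 0L) { skipped <- c(skipped, id); next }
    rd <- quantify_allelic_ratio(dna, curve)
    rc <- quantify_allelic_ratio(cdna, curve)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = id, ratio_dna = rd$ratio, ratio_cdna = rc$ratio,
      ratio_normalized = rc$ratio / rd$ratio, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(sprintf("unpaired samples excluded: %s",
                    paste(skipped, collapse = ", ")))
  do.call(rbind, rows)
}

#' Test for allelic imbalance across cell lines
#'
#' Paired two-sided t-test on `log2(ratio_cdna) - log2(ratio_dna)` across
#' lines; means are reported back-transformed (geometric means). When every
#' paired difference is exactly zero the P-value is 1 by convention.
#'
#' @param results output of [astq_quantify_lines()] (needs at least 2 lines).
#' @return list `mean_cdna_ratio`, `mean_dna_ratio`, `mean_ratio_normalized`,
#'   `p`, `n_lines`.
#' @export
allelic_imbalance_test <- function(results) {
  if (is.null(results) || nrow(results) < 2L)
    stop("need at least 2 paired cell lines", call. = FALSE)
  d <- log2(results$ratio_cdna) - log2(results$ratio_dna)
  p <- if (stats::sd(d) == 0) {
    if (all(d == 0)) 1 else 0
  } else {
    stats::t.test(d)$p.value
  }
  list(mean_cdna_ratio = 2^mean(log2(results$ratio_cdna)),
       mean_dna_ratio = 2^mean(log2(results$ratio_dna)),
       mean_ratio_normalized = 2^mean(d), p = p, n_lines = nrow(results))
}

#' Relative expression by the delta-Ct method
#'
#' `2^-(Ct_target - Ct_reference)`: one cycle later than the reference means
#' half the template.
#'
#' @param ct_target,ct_reference finite Ct values (vectorized).
#' @return positive relative expression level(s).
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite", call. = FALSE)
  2^-(ct_target - ct_reference)
}
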