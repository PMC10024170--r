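#' Convert LOD scores to p-values
#'
#' Transforms LOD scores to nominal p-values via the upper tail of a
#' chi-square with 2 degrees of freedom (additive and dominance regressors
#' both fitted) at `2 ln(10) LOD`.
#'
#' @param lod Non-negative LOD scores.
#' @return p-values in (0, 1\].
#' @export
lod_to_p <- function(lod) {
  stopifnot(all(lod >= -1e-12, na.rm = TRUE))
  stats::pchisq(2 * log(10) * pmax(lod, 0), df = 2, lower.tail = FALSE)
}

#' Benjamini-Hochberg selection
#'
#' Step-up selection controlling the false discovery rate at level `q`.
#'
#' @param pvals Finite p-values.
#' @param q FDR level (default 0.10).
#' @return Integer indices of selected hypotheses (empty when none pass).
#' @export
fdr_select <- function(pvals, q = 0.10) {
  stopifnot(all(is.finite(pvals)), q > 0, q < 1)
  which(stats::p.adjust(pvals, method = "BH") <= q)
}

#' Collapse selected bins into QTL peaks
#'
#' Merges runs of selected bins into peaks: consecutive selected bins on
#' the same chromosome whose starts are within `merge_mb` megabases join
#' the same QTL. Each QTL is represented by its maximum-LOD bin and
#' assigned a significance tier by comparison with the genome-wide
#' permutation threshold.
#'
#' @param scan An `ail_scan`.
#' @param selected Indices of selected bins (e.g. from [fdr_select()]
#'   and/or threshold exceedance).
#' @param threshold Genome-wide LOD threshold used for the tier.
#' @param merge_mb Merge distance in Mb (default 15).
#' @return `data.frame` of class `qtl_set`: `chrom`, `start`, `lod`,
#'   `a_hat`, `d_hat`, `se_a`, `tier` (`"genome-wide"` or
#'   `"FDR-suggestive"`), `n_bins` (bins merged into the peak).
#' @export
collapse_peaks <- function(scan, selected, threshold, merge_mb = 15) {
  sel <- sort(unique(selected))
  if (length(sel) == 0L) {
    out <- scan[0, c("chrom", "start", "lod", "a_hat", "d_hat", "se_a")]
    out$tier <- character(0)
    out$n_bins <- integer(0)
    class(out) <- c("qtl_set", "data.frame")
    return(out)
  }
  s <- scan[sel, , drop = FALSE]
  new_cluster <- c(TRUE, s$chrom[-1L] != s$chrom[-nrow(s)] |
                     diff(s$start) > merge_mb * 1e6)
  cl <- cumsum(new_cluster)
  rows <- vapply(split(seq_len(nrow(s)), cl), function(i) {
    i[which.max(s$lod[i])]
  }, integer(1))
  out <- s[rows, c("chrom", "start", "lod", "a_hat", "d_hat", "se_a")]
  out$tier <- ifelse(out$lod >= threshold, "genome-wide", "FDR-suggestive")
  out$n_bins <- as.integer(table(cl))
  rownames(out) <- NULL
  class(out) <- c("qtl_set", "data.frame")
  out
}

#' Joint multi-QTL fit with drop-one variance accounting
#'
#' Regresses the sex-corrected residuals of the standardized phenotype on
#' the additive and dominance regressors of all QTL bins jointly, and
#' reports for each QTL the drop-one percentage of residual variance
#' explained: `100 (RSS_without - RSS_full) / TSS` of the residualized
#' phenotype.
#'
#' @param geno Bin genotype matrix.
#' @param phen A `phenotype_table` (standardized if needed).
#' @param qtl_bins Column names or indices of the QTL bins.
#' @return `data.frame` with `bin`, `a_joint`, `d_joint`, `pct_var`;
#'   attributes `r2_joint` (joint model R-squared, percent) and `dropped`
#'   (QTL removed for rank deficiency, if any).
#' @export
fit_multi_qtl <- function(geno, phen, qtl_bins) {
  if (!"z" %in% names(phen)) phen <- standardize(phen)
  mp <- match_geno_phen(geno, phen)
  geno <- mp$geno; phen <- mp$phen
  if (is.numeric(qtl_bins)) qtl_bins <- colnames(geno)[qtl_bins]
  stopifnot(all(qtl_bins %in% colnames(geno)))

  sex <- as.numeric(phen$sex == "M")
  r <- if (stats::var(sex) > 0) {
    stats::lsfit(cbind(sex), phen$z)$residuals
  } else {
    phen$z - mean(phen$z)
  }
  reg <- impute_regressors(geno[, qtl_bins, drop = FALSE])
  X <- matrix(0, nrow(geno), 2L * length(qtl_bins))
  X[, seq(1L, ncol(X), 2L)] <- reg$A
  X[, seq(2L, ncol(X), 2L)] <- reg$D
  col_qtl <- rep(seq_along(qtl_bins), each = 2L)
  col_kind <- rep(c("a", "d"), length(qtl_bins))
  colnames(X) <- paste0(qtl_bins[col_qtl], ":", col_kind)

  # resolve aliasing at column level: an inestimable dominance column is
  # simply omitted; a QTL whose additive column is aliased is dropped
  dropped <- character(0)
  repeat {
    qr_x <- qr(cbind(1, scale(X, scale = FALSE)))
    if (qr_x$rank == ncol(X) + 1L) break
    aliased <- setdiff(seq_len(ncol(X) + 1L),
                       qr_x$pivot[seq_len(qr_x$rank)]) - 1L
    aliased <- aliased[aliased > 0L]
    bad_qtl <- unique(col_qtl[aliased[col_kind[aliased] == "a"]])
    if (length(bad_qtl)) {
      warning(sprintf("rank deficiency: dropping QTL %s",
                      paste(qtl_bins[bad_qtl], collapse = ", ")))
      dropped <- c(dropped, qtl_bins[bad_qtl])
      keep <- !(col_qtl %in% bad_qtl)
    } else {
      keep <- !(seq_len(ncol(X)) %in% aliased)
    }
    X <- X[, keep, drop = FALSE]
    col_qtl <- col_qtl[keep]
    col_kind <- col_kind[keep]
    if (ncol(X) == 0L) stop("all QTL dropped for rank deficiency")
  }
  kept_qtl <- sort(unique(col_qtl))

  fit_full <- stats::lsfit(X, r)
  rss_full <- sum(fit_full$residuals^2)
  tss <- sum((r - mean(r))^2)
  coefs <- fit_full$coefficients
  pct_var <- vapply(kept_qtl, function(k) {
    cols <- which(col_qtl != k)
    rss_wo <- if (length(cols)) {
      sum(stats::lsfit(X[, cols, drop = FALSE], r)$residuals^2)
    } else {
      tss
    }
    100 * (rss_wo - rss_full) / tss
  }, numeric(1))

  get_coef <- function(k, kind) {
    nm <- paste0(qtl_bins[k], ":", kind)
    if (nm %in% names(coefs)) unname(coefs[nm]) else NA_real_
  }
  out <- data.frame(bin = qtl_bins[kept_qtl],
                    a_joint = vapply(kept_qtl, get_coef, numeric(1), "a"),
                    d_joint = vapply(kept_qtl, get_coef, numeric(1), "d"),
                    pct_var = pct_var,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "r2_joint") <- 100 * (1 - rss_full / tss)
  attr(out, "dropped") <- dropped
  out
}

#' Per-QTL effect sizes in grams
#'
#' Fits each QTL individually (`z ~ sex + a + d`) and converts the
#' standardized additive estimate to grams by multiplying with the
#' population standard deviation of the raw weights (pooled over all
#' scanned individuals).
#'
#' @inheritParams fit_multi_qtl
#' @param sd_pop Population SD of raw weight in grams; computed from
#'   `phen$weight` (divide-by-n convention) when `NULL`.
#' @return `data.frame` with `bin`, `a_std`, `se_std`, `a_g`, `se_g`;
#'   attribute `sd_pop`.
#' @export
qtl_effects <- function(geno, phen, qtl_bins, sd_pop = NULL) {
  if (!"z" %in% names(phen)) phen <- standardize(phen)
  mp <- match_geno_phen(geno, phen)
  geno <- mp$geno; phen <- mp$phen
  if (is.numeric(qtl_bins)) qtl_bins <- colnames(geno)[qtl_bins]
  if (is.null(sd_pop))
    sd_pop <- sqrt(mean((phen$weight - mean(phen$weight))^2))
  sex <- as.numeric(phen$sex == "M")
  n <- nrow(phen)
  reg <- impute_regressors(geno[, qtl_bins, drop = FALSE])
  eng <- hk_engine(reg$A, reg$D, sex, phen$z)
  se_std <- sqrt(pmax(eng$RSS1 / (n - 4) * eng$va, 0))
  out <- data.frame(bin = qtl_bins, a_std = eng$a_hat, se_std = se_std,
                    a_g = eng$a_hat * sd_pop, se_g = se_std * sd_pop,
                    stringsAsFactors = FALSE)
  attr(out, "sd_pop") <- sd_pop
  out
}

#' Line-difference accounting for a set of QTL
#'
#' Sums additive effect estimates (grams), doubles the sum (the distance
#' between opposite homozygotes is `2a` per locus), and expresses the
#' doubled sum as a percentage of the phenotypic difference between the
#' founder lines.
#'
#' @param a_grams Additive effect estimates in grams.
#' @param line_difference Between-line difference in grams (default
#'   1,341 g, the divergence of the high and low Virginia body weight
#'   lines after 40 generations of selection).
#' @return List with `sum_a`, `two_sum_a`, `fraction_pct`.
#' @export
line_difference_accounting <- function(a_grams, line_difference = 1341) {
  sum_a <- sum(a_grams)
  two_sum_a <- 2 * sum_a
  list(sum_a = sum_a, two_sum_a = two_sum_a,
       fraction_pct = 100 * two_sum_a / line_difference)
}

#' Published significant QTL for 56-day body weight in the Virginia lines
#'
#' Reference table of the 12 genome-wide significant QTL reported for
#' 56-day body weight in the F2-F18 advanced intercross of the Virginia
#' body weight chicken lines: chromosome, position (Mb), additive effect
#' and standard error (grams), percent residual variance explained, and
#' LOD score.
#'
#' @return A `data.frame` with columns `chrom`, `pos_mb`, `a_g`, `se_g`,
#'   `pct_var`, `lod`.
#' @export
virginia_qtl_table <- function() {
  data.frame(
    chrom = c("1", "1", "3", "4", "4", "4", "5", "7", "10", "11", "13", "23"),
    pos_mb = c(56, 171, 74, 11, 23, 36, 30, 21, 9, 7, 12, 6),
    a_g = c(19.6, 31.6, 20.3, 20.7, 20.4, 25.6, 20.9, 25.6, 22.3, 13.2,
            19.6, 10.9),
    se_g = c(4.0, 4.1, 4.2, 4.4, 4.0, 4.2, 4.3, 4.0, 3.9, 4.0, 3.9, 4.3),
    pct_var = c(0.43, 1.21, 0.31, 0.28, 0.07, 0.45, 0.31, 1.26, 0.27, 0.32,
                0.32, 0.47),
    lod = c(5.79, 13.08, 5.41, 5.29, 6, 8.2, 5.22, 9.6, 7.25, 4.22, 5.83,
            4.32),
    stringsAsFactors = FALSE
  )
}

#' Genotype information content
#'
#' Computes, per bin, `IC = Var(a) + 2 Var(d)` across individuals
#' (population-variance convention), where `a` and `d` are the
#' Haley-Knott regressors of the bin scores. A fully informative F2 bin
#' (hard calls at frequencies 1/4, 1/2, 1/4) gives IC = 1; completely
#' uninformative bins (all heterozygous, or monomorphic) give 0. IC is
#' bounded by 1.5.
#'
#' Missing genotypes carry no information: they enter the variances as the
#' mean of the observed regressors (the expectation under no data), so the
#' variance contribution of a bin scales with the fraction of individuals
#' actually genotyped. Randomly masking genotypes therefore lowers IC, and
#' better-resolved genotyping raises it.
#'
#' @param geno Bin genotype matrix (individuals x bins) or a single bin's
#'   score vector.
#' @return Named numeric vector of IC values per bin; `NA` for bins with
#'   fewer than 2 non-missing genotypes.
#' @export
information_content <- function(geno) {
  if (is.null(dim(geno))) geno <- cbind(geno)
  n <- nrow(geno)
  var_imp <- function(x) {
    obs <- x[!is.na(x)]
    if (length(obs) < 2L) return(NA_real_)
    sum((obs - mean(obs))^2) / n
  }
  a <- geno
  d <- 1 - abs(geno)
  ic <- vapply(seq_len(ncol(geno)), function(b) {
    var_imp(a[, b]) + 2 * var_imp(d[, b])
  }, numeric(1))
  names(ic) <- colnames(geno)
  ic
}
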