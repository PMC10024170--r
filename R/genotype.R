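#' Score 1 Mb bins from segment calls
#'
#' Converts base-pair segments (HH/HET/LL) into per-bin genotype scores on
#' the continuous (1, 0, -1) scale. Bins covered by a single state score
#' exactly 1, 0 or -1; bins containing breakpoints score the
#' base-pair-weighted average of the state codes over the covered part of
#' the bin. Bins wholly outside the covered span are missing.
#'
#' @param segments A `segment_calls` data.frame (one chromosome).
#' @param bin_start,bin_end Numeric vectors of bin boundaries (half-open
#'   `[start, end)` bins).
#' @return `data.frame` with `score`, `n_breaks` (breakpoints falling in
#'   the bin), and `states` (comma-collapsed ordered state sequence
#'   overlapping the bin, `NA` when missing).
#' @export
score_bins <- function(segments, bin_start, bin_end) {
  nb <- length(bin_start)
  score <- rep(NA_real_, nb)
  n_breaks <- integer(nb)
  states <- rep(NA_character_, nb)
  if (nrow(segments) == 0L)
    return(data.frame(score = score, n_breaks = n_breaks, states = states,
                      stringsAsFactors = FALSE))
  code <- .state_codes[segments$state]
  brk <- segments$end[-nrow(segments)]
  for (b in seq_len(nb)) {
    ov <- pmin(segments$end, bin_end[b]) - pmax(segments$start, bin_start[b])
    pos_ov <- ov > 0
    tot <- sum(ov[pos_ov])
    if (tot <= 0) next
    score[b] <- sum(code[pos_ov] * ov[pos_ov]) / tot
    n_breaks[b] <- sum(brk >= bin_start[b] & brk < bin_end[b])
    st <- segments$state[pos_ov]
    states[b] <- paste(st, collapse = ",")
  }
  data.frame(score = score, n_breaks = n_breaks, states = states,
             stringsAsFactors = FALSE)
}

# TRUE if `short` can be obtained from `long` by deleting states
# (order-preserving subsequence test).
is_subsequence <- function(short, long) {
  i <- 1L
  for (s in long) {
    if (i <= length(short) && short[i] == s) i <- i + 1L
  }
  i > length(short)
}

#' Reconcile forward and reverse bin estimates
#'
#' Filters bins where the forward and reverse runs disagree by more than
#' one recombination event: a bin is set to missing when the inferred
#' breakpoint counts differ by more than one, or the ordered state
#' sequences cannot be reconciled by shifting a single breakpoint (one
#' sequence must be an order-preserving subsequence of the other with at
#' most one state inserted). Otherwise the forward value is kept.
#'
#' @param fwd,rev Outputs of [score_bins()] on the same bin grid.
#' @param strict If `TRUE`, any difference in breakpoint count or state
#'   sequence sets the bin to missing.
#' @return Numeric vector of reconciled scores (`NA` where filtered).
#' @export
reconcile_directions <- function(fwd, rev, strict = FALSE) {
  stopifnot(nrow(fwd) == nrow(rev))
  out <- fwd$score
  for (b in seq_len(nrow(fwd))) {
    if (is.na(fwd$score[b]) || is.na(rev$score[b])) {
      out[b] <- NA_real_
      next
    }
    same_seq <- identical(fwd$states[b], rev$states[b])
    if (strict) {
      if (fwd$n_breaks[b] != rev$n_breaks[b] || !same_seq ||
            fwd$score[b] != rev$score[b])
        out[b] <- NA_real_
      next
    }
    if (abs(fwd$n_breaks[b] - rev$n_breaks[b]) > 1L) {
      out[b] <- NA_real_
      next
    }
    if (same_seq) next
    sf <- strsplit(fwd$states[b], ",", fixed = TRUE)[[1L]]
    sr <- strsplit(rev$states[b], ",", fixed = TRUE)[[1L]]
    dl <- length(sf) - length(sr)
    ok <- if (dl == 0L) {
      identical(sf, sr)
    } else if (abs(dl) == 1L) {
      if (dl > 0L) is_subsequence(sr, sf) else is_subsequence(sf, sr)
    } else FALSE
    if (!ok) out[b] <- NA_real_
  }
  out
}

#' Combine window sizes and apply bin quality filters
#'
#' Selects, per bin, the genotype from the small-window run where the
#' panel marker density is below `density_threshold` markers/Mb and from
#' the large-window run otherwise; then sets ambiguous scores (strictly
#' inside (0.2, 0.8) or (-0.8, -0.2)) to missing; finally masks bins
#' genotyped in fewer than `min_individuals` individuals.
#'
#' @param bins_small,bins_large Numeric matrices individuals x bins of
#'   reconciled scores for the small and large window size.
#' @param density Panel marker density per bin (markers/Mb).
#' @param density_threshold Markers/Mb cutoff (default 20).
#' @param min_individuals Minimum individuals genotyped per bin
#'   (default 100; scale down for small cohorts).
#' @return Matrix of filtered scores with attribute `n_genotyped`.
#' @export
combine_window_sizes <- function(bins_small, bins_large, density,
                                 density_threshold = 20,
                                 min_individuals = 100) {
  stopifnot(all(dim(bins_small) == dim(bins_large)),
            length(density) == ncol(bins_small))
  use_small <- density < density_threshold
  out <- bins_large
  out[, use_small] <- bins_small[, use_small]
  amb <- !is.na(out) & (abs(out) > 0.2 & abs(out) < 0.8)
  out[amb] <- NA_real_
  n_genotyped <- colSums(!is.na(out))
  low <- n_genotyped < min_individuals
  out[, low] <- NA_real_
  attr(out, "n_genotyped") <- n_genotyped
  out
}

#' Call line-origin genotypes in 1 Mb bins for a cohort
#'
#' Full genotyping pipeline: for every individual and chromosome, sliding
#' windows of line-allele read fractions are segmented into HH/HET/LL
#' states in both directions at two window sizes
#' ([run_bidirectional()]), bin scores are computed and
#' forward/reverse-reconciled per window size, window sizes are combined by
#' the marker-density rule, and ambiguity plus minimum-cohort filters are
#' applied ([combine_window_sizes()]).
#'
#' @param counts A `read_counts` table (`individual`, `chrom`, `pos`,
#'   `n_h`, `n_l`).
#' @param panel The `marker_panel` the counts refer to.
#' @param chromosomes `data.frame` with `chrom` and `length` (bp).
#' @param window_sizes Two window sizes in markers, small then large
#'   (default `c(50, 200)`).
#' @param rho Per-window-step switch probability.
#' @param density_threshold Markers/Mb cutoff selecting between window
#'   sizes.
#' @param min_individuals Minimum individuals per bin.
#' @param strict Strict forward/reverse reconciliation (see
#'   [reconcile_directions()]).
#' @param max_tries Emission-fit retry bound.
#' @return Numeric matrix of class `bin_genotypes` (individuals x bins,
#'   `NA` = missing) with attributes `bins` (chrom, start, end, density,
#'   n_genotyped) and `fallback_rate` (fraction of emission fits that used
#'   hardcoded thresholds).
#' @export
call_genotypes <- function(counts, panel, chromosomes,
                           window_sizes = c(50, 200), rho = 1e-3,
                           density_threshold = 20, min_individuals = 100,
                           strict = FALSE, max_tries = 20) {
  stopifnot(length(window_sizes) == 2L)
  window_sizes <- sort(window_sizes)
  ids <- sort(unique(counts$individual))
  chroms <- data.frame(chrom = as.character(chromosomes$chrom),
                       length = chromosomes$length, stringsAsFactors = FALSE)

  bin_list <- lapply(seq_len(nrow(chroms)), function(c) {
    n_bin <- ceiling(chroms$length[c] / 1e6)
    start <- (seq_len(n_bin) - 1L) * 1e6
    end <- pmin(start + 1e6, chroms$length[c])
    dens <- vapply(seq_len(n_bin), function(b) {
      sum(panel$chrom == chroms$chrom[c] & panel$pos > start[b] &
            panel$pos <= end[b]) / ((end[b] - start[b]) / 1e6)
    }, numeric(1))
    data.frame(chrom = chroms$chrom[c], start = start, end = end,
               density = dens, stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, bin_list)
  nb <- nrow(bins)
  col_names <- paste0(bins$chrom, ":",
                      format(bins$start, scientific = FALSE, trim = TRUE))

  mat_small <- matrix(NA_real_, length(ids), nb, dimnames = list(ids, col_names))
  mat_large <- mat_small
  n_fits <- 0L
  n_fallback <- 0L

  cnt_by_ind <- split(counts, counts$individual)
  offsets <- c(0L, cumsum(vapply(bin_list, nrow, integer(1))))

  for (i in seq_along(ids)) {
    ci <- cnt_by_ind[[ids[i]]]
    by_chr <- split(ci, ci$chrom)
    for (c in seq_len(nrow(chroms))) {
      cc <- by_chr[[chroms$chrom[c]]]
      if (is.null(cc) || nrow(cc) == 0L) next
      cc <- cc[order(cc$pos), , drop = FALSE]
      cols <- (offsets[c] + 1L):offsets[c + 1L]
      b <- bin_list[[c]]
      for (k in 1:2) {
        res <- run_bidirectional(cc, window_sizes[k], rho = rho,
                                 max_tries = max_tries)
        if (res$uncallable) next
        n_fits <- n_fits + 1L
        if (res$params$fallback_used) n_fallback <- n_fallback + 1L
        sf <- score_bins(res$forward, b$start, b$end)
        sr <- score_bins(res$reverse, b$start, b$end)
        rec <- reconcile_directions(sf, sr, strict = strict)
        if (k == 1L) mat_small[i, cols] <- rec else mat_large[i, cols] <- rec
      }
    }
  }

  out <- combine_window_sizes(mat_small, mat_large, bins$density,
                              density_threshold = density_threshold,
                              min_individuals = min_individuals)
  bins$n_genotyped <- attr(out, "n_genotyped")
  attr(out, "n_genotyped") <- NULL
  attr(out, "bins") <- bins
  attr(out, "fallback_rate") <- if (n_fits > 0) n_fallback / n_fits else NA_real_
  class(out) <- c("bin_genotypes", class(out))
  out
}

#' @export
print.bin_genotypes <- function(x, ...) {
  bins <- attr(x, "bins")
  cat(sprintf("Bin genotype matrix: %d individuals x %d bins (%d chromosome(s))\n",
              nrow(x), ncol(x), length(unique(bins$chrom))))
  cat(sprintf("  called: %.1f%%; emission fallback rate: %.1f%%\n",
              100 * mean(!is.na(x)), 100 * attr(x, "fallback_rate")))
  invisible(x)
}

#' @export
summary.bin_genotypes <- function(object, ...) {
  bins <- attr(object, "bins")
  data.frame(bins,
             called = colSums(!is.na(object)),
             mean_score = colMeans(object, na.rm = TRUE))
}
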