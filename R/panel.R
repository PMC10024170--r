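#' Select markers informative for founder line origin
#'
#' Screens biallelic sites for a founder-line frequency difference: a site is
#' retained when the frequency of one allele in the H-line founders exceeds
#' its frequency in the L-line founders by at least `min_freq_gap`. With the
#' default gap of 1 only fixed line differences pass; smaller gaps admit
#' near-fixed sites. The allele at higher H-line frequency becomes the
#' site's `h_allele`.
#'
#' Sites with more than two observed alleles are skipped with a warning;
#' missing founder calls are ignored (frequencies are over non-missing
#' calls).
#'
#' @param genotypes Character matrix, sites x founders, entries `"A/G"`
#'   style diploid calls (`NA` or `"./."` for missing).
#' @param line Character vector, `"H"` or `"L"`, one entry per founder
#'   column.
#' @param sites `data.frame` with `chrom` and `pos` aligned with the rows of
#'   `genotypes`.
#' @param min_freq_gap Minimum H-minus-L frequency difference (default 1 =
#'   fixed differences only).
#' @return `data.frame` of class `marker_panel`: `chrom`, `pos`, `h_allele`,
#'   `l_allele`, `freq_h`, `freq_l` (both frequencies refer to `h_allele`),
#'   ordered by chromosome and position.
#' @export
select_informative_markers <- function(genotypes, line, sites,
                                       min_freq_gap = 1) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) == length(line),
            nrow(genotypes) == nrow(sites), min_freq_gap > 0)
  line <- as.character(line)
  stopifnot(all(line %in% c("H", "L")))

  g <- genotypes
  g[g %in% c("./.", ".", "")] <- NA_character_
  a1 <- substr(g, 1L, 1L)
  a2 <- substr(g, 3L, 3L)
  a1[a1 == "."] <- NA_character_
  a2[a2 == "."] <- NA_character_

  bases <- c("A", "C", "G", "T")
  is_h <- line == "H"
  count_base <- function(b, cols) {
    rowSums(a1[, cols, drop = FALSE] == b, na.rm = TRUE) +
      rowSums(a2[, cols, drop = FALSE] == b, na.rm = TRUE)
  }
  ch <- vapply(bases, count_base, numeric(nrow(g)), cols = is_h)
  cl <- vapply(bases, count_base, numeric(nrow(g)), cols = !is_h)
  if (nrow(g) == 1L) { ch <- matrix(ch, 1L); cl <- matrix(cl, 1L) }

  n_alleles <- rowSums((ch + cl) > 0)
  multi <- n_alleles > 2L
  if (any(multi))
    warning(sprintf("skipped %d site(s) with more than 2 alleles", sum(multi)))

  tot_h <- rowSums(ch)
  tot_l <- rowSums(cl)
  fh <- ch / ifelse(tot_h > 0, tot_h, NA)
  fl <- cl / ifelse(tot_l > 0, tot_l, NA)
  gap <- fh - fl                      # per-allele H-minus-L frequency gap
  gap[is.na(gap)] <- -Inf
  best <- max.col(gap, ties.method = "first")
  best_gap <- gap[cbind(seq_len(nrow(g)), best)]

  keep <- !multi & n_alleles == 2L & best_gap >= min_freq_gap &
    is.finite(best_gap)
  if (!any(keep)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      h_allele = character(0), l_allele = character(0),
                      freq_h = numeric(0), freq_l = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("marker_panel", "data.frame")
    return(out)
  }

  idx <- which(keep)
  h_allele <- bases[best[idx]]
  # the other observed allele
  l_allele <- vapply(idx, function(i) {
    obs <- bases[(ch[i, ] + cl[i, ]) > 0]
    setdiff(obs, bases[best[i]])[1L]
  }, "")
  out <- data.frame(chrom = as.character(sites$chrom[idx]),
                    pos = as.integer(sites$pos[idx]),
                    h_allele = h_allele, l_allele = l_allele,
                    freq_h = fh[cbind(idx, best[idx])],
                    freq_l = fl[cbind(idx, best[idx])],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' Extract per-individual line-allele read counts at panel sites
#'
#' Maps raw allele-level read counts onto a marker panel: for every
#' individual and panel site with at least one read, counts reads matching
#' the site's `h_allele` and `l_allele`. Reads matching neither allele are
#' dropped and tallied in the `dropped_reads` attribute.
#'
#' @param variants Long-format `data.frame` of observed reads:
#'   `individual`, `chrom`, `pos`, `allele`, `count`.
#' @param panel A `marker_panel`.
#' @param individuals Optional full roster; individuals with no usable reads
#'   are reported via message (they simply have no rows in the sparse
#'   table).
#' @return `read_counts` data.frame (`individual`, `chrom`, `pos`, `n_h`,
#'   `n_l`), entries restricted to `n_h + n_l >= 1`, with attribute
#'   `dropped_reads`.
#' @export
extract_line_counts <- function(variants, panel, individuals = NULL) {
  stopifnot(all(c("individual", "chrom", "pos", "allele", "count")
                %in% names(variants)))
  key_v <- paste(variants$chrom, variants$pos)
  key_p <- paste(panel$chrom, panel$pos)
  m <- match(key_v, key_p)
  in_panel <- !is.na(m)
  v <- variants[in_panel, , drop = FALSE]
  pm <- m[in_panel]

  is_h <- v$allele == panel$h_allele[pm]
  is_l <- v$allele == panel$l_allele[pm]
  dropped <- sum(v$count[!is_h & !is_l])

  grp <- paste(v$individual, v$chrom, v$pos, sep = "\r")
  n_h <- rowsum(v$count * is_h, grp)
  n_l <- rowsum(v$count * is_l, grp)
  parts <- strsplit(rownames(n_h), "\r", fixed = TRUE)
  out <- data.frame(
    individual = vapply(parts, `[`, "", 1L),
    chrom = vapply(parts, `[`, "", 2L),
    pos = as.integer(vapply(parts, `[`, "", 3L)),
    n_h = as.integer(n_h), n_l = as.integer(n_l),
    stringsAsFactors = FALSE
  )
  out <- out[out$n_h + out$n_l >= 1L, , drop = FALSE]
  out <- out[order(out$individual, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(individuals)) {
    absent <- setdiff(individuals, unique(out$individual))
    if (length(absent))
      message(sprintf("%d individual(s) without panel-informative reads: %s",
                      length(absent),
                      paste(utils::head(absent, 5L), collapse = ", ")))
  }
  class(out) <- c("read_counts", "data.frame")
  attr(out, "dropped_reads") <- dropped
  out
}

#' Fraction of covered sites that are line-informative
#'
#' For each individual, the fraction of its covered variant sites that
#' belong to the informative marker panel. In deep intercrosses of outbred
#' lines this fraction declines over generations as more founders
#' contribute to each genome.
#'
#' @param counts A `read_counts` table (panel sites with >= 1 read).
#' @param total_sites Named numeric vector: per-individual total number of
#'   covered variant sites (the denominator).
#' @return Named numeric vector of fractions in \[0, 1\]; `NA` where the
#'   total is zero or missing.
#' @export
informative_fraction <- function(counts, total_sites) {
  stopifnot(!is.null(names(total_sites)))
  inform <- table(counts$individual)
  n_inf <- as.numeric(inform[names(total_sites)])
  n_inf[is.na(n_inf)] <- 0
  bad <- !is.finite(total_sites) | total_sites <= 0
  if (any(bad))
    warning(sprintf("%d individual(s) with zero covered sites reported as NA",
                    sum(bad)))
  out <- ifelse(bad, NA_real_, n_inf / total_sites)
  names(out) <- names(total_sites)
  out
}
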