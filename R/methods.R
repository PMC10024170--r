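#' @export
print.ail_scan <- function(x, ...) {
  cat(sprintf("Haley-Knott genome scan: %d bins on %d chromosome(s), n = %s\n",
              nrow(x), length(unique(x$chrom)),
              if (is.null(attr(x, "n"))) "?" else attr(x, "n")))
  top <- x[order(-x$lod), ][seq_len(min(5L, nrow(x))), ]
  cat("Top bins:\n")
  print(data.frame(chrom = top$chrom, Mb = top$start / 1e6,
                   LOD = round(top$lod, 2), a = round(top$a_hat, 3),
                   d = round(top$d_hat, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.ail_scan <- function(object, threshold = NULL, ...) {
  cat(sprintf("Bins: %d; max LOD %.2f (chromosome %s, %.0f Mb)\n",
              nrow(object), max(object$lod),
              object$chrom[which.max(object$lod)],
              object$start[which.max(object$lod)] / 1e6))
  if (!is.null(threshold))
    cat(sprintf("Bins above genome-wide threshold %.2f: %d\n",
                threshold, sum(object$lod >= threshold)))
  invisible(object)
}

#' Plot a genome scan LOD profile
#'
#' @param x An `ail_scan`.
#' @param threshold Optional genome-wide LOD threshold drawn as a line.
#' @param ... Passed to [plot()].
#' @export
plot.ail_scan <- function(x, threshold = NULL, ...) {
  chroms <- unique(x$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(cn)
    max(x$start[x$chrom == cn]) + 1e6, numeric(1))))
  names(offs) <- c(chroms, "end")
  xs <- x$start + offs[x$chrom]
  cols <- (match(x$chrom, chroms) %% 2L) + 1L
  graphics::plot(xs / 1e6, x$lod, col = c("grey25", "steelblue")[cols],
                 pch = 16, cex = 0.6, xlab = "position (Mb, concatenated)",
                 ylab = "LOD", ...)
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(x)
}

#' @export
print.qtl_set <- function(x, ...) {
  cat(sprintf("QTL set: %d peak(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- data.frame(chrom = x$chrom, Mb = x$start / 1e6,
                       LOD = round(x$lod, 2), tier = x$tier)
    if (!is.null(x$a_g)) show$a_g <- round(x$a_g, 1)
    if (!is.null(x$pct_var)) show$pct_var <- round(x$pct_var, 2)
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("Marker panel: %d line-informative site(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x))
    cat(sprintf("  fixed differences: %d (gap = 1)\n",
                sum(x$freq_h - x$freq_l >= 1 - 1e-9)))
  invisible(x)
}
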