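#' Sliding windows of line-allele read fractions
#'
#' Builds sliding windows of `w` consecutive covered panel markers (step 1
#' marker) for one individual and chromosome, and computes per window the
#' read-weighted H-allele fraction `f = sum(n_h) / sum(n_h + n_l)`.
#'
#' @param counts `data.frame` with `pos`, `n_h`, `n_l` for one individual
#'   and one chromosome, sorted by position.
#' @param w Window size in markers (>= 2).
#' @return `data.frame` of class `window_series` with columns
#'   `first_marker`, `last_marker` (indices into the covered-marker vector),
#'   `first_bp`, `last_bp`, `f`, `n_reads`, plus attributes `pos` (covered
#'   marker positions) and `w`. Zero rows (chromosome uncallable) when fewer
#'   than `w` markers are covered.
#' @export
build_windows <- function(counts, w) {
  stopifnot(w >= 2)
  if (is.unsorted(counts$pos, strictly = FALSE))
    counts <- counts[order(counts$pos), , drop = FALSE]
  n <- nrow(counts)
  if (n < w) {
    out <- data.frame(first_marker = integer(0), last_marker = integer(0),
                      first_bp = numeric(0), last_bp = numeric(0),
                      f = numeric(0), n_reads = numeric(0))
    attr(out, "pos") <- counts$pos
    attr(out, "w") <- w
    attr(out, "uncallable") <- TRUE
    class(out) <- c("window_series", "data.frame")
    return(out)
  }
  ch <- c(0, cumsum(counts$n_h))
  ct <- c(0, cumsum(counts$n_h + counts$n_l))
  i1 <- seq_len(n - w + 1L)
  i2 <- i1 + w - 1L
  nh <- ch[i2 + 1L] - ch[i1]
  nt <- ct[i2 + 1L] - ct[i1]
  out <- data.frame(first_marker = i1, last_marker = i2,
                    first_bp = counts$pos[i1], last_bp = counts$pos[i2],
                    f = nh / nt, n_reads = nt)
  attr(out, "pos") <- counts$pos
  attr(out, "w") <- w
  attr(out, "uncallable") <- FALSE
  class(out) <- c("window_series", "data.frame")
  out
}
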