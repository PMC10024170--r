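#' Simulation configuration for an advanced intercross line
#'
#' Builds and validates the parameter set used by [simulate_ail()] and the
#' stage-level simulator functions. Defaults describe a desk-scale version of
#' a two-line divergent intercross: two outbred founder lines (29 high-line
#' and 30 low-line birds), a three-chromosome genome, and low-coverage
#' (0.4X) sequencing of the intercross offspring.
#'
#' @param n_founders_high,n_founders_low Number of founders of the high (H)
#'   and low (L) line.
#' @param chromosomes `data.frame` with columns `chrom` (identifier),
#'   `length` (bp) and `cm_per_mb` (recombination rate; the genetic map is
#'   linear in physical position).
#' @param markers_per_mb Density of candidate markers (evenly spaced).
#' @param p_fixed Fraction of markers fixed for alternative alleles between
#'   the two founder lines; the rest segregate within lines.
#' @param within_line_maf Allele frequency of the H-labelled allele at
#'   within-line segregating markers (point mass; both lines use the same
#'   frequency so these markers carry no line information on average).
#' @param generation_sizes Named integer vector, e.g. `c(F1 = 60, F2 = 200)`.
#'   Generations are bred in order F1, F2, ... with F1 formed by H x L
#'   founder pairings and later generations by random pairing of distinct
#'   parents from the previous generation.
#' @param qtl `NULL` or a `data.frame` with columns `chrom`, `pos` (bp),
#'   `a` (additive effect, grams) and `d` (dominance effect, grams). `a` is
#'   half the difference between opposite line-origin homozygotes.
#' @param sex_effect Grams added for the non-reference sex.
#' @param generation_means Named numeric vector of generation means (grams).
#'   Unnamed generations default to `default_mean`.
#' @param default_mean Fallback generation mean in grams.
#' @param residual_sd Residual standard deviation in grams.
#' @param coverage Mean sequencing depth per marker (Poisson).
#' @param seq_error Per-read probability that the reported allele is flipped
#'   to the other line's allele.
#' @param seed Master seed; per-stage streams are derived from it (see
#'   Details).
#'
#' @details A single master seed drives the whole simulation. Stage seeds are
#' derived as `seed + k` with fixed offsets k = 1 (founders), 2 (pedigree),
#' 3 (phenotypes), 4 (read counts) so each stage is independently
#' reproducible.
#'
#' @return An object of class `ail_config` (a validated list).
#' @export
ail_config <- function(n_founders_high = 29L,
                       n_founders_low = 30L,
                       chromosomes = data.frame(
                         chrom = c("1", "2", "3"),
                         length = c(50e6, 30e6, 10e6),
                         cm_per_mb = 1
                       ),
                       markers_per_mb = 100,
                       p_fixed = 1,
                       within_line_maf = 0.5,
                       generation_sizes = c(F1 = 60, F2 = 200),
                       qtl = NULL,
                       sex_effect = 150,
                       generation_means = NULL,
                       default_mean = 900,
                       residual_sd = 100,
                       coverage = 0.4,
                       seq_error = 0.002,
                       seed = 1L) {
  cfg <- list(
    n_founders_high = as.integer(n_founders_high),
    n_founders_low = as.integer(n_founders_low),
    chromosomes = chromosomes,
    markers_per_mb = markers_per_mb,
    p_fixed = p_fixed,
    within_line_maf = within_line_maf,
    generation_sizes = generation_sizes,
    qtl = qtl,
    sex_effect = sex_effect,
    generation_means = generation_means,
    default_mean = default_mean,
    residual_sd = residual_sd,
    coverage = coverage,
    seq_error = seq_error,
    seed = as.integer(seed)
  )
  class(cfg) <- "ail_config"
  validate_ail_config(cfg)
  cfg
}

validate_ail_config <- function(cfg) {
  stopifnot(is.data.frame(cfg$chromosomes))
  if (nrow(cfg$chromosomes) < 1L)
    stop("configuration error: at least one chromosome is required")
  if (!all(c("chrom", "length", "cm_per_mb") %in% names(cfg$chromosomes)))
    stop("configuration error: chromosomes needs columns chrom, length, cm_per_mb")
  if (any(cfg$chromosomes$length <= 0))
    stop("configuration error: chromosome lengths must be positive")
  if (any(cfg$chromosomes$cm_per_mb < 0))
    stop("configuration error: cm_per_mb must be non-negative")
  if (anyDuplicated(cfg$chromosomes$chrom))
    stop("configuration error: duplicated chromosome identifiers")
  if (cfg$n_founders_high < 1L || cfg$n_founders_low < 1L)
    stop("configuration error: founder counts must be positive")
  if (cfg$markers_per_mb <= 0)
    stop("configuration error: markers_per_mb must be positive")
  n_mark <- sum(floor(cfg$chromosomes$length / 1e6 * cfg$markers_per_mb))
  if (n_mark < 1L)
    stop("configuration error: marker density yields zero markers")
  if (cfg$p_fixed < 0 || cfg$p_fixed > 1)
    stop("configuration error: p_fixed must lie in [0, 1]")
  if (cfg$within_line_maf <= 0 || cfg$within_line_maf >= 1)
    stop("configuration error: within_line_maf must lie in (0, 1)")
  if (length(cfg$generation_sizes) < 1L || is.null(names(cfg$generation_sizes)))
    stop("configuration error: generation_sizes must be a named vector")
  if (any(cfg$generation_sizes < 2))
    stop("pedigree error: every generation needs at least 2 individuals")
  if (cfg$coverage < 0)
    stop("configuration error: coverage must be >= 0")
  if (cfg$seq_error < 0 || cfg$seq_error >= 0.5)
    stop("configuration error: seq_error must lie in [0, 0.5)")
  if (cfg$residual_sd < 0)
    stop("configuration error: residual_sd must be >= 0")
  if (!is.null(cfg$qtl)) {
    stopifnot(is.data.frame(cfg$qtl),
              all(c("chrom", "pos", "a", "d") %in% names(cfg$qtl)))
    m <- match(as.character(cfg$qtl$chrom), as.character(cfg$chromosomes$chrom))
    if (anyNA(m))
      stop("specification error: QTL placed on unsimulated chromosome")
    if (any(cfg$qtl$pos < 1 | cfg$qtl$pos > cfg$chromosomes$length[m]))
      stop("specification error: QTL position outside its chromosome")
  }
  invisible(cfg)
}

#' @export
print.ail_config <- function(x, ...) {
  cat("AIL simulation configuration\n")
  cat(sprintf("  founders: %d H + %d L\n", x$n_founders_high, x$n_founders_low))
  cat(sprintf("  genome: %d chromosome(s), %.0f Mb total, %g markers/Mb\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              x$markers_per_mb))
  cat(sprintf("  p_fixed: %g, coverage: %gX, seq_error: %g\n",
              x$p_fixed, x$coverage, x$seq_error))
  cat(sprintf("  generations: %s\n",
              paste(sprintf("%s=%d", names(x$generation_sizes),
                            x$generation_sizes), collapse = ", ")))
  cat(sprintf("  QTL: %d, sex effect %g g, residual SD %g g, seed %d\n",
              if (is.null(x$qtl)) 0L else nrow(x$qtl),
              x$sex_effect, x$residual_sd, x$seed))
  invisible(x)
}
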