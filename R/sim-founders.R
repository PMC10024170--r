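#' Simulate founder haplotypes for two divergent lines
#'
#' Draws diploid founder haplotypes for the H (high) and L (low) selected
#' lines at an evenly spaced marker grid. A fraction `p_fixed` of markers is
#' fixed for alternative alleles between the lines (always line-informative);
#' the remainder segregate within both lines at frequency `within_line_maf`
#' and carry no systematic line difference.
#'
#' Founder haplotypes are returned as a logical matrix over haplotypes x
#' markers where `TRUE` means the haplotype carries the H-labelled allele.
#' Haplotypes `2i - 1` and `2i` belong to founder `i`; H-line founders come
#' first.
#'
#' @param config An [ail_config()].
#' @return A list of class `ail_founders` with elements:
#'   \describe{
#'     \item{panel_truth}{`data.frame` of markers: `chrom`, `pos`,
#'       `h_allele`, `l_allele`, `fixed` (logical).}
#'     \item{haplotypes}{logical matrix, `2*(nH+nL)` rows.}
#'     \item{line}{per-founder line label, `"H"` or `"L"`.}
#'     \item{founder_id}{founder identifiers.}
#'   }
#' @export
simulate_founders <- function(config) {
  validate_ail_config(config)
  set.seed(config$seed + 1L)

  chroms <- config$chromosomes
  marker_list <- lapply(seq_len(nrow(chroms)), function(i) {
    n <- floor(chroms$length[i] / 1e6 * config$markers_per_mb)
    spacing <- chroms$length[i] / n
    data.frame(
      chrom = rep(as.character(chroms$chrom[i]), n),
      pos = as.integer(floor(spacing * (seq_len(n) - 0.5))) + 1L,
      stringsAsFactors = FALSE
    )
  })
  markers <- do.call(rbind, marker_list)
  n_mark <- nrow(markers)

  bases <- c("A", "C", "G", "T")
  h_allele <- sample(bases, n_mark, replace = TRUE)
  l_allele <- vapply(h_allele, function(b) sample(setdiff(bases, b), 1L), "")
  fixed <- runif(n_mark) < config$p_fixed

  n_h <- config$n_founders_high
  n_l <- config$n_founders_low
  n_hap_h <- 2L * n_h
  n_hap_l <- 2L * n_l

  # TRUE = haplotype carries the H-labelled allele
  hap <- matrix(FALSE, nrow = n_hap_h + n_hap_l, ncol = n_mark)
  hap[seq_len(n_hap_h), fixed] <- TRUE
  # L haplotypes at fixed markers stay FALSE
  if (any(!fixed)) {
    seg <- which(!fixed)
    p <- config$within_line_maf
    hap[, seg] <- matrix(runif(length(seg) * nrow(hap)) < p,
                         nrow = nrow(hap))
  }

  founder_line <- c(rep("H", n_h), rep("L", n_l))
  founder_id <- c(sprintf("H%02d", seq_len(n_h)), sprintf("L%02d", seq_len(n_l)))
  rownames(hap) <- paste0(rep(founder_id, each = 2L), c("_1", "_2"))

  structure(
    list(
      panel_truth = cbind(markers,
                          data.frame(h_allele = h_allele, l_allele = l_allele,
                                     fixed = fixed, stringsAsFactors = FALSE)),
      haplotypes = hap,
      line = founder_line,
      founder_id = founder_id
    ),
    class = "ail_founders"
  )
}

#' Founder genotype matrix in allele-character form
#'
#' Collapses the simulated founder haplotypes to diploid genotypes of the
#' form `"A/G"`, one row per marker and one column per founder, the layout
#' expected by [select_informative_markers()].
#'
#' @param founders An `ail_founders` object.
#' @return Character matrix markers x founders.
#' @export
founder_genotypes <- function(founders) {
  hap <- founders$haplotypes
  pt <- founders$panel_truth
  n_f <- length(founders$founder_id)
  out <- matrix(NA_character_, nrow = nrow(pt), ncol = n_f,
                dimnames = list(NULL, founders$founder_id))
  for (i in seq_len(n_f)) {
    a1 <- ifelse(hap[2L * i - 1L, ], pt$h_allele, pt$l_allele)
    a2 <- ifelse(hap[2L * i, ], pt$h_allele, pt$l_allele)
    out[, i] <- paste(a1, a2, sep = "/")
  }
  out
}
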