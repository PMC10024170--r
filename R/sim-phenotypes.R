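#' Simulate body-weight phenotypes on an AIL pedigree
#'
#' Generates a 56-day body-weight style phenotype for every individual:
#' \deqn{w = \mu_{gen} + s \cdot I(\mathrm{sex~non\mbox{-}ref}) + \sum_i (a_i x_i + d_i h_i) + e}
#' where `x` in \{-1, 0, 1\} is the line-origin additive code at the QTL
#' (+1 = H-line homozygote), `h` the heterozygote indicator, and
#' `e ~ Normal(0, residual_sd)`. Sex `"F"` is the reference level.
#'
#' @param pedigree An `ail_pedigree`.
#' @param config The [ail_config()] (supplies QTL, effects, means, seed).
#' @return A list of class `ail_phenotypes` with `phenotypes` (data.frame
#'   `id`, `generation`, `sex`, `weight`) and `truth` (the phenotype
#'   decomposition: `genetic_value`, `sex_term`, `generation_term`,
#'   `residual`, plus per-QTL additive codes as a matrix `qtl_x`).
#' @export
simulate_phenotypes <- function(pedigree, config) {
  set.seed(config$seed + 3L)
  ind <- pedigree$individuals
  n <- nrow(ind)
  chroms <- pedigree$chromosomes

  gm <- rep(config$default_mean, n)
  if (!is.null(config$generation_means)) {
    m <- match(ind$generation, names(config$generation_means))
    gm[!is.na(m)] <- config$generation_means[m[!is.na(m)]]
  }
  sex_term <- ifelse(ind$sex == "M", config$sex_effect, 0)

  qtl <- config$qtl
  genetic <- numeric(n)
  qtl_x <- NULL
  if (!is.null(qtl) && nrow(qtl) > 0L) {
    ci <- match(as.character(qtl$chrom), as.character(chroms$chrom))
    if (anyNA(ci))
      stop("specification error: QTL on unsimulated chromosome")
    qtl_x <- matrix(NA_real_, n, nrow(qtl))
    for (q in seq_len(nrow(qtl))) {
      x <- vapply(ind$id, function(id) {
        g <- pedigree$genomes[[id]][[ci[q]]]
        sum(hap_is_h(g$h1, qtl$pos[q], pedigree$n_hap_h),
            hap_is_h(g$h2, qtl$pos[q], pedigree$n_hap_h)) - 1
      }, numeric(1))
      qtl_x[, q] <- x
      genetic <- genetic + qtl$a[q] * x + qtl$d[q] * (x == 0)
    }
  }
  residual <- stats::rnorm(n, 0, config$residual_sd)
  weight <- gm + sex_term + genetic + residual

  phen <- data.frame(id = ind$id, generation = ind$generation, sex = ind$sex,
                     weight = weight, stringsAsFactors = FALSE)
  truth <- data.frame(id = ind$id, genetic_value = genetic,
                      sex_term = sex_term, generation_term = gm,
                      residual = residual, stringsAsFactors = FALSE)
  structure(list(phenotypes = phen, truth = truth, qtl_x = qtl_x),
            class = "ail_phenotypes")
}

#' Simulate low-coverage read counts at panel markers
#'
#' Per individual and marker, sequencing depth is Poisson(`coverage`); each
#' read samples one of the two haplotypes uniformly and reports that
#' haplotype's allele, flipped to the other line's allele with probability
#' `seq_error`. Markers with zero depth are absent from the table.
#'
#' @param pedigree An `ail_pedigree`.
#' @param founders The `ail_founders` the pedigree descends from.
#' @param config The [ail_config()].
#' @param ids Individuals to sequence (default all).
#' @return `data.frame` of class `read_counts`: `individual`, `chrom`,
#'   `pos`, `n_h`, `n_l` (reads supporting the H- and L-labelled allele).
#' @export
simulate_reads <- function(pedigree, founders, config, ids = NULL) {
  set.seed(config$seed + 4L)
  if (is.null(ids)) ids <- pedigree$individuals$id
  pt <- founders$panel_truth
  chroms <- pedigree$chromosomes
  hap <- founders$haplotypes
  err <- config$seq_error

  res <- vector("list", length(ids) * nrow(chroms))
  k <- 0L
  for (c in seq_len(nrow(chroms))) {
    cn <- as.character(chroms$chrom[c])
    idx <- which(pt$chrom == cn)
    pos <- pt$pos[idx]
    nm <- length(idx)
    for (i in seq_along(ids)) {
      depth <- stats::rpois(nm, config$coverage)
      cov <- which(depth > 0L)
      if (length(cov) == 0L) next
      g <- pedigree$genomes[[ids[i]]][[c]]
      src1 <- hap_src_at(g$h1, pos[cov])
      src2 <- hap_src_at(g$h2, pos[cov])
      # allele carried by each haplotype at covered markers (TRUE = H allele)
      a1 <- hap[cbind(src1, idx[cov])]
      a2 <- hap[cbind(src2, idx[cov])]
      d <- depth[cov]
      from1 <- stats::rbinom(length(cov), d, 0.5)
      from2 <- d - from1
      # reads carrying the H allele before error
      h_true <- from1 * a1 + from2 * a2
      l_true <- d - h_true
      flip_h <- stats::rbinom(length(cov), h_true, err)
      flip_l <- stats::rbinom(length(cov), l_true, err)
      n_h <- h_true - flip_h + flip_l
      k <- k + 1L
      res[[k]] <- data.frame(individual = ids[i], chrom = cn, pos = pos[cov],
                             n_h = as.integer(n_h), n_l = as.integer(d - n_h),
                             stringsAsFactors = FALSE)
    }
  }
  out <- if (k == 0L) {
    data.frame(individual = character(0), chrom = character(0),
               pos = integer(0), n_h = integer(0), n_l = integer(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, res[seq_len(k)])
  }
  class(out) <- c("read_counts", "data.frame")
  out
}

#' Run the full AIL simulation
#'
#' Convenience wrapper chaining [simulate_founders()],
#' [simulate_pedigree()], [simulate_phenotypes()] and [simulate_reads()]
#' with per-stage seeds derived from the master seed.
#'
#' @param config An [ail_config()].
#' @param sequence_ids Individuals to generate read counts for (default all;
#'   pass e.g. only the final generations to mimic a study where early
#'   breeding generations were not sequenced).
#' @return List of class `ail_sim` with `founders`, `pedigree`,
#'   `phenotypes`, `counts`, `truth_bins`, and the `config`.
#' @export
simulate_ail <- function(config, sequence_ids = NULL) {
  founders <- simulate_founders(config)
  pedigree <- simulate_pedigree(founders, config)
  phen <- simulate_phenotypes(pedigree, config)
  counts <- simulate_reads(pedigree, founders, config, ids = sequence_ids)
  tb <- truth_bins(pedigree)
  structure(list(founders = founders, pedigree = pedigree,
                 phenotypes = phen, counts = counts, truth_bins = tb,
                 config = config),
            class = "ail_sim")
}

#' @export
print.ail_sim <- function(x, ...) {
  cat("AIL simulation\n")
  print(x$config)
  cat(sprintf("  read-count rows: %d; truth bins: %d x %d\n",
              nrow(x$counts), nrow(x$truth_bins), ncol(x$truth_bins)))
  invisible(x)
}
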