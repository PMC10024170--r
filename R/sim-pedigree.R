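# Mosaic haplotypes are run-length encoded: a haplotype on a chromosome is
# list(ends, src) where ends[k] is the bp end (inclusive upper bound) of
# segment k, ends[length(ends)] == chromosome length, and src[k] is the
# founder-haplotype index the segment was copied from. Line origin of a
# segment follows from its source index (H haplotypes come first).

new_hap <- function(ends, src) list(ends = as.numeric(ends), src = as.integer(src))

# Extract the sub-haplotype covering (lo, hi] from `hap`.
hap_slice <- function(hap, lo, hi) {
  i1 <- findInterval(lo, hap$ends, left.open = FALSE) + 1L
  i2 <- findInterval(hi - 1e-9, hap$ends) + 1L
  i2 <- min(i2, length(hap$ends))
  ends <- hap$ends[i1:i2]
  ends[length(ends)] <- hi
  list(ends = ends, src = hap$src[i1:i2])
}

# Source haplotype index at each query position (vectorised).
hap_src_at <- function(hap, pos) {
  hap$src[findInterval(pos - 1e-9, hap$ends) + 1L]
}

# Collapse adjacent segments with identical source.
hap_compact <- function(ends, src) {
  if (length(src) > 1L) {
    keep <- c(src[-1L] != src[-length(src)], TRUE)
    ends <- ends[keep]
    src <- src[keep]
  }
  new_hap(ends, src)
}

#' Single meiosis on one chromosome
#'
#' Draws a gamete from two parental haplotypes. The crossover count is
#' Poisson with mean equal to the chromosome's genetic map length in
#' Morgans (no interference, Haldane model); crossover positions are
#' uniform on the genetic map, which is linear in bp here.
#'
#' @param h1,h2 Parental haplotypes (run-length encoded).
#' @param length_bp Chromosome length.
#' @param morgans Map length in Morgans.
#' @return A recombinant haplotype.
#' @keywords internal
meiose <- function(h1, h2, length_bp, morgans) {
  k <- stats::rpois(1L, morgans)
  first <- stats::runif(1L) < 0.5
  if (k == 0L) return(if (first) h1 else h2)
  cuts <- sort(stats::runif(k, 0, length_bp))
  bounds <- c(0, cuts, length_bp)
  ends <- numeric(0)
  src <- integer(0)
  use1 <- first
  for (j in seq_len(length(bounds) - 1L)) {
    lo <- bounds[j]; hi <- bounds[j + 1L]
    if (hi - lo <= 0) { use1 <- !use1; next }
    piece <- hap_slice(if (use1) h1 else h2, lo, hi)
    ends <- c(ends, piece$ends)
    src <- c(src, piece$src)
    use1 <- !use1
  }
  hap_compact(ends, src)
}

#' Simulate an advanced intercross pedigree
#'
#' Breeds the configured generations from the founder lines. F1 individuals
#' are formed by pairing a random H founder with a random L founder; each
#' later generation is produced by random pairing of two distinct parents
#' drawn from the previous generation (no selfing, no sex restriction on
#' mating, no selection). Each offspring receives one recombinant gamete
#' from each parent ([meiose()]).
#'
#' Sexes are assigned alternately within each generation and then shuffled.
#'
#' @param founders An `ail_founders` object.
#' @param config The [ail_config()] used to create `founders`.
#' @return An object of class `ail_pedigree`: list with `individuals`
#'   (data.frame id, generation, sex), `genomes` (per individual, per
#'   chromosome, haplotype pair), `chromosomes`, and `n_hap_h` (count of
#'   H-line founder haplotypes, used to map segment sources to lines).
#' @export
simulate_pedigree <- function(founders, config) {
  validate_ail_config(config)
  set.seed(config$seed + 2L)

  chroms <- config$chromosomes
  n_chr <- nrow(chroms)
  morgans <- chroms$length / 1e6 * chroms$cm_per_mb / 100
  n_h <- config$n_founders_high
  n_hap_h <- 2L * n_h
  n_founders <- n_h + config$n_founders_low

  founder_genome <- function(i) {
    lapply(seq_len(n_chr), function(c) {
      L <- chroms$length[c]
      list(h1 = new_hap(L, 2L * i - 1L), h2 = new_hap(L, 2L * i))
    })
  }

  gens <- names(config$generation_sizes)
  genomes <- list()
  individuals <- list()
  prev <- NULL   # list of genomes of the previous generation

  for (g in seq_along(gens)) {
    n_off <- as.integer(config$generation_sizes[g])
    gen_name <- gens[g]
    if (g == 1L) {
      sires <- sample.int(n_h, n_off, replace = TRUE)
      dams <- n_h + sample.int(n_founders - n_h, n_off, replace = TRUE)
      parent_pool <- lapply(seq_len(n_founders), founder_genome)
    } else {
      if (length(prev) < 2L)
        stop("pedigree error: previous generation has fewer than 2 individuals")
      sires <- sample.int(length(prev), n_off, replace = TRUE)
      dams <- vapply(sires, function(s) {
        repeat {
          d <- sample.int(length(prev), 1L)
          if (d != s) return(d)
        }
      }, integer(1))
      parent_pool <- prev
    }
    off <- vector("list", n_off)
    for (i in seq_len(n_off)) {
      gs <- parent_pool[[sires[i]]]
      gd <- parent_pool[[dams[i]]]
      off[[i]] <- lapply(seq_len(n_chr), function(c) {
        list(h1 = meiose(gs[[c]]$h1, gs[[c]]$h2, chroms$length[c], morgans[c]),
             h2 = meiose(gd[[c]]$h1, gd[[c]]$h2, chroms$length[c], morgans[c]))
      })
    }
    sex <- sample(rep_len(c("F", "M"), n_off))
    ids <- sprintf("%s_%04d", gen_name, seq_len(n_off))
    names(off) <- ids
    individuals[[g]] <- data.frame(id = ids, generation = gen_name, sex = sex,
                                   stringsAsFactors = FALSE)
    genomes <- c(genomes, off)
    prev <- off
  }

  structure(
    list(
      individuals = do.call(rbind, individuals),
      genomes = genomes,
      chromosomes = chroms,
      n_hap_h = n_hap_h
    ),
    class = "ail_pedigree"
  )
}

#' @export
print.ail_pedigree <- function(x, ...) {
  tab <- table(factor(x$individuals$generation,
                      levels = unique(x$individuals$generation)))
  cat("AIL pedigree:", nrow(x$individuals), "individuals\n")
  print(tab)
  invisible(x)
}

# Line-origin (TRUE = H) of a haplotype at given positions.
hap_is_h <- function(hap, pos, n_hap_h) hap_src_at(hap, pos) <= n_hap_h

# Number of line-origin changepoints on a haplotype (for truth accounting).
hap_line_breaks <- function(hap, n_hap_h) {
  ishp <- hap$src <= n_hap_h
  sum(ishp[-1L] != ishp[-length(ishp)])
}

#' True line-origin scores in 1 Mb bins
#'
#' Computes, for every individual and 1 Mb bin, the base-pair weighted
#' line-origin score on the (1, 0, -1) scale: +1 for H-line homozygous,
#' 0 heterozygous, -1 L-line homozygous, averaged over the base pairs of
#' the bin across both haplotypes.
#'
#' @param pedigree An `ail_pedigree`.
#' @param ids Individuals to include (default all).
#' @return Numeric matrix individuals x bins with column names
#'   `"chrom:binstart"` (0-based bin start in bp) and attribute `bins`, a
#'   data.frame with `chrom`, `start`, `end`.
#' @export
truth_bins <- function(pedigree, ids = NULL) {
  chroms <- pedigree$chromosomes
  if (is.null(ids)) ids <- pedigree$individuals$id
  bin_list <- lapply(seq_len(nrow(chroms)), function(c) {
    n_bin <- ceiling(chroms$length[c] / 1e6)
    start <- (seq_len(n_bin) - 1L) * 1e6
    data.frame(chrom = as.character(chroms$chrom[c]), start = start,
               end = pmin(start + 1e6, chroms$length[c]),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, bin_list)
  out <- matrix(NA_real_, nrow = length(ids), ncol = nrow(bins),
                dimnames = list(ids, paste0(bins$chrom, ":",
                                            format(bins$start, scientific = FALSE,
                                                   trim = TRUE))))
  offsets <- c(0L, cumsum(vapply(bin_list, nrow, integer(1))))
  for (i in seq_along(ids)) {
    genome <- pedigree$genomes[[ids[i]]]
    for (c in seq_len(nrow(chroms))) {
      b <- bin_list[[c]]
      h_len <- hap_h_overlap(genome[[c]]$h1, b$start, b$end, pedigree$n_hap_h) +
        hap_h_overlap(genome[[c]]$h2, b$start, b$end, pedigree$n_hap_h)
      tot <- 2 * (b$end - b$start)
      out[i, (offsets[c] + 1L):offsets[c + 1L]] <- 2 * h_len / tot - 1
    }
  }
  attr(out, "bins") <- bins
  out
}

#' Per-individual fraction of covered markers informative for line origin
#'
#' A covered marker is personally informative for an individual when it is
#' fixed for alternative alleles between the H- and L-line founder
#' haplotypes that actually contribute to that individual's genome. With
#' fully fixed line differences (`p_fixed = 1`) every marker qualifies; as
#' within-line segregating markers are used and more founders contribute
#' over the generations, the expected fraction declines.
#'
#' @param pedigree An `ail_pedigree`.
#' @param founders The corresponding `ail_founders`.
#' @param counts A `read_counts` table for the individuals of interest.
#' @return Named numeric vector, one fraction per individual present in
#'   `counts`.
#' @export
personal_informative_fraction <- function(pedigree, founders, counts) {
  pt <- founders$panel_truth
  hap <- founders$haplotypes
  key_p <- paste(pt$chrom, pt$pos)
  ids <- unique(counts$individual)
  out <- numeric(length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    genome <- pedigree$genomes[[ids[i]]]
    srcs <- unique(unlist(lapply(genome, function(g) c(g$h1$src, g$h2$src))))
    src_h <- srcs[srcs <= pedigree$n_hap_h]
    src_l <- srcs[srcs > pedigree$n_hap_h]
    informative <- colSums(hap[src_h, , drop = FALSE]) == length(src_h) &
      colSums(hap[src_l, , drop = FALSE]) == 0L
    ci <- counts[counts$individual == ids[i], ]
    m <- match(paste(ci$chrom, ci$pos), key_p)
    out[i] <- mean(informative[m])
  }
  out
}

# Total bp of H-line origin of `hap` within each [start, end) interval.
hap_h_overlap <- function(hap, start, end, n_hap_h) {
  is_h <- hap$src <= n_hap_h
  seg_start <- c(0, hap$ends[-length(hap$ends)])
  seg_end <- hap$ends
  ks <- which(is_h)
  out <- numeric(length(start))
  for (k in ks) {
    ov <- pmin(end, seg_end[k]) - pmax(start, seg_start[k])
    out <- out + pmax(ov, 0)
  }
  out
}
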