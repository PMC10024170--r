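# Plain-text artifacts with '#'-prefixed header lines carrying provenance
# (seed, package version), so pipeline outputs stay diff-able.

write_commented <- function(df, path, meta = list(), sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(package = paste0("ailmap ", as.character(utils::packageVersion("ailmap")))),
            meta)
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
}

read_commented <- function(path, sep = "\t") {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write and read pipeline tables
#'
#' Writers emit plain TSV/CSV with `#`-prefixed provenance headers (seed,
#' package version); readers skip those headers. Tables: marker panel,
#' read counts, phenotypes (CSV), truth/estimated bin genotype matrices.
#'
#' @param x Object to write.
#' @param path File path.
#' @param meta Named list of extra provenance fields (e.g. `seed`).
#' @return Readers return the corresponding object; writers return the
#'   path invisibly.
#' @name ailmap_io
NULL

#' @rdname ailmap_io
#' @export
write_panel <- function(x, path, meta = list()) {
  write_commented(x, path, meta)
  invisible(path)
}

#' @rdname ailmap_io
#' @export
read_panel <- function(path) {
  out <- read_commented(path)
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' @rdname ailmap_io
#' @export
write_counts <- function(x, path, meta = list()) {
  write_commented(x, path, meta)
  invisible(path)
}

#' @rdname ailmap_io
#' @export
read_counts <- function(path) {
  out <- read_commented(path)
  out$chrom <- as.character(out$chrom)
  class(out) <- c("read_counts", "data.frame")
  out
}

#' @rdname ailmap_io
#' @export
write_phenotypes <- function(x, path, meta = list()) {
  write_commented(x, path, meta, sep = ",")
  invisible(path)
}

#' @rdname ailmap_io
#' @export
read_phenotypes <- function(path) {
  out <- read_commented(path, sep = ",")
  out$generation <- as.character(out$generation)
  out
}

#' @rdname ailmap_io
#' @export
write_geno_matrix <- function(x, path, meta = list()) {
  df <- data.frame(individual = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_commented(df, path, meta)
  invisible(path)
}

#' @rdname ailmap_io
#' @export
read_geno_matrix <- function(path) {
  df <- read_commented(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$individual
  parts <- strsplit(colnames(m), ":", fixed = TRUE)
  attr(m, "bins") <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.numeric(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  class(m) <- c("bin_genotypes", class(m))
  m
}

#' Write founder genotypes as VCF
#'
#' Emits a minimal VCF 4.2 with one sample per founder and a GT field,
#' using the H-labelled allele as REF and the L-labelled allele as ALT.
#'
#' @param founders An `ail_founders` object.
#' @param path Output path (uncompressed `.vcf`).
#' @return The path, invisibly.
#' @export
write_founder_vcf <- function(founders, path) {
  pt <- founders$panel_truth
  hap <- founders$haplotypes
  n_f <- length(founders$founder_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ailmap_simulator",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  for (cn in unique(pt$chrom))
    writeLines(sprintf("##contig=<ID=%s>", cn), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", founders$founder_id), collapse = "\t"),
             con)
  gt1 <- matrix(ifelse(hap[seq(1L, 2L * n_f, 2L), , drop = FALSE], "0", "1"),
                nrow = n_f)
  gt2 <- matrix(ifelse(hap[seq(2L, 2L * n_f, 2L), , drop = FALSE], "0", "1"),
                nrow = n_f)
  gt <- matrix(paste(gt1, gt2, sep = "/"), nrow = n_f)
  lines <- vapply(seq_len(nrow(pt)), function(i) {
    paste(c(pt$chrom[i], pt$pos[i], ".", pt$h_allele[i], pt$l_allele[i],
            ".", "PASS", ".", "GT", gt[, i]), collapse = "\t")
  }, "")
  writeLines(lines, con)
  invisible(path)
}

#' Read founder genotypes from VCF
#'
#' Parses a founder VCF into the site table and diploid allele-character
#' genotype matrix expected by [select_informative_markers()]. The founder
#' line is taken from the first character of each sample name (`H`/`L`)
#' unless given explicitly.
#'
#' @param path VCF path.
#' @param line Optional per-sample line labels (`"H"`/`"L"`).
#' @return List with `sites` (`chrom`, `pos`), `genotypes` (site x sample
#'   character matrix, `"A/G"` form) and `line`.
#' @export
read_founder_vcf <- function(path, line = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt_codes <- vcfR::extract.gt(v, element = "GT")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  conv <- function(code) {
    a1 <- substr(code, 1L, 1L)
    a2 <- substr(code, 3L, 3L)
    b1 <- ifelse(a1 == "0", ref, ifelse(a1 == "1", alt, NA))
    b2 <- ifelse(a2 == "0", ref, ifelse(a2 == "1", alt, NA))
    ifelse(is.na(b1) | is.na(b2), NA_character_, paste(b1, b2, sep = "/"))
  }
  g <- apply(gt_codes, 2L, conv)
  if (is.null(dim(g))) g <- matrix(g, nrow = nrow(gt_codes),
                                   dimnames = dimnames(gt_codes))
  if (is.null(line)) line <- substr(colnames(gt_codes), 1L, 1L)
  list(sites = data.frame(chrom = as.character(fix[, "CHROM"]),
                          pos = as.integer(fix[, "POS"]),
                          stringsAsFactors = FALSE),
       genotypes = g, line = line)
}
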