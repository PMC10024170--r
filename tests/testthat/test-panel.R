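test_that("fixed line differences are retained with the H allele assigned", {
  g <- rbind(c("A/A", "A/A", "G/G", "G/G"))
  sites <- data.frame(chrom = "1", pos = 100L)
  p <- select_informative_markers(g, c("H", "H", "L", "L"), sites)
  expect_identical(nrow(p), 1L)
  expect_identical(p$h_allele, "A")
  expect_identical(p$l_allele, "G")
  expect_equal(p$freq_h, 1)
  expect_equal(p$freq_l, 0)
})

test_that("uninformative and sub-gap sites are excluded", {
  # same frequency in both lines
  g <- rbind(c("A/G", "A/G", "A/G", "A/G"))
  sites <- data.frame(chrom = "1", pos = 1L)
  p <- select_informative_markers(g, c("H", "H", "L", "L"), sites,
                                  min_freq_gap = 0.1)
  expect_identical(nrow(p), 0L)

  # freq_h = 1.0, freq_l = 0.05 -> gap 0.95: kept at 0.9, dropped at 1.0
  nl <- 10L
  gt_l <- c("A/G", rep("G/G", nl - 1L))     # l-line freq of A = 0.05
  g2 <- matrix(c(rep("A/A", 4L), gt_l), nrow = 1L)
  line2 <- c(rep("H", 4L), rep("L", nl))
  sites2 <- data.frame(chrom = "1", pos = 5L)
  expect_identical(nrow(select_informative_markers(g2, line2, sites2,
                                                   min_freq_gap = 0.9)), 1L)
  expect_identical(nrow(select_informative_markers(g2, line2, sites2,
                                                   min_freq_gap = 1.0)), 0L)
})

test_that("multi-allelic sites are skipped with a warning and missing calls ignored", {
  g <- rbind(c("A/C", "G/G", "T/T", "T/T"),
             c("A/A", NA, "G/G", "./."))
  sites <- data.frame(chrom = "1", pos = c(10L, 20L))
  expect_warning(p <- select_informative_markers(g, c("H", "H", "L", "L"),
                                                 sites),
                 "more than 2 alleles")
  # site 2: frequencies over non-missing calls only -> fixed difference
  expect_identical(p$pos, 20L)
  expect_equal(p$freq_h, 1)
})

test_that("panel built from fully fixed simulated founders is the marker set", {
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 2e6,
                                             cm_per_mb = 1),
                    p_fixed = 1, seed = 15)
  f <- simulate_founders(cfg)
  g <- founder_genotypes(f)
  p <- select_informative_markers(g, f$line, f$panel_truth[, c("chrom", "pos")])
  expect_identical(p$pos, f$panel_truth$pos)
  expect_identical(p$h_allele, f$panel_truth$h_allele)
  expect_true(all(p$freq_h > p$freq_l))
})

test_that("decreasing the frequency gap never removes markers", {
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 3e6,
                                             cm_per_mb = 1),
                    p_fixed = 0.4, within_line_maf = 0.3, seed = 16)
  f <- simulate_founders(cfg)
  g <- founder_genotypes(f)
  sites <- f$panel_truth[, c("chrom", "pos")]
  sizes <- vapply(c(1, 0.9, 0.7, 0.5, 0.3),
                  function(gap) nrow(select_informative_markers(g, f$line,
                                                                sites, gap)),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("line-allele counts are extracted and reads conserved", {
  panel <- data.frame(chrom = "1", pos = c(100L, 200L),
                      h_allele = c("A", "C"), l_allele = c("G", "T"),
                      freq_h = 1, freq_l = 0, stringsAsFactors = FALSE)
  class(panel) <- c("marker_panel", "data.frame")
  v <- data.frame(
    individual = c("i1", "i1", "i1", "i1", "i2", "i2"),
    chrom = "1",
    pos = c(100L, 100L, 200L, 300L, 100L, 200L),
    allele = c("A", "G", "T", "A", "A", "C"),
    count = c(2L, 1L, 1L, 5L, 1L, 3L),
    stringsAsFactors = FALSE
  )
  cnt <- extract_line_counts(v, panel)
  # site not in panel (pos 300) contributes nothing
  expect_identical(nrow(cnt), 4L)
  expect_identical(cnt$n_h[cnt$individual == "i1" & cnt$pos == 100L], 2L)
  expect_identical(cnt$n_l[cnt$individual == "i1" & cnt$pos == 100L], 1L)
  expect_identical(cnt$n_l[cnt$individual == "i1" & cnt$pos == 200L], 1L)
  expect_identical(attr(cnt, "dropped_reads"), 0L)
  # conservation: n_h + n_l + dropped = reads at panel sites
  v$allele[6] <- "G"                       # read matching neither allele
  cnt2 <- extract_line_counts(v, panel)
  at_panel <- sum(v$count[v$pos %in% panel$pos])
  expect_identical(sum(cnt2$n_h) + sum(cnt2$n_l) + attr(cnt2, "dropped_reads"),
                   at_panel)
  expect_message(extract_line_counts(v, panel, individuals = c("i1", "i2", "i3")),
                 "i3")
})

test_that("informative fraction reproduces simple arithmetic and bounds", {
  cnt <- data.frame(individual = rep("i1", 4700), chrom = "1",
                    pos = seq_len(4700), n_h = 1L, n_l = 0L)
  frac <- informative_fraction(cnt, c(i1 = 100000))
  expect_equal(unname(frac), 0.047)
  frac0 <- informative_fraction(cnt[0, ], c(i1 = 1000))
  expect_equal(unname(frac0), 0)
  expect_warning(fr <- informative_fraction(cnt, c(i1 = 100000, i2 = 0)),
                 "zero covered")
  expect_true(is.na(fr["i2"]))
  # property: randomized tables stay in [0, 1]
  set.seed(1)
  for (r in 1:20) {
    n <- sample(1:50, 1)
    tot <- sample(50:100, 3)
    names(tot) <- c("a", "b", "c")
    cnt_r <- data.frame(individual = sample(names(tot), n, TRUE),
                        chrom = "1", pos = sample(1e4, n), n_h = 1L, n_l = 0L)
    fr <- informative_fraction(cnt_r, tot)
    expect_true(all(fr >= 0 & fr <= 1, na.rm = TRUE))
  }
})

test_that("founder VCF round-trips through vcfR into the same panel", {
  cfg <- ail_config(chromosomes = data.frame(chrom = c("1", "2"),
                                             length = c(1e6, 5e5),
                                             cm_per_mb = 1),
                    p_fixed = 0.8, seed = 44)
  f <- simulate_founders(cfg)
  vcf <- tempfile(fileext = ".vcf")
  write_founder_vcf(f, vcf)
  fv <- read_founder_vcf(vcf)
  expect_identical(fv$line, f$line)
  expect_identical(fv$sites$pos, f$panel_truth$pos)
  p_direct <- select_informative_markers(founder_genotypes(f), f$line,
                                         f$panel_truth[, c("chrom", "pos")])
  p_vcf <- select_informative_markers(fv$genotypes, fv$line, fv$sites)
  expect_equal(p_vcf, p_direct)
  unlink(vcf)
})
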