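test_that("configuration validation rejects impossible designs", {
  expect_error(ail_config(chromosomes = data.frame(chrom = character(0),
                                                   length = numeric(0),
                                                   cm_per_mb = numeric(0))),
               "at least one chromosome")
  expect_error(ail_config(p_fixed = 1.2), "p_fixed")
  expect_error(ail_config(seq_error = 0.5), "seq_error")
  expect_error(ail_config(generation_sizes = c(F1 = 1)), "at least 2")
  expect_error(ail_config(markers_per_mb = 0.001,
                          chromosomes = data.frame(chrom = "1", length = 2e6,
                                                   cm_per_mb = 1)),
               "zero markers")
  expect_error(ail_config(qtl = data.frame(chrom = "9", pos = 1e6,
                                           a = 1, d = 0)),
               "unsimulated chromosome")
  expect_error(ail_config(qtl = data.frame(chrom = "1", pos = 99e6,
                                           a = 1, d = 0)),
               "outside its chromosome")
})

test_that("fixed-difference founders are homozygous by line", {
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 2e6,
                                             cm_per_mb = 1),
                    p_fixed = 1, seed = 7)
  f <- simulate_founders(cfg)
  n_hap_h <- 2L * cfg$n_founders_high
  expect_true(all(f$haplotypes[seq_len(n_hap_h), ]))
  expect_false(any(f$haplotypes[-seq_len(n_hap_h), ]))
  expect_true(all(f$panel_truth$fixed))
  expect_true(all(f$panel_truth$h_allele != f$panel_truth$l_allele))
  # positions strictly increasing within chromosome
  expect_true(all(diff(f$panel_truth$pos) > 0))
})

test_that("within-line allele frequencies match the configured point mass", {
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 5e6,
                                             cm_per_mb = 1),
                    p_fixed = 0, within_line_maf = 0.5, seed = 8)
  f <- simulate_founders(cfg)
  n_hap_h <- 2L * cfg$n_founders_high
  freq_h <- colMeans(f$haplotypes[seq_len(n_hap_h), ])
  freq_l <- colMeans(f$haplotypes[-seq_len(n_hap_h), ])
  n_mark <- ncol(f$haplotypes)
  # overall mean within 3 SE of the binomial sampling distribution
  se_h <- sqrt(0.25 / (n_hap_h * n_mark))
  expect_lt(abs(mean(freq_h) - 0.5), 3 * se_h)
  expect_lt(abs(mean(freq_l) - 0.5), 3 * sqrt(0.25 / (60 * n_mark)))
  # and per-marker frequencies consistent with Binomial(2n, 0.5)
  expect_gt(mean(abs(freq_h - 0.5) <= 3 * sqrt(0.25 / n_hap_h)), 0.99)
})

test_that("same seed reproduces the simulation exactly", {
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 3e6,
                                             cm_per_mb = 1),
                    generation_sizes = c(F1 = 6, F2 = 10), seed = 99)
  s1 <- simulate_ail(cfg)
  s2 <- simulate_ail(cfg)
  expect_identical(s1$founders$haplotypes, s2$founders$haplotypes)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$phenotypes$phenotypes, s2$phenotypes$phenotypes)
  expect_identical(s1$truth_bins, s2$truth_bins)
})

test_that("zero map length gives unrecombined parental haplotypes", {
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 5e6,
                                             cm_per_mb = 0),
                    generation_sizes = c(F1 = 6, F2 = 10), seed = 3)
  ped <- simulate_pedigree(simulate_founders(cfg), cfg)
  segs <- vapply(ped$genomes, function(g)
    max(length(g[[1]]$h1$src), length(g[[1]]$h2$src)), numeric(1))
  expect_true(all(segs == 1))
})

test_that("meiosis draws Poisson crossovers with the map-length mean", {
  set.seed(41)
  h1 <- ailmap:::new_hap(100e6, 1L)
  h2 <- ailmap:::new_hap(100e6, 2L)
  k <- vapply(seq_len(10000), function(i) {
    g <- ailmap:::meiose(h1, h2, 100e6, morgans = 1)
    length(g$src) - 1L
  }, integer(1))
  expect_gte(mean(k), 0.97)
  expect_lte(mean(k), 1.03)
})

test_that("F1 individuals are heterozygous everywhere under fixed lines", {
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 10e6,
                                             cm_per_mb = 1),
                    p_fixed = 1, generation_sizes = c(F1 = 12, F2 = 4),
                    seed = 5)
  ped <- simulate_pedigree(simulate_founders(cfg), cfg)
  tb <- truth_bins(ped, ids = grep("^F1", ped$individuals$id, value = TRUE))
  expect_true(all(tb == 0))
})

test_that("mosaic segments tile chromosomes exactly", {
  cfg <- ail_config(chromosomes = data.frame(chrom = c("1", "2"),
                                             length = c(7e6, 3e6),
                                             cm_per_mb = c(2, 1)),
                    generation_sizes = c(F1 = 8, F2 = 12, F3 = 12), seed = 21)
  ped <- simulate_pedigree(simulate_founders(cfg), cfg)
  for (g in ped$genomes) {
    for (c in 1:2) {
      for (h in c("h1", "h2")) {
        ends <- g[[c]][[h]]$ends
        expect_identical(ends[length(ends)], cfg$chromosomes$length[c])
        expect_true(all(diff(ends) > 0))
        expect_identical(length(ends), length(g[[c]][[h]]$src))
      }
    }
  }
})

test_that("F2 heterozygosity at fixed markers is near one half", {
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 10e6,
                                             cm_per_mb = 1),
                    generation_sizes = c(F1 = 40, F2 = 500), seed = 31)
  ped <- simulate_pedigree(simulate_founders(cfg), cfg)
  ids <- grep("^F2", ped$individuals$id, value = TRUE)
  pos <- c(2e6, 5e6, 8e6)
  het <- vapply(ids, function(id) {
    g <- ped$genomes[[id]][[1]]
    mean(ailmap:::hap_is_h(g$h1, pos, ped$n_hap_h) !=
           ailmap:::hap_is_h(g$h2, pos, ped$n_hap_h))
  }, numeric(1))
  expect_lt(abs(mean(het) - 0.5), 3 * sqrt(0.25 / length(ids)))
})

test_that("phenotype decomposition sums to the weight and scales linearly", {
  qtl <- data.frame(chrom = "1", pos = 5e6, a = 40, d = 10)
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 10e6,
                                             cm_per_mb = 1),
                    generation_sizes = c(F1 = 10, F2 = 40), qtl = qtl,
                    seed = 17)
  ped <- simulate_pedigree(simulate_founders(cfg), cfg)
  ph <- simulate_phenotypes(ped, cfg)
  with_parts <- ph$truth$genetic_value + ph$truth$sex_term +
    ph$truth$generation_term + ph$truth$residual
  expect_equal(ph$phenotypes$weight, with_parts)

  # doubling a doubles the genetic gap between opposite homozygotes
  cfg2 <- ail_config(chromosomes = cfg$chromosomes,
                     generation_sizes = cfg$generation_sizes,
                     qtl = transform(qtl, a = 80), seed = 17)
  ph2 <- simulate_phenotypes(ped, cfg2)
  x <- ph$qtl_x[, 1]
  if (any(x == 1) && any(x == -1)) {
    gap1 <- mean(ph$truth$genetic_value[x == 1]) -
      mean(ph$truth$genetic_value[x == -1])
    gap2 <- mean(ph2$truth$genetic_value[x == 1]) -
      mean(ph2$truth$genetic_value[x == -1])
    expect_equal(gap2, 2 * gap1)
  }
})

test_that("noise-free weights are exact arithmetic", {
  qtl <- data.frame(chrom = "1", pos = 5e6, a = 40, d = 10)
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 10e6,
                                             cm_per_mb = 1),
                    generation_sizes = c(F1 = 10, F2 = 60), qtl = qtl,
                    residual_sd = 0, sex_effect = 150, default_mean = 900,
                    seed = 13)
  ped <- simulate_pedigree(simulate_founders(cfg), cfg)
  ph <- simulate_phenotypes(ped, cfg)
  hom_h <- which(ph$qtl_x[, 1] == 1)
  expect_gt(length(hom_h), 0)
  i <- hom_h[1]
  sex_term <- ifelse(ph$phenotypes$sex[i] == "M", 150, 0)
  expect_equal(ph$phenotypes$weight[i], 900 + sex_term + 40)
})

test_that("phenotype variance matches the residual model without QTL", {
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 2e6,
                                             cm_per_mb = 1),
                    generation_sizes = c(F1 = 10, F2 = 1000),
                    sex_effect = 0, default_mean = 0, residual_sd = 100,
                    seed = 23)
  ped <- simulate_pedigree(simulate_founders(cfg), cfg)
  ph <- simulate_phenotypes(ped, cfg)
  w <- ph$phenotypes$weight[ph$phenotypes$generation == "F2"]
  se_var <- 100^2 * sqrt(2 / (length(w) - 1))
  expect_lt(abs(var(w) - 100^2), 3 * se_var)
})

test_that("read simulation respects depth and error models", {
  cfg0 <- ail_config(chromosomes = data.frame(chrom = "1", length = 2e6,
                                              cm_per_mb = 1),
                     generation_sizes = c(F1 = 4, F2 = 4), coverage = 0,
                     seed = 2)
  sim0 <- simulate_ail(cfg0)
  expect_identical(nrow(sim0$counts), 0L)

  # error-free reads from an all-H genome carry only the H allele
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 2e6,
                                             cm_per_mb = 1),
                    p_fixed = 1, seq_error = 0, seed = 6)
  founders <- simulate_founders(cfg)
  hom_ped <- structure(list(
    individuals = data.frame(id = "X1", generation = "F0", sex = "F",
                             stringsAsFactors = FALSE),
    genomes = list(X1 = list(list(h1 = ailmap:::new_hap(2e6, 1L),
                                  h2 = ailmap:::new_hap(2e6, 3L)))),
    chromosomes = cfg$chromosomes, n_hap_h = 58L), class = "ail_pedigree")
  cnt <- simulate_reads(hom_ped, founders, cfg)
  expect_gt(nrow(cnt), 0)
  expect_true(all(cnt$n_l == 0))
  expect_true(all(cnt$n_h >= 1))

  # mean depth over many marker-individual pairs matches the Poisson mean
  cfg2 <- ail_config(chromosomes = data.frame(chrom = "1", length = 10e6,
                                              cm_per_mb = 1),
                     generation_sizes = c(F1 = 10, F2 = 100),
                     coverage = 0.4, seed = 9)
  sim2 <- simulate_ail(cfg2)
  n_pairs <- 1000 * (10 + 100)
  mean_depth <- sum(sim2$counts$n_h + sim2$counts$n_l) / n_pairs
  expect_lt(abs(mean_depth - 0.4), 3 * sqrt(0.4 / n_pairs))
})

test_that("personally informative markers decline over generations", {
  gs <- c(F1 = 20, F2 = 20, F5 = 20, F9 = 20)
  names(gs) <- c("F1", "F2", "F5", "F9")   # labels only; breeding is serial
  cfg <- ail_config(chromosomes = data.frame(chrom = "1", length = 10e6,
                                             cm_per_mb = 1),
                    p_fixed = 0.3, generation_sizes = gs, seed = 77)
  founders <- simulate_founders(cfg)
  ped <- simulate_pedigree(founders, cfg)
  cnt <- simulate_reads(ped, founders, cfg)
  frac <- personal_informative_fraction(ped, founders, cnt)
  gen <- ped$individuals$generation[match(names(frac), ped$individuals$id)]
  means <- tapply(frac, gen, mean)[c("F2", "F5", "F9")]
  expect_true(all(diff(means) < 0))
  expect_true(all(frac >= cfg$p_fixed - 0.05))
})
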