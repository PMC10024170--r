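toy_phen <- function(z, sex, weight = NULL, gen = "F2") {
  n <- length(z)
  out <- data.frame(id = sprintf("i%03d", seq_len(n)), generation = gen,
                    sex = sex, weight = if (is.null(weight)) z else weight,
                    z = z, stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

toy_geno <- function(scores) {
  m <- as.matrix(scores)
  rownames(m) <- sprintf("i%03d", seq_len(nrow(m)))
  colnames(m) <- paste0("1:", (seq_len(ncol(m)) - 1L) * 1e6)
  m
}

test_that("standardization centers and scales within generation", {
  phen <- data.frame(id = c("a", "b", "c"), generation = "F2",
                     sex = "F", weight = c(100, 200, 300))
  out <- standardize(phen)
  expect_equal(out$z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  phen2 <- rbind(phen,
                 data.frame(id = c("d", "e"), generation = "F3", sex = "M",
                            weight = c(1000, 1200)))
  out2 <- standardize(phen2)
  for (g in c("F2", "F3")) {
    expect_lt(abs(mean(out2$z[out2$generation == g])), 1e-9)
    zg <- out2$z[out2$generation == g]
    expect_lt(abs(sqrt(mean((zg - mean(zg))^2)) - 1), 1e-9)
  }

  # idempotence on already standardized data
  out3 <- standardize(transform(out, weight = z))
  expect_equal(out3$z, out$z, tolerance = 1e-12)

  # zero-variance generation excluded with a warning
  phen3 <- rbind(phen, data.frame(id = c("f", "g"), generation = "F4",
                                  sex = "F", weight = c(5, 5)))
  expect_warning(out4 <- standardize(phen3), "F4")
  expect_false("F4" %in% out4$generation)
})

test_that("bin scores map to additive and dominance regressors", {
  expect_equal(unname(regressors(1)), cbind(1, 0), ignore_attr = TRUE)
  expect_equal(unname(regressors(0)), cbind(0, 1), ignore_attr = TRUE)
  expect_equal(unname(regressors(-1)), cbind(-1, 0), ignore_attr = TRUE)
  expect_equal(unname(regressors(0.9)), cbind(0.9, 0.1), ignore_attr = TRUE)
  expect_error(regressors(1.5))
})

test_that("scan LOD matches the independent least-squares oracle", {
  set.seed(77)
  for (trial in 1:100) {
    n <- sample(20:200, 1)
    score <- sample(c(-1, 0, 1), n, replace = TRUE)
    sex <- rbinom(n, 1, 0.5)
    z <- 0.2 * score + 0.1 * sex + rnorm(n)
    z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
    geno <- toy_geno(cbind(score))
    phen <- toy_phen(z, ifelse(sex == 1, "M", "F"))
    sc <- hk_scan(geno, phen)
    expect_equal(sc$lod, ols_lod(z, sex, score, 1 - abs(score)),
                 tolerance = 1e-8)
  }
})

test_that("constant bins score zero and duplication doubles the LOD", {
  set.seed(8)
  n <- 60
  score <- sample(c(-1, 0, 1), n, replace = TRUE)
  z <- 0.3 * score + rnorm(n)
  sex <- sample(c("M", "F"), n, TRUE)
  geno <- toy_geno(cbind(rep(1, n), score))
  phen <- toy_phen(z, sex)
  sc <- hk_scan(geno, phen)
  expect_equal(sc$lod[1], 0)
  # duplicating every observation doubles n and hence the LOD
  geno2 <- rbind(geno, geno)
  rownames(geno2) <- sprintf("i%03d", seq_len(2 * n))
  phen2 <- toy_phen(rep(z, 2), rep(sex, 2))
  sc2 <- hk_scan(geno2, phen2)
  expect_equal(sc2$lod[2], 2 * sc$lod[2], tolerance = 1e-8)
})

test_that("missing scores are mean-imputed and complete-case mode agrees with an oracle", {
  set.seed(9)
  n <- 80
  score <- sample(c(-1, 0, 1), n, replace = TRUE)
  score[sample(n, 15)] <- NA
  z <- rnorm(n)
  sex <- rbinom(n, 1, 0.5)
  geno <- toy_geno(cbind(score))
  phen <- toy_phen(z, ifelse(sex == 1, "M", "F"))
  imp <- ifelse(is.na(score), mean(score, na.rm = TRUE), score)
  sc <- hk_scan(geno, phen)
  expect_equal(sc$lod, ols_lod(z, sex, imp, 1 - abs(imp)), tolerance = 1e-8)
  obs <- !is.na(score)
  sc_cc <- hk_scan(geno, phen, impute = "complete")
  expect_equal(sc_cc$lod,
               ols_lod(z[obs], sex[obs], score[obs], 1 - abs(score[obs])),
               tolerance = 1e-8)
  expect_identical(sc_cc$n_used, sum(obs))
})

test_that("permutation thresholds are reproducible and monotone in alpha", {
  set.seed(10)
  n <- 100
  geno <- toy_geno(matrix(sample(c(-1, 0, 1), n * 5, TRUE), n))
  phen <- toy_phen(rnorm(n), sample(c("M", "F"), n, TRUE))
  t1 <- permutation_threshold(geno, phen, n_perm = 200, seed = 3)
  t2 <- permutation_threshold(geno, phen, n_perm = 200, seed = 3)
  expect_identical(as.numeric(t1), as.numeric(t2))
  ml <- attr(t1, "max_lods")
  expect_identical(length(ml), 200L)
  q <- vapply(c(0.2, 0.1, 0.05, 0.01), function(a)
    quantile(ml, 1 - a, names = FALSE), numeric(1))
  expect_true(all(diff(q) >= 0))
})

test_that("LOD to p-value conversion uses the 2-df chi-square tail", {
  expect_equal(lod_to_p(0), 1)
  expect_equal(lod_to_p(4.01), 9.77e-5, tolerance = 1e-2)
  expect_equal(lod_to_p(4.01),
               pchisq(2 * log(10) * 4.01, df = 2, lower.tail = FALSE))
  lods <- seq(0, 10, by = 0.5)
  expect_true(all(diff(lod_to_p(lods)) < 0))
})

test_that("FDR selection matches the textbook step-up rule", {
  p <- c(0.001, rep(0.5, 9))
  expect_identical(fdr_select(p, q = 0.1), 1L)
  expect_identical(fdr_select(rep(1, 20), q = 0.1), integer(0))
  set.seed(11)
  for (trial in 1:1000) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.3)
    expect_identical(fdr_select(p, q), bh_oracle(p, q))
  }
})

test_that("selected bins collapse into distance-merged peaks with tiers", {
  scan <- data.frame(chrom = rep(c("1", "2"), c(40, 30)),
                     start = c((0:39) * 1e6, (0:29) * 1e6),
                     lod = 0.1, a_hat = 0, d_hat = 0, se_a = 0.1,
                     stringsAsFactors = FALSE)
  scan$lod[c(5, 8, 30, 45)] <- c(6, 5, 4.5, 3.8)
  class(scan) <- c("ail_scan", "data.frame")
  # bins 5 and 8 are 3 Mb apart -> one QTL; bin 30 is > 15 Mb away
  q <- collapse_peaks(scan, c(5, 8, 30, 45), threshold = 4.01)
  expect_identical(nrow(q), 3L)
  expect_equal(q$lod, c(6, 4.5, 3.8))
  expect_identical(q$tier, c("genome-wide", "genome-wide", "FDR-suggestive"))
  expect_identical(q$chrom, c("1", "1", "2"))
  # bins on different chromosomes never merge even when starts are close
  q2 <- collapse_peaks(scan, c(40, 41), threshold = 4.01)
  expect_identical(nrow(q2), 2L)
  expect_identical(nrow(collapse_peaks(scan, integer(0), 4.01)), 0L)
})

test_that("drop-one variance accounting matches marginal and orthogonal oracles", {
  set.seed(12)
  n <- 400
  s1 <- sample(c(-1, 0, 1), n, TRUE)
  z <- 0.4 * s1 + rnorm(n)
  z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  phen <- toy_phen(z, rep(c("M", "F"), n / 2))
  geno <- toy_geno(cbind(s1))
  jt <- fit_multi_qtl(geno, phen, 1)
  sex <- as.numeric(phen$sex == "M")
  r <- residuals(lm(z ~ sex))
  marg <- summary(lm(r ~ s1 + I(1 - abs(s1))))$r.squared
  expect_equal(jt$pct_var, 100 * marg, tolerance = 1e-6)

  # orthogonal design: drop-one contributions sum to the joint R-squared
  s2 <- rep(c(-1, 1), n / 2)                       # balanced, independent
  s3 <- rep(c(-1, 1), each = n / 2)
  z2 <- 0.3 * s2 + 0.2 * s3 + rnorm(n)
  phen2 <- toy_phen(z2, rep("F", n))
  geno2 <- toy_geno(cbind(s2, s3))
  jt2 <- fit_multi_qtl(geno2, phen2, 1:2)
  r2j <- attr(jt2, "r2_joint")
  # s2 and s3 here are orthogonal and purely additive
  expect_equal(sum(jt2$pct_var), r2j, tolerance = 1e-6)

  # duplicated QTL exercises the rank-deficiency path
  geno3 <- toy_geno(cbind(s1, s1))
  expect_warning(jt3 <- fit_multi_qtl(geno3, phen, 1:2), "rank deficiency")
  expect_identical(nrow(jt3), 1L)
})

test_that("published additive effects account for the line difference", {
  tab <- virginia_qtl_table()
  expect_identical(nrow(tab), 12L)
  acc <- line_difference_accounting(tab$a_g)
  expect_equal(acc$sum_a, 250.7, tolerance = 1e-9)
  expect_equal(acc$two_sum_a, 501.4, tolerance = 1e-9)
  expect_equal(acc$fraction_pct, 37.4, tolerance = 0.05)
})

test_that("grams conversion multiplies standardized effects by the population SD", {
  set.seed(13)
  n <- 200
  s <- sample(c(-1, 0, 1), n, TRUE)
  w <- 900 + 50 * s + rnorm(n, 0, 100)
  phen <- standardize(data.frame(id = sprintf("i%03d", 1:n),
                                 generation = "F2", sex = "F", weight = w))
  geno <- toy_geno(cbind(s))
  eff <- qtl_effects(geno, phen, 1)
  sd_pop <- sqrt(mean((w - mean(w))^2))
  expect_equal(attr(eff, "sd_pop"), sd_pop)
  expect_equal(eff$a_g, eff$a_std * sd_pop)
  expect_equal(eff$a_g, 50, tolerance = 3 * eff$se_g)
  # explicit SD override: a_std 0.5 at SD 100 g is 50 g
  eff2 <- qtl_effects(geno, phen, 1, sd_pop = 100)
  expect_equal(eff2$a_g, eff2$a_std * 100)
})

test_that("information content is the variance combination of the regressors", {
  # exact F2 frequencies: 1/4, 1/2, 1/4
  s <- rep(c(1, 0, -1), c(25, 50, 25))
  expect_equal(unname(information_content(s)), 1)
  expect_equal(unname(information_content(rep(0, 50))), 0)
  expect_equal(unname(information_content(rep(1, 50))), 0)
  expect_true(is.na(information_content(c(1, rep(NA, 9)))))
  # an even homozygote split has maximal additive variance
  expect_equal(unname(information_content(rep(c(1, -1), 25))), 1)
  set.seed(14)
  r <- information_content(matrix(runif(500, -1, 1), 50))
  expect_true(all(r >= 0 & r <= 1.5))
})
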