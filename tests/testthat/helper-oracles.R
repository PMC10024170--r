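# Independent oracles and fixture builders shared across test files.

# nearest hard state of a continuous bin score
near_state <- function(x) round(pmax(pmin(x, 1), -1))

# brute-force Haley-Knott LOD by explicit normal equations
ols_lod <- function(z, sex, a, d) {
  n <- length(z)
  X1 <- cbind(1, sex, a, d)
  X0 <- cbind(1, sex)
  b1 <- solve(t(X1) %*% X1, t(X1) %*% z)
  b0 <- solve(t(X0) %*% X0, t(X0) %*% z)
  rss1 <- sum((z - X1 %*% b1)^2)
  rss0 <- sum((z - X0 %*% b0)^2)
  (n / 2) * log10(rss0 / rss1)
}

# textbook Benjamini-Hochberg step-up selection
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= q * seq_len(m) / m)
  if (length(k) == 0L) return(integer(0))
  sort(o[seq_len(max(k))])
}

# exhaustive most-probable 3-state path (log-space), for small n
enum_path <- function(le, rho) {
  n <- ncol(le)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  lp <- log(1 / 3) + le[cbind(paths[, 1L], 1L)]
  if (n > 1L) {
    for (t in 2:n) {
      lp <- lp + le[cbind(paths[, t], t)] +
        ifelse(paths[, t] == paths[, t - 1L], log(1 - 2 * rho), log(rho))
    }
  }
  unname(paths[which.max(lp), ])
}

# counts fixture: one individual-chromosome table from per-marker H/L reads
make_counts <- function(pos, n_h, n_l) {
  data.frame(pos = pos, n_h = n_h, n_l = n_l)
}

# small simulated cohort reused by genotyper tests
small_f2_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- ail_config(
        chromosomes = data.frame(chrom = c("1", "2"),
                                 length = c(15e6, 8e6), cm_per_mb = 1),
        generation_sizes = c(F1 = 16, F2 = 30),
        qtl = data.frame(chrom = "1", pos = 6e6, a = 60, d = 0),
        seed = 424
      )
      cache <<- simulate_ail(cfg)
    }
    cache
  }
})
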