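#' Standardize phenotypes within generation
#'
#' Computes z-scores within each generation: the generation mean is
#' subtracted and the result divided by the within-generation standard
#' deviation (population convention, divide by n). This removes
#' generational batch effects without the overcorrection risk of fitting
#' generation as a random or fixed effect in the presence of kinship.
#'
#' @param phen `data.frame` with `id`, `generation`, `sex`, `weight`.
#' @return The table with a `z` column appended, class `phenotype_table`.
#'   Generations with zero weight variance are excluded with a warning.
#' @export
standardize <- function(phen) {
  stopifnot(all(c("id", "generation", "weight") %in% names(phen)))
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  keep <- rep(TRUE, nrow(phen))
  z <- rep(NA_real_, nrow(phen))
  for (g in unique(phen$generation)) {
    i <- phen$generation == g
    s <- sd_pop(phen$weight[i])
    if (sum(i) < 2L || s < 1e-12) {
      warning(sprintf("generation %s excluded: zero weight SD", g))
      keep[i] <- FALSE
      next
    }
    z[i] <- (phen$weight[i] - mean(phen$weight[i])) / s
  }
  out <- phen[keep, , drop = FALSE]
  out$z <- z[keep]
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Additive and dominance regressors from a bin genotype score
#'
#' Maps the continuous line-origin score to Haley-Knott regressors:
#' `a = P(hom H) - P(hom L)` and `d = P(het)`. Consistent with hard calls
#' (score 1 -> (1, 0); score 0 -> (0, 1); score -1 -> (-1, 0)), the linear
#' extension used for fractional scores is `a = score`,
#' `d = 1 - |score|`.
#'
#' @param score Numeric scores in \[-1, 1\] (`NA` allowed; propagated and
#'   left for imputation downstream).
#' @return Matrix with columns `a` and `d`.
#' @export
regressors <- function(score) {
  stopifnot(all(abs(score) <= 1 + 1e-9, na.rm = TRUE))
  cbind(a = score, d = 1 - abs(score))
}

# Closed-form Haley-Knott least squares via crossproducts.
#
# Fits z ~ 1 + sex + a + d against the null z ~ 1 + sex for every bin, for
# the observed data and (optionally) many joint permutations of (z, sex)
# against the genotype rows, without refitting: all permutation-dependent
# quantities reduce to the crossproducts t(A) %*% sex_p and t(A) %*% z_p,
# so one matrix product per regressor block serves every bin and
# permutation. Returns LOD, effect estimates and their variance factors.
hk_engine <- function(A, D, sex, z, perm = NULL) {
  n <- length(z)
  B <- ncol(A)
  Ss <- sum(sex); Sss <- sum(sex * sex)
  det0 <- n * Sss - Ss * Ss
  if (det0 <= 0) {                      # constant covariate: intercept only
    sex <- rep(0, n); Ss <- 0; Sss <- 0
    i11 <- 1 / n; i12 <- 0; i22 <- 0
    inv <- c(i11, i12, i22)
  } else {
    inv <- c(Sss, -Ss, n) / det0        # (X0'X0)^{-1} entries 11, 12, 22
  }
  i11 <- inv[1]; i12 <- inv[2]; i22 <- inv[3]
  Sy <- sum(z); Syy <- sum(z * z); Ssy <- sum(sex * z)
  w1 <- i11 * Sy + i12 * Ssy
  w2 <- i12 * Sy + i22 * Ssy
  RSS0 <- Syy - (Sy * w1 + Ssy * w2)

  Sa <- colSums(A); Sd <- colSums(D)
  Saa <- colSums(A * A); Sdd <- colSums(D * D); Sad <- colSums(A * D)

  if (is.null(perm)) {
    SX <- cbind(crossprod(A, sex), crossprod(D, sex),
                crossprod(A, z), crossprod(D, z))
    sa <- SX[, 1]; sd_ <- SX[, 2]; ya <- SX[, 3]; yd <- SX[, 4]
    P <- 1L
  } else {
    P <- ncol(perm)
    Sp <- matrix(sex[perm], n, P)
    Zp <- matrix(z[perm], n, P)
    sa <- crossprod(A, Sp); sd_ <- crossprod(D, Sp)
    ya <- crossprod(A, Zp); yd <- crossprod(D, Zp)
  }

  u1 <- ya - w1 * Sa - w2 * sa
  u2 <- yd - w1 * Sd - w2 * sd_
  A11 <- Saa - (i11 * Sa * Sa + 2 * i12 * Sa * sa + i22 * sa * sa)
  A12 <- Sad - (i11 * Sa * Sd + i12 * (Sa * sd_ + sa * Sd) + i22 * sa * sd_)
  A22 <- Sdd - (i11 * Sd * Sd + 2 * i12 * Sd * sd_ + i22 * sd_ * sd_)
  det <- A11 * A22 - A12 * A12
  scale <- pmax(abs(A11) * abs(A22), 1e-12)
  ok <- det > 1e-10 * scale

  drss <- (u1 * u1 * A22 - 2 * u1 * u2 * A12 + u2 * u2 * A11) / det
  a_hat <- (A22 * u1 - A12 * u2) / det
  d_hat <- (A11 * u2 - A12 * u1) / det
  va <- A22 / det                       # var(a_hat) = sigma^2 * va
  # rank-deficient bins: fall back to the largest usable single regressor
  if (any(!ok)) {
    one_a <- !ok & A11 > 1e-10
    one_d <- !ok & !one_a & A22 > 1e-10
    drss[!ok] <- 0
    a_hat[!ok] <- 0; d_hat[!ok] <- 0; va[!ok] <- NA_real_
    drss[one_a] <- (u1 * u1 / A11)[one_a]
    a_hat[one_a] <- (u1 / A11)[one_a]
    va[one_a] <- (1 / A11)[one_a]
    drss[one_d] <- (u2 * u2 / A22)[one_d]
    d_hat[one_d] <- (u2 / A22)[one_d]
  }
  drss <- pmin(pmax(drss, 0), RSS0)
  RSS1 <- RSS0 - drss
  list(n = n, RSS0 = RSS0, RSS1 = RSS1,
       lod = (n / 2) * log10(RSS0 / pmax(RSS1, .Machine$double.xmin)),
       a_hat = a_hat, d_hat = d_hat, va = va)
}

# Mean-impute missing scores per bin and derive (A, D) regressor matrices.
impute_regressors <- function(geno) {
  A <- as.matrix(geno)
  cm <- colMeans(A, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(A))
  if (length(idx)) A[idx] <- cm[(idx - 1L) %/% nrow(A) + 1L]
  list(A = A, D = 1 - abs(A))
}

# Align genotype rows with phenotype rows by individual id.
match_geno_phen <- function(geno, phen) {
  ids <- intersect(rownames(geno), phen$id)
  if (length(ids) < 2L)
    stop("fewer than 2 individuals shared between genotypes and phenotypes")
  dropped <- nrow(phen) - length(ids)
  if (dropped > 0)
    message(sprintf("%d phenotyped individual(s) without genotypes dropped",
                    dropped))
  phen <- phen[match(ids, phen$id), , drop = FALSE]
  list(geno = geno[ids, , drop = FALSE], phen = phen)
}

#' Haley-Knott genome scan
#'
#' Regresses standardized weight on the additive and dominance regressors
#' of every 1 Mb bin with sex as a covariate, reporting
#' `LOD = (n/2) log10(RSS0/RSS1)` against the null model with sex only.
#' Missing bin scores are mean-imputed per bin (keeping n constant across
#' bins); `impute = "complete"` uses complete cases per bin instead.
#'
#' @param geno `bin_genotypes` matrix (or any individuals x bins score
#'   matrix with rownames).
#' @param phen A `phenotype_table`; [standardize()] is applied if the `z`
#'   column is absent.
#' @param impute `"mean"` (default) or `"complete"`.
#' @param lod_cap Finite LOD reported when the full-model residual sum of
#'   squares underflows.
#' @return `data.frame` of class `ail_scan`: `chrom`, `start`, `lod`,
#'   `a_hat`, `d_hat`, `se_a`, `p`, `n_used` (one row per bin; bins with no
#'   genotyped individual get LOD 0). Attribute `n` is the matched sample
#'   size.
#' @export
hk_scan <- function(geno, phen, impute = c("mean", "complete"),
                    lod_cap = 50) {
  impute <- match.arg(impute)
  if (!"z" %in% names(phen)) phen <- standardize(phen)
  mp <- match_geno_phen(geno, phen)
  geno <- mp$geno; phen <- mp$phen
  n <- nrow(phen)
  sex <- as.numeric(phen$sex == "M")
  z <- phen$z
  bins <- attr(geno, "bins")
  if (is.null(bins)) {
    parts <- strsplit(colnames(geno), ":", fixed = TRUE)
    bins <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                       start = as.numeric(vapply(parts, `[`, "", 2L)),
                       stringsAsFactors = FALSE)
  }

  if (impute == "mean") {
    reg <- impute_regressors(geno)
    eng <- hk_engine(reg$A, reg$D, sex, z)
    lod <- eng$lod; a_hat <- eng$a_hat; d_hat <- eng$d_hat
    sigma2 <- eng$RSS1 / (n - 4)
    se_a <- sqrt(pmax(sigma2 * eng$va, 0))
    n_used <- rep(n, ncol(geno))
  } else {
    B <- ncol(geno)
    lod <- a_hat <- d_hat <- se_a <- numeric(B)
    n_used <- integer(B)
    for (b in seq_len(B)) {
      obs <- !is.na(geno[, b])
      n_used[b] <- sum(obs)
      if (n_used[b] < 5L) { lod[b] <- 0; next }
      eng <- hk_engine(cbind(geno[obs, b]), cbind(1 - abs(geno[obs, b])),
                       sex[obs], z[obs])
      lod[b] <- eng$lod; a_hat[b] <- eng$a_hat; d_hat[b] <- eng$d_hat
      se_a[b] <- sqrt(pmax(eng$RSS1 / (n_used[b] - 4) * eng$va, 0))
    }
  }
  capped <- is.finite(lod) & lod > lod_cap
  if (any(capped)) {
    warning(sprintf("%d bin(s) with vanishing residual variance; LOD capped at %g",
                    sum(capped), lod_cap))
    lod[capped] <- lod_cap
  }
  lod[!is.finite(lod)] <- lod_cap
  out <- data.frame(chrom = bins$chrom, start = bins$start, lod = lod,
                    a_hat = a_hat, d_hat = d_hat, se_a = se_a,
                    p = lod_to_p(lod), n_used = n_used,
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n
  class(out) <- c("ail_scan", "data.frame")
  out
}

#' Genome-wide permutation significance threshold
#'
#' Estimates the genome-wide LOD threshold by permuting the (z, sex) pairs
#' jointly against the genotype rows, recording the maximum LOD over all
#' bins for each permutation, and returning the empirical `1 - alpha`
#' quantile.
#'
#' @inheritParams hk_scan
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Genome-wide type-I error rate.
#' @param seed Seed for the permutation stream.
#' @return The LOD threshold, with the per-permutation maxima in attribute
#'   `max_lods`.
#' @export
permutation_threshold <- function(geno, phen, n_perm = 10000, alpha = 0.05,
                                  seed = NULL) {
  stopifnot(n_perm >= 100)
  if (!"z" %in% names(phen)) phen <- standardize(phen)
  mp <- match_geno_phen(geno, phen)
  geno <- mp$geno; phen <- mp$phen
  n <- nrow(phen)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) sample.int(n),
                 integer(n))
  reg <- impute_regressors(geno)
  sex <- as.numeric(phen$sex == "M")
  # chunk permutations to bound memory on large cohorts
  chunk <- max(1L, floor(2e7 / n))
  starts <- seq(1L, n_perm, by = chunk)
  max_lods <- numeric(n_perm)
  for (s in starts) {
    cols <- s:min(s + chunk - 1L, n_perm)
    eng <- hk_engine(reg$A, reg$D, sex, phen$z, perm = perm[, cols, drop = FALSE])
    lods <- matrix(eng$lod, ncol = length(cols))
    max_lods[cols] <- apply(lods, 2L, max)
  }
  thr <- stats::quantile(max_lods, 1 - alpha, names = FALSE, type = 7)
  attr(thr, "max_lods") <- max_lods
  thr
}
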