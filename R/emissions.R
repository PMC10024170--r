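# Genotype-state regions on the H-read-fraction scale. LL segments
# concentrate near 0, heterozygous near 0.5, HH near 1; the regions
# constrain the mixture component means so a component cannot wander into
# another state's territory when its own state is rare on a chromosome.
.state_names <- c("HH", "HET", "LL")
.state_codes <- c(HH = 1, HET = 0, LL = -1)
.mean_regions <- list(HH = c(0.65, 1), HET = c(0.35, 0.65), LL = c(0, 0.35))

# Hardcoded fallback emission thresholds: wide symmetric guard bands suited
# to the noise of a ~0.4X read regime.
.fallback_thresholds <- c(t_low = 0.1, t_het_lo = 0.35,
                          t_het_hi = 0.65, t_high = 0.9)

.f_eps <- 1e-4          # clamp f away from {0, 1} for beta likelihoods
.nu_cap <- 1e4          # precision cap; a fit at the cap is degenerate

clamp_f <- function(f) pmin(pmax(f, .f_eps), 1 - .f_eps)

#' Fit three-state beta emission distributions to window fractions
#'
#' Fits a 3-component beta mixture (states HH, HET, LL) to the H-read
#' fractions of a window series by maximum likelihood. Component means are
#' constrained to state-specific regions (HH in (0.65, 1\], HET in
#' \[0.35, 0.65\], LL in \[0, 0.35)). Minimization restarts with
#' deterministically perturbed initial values after each failed attempt;
#' after `max_tries` failures, or immediately when the fraction
#' distribution is unimodal at an extreme (uniform ancestry across the
#' chromosome) or a state region holds fewer than 2 windows, hardcoded
#' genotype emission thresholds are used instead.
#'
#' An attempt fails when the optimizer does not converge, the likelihood is
#' non-finite, or a fitted component is degenerate: precision at its upper
#' bound (an effective point mass) or component means closer than 0.2 (a
#' state fitted onto another state's noise tail).
#'
#' @param series A `window_series` from [build_windows()] (or a numeric
#'   vector of fractions).
#' @param max_tries Maximum number of minimization attempts before falling
#'   back to hardcoded thresholds.
#' @return List of class `emission_params`: `fallback_used`, `thresholds`
#'   (when fallback), `shape1`, `shape2`, `weight` (named per state, when
#'   fitted), `n_tries`, `reason`.
#' @export
fit_emissions <- function(series, max_tries = 20) {
  f <- if (is.data.frame(series)) series$f else as.numeric(series)
  stopifnot(length(f) >= 1)
  f <- clamp_f(f)
  n <- length(f)
  # overlapping sliding windows are highly autocorrelated; a deterministic
  # stride subsample is ample for estimating the emission shapes
  f_fit <- if (n > 500L) f[round(seq(1L, n, length.out = 500L))] else f

  fallback <- function(reason, n_tries) {
    structure(list(fallback_used = TRUE, thresholds = .fallback_thresholds,
                   shape1 = NULL, shape2 = NULL, weight = NULL,
                   n_tries = as.integer(n_tries), reason = reason),
              class = "emission_params")
  }

  # uniform ancestry: nearly all mass at one extreme
  if (mean(f > 0.9) >= 0.95 || mean(f < 0.1) >= 0.95)
    return(fallback("uniform_ancestry", 0L))

  region_of <- function(x) {
    ifelse(x >= 0.65, 1L, ifelse(x >= 0.35, 2L, 3L))   # HH, HET, LL
  }
  reg <- region_of(f)
  support <- tabulate(reg, 3L)
  if (any(support < 2L))
    return(fallback("insufficient_support", 0L))

  # each state region must hold a credible population near its expected
  # center, not just the noise tail of a neighboring state; otherwise a
  # mixture fit could only place a component on that tail
  med <- vapply(1:3, function(s) stats::median(f[reg == s]), numeric(1))
  if (med[1] < 0.8 || abs(med[2] - 0.5) > 0.1 || med[3] > 0.2)
    return(fallback("insufficient_separation", 0L))

  # initial values from per-region moments
  mu0 <- vapply(1:3, function(s) mean(f[reg == s]), numeric(1))
  v0 <- vapply(1:3, function(s) stats::var(f[reg == s]), numeric(1))
  v0[!is.finite(v0) | v0 < 1e-6] <- 1e-4
  nu0 <- pmin(pmax(mu0 * (1 - mu0) / v0 - 1, 2.5), .nu_cap / 2)
  pi0 <- pmax(support / n, 0.01)

  lo_hi <- do.call(rbind, .mean_regions)            # rows: HH, HET, LL
  r_lo <- lo_hi[, 1]
  r_span <- lo_hi[, 2] - lo_hi[, 1]
  log_nu_cap <- log(.nu_cap)
  to_theta <- function(mu, s) {
    z <- (mu - r_lo[s]) / r_span[s]
    z <- pmin(pmax(z, 0.02), 0.98)
    log(z / (1 - z))
  }
  unpack <- function(par) {
    mu <- r_lo + r_span / (1 + exp(-par[1:3]))
    eta <- par[4:6]
    eta[eta > log_nu_cap] <- log_nu_cap
    nu <- 2 + exp(eta)
    lw <- c(0, par[7], par[8])
    w <- exp(lw - max(lw)); w <- w / sum(w)
    list(mu = mu, nu = nu, w = w,
         a = mu * nu, b = (1 - mu) * nu)
  }
  lf <- log(f_fit)
  l1f <- log1p(-f_fit)
  nll <- function(par) {
    p <- unpack(par)
    # beta log-densities by hand (dbeta's argument checking dominates
    # the fit otherwise), combined by log-sum-exp
    l1 <- (p$a[1] - 1) * lf + (p$b[1] - 1) * l1f - lbeta(p$a[1], p$b[1]) +
      log(p$w[1])
    l2 <- (p$a[2] - 1) * lf + (p$b[2] - 1) * l1f - lbeta(p$a[2], p$b[2]) +
      log(p$w[2])
    l3 <- (p$a[3] - 1) * lf + (p$b[3] - 1) * l1f - lbeta(p$a[3], p$b[3]) +
      log(p$w[3])
    m <- pmax(l1, l2, l3)
    ll <- m + log(exp(l1 - m) + exp(l2 - m) + exp(l3 - m))
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }

  par0 <- c(vapply(1:3, function(s) to_theta(mu0[s], s), numeric(1)),
            log(nu0 - 2), log(pi0[2:3] / pi0[1]))

  for (try in seq_len(max_tries)) {
    # deterministic perturbation keeps results identical across platforms
    jit <- if (try == 1L) rep(0, 8) else
      0.4 * (try - 1L) * cos(7 * (try - 1L) * seq_len(8))
    fit <- tryCatch(
      stats::nlminb(par0 + jit, nll,
                    control = list(iter.max = 500, eval.max = 800)),
      error = function(e) NULL
    )
    if (is.null(fit) || fit$convergence != 0 || !is.finite(fit$objective))
      next
    p <- unpack(fit$par)
    if (any(p$nu >= .nu_cap * 0.999 + 2))    # precision at cap: point mass
      next
    # overlapping components (e.g. a state fitted onto another state's
    # noise tail) cannot be trusted as distinct genotype emissions
    if (min(abs(diff(sort(p$mu)))) < 0.2)
      next
    names(p$mu) <- names(p$nu) <- names(p$w) <- .state_names
    names(p$a) <- names(p$b) <- .state_names
    return(structure(list(fallback_used = FALSE, thresholds = NULL,
                          shape1 = p$a, shape2 = p$b, weight = p$w,
                          mean = p$mu, n_tries = try,
                          reason = "fitted"),
                     class = "emission_params"))
  }
  fallback("max_tries_exceeded", max_tries)
}

#' @export
print.emission_params <- function(x, ...) {
  if (x$fallback_used) {
    cat("Emission parameters: hardcoded thresholds (", x$reason, ")\n", sep = "")
    print(x$thresholds)
  } else {
    cat("Emission parameters: fitted beta mixture (tries:", x$n_tries, ")\n")
    print(rbind(mean = x$mean, weight = x$weight))
  }
  invisible(x)
}

# Log emission densities, states x windows. Under fallback thresholds each
# state emits log(1) inside its band and a strong penalty outside;
# fractions outside every band are uninformative (flat across states).
emission_logdens <- function(f, params) {
  f <- clamp_f(f)
  n <- length(f)
  le <- matrix(0, nrow = 3L, ncol = n, dimnames = list(.state_names, NULL))
  if (params$fallback_used) {
    t <- params$thresholds
    in_hh <- f >= t["t_high"]
    in_het <- f >= t["t_het_lo"] & f <= t["t_het_hi"]
    in_ll <- f <= t["t_low"]
    inform <- in_hh | in_het | in_ll
    # out-of-band penalty just under twice the default switch penalty:
    # an isolated single-window outlier can never outvote the path prior,
    # while two or more consecutive discordant windows can
    pen <- log(2e-6)
    le["HH", inform] <- ifelse(in_hh[inform], 0, pen)
    le["HET", inform] <- ifelse(in_het[inform], 0, pen)
    le["LL", inform] <- ifelse(in_ll[inform], 0, pen)
  } else {
    for (s in .state_names)
      le[s, ] <- stats::dbeta(f, params$shape1[s], params$shape2[s],
                              log = TRUE)
  }
  le
}
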