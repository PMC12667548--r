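# Independent oracles, written before and apart from the implementation.

# Pearson r by direct evaluation of the covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# Benjamini-Hochberg step-up by literal enumeration: largest k with
# p_(k) <= q k / m is the cutoff.
oracle_bh_sig <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  sig <- logical(m)
  if (length(k)) sig[o[seq_len(max(k))]] <- TRUE
  sig
}

# Steiger's z for dependent correlations with no shared variable, coded
# directly from the printed equations: Fisher transforms, pooled rbar, the
# pooled covariance c, and z = (Z_jk - Z_hm) / sqrt(2(1 - c)/(n - 3)).
oracle_steiger <- function(r_jk, r_hm, r_jh, r_jm, r_kh, r_km, n) {
  Z_jk <- 0.5 * log((1 + r_jk) / (1 - r_jk))
  Z_hm <- 0.5 * log((1 + r_hm) / (1 - r_hm))
  rbar <- (r_jk + r_hm) / 2
  num <- 0.5 * rbar^2 * (r_jh^2 + r_jm^2 + r_kh^2 + r_km^2) +
    (r_jh * r_km + r_jm * r_kh) -
    rbar * (r_jh * r_jm + r_kh * r_km + r_jh * r_kh + r_jm * r_km)
  c_val <- num / (1 - rbar^2)^2
  z <- (Z_jk - Z_hm) / sqrt(2 * (1 - c_val) / (n - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# Draw an admissible 4-variable correlation matrix by correlating random
# Gaussian data (always positive semi-definite).
random_admissible_cor <- function(n_obs = 8) {
  cor(matrix(rnorm(n_obs * 4), n_obs, 4))
}

# Two-stage OLS residualization then Pearson: the partial-correlation oracle.
oracle_partial_r <- function(x, y, covs) {
  rx <- residuals(lm(x ~ ., data = as.data.frame(covs)))
  ry <- residuals(lm(y ~ ., data = as.data.frame(covs)))
  cor(rx, ry)
}

# One-way ANOVA ICC(1) estimator.
oracle_icc1 <- function(values, groups) {
  groups <- factor(groups)
  k <- length(unique(table(groups)))
  stopifnot(k == 1)  # balanced design expected in these tests
  n_per <- unname(table(groups)[1])
  fit <- anova(lm(values ~ groups))
  msb <- fit$`Mean Sq`[1]; msw <- fit$`Mean Sq`[2]
  (msb - msw) / (msb + (n_per - 1) * msw)
}

# Small default-ish cohort for quick tests.
tiny_cohort <- function(n = 60, seed = 7, ...) {
  simulate_cohort(simulation_config(n_participants = n, seed = seed, ...))
}
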