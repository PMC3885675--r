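# Independent from-scratch oracles used to verify the package's
# statistics. These deliberately use naive direct computation (explicit
# loops, enumeration, quadrature) and never share code with the package.

oracle_moments <- function(v) {
  n <- length(v)
  s <- 0
  for (x in v) s <- s + x
  m <- s / n
  s2 <- s3 <- s4 <- 0
  for (x in v) {
    d <- x - m
    s2 <- s2 + d^2
    s3 <- s3 + d^3
    s4 <- s4 + d^4
  }
  m2 <- s2 / n
  list(mean = m,
       sd = sqrt(s2 / (n - 1)),
       skewness = (s3 / n) / m2^1.5,
       kurtosis = (s4 / n) / m2^2 - 3)
}

# linear interpolation between order statistics at h = (n - 1) p / 100
oracle_percentile <- function(v, p) {
  sv <- sort(v)
  n <- length(sv)
  h <- (n - 1) * p / 100
  lo <- floor(h)
  if (lo >= n - 1) return(sv[n])
  sv[lo + 1] + (h - lo) * (sv[lo + 2] - sv[lo + 1])
}

# Welch statistic from the formula; two-sided p by numerical quadrature of
# the t density (gamma-function normalization, no pt()).
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  tail_p <- integrate(dens, abs(t_stat), Inf, rel.tol = 1e-12)$value
  list(statistic = t_stat, df = df, p_value = 2 * tail_p)
}

oracle_chi2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  # df = 1: chi2 tail equals the two-sided normal tail of sqrt(stat)
  list(statistic = stat, p_value = 2 * pnorm(-sqrt(stat)))
}

# Fisher two-sided p by full enumeration over all tables with the
# observed margins (point-probability method).
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  supp <- max(0, k - n):min(k, m)
  pr <- dhyper(supp, m, n, k)
  p_obs <- dhyper(x_obs, m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# AUC by exhaustive pair counting.
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  wins <- 0
  for (a in sp) for (b in sn) {
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  wins / (length(sp) * length(sn))
}

# Stratified (class-preserving) bootstrap variance of an AUC statistic.
boot_auc_var <- function(stat_fn, pos, n_boot, seed) {
  ip <- which(pos); im <- which(!pos)
  vals <- withr::with_seed(seed, {
    replicate(n_boot, {
      idx <- c(sample(ip, replace = TRUE), sample(im, replace = TRUE))
      stat_fn(idx)
    })
  })
  var(vals)
}
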