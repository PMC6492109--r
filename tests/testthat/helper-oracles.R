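## Monte-Carlo moments of tau_kl^2 = X + Y - 2 rho sqrt(XY) with X, Y iid
## log-normal(m, s^2) and rho ~ Beta scaled to the requested moments.
## Returns estimates and standard errors; the arbiter for the analytic
## implied-moment expressions.
mc_contrast_moments <- function(m, s, rho_mean = 0.5, rho_var = 0.07,
                                n = 1e6, seed = 101) {
  set.seed(seed)
  X <- exp(rnorm(n, m, s))
  Y <- exp(rnorm(n, m, s))
  k <- rho_mean * (1 - rho_mean) / rho_var - 1
  rho <- rbeta(n, rho_mean * k, (1 - rho_mean) * k)
  v <- X + Y - 2 * rho * sqrt(X * Y)
  mean_se <- sd(v) / sqrt(n)
  ## standard error of the sample variance via the fourth central moment
  m4 <- mean((v - mean(v))^4)
  var_se <- sqrt(max(m4 - var(v)^2, 0) / n)
  list(mean = mean(v), var = var(v), mean_se = mean_se, var_se = var_se)
}

## brute-force equal-tailed quantile via full sort (linear interpolation,
## type 7), independent of stats::quantile
sorted_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

## fine-grid numeric integration of the 2-treatment approach-1 posterior:
## p(d, tau | data) with mu_j, delta_j integrated out per study on grids.
## Returns the marginal posterior median of d.
grid_posterior_median_d <- function(r, n, tau_upper = 2,
                                    mu_grid = seq(-5, 5, length.out = 161),
                                    de_grid = seq(-5, 5, length.out = 161),
                                    d_grid = seq(-3, 3, length.out = 241),
                                    tau_grid = seq(1e-3, 2, length.out = 80)) {
  ## r, n: matrices (studies x 2), column 1 = baseline arm
  ns <- nrow(r)
  w <- matrix(NA_real_, ns, length(de_grid))
  for (j in seq_len(ns)) {
    la <- dbinom(r[j, 1], n[j, 1], plogis(mu_grid), log = TRUE) +
      dnorm(mu_grid, 0, 100, log = TRUE)
    lb <- outer(mu_grid, de_grid, function(m, d)
      dbinom(r[j, 2], n[j, 2], plogis(m + d), log = TRUE))
    w[j, ] <- colSums(exp(la + lb))   # integrate mu out
  }
  post_d <- numeric(length(d_grid))
  for (ti in seq_along(tau_grid)) {
    phi <- outer(de_grid, d_grid, function(de, d)
      dnorm(de, d, tau_grid[ti]))
    Lj <- w %*% phi                   # ns x length(d_grid)
    post_d <- post_d + exp(colSums(log(Lj))) *
      dnorm(d_grid, 0, 100)           # flat tau prior within (0, upper)
  }
  cdf <- cumsum(post_d) / sum(post_d)
  stats::approx(cdf, d_grid, xout = 0.5, ties = "ordered")$y
}

## small two-arm network data frame used across tests
toy_arms <- function() {
  data.frame(
    study = rep(c("s1", "s2", "s3"), each = 2),
    treatment = c("A", "B", "A", "C", "B", "C"),
    events = c(12L, 18L, 10L, 14L, 9L, 11L),
    total = c(50L, 50L, 40L, 40L, 45L, 45L))
}

toy_treatments <- function() {
  data.frame(treatment = c("A", "B", "C"),
             class = c("control", "nonpharmacological",
                       "nonpharmacological"))
}
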