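test_that("log likelihood matches a brute-force binomial summation", {
  net <- prostate_network()
  set.seed(5)
  state <- list(
    mu = rnorm(length(net$studies), -0.5, 0.5),
    delta = lapply(net$studies, function(s)
      rnorm(length(s$treatments) - 1L, 0, 0.3)))
  ll <- log_likelihood(net, state)
  ## independent summation straight over the arm table
  brute <- 0
  for (j in seq_along(net$studies)) {
    st <- net$studies[[j]]
    for (i in seq_along(st$rows)) {
      eta <- state$mu[j] + if (i == 1) 0 else state$delta[[j]][i - 1]
      r <- net$arms$events[st$rows[i]]
      n <- net$arms$total[st$rows[i]]
      pp <- 1 / (1 + exp(-eta))
      brute <- brute + lchoose(n, r) + r * log(pp) + (n - r) * log(1 - pp)
    }
  }
  expect_equal(ll, brute, tolerance = 1e-10)
  ## a fifty-fifty arm contributes log C(33,3) + 33 log(1/2)
  one <- nma_network(data.frame(study = 1, treatment = c("X", "Y"),
                                events = c(3, 3), total = c(33, 33)))
  ll0 <- log_likelihood(one, list(mu = 0, delta = list(0)))
  expect_equal(ll0, 2 * (lchoose(33, 3) + 33 * log(0.5)))
})

test_that("log prior respects supports and closed forms", {
  net <- nma_network(toy_arms(), toy_treatments())
  st_common <- het_common("vague")
  base <- list(mu = c(0, 0, 0), delta = list(0.1, -0.1, 0.2),
               d = c(0.1, 0.2))
  ## tau outside the Uniform(0, 2) support has zero mass
  s1 <- c(base, list(het = list(tau = 2.5)))
  expect_identical(log_prior(s1, st_common, net), -Inf)
  s2 <- c(base, list(het = list(tau = 0.5)))
  lp <- log_prior(s2, st_common, net)
  expect_true(is.finite(lp))
  ## informative prior density at tau^2 = e^m equals the log-normal value
  pr <- lognormal_prior(-4.28, 1.61)
  s3 <- c(base, list(het = list(tau2 = exp(pr$m))))
  lp3 <- log_prior(s3, het_common(pr), net)
  analytic <- dlnorm(exp(pr$m), pr$m, pr$s, log = TRUE) +
    sum(dnorm(c(s3$mu, s3$d), 0, 100, log = TRUE))
  Sg <- sigma_common(exp(pr$m), 2)
  for (j in 1:3) {
    stj <- net$studies[[j]]
    d0 <- c(0, s3$d)
    mean_j <- d0[stj$treatments[2] + 1L] - d0[stj$treatments[1] + 1L]
    analytic <- analytic +
      dnorm(s3$delta[[j]], mean_j,
            sqrt(contrast_variance(Sg, stj$treatments[1],
                                   stj$treatments[2])), log = TRUE)
  }
  expect_equal(lp3, analytic, tolerance = 1e-10)
})

test_that("posterior density identity holds at fixed states", {
  ## log posterior = log likelihood + log prior up to a constant: differences
  ## of the sum between two states equal differences of the components
  net <- nma_network(toy_arms(), toy_treatments())
  str <- het_arm_based(arm_prior = lognormal_prior(-3.31, 1.70),
                       angle_prior = beta_prior(0.93, 1.07))
  mk_state <- function(seed) {
    set.seed(seed)
    list(mu = rnorm(3, 0, 0.5), delta = list(rnorm(1), rnorm(1), rnorm(1)),
         d = rnorm(2, 0, 0.5),
         het = list(tau = runif(3, 0.1, 1), cosines = runif(3, 0.1, 0.9)))
  }
  a <- mk_state(1)
  b <- mk_state(2)
  post <- function(s) log_likelihood(net, s) + log_prior(s, str, net)
  expect_equal(post(a) - post(b),
               (log_likelihood(net, a) - log_likelihood(net, b)) +
                 (log_prior(a, str, net) - log_prior(b, str, net)))
  expect_true(is.finite(post(a)))
})

test_that("functional contrasts obey the consistency equations", {
  D <- functional_contrasts(c(0.5, 0.8))
  expect_equal(D["1", "2"], 0.3)
  set.seed(8)
  d <- rnorm(5)
  D <- functional_contrasts(d)
  expect_equal(D, -t(D))
  ## transitivity d_kl + d_lm = d_km
  for (k in 1:6) for (l in 1:6) for (m in 1:6) {
    expect_equal(D[k, l] + D[l, m], D[k, m], tolerance = 1e-12)
  }
})

test_that("the sampler is deterministic given a seed", {
  net <- nma_network(toy_arms(), toy_treatments())
  cfg <- mcmc_config(chains = 2, iterations = 300, burn_in = 200, seed = 77)
  f1 <- nma_fit(net, het_common("vague"), cfg)
  f2 <- nma_fit(net, het_common("vague"), cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- nma_fit(net, het_common("vague"),
                mcmc_config(chains = 2, iterations = 300, burn_in = 200,
                            seed = 78))
  expect_false(identical(f1$draws, f3$draws))
  ## stored draw counts respect thinning
  cfg_t <- mcmc_config(chains = 1, iterations = 300, burn_in = 100,
                       thin = 3, seed = 1)
  ft <- nma_fit(net, het_common("vague"), cfg_t)
  expect_equal(nrow(ft$draws[[1]]$d), 100L)
})

test_that("prior-only runs reproduce the implied heterogeneity priors", {
  net <- nma_network(toy_arms(), toy_treatments())
  ## approach 1 with an informative prior: tau quantiles follow the
  ## log-normal exactly
  pr <- lognormal_prior(-2.75, 1.61)
  cfg <- mcmc_config(chains = 2, iterations = 8000, burn_in = 2000,
                     seed = 9)
  fit <- nma_fit(net, het_common(pr), cfg, prior_only = TRUE)
  tau_draws <- do.call(rbind, lapply(fit$draws, `[[`, "tau"))[, 1]
  qs <- quantile(tau_draws, c(0.25, 0.5, 0.75), names = FALSE)
  expected <- sqrt(exp(pr$m + pr$s * qnorm(c(0.25, 0.5, 0.75))))
  expect_lt(max(abs(qs / expected - 1)), 0.12)
  ## approach 3: sampler prior marginals match forward Monte Carlo
  str3 <- het_arm_based(arm_prior = lognormal_prior(-3.31, 1.70),
                        angle_prior = beta_prior(0.93, 1.07))
  fit3 <- nma_fit(net, str3, cfg, prior_only = TRUE)
  fwd <- prior_monte_carlo(str3, 3, n_draws = 2e5, seed = 10)
  t3 <- do.call(rbind, lapply(fit3$draws, `[[`, "tau"))
  for (q in 1:3) {
    med_mcmc <- median(t3[, q])
    med_fwd <- fwd$quantiles[q, "50%"]
    expect_lt(abs(med_mcmc / med_fwd - 1), 0.15)
  }
})

test_that("all four heterogeneity structures fit a small network", {
  ## short chains; checks that every structure runs, returns finite draws,
  ## and keeps tau within its support
  des <- simulation_design(4, studies = 10, d = c(0.3, -0.2, 0.1),
                           Sigma = 0.04, arm_size = 80L)
  net <- simulate_network(des, seed = 3)$network
  cfg <- mcmc_config(chains = 1, iterations = 600, burn_in = 400, seed = 5)
  structures <- list(
    common = het_common(lognormal_prior(-2.75, 1.61)),
    proportional = het_proportional(vague = TRUE),
    arm_based = het_arm_based(arm_prior = lognormal_prior(-3.31, 1.70)),
    wishart = het_scaled_wishart(
      match_scaled_wishart(lognormal_prior(-2.75, 1.61), p = 3)))
  for (nm in names(structures)) {
    fit <- nma_fit(net, structures[[nm]], cfg)
    tau <- do.call(rbind, lapply(fit$draws, `[[`, "tau"))
    expect_true(all(is.finite(tau)), label = nm)
    expect_true(all(tau >= 0), label = nm)
    s <- summary(fit)
    expect_true(all(s$lower <= s$median & s$median <= s$upper), label = nm)
  }
})

test_that("informative proportional fits use catalog offsets end to end", {
  net <- prostate_network()
  spec <- proportional_spec(net, "prostate")
  str <- het_proportional(spec)
  cfg <- mcmc_config(chains = 1, iterations = 500, burn_in = 300, seed = 2)
  fit <- nma_fit(net, str, cfg)
  tau <- do.call(rbind, lapply(fit$draws, `[[`, "tau"))
  ## active-vs-active heterogeneity exceeds vs-control by the offset ratio
  ## draw by draw (tau_BC / tau_AB is fixed by the offsets)
  i_ab <- match("tau_AB", fit$pair_names)
  i_bc <- match("tau_BC", fit$pair_names)
  expect_equal(unname(tau[, i_bc] / tau[, i_ab]),
               rep(exp((-3.50 - -4.17) / 2), nrow(tau)), tolerance = 1e-10)
})
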