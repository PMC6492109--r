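test_that("spherical construction reproduces the 3-treatment closed form", {
  ## right angles give the identity
  expect_equal(spherical_to_correlation(rep(0, 3))$R, diag(3))
  ## generic cosines match rho_23 = c12 c13 + s12 s13 c23
  set.seed(1)
  for (i in 1:20) {
    cc <- runif(3, 0.01, 0.99)
    R <- spherical_to_correlation(cc)$R
    expect_equal(R[1, 2], cc[1])
    expect_equal(R[1, 3], cc[2])
    expect_equal(R[2, 3],
                 cc[1] * cc[2] + sqrt(1 - cc[1]^2) * sqrt(1 - cc[2]^2) *
                   cc[3],
                 tolerance = 1e-12)
  }
  ## angles of zero give a degenerate rank-1 matrix with rho = 1
  R <- spherical_to_correlation(c(1 - 1e-12, 1 - 1e-12, 0.3))$R
  expect_equal(R[2, 3], 1, tolerance = 1e-5)
})

test_that("spherical correlation matrices are PSD by construction", {
  set.seed(7)
  for (i in 1:2000) {
    nt <- sample(3:6, 1)
    cc <- rbeta(choose(nt, 2), 0.8, 1)
    R <- spherical_to_correlation(cc)$R
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(R, t(R))
    expect_equal(unname(diag(R)), rep(1, nt))
  }
})

test_that("matrix and vector cosine input agree", {
  cc <- c(0.2, 0.4, 0.6, 0.1, 0.3, 0.5)
  Cm <- matrix(0, 4, 4)
  Cm[t(combn(4, 2))] <- cc
  Cm <- Cm + t(Cm)
  expect_equal(spherical_to_correlation(cc)$R,
               spherical_to_correlation(Cm)$R)
})

test_that("the common-variance matrix gives equal contrast variances", {
  S <- sigma_common(1, 3)
  prs <- combn(0:3, 2)
  for (i in seq_len(ncol(prs))) {
    expect_equal(contrast_variance(S, prs[1, i], prs[2, i]), 1)
  }
  expect_equal(sigma_common(0, 4), matrix(0, 4, 4))
  ## eigenvalues of the pattern matrix: (p+1)/2 once, 1/2 repeated
  ev <- eigen(sigma_common(1, 7), symmetric = TRUE)$values
  expect_equal(ev, c(4, rep(0.5, 6)))
  expect_error(sigma_common(-1, 3), "non-negative")
})

test_that("proportional covariance inverts the contrast-variance identity", {
  nt <- 4
  off <- matrix(0, nt, nt)
  ## two-type pattern: active-vs-active offset differs from vs-control
  off[2:nt, 2:nt] <- -2.26 - (-2.92)
  diag(off) <- 0
  ## absolute offsets: reference comparisons get m0k
  off[1, 2:nt] <- off[2:nt, 1] <- 0
  S <- sigma_proportional(0.3, off)
  for (k in 1:(nt - 1)) {
    expect_equal(contrast_variance(S, 0, k), 0.3)
    for (l in seq_len(nt - 1)) {
      if (k < l) {
        expect_equal(contrast_variance(S, k, l), 0.3 * exp(off[k + 1, l + 1]))
      }
    }
  }
  ## zero offsets reduce to the common-variance matrix
  expect_equal(sigma_proportional(0.7, matrix(0, 5, 5)),
               sigma_common(0.7, 4))
  ## PSD verdict is invariant to the scale tau^2
  expect_true(is_psd(sigma_proportional(0.001, off)))
  expect_true(is_psd(sigma_proportional(100, off)))
  ## an invalid pattern errors, naming the eigenvalue
  bad <- matrix(0, 6, 6)
  bad[2:6, 2:6] <- 1.2   # e^m too large for p = 5
  diag(bad) <- 0
  expect_error(sigma_proportional(1, bad), "second-order consistency")
})

test_that("arm-based covariance satisfies the contrast-variance relation", {
  set.seed(11)
  for (i in 1:200) {
    nt <- sample(3:6, 1)
    tau <- runif(nt, 0, 2)
    R <- spherical_to_correlation(rbeta(choose(nt, 2), 0.9, 1.1))$R
    S <- sigma_arm_based(tau, R)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(abs(ev), 1))
    prs <- combn(seq_len(nt) - 1L, 2)
    for (q in seq_len(ncol(prs))) {
      k <- prs[1, q]; l <- prs[2, q]
      expect_equal(contrast_variance(S, k, l),
                   tau[k + 1]^2 + tau[l + 1]^2 -
                     2 * R[k + 1, l + 1] * tau[k + 1] * tau[l + 1],
                   tolerance = 1e-10)
    }
  }
  ## equal arm SDs with rho = 0.5 reduce exactly to the common model
  tau <- rep(0.6, 5)
  R <- matrix(0.5, 5, 5); diag(R) <- 1
  expect_equal(sigma_arm_based(tau, R), sigma_common(0.36, 4),
               tolerance = 1e-12)
})

test_that("trial covariance re-bases correctly and is coherent", {
  S <- sigma_common(0.5, 4)
  ## two-arm trial: 1x1 matrix of the contrast variance
  V <- trial_contrast_covariance(S, c(1, 3))
  expect_equal(dim(V), c(1L, 1L))
  expect_equal(V[1, 1], 0.5)
  ## equal variances: off-diagonal tau^2 / 2
  V <- trial_contrast_covariance(S, c(0, 2, 3))
  expect_equal(V[1, 2], 0.25)
  ## re-basing invariance: Var(delta_bY - delta_bX) = tau_XY^2
  set.seed(2)
  tau <- runif(5, 0.1, 1.5)
  R <- spherical_to_correlation(rbeta(10, 0.9, 1.1))$R
  Sg <- sigma_arm_based(tau, R)
  V <- trial_contrast_covariance(Sg, c(1, 2, 4), baseline = 1)
  expect_equal(V[1, 1] + V[2, 2] - 2 * V[1, 2],
               contrast_variance(Sg, 2, 4), tolerance = 1e-10)
})

test_that("sequential conditionals reproduce the joint normal density", {
  ## closed form for the bivariate equal-variance case
  tau2 <- 0.8
  V <- matrix(c(tau2, tau2 / 2, tau2 / 2, tau2), 2, 2)
  fac <- conditional_factors(c(0, 0), V)
  expect_equal(fac[[2]]$var, 3 * tau2 / 4)
  ## diagonal covariance: independent conditionals
  facd <- conditional_factors(c(1, 2), diag(c(2, 3)))
  expect_equal(facd[[2]]$coef, 0)
  expect_equal(facd[[2]]$mean_fn(99), 2)
  ## random 3-dim cases: product of conditionals equals the joint density
  set.seed(3)
  for (i in 1:50) {
    A <- matrix(rnorm(9), 3, 3)
    V <- crossprod(A) + diag(0.1, 3)
    mu <- rnorm(3)
    x <- rnorm(3)
    seq_ld <- hetnma:::mvn_logdensity_seq(x, mu, V)
    chol_ld <- hetnma:::mvn_logdensity_chol(x, mu, chol(V))
    expect_equal(seq_ld, chol_ld, tolerance = 1e-10)
  }
  ## singular leading block: pseudo-inverse path, zero conditional variance
  V <- matrix(c(1, 1, 1, 1), 2, 2)
  fac <- conditional_factors(c(0, 0), V)
  expect_equal(fac[[2]]$var, 0)
})

test_that("heterogeneity SDs satisfy the triangle inequality (all models)", {
  set.seed(13)
  check_triangle <- function(S, nt) {
    for (tri in utils::combn(0:(nt - 1), 3, simplify = FALSE)) {
      tAB <- sqrt(contrast_variance(S, tri[1], tri[2]))
      tBC <- sqrt(contrast_variance(S, tri[2], tri[3]))
      tAC <- sqrt(contrast_variance(S, tri[1], tri[3]))
      expect_lte(tAC, tAB + tBC + 1e-8)
    }
  }
  for (i in 1:100) {
    nt <- 4
    check_triangle(sigma_common(runif(1, 0, 2), nt - 1), nt)
    check_triangle(sigma_arm_based(
      runif(nt, 0, 2),
      spherical_to_correlation(rbeta(6, 0.93, 1.07))$R), nt)
    off <- matrix(0, nt, nt)
    off[2:nt, 2:nt] <- runif(1, -1, 0.9)
    diag(off) <- 0
    check_triangle(sigma_proportional(runif(1, 0.01, 2), off), nt)
    spec <- match_scaled_wishart(lognormal_prior(-2.75, 1.61), p = nt - 1)
    W <- rWishart(1, spec$t, solve(spec$S))[, , 1]
    check_triangle(exp(rnorm(1, spec$m_lambda, spec$s_lambda)) *
                     chol2inv(chol(W)), nt)
  }
})
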