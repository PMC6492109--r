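#' Heterogeneity structures
#'
#' Constructors for the four between-study heterogeneity models.  Each
#' returns a `"het_structure"` object accepted by [nma_fit()] and
#' [prior_monte_carlo()].
#'
#' * `het_common()`: a single variance \eqn{\tau^2} for every comparison,
#'   \eqn{\Sigma = \tau^2 P} with unit diagonal and 0.5 off-diagonal
#'   \eqn{P}.  The prior is either a [lognormal_prior()] on \eqn{\tau^2} or,
#'   with `prior = "vague"`, \eqn{\tau \sim} Uniform(0, `upper`) on the
#'   standard-deviation scale.
#' * `het_proportional()`: comparison-specific variances proportional to a
#'   common scale, \eqn{\tau_{kl}^2 = \tau^2 e^{m_{kl}}}.  Informative form:
#'   fixed offsets (e.g. from [proportional_spec()]) and
#'   \eqn{\tau^2 \sim} log-normal(0, \eqn{s^2}).  Vague form
#'   (`vague = TRUE`): \eqn{\tau \sim} Uniform(0, `upper`), offsets 0 for
#'   contrasts with the reference and a single free offset
#'   \eqn{m \sim N(0, 0.5^2)} shared by all active-vs-active contrasts.
#'   States whose implied \eqn{\Sigma} is not positive semidefinite have
#'   zero prior mass.
#' * `het_arm_based()`: latent arm variances \eqn{\tau_k^2} and a
#'   spherically parameterized between-arm correlation matrix with
#'   \eqn{\cos(\phi_{kl})} Beta priors.  `arm_prior` is a
#'   [lognormal_prior()] on each \eqn{\tau_k^2} (use [match_arm_prior()] to
#'   derive it from a contrast-level target) or `"vague"` for
#'   \eqn{\tau_k \sim} Uniform(0, `upper`).  `angle_prior` defaults to the
#'   catalog entry for the network size ([angle_prior()]).
#' * `het_scaled_wishart()`: \eqn{\Sigma^{-1} = M/\lambda},
#'   \eqn{M \sim Wishart(S, t)},
#'   \eqn{\log\lambda \sim N(m_\lambda, s_\lambda^2)}, from a
#'   [scaled_wishart_spec()] (usually [match_scaled_wishart()]).
#'
#' @param prior For `het_common`: a [lognormal_prior()] for \eqn{\tau^2} or
#'   the string `"vague"`.
#' @param upper Upper bound of the vague Uniform prior on the SD scale.
#' @param offsets Symmetric matrix of log offsets \eqn{m_{kl}} over all
#'   treatments (reference first), zero diagonal; or a list with elements
#'   `offsets` and `s` as returned by [proportional_spec()].
#' @param s Common log-scale standard deviation for `het_proportional`.
#' @param vague Logical; use the vague form of `het_proportional`.
#' @param arm_prior A [lognormal_prior()] for the arm variances or
#'   `"vague"`.
#' @param angle_prior A [beta_prior()] for the angle cosines, or `NULL` to
#'   use the catalog entry for the network size at fit time.
#' @param spec A [scaled_wishart_spec()].
#' @return A `"het_structure"` object.
#' @name het_structure
NULL

#' @rdname het_structure
#' @export
het_common <- function(prior = "vague", upper = 2) {
  vague <- identical(prior, "vague")
  if (!vague && !inherits(prior, "lognormal_prior")) {
    stop("prior must be \"vague\" or a lognormal_prior()")
  }
  structure(list(prior = if (vague) NULL else prior, vague = vague,
                 upper = upper),
            class = c("het_common", "het_structure"))
}

#' @rdname het_structure
#' @export
het_proportional <- function(offsets = NULL, s = NULL, vague = FALSE,
                             upper = 2) {
  if (is.list(offsets) && !is.matrix(offsets)) {
    s <- offsets$s
    offsets <- offsets$offsets
  }
  if (vague) {
    structure(list(offsets = NULL, s = NULL, vague = TRUE, upper = upper),
              class = c("het_proportional", "het_structure"))
  } else {
    stopifnot(is.matrix(offsets), isSymmetric(unname(offsets), tol = 1e-10),
              all(diag(offsets) == 0), is.numeric(s), s > 0)
    ## PSD depends on the offsets only; fail early
    sigma_proportional(1, offsets, check = TRUE)
    structure(list(offsets = offsets, s = s, vague = FALSE, upper = upper),
              class = c("het_proportional", "het_structure"))
  }
}

#' @rdname het_structure
#' @export
het_arm_based <- function(arm_prior = "vague", angle_prior = NULL,
                          upper = 2) {
  vague <- identical(arm_prior, "vague")
  if (!vague && !inherits(arm_prior, "lognormal_prior")) {
    stop("arm_prior must be \"vague\" or a lognormal_prior()")
  }
  if (!is.null(angle_prior)) stopifnot(inherits(angle_prior, "beta_prior"))
  structure(list(arm_prior = if (vague) NULL else arm_prior, vague = vague,
                 angle_prior = angle_prior, upper = upper),
            class = c("het_arm_based", "het_structure"))
}

#' @rdname het_structure
#' @export
het_scaled_wishart <- function(spec) {
  stopifnot(inherits(spec, "scaled_wishart_spec"))
  structure(list(spec = spec),
            class = c("het_scaled_wishart", "het_structure"))
}

#' @export
print.het_structure <- function(x, ...) {
  cat("heterogeneity structure:", class(x)[1], "\n")
  invisible(x)
}

## ---- internal generic surface used by the sampler --------------------------
## Parameters live on an unconstrained-ish sampling scale; het_logprior
## includes the Jacobians of those transforms.  nt = number of treatments
## (p + 1).

het_npar <- function(str, nt) UseMethod("het_npar")
het_par_names <- function(str, nt) UseMethod("het_par_names")
het_init <- function(str, nt) UseMethod("het_init")
het_logprior <- function(str, par, nt) UseMethod("het_logprior")
het_sigma <- function(str, par, nt) UseMethod("het_sigma")
het_monitor <- function(str, par, nt) UseMethod("het_monitor")
het_sample_prior <- function(str, nt, n) UseMethod("het_sample_prior")
het_logprior_natural <- function(str, het, nt)
  UseMethod("het_logprior_natural")

n_pairs <- function(nt) nt * (nt - 1L) / 2L

## ---- approach 1: common variance -------------------------------------------

#' @export
het_npar.het_common <- function(str, nt) 1L

#' @export
het_par_names.het_common <- function(str, nt) "tau"

#' @export
het_init.het_common <- function(str, nt) {
  if (str$vague) runif(1, 0.02, str$upper / 4) else rnorm(1, str$prior$m, 0.5)
}

#' @export
het_logprior.het_common <- function(str, par, nt) {
  if (str$vague) {
    if (par <= 0 || par >= str$upper) -Inf else -log(str$upper)
  } else {
    dnorm(par, str$prior$m, str$prior$s, log = TRUE)
  }
}

#' @export
het_sigma.het_common <- function(str, par, nt) {
  tau2 <- if (str$vague) par^2 else exp(par)
  sigma_common(tau2, nt - 1L)
}

#' @export
het_monitor.het_common <- function(str, par, nt) {
  c(tau = if (str$vague) par else exp(par / 2))
}

#' @export
het_sample_prior.het_common <- function(str, nt, n) {
  tau2 <- if (str$vague) runif(n, 0, str$upper)^2 else
    exp(rnorm(n, str$prior$m, str$prior$s))
  matrix(tau2, n, n_pairs(nt))
}

#' @export
het_logprior_natural.het_common <- function(str, het, nt) {
  if (str$vague) {
    stats::dunif(het$tau, 0, str$upper, log = TRUE)
  } else {
    dlnorm(het$tau2, str$prior$m, str$prior$s, log = TRUE)
  }
}

## ---- approach 2: proportional variances ------------------------------------

## PSD bound for the vague two-level pattern: Sigma/tau^2 is compound
## symmetric with off-diagonal (2 - e^m)/2, PSD iff e^m <= 2 + 2/(p - 1)
prop_vague_psd <- function(m, p) {
  p < 2 | exp(m) <= 2 + 2 / (p - 1)
}

#' @export
het_npar.het_proportional <- function(str, nt) if (str$vague) 2L else 1L

#' @export
het_par_names.het_proportional <- function(str, nt) {
  if (str$vague) c("tau", "m") else "tau"
}

#' @export
het_init.het_proportional <- function(str, nt) {
  if (str$vague) c(runif(1, 0.02, str$upper / 4), rnorm(1, 0, 0.1)) else
    rnorm(1, 0, 0.5)
}

#' @export
het_logprior.het_proportional <- function(str, par, nt) {
  if (str$vague) {
    if (par[1] <= 0 || par[1] >= str$upper) return(-Inf)
    if (!prop_vague_psd(par[2], nt - 1L)) return(-Inf)
    -log(str$upper) + dnorm(par[2], 0, 0.5, log = TRUE)
  } else {
    dnorm(par, 0, str$s, log = TRUE)
  }
}

prop_offsets <- function(str, m, nt) {
  if (!str$vague) return(str$offsets)
  off <- matrix(m, nt, nt)
  off[1, ] <- off[, 1] <- 0
  diag(off) <- 0
  off
}

#' @export
het_sigma.het_proportional <- function(str, par, nt) {
  if (str$vague) {
    sigma_proportional(par[1]^2, prop_offsets(str, par[2], nt), check = FALSE)
  } else {
    sigma_proportional(exp(par), str$offsets, check = FALSE)
  }
}

#' @export
het_monitor.het_proportional <- function(str, par, nt) {
  if (str$vague) c(tau = par[1], m = par[2]) else c(tau = exp(par / 2))
}

#' @export
het_sample_prior.het_proportional <- function(str, nt, n) {
  prs <- treatment_pairs(nt)
  if (str$vague) {
    tau2 <- runif(n, 0, str$upper)^2
    m <- rnorm(n, 0, 0.5)
    keep <- prop_vague_psd(m, nt - 1L)   # prior is conditioned on PSD
    tau2 <- tau2[keep]
    m <- m[keep]
    active <- prs[1, ] != 0L
    out <- matrix(tau2, length(tau2), n_pairs(nt))
    out[, active] <- out[, active] * exp(m)
    out
  } else {
    tau2 <- exp(rnorm(n, 0, str$s))
    off <- str$offsets[cbind(prs[1, ] + 1L, prs[2, ] + 1L)]
    outer(tau2, exp(off))
  }
}

#' @export
het_logprior_natural.het_proportional <- function(str, het, nt) {
  if (str$vague) {
    if (!prop_vague_psd(het$m, nt - 1L)) return(-Inf)
    stats::dunif(het$tau, 0, str$upper, log = TRUE) +
      dnorm(het$m, 0, 0.5, log = TRUE)
  } else {
    dlnorm(het$tau2, 0, str$s, log = TRUE)
  }
}

## ---- approach 3: arm-based variances + spherical correlations --------------

armbased_angle_prior <- function(str, nt) {
  if (!is.null(str$angle_prior)) str$angle_prior else angle_prior(nt)
}

#' @export
het_npar.het_arm_based <- function(str, nt) nt + n_pairs(nt)

#' @export
het_par_names.het_arm_based <- function(str, nt) {
  prs <- treatment_pairs(nt)
  c(paste0("tau", seq_len(nt) - 1L),
    paste0("c", prs[1, ], "_", prs[2, ]))
}

#' @export
het_init.het_arm_based <- function(str, nt) {
  tpar <- if (str$vague) runif(nt, 0.05, str$upper / 2) else
    rnorm(nt, str$arm_prior$m, 0.5)
  c(tpar, rnorm(n_pairs(nt), 0, 0.3))
}

#' @export
het_logprior.het_arm_based <- function(str, par, nt) {
  tpar <- par[seq_len(nt)]
  z <- par[-seq_len(nt)]
  lp <- if (str$vague) {
    if (any(tpar <= 0 | tpar >= str$upper)) return(-Inf)
    -nt * log(str$upper)
  } else {
    sum(dnorm(tpar, str$arm_prior$m, str$arm_prior$s, log = TRUE))
  }
  ap <- armbased_angle_prior(str, nt)
  cc <- plogis(z)
  ## Beta density for c = logistic(z), with Jacobian c(1 - c)
  lp + sum(dbeta(cc, ap$a, ap$b, log = TRUE) + log(cc) + log1p(-cc))
}

#' @export
het_sigma.het_arm_based <- function(str, par, nt) {
  tau <- if (str$vague) par[seq_len(nt)] else exp(par[seq_len(nt)] / 2)
  cc <- plogis(par[-seq_len(nt)])
  R <- spherical_to_correlation(cc)$R
  sigma_arm_based(tau, R)
}

#' @export
het_monitor.het_arm_based <- function(str, par, nt) {
  tau <- if (str$vague) par[seq_len(nt)] else exp(par[seq_len(nt)] / 2)
  setNames(tau, paste0("tau", seq_len(nt) - 1L))
}

## vectorized spherical construction over n draws: C is n x npairs matrix of
## cosines (combn order); returns function rho(k, l) giving n-vector
spherical_rho_draws <- function(C, nt) {
  n <- nrow(C)
  pair_col <- matrix(0L, nt, nt)
  prs <- utils::combn(nt, 2L)
  pair_col[t(prs)] <- seq_len(ncol(prs))
  L <- vector("list", nt)
  L[[1]] <- list(rep(1, n))
  for (j in 2:nt) {
    col <- vector("list", j)
    sprod <- rep(1, n)
    for (i in 1:(j - 1)) {
      cij <- C[, pair_col[i, j]]
      col[[i]] <- cij * sprod
      sprod <- sprod * sqrt(1 - cij^2)
    }
    col[[j]] <- sprod
    L[[j]] <- col
  }
  function(k, l) {
    out <- rep(0, n)
    for (m in seq_len(min(k, l))) out <- out + L[[k]][[m]] * L[[l]][[m]]
    out
  }
}

#' @export
het_sample_prior.het_arm_based <- function(str, nt, n) {
  ap <- armbased_angle_prior(str, nt)
  tau <- if (str$vague) {
    matrix(runif(n * nt, 0, str$upper), n, nt)
  } else {
    matrix(exp(rnorm(n * nt, str$arm_prior$m, str$arm_prior$s) / 2), n, nt)
  }
  C <- matrix(rbeta(n * n_pairs(nt), ap$a, ap$b), n, n_pairs(nt))
  rho <- spherical_rho_draws(C, nt)
  prs <- treatment_pairs(nt)
  out <- matrix(NA_real_, n, ncol(prs))
  for (q in seq_len(ncol(prs))) {
    k <- prs[1, q] + 1L
    l <- prs[2, q] + 1L
    out[, q] <- tau[, k]^2 + tau[, l]^2 - 2 * rho(k, l) * tau[, k] * tau[, l]
  }
  out
}

#' @export
het_logprior_natural.het_arm_based <- function(str, het, nt) {
  ap <- armbased_angle_prior(str, nt)
  lp <- if (str$vague) {
    sum(stats::dunif(het$tau, 0, str$upper, log = TRUE))
  } else {
    sum(dlnorm(het$tau^2, str$arm_prior$m, str$arm_prior$s, log = TRUE))
  }
  lp + sum(dbeta(het$cosines, ap$a, ap$b, log = TRUE))
}

## ---- approach 4: scaled inverse Wishart ------------------------------------

## parameter layout: log(lambda), log-diagonal of U (p), upper off-diagonals
## of U column-major (p(p-1)/2), where M = U'U

#' @export
het_npar.het_scaled_wishart <- function(str, nt) {
  p <- nt - 1L
  1L + p + p * (p - 1L) / 2L
}

#' @export
het_par_names.het_scaled_wishart <- function(str, nt) {
  p <- nt - 1L
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  c("log_lambda", paste0("logU", seq_len(p), seq_len(p)),
    if (p > 1) paste0("U", idx[, 1], idx[, 2]))
}

wishart_unpack <- function(par, p) {
  U <- matrix(0, p, p)
  diag(U) <- exp(par[1L + seq_len(p)])
  if (p > 1) U[upper.tri(U)] <- par[-seq_len(1L + p)]
  U
}

## log density of M ~ Wishart(rate S, df t): the convention in which
## Sigma_kk ~ IG((t-p+1)/2, S_kk/2) marginally for Sigma = M^{-1}
dwishart_rate_log <- function(M, S, t) {
  p <- nrow(M)
  cM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(cM)) return(-Inf)
  ldetM <- 2 * sum(log(diag(cM)))
  ldetS <- 2 * sum(log(diag(chol(S))))
  (t - p - 1) / 2 * ldetM - sum(S * M) / 2 +
    t / 2 * ldetS - t * p / 2 * log(2) - lmvgamma(t / 2, p)
}

lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

#' @export
het_logprior.het_scaled_wishart <- function(str, par, nt) {
  sp <- str$spec
  p <- sp$p
  U <- wishart_unpack(par, p)
  M <- crossprod(U)
  ldiag <- log(diag(U))
  ## Jacobian: M -> U is 2^p prod u_ii^(p-i+1); diag is sampled on log scale
  ljac <- p * log(2) + sum((p - seq_len(p) + 1) * ldiag) + sum(ldiag)
  dnorm(par[1], sp$m_lambda, sp$s_lambda, log = TRUE) +
    dwishart_rate_log(M, sp$S, sp$t) + ljac
}

#' @export
het_init.het_scaled_wishart <- function(str, nt) {
  sp <- str$spec
  p <- sp$p
  U <- chol(sp$t * solve(sp$S))   # Wishart mean under the rate convention
  c(rnorm(1, sp$m_lambda, 0.3), log(diag(U)) + rnorm(p, 0, 0.05),
    if (p > 1) U[upper.tri(U)] + rnorm(p * (p - 1) / 2, 0, 0.05))
}

#' @export
het_sigma.het_scaled_wishart <- function(str, par, nt) {
  p <- str$spec$p
  stopifnot(nt - 1L == p)
  U <- wishart_unpack(par, p)
  exp(par[1]) * chol2inv(U)
}

#' @export
het_monitor.het_scaled_wishart <- function(str, par, nt) {
  c(lambda = exp(par[1]))
}

#' @export
het_sample_prior.het_scaled_wishart <- function(str, nt, n) {
  sp <- str$spec
  p <- sp$p
  stopifnot(nt - 1L == p)
  lam <- exp(rnorm(n, sp$m_lambda, sp$s_lambda))
  W <- rWishart(n, df = sp$t, Sigma = solve(sp$S))
  Winv <- invert_spd_array(W)
  prs <- treatment_pairs(nt)
  out <- matrix(NA_real_, n, ncol(prs))
  for (q in seq_len(ncol(prs))) {
    k <- prs[1, q]
    l <- prs[2, q]
    out[, q] <- if (k == 0L) {
      Winv[l, l, ]
    } else {
      Winv[k, k, ] + Winv[l, l, ] - 2 * Winv[k, l, ]
    }
  }
  lam * out
}

## invert an array of symmetric positive definite matrices; closed forms for
## p <= 3 (vectorized), chunked solve() otherwise
invert_spd_array <- function(W) {
  p <- dim(W)[1]
  n <- dim(W)[3]
  out <- array(NA_real_, dim(W))
  if (p == 1) {
    out[1, 1, ] <- 1 / W[1, 1, ]
  } else if (p == 2) {
    a <- W[1, 1, ]; b <- W[1, 2, ]; d <- W[2, 2, ]
    det <- a * d - b * b
    out[1, 1, ] <- d / det
    out[2, 2, ] <- a / det
    out[1, 2, ] <- out[2, 1, ] <- -b / det
  } else if (p == 3) {
    a <- W[1, 1, ]; b <- W[1, 2, ]; c3 <- W[1, 3, ]
    d <- W[2, 2, ]; e <- W[2, 3, ]; f <- W[3, 3, ]
    det <- a * (d * f - e * e) - b * (b * f - e * c3) + c3 * (b * e - d * c3)
    out[1, 1, ] <- (d * f - e * e) / det
    out[2, 2, ] <- (a * f - c3 * c3) / det
    out[3, 3, ] <- (a * d - b * b) / det
    out[1, 2, ] <- out[2, 1, ] <- -(b * f - e * c3) / det
    out[1, 3, ] <- out[3, 1, ] <- (b * e - d * c3) / det
    out[2, 3, ] <- out[3, 2, ] <- -(a * e - b * c3) / det
  } else {
    for (i in seq_len(n)) out[, , i] <- chol2inv(chol(W[, , i]))
  }
  out
}

#' @export
het_logprior_natural.het_scaled_wishart <- function(str, het, nt) {
  sp <- str$spec
  dlnorm(het$lambda, sp$m_lambda, sp$s_lambda, log = TRUE) +
    dwishart_rate_log(het$M, sp$S, sp$t)
}
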