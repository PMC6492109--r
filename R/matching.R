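#' Moments of the implied prior for a contrast heterogeneity variance
#'
#' Under the arm-based model the heterogeneity variance of a comparison is
#' \eqn{\tau_{kl}^2 = \tau_k^2 + \tau_l^2 - 2\rho_{kl}\tau_k\tau_l} with
#' \eqn{\tau_k^2, \tau_l^2} independent log-normal\eqn{(m, s^2)} and
#' \eqn{\rho_{kl}} independent of both with mean `rho_mean` and variance
#' `rho_var`.  This function returns the exact mean and variance of the
#' implied prior for \eqn{\tau_{kl}^2}:
#' \deqn{E[\tau_{kl}^2] = 2 e^m e^{s^2/4}\,(e^{s^2/4} - m_\rho)}
#' \deqn{Var[\tau_{kl}^2] = 2 e^{2m} e^{s^2}(e^{s^2}-1) + 4 s_\rho^2 e^{2m} e^{s^2}
#'   + 4 m_\rho^2 e^{2m} e^{s^2/2}(e^{s^2/2}-1)
#'   - 8 m_\rho e^{2m} e^{3 s^2/4}(e^{s^2/2}-1).}
#' The variance follows from expanding
#' \eqn{E[\tau_{kl}^4]} using log-normal moments
#' \eqn{E[(\tau_k^2)^a] = e^{am + a^2 s^2/2}} and the independence of
#' \eqn{\rho_{kl}}; it only involves \eqn{\rho_{kl}} through its first two
#' moments.
#'
#' @param arm A [lognormal_prior()] for the arm-based variances
#'   \eqn{\tau_k^2}, or a numeric `m` (then `s` must be given).
#' @param s Standard deviation of the log arm variance when `arm` is numeric.
#' @param rho_mean,rho_var Prior mean and variance of the between-arm
#'   correlation \eqn{\rho_{kl}}; the defaults approximate a Uniform(0, 1)
#'   correlation conditioned on positive semidefiniteness.
#' @return Named numeric vector with elements `mean` and `var`.
#' @seealso [match_arm_prior()] for the inverse problem.
#' @export
implied_contrast_moments <- function(arm, s = NULL, rho_mean = 0.5,
                                     rho_var = 0.07) {
  if (inherits(arm, "lognormal_prior")) {
    m <- arm$m
    s <- arm$s
  } else {
    stopifnot(is.numeric(arm), !is.null(s))
    m <- arm
  }
  stopifnot(s >= 0, rho_var >= 0)
  e4 <- exp(s^2 / 4)
  e2 <- exp(s^2 / 2)
  e1 <- exp(s^2)
  mn <- 2 * exp(m) * e4 * (e4 - rho_mean)
  vr <- 2 * exp(2 * m) * e1 * (e1 - 1) +
    4 * rho_var * exp(2 * m) * e1 +
    4 * rho_mean^2 * exp(2 * m) * e2 * (e2 - 1) -
    8 * rho_mean * exp(2 * m) * exp(3 * s^2 / 4) * (e2 - 1)
  c(mean = mn, var = vr)
}

## mean and variance of a log-normal(m, s^2) random variable
lognormal_moments <- function(m, s) {
  c(mean = exp(m + s^2 / 2), var = exp(2 * m + s^2) * (exp(s^2) - 1))
}

#' Match an arm-level log-normal prior to a target contrast-level prior
#'
#' Solves the moment-matching equations of the arm-based heterogeneity model:
#' finds \eqn{(m_A, s_A)} such that independent log-normal\eqn{(m_A, s_A^2)}
#' priors for the arm variances \eqn{\tau_k^2}, combined with correlations
#' \eqn{\rho_{kl}} having the stated prior moments, imply a prior for every
#' contrast variance \eqn{\tau_{kl}^2} whose mean and variance equal those of
#' the target log-normal\eqn{(m_D, s_D^2)} distribution.  The implied prior
#' itself is not log-normal.
#'
#' The two equations (see [implied_contrast_moments()]) are solved by a
#' damped Newton iteration on \eqn{(m, \log s)} with relative residual
#' tolerance `tol`, starting from \eqn{(m_D - 0.5, \log s_D)} and restarting
#' from jittered points on failure.
#'
#' @param target A [lognormal_prior()] for \eqn{\tau_{kl}^2} (e.g. from
#'   [predictive_prior()]).
#' @inheritParams implied_contrast_moments
#' @param tol Relative residual tolerance for convergence.
#' @param max_restarts Number of jittered restarts before giving up.
#' @return A [lognormal_prior()] for the arm variances \eqn{\tau_k^2}.
#' @examples
#' match_arm_prior(lognormal_prior(-4.28, 1.61))  # ~ log-N(-4.84, 1.70^2)
#' @export
match_arm_prior <- function(target, rho_mean = 0.5, rho_var = 0.07,
                            tol = 1e-10, max_restarts = 5L) {
  stopifnot(inherits(target, "lognormal_prior"))
  tgt <- lognormal_moments(target$m, target$s)
  resid <- function(par) {
    im <- implied_contrast_moments(par[1], exp(par[2]), rho_mean, rho_var)
    c(im[[1]] / tgt[[1]] - 1, im[[2]] / tgt[[2]] - 1)
  }
  start <- c(target$m - 0.5, log(target$s))
  for (attempt in seq_len(max_restarts + 1L)) {
    par <- start
    if (attempt > 1L) par <- par + stats::rnorm(2L, 0, 0.25 * (attempt - 1L))
    r <- resid(par)
    ok <- FALSE
    for (it in 1:200) {
      if (max(abs(r)) < tol) {
        ok <- TRUE
        break
      }
      J <- matrix(0, 2, 2)
      h <- 1e-7
      for (j in 1:2) {
        pp <- par
        pp[j] <- pp[j] + h
        J[, j] <- (resid(pp) - r) / h
      }
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        r_new <- resid(par - lam * step)
        if (all(is.finite(r_new)) &&
            (max(abs(r_new)) < max(abs(r)) || lam < 1e-4)) break
        lam <- lam / 2
      }
      par <- par - lam * step
      r <- r_new
    }
    if (ok) return(lognormal_prior(par[1], exp(par[2])))
  }
  stop(sprintf(
    "moment matching failed to converge: residuals (%.3g, %.3g)", r[1], r[2]))
}

#' Scaled inverse-Wishart specification
#'
#' Container for the hyperparameters of the scaled inverse-Wishart
#' heterogeneity prior: \eqn{\Sigma^{-1} = M/\lambda} with
#' \eqn{M \sim Wishart(S, t)} (rate parameterization: the marginal for each
#' diagonal entry is \eqn{\Sigma_{kk} \sim IG((t-p+1)/2,\, S_{kk}/2)} when
#' \eqn{\lambda = 1}) and \eqn{\log\lambda \sim N(m_\lambda, s_\lambda^2)}.
#'
#' @param p Dimension of \eqn{\Sigma} (number of non-reference treatments).
#' @param t Degrees of freedom (\eqn{\ge p}).
#' @param S Scale matrix (p x p).
#' @param m_lambda,s_lambda Hyperparameters of \eqn{\log\lambda}.
#' @return An object of class `"scaled_wishart_spec"`.
#' @seealso [match_scaled_wishart()] which constructs matched specifications.
#' @export
scaled_wishart_spec <- function(p, t, S, m_lambda, s_lambda) {
  stopifnot(p >= 1, t >= p, is.matrix(S), nrow(S) == p, ncol(S) == p,
            isSymmetric(S), s_lambda > 0)
  structure(list(p = as.integer(p), t = t, S = S,
                 m_lambda = m_lambda, s_lambda = s_lambda),
            class = "scaled_wishart_spec")
}

#' @export
print.scaled_wishart_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "scaled inverse-Wishart spec: p = %d, t = %g, S_kk = %g, S_kl = %g,\n",
    "  log(lambda) ~ N(%.4f, %.4f^2)\n"),
    x$p, x$t, x$S[1, 1], if (x$p > 1) x$S[1, 2] else NA, x$m_lambda,
    x$s_lambda))
  invisible(x)
}

#' Match a scaled inverse-Wishart prior to a target log-normal prior
#'
#' Chooses the hyperparameters of the scaled inverse-Wishart prior
#' \eqn{\Sigma^{-1} = M/\lambda}, \eqn{M \sim Wishart(S, t)},
#' \eqn{\log\lambda \sim N(m_\lambda, s_\lambda^2)} so that each log
#' heterogeneity variance \eqn{\log \Sigma_{kk}} has the same mean and
#' variance as the target \eqn{\log \tau_{kl}^2 \sim N(m_D, s_D^2)}.  Using
#' the inverse-gamma marginal \eqn{\Sigma_{kk} \sim IG((t-p+1)/2, S_{kk}/2)}
#' (for \eqn{\lambda = 1}), the closed-form solution is
#' \deqn{m_\lambda = m_D - \log(S_{kk}/2) + \psi((t-p+1)/2), \qquad
#'       s_\lambda^2 = s_D^2 - \psi_1((t-p+1)/2),}
#' with \eqn{\psi} and \eqn{\psi_1} the digamma and trigamma functions.
#'
#' The degrees of freedom default to \eqn{t = p + 1}, the smallest value that
#' permits matching the catalogued target variances (at \eqn{t = p} the
#' trigamma term \eqn{\psi_1(1/2) = \pi^2/2} exceeds every catalogued
#' \eqn{s_D^2}) while implying the lowest prior correlation between
#' heterogeneity variances, i.e. the least borrowing across comparisons.  The
#' diagonal scale is fixed at \eqn{S_{kk} = 1} (its magnitude is absorbed by
#' \eqn{m_\lambda}) and the off-diagonals at \eqn{S_{kl} = S_{kk}/2}, which
#' makes the implied priors for non-reference contrast variances
#' \eqn{\Sigma_{kk} + \Sigma_{ll} - 2\Sigma_{kl}} identical to those for the
#' reference contrasts.
#'
#' @param target A [lognormal_prior()] for \eqn{\tau_{kl}^2}.
#' @param p Dimension of \eqn{\Sigma}.
#' @param t Degrees of freedom; default \eqn{p + 1}.
#' @return A [scaled_wishart_spec()].
#' @examples
#' match_scaled_wishart(lognormal_prior(-4.28, 1.61), p = 7)
#' @export
match_scaled_wishart <- function(target, p, t = p + 1) {
  stopifnot(inherits(target, "lognormal_prior"), p >= 1, t >= p)
  a <- (t - p + 1) / 2
  tri <- trigamma(a)
  if (target$s^2 <= tri) {
    stop(sprintf(paste0(
      "target log-variance s_D^2 = %.4f does not exceed trigamma((t-p+1)/2)",
      " = %.4f; matching is infeasible at these degrees of freedom ",
      "(t = p would require s_D^2 > pi^2/2)"), target$s^2, tri))
  }
  S <- matrix(0.5, p, p)
  diag(S) <- 1
  scaled_wishart_spec(
    p = p, t = t, S = S,
    m_lambda = target$m - log(1 / 2) + digamma(a),
    s_lambda = sqrt(target$s^2 - tri))
}

#' Proportional-heterogeneity prior specification for a network
#'
#' Builds the inputs of the proportional-variances model (approach 2) from a
#' catalog context: every contrast \eqn{k, l} receives the log offset
#' \eqn{m_{kl}} of its comparison type's catalogued prior, and the common
#' log-scale standard deviation \eqn{s} is the weighted average of the
#' catalogued standard deviations, weighted by the number of study
#' comparisons of each type in the network.  The model is then
#' \eqn{\tau^2 \sim} log-normal\eqn{(0, s^2)},
#' \eqn{\tau_{kl}^2 = \tau^2 e^{m_{kl}}}.
#'
#' @param network An [nma_network()].
#' @param context Catalog context key passed to [comparison_prior()].
#' @param extra Optional extra catalog rows, see [comparison_prior()].
#' @return A list with elements `offsets` (symmetric matrix of \eqn{m_{kl}}
#'   over treatments, zero diagonal), `s` (common log-scale SD), and
#'   `weights` (study count per comparison type), ready for
#'   [het_proportional()].
#' @export
proportional_spec <- function(network, context, extra = NULL) {
  stopifnot(inherits(network, "nma_network"))
  nt <- nrow(network$treatments)
  klass <- network$treatments$class
  labels <- network$treatments$label
  offsets <- matrix(0, nt, nt, dimnames = list(labels, labels))
  ## study counts per comparison type (multi-arm studies contribute one
  ## count per within-study pair)
  counts <- integer(0)
  for (st in network$studies) {
    prs <- utils::combn(sort(st$treatments), 2L)
    for (i in seq_len(ncol(prs))) {
      ty <- classify_comparison(klass[prs[1, i] + 1L], klass[prs[2, i] + 1L])
      counts[ty] <- if (is.na(counts[ty])) 1L else counts[ty] + 1L
    }
  }
  counts <- counts[!is.na(counts)]
  svals <- numeric(length(counts))
  names(svals) <- names(counts)
  for (ty in names(counts)) svals[ty] <- comparison_prior(context, ty, extra)$s
  s <- sum(counts * svals) / sum(counts)
  for (k in 1:(nt - 1)) {
    for (l in (k + 1):nt) {
      ty <- classify_comparison(klass[k], klass[l])
      pr <- comparison_prior(context, ty, extra)
      offsets[k, l] <- offsets[l, k] <- pr$m
    }
  }
  list(offsets = offsets, s = s, weights = counts)
}
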