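#' Correlation matrix from spherical angles
#'
#' Builds a valid between-arm correlation matrix \eqn{R} from the cosines
#' \eqn{c_{kl} = \cos(\phi_{kl}) \in (0, 1)} of spherical angles via the
#' Cholesky construction \eqn{R = L^T L}: column \eqn{j} of the
#' upper-triangular \eqn{L} uses the angles \eqn{\phi_{1j}, \ldots,
#' \phi_{(j-1)j}} in order,
#' \deqn{L_{ij} = \cos\phi_{ij} \prod_{m<i} \sin\phi_{mj} \ (i < j), \qquad
#'       L_{jj} = \prod_{m<j} \sin\phi_{mj},}
#' which guarantees positive semidefiniteness for any angles.  For three
#' treatments this reduces to \eqn{\rho_{12} = \cos\phi_{12}},
#' \eqn{\rho_{13} = \cos\phi_{13}},
#' \eqn{\rho_{23} = \cos\phi_{12}\cos\phi_{13} +
#' \sin\phi_{12}\sin\phi_{13}\cos\phi_{23}}.
#'
#' @param cosines Either a numeric vector of length `choose(n, 2)` with the
#'   cosines of the unordered pairs in `combn(n, 2)` order, or a symmetric
#'   matrix whose upper triangle holds them.
#' @return A list of class `"correlation_matrix"` with elements `R` (the
#'   correlation matrix) and `L` (its upper-triangular Cholesky factor,
#'   \eqn{R = L^T L}).
#' @examples
#' spherical_to_correlation(rep(0, 3))$R        # identity (angles pi/2)
#' spherical_to_correlation(c(0.5, 0.5, 0.5))$R
#' @export
spherical_to_correlation <- function(cosines) {
  if (is.matrix(cosines)) {
    n <- nrow(cosines)
    idx <- utils::combn(n, 2L)
    cosines <- cosines[cbind(idx[1, ], idx[2, ])]
  } else {
    n <- (1 + sqrt(1 + 8 * length(cosines))) / 2
    if (n != round(n)) stop("length of cosines must be choose(n, 2)")
    n <- as.integer(n)
  }
  if (any(cosines <= -1 | cosines >= 1)) {
    stop("cosines must lie in (-1, 1)")
  }
  C <- matrix(0, n, n)
  C[lower.tri(C)] <- cosines   # combn order fills by column of lower triangle
  C <- C + t(C)
  L <- matrix(0, n, n)
  L[1, 1] <- 1
  for (j in 2:n) {
    sprod <- 1
    for (i in 1:(j - 1)) {
      cij <- C[i, j]
      L[i, j] <- cij * sprod
      sprod <- sprod * sqrt(1 - cij^2)
    }
    L[j, j] <- sprod
  }
  R <- crossprod(L)
  R[abs(R) > 1] <- sign(R[abs(R) > 1])  # guard rounding at |rho| = 1
  diag(R) <- 1
  structure(list(R = R, L = L), class = "correlation_matrix")
}

#' Positive semidefiniteness check
#'
#' Checks symmetry and positive semidefiniteness by symmetric eigenvalue
#' decomposition with a relative tolerance: the smallest eigenvalue must be
#' at least `-tol` times the largest (in magnitude).
#'
#' @param m Symmetric matrix.
#' @param tol Relative tolerance (default `1e-8`).
#' @return Logical.
#' @export
is_psd <- function(m, tol = 1e-8) {
  if (!isSymmetric(m, tol = 1e-8)) return(FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1e-300)
  min(ev) >= -tol * scale
}

#' Contrast covariance under equal heterogeneity variances
#'
#' Builds \eqn{\Sigma = \tau^2 P} with \eqn{P} the \eqn{p \times p} matrix
#' with unit diagonal and off-diagonal entries 0.5, so every contrast
#' variance \eqn{\tau_{kl}^2} equals \eqn{\tau^2}.  \eqn{P} has eigenvalues
#' \eqn{(p+1)/2} and \eqn{1/2}, hence \eqn{\Sigma} is positive definite for
#' \eqn{\tau^2 > 0}.
#'
#' @param tau2 Common heterogeneity variance (\eqn{\ge 0}).
#' @param p Number of non-reference treatments.
#' @return A `p` x `p` covariance matrix over the basic contrasts.
#' @export
sigma_common <- function(tau2, p) {
  stopifnot(length(tau2) == 1L, is.finite(tau2), p >= 1)
  if (tau2 < 0) stop("tau2 must be non-negative")
  S <- matrix(tau2 / 2, p, p)
  diag(S) <- tau2
  S
}

#' Contrast covariance under proportional heterogeneity variances
#'
#' Builds \eqn{\Sigma} such that every contrast variance is
#' \eqn{\tau_{kl}^2 = \tau^2 e^{m_{kl}}}: the diagonal is
#' \eqn{\Sigma_{kk} = \tau^2 e^{m_{0k}}} and the off-diagonals invert the
#' contrast-variance identity,
#' \eqn{\Sigma_{kl} = (\tau^2 e^{m_{0k}} + \tau^2 e^{m_{0l}} -
#' \tau^2 e^{m_{kl}})/2}.  Whether the result is positive semidefinite
#' depends only on the offsets, not on \eqn{\tau^2}.
#'
#' @param tau2 Scale variance (\eqn{\ge 0}).
#' @param offsets Symmetric `(p+1)` x `(p+1)` matrix of log offsets
#'   \eqn{m_{kl}} over all treatments including the reference (row/column 1),
#'   zero diagonal.
#' @param check If `TRUE` (default), error when the result is not positive
#'   semidefinite, naming the offending eigenvalue.
#' @return A `p` x `p` covariance matrix over the basic contrasts.
#' @export
sigma_proportional <- function(tau2, offsets, check = TRUE) {
  stopifnot(is.matrix(offsets), nrow(offsets) == ncol(offsets),
            isSymmetric(unname(offsets), tol = 1e-10))
  if (tau2 < 0) stop("tau2 must be non-negative")
  nt <- nrow(offsets)
  p <- nt - 1L
  stopifnot(p >= 1)
  v0 <- tau2 * exp(offsets[1, -1])        # tau_{0k}^2
  S <- matrix(0, p, p)
  for (k in seq_len(p)) {
    for (l in seq_len(p)) {
      S[k, l] <- if (k == l) v0[k] else {
        (v0[k] + v0[l] - tau2 * exp(offsets[k + 1, l + 1])) / 2
      }
    }
  }
  if (check && tau2 > 0 && !is_psd(S)) {
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    stop(sprintf(paste0(
      "proportional offsets imply a non positive-semidefinite contrast ",
      "covariance (smallest eigenvalue %.3g); second-order consistency ",
      "would be violated"), min(ev)))
  }
  S
}

#' Contrast covariance from arm-based variances and correlations
#'
#' Builds \eqn{\Sigma} for the basic contrasts \eqn{\delta_{j0k} =
#' \theta_{jk} - \theta_{j0}} from latent arm standard deviations
#' \eqn{\tau_k} and a between-arm correlation matrix \eqn{R}:
#' \deqn{\Sigma_{kk} = \tau_0^2 + \tau_k^2 - 2\rho_{0k}\tau_0\tau_k, \qquad
#'  \Sigma_{kl} = \tau_0^2 + \rho_{kl}\tau_k\tau_l - \rho_{0k}\tau_0\tau_k -
#'  \rho_{0l}\tau_0\tau_l,}
#' so that every contrast variance satisfies
#' \eqn{\tau_{kl}^2 = \tau_k^2 + \tau_l^2 - 2\rho_{kl}\tau_k\tau_l}.
#' \eqn{\Sigma} is positive semidefinite whenever \eqn{R} is.
#'
#' @param tau Vector of arm standard deviations \eqn{\tau_0, \ldots, \tau_p}
#'   (\eqn{\ge 0}).
#' @param R Between-arm correlation matrix (`(p+1)` x `(p+1)`), e.g. from
#'   [spherical_to_correlation()].
#' @return A `p` x `p` covariance matrix over the basic contrasts.
#' @export
sigma_arm_based <- function(tau, R) {
  if (inherits(R, "correlation_matrix")) R <- R$R
  nt <- length(tau)
  stopifnot(nt >= 2, all(tau >= 0), is.matrix(R), nrow(R) == nt,
            ncol(R) == nt)
  ## covariance of theta_k - theta_0 and theta_l - theta_0
  D <- diag(tau, nt)
  V <- D %*% R %*% D                       # Cov(theta)
  A <- cbind(-1, diag(1, nt - 1))          # contrasts with arm 0
  A %*% V %*% t(A)
}

#' Heterogeneity variance of an arbitrary comparison
#'
#' Extracts \eqn{\tau_{kl}^2 = Var(\delta_{j0k} - \delta_{j0l}) =
#' \Sigma_{kk} + \Sigma_{ll} - 2\Sigma_{kl}} from a contrast covariance
#' matrix; comparisons with the reference (\eqn{k = 0}) give
#' \eqn{\Sigma_{ll}}.
#'
#' @param Sigma `p` x `p` contrast covariance matrix.
#' @param k,l Treatment ids in `0:p`, `k != l`.
#' @return The heterogeneity variance \eqn{\tau_{kl}^2}.
#' @export
contrast_variance <- function(Sigma, k, l) {
  stopifnot(k != l, k >= 0, l >= 0, k <= nrow(Sigma), l <= nrow(Sigma))
  if (k == 0) return(Sigma[l, l])
  if (l == 0) return(Sigma[k, k])
  Sigma[k, k] + Sigma[l, l] - 2 * Sigma[k, l]
}

#' Covariance of the contrasts reported by one trial
#'
#' Re-bases the network-level contrast covariance \eqn{\Sigma} (contrasts
#' with the reference treatment) to the contrasts a given trial actually
#' forms: \eqn{\delta_{jbk}} for each non-baseline arm \eqn{k}, with
#' \eqn{b} the trial baseline.  Variances are the contrast variances
#' \eqn{\tau_{bk}^2} and covariances follow the usual multi-arm identity
#' \eqn{Cov(\delta_{jbk}, \delta_{jbl}) = (\tau_{bk}^2 + \tau_{bl}^2 -
#' \tau_{kl}^2)/2}.
#'
#' @param Sigma `p` x `p` contrast covariance matrix.
#' @param arms Treatment ids present in the trial (subset of `0:p`).
#' @param baseline Baseline treatment id (must be in `arms`).
#' @return Covariance matrix of dimension `length(arms) - 1`, ordered by
#'   increasing treatment id of the non-baseline arms.
#' @export
trial_contrast_covariance <- function(Sigma, arms, baseline = min(arms)) {
  stopifnot(baseline %in% arms)
  ks <- sort(setdiff(arms, baseline))
  m <- length(ks)
  V <- matrix(0, m, m)
  for (i in seq_len(m)) {
    V[i, i] <- contrast_variance(Sigma, baseline, ks[i])
    if (i < m) {
      for (j in (i + 1):m) {
        V[i, j] <- V[j, i] <-
          (contrast_variance(Sigma, baseline, ks[i]) +
             contrast_variance(Sigma, baseline, ks[j]) -
             contrast_variance(Sigma, ks[i], ks[j])) / 2
      }
    }
  }
  dimnames(V) <- list(ks, ks)
  V
}

#' Sequential conditional decomposition of a multivariate normal
#'
#' Factorizes \eqn{N(\mu, V)} into ordered univariate conditionals
#' \eqn{x_1,\; x_2 \mid x_1,\; \ldots}, as used to express the correlated
#' random effects of a multi-arm trial as a sequence of draws each
#' conditional on the previous ones.  Component \eqn{i} has conditional mean
#' \eqn{\mu_i + c_i^T (x_{<i} - \mu_{<i})} and a fixed conditional variance.
#' Singular leading submatrices are handled with the pseudo-inverse, giving
#' zero conditional variance for fully determined components.
#'
#' @param mean Mean vector.
#' @param cov Covariance matrix (positive semidefinite).
#' @return A list of length `length(mean)`; element `i` has `coef` (length
#'   `i - 1`), `var`, and a function `mean_fn(x_prev)`.
#' @export
conditional_factors <- function(mean, cov) {
  d <- length(mean)
  stopifnot(is.matrix(cov), nrow(cov) == d, ncol(cov) == d)
  out <- vector("list", d)
  for (i in seq_len(d)) {
    if (i == 1L) {
      coef <- numeric(0)
      v <- cov[1, 1]
    } else {
      V11 <- cov[seq_len(i - 1), seq_len(i - 1), drop = FALSE]
      v12 <- cov[seq_len(i - 1), i]
      V11inv <- tryCatch(solve(V11), error = function(e) pseudo_inverse(V11))
      coef <- drop(V11inv %*% v12)
      v <- max(cov[i, i] - sum(v12 * coef), 0)
    }
    mu_i <- mean[i]
    mu_prev <- mean[seq_len(i - 1)]
    out[[i]] <- list(
      coef = coef, var = v,
      mean_fn = local({
        coef_i <- coef; mu_ii <- mu_i; mu_prev_i <- mu_prev
        function(x_prev) mu_ii + sum(coef_i * (x_prev - mu_prev_i))
      }))
  }
  out
}

pseudo_inverse <- function(m, tol = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 1e-300)
  if (!any(pos)) return(matrix(0, nrow(m), ncol(m)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

## log density of N(mean, cov) evaluated via the sequential decomposition;
## equals the joint density when cov is positive definite
mvn_logdensity_seq <- function(x, mean, cov) {
  fac <- conditional_factors(mean, cov)
  ll <- 0
  for (i in seq_along(x)) {
    mu_i <- fac[[i]]$mean_fn(x[seq_len(i - 1)])
    v <- fac[[i]]$var
    if (v <= 0) {
      ll <- ll + if (abs(x[i] - mu_i) < 1e-8) 0 else -Inf
    } else {
      ll <- ll + dnorm(x[i], mu_i, sqrt(v), log = TRUE)
    }
  }
  ll
}

## fast joint MVN log density given a Cholesky factor (upper) of cov
mvn_logdensity_chol <- function(x, mean, chol_cov) {
  z <- backsolve(chol_cov, x - mean, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(chol_cov))) -
    0.5 * length(x) * log(2 * pi)
}
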