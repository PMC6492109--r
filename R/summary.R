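## pooled draw matrix across chains for all monitored quantities, with the
## functional contrasts expanded from the basic parameters
fit_draw_matrix <- function(fit, functional = TRUE, per_chain = FALSE) {
  nt <- nrow(fit$network$treatments)
  labels <- fit$network$treatments$label
  expand <- function(dr) {
    out <- cbind(dr$d, dr$tau, dr$het)
    if (functional && nt > 2) {
      prs <- fit$pairs
      extra <- prs[, prs[1, ] != 0L, drop = FALSE]
      if (ncol(extra)) {
        fc <- dr$d[, extra[2, ], drop = FALSE] -
          dr$d[, extra[1, ], drop = FALSE]
        colnames(fc) <- paste0("d_", pair_labels(extra, labels))
        out <- cbind(out, fc)
      }
    }
    out
  }
  mats <- lapply(fit$draws, expand)
  if (per_chain) mats else do.call(rbind, mats)
}

#' Posterior summaries for a fitted model
#'
#' Pooled-chain posterior medians and equal-tailed credible intervals for
#' the basic parameters, all functional contrasts, all pairwise
#' heterogeneity standard deviations \eqn{\tau_{kl}}, and structure-specific
#' hyperparameters.  Quantiles use linear interpolation of order statistics
#' (type 7).
#'
#' @param object An [nma_fit()].
#' @param level Credible level (default 0.95).
#' @param ... Unused.
#' @return A data frame with columns `parameter`, `median`, `lower`,
#'   `upper`.
#' @export
summary.nma_fit <- function(object, level = 0.95, ...) {
  m <- fit_draw_matrix(object)
  if (nrow(m) == 0L) stop("no post-burn-in draws to summarize")
  a <- (1 - level) / 2
  qs <- t(apply(m, 2, quantile, probs = c(0.5, a, 1 - a), names = FALSE))
  out <- data.frame(parameter = colnames(m), median = qs[, 1],
                    lower = qs[, 2], upper = qs[, 3],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("nma_summary", "data.frame")
  attr(out, "level") <- level
  out
}

#' @export
print.nma_summary <- function(x, digits = 2, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  cat(sprintf("posterior medians and %g%% credible intervals\n",
              100 * attr(x, "level")))
  cat(sprintf("%-12s %8s (%s, %s)\n", x$parameter, fmt(x$median),
              fmt(x$lower), fmt(x$upper)), sep = "")
  invisible(x)
}

#' Convergence diagnostics
#'
#' Split-chain potential scale reduction factors (split R-hat) and effective
#' sample sizes for every monitored quantity.  Each chain is split in half,
#' and R-hat compares between- and within-half variances; the effective
#' sample size uses the initial-positive-sequence autocorrelation estimator
#' on the pooled chains.
#'
#' @param fit An [nma_fit()] with at least 2 chains (or one chain of at
#'   least 4 draws, split in two).
#' @param threshold Flag quantities with R-hat above this value.
#' @return Data frame with columns `parameter`, `rhat`, `ess`, `flagged`.
#' @export
convergence <- function(fit, threshold = 1.01) {
  mats <- fit_draw_matrix(fit, per_chain = TRUE)
  params <- colnames(mats[[1]])
  rhat <- vapply(seq_along(params), function(j) {
    split_rhat(lapply(mats, function(m) m[, j]))
  }, 0)
  ess <- vapply(seq_along(params), function(j) {
    sum(vapply(mats, function(m) ess_ips(m[, j]), 0))
  }, 0)
  data.frame(parameter = params, rhat = rhat, ess = ess,
             flagged = is.finite(rhat) & rhat > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

## split-chain R-hat (each chain halved; between/within variance ratio)
split_rhat <- function(chains) {
  halves <- list()
  for (x in chains) {
    n <- length(x) %/% 2
    if (n < 2) return(NA_real_)
    halves <- c(halves, list(x[seq_len(n)], x[n + seq_len(n)]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## effective sample size by the initial positive sequence estimator
ess_ips <- function(x, max_lag = min(length(x) - 1L, 1000L)) {
  n <- length(x)
  if (n < 4 || var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  s <- 0
  k <- 1
  while (k + 1 <= length(ac) - 1) {
    pair <- ac[k + 1] + ac[k + 2]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

#' Forward Monte-Carlo characterization of a heterogeneity prior
#'
#' Samples the heterogeneity block of a structure (no data, no other model
#' parameters) and summarizes the implied priors for every pairwise
#' heterogeneity SD \eqn{\tau_{kl}}: per-comparison quantiles, quantiles
#' pooled across all comparisons, and the Pearson correlation matrix of the
#' log heterogeneity variances, together with its averages over comparison
#' pairs sharing a treatment and over disjoint pairs.
#'
#' @param structure A [het_structure] object.
#' @param n_treatments Number of treatments in the network.
#' @param n_draws Number of Monte-Carlo draws (default `1e6`).
#' @param seed Integer seed.
#' @return An object of class `"prior_mc"`: list with `pair_names`,
#'   `quantiles` (matrix, rows = comparisons), `pooled_quantiles`,
#'   `logtau2_cor`, `cor_shared`, `cor_disjoint`, `logtau2_mean`,
#'   `logtau2_var`, `n_draws`, `n_effective` (draws retained after any
#'   positive-semidefiniteness conditioning), and `seed`.
#' @export
prior_monte_carlo <- function(structure, n_treatments, n_draws = 1e6,
                              seed = 1L) {
  stopifnot(inherits(structure, "het_structure"), n_treatments >= 2)
  if (inherits(structure, "het_arm_based") &&
      is.null(structure$angle_prior)) {
    structure$angle_prior <- angle_prior(n_treatments)
  }
  set.seed(seed)
  tau2 <- het_sample_prior(structure, as.integer(n_treatments),
                           as.integer(n_draws))
  prs <- treatment_pairs(n_treatments)
  pn <- pair_labels(prs, LETTERS[seq_len(n_treatments)])
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  tau <- sqrt(tau2)
  qs <- t(apply(tau, 2, quantile, probs = probs, names = FALSE))
  dimnames(qs) <- list(pn, paste0(probs * 100, "%"))
  pooled <- quantile(tau, probs = probs, names = FALSE)
  names(pooled) <- paste0(probs * 100, "%")
  lt <- log(tau2)
  cm <- stats::cor(lt)
  dimnames(cm) <- list(pn, pn)
  shared <- disjoint <- c()
  np <- ncol(prs)
  if (np > 1) {
    for (i in seq_len(np - 1)) {
      for (j in (i + 1):np) {
        common <- length(intersect(prs[, i], prs[, j])) > 0
        if (common) shared <- c(shared, cm[i, j]) else
          disjoint <- c(disjoint, cm[i, j])
      }
    }
  }
  structure(list(
    pair_names = pn, quantiles = qs, pooled_quantiles = pooled,
    logtau2_cor = cm,
    cor_shared = if (length(shared)) mean(shared) else NA_real_,
    cor_disjoint = if (length(disjoint)) mean(disjoint) else NA_real_,
    logtau2_mean = colMeans(lt), logtau2_var = apply(lt, 2, var),
    n_draws = n_draws, n_effective = nrow(tau2), seed = seed),
    class = "prior_mc")
}

#' @export
print.prior_mc <- function(x, ...) {
  cat(sprintf("prior Monte Carlo (%d draws kept of %d)\n",
              x$n_effective, x$n_draws))
  cat("tau quantiles by comparison:\n")
  print(round(x$quantiles, 3))
  cat("pooled tau quantiles:\n")
  print(round(x$pooled_quantiles, 3))
  cat(sprintf(
    "mean correlation of log tau^2: %.3f (shared treatment), %.3f (disjoint)\n",
    x$cor_shared, x$cor_disjoint))
  invisible(x)
}
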