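#' MCMC configuration
#'
#' Settings for the adaptive Metropolis-within-Gibbs sampler.  The defaults
#' (4 chains of 100000 sampling iterations after a burn-in of 20000) mirror
#' common practice for these models; proposal step sizes adapt towards an
#' acceptance rate of 0.44 during burn-in only.
#'
#' @param chains Number of independent chains.
#' @param iterations Sampling iterations per chain (after burn-in).
#' @param burn_in Burn-in (adaptation) iterations per chain, discarded.
#' @param thin Thinning interval for stored draws.
#' @param seed Integer seed; chain streams are derived from it, and two runs
#'   with the same configuration produce identical draws.
#' @param adapt_interval Iterations between step-size adaptations.
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(chains = 4L, iterations = 100000L, burn_in = 20000L,
                        thin = 1L, seed = 1L, adapt_interval = 50L) {
  stopifnot(chains >= 1, iterations >= 1, burn_in >= 0, thin >= 1,
            iterations %% thin == 0)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval)),
            class = "mcmc_config")
}

#' All pairwise treatment contrasts from the basic parameters
#'
#' Expands the basic parameters \eqn{d_{01}, \ldots, d_{0p}} into the full
#' antisymmetric matrix of treatment contrasts via the consistency equations
#' \eqn{d_{kl} = d_{0l} - d_{0k}}.
#'
#' @param d Numeric vector of basic parameters (contrasts with treatment 0).
#' @return A `(p+1)` x `(p+1)` antisymmetric matrix `D` with
#'   `D[k+1, l+1]` = \eqn{d_{kl}}.
#' @examples
#' functional_contrasts(c(0.5, 0.8))["1", "2"]  # d_12 = 0.3
#' @export
functional_contrasts <- function(d) {
  d0 <- c(0, d)
  D <- outer(d0, d0, function(a, b) b - a)
  dimnames(D) <- list(seq_along(d0) - 1L, seq_along(d0) - 1L)
  D
}

## ---- internal data preparation ---------------------------------------------

fit_prep <- function(network) {
  arms <- network$arms
  studies <- network$studies
  ns <- length(studies)
  nt <- nrow(network$treatments)
  p <- nt - 1L
  na <- nrow(arms)
  study_ids <- vapply(studies, `[[`, "", "id")
  study_idx <- match(arms$study, study_ids)

  delta_idx_arm <- integer(na)
  delta_study <- integer(0)
  delta_trt <- integer(0)
  delta_row <- integer(0)
  A_list <- vector("list", ns)
  for (j in seq_len(ns)) {
    st <- studies[[j]]
    ks <- st$treatments[-1L]                 # non-baseline, sorted
    rows <- st$rows[-1L]
    idx <- length(delta_study) + seq_along(ks)
    delta_idx_arm[rows] <- idx
    delta_study <- c(delta_study, rep(j, length(ks)))
    delta_trt <- c(delta_trt, ks)
    delta_row <- c(delta_row, rows)
    A <- matrix(0, length(ks), p)
    for (i in seq_along(ks)) {
      A[i, ks[i]] <- 1
      if (st$baseline > 0L) A[i, st$baseline] <- A[i, st$baseline] - 1
    }
    A_list[[j]] <- A
  }
  nd <- length(delta_study)

  n_arms_study <- vapply(studies, function(s) length(s$treatments), 0L)
  two <- which(n_arms_study == 2L)
  multi <- which(n_arms_study > 2L)
  d2_idx <- vapply(two, function(j) delta_idx_arm[studies[[j]]$rows[2L]], 0L)
  d2_row <- delta_row[d2_idx]
  d2_b <- vapply(two, function(j) studies[[j]]$baseline, 0L)
  d2_k <- delta_trt[d2_idx]

  ## sparse triplets for the two-arm contributions to the d-update precision
  ti <- tj <- ts <- tsign <- integer(0)
  ri <- rs <- rsign <- integer(0)
  for (q in seq_along(two)) {
    b <- d2_b[q]
    k <- d2_k[q]
    ti <- c(ti, k); tj <- c(tj, k); ts <- c(ts, q); tsign <- c(tsign, 1L)
    ri <- c(ri, k); rs <- c(rs, q); rsign <- c(rsign, 1L)
    if (b > 0L) {
      ti <- c(ti, b, k, b); tj <- c(tj, b, b, k)
      ts <- c(ts, q, q, q); tsign <- c(tsign, 1L, -1L, -1L)
      ri <- c(ri, b); rs <- c(rs, q); rsign <- c(rsign, -1L)
    }
  }
  list(ns = ns, nt = nt, p = p, na = na, nd = nd,
       study_idx = study_idx, trt = arms$trt, r = arms$events,
       n = arms$total, delta_idx_arm = delta_idx_arm,
       delta_study = delta_study, delta_trt = delta_trt,
       delta_row = delta_row, A_list = A_list, two = two, multi = multi,
       d2_idx = d2_idx, d2_row = d2_row, d2_b = d2_b, d2_k = d2_k,
       trip = list(i = ti, j = tj, s = ts, sign = tsign),
       rtrip = list(i = ri, s = rs, sign = rsign),
       studies = studies, labels = network$treatments$label)
}

## contrast variances for vectors of treatment ids (0-based), given Sigma
cv_vec <- function(Sigma, b, k) {
  dS <- diag(Sigma)
  out <- numeric(length(b))
  z <- b == 0L
  out[z] <- dS[k[z]]
  if (any(!z)) {
    out[!z] <- dS[b[!z]] + dS[k[!z]] - 2 * Sigma[cbind(b[!z], k[!z])]
  }
  out
}

## per-study covariance objects under Sigma; NULL if any factorization fails
sigma_caches <- function(prep, Sigma) {
  v2 <- cv_vec(Sigma, prep$d2_b, prep$d2_k)
  if (any(!is.finite(v2)) || any(v2 <= 0)) return(NULL)
  multi <- lapply(prep$multi, function(j) {
    st <- prep$studies[[j]]
    V <- trial_contrast_covariance(Sigma, st$treatments, st$baseline)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    list(V = V, chol = ch, Vinv = Vinv)
  })
  if (length(multi) && any(vapply(multi, is.null, TRUE))) return(NULL)
  list(v2 = v2, multi = multi)
}

## total random-effects log density given caches, d, delta
re_logdensity <- function(prep, cache, d, delta) {
  m2 <- d[prep$d2_k]
  bpos <- prep$d2_b > 0L
  m2[bpos] <- m2[bpos] - d[prep$d2_b[bpos]]
  out <- sum(dnorm(delta[prep$d2_idx], m2, sqrt(cache$v2), log = TRUE))
  for (q in seq_along(prep$multi)) {
    j <- prep$multi[q]
    st <- prep$studies[[j]]
    idx <- prep$delta_idx_arm[st$rows[-1L]]
    mean_j <- drop(prep$A_list[[j]] %*% d)
    out <- out + mvn_logdensity_chol(delta[idx], mean_j,
                                     cache$multi[[q]]$chol)
  }
  out
}

## ---- the sampler ------------------------------------------------------------

#' Fit a Bayesian network meta-analysis model
#'
#' Samples the posterior of the consistency model for arm-level binary data,
#' \deqn{r_{jk} \sim Bin(\pi_{jk}, n_{jk}), \quad
#'       logit(\pi_{jk}) = \mu_j + \delta_{jbk}\,[k \ne b_j],}
#' with study-specific random effects \eqn{\delta_j \sim N(d, \Sigma)} (the
#' multi-arm covariance handled by re-basing \eqn{\Sigma} to the trial's
#' contrasts and sampling each component conditional on the previous ones),
#' vague \eqn{N(0, 10^4)} priors on the baseline log odds \eqn{\mu_j} and
#' basic parameters \eqn{d_{0k}}, and a heterogeneity prior selected by
#' `structure` (see [het_structure]).
#'
#' The sampler is a seeded component-wise adaptive random-walk
#' Metropolis-within-Gibbs: \eqn{\mu_j} and \eqn{\delta_{jbk}} receive
#' vectorized random-walk updates, the basic parameters are drawn from their
#' exact Gaussian full conditional, and heterogeneity parameters are updated
#' component-wise on transformed scales (log for variances and the Wishart
#' Cholesky diagonal, logit for angle cosines).  Step sizes adapt towards an
#' acceptance rate of 0.44 during burn-in only.
#'
#' @param network An [nma_network()]; must be connected.
#' @param structure A [het_structure] object.
#' @param config An [mcmc_config()].
#' @param prior_only If `TRUE`, drop the binomial likelihood and sample the
#'   joint prior (useful to check the implied heterogeneity priors).
#' @return An object of class `"nma_fit"` with per-chain draws of the basic
#'   parameters, all pairwise heterogeneity SDs \eqn{\tau_{kl}}, and
#'   structure-specific hyperparameters; see [summary.nma_fit()] and
#'   [convergence()].
#' @export
nma_fit <- function(network, structure, config = mcmc_config(),
                    prior_only = FALSE) {
  stopifnot(inherits(network, "nma_network"),
            inherits(structure, "het_structure"),
            inherits(config, "mcmc_config"))
  val <- validate_network(network)
  if (!val$connected) {
    stop("the evidence network is disconnected; fitting requires a ",
         "connected comparison graph")
  }
  if (inherits(structure, "het_arm_based") &&
      is.null(structure$angle_prior)) {
    structure$angle_prior <- angle_prior(nrow(network$treatments))
  }
  prep <- fit_prep(network)
  nt <- prep$nt

  prs <- treatment_pairs(nt)
  pair_names <- paste0("tau_", pair_labels(prs, prep$labels))
  d_names <- paste0("d_", prep$labels[1], prep$labels[-1])

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$chains)

  draws <- vector("list", config$chains)
  accept <- vector("list", config$chains)
  t0 <- proc.time()[["elapsed"]]
  for (ch in seq_len(config$chains)) {
    res <- run_chain(prep, structure, config, chain_seeds[ch], prior_only,
                     prs)
    colnames(res$d) <- d_names
    colnames(res$tau) <- pair_names
    draws[[ch]] <- res[c("d", "tau", "het")]
    accept[[ch]] <- res$accept
  }
  structure(
    list(draws = draws, network = network, het = structure, config = config,
         pairs = prs, pair_names = pair_names, d_names = d_names,
         prior_only = prior_only, accept = accept,
         elapsed = proc.time()[["elapsed"]] - t0),
    class = "nma_fit")
}

run_chain <- function(prep, str, cfg, seed, prior_only, prs) {
  set.seed(seed)
  ns <- prep$ns
  p <- prep$p
  nt <- prep$nt
  nd <- prep$nd
  nh <- het_npar(str, nt)

  ## initial values from empirical logits, jittered
  elogit <- qlogis((prep$r + 0.5) / (prep$n + 1))
  base_row <- vapply(prep$studies, function(s) s$rows[1L], 0L)
  mu <- elogit[base_row] + rnorm(ns, 0, 0.1)
  delta <- elogit[prep$delta_row] - mu[prep$delta_study] + rnorm(nd, 0, 0.1)
  d <- rnorm(p, 0, 0.1)
  hpar <- het_init(str, nt)
  lp_h <- het_logprior(str, hpar, nt)
  Sigma <- het_sigma(str, hpar, nt)
  cache <- sigma_caches(prep, Sigma)
  tries <- 0
  while ((!is.finite(lp_h) || is.null(cache)) && tries < 100) {
    hpar <- het_init(str, nt)
    lp_h <- het_logprior(str, hpar, nt)
    Sigma <- het_sigma(str, hpar, nt)
    cache <- sigma_caches(prep, Sigma)
    tries <- tries + 1
  }
  if (is.null(cache)) stop("could not initialize heterogeneity parameters")

  eta <- mu[prep$study_idx]
  nz <- prep$delta_idx_arm > 0L
  eta[nz] <- eta[nz] + delta[prep$delta_idx_arm[nz]]
  ll_arm <- if (prior_only) numeric(prep$na) else
    dbinom(prep$r, prep$n, plogis(eta), log = TRUE)

  ## adaptive step sizes
  ls_mu <- rep(log(0.3), ns)
  ls_de <- rep(log(0.3), nd)
  ls_h <- rep(log(0.3), nh)
  acc_mu <- int_mu <- numeric(ns)
  acc_de <- int_de <- numeric(nd)
  acc_h <- int_h <- numeric(nh)

  kept <- cfg$iterations %/% cfg$thin
  out_d <- matrix(NA_real_, kept, p)
  out_tau <- matrix(NA_real_, kept, ncol(prs))
  mon0 <- het_monitor(str, hpar, nt)
  out_het <- matrix(NA_real_, kept, length(mon0))
  colnames(out_het) <- names(mon0)

  total_iters <- cfg$burn_in + cfg$iterations
  krow <- 0L
  prior_prec <- 1e-4  # N(0, 10^4) on mu and d

  for (it in seq_len(total_iters)) {
    adapting <- it <= cfg$burn_in

    ## --- baseline log odds mu ------------------------------------------
    if (prior_only) {
      mu <- rnorm(ns, 0, 100)
    } else {
      prop <- mu + exp(ls_mu) * rnorm(ns)
      eta_p <- prop[prep$study_idx]
      eta_p[nz] <- eta_p[nz] + delta[prep$delta_idx_arm[nz]]
      ll_p <- dbinom(prep$r, prep$n, plogis(eta_p), log = TRUE)
      dll <- rowsum(ll_p - ll_arm, prep$study_idx, reorder = TRUE)[, 1]
      logr <- dll + (mu^2 - prop^2) / (2 * 1e4)
      acc <- log(runif(ns)) < logr
      if (any(acc)) {
        mu[acc] <- prop[acc]
        upd <- acc[prep$study_idx]
        eta[upd] <- eta_p[upd]
        ll_arm[upd] <- ll_p[upd]
      }
      acc_mu <- acc_mu + acc
      int_mu <- int_mu + 1
    }

    ## --- random effects delta ------------------------------------------
    if (prior_only) {
      ## draw delta_j ~ N(A_j d, V_j) directly
      m2 <- d[prep$d2_k]
      bpos <- prep$d2_b > 0L
      m2[bpos] <- m2[bpos] - d[prep$d2_b[bpos]]
      delta[prep$d2_idx] <- rnorm(length(m2), m2, sqrt(cache$v2))
      for (q in seq_along(prep$multi)) {
        j <- prep$multi[q]
        st <- prep$studies[[j]]
        idx <- prep$delta_idx_arm[st$rows[-1L]]
        mean_j <- drop(prep$A_list[[j]] %*% d)
        delta[idx] <- mean_j +
          drop(crossprod(cache$multi[[q]]$chol, rnorm(length(idx))))
      }
    } else {
      ## two-arm studies: vectorized random-walk updates
      cur <- delta[prep$d2_idx]
      m2 <- d[prep$d2_k]
      bpos <- prep$d2_b > 0L
      m2[bpos] <- m2[bpos] - d[prep$d2_b[bpos]]
      prop <- cur + exp(ls_de[prep$d2_idx]) * rnorm(length(cur))
      eta_p <- eta[prep$d2_row] - cur + prop
      ll_p <- dbinom(prep$r[prep$d2_row], prep$n[prep$d2_row],
                     plogis(eta_p), log = TRUE)
      logr <- ll_p - ll_arm[prep$d2_row] +
        dnorm(prop, m2, sqrt(cache$v2), log = TRUE) -
        dnorm(cur, m2, sqrt(cache$v2), log = TRUE)
      acc <- log(runif(length(cur))) < logr
      if (any(acc)) {
        delta[prep$d2_idx[acc]] <- prop[acc]
        eta[prep$d2_row[acc]] <- eta_p[acc]
        ll_arm[prep$d2_row[acc]] <- ll_p[acc]
      }
      acc_de[prep$d2_idx] <- acc_de[prep$d2_idx] + acc
      int_de[prep$d2_idx] <- int_de[prep$d2_idx] + 1
      ## multi-arm studies: conditional component updates
      for (q in seq_along(prep$multi)) {
        j <- prep$multi[q]
        st <- prep$studies[[j]]
        rows <- st$rows[-1L]
        idx <- prep$delta_idx_arm[rows]
        mean_j <- drop(prep$A_list[[j]] %*% d)
        Vinv <- cache$multi[[q]]$Vinv
        for (i in seq_along(idx)) {
          di <- idx[i]
          others <- seq_along(idx)[-i]
          cond_var <- 1 / Vinv[i, i]
          cond_mean <- mean_j[i] - cond_var *
            sum(Vinv[i, others] * (delta[idx[others]] - mean_j[others]))
          cur_i <- delta[di]
          prop_i <- cur_i + exp(ls_de[di]) * rnorm(1)
          eta_pi <- eta[rows[i]] - cur_i + prop_i
          ll_pi <- dbinom(prep$r[rows[i]], prep$n[rows[i]],
                          plogis(eta_pi), log = TRUE)
          logr <- ll_pi - ll_arm[rows[i]] +
            dnorm(prop_i, cond_mean, sqrt(cond_var), log = TRUE) -
            dnorm(cur_i, cond_mean, sqrt(cond_var), log = TRUE)
          if (is.finite(logr) && log(runif(1)) < logr) {
            delta[di] <- prop_i
            eta[rows[i]] <- eta_pi
            ll_arm[rows[i]] <- ll_pi
            acc_de[di] <- acc_de[di] + 1
          }
          int_de[di] <- int_de[di] + 1
        }
      }
    }

    ## --- basic parameters d: exact Gaussian full conditional ------------
    P <- matrix(0, p, p)
    rhs <- numeric(p)
    w2 <- 1 / cache$v2
    if (length(prep$trip$i)) {
      vals <- prep$trip$sign * w2[prep$trip$s]
      li <- (prep$trip$j - 1L) * p + prep$trip$i
      tab <- rowsum(vals, li, reorder = TRUE)
      P[as.integer(rownames(tab))] <- P[as.integer(rownames(tab))] + tab[, 1]
      rvals <- prep$rtrip$sign * w2[prep$rtrip$s] *
        delta[prep$d2_idx[prep$rtrip$s]]
      rtab <- rowsum(rvals, prep$rtrip$i, reorder = TRUE)
      rhs[as.integer(rownames(rtab))] <-
        rhs[as.integer(rownames(rtab))] + rtab[, 1]
    }
    for (q in seq_along(prep$multi)) {
      j <- prep$multi[q]
      st <- prep$studies[[j]]
      idx <- prep$delta_idx_arm[st$rows[-1L]]
      A <- prep$A_list[[j]]
      Vinv <- cache$multi[[q]]$Vinv
      P <- P + t(A) %*% Vinv %*% A
      rhs <- rhs + drop(t(A) %*% Vinv %*% delta[idx])
    }
    diag(P) <- diag(P) + prior_prec
    chP <- chol(P)
    mean_d <- backsolve(chP, backsolve(chP, rhs, transpose = TRUE))
    d <- mean_d + backsolve(chP, rnorm(p))

    ## --- heterogeneity block: component-wise MH -------------------------
    re_cur <- re_logdensity(prep, cache, d, delta)
    for (c in seq_len(nh)) {
      hprop <- hpar
      hprop[c] <- hprop[c] + exp(ls_h[c]) * rnorm(1)
      lp_p <- het_logprior(str, hprop, nt)
      int_h[c] <- int_h[c] + 1
      if (!is.finite(lp_p)) next
      Sig_p <- het_sigma(str, hprop, nt)
      cache_p <- sigma_caches(prep, Sig_p)
      if (is.null(cache_p)) next
      re_p <- re_logdensity(prep, cache_p, d, delta)
      if (is.finite(re_p) && log(runif(1)) < (lp_p - lp_h + re_p - re_cur)) {
        hpar <- hprop
        lp_h <- lp_p
        Sigma <- Sig_p
        cache <- cache_p
        re_cur <- re_p
        acc_h[c] <- acc_h[c] + 1
      }
    }

    ## --- adaptation ------------------------------------------------------
    if (adapting && it %% cfg$adapt_interval == 0L) {
      gain <- min(0.25, 2 / sqrt(it / cfg$adapt_interval))
      ls_mu <- ls_mu + gain * (acc_mu / pmax(int_mu, 1) - 0.44)
      ls_de <- ls_de + gain * (acc_de / pmax(int_de, 1) - 0.44)
      ls_h <- ls_h + gain * (acc_h / pmax(int_h, 1) - 0.44)
      acc_mu[] <- int_mu[] <- 0
      acc_de[] <- int_de[] <- 0
      acc_h[] <- int_h[] <- 0
    }

    ## --- record ----------------------------------------------------------
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
      krow <- krow + 1L
      out_d[krow, ] <- d
      out_tau[krow, ] <- sqrt(cv_vec(Sigma, prs[1, ], prs[2, ]))
      out_het[krow, ] <- het_monitor(str, hpar, nt)
    }
  }
  list(d = out_d, tau = out_tau, het = out_het,
       accept = list(mu = acc_mu / pmax(int_mu, 1),
                     delta = acc_de / pmax(int_de, 1),
                     het = acc_h / pmax(int_h, 1)))
}

#' @export
print.nma_fit <- function(x, ...) {
  cat(sprintf(
    "nma_fit: %s heterogeneity, %d chains x %d iterations (burn-in %d)%s\n",
    class(x$het)[1], x$config$chains, x$config$iterations, x$config$burn_in,
    if (x$prior_only) " [prior only]" else ""))
  cat(sprintf("elapsed: %.1f s\n", x$elapsed))
  print(summary(x))
  invisible(x)
}

## ---- exported density pieces -------------------------------------------------

## Sigma from a natural-scale heterogeneity state
het_sigma_natural <- function(str, het, nt) {
  if (inherits(str, "het_common")) {
    tau2 <- if (str$vague) het$tau^2 else het$tau2
    sigma_common(tau2, nt - 1L)
  } else if (inherits(str, "het_proportional")) {
    if (str$vague) {
      sigma_proportional(het$tau^2, prop_offsets(str, het$m, nt),
                         check = FALSE)
    } else {
      sigma_proportional(het$tau2, str$offsets, check = FALSE)
    }
  } else if (inherits(str, "het_arm_based")) {
    sigma_arm_based(het$tau, spherical_to_correlation(het$cosines)$R)
  } else if (inherits(str, "het_scaled_wishart")) {
    het$lambda * chol2inv(chol(het$M))
  } else {
    stop("unknown heterogeneity structure")
  }
}

#' Log likelihood of the arm-level binomial model
#'
#' Evaluates \eqn{\sum_{j,k} \log Bin(r_{jk}; \pi_{jk}, n_{jk})} with
#' \eqn{logit(\pi_{jk}) = \mu_j + \delta_{jbk}} (baseline arms have
#' \eqn{\delta = 0}).
#'
#' @param network An [nma_network()].
#' @param state List with elements `mu` (one per study, in the order of
#'   `network$studies`) and `delta` (list, one numeric vector per study with
#'   the contrasts of its non-baseline arms in increasing treatment order).
#' @return Log likelihood (scalar); `-Inf` for out-of-support states.
#' @export
log_likelihood <- function(network, state) {
  stopifnot(inherits(network, "nma_network"))
  ll <- 0
  for (j in seq_along(network$studies)) {
    st <- network$studies[[j]]
    dj <- c(0, state$delta[[j]])
    eta <- state$mu[j] + dj
    rows <- st$rows
    ll <- ll + sum(dbinom(network$arms$events[rows],
                          network$arms$total[rows], plogis(eta),
                          log = TRUE))
  }
  ll
}

#' Log prior density of the model parameters
#'
#' Sums the vague \eqn{N(0, 10^4)} priors on baselines and basic parameters,
#' the random-effects density of each study's contrasts (factorized through
#' the sequential conditional decomposition, see [conditional_factors()]),
#' and the structure-specific heterogeneity hyperprior evaluated on the
#' natural scale.
#'
#' @param state List with elements `mu`, `delta` (as in [log_likelihood()]),
#'   `d` (basic parameters), and `het` (natural-scale heterogeneity block:
#'   `tau` or `tau2` for [het_common()]; `tau2` and optionally `m` for
#'   [het_proportional()]; `tau` (length nt) and `cosines` for
#'   [het_arm_based()]; `M` and `lambda` for [het_scaled_wishart()]).
#' @param structure A [het_structure] object.
#' @param network An [nma_network()].
#' @return Log prior density (scalar); `-Inf` outside the support.
#' @export
log_prior <- function(state, structure, network) {
  stopifnot(inherits(structure, "het_structure"),
            inherits(network, "nma_network"))
  nt <- nrow(network$treatments)
  if (inherits(structure, "het_arm_based") &&
      is.null(structure$angle_prior)) {
    structure$angle_prior <- angle_prior(nt)
  }
  lp <- het_logprior_natural(structure, state$het, nt)
  if (!is.finite(lp)) return(-Inf)
  lp <- lp + sum(dnorm(state$mu, 0, 100, log = TRUE)) +
    sum(dnorm(state$d, 0, 100, log = TRUE))
  Sigma <- het_sigma_natural(structure, state$het, nt)
  for (j in seq_along(network$studies)) {
    st <- network$studies[[j]]
    ks <- st$treatments[-1L]
    d0 <- c(0, state$d)
    mean_j <- d0[ks + 1L] - d0[st$baseline + 1L]
    V <- trial_contrast_covariance(Sigma, st$treatments, st$baseline)
    lp <- lp + mvn_logdensity_seq(state$delta[[j]], mean_j, V)
  }
  lp
}
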