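#' Log-normal prior for a heterogeneity variance
#'
#' Represents a prior \eqn{\log(\tau^2) \sim N(m, s^2)} for a between-study
#' heterogeneity variance on the log odds-ratio squared scale.  The median of
#' \eqn{\tau^2} is \eqn{e^m} and the median of the heterogeneity standard
#' deviation \eqn{\tau} is \eqn{e^{m/2}}.
#'
#' @param m Mean of the log variance.
#' @param s Standard deviation of the log variance (> 0).
#' @return An object of class `"lognormal_prior"` with elements `m` and `s`.
#' @examples
#' pr <- lognormal_prior(-4.28, 1.61)
#' quantile(pr, c(0.025, 0.5, 0.975))  # quantiles of tau^2
#' @export
lognormal_prior <- function(m, s) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m),
            is.numeric(s), length(s) == 1L, is.finite(s), s > 0)
  structure(list(m = as.numeric(m), s = as.numeric(s)),
            class = "lognormal_prior")
}

#' @export
print.lognormal_prior <- function(x, ...) {
  cat(sprintf("log-Normal(%g, %g^2) prior for a variance (median %.3g)\n",
              x$m, x$s, exp(x$m)))
  invisible(x)
}

#' @param x A `lognormal_prior` object.
#' @param probs Probabilities.
#' @param ... Unused.
#' @rdname lognormal_prior
#' @export
quantile.lognormal_prior <- function(x, probs = c(0.025, 0.5, 0.975), ...) {
  setNames(exp(x$m + x$s * stats::qnorm(probs)), paste0(probs * 100, "%"))
}

#' Beta prior for a correlation-angle cosine
#'
#' Represents a \eqn{Beta(a, b)} prior for \eqn{\cos(\phi_{kl}) \in (0, 1)},
#' the cosine of an angle in the spherical parameterization of the between-arm
#' correlation matrix used by the arm-based heterogeneity model.
#'
#' @param a,b Positive shape parameters.
#' @return An object of class `"beta_prior"` with elements `a` and `b`.
#' @seealso [angle_prior()] for catalog entries tuned by network size.
#' @export
beta_prior <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0,
            is.numeric(b), length(b) == 1L, is.finite(b), b > 0)
  structure(list(a = as.numeric(a), b = as.numeric(b)), class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) prior for cos(phi) (mean %.3f)\n",
              x$a, x$b, x$a / (x$a + x$b)))
  invisible(x)
}

#' Outcome types with catalogued heterogeneity priors
#'
#' @return Character vector of outcome-type keys accepted by
#'   [predictive_prior()] and [arm_prior()].
#' @export
outcome_types <- function() catalog("heterogeneity_priors_outcome")$outcome

#' Data-based predictive prior for a contrast-level heterogeneity variance
#'
#' Returns the catalogued log-normal predictive distribution for the
#' heterogeneity variance \eqn{\tau_{kl}^2} of a binary-outcome comparison,
#' estimated from a large collection of past meta-analyses and indexed by
#' outcome type.  These distributions are suitable as informative priors for
#' the common variance model and as matching targets for the unequal-variance
#' models.
#'
#' @param outcome One of [outcome_types()].
#' @return A [lognormal_prior()] for \eqn{\tau_{kl}^2}.
#' @examples
#' predictive_prior("all_cause_mortality")
#' @export
predictive_prior <- function(outcome) {
  tab <- catalog("heterogeneity_priors_outcome")
  i <- match(outcome, tab$outcome)
  if (is.na(i)) {
    stop("unknown outcome type ", sQuote(outcome),
         "; see outcome_types() for the catalog")
  }
  lognormal_prior(tab$m_d[i], tab$s_d[i])
}

#' Arm-level heterogeneity prior matched to a catalogued predictive prior
#'
#' Returns the catalogued log-normal prior for the latent arm-based variances
#' \eqn{\tau_k^2} whose implied prior for every contrast variance
#' \eqn{\tau_{kl}^2} has the same mean and variance as the corresponding
#' predictive distribution from [predictive_prior()], assuming between-arm
#' correlations with prior mean 0.5 and variance 0.07.  These are the
#' pre-solved outputs of [match_arm_prior()].
#'
#' @inheritParams predictive_prior
#' @return A [lognormal_prior()] for \eqn{\tau_k^2}.
#' @examples
#' arm_prior("all_cause_mortality")
#' @export
arm_prior <- function(outcome) {
  tab <- catalog("heterogeneity_priors_outcome")
  i <- match(outcome, tab$outcome)
  if (is.na(i)) {
    stop("unknown outcome type ", sQuote(outcome),
         "; see outcome_types() for the catalog")
  }
  lognormal_prior(tab$m_a[i], tab$s_a[i])
}

#' Catalogued Beta prior for correlation-angle cosines
#'
#' Returns the Beta prior for the cosines \eqn{\cos(\phi_{kl})} in the
#' spherical parameterization of the between-arm correlation matrix, chosen so
#' that the implied priors for the correlations \eqn{\rho_{kl}} have
#' approximately mean 0.5 and variance 0.07 for the given network size.
#'
#' @param n_treatments Total number of treatments in the network (4 to 10).
#' @return A [beta_prior()].
#' @examples
#' angle_prior(8)
#' @export
angle_prior <- function(n_treatments) {
  tab <- catalog("angle_priors")
  i <- match(n_treatments, tab$n_treatments)
  if (is.na(i)) {
    stop("no catalogued angle prior for ", n_treatments, " treatments; ",
         "supply a custom beta_prior() (the catalog covers 4 to 10)")
  }
  beta_prior(tab$a[i], tab$b[i])
}

#' Comparison-type specific heterogeneity priors
#'
#' Returns the catalogued log-normal predictive distribution for
#' \eqn{\tau_{kl}^2} indexed by outcome context and intervention comparison
#' type, for use with the proportional-variances model.  The bundled catalog
#' covers the two worked contexts: `"smoking"` (smoking cessation counselling,
#' a subjective outcome) and `"prostate"` (localised prostate cancer,
#' all-cause mortality).  Users can register further entries from their own
#' catalog file with the `extra` argument.
#'
#' @param context Catalog context key, e.g. `"smoking"`.
#' @param type Comparison type as returned by [classify_comparison()], e.g.
#'   `"nonpharm_vs_control"`.
#' @param extra Optional data frame with columns
#'   `context, comparison_type, m, s` appended to the bundled catalog.
#' @return A [lognormal_prior()] for \eqn{\tau_{kl}^2}.
#' @examples
#' comparison_prior("smoking", "nonpharm_vs_control")
#' @export
comparison_prior <- function(context, type, extra = NULL) {
  tab <- catalog("heterogeneity_priors_comparison")
  if (!is.null(extra)) {
    stopifnot(all(c("context", "comparison_type", "m", "s") %in% names(extra)))
    tab <- rbind(tab, extra[names(tab)])
  }
  i <- which(tab$context == context & tab$comparison_type == type)
  if (length(i) != 1L) {
    stop("no catalogued prior for context ", sQuote(context),
         " and comparison type ", sQuote(type))
  }
  lognormal_prior(tab$m[i], tab$s[i])
}
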