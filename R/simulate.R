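#' The localised prostate cancer evidence network
#'
#' Loads the bundled 17-trial network comparing eight treatments for
#' localised prostate cancer with respect to all-cause mortality:
#' observational management (A, the reference, control type), prostatectomy
#' (B), five radiotherapy regimes (C-G) and cryotherapy (H), all
#' nonpharmacological.  All 17 studies are two-arm.
#'
#' @return An [nma_network()].
#' @examples
#' net <- prostate_network()
#' validate_network(net)
#' @export
prostate_network <- function() {
  read_network_table(
    system.file("extdata", "prostate_arms.csv", package = "hetnma"),
    treatments = system.file("extdata", "prostate_treatments.csv",
                             package = "hetnma"),
    reference = "A")
}

#' Design skeleton of the smoking cessation network
#'
#' Returns the structure (not the outcome data, which are not bundled) of
#' the classic 24-trial network comparing four smoking cessation
#' counselling interventions: no intervention (A, control), self-help (B),
#' individual counselling (C), and group counselling (D), all
#' nonpharmacological.  Direct evidence exists on all six pairwise
#' comparisons, and two trials have three arms.  The skeleton is useful for
#' documentation, for shaping simulations, and for building
#' [proportional_spec()]-style weights; analysing the real data requires
#' the user to supply the outcome counts to [read_network_table()].
#'
#' @return A list with elements `treatments` (data frame), `comparisons`
#'   (data frame `treatment1`, `treatment2`, `n_studies`), `n_trials`, and
#'   `n_three_arm`.
#' @export
smoking_design <- function() {
  treatments <- data.frame(
    treatment = c("A", "B", "C", "D"),
    class = c("control", rep("nonpharmacological", 3)),
    label = c("no intervention", "self-help", "individual counselling",
              "group counselling"),
    stringsAsFactors = FALSE)
  comparisons <- data.frame(
    treatment1 = c("A", "A", "A", "B", "B", "C"),
    treatment2 = c("B", "C", "D", "C", "D", "D"),
    n_studies = c(3L, 15L, 2L, 2L, 2L, 4L),
    stringsAsFactors = FALSE)
  list(treatments = treatments, comparisons = comparisons,
       n_trials = 24L, n_three_arm = 2L)
}

#' Simulation design for a synthetic evidence network
#'
#' Describes the generative model from which [simulate_network()] draws
#' data: the treatments, the arm composition of each study, the true basic
#' parameters, the true contrast covariance \eqn{\Sigma}, the distribution
#' of the study baseline log odds, and the per-arm sample size.
#'
#' @param treatments Data frame with columns `treatment` and `class` (and
#'   optionally `label`), reference first; or an integer number of
#'   treatments (labelled A, B, ... with the first a control).
#' @param studies List of integer vectors of treatment ids (0-based) giving
#'   each study's arms; or an integer number of two-arm studies whose
#'   comparisons are cycled through all pairs so the network is connected.
#' @param d True basic parameters (length number of treatments - 1).
#' @param Sigma True contrast covariance matrix (positive semidefinite), or
#'   a single \eqn{\tau^2} for [sigma_common()].
#' @param baseline_mean,baseline_sd Normal distribution of the study
#'   baseline log odds \eqn{\mu_j}; the default centres event risks near
#'   0.3.
#' @param arm_size Number of patients per arm (recycled).
#' @return An object of class `"simulation_design"`.
#' @export
simulation_design <- function(treatments, studies, d, Sigma,
                              baseline_mean = qlogis(0.3),
                              baseline_sd = 0.5, arm_size = 100L) {
  if (is.numeric(treatments) && length(treatments) == 1L) {
    nt <- as.integer(treatments)
    treatments <- data.frame(
      treatment = LETTERS[seq_len(nt)],
      class = c("control", rep("nonpharmacological", nt - 1L)),
      stringsAsFactors = FALSE)
  }
  nt <- nrow(treatments)
  p <- nt - 1L
  stopifnot(length(d) == p)
  if (is.numeric(Sigma) && length(Sigma) == 1L) {
    Sigma <- sigma_common(Sigma, p)
  }
  stopifnot(is.matrix(Sigma), nrow(Sigma) == p, ncol(Sigma) == p)
  if (!is_psd(Sigma)) stop("true Sigma must be positive semidefinite")
  if (is.numeric(studies) && length(studies) == 1L) {
    prs <- utils::combn(nt, 2L) - 1L
    studies <- lapply(seq_len(studies), function(i) {
      prs[, (i - 1L) %% ncol(prs) + 1L]
    })
  }
  stopifnot(length(studies) >= 1,
            all(vapply(studies, function(s)
      length(s) >= 2 && all(s %in% (seq_len(nt) - 1L)), TRUE)))
  structure(list(treatments = treatments, studies = studies, d = d,
                 Sigma = Sigma, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 arm_size = rep_len(as.integer(arm_size), length(studies))),
            class = "simulation_design")
}

#' Simulate an evidence network from the generative model
#'
#' Draws data from the random-effects consistency model: per study a
#' baseline log odds \eqn{\mu_j}, a vector of contrasts from the normal
#' random-effects distribution (mean and covariance re-based to the study's
#' arms through [trial_contrast_covariance()]), and binomial arm counts.
#' Both the data and the underlying truth are returned so that parameter
#' recovery can be checked.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A list with elements `network` (an [nma_network()]) and `truth`
#'   (list: `mu`, `delta` per study, `d`, `Sigma`).
#' @export
simulate_network <- function(design, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  nt <- nrow(design$treatments)
  labels <- design$treatments$treatment
  d0 <- c(0, design$d)
  rows <- list()
  mu <- numeric(length(design$studies))
  deltas <- vector("list", length(design$studies))
  for (j in seq_along(design$studies)) {
    arms <- sort(design$studies[[j]])
    b <- arms[1L]
    ks <- arms[-1L]
    mu[j] <- rnorm(1, design$baseline_mean, design$baseline_sd)
    V <- trial_contrast_covariance(design$Sigma, arms, b)
    mean_j <- d0[ks + 1L] - d0[b + 1L]
    ch <- chol(V + diag(1e-12, nrow(V)))
    delta_j <- mean_j + drop(crossprod(ch, rnorm(length(ks))))
    deltas[[j]] <- delta_j
    eta <- c(mu[j], mu[j] + delta_j)
    n_arm <- design$arm_size[j]
    r <- rbinom(length(arms), n_arm, plogis(eta))
    rows[[j]] <- data.frame(study = paste0("S", j),
                            treatment = labels[arms + 1L],
                            events = r, total = n_arm,
                            stringsAsFactors = FALSE)
  }
  arms_df <- do.call(rbind, rows)
  net <- nma_network(arms_df, treatments = design$treatments)
  list(network = net,
       truth = list(mu = mu, delta = deltas, d = design$d,
                    Sigma = design$Sigma))
}
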