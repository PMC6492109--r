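#' Evidence network for an arm-level binary-outcome meta-analysis
#'
#' Constructs the data object used throughout the package: a set of studies,
#' each with two or more arms, where arm \eqn{k} of study \eqn{j} reports
#' \eqn{r_{jk}} events out of \eqn{n_{jk}} patients.  Treatments are indexed
#' \eqn{0, \ldots, p} with 0 the overall reference; within each study the
#' baseline treatment \eqn{b_j} is the lowest-indexed treatment present.
#'
#' @param arms Data frame with columns `study`, `treatment` (label), `events`,
#'   `total`, one row per arm.
#' @param treatments Optional data frame with columns `treatment` (label) and
#'   `class` (one of `"pharmacological"`, `"nonpharmacological"`,
#'   `"control"`), plus an optional `label` column with a long name.  Row
#'   order fixes the treatment indexing.  If omitted, treatments are indexed
#'   in order of first appearance with class `NA`.
#' @param reference Optional treatment label to use as the overall reference
#'   (index 0); defaults to the first row of `treatments`.
#' @return An object of class `"nma_network"`: a list with elements
#'   `treatments` (data frame: `id`, `label`, `class`, `long_label`), `arms`
#'   (data frame: `study`, `trt`, `events`, `total`, with `trt` the integer
#'   treatment id), and `studies` (list of per-study records with elements
#'   `id`, `treatments`, `baseline`, `rows`).
#' @examples
#' net <- nma_network(data.frame(
#'   study = c(1, 1, 2, 2), treatment = c("A", "B", "A", "C"),
#'   events = c(5, 7, 4, 9), total = c(50, 50, 40, 40)))
#' validate_network(net)
#' @export
nma_network <- function(arms, treatments = NULL, reference = NULL) {
  required <- c("study", "treatment", "events", "total")
  missing_cols <- setdiff(required, names(arms))
  if (length(missing_cols)) {
    stop("missing column(s) in arm table: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(arms) == 0L) stop("no arm records")
  ev <- arms$events
  tot <- arms$total
  if (!is.numeric(ev) || !is.numeric(tot) ||
      any(!is.finite(ev)) || any(!is.finite(tot)) ||
      any(ev != round(ev)) || any(tot != round(tot))) {
    stop("events and total must be integer counts")
  }
  if (any(tot < 1)) stop("arm totals must be at least 1")
  if (any(ev < 0) || any(ev > tot)) {
    stop("events must satisfy 0 <= events <= total")
  }
  study <- as.character(arms$study)
  label <- as.character(arms$treatment)
  if (anyDuplicated(paste(study, label, sep = "\r"))) {
    stop("duplicate (study, treatment) arm rows")
  }

  if (is.null(treatments)) {
    treatments <- data.frame(treatment = unique(label), class = NA_character_,
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("treatment", "class") %in% names(treatments)))
  tlab <- as.character(treatments$treatment)
  if (anyDuplicated(tlab)) stop("treatment labels must be unique")
  unknown <- setdiff(label, tlab)
  if (length(unknown)) {
    stop("arm table refers to treatments missing from the treatment table: ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(reference)) {
    i <- match(reference, tlab)
    if (is.na(i)) stop("reference treatment ", sQuote(reference), " not found")
    ord <- c(i, setdiff(seq_along(tlab), i))
    treatments <- treatments[ord, , drop = FALSE]
    tlab <- tlab[ord]
  }
  unused <- setdiff(tlab, label)
  if (length(unused)) {
    stop("treatment(s) not present in any study: ",
         paste(unused, collapse = ", "))
  }
  trt_df <- data.frame(
    id = seq_along(tlab) - 1L,
    label = tlab,
    class = as.character(treatments$class),
    long_label = if ("label" %in% names(treatments))
      as.character(treatments$label) else tlab,
    stringsAsFactors = FALSE)

  arms_df <- data.frame(
    study = study,
    trt = trt_df$id[match(label, trt_df$label)],
    events = as.integer(ev),
    total = as.integer(tot),
    stringsAsFactors = FALSE)

  studies <- lapply(unique(study), function(s) {
    rows <- which(arms_df$study == s)
    trts <- arms_df$trt[rows]
    o <- order(trts)
    rows <- rows[o]
    trts <- trts[o]
    if (length(trts) < 2L) {
      stop("study ", sQuote(s), " has fewer than 2 arms")
    }
    ## baseline: lowest treatment index present in the study
    list(id = s, treatments = trts, baseline = trts[1L], rows = rows)
  })
  net <- structure(list(treatments = trt_df, arms = arms_df,
                        studies = studies),
                   class = "nma_network")
  net
}

#' Read an evidence network from delimited text files
#'
#' Reads a comma-separated arm table (`study,treatment,events,total`, header
#' required, UTF-8) and optionally a treatment table
#' (`treatment,class[,label]`), returning an [nma_network()].  Alternative
#' column names can be mapped with `schema`.
#'
#' @param path Path to the arm table CSV.
#' @param treatments Path to a treatment table CSV, or a data frame, or
#'   `NULL`.
#' @param reference Optional reference treatment label.
#' @param schema Optional named character vector mapping the required names
#'   to the file's column names, e.g. `c(events = "r", total = "n")`.
#' @return An [nma_network()].
#' @export
read_network_table <- function(path, treatments = NULL, reference = NULL,
                               schema = NULL) {
  arms <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      i <- match(schema[[std]], names(arms))
      if (!is.na(i)) names(arms)[i] <- std
    }
  }
  if (nrow(arms) == 0L) stop("no arm records")
  if (is.character(treatments)) {
    treatments <- read.csv(treatments, stringsAsFactors = FALSE)
  }
  nma_network(arms, treatments = treatments, reference = reference)
}

#' Write an evidence network back to delimited text
#'
#' Writes the arm table (and optionally the treatment table) in the same CSV
#' dialect accepted by [read_network_table()], so that a write/read round
#' trip is the identity on the (study, treatment, events, total) records.
#'
#' @param network An [nma_network()].
#' @param path Output path for the arm table.
#' @param treatments_path Optional output path for the treatment table.
#' @return `network`, invisibly.
#' @export
write_network_table <- function(network, path, treatments_path = NULL) {
  stopifnot(inherits(network, "nma_network"))
  arms <- network$arms
  out <- data.frame(study = arms$study,
                    treatment = network$treatments$label[arms$trt + 1L],
                    events = arms$events, total = arms$total)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(treatments_path)) {
    td <- network$treatments
    write.csv(data.frame(treatment = td$label, class = td$class,
                         label = td$long_label),
              treatments_path, row.names = FALSE, quote = FALSE)
  }
  invisible(network)
}

#' @export
print.nma_network <- function(x, ...) {
  cat(sprintf("nma_network: %d studies, %d treatments, %d arms\n",
              length(x$studies), nrow(x$treatments), nrow(x$arms)))
  cat("treatments:", paste(x$treatments$label, collapse = ", "), "\n")
  invisible(x)
}

#' Validate an evidence network
#'
#' Reports the direct comparisons in the network with their study counts,
#' whether the comparison graph (treatments as nodes, within-study pairs as
#' edges) is connected, and which studies have more than two arms.
#' Disconnection is reported rather than raised; [nma_fit()] refuses
#' disconnected networks.
#'
#' @param network An [nma_network()].
#' @return An object of class `"nma_validation"`: list with `comparisons`
#'   (data frame `treatment1`, `treatment2`, `n_studies`), `connected`
#'   (logical), and `multiarm` (character vector of study ids).
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "nma_network"))
  labels <- network$treatments$label
  edges <- list()
  multiarm <- character(0)
  for (st in network$studies) {
    if (length(st$treatments) > 2L) multiarm <- c(multiarm, st$id)
    prs <- utils::combn(st$treatments, 2L)
    for (i in seq_len(ncol(prs))) {
      key <- paste(prs[1, i], prs[2, i], sep = "-")
      edges[[key]] <- (if (is.null(edges[[key]])) 0L else edges[[key]]) + 1L
    }
  }
  keys <- do.call(rbind, strsplit(names(edges), "-", fixed = TRUE))
  ord <- order(as.integer(keys[, 1]), as.integer(keys[, 2]))
  comparisons <- data.frame(
    treatment1 = labels[as.integer(keys[ord, 1]) + 1L],
    treatment2 = labels[as.integer(keys[ord, 2]) + 1L],
    n_studies = unname(unlist(edges))[ord],
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    comparisons[, 1:2], directed = FALSE,
    vertices = data.frame(name = labels))
  connected <- igraph::is_connected(g)
  structure(list(comparisons = comparisons, connected = connected,
                 multiarm = multiarm),
            class = "nma_validation")
}

#' @export
print.nma_validation <- function(x, ...) {
  cat("direct comparisons (study counts):\n")
  with(x$comparisons,
       cat(paste0("  ", treatment1, " vs ", treatment2, ": ", n_studies,
                  collapse = "\n"), "\n"))
  cat("connected:", x$connected, "\n")
  if (length(x$multiarm)) {
    cat("multi-arm studies:", paste(x$multiarm, collapse = ", "), "\n")
  } else {
    cat("no multi-arm studies\n")
  }
  invisible(x)
}

#' Classify an intervention comparison
#'
#' Classifies the comparison of two treatments into one of five categories
#' used to select comparison-type specific heterogeneity priors: both
#' pharmacological, pharmacological vs nonpharmacological, both
#' nonpharmacological, or either active class vs placebo/control.  The
#' classification is symmetric in its arguments.
#'
#' @param a,b Treatment classes (`"pharmacological"`, `"nonpharmacological"`,
#'   or `"control"`).
#' @return One of `"pharm_vs_pharm"`, `"pharm_vs_nonpharm"`,
#'   `"nonpharm_vs_nonpharm"`, `"pharm_vs_control"`, `"nonpharm_vs_control"`.
#' @export
classify_comparison <- function(a, b) {
  valid <- c("pharmacological", "nonpharmacological", "control")
  a <- match.arg(a, valid)
  b <- match.arg(b, valid)
  if (a == "control" && b == "control") {
    stop("cannot classify a comparison of two control treatments")
  }
  key <- sort(c(a, b))
  if (identical(key, c("pharmacological", "pharmacological"))) {
    "pharm_vs_pharm"
  } else if (identical(key, c("nonpharmacological", "pharmacological"))) {
    "pharm_vs_nonpharm"
  } else if (identical(key, c("nonpharmacological", "nonpharmacological"))) {
    "nonpharm_vs_nonpharm"
  } else if (identical(key, c("control", "pharmacological"))) {
    "pharm_vs_control"
  } else {
    "nonpharm_vs_control"
  }
}
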