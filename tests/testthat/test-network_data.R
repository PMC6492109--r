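test_that("the prostate fixture loads with the printed structure", {
  net <- prostate_network()
  expect_s3_class(net, "nma_network")
  expect_length(net$studies, 17L)
  expect_equal(nrow(net$treatments), 8L)
  expect_equal(nrow(net$arms), 34L)
  expect_true(all(vapply(net$studies, function(s)
    length(s$treatments), 0L) == 2L))
  expect_equal(net$treatments$label, LETTERS[1:8])
  expect_equal(net$treatments$class[1], "control")
  expect_true(all(net$treatments$class[-1] == "nonpharmacological"))
  ## spot-check printed rows
  s1 <- net$studies[[1]]
  expect_equal(net$arms$events[s1$rows], c(36L, 36L))
  expect_equal(net$arms$total[s1$rows], c(46L, 49L))
  s16 <- net$studies[[16]]
  expect_equal(net$treatments$label[net$arms$trt[s16$rows] + 1L],
               c("F", "G"))
  expect_equal(net$arms$events[s16$rows], c(1L, 1L))
  expect_equal(net$arms$total[s16$rows], c(44L, 47L))
})

test_that("bundled fixtures are unchanged (pinned checksums)", {
  files <- c(prostate_arms.csv = "1f4038302faab022af27b7b8f2586ff0",
             prostate_treatments.csv = "ccde1ffc2490946059fdccc47585b3bd",
             heterogeneity_priors_outcome.csv =
               "73aa18a1ea273f53ebf03f2030fbad1d",
             heterogeneity_priors_comparison.csv =
               "ef74750776fc6937fc108aad5e136446",
             angle_priors.csv = "d0647e07ddcd5972c3e12fd64bb5d850")
  for (f in names(files)) {
    path <- system.file("extdata", f, package = "hetnma")
    expect_equal(unname(tools::md5sum(path)), unname(files[f]), label = f)
  }
})

test_that("validation reports comparisons, connectivity, multi-arm studies", {
  rep <- validate_network(prostate_network())
  cmp <- rep$comparisons
  key <- paste0(cmp$treatment1, cmp$treatment2)
  counts <- setNames(cmp$n_studies, key)
  expect_equal(counts[c("AB", "AE", "BC", "CD", "CE", "CF", "CH", "EF",
                        "FG")],
               c(AB = 3L, AE = 1L, BC = 1L, CD = 2L, CE = 1L, CF = 1L,
                 CH = 2L, EF = 4L, FG = 2L))
  expect_equal(nrow(cmp), 9L)
  expect_true(rep$connected)
  expect_length(rep$multiarm, 0L)

  one <- nma_network(data.frame(study = c(1, 1), treatment = c("A", "B"),
                                events = c(1, 2), total = c(10, 10)))
  v1 <- validate_network(one)
  expect_true(v1$connected)
  expect_equal(v1$comparisons$n_studies, 1L)

  disjoint <- nma_network(data.frame(
    study = c(1, 1, 2, 2), treatment = c("A", "B", "C", "D"),
    events = 1, total = 10))
  expect_false(validate_network(disjoint)$connected)
  expect_error(nma_fit(disjoint, het_common("vague")), "disconnected")
})

test_that("comparison counts sum to the number of within-study pairs", {
  des <- simulation_design(4, studies = list(0:2, c(0L, 1L), c(1L, 3L),
                                             0:3, c(2L, 3L)),
                           d = c(0.2, -0.1, 0), Sigma = 0.04)
  net <- simulate_network(des, seed = 9)$network
  rep <- validate_network(net)
  expected <- sum(vapply(net$studies, function(s)
    choose(length(s$treatments), 2L), 0))
  expect_equal(sum(rep$comparisons$n_studies), expected)
  expect_equal(sort(rep$multiarm), sort(c("S1", "S4")))
})

test_that("malformed arm tables are rejected with clear errors", {
  ok <- toy_arms()
  expect_error(nma_network(ok[, -3]), "missing column")
  expect_error(nma_network(ok[0, ]), "no arm records")
  bad <- ok; bad$events[1] <- 60L
  expect_error(nma_network(bad), "events <= total")
  bad <- ok; bad$events[1] <- 1.5
  expect_error(nma_network(bad), "integer counts")
  bad <- rbind(ok, ok[1, ])
  expect_error(nma_network(bad), "duplicate")
  bad <- ok; bad$total[2] <- 0L
  expect_error(nma_network(bad), "at least 1")
  ## r = 0 and r = n are legitimate
  edge <- ok; edge$events[1] <- 0L; edge$events[2] <- 50L
  expect_s3_class(nma_network(edge), "nma_network")
  ## empty file
  tmp <- tempfile(fileext = ".csv")
  writeLines("study,treatment,events,total", tmp)
  expect_error(read_network_table(tmp), "no arm records")
})

test_that("write/read round trip is the identity on arm records", {
  des <- simulation_design(3, studies = 6, d = c(0.3, -0.2), Sigma = 0.02)
  net <- simulate_network(des, seed = 5)$network
  arms_csv <- tempfile(fileext = ".csv")
  trts_csv <- tempfile(fileext = ".csv")
  write_network_table(net, arms_csv, trts_csv)
  back <- read_network_table(arms_csv, treatments = trts_csv)
  expect_equal(back$arms, net$arms)
  expect_equal(back$treatments, net$treatments)
})

test_that("baseline is the lowest treatment index and reference is honored", {
  arms <- data.frame(study = c(1, 1, 2, 2),
                     treatment = c("B", "C", "C", "A"),
                     events = c(1, 2, 3, 4), total = rep(10, 4))
  trts <- data.frame(treatment = c("A", "B", "C"),
                     class = c("control", rep("pharmacological", 2)))
  net <- nma_network(arms, trts)
  expect_equal(net$studies[[1]]$baseline, 1L)  # B
  expect_equal(net$studies[[2]]$baseline, 0L)  # A
  ## renaming the reference reindexes treatments
  net2 <- nma_network(arms, trts, reference = "C")
  expect_equal(net2$treatments$label[1], "C")
  expect_equal(net2$studies[[2]]$baseline, 0L)  # C now indexes 0
})

test_that("schema mapping renames columns on read", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(trial = c(1, 1), arm = c("A", "B"),
                       r = c(2, 3), n = c(10, 10)), tmp, row.names = FALSE)
  net <- read_network_table(tmp, schema = c(study = "trial",
                                            treatment = "arm",
                                            events = "r", total = "n"))
  expect_equal(nrow(net$arms), 2L)
})

test_that("comparison classification is symmetric over the five types", {
  expect_equal(classify_comparison("control", "nonpharmacological"),
               "nonpharm_vs_control")
  expect_equal(classify_comparison("nonpharmacological",
                                   "nonpharmacological"),
               "nonpharm_vs_nonpharm")
  expect_equal(classify_comparison("pharmacological", "pharmacological"),
               "pharm_vs_pharm")
  expect_equal(classify_comparison("pharmacological", "control"),
               "pharm_vs_control")
  classes <- c("pharmacological", "nonpharmacological", "control")
  for (a in classes) {
    for (b in classes) {
      if (a == "control" && b == "control") next
      expect_equal(classify_comparison(a, b), classify_comparison(b, a))
    }
  }
  expect_error(classify_comparison("control", "control"), "control")
})
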