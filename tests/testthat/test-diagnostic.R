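perfect_test_params <- function() {
  p <- base_params()
  p$accuracies <- lapply(p$accuracies, function(a) {
    a$sensitivity <- 1; a$specificity <- 1; a
  })
  p$population$uptake_counselling <- 1
  p$population$uptake_mutation_test <- 1
  p
}

test_that("strategy construction matches the published cascades", {
  s11 <- build_strategy("S1_1")
  expect_length(s11$nodes, 0)

  s5 <- build_strategy("S5")
  expect_equal(s5$nodes$msi$test, "MSI")
  expect_equal(s5$nodes$msi$branches$pos, "braf")
  expect_equal(s5$nodes$braf$branches$pos, "REFER")
  expect_equal(s5$nodes$braf$branches$neg, "NOREFER")

  s8 <- build_strategy("S8")
  expect_identical(s8$root, "REFER")

  s3 <- build_strategy("S3")
  expect_equal(s3$nodes$ihc$branches$mlh1, "braf")   # BRAF only on MLH1 loss
  expect_equal(s3$nodes$ihc$branches$other, "REFER")

  expect_true(build_strategy("S6")$parallel_ihc_at_mutation)
  expect_error(build_strategy("S99"), "unknown strategy")

  dump <- format_strategy(s5)
  expect_match(dump[1], "Strategy 5")
  expect_match(paste(dump, collapse = "\n"), "MSI")
})

test_that("no-testing strategy classifies everyone negative at zero cost", {
  p <- base_params()
  d <- evaluate_probands(build_strategy("S1_1"), p)
  expect_equal(d$diagnostic_cost, 0)
  expect_equal(sum(d$joint_probands[, c("LS_POSITIVE", "LS_ASSUMED")]), 0)
  expect_equal(sum(d$joint_probands), p$population$n_probands)
})

test_that("perfect tests with full uptake classify without error", {
  p <- perfect_test_params()
  n <- p$population$n_probands; prev <- p$population$ls_prevalence
  d <- evaluate_probands(build_strategy("S8"), p)
  expect_equal(d$joint_probands["LS", "LS_POSITIVE"], n * prev, tolerance = 1e-9)
  expect_equal(d$joint_probands["NONLS", "LS_NEGATIVE"], n * (1 - prev),
               tolerance = 1e-9)
  expect_equal(sum(d$joint_probands) -
                 d$joint_probands["LS", "LS_POSITIVE"] -
                 d$joint_probands["NONLS", "LS_NEGATIVE"], 0, tolerance = 1e-9)
  m <- confusion_metrics(d)
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1),
               ignore_attr = TRUE)
})

test_that("hand-enumerated single positive path for the MSI-led cascade", {
  # p=0.084, sens(MSI)=0.9, spec(MSI)=0.9, BRAF and MUTATION perfect,
  # full uptake, n=1000 -> expected LS positives 1000*0.084*0.9 = 75.6
  p <- perfect_test_params()
  p$population$n_probands <- 1000L
  p$accuracies <- list(
    list(test_id = "MSI", sensitivity = 0.9, specificity = 0.9,
         conditional_on = NULL),
    list(test_id = "BRAF", sensitivity = 1, specificity = 1,
         conditional_on = NULL),
    list(test_id = "MUTATION", sensitivity = 1, specificity = 1,
         conditional_on = NULL),
    list(test_id = "AMSTERDAM2", sensitivity = 0, specificity = 1,
         conditional_on = NULL))
  d <- evaluate_probands(build_strategy("S5"), p)
  expect_equal(d$joint_probands["LS", "LS_POSITIVE"], 75.6, tolerance = 1e-9)
  # BRAF with perfect specificity removes no carriers but all MSI false
  # positives route through it and are ruled in (spec=1 means no sporadic
  # tumour shows wild-type BRAF)
  expect_equal(d$joint_probands["NONLS", "LS_POSITIVE"], 0, tolerance = 1e-9)
})

test_that("confusion metrics follow Bayes arithmetic and handle empty cells", {
  d <- structure(list(
    joint_probands = matrix(c(75.6, 91.6, 8.4 - 8.4, 0, 8.4, 824.4), 2, 3,
                            dimnames = list(c("LS", "NONLS"),
                                            c("LS_POSITIVE", "LS_ASSUMED",
                                              "LS_NEGATIVE")))),
    class = "ls_diag_outcomes")
  m <- confusion_metrics(d)
  expect_equal(m$sensitivity, 0.9, ignore_attr = TRUE)
  expect_equal(m$specificity, 0.9, ignore_attr = TRUE)
  expect_equal(m$ppv, 75.6 / (75.6 + 91.6), tolerance = 1e-12,
               ignore_attr = TRUE)

  d0 <- structure(list(
    joint_probands = matrix(c(0, 0, 0, 0, 10, 90), 2, 3,
                            dimnames = dimnames(d$joint_probands))),
    class = "ls_diag_outcomes")
  expect_true(is.nan(confusion_metrics(d0)$ppv))
})

test_that("expected-value evaluation equals brute-force path enumeration", {
  # all nine strategies, anchored set plus random parameter draws
  seeds <- c(0, 1:7)
  for (sd in seeds) {
    p <- if (sd == 0) base_params() else generate_parameter_set(sd, "random")
    for (id in strategy_ids()) {
      s <- build_strategy(id)
      d <- evaluate_probands(s, p)
      o <- oracle_evaluate(s, p)
      expect_equal(d$joint_probands, o$joint, tolerance = 1e-12, info = id)
      expect_equal(d$diagnostic_cost, o$cost, tolerance = 1e-12, info = id)
      expect_equal(d$n_genetic_tests_taken, o$genetic_tests,
                   tolerance = 1e-12, info = id)
      for (nm in names(o$tests))
        expect_equal(d$tests_used[[nm]], o$tests[[nm]], tolerance = 1e-12,
                     info = paste(id, nm))
      # probability conservation
      expect_equal(sum(d$joint_probands), p$population$n_probands,
                   tolerance = 1e-9, info = id)
    }
  }
})

test_that("oracle equivalence holds across 50 random draws for the key cascade", {
  for (sd in 1:50) {
    p <- generate_parameter_set(sd, "random")
    s <- build_strategy("S5")
    d <- evaluate_probands(s, p)
    o <- oracle_evaluate(s, p)
    expect_equal(d$joint_probands, o$joint, tolerance = 1e-12)
  }
})

test_that("monotonicity: specificity and surveillance uptake", {
  p <- base_params()
  d0 <- evaluate_probands(build_strategy("S5"), p)
  # raise MSI specificity: non-carrier positives cannot increase
  p2 <- p
  p2$accuracies[[1]]$specificity <- min(1, p$accuracies[[1]]$specificity + 0.05)
  d2 <- evaluate_probands(build_strategy("S5"), p2)
  expect_lte(d2$joint_probands["NONLS", "LS_POSITIVE"],
             d0$joint_probands["NONLS", "LS_POSITIVE"])
  # raise surveillance uptake: acceptance cannot decrease
  p3 <- apply_univariate_override(
    p, "population$uptake_surveillance",
    min(1, p$population$uptake_surveillance + 0.04))
  d3 <- evaluate_probands(build_strategy("S5"), p3)
  expect_true(all(d3$n_accepting_surveillance >= d0$n_accepting_surveillance))
})

test_that("BRAF triage improves specificity without compromising sensitivity", {
  for (sd in c(0, 3, 9)) {
    p <- if (sd == 0) base_params() else generate_parameter_set(sd, "random")
    d4 <- cascade_relatives(evaluate_probands(build_strategy("S4"), p), p)
    d5 <- cascade_relatives(evaluate_probands(build_strategy("S5"), p), p)
    m4 <- confusion_metrics(d4); m5 <- confusion_metrics(d5)
    expect_gte(m5$specificity, m4$specificity - 1e-12)
    # with a perfect BRAF sensitivity, cascade sensitivity is unchanged
    pb <- p
    pb$accuracies <- lapply(pb$accuracies, function(a) {
      if (a$test_id == "BRAF") a$sensitivity <- 1
      a
    })
    d4b <- evaluate_probands(build_strategy("S4"), pb)
    d5b <- evaluate_probands(build_strategy("S5"), pb)
    expect_equal(confusion_metrics(d5b)$sensitivity,
                 confusion_metrics(d4b)$sensitivity, tolerance = 1e-12)
  }
})

test_that("relative cascade: Mendelian arithmetic and conservation", {
  p <- base_params()
  # 10 confirmed probands, 5 FDRs each, full uptake, depth 1 via R2 = 0:
  # 50 predictive tests, 25 expected carriers found
  p2 <- apply_univariate_override(p, "population$uptake_predictive_test", 1)
  p2 <- apply_univariate_override(
    p2, "population$relatives_second_degree_per_carrier", 0)
  d <- evaluate_probands(build_strategy("S5"), p2)
  d$joint_probands[] <- 0
  d$joint_probands["LS", "LS_POSITIVE"] <- 10
  d$joint_probands["NONLS", "LS_NEGATIVE"] <- p2$population$n_probands - 10
  d2 <- cascade_relatives(d, p2)
  expect_equal(d2$tests_used[["PREDICTIVE"]], 50)
  expect_equal(d2$joint_relatives["LS", "LS_POSITIVE"], 25)

  # conservation: relative population is fixed by family structure
  for (id in c("S1_1", "S5", "S8")) {
    dd <- cascade_relatives(evaluate_probands(build_strategy(id), p), p)
    pop <- p$population
    expect_equal(sum(dd$joint_relatives),
                 pop$n_probands * pop$relatives_per_positive_proband *
                   (1 + pop$relatives_second_degree_per_carrier),
                 tolerance = 1e-6, info = id)
    expect_true(all(dd$joint_relatives >= 0))
  }

  # no confirmed or assumed probands: nothing tested, no relative cost
  d0 <- cascade_relatives(evaluate_probands(build_strategy("S1_1"), p), p)
  expect_equal(d0$tests_used[["PREDICTIVE"]], 0)
  expect_equal(d0$relative_test_cost, 0)

  # no relatives: proband-only analysis
  pr0 <- apply_univariate_override(
    p, "population$relatives_per_positive_proband", 0)
  dr0 <- cascade_relatives(evaluate_probands(build_strategy("S5"), pr0), pr0)
  expect_equal(sum(dr0$joint_relatives), 0)
})

test_that("diagnostic outcomes export as a delimited table", {
  p <- base_params()
  d <- cascade_relatives(evaluate_probands(build_strategy("S5"), p), p)
  f <- tempfile(fileext = ".tsv")
  tab <- write_diag_outcomes(d, f)
  expect_true(file.exists(f))
  expect_equal(nrow(tab), 12)      # 2 roles x 2 statuses x 3 classes
  expect_equal(sum(tab$count[tab$role == "probands"]),
               p$population$n_probands, tolerance = 1e-9)
})
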