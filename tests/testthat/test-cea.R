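mk_result <- function(id, cost, qalys) {
  structure(list(strategy_id = id, cost = list(), total_cost = cost,
                 qalys_short = 0, qalys_long = qalys, total_qalys = qalys),
            class = "ls_strategy_result")
}

test_that("ICER and INHB closed forms reproduce the published arithmetic", {
  expect_equal(icer(984500, 179.3), 5491)
  expect_equal(icer(2403400, 312.9), 7681)
  expect_equal(icer(0, 5), 0)
  expect_error(icer(100, 0), "zero QALY")

  expect_equal(inhb(984500, 179.3, 20000), 130.075, tolerance = 1e-9)
  expect_equal(round_half_away(inhb(984500, 179.3, 20000), 1), 130.1)
  expect_equal(round_half_away(inhb(384900, 63.9, 20000), 1), 44.7)
  expect_equal(inhb(0, 0, 20000), 0)
  expect_error(inhb(1, 1, 0), "wtp")
})

test_that("frontier classification reproduces the published dominance labels", {
  fx <- generate_table2_fixture()
  res <- lapply(seq_len(nrow(fx)), function(i)
    mk_result(fx$strategy_id[i], fx$dc_total[i] * 1000, fx$dq_total[i]))
  fr <- find_frontier(res)
  lab <- setNames(fr$labels$label, fr$labels$strategy_id)
  expect_equal(unname(lab[c("S2", "S4", "S6")]), rep("DOMINATED", 3))
  expect_equal(unname(lab[c("S1_2", "S3")]), rep("EXTENDED_DOMINATED", 2))
  expect_equal(unname(lab[c("S1_1", "S5", "S7", "S8")]),
               rep("ON_FRONTIER", 4))
  expect_equal(fr$ladder$strategy_id, c("S1_1", "S5", "S7", "S8"))
  ic <- fr$ladder$icer_vs_previous[-1]
  expect_true(all(diff(ic) > 0))               # strictly increasing ladder
})

test_that("degenerate and derived frontier cases", {
  expect_equal(find_frontier(list(mk_result("A", 5, 1)))$labels$label,
               "ON_FRONTIER")
  # A=(0,0), B=(10,1), C=(12,3): B extended dominated
  fr <- find_frontier(list(mk_result("A", 0, 0), mk_result("B", 10, 1),
                           mk_result("C", 12, 3)))
  lab <- setNames(fr$labels$label, fr$labels$strategy_id)
  expect_equal(unname(lab["B"]), "EXTENDED_DOMINATED")
  expect_equal(fr$ladder$strategy_id, c("A", "C"))
  # brute force: B never maximises NHB at any willingness-to-pay
  for (l in c(0.5, 1, 2, 4, 6, 10, 50)) {
    best <- oracle_best_at_lambda(c(0, 10, 12), c(0, 1, 3), l)
    expect_true(best != 2)
  }
})

test_that("frontier agrees with brute-force NHB maximisation", {
  set.seed(100)
  for (inst in 1:50) {
    k <- sample(3:9, 1)
    costs <- stats::runif(k, 0, 1e6)
    qalys <- stats::runif(k, 0, 300)
    res <- lapply(seq_len(k), function(i)
      mk_result(paste0("X", i), costs[i], qalys[i]))
    fr <- find_frontier(res)
    lab <- setNames(fr$labels$label, fr$labels$strategy_id)
    for (l in stats::runif(2, 100, 1e5)) {
      best <- oracle_best_at_lambda(costs, qalys, l)
      expect_equal(unname(lab[paste0("X", best)]), "ON_FRONTIER")
    }
  }
})

test_that("frontier is invariant to input order and cost rescaling", {
  fx <- generate_table2_fixture()
  res <- lapply(seq_len(nrow(fx)), function(i)
    mk_result(fx$strategy_id[i], fx$dc_total[i] * 1000, fx$dq_total[i]))
  fr1 <- find_frontier(res)
  set.seed(8)
  fr2 <- find_frontier(sample(res))
  expect_identical(fr1$labels, fr2$labels)
  expect_identical(fr1$ladder$strategy_id, fr2$ladder$strategy_id)
  # positive affine rescaling of costs preserves the labels
  res3 <- lapply(res, function(r) { r$total_cost <- 3 * r$total_cost + 50; r })
  fr3 <- find_frontier(res3)
  expect_identical(fr1$labels, fr3$labels)
})

test_that("ICER/INHB consistency at the threshold", {
  set.seed(12)
  for (i in 1:100) {
    dc <- stats::runif(1, -1e5, 1e6); dq <- stats::runif(1, 0.01, 100)
    l <- stats::runif(1, 1000, 1e5)
    expect_equal(inhb(dc, dq, l) > 0, icer(dc, dq, rounded = FALSE) < l)
  }
})

test_that("ties in cost and QALYs retain both strategies with a warning", {
  res <- list(mk_result("A", 0, 0), mk_result("B", 10, 2),
              mk_result("C", 10, 2))
  expect_warning(fr <- find_frontier(res), "tied")
  lab <- setNames(fr$labels$label, fr$labels$strategy_id)
  expect_equal(unname(lab["B"]), "ON_FRONTIER")
  expect_equal(unname(lab["C"]), "ON_FRONTIER")
})

test_that("cost-utility plane table is complete and order-invariant", {
  fx <- generate_table2_fixture()
  res <- lapply(seq_len(nrow(fx)), function(i)
    mk_result(fx$strategy_id[i], fx$dc_total[i] * 1000, fx$dq_total[i]))
  pl <- cost_utility_plane(res, anchor_id = "S1_1")
  expect_equal(nrow(pl), 9)
  expect_equal(sum(pl$label == "ON_FRONTIER"), 4)
  set.seed(2)
  pl2 <- cost_utility_plane(sample(res), anchor_id = "S1_1")
  expect_equal(pl[order(pl$strategy_id), ], pl2[order(pl2$strategy_id), ],
               ignore_attr = TRUE)
  pl1 <- cost_utility_plane(list(mk_result("A", 1, 1)))
  expect_equal(nrow(pl1), 1)
  expect_equal(pl1$label, "ON_FRONTIER")
})

test_that("combining submodels is linear in the diagnostic counts", {
  p <- base_params()
  profs <- management_profiles(p)
  mgmt <- simulate_cohort(profs, p, 200, 31L)
  d <- cascade_relatives(evaluate_probands(build_strategy("S5"), p), p)
  r1 <- combine_submodels(d, mgmt, p)
  expect_equal(r1$total_cost, sum(unlist(r1$cost)), tolerance = 1e-6)
  expect_equal(r1$total_qalys, r1$qalys_short + r1$qalys_long,
               tolerance = 1e-9)

  # homogeneity: doubling every diagnostic count doubles every category
  d2 <- d
  d2$joint_probands <- 2 * d$joint_probands
  d2$joint_relatives <- 2 * d$joint_relatives
  d2$diagnostic_cost <- 2 * d$diagnostic_cost
  d2$n_genetic_tests_taken <- 2 * d$n_genetic_tests_taken
  r2 <- combine_submodels(d2, mgmt, p)
  expect_equal(r2$total_cost, 2 * r1$total_cost, tolerance = 1e-6)
  expect_equal(unlist(r2$cost), 2 * unlist(r1$cost), tolerance = 1e-6)
  expect_equal(r2$total_qalys, 2 * r1$total_qalys, tolerance = 1e-9)
})

test_that("combine reproduces a hand-computed weighted sum on a small fixture", {
  p <- base_params()
  profs <- list(
    ls_profile("proband", "male", TRUE, start_age = 45),
    ls_profile("proband", "female", TRUE, start_age = 45),
    ls_profile("relative", "male", FALSE, start_age = 30),
    ls_profile("relative", "female", FALSE, start_age = 30))
  # fabricate management means: costs in one category only
  mgmt <- data.frame(profile_id = 1:4, weight = 1,
                     cost_crc_prevention = c(1000, 0, 0, 0),
                     cost_crc_treatment = c(0, 2000, 0, 0),
                     cost_ec_prevention = 0, cost_ec_treatment = 0,
                     qalys_long = c(10, 11, 12, 0), qalys_short = 0,
                     ly_undisc = 0, ly_disc = 0, n_colonoscopies = 0,
                     n_complications = 0, n_crcs = 0, n_ecs = 0)
  attr(mgmt, "profiles") <- profs
  d <- structure(list(
    strategy_id = "S5",
    joint_probands = matrix(0, 2, 3,
                            dimnames = list(c("LS", "NONLS"),
                                            c("LS_POSITIVE", "LS_ASSUMED",
                                              "LS_NEGATIVE"))),
    joint_relatives = matrix(0, 2, 3,
                             dimnames = list(c("LS", "NONLS"),
                                             c("LS_POSITIVE", "LS_ASSUMED",
                                               "LS_NEGATIVE"))),
    diagnostic_cost = 500, n_genetic_tests_taken = 0),
    class = "ls_diag_outcomes")
  d$joint_probands["LS", "LS_NEGATIVE"] <- 10    # split across sexes
  d$joint_relatives["NONLS", "LS_NEGATIVE"] <- 4
  r <- combine_submodels(d, mgmt, p)
  # probands: 10 split 5 male / 5 female; relatives: 4 male-share = 2
  expect_equal(r$cost$crc_prevention, 5 * 1000)
  expect_equal(r$cost$crc_treatment, 5 * 2000)
  expect_equal(r$cost$diagnosis, 500)
  expect_equal(r$total_cost, 500 + 5000 + 10000)
  expect_equal(r$qalys_long, 5 * 10 + 5 * 11 + 2 * 12)

  # a populated cell without a matching profile is an error
  d$joint_probands["NONLS", "LS_NEGATIVE"] <- 3   # needs female NONLS proband
  expect_error(combine_submodels(d, mgmt, p), "missing management profile")
})
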