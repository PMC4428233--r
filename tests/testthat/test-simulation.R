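test_that("discount factor closed form", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(1, 0.035), 1 / 1.035, tolerance = 1e-12)
  expect_equal(discount_factor(20, 0.035), prod(rep(1 / 1.035, 20)),
               tolerance = 1e-12)
  expect_equal(discount_factor(2.5, 0), 1)
  expect_error(discount_factor(-1, 0.035), ">= 0")
})

test_that("null process: death at the horizon with no events", {
  p <- null_world()
  pr <- ls_profile("relative", "male", TRUE, start_age = 30)
  h <- simulate_individual(pr, p, 123L)
  expect_equal(attr(h, "death_age"), 100)
  expect_equal(nrow(h), 1)                       # only the terminal event
  expect_equal(h$kind, "other_death")
})

test_that("biennial schedule yields 26 colonoscopies for a full-span survivor", {
  p <- null_world()
  pr <- ls_profile("relative", "male", TRUE, "LS_POSITIVE",
                   accepted_surveillance = TRUE, start_age = 25)
  h <- simulate_individual(pr, p, 5L)
  cols <- h$age[h$kind == "colonoscopy"]
  expect_length(cols, 26)
  expect_equal(cols, seq(25, 75, by = 2))
  # late entrant follows entry + 2k
  pr2 <- ls_profile("relative", "male", TRUE, "LS_POSITIVE",
                    accepted_surveillance = TRUE, start_age = 30)
  h2 <- simulate_individual(pr2, p, 5L)
  expect_equal(h2$age[h2$kind == "colonoscopy"], seq(30, 74, by = 2))
})

test_that("life histories respect structural invariants", {
  p <- base_params()
  set.seed(31)
  profs <- management_profiles(p)
  U <- lynchcea:::rng_block(8L, 60)
  for (pr in profs[c(1, 6, 12, 18, 23)]) {
    for (i in 1:60) {
      h <- simulate_individual(pr, p, U[i, ])
      expect_true(!is.unsorted(h$age))
      d <- attr(h, "death_age")
      expect_true(all(h$age <= d))
      expect_lte(sum(h$kind == "crc_incidence"), 2)
      # no endometrial cancer after H-BSO
      th <- h$age[h$kind == "hbso"]
      te <- h$age[h$kind == "ec_incidence"]
      if (length(th) && length(te)) expect_lt(te, th)
      # colonoscopies only as scheduled
      cols <- h$age[h$kind == "colonoscopy"]
      if (pr$accepted_surveillance && length(cols))
        expect_true(all(cols >= 25 & cols <= 75))
    }
  }
})

test_that("accrual: death at entry gives a zero outcome", {
  p <- base_params()
  pr <- ls_profile("proband", "male", TRUE, start_age = 45)
  h <- structure(data.frame(age = 45, kind = "other_death",
                            stage = NA_integer_),
                 class = c("ls_life_history", "data.frame"),
                 profile = pr, death_age = 45)
  a <- accrue(h, pr, p)
  expect_equal(a$qalys_total, 0)
  expect_equal(a$life_years_undiscounted, 0)
  expect_equal(sum(unlist(a$cost)), 0)
})

test_that("accrual: closed-form discounted integral of a constant utility", {
  # utility 1.0 from age 50 to 52 at 3.5%: integral of 1.035^-t on [0,2]
  p <- base_params()
  p$utilities$population_norms$male <- c(1, 0, 0)
  pr <- ls_profile("proband", "male", FALSE, start_age = 50)
  h <- structure(data.frame(age = 52, kind = "other_death",
                            stage = NA_integer_),
                 class = c("ls_life_history", "data.frame"),
                 profile = pr, death_age = 52)
  a <- accrue(h, pr, p)
  expected <- (1 - 1.035^-2) / log(1.035)
  expect_equal(a$qalys_long, expected, tolerance = 1e-9)
  # the continuous-time integral (1.9328) sits just below the discrete
  # annual sum 1 + 1.035^-1 = 1.9662, as it must
  expect_equal(expected, 1.9328, tolerance = 1e-4)
  expect_lt(expected, 1 + 1 / 1.035)
})

test_that("metastatic disutility applies from Dukes' D diagnosis to death", {
  p <- base_params()
  p$utilities$population_norms$male <- c(1, 0, 0)
  pr <- ls_profile("proband", "male", TRUE, start_age = 58)
  h <- structure(data.frame(age = c(60, 62), kind = c("crc_incidence",
                                                      "crc_death"),
                            stage = c(4L, NA_integer_)),
                 class = c("ls_life_history", "data.frame"),
                 profile = pr, death_age = 62)
  a <- accrue(h, pr, p)
  dq <- log(1.035)
  base <- (1 - exp(-dq * 4)) / dq
  dis <- 0.13 * (exp(-dq * 2) - exp(-dq * 4)) / dq
  expect_equal(a$qalys_long, base - dis, tolerance = 1e-9)
})

test_that("QALYs equal discounted life years when norms are 1 and disutilities 0", {
  p <- base_params()
  p$utilities$population_norms$male <- c(1, 0, 0)
  p$utilities$population_norms$female <- c(1, 0, 0)
  p$utilities$disutility_metastatic_crc <- 0
  p$utilities$disutility_genetic_testing <- 0
  m <- simulate_cohort(management_profiles(p), p, 400, 21L)
  expect_equal(m$qalys_long + m$qalys_short, m$ly_disc, tolerance = 1e-9)
})

test_that("cohort of one equals simulate_individual plus accrue", {
  p <- base_params()
  pr <- ls_profile("relative", "female", TRUE, "LS_POSITIVE",
                   accepted_surveillance = TRUE, accepted_hbso = TRUE,
                   start_age = 30)
  m <- simulate_cohort(list(pr), p, 1, 77L)
  U <- lynchcea:::rng_block(77L, 1)
  h <- simulate_individual(pr, p, U[1, ])
  a <- accrue(h, pr, p)
  expect_equal(m$cost_crc_prevention, a$cost$crc_prevention, tolerance = 1e-9)
  expect_equal(m$cost_crc_treatment, a$cost$crc_treatment, tolerance = 1e-9)
  expect_equal(m$cost_ec_prevention, a$cost$ec_prevention, tolerance = 1e-9)
  expect_equal(m$qalys_long, a$qalys_long, tolerance = 1e-9)
  expect_equal(m$ly_disc, a$life_years_discounted, tolerance = 1e-9)
})

test_that("identical seeds give bit-identical cohort outputs", {
  p <- base_params()
  profs <- management_profiles(p)[c(2, 9, 20)]
  m1 <- simulate_cohort(profs, p, 300, 42L)
  m2 <- simulate_cohort(profs, p, 300, 42L)
  expect_identical(m1, m2)
  m3 <- simulate_cohort(profs, p, 300, 43L)
  expect_false(identical(m1$qalys_long, m3$qalys_long))
})

test_that("conservation: discounted <= undiscounted life years <= horizon span", {
  p <- base_params()
  m <- simulate_cohort(management_profiles(p), p, 500, 3L)
  expect_true(all(m$ly_disc <= m$ly_undisc + 1e-12))
  starts <- vapply(attr(m, "profiles"), function(pr) pr$start_age, 0)
  expect_true(all(m$ly_undisc <= 100 - starts + 1e-12))
})

test_that("surveillance arm never has more CRCs under common random numbers", {
  # cancer deaths disabled so the two arms share every death time; the
  # shared-uniform inversion then guarantees pathwise dominance
  p <- base_params()
  for (st in c("A", "B", "C", "D"))
    p <- apply_univariate_override(p, paste0("hazards$crc_excess_", st),
                                   zero_hazard())
  p <- apply_univariate_override(p, "simulation$p_colonoscopy_death", 0)
  prs <- ls_profile("relative", "male", TRUE, "LS_POSITIVE",
                    accepted_surveillance = TRUE, start_age = 25)
  prn <- ls_profile("relative", "male", TRUE, "LS_POSITIVE",
                    accepted_surveillance = FALSE, start_age = 25)
  n <- 5000
  U <- lynchcea:::rng_block(13L, n)
  cs <- lynchcea:::build_context(prs, p)
  cn <- lynchcea:::build_context(prn, p)
  sos <- lynchcea:::sim_engine(cs, U, p)
  son <- lynchcea:::sim_engine(cn, U, p)
  ncrc_s <- is.finite(sos$crc1) + is.finite(sos$crc2)
  ncrc_n <- is.finite(son$crc1) + is.finite(son$crc2)
  expect_true(all(ncrc_s <= ncrc_n))
  # incidence times are pathwise delayed
  expect_true(all(sos$crc1 >= son$crc1 - 1e-9 | !is.finite(son$crc1)))
})

test_that("hazard-ratio transform matches paired simulation within 3 SE", {
  p <- base_params()
  p2 <- apply_univariate_override(p, "hazards$mortality_male", zero_hazard())
  p1 <- apply_univariate_override(p2, "surveillance$hr_index_crc", 1)
  pr <- ls_profile("relative", "male", TRUE, "LS_POSITIVE",
                   accepted_surveillance = TRUE, start_age = 0)
  n <- 50000
  U <- lynchcea:::rng_block(17L, n)
  c1 <- lynchcea:::build_context(pr, p1)   # hr = 1
  c2 <- lynchcea:::build_context(pr, p2)   # hr = 0.387
  # surveillance window spans [25, 75]; compare risk accrued inside it
  f1 <- mean(lynchcea:::sim_engine(c1, U, p1)$crc1 <= 70)
  f2 <- mean(lynchcea:::sim_engine(c2, U, p2)$crc1 <= 70)
  F25 <- cumulative_risk(p$hazards$crc_index_ls_male, 25)
  expected <- 1 - (1 - F25) *
    (1 - transform_cumulative_risk(
      1 - (1 - cumulative_risk(p$hazards$crc_index_ls_male, 70)) / (1 - F25),
      0.387))
  expect_lt(abs(f2 - expected), 3 * sqrt(expected * (1 - expected) / n))
  expect_gt(f1, f2)
})

test_that("simulated histories recover the input hazard (Nelson-Aalen)", {
  library(survival)
  p <- base_params()
  p <- apply_univariate_override(p, "hazards$mortality_male", zero_hazard())
  pr <- ls_profile("relative", "male", TRUE, start_age = 0)
  n <- 40000
  U <- lynchcea:::rng_block(19L, n)
  ctx <- lynchcea:::build_context(pr, p)
  t1 <- lynchcea:::sim_engine(ctx, U, p)$crc1
  time <- pmin(t1, 70); event <- as.integer(t1 <= 70)
  fit <- survfit(Surv(time, event) ~ 1, stype = 2, ctype = 1)
  H_hat <- stats::approx(fit$time, fit$cumhaz, xout = c(40, 50, 60, 70))$y
  H_true <- cumulative_hazard(p$hazards$crc_index_ls_male, c(40, 50, 60, 70))
  # Monte-Carlo tolerance: ~3 SE of the Nelson-Aalen estimator
  expect_true(all(abs(H_hat - H_true) < 3 * sqrt(H_true / (n * 0.6)) + 0.003))
})
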