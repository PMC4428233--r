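# Independent oracles used by the property suites.  These deliberately
# re-derive quantities by different algorithms than the package code.

# Brute-force evaluation of a diagnostic strategy by explicit root-to-leaf
# path enumeration.  Every path (including the counselling / mutation-test
# / family-history sub-branches behind a referral) is expanded with its
# probability per stratum; expectations are sums over the path list.
oracle_evaluate <- function(strategy, params) {
  pop <- params$population
  spectrum <- params$diagnostics$mutation_spectrum
  strata <- c(names(spectrum), "NONLS")
  mass0 <- c(pop$ls_prevalence * spectrum,
             NONLS = 1 - pop$ls_prevalence) * pop$n_probands

  unit_cost <- c(MSI = params$costs$msi, IHC4 = params$costs$ihc4,
                 BRAF = params$costs$braf,
                 METHYLATION = params$costs$methylation,
                 MUTATION = params$costs$mutation_test,
                 AMSTERDAM2 = params$costs$amsterdam)

  get_acc <- function(test, cond) {
    hit <- NULL
    for (a in params$accuracies) {
      if (a$test_id == test && identical(a$conditional_on, cond)) hit <- a
    }
    if (is.null(hit)) for (a in params$accuracies)
      if (a$test_id == test && is.null(a$conditional_on)) hit <- a
    hit
  }
  p_pos <- function(test, cond, stratum) {
    a <- get_acc(test, cond)
    if (stratum == "NONLS") 1 - a$specificity else a$sensitivity
  }

  # path: list(prob = per-stratum vector, cost = scalar per unit mass,
  #            tests = named counts, class = terminal or NULL, ntest = 0/1)
  paths <- list()
  emit <- function(prob, cost, tests, class, gtest)
    paths[[length(paths) + 1]] <<- list(prob = prob, cost = cost,
                                        tests = tests, class = class,
                                        gtest = gtest)

  u1 <- pop$uptake_counselling; u2 <- pop$uptake_mutation_test
  ams_pos <- vapply(strata, function(s) p_pos("AMSTERDAM2", NULL, s), 0)
  mut_pos <- vapply(strata, function(s) p_pos("MUTATION", NULL, s), 0)

  expand_refer <- function(prob, cost, tests) {
    ihc_extra <- if (strategy$parallel_ihc_at_mutation) params$costs$ihc4 else 0
    ihc_tests <- if (strategy$parallel_ihc_at_mutation) c(IHC4 = 1) else numeric(0)
    # declined counselling
    emit(prob * (1 - u1) * ams_pos, cost, tests, "LS_ASSUMED", 0)
    emit(prob * (1 - u1) * (1 - ams_pos), cost, tests, "LS_NEGATIVE", 0)
    # counselled, declined test
    c1 <- cost + params$costs$counselling
    emit(prob * u1 * (1 - u2) * ams_pos, c1, tests, "LS_ASSUMED", 0)
    emit(prob * u1 * (1 - u2) * (1 - ams_pos), c1, tests, "LS_NEGATIVE", 0)
    # tested
    c2 <- c1 + params$costs$mutation_test + ihc_extra
    t2 <- add_counts(tests, c(MUTATION = 1, ihc_tests))
    emit(prob * u1 * u2 * mut_pos, c2, t2, "LS_POSITIVE", 1)
    emit(prob * u1 * u2 * (1 - mut_pos) * ams_pos, c2, t2, "LS_ASSUMED", 1)
    emit(prob * u1 * u2 * (1 - mut_pos) * (1 - ams_pos), c2, t2,
         "LS_NEGATIVE", 1)
  }

  add_counts <- function(a, b) {
    for (nm in names(b)) a[nm] <- (if (is.na(a[nm] %||% NA)) 0 else a[nm]) + b[nm]
    a
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x

  # preceding MSI/IHC context for conditional accuracies
  expand <- function(target, prob, cost, tests, context) {
    if (target == "REFER") return(expand_refer(prob, cost, tests))
    if (target == "ASSUME") return(emit(prob, cost, tests, "LS_ASSUMED", 0))
    if (target == "NOREFER") return(emit(prob, cost, tests, "LS_NEGATIVE", 0))
    nd <- strategy$nodes[[target]]
    test <- sub("_PANEL", "", nd$test)
    cond <- if (test %in% c("BRAF", "METHYLATION")) context else NULL
    newctx <- if (test %in% c("MSI", "IHC4")) test else context
    cost2 <- cost + unit_cost[[test]]
    tests2 <- add_counts(tests, stats::setNames(1, test))
    pp <- vapply(strata, function(s) p_pos(test, cond, s), 0)
    if (nd$test == "IHC4_PANEL") {
      rho <- params$diagnostics$p_ihc_concordant
      pf <- vapply(strata, function(s) {
        if (s == "NONLS") params$diagnostics$p_sporadic_mlh1_pattern
        else if (s == "MLH1") rho else (1 - rho) * 0.5
      }, 0)
      expand(nd$branches$mlh1, prob * pp * pf, cost2, tests2, newctx)
      expand(nd$branches$other, prob * pp * (1 - pf), cost2, tests2, newctx)
      expand(nd$branches$normal, prob * (1 - pp), cost2, tests2, newctx)
    } else {
      expand(nd$branches$pos, prob * pp, cost2, tests2, newctx)
      expand(nd$branches$neg, prob * (1 - pp), cost2, tests2, newctx)
    }
  }
  expand(strategy$root, stats::setNames(rep(1, length(strata)), strata),
         0, numeric(0), NULL)

  joint <- matrix(0, 2, 3, dimnames = list(c("LS", "NONLS"),
                                           c("LS_POSITIVE", "LS_ASSUMED",
                                             "LS_NEGATIVE")))
  cost <- 0; tests <- numeric(0); gtests <- 0
  is_ls <- strata != "NONLS"
  for (p in paths) {
    m <- mass0 * p$prob
    joint["LS", p$class] <- joint["LS", p$class] + sum(m[is_ls])
    joint["NONLS", p$class] <- joint["NONLS", p$class] + sum(m[!is_ls])
    cost <- cost + sum(m) * p$cost
    tests <- add_counts(tests, p$tests * sum(m))
    gtests <- gtests + p$gtest * sum(m)
  }
  list(joint = joint, cost = cost, tests = tests, genetic_tests = gtests)
}

# Brute-force net-health-benefit maximiser over a lambda grid.
oracle_best_at_lambda <- function(costs, qalys, lambda) {
  which.max(qalys - costs / lambda)
}

# Independent inversion sampler for a two-interval piecewise-constant
# hazard (used to cross-check calibration by simulation).
oracle_sample_two_piece <- function(n, a1, r1, a2, r2) {
  u <- stats::runif(n)
  e <- -log(u)
  t <- ifelse(e < r1 * a1, e / r1,
              ifelse(e < r1 * a1 + r2 * (a2 - a1),
                     a1 + (e - r1 * a1) / r2, Inf))
  t
}

base_params <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- generate_parameter_set()
    p
  }
})

zero_hazard <- function() hazard_fn(c(0, 100), 0)

# Parameter set with every stochastic channel silenced (no deaths, no
# cancers, no procedure risks): the null-process world.
null_world <- function() {
  p <- base_params()
  for (h in c("mortality_male", "mortality_female",
              "crc_index_ls_male", "crc_index_ls_female",
              "crc_index_sporadic_male", "crc_index_sporadic_female",
              "crc_metachronous_ls", "crc_metachronous_sporadic",
              "ec_ls", "ec_sporadic"))
    p <- apply_univariate_override(p, paste0("hazards$", h), zero_hazard())
  p <- apply_univariate_override(p, "simulation$p_colonoscopy_death", 0)
  p <- apply_univariate_override(p, "simulation$p_colonoscopy_complication", 0)
  p <- apply_univariate_override(p, "simulation$p_hbso_death", 0)
  p
}
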