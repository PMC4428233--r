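CLASSIFICATIONS <- c("LS_POSITIVE", "LS_ASSUMED", "LS_NEGATIVE")
LS_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2")

#' Build one of the nine diagnostic strategies
#'
#' Each strategy is a small decision tree over tumour/family-history tests.
#' Terminals are `REFER` (genetic counselling and diagnostic mutation
#' testing, with family-history fallback on decline or negative result),
#' `ASSUME` (classified Lynch-assumed without genetic testing) and
#' `NOREFER` (classified Lynch-negative).
#'
#' * `S1_1` - no testing; everyone Lynch-negative (zero test nodes).
#' * `S1_2` - Amsterdam II family-history criteria only.
#' * `S2`   - IHC four-panel; mutation testing if abnormal.
#' * `S3`   - IHC four-panel; BRAF V600E if MLH1 abnormal (ruling out if
#'   the mutation is found); mutation testing if another protein is
#'   abnormal or BRAF V600E is absent.
#' * `S4`   - MSI; mutation testing if MSI-high.
#' * `S5`   - MSI; BRAF V600E if MSI-high; mutation testing if BRAF
#'   wild-type.
#' * `S6`   - as `S5`, with IHC run in parallel at the mutation-testing
#'   step (cost only; no diagnostic branching).
#' * `S7`   - IHC four-panel; mutation testing if abnormal, otherwise
#'   follow `S5`.
#' * `S8`   - direct mutation testing for every proband.
#'
#' @param strategy_id one of the identifiers above.
#' @return an object of class `ls_strategy`.
#' @export
build_strategy <- function(strategy_id) {
  node <- function(test, branches) list(test = test, branches = branches)
  n <- switch(strategy_id,
    S1_1 = list(root = "NOREFER", nodes = list()),
    S1_2 = list(root = "ams", nodes = list(
      ams = node("AMSTERDAM2", list(pos = "ASSUME", neg = "NOREFER")))),
    S2 = list(root = "ihc", nodes = list(
      ihc = node("IHC4", list(pos = "REFER", neg = "NOREFER")))),
    S3 = list(root = "ihc", nodes = list(
      ihc = node("IHC4_PANEL", list(mlh1 = "braf", other = "REFER",
                                    normal = "NOREFER")),
      braf = node("BRAF", list(pos = "REFER", neg = "NOREFER")))),
    S4 = list(root = "msi", nodes = list(
      msi = node("MSI", list(pos = "REFER", neg = "NOREFER")))),
    S5 = list(root = "msi", nodes = list(
      msi = node("MSI", list(pos = "braf", neg = "NOREFER")),
      braf = node("BRAF", list(pos = "REFER", neg = "NOREFER")))),
    S6 = list(root = "msi", nodes = list(
      msi = node("MSI", list(pos = "braf", neg = "NOREFER")),
      braf = node("BRAF", list(pos = "REFER", neg = "NOREFER")))),
    S7 = list(root = "ihc", nodes = list(
      ihc = node("IHC4", list(pos = "REFER", neg = "msi")),
      msi = node("MSI", list(pos = "braf", neg = "NOREFER")),
      braf = node("BRAF", list(pos = "REFER", neg = "NOREFER")))),
    S8 = list(root = "REFER", nodes = list()),
    stopf("unknown strategy id '%s'", strategy_id)
  )
  structure(list(strategy_id = strategy_id, root = n$root, nodes = n$nodes,
                 parallel_ihc_at_mutation = identical(strategy_id, "S6")),
            class = "ls_strategy")
}

#' All nine strategy identifiers
#' @export
strategy_ids <- function() {
  c("S1_1", "S1_2", "S2", "S3", "S4", "S5", "S6", "S7", "S8")
}

#' Human-readable display label for a strategy
#' @param strategy_id strategy identifier.
#' @export
strategy_label <- function(strategy_id) {
  c(S1_1 = "1(1)", S1_2 = "1(2)", S2 = "2", S3 = "3", S4 = "4",
    S5 = "5", S6 = "6", S7 = "7", S8 = "8")[[strategy_id]]
}

#' @export
print.ls_strategy <- function(x, ...) {
  cat(format_strategy(x), sep = "\n")
  invisible(x)
}

#' Indented text dump of a strategy tree (for audit)
#' @param strategy an `ls_strategy`.
#' @return character vector of lines.
#' @export
format_strategy <- function(strategy) {
  out <- sprintf("Strategy %s", strategy_label(strategy$strategy_id))
  rec <- function(target, depth, label) {
    pad <- strrep("  ", depth)
    if (target %in% c("REFER", "ASSUME", "NOREFER")) {
      out <<- c(out, sprintf("%s%s-> %s", pad, label, target))
    } else {
      nd <- strategy$nodes[[target]]
      out <<- c(out, sprintf("%s%s-> test %s", pad, label, nd$test))
      for (b in names(nd$branches)) rec(nd$branches[[b]], depth + 1,
                                        sprintf("[%s] ", b))
    }
  }
  rec(strategy$root, 1, "")
  if (strategy$parallel_ihc_at_mutation)
    out <- c(out, "  (IHC four-panel run in parallel at mutation testing; cost only)")
  out
}

# Preceding-test context used to pick conditional BRAF/methylation
# accuracies: the nearest upstream MSI or IHC node.
preceding_test <- function(strategy, node_name) {
  find <- function(target, context) {
    if (target %in% c("REFER", "ASSUME", "NOREFER")) return(NULL)
    if (target == node_name) return(context)
    nd <- strategy$nodes[[target]]
    ctx <- if (nd$test %in% c("MSI", "IHC4", "IHC4_PANEL"))
      sub("_PANEL", "", nd$test) else context
    for (b in nd$branches) {
      r <- find(b, ctx)
      if (!is.null(r)) return(r)
    }
    NULL
  }
  find(strategy$root, NULL)
}

# P(branch | stratum) for one node.  Strata are the Lynch mutation genes
# plus "NONLS"; gene-level resolution is only consequential for the
# IHC4_PANEL three-way branch.
branch_probs <- function(strategy, node_name, params) {
  nd <- strategy$nodes[[node_name]]
  test <- sub("_PANEL", "", nd$test)
  cond <- if (nd$test %in% c("BRAF", "METHYLATION"))
    preceding_test(strategy, node_name) else NULL
  a <- get_accuracy(params, test, cond)
  strata <- c(LS_GENES, "NONLS")
  p_pos <- ifelse(strata == "NONLS", 1 - a$specificity, a$sensitivity)
  if (nd$test == "IHC4_PANEL") {
    rho <- params$diagnostics$p_ihc_concordant
    pf <- ifelse(strata == "NONLS", params$diagnostics$p_sporadic_mlh1_pattern,
                 ifelse(strata == "MLH1", rho, (1 - rho) * 0.5))
    out <- rbind(mlh1 = p_pos * pf, other = p_pos * (1 - pf),
                 normal = 1 - p_pos)
  } else {
    out <- rbind(pos = p_pos, neg = 1 - p_pos)
  }
  colnames(out) <- strata
  out
}

empty_joint <- function() {
  matrix(0, 2, 3, dimnames = list(c("LS", "NONLS"), CLASSIFICATIONS))
}

#' Evaluate a strategy's decision tree over the proband cohort
#'
#' Expected-value tree walk: the annual proband cohort is split into Lynch
#' strata (by mutated gene) and a sporadic stratum; every test node applies
#' its (possibly conditional) sensitivity to carriers and false-positive
#' rate to non-carriers.  Probands referred for genetic testing may decline
#' counselling or testing and are then classified Lynch-assumed or
#' Lynch-negative on family history; a negative mutation test falls back to
#' family history the same way.
#'
#' @param strategy an `ls_strategy` from [build_strategy()].
#' @param params a validated [ls_parameters] object.
#' @return an object of class `ls_diag_outcomes` with elements
#'   `joint_probands` (2 x 3 expected counts over true status x
#'   classification), `tests_used` (named expected test counts),
#'   `diagnostic_cost` (GBP, discounted at time zero),
#'   `n_genetic_tests_taken`, `n_accepting_surveillance` (by true status)
#'   and `n_mutation_confirmed` (by true status; seeds the relative
#'   cascade).
#' @export
evaluate_probands <- function(strategy, params) {
  pop <- params$population
  n <- pop$n_probands
  p <- pop$ls_prevalence
  spectrum <- params$diagnostics$mutation_spectrum
  strata <- c(LS_GENES, "NONLS")
  mass <- c(p * spectrum[LS_GENES], NONLS = 1 - p) * n

  acc <- list(joint = empty_joint(), tests = numeric(0), cost = 0,
              genetic_tests = c(LS = 0, NONLS = 0))
  add_tests <- function(test, m) {
    acc$tests[test] <<- (acc$tests[test] %||% 0)
    if (is.na(acc$tests[test])) acc$tests[test] <- 0
    acc$tests[test] <<- acc$tests[test] + sum(m)
  }
  true_row <- ifelse(strata == "NONLS", "NONLS", "LS")
  add_class <- function(cls, m) {
    for (r in c("LS", "NONLS"))
      acc$joint[r, cls] <<- acc$joint[r, cls] + sum(m[true_row == r])
  }

  test_unit_cost <- function(test) {
    switch(test, MSI = params$costs$msi, IHC4 = params$costs$ihc4,
           BRAF = params$costs$braf, METHYLATION = params$costs$methylation,
           MUTATION = params$costs$mutation_test,
           AMSTERDAM2 = params$costs$amsterdam)
  }

  ams <- get_accuracy(params, "AMSTERDAM2")
  p_fh <- ifelse(strata == "NONLS", 1 - ams$specificity, ams$sensitivity)

  refer <- function(m) {
    u_test <- pop$uptake_counselling * pop$uptake_mutation_test
    acc$cost <<- acc$cost + sum(m) * pop$uptake_counselling * params$costs$counselling
    testers <- m * u_test
    acc$cost <<- acc$cost + sum(testers) * params$costs$mutation_test
    if (strategy$parallel_ihc_at_mutation) {
      acc$cost <<- acc$cost + sum(testers) * params$costs$ihc4
      add_tests("IHC4", testers)
    }
    add_tests("MUTATION", testers)
    for (r in c("LS", "NONLS"))
      acc$genetic_tests[r] <<- acc$genetic_tests[r] + sum(testers[true_row == r])
    mut <- get_accuracy(params, "MUTATION")
    p_mutpos <- ifelse(strata == "NONLS", 1 - mut$specificity, mut$sensitivity)
    add_class("LS_POSITIVE", testers * p_mutpos)
    fallback <- testers * (1 - p_mutpos) + m * (1 - u_test)
    add_class("LS_ASSUMED", fallback * p_fh)
    add_class("LS_NEGATIVE", fallback * (1 - p_fh))
  }

  walk <- function(target, m) {
    if (sum(m) == 0 && target %in% c("REFER", "ASSUME", "NOREFER")) return()
    if (target == "REFER") { refer(m); return() }
    if (target == "ASSUME") { add_class("LS_ASSUMED", m); return() }
    if (target == "NOREFER") { add_class("LS_NEGATIVE", m); return() }
    nd <- strategy$nodes[[target]]
    test <- sub("_PANEL", "", nd$test)
    add_tests(test, m)
    acc$cost <<- acc$cost + sum(m) * test_unit_cost(test)
    bp <- branch_probs(strategy, target, params)
    for (b in names(nd$branches)) walk(nd$branches[[b]], m * bp[b, ])
  }
  walk(strategy$root, mass)

  n_surv <- acc$joint[, "LS_POSITIVE"] + acc$joint[, "LS_ASSUMED"]
  structure(list(
    strategy_id = strategy$strategy_id,
    joint_probands = acc$joint,
    joint_relatives = NULL,
    tests_used = acc$tests,
    diagnostic_cost = acc$cost,
    n_genetic_tests_taken = sum(acc$genetic_tests),
    n_accepting_surveillance = n_surv * pop$uptake_surveillance,
    n_mutation_confirmed = acc$joint[, "LS_POSITIVE"]
  ), class = "ls_diag_outcomes")
}

#' Cascade predictive testing to relatives
#'
#' The relative population is fixed across strategies (so that incremental
#' comparisons hold the cohort constant): every proband family contributes
#' `relatives_per_positive_proband` first-degree relatives (FDRs), each of
#' whom has `relatives_second_degree_per_carrier` more distant relatives.
#' Only families with a mutation-confirmed proband are offered predictive
#' testing (with uptake); each FDR carries the family mutation with
#' probability 0.5, and confirmed carriers seed one further cascade
#' generation.  FDRs of Lynch-assumed probands are classified Lynch-assumed
#' without testing; all other relatives remain Lynch-negative (untested).
#'
#' @param proband_outcomes result of [evaluate_probands()].
#' @param params a validated [ls_parameters] object.
#' @return the outcomes object with `joint_relatives`, updated costs, test
#'   counts and surveillance acceptance.
#' @export
cascade_relatives <- function(proband_outcomes, params) {
  po <- proband_outcomes
  pop <- params$population
  R <- pop$relatives_per_positive_proband
  R2 <- pop$relatives_second_degree_per_carrier
  depth <- pop$cascade_depth
  u <- pop$uptake_predictive_test

  # Joint is indexed by the *relative's* own true Lynch status.  In truly
  # affected families an FDR carries the pathogenic mutation with
  # probability 0.5; second-degree relatives reached through a confirmed
  # carrier also carry it with probability 0.5, unreached ones with 0.25.
  # Mutation-test false positives in sporadic families are treated as a
  # benign familial variant (inherited and detected with the same
  # Mendelian arithmetic but conferring no cancer risk).
  jr <- empty_joint()
  tested <- 0
  add <- function(true, cls, m) jr[true, cls] <<- jr[true, cls] + m

  for (fam in c("LS", "NONLS")) {
    carrier_true <- function(pc) if (fam == "LS") pc else 0
    n_tot <- sum(po$joint_probands[fam, ])
    np <- po$joint_probands[fam, "LS_POSITIVE"]
    na <- po$joint_probands[fam, "LS_ASSUMED"]

    # --- FDRs of mutation-confirmed probands: offered predictive testing
    fdr <- np * R
    fdr_tested <- fdr * u
    tested <- tested + fdr_tested
    det <- fdr_tested * 0.5                       # variant detected
    add(if (fam == "LS") "LS" else "NONLS", "LS_POSITIVE", det)
    add("NONLS", "LS_NEGATIVE", fdr_tested * 0.5) # tested, variant absent
    fdr_unt <- fdr * (1 - u)
    add("LS", "LS_NEGATIVE", fdr_unt * carrier_true(0.5))
    add("NONLS", "LS_NEGATIVE", fdr_unt * (1 - carrier_true(0.5)))

    # --- second generation through confirmed carriers (cascade depth 1)
    reached <- if (depth >= 1) det * R2 else 0
    sdr_tested <- reached * u
    tested <- tested + sdr_tested
    add(if (fam == "LS") "LS" else "NONLS", "LS_POSITIVE", sdr_tested * 0.5)
    add("NONLS", "LS_NEGATIVE", sdr_tested * 0.5)
    reached_unt <- reached * (1 - u)
    add("LS", "LS_NEGATIVE", reached_unt * carrier_true(0.5))
    add("NONLS", "LS_NEGATIVE", reached_unt * (1 - carrier_true(0.5)))
    sdr_unreached <- np * R * R2 - reached
    add("LS", "LS_NEGATIVE", sdr_unreached * carrier_true(0.25))
    add("NONLS", "LS_NEGATIVE", sdr_unreached * (1 - carrier_true(0.25)))

    # --- FDRs of Lynch-assumed probands: assumed without testing
    add("LS", "LS_ASSUMED", na * R * carrier_true(0.5))
    add("NONLS", "LS_ASSUMED", na * R * (1 - carrier_true(0.5)))
    add("LS", "LS_NEGATIVE", na * R * R2 * carrier_true(0.25))
    add("NONLS", "LS_NEGATIVE", na * R * R2 * (1 - carrier_true(0.25)))

    # --- relatives of Lynch-negative probands: never contacted
    rest <- (n_tot - np - na) * (R + R * R2)
    frac_carrier <- carrier_true((0.5 * R + 0.25 * R * R2) /
                                   max(R + R * R2, 1e-300))
    add("LS", "LS_NEGATIVE", rest * frac_carrier)
    add("NONLS", "LS_NEGATIVE", rest * (1 - frac_carrier))
  }

  po$joint_relatives <- jr
  po$tests_used["PREDICTIVE"] <- tested
  po$relative_test_cost <- tested * (params$costs$predictive_test +
                                     params$costs$counselling)
  po$diagnostic_cost <- po$diagnostic_cost + po$relative_test_cost
  po$n_genetic_tests_taken <- po$n_genetic_tests_taken + tested
  po$n_accepting_surveillance_relatives <-
    (jr[, "LS_POSITIVE"] + jr[, "LS_ASSUMED"]) * pop$uptake_surveillance
  po
}

#' Diagnostic confusion-matrix metrics
#'
#' Sensitivity, specificity, positive and negative predictive value of a
#' strategy's proband classifications.  A Lynch-assumed classification
#' counts as a positive diagnosis (recorded in the output).  Ratios with a
#' zero denominator are returned as `NaN` (not-a-value), not an error.
#'
#' @param outcomes an `ls_diag_outcomes` object.
#' @param role `"probands"` (default) or `"relatives"`.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv` and the
#'   decision rule used.
#' @export
confusion_metrics <- function(outcomes, role = c("probands", "relatives")) {
  role <- match.arg(role)
  j <- if (role == "probands") outcomes$joint_probands else outcomes$joint_relatives
  pos <- j[, "LS_POSITIVE"] + j[, "LS_ASSUMED"]
  neg <- j[, "LS_NEGATIVE"]
  ratio <- function(a, b) if (b == 0) NaN else a / b
  list(
    sensitivity = ratio(pos["LS"], pos["LS"] + neg["LS"]),
    specificity = ratio(neg["NONLS"], pos["NONLS"] + neg["NONLS"]),
    ppv = ratio(pos["LS"], sum(pos)),
    npv = ratio(neg["NONLS"], sum(neg)),
    positive_rule = "LS_POSITIVE or LS_ASSUMED counted as positive diagnosis"
  )
}

#' Write diagnostic outcomes as a delimited table
#' @param outcomes an `ls_diag_outcomes` object.
#' @param path output TSV path (or `""` for stdout).
#' @export
write_diag_outcomes <- function(outcomes, path = "") {
  rows <- expand.grid(true_status = c("LS", "NONLS"),
                      classification = CLASSIFICATIONS,
                      stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(c("probands", "relatives"), function(role) {
    j <- if (role == "probands") outcomes$joint_probands else outcomes$joint_relatives
    if (is.null(j)) return(NULL)
    cbind(strategy = outcomes$strategy_id, role = role, rows,
          count = j[cbind(rows$true_status, rows$classification)])
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
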