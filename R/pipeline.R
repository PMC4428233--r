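#' Run the full cost-utility analysis
#'
#' Evaluates every requested strategy's diagnostic decision tree, cascades
#' testing to relatives, simulates the management profile cells once
#' (shared across strategies, with common random numbers) and combines the
#' submodels into strategy results, the cost-effectiveness frontier and a
#' plot-ready cost-utility plane.
#'
#' @param params a validated [ls_parameters] object.
#' @param strategies character ids or `ls_strategy` objects.
#' @param n_replicates simulation replicates per management cell.
#' @param seed integer seed (drives all randomness; identical seeds give
#'   bit-identical bundles).
#' @return a result bundle: list with `results` (per-strategy
#'   `ls_strategy_result`), `diag` (per-strategy diagnostic outcomes),
#'   `mgmt` (per-profile simulation means), `frontier`, `plane`,
#'   `incremental` (anchored on the no-testing strategy when present) and
#'   `manifest`.
#' @export
run_cea <- function(params, strategies = strategy_ids(),
                    n_replicates = 2000, seed = 1L) {
  rep <- validate_parameters(params)
  if (length(rep) > 0)
    stopf("invalid parameters: %s", paste(rep, collapse = "; "))
  strat <- lapply(strategies, function(s)
    if (inherits(s, "ls_strategy")) s else build_strategy(s))

  diag <- lapply(strat, function(s)
    cascade_relatives(evaluate_probands(s, params), params))
  profs <- management_profiles(params)
  mgmt <- simulate_cohort(profs, params, n_replicates, seed)
  results <- lapply(diag, combine_submodels, mgmt = mgmt, params = params)

  frontier <- find_frontier(results)
  plane <- cost_utility_plane(results, wtp = params$econ$wtp)
  ids <- vapply(results, function(r) r$strategy_id, "")
  anchor <- if ("S1_1" %in% ids) "S1_1" else ids[which.min(
    vapply(results, function(r) r$total_cost, 0))]
  incr <- incremental_table(results, anchor, params$econ$wtp)

  list(results = results, diag = diag, mgmt = mgmt,
       frontier = frontier, plane = plane, incremental = incr,
       manifest = list(seed = seed, n_replicates = n_replicates,
                       anchor = anchor,
                       strategies = ids,
                       parameters_hash = params_hash(params),
                       package_version = as.character(
                         utils::packageVersion("lynchcea"))))
}

# Incremental cost/QALY table versus an anchor strategy, mirroring the
# published table layout (categories, short/long QALYs, ICER and INHB).
incremental_table <- function(results, anchor_id, wtp) {
  ids <- vapply(results, function(r) r$strategy_id, "")
  a <- results[[match(anchor_id, ids)]]
  rows <- lapply(results, function(r) {
    dc <- r$total_cost - a$total_cost
    dq <- r$total_qalys - a$total_qalys
    data.frame(
      strategy_id = r$strategy_id,
      dc_diagnosis = r$cost$diagnosis - a$cost$diagnosis,
      dc_crc_prevention = r$cost$crc_prevention - a$cost$crc_prevention,
      dc_crc_treatment = r$cost$crc_treatment - a$cost$crc_treatment,
      dc_ec_prevention = r$cost$ec_prevention - a$cost$ec_prevention,
      dc_ec_treatment = r$cost$ec_treatment - a$cost$ec_treatment,
      dc_total = dc,
      dq_short = r$qalys_short - a$qalys_short,
      dq_long = r$qalys_long - a$qalys_long,
      dq_total = dq,
      icer_vs_anchor = if (dq == 0) NA_real_ else icer(dc, dq),
      inhb_vs_anchor = inhb(dc, dq, wtp),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

params_hash <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  write_parameters(params, f)
  unname(tools::md5sum(f))
}

#' Replay the cost-utility arithmetic on supplied incrementals
#'
#' Bypasses the simulation entirely: takes incremental (cost, QALY) pairs
#' versus the no-testing anchor — such as the published base-case table
#' from [generate_table2_fixture()] — and runs only the CEA engine (ICERs,
#' INHB, dominance, frontier).  This is the exact-reproduction surface for
#' published tables.
#'
#' @param fixture data.frame with columns `strategy_id`, `dc_total` (GBP
#'   thousands) and `dq_total` (QALYs).
#' @param wtp willingness-to-pay (GBP/QALY).
#' @return list with `table` (ICER and INHB versus the anchor), `frontier`
#'   and `plane`.
#' @export
replay_cea <- function(fixture, wtp = 20000) {
  results <- lapply(seq_len(nrow(fixture)), function(i) {
    structure(list(strategy_id = fixture$strategy_id[i],
                   cost = list(), total_cost = fixture$dc_total[i] * 1000,
                   qalys_short = fixture$dq_short[i] %||% NA_real_,
                   qalys_long = fixture$dq_long[i] %||% NA_real_,
                   total_qalys = fixture$dq_total[i]),
              class = "ls_strategy_result")
  })
  ids <- fixture$strategy_id
  anchor <- which(fixture$dc_total == 0 & fixture$dq_total == 0)[1]
  tab <- data.frame(
    strategy_id = ids,
    dc_total = fixture$dc_total,
    dq_total = fixture$dq_total,
    icer = ifelse(fixture$dq_total == 0, NA_real_,
                  round_half_away(fixture$dc_total * 1000 / fixture$dq_total)),
    inhb = round_half_away(
      inhb(fixture$dc_total * 1000, fixture$dq_total, wtp), 1),
    stringsAsFactors = FALSE
  )
  list(table = tab, frontier = find_frontier(results),
       plane = cost_utility_plane(results, anchor_id = ids[anchor], wtp = wtp))
}

#' Run the base case from a configuration and write all outputs
#'
#' @param config list with elements `parameter_file` (or `params`),
#'   `strategies`, `seed`, `n_replicates`, `output_dir`.
#' @return the result bundle, invisibly; writes delimited tables
#'   (incremental cost-utility, secondary outcomes, frontier, plane) and a
#'   JSON run manifest to `output_dir`.
#' @export
run_base_case <- function(config) {
  params <- config$params %||% read_parameters(config$parameter_file)
  bundle <- run_cea(params,
                    strategies = config$strategies %||% strategy_ids(),
                    n_replicates = config$n_replicates %||% 2000,
                    seed = config$seed %||% 1L)
  out <- config$output_dir
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(bundle$incremental, "incremental_cost_utility.tsv")
    wt(secondary_outcomes_table(bundle), "secondary_outcomes.tsv")
    wt(bundle$frontier$labels, "frontier_labels.tsv")
    wt(bundle$frontier$ladder, "frontier_ladder.tsv")
    wt(bundle$plane, "cost_utility_plane.tsv")
    jsonlite::write_json(bundle$manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}

# Secondary outcomes (colonoscopies, cancers, life expectancy) versus the
# anchor strategy.
secondary_outcomes_table <- function(bundle) {
  ids <- vapply(bundle$results, function(r) r$strategy_id, "")
  a <- bundle$results[[match(bundle$manifest$anchor, ids)]]
  do.call(rbind, lapply(bundle$results, function(r) data.frame(
    strategy_id = r$strategy_id,
    n_colonoscopies = r$n_colonoscopies,
    d_colonoscopies = r$n_colonoscopies - a$n_colonoscopies,
    n_crcs = r$n_crcs, d_crcs = r$n_crcs - a$n_crcs,
    n_ecs = r$n_ecs, d_ecs = r$n_ecs - a$n_ecs,
    life_years = r$life_years_undiscounted,
    d_life_years = r$life_years_undiscounted - a$life_years_undiscounted,
    stringsAsFactors = FALSE
  )))
}

#' Human-readable summary of a result bundle
#'
#' Names the maximum-INHB strategy (ties disclosed), the frontier and the
#' headline ICERs versus the anchor.
#'
#' @param bundle result of [run_cea()] (or [replay_cea()] table wrapped in
#'   a bundle-like list).
#' @return character vector of report lines (also printed).
#' @export
run_report <- function(bundle) {
  inc <- bundle$incremental
  lines <- character(0)
  say <- function(...) lines <<- c(lines, sprintf(...))
  best <- inc$strategy_id[which(inc$inhb_vs_anchor ==
                                  max(inc$inhb_vs_anchor))]
  say("Strategies analysed: %s", paste(inc$strategy_id, collapse = ", "))
  say("Greatest net health benefit: %s (INHB %.1f QALYs vs %s)",
      paste(best, collapse = " and "), max(inc$inhb_vs_anchor),
      bundle$manifest$anchor)
  fr <- bundle$frontier$labels
  say("On frontier: %s",
      paste(fr$strategy_id[fr$label == "ON_FRONTIER"], collapse = ", "))
  say("Dominated: %s",
      paste(fr$strategy_id[fr$label == "DOMINATED"], collapse = ", "))
  say("Extended dominated: %s",
      paste(fr$strategy_id[fr$label == "EXTENDED_DOMINATED"], collapse = ", "))
  for (i in seq_len(nrow(inc))) {
    if (!is.na(inc$icer_vs_anchor[i]) && inc$strategy_id[i] != bundle$manifest$anchor)
      say("  %s: ICER GBP %s/QALY, INHB %.1f", inc$strategy_id[i],
          format(inc$icer_vs_anchor[i], big.mark = ","), inc$inhb_vs_anchor[i])
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Command-line interface
#'
#' Subcommands: `validate`, `cea`, `replay`, `scenario`, `tornado`,
#' `project`, `synth`.  Run as
#' `Rscript -e 'lynchcea::lynchcea_cli()' <subcommand> [options]`.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit status, invisibly.
#' @export
lynchcea_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: lynchcea_cli <command> [args]",
    "  validate <params.json>",
    "  synth <out.json> [anchored|random] [seed]",
    "  cea <params.json> <outdir> [seed] [n_replicates]",
    "  replay <outdir>",
    "  scenario <params.json> <scenario_id> <outdir> [seed] [n_replicates]",
    "  project <params.json> <strategy_id> <years> <out.tsv>",
    sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; a <- args[-1]
  switch(cmd,
    validate = {
      rep <- validate_parameters(read_parameters(a[1]))
      if (length(rep) == 0) message("parameter set valid")
      else { message(paste(rep, collapse = "\n")); return(invisible(1L)) }
    },
    synth = {
      p <- generate_parameter_set(
        seed = if (length(a) >= 3) as.integer(a[3]) else 1L,
        realism = if (length(a) >= 2) a[2] else "anchored")
      write_parameters(p, a[1])
      message("wrote ", a[1])
    },
    cea = {
      bundle <- run_base_case(list(
        parameter_file = a[1], output_dir = a[2],
        seed = if (length(a) >= 3) as.integer(a[3]) else 1L,
        n_replicates = if (length(a) >= 4) as.integer(a[4]) else 2000))
      run_report(bundle)
    },
    replay = {
      rp <- replay_cea(generate_table2_fixture())
      dir.create(a[1], showWarnings = FALSE, recursive = TRUE)
      utils::write.table(rp$table, file.path(a[1], "replay_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(rp$frontier$labels,
                         file.path(a[1], "replay_frontier.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      print(rp$frontier)
    },
    scenario = {
      params <- read_parameters(a[1])
      bundle <- run_scenario(scenario_spec(a[2]), params,
                             seed = if (length(a) >= 4) as.integer(a[4]) else 1L,
                             n_replicates = if (length(a) >= 5)
                               as.integer(a[5]) else 2000)
      dir.create(a[3], showWarnings = FALSE, recursive = TRUE)
      utils::write.table(bundle$incremental,
                         file.path(a[3], paste0("scenario_", a[2], ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      run_report(bundle)
    },
    project = {
      params <- read_parameters(a[1])
      ds <- project_demand(a[2], params, years = as.integer(a[3]))
      utils::write.table(ds, a[4], sep = "\t", quote = FALSE, row.names = FALSE)
      message(sprintf("steady state: %.0f colonoscopies/year",
                      attr(ds, "steady_state")))
    },
    { message(usage); return(invisible(1L)) }
  )
  invisible(0L)
}
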