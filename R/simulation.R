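# Individual patient simulation: continuous-time competing-risks sampling
# from piecewise-constant hazards by inversion (no model cycles).  A fixed
# block of uniforms drives each replicate so that policy arms, strategies
# and sensitivity runs are paired (common random numbers): column layout
# below, plus one complication and one death draw per potential colonoscopy.

N_CORE_U <- 10L      # death, crc1, stage1, csurv1, crc2, stage2, csurv2,
                     # ec, ecsurv, hbso_death
MAX_COLS <- 30L      # upper bound on scheduled colonoscopies per life
U_BLOCK <- N_CORE_U + 2L * MAX_COLS

#' Construct an individual profile
#'
#' A profile describes one simulated stratum of the cohort: role (probands
#' enter with a prior colorectal cancer), sex, true carrier status, the
#' assigned classification and the accepted risk-reducing interventions.
#'
#' @param role `"proband"` or `"relative"`.
#' @param sex `"male"` or `"female"`.
#' @param true_ls logical: carries a pathogenic mismatch-repair mutation.
#' @param classification one of `LS_POSITIVE`, `LS_ASSUMED`, `LS_NEGATIVE`.
#' @param accepted_surveillance logical.
#' @param accepted_hbso logical (females only).
#' @param start_age age at model entry (probands: age at CRC diagnosis).
#' @param took_genetic_test logical; triggers the four-month testing
#'   disutility when accrued at the individual level.
#' @return an object of class `ls_profile`.
#' @export
ls_profile <- function(role, sex, true_ls, classification = "LS_NEGATIVE",
                       accepted_surveillance = FALSE, accepted_hbso = FALSE,
                       start_age = if (role == "proband") 45 else 30,
                       took_genetic_test = FALSE) {
  stopifnot(role %in% c("proband", "relative"),
            sex %in% c("male", "female"),
            classification %in% CLASSIFICATIONS,
            start_age >= 0)
  if (sex == "male" && accepted_hbso) stopf("H-BSO applies to females only")
  structure(list(role = role, sex = sex, true_ls = true_ls,
                 classification = classification,
                 prior_crc = (role == "proband"),
                 accepted_surveillance = accepted_surveillance,
                 accepted_hbso = accepted_hbso,
                 start_age = start_age,
                 took_genetic_test = took_genetic_test),
            class = "ls_profile")
}

# Colonoscopy schedule for a profile: biennial in [25, 75] for accepted
# surveillance (late entrants start at entry and follow entry + 2k);
# probands not under Lynch surveillance receive routine post-CRC follow-up
# colonoscopies at configured offsets.
colonoscopy_schedule <- function(profile, params) {
  pol <- params$policy
  if (profile$accepted_surveillance) {
    from <- max(profile$start_age, pol$surveillance_start_age)
    if (from > pol$surveillance_stop_age) return(numeric(0))
    seq(from, pol$surveillance_stop_age, by = pol$surveillance_interval)
  } else if (profile$prior_crc) {
    s <- profile$start_age + pol$proband_followup_offsets
    s[s <= pol$surveillance_stop_age]
  } else {
    numeric(0)
  }
}

# Precomputed per-profile simulation context (hazards with surveillance
# multipliers and H-BSO truncation applied, schedules, costs, discounting).
build_context <- function(profile, params) {
  pol <- params$policy
  hz <- params$hazards
  sex <- profile$sex
  surv <- profile$accepted_surveillance
  w0 <- max(profile$start_age, pol$surveillance_start_age)
  w1 <- pol$surveillance_stop_age

  ls_tag <- if (profile$true_ls) "ls" else "sporadic"
  if (profile$prior_crc) {
    h1 <- hz[[paste0("crc_metachronous_", ls_tag)]]
    if (surv) h1 <- window_multiply_hazard(h1, params$surveillance$hr_metachronous_crc, w0, w1)
    h2 <- NULL                       # lifetime maximum of two CRCs
  } else {
    h1 <- hz[[paste0("crc_index_", ls_tag, "_", sex)]]
    if (surv) h1 <- window_multiply_hazard(h1, params$surveillance$hr_index_crc, w0, w1)
    h2 <- if (params$policy$max_crcs >= 2) hz[[paste0("crc_metachronous_", ls_tag)]] else NULL
    if (!is.null(h2) && surv)
      h2 <- window_multiply_hazard(h2, params$surveillance$hr_metachronous_crc, w0, w1)
  }

  th <- Inf; he <- NULL
  if (sex == "female") {
    he <- hz[[if (profile$true_ls) "ec_ls" else "ec_sporadic"]]
    if (profile$accepted_hbso) {
      th <- max(pol$hbso_offer_age, profile$start_age)
      he <- truncate_hazard(he, th)
    }
  }

  sched <- colonoscopy_schedule(profile, params)
  if (length(sched) > MAX_COLS)
    stopf("colonoscopy schedule exceeds internal bound of %d", MAX_COLS)

  list(profile = profile,
       start = profile$start_age,
       horizon = pol$horizon_age,
       h_mort = hz[[paste0("mortality_", sex)]],
       h_crc1 = h1, h_crc2 = h2, h_ec = he, th = th,
       sched = sched,
       surv_window = if (surv) c(w0, w1) else c(Inf, Inf),
       stage_cum_sympt = cumsum(params$simulation$stage_dist_symptomatic),
       stage_cum_det = cumsum(params$simulation$stage_dist_detected),
       h_excess = list(hz$crc_excess_A, hz$crc_excess_B,
                       hz$crc_excess_C, hz$crc_excess_D),
       h_ec_excess = hz$ec_excess,
       delta_c = log(1 + params$econ$discount_rate_costs),
       delta_q = log(1 + params$econ$discount_rate_qalys),
       norm_coefs = params$utilities$population_norms[[sex]])
}

# stage index from a shared uniform and a cumulative stage distribution;
# inverse-CDF sampling keeps surveillance-detected stages stochastically
# earlier under common random numbers.
sample_stage <- function(u, cum) findInterval(u, cum, left.open = TRUE) + 1L

# Vectorised engine: simulates n = nrow(U) replicates of one profile.
# Returns per-replicate event quantities (ages are real ages, Inf = never).
sim_engine <- function(ctx, U, params) {
  n <- nrow(U)
  start <- ctx$start
  sim <- params$simulation
  L <- length(ctx$sched)

  # general mortality and horizon
  d_gen <- sample_event_age(ctx$h_mort, U[, 1], start)
  d <- pmin(d_gen, ctx$horizon)
  death_cause <- rep("other_death", n)

  # colonoscopy-procedure deaths (first fatal scheduled colonoscopy)
  cd_age <- rep(Inf, n)
  if (L > 0) {
    dmask <- U[, N_CORE_U + MAX_COLS + seq_len(L), drop = FALSE] < sim$p_colonoscopy_death
    any_d <- rowSums(dmask) > 0
    if (any(any_d)) {
      first <- max.col(dmask, ties.method = "first")
      cd_age[any_d] <- ctx$sched[first[any_d]]
    }
    upd <- cd_age < d
    d[upd] <- cd_age[upd]
    death_cause[upd] <- "colonoscopy_death"
  }

  # H-BSO (deterministic offer age) and endometrial cancer incidence
  te <- rep(Inf, n); de <- rep(Inf, n); hbso_done <- rep(FALSE, n)
  hbso_death <- rep(FALSE, n)
  if (!is.null(ctx$h_ec)) {
    te <- sample_event_age(ctx$h_ec, U[, 8], start)
    if (is.finite(ctx$th)) {
      hbso_done <- ctx$th < pmin(te, d)
      hbso_death <- hbso_done & U[, 10] < sim$p_hbso_death
      d[hbso_death] <- ctx$th
      death_cause[hbso_death] <- "hbso_death"
    }
    se <- sample_event_age(ctx$h_ec_excess, U[, 9], 0)
    de <- te + se
  }

  # potential CRC incidences (validity resolved against evolving death age)
  t1 <- sample_event_age(ctx$h_crc1, U[, 2], start)
  det1 <- t1 >= ctx$surv_window[1] & t1 <= ctx$surv_window[2]
  stage1 <- ifelse(det1, sample_stage(U[, 3], ctx$stage_cum_det),
                   sample_stage(U[, 3], ctx$stage_cum_sympt))
  s1 <- rep(Inf, n)
  for (st in 1:4) {
    w <- stage1 == st
    if (any(w)) s1[w] <- sample_event_age(ctx$h_excess[[st]], U[w, 4], 0)
  }
  dc1 <- t1 + s1

  if (!is.null(ctx$h_crc2)) {
    t2 <- sample_event_age(ctx$h_crc2, U[, 5], start = pmax(t1, start))
    det2 <- t2 >= ctx$surv_window[1] & t2 <= ctx$surv_window[2]
    stage2 <- ifelse(det2, sample_stage(U[, 6], ctx$stage_cum_det),
                     sample_stage(U[, 6], ctx$stage_cum_sympt))
    s2 <- rep(Inf, n)
    for (st in 1:4) {
      w <- stage2 == st
      if (any(w)) s2[w] <- sample_event_age(ctx$h_excess[[st]], U[w, 7], 0)
    }
    dc2 <- t2 + s2
  } else {
    t2 <- rep(Inf, n); stage2 <- rep(NA_integer_, n); dc2 <- rep(Inf, n)
    det2 <- rep(FALSE, n)
  }

  # resolve incidence validity in chronological order (three orderings)
  resolve <- function(d) {
    ordA <- te <= t1
    ordC <- !ordA & te > t2
    ordB <- !(ordA | ordC)
    run <- function(seq_ids) {
      dd <- d
      v <- list(e = rep(FALSE, n), c1 = rep(FALSE, n), c2 = rep(FALSE, n))
      for (id in seq_ids) {
        if (id == "e") {
          v$e <- te < dd
          dd <- ifelse(v$e, pmin(dd, de), dd)
        } else if (id == "c1") {
          v$c1 <- t1 < dd
          dd <- ifelse(v$c1, pmin(dd, dc1), dd)
        } else {
          v$c2 <- v$c1 & t2 < dd
          dd <- ifelse(v$c2, pmin(dd, dc2), dd)
        }
      }
      list(d = dd, v = v)
    }
    A <- run(c("e", "c1", "c2")); B <- run(c("c1", "e", "c2"))
    C <- run(c("c1", "c2", "e"))
    pick <- function(f) ifelse(ordA, f(A), ifelse(ordB, f(B), f(C)))
    list(d = pick(function(x) x$d),
         v_e = pick(function(x) x$v$e) > 0,
         v1 = pick(function(x) x$v$c1) > 0,
         v2 = pick(function(x) x$v$c2) > 0)
  }
  res <- resolve(d)
  dfinal <- res$d
  death_cause[res$v1 & dc1 <= dfinal & dfinal < d] <- "crc_death"
  death_cause[res$v2 & dc2 <= dfinal & dfinal < d] <- "crc_death"
  death_cause[res$v_e & de <= dfinal & dfinal < d] <- "ec_death"

  # H-BSO can be pre-empted by an earlier death resolved above
  hbso_done <- hbso_done & ctx$th < dfinal | hbso_death

  list(n = n, start = start, death = dfinal, death_cause = death_cause,
       crc1 = ifelse(res$v1, t1, Inf), stage1 = stage1, det1 = det1,
       crc_death1 = ifelse(res$v1 & dc1 <= dfinal, dc1, Inf),
       crc2 = ifelse(res$v2, t2, Inf), stage2 = stage2, det2 = det2,
       crc_death2 = ifelse(res$v2 & dc2 <= dfinal, dc2, Inf),
       ec = ifelse(res$v_e, te, Inf),
       ec_death = ifelse(res$v_e & de <= dfinal, de, Inf),
       hbso = ifelse(hbso_done, ctx$th, Inf),
       comp_mask = if (L > 0)
         U[, N_CORE_U + seq_len(L), drop = FALSE] < sim$p_colonoscopy_complication
       else NULL)
}

# Vectorised accrual of discounted costs and QALYs from engine output.
accrue_engine <- function(ctx, sim_out, params) {
  so <- sim_out
  n <- so$n
  start <- so$start
  tdeath <- so$death - start               # model time of death
  dc <- ctx$delta_c; dq <- ctx$delta_q
  costs <- params$costs
  ut <- params$utilities
  L <- length(ctx$sched)

  dfc <- function(t) exp(-dc * t)          # discount factor, cost stream
  i0q <- function(t0, t1) disc_int_powers(pmax(t0, 0), pmax(t1, t0, 0), dq)$i0

  # colonoscopies and complications (crc_prevention)
  n_col <- numeric(n); cost_prev <- numeric(n); n_comp <- numeric(n)
  col_disutil <- numeric(n)
  if (L > 0) {
    toff <- ctx$sched - start
    alive <- outer(so$death, ctx$sched, ">")
    dfs <- dfc(toff)
    n_col <- rowSums(alive)
    unit <- costs$colonoscopy * params$econ$colonoscopy_cost_multiplier
    cost_prev <- (alive %*% dfs) * unit
    comp <- so$comp_mask & alive
    n_comp <- rowSums(comp)
    cost_prev <- cost_prev + (comp %*% dfs) * costs$colonoscopy_complication
    cost_prev <- as.numeric(cost_prev)
    if (ut$disutility_colonoscopy > 0)
      col_disutil <- as.numeric((alive %*% exp(-dq * toff))) *
        ut$disutility_colonoscopy
  }

  # cancer treatment costs
  stage_cost <- c(costs$crc_stage_A, costs$crc_stage_B,
                  costs$crc_stage_C, costs$crc_stage_D)
  cost_crc <- numeric(n)
  w <- is.finite(so$crc1)
  cost_crc[w] <- stage_cost[so$stage1[w]] * dfc(so$crc1[w] - start)
  w2 <- is.finite(so$crc2)
  cost_crc[w2] <- cost_crc[w2] + stage_cost[so$stage2[w2]] * dfc(so$crc2[w2] - start)
  pall <- (is.finite(so$crc_death1) & so$stage1 == 4L & so$crc_death1 >= so$death) |
          (is.finite(so$crc_death2) & !is.na(so$stage2) & so$stage2 == 4L &
             so$crc_death2 >= so$death)
  cost_crc[pall] <- cost_crc[pall] + costs$crc_palliative * dfc(tdeath[pall])

  cost_ec_prev <- ifelse(is.finite(so$hbso), costs$hbso * dfc(so$hbso - start), 0)
  cost_ec <- ifelse(is.finite(so$ec), costs$ec_treatment * dfc(so$ec - start), 0)

  # QALYs: age/sex norm utility integrated with continuous discounting,
  # minus disutility windows
  q <- disc_int_quadratic(0, tdeath, start, ctx$norm_coefs, dq)
  tD <- pmin(ifelse(is.finite(so$crc1) & so$stage1 == 4L, so$crc1, Inf),
             ifelse(is.finite(so$crc2) & !is.na(so$stage2) & so$stage2 == 4L,
                    so$crc2, Inf))
  wD <- is.finite(tD)
  if (any(wD))
    q[wD] <- q[wD] - ut$disutility_metastatic_crc *
      i0q(tD[wD] - start, tdeath[wD])
  if (ut$disutility_ec > 0) {
    wE <- is.finite(so$ec)
    q[wE] <- q[wE] - ut$disutility_ec * i0q(so$ec[wE] - start, tdeath[wE])
  }
  if (ut$disutility_hbso > 0) {
    wH <- is.finite(so$hbso)
    q[wH] <- q[wH] - ut$disutility_hbso * i0q(so$hbso[wH] - start, tdeath[wH])
  }
  q <- q - col_disutil

  q_short <- rep(if (isTRUE(ctx$profile$took_genetic_test))
    -ut$disutility_genetic_testing * ut$genetic_testing_disutility_years else 0, n)

  data.frame(
    cost_crc_prevention = cost_prev,
    cost_crc_treatment = cost_crc,
    cost_ec_prevention = cost_ec_prev,
    cost_ec_treatment = cost_ec,
    qalys_long = q,
    qalys_short = q_short,
    ly_undisc = tdeath,
    ly_disc = disc_int_powers(0, tdeath, dq)$i0,
    n_colonoscopies = n_col,
    n_complications = n_comp,
    n_crcs = as.numeric(is.finite(so$crc1)) + as.numeric(is.finite(so$crc2)),
    n_ecs = as.numeric(is.finite(so$ec))
  )
}

#' Simulate one individual's life history
#'
#' Draws one lifetime of timed events (colonoscopies, cancers, surgery,
#' death) for a profile using continuous-time inversion sampling from the
#' model's piecewise-constant hazards.  Under surveillance the applicable
#' colorectal cancer hazard is multiplied by the index or metachronous
#' hazard ratio; scheduled colonoscopies carry complication and procedural
#' death risks; H-BSO at the configured offer age removes subsequent
#' endometrial cancer risk.  At most two colorectal cancers can occur over
#' a lifetime (probands enter having had the first).
#'
#' @param profile an [ls_profile()].
#' @param params a validated [ls_parameters] object.
#' @param rng_stream either an integer seed or a numeric vector of
#'   `r U_BLOCK` uniforms (the fixed per-replicate block used for common
#'   random numbers).
#' @return a `ls_life_history`: data.frame of events with columns `age`,
#'   `kind`, `stage` and attributes `profile`, `death_age`.
#' @export
simulate_individual <- function(profile, params, rng_stream = 1L) {
  u <- if (length(rng_stream) == 1) {
    old <- get0(".Random.seed", envir = .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
    set.seed(as.integer(rng_stream))
    stats::runif(U_BLOCK)
  } else {
    stopifnot(length(rng_stream) == U_BLOCK)
    as.numeric(rng_stream)
  }
  ctx <- build_context(profile, params)
  so <- sim_engine(ctx, matrix(u, nrow = 1), params)

  ev <- data.frame(age = numeric(0), kind = character(0), stage = integer(0))
  add <- function(age, kind, stage = NA_integer_)
    ev <<- rbind(ev, data.frame(age = age, kind = kind, stage = stage))
  d <- so$death
  for (k in seq_along(ctx$sched)) {
    a <- ctx$sched[k]
    if (a >= d) break
    add(a, "colonoscopy")
    if (so$comp_mask[1, k]) add(a, "colonoscopy_complication")
  }
  if (is.finite(so$hbso)) add(so$hbso, "hbso")
  if (is.finite(so$crc1)) add(so$crc1, "crc_incidence", so$stage1)
  if (is.finite(so$crc2)) add(so$crc2, "crc_incidence", so$stage2)
  if (is.finite(so$ec)) add(so$ec, "ec_incidence")
  add(d, so$death_cause)
  ev <- ev[order(ev$age), ]
  rownames(ev) <- NULL
  structure(ev, class = c("ls_life_history", "data.frame"),
            profile = profile, death_age = d,
            detected = c(so$det1[1], so$det2[1]))
}

#' Accrue discounted costs and QALYs from a life history
#'
#' Independent event-list accrual (the vectorised cohort engine computes
#' the same quantities in closed form; the two paths cross-validate each
#' other).  QALYs integrate the age/sex population-norm utility minus
#' active disutilities (metastatic colorectal cancer from Dukes' D
#' diagnosis until death; genetic testing for four months, booked to
#' short-term QALYs), discounted continuously by piecewise integration.
#' Costs are booked at event times with [discount_factor()]; colonoscopy
#' costs carry the colonoscopy cost multiplier.  Categories: colonoscopies
#' and complications to CRC prevention, cancer stage costs to CRC
#' treatment, H-BSO to EC prevention, endometrial cancer to EC treatment.
#'
#' @param history a `ls_life_history` from [simulate_individual()].
#' @param profile the matching [ls_profile()].
#' @param params a validated [ls_parameters] object.
#' @return list of discounted cost categories, life years and QALYs.
#' @export
accrue <- function(history, profile, params) {
  if (!identical(attr(history, "profile")$role, profile$role) ||
      !identical(attr(history, "profile")$sex, profile$sex))
    stopf("history/profile mismatch")
  start <- profile$start_age
  d <- attr(history, "death_age")
  td <- d - start
  rc <- params$econ$discount_rate_costs
  dq <- log(1 + params$econ$discount_rate_qalys)
  costs <- params$costs
  ut <- params$utilities
  cat <- c(crc_prevention = 0, crc_treatment = 0,
           ec_prevention = 0, ec_treatment = 0)
  stage_cost <- c(costs$crc_stage_A, costs$crc_stage_B,
                  costs$crc_stage_C, costs$crc_stage_D)
  tD <- Inf
  n_crc <- 0
  for (i in seq_len(nrow(history))) {
    a <- history$age[i]; t <- a - start
    k <- history$kind[i]
    df <- discount_factor(t, rc)
    if (k == "colonoscopy") {
      cat["crc_prevention"] <- cat["crc_prevention"] +
        costs$colonoscopy * params$econ$colonoscopy_cost_multiplier * df
    } else if (k == "colonoscopy_complication") {
      cat["crc_prevention"] <- cat["crc_prevention"] +
        costs$colonoscopy_complication * df
    } else if (k == "crc_incidence") {
      n_crc <- n_crc + 1
      st <- history$stage[i]
      cat["crc_treatment"] <- cat["crc_treatment"] + stage_cost[st] * df
      if (st == 4L) tD <- min(tD, a)
    } else if (k == "ec_incidence") {
      cat["ec_treatment"] <- cat["ec_treatment"] + costs$ec_treatment * df
    } else if (k == "hbso") {
      cat["ec_prevention"] <- cat["ec_prevention"] + costs$hbso * df
    } else if (k == "crc_death" && is.finite(tD)) {
      cat["crc_treatment"] <- cat["crc_treatment"] + costs$crc_palliative * df
    }
  }
  qalys <- disc_int_quadratic(0, td, start,
                              params$utilities$population_norms[[profile$sex]], dq)
  sub_window <- function(from_age, dis) {
    if (dis <= 0 || !is.finite(from_age) || from_age >= d) return(0)
    dis * disc_int_powers(from_age - start, td, dq)$i0
  }
  qalys <- qalys - sub_window(tD, ut$disutility_metastatic_crc)
  ev_ec <- history$age[history$kind == "ec_incidence"]
  if (length(ev_ec)) qalys <- qalys - sub_window(ev_ec[1], ut$disutility_ec)
  ev_h <- history$age[history$kind == "hbso"]
  if (length(ev_h)) qalys <- qalys - sub_window(ev_h[1], ut$disutility_hbso)
  q_short <- if (isTRUE(profile$took_genetic_test))
    -ut$disutility_genetic_testing * ut$genetic_testing_disutility_years else 0

  list(cost = as.list(cat),
       life_years_undiscounted = td,
       life_years_discounted = disc_int_powers(0, td, dq)$i0,
       qalys_long = qalys,
       qalys_short = q_short,
       qalys_total = qalys + q_short,
       n_crcs = n_crc)
}

#' Simulate a weighted cohort of profiles
#'
#' Runs the vectorised engine for every profile with common random numbers:
#' replicate `i` of every profile (and of every policy or sensitivity arm
#' sharing the seed) consumes the same fixed block of uniforms, so
#' between-arm increments are paired.  Reproducible bit-for-bit given the
#' seed.
#'
#' @param profiles list of [ls_profile()] objects.
#' @param params a validated [ls_parameters] object.
#' @param n_replicates replicates per profile (>= 1).
#' @param seed integer seed.
#' @param weights optional nonnegative weights (expected counts) per
#'   profile, recorded in the output.
#' @return data.frame with one row per profile: mean discounted cost
#'   categories, QALYs, life years, event counts and Monte-Carlo standard
#'   errors of total cost and QALYs.
#' @export
simulate_cohort <- function(profiles, params, n_replicates, seed,
                            weights = NULL) {
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  weights <- weights %||% rep(1, length(profiles))
  stopifnot(length(weights) == length(profiles), all(weights >= 0))
  U <- rng_block(seed, n_replicates)
  out <- lapply(seq_along(profiles), function(i) {
    ctx <- build_context(profiles[[i]], params)
    so <- sim_engine(ctx, U, params)
    acc <- accrue_engine(ctx, so, params)
    m <- colMeans(acc)
    tot_cost <- rowSums(acc[, c("cost_crc_prevention", "cost_crc_treatment",
                                "cost_ec_prevention", "cost_ec_treatment")])
    tot_q <- acc$qalys_long + acc$qalys_short
    data.frame(profile_id = i, weight = weights[i], t(m),
               se_cost = stats::sd(tot_cost) / sqrt(n_replicates),
               se_qalys = stats::sd(tot_q) / sqrt(n_replicates))
  })
  res <- do.call(rbind, out)
  attr(res, "profiles") <- profiles
  attr(res, "seed") <- seed
  attr(res, "n_replicates") <- n_replicates
  res
}

# Fixed uniform block matrix shared across profiles and arms.
rng_block <- function(seed, n_replicates) {
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(as.integer(seed))
  matrix(stats::runif(n_replicates * U_BLOCK), nrow = n_replicates)
}
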