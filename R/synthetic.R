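# Synthetic cohort generation.
#
# A cohort design fixes who the mice are (experiment, injury paradigm,
# schedule, age, treatment) and which outcome codes each mouse is measured on;
# an effect specification fixes the generative model for measurement values.
# Values follow
#   value = baseline + dir * effect * sd * 1[TBI] * (1 - attenuation * 1[treated])
#           + anesthesia_slope * n_hits + experiment_effect + noise,
# where dir = +1 if higher raw values are "bad" for the parameter family (so a
# positive planted effect always shifts the TBI group toward the bad side),
# noise is Gaussian with the family's SD, and values are truncated at zero
# (latencies, durations and counts have a floor). Loss-of-consciousness times
# increase monotonically with drop height on top of an anesthesia-only
# baseline, so sham mice (height 0) still receive near-baseline draws.

#' Effect specification for synthetic cohorts
#'
#' One row per level-3 parameter family (optionally per week): baseline mean
#' and SD in measurement units, the standardized injury effect size, the
#' anesthesia slope (units per procedure), the between-experiment SD (units),
#' and the treatment attenuation fraction. A row with `week = NA` applies to
#' all weeks of the family; a `(level3, week)` row takes precedence.
#'
#' @param level3,week,baseline,sd,effect,anesthesia_slope,experiment_sd,attenuation
#'   Vectors of equal length (week may be `NA`).
#' @return An `effect_spec` tibble.
#' @export
effect_spec <- function(level3, week = NA_integer_, baseline, sd, effect = 0,
                        anesthesia_slope = 0, experiment_sd = 0, attenuation = 0) {
  out <- tibble::tibble(
    level3 = level3, week = as.integer(week), baseline = baseline, sd = sd,
    effect = effect, anesthesia_slope = anesthesia_slope,
    experiment_sd = experiment_sd, attenuation = attenuation
  )
  stopifnot(all(out$sd > 0), all(out$attenuation >= 0 & out$attenuation <= 1))
  class(out) <- c("effect_spec", class(out))
  out
}

# Family baselines in plausible measurement units (seconds, counts, meters,
# percent). Effects default to zero.
.family_baselines <- function() {
  tibble::tribble(
    ~level3,   ~baseline, ~sd,
    "LOC",      20,  12,
    "MWM:H",    40,  12,
    "MWM:V",    30,  10,
    "MWM:P",    25,   8,
    "MWM:PF",    5, 1.5,
    "NR:O",     60,  15,
    "NR:L",     60,  15,
    "YM",       65,  10,
    "EPM",      60,  25,
    "OF:S:P",   40,  15,
    "OF:S:D",   20,   5,
    "OF:C:P",   50,  15,
    "FST",     100,  30,
    "LDB",      50,  15,
    "TST",     120,  35,
    "SPT",      75,  10,
    "Rota",    180,  50
  )
}

#' Null effect specification
#'
#' Baseline means and SDs for every parameter family, zero injury effect, no
#' anesthesia slope, no experiment heterogeneity.
#'
#' @return An `effect_spec` tibble.
#' @export
null_effects <- function() {
  b <- .family_baselines()
  effect_spec(level3 = b$level3, baseline = b$baseline, sd = b$sd)
}

# Concave week profile peaking at `peak`, zero at the half-width and beyond.
.week_profile <- function(week, peak, half_width = 18) {
  pmax(0, 1 - ((week - peak) / half_width)^2)
}

#' Effect specification emulating the study's qualitative structure
#'
#' Plants injury effects on every behavioral family with a concave week
#' profile peaking at week 13 (detectability greatest 3-4 months after first
#' injury), with the Morris water maze hidden/probe-frequency families
#' strongest (1.5 SD at peak), anxiety/depression families intermediate, and
#' the rotarod weakest; plus a mild anesthesia dose effect and
#' between-experiment variation. These are configuration choices for the
#' generator, not estimates from real data.
#'
#' @param mwm_amplitude Peak standardized effect for MWM hidden trials
#'   (default 1.5).
#' @param peak_week Week of maximal detectability (default 13).
#' @return An `effect_spec` tibble with one row per (family, nominal week).
#' @export
fixture_effects <- function(mwm_amplitude = 1.5, peak_week = 13) {
  amp <- c("MWM:H" = mwm_amplitude, "MWM:PF" = mwm_amplitude - 0.1,
           "MWM:P" = 1.0, "MWM:V" = 0.6,
           "NR:O" = 0.5, "NR:L" = 0.5, "YM" = 0.5,
           "EPM" = 0.9, "OF:S:P" = 0.9, "OF:S:D" = 0.7, "OF:C:P" = 0.9,
           "FST" = 1.2, "LDB" = 0.4, "TST" = 0.4, "SPT" = 0.4,
           "Rota" = 0.15, "LOC" = 0)
  b <- .family_baselines()
  grid <- tidyr::expand_grid(level3 = b$level3, week = nominal_weeks())
  grid <- dplyr::left_join(grid, b, by = "level3")
  effect_spec(
    level3 = grid$level3, week = grid$week,
    baseline = grid$baseline, sd = grid$sd,
    effect = unname(amp[grid$level3]) * .week_profile(grid$week, peak_week),
    anesthesia_slope = ifelse(grid$level3 == "LOC", 0, 0.06 * grid$sd),
    experiment_sd = ifelse(grid$level3 == "LOC", 0, 0.25 * grid$sd),
    attenuation = 0.3
  )
}

#' Build a cohort design from experiment blocks
#'
#' Each block describes one homogeneous experiment arm: group sizes, injury
#' paradigm, schedule, age, treatment, and the battery of outcome codes every
#' mouse in the block is measured on.
#'
#' @param blocks A data frame with columns `experiment_id`, `n_tbi`, `n_sham`,
#'   `drop_height_in`, `n_hits`, `schedule`, `age_weeks`, `treatment`,
#'   `treatment_route`, and a list-column `battery` of code strings.
#' @param registry Registry tibble; battery codes must resolve.
#' @return A `cohort_design`: list with tibbles `mice` (one row per mouse) and
#'   `assignments` (one row per planned measurement).
#' @export
design_from_blocks <- function(blocks, registry = default_registry()) {
  blocks <- tibble::as_tibble(blocks)
  all_codes <- unique(unlist(blocks$battery))
  resolve_codes(all_codes, registry)  # errors on unknown codes
  mice_rows <- list()
  assign_rows <- list()
  counter <- 0L
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    n <- b$n_tbi + b$n_sham
    if (n == 0L) next
    ids <- sprintf("m%04d", counter + seq_len(n))
    counter <- counter + n
    grp <- c(rep("TBI", b$n_tbi), rep("sham", b$n_sham))
    mice_rows[[length(mice_rows) + 1L]] <- tibble::tibble(
      mouse_id = ids, experiment_id = b$experiment_id, group = grp,
      drop_height_in = ifelse(grp == "TBI", b$drop_height_in, 0),
      n_hits = b$n_hits, schedule = b$schedule, age_weeks = b$age_weeks,
      treatment = b$treatment, treatment_route = b$treatment_route
    )
    battery <- b$battery[[1]]
    assign_rows[[length(assign_rows) + 1L]] <- tibble::tibble(
      mouse_id = rep(ids, each = length(battery)),
      outcome_code = rep(battery, times = n)
    )
  }
  structure(
    list(mice = dplyr::bind_rows(mice_rows),
         assignments = dplyr::bind_rows(assign_rows)),
    class = "cohort_design"
  )
}

# Stable 32-bit sub-seed derived from a base seed and a string tag.
.derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * (seq_along(utf8ToInt(tag)) %% 31 + 1))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

#' Generate a synthetic cohort from a design and effect specification
#'
#' Draws measurement values for every planned (mouse, code) assignment under
#' the generative model described above, and records every planted effect in a
#' truth table. Redundant parameters are generated as the session complement
#' of their siblings (e.g. closed-arm time = session length minus open-arm
#' time), so they genuinely carry no degree of freedom. The same
#' (design, effects, seed) always yields identical output.
#'
#' @param design A `cohort_design`.
#' @param effects An `effect_spec`.
#' @param seed Integer seed.
#' @param registry Registry tibble.
#' @return A list with `cohort` (a [tbi_cohort()]) and `truth` (a tibble of
#'   the planted per-code effects).
#' @export
generate_cohort <- function(design, effects, seed, registry = default_registry()) {
  stopifnot(inherits(design, "cohort_design"))
  mice <- design$mice
  asg <- design$assignments
  parsed <- resolve_codes(unique(asg$outcome_code), registry)
  spec <- .resolve_effects(parsed, effects)

  asg <- dplyr::left_join(asg, spec, by = "outcome_code")
  asg <- dplyr::left_join(
    asg, mice[, c("mouse_id", "experiment_id", "group", "drop_height_in",
                  "n_hits", "treatment")], by = "mouse_id")
  asg <- dplyr::arrange(asg, .data$mouse_id, .data$outcome_code)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(.derive_seed(seed, "generate_cohort"), kind = "Mersenne-Twister")

  # experiment random effects, one draw per (experiment, family), fixed order
  exp_keys <- sort(unique(paste(asg$experiment_id, asg$level3, sep = "\r")))
  exp_eff <- stats::rnorm(length(exp_keys))
  names(exp_eff) <- exp_keys
  z_exp <- exp_eff[paste(asg$experiment_id, asg$level3, sep = "\r")]

  tbi <- as.numeric(asg$group == "TBI")
  treated <- as.numeric(asg$treatment != "none")
  dir_sign <- ifelse(asg$good_direction == "lower_better", 1, -1)
  is_loc <- asg$test == "LOC"

  mu <- asg$baseline +
    dir_sign * asg$effect * asg$sd * tbi * (1 - asg$attenuation * treated) +
    asg$anesthesia_slope * asg$n_hits +
    asg$experiment_sd * z_exp
  # LOC: monotone in drop height; sham mice sit at the anesthesia-only baseline
  mu[is_loc] <- asg$baseline[is_loc] + 0.9 * asg$drop_height_in[is_loc] +
    asg$experiment_sd[is_loc] * z_exp[is_loc]
  value <- pmax(0, mu + stats::rnorm(nrow(asg), 0, asg$sd))

  meas <- tibble::tibble(mouse_id = asg$mouse_id, outcome_code = asg$outcome_code,
                         value = value)
  meas <- .apply_redundancy(meas, registry)

  truth <- spec |>
    dplyr::mutate(signed_shift = ifelse(.data$good_direction == "lower_better", 1, -1) *
                    .data$effect * .data$sd) |>
    dplyr::select("outcome_code", "level3", "week", "good_direction", "baseline",
                  "sd", "effect", "signed_shift", "anesthesia_slope",
                  "experiment_sd", "attenuation")

  list(cohort = tbi_cohort(mice, meas, registry), truth = truth)
}

# Join parsed codes to the effect spec: (level3, week) rows first, then
# (level3, any-week) rows; families without a row get their default baseline.
.resolve_effects <- function(parsed, effects) {
  effects <- tibble::as_tibble(effects)
  base <- .family_baselines()
  spec <- parsed[, c("code", "test", "week", "level3", "good_direction")]
  names(spec)[names(spec) == "code"] <- "outcome_code"
  exact <- effects[!is.na(effects$week), ]
  anyw <- effects[is.na(effects$week), ]
  spec <- dplyr::left_join(spec, exact,
                           by = c("level3", "week"), suffix = c("", ".e"))
  if (nrow(anyw) > 0L) {
    fill <- dplyr::left_join(spec[is.na(spec$baseline), c("outcome_code", "level3")],
                             anyw[, setdiff(names(anyw), "week")], by = "level3")
    spec[is.na(spec$baseline), c("baseline", "sd", "effect", "anesthesia_slope",
                                 "experiment_sd", "attenuation")] <-
      fill[, c("baseline", "sd", "effect", "anesthesia_slope",
               "experiment_sd", "attenuation")]
  }
  miss <- is.na(spec$baseline)
  if (any(miss)) {
    deflt <- dplyr::left_join(spec[miss, c("outcome_code", "level3")], base, by = "level3")
    if (anyNA(deflt$baseline)) {
      stop("no effect specification or default baseline for families: ",
           paste(unique(deflt$level3[is.na(deflt$baseline)]), collapse = ", "),
           call. = FALSE)
    }
    spec$baseline[miss] <- deflt$baseline
    spec$sd[miss] <- deflt$sd
    spec$effect[miss] <- 0
    spec$anesthesia_slope[miss] <- 0
    spec$experiment_sd[miss] <- 0
    spec$attenuation[miss] <- 0
  }
  spec
}

# Redundant parameters are session complements of their siblings.
.apply_redundancy <- function(meas, registry) {
  u <- unique(meas$outcome_code)
  parsed_u <- parse_code(u)
  j <- match(meas$outcome_code, u)
  stub <- paste0(parsed_u$test, ifelse(is.na(parsed_u$subtype), "",
                                       paste0(":", parsed_u$subtype)))[j]
  wk <- parsed_u$week[j]
  key <- function(s) paste(meas$mouse_id, wk, sep = "\r")[stub == s]
  val <- function(s) stats::setNames(meas$value[stub == s], key(s))
  session <- 300
  for (pair in list(c("EPM:C", "EPM:O"), c("OF:S:W", "OF:S:C"))) {
    tgt <- stub == pair[[1]]
    if (!any(tgt)) next
    sib <- val(pair[[2]])[paste(meas$mouse_id, wk, sep = "\r")[tgt]]
    meas$value[tgt] <- pmax(0, session - ifelse(is.na(sib), meas$value[tgt], sib))
  }
  tgt <- stub == "OF:C:W"
  if (any(tgt)) {
    k <- paste(meas$mouse_id, wk, sep = "\r")[tgt]
    sib <- val("OF:C:C")[k]
    sib2 <- val("OF:C:N")[k]
    tot <- ifelse(is.na(sib), 0, sib) + ifelse(is.na(sib2), 0, sib2)
    meas$value[tgt] <- pmax(0, session - tot)
  }
  meas
}

#' The 15 core outcome codes of the design fixture
#'
#' The fifteen highest-availability non-redundant behavioral outcomes of the
#' measurement design (all at week 2), on which the fixture's complete-case
#' core is built.
#'
#' @return Character vector of 15 codes.
#' @export
fixture_core_codes <- function() {
  c("MWM:H1:W2", "MWM:H2:W2", "MWM:H3:W2", "MWM:H4:W2",
    "MWM:V1:W2", "MWM:V2:W2", "MWM:P1:W2", "MWM:P2:W2",
    "MWM:PF1:W2", "MWM:PF2:W2", "EPM:O:W2",
    "OF:C:C:W2", "OF:C:N:W2", "Rota:D2:W2", "Rota:D3:W2")
}

# Codes measured in the same session share one mouse allocation.
.linked_stub_groups <- function() {
  list(c("EPM:O", "EPM:C"),
       c("OF:S:C", "OF:S:W", "OF:S:D"),
       c("OF:C:C", "OF:C:N", "OF:C:W"),
       c("Rota:D2", "Rota:D3"))
}

#' Deterministic cohort design reproducing the reference design margins
#'
#' Builds a fixed design of 1203 mice in 58 experiments whose generated cohort
#' reproduces, exactly: the group split (675 TBI / 528 sham); the drop-height,
#' procedure-schedule, age and treatment margins of the mouse characteristics
#' table; every per-(parameter, week) measurement count of the measurement
#' design; and a complete-case core of 301 mice (180 TBI, 121 sham) measured
#' on the 15 [fixture_core_codes()]. Joint missingness beyond those margins is
#' one deterministic allocation (the true experiment-level allocation is not
#' published): core mice receive exactly the core battery (plus redundant
#' siblings and loss-of-consciousness times), and remaining cell counts are
#' ring-allocated over the other 902 mice. The margins are re-checked at build
#' time; a violation is an error.
#'
#' @param registry Registry tibble.
#' @return A `cohort_design`.
#' @export
fixture_design <- function(registry = default_registry()) {
  mice <- .fixture_mice()
  asg <- .fixture_assignments(mice, registry)
  design <- structure(list(mice = mice, assignments = asg), class = "cohort_design")
  .validate_fixture(design, registry)
  design
}

# Mouse-level attribute table satisfying the characteristics-table margins.
.fixture_mice <- function() {
  sched <- tibble::tribble(
    ~schedule,          ~n_hits, ~n_tbi, ~n_sham, ~n_exp,
    "1x",                1L,      116L,   76L,     9L,
    "2_in_1_day",        2L,      28L,    6L,      2L,
    "4_in_4_days",       4L,      56L,    24L,     4L,
    "5_in_5_days",       5L,      301L,   266L,    27L,
    "5_in_5_weeks",      5L,      24L,    24L,     2L,
    "5_in_10_weeks",     5L,      24L,    24L,     2L,
    "5_in_5_months",     5L,      24L,    24L,     2L,
    "7_in_9_days",       7L,      102L,   76L,     9L,
    "6to13_in_5_days",   NA,      0L,     8L,      1L
  )
  rows <- list()
  exp_counter <- 0L
  for (i in seq_len(nrow(sched))) {
    s <- sched[i, ]
    n <- s$n_tbi + s$n_sham
    # interleave TBI and sham by within-group quantile so every experiment
    # chunk carries both groups at roughly the schedule's ratio
    grp <- c(rep("TBI", s$n_tbi), rep("sham", s$n_sham))
    q <- c(if (s$n_tbi > 0) (seq_len(s$n_tbi) - 0.5) / s$n_tbi,
           if (s$n_sham > 0) (seq_len(s$n_sham) - 0.25) / s$n_sham)
    grp <- grp[order(q)]
    hits <- if (is.na(s$n_hits)) 6:13 else rep(s$n_hits, n)
    chunk <- rep(seq_len(s$n_exp), each = ceiling(n / s$n_exp))[seq_len(n)]
    rows[[i]] <- tibble::tibble(
      schedule = s$schedule, group = grp, n_hits = hits,
      experiment_id = sprintf("E%02d", exp_counter + chunk)
    )
    exp_counter <- exp_counter + s$n_exp
  }
  mice <- dplyr::bind_rows(rows)
  mice$mouse_id <- sprintf("m%04d", seq_len(nrow(mice)))
  # heights (TBI only), ages and treatments: margin-exact assignment in the
  # fixed schedule/interleave order
  is_tbi <- mice$group == "TBI"
  mice$drop_height_in <- 0
  mice$drop_height_in[is_tbi] <-
    rep(c(28, 42, 46, 50, 60), times = c(218, 319, 35, 63, 40))
  mice$age_weeks <- NA_integer_
  mice$age_weeks[is_tbi] <- rep(c(5L, 8L, 12L, 28L), times = c(54, 563, 35, 23))
  mice$age_weeks[!is_tbi] <- rep(c(5L, 8L, 12L, 28L), times = c(47, 445, 12, 24))
  trt <- tibble::tribble(
    ~treatment,       ~treatment_route,  ~n_tbi, ~n_sham,
    "flicker",        "external",         30L, 30L,
    "tau_het_ko",     "genetic",          14L, 14L,
    "tau_hom_ko",     "genetic",          12L, 12L,
    "enrichment",     "housing",          88L, 61L,
    "single_housing", "housing",          12L, 0L,
    "cis_p_tau",      "intraperitoneal",  38L, 9L,
    "crp",            "intraperitoneal",  6L,  0L,
    "memantine",      "intraperitoneal",  46L, 19L,
    "igg",            "intraperitoneal",  33L, 10L,
    "saline",         "intraperitoneal",  58L, 17L,
    "anti_cd3",       "intranasal",       17L, 6L,
    "igg",            "intranasal",       18L, 6L,
    "memantine",      "oral",             25L, 24L,
    "saline",         "oral",             23L, 25L,
    "none",           "none",             255L, 295L
  )
  mice$treatment <- NA_character_
  mice$treatment_route <- NA_character_
  mice$treatment[is_tbi] <- rep(trt$treatment, times = trt$n_tbi)
  mice$treatment_route[is_tbi] <- rep(trt$treatment_route, times = trt$n_tbi)
  mice$treatment[!is_tbi] <- rep(trt$treatment, times = trt$n_sham)
  mice$treatment_route[!is_tbi] <- rep(trt$treatment_route, times = trt$n_sham)
  mice[, c("mouse_id", "experiment_id", "group", "drop_height_in", "n_hits",
           "schedule", "age_weeks", "treatment", "treatment_route")]
}

# Measurement assignments reproducing every nonzero design cell.
.fixture_assignments <- function(mice, registry) {
  core <- fixture_core_codes()
  # complete-case core: 180 TBI + 121 sham from the 5-days-schedule mice
  d <- mice[mice$schedule == "5_in_5_days", ]
  core_ids <- c(d$mouse_id[d$group == "TBI"][1:180],
                d$mouse_id[d$group == "sham"][1:121])
  other_ids <- setdiff(mice$mouse_id, core_ids)
  n_other <- length(other_ids)

  reg <- registry
  stub <- paste0(reg$test, ifelse(is.na(reg$subtype), "",
                                  paste0(":", reg$subtype)),
                 ifelse(is.na(reg$index), "", reg$index))
  linked <- .linked_stub_groups()
  link_of <- stats::setNames(rep(seq_along(linked), lengths(linked)), unlist(linked))
  # allocation key: linked session stubs share one arc per week
  alloc_key <- ifelse(stub %in% names(link_of),
                      paste0("link", link_of[stub], ":W", reg$week),
                      reg$code)

  out <- list()
  pos <- 0L
  arc_of <- list()  # alloc_key -> mouse ids, filled once per key
  loc_rows <- reg$test == "LOC"
  for (i in seq_len(nrow(reg))) {
    code <- reg$code[[i]]
    n_cell <- reg$design_n[[i]]
    if (loc_rows[[i]]) {
      k <- reg$index[[i]]
      eligible <- mice$mouse_id[mice$n_hits >= k]
      eligible <- c(intersect(core_ids, eligible), setdiff(eligible, core_ids))
      ids <- eligible[seq_len(n_cell)]
    } else {
      key <- alloc_key[[i]]
      if (is.null(arc_of[[key]])) {
        if (code %in% core) {
          n_extra <- n_cell - length(core_ids)
          stopifnot(n_extra >= 0)
          idx <- (pos + seq_len(n_extra) - 1L) %% n_other + 1L
          pos <- pos + n_extra
          arc_of[[key]] <- c(core_ids, other_ids[idx])
        } else {
          idx <- (pos + seq_len(n_cell) - 1L) %% n_other + 1L
          pos <- pos + n_cell
          arc_of[[key]] <- other_ids[idx]
        }
      }
      ids <- arc_of[[key]]
      stopifnot(length(ids) == n_cell)
    }
    out[[i]] <- tibble::tibble(mouse_id = ids, outcome_code = code)
  }
  dplyr::bind_rows(out)
}

# Build-time margin check for the fixture design.
.validate_fixture <- function(design, registry) {
  mice <- design$mice
  asg <- design$assignments
  stopifnot(
    nrow(mice) == 1203L,
    sum(mice$group == "TBI") == 675L,
    sum(mice$group == "sham") == 528L,
    length(unique(mice$experiment_id)) == 58L
  )
  h <- table(mice$drop_height_in[mice$group == "TBI"])
  stopifnot(identical(as.integer(h[c("28", "42", "46", "50", "60")]),
                      c(218L, 319L, 35L, 63L, 40L)))
  cell <- asg |> dplyr::count(.data$outcome_code)
  chk <- dplyr::left_join(registry, cell, by = c(code = "outcome_code"))
  if (!isTRUE(all(chk$n == chk$design_n))) {
    bad <- chk$code[is.na(chk$n) | chk$n != chk$design_n]
    stop("fixture cell counts deviate from the design for: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(paste(asg$mouse_id, asg$outcome_code))) {
    stop("fixture assigns a (mouse, code) cell twice", call. = FALSE)
  }
  core <- fixture_core_codes()
  on_core <- asg[asg$outcome_code %in% core, ]
  cc <- names(which(table(on_core$mouse_id) == length(core)))
  if (length(cc) != 301L) {
    stop("fixture complete-case core has ", length(cc), " mice, expected 301",
         call. = FALSE)
  }
  grp <- mice$group[match(cc, mice$mouse_id)]
  stopifnot(sum(grp == "TBI") == 180L, sum(grp == "sham") == 121L)
  invisible(design)
}

#' Design with a planted week-dependent injury effect
#'
#' A fully crossed design (every mouse measured on the whole battery) in which
#' one Morris water maze hidden-trial effect follows a concave week profile
#' maximal at `peak_week`, while an anxiety family and a motor family carry no
#' effect. Used for parameter-recovery checks of the selection cascade and the
#' time-trend fit: the cascade should pick a peak-week MWM variable, and the
#' fitted AUC parabola should peak near `peak_week`.
#'
#' @param peak_week Week of maximal effect (must be a nominal week).
#' @param amplitude Peak standardized effect size (default 1.5).
#' @param n_tbi,n_sham Group sizes (default 200 each).
#' @param weeks Testing weeks for the battery (default 2, 13, 28).
#' @param n_experiments Number of experiment blocks (default 8).
#' @return A list with `design` (a `cohort_design`) and `effects` (an
#'   `effect_spec`).
#' @export
planted_week_effect_design <- function(peak_week = 13, amplitude = 1.5,
                                       n_tbi = 200, n_sham = 200,
                                       weeks = c(2L, 13L, 28L),
                                       n_experiments = 8) {
  stopifnot(peak_week %in% nominal_weeks())
  battery <- c(paste0("MWM:H1:W", weeks), paste0("MWM:H2:W", weeks),
               paste0("EPM:O:W", weeks), paste0("Rota:D2:W", weeks))
  per <- ceiling(c(n_tbi, n_sham) / n_experiments)
  blocks <- tibble::tibble(
    experiment_id = sprintf("PX%02d", seq_len(n_experiments)),
    n_tbi = diff(round(seq(0, n_tbi, length.out = n_experiments + 1))),
    n_sham = diff(round(seq(0, n_sham, length.out = n_experiments + 1))),
    drop_height_in = 42, n_hits = 5L, schedule = "5_in_5_days",
    age_weeks = 8L, treatment = "none", treatment_route = "none",
    battery = replicate(n_experiments, battery, simplify = FALSE)
  )
  design <- design_from_blocks(blocks)
  b <- .family_baselines()
  grid <- tidyr::expand_grid(level3 = c("MWM:H", "EPM", "Rota"), week = as.integer(weeks))
  grid <- dplyr::left_join(grid, b, by = "level3")
  effects <- effect_spec(
    level3 = grid$level3, week = grid$week,
    baseline = grid$baseline, sd = grid$sd,
    effect = ifelse(grid$level3 == "MWM:H",
                    amplitude * .week_profile(grid$week, peak_week, 15), 0),
    experiment_sd = 0.15 * grid$sd
  )
  list(design = design, effects = effects)
}
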