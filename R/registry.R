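# Hierarchical registry of behavioral outcome codes.
#
# A measured parameter is identified by a code string "TEST[:SUBTYPE][INDEX]:W<week>"
# (e.g. "MWM:H5:W13" = Morris water maze, hidden trial 5, week 13). The registry
# places every code in a three-level taxonomy: level 1 = behavioral category
# (severity / cognitive / anxiety_depression / motor), level 2 = test, level 3 =
# parameter family (test + subtype, week-free), and annotates directionality
# (whether higher raw values indicate good outcome) and redundancy (parameters
# with no degree of freedom given their siblings, e.g. closed-arm time when
# open-arm time is recorded).

# Per-test grammar: which subtypes are legal and whether a trial/day index is
# required. OF subtypes are two-part (arena:zone).
.test_grammar <- function() {
  tibble::tribble(
    ~test,  ~subtypes,                                      ~index,     ~level1,              ~level2,
    "LOC",  list(character(0)),                             "required", "severity",           "Loss of consciousness",
    "MWM",  list(c("H", "V", "P", "PF")),                   "required", "cognitive",          "Morris water maze",
    "NR",   list(c("O", "L")),                              "none",     "cognitive",          "Novel recognition",
    "YM",   list(character(0)),                             "none",     "cognitive",          "Y-maze",
    "EPM",  list(c("O", "C", "D")),                         "none",     "anxiety_depression", "Elevated plus maze",
    "OF",   list(c("S:C", "S:W", "S:D", "C:C", "C:N", "C:W")), "none",  "anxiety_depression", "Open field",
    "FST",  list("D"),                                      "required", "anxiety_depression", "Forced swim test",
    "LDB",  list(character(0)),                             "none",     "anxiety_depression", "Light-dark box",
    "TST",  list(character(0)),                             "none",     "anxiety_depression", "Tail suspension test",
    "SPT",  list("D"),                                      "required", "anxiety_depression", "Sucrose preference test",
    "Rota", list("D"),                                      "required", "motor",              "Rotarod"
  )
}

#' Nominal testing weeks
#'
#' The weeks (after the first TBI/sham procedure) at which behavioral outcomes
#' are scheduled in the measurement design.
#'
#' @return Integer vector of nominal weeks.
#' @export
nominal_weeks <- function() {
  c(0L, 1L, 2L, 3L, 4L, 6L, 12L, 13L, 16L, 17L, 26L, 28L)
}

#' Parse behavioral outcome codes
#'
#' Parses code strings of the form `TEST[:SUBTYPE][INDEX]:W<week>` into their
#' structured components. The grammar is strict: unknown test tokens, subtypes
#' not declared for the test, a missing index where the test requires one (or
#' vice versa), and malformed week suffixes are all errors naming the offending
#' token.
#'
#' @param x Character vector of code strings, e.g. `"MWM:H5:W13"`, `"LDB:W2"`,
#'   `"OF:S:C:W4"`.
#' @return A tibble with one row per code: `code` (canonical string), `test`,
#'   `subtype` (`NA` if none), `index` (`NA` if none), `week`.
#' @examples
#' parse_code(c("MWM:H5:W13", "OF:S:C:W4", "LDB:W2"))
#' @export
parse_code <- function(x) {
  stopifnot(is.character(x))
  grammar <- .test_grammar()
  rows <- lapply(x, function(code) {
    parts <- strsplit(code, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop("malformed outcome code '", code, "': expected TEST[:SUBTYPE][INDEX]:W<week>",
           call. = FALSE)
    }
    test <- parts[[1]]
    gi <- match(test, grammar$test)
    if (is.na(gi)) {
      stop("unknown test token '", test, "' in code '", code, "'", call. = FALSE)
    }
    wk_tok <- parts[[length(parts)]]
    if (!grepl("^W[0-9]+$", wk_tok)) {
      stop("malformed week token '", wk_tok, "' in code '", code, "'", call. = FALSE)
    }
    week <- as.integer(sub("^W", "", wk_tok))
    mid <- parts[seq_len(length(parts) - 1L)][-1L]
    subtype <- NA_character_
    index <- NA_integer_
    if (length(mid) > 0L) {
      last <- mid[[length(mid)]]
      m <- regmatches(last, regexec("^([A-Za-z]*)([0-9]*)$", last))[[1]]
      if (length(m) == 0L || (m[[2]] == "" && m[[3]] == "")) {
        stop("malformed token '", last, "' in code '", code, "'", call. = FALSE)
      }
      letters_part <- m[[2]]
      digits_part <- m[[3]]
      sub_parts <- c(mid[-length(mid)], if (nzchar(letters_part)) letters_part)
      if (length(sub_parts) > 0L) subtype <- paste(sub_parts, collapse = ":")
      if (nzchar(digits_part)) index <- as.integer(digits_part)
    }
    allowed <- grammar$subtypes[[gi]][[1]]
    if (is.na(subtype)) {
      if (length(allowed) > 0L) {
        stop("code '", code, "': test ", test, " requires a subtype (one of ",
             paste(allowed, collapse = ", "), ")", call. = FALSE)
      }
    } else {
      if (!subtype %in% allowed) {
        stop("code '", code, "': subtype '", subtype, "' not allowed for test ",
             test, call. = FALSE)
      }
    }
    if (grammar$index[[gi]] == "required" && is.na(index)) {
      stop("code '", code, "': test ", test, " requires a trial/day/hit index",
           call. = FALSE)
    }
    if (grammar$index[[gi]] == "none" && !is.na(index)) {
      stop("code '", code, "': test ", test, " does not take an index", call. = FALSE)
    }
    if (!is.na(index) && index < 1L) {
      stop("code '", code, "': index must be a positive integer", call. = FALSE)
    }
    tibble::tibble(test = test, subtype = subtype, index = index, week = week)
  })
  out <- dplyr::bind_rows(rows)
  out$code <- format_code(out)
  out[, c("code", "test", "subtype", "index", "week")]
}

#' Format parsed codes back to canonical strings
#'
#' @param parsed A data frame with columns `test`, `subtype`, `index`, `week`
#'   (as produced by [parse_code()]).
#' @return Character vector of canonical code strings; `format_code(parse_code(x))`
#'   reproduces `x` for every valid code.
#' @export
format_code <- function(parsed) {
  mid <- ifelse(is.na(parsed$subtype),
                ifelse(is.na(parsed$index), "", paste0(":", parsed$index)),
                paste0(":", parsed$subtype,
                       ifelse(is.na(parsed$index), "", parsed$index)))
  paste0(parsed$test, mid, ":W", parsed$week)
}

# Level-3 parameter family of a parsed code (test + subtype, week-free).
# EPM parameters form a single family; OF families follow the arena/zone
# taxonomy (square position, square distance, circle position).
.level3_family <- function(test, subtype) {
  dplyr::case_when(
    test == "EPM" ~ "EPM",
    test %in% c("FST", "SPT", "Rota") ~ test,  # day index within one family
    test == "OF" & subtype %in% c("S:C", "S:W") ~ "OF:S:P",
    test == "OF" & subtype == "S:D" ~ "OF:S:D",
    test == "OF" & subtype %in% c("C:C", "C:N", "C:W") ~ "OF:C:P",
    is.na(subtype) ~ test,
    TRUE ~ paste0(test, ":", subtype)
  )
}

# Good-outcome direction of the raw value for each (test, subtype).
.good_direction <- function(test, subtype) {
  dplyr::case_when(
    test == "LOC" ~ "lower_better",        # longer unconsciousness = more severe
    test == "MWM" & subtype %in% c("H", "V") ~ "lower_better",  # latency to platform
    test == "MWM" & subtype %in% c("P", "PF") ~ "higher_better", # time at / crossings of platform site
    test == "NR" ~ "higher_better",        # time at novel object/location
    test == "YM" ~ "higher_better",        # alternation
    test == "EPM" & subtype == "O" ~ "higher_better",
    test == "EPM" & subtype == "C" ~ "lower_better",
    test == "EPM" & subtype == "D" ~ "higher_better",
    test == "OF" & subtype %in% c("S:C", "C:C", "C:N") ~ "higher_better",
    test == "OF" & subtype %in% c("S:W", "C:W") ~ "lower_better",
    test == "OF" & subtype == "S:D" ~ "higher_better",
    test == "FST" ~ "lower_better",        # immobility
    test == "LDB" ~ "higher_better",       # locomotor activity
    test == "TST" ~ "lower_better",        # immobility
    test == "SPT" ~ "higher_better",       # sucrose preference
    test == "Rota" ~ "higher_better",      # latency to fall
    TRUE ~ NA_character_
  )
}

# Measurement design: number of mice measured for each level-3 parameter at
# each nominal week. Weeks in column order 0,1,2,3,4,6,12,13,16,17,26,28.
.design_counts <- function() {
  w <- nominal_weeks()
  row <- function(code_stub, counts) {
    stopifnot(length(counts) == length(w))
    keep <- counts > 0
    tibble::tibble(stub = code_stub, week = w[keep], design_n = as.integer(counts[keep]))
  }
  dplyr::bind_rows(
    row("LOC:1",   c(1146, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
    row("LOC:2",   c(976,  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
    row("LOC:3",   c(957,  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
    row("LOC:4",   c(957,  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
    row("LOC:5",   c(873,  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
    row("LOC:6",   c(178,  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
    row("LOC:7",   c(178,  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
    row("MWM:H1",  c(0, 0, 622, 108, 25, 24, 47, 100, 0, 70, 24, 305)),
    row("MWM:H2",  c(0, 0, 622, 108, 25, 24, 47, 100, 0, 70, 24, 305)),
    row("MWM:H3",  c(0, 0, 622, 108, 25, 24, 47, 100, 0, 70, 24, 305)),
    row("MWM:H4",  c(0, 0, 622, 83,  25, 24, 47, 100, 0, 70, 24, 305)),
    row("MWM:H5",  c(0, 0, 233, 83,  0,  0,  47, 77,  0, 0,  24, 0)),
    row("MWM:V1",  c(0, 0, 586, 108, 25, 0,  47, 100, 0, 70, 24, 305)),
    row("MWM:V2",  c(0, 0, 548, 83,  25, 0,  47, 76,  0, 70, 0,  305)),
    row("MWM:P1",  c(0, 0, 598, 108, 25, 24, 47, 76,  0, 70, 0,  305)),
    row("MWM:P2",  c(0, 0, 598, 83,  25, 0,  47, 53,  0, 70, 0,  305)),
    row("MWM:PF1", c(0, 0, 580, 83,  25, 24, 47, 64,  0, 70, 0,  149)),
    row("MWM:PF2", c(0, 0, 580, 83,  25, 0,  47, 64,  0, 70, 0,  149)),
    row("NR:O",    c(0, 0, 31,  0,   0,  0,  0,  0,   0, 67, 0,  0)),
    row("NR:L",    c(0, 0, 0,   24,  0,  0,  0,  0,   0, 0,  0,  0)),
    row("EPM:O",   c(12, 0, 573, 108, 136, 24, 47, 100, 134, 67, 24, 305)),
    row("EPM:C",   c(12, 0, 573, 108, 136, 24, 47, 100, 134, 67, 24, 305)),
    row("EPM:D",   c(12, 0, 44,  0,   136, 0,  0,  23,  134, 40, 0,  305)),
    row("OF:S:C",  c(0, 0, 0,   0,   136, 0,  0,  0,   134, 0,  0,  149)),
    row("OF:S:W",  c(0, 0, 0,   0,   136, 0,  0,  0,   134, 0,  0,  149)),
    row("OF:S:D",  c(0, 0, 0,   0,   136, 0,  0,  0,   134, 0,  0,  149)),
    row("OF:C:C",  c(0, 0, 393, 64,  0,  0,  47, 100, 0, 0,  24, 156)),
    row("OF:C:N",  c(0, 0, 393, 64,  0,  0,  47, 100, 0, 0,  24, 156)),
    row("OF:C:W",  c(0, 0, 393, 64,  0,  0,  47, 100, 0, 0,  24, 156)),
    row("FST:D1",  c(0, 0, 60,  0,   0,  0,  0,  47,  0, 30, 0,  0)),
    row("FST:D2",  c(0, 0, 60,  0,   0,  0,  0,  24,  0, 0,  0,  0)),
    row("FST:D3",  c(0, 0, 36,  0,   0,  0,  0,  10,  0, 0,  0,  0)),
    row("LDB",     c(0, 0, 27,  0,   0,  24, 0,  0,   0, 0,  0,  0)),
    row("TST",     c(0, 0, 0,   0,   0,  24, 0,  21,  0, 0,  0,  0)),
    row("SPT:D2",  c(0, 0, 0,   0,   0,  24, 0,  0,   0, 0,  0,  0)),
    row("SPT:D3",  c(0, 0, 0,   0,   0,  24, 0,  0,   0, 0,  0,  0)),
    row("SPT:D4",  c(0, 0, 0,   0,   0,  24, 0,  0,   0, 0,  0,  0)),
    row("Rota:D2", c(12, 23, 430, 108, 0, 24, 47, 100, 0, 70, 24, 305)),
    row("Rota:D3", c(12, 23, 430, 108, 0, 24, 47, 100, 0, 70, 24, 305))
  )
}

#' Default registry of behavioral outcome descriptors
#'
#' One descriptor per measured (parameter, week) cell of the measurement
#' design: the full code, its parsed components, the three taxonomy levels,
#' the good-outcome direction of the raw value, the redundancy flag
#' (parameters carrying no degree of freedom given their siblings: EPM closed
#' arm, OF square wall, OF circle wall), and the number of mice the design
#' measures for the cell (`design_n`).
#'
#' @return A tibble of outcome descriptors, one row per code.
#' @examples
#' reg <- default_registry()
#' dplyr::filter(reg, level3 == "MWM:H", week == 13)
#' @export
default_registry <- function() {
  des <- .design_counts()
  codes <- paste0(des$stub, ":W", des$week)
  parsed <- parse_code(codes)
  grammar <- .test_grammar()
  gi <- match(parsed$test, grammar$test)
  redundant_subtypes <- c("EPM:C", "OF:S:W", "OF:C:W")
  out <- tibble::tibble(
    code = parsed$code,
    test = parsed$test,
    subtype = parsed$subtype,
    index = parsed$index,
    week = parsed$week,
    level1 = grammar$level1[gi],
    level2 = grammar$level2[gi],
    level3 = .level3_family(parsed$test, parsed$subtype),
    good_direction = .good_direction(parsed$test, parsed$subtype),
    redundant = paste0(parsed$test, ifelse(is.na(parsed$subtype), "",
                                           paste0(":", parsed$subtype))) %in% redundant_subtypes,
    design_n = des$design_n
  )
  stopifnot(!anyDuplicated(out$code))
  out
}

#' Read a registry override from a YAML or JSON file
#'
#' The file must contain a list of descriptor records with fields `code`,
#' `level1`, `level2`, `level3`, `good_direction`, `redundant`, and optionally
#' `design_n`. Codes are validated against the grammar.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A registry tibble with the same columns as [default_registry()].
#' @export
read_registry <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    dplyr::bind_rows(lapply(yaml::read_yaml(path), tibble::as_tibble))
  }
  recs <- tibble::as_tibble(recs)
  needed <- c("code", "level1", "level2", "level3", "good_direction", "redundant")
  missing <- setdiff(needed, names(recs))
  if (length(missing) > 0L) {
    stop("registry file lacks fields: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  parsed <- parse_code(recs$code)
  tibble::tibble(
    code = parsed$code, test = parsed$test, subtype = parsed$subtype,
    index = parsed$index, week = parsed$week,
    level1 = recs$level1, level2 = recs$level2, level3 = recs$level3,
    good_direction = recs$good_direction, redundant = as.logical(recs$redundant),
    design_n = if ("design_n" %in% names(recs)) as.integer(recs$design_n) else NA_integer_
  )
}

#' Resolve codes against a registry
#'
#' @param codes Character vector of code strings.
#' @param registry Registry tibble (default [default_registry()]).
#' @return The registry rows for `codes`, in the order given. Codes absent from
#'   the registry are an error.
#' @export
resolve_codes <- function(codes, registry = default_registry()) {
  i <- match(codes, registry$code)
  if (anyNA(i)) {
    stop("code(s) not found in registry: ",
         paste(codes[is.na(i)], collapse = ", "), call. = FALSE)
  }
  registry[i, ]
}

#' Candidate behavioral codes
#'
#' The default candidate set for combination searches: every registry code
#' except injury-severity parameters (loss of consciousness, used as a
#' covariate source rather than a behavioral outcome) and redundant parameters
#' (no degree of freedom).
#'
#' @param registry Registry tibble.
#' @param include_severity Keep severity (LOC) codes? Default `FALSE`.
#' @param include_redundant Keep redundant codes? Default `FALSE`.
#' @return Character vector of codes.
#' @export
behavioral_codes <- function(registry = default_registry(),
                             include_severity = FALSE,
                             include_redundant = FALSE) {
  keep <- rep(TRUE, nrow(registry))
  if (!include_severity) keep <- keep & registry$level1 != "severity"
  if (!include_redundant) keep <- keep & !registry$redundant
  registry$code[keep]
}

#' Group codes into level-3 parameter families by week
#'
#' Partitions a set of codes into groups sharing a level-3 parameter family
#' and testing week (e.g. Morris water maze hidden trials 1-5 at week 17 form
#' one group). This is the grouping at which the selection cascade starts.
#'
#' @param codes Character vector of code strings, all resolvable in `registry`.
#' @param registry Registry tibble.
#' @return A tibble with columns `level3`, `week`, `level1`, `level2`, `codes`
#'   (list-column of member code strings, canonically ordered), `n_members`.
#' @examples
#' group_level3(c("MWM:H1:W17", "MWM:H2:W17", "MWM:PF1:W17"))
#' @export
group_level3 <- function(codes, registry = default_registry()) {
  if (length(codes) == 0L) {
    return(tibble::tibble(level3 = character(), week = integer(),
                          level1 = character(), level2 = character(),
                          codes = list(), n_members = integer()))
  }
  res <- resolve_codes(codes, registry)
  res |>
    dplyr::group_by(.data$level3, .data$week) |>
    dplyr::summarise(
      level1 = .data$level1[[1]],
      level2 = .data$level2[[1]],
      codes = list(sort(.data$code)),
      n_members = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$level3, .data$week)
}
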