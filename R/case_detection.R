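#' Read / write coded clinical event streams
#'
#' Events CSV: `patient_id,practice_id,date,code` with ISO-8601 dates.
#'
#' @param path CSV path.
#' @return A tibble of events with a `Date`-typed `date` column.
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      practice_id = readr::col_character(),
      date = readr::col_date(format = "%Y-%m-%d"),
      code = readr::col_character()
    )
  )
  validate_events(ev)
}

#' @rdname read_events
#' @param events An event tibble.
#' @export
write_events <- function(events, path) {
  readr::write_csv(validate_events(events), path)
  invisible(path)
}

validate_events <- function(events) {
  events <- as_tibble(events)
  needed <- c("patient_id", "practice_id", "date", "code")
  if (!all(needed %in% names(events))) {
    abort(paste0(
      "events must have columns ", paste(needed, collapse = ", ")
    ))
  }
  events$date <- as.Date(events$date)
  if (anyNA(events$date)) abort("events contain invalid dates")
  if (any(!nzchar(events$code)) || anyNA(events$code)) {
    abort("events contain empty codes")
  }
  events
}

#' Keep only events whose code is in a codelist
#'
#' @param events Event tibble (see [read_events()] for columns).
#' @param codes Character vector of concept codes (e.g. a resolved level-1
#'   codelist), or a `codelist_set` (its level-1 list is used).
#' @return The in-list events, original order preserved.
#' @export
filter_ari_events <- function(events, codes) {
  events <- validate_events(events)
  codes <- as_codes(codes)
  events[events$code %in% codes, , drop = FALSE]
}

as_codes <- function(codes) {
  if (inherits(codes, "codelist_set")) {
    hier <- attr(codes, "hierarchy")
    return(codelist_codes(codes, hier$level1))
  }
  unique(as.character(codes))
}

#' Group date-sorted events into infection episodes
#'
#' The episode-deduplication rule: scanning a patient's ARI events in date
#' order, an event opens a new case iff it falls strictly more than
#' `window_days` after the previous ARI event (`mode = "rolling"`, the
#' default — the window rolls forward from the most recent event, so a
#' long run of closely spaced recordings stays one episode). A gap of
#' exactly `window_days` joins the current episode. The alternative
#' `mode = "fixed"` anchors the window at the episode's opening (index)
#' event instead, for sensitivity analysis.
#'
#' @param dates Ascending `Date` vector of one patient's ARI event dates.
#' @param window_days Deduplication window (days), default 28.
#' @param mode `"rolling"` (default) or `"fixed"`.
#' @return Integer vector of case ids (1, 2, ...), one per event; events
#'   sharing an id belong to one episode.
#' @examples
#' d <- as.Date("2023-01-01") + c(0, 10, 40)
#' deduplicate_to_cases(d) # 1 1 2
#' @export
deduplicate_to_cases <- function(dates, window_days = 28,
                                 mode = c("rolling", "fixed")) {
  mode <- match.arg(mode)
  dates <- as.Date(dates)
  if (anyNA(dates)) abort("dates contain NA")
  n <- length(dates)
  if (n == 0) return(integer(0))
  if (is.unsorted(dates)) {
    abort("events must be sorted ascending by date within a patient")
  }
  if (mode == "rolling") {
    gaps <- as.numeric(diff(dates))
    return(cumsum(c(TRUE, gaps > window_days)))
  }
  # fixed: window anchored at each episode's index date
  ids <- integer(n)
  current <- 1L
  anchor <- dates[[1]]
  ids[[1]] <- 1L
  for (i in seq_len(n)[-1]) {
    if (as.numeric(dates[[i]] - anchor) > window_days) {
      current <- current + 1L
      anchor <- dates[[i]]
    }
    ids[[i]] <- current
  }
  ids
}

level2_rank <- function(level2, priority) {
  r <- match(level2, priority)
  r[is.na(r)] <- length(priority) + 1L
  r
}

# long membership table: one row per (code, level3, level2, rank)
codelist_membership <- function(codelists, priority) {
  stopifnot(inherits(codelists, "codelist_set"))
  l3 <- filter(as_tibble(codelists), .data$level == 3L)
  memb <- tidyr::unnest(
    select(l3, level3 = "indicator_id", level2 = "level2_parent",
           codes = "codes"),
    cols = "codes"
  )
  memb <- rename(memb, code = "codes")
  memb$l2_rank <- level2_rank(memb$level2, priority)
  memb
}

#' Classify an episode's constituent events to a level-3 indicator
#'
#' Collects every level-3 indicator matched by any constituent event and
#' picks one deterministically: the indicator whose level-2 parent ranks
#' highest in `priority` wins; within the winning group the
#' earliest-dated matching event decides, with remaining ties broken by
#' level-3 id (lexicographic).
#'
#' @param case_events Tibble with `date` and `code` for one episode.
#' @param codelists A resolved `codelist_set`.
#' @param priority Character vector of level-2 ids, highest priority
#'   first. Defaults to the hierarchy's own level-2 order.
#' @return A list with `level3` and `level2`.
#' @export
classify_case <- function(case_events, codelists, priority = NULL) {
  stopifnot(inherits(codelists, "codelist_set"))
  if (is.null(priority)) priority <- attr(codelists, "hierarchy")$level2
  memb <- codelist_membership(codelists, priority)
  hits <- inner_join(
    select(as_tibble(case_events), "date", "code"),
    memb,
    by = "code", relationship = "many-to-many"
  )
  if (nrow(hits) == 0) {
    abort(paste0(
      "episode contains events matching no level-3 indicator (codes: ",
      paste(unique(case_events$code), collapse = ", "),
      "); filter events to the level-1 codelist first"
    ))
  }
  hits <- arrange(hits, .data$l2_rank, .data$date, .data$level3)
  list(level3 = hits$level3[[1]], level2 = hits$level2[[1]])
}

#' Detect deduplicated ARI cases from a coded event stream
#'
#' The phenotyping core: events are filtered to the level-1 codelist,
#' grouped by patient, sorted deterministically (date, then level-2
#' priority of the code's best match, then code), grouped into episodes
#' with the `window_days` rule ([deduplicate_to_cases()]), and — when a
#' resolved hierarchy is supplied — each episode is classified to a
#' level-3/level-2 indicator ([classify_case()]). Passing a plain
#' character codelist instead runs the flat (legacy-style) algorithm:
#' same filtering and deduplication, no classification.
#'
#' @param events Event tibble (`patient_id`, `practice_id`, `date`,
#'   `code`).
#' @param codelists A `codelist_set` from [resolve_codelists()], or a
#'   character vector of codes for a flat codelist.
#' @param window_days Deduplication window, default 28 days.
#' @param dedup_mode `"rolling"` (default) or `"fixed"`.
#' @param level2_priority Level-2 priority order for classification;
#'   defaults to the hierarchy's level-2 order.
#' @return Tibble of cases sorted by (patient, index date):
#'   `patient_id`, `practice_id`, `index_date`, `level3`, `level2`,
#'   `n_events`. For a flat codelist `level3`/`level2` are `NA`.
#' @export
detect_cases <- function(events, codelists, window_days = 28,
                         dedup_mode = c("rolling", "fixed"),
                         level2_priority = NULL) {
  dedup_mode <- match.arg(dedup_mode)
  hierarchical <- inherits(codelists, "codelist_set")
  ari <- filter_ari_events(events, codelists)
  empty <- tibble(
    patient_id = character(), practice_id = character(),
    index_date = as.Date(character()),
    level3 = character(), level2 = character(), n_events = integer()
  )
  if (nrow(ari) == 0) return(empty)

  if (hierarchical) {
    if (is.null(level2_priority)) {
      level2_priority <- attr(codelists, "hierarchy")$level2
    }
    memb <- codelist_membership(codelists, level2_priority)
    # a code's sort rank is its best (lowest) level-2 rank across memberships
    code_rank <- summarise(
      group_by(memb, .data$code),
      l2_rank = min(.data$l2_rank), .groups = "drop"
    )
    ari <- left_join(ari, code_rank, by = "code")
  } else {
    ari$l2_rank <- 1L
  }

  # deterministic within-patient order: date, level-2 priority, code
  ari <- arrange(ari, .data$patient_id, .data$date, .data$l2_rank, .data$code)
  ari <- group_by(ari, .data$patient_id)
  ari <- mutate(
    ari,
    case_seq = deduplicate_to_cases(.data$date, window_days, dedup_mode)
  )
  ari <- ungroup(ari)

  grouped <- group_by(ari, .data$patient_id, .data$case_seq)
  cases <- summarise(
    grouped,
    practice_id = first(.data$practice_id),
    index_date = min(.data$date),
    n_events = n(),
    .groups = "drop"
  )

  if (hierarchical) {
    hits <- inner_join(
      select(ari, "patient_id", "case_seq", "date", "code"),
      memb,
      by = "code", relationship = "many-to-many"
    )
    hits <- arrange(
      hits, .data$patient_id, .data$case_seq,
      .data$l2_rank, .data$date, .data$level3
    )
    best <- slice(group_by(hits, .data$patient_id, .data$case_seq), 1)
    best <- ungroup(best)
    cases <- left_join(
      cases,
      select(best, "patient_id", "case_seq", "level3", "level2"),
      by = c("patient_id", "case_seq")
    )
  } else {
    cases$level3 <- NA_character_
    cases$level2 <- NA_character_
  }

  cases <- arrange(cases, .data$patient_id, .data$index_date)
  select(
    cases, "patient_id", "practice_id", "index_date",
    "level3", "level2", "n_events"
  )
}

#' Write a detected-case table to CSV
#'
#' Columns `patient_id,practice_id,index_date,level3,level2,n_events`.
#' @param cases Case tibble from [detect_cases()].
#' @param path Output path.
#' @export
write_cases <- function(cases, path) {
  readr::write_csv(cases, path)
  invisible(path)
}

#' @rdname write_cases
#' @export
read_cases <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      practice_id = readr::col_character(),
      index_date = readr::col_date(format = "%Y-%m-%d"),
      level3 = readr::col_character(),
      level2 = readr::col_character(),
      n_events = readr::col_integer()
    )
  )
}
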