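#' Part 1 validation report: codelist comparison
#'
#' Resolves the hierarchy's level-1 codelist against the terminology and
#' performs the set analysis against a legacy flat codelist: sizes,
#' intersection, codes unique to each list, and the percentage change in
#' codelist size.
#'
#' @param old_codelist Character vector: the legacy flat codelist.
#' @param hierarchy An [indicator_hierarchy()].
#' @param graph A [concept_graph()].
#' @return A list of class `part1_report`: the `codelist_comparison` for
#'   level 1 plus per-indicator codelist sizes.
#' @export
run_part1 <- function(old_codelist, hierarchy, graph) {
  codelists <- resolve_codelists(hierarchy, graph)
  new_l1 <- codelist_codes(codelists, hierarchy$level1)
  cmp <- compare_codelists(old_codelist, new_l1)
  sizes <- select(
    as_tibble(codelists), "indicator_id", "level", "n_codes"
  )
  structure(
    list(comparison = cmp, codelist_sizes = sizes),
    class = "part1_report"
  )
}

#' Part 2 validation report: old-vs-new case comparison
#'
#' Runs case detection twice over the same event stream — once with the
#' legacy flat codelist, once with the resolved hierarchy — and compares
#' the two case tables. Cases are matched on (patient, index date):
#' `newly_included` are new-algorithm cases with no matching old case,
#' `newly_excluded` the reverse, so the bookkeeping identity
#' `new_total = old_total + newly_included - newly_excluded` holds
#' exactly by construction. Per-code frequency tables (by index-event
#' code) are reported for both unmatched sets.
#'
#' @param events Event tibble.
#' @param old_codelist Character vector (legacy flat codelist).
#' @param codelists A resolved `codelist_set` (the new algorithm).
#' @param window_days,dedup_mode Passed to [detect_cases()].
#' @return A list of class `part2_report` with `old_total`, `new_total`,
#'   `newly_included`, `newly_excluded`, `percent_change` (case counts),
#'   the unmatched case tables, per-code frequency tibbles, and
#'   `identity_holds`.
#' @export
run_part2 <- function(events, old_codelist, codelists,
                      window_days = 28, dedup_mode = "rolling") {
  stopifnot(inherits(codelists, "codelist_set"))
  old_cases <- detect_cases(
    events, old_codelist, window_days = window_days, dedup_mode = dedup_mode
  )
  new_cases <- detect_cases(
    events, codelists, window_days = window_days, dedup_mode = dedup_mode
  )
  key <- c("patient_id", "index_date")
  included <- anti_join(new_cases, old_cases, by = key)
  excluded <- anti_join(old_cases, new_cases, by = key)

  index_code_freq <- function(case_tbl, codes) {
    # frequency of index-event codes among a set of cases
    ari <- filter_ari_events(events, codes)
    ari <- arrange(ari, .data$patient_id, .data$date, .data$code)
    idx <- inner_join(
      distinct(ari, .data$patient_id, .data$date, .keep_all = TRUE),
      select(case_tbl, "patient_id", date = "index_date"),
      by = c("patient_id", "date")
    )
    arrange(count(idx, .data$code, name = "n_cases"), desc(.data$n_cases),
            .data$code)
  }

  pct <- if (nrow(old_cases) > 0) {
    percent_change(nrow(old_cases), nrow(new_cases))
  } else {
    NA_real_
  }
  structure(
    list(
      old_total = nrow(old_cases),
      new_total = nrow(new_cases),
      newly_included = nrow(included),
      newly_excluded = nrow(excluded),
      percent_change = pct,
      included_cases = included,
      excluded_cases = excluded,
      included_code_freq = index_code_freq(
        included,
        codelist_codes(codelists, attr(codelists, "hierarchy")$level1)
      ),
      excluded_code_freq = index_code_freq(excluded, old_codelist),
      identity_holds =
        nrow(new_cases) == nrow(old_cases) + nrow(included) - nrow(excluded)
    ),
    class = "part2_report"
  )
}

#' Part 3 validation report: weekly rate comparison
#'
#' Applies the denominator reliability filter, computes weekly stratified
#' rate tables for both algorithms over the shared reliable practices,
#' and summarises season totals, median weekly rates and percentage
#' changes per indicator and stratum. Indicators without an old-algorithm
#' equivalent get `NA` changes.
#'
#' @param old_cases,new_cases Case tibbles from [detect_cases()] (the old
#'   table is typically unclassified).
#' @param registers List with `practices` and `patients` (see
#'   [read_registers()]).
#' @param period A [surveillance_period()].
#' @param strata Strata passed to [weekly_rates()].
#' @param level1 Level-1 indicator id.
#' @param max_jump Reliability threshold, see
#'   [filter_reliable_practices()].
#' @return A list of class `part3_report`: `reliable_practices`, both
#'   rate tables, season `summary` tibble (per indicator and stratum:
#'   old/new totals, old/new median weekly rates, percent changes), and
#'   the headline `old_total`, `new_total`, `additional_cases`.
#' @export
run_part3 <- function(old_cases, new_cases, registers, period,
                      strata = c("all", "age_band", "risk_group"),
                      level1 = "ARI", max_jump = 0.2) {
  reliable <- filter_reliable_practices(
    registers$practices, period, max_jump
  )
  if (length(reliable) == 0) {
    abort("no practice has a reliable denominator over the period")
  }
  old_rates <- weekly_rates(
    old_cases, registers, period,
    level1 = level1, level2 = character(0), strata = strata,
    reliable_practices = reliable
  )
  new_rates <- weekly_rates(
    new_cases, registers, period,
    level1 = level1, strata = strata,
    reliable_practices = reliable
  )

  season_total <- function(tbl, ind, stratum) {
    sum(tbl$cases[tbl$indicator == ind & tbl$stratum == stratum])
  }
  combos <- distinct(
    select(as_tibble(new_rates), "indicator", "stratum")
  )
  summary <- combos
  summary$old_cases <- NA_integer_
  summary$new_cases <- NA_integer_
  summary$old_median_rate <- NA_real_
  summary$new_median_rate <- NA_real_
  for (i in seq_len(nrow(summary))) {
    ind <- summary$indicator[[i]]
    st <- summary$stratum[[i]]
    summary$new_cases[[i]] <- season_total(new_rates, ind, st)
    summary$new_median_rate[[i]] <- median_weekly_rate(new_rates, ind, st)
    if (ind %in% unique(old_rates$indicator)) {
      summary$old_cases[[i]] <- season_total(old_rates, ind, st)
      summary$old_median_rate[[i]] <- median_weekly_rate(old_rates, ind, st)
    }
  }
  safe_pct <- function(o, n) {
    if (is.na(o) || o <= 0) NA_real_ else percent_change(o, n)
  }
  summary$cases_percent_change <- mapply(
    safe_pct, summary$old_cases, summary$new_cases
  )
  summary$rate_percent_change <- mapply(
    safe_pct, summary$old_median_rate, summary$new_median_rate
  )

  old_total <- season_total(old_rates, level1, "all")
  new_total <- season_total(new_rates, level1, "all")
  structure(
    list(
      reliable_practices = reliable,
      old_rates = old_rates,
      new_rates = new_rates,
      summary = summary,
      old_total = old_total,
      new_total = new_total,
      additional_cases = new_total - old_total
    ),
    class = "part3_report"
  )
}

#' @export
print.part1_report <- function(x, ...) {
  cat("Part 1: codelist comparison\n")
  print(x$comparison)
  invisible(x)
}

#' @export
print.part2_report <- function(x, ...) {
  cat("Part 2: case comparison\n")
  cat("  old total: ", x$old_total, "   new total: ", x$new_total, "\n",
      sep = "")
  cat("  newly included: ", x$newly_included,
      "   newly excluded: ", x$newly_excluded, "\n", sep = "")
  cat("  percent change: ", x$percent_change, "\n", sep = "")
  invisible(x)
}

#' @export
print.part3_report <- function(x, ...) {
  cat("Part 3: weekly rate comparison\n")
  cat("  reliable practices: ", length(x$reliable_practices), "\n", sep = "")
  cat("  season totals (all): old ", x$old_total, ", new ", x$new_total,
      " (additional ", x$additional_cases, ")\n", sep = "")
  invisible(x)
}

#' Serialise a validation report to JSON
#'
#' Tibbles become arrays of row objects; the result is readable back with
#' [jsonlite::read_json()].
#'
#' @param report A `part1_report`, `part2_report` or `part3_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  to_plain <- function(x) {
    if (inherits(x, "codelist_comparison")) x <- unclass(x)
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, to_plain))
    x
  }
  jsonlite::write_json(
    to_plain(unclass(report)), path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
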