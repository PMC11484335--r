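#' ISO-8601 week of a date
#'
#' ISO weeks run Monday to Sunday; week 1 is the week containing the
#' year's first Thursday, so the ISO week-numbering year can differ from
#' the calendar year at the boundaries (2023-01-01 falls in 2022-W52).
#'
#' @param date A `Date` vector.
#' @return Tibble with columns `iso_year` and `iso_week`.
#' @export
iso_week_of <- function(date) {
  date <- as.Date(date)
  if (anyNA(date)) abort("invalid dates")
  tibble(
    iso_year = as.integer(lubridate::isoyear(date)),
    iso_week = as.integer(lubridate::isoweek(date))
  )
}

#' Monday of a given ISO week
#'
#' @param iso_year,iso_week Integer vectors (recycled).
#' @return A `Date` vector.
#' @export
iso_week_monday <- function(iso_year, iso_week) {
  # Jan 4 always lies in ISO week 1 of its year
  jan4 <- as.Date(paste0(iso_year, "-01-04"))
  week1_monday <- jan4 - (as.integer(format(jan4, "%u")) - 1L)
  week1_monday + (iso_week - 1L) * 7L
}

#' Define a surveillance reporting period as consecutive ISO weeks
#'
#' The default influenza surveillance year runs ISO week 39 of one year
#' to week 38 of the next (52 weeks).
#'
#' @param start_year,start_week First ISO week of the period.
#' @param n_weeks Number of consecutive weeks.
#' @return Tibble with `iso_year`, `iso_week` and the week's `monday`,
#'   in order.
#' @export
surveillance_period <- function(start_year = 2022, start_week = 39,
                                n_weeks = 52) {
  if (n_weeks < 1) abort("period must contain at least one week")
  mondays <- iso_week_monday(start_year, start_week) + 7L * (seq_len(n_weeks) - 1L)
  wk <- iso_week_of(mondays)
  tibble(iso_year = wk$iso_year, iso_week = wk$iso_week, monday = mondays)
}

#' Age band at a reference date
#'
#' Bands are 0-17, 18-69 and 70+ completed years; together they partition
#' all non-negative ages. Age is in completed years, so a person reaches
#' 18-69 exactly on their 18th birthday.
#'
#' @param date_of_birth,reference_date `Date` vectors (recycled).
#' @return Factor with levels `"0-17"`, `"18-69"`, `"70+"`.
#' @export
age_band_of <- function(date_of_birth, reference_date) {
  dob <- as.Date(date_of_birth)
  ref <- as.Date(reference_date)
  if (any(dob > ref)) abort("date of birth after reference date")
  age <- completed_years(dob, ref)
  cut(
    age,
    breaks = c(-1, 17, 69, Inf),
    labels = c("0-17", "18-69", "70+")
  )
}

completed_years <- function(dob, ref) {
  dob_lt <- as.POSIXlt(dob)
  ref_lt <- as.POSIXlt(ref)
  years <- ref_lt$year - dob_lt$year
  before_birthday <- (ref_lt$mon < dob_lt$mon) |
    (ref_lt$mon == dob_lt$mon & ref_lt$mday < dob_lt$mday)
  years - as.integer(before_birthday)
}

#' Read practice registers
#'
#' `practices.csv`: `practice_id,iso_year,iso_week,list_size` (weekly
#' denominators). `patients.csv`: `patient_id,practice_id,dob,risk_group`
#' with `risk_group` logical.
#'
#' @param practices_csv,patients_csv Paths.
#' @return A list with tibbles `practices` and `patients`.
#' @export
read_registers <- function(practices_csv, patients_csv) {
  practices <- readr::read_csv(
    practices_csv,
    col_types = readr::cols(
      practice_id = readr::col_character(),
      iso_year = readr::col_integer(),
      iso_week = readr::col_integer(),
      list_size = readr::col_integer()
    )
  )
  patients <- readr::read_csv(
    patients_csv,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      practice_id = readr::col_character(),
      dob = readr::col_date(format = "%Y-%m-%d"),
      risk_group = readr::col_logical()
    )
  )
  list(practices = practices, patients = patients)
}

#' Practices with reliable weekly denominators
#'
#' Real sentinel networks cannot always compute a trustworthy denominator
#' for every practice; such practices must be excluded before rates are
#' calculated. The rule used here (a documented, configurable stand-in):
#' a practice is reliable over a period iff it reports a positive list
#' size for every week AND no week-on-week relative change in list size
#' exceeds `max_jump` (default 20%).
#'
#' @param practices Weekly register tibble
#'   (`practice_id,iso_year,iso_week,list_size`).
#' @param period A [surveillance_period()] tibble.
#' @param max_jump Maximum tolerated relative week-on-week change.
#' @return Character vector of reliable practice ids (sorted).
#' @export
filter_reliable_practices <- function(practices, period, max_jump = 0.2) {
  if (is.null(period) || nrow(period) == 0) abort("empty reporting period")
  practices <- as_tibble(practices)
  in_period <- inner_join(
    practices,
    select(period, "iso_year", "iso_week"),
    by = c("iso_year", "iso_week")
  )
  ok <- vapply(
    split(in_period, in_period$practice_id),
    function(p) {
      p <- arrange(p, .data$iso_year, .data$iso_week)
      if (nrow(p) < nrow(period)) return(FALSE)
      if (any(is.na(p$list_size)) || any(p$list_size <= 0)) return(FALSE)
      sizes <- p$list_size
      jumps <- abs(diff(sizes)) / utils::head(sizes, -1)
      all(jumps <= max_jump)
    },
    logical(1)
  )
  sort(names(ok)[ok])
}

#' Weekly stratified incidence rates per 100,000
#'
#' Bins classified cases by ISO week of index date, indicator (level 1
#' plus each level-2 group present in the hierarchy) and stratum, divides
#' by the appropriate denominator, and reports rates per 100,000
#' registered patients. Practices failing the reliability rule are
#' excluded from both numerator and denominator; cases from practices
#' absent from the register are dropped (their count is recorded in the
#' `dropped_cases` attribute and reported via a warning).
#'
#' Denominators: for the `"all"` stratum, the summed weekly list size of
#' included practices; for age-band and risk-group strata, the count of
#' roster patients of included practices in the stratum, with age
#' evaluated at the week's Monday.
#'
#' @param cases Case tibble from [detect_cases()]. Unclassified (flat
#'   algorithm) cases are tallied under the level-1 indicator only.
#' @param registers List with `practices` and `patients` tibbles (see
#'   [read_registers()]).
#' @param period A [surveillance_period()].
#' @param level1 Level-1 indicator id used in output rows.
#' @param level2 Level-2 ids to report (default: those present in
#'   `cases`).
#' @param strata Any of `"all"`, `"age_band"`, `"risk_group"`.
#' @param reliable_practices Optional pre-computed inclusion list;
#'   computed from the register with [filter_reliable_practices()]
#'   defaults otherwise.
#' @param max_jump Passed to [filter_reliable_practices()].
#' @return Tibble `iso_year, iso_week, indicator, stratum, cases,
#'   denominator, rate_per_100k` covering every week of the period
#'   (zero-case weeks included). Rows with zero denominator carry `NA`
#'   rate.
#' @export
weekly_rates <- function(cases, registers, period,
                         level1 = "ARI", level2 = NULL,
                         strata = "all",
                         reliable_practices = NULL,
                         max_jump = 0.2) {
  stopifnot(all(strata %in% c("all", "age_band", "risk_group")))
  practices <- as_tibble(registers$practices)
  patients <- as_tibble(registers$patients)
  if (is.null(reliable_practices)) {
    reliable_practices <- filter_reliable_practices(practices, period, max_jump)
  }
  if (length(reliable_practices) == 0) {
    abort("no practice has a reliable denominator over the period")
  }
  if (is.null(level2)) {
    level2 <- sort(unique(cases$level2[!is.na(cases$level2)]))
  }

  registered <- cases$practice_id %in% practices$practice_id
  n_unregistered <- sum(!registered)
  if (n_unregistered > 0) {
    warn(paste0(
      n_unregistered,
      " case(s) dropped: practice absent from the register"
    ))
  }
  kept <- cases[registered & cases$practice_id %in% reliable_practices, ,
                drop = FALSE]

  wk <- iso_week_of(kept$index_date)
  kept$iso_year <- wk$iso_year
  kept$iso_week <- wk$iso_week
  kept <- inner_join(
    kept, select(period, "iso_year", "iso_week", "monday"),
    by = c("iso_year", "iso_week")
  )
  kept <- left_join(
    kept,
    select(patients, "patient_id", "dob", "risk_group"),
    by = "patient_id"
  )

  # one row per (case, indicator): level 1 always, level 2 when classified
  case_ind <- bind_rows(
    mutate(kept, indicator = level1),
    filter(mutate(kept, indicator = .data$level2), !is.na(.data$indicator))
  )
  indicators <- c(level1, level2)

  # stratum labels per case
  stratify_cases <- function(df, stratum_var) {
    if (stratum_var == "all") {
      df$stratum <- "all"
    } else if (stratum_var == "age_band") {
      if (anyNA(df$dob) && nrow(df) > 0) {
        abort("cases reference patients missing from the roster; cannot age-stratify")
      }
      df$stratum <- as.character(age_band_of(df$dob, df$index_date))
    } else {
      df$stratum <- ifelse(df$risk_group, "risk", "no_risk")
    }
    df
  }

  weekly_denominator <- function(stratum_var) {
    base <- inner_join(
      filter(practices, .data$practice_id %in% reliable_practices),
      select(period, "iso_year", "iso_week", "monday"),
      by = c("iso_year", "iso_week")
    )
    if (stratum_var == "all") {
      return(summarise(
        group_by(base, .data$iso_year, .data$iso_week),
        stratum = "all", denominator = sum(.data$list_size), .groups = "drop"
      ))
    }
    roster <- filter(patients, .data$practice_id %in% reliable_practices)
    weeks <- distinct(select(period, "iso_year", "iso_week", "monday"))
    grid <- crossing(weeks, roster)
    if (stratum_var == "age_band") {
      grid$stratum <- as.character(age_band_of(grid$dob, grid$monday))
    } else {
      grid$stratum <- ifelse(grid$risk_group, "risk", "no_risk")
    }
    summarise(
      group_by(grid, .data$iso_year, .data$iso_week, .data$stratum),
      denominator = dplyr::n(), .groups = "drop"
    )
  }

  stratum_levels <- function(stratum_var) {
    switch(stratum_var,
      all = "all",
      age_band = c("0-17", "18-69", "70+"),
      risk_group = c("no_risk", "risk")
    )
  }

  out <- list()
  for (sv in strata) {
    tallied <- stratify_cases(case_ind, sv)
    counts <- count(
      tallied, .data$iso_year, .data$iso_week, .data$indicator,
      .data$stratum, name = "cases"
    )
    full <- crossing(
      select(period, "iso_year", "iso_week"),
      indicator = indicators,
      stratum = stratum_levels(sv)
    )
    counts <- left_join(
      full, counts,
      by = c("iso_year", "iso_week", "indicator", "stratum")
    )
    counts$cases <- ifelse(is.na(counts$cases), 0L, counts$cases)
    denom <- weekly_denominator(sv)
    counts <- left_join(
      counts, denom, by = c("iso_year", "iso_week", "stratum")
    )
    counts$denominator <- ifelse(
      is.na(counts$denominator), 0L, counts$denominator
    )
    out[[sv]] <- counts
  }
  out <- bind_rows(out)
  out$rate_per_100k <- ifelse(
    out$denominator > 0,
    100000 * out$cases / out$denominator,
    NA_real_
  )
  out <- arrange(
    out, .data$iso_year, .data$iso_week, .data$indicator, .data$stratum
  )
  attr(out, "reliable_practices") <- reliable_practices
  attr(out, "dropped_cases") <- n_unregistered
  out
}

#' Median weekly rate for one indicator and stratum
#'
#' The season-summary statistic: the median of the weekly rates over the
#' reporting period (even week counts average the two central values),
#' rounded half-up to one decimal for presentation.
#'
#' @param table A [weekly_rates()] tibble.
#' @param indicator Indicator id.
#' @param stratum Stratum label (default `"all"`).
#' @return Median weekly rate per 100,000, one decimal.
#' @export
median_weekly_rate <- function(table, indicator, stratum = "all") {
  rows <- table[table$indicator == indicator & table$stratum == stratum, ,
                drop = FALSE]
  rates <- rows$rate_per_100k[!is.na(rows$rate_per_100k)]
  if (length(rates) == 0) {
    abort(paste0(
      "no rate rows for indicator '", indicator,
      "', stratum '", stratum, "'"
    ))
  }
  round_half_up(median(rates), 1)
}

#' Signed percentage change, one decimal
#'
#' `100 * (new - old) / old`, rounded half-up to one decimal — the
#' "% change" column of old-vs-new comparison tables.
#'
#' @param old_value,new_value Numeric scalars; `old_value` must be
#'   positive.
#' @return Signed percentage.
#' @examples
#' percent_change(205.6, 258.9) # 25.9
#' @export
percent_change <- function(old_value, new_value) {
  if (!is.numeric(old_value) || length(old_value) != 1 ||
      is.na(old_value) || old_value <= 0) {
    abort("`old_value` must be a single positive number")
  }
  round_half_up(100 * (new_value - old_value) / old_value, 1)
}

#' Write a weekly rate table to CSV
#'
#' Columns `iso_year,iso_week,indicator,stratum,cases,denominator,
#' rate_per_100k`.
#' @param table A [weekly_rates()] tibble.
#' @param path Output path.
#' @export
write_rate_table <- function(table, path) {
  readr::write_csv(as_tibble(table), path)
  invisible(path)
}
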