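test_that("event filtering keeps in-list events in order", {
  ev <- make_events(
    "PT1",
    c("2022-10-01", "2022-10-02", "2022-10-03"),
    c("in1", "out", "in2")
  )
  expect_equal(nrow(filter_ari_events(ev, character(0))), 0)
  kept <- filter_ari_events(ev, c("in1", "in2"))
  expect_equal(kept$code, c("in1", "in2"))
  expect_equal(kept$date, as.Date(c("2022-10-01", "2022-10-03")))

  # random streams match a plain membership filter
  set.seed(601)
  codes <- sprintf("c%02d", 1:20)
  for (rep in 1:10) {
    ev <- make_events(
      "PT1",
      as.Date("2022-10-01") + sample(0:90, 40, TRUE),
      sample(codes, 40, TRUE)
    )
    keep <- sample(codes, 8)
    expect_equal(filter_ari_events(ev, keep), ev[ev$code %in% keep, ])
  }
})

test_that("window rule: strictly-more-than gap opens a new episode", {
  d <- function(...) as.Date("2023-01-01") + c(...)
  expect_equal(deduplicate_to_cases(d(0)), 1L)
  # 10-day gap joins; 30-day gap opens
  expect_equal(deduplicate_to_cases(d(0, 10, 40)), c(1L, 1L, 2L))
  # gaps of exactly 28 days never open a new episode (strict inequality)
  expect_equal(deduplicate_to_cases(d(0, 28, 56, 84)), rep(1L, 4))
  expect_equal(deduplicate_to_cases(d(0, 29)), c(1L, 2L))
  expect_error(deduplicate_to_cases(d(10, 0)), "sorted")
})

test_that("rolling and fixed modes match the straight-line oracle", {
  set.seed(602)
  for (rep in 1:200) {
    n <- sample(1:30, 1)
    dates <- as.Date("2022-10-01") + sort(sample(0:400, n, TRUE))
    window <- sample(c(7, 14, 28), 1)
    for (mode in c("rolling", "fixed")) {
      expect_equal(
        deduplicate_to_cases(dates, window, mode),
        oracle_dedup(dates, window, mode),
        info = paste("rep", rep, mode)
      )
    }
  }
})

test_that("modes disagree exactly when repeats extend past the fixed window", {
  d <- as.Date("2023-01-01") + c(0, 20, 40, 60)
  # each consecutive gap is 20 <= 28, so rolling keeps one episode
  expect_equal(max(deduplicate_to_cases(d, 28, "rolling")), 1L)
  # day 40 is > 28 from the day-0 index, so fixed opens a second episode
  expect_equal(deduplicate_to_cases(d, 28, "fixed"), c(1L, 1L, 2L, 2L))
})

test_that("episodes are classified by level-2 priority, then date, then id", {
  fx <- two_group_overlap(c("ILI", "URTI"))
  cls <- fx$codelists

  # single event matching one level-3
  got <- classify_case(
    make_events("PT1", "2022-10-01", "ind_urti"), cls
  )
  expect_equal(got$level3, "ind_urti")
  expect_equal(got$level2, "URTI")

  # URTI-coded plus ILI-coded event: ILI outranks URTI
  got <- classify_case(
    make_events("PT1", c("2022-10-05", "2022-10-06"),
                c("ind_urti", "ind_ili")),
    cls
  )
  expect_equal(got$level2, "ILI")

  # events with no level-3 match must have been filtered upstream
  expect_error(
    classify_case(make_events("PT1", "2022-10-01", "mystery"), cls),
    "no level-3"
  )
})

test_that("a code in two groups resolves per priority for every group pair", {
  combos <- utils::combn(ARI_LEVEL2_GROUPS, 2)
  for (j in seq_len(ncol(combos))) {
    pair <- combos[, j]
    fx <- two_group_overlap(pair)
    got <- classify_case(
      make_events("PT1", "2022-10-01", "shared"), fx$codelists
    )
    expected <- pair[[which.min(match(pair, ARI_LEVEL2_GROUPS))]]
    expect_equal(got$level2, expected, info = paste(pair, collapse = "/"))
    # a reversed priority flips the choice
    rev_priority <- rev(ARI_LEVEL2_GROUPS)
    got_rev <- classify_case(
      make_events("PT1", "2022-10-01", "shared"),
      fx$codelists, priority = rev_priority
    )
    expected_rev <- pair[[which.min(match(pair, rev_priority))]]
    expect_equal(got_rev$level2, expected_rev)
  }
})

test_that("detect_cases runs the full per-patient pipeline", {
  fx <- two_group_overlap()
  ev <- dplyr::bind_rows(
    make_events("PT1", "2022-10-01", "ind_urti"),
    make_events("PT2", "2022-11-01", "ind_ili", practice_id = "P002")
  )
  cases <- detect_cases(ev, fx$codelists)
  expect_equal(nrow(cases), 2)
  expect_equal(cases$level2, c("URTI", "ILI")) # sorted by patient id
  expect_equal(cases$practice_id, c("P001", "P002"))

  # same input twice: identical output
  expect_identical(detect_cases(ev, fx$codelists),
                   detect_cases(ev, fx$codelists))
})

test_that("detect_cases matches a naive reimplementation on a simulated stream", {
  cfg <- sim_config(seed = 1, n_practices = 2, patients_per_practice = 250,
                    n_weeks = 30)
  sim <- simulate_surveillance_data(cfg)
  got <- detect_cases(sim$events, sim$codelists)
  want <- oracle_detect(sim$events, sim$codelists)
  expect_gt(nrow(got), 0)
  expect_equal(as.data.frame(got), want)
})

test_that("flat codelists detect but do not classify", {
  fx <- two_group_overlap()
  ev <- make_events("PT1", c("2022-10-01", "2022-12-01"),
                    c("ind_urti", "ind_urti"))
  cases <- detect_cases(ev, c("ind_urti", "ind_ili"))
  expect_equal(nrow(cases), 2)
  expect_true(all(is.na(cases$level3)))
  expect_true(all(is.na(cases$level2)))
})

test_that("case count is bounded by event count, equal when gaps exceed the window", {
  fx <- two_group_overlap()
  set.seed(603)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    ev <- make_events(
      "PT1",
      as.Date("2022-10-01") + sort(sample(0:300, n)),
      sample(c("ind_urti", "ind_ili", "ind_lrti"), n, TRUE)
    )
    cases <- detect_cases(ev, fx$codelists)
    expect_lte(nrow(cases), nrow(ev))
    gaps <- diff(sort(ev$date))
    if (all(gaps > 28)) expect_equal(nrow(cases), nrow(ev))
  }
})

test_that("inserting an event inside an episode never raises the case count", {
  fx <- two_group_overlap()
  set.seed(604)
  for (rep in 1:20) {
    dates <- as.Date("2022-10-01") + sort(sample(0:200, 6))
    ev <- make_events("PT1", dates, "ind_urti")
    base_cases <- nrow(detect_cases(ev, fx$codelists))
    # insert next to an existing event (gap <= window to its neighbour,
    # not extending any gap beyond the window)
    anchor <- sample(dates, 1)
    extra <- make_events("PT1", anchor + sample(0:3, 1), "ind_ili")
    more <- nrow(detect_cases(dplyr::bind_rows(ev, extra), fx$codelists))
    expect_lte(more, base_cases)
  }
})

test_that("classified level-2 is always the hierarchy parent of level-3", {
  sim <- simulate_surveillance_data(
    sim_config(seed = 3, n_practices = 3, patients_per_practice = 200)
  )
  cases <- detect_cases(sim$events, sim$codelists)
  l3 <- sim$hierarchy$level3
  expect_gt(nrow(cases), 0)
  expect_equal(
    cases$level2,
    l3$level2_parent[match(cases$level3, l3$id)]
  )
})

test_that("case tables round-trip through CSV", {
  fx <- two_group_overlap()
  ev <- make_events("PT1", "2022-10-01", "ind_urti")
  cases <- detect_cases(ev, fx$codelists)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cases.csv")
  write_cases(cases, path)
  expect_equal(as.data.frame(read_cases(path)), as.data.frame(cases))
})
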