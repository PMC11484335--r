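test_that("hierarchy construction validates structure and rules", {
  ids <- paste0("i", 1:5)
  ok <- data.frame(
    id = ids, level2_parent = ARI_LEVEL2_GROUPS, ecl = paste0("<<", ids)
  )
  expect_s3_class(indicator_hierarchy(ok), "indicator_hierarchy")

  # a childless level-2 group is rejected
  bad <- ok
  bad$level2_parent[1] <- "ECLD"
  expect_error(indicator_hierarchy(bad), "ILI")

  # unparseable rule is rejected, naming the indicator
  bad2 <- ok
  bad2$ecl[3] <- "<<A MINUS"
  expect_error(indicator_hierarchy(bad2), "i3")

  # unknown parent group
  bad3 <- ok
  bad3$level2_parent[2] <- "SARI"
  expect_error(indicator_hierarchy(bad3), "SARI")
})

test_that("disjoint singleton rules compose by union", {
  fx <- singleton_hierarchy()
  cls <- resolve_codelists(fx$hierarchy, fx$graph)
  expect_equal(nrow(cls), 1 + 5 + 5)
  expect_equal(codelist_codes(cls, "ARI"),
               sort(fx$hierarchy$level3$id))
  expect_equal(length(codelist_codes(cls, "ARI")), 5)
  for (g in ARI_LEVEL2_GROUPS) {
    expect_equal(length(codelist_codes(cls, g)), 1)
  }
})

test_that("a code shared by two level-3 children is counted once in the union", {
  fx <- two_group_overlap(c("ILI", "URTI"))
  cls <- fx$codelists
  expect_true("shared" %in% codelist_codes(cls, "ind_ili"))
  expect_true("shared" %in% codelist_codes(cls, "ind_urti"))
  # level-1 union counts it once
  l3_sizes <- sum(cls$n_codes[cls$level == 3])
  expect_equal(length(codelist_codes(cls, "ARI")), l3_sizes - 1)
})

test_that("level composition invariant holds on the synthetic fixture", {
  term <- generate_terminology(sim_config(seed = 7))
  cls <- term$codelists
  l1 <- codelist_codes(cls, "ARI")
  l2_union <- sort(unique(unlist(cls$codes[cls$level == 2])))
  l3_union <- sort(unique(unlist(cls$codes[cls$level == 3])))
  expect_equal(l1, l2_union)
  expect_equal(l1, l3_union)
})

test_that("resolution errors name the indicator and the missing code", {
  g <- tiny_graph()
  h <- indicator_hierarchy(data.frame(
    id = paste0("i", 1:5),
    level2_parent = ARI_LEVEL2_GROUPS,
    ecl = c("<<A", "<<B", "<<C", "<<D", "<<MISSING")
  ))
  expect_error(resolve_codelists(h, g), "i5")
  expect_error(resolve_codelists(h, g), "MISSING")
})

test_that("compare_codelists performs exact set arithmetic", {
  # identical lists
  cmp <- compare_codelists(c("x", "y"), c("y", "x"))
  expect_equal(cmp$intersection, c("x", "y"))
  expect_equal(cmp$only_a, character(0))
  expect_equal(cmp$only_b, character(0))
  expect_equal(cmp$percent_change, 0)

  # empty `a` flags the undefined percentage
  expect_warning(cmp0 <- compare_codelists(character(0), "x"), "undefined")
  expect_true(is.na(cmp0$percent_change))

  # random sets vs element-by-element counting
  set.seed(501)
  universe <- sprintf("code%03d", 1:150)
  for (rep in 1:25) {
    a <- sample(universe, sample(0:100, 1))
    b <- sample(universe, sample(1:100, 1))
    cmp <- compare_codelists(a, b)
    both <- sum(vapply(unique(a), function(x) x %in% b, logical(1)))
    expect_equal(length(cmp$intersection), both)
    expect_equal(cmp$size_a, length(unique(a)))
    expect_equal(cmp$size_b, length(unique(b)))
    # size identities
    expect_equal(cmp$size_a, length(cmp$intersection) + length(cmp$only_a))
    expect_equal(cmp$size_b, length(cmp$intersection) + length(cmp$only_b))
  }
})

test_that("code-frequency coverage finds the minimal covering prefix", {
  # one dominant code
  expect_equal(code_frequency_coverage(c(big = 100), 0.9)$k, 1L)

  cov <- code_frequency_coverage(c(a = 50, b = 30, c = 20), 0.8)
  expect_equal(cov$k, 2L)
  expect_equal(cov$covered_fraction, 0.8)

  expect_error(code_frequency_coverage(c(a = 0, b = 0), 0.5), "zero")
  expect_error(code_frequency_coverage(c(a = 1), 1.5), "threshold")

  # exhaustive prefix oracle on random counts
  set.seed(502)
  for (rep in 1:20) {
    counts <- stats::setNames(
      sample(0:40, 200, replace = TRUE),
      sprintf("c%03d", 1:200)
    )
    if (sum(counts) == 0) counts[1] <- 1
    threshold <- runif(1, 0.05, 1)
    got <- code_frequency_coverage(counts, threshold)
    ord <- order(-counts, names(counts))
    sorted <- counts[ord]
    k_oracle <- NA
    for (k in seq_along(sorted)) {
      if (sum(sorted[seq_len(k)]) / sum(counts) >= threshold) {
        k_oracle <- k
        break
      }
    }
    expect_equal(got$k, k_oracle)
  }
})

test_that("coverage k is monotone in the threshold", {
  set.seed(503)
  counts <- stats::setNames(sample(1:50, 80, TRUE), sprintf("c%02d", 1:80))
  ks <- vapply(
    seq(0.1, 1, by = 0.1),
    function(th) code_frequency_coverage(counts, th)$k,
    integer(1)
  )
  expect_true(all(diff(ks) >= 0))
})

test_that("indicator definitions round-trip through JSON", {
  term <- generate_terminology(sim_config(seed = 11))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "indicators.json")
  write_indicator_definitions(term$hierarchy, path)
  back <- read_indicator_definitions(path)
  expect_equal(back$level1, term$hierarchy$level1)
  expect_equal(back$level2, term$hierarchy$level2)
  expect_equal(as.data.frame(back$level3),
               as.data.frame(term$hierarchy$level3))
  # resolved codelists are identical after the round trip
  expect_equal(
    resolve_codelists(back, term$graph)$codes,
    term$codelists$codes
  )
})

test_that("codelist CSV export is flat and labelled", {
  fx <- two_group_overlap()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "codelists.csv")
  flat <- export_codelists_csv(fx$codelists, fx$graph, path)
  expect_true(file.exists(path))
  expect_named(flat, c("indicator_id", "level", "code", "label"))
  expect_equal(sum(flat$level == 1), length(codelist_codes(fx$codelists, "ARI")))
  expect_false(anyNA(flat$label))
})

test_that("shipped fixture terminology resolves to the manifest sizes", {
  dir <- system.file("extdata", "fixture_terminology", package = "ariphen")
  graph <- read_terminology(
    file.path(dir, "concepts.csv"), file.path(dir, "edges.csv")
  )
  hierarchy <- read_indicator_definitions(file.path(dir, "indicators.json"))
  manifest <- jsonlite::read_json(
    file.path(dir, "manifest.json"), simplifyVector = TRUE
  )
  cls <- resolve_codelists(hierarchy, graph)
  expect_equal(codelist_codes(cls, "ARI"), 
               sort(codelist_codes(cls, "ARI")))
  expect_equal(cls$n_codes[cls$level == 1], manifest$level1_size)
  for (g in names(manifest$level2_sizes)) {
    expect_equal(
      cls$n_codes[cls$indicator_id == g], manifest$level2_sizes[[g]],
      info = g
    )
  }
  for (id in names(manifest$level3_sizes)) {
    expect_equal(
      cls$n_codes[cls$indicator_id == id], manifest$level3_sizes[[id]],
      info = id
    )
  }
  # and the in-test naive oracle agrees with the resolved level-3 sets
  for (i in seq_len(nrow(hierarchy$level3))) {
    expect_equal(
      codelist_codes(cls, hierarchy$level3$id[[i]]),
      oracle_evaluate(graph$concepts, graph$edges,
                      parse_ecl(hierarchy$level3$ecl[[i]]))
    )
  }
})
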