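#' Default seasonal incidence curves for the synthetic event generator
#'
#' One row per level-2 indicator group: a weekly baseline rate per
#' 100,000 registered patients plus a Gaussian-shaped winter peak,
#' `rate(w) = baseline * (1 + (peak_multiplier - 1) *
#' exp(-(w - peak_week)^2 / (2 * peak_width^2)))`, with `w` the week
#' index within the surveillance year (1..52, which starts in early
#' autumn, so peaks around weeks 13-16 fall in midwinter). Defaults are
#' chosen to resemble a temperate-climate respiratory season in primary
#' care: URTI dominant, LRTI second, ILI low and sharply peaked, ECLD
#' and ARI-NOS small.
#'
#' @return Tibble with columns `level2`, `baseline_per_100k`,
#'   `peak_multiplier`, `peak_week`, `peak_width`.
#' @export
default_incidence_curves <- function() {
  tibble(
    level2 = c("ILI", "ECLD", "LRTI", "URTI", "ARI-NOS"),
    baseline_per_100k = c(2, 8, 55, 110, 14),
    peak_multiplier = c(8, 3, 2.8, 2.2, 2),
    peak_week = c(15, 16, 14, 13, 14),
    peak_width = c(3, 6, 6, 7, 6)
  )
}

#' Configuration for the synthetic surveillance data generator
#'
#' All randomness in a simulation derives from `seed` (distinct stage
#' offsets keep [generate_terminology()], [generate_population()] and
#' [generate_events()] independently reproducible); identical config and
#' seed give byte-identical outputs.
#'
#' @param seed Integer seed.
#' @param n_practices,patients_per_practice Register dimensions.
#' @param start_year,start_week,n_weeks Surveillance period (ISO weeks).
#' @param incidence Seasonal curve table, see
#'   [default_incidence_curves()].
#' @param repeat_mean_extra Mean number of repeat codings per episode
#'   beyond the first (geometric); 0 disables repeat coding.
#' @param repeat_gap_range Within-episode gap between consecutive
#'   codings, days, drawn uniformly from this range; repeats falling
#'   more than `window_days` after onset are not emitted.
#' @param window_days Episode window the generator respects (and the
#'   detector's default), days.
#' @param min_episode_gap_days Minimum gap between a patient's true
#'   episode onsets; keeping it above `window_days +
#'   max(repeat_gap_range)` guarantees distinct episodes remain
#'   separable.
#' @param miscode_rate_per_100k Weekly rate of injected miscoded events
#'   (chronic / recurrent / non-infective decoy codes) per 100,000
#'   patients; 0 disables miscoding.
#' @param p_new_only_code Probability that a true-episode event uses a
#'   code present only in the new (rule-based) codelists, emulating
#'   symptom codes a legacy flat codelist missed.
#' @param age_dist Probabilities for the 0-17 / 18-69 / 70+ age bands.
#' @param risk_prevalence Bernoulli probability of risk-group
#'   membership.
#' @param practice_dropout_prob Probability that a practice has missing
#'   register weeks (making its denominator unreliable).
#' @param old_codelist_style `"realistic"` (legacy list misses the
#'   new-only codes and contains the decoys) or `"superset"` (legacy
#'   list = all new codes plus decoys, isolating miscoding as the only
#'   old/new difference).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_practices = 20L,
                       patients_per_practice = 500L,
                       start_year = 2022L,
                       start_week = 39L,
                       n_weeks = 52L,
                       incidence = default_incidence_curves(),
                       repeat_mean_extra = 1,
                       repeat_gap_range = c(1L, 21L),
                       window_days = 28L,
                       min_episode_gap_days = 60L,
                       miscode_rate_per_100k = 5,
                       p_new_only_code = 0.15,
                       age_dist = c(0.21, 0.655, 0.135),
                       risk_prevalence = 0.25,
                       practice_dropout_prob = 0.15,
                       old_codelist_style = c("realistic", "superset")) {
  old_codelist_style <- match.arg(old_codelist_style)
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_practices >= 1, patients_per_practice >= 1, n_weeks >= 1,
    repeat_mean_extra >= 0,
    length(repeat_gap_range) == 2, repeat_gap_range[1] >= 1,
    repeat_gap_range[2] >= repeat_gap_range[1],
    window_days >= 1,
    min_episode_gap_days > window_days + repeat_gap_range[2],
    miscode_rate_per_100k >= 0,
    p_new_only_code >= 0, p_new_only_code <= 1,
    length(age_dist) == 3, all(age_dist >= 0),
    abs(sum(age_dist) - 1) < 1e-8,
    risk_prevalence >= 0, risk_prevalence <= 1,
    practice_dropout_prob >= 0, practice_dropout_prob <= 1
  )
  structure(
    list(
      seed = as.integer(seed),
      n_practices = as.integer(n_practices),
      patients_per_practice = as.integer(patients_per_practice),
      start_year = as.integer(start_year),
      start_week = as.integer(start_week),
      n_weeks = as.integer(n_weeks),
      incidence = as_tibble(incidence),
      repeat_mean_extra = repeat_mean_extra,
      repeat_gap_range = as.integer(repeat_gap_range),
      window_days = as.integer(window_days),
      min_episode_gap_days = as.integer(min_episode_gap_days),
      miscode_rate_per_100k = miscode_rate_per_100k,
      p_new_only_code = p_new_only_code,
      age_dist = age_dist,
      risk_prevalence = risk_prevalence,
      practice_dropout_prob = practice_dropout_prob,
      old_codelist_style = old_codelist_style
    ),
    class = "sim_config"
  )
}

# static blueprint of the 16 level-3 indicators (1 ILI / 3 ECLD / 4 LRTI /
# 6 URTI / 2 ARI-NOS) with invented placeholder ids
level3_blueprint <- function() {
  tibble(
    id = c(
      "ili",
      "ecld_asthma", "ecld_copd", "ecld_bronchiectasis",
      "lrti_pneumonia", "lrti_acute_bronchitis", "lrti_bronchiolitis",
      "lrti_nos",
      "urti_sinusitis", "urti_pharyngitis", "urti_laryngitis",
      "urti_otitis_media", "urti_coryza", "urti_nos",
      "arinos_unspecified", "arinos_suspected_covid"
    ),
    level2_parent = c(
      "ILI",
      rep("ECLD", 3),
      rep("LRTI", 4),
      rep("URTI", 6),
      rep("ARI-NOS", 2)
    )
  )
}

#' Generate a synthetic polyhierarchical terminology and ARI hierarchy
#'
#' Builds an invented respiratory terminology of roughly 150 concepts: an
#' anchor concept per level-3 indicator with a small descendant subtree,
#' extra is-a edges giving some concepts a second parent within the same
#' level-2 group (polyhierarchy), exclusion subtrees of chronic/recurrent
#' concepts hanging under three anchors (removed by `MINUS` rules), and
#' standalone decoy branches of chronic, recurrent and non-infective
#' conditions. The returned legacy-style ("old") flat codelist contains
#' all decoy codes and — in the `"realistic"` style — misses a random
#' subset of the new codes (the "new only" codes); decoy codes are
#' disjoint from the resolved new level-1 codelist by construction.
#'
#' @param config A [sim_config()].
#' @return A list: `graph` ([concept_graph()]), `hierarchy`
#'   ([indicator_hierarchy()]), `codelists` (resolved `codelist_set`),
#'   `old_codelist`, `decoy_codes` (with a `class` attribute tibble
#'   `decoy_classes`), `new_only_codes`.
#' @export
generate_terminology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bp <- level3_blueprint()

  concepts <- list()
  edges <- list()
  add_concept <- function(code, label) {
    concepts[[length(concepts) + 1L]] <<- tibble(code = code, label = label)
  }
  add_edge <- function(child, parent) {
    edges[[length(edges) + 1L]] <<- tibble(child = child, parent = parent)
  }

  add_concept("resp_cond", "Respiratory condition")
  for (g in ARI_LEVEL2_GROUPS) {
    gcode <- paste0("grp_", tolower(gsub("-", "", g)))
    add_concept(gcode, paste("Group concept:", g))
    add_edge(gcode, "resp_cond")
  }

  subtree_nodes <- list() # per level-3: codes eligible for extra parents
  for (i in seq_len(nrow(bp))) {
    id <- bp$id[[i]]
    g <- bp$level2_parent[[i]]
    anchor <- paste0("c_", id)
    gcode <- paste0("grp_", tolower(gsub("-", "", g)))
    add_concept(anchor, paste("Anchor:", gsub("_", " ", id)))
    add_edge(anchor, gcode)
    n_desc <- sample(4:7, 1)
    nodes <- anchor
    for (k in seq_len(n_desc)) {
      code <- sprintf("c_%s_%02d", id, k)
      add_concept(code, sprintf("%s, presentation %d", gsub("_", " ", id), k))
      # attach to the anchor or a random earlier node in this subtree
      add_edge(code, sample(nodes, 1))
      nodes <- c(nodes, code)
    }
    subtree_nodes[[id]] <- nodes
  }

  # polyhierarchy: extra parents within the same level-2 group
  for (g in unique(bp$level2_parent)) {
    ids <- bp$id[bp$level2_parent == g]
    if (length(ids) < 2) next
    for (j in seq_len(2)) {
      from_id <- sample(ids, 1)
      to_id <- sample(setdiff(ids, from_id), 1)
      child <- sample(setdiff(subtree_nodes[[from_id]],
                              paste0("c_", from_id)), 1)
      add_edge(child, paste0("c_", to_id))
    }
  }

  # exclusion subtrees: chronic/recurrent concepts under three anchors,
  # excluded from the rules with MINUS
  exclusions <- tibble(
    id = c("ecld_copd", "lrti_acute_bronchitis", "urti_sinusitis"),
    excl_root = c("x_copd_chronic", "x_bronchitis_recurrent",
                  "x_sinusitis_chronic"),
    excl_class = c("chronic", "recurrent", "chronic")
  )
  excl_codes <- character()
  excl_class <- character()
  for (i in seq_len(nrow(exclusions))) {
    root <- exclusions$excl_root[[i]]
    add_concept(root, gsub("_", " ", sub("^x_", "", root)))
    add_edge(root, paste0("c_", exclusions$id[[i]]))
    excl_codes <- c(excl_codes, root)
    excl_class <- c(excl_class, exclusions$excl_class[[i]])
    for (k in 1:2) {
      code <- sprintf("%s_%02d", root, k)
      add_concept(code, sprintf("%s, form %d",
                                gsub("_", " ", sub("^x_", "", root)), k))
      add_edge(code, root)
      excl_codes <- c(excl_codes, code)
      excl_class <- c(excl_class, exclusions$excl_class[[i]])
    }
  }

  # standalone decoy branches (never referenced by any rule)
  standalone <- tibble(
    code = c(
      "d_copd_nos", "d_chronic_bronchitis", "d_asthma_chronic",
      "d_pulmonary_fibrosis", "d_emphysema",
      "d_allergic_rhinitis", "d_hay_fever", "d_vasomotor_rhinitis",
      "d_nasal_polyp", "d_chronic_cough",
      "d_recurrent_tonsillitis", "d_recurrent_sinusitis_hx",
      "d_recurrent_chest_infection_hx", "d_post_viral_cough",
      "d_bronchiectasis_stable"
    ),
    class = c(
      rep("chronic", 5),
      rep("non_infective", 5),
      rep("recurrent", 5)
    )
  )
  add_concept("decoy_root", "Non-acute respiratory concepts")
  add_edge("decoy_root", "resp_cond")
  for (i in seq_len(nrow(standalone))) {
    add_concept(standalone$code[[i]],
                gsub("_", " ", sub("^d_", "", standalone$code[[i]])))
    add_edge(standalone$code[[i]], "decoy_root")
  }

  graph <- concept_graph(bind_rows(concepts), bind_rows(edges))

  rules <- vapply(seq_len(nrow(bp)), function(i) {
    id <- bp$id[[i]]
    anchor <- paste0("c_", id)
    j <- match(id, exclusions$id)
    if (!is.na(j)) {
      paste0("<<", anchor, " MINUS <<", exclusions$excl_root[[j]])
    } else if (id == "arinos_unspecified") {
      # OR form for grammar coverage; both operands are in the subtree
      paste0("(", anchor, " OR <", anchor, ")")
    } else {
      paste0("<<", anchor)
    }
  }, character(1))
  hierarchy <- indicator_hierarchy(
    tibble(id = bp$id, level2_parent = bp$level2_parent, ecl = rules)
  )
  codelists <- resolve_codelists(hierarchy, graph)
  new_l1 <- codelist_codes(codelists, "ARI")

  decoy_codes <- c(excl_codes, standalone$code)
  decoy_classes <- tibble(
    code = decoy_codes,
    class = c(excl_class, standalone$class)
  )
  stopifnot(length(intersect(decoy_codes, new_l1)) == 0)

  n_new_only <- max(1L, round(config$p_new_only_code * length(new_l1)))
  new_only <- sort(sample(new_l1, n_new_only))
  old_codelist <- switch(config$old_codelist_style,
    realistic = sort(c(setdiff(new_l1, new_only), decoy_codes)),
    superset = sort(c(new_l1, decoy_codes))
  )

  list(
    graph = graph,
    hierarchy = hierarchy,
    codelists = codelists,
    old_codelist = old_codelist,
    decoy_codes = decoy_codes,
    decoy_classes = decoy_classes,
    new_only_codes = new_only
  )
}

#' Generate synthetic practice registers
#'
#' Patients get a date of birth drawn from the configured age-band
#' distribution (uniform within band) and a Bernoulli risk-group flag.
#' Weekly list sizes are constant at the practice roster size; practices
#' selected for dropout lose a few random register weeks, which makes
#' them fail the denominator reliability rule.
#'
#' @param config A [sim_config()].
#' @return A list with `practices` (weekly register), `patients`
#'   (roster) and `period` (the [surveillance_period()] used).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  period <- surveillance_period(
    config$start_year, config$start_week, config$n_weeks
  )
  season_start <- period$monday[[1]]
  n_pat <- config$n_practices * config$patients_per_practice

  practice_ids <- sprintf("P%03d", seq_len(config$n_practices))
  patients <- tibble(
    patient_id = sprintf("PT%06d", seq_len(n_pat)),
    practice_id = rep(practice_ids, each = config$patients_per_practice)
  )
  band <- sample.int(3, n_pat, replace = TRUE, prob = config$age_dist)
  lo <- c(0, 18, 70)[band]
  hi <- c(17, 69, 95)[band]
  age_days <- floor(runif(n_pat, lo * 365.25, (hi + 1) * 365.25))
  patients$dob <- season_start - age_days
  patients$risk_group <- runif(n_pat) < config$risk_prevalence

  practices <- crossing(
    practice_id = practice_ids,
    select(period, "iso_year", "iso_week")
  )
  practices$list_size <- config$patients_per_practice
  dropout <- practice_ids[
    runif(config$n_practices) < config$practice_dropout_prob
  ]
  if (length(dropout) > 0) {
    drop_rows <- logical(nrow(practices))
    for (p in dropout) {
      idx <- which(practices$practice_id == p)
      k <- sample(1:5, 1)
      drop_rows[sample(idx, min(k, length(idx)))] <- TRUE
    }
    practices <- practices[!drop_rows, , drop = FALSE]
  }
  list(
    practices = select(
      practices, "practice_id", "iso_year", "iso_week", "list_size"
    ),
    patients = patients,
    period = period
  )
}

weekly_group_rate <- function(incidence, week_index) {
  # per-100k weekly episode-onset rate for each level-2 group
  sapply(seq_len(nrow(incidence)), function(i) {
    r <- incidence[i, ]
    r$baseline_per_100k * (
      1 + (r$peak_multiplier - 1) *
        exp(-(week_index - r$peak_week)^2 / (2 * r$peak_width^2))
    )
  })
}

#' Generate a seasonal coded event stream with known ground truth
#'
#' For each patient-week and level-2 group, an episode onset is drawn
#' from the configured seasonal intensity; onsets closer than
#' `min_episode_gap_days` to a previous onset of the same patient are
#' discarded, so true episodes are always separable by the window rule.
#' Each kept episode is assigned a uniformly chosen level-3 indicator of
#' its group and emits its onset coding plus a geometric number of
#' repeat codings at uniform gaps, truncated to the episode window.
#' Miscoded decoy events (chronic / recurrent / non-infective codes,
#' never part of the new codelists) are injected independently per
#' patient-week and then thinned so that no decoy falls within
#' `window_days + 1` days of a true event — decoy episodes are therefore
#' temporally disjoint from true episodes as well as disjoint in code.
#'
#' @param config A [sim_config()].
#' @param terminology Output of [generate_terminology()].
#' @param population Output of [generate_population()].
#' @return A list: `events` (the full stream, true + decoy, sorted),
#'   `truth_episodes` (one row per true episode with onset date and
#'   level-3/2 labels), `truth_decoy_events`, and `truth_decoy_cases`
#'   (decoy events grouped into episodes by the same window rule, i.e.
#'   the false-positive cases a flat legacy codelist would add).
#' @export
generate_events <- function(config, terminology, population) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  period <- population$period
  patients <- population$patients
  n_pat <- nrow(patients)
  inc <- config$incidence
  bp <- level3_blueprint()
  l3_codes <- list()
  for (id in bp$id) {
    l3_codes[[id]] <- codelist_codes(terminology$codelists, id)
  }
  new_only <- terminology$new_only_codes

  # candidate episode onsets, vectorized per (group, week)
  onset_pat <- integer(0)
  onset_date <- as.Date(character(0))
  onset_grp <- character(0)
  for (w in seq_len(nrow(period))) {
    rates <- weekly_group_rate(inc, w)
    for (gi in seq_len(nrow(inc))) {
      p <- rates[[gi]] / 1e5
      if (p <= 0) next
      hit <- which(runif(n_pat) < p)
      if (length(hit) == 0) next
      onset_pat <- c(onset_pat, hit)
      onset_date <- c(
        onset_date,
        period$monday[[w]] + sample(0:6, length(hit), replace = TRUE)
      )
      onset_grp <- c(onset_grp, rep(inc$level2[[gi]], length(hit)))
    }
  }
  cand <- tibble(
    pat = onset_pat, onset = onset_date, level2 = onset_grp
  )
  # deterministic tie-break before the greedy gap filter
  cand <- arrange(cand, .data$pat, .data$onset, .data$level2)

  # greedy thinning: enforce the minimum inter-episode gap per patient
  keep <- logical(nrow(cand))
  if (nrow(cand) > 0) {
    last_pat <- -1L
    last_date <- as.Date("1900-01-01")
    for (i in seq_len(nrow(cand))) {
      if (cand$pat[[i]] != last_pat ||
          as.numeric(cand$onset[[i]] - last_date) >=
            config$min_episode_gap_days) {
        keep[[i]] <- TRUE
        last_pat <- cand$pat[[i]]
        last_date <- cand$onset[[i]]
      }
    }
  }
  episodes <- cand[keep, , drop = FALSE]

  # level-3 assignment within the group, uniformly
  n_epi <- nrow(episodes)
  episodes$level3 <- vapply(episodes$level2, function(g) {
    ids <- bp$id[bp$level2_parent == g]
    ids[[sample.int(length(ids), 1)]]
  }, character(1))

  draw_code <- function(l3) {
    pool <- l3_codes[[l3]]
    pool_new <- intersect(pool, new_only)
    pool_old <- setdiff(pool, new_only)
    if (length(pool_new) > 0 && runif(1) < config$p_new_only_code) {
      pool <- pool_new
    } else if (length(pool_old) > 0) {
      pool <- pool_old
    }
    pool[[sample.int(length(pool), 1)]]
  }

  # emit events per episode
  geom_p <- 1 / (1 + config$repeat_mean_extra)
  ev_pat <- integer(0); ev_date <- as.Date(character(0))
  ev_code <- character(0); ev_epi <- integer(0)
  n_events_per_epi <- integer(n_epi)
  for (i in seq_len(n_epi)) {
    offsets <- 0
    if (config$repeat_mean_extra > 0) {
      n_extra <- rgeom(1, geom_p)
      if (n_extra > 0) {
        gaps <- sample(
          seq(config$repeat_gap_range[[1]], config$repeat_gap_range[[2]]),
          n_extra, replace = TRUE
        )
        offs <- cumsum(gaps)
        offsets <- c(0, offs[offs <= config$window_days])
      }
    }
    codes <- vapply(
      offsets, function(o) draw_code(episodes$level3[[i]]), character(1)
    )
    ev_pat <- c(ev_pat, rep(episodes$pat[[i]], length(offsets)))
    ev_date <- c(ev_date, episodes$onset[[i]] + offsets)
    ev_code <- c(ev_code, codes)
    ev_epi <- c(ev_epi, rep(i, length(offsets)))
    n_events_per_epi[[i]] <- length(offsets)
  }

  # decoy miscodes: independent weekly process, then a temporal guard
  d_pat <- integer(0); d_date <- as.Date(character(0))
  d_code <- character(0)
  if (config$miscode_rate_per_100k > 0) {
    p_mis <- config$miscode_rate_per_100k / 1e5
    for (w in seq_len(nrow(period))) {
      hit <- which(runif(n_pat) < p_mis)
      if (length(hit) == 0) next
      d_pat <- c(d_pat, hit)
      d_date <- c(
        d_date, period$monday[[w]] + sample(0:6, length(hit), replace = TRUE)
      )
      d_code <- c(
        d_code,
        terminology$decoy_codes[
          sample.int(length(terminology$decoy_codes), length(hit),
                     replace = TRUE)
        ]
      )
    }
    if (length(d_pat) > 0) {
      guard <- config$window_days + 1L
      true_by_pat <- split(ev_date, ev_pat)
      ok <- vapply(seq_along(d_pat), function(i) {
        td <- true_by_pat[[as.character(d_pat[[i]])]]
        if (is.null(td)) return(TRUE)
        all(abs(as.numeric(td - d_date[[i]])) >= guard)
      }, logical(1))
      d_pat <- d_pat[ok]; d_date <- d_date[ok]; d_code <- d_code[ok]
    }
  }

  pid <- patients$patient_id
  prid <- patients$practice_id
  events <- bind_rows(
    tibble(
      patient_id = pid[ev_pat], practice_id = prid[ev_pat],
      date = ev_date, code = ev_code
    ),
    tibble(
      patient_id = pid[d_pat], practice_id = prid[d_pat],
      date = d_date, code = d_code
    )
  )
  events <- arrange(events, .data$patient_id, .data$date, .data$code)

  truth_episodes <- tibble(
    patient_id = pid[episodes$pat],
    practice_id = prid[episodes$pat],
    onset_date = episodes$onset,
    level3 = episodes$level3,
    level2 = episodes$level2,
    n_events = n_events_per_epi
  )
  truth_episodes <- arrange(
    truth_episodes, .data$patient_id, .data$onset_date
  )

  truth_decoy_events <- tibble(
    patient_id = pid[d_pat], practice_id = prid[d_pat],
    date = d_date, code = d_code
  )
  truth_decoy_events <- arrange(
    truth_decoy_events, .data$patient_id, .data$date, .data$code
  )
  # decoy events grouped into would-be cases by the same window rule
  truth_decoy_cases <- if (nrow(truth_decoy_events) == 0) {
    tibble(
      patient_id = character(), index_date = as.Date(character()),
      n_events = integer()
    )
  } else {
    dd <- group_by(truth_decoy_events, .data$patient_id)
    dd <- mutate(
      dd, case_seq = deduplicate_to_cases(.data$date, config$window_days)
    )
    summarise(
      group_by(ungroup(dd), .data$patient_id, .data$case_seq),
      index_date = min(.data$date), n_events = n(), .groups = "drop"
    )
  }

  list(
    events = events,
    truth_episodes = truth_episodes,
    truth_decoy_events = truth_decoy_events,
    truth_decoy_cases = truth_decoy_cases
  )
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining [generate_terminology()],
#' [generate_population()] and [generate_events()].
#'
#' @param config A [sim_config()].
#' @return A list combining all three stages' outputs plus the `config`.
#' @export
simulate_surveillance_data <- function(config = sim_config()) {
  term <- generate_terminology(config)
  pop <- generate_population(config)
  ev <- generate_events(config, term, pop)
  c(list(config = config), term, pop, ev)
}

#' Write a simulation to a directory of plain-text files
#'
#' Emits `concepts.csv`, `edges.csv`, `indicators.json`,
#' `old_codelist.csv`, `practices.csv`, `patients.csv`, `events.csv`,
#' `truth_episodes.csv` and `truth_decoy_events.csv`.
#'
#' @param sim Output of [simulate_surveillance_data()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_terminology(sim$graph, p("concepts.csv"), p("edges.csv"))
  write_indicator_definitions(sim$hierarchy, p("indicators.json"))
  readr::write_csv(tibble(code = sim$old_codelist), p("old_codelist.csv"))
  readr::write_csv(sim$practices, p("practices.csv"))
  readr::write_csv(sim$patients, p("patients.csv"))
  write_events(sim$events, p("events.csv"))
  readr::write_csv(sim$truth_episodes, p("truth_episodes.csv"))
  readr::write_csv(sim$truth_decoy_events, p("truth_decoy_events.csv"))
  invisible(vapply(
    c("concepts.csv", "edges.csv", "indicators.json", "old_codelist.csv",
      "practices.csv", "patients.csv", "events.csv", "truth_episodes.csv",
      "truth_decoy_events.csv"),
    p, character(1)
  ))
}
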