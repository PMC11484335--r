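#' The default level-2 indicator groups, in surveillance priority order
#'
#' ILI (influenza-like illness), ECLD (exacerbation of chronic lung
#' disease), LRTI and URTI (lower/upper respiratory tract infection), and
#' the residual ARI-NOS group. The order doubles as the default
#' case-classification priority: ILI is kept as its own group for
#' influenza surveillance primacy, and ARI-NOS, being the "no specific
#' information" residual, ranks last.
#' @export
ARI_LEVEL2_GROUPS <- c("ILI", "ECLD", "LRTI", "URTI", "ARI-NOS")

#' Define a three-level indicator hierarchy
#'
#' The ARI clinical model has a single level-1 umbrella indicator, a small
#' set of level-2 groups, and level-3 indicators each bound to an ECL rule
#' that selects its concept codes from a terminology. Level-2 and level-1
#' codelists are not authored directly: they are inferred as unions of
#' their level-3 children (see [resolve_codelists()]).
#'
#' @param level3 A data frame with columns `id`, `level2_parent` and `ecl`
#'   (rule text in the [parse_ecl()] subset).
#' @param level2 Character vector of level-2 group ids, in priority order.
#' @param level1 The level-1 indicator id.
#' @return An object of class `indicator_hierarchy`.
#' @export
indicator_hierarchy <- function(level3,
                                level2 = ARI_LEVEL2_GROUPS,
                                level1 = "ARI") {
  level3 <- as_tibble(level3)
  needed <- c("id", "level2_parent", "ecl")
  if (!all(needed %in% names(level3))) {
    abort("`level3` must have columns id, level2_parent, ecl")
  }
  level3 <- select(level3, all_of(needed))
  if (anyDuplicated(level3$id)) {
    abort("level-3 indicator ids must be unique")
  }
  if (level1 %in% c(level2, level3$id) || any(level2 %in% level3$id)) {
    abort("indicator ids must be distinct across levels")
  }
  bad_parent <- setdiff(level3$level2_parent, level2)
  if (length(bad_parent) > 0) {
    abort(paste0(
      "level-3 indicators reference unknown level-2 groups: ",
      paste(unique(bad_parent), collapse = ", ")
    ))
  }
  childless <- setdiff(level2, level3$level2_parent)
  if (length(childless) > 0) {
    abort(paste0(
      "every level-2 group needs at least one level-3 child; missing: ",
      paste(childless, collapse = ", ")
    ))
  }
  # rules must at least parse at definition time
  for (i in seq_len(nrow(level3))) {
    tryCatch(parse_ecl(level3$ecl[[i]]), error = function(e) {
      abort(paste0(
        "ECL rule for indicator '", level3$id[[i]], "' does not parse: ",
        conditionMessage(e)
      ))
    })
  }
  structure(
    list(level1 = level1, level2 = level2, level3 = level3),
    class = "indicator_hierarchy"
  )
}

#' @export
print.indicator_hierarchy <- function(x, ...) {
  counts <- table(factor(x$level3$level2_parent, levels = x$level2))
  cat("<indicator_hierarchy> level 1: ", x$level1, "\n", sep = "")
  cat("  level 2 (priority order): ",
      paste0(x$level2, " (", as.integer(counts), ")", collapse = ", "),
      "\n", sep = "")
  cat("  level 3: ", nrow(x$level3), " indicators\n", sep = "")
  invisible(x)
}

#' Read / write indicator definitions as JSON
#'
#' The on-disk form is a JSON object with a `level1` id, an ordered
#' `level2` array, and a `level3` array of `{id, level2_parent, ecl}`
#' records. The schema is validated on load.
#'
#' @param path JSON file path.
#' @return [read_indicator_definitions()] returns an
#'   [indicator_hierarchy()]; the writer returns the path, invisibly.
#' @export
read_indicator_definitions <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("level1", "level2", "level3") %in% names(x))) {
    abort("indicator definition JSON must have keys level1, level2, level3")
  }
  indicator_hierarchy(
    level3 = as_tibble(x$level3),
    level2 = as.character(x$level2),
    level1 = as.character(x$level1)
  )
}

#' @rdname read_indicator_definitions
#' @param hierarchy An [indicator_hierarchy()].
#' @export
write_indicator_definitions <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "indicator_hierarchy"))
  jsonlite::write_json(
    list(
      level1 = hierarchy$level1,
      level2 = hierarchy$level2,
      level3 = hierarchy$level3
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Resolve an indicator hierarchy to concrete codelists
#'
#' Evaluates every level-3 ECL rule against the terminology, then composes
#' level-2 codelists as the union of their level-3 children and the
#' level-1 codelist as the union of all level-3 codelists. A code may
#' legitimately appear in several level-3 codelists (the terminology is
#' polyhierarchical); disambiguation happens at case classification, not
#' here.
#'
#' @param hierarchy An [indicator_hierarchy()].
#' @param graph A [concept_graph()].
#' @return A `codelist_set`: a tibble with one row per indicator
#'   (`indicator_id`, `level`, `level2_parent`, `n_codes`, and a `codes`
#'   list-column of sorted code vectors), carrying the hierarchy as an
#'   attribute.
#' @export
resolve_codelists <- function(hierarchy, graph) {
  stopifnot(inherits(hierarchy, "indicator_hierarchy"))
  stopifnot(inherits(graph, "concept_graph"))
  l3 <- hierarchy$level3
  l3_codes <- vector("list", nrow(l3))
  for (i in seq_len(nrow(l3))) {
    l3_codes[[i]] <- tryCatch(
      evaluate_ecl(graph, l3$ecl[[i]]),
      error = function(e) {
        abort(paste0(
          "failed to resolve indicator '", l3$id[[i]], "': ",
          conditionMessage(e)
        ))
      }
    )
  }
  names(l3_codes) <- l3$id
  l2_codes <- lapply(hierarchy$level2, function(g) {
    sort(unique(unlist(l3_codes[l3$id[l3$level2_parent == g]])))
  })
  names(l2_codes) <- hierarchy$level2
  l1_codes <- sort(unique(unlist(l3_codes)))

  out <- bind_rows(
    tibble(
      indicator_id = hierarchy$level1, level = 1L,
      level2_parent = NA_character_, codes = list(l1_codes)
    ),
    tibble(
      indicator_id = hierarchy$level2, level = 2L,
      level2_parent = NA_character_, codes = unname(l2_codes)
    ),
    tibble(
      indicator_id = l3$id, level = 3L,
      level2_parent = l3$level2_parent, codes = unname(l3_codes)
    )
  )
  out$n_codes <- unname(lengths(out$codes))
  out <- select(
    out, "indicator_id", "level", "level2_parent", "n_codes", "codes"
  )
  structure(out, class = c("codelist_set", class(out)), hierarchy = hierarchy)
}

#' Extract one codelist from a resolved set
#'
#' @param codelists A `codelist_set` from [resolve_codelists()].
#' @param indicator_id Indicator id at any level.
#' @return Character vector of codes.
#' @export
codelist_codes <- function(codelists, indicator_id) {
  stopifnot(inherits(codelists, "codelist_set"))
  i <- match(indicator_id, codelists$indicator_id)
  if (is.na(i)) abort(paste0("unknown indicator: ", indicator_id))
  codelists$codes[[i]]
}

#' Export a resolved codelist set as a flat CSV
#'
#' One row per (indicator, code) with the concept label looked up from the
#' terminology: `indicator_id,level,code,label`.
#'
#' @inheritParams codelist_codes
#' @param graph The [concept_graph()] the set was resolved against.
#' @param path Output CSV path.
#' @return The exported tibble, invisibly.
#' @export
export_codelists_csv <- function(codelists, graph, path) {
  stopifnot(inherits(codelists, "codelist_set"))
  flat <- tidyr::unnest(
    select(as_tibble(codelists), "indicator_id", "level", "codes"),
    cols = "codes"
  )
  flat <- rename(flat, code = "codes")
  flat <- left_join(flat, graph$concepts, by = "code")
  readr::write_csv(flat, path)
  invisible(flat)
}

#' Set analysis of two codelists
#'
#' The codelist-validation comparison: sizes, intersection, codes unique
#' to each side, and the signed percentage change in size from `a` to `b`
#' (one decimal, half-up). Used to compare a legacy flat codelist against
#' a newly resolved one.
#'
#' @param a,b Character vectors of codes (duplicates ignored), or single
#'   codelist rows' code vectors.
#' @return A list of class `codelist_comparison` with elements `size_a`,
#'   `size_b`, `intersection`, `only_a`, `only_b`, `percent_change`
#'   (`NA` with a warning when `a` is empty).
#' @examples
#' cmp <- compare_codelists(c("x", "y", "z"), c("y", "z", "w"))
#' cmp$percent_change
#' @export
compare_codelists <- function(a, b) {
  a <- sort(unique(as.character(a)))
  b <- sort(unique(as.character(b)))
  inter <- intersect(a, b)
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  pct <- if (length(a) == 0) {
    if (length(b) > 0) {
      warn("percent change undefined: codelist `a` is empty")
    }
    NA_real_
  } else {
    round_half_up(100 * (length(b) - length(a)) / length(a), 1)
  }
  structure(
    list(
      size_a = length(a), size_b = length(b),
      intersection = inter, only_a = only_a, only_b = only_b,
      percent_change = pct
    ),
    class = "codelist_comparison"
  )
}

#' @export
print.codelist_comparison <- function(x, ...) {
  cat("<codelist_comparison>\n")
  cat("  size a: ", x$size_a, "   size b: ", x$size_b, "\n", sep = "")
  cat("  in both: ", length(x$intersection),
      "   only a: ", length(x$only_a),
      "   only b: ", length(x$only_b), "\n", sep = "")
  cat("  percent change a -> b: ",
      ifelse(is.na(x$percent_change), "undefined", x$percent_change),
      "\n", sep = "")
  invisible(x)
}

#' How many codes account for a share of recorded events?
#'
#' Codes are ranked by descending event count (ties broken by code, so the
#' result is deterministic); `k` is the smallest number of top codes whose
#' cumulative share of all events reaches `threshold`, and
#' `covered_fraction` is that prefix's actual share. This is the
#' code-frequency concentration analysis: in coded primary-care data a
#' small number of codes typically records the vast majority of events.
#'
#' @param event_code_counts Named non-negative numeric vector: events per
#'   code.
#' @param threshold Target cumulative share, in (0, 1].
#' @return A list with `k` and `covered_fraction`.
#' @examples
#' code_frequency_coverage(c(a = 50, b = 30, c = 20), 0.8)
#' @export
code_frequency_coverage <- function(event_code_counts, threshold) {
  if (is.null(names(event_code_counts)) ||
      any(!nzchar(names(event_code_counts)))) {
    abort("`event_code_counts` must be a named vector")
  }
  if (any(event_code_counts < 0) || anyNA(event_code_counts)) {
    abort("event counts must be non-negative")
  }
  if (length(threshold) != 1 || threshold <= 0 || threshold > 1) {
    abort("`threshold` must be in (0, 1]")
  }
  total <- sum(event_code_counts)
  if (total == 0) {
    abort("all event counts are zero; coverage is undefined")
  }
  ord <- order(-event_code_counts, names(event_code_counts))
  shares <- cumsum(event_code_counts[ord]) / total
  k <- which(shares >= threshold)[1]
  list(k = as.integer(k), covered_fraction = unname(shares[[k]]))
}
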