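# Small hand-built fixtures shared across tests.

# A -> (B, C); B -> D; C -> D (D has two parents); C -> E
tiny_graph <- function() {
  concept_graph(
    data.frame(
      code = c("A", "B", "C", "D", "E"),
      label = c("root", "left", "right", "shared leaf", "leaf")
    ),
    data.frame(
      child = c("B", "C", "D", "D", "E"),
      parent = c("A", "A", "B", "C", "C")
    )
  )
}

# minimal complete hierarchy: one level-3 indicator per level-2 group,
# rules select single concepts from a flat five-concept terminology
singleton_hierarchy <- function() {
  groups <- ARI_LEVEL2_GROUPS
  ids <- paste0("ind_", tolower(gsub("-", "", groups)))
  list(
    graph = concept_graph(
      data.frame(code = ids, label = ids),
      data.frame(child = character(), parent = character())
    ),
    hierarchy = indicator_hierarchy(
      data.frame(id = ids, level2_parent = groups, ecl = ids)
    )
  )
}

# hierarchy over an explicit terminology where one code ("shared") belongs
# to level-3 indicators under two different level-2 groups
two_group_overlap <- function(groups = c("ILI", "URTI")) {
  ids <- paste0("ind_", tolower(gsub("-", "", ARI_LEVEL2_GROUPS)))
  names(ids) <- ARI_LEVEL2_GROUPS
  concepts <- data.frame(
    code = c(ids, "shared"),
    label = c(ids, "shared presentation")
  )
  edges <- data.frame(
    child = c("shared", "shared"),
    parent = unname(ids[groups])
  )
  graph <- concept_graph(concepts, edges)
  hierarchy <- indicator_hierarchy(
    data.frame(
      id = unname(ids),
      level2_parent = ARI_LEVEL2_GROUPS,
      ecl = paste0("<<", unname(ids))
    )
  )
  list(graph = graph, hierarchy = hierarchy,
       codelists = resolve_codelists(hierarchy, graph))
}

make_events <- function(patient_id, dates, codes,
                        practice_id = "P001") {
  tibble::tibble(
    patient_id = patient_id,
    practice_id = practice_id,
    date = as.Date(dates),
    code = codes
  )
}

# single-practice register covering a period, constant list size
flat_register <- function(period, list_size, practice_id = "P001",
                          n_patients = 0) {
  practices <- tibble::tibble(
    practice_id = practice_id,
    iso_year = period$iso_year,
    iso_week = period$iso_week,
    list_size = as.integer(list_size)
  )
  patients <- if (n_patients > 0) {
    tibble::tibble(
      patient_id = sprintf("PT%04d", seq_len(n_patients)),
      practice_id = practice_id,
      dob = as.Date("1980-06-15"),
      risk_group = FALSE
    )
  } else {
    tibble::tibble(
      patient_id = character(), practice_id = character(),
      dob = as.Date(character()), risk_group = logical()
    )
  }
  list(practices = practices, patients = patients)
}
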