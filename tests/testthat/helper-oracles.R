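# Independent oracles: deliberately naive reimplementations used to check
# the package's optimised code paths. They share no code with R/.

# descendants by repeated edge expansion to a fixed point
oracle_descendants <- function(concepts, edges, code, include_self = TRUE) {
  found <- code
  repeat {
    more <- edges$child[edges$parent %in% found]
    new <- setdiff(more, found)
    if (length(new) == 0) break
    found <- c(found, new)
  }
  if (!include_self) found <- setdiff(found, code)
  sort(unique(found))
}

# set-algebra evaluation of an ecl_expr AST against the oracle reachability
oracle_evaluate <- function(concepts, edges, expr) {
  ev <- function(node) {
    switch(node$kind,
      self = node$code,
      desc = oracle_descendants(concepts, edges, node$code, FALSE),
      desc_or_self = oracle_descendants(concepts, edges, node$code, TRUE),
      and = intersect(ev(node$lhs), ev(node$rhs)),
      or = union(ev(node$lhs), ev(node$rhs)),
      minus = setdiff(ev(node$lhs), ev(node$rhs))
    )
  }
  sort(unique(ev(expr)))
}

# straight-line scan grouping dates into episodes
oracle_dedup <- function(dates, window, mode = "rolling") {
  n <- length(dates)
  if (n == 0) return(integer(0))
  ids <- integer(n)
  ids[1] <- 1L
  anchor <- dates[1] # previous event (rolling) or episode index (fixed)
  for (i in seq_len(n)[-1]) {
    gap <- as.numeric(dates[i] - anchor)
    if (gap > window) {
      ids[i] <- ids[i - 1] + 1L
      anchor <- dates[i]
    } else {
      ids[i] <- ids[i - 1]
      if (mode == "rolling") anchor <- dates[i]
    }
  }
  ids
}

# random DAG: edges always point from a higher-numbered child to a
# lower-numbered parent, so acyclicity holds by construction
random_dag <- function(n_nodes, n_edges) {
  codes <- sprintf("n%02d", seq_len(n_nodes))
  concepts <- data.frame(code = codes, label = codes)
  pairs <- t(utils::combn(n_nodes, 2)) # col1 < col2
  take <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  edges <- data.frame(
    child = codes[pairs[take, 2]],
    parent = codes[pairs[take, 1]]
  )
  list(concepts = concepts, edges = edges)
}

# random ECL string over the graph's codes, bounded depth
random_ecl <- function(codes, depth) {
  if (depth == 0 || runif(1) < 0.4) {
    op <- sample(c("", "<", "<<"), 1)
    return(paste0(op, sample(codes, 1)))
  }
  kind <- sample(c("AND", "OR", "MINUS"), 1)
  paste0(
    "(", random_ecl(codes, depth - 1), " ", kind, " ",
    random_ecl(codes, depth - 1), ")"
  )
}

# naive end-to-end case detection: membership filter, per-patient scan,
# priority classification by explicit search
oracle_detect <- function(events, codelists, window = 28, mode = "rolling") {
  hier <- attr(codelists, "hierarchy")
  l3 <- codelists[codelists$level == 3L, ]
  l1_codes <- codelists$codes[[match(hier$level1, codelists$indicator_id)]]
  priority <- hier$level2

  ev <- events[events$code %in% l1_codes, ]
  # a code's sort rank: best level-2 rank over its level-3 memberships
  code_rank <- sapply(unique(ev$code), function(cd) {
    ranks <- c()
    for (i in seq_len(nrow(l3))) {
      if (cd %in% l3$codes[[i]]) {
        ranks <- c(ranks, match(l3$level2_parent[[i]], priority))
      }
    }
    min(ranks)
  })
  ev$rank <- code_rank[ev$code]

  out <- NULL
  for (pid in sort(unique(ev$patient_id))) {
    pe <- ev[ev$patient_id == pid, ]
    pe <- pe[order(pe$date, pe$rank, pe$code), ]
    ids <- oracle_dedup(pe$date, window, mode)
    for (cid in unique(ids)) {
      ce <- pe[ids == cid, ]
      # all (event, level3) matches
      best <- NULL
      for (j in seq_len(nrow(ce))) {
        for (i in seq_len(nrow(l3))) {
          if (ce$code[[j]] %in% l3$codes[[i]]) {
            cand <- list(
              rank = match(l3$level2_parent[[i]], priority),
              date = ce$date[[j]],
              level3 = l3$indicator_id[[i]],
              level2 = l3$level2_parent[[i]]
            )
            if (is.null(best) ||
                cand$rank < best$rank ||
                (cand$rank == best$rank && cand$date < best$date) ||
                (cand$rank == best$rank && cand$date == best$date &&
                 cand$level3 < best$level3)) {
              best <- cand
            }
          }
        }
      }
      out <- rbind(out, data.frame(
        patient_id = pid,
        practice_id = ce$practice_id[[1]],
        index_date = min(ce$date),
        level3 = best$level3,
        level2 = best$level2,
        n_events = nrow(ce),
        stringsAsFactors = FALSE
      ))
    }
  }
  out <- out[order(out$patient_id, out$index_date), ]
  rownames(out) <- NULL
  out
}

# naive weekly counts: double loop over weeks and indicators
oracle_weekly_counts <- function(cases, period, indicators, level1) {
  res <- NULL
  for (w in seq_len(nrow(period))) {
    wk_start <- period$monday[[w]]
    wk_end <- wk_start + 6
    in_week <- cases$index_date >= wk_start & cases$index_date <= wk_end
    for (ind in indicators) {
      n <- if (ind == level1) {
        sum(in_week)
      } else {
        sum(in_week & !is.na(cases$level2) & cases$level2 == ind)
      }
      res <- rbind(res, data.frame(
        iso_year = period$iso_year[[w]], iso_week = period$iso_week[[w]],
        indicator = ind, cases = n
      ))
    }
  }
  res
}
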