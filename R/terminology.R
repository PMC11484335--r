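#' Build a polyhierarchical concept graph
#'
#' A concept graph is the in-memory form of a SNOMED-like clinical
#' terminology: a set of coded concepts plus directed is-a edges from child
#' to parent. Concepts may have multiple parents (polyhierarchy); the is-a
#' relation must be acyclic. Reachability (used by descendant queries and
#' ECL evaluation) is computed once at construction and cached, so queries
#' are cheap; use [graph_add_edges()] / [graph_add_concepts()] to derive a
#' modified graph with a fresh cache.
#'
#' @param concepts A data frame with columns `code` (unique, non-empty
#'   character) and `label`.
#' @param edges A data frame with columns `child` and `parent`, both
#'   referring to codes present in `concepts`. May have zero rows.
#' @return An object of class `concept_graph`.
#' @examples
#' g <- concept_graph(
#'   tibble::tibble(code = c("A", "B"), label = c("root", "leaf")),
#'   tibble::tibble(child = "B", parent = "A")
#' )
#' transitive_descendants(g, "A")
#' @export
concept_graph <- function(concepts, edges = NULL) {
  concepts <- as_tibble(concepts)
  if (!all(c("code", "label") %in% names(concepts))) {
    abort("`concepts` must have columns `code` and `label`")
  }
  concepts$code <- as.character(concepts$code)
  concepts$label <- as.character(concepts$label)
  if (any(!nzchar(concepts$code)) || anyNA(concepts$code)) {
    abort("concept codes must be non-empty")
  }
  if (anyDuplicated(concepts$code)) {
    dup <- unique(concepts$code[duplicated(concepts$code)])
    abort(paste0("duplicate concept codes: ", paste(dup, collapse = ", ")))
  }
  if (is.null(edges)) {
    edges <- tibble(child = character(), parent = character())
  }
  edges <- as_tibble(edges)
  if (!all(c("child", "parent") %in% names(edges))) {
    abort("`edges` must have columns `child` and `parent`")
  }
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  edges <- distinct(edges)
  missing <- setdiff(c(edges$child, edges$parent), concepts$code)
  if (length(missing) > 0) {
    abort(paste0(
      "edge endpoints not present in concepts: ",
      paste(sort(missing), collapse = ", ")
    ))
  }
  if (any(edges$child == edges$parent)) {
    abort("self-loop is-a edges are not allowed")
  }
  # child -> parent arrows; descendants of c are vertices that can reach c
  ig <- igraph::graph_from_data_frame(
    edges,
    directed = TRUE,
    vertices = concepts$code
  )
  if (!igraph::is_dag(ig)) {
    abort("is-a relation contains a cycle; a concept may not be its own ancestor")
  }
  structure(
    list(concepts = concepts, edges = edges, igraph = ig),
    class = "concept_graph"
  )
}

#' @export
print.concept_graph <- function(x, ...) {
  cat(
    "<concept_graph> ", nrow(x$concepts), " concepts, ",
    nrow(x$edges), " is-a edges\n",
    sep = ""
  )
  invisible(x)
}

#' Codes present in a concept graph
#' @param graph A [concept_graph()].
#' @return Character vector of concept codes.
#' @export
concept_codes <- function(graph) {
  stopifnot(inherits(graph, "concept_graph"))
  graph$concepts$code
}

#' Derive a graph with additional edges or concepts
#'
#' The reachability cache belongs to a single immutable graph; these
#' helpers return a new validated graph (with a fresh cache) rather than
#' mutating in place, so stale descendant sets can never be observed.
#'
#' @param graph A [concept_graph()].
#' @param edges,concepts Rows to append, in the constructor's format.
#' @return A new `concept_graph`.
#' @export
graph_add_edges <- function(graph, edges) {
  stopifnot(inherits(graph, "concept_graph"))
  concept_graph(graph$concepts, bind_rows(graph$edges, as_tibble(edges)))
}

#' @rdname graph_add_edges
#' @export
graph_add_concepts <- function(graph, concepts) {
  stopifnot(inherits(graph, "concept_graph"))
  concept_graph(bind_rows(graph$concepts, as_tibble(concepts)), graph$edges)
}

check_known_code <- function(graph, code) {
  if (length(code) != 1 || is.na(code) || !nzchar(code)) {
    abort("`code` must be a single non-empty string")
  }
  if (!code %in% graph$concepts$code) {
    abort(paste0("unknown concept code: ", code))
  }
}

#' Transitive descendants of a concept
#'
#' All concepts whose ancestor set (following is-a edges) contains `code`.
#' In ECL terms this realises `<code` (`include_self = FALSE`) and `<<code`
#' (`include_self = TRUE`).
#'
#' @param graph A [concept_graph()].
#' @param code A single concept code present in the graph.
#' @param include_self Include `code` itself in the result?
#' @return Character vector of codes (unordered set semantics; returned
#'   sorted for reproducibility).
#' @export
transitive_descendants <- function(graph, code, include_self = TRUE) {
  stopifnot(inherits(graph, "concept_graph"))
  check_known_code(graph, code)
  reach <- igraph::subcomponent(graph$igraph, code, mode = "in")
  out <- igraph::V(graph$igraph)$name[as.integer(reach)]
  if (!include_self) out <- setdiff(out, code)
  sort(unique(out))
}

#' Transitive ancestors of a concept
#'
#' @inheritParams transitive_descendants
#' @return Character vector of codes.
#' @export
transitive_ancestors <- function(graph, code, include_self = FALSE) {
  stopifnot(inherits(graph, "concept_graph"))
  check_known_code(graph, code)
  reach <- igraph::subcomponent(graph$igraph, code, mode = "out")
  out <- igraph::V(graph$igraph)$name[as.integer(reach)]
  if (!include_self) out <- setdiff(out, code)
  sort(unique(out))
}

# ---------------------------------------------------------------------------
# ECL subset parser
#
# Grammar (a small core of SNOMED CT's Expression Constraint Language):
#   expr    := term (("AND" | "OR" | "MINUS") term)*      left-associative,
#                                                         equal precedence
#   term    := "<<" CODE | "<" CODE | CODE | "(" expr ")"
#   CODE    := [^()<\s]+  (an opaque code token)
#
# Unary constraints bind tightest. AND/OR/MINUS associate left-to-right at
# equal precedence; use parentheses for anything non-trivial. The canonical
# printer (format()) fully parenthesizes, and parse_ecl() round-trips it.
# ---------------------------------------------------------------------------

ecl_node <- function(kind, code = NULL, lhs = NULL, rhs = NULL) {
  structure(
    list(kind = kind, code = code, lhs = lhs, rhs = rhs),
    class = "ecl_expr"
  )
}

tokenize_ecl <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch == "(") {
      push("lparen", "(", i); i <- i + 1L
    } else if (ch == ")") {
      push("rparen", ")", i); i <- i + 1L
    } else if (ch == "<") {
      if (i < n && substr(text, i + 1L, i + 1L) == "<") {
        push("desc_or_self", "<<", i); i <- i + 2L
      } else {
        push("desc", "<", i); i <- i + 1L
      }
    } else {
      j <- i
      while (j <= n && !grepl("^[\\s()<]$", substr(text, j, j), perl = TRUE)) {
        j <- j + 1L
      }
      word <- substr(text, i, j - 1L)
      if (word %in% c("AND", "OR", "MINUS")) {
        push("binop", word, i)
      } else {
        push("code", word, i)
      }
      i <- j
    }
  }
  tokens
}

#' Parse an ECL-subset expression
#'
#' Supports the descendant/exclusion core of SNOMED CT's Expression
#' Constraint Language: `<<C` (descendant-or-self), `<C` (descendant), bare
#' `C` (self), infix `AND`, `OR`, `MINUS` and parentheses. Binary operators
#' share one precedence level and associate left-to-right; unary
#' constraints bind tightest. [format()][format.ecl_expr] prints the
#' canonical fully-parenthesized form, which re-parses to the same tree.
#'
#' @param text A single ECL string, e.g. `"(<<A OR <<B) MINUS <C"`.
#' @return An abstract syntax tree of class `ecl_expr` with node kinds
#'   `self`, `desc`, `desc_or_self`, `and`, `or`, `minus`.
#' @examples
#' format(parse_ecl("(<<A OR <<B) MINUS <C"))
#' @export
parse_ecl <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    abort("`text` must be a single string")
  }
  tokens <- tokenize_ecl(text)
  if (length(tokens) == 0) {
    abort("ECL parse error: empty expression")
  }
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() {
    tok <- tokens[[pos]]
    pos <<- pos + 1L
    tok
  }
  fail <- function(msg, tok = peek()) {
    at <- if (is.null(tok)) paste0("end of input (position ", nchar(text) + 1L, ")")
          else paste0("position ", tok$pos, " near '", tok$value, "'")
    abort(paste0("ECL parse error at ", at, ": ", msg))
  }

  parse_term <- function() {
    tok <- peek()
    if (is.null(tok)) fail("expected a constraint")
    if (tok$type %in% c("desc", "desc_or_self")) {
      advance()
      code_tok <- peek()
      if (is.null(code_tok) || code_tok$type != "code") {
        fail(paste0("expected a concept code after '", tok$value, "'"), code_tok)
      }
      advance()
      kind <- if (tok$type == "desc") "desc" else "desc_or_self"
      return(ecl_node(kind, code = code_tok$value))
    }
    if (tok$type == "code") {
      advance()
      return(ecl_node("self", code = tok$value))
    }
    if (tok$type == "lparen") {
      advance()
      inner <- parse_expr()
      close <- peek()
      if (is.null(close) || close$type != "rparen") {
        fail("expected ')'", close)
      }
      advance()
      return(inner)
    }
    fail("expected a constraint")
  }

  parse_expr <- function() {
    lhs <- parse_term()
    repeat {
      tok <- peek()
      if (is.null(tok) || tok$type != "binop") break
      advance()
      rhs <- parse_term()
      lhs <- ecl_node(tolower(tok$value), lhs = lhs, rhs = rhs)
    }
    lhs
  }

  out <- parse_expr()
  leftover <- peek()
  if (!is.null(leftover)) {
    fail("unexpected trailing input", leftover)
  }
  out
}

#' Canonical printer for ECL expressions
#'
#' Fully parenthesizes every binary operation, so precedence is explicit
#' and `parse_ecl(format(x))` reproduces `x`.
#'
#' @param x An `ecl_expr`.
#' @param ... Unused.
#' @return A single string.
#' @export
format.ecl_expr <- function(x, ...) {
  switch(x$kind,
    self = x$code,
    desc = paste0("<", x$code),
    desc_or_self = paste0("<<", x$code),
    and = paste0("(", format(x$lhs), " AND ", format(x$rhs), ")"),
    or = paste0("(", format(x$lhs), " OR ", format(x$rhs), ")"),
    minus = paste0("(", format(x$lhs), " MINUS ", format(x$rhs), ")"),
    abort(paste0("unknown ECL node kind: ", x$kind))
  )
}

#' @export
print.ecl_expr <- function(x, ...) {
  cat("<ecl_expr> ", format(x), "\n", sep = "")
  invisible(x)
}

ecl_leaf_codes <- function(expr) {
  if (!is.null(expr$code)) return(expr$code)
  c(ecl_leaf_codes(expr$lhs), ecl_leaf_codes(expr$rhs))
}

#' Evaluate an ECL expression against a concept graph
#'
#' Resolves the expression to the concrete set of concept codes it selects:
#' `C` selects `{C}`, `<<C` the descendants of `C` including itself, `<C`
#' the strict descendants; `AND`, `OR` and `MINUS` are set intersection,
#' union and difference.
#'
#' @param graph A [concept_graph()].
#' @param expr An `ecl_expr` from [parse_ecl()], or an ECL string.
#' @return Sorted character vector of selected codes (possibly empty).
#' @examples
#' g <- concept_graph(
#'   tibble::tibble(code = c("A", "B"), label = c("a", "b")),
#'   tibble::tibble(child = "B", parent = "A")
#' )
#' evaluate_ecl(g, "<<A")
#' @export
evaluate_ecl <- function(graph, expr) {
  stopifnot(inherits(graph, "concept_graph"))
  if (is.character(expr)) expr <- parse_ecl(expr)
  stopifnot(inherits(expr, "ecl_expr"))
  unknown <- setdiff(ecl_leaf_codes(expr), graph$concepts$code)
  if (length(unknown) > 0) {
    abort(paste0(
      "ECL expression references unknown codes: ",
      paste(sort(unique(unknown)), collapse = ", ")
    ))
  }
  eval_node <- function(node) {
    switch(node$kind,
      self = node$code,
      desc = transitive_descendants(graph, node$code, include_self = FALSE),
      desc_or_self = transitive_descendants(graph, node$code, include_self = TRUE),
      and = intersect(eval_node(node$lhs), eval_node(node$rhs)),
      or = union(eval_node(node$lhs), eval_node(node$rhs)),
      minus = setdiff(eval_node(node$lhs), eval_node(node$rhs)),
      abort(paste0("unknown ECL node kind: ", node$kind))
    )
  }
  sort(unique(eval_node(expr)))
}

#' Read a terminology from CSV files
#'
#' @param concepts_csv Path to a CSV with header `code,label`.
#' @param edges_csv Path to a CSV with header `child_code,parent_code`
#'   (or `child,parent`).
#' @return A [concept_graph()].
#' @export
read_terminology <- function(concepts_csv, edges_csv) {
  concepts <- readr::read_csv(
    concepts_csv,
    col_types = readr::cols(.default = readr::col_character())
  )
  edges <- readr::read_csv(
    edges_csv,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (all(c("child_code", "parent_code") %in% names(edges))) {
    edges <- rename(edges, child = "child_code", parent = "parent_code")
  }
  concept_graph(concepts, edges)
}

#' Write a terminology to CSV files
#'
#' @param graph A [concept_graph()].
#' @param concepts_csv,edges_csv Output paths.
#' @return Invisibly, the paths written.
#' @export
write_terminology <- function(graph, concepts_csv, edges_csv) {
  stopifnot(inherits(graph, "concept_graph"))
  readr::write_csv(graph$concepts, concepts_csv)
  readr::write_csv(
    rename(graph$edges, child_code = "child", parent_code = "parent"),
    edges_csv
  )
  invisible(c(concepts_csv, edges_csv))
}
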