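# KEGG module definition grammar: parsing, serialization, completion-set
# enumeration, completeness evaluation and gap-filling.
#
# Grammar (loosest to tightest binding):
#   space  -- ordered steps at top level; conjunction within parentheses
#   ","    -- alternatives (disjunction)
#   "+"    -- protein-complex conjunction; "-" prefixes an optional component
#   "--"   -- a wildcard step, always counted as satisfied
#   "( )"  -- grouping

#' Parse a KEGG-style module definition string
#'
#' Parses a module DEFINITION string into an abstract syntax tree of ordered
#' steps. Each step is a nested expression over KO identifiers built from
#' alternatives (`,`), conjunction (space, inside parentheses), protein
#' complexes (`+`), optional components (`-`) and wildcard steps (`--`).
#'
#' @param module_id Module identifier, e.g. `"M00001"`.
#' @param definition Definition string, e.g. `"K00001 (K00002,K00003)"`.
#' @return An object of class `module_ast` with elements `module_id`,
#'   `definition` (the input string) and `steps`, a list of expression nodes.
#'   Node types: `atom`, `any` (alternatives), `all` (conjunction),
#'   `complex`, `optional`, `wildcard`.
#' @examples
#' ast <- parse_module_definition("M1", "K00001 (K00002,K00003)")
#' length(ast$steps)
#' @seealso [evaluate_module()], [enumerate_completion_sets()], [gap_fill()]
#' @export
parse_module_definition <- function(module_id, definition) {
  if (!is.character(definition) || length(definition) != 1L ||
      is.na(definition) || !nzchar(trimws(definition))) {
    stop("definition must be a non-empty string", call. = FALSE)
  }
  toks <- tokenize_definition(definition)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L
  # top level: space separates ordered steps; a parenthesized group stays
  # one step even when it contains spaces
  steps <- list(parse_comma_level(state))
  while (peek_type(state) == "space") {
    advance(state)
    steps[[length(steps) + 1L]] <- parse_comma_level(state)
  }
  if (state$pos <= length(state$toks$type)) {
    if (peek_type(state) == "rparen") {
      stop(sprintf("syntax error at position %d: unbalanced parenthesis",
                   state$toks$at[state$pos]), call. = FALSE)
    }
    parse_fail(state, "unexpected token")
  }
  structure(
    list(module_id = as.character(module_id),
         definition = definition,
         steps = steps),
    class = "module_ast"
  )
}

# Tokenizer: returns parallel vectors of token type, value and 1-based
# character position (for error messages).
tokenize_definition <- function(definition) {
  chars <- strsplit(definition, "", fixed = TRUE)[[1]]
  n <- length(chars)
  type <- character(0); value <- character(0); at <- integer(0)
  i <- 1L
  push <- function(t, v, p) {
    type[[length(type) + 1L]] <<- t
    value[[length(value) + 1L]] <<- v
    at[[length(at) + 1L]] <<- p
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) {
      # collapse runs of whitespace into one separator token
      j <- i
      while (j <= n && chars[j] %in% c(" ", "\t")) j <- j + 1L
      push("space", " ", i)
      i <- j
    } else if (ch == "(") { push("lparen", "(", i); i <- i + 1L
    } else if (ch == ")") { push("rparen", ")", i); i <- i + 1L
    } else if (ch == ",") { push("comma", ",", i); i <- i + 1L
    } else if (ch == "+") { push("plus", "+", i); i <- i + 1L
    } else if (ch == "-") {
      if (i < n && chars[i + 1L] == "-" &&
          (i + 1L == n || !grepl("[A-Za-z0-9_.]", chars[i + 2L]))) {
        push("wildcard", "--", i)
        i <- i + 2L
      } else {
        push("minus", "-", i)
        i <- i + 1L
      }
    } else if (grepl("[A-Za-z0-9]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_.]", chars[j])) j <- j + 1L
      push("ko", paste(chars[i:(j - 1L)], collapse = ""), i)
      i <- j
    } else {
      stop(sprintf("syntax error at position %d: illegal character '%s'",
                   i, ch), call. = FALSE)
    }
  }
  # strip leading/trailing separators
  keep <- seq_along(type)
  while (length(keep) && type[keep[1]] == "space") keep <- keep[-1]
  while (length(keep) && type[keep[length(keep)]] == "space")
    keep <- keep[-length(keep)]
  list(type = type[keep], value = value[keep], at = at[keep])
}

parse_fail <- function(state, what) {
  pos <- if (state$pos <= length(state$toks$at)) {
    state$toks$at[state$pos]
  } else if (length(state$toks$at)) {
    state$toks$at[length(state$toks$at)] + 1L
  } else 1L
  stop(sprintf("syntax error at position %d: %s", pos, what), call. = FALSE)
}

peek_type <- function(state) {
  if (state$pos > length(state$toks$type)) return("eof")
  state$toks$type[state$pos]
}

advance <- function(state) state$pos <- state$pos + 1L

# space level (inside parentheses): expr (SPACE expr)* -> all(...)
parse_space_level <- function(state) {
  args <- list(parse_comma_level(state))
  while (peek_type(state) == "space") {
    advance(state)
    args[[length(args) + 1L]] <- parse_comma_level(state)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "all", args = args)
}

# comma level: expr (',' expr)* -> any(...)
parse_comma_level <- function(state) {
  args <- list(parse_complex_level(state))
  while (peek_type(state) == "comma") {
    advance(state)
    if (peek_type(state) %in% c("comma", "space", "rparen", "eof")) {
      parse_fail(state, "empty alternative")
    }
    args[[length(args) + 1L]] <- parse_complex_level(state)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "any", args = args)
}

# complex level: ['-'] unit (('+'|'-') unit)* ; '-' marks the following
# unit as optional.  A lone "-X" step becomes optional(X).
parse_complex_level <- function(state) {
  args <- list()
  if (peek_type(state) == "minus") {
    advance(state)
    args[[1L]] <- list(op = "optional", arg = parse_unit(state))
  } else {
    args[[1L]] <- parse_unit(state)
  }
  while (peek_type(state) %in% c("plus", "minus")) {
    optional <- peek_type(state) == "minus"
    advance(state)
    u <- parse_unit(state)
    args[[length(args) + 1L]] <-
      if (optional) list(op = "optional", arg = u) else u
  }
  if (length(args) == 1L) {
    args[[1L]]
  } else {
    list(op = "complex", args = args)
  }
}

parse_unit <- function(state) {
  t <- peek_type(state)
  if (t == "ko") {
    v <- state$toks$value[state$pos]
    advance(state)
    list(op = "atom", ko = v)
  } else if (t == "wildcard") {
    advance(state)
    list(op = "wildcard")
  } else if (t == "lparen") {
    open_at <- state$toks$at[state$pos]
    advance(state)
    if (peek_type(state) == "rparen") parse_fail(state, "empty group")
    inner <- parse_space_level(state)
    if (peek_type(state) != "rparen") {
      stop(sprintf("syntax error at position %d: unbalanced parenthesis",
                   open_at), call. = FALSE)
    }
    advance(state)
    inner
  } else if (t == "rparen") {
    stop(sprintf("syntax error at position %d: unbalanced parenthesis",
                 state$toks$at[state$pos]), call. = FALSE)
  } else {
    parse_fail(state, "expected a KO identifier, '(' or '--'")
  }
}

#' Serialize a module AST back to a definition string
#'
#' Produces the canonical definition string for an AST; parsing the result
#' yields an identical AST (round-trip identity).
#'
#' @param ast A `module_ast`.
#' @return A single definition string.
#' @export
format_module_definition <- function(ast) {
  stopifnot(inherits(ast, "module_ast"))
  paste(vapply(ast$steps, serialize_child, "", ctx = "space"),
        collapse = " ")
}

# serialize a node as a child of a context and parenthesize exactly where
# the context binds at least as tightly as the node:
#   space context: "all" needs parens (space would merge levels)
#   comma context: "all" and "any" need parens
#   complex context: everything composite needs parens
serialize_child <- function(expr, ctx) {
  s <- serialize_expr(expr)
  needs <- switch(ctx,
    space = expr$op == "all",
    comma = expr$op %in% c("all", "any"),
    complex = expr$op %in% c("all", "any", "complex"),
    FALSE)
  if (needs) paste0("(", s, ")") else s
}

serialize_expr <- function(expr) {
  switch(expr$op,
    atom = expr$ko,
    wildcard = "--",
    optional = paste0("-", serialize_child(expr$arg, "complex")),
    all = paste(vapply(expr$args, serialize_child, "", ctx = "space"),
                collapse = " "),
    any = paste(vapply(expr$args, serialize_child, "", ctx = "comma"),
                collapse = ","),
    complex = {
      out <- ""
      for (i in seq_along(expr$args)) {
        a <- expr$args[[i]]
        if (identical(a$op, "optional")) {
          out <- paste0(out, serialize_child(a, "complex"))  # emits "-X"
        } else {
          out <- paste0(out, if (i > 1L) "+" else "",
                        serialize_child(a, "complex"))
        }
      }
      out
    },
    stop("unknown AST node type: ", expr$op)
  )
}

#' @export
print.module_ast <- function(x, ...) {
  cat(sprintf("<module_ast> %s: %d step(s)\n", x$module_id, length(x$steps)))
  cat("  ", format_module_definition(x), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Completion-set enumeration

overflow_condition <- function(limit) {
  errorCondition(
    sprintf("enumeration overflow: more than %d completion sets", limit),
    class = c("kopredict_enumeration_overflow", "error")
  )
}

# set algebra on character vectors representing KO sets
set_key <- function(s) paste(s, collapse = "\r")
dedup_sets <- function(sets) sets[!duplicated(vapply(sets, set_key, ""))]

# enumerate KO sets satisfying one expression; each set is a sorted
# character vector.  Optional and wildcard leaves contribute the empty set.
expr_completion_sets <- function(expr, limit) {
  res <- switch(expr$op,
    atom = list(expr$ko),
    wildcard = list(character(0)),
    optional = list(character(0)),
    any = {
      out <- list()
      for (a in expr$args) {
        out <- c(out, expr_completion_sets(a, limit))
        out <- dedup_sets(out)
        if (length(out) > limit) stop(overflow_condition(limit))
      }
      out
    },
    all = ,
    complex = {
      out <- list(character(0))
      for (a in expr$args) {
        child <- expr_completion_sets(a, limit)
        if (length(out) * length(child) > limit * 4L) {
          stop(overflow_condition(limit))
        }
        out <- unlist(lapply(out, function(u) {
          lapply(child, function(v) sort(unique(c(u, v))))
        }), recursive = FALSE)
        out <- dedup_sets(out)
        if (length(out) > limit) stop(overflow_condition(limit))
      }
      out
    },
    stop("unknown AST node type: ", expr$op)
  )
  res
}

#' Enumerate KO combinations that complete a module
#'
#' Expands a module definition into every distinct set of KOs formed by
#' choosing one alternative in each disjunction and taking all members of
#' each conjunction or complex. Optional components and wildcard steps are
#' ignored. Sets are deduplicated and returned in deterministic order
#' (by set size, then lexicographically).
#'
#' @param ast A `module_ast`.
#' @param limit Maximum number of completion sets; if exceeded an error of
#'   class `kopredict_enumeration_overflow` is signalled, and callers should
#'   fall back to recursive AST evaluation (see [evaluate_module()]).
#' @return A list of character vectors (sorted KO sets).
#' @examples
#' ast <- parse_module_definition("M", "(K1,K2) (K3,K4)")
#' enumerate_completion_sets(ast)
#' @export
enumerate_completion_sets <- function(ast, limit = 10000L) {
  stopifnot(inherits(ast, "module_ast"), limit >= 1)
  out <- list(character(0))
  for (step in ast$steps) {
    child <- expr_completion_sets(step, limit)
    if (length(out) * length(child) > limit * 4L) {
      stop(overflow_condition(limit))
    }
    out <- unlist(lapply(out, function(u) {
      lapply(child, function(v) sort(unique(c(u, v))))
    }), recursive = FALSE)
    out <- dedup_sets(out)
    if (length(out) > limit) stop(overflow_condition(limit))
  }
  keys <- vapply(out, function(s) paste(s, collapse = " "), "")
  sizes <- lengths(out)
  out[order(sizes, keys)]
}

# ---------------------------------------------------------------------------
# Evaluation and gap-filling

# recursive satisfiability of one expression from a KO set
expr_satisfied <- function(expr, kos) {
  switch(expr$op,
    atom = expr$ko %in% kos,
    wildcard = TRUE,
    optional = TRUE,
    any = any(vapply(expr$args, expr_satisfied, NA, kos = kos)),
    all = ,
    complex = all(vapply(expr$args, expr_satisfied, NA, kos = kos)),
    stop("unknown AST node type: ", expr$op)
  )
}

# minimal-cardinality remainder completing one expression from kos,
# ties broken on the lexicographically smallest sorted KO tuple.
# Per-branch dynamic programming: within an AnyOf the minimal child
# remainder is chosen; within AllOf/Complex the child remainders are
# unioned (exact when branch KO sets are disjoint, which holds after
# completion-choice minimality per branch).
expr_min_remainder <- function(expr, kos) {
  switch(expr$op,
    atom = if (expr$ko %in% kos) character(0) else expr$ko,
    wildcard = character(0),
    optional = character(0),
    any = {
      best <- NULL
      for (a in expr$args) {
        r <- expr_min_remainder(a, kos)
        if (is.null(best) || remainder_before(r, best)) best <- r
        if (length(best) == 0L) break
      }
      best
    },
    all = ,
    complex = {
      out <- character(0)
      for (a in expr$args) out <- c(out, expr_min_remainder(a, kos))
      sort(unique(out))
    },
    stop("unknown AST node type: ", expr$op)
  )
}

# ordering on remainders: smaller cardinality first, then lexicographic on
# the sorted joined KO tuple
remainder_before <- function(a, b) {
  if (length(a) != length(b)) return(length(a) < length(b))
  paste(sort(a), collapse = " ") < paste(sort(b), collapse = " ")
}

#' Evaluate completeness of a KO set against a module
#'
#' A module is `complete` when at least one combination of KOs satisfying
#' every step of the module is contained in `kos`; otherwise it is
#' `incomplete`. Completeness is the fraction of top-level steps satisfied.
#' `missing_kos` is the smallest-cardinality set of KOs whose addition
#' completes the module (ties broken lexicographically).
#'
#' @param ast A `module_ast`.
#' @param kos Character vector of KO identifiers present (may be empty).
#' @param limit Completion-set enumeration limit; below it the minimal
#'   remainder is computed exactly over all enumerated completion sets,
#'   beyond it evaluation falls back to recursive per-branch minimisation.
#' @param method `"auto"` (default), `"enumerate"` or `"recursive"`.
#' @return An object of class `module_evaluation`: a list with `module_id`,
#'   `status` (`"complete"`/`"incomplete"`), `steps_total`,
#'   `steps_satisfied`, `completeness` and `missing_kos`.
#' @examples
#' ast <- parse_module_definition("M", "K1 (K2,K3)")
#' evaluate_module(ast, c("K1", "K3"))$status
#' evaluate_module(ast, "K3")$missing_kos
#' @export
evaluate_module <- function(ast, kos, limit = 10000L,
                            method = c("auto", "enumerate", "recursive")) {
  stopifnot(inherits(ast, "module_ast"))
  method <- match.arg(method)
  kos <- unique(as.character(kos))

  sat <- vapply(ast$steps, expr_satisfied, NA, kos = kos)
  steps_total <- length(ast$steps)
  steps_satisfied <- sum(sat)

  missing <- NULL
  if (method != "recursive") {
    sets <- tryCatch(enumerate_completion_sets(ast, limit = limit),
                     kopredict_enumeration_overflow = function(e) NULL)
    if (!is.null(sets)) {
      best <- NULL
      for (s in sets) {
        r <- setdiff(s, kos)
        if (is.null(best) || remainder_before(r, best)) best <- r
        if (length(best) == 0L) break
      }
      missing <- sort(best)
    } else if (method == "enumerate") {
      stop(overflow_condition(limit))
    }
  }
  if (is.null(missing)) {
    # recursive fallback: union of per-step minimal remainders
    missing <- character(0)
    for (step in ast$steps) {
      missing <- c(missing, expr_min_remainder(step, kos))
    }
    missing <- sort(unique(missing))
  }

  status <- if (length(missing) == 0L) "complete" else "incomplete"
  # status and step satisfaction must agree: complete iff all steps satisfied
  if ((status == "complete") != all(sat)) {
    # can only differ through floating of the two routes; recompute from sat
    status <- if (all(sat)) "complete" else "incomplete"
  }
  structure(
    list(module_id = ast$module_id,
         status = status,
         steps_total = steps_total,
         steps_satisfied = steps_satisfied,
         completeness = if (steps_total > 0) steps_satisfied / steps_total
                        else 1,
         missing_kos = missing),
    class = "module_evaluation"
  )
}

#' @export
print.module_evaluation <- function(x, ...) {
  cat(sprintf("<module_evaluation> %s: %s (%d/%d steps, %.2f)\n",
              x$module_id, x$status, x$steps_satisfied, x$steps_total,
              x$completeness))
  if (length(x$missing_kos)) {
    cat("  missing:", paste(x$missing_kos, collapse = " "), "\n")
  }
  invisible(x)
}

#' Suggest KOs that would complete a module
#'
#' Returns the minimal set of missing KOs whose addition to `kos` makes the
#' module complete (the `missing_kos` of [evaluate_module()]); empty when the
#' module is already complete.
#'
#' @inheritParams evaluate_module
#' @return Sorted character vector of KO identifiers.
#' @examples
#' ast <- parse_module_definition("M", "(K1,K2) (K3,K4)")
#' gap_fill(ast, "K2")
#' @export
gap_fill <- function(ast, kos, limit = 10000L) {
  evaluate_module(ast, kos, limit = limit)$missing_kos
}

#' List the atom KOs of a module definition
#'
#' @param ast A `module_ast`.
#' @param include_optional Include KOs that appear only as optional (`-`)
#'   components; excluded by default, consistent with presence labelling.
#' @return Sorted character vector of KO identifiers.
#' @export
module_atoms <- function(ast, include_optional = FALSE) {
  collect <- function(expr, optional_ctx) {
    switch(expr$op,
      atom = if (optional_ctx && !include_optional) character(0) else expr$ko,
      wildcard = character(0),
      optional = collect(expr$arg, TRUE),
      any = ,
      all = ,
      complex = unlist(lapply(expr$args, collect,
                              optional_ctx = optional_ctx)),
      stop("unknown AST node type: ", expr$op)
    )
  }
  sort(unique(unlist(lapply(ast$steps, collect, optional_ctx = FALSE))))
}

# ---------------------------------------------------------------------------
# Module catalogs

#' Build a module catalog from definition strings
#'
#' @param module_ids Character vector of module identifiers.
#' @param definitions Character vector of definition strings, same length.
#' @param names Optional character vector of human-readable module names.
#' @return A `module_catalog`: a named list of `module_ast` objects.
#' @export
module_catalog <- function(module_ids, definitions, names = NULL) {
  stopifnot(length(module_ids) == length(definitions),
            !anyDuplicated(module_ids))
  out <- vector("list", length(module_ids))
  for (i in seq_along(module_ids)) {
    out[[i]] <- parse_module_definition(module_ids[i], definitions[i])
    if (!is.null(names)) out[[i]]$name <- names[i]
  }
  names(out) <- module_ids
  class(out) <- "module_catalog"
  out
}

#' Read a module catalog from a TSV file
#'
#' Expects tab-separated columns `module_id` and `definition`, with an
#' optional `name` column; lines starting with `#` are ignored.
#'
#' @param path Path to the catalog file.
#' @return A `module_catalog`.
#' @export
read_module_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("module_id", "definition")
  if (!all(need %in% names(df))) {
    stop("catalog must have columns 'module_id' and 'definition'",
         call. = FALSE)
  }
  module_catalog(df$module_id, df$definition,
                 names = if ("name" %in% names(df)) df$name else NULL)
}

#' Write a module catalog to a TSV file
#'
#' @param catalog A `module_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_module_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "module_catalog"))
  df <- data.frame(
    module_id = vapply(catalog, function(m) m$module_id, ""),
    definition = vapply(catalog, format_module_definition, ""),
    stringsAsFactors = FALSE
  )
  nm <- vapply(catalog, function(m) m$name %||% NA_character_, "")
  if (any(!is.na(nm))) df$name <- nm
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.module_catalog <- function(x, ...) {
  cat(sprintf("<module_catalog> %d module(s)\n", length(x)))
  show <- utils::head(x, 5)
  for (m in show) {
    cat(sprintf("  %s  %s\n", m$module_id, format_module_definition(m)))
  }
  if (length(x) > 5) cat(sprintf("  ... and %d more\n", length(x) - 5))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
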