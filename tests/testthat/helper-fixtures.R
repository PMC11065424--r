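# Shared fixtures and generators for the test suite.

# A small hand-written catalog exercising all grammar constructs.
tiny_catalog <- function() {
  module_catalog(
    c("M1", "M2", "M3", "M4"),
    c("K1 K2",
      "K1 (K2,K3)",
      "(K1,K2) (K3,K4)",
      "K1+K2-K3")
  )
}

# Random AST generator for property tests: at most `max_atoms` atoms drawn
# from a small alphabet (shared KOs across branches are possible).
random_ast <- function(max_atoms = 12L, alphabet = sprintf("K%02d", 1:8)) {
  atoms_left <- sample(3:max_atoms, 1L)
  gen_expr <- function(depth, budget) {
    if (budget <= 1L || depth >= 3L || stats::runif(1) < 0.4) {
      return(list(expr = sample(alphabet, 1L), used = 1L))
    }
    n_children <- sample(2:min(3L, budget), 1L)
    op <- sample(c(",", " ", "+"), 1L)
    parts <- character(n_children)
    used <- 0L
    for (i in seq_len(n_children)) {
      child <- gen_expr(depth + 1L, max(1L, budget %/% n_children))
      parts[i] <- child$expr
      used <- used + child$used
    }
    expr <- if (op == ",") {
      paste0("(", paste(parts, collapse = ","), ")")
    } else if (op == " ") {
      paste0("(", paste(parts, collapse = " "), ")")
    } else {
      # '+' operands must bind tighter: wrap non-atomic parts
      parts <- ifelse(grepl("[ ,]", parts), paste0("(", parts, ")"), parts)
      paste(parts, collapse = "+")
    }
    list(expr = expr, used = used)
  }
  steps <- character(0)
  used <- 0L
  while (used < atoms_left) {
    s <- gen_expr(1L, atoms_left - used)
    steps <- c(steps, s$expr)
    used <- used + s$used
  }
  parse_module_definition("MR", paste(steps, collapse = " "))
}

# Brute-force completeness oracle: exists an enumerated completion set
# contained in kos.
oracle_complete <- function(ast, kos) {
  sets <- enumerate_completion_sets(ast, limit = 100000L)
  any(vapply(sets, function(s) all(s %in% kos), NA))
}

# A small deterministic world for classifier tests (cached per test run).
.test_world_cache <- new.env(parent = emptyenv())
small_world <- function() {
  if (is.null(.test_world_cache$world)) {
    .test_world_cache$world <- generate_world(
      synthetic_world_config(n_genomes = 200L, seed = 42L))
  }
  .test_world_cache$world
}
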