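# Parsing, enumeration, evaluation and gap-filling of module definitions.

test_that("definitions parse into the expected step structure", {
  m1 <- parse_module_definition("M1", "K00001 K00002")
  expect_length(m1$steps, 2L)
  expect_equal(vapply(m1$steps, function(s) s$op, ""), c("atom", "atom"))

  m2 <- parse_module_definition("M2", "K00001 (K00002,K00003)")
  expect_length(m2$steps, 2L)
  expect_equal(m2$steps[[1]]$op, "atom")
  expect_equal(m2$steps[[2]]$op, "any")
  expect_equal(vapply(m2$steps[[2]]$args, function(a) a$ko, ""),
               c("K00002", "K00003"))

  m3 <- parse_module_definition("M3", "K00001+K00002-K00003")
  expect_length(m3$steps, 1L)
  step <- m3$steps[[1]]
  expect_equal(step$op, "complex")
  expect_equal(step$args[[1]]$ko, "K00001")
  expect_equal(step$args[[2]]$ko, "K00002")
  expect_equal(step$args[[3]]$op, "optional")
  expect_equal(step$args[[3]]$arg$ko, "K00003")

  # comma binds tighter than space inside parentheses
  m4 <- parse_module_definition("M4", "(K1 K2,K3)")
  expect_length(m4$steps, 1L)
  expect_equal(m4$steps[[1]]$op, "all")
  expect_equal(m4$steps[[1]]$args[[2]]$op, "any")

  # wildcard step
  m5 <- parse_module_definition("M5", "K1 -- K2")
  expect_equal(m5$steps[[2]]$op, "wildcard")
})

test_that("syntax errors carry a character position", {
  expect_error(parse_module_definition("M", "K1 (K2,K3"),
               "position 4.*unbalanced")
  expect_error(parse_module_definition("M", "K1 K2)"),
               "unbalanced")
  expect_error(parse_module_definition("M", "K1 (K2,,K3)"),
               "empty alternative")
  expect_error(parse_module_definition("M", "K1,"),
               "empty alternative")
  expect_error(parse_module_definition("M", "K1 ? K2"),
               "position 4.*illegal")
  expect_error(parse_module_definition("M", ""), "non-empty")
  expect_error(parse_module_definition("M", "()"), "empty group")
})

test_that("serialization round-trips the AST unchanged", {
  defs <- c("K00001 K00002",
            "K00001 (K00002,K00003)",
            "K00001+K00002-K00003",
            "(K1,K2) (K3,K4)",
            "((K1 K2),K3) K4",
            "K1+K2,K3 -- -K9",
            "(K1,K2+K3) (K4 K5,K6)")
  for (d in defs) {
    ast <- parse_module_definition("M", d)
    text <- format_module_definition(ast)
    expect_identical(parse_module_definition("M", text)$steps, ast$steps,
                     label = sprintf("round trip of '%s' via '%s'", d, text))
  }
})

test_that("serialization round-trips random ASTs", {
  set.seed(101)
  for (i in 1:200) {
    ast <- random_ast()
    text <- format_module_definition(ast)
    expect_identical(parse_module_definition("MR", text)$steps, ast$steps,
                     label = sprintf("case %d: '%s'", i, text))
  }
})

test_that("completion sets enumerate alternatives and complexes", {
  sets <- enumerate_completion_sets(parse_module_definition("M", "K1 (K2,K3)"))
  expect_equal(sets, list(c("K1", "K2"), c("K1", "K3")))

  sets <- enumerate_completion_sets(
    parse_module_definition("M", "(K1,K2) (K3,K4)"))
  expect_equal(sets, list(c("K1", "K3"), c("K1", "K4"),
                          c("K2", "K3"), c("K2", "K4")))

  expect_equal(enumerate_completion_sets(parse_module_definition("M", "K1+K2")),
               list(c("K1", "K2")))

  # optional and wildcard contribute nothing
  expect_equal(
    enumerate_completion_sets(parse_module_definition("M", "K1-K2 --")),
    list("K1"))

  # shared KOs across branches deduplicate
  sets <- enumerate_completion_sets(
    parse_module_definition("M", "(K1,K2) (K1,K3)"))
  expect_equal(sets, list(c("K1"), c("K1", "K2"), c("K1", "K3"),
                          c("K2", "K3")))
})

test_that("enumeration signals overflow beyond the limit", {
  # 4 steps x 3 alternatives = 81 sets
  ast <- parse_module_definition("M",
    "(A1,A2,A3) (B1,B2,B3) (C1,C2,C3) (D1,D2,D3)")
  expect_length(enumerate_completion_sets(ast, limit = 100L), 81L)
  expect_error(enumerate_completion_sets(ast, limit = 50L),
               class = "kopredict_enumeration_overflow")
  # recursive evaluation still works past the limit
  ev <- evaluate_module(ast, c("A1", "B2", "C3"), limit = 50L)
  expect_equal(ev$status, "incomplete")
  expect_equal(ev$steps_satisfied, 3L)
  expect_length(ev$missing_kos, 1L)
})

test_that("enumeration count matches the product of disjoint alternatives", {
  set.seed(7)
  for (i in 1:20) {
    n_steps <- sample(1:4, 1)
    alts <- sample(1:3, n_steps, replace = TRUE)
    ko <- 0L
    steps <- vapply(seq_len(n_steps), function(s) {
      kos <- sprintf("X%03d", ko + seq_len(alts[s]))
      ko <<- ko + alts[s]
      if (alts[s] == 1L) kos else paste0("(", paste(kos, collapse = ","), ")")
    }, "")
    ast <- parse_module_definition("M", paste(steps, collapse = " "))
    expect_length(enumerate_completion_sets(ast), prod(alts))
  }
})

test_that("evaluation reports status, step counts and minimal remainder", {
  ast <- parse_module_definition("M", "K1 (K2,K3)")
  ev <- evaluate_module(ast, c("K1", "K3"))
  expect_equal(ev$status, "complete")
  expect_equal(ev$completeness, 1.0)
  expect_length(ev$missing_kos, 0L)

  ev <- evaluate_module(ast, "K3")
  expect_equal(ev$status, "incomplete")
  expect_equal(ev$completeness, 0.5)
  expect_equal(ev$missing_kos, "K1")

  # empty KO set: nothing satisfiable
  ev <- evaluate_module(ast, character(0))
  expect_equal(ev$steps_satisfied, 0L)
  expect_equal(ev$completeness, 0)

  # optional and wildcard steps are always satisfied
  ev <- evaluate_module(parse_module_definition("M", "-K1 --"), character(0))
  expect_equal(ev$status, "complete")
  expect_equal(ev$completeness, 1.0)
})

test_that("gap fill returns the minimal lexicographic completion remainder", {
  expect_equal(gap_fill(parse_module_definition("M", "K1 K2"), "K1"), "K2")
  # 4 completion sets, minimal remainders {K3} and {K4}; K3 wins the tie
  expect_equal(gap_fill(parse_module_definition("M", "(K1,K2) (K3,K4)"),
                        "K2"), "K3")
  expect_equal(gap_fill(parse_module_definition("M", "K1 (K2,K3)"),
                        c("K1", "K2")), character(0))
})

test_that("recursive evaluation agrees with brute-force enumeration", {
  set.seed(202)
  n_pairs <- 0L
  while (n_pairs < 2000L) {
    ast <- random_ast()
    atoms <- module_atoms(ast, include_optional = TRUE)
    for (j in 1:10) {
      kos <- atoms[stats::runif(length(atoms)) < stats::runif(1)]
      ev <- evaluate_module(ast, kos, method = "recursive")
      expect_identical(ev$status == "complete", oracle_complete(ast, kos),
                       label = sprintf("'%s' with {%s}",
                                       format_module_definition(ast),
                                       paste(kos, collapse = ",")))
      n_pairs <- n_pairs + 1L
    }
  }
})

test_that("gap fill is sound: adding it always completes the module", {
  set.seed(303)
  for (i in 1:300) {
    ast <- random_ast()
    atoms <- module_atoms(ast, include_optional = TRUE)
    kos <- atoms[stats::runif(length(atoms)) < 0.5]
    for (method in c("enumerate", "recursive")) {
      fill <- evaluate_module(ast, kos, method = method)$missing_kos
      ev2 <- evaluate_module(ast, union(kos, fill), method = method)
      expect_equal(ev2$status, "complete",
                   label = sprintf("%s: '%s' + {%s}", method,
                                   format_module_definition(ast),
                                   paste(fill, collapse = ",")))
    }
  }
})

test_that("completeness is monotone in the KO set", {
  set.seed(404)
  for (i in 1:200) {
    ast <- random_ast()
    atoms <- module_atoms(ast, include_optional = TRUE)
    a <- atoms[stats::runif(length(atoms)) < 0.4]
    extra <- setdiff(atoms, a)
    b <- union(a, extra[stats::runif(length(extra)) < 0.5])
    ev_a <- evaluate_module(ast, a)
    ev_b <- evaluate_module(ast, b)
    expect_lte(ev_a$completeness, ev_b$completeness)
    if (ev_a$status == "complete") expect_equal(ev_b$status, "complete")
  }
})

test_that("module catalogs round-trip through TSV", {
  cat1 <- tiny_catalog()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_module_catalog(cat1, path)
  cat2 <- read_module_catalog(path)
  expect_equal(names(cat2), names(cat1))
  for (m in names(cat1)) {
    expect_identical(cat2[[m]]$steps, cat1[[m]]$steps)
  }
  # comment lines are ignored
  lines <- readLines(path)
  writeLines(c("# comment", lines[1], "# another", lines[-1]), path)
  expect_equal(names(read_module_catalog(path)), names(cat1))
})
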