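# Performance metrics and the benchmark harness.

test_that("metrics follow their defining formulas", {
  m <- compute_metrics(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(m$precision, 1.0)
  expect_equal(m$recall, 1.0)
  expect_equal(m$f1, 1.0)

  m <- compute_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(m$prevalence, 0.5)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 4 / 6)
})

test_that("zero denominators yield NA, never zero", {
  m <- compute_metrics(tp = 0, fp = 0, tn = 5, fn = 5)
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
  expect_equal(m$recall, 0)
  m2 <- compute_metrics(tp = 0, fp = 0, tn = 10, fn = 0)
  expect_true(is.na(m2$recall))
  expect_true(is.na(m2$f1))
})

test_that("confusion counts accumulate from prediction vectors", {
  cc <- confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(cc$tp, 2L)
  expect_equal(cc$fn, 1L)
  expect_equal(cc$fp, 1L)
  expect_equal(cc$tn, 1L)
  m <- compute_metrics(cc)
  expect_equal(m$prevalence, 3 / 5)
})

test_that("Bayes-route PPV and NPV match the count route (fuzz)", {
  expect_true(verify_ppv_identity(3, 1, 4, 2))
  expect_true(verify_ppv_identity(1, 9, 89, 1))
  set.seed(99)
  n_checked <- 0L
  while (n_checked < 2000L) {
    tp <- rpois(1, 20); fp <- rpois(1, 5)
    tn <- rpois(1, 50); fn <- rpois(1, 8)
    if (min(tp + fp, tp + fn, tn + fp, tn + fn) == 0) next
    expect_true(verify_ppv_identity(tp, fp, tn, fn),
                label = sprintf("tp=%d fp=%d tn=%d fn=%d", tp, fp, tn, fn))
    n_checked <- n_checked + 1L
  }
})

test_that("defined metrics stay in [0,1] and F1 lies between precision and recall", {
  set.seed(123)
  for (i in 1:500) {
    m <- compute_metrics(rpois(1, 10), rpois(1, 10),
                         rpois(1, 10), rpois(1, 10))
    vals <- unlist(m)
    expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 1))
    if (!is.na(m$f1)) {
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    }
  }
})

test_that("the harness emits the tidy five-column format with aggregates", {
  world <- small_world()
  genomes <- world$genomes[1:30]
  labels <- world$labels[1:30, , drop = FALSE]
  scheme <- downsample_scheme(c(0.4, 0.8), seed = 5L)
  res <- run_benchmark(list(oracle = classifier_oracle(labels),
                            unique_gene = classifier_unique_gene(world$catalog)),
                       genomes, labels, scheme)
  expect_equal(names(res),
               c("Module name", "Percent of protein families retained",
                 "Model type", "Metric", "Score"))
  # 2 classifiers x 2 fractions x (12 modules + 2 aggregates) x 5 metrics
  expect_equal(nrow(res), 2L * 2L * 14L * 5L)
  expect_setequal(unique(res$Metric),
                  c("precision", "recall", "f1", "ppv", "npv"))
  expect_setequal(unique(res[["Percent of protein families retained"]]),
                  c(40, 80))
})

test_that("a perfect oracle scores 1.0 on every defined metric", {
  world <- small_world()
  genomes <- world$genomes[1:40]
  labels <- world$labels[1:40, , drop = FALSE]
  res <- run_benchmark(list(oracle = classifier_oracle(labels)),
                       genomes, labels,
                       downsample_scheme(c(0.3, 0.6), seed = 2L))
  defined <- res$Score[!is.na(res$Score)]
  expect_true(all(abs(defined - 1.0) < 1e-12))
})

test_that("harness output is reproducible for a fixed seed", {
  world <- small_world()
  genomes <- world$genomes[1:25]
  labels <- world$labels[1:25, , drop = FALSE]
  cls <- list(prop = classifier_proportional(world$catalog))
  scheme <- downsample_scheme(c(0.5), seed = 77L)
  r1 <- suppressMessages(run_benchmark(cls, genomes, labels, scheme))
  r2 <- suppressMessages(run_benchmark(cls, genomes, labels, scheme))
  expect_identical(r1, r2)
})

test_that("classifier failures are recorded as error rows without aborting", {
  world <- small_world()
  genomes <- world$genomes[1:10]
  labels <- world$labels[1:10, , drop = FALSE]
  cls <- list(broken = function(...) stop("boom"),
              oracle = classifier_oracle(labels))
  res <- run_benchmark(cls, genomes, labels,
                       downsample_scheme(c(0.5), seed = 1L))
  expect_true(any(res$Metric == "error" & res[["Model type"]] == "broken"))
  expect_true(any(res[["Model type"]] == "oracle" & res$Metric == "f1"))
})

test_that("proportional-rule precision improves with retention", {
  # with the full definition as denominator, a high retention bar is hard
  # to clear by chance, so false positives shrink as retention grows
  world <- small_world()
  genomes <- world$genomes
  labels <- world$labels
  res <- suppressMessages(run_benchmark(
    list(prop = classifier_proportional(world$catalog,
                                        denominator = "definition")),
    genomes, labels, downsample_scheme(c(0.1, 0.9), seed = 3L),
    metrics = "precision", aggregate = "micro"))
  mic <- res[res[["Module name"]] == "(micro)", ]
  p10 <- mic$Score[mic[["Percent of protein families retained"]] == 10]
  p90 <- mic$Score[mic[["Percent of protein families retained"]] == 90]
  expect_lte(p10, p90)
})

test_that("benchmark tables round-trip through TSV", {
  world <- small_world()
  labels <- world$labels[1:10, , drop = FALSE]
  res <- run_benchmark(list(oracle = classifier_oracle(labels)),
                       world$genomes[1:10], labels,
                       downsample_scheme(c(0.5), seed = 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark_tsv(res, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(names(back), names(res))
  expect_equal(nrow(back), nrow(res))
})
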