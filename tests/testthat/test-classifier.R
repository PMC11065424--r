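# Prevalence partitioning, stratified splitting, fitting and prediction.

test_that("modules partition by prevalence with inclusive bounds", {
  labels <- cbind(a = rep(c(1L, 0L), c(50, 50)),    # 0.50
                  b = rep(c(1L, 0L), c(5, 95)),     # 0.05
                  c = rep(c(1L, 0L), c(95, 5)),     # 0.95
                  d = rep(c(1L, 0L), c(10, 90)),    # 0.10 -> balanced
                  e = rep(c(1L, 0L), c(90, 10)))    # 0.90 -> balanced
  p <- partition_modules(labels)
  expect_setequal(p$balanced_modules, c("a", "d", "e"))
  expect_setequal(p$imbalanced_modules, c("b", "c"))
  # exhaustive and disjoint over retained modules
  expect_length(intersect(p$balanced_modules, p$imbalanced_modules), 0L)
  expect_setequal(c(p$balanced_modules, p$imbalanced_modules),
                  colnames(labels))
})

test_that("modules under the positive-count floor are excluded", {
  labels <- cbind(a = rep(c(1L, 0L), c(50, 50)),
                  b = rep(c(1L, 0L), c(2, 98)))
  p <- partition_modules(labels, min_positive_count = 3L)
  expect_equal(p$dropped, "b")
  expect_setequal(c(p$balanced_modules, p$imbalanced_modules), "a")
  expect_error(partition_modules(labels, min_positive_count = 60L),
               "no modules retained")
})

test_that("stratified split preserves per-label prevalence", {
  world <- small_world()
  ex <- expand_with_downsampled(world$genomes, world$labels,
                                downsample_scheme(c(0.3, 0.7), seed = 4L))
  sp <- stratified_multilabel_split(ex$labels, 0.25, seed = 6L)
  # indices partition the rows
  expect_setequal(c(sp$train, sp$test), seq_len(nrow(ex$labels)))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_equal(length(sp$test), round(0.25 * nrow(ex$labels)))
  # per-label prevalence preserved within 0.05 for labels with >= 20 pos
  for (m in colnames(ex$labels)) {
    if (sum(ex$labels[, m]) >= 20L) {
      d <- abs(mean(ex$labels[sp$train, m]) - mean(ex$labels[sp$test, m]))
      expect_lte(d, 0.05)
    }
  }
  # deterministic given seed
  sp2 <- stratified_multilabel_split(ex$labels, 0.25, seed = 6L)
  expect_identical(sp, sp2)
})

test_that("single-label and degenerate all-zero labels split cleanly", {
  set.seed(8)
  y <- cbind(m = rbinom(1000, 1, 0.3))
  sp <- stratified_multilabel_split(y, 0.25, seed = 2L)
  expect_lte(abs(mean(y[sp$test, ]) - 0.3), 0.05)

  z <- cbind(m = integer(400))  # no positives at all
  sp <- stratified_multilabel_split(z, 0.25, seed = 2L)
  expect_equal(length(sp$test), 100L)
})

test_that("classifier configuration validates its inputs", {
  cfg <- classifier_config()
  expect_equal(cfg$hidden_layers, 5L)
  expect_equal(cfg$hidden_units, 2048L)
  expect_equal(cfg$dropout_rate, 0.10)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$threshold, 0.5)
  expect_error(classifier_config(dropout_rate = 1.2))
  expect_error(classifier_config(threshold = -0.1))
})

test_that("presence calls use an inclusive threshold", {
  expect_equal(kopredict:::decide_presence(0.5, 0.5), 1L)
  expect_equal(kopredict:::decide_presence(0.499999, 0.5), 0L)
  expect_equal(kopredict:::decide_presence(c(0.2, 0.5, 0.9), 0.5),
               c(0L, 1L, 1L))
})

# one small fitted pair reused across the remaining tests
fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      world <- small_world()
      x <- build_feature_matrix(world$genomes, world$ko_universe)
      cfg <- classifier_config(hidden_layers = 1L, hidden_units = 64L,
                               epochs = 60L, batch_size = 32L,
                               patience = 15L, seed = 3L)
      cache <<- list(
        world = world, x = x,
        fit = fit_module_classifier(x, world$labels, config = cfg))
    }
    cache
  }
})

test_that("fitting requires both prevalence partitions", {
  world <- small_world()
  x <- build_feature_matrix(world$genomes, world$ko_universe)
  balanced_only <- partition_modules(world$labels)
  balanced_only$imbalanced_modules <- character(0)
  expect_error(
    fit_module_classifier(x, world$labels, partition = balanced_only),
    "non-empty")
})

test_that("predictions cover every retained module exactly once, in [0,1]", {
  fx <- fit_small()
  p <- predict(fx$fit, fx$x, type = "prob")
  expect_setequal(colnames(p), c(fx$fit$partition$balanced_modules,
                                 fx$fit$partition$imbalanced_modules))
  expect_false(anyDuplicated(colnames(p)) > 0)
  expect_true(all(p >= 0 & p <= 1))
  cls <- predict(fx$fit, fx$x, type = "class")
  expect_true(all(cls %in% c(0L, 1L)))
})

test_that("prediction projects unseen KOs out of the input", {
  fx <- fit_small()
  g <- fx$world$genomes[[1]]
  noisy <- genome_annotation(g$genome_id, c(g$kos, "ZZZ99"))
  expect_equal(suppressMessages(predict(fx$fit, list(noisy))),
               suppressMessages(predict(fx$fit, list(g))))
})

test_that("complete modules bypass the model and get gap-fill semantics", {
  fx <- fit_small()
  world <- fx$world
  g <- world$genomes[[which(rowSums(world$labels) > 0)[1]]]
  res <- predict_modules(fx$fit, g, world$catalog)
  expect_equal(nrow(res), length(world$catalog))
  complete_mods <- colnames(world$labels)[world$labels[g$genome_id, ] == 1L]
  got <- res[res$module_id %in% complete_mods, ]
  expect_true(all(got$status == "complete"))
  expect_true(all(got$probability == 1.0))
  expect_true(all(got$missing_kos == ""))
  # a complete module is never reported predicted_absent
  expect_false(any(res$status == "predicted_absent" &
                     res$completeness == 1))
  # gap-fill KOs only on predicted-present incomplete modules
  pp <- res[res$status == "predicted_present", ]
  if (nrow(pp)) {
    for (i in seq_len(nrow(pp))) {
      fill <- strsplit(pp$missing_kos[i], ";")[[1]]
      expect_gt(length(fill), 0)
      ev <- evaluate_module(world$catalog[[pp$module_id[i]]],
                            union(g$kos, fill))
      expect_equal(ev$status, "complete")
    }
  }
  absent <- res[res$status == "predicted_absent", ]
  expect_true(all(absent$missing_kos == ""))
})

test_that("requested modules restrict output and unknown ids error", {
  fx <- fit_small()
  g <- fx$world$genomes[[1]]
  m2 <- names(fx$world$catalog)[2]
  res <- predict_modules(fx$fit, g, fx$world$catalog, requested = m2)
  expect_equal(res$module_id, m2)
  expect_error(
    predict_modules(fx$fit, g, fx$world$catalog, requested = "M_unknown"),
    "M_unknown")
})

test_that("a saved and reloaded classifier reproduces its predictions", {
  fx <- fit_small()
  path <- withr::local_tempfile(fileext = ".json")
  save_module_classifier(fx$fit, path)
  reloaded <- load_module_classifier(path)
  expect_equal(predict(reloaded, fx$x[1:10, ]),
               predict(fx$fit, fx$x[1:10, ]), tolerance = 1e-12)
  expect_equal(reloaded$partition$balanced_modules,
               fx$fit$partition$balanced_modules)
})
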