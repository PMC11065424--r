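# Canned desk-scale experiment protocols.  These are the package's own
# study conditions: the vignette documents the problem sizes and training
# configurations and why they were chosen.

#' Desk-scale recovery experiment
#'
#' Generates a synthetic world of complete genomes, splits 75/25 with
#' multi-label stratification, trains the classifier pair on the complete
#' training genomes only (labels are then a noise-free deterministic
#' function of the features), and measures per-module F1 of the raw network
#' predictions on the held-out complete genomes.
#'
#' @param seed Master seed for the world, split and training.
#' @param n_genomes Number of complete genomes (default 6000; see the
#'   methods vignette for the sizing rationale).
#' @param config Training configuration; default is the desk-scale
#'   configuration described in the methods vignette.
#' @return A list: `fit`, `world`, `split`, `f1` (named per-module vector),
#'   `min_f1`, `mean_f1`.
#' @export
run_recovery_experiment <- function(seed = 1L, n_genomes = 6000L,
                                    config = NULL) {
  if (is.null(config)) {
    config <- classifier_config(hidden_layers = 1L, hidden_units = 256L,
                                l2_strength = 1e-4, epochs = 400L,
                                batch_size = 32L, patience = 80L,
                                seed = derive_seed(seed, "train"))
  }
  world <- generate_world(synthetic_world_config(
    n_genomes = n_genomes, seed = derive_seed(seed, "world")))
  x <- build_feature_matrix(world$genomes, world$ko_universe)
  sp <- stratified_multilabel_split(world$labels, 0.25,
                                    seed = derive_seed(seed, "split"))
  partition <- partition_modules(world$labels[sp$train, , drop = FALSE])
  fit <- fit_module_classifier(x[sp$train, , drop = FALSE],
                               world$labels[sp$train, , drop = FALSE],
                               partition = partition, config = config)
  pred <- predict(fit, x[sp$test, , drop = FALSE], type = "class")
  truth <- world$labels[sp$test, colnames(pred), drop = FALSE]
  f1 <- vapply(colnames(pred), function(m) {
    compute_metrics(confusion_counts(truth[, m], pred[, m]))$f1
  }, 0)
  list(fit = fit, world = world, split = sp, f1 = f1,
       min_f1 = min(f1), mean_f1 = mean(f1))
}

#' Desk-scale degradation and baseline experiment
#'
#' Generates a synthetic world, expands it with downsampled variants over
#' the 10--90\% retention grid, splits 75/25 with multi-label
#' stratification, and trains the classifier pair on the mixture (the
#' protocol matching how the real tool is trained). Returns (a) mean
#' per-module recall of the raw networks on held-out rows at each retention
#' level, and (b) the benchmark table comparing the full
#' reconstruct-then-predict pipeline with the two naive rules on held-out
#' complete genomes.
#'
#' @param seed Master seed.
#' @param n_genomes Number of complete genomes (default 1000; see the
#'   methods vignette for the sizing rationale).
#' @param benchmark_fractions Retention grid for the baseline comparison;
#'   the default adds 10\% to the 30--70\% band so the naive rules'
#'   degenerate permissiveness at low retention is measurable.
#' @param config Training configuration; default is the desk-scale
#'   mixture configuration described in the methods vignette.
#' @return A list: `fit`, `world`, `recall_by_retain` (named numeric),
#'   `benchmark` (tidy results table), `macro_f1` and `macro_specificity`
#'   (retention x classifier matrices of macro-mean scores).
#' @export
run_degradation_experiment <- function(seed = 1L, n_genomes = 1000L,
                                       benchmark_fractions =
                                         c(0.1, seq(0.3, 0.7, by = 0.1)),
                                       config = NULL) {
  if (is.null(config)) {
    config <- classifier_config(hidden_layers = 2L, hidden_units = 256L,
                                l2_strength = 3e-4, epochs = 200L,
                                batch_size = 64L, patience = 30L,
                                seed = derive_seed(seed, "train"))
  }
  world <- generate_world(synthetic_world_config(
    n_genomes = n_genomes, seed = derive_seed(seed, "world")))
  scheme <- downsample_scheme(seed = derive_seed(seed, "downsample"))
  ex <- expand_with_downsampled(world$genomes, world$labels, scheme)
  x <- build_feature_matrix(ex$genomes, world$ko_universe)
  sp <- stratified_multilabel_split(ex$labels, 0.25,
                                    seed = derive_seed(seed, "split"))
  partition <- partition_modules(world$labels)  # complete genomes only
  fit <- fit_module_classifier(x[sp$train, , drop = FALSE],
                               ex$labels[sp$train, , drop = FALSE],
                               partition = partition, config = config)

  # raw-network mean per-module recall at each retention level
  recall_by_retain <- vapply(scheme$retain_fractions, function(r) {
    idx <- sp$test[abs(ex$retain[sp$test] - r) < 1e-9]
    pred <- predict(fit, x[idx, , drop = FALSE], type = "class")
    truth <- ex$labels[idx, colnames(pred), drop = FALSE]
    recs <- vapply(colnames(pred), function(m) {
      compute_metrics(confusion_counts(truth[, m], pred[, m]))$recall
    }, 0)
    mean(recs, na.rm = TRUE)
  }, 0)
  names(recall_by_retain) <- sprintf("retain_%02d",
                                     round(100 * scheme$retain_fractions))

  # pipeline vs naive rules on held-out complete genomes
  tc <- sp$test[ex$retain[sp$test] == 1]
  ids <- rownames(ex$labels)[tc]
  gi <- match(ids, vapply(world$genomes, function(g) g$genome_id, ""))
  classifiers <- list(
    neural_pair = classifier_model(fit, world$catalog),
    proportional = classifier_proportional(world$catalog),
    unique_gene = classifier_unique_gene(world$catalog))
  bench <- run_benchmark(classifiers, world$genomes[gi],
                         world$labels[gi, , drop = FALSE],
                         downsample_scheme(benchmark_fractions,
                                           seed = derive_seed(seed,
                                                              "bench")),
                         metrics = c("precision", "recall", "specificity",
                                     "f1", "ppv", "npv"))
  macro_of <- function(metric) {
    mac <- bench[bench[["Module name"]] == "(macro mean)" &
                   bench$Metric == metric, ]
    tapply(mac$Score,
           list(mac[["Percent of protein families retained"]],
                mac[["Model type"]]), identity)
  }
  list(fit = fit, world = world, recall_by_retain = recall_by_retain,
       benchmark = bench, macro_f1 = macro_of("f1"),
       macro_specificity = macro_of("specificity"))
}
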