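# Performance metrics and the downsampling benchmark harness.

#' Confusion counts from truth and prediction vectors
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  structure(list(tp = sum(truth == 1L & predicted == 1L),
                 fp = sum(truth == 0L & predicted == 1L),
                 tn = sum(truth == 0L & predicted == 0L),
                 fn = sum(truth == 1L & predicted == 0L)),
            class = "confusion_counts")
}

safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Classifier performance metrics from confusion counts
#'
#' Computes precision, recall, specificity, F1 score, positive and negative
#' predictive value, and prevalence:
#' \itemize{
#'   \item precision = tp / (tp + fp)
#'   \item recall = tp / (tp + fn)
#'   \item specificity = tn / (tn + fp)
#'   \item f1 = 2 (precision x recall) / (precision + recall)
#'   \item ppv = recall x prevalence /
#'     (recall x prevalence + (1 - specificity)(1 - prevalence))
#'   \item npv = specificity x (1 - prevalence) /
#'     ((1 - recall) prevalence + specificity (1 - prevalence))
#'   \item prevalence = (tp + fn) / (tp + fp + tn + fn)
#' }
#' Zero-denominator cases are `NA`, never 0. The Bayes-route PPV and NPV
#' equal `tp/(tp+fp)` and `tn/(tn+fn)` whenever both routes are defined
#' (see [verify_ppv_identity()]).
#'
#' @param tp True-positive count, or a `confusion_counts` object.
#' @param fp,tn,fn Remaining counts when given separately.
#' @return A named list of the seven metrics.
#' @examples
#' compute_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
#' @export
compute_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (inherits(tp, "confusion_counts")) {
    counts <- tp
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  }
  total <- tp + fp + tn + fn
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  prevalence <- safe_div(tp + fn, total)
  ppv <- if (anyNA(c(recall, specificity, prevalence))) NA_real_ else {
    den <- recall * prevalence + (1 - specificity) * (1 - prevalence)
    if (den == 0) NA_real_ else recall * prevalence / den
  }
  npv <- if (anyNA(c(recall, specificity, prevalence))) NA_real_ else {
    den <- (1 - recall) * prevalence + specificity * (1 - prevalence)
    if (den == 0) NA_real_ else specificity * (1 - prevalence) / den
  }
  list(precision = precision, recall = recall, specificity = specificity,
       f1 = f1, ppv = ppv, npv = npv, prevalence = prevalence)
}

#' Check the Bayes-route PPV/NPV identity
#'
#' Verifies that positive predictive value computed from recall,
#' specificity and prevalence equals `tp / (tp + fp)`, and negative
#' predictive value equals `tn / (tn + fn)`, within `tol`. Holds for every
#' confusion table with no zero denominators.
#'
#' @param tp,fp,tn,fn Confusion counts (no zero denominators).
#' @param tol Absolute tolerance.
#' @return Logical.
#' @export
verify_ppv_identity <- function(tp, fp, tn, fn, tol = 1e-12) {
  m <- compute_metrics(tp, fp, tn, fn)
  ppv_counts <- tp / (tp + fp)
  npv_counts <- tn / (tn + fn)
  if (anyNA(c(m$ppv, m$npv))) return(NA)
  abs(m$ppv - ppv_counts) <= tol && abs(m$npv - npv_counts) <= tol
}

# ---------------------------------------------------------------------------
# Pluggable classifier adapters for the benchmark harness.  Each adapter is
# a function(downsampled_genomes, retain, complete_genomes) returning a 0/1
# matrix (genomes x catalog modules).

#' Benchmark adapter for a fitted classifier pair
#'
#' Wraps a `module_classifier` as a harness plug-in: a module is called
#' present when it is reconstructed complete from the downsampled KOs or
#' its predicted probability reaches the threshold (the full
#' reconstruct-then-predict pipeline).
#'
#' @param object A fitted `module_classifier`.
#' @param catalog A `module_catalog`.
#' @param threshold Optional threshold override.
#' @return A classifier function for [run_benchmark()].
#' @export
classifier_model <- function(object, catalog, threshold = NULL) {
  thr <- threshold %||% object$config$threshold
  mods <- names(catalog)
  covered <- modules_covered(object)
  function(genomes, retain, complete_genomes) {
    complete_now <- label_modules(genomes, catalog)
    probs <- predict(object, genomes, type = "prob")
    out <- complete_now[, mods, drop = FALSE]
    usable <- intersect(mods, covered)
    called <- decide_presence(probs[, usable, drop = FALSE], thr)
    out[, usable] <- pmax(out[, usable, drop = FALSE],
                          matrix(called, nrow(out), length(usable)))
    out
  }
}

#' Benchmark adapter for the proportional-completeness rule
#'
#' @param catalog A `module_catalog`.
#' @param denominator Passed to [proportional_rule()].
#' @return A classifier function for [run_benchmark()].
#' @export
classifier_proportional <- function(catalog,
                                    denominator = c("complete",
                                                    "definition")) {
  denominator <- match.arg(denominator)
  function(genomes, retain, complete_genomes) {
    out <- matrix(0L, length(genomes), length(catalog),
                  dimnames = list(
                    vapply(genomes, function(g) g$genome_id, ""),
                    names(catalog)))
    for (i in seq_along(genomes)) {
      for (m in names(catalog)) {
        out[i, m] <- proportional_rule(genomes[[i]], complete_genomes[[i]],
                                       catalog[[m]], retain,
                                       denominator = denominator)
      }
    }
    out
  }
}

#' Benchmark adapter for the unique-gene rule
#'
#' @param catalog A `module_catalog`.
#' @return A classifier function for [run_benchmark()].
#' @export
classifier_unique_gene <- function(catalog) {
  function(genomes, retain, complete_genomes) {
    t(vapply(genomes, unique_gene_rule, integer(length(catalog)),
             catalog = catalog))
  }
}

#' Oracle adapter returning the true labels (for harness validation)
#'
#' @param labels The ground-truth label matrix over the complete genomes.
#' @return A classifier function for [run_benchmark()].
#' @export
classifier_oracle <- function(labels) {
  function(genomes, retain, complete_genomes) labels
}

#' Run the downsampling benchmark
#'
#' For every retain fraction of the scheme, every complete genome is
#' downsampled (seeded per genome and fraction), each classifier predicts
#' module presence from the downsampled annotations, and predictions are
#' scored per module against the complete genomes' labels. Emits the tidy
#' source-data format with columns `Module name`, `Percent of protein
#' families retained`, `Model type`, `Metric` and `Score`, including
#' macro-average rows (`Module name` = `"(macro mean)"`, unweighted mean
#' over modules with defined scores) and optionally micro-average rows
#' (`"(micro)"`, metrics of the pooled confusion table).
#'
#' @param classifiers Named list of classifier functions (see
#'   [classifier_model()] and friends).
#' @param genomes List of complete `genome_annotation` objects.
#' @param labels Ground-truth label matrix over `genomes`.
#' @param scheme A [downsample_scheme()].
#' @param metrics Which metrics to report; default the five used in model
#'   evaluation (precision, recall, F1, PPV, NPV).
#' @param aggregate Aggregation rows to emit: `"macro"`, `"micro"`, both,
#'   or `character(0)` for none.
#' @return A data.frame in the tidy five-column format. Classifier failures
#'   are recorded as rows with `Metric = "error"` and `NA` score; the
#'   harness continues.
#' @export
run_benchmark <- function(classifiers, genomes, labels, scheme,
                          metrics = c("precision", "recall", "f1",
                                      "ppv", "npv"),
                          aggregate = c("macro", "micro")) {
  stopifnot(is.list(classifiers), !is.null(names(classifiers)),
            inherits(scheme, "downsample_scheme"),
            nrow(labels) == length(genomes))
  aggregate <- intersect(aggregate, c("macro", "micro"))
  mods <- colnames(labels)
  rows <- list()
  emit <- function(module, pct, model, metric, score) {
    rows[[length(rows) + 1L]] <<- data.frame(
      `Module name` = module,
      `Percent of protein families retained` = pct,
      `Model type` = model,
      Metric = metric,
      Score = score,
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  for (f in scheme$retain_fractions) {
    pct <- round(100 * f)
    downsampled <- lapply(genomes, function(g) {
      downsample_annotation(g, f,
                            seed = derive_seed(scheme$seed,
                                               paste0(g$genome_id, "|", f)))
    })
    for (cl_name in names(classifiers)) {
      pred <- tryCatch(
        classifiers[[cl_name]](downsampled, f, genomes),
        error = function(e) e)
      if (inherits(pred, "error")) {
        emit(NA_character_, pct, cl_name, "error", NA_real_)
        next
      }
      pooled <- list(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
      per_module <- list()
      for (m in mods) {
        cc <- confusion_counts(labels[, m], pred[, m])
        pooled <- Map(`+`, pooled, cc[c("tp", "fp", "tn", "fn")])
        mm <- compute_metrics(cc)
        per_module[[m]] <- mm
        for (met in metrics) emit(m, pct, cl_name, met, mm[[met]])
      }
      if ("macro" %in% aggregate) {
        n_na <- 0L
        for (met in metrics) {
          vals <- vapply(per_module, function(mm) mm[[met]], 0)
          n_na <- n_na + sum(is.na(vals))
          emit("(macro mean)", pct, cl_name, met, mean(vals, na.rm = TRUE))
        }
        if (n_na > 0L) {
          message(sprintf(
            "run_benchmark: %d undefined per-module score(s) excluded from macro means (%s, %d%%)",
            n_na, cl_name, pct))
        }
      }
      if ("micro" %in% aggregate) {
        mm <- compute_metrics(pooled$tp, pooled$fp, pooled$tn, pooled$fn)
        for (met in metrics) emit("(micro)", pct, cl_name, met, mm[[met]])
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a benchmark results table to TSV
#'
#' @param results A [run_benchmark()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
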