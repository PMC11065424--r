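# The module-presence classifier pair: prevalence partition, multi-label
# stratified splitting, fitting, prediction, and archive serialization.

#' Hyperparameters for the module classifier pair
#'
#' Defaults mirror the reference architecture: five fully connected hidden
#' layers of 2048 ReLU units with he_uniform initialization, sigmoid output
#' layer, binary cross-entropy loss with the Adam optimizer at learning
#' rate 0.001, dropout of 10\% applied at all layers except the final one,
#' and L2 regularization of the hidden-layer weights.
#'
#' @param hidden_layers Number of hidden layers (0 gives a logistic
#'   regression-like model).
#' @param hidden_units Units per hidden layer.
#' @param dropout_rate Dropout rate on hidden activations.
#' @param l2_strength L2 penalty on hidden-layer weights.
#' @param learning_rate Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param seed Training seed.
#' @param threshold Decision threshold on the sigmoid output
#'   (`probability >= threshold` means predicted present).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(hidden_layers = 5L, hidden_units = 2048L,
                              dropout_rate = 0.10, l2_strength = 1e-4,
                              learning_rate = 0.001, epochs = 50L,
                              batch_size = 256L, patience = 5L,
                              seed = 1L, threshold = 0.5) {
  stopifnot(hidden_layers >= 0, hidden_units >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            l2_strength >= 0, learning_rate > 0,
            epochs >= 1, batch_size >= 1, patience >= 1,
            threshold >= 0, threshold <= 1)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate,
                 l2_strength = l2_strength,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 threshold = threshold),
            class = "classifier_config")
}

decide_presence <- function(probability, threshold) {
  as.integer(probability >= threshold)
}

#' Partition modules by training prevalence
#'
#' Modules whose prevalence (fraction of complete training genomes in which
#' the module is complete) lies in `[low, high]` go to the balanced model;
#' the rest go to the imbalanced model. Modules with fewer than
#' `min_positive_count` positive genomes are excluded entirely.
#'
#' @param labels 0/1 label matrix over complete training genomes.
#' @param low,high Prevalence bounds of the balanced partition (inclusive).
#' @param min_positive_count Minimum positive genomes for a module to be
#'   retained.
#' @return A `module_partition` with `balanced_modules`,
#'   `imbalanced_modules`, `prevalence` (named, retained modules only) and
#'   the thresholds.
#' @export
partition_modules <- function(labels, low = 0.10, high = 0.90,
                              min_positive_count = 1L) {
  stopifnot(nrow(labels) > 0, ncol(labels) > 0, low < high)
  positives <- colSums(labels)
  keep <- positives >= min_positive_count
  if (!any(keep)) {
    stop("no modules retained: all have fewer than ", min_positive_count,
         " positive genomes", call. = FALSE)
  }
  prevalence <- colMeans(labels)[keep]
  mods <- colnames(labels)[keep]
  balanced <- mods[prevalence >= low & prevalence <= high]
  imbalanced <- setdiff(mods, balanced)
  structure(list(balanced_modules = balanced,
                 imbalanced_modules = imbalanced,
                 prevalence = stats::setNames(prevalence, mods),
                 low = low, high = high,
                 min_positive_count = as.integer(min_positive_count),
                 dropped = colnames(labels)[!keep]),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf(
    "<module_partition> balanced [%g, %g]: %d module(s); imbalanced: %d; dropped: %d\n",
    x$low, x$high, length(x$balanced_modules),
    length(x$imbalanced_modules), length(x$dropped)))
  invisible(x)
}

#' Multi-label stratified train/test split
#'
#' Iterative stratification: labels are processed from rarest to most
#' common, and each example carrying the current label is assigned to the
#' subset with the greatest remaining demand for that label (ties broken by
#' remaining capacity, then randomly). Examples with no positive labels
#' fall back to plain random assignment by remaining capacity. This keeps
#' each label's positive/negative proportions approximately equal across
#' the two subsets.
#'
#' @param labels 0/1 label matrix (rows are examples).
#' @param test_fraction Fraction of rows assigned to the test subset.
#' @param seed Integer seed; the split is deterministic given it.
#' @return A list with sorted integer vectors `train` and `test`
#'   partitioning `seq_len(nrow(labels))`; `length(test)` equals
#'   `round(test_fraction * nrow(labels))`.
#' @export
stratified_multilabel_split <- function(labels, test_fraction = 0.25,
                                        seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labels <- as.matrix(labels)
  n <- nrow(labels)
  k <- ncol(labels)
  with_seed(seed, {
    prop <- c(train = 1 - test_fraction, test = test_fraction)
    # remaining capacity per subset; test gets round(t*n)
    cap <- c(train = n - round(test_fraction * n),
             test = round(test_fraction * n))
    # desired positives per label per subset
    pos_total <- colSums(labels)
    desired <- cbind(train = pos_total * prop[1], test = pos_total * prop[2])
    assigned <- integer(n)  # 0 = unassigned, 1 = train, 2 = test
    remaining_pos <- pos_total

    repeat {
      active <- which(remaining_pos > 0)
      if (!length(active)) break
      l <- active[which.min(remaining_pos[active])]
      rows <- which(assigned == 0L & labels[, l] == 1L)
      for (r in rows) {
        s <- pick_subset(desired[l, ], cap)
        assigned[r] <- s
        cap[s] <- cap[s] - 1L
        pos_r <- which(labels[r, ] == 1L)
        desired[pos_r, s] <- desired[pos_r, s] - 1
        remaining_pos[pos_r] <- remaining_pos[pos_r] - 1L
      }
      remaining_pos[l] <- 0L  # guard against ties leaving it active
    }
    # all-zero rows (or all labels exhausted): assign by remaining capacity
    for (r in which(assigned == 0L)) {
      s <- pick_subset(cap, cap)
      assigned[r] <- s
      cap[s] <- cap[s] - 1L
    }
    list(train = which(assigned == 1L), test = which(assigned == 2L))
  })
}

# choose the subset with the larger score; ties by capacity, then random
pick_subset <- function(score, cap) {
  best <- which(score == max(score))
  if (length(best) > 1L) {
    best <- best[cap[best] == max(cap[best])]
    if (length(best) > 1L) best <- sample(best, 1L)
  }
  if (cap[best] <= 0L) best <- which.max(cap)  # capacity exhausted
  as.integer(best)
}

#' Fit the module-presence classifier pair
#'
#' Trains two multi-label feed-forward networks on identical features: one
#' for modules with balanced training prevalence (within `[low, high]` of
#' the partition), one for the imbalanced rest. Each network takes the KO
#' presence/absence vector as input and emits one sigmoid probability per
#' module in its partition. An internal stratified 80/20
#' train/validation split drives early stopping on validation loss.
#'
#' @param features 0/1 feature matrix (genomes x KO universe), as from
#'   [build_feature_matrix()].
#' @param labels 0/1 label matrix (genomes x modules), rows aligned with
#'   `features`.
#' @param partition A [partition_modules()] result; computed from `labels`
#'   when `NULL`. Compute it on complete genomes only when training data
#'   include downsampled variants.
#' @param config A [classifier_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `module_classifier` with components
#'   `balanced`, `imbalanced` (fitted networks), `ko_universe`,
#'   `partition`, `config`. Methods: `print`, `summary`, `predict`, `plot`.
#' @examples
#' \donttest{
#' world <- generate_world(synthetic_world_config(n_genomes = 120))
#' x <- build_feature_matrix(world$genomes, world$ko_universe)
#' fit <- fit_module_classifier(x, world$labels,
#'   config = classifier_config(hidden_layers = 1, hidden_units = 16,
#'                              epochs = 5))
#' predict(fit, x[1:3, ])
#' }
#' @export
fit_module_classifier <- function(features, labels, partition = NULL,
                                  config = classifier_config(),
                                  verbose = FALSE) {
  stopifnot(is.matrix(features), nrow(features) == nrow(labels))
  if (is.null(partition)) partition <- partition_modules(labels)
  if (!length(partition$balanced_modules) ||
      !length(partition$imbalanced_modules)) {
    stop("both partitions must be non-empty; got ",
         length(partition$balanced_modules), " balanced and ",
         length(partition$imbalanced_modules), " imbalanced module(s)",
         call. = FALSE)
  }
  fit_one <- function(mods, seed) {
    mlp_fit(features, labels[, mods, drop = FALSE],
            hidden_layers = config$hidden_layers,
            hidden_units = config$hidden_units,
            dropout = config$dropout_rate,
            l2 = config$l2_strength,
            lr = config$learning_rate,
            epochs = config$epochs,
            batch_size = config$batch_size,
            patience = config$patience,
            seed = seed, verbose = verbose)
  }
  balanced <- fit_one(partition$balanced_modules, config$seed)
  imbalanced <- fit_one(partition$imbalanced_modules, config$seed + 1L)
  structure(list(balanced = balanced,
                 imbalanced = imbalanced,
                 ko_universe = colnames(features),
                 partition = partition,
                 config = config),
            class = "module_classifier")
}

#' @export
print.module_classifier <- function(x, ...) {
  cat("<module_classifier>\n")
  cat(sprintf("  input: %d KOs; architecture: %d x %d hidden units\n",
              length(x$ko_universe), x$config$hidden_layers,
              x$config$hidden_units))
  cat(sprintf("  balanced model:   %d module(s), best epoch %d\n",
              length(x$partition$balanced_modules), x$balanced$best_epoch))
  cat(sprintf("  imbalanced model: %d module(s), best epoch %d\n",
              length(x$partition$imbalanced_modules),
              x$imbalanced$best_epoch))
  invisible(x)
}

#' @export
summary.module_classifier <- function(object, ...) {
  out <- list(
    n_kos = length(object$ko_universe),
    config = object$config,
    modules = modules_covered(object),
    balanced = list(
      modules = object$partition$balanced_modules,
      best_epoch = object$balanced$best_epoch,
      val_loss = min(object$balanced$history$val_loss)),
    imbalanced = list(
      modules = object$partition$imbalanced_modules,
      best_epoch = object$imbalanced$best_epoch,
      val_loss = min(object$imbalanced$history$val_loss))
  )
  class(out) <- "summary.module_classifier"
  out
}

#' @export
print.summary.module_classifier <- function(x, ...) {
  cat("Module-presence classifier pair\n")
  cat(sprintf("  KO universe: %d features\n", x$n_kos))
  cat(sprintf("  architecture: %d hidden layer(s) x %d units, dropout %.2f, L2 %g\n",
              x$config$hidden_layers, x$config$hidden_units,
              x$config$dropout_rate, x$config$l2_strength))
  cat(sprintf("  balanced:   %d modules, best val loss %.5f (epoch %d)\n",
              length(x$balanced$modules), x$balanced$val_loss,
              x$balanced$best_epoch))
  cat(sprintf("  imbalanced: %d modules, best val loss %.5f (epoch %d)\n",
              length(x$imbalanced$modules), x$imbalanced$val_loss,
              x$imbalanced$best_epoch))
  invisible(x)
}

# modules the pair covers, balanced first
modules_covered <- function(object) {
  c(object$partition$balanced_modules, object$partition$imbalanced_modules)
}

# project a feature matrix or annotation list onto the training universe
project_features <- function(object, newdata) {
  if (inherits(newdata, "genome_annotation")) newdata <- list(newdata)
  if (is.list(newdata)) {
    return(suppressMessages(
      build_feature_matrix(newdata, object$ko_universe)))
  }
  stopifnot(is.matrix(newdata))
  missing_cols <- setdiff(object$ko_universe, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$ko_universe)
  if (length(extra)) {
    message(sprintf("predict: dropped %d KO column(s) outside the training universe",
                    length(extra)))
  }
  out <- matrix(0L, nrow(newdata), length(object$ko_universe),
                dimnames = list(rownames(newdata), object$ko_universe))
  shared <- intersect(colnames(newdata), object$ko_universe)
  out[, shared] <- newdata[, shared]
  out
}

#' Predict module presence probabilities
#'
#' @param object A fitted `module_classifier`.
#' @param newdata A feature matrix, a list of `genome_annotation` objects,
#'   or a single `genome_annotation`; KOs outside the training universe are
#'   dropped with a reported count.
#' @param type `"prob"` for sigmoid probabilities, `"class"` for 0/1 calls
#'   at the configured threshold.
#' @param threshold Overrides `config$threshold` when given.
#' @param ... Unused.
#' @return Matrix (genomes x retained modules, balanced modules first) of
#'   probabilities or 0/1 calls.
#' @export
predict.module_classifier <- function(object, newdata,
                                      type = c("prob", "class"),
                                      threshold = NULL, ...) {
  type <- match.arg(type)
  x <- project_features(object, newdata)
  p <- cbind(mlp_predict(object$balanced, x),
             mlp_predict(object$imbalanced, x))
  p <- p[, modules_covered(object), drop = FALSE]
  if (type == "class") {
    thr <- threshold %||% object$config$threshold
    cls <- decide_presence(p, thr)
    p <- matrix(cls, nrow(p), ncol(p), dimnames = dimnames(p))
  }
  p
}

#' @export
plot.module_classifier <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (part in c("balanced", "imbalanced")) {
    h <- x[[part]]$history
    graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss),
                      type = "l", lty = 1:2, col = c(1, 2),
                      xlab = "epoch", ylab = "loss", main = part, ...)
    graphics::legend("topright", c("train", "validation"),
                     lty = 1:2, col = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Reconstruct, predict and gap-fill modules for genomes
#'
#' The full prediction pipeline for one genome (or a list): modules whose
#' definition is already satisfied by the genome's KOs are reported
#' `complete` with probability 1.0 and no model call; incomplete modules
#' receive the sigmoid probability from their partition's network and are
#' `predicted_present` when the probability reaches the decision threshold,
#' otherwise `predicted_absent`. Gap-filling KOs are attached to
#' `predicted_present` incomplete modules.
#'
#' @param object A fitted `module_classifier`.
#' @param genomes A `genome_annotation` or list of them.
#' @param catalog A `module_catalog` (typically the training catalog).
#' @param requested Optional character vector restricting output to these
#'   module ids; unknown ids raise an error naming them.
#' @param threshold Overrides the configured decision threshold.
#' @param limit Completion-set enumeration limit.
#' @return A data.frame with one row per (genome, module): `genome_id`,
#'   `module_id`, `status` (`complete` / `predicted_present` /
#'   `predicted_absent` / `no_model` for catalog modules the pair was not
#'   trained on), `probability`, `completeness`, `missing_kos`
#'   (semicolon-joined gap-fill suggestions).
#' @export
predict_modules <- function(object, genomes, catalog, requested = NULL,
                            threshold = NULL, limit = 10000L) {
  stopifnot(inherits(object, "module_classifier"),
            inherits(catalog, "module_catalog"))
  if (inherits(genomes, "genome_annotation")) genomes <- list(genomes)
  mods <- names(catalog)
  if (!is.null(requested)) {
    unknown <- setdiff(requested, mods)
    if (length(unknown)) {
      stop("unknown module id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    mods <- requested
  }
  thr <- threshold %||% object$config$threshold
  probs <- predict(object, genomes, type = "prob")
  covered <- colnames(probs)

  rows <- vector("list", length(genomes) * length(mods))
  pos <- 1L
  for (g in seq_along(genomes)) {
    genome <- genomes[[g]]
    for (m in mods) {
      ev <- evaluate_module(catalog[[m]], genome$kos, limit = limit)
      if (ev$status == "complete") {
        status <- "complete"; prob <- 1; fill <- character(0)
      } else if (m %in% covered) {
        prob <- unname(probs[g, m])
        if (decide_presence(prob, thr) == 1L) {
          status <- "predicted_present"
          fill <- ev$missing_kos
        } else {
          status <- "predicted_absent"
          fill <- character(0)
        }
      } else {
        status <- "no_model"; prob <- NA_real_; fill <- character(0)
      }
      rows[[pos]] <- data.frame(
        genome_id = genome$genome_id, module_id = m, status = status,
        probability = prob, completeness = ev$completeness,
        missing_kos = paste(fill, collapse = ";"),
        stringsAsFactors = FALSE)
      pos <- pos + 1L
    }
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Archive serialization (versioned JSON: architecture + weights +
# ko_universe + partition in one file)

#' Save a fitted classifier to a JSON archive
#'
#' @param object A `module_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_module_classifier <- function(object, path) {
  stopifnot(inherits(object, "module_classifier"))
  pack_net <- function(fit) {
    list(W = lapply(fit$net$W, function(w) unclass(w)),
         b = fit$net$b,
         dims = fit$net$dims,
         labels = fit$labels,
         best_epoch = fit$best_epoch,
         history = fit$history)
  }
  payload <- list(
    format = "kopredict_model", version = 1L,
    ko_universe = object$ko_universe,
    config = unclass(object$config),
    partition = unclass(object$partition),
    balanced = pack_net(object$balanced),
    imbalanced = pack_net(object$imbalanced)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier archive written by [save_module_classifier()]
#'
#' @param path Archive path.
#' @return A `module_classifier`.
#' @export
load_module_classifier <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "kopredict_model")) {
    stop("not a kopredict model archive: ", path, call. = FALSE)
  }
  unpack_net <- function(p) {
    W <- lapply(p$W, function(w) as.matrix(w))
    list(net = list(W = W, b = lapply(p$b, as.numeric), dims = p$dims),
         labels = p$labels, best_epoch = p$best_epoch,
         history = as.data.frame(p$history))
  }
  partition <- payload$partition
  partition$prevalence <- unlist(partition$prevalence)
  class(partition) <- "module_partition"
  config <- payload$config
  class(config) <- "classifier_config"
  structure(list(balanced = unpack_net(payload$balanced),
                 imbalanced = unpack_net(payload$imbalanced),
                 ko_universe = payload$ko_universe,
                 partition = partition,
                 config = config),
            class = "module_classifier")
}
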