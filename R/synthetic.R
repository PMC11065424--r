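# Synthetic module catalogs and genome collections with controlled
# module-prevalence structure, plus annotation downsampling to simulate
# genome incompleteness.

#' Configuration for a synthetic module/genome world
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: 12 modules over a 120-KO universe, 500 genomes, and prevalence
#' targets spanning both the balanced (10--90\%) and imbalanced (<10\% or
#' >90\%) ranges with a mean positive-class rate of 26.25\%.
#'
#' Each module's definition opens with a private "signature" KO (a required
#' single-atom step unique to that module); its remaining atoms are drawn
#' from a small shared pool reused across modules, mirroring how real
#' metabolic modules share enzyme subunits while retaining
#' pathway-specific marker genes. KOs in neither group form a background
#' added independently per genome.
#'
#' @param n_kos Size of the KO universe.
#' @param n_modules Number of modules in the catalog.
#' @param module_size_range Integer (min, max) number of atom KOs per module
#'   (including the private signature KO).
#' @param p_alternative Probability that a step is a two-way alternative.
#' @param n_genomes Number of complete genomes.
#' @param prevalence_targets Per-module target prevalences, recycled to
#'   `n_modules`; must contain values inside and outside [0.10, 0.90].
#' @param background_ko_rate Per-genome inclusion probability of each KO not
#'   used by any module.
#' @param shared_pool_size Number of KOs in the shared pool from which
#'   non-signature module atoms are drawn.
#' @param seed Master seed; the whole world is reproducible from it.
#' @return A `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(n_kos = 120L,
                                   n_modules = 12L,
                                   module_size_range = c(3L, 6L),
                                   p_alternative = 0.3,
                                   n_genomes = 500L,
                                   prevalence_targets = c(
                                     0.03, 0.05, 0.08, 0.10, 0.12, 0.15,
                                     0.20, 0.25, 0.30, 0.40, 0.55, 0.92),
                                   background_ko_rate = 0.10,
                                   shared_pool_size = 20L,
                                   seed = 1L) {
  stopifnot(n_kos >= 1, n_modules >= 1,
            length(module_size_range) == 2L,
            module_size_range[1] >= 1,
            module_size_range[2] >= module_size_range[1],
            p_alternative >= 0, p_alternative <= 1,
            n_genomes >= 2,
            all(prevalence_targets > 0), all(prevalence_targets < 1),
            background_ko_rate >= 0, background_ko_rate <= 1,
            shared_pool_size >= 1)
  prevalence_targets <- rep_len(prevalence_targets, n_modules)
  inside <- prevalence_targets >= 0.10 & prevalence_targets <= 0.90
  if (!any(inside) || all(inside)) {
    stop("prevalence_targets must include values inside and outside ",
         "[0.10, 0.90] so both model partitions are non-empty",
         call. = FALSE)
  }
  if (shared_pool_size < module_size_range[2] - 1L) {
    stop("infeasible config: shared pool smaller than the largest module",
         call. = FALSE)
  }
  if (n_kos < n_modules + shared_pool_size) {
    stop(sprintf(
      "infeasible config: %d KOs cannot host %d signature KOs plus a shared pool of %d",
      n_kos, n_modules, shared_pool_size), call. = FALSE)
  }
  structure(list(n_kos = as.integer(n_kos),
                 n_modules = as.integer(n_modules),
                 module_size_range = as.integer(module_size_range),
                 p_alternative = p_alternative,
                 n_genomes = as.integer(n_genomes),
                 prevalence_targets = prevalence_targets,
                 background_ko_rate = background_ko_rate,
                 shared_pool_size = as.integer(shared_pool_size),
                 seed = as.integer(seed)),
            class = "synthetic_world_config")
}

# Derive a 32-bit child seed from a master seed and a string key, so that
# per-genome / per-fraction draws do not depend on iteration order.
derive_seed <- function(master, key) {
  h <- as.double(master) %% 2147483647
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# evaluate an expression with a private RNG stream, restoring the caller's
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic world of modules and genomes
#'
#' Draws a module catalog whose presence is a deterministic boolean function
#' of KO sets, then genomes realising per-module prevalence targets:
#' genomes assigned positive for a module carry one randomly chosen full
#' completion set; negative genomes carry a random partial subset of the
#' module's atoms and are repaired (by removing the module's private
#' signature KO) whenever shared atoms would accidentally complete the
#' module. KOs used by no module form a background added independently at
#' `background_ko_rate`. Labels are recomputed from the generated genomes
#' with [label_modules()] and are therefore self-consistent by
#' construction.
#'
#' @param config A [synthetic_world_config()].
#' @return A `synthetic_world` list: `catalog` (a `module_catalog`),
#'   `genomes` (list of `genome_annotation`), `labels` (genome x module 0/1
#'   matrix), `ko_universe` and `config`.
#' @export
generate_world <- function(config = synthetic_world_config()) {
  stopifnot(inherits(config, "synthetic_world_config"))
  with_seed(config$seed, {
    ko_pool <- sprintf("K%05d", seq_len(config$n_kos))
    ids <- sprintf("M%04d", seq_len(config$n_modules))
    private <- ko_pool[seq_len(config$n_modules)]            # signature KOs
    shared <- ko_pool[config$n_modules + seq_len(config$shared_pool_size)]

    # --- module catalog: private first step + shared-pool atoms ---------
    shared_draws <- vector("list", config$n_modules)
    sizes <- sample(seq(config$module_size_range[1],
                        config$module_size_range[2]),
                    config$n_modules, replace = TRUE)
    for (m in seq_len(config$n_modules)) {
      shared_draws[[m]] <- sample(shared, sizes[m] - 1L)
    }
    # shared atoms must actually be shared: re-draw any pool KO used by a
    # single module onto one already used twice or more
    usage <- table(unlist(shared_draws))
    lonely <- names(usage)[usage == 1L]
    popular <- names(usage)[usage >= 2L]
    for (ko in lonely) {
      m <- which(vapply(shared_draws, function(d) ko %in% d, NA))
      repl <- setdiff(popular, shared_draws[[m]])
      if (length(repl)) {
        shared_draws[[m]][shared_draws[[m]] == ko] <- repl[1L]
      }
    }
    defs <- character(config$n_modules)
    for (m in seq_len(config$n_modules)) {
      atoms <- shared_draws[[m]]
      steps <- private[m]  # required signature step
      i <- 1L
      while (i <= length(atoms)) {
        left <- length(atoms) - i + 1L
        r <- stats::runif(1)
        if (left >= 2L && r < config$p_alternative) {
          steps <- c(steps, paste0("(", atoms[i], ",", atoms[i + 1L], ")"))
          i <- i + 2L
        } else if (left >= 2L && r < config$p_alternative + 0.2) {
          steps <- c(steps, paste0(atoms[i], "+", atoms[i + 1L]))
          i <- i + 2L
        } else {
          steps <- c(steps, atoms[i])
          i <- i + 1L
        }
      }
      defs[m] <- paste(steps, collapse = " ")
    }
    catalog <- module_catalog(ids, defs)
    module_kos <- lapply(catalog, module_atoms, include_optional = TRUE)
    background <- setdiff(ko_pool, unlist(module_kos))

    # --- prevalence assignment with repair ------------------------------
    n <- config$n_genomes
    assign_mat <- matrix(0L, n, config$n_modules,
                         dimnames = list(sprintf("G%05d", seq_len(n)), ids))
    for (m in seq_len(config$n_modules)) {
      assign_mat[, m] <- stats::rbinom(n, 1L, config$prevalence_targets[m])
      # both classes must exist for training
      if (sum(assign_mat[, m]) == 0L) assign_mat[sample(n, 1L), m] <- 1L
      if (sum(assign_mat[, m]) == n) assign_mat[sample(n, 1L), m] <- 0L
    }

    # --- realize genomes -------------------------------------------------
    completion_sets <- lapply(catalog, enumerate_completion_sets)
    genomes <- vector("list", n)
    for (g in seq_len(n)) {
      kos <- character(0)
      for (m in seq_len(config$n_modules)) {
        if (assign_mat[g, m] == 1L) {
          sets <- completion_sets[[m]]
          kos <- c(kos, sets[[sample(length(sets), 1L)]])
        } else {
          # partial presence: random subset of the module's atoms
          atoms <- module_kos[[m]]
          kos <- c(kos, atoms[stats::runif(length(atoms)) < 0.4])
        }
      }
      kos <- unique(kos)
      # repair: shared atoms (or the subset draw) may have completed a
      # module assigned negative; dropping its private signature KO breaks
      # every completion set of that module and no other
      for (m in seq_len(config$n_modules)) {
        if (assign_mat[g, m] == 0L &&
            any(vapply(completion_sets[[m]],
                       function(s) all(s %in% kos), NA))) {
          kos <- setdiff(kos, private[m])
        }
      }
      if (length(background)) {
        kos <- c(kos,
                 background[stats::runif(length(background)) <
                              config$background_ko_rate])
      }
      genomes[[g]] <- genome_annotation(rownames(assign_mat)[g], kos)
    }

    labels <- label_modules(genomes, catalog)
    if (!identical(unname(labels), unname(assign_mat))) {
      stop("internal error: generated labels disagree with assignment")
    }
    structure(list(catalog = catalog,
                   genomes = genomes,
                   labels = labels,
                   ko_universe = ko_pool,
                   config = config),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d genomes, %d modules, %d KOs (seed %d)\n",
    length(x$genomes), length(x$catalog), length(x$ko_universe),
    x$config$seed))
  prev <- colMeans(x$labels)
  cat(sprintf("  module prevalence: %.2f-%.2f (mean %.3f)\n",
              min(prev), max(prev), mean(prev)))
  invisible(x)
}

#' Downsample a genome's KO annotations
#'
#' Retains `round(retain * |kos|)` KOs (round half up), sampled uniformly
#' without replacement; simulates an incomplete genome while the complete
#' genome's module labels stay the ground truth.
#'
#' @param genome A `genome_annotation`.
#' @param retain Fraction of KOs to retain, in (0, 1]; `retain = 1` returns
#'   the genome unchanged.
#' @param seed Integer seed; sampling is deterministic given it.
#' @return A `genome_annotation` with the retained subset of KOs.
#' @export
downsample_annotation <- function(genome, retain, seed = 1L) {
  stopifnot(inherits(genome, "genome_annotation"),
            retain > 0, retain <= 1)
  if (retain == 1 || length(genome$kos) == 0L) return(genome)
  n <- length(genome$kos)
  n_keep <- as.integer(floor(retain * n + 0.5))  # round half up
  kept <- with_seed(seed, sample(genome$kos, n_keep))
  genome_annotation(genome$genome_id, kept)
}

#' A downsampling scheme
#'
#' @param retain_fractions Fractions of annotations to retain; default the
#'   10--90\% grid in steps of 10\%.
#' @param seed Master seed; per-genome, per-fraction child seeds are derived
#'   by hashing the genome id and fraction, so results do not depend on
#'   iteration order.
#' @return A `downsample_scheme` list.
#' @export
downsample_scheme <- function(retain_fractions = seq(0.1, 0.9, by = 0.1),
                              seed = 1L) {
  stopifnot(all(retain_fractions > 0), all(retain_fractions <= 1))
  structure(list(retain_fractions = retain_fractions,
                 seed = as.integer(seed)),
            class = "downsample_scheme")
}

#' Number of observations after downsampling expansion
#'
#' Every complete genome contributes itself plus one downsampled copy per
#' retain fraction, so the expanded collection has
#' `n_genomes * (1 + n_fractions)` observations.
#'
#' @param n_genomes Number of complete genomes.
#' @param retain_fractions The scheme's retain fractions (or their count).
#' @return Integer observation count.
#' @export
expansion_count <- function(n_genomes, retain_fractions) {
  k <- if (length(retain_fractions) == 1L && retain_fractions >= 1) {
    as.integer(retain_fractions)
  } else {
    length(retain_fractions)
  }
  as.integer(n_genomes) * (1L + k)
}

#' Expand genomes with downsampled variants
#'
#' Returns the complete genomes plus one downsampled copy per retain
#' fraction; each copy inherits its complete genome's label row verbatim.
#'
#' @param genomes List of complete `genome_annotation` objects.
#' @param labels Label matrix computed on the complete genomes
#'   (rows aligned with `genomes`).
#' @param scheme A [downsample_scheme()].
#' @return A list with `genomes` (length `n * (1 + k)`), `labels` (matching
#'   rows), and `retain` (numeric vector; 1 for the complete originals).
#' @export
expand_with_downsampled <- function(genomes, labels, scheme) {
  stopifnot(inherits(scheme, "downsample_scheme"),
            nrow(labels) == length(genomes))
  fr <- scheme$retain_fractions
  total <- expansion_count(length(genomes), fr)
  out <- vector("list", total)
  retain <- numeric(total)
  lab <- matrix(0L, total, ncol(labels),
                dimnames = list(NULL, colnames(labels)))
  pos <- 1L
  ids <- character(total)
  for (g in seq_along(genomes)) {
    out[[pos]] <- genomes[[g]]
    ids[pos] <- genomes[[g]]$genome_id
    retain[pos] <- 1
    lab[pos, ] <- labels[g, ]
    pos <- pos + 1L
    for (f in fr) {
      child <- derive_seed(scheme$seed,
                           paste0(genomes[[g]]$genome_id, "|", f))
      ds <- downsample_annotation(genomes[[g]], f, seed = child)
      ds$genome_id <- sprintf("%s|r%02d", genomes[[g]]$genome_id,
                              round(100 * f))
      out[[pos]] <- ds
      ids[pos] <- ds$genome_id
      retain[pos] <- f
      lab[pos, ] <- labels[g, ]
      pos <- pos + 1L
    }
  }
  rownames(lab) <- ids
  list(genomes = out, labels = lab, retain = retain)
}
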