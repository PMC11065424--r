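# Reading KO annotations and building presence/absence matrices.

ko_token_re <- "^[A-Za-z0-9][A-Za-z0-9_.]*$"

#' Construct a genome annotation
#'
#' @param genome_id Genome identifier.
#' @param kos Character vector of KO identifiers (duplicates collapse).
#' @return An object of class `genome_annotation` with fields `genome_id`
#'   and `kos` (sorted, unique).
#' @export
genome_annotation <- function(genome_id, kos = character(0)) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            nzchar(genome_id))
  kos <- as.character(kos)
  bad <- kos[!grepl(ko_token_re, kos)]
  if (length(bad)) {
    stop("invalid KO identifier(s): ", paste(utils::head(bad, 3),
                                             collapse = ", "),
         call. = FALSE)
  }
  structure(list(genome_id = genome_id, kos = sort(unique(kos))),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d KO(s)\n",
              x$genome_id, length(x$kos)))
  invisible(x)
}

#' Read KO annotations for one genome
#'
#' Supported dialects:
#' \describe{
#'   \item{`kofamscan`}{KofamScan detail format (columns: significance flag,
#'     gene, KO, threshold, score, e-value, definition). Only rows flagged
#'     `*` — annotations above the HMM's adaptive scoring threshold —
#'     contribute their KO. The two-column mapper format (gene, KO) is
#'     auto-detected and accepted as well.}
#'   \item{`koala`}{blastKOALA/ghostKOALA-style two-column TSV (gene, KO);
#'     rows with an empty KO column are skipped.}
#'   \item{`kolist`}{one KO identifier per line.}
#' }
#' Lines starting with `#` and blank lines are ignored in all dialects;
#' duplicate KOs collapse to a set.
#'
#' @param path Path to the annotation file.
#' @param format One of `"kofamscan"`, `"koala"`, `"kolist"`.
#' @param genome_id Genome identifier; defaults to the file name without
#'   extension.
#' @return A `genome_annotation`.
#' @export
read_annotations <- function(path,
                             format = c("kofamscan", "koala", "kolist"),
                             genome_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  if (is.null(genome_id)) {
    genome_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)

  kos <- switch(format,
    kolist = {
      out <- character(0)
      for (i in idx) {
        tok <- trimws(lines[i])
        if (!grepl(ko_token_re, tok) || grepl("\\s", tok)) {
          stop(sprintf("parse error at line %d of %s: not a KO identifier",
                       i, path), call. = FALSE)
        }
        out <- c(out, tok)
      }
      out
    },
    koala = {
      out <- character(0)
      for (i in idx) {
        fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(fields) < 1L || length(fields) > 2L) {
          stop(sprintf("parse error at line %d of %s: expected 2 columns",
                       i, path), call. = FALSE)
        }
        ko <- if (length(fields) == 2L) trimws(fields[2]) else ""
        if (!nzchar(ko)) next  # unannotated gene
        if (!grepl(ko_token_re, ko)) {
          stop(sprintf(
            "parse error at line %d of %s: non-KO token in KO column",
            i, path), call. = FALSE)
        }
        out <- c(out, ko)
      }
      out
    },
    kofamscan = {
      body <- lines[idx]
      detail <- any(grepl("^[* ]", body))
      out <- character(0)
      for (i in idx) {
        line <- lines[i]
        if (detail) {
          flagged <- startsWith(line, "*")
          if (!flagged) next  # below the adaptive threshold
          fields <- strsplit(trimws(sub("^\\*", "", line)), "\\s+")[[1]]
          if (length(fields) < 2L) {
            stop(sprintf(
              "parse error at line %d of %s: too few columns for %s",
              i, path, "kofamscan detail format"), call. = FALSE)
          }
          ko <- fields[2]
        } else {
          fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
          if (length(fields) < 2L || !nzchar(trimws(fields[2]))) next
          ko <- trimws(fields[2])
        }
        if (!grepl(ko_token_re, ko)) {
          stop(sprintf(
            "parse error at line %d of %s: non-KO token in KO column",
            i, path), call. = FALSE)
        }
        out <- c(out, ko)
      }
      out
    }
  )
  genome_annotation(genome_id, kos)
}

#' Write a genome annotation as a KO list
#'
#' @param annotation A `genome_annotation`.
#' @param path Output path (one KO per line).
#' @return `path`, invisibly.
#' @export
write_annotation_kolist <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  writeLines(annotation$kos, path)
  invisible(path)
}

#' Build a KO presence/absence feature matrix
#'
#' One row per genome, one column per KO in the universe; entry 1 when the
#' genome carries the KO. KOs outside the universe are dropped (their count
#' is reported via `message()`); the universe is fixed at training time and
#' never extended at prediction time.
#'
#' @param annotations List of `genome_annotation` objects.
#' @param ko_universe Sorted, duplicate-free character vector of KOs.
#' @return Integer matrix with `genome_id` row names and KO column names.
#' @export
build_feature_matrix <- function(annotations, ko_universe) {
  if (length(ko_universe) == 0L) stop("empty KO universe", call. = FALSE)
  ko_universe <- as.character(ko_universe)
  if (anyDuplicated(ko_universe)) stop("duplicated KOs in universe",
                                       call. = FALSE)
  if (is.unsorted(ko_universe)) stop("KO universe must be sorted",
                                     call. = FALSE)
  if (inherits(annotations, "genome_annotation")) {
    annotations <- list(annotations)
  }
  ids <- vapply(annotations, function(a) a$genome_id, "")
  if (anyDuplicated(ids)) stop("duplicated genome ids", call. = FALSE)
  m <- matrix(0L, nrow = length(annotations), ncol = length(ko_universe),
              dimnames = list(ids, ko_universe))
  dropped <- 0L
  for (i in seq_along(annotations)) {
    kos <- annotations[[i]]$kos
    hit <- kos %in% ko_universe
    dropped <- dropped + sum(!hit)
    m[i, kos[hit]] <- 1L
  }
  if (dropped > 0L) {
    message(sprintf("build_feature_matrix: dropped %d KO(s) outside the universe",
                    dropped))
  }
  m
}

#' Label module presence for a collection of genomes
#'
#' @param annotations List of `genome_annotation` objects.
#' @param catalog A `module_catalog`.
#' @param limit Completion-set enumeration limit per module.
#' @return Integer 0/1 matrix, genomes in rows, modules in columns; entry 1
#'   when [evaluate_module()] reports the module complete.
#' @export
label_modules <- function(annotations, catalog, limit = 10000L) {
  stopifnot(inherits(catalog, "module_catalog"))
  if (inherits(annotations, "genome_annotation")) {
    annotations <- list(annotations)
  }
  ids <- vapply(annotations, function(a) a$genome_id, "")
  m <- matrix(0L, nrow = length(annotations), ncol = length(catalog),
              dimnames = list(ids, names(catalog)))
  for (j in seq_along(catalog)) {
    ast <- catalog[[j]]
    # enumerate once per module, reuse across genomes
    sets <- tryCatch(enumerate_completion_sets(ast, limit = limit),
                     kopredict_enumeration_overflow = function(e) NULL)
    for (i in seq_along(annotations)) {
      kos <- annotations[[i]]$kos
      complete <- if (!is.null(sets)) {
        any(vapply(sets, function(s) all(s %in% kos), NA))
      } else {
        identical(evaluate_module(ast, kos, limit = limit,
                                  method = "recursive")$status, "complete")
      }
      if (complete) m[i, j] <- 1L
    }
  }
  m
}

#' Write a 0/1 matrix (features or labels) to TSV
#'
#' Header row of column ids, first column `genome_id`; values 0/1. The
#' round trip through [read_matrix_tsv()] is bit-exact.
#'
#' @param m Integer matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(genome_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 0/1 matrix written by [write_matrix_tsv()]
#'
#' @param path Input path.
#' @return Integer matrix with `genome_id` row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$genome_id
  m
}

# union of KO sets across annotations, sorted: a training-time universe
#' Derive a sorted KO universe from annotations and/or a catalog
#'
#' @param annotations Optional list of `genome_annotation` objects.
#' @param catalog Optional `module_catalog` whose atom KOs are included.
#' @return Sorted character vector of KO identifiers.
#' @export
ko_universe <- function(annotations = NULL, catalog = NULL) {
  kos <- character(0)
  if (!is.null(annotations)) {
    if (inherits(annotations, "genome_annotation")) {
      annotations <- list(annotations)
    }
    kos <- c(kos, unlist(lapply(annotations, function(a) a$kos)))
  }
  if (!is.null(catalog)) {
    kos <- c(kos, unlist(lapply(catalog, module_atoms,
                                include_optional = TRUE)))
  }
  if (!length(kos)) stop("no KOs to build a universe from", call. = FALSE)
  sort(unique(kos))
}
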