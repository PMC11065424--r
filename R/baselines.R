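# The two naive classification rules used as benchmark competitors.

#' Proportional-completeness rule
#'
#' Classifies a module as present in a downsampled annotation set when the
#' proportion of the module's genes still present is at least the overall
#' proportion of annotations retained. The module's gene set defaults to
#' its atom KOs present in the complete genome (`denominator =
#' "complete"`); `denominator = "definition"` uses all atom KOs of the
#' definition instead. Optional components are excluded either way. A
#' module with an empty gene set is classified absent.
#'
#' @param downsampled The downsampled `genome_annotation`.
#' @param complete The complete `genome_annotation` the downsampling
#'   started from.
#' @param ast The module's `module_ast`.
#' @param retain Fraction of annotations retained during downsampling.
#' @param denominator `"complete"` or `"definition"`.
#' @return Integer 0/1.
#' @export
proportional_rule <- function(downsampled, complete, ast, retain,
                              denominator = c("complete", "definition")) {
  stopifnot(retain > 0, retain <= 1)
  denominator <- match.arg(denominator)
  atoms <- module_atoms(ast, include_optional = FALSE)
  genes <- if (denominator == "complete") {
    intersect(atoms, complete$kos)
  } else {
    atoms
  }
  if (length(genes) == 0L) return(0L)
  frac <- sum(genes %in% downsampled$kos) / length(genes)
  as.integer(frac >= retain)
}

#' Unique-gene rule
#'
#' A KO is unique to a module when it appears among that module's atoms and
#' in no other catalog module. The rule classifies a module as present when
#' the genome carries at least one KO unique to it; modules with no unique
#' KOs are always classified absent.
#'
#' @param genome A `genome_annotation`.
#' @param catalog A `module_catalog`.
#' @return Named integer 0/1 vector over catalog modules.
#' @export
unique_gene_rule <- function(genome, catalog) {
  stopifnot(inherits(catalog, "module_catalog"), length(catalog) > 0)
  uniq <- unique_module_kos(catalog)
  out <- vapply(names(catalog), function(m) {
    as.integer(length(uniq[[m]]) > 0L && any(uniq[[m]] %in% genome$kos))
  }, 0L)
  names(out) <- names(catalog)
  out
}

# KOs unique to each module (relative to all other catalog modules);
# optional components excluded for consistency with presence labeling
unique_module_kos <- function(catalog) {
  atom_sets <- lapply(catalog, module_atoms, include_optional = FALSE)
  all_kos <- unlist(atom_sets)
  counts <- table(all_kos)
  shared <- names(counts)[counts > 1L]
  lapply(atom_sets, function(a) setdiff(a, shared))
}
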