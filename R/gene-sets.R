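#' Generate a synthetic gene-set collection
#'
#' Draws `n_sets` random gene sets from a gene universe, optionally adding
#' one "enriched" set built from a supplied pool of genes (e.g. simulated
#' ATC-induced markers) so that downstream enrichment analysis has a known
#' positive.
#'
#' @param gene_ids Character vector: the gene universe.
#' @param n_sets Number of random sets.
#' @param set_size_range Integer pair: sizes drawn uniformly in this range.
#' @param enriched_set Optional character vector of genes forming an
#'   additional set named `ENRICHED_SET`; must be a subset of `gene_ids`.
#' @param seed Integer seed; fixed seed gives identical collections (and
#'   identical GMT bytes through [write_gmt()]).
#' @return Named list of character vectors (a gene-set collection).
#' @export
make_gene_sets <- function(gene_ids, n_sets = 10L,
                           set_size_range = c(15L, 50L),
                           enriched_set = NULL, seed = 1L) {
  if (max(set_size_range) > length(gene_ids))
    stop("set sizes exceed the size of the gene universe", call. = FALSE)
  if (!is.null(enriched_set) && !all(enriched_set %in% gene_ids))
    stop("'enriched_set' must be a subset of 'gene_ids'", call. = FALSE)
  with_seed(seed, {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                    replace = TRUE)
    sets <- lapply(sizes, function(k) sample(gene_ids, k))
    names(sets) <- sprintf("RANDOM_SET_%02d", seq_len(n_sets))
    if (!is.null(enriched_set)) sets$ENRICHED_SET <- unique(enriched_set)
    sets
  })
}

#' Write a gene-set collection to GMT
#'
#' One line per set: name, description, then tab-separated member genes.
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names", call. = FALSE)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
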