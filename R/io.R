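#' Read / write a count matrix as TSV
#'
#' Genes as rows, first column the gene id, samples as remaining columns.
#'
#' @param path File path.
#' @return `read_counts`: integer matrix with dimnames.
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids", call. = FALSE)
  m
}

#' @rdname read_counts
#' @param counts Integer matrix, genes x samples.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet (TSV: sample_id, class, cohort)
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class")
  if (!all(need %in% names(d)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

#' Packaged thyroid IHC cohort count table
#'
#' Marker positivity counts (any detectable expression) for IGF2BP1,
#' MAGEA3 and MYC across three thyroid tumor cohorts: an RNA-seq test
#' cohort (10 ATC, 6 PTC, 6 FTC), an in-house tissue microarray
#' (20 ATC, 18 PDTC, 82 PTC, 29 FTC) and a commercial tissue microarray
#' (6 ATC, 44 PTC, 20 FTC). Pooled, this gives 36 ATC and 205 non-ATC
#' carcinomas — the input of the diagnostic-accuracy stage.
#'
#' @return Data frame: `cohort`, `tumor_class`, `marker`, `n_total`,
#'   `n_positive`.
#' @export
thyroid_cohort_counts <- function() {
  path <- system.file("extdata", "thyroid_cohort_counts.csv",
                      package = "atcmarkers", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Packaged cancer-testis gene list
#'
#' Gene symbols of reported cancer-testis (germline-restricted) antigens
#' used to annotate the marker screen, one symbol per line.
#'
#' @return Character vector of gene symbols.
#' @export
ct_gene_list <- function() {
  path <- system.file("extdata", "cancer_testis_genes.txt",
                      package = "atcmarkers", mustWork = TRUE)
  readLines(path)
}
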