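#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample normalization after Robinson & Oshlack: for each sample
#' against a reference, per-gene log2 expression ratios (M) are doubly
#' trimmed — 30% on each tail of M and 5% on each tail of the average log2
#' abundance (A) — and the surviving M values are averaged with inverse
#' asymptotic-variance (delta-method binomial) weights. Factors are rescaled
#' so their geometric mean is 1.
#'
#' Genes with a zero count in either the sample or the reference are dropped
#' before trimming. If no genes survive, the factor falls back to 1 with a
#' warning. The reference sample, when not given, is the column whose
#' library-size-scaled upper quartile is closest to the mean upper quartile.
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   column names.
#' @param reference Column name or index of the reference sample, or `NULL`
#'   for automatic choice.
#' @param logratio_trim,abundance_trim Two-sided trim fractions on M and A.
#' @return A list of class `norm_factors`: `factors` (named, geometric mean
#'   1), `lib_sizes` (column sums), `eff_lib_sizes` (their product), and
#'   `reference`.
#' @export
tmm_norm_factors <- function(counts, reference = NULL,
                             logratio_trim = 0.3, abundance_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two samples", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lib_sizes <- colSums(counts)
  if (any(lib_sizes == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[lib_sizes == 0], collapse = ", "), call. = FALSE)

  if (is.null(reference)) {
    uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib_sizes
    reference <- which.min(abs(uq - mean(uq)))
  } else if (is.character(reference)) {
    reference <- match(reference, colnames(counts))
    if (is.na(reference)) stop("reference sample not found", call. = FALSE)
  }

  f <- vapply(seq_len(ncol(counts)), function(s) {
    tmm_pair_factor(counts[, s], counts[, reference],
                    lib_sizes[s], lib_sizes[reference],
                    logratio_trim, abundance_trim,
                    sample_name = colnames(counts)[s])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  structure(list(factors = f, lib_sizes = lib_sizes,
                 eff_lib_sizes = lib_sizes * f,
                 reference = reference),
            class = "norm_factors")
}

# One sample against the reference: doubly trimmed, precision-weighted mean
# of per-gene log2 ratios. Rank-based trimming keeps a gene only when its M
# rank lies within [floor(n*trim)+1, n-floor(n*trim)] and likewise for A.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim, abundance_trim, sample_name = "") {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0L) {
    warning("no genes shared with the reference for sample ", sample_name,
            "; factor set to 1")
    return(1)
  }
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  M <- log2(p_obs / p_ref)
  A <- 0.5 * log2(p_obs * p_ref)
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)

  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abundance_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) {
    warning("no genes survive TMM trimming for sample ", sample_name,
            "; factor set to 1")
    return(1)
  }
  lf <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(lf)) return(1)
  2^lf
}

#' Fragments per million on TMM-effective library sizes
#'
#' `FPM[g, s] = counts[g, s] / (lib_size_s * factor_s) * 1e6`. With all
#' factors equal to 1 every column sums to one million.
#'
#' @param counts Count matrix, genes x samples.
#' @param factors A `norm_factors` object aligned to the columns of
#'   `counts`, or `NULL` to compute TMM factors first.
#' @return Numeric matrix of FPM values.
#' @export
compute_fpm <- function(counts, factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- tmm_norm_factors(counts)
  stopifnot(inherits(factors, "norm_factors"))
  eff <- factors$eff_lib_sizes
  if (length(eff) != ncol(counts))
    stop("normalization factors do not match the sample columns", call. = FALSE)
  if (any(eff <= 0)) stop("zero effective library size", call. = FALSE)
  sweep(counts, 2, eff, "/") * 1e6
}
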