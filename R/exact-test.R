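#' Negative-binomial conditional exact test
#'
#' Two-group per-gene test in the style of the classic exact NB test for
#' RNA-seq: effective library sizes are first equalized by mean-preserving
#' scaling of the counts to their geometric-mean library size (rounded back
#' to integers); within each group the scaled counts are summed; and the
#' two-sided p-value is computed from the conditional distribution of one
#' group's total given the overall total under NB(phi) — a negative
#' hypergeometric that is free of the unknown mean. The p-value is the
#' tie-inclusive minimum-likelihood ("exact double") tail: the sum of all
#' conditional probabilities not exceeding that of the observed split,
#' capped at 1. With `phi = 0` the conditional law is binomial (Poisson
#' limit).
#'
#' Log2 fold changes are computed on FPM group means with a prior count of
#' `prior_count` per group (expressed in FPM through the mean effective
#' library size), which keeps estimates finite for genes unexpressed in one
#' group — exactly the genes the de novo screen targets.
#'
#' @param counts Count matrix, genes x samples.
#' @param group Factor with exactly two levels; positive log2 fold change
#'   means higher expression in the second level.
#' @param dispersion Common NB dispersion phi (>= 0), e.g. from
#'   [estimate_common_dispersion()].
#' @param factors Optional `norm_factors`; computed by TMM when `NULL`.
#' @param prior_count Prior count per group for the fold-change offset.
#' @return A data.frame with one row per gene: `gene`, `log2_fc`,
#'   `p_value`, `fdr` (Benjamini–Hochberg), `mean_fpm_test` (second level),
#'   `mean_fpm_ref` (first level), `mean_fpm`. The comparison levels are
#'   stored in `attr(, "comparison")`.
#' @export
nb_exact_test <- function(counts, group, dispersion, factors = NULL,
                          prior_count = 0.125) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2L)
    stop("'group' must have exactly two levels", call. = FALSE)
  if (any(table(group) == 0L)) stop("empty group", call. = FALSE)
  if (inherits(dispersion, "dispersion_estimate")) dispersion <- dispersion$phi
  if (!is.numeric(dispersion) || dispersion < 0)
    stop("'dispersion' must be a non-negative number", call. = FALSE)
  if (is.null(factors)) factors <- tmm_norm_factors(counts)

  eff <- factors$eff_lib_sizes
  common <- exp(mean(log(eff)))
  z <- round(sweep(counts, 2, common / eff, "*"))

  ref_cols <- group == levels(group)[1]
  test_cols <- group == levels(group)[2]
  n_ref <- sum(ref_cols); n_test <- sum(test_cols)
  y_ref <- rowSums(z[, ref_cols, drop = FALSE])
  y_test <- rowSums(z[, test_cols, drop = FALSE])

  p <- vapply(seq_len(nrow(counts)), function(g) {
    nb_exact_pvalue(y_test[g], y_ref[g], n_test, n_ref, dispersion)
  }, numeric(1))

  fpm <- compute_fpm(counts, factors)
  prior_fpm <- prior_count * 1e6 / mean(eff)
  m_ref <- rowMeans(fpm[, ref_cols, drop = FALSE])
  m_test <- rowMeans(fpm[, test_cols, drop = FALSE])
  log2_fc <- log2((m_test + prior_fpm) / (m_ref + prior_fpm))

  res <- data.frame(
    gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    log2_fc = log2_fc, p_value = p, fdr = bh_fdr(p),
    mean_fpm_test = m_test, mean_fpm_ref = m_ref,
    mean_fpm = rowMeans(fpm), row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "comparison") <- paste(levels(group)[2], "vs", levels(group)[1])
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided conditional exact p-value for one gene.
# y_a, y_b: integer group totals after library-size equalization;
# n_a, n_b: group sizes; phi: common dispersion (0 -> Poisson/binomial).
# Conditional pmf of the group-A total X given T = y_a + y_b is computed on
# its integer support; for very large totals the support is restricted to
# windows around the conditional mode and the observation outside which
# probabilities are negligible (< 1e-12 of the p-value).
nb_exact_pvalue <- function(y_a, y_b, n_a, n_b, phi) {
  t_tot <- y_a + y_b
  if (t_tot == 0) return(1)
  m <- t_tot / (n_a + n_b)  # per-sample common mean (cancels conditionally)

  logf <- function(x) {
    if (phi > 0) {
      stats::dnbinom(x, size = n_a / phi, mu = n_a * m, log = TRUE) +
        stats::dnbinom(t_tot - x, size = n_b / phi, mu = n_b * m, log = TRUE)
    } else {
      stats::dpois(x, n_a * m, log = TRUE) +
        stats::dpois(t_tot - x, n_b * m, log = TRUE)
    }
  }

  if (t_tot <= 50000) {
    support <- 0:t_tot
  } else {
    p_a <- n_a / (n_a + n_b)
    sd_c <- sqrt(t_tot * p_a * (1 - p_a) * (1 + phi * m))
    w <- max(2000, ceiling(60 * sd_c))
    mode_c <- round(t_tot * p_a)
    support <- sort(unique(c(
      max(0, mode_c - w):min(t_tot, mode_c + w),
      max(0, y_a - w):min(t_tot, y_a + w))))
  }

  lf <- logf(support)
  lz <- max(lf) + log(sum(exp(lf - max(lf))))
  lf_obs <- lf[match(y_a, support)]
  keep <- lf <= lf_obs + 1e-8  # tie-inclusive, tolerant to rounding
  min(1, sum(exp(lf[keep] - lz)))
}

#' Benjamini–Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotone enforcement (delegates to
#' [stats::p.adjust()] after validating the input).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' PCA embedding of log expression for cohort QC
#'
#' Singular-value decomposition of `log2(FPM + pseudocount)`, gene-centered,
#' as used to check that tumor classes separate in expression space.
#'
#' @param fpm FPM matrix, genes x samples.
#' @param n_components Number of components to return.
#' @param pseudocount Added before the log transform.
#' @return List: `coords` (samples x components) and `explained_variance`
#'   (fractions, non-increasing).
#' @export
pca_embed <- function(fpm, n_components = 2L, pseudocount = 1) {
  fpm <- as.matrix(fpm)
  if (ncol(fpm) < 2L) stop("PCA needs at least two samples", call. = FALSE)
  if (n_components > min(dim(fpm)))
    stop("'n_components' exceeds the matrix rank bound", call. = FALSE)
  x <- t(log2(fpm + pseudocount))          # samples x genes
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)])
}
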