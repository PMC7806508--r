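#' Relative standard deviation of expression in ATC
#'
#' The screen's consistency statistic: per gene, the sample standard
#' deviation (n - 1 denominator) of FPM across ATC samples divided by the
#' ATC mean. Genes with zero ATC mean have undefined RSD and are returned
#' as `NA` (they are excluded from ranking).
#'
#' @param fpm FPM matrix, genes x samples.
#' @param atc_samples Column names (or indices) of the ATC samples; at
#'   least two.
#' @return Named numeric vector of RSD values (`NA` where undefined).
#' @export
compute_rsd <- function(fpm, atc_samples) {
  fpm <- as.matrix(fpm)
  x <- fpm[, atc_samples, drop = FALSE]
  if (ncol(x) < 2L) stop("RSD needs at least two ATC samples", call. = FALSE)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  rsd <- ifelse(mu > 0, sdv / mu, NA_real_)
  names(rsd) <- rownames(fpm)
  rsd
}

#' Thresholds of the de novo expression screen
#'
#' @param max_noatc_mean_fpm Genes must have mean FPM strictly below this in
#'   the non-ATC samples (default 1).
#' @param min_fold_change ATC / non-ATC fold change must strictly exceed
#'   this (default 50).
#' @param max_fdr FDR threshold, non-strict (default 0.01).
#' @param top_k Number of markers retained after RSD ranking (default 20).
#' @return A list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(max_noatc_mean_fpm = 1, min_fold_change = 50,
                              max_fdr = 0.01, top_k = 20L) {
  if (max_noatc_mean_fpm <= 0 || min_fold_change <= 0 || max_fdr <= 0)
    stop("screen thresholds must be positive", call. = FALSE)
  if (top_k < 1) stop("'top_k' must be at least 1", call. = FALSE)
  structure(list(max_noatc_mean_fpm = max_noatc_mean_fpm,
                 min_fold_change = min_fold_change,
                 max_fdr = max_fdr, top_k = as.integer(top_k)),
            class = "screen_thresholds")
}

#' De novo expression filter
#'
#' Selects ATC-exclusive candidates from a differential-expression table:
#' mean FPM in non-ATC samples strictly below `max_noatc_mean_fpm`, ATC
#' versus non-ATC fold change strictly above `min_fold_change`, and FDR at
#' most `max_fdr`. The fold change is `2^log2_fc`, i.e. the ratio of
#' prior-offset group means, consistent with the DE fold change (a raw
#' ratio would be infinite for exactly the de novo genes of interest).
#'
#' @param de Differential-expression table from [nb_exact_test()] with the
#'   ATC group as test level (columns `gene`, `log2_fc`, `fdr`,
#'   `mean_fpm_test`, `mean_fpm_ref`).
#' @param thresholds A [screen_thresholds()].
#' @return Character vector of candidate gene ids.
#' @export
de_novo_filter <- function(de, thresholds = screen_thresholds()) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  need <- c("gene", "log2_fc", "fdr", "mean_fpm_ref")
  if (!all(need %in% names(de)))
    stop("'de' lacks columns: ", paste(setdiff(need, names(de)), collapse = ", "),
         call. = FALSE)
  if (nrow(de) == 0L) return(character(0))
  pass <- de$mean_fpm_ref < thresholds$max_noatc_mean_fpm &
    2^de$log2_fc > thresholds$min_fold_change &
    de$fdr <= thresholds$max_fdr
  de$gene[pass]
}

#' Rank de novo candidates by RSD and annotate cancer-testis genes
#'
#' Candidates are ordered by increasing RSD (most consistent ATC expression
#' first); ties are broken by ascending FDR, then by gene id. The top
#' `top_k` are retained and flagged against a cancer-testis gene list.
#'
#' @param candidates Character vector of candidate gene ids (from
#'   [de_novo_filter()]).
#' @param de The differential-expression table the candidates came from.
#' @param rsd Named RSD vector (from [compute_rsd()]); every candidate must
#'   have a finite value — candidates with undefined RSD are an error,
#'   genes with zero ATC mean must be excluded upstream.
#' @param top_k Number of markers to retain.
#' @param ct_genes Character vector of cancer-testis gene symbols.
#' @return Data frame of marker records: `rank`, `gene`, `mean_fpm_atc`,
#'   `mean_fpm_noatc`, `log2_fc`, `fdr`, `rsd`, `is_cancer_testis`.
#' @export
rank_markers <- function(candidates, de, rsd, top_k = 20L,
                         ct_genes = character(0)) {
  if (length(candidates) == 0L) {
    return(data.frame(rank = integer(0), gene = character(0),
                      mean_fpm_atc = numeric(0), mean_fpm_noatc = numeric(0),
                      log2_fc = numeric(0), fdr = numeric(0), rsd = numeric(0),
                      is_cancer_testis = logical(0)))
  }
  r <- rsd[candidates]
  if (any(is.na(r)))
    stop("RSD missing or undefined for candidate(s): ",
         paste(candidates[is.na(r)], collapse = ", "), call. = FALSE)
  d <- de[match(candidates, de$gene), ]
  ord <- order(r, d$fdr, candidates)
  keep <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(
    rank = seq_along(keep),
    gene = candidates[keep],
    mean_fpm_atc = d$mean_fpm_test[keep],
    mean_fpm_noatc = d$mean_fpm_ref[keep],
    log2_fc = d$log2_fc[keep],
    fdr = d$fdr[keep],
    rsd = unname(r[keep]),
    is_cancer_testis = candidates[keep] %in% ct_genes,
    stringsAsFactors = FALSE)
}

#' Run the full ATC marker screen on a cohort
#'
#' Convenience wrapper chaining TMM normalization, FPM, common-dispersion
#' estimation, the NB exact test of ATC against all other samples
#' ("noATC"), the de novo filter, RSD ranking and cancer-testis annotation.
#'
#' @param counts Count matrix, genes x samples.
#' @param samples Sample sheet with columns `sample_id` and `class`
#'   (classes among ATC, PTC, FTC, PDTC, NT), aligned to the matrix
#'   columns by `sample_id`.
#' @param ct_genes Cancer-testis gene list.
#' @param thresholds A [screen_thresholds()].
#' @return List: `markers` (ranked marker table), `candidates`, `de`
#'   (full DE table with `mean_fpm_atc` / `mean_fpm_noatc` aliases), `rsd`,
#'   `factors`, `dispersion`.
#' @export
run_marker_screen <- function(counts, samples, ct_genes = character(0),
                              thresholds = screen_thresholds()) {
  counts <- as.matrix(counts)
  if (!all(colnames(counts) %in% samples$sample_id))
    stop("sample sheet does not cover all matrix columns", call. = FALSE)
  cls <- samples$class[match(colnames(counts), samples$sample_id)]
  if (!any(cls == "ATC")) stop("no ATC samples in the cohort", call. = FALSE)
  group <- factor(ifelse(cls == "ATC", "ATC", "noATC"),
                  levels = c("noATC", "ATC"))

  factors <- tmm_norm_factors(counts)
  fpm <- compute_fpm(counts, factors)
  disp <- estimate_common_dispersion(counts, group, factors)
  de <- nb_exact_test(counts, group, disp, factors)
  de$mean_fpm_atc <- de$mean_fpm_test
  de$mean_fpm_noatc <- de$mean_fpm_ref

  rsd <- compute_rsd(fpm, which(group == "ATC"))
  candidates <- de_novo_filter(de, thresholds)
  candidates <- candidates[!is.na(rsd[candidates])]  # zero ATC mean: no RSD
  markers <- rank_markers(candidates, de, rsd, thresholds$top_k, ct_genes)

  list(markers = markers, candidates = candidates, de = de, rsd = rsd,
       factors = factors, dispersion = disp)
}
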