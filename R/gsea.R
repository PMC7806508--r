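#' Rank genes by fold change for preranked GSEA
#'
#' @param de Differential-expression table with columns `gene` and
#'   `log2_fc`.
#' @return Named numeric vector of scores, sorted by descending log2 fold
#'   change; ties are broken by ascending gene id so the order is
#'   deterministic.
#' @export
rank_by_fold_change <- function(de) {
  if (anyDuplicated(de$gene)) stop("duplicate gene ids", call. = FALSE)
  if (any(!is.finite(de$log2_fc))) stop("ranking scores must be finite", call. = FALSE)
  ord <- order(-de$log2_fc, de$gene)
  stats::setNames(de$log2_fc[ord], de$gene[ord])
}

#' Weighted Kolmogorov–Smirnov enrichment score
#'
#' Classic GSEA running sum over a ranked gene list: at each gene in the
#' set ("hit") the sum increases by `|score|^weight` normalized by the sum
#' over all hits; at each miss it decreases by `1/(N - N_hits)`. The
#' enrichment score is the signed extremum of the running sum.
#'
#' @param scores Named numeric vector of ranking scores; re-sorted to
#'   descending order internally (ties by gene id).
#' @param gene_set Character vector of member genes.
#' @param weight Exponent on the scores (classic default 1; 0 gives the
#'   unweighted KS statistic).
#' @return List: `es`, `running` (the full running-sum profile, one value
#'   per gene, ending at 0), `hit_index` (positions of the set in the
#'   ranked list), and `leading_edge` (set genes at or before / after the
#'   extremum for positive / negative ES).
#' @export
enrichment_score <- function(scores, gene_set, weight = 1) {
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  n <- length(scores)
  hit <- names(scores) %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set does not intersect the universe", call. = FALSE)
  if (n_hit == n)
    stop("gene set covers the whole universe; miss decrement undefined",
         call. = FALSE)
  w <- abs(scores)^weight
  w_hit <- w * hit
  nr <- sum(w_hit)
  inc <- if (nr > 0) w_hit / nr else hit / n_hit  # all-zero hit scores: equal weights
  dec <- (!hit) / (n - n_hit)
  running <- unname(cumsum(inc - dec))
  i_max <- which.max(running); i_min <- which.min(running)
  es <- if (running[i_max] > -running[i_min]) running[i_max] else running[i_min]
  hit_index <- which(hit)
  leading <- if (es >= 0) names(scores)[hit_index[hit_index <= i_max]]
             else names(scores)[hit_index[hit_index >= i_min]]
  list(es = es, running = running, hit_index = hit_index,
       leading_edge = leading)
}

# ES from hit positions only (O(n_hit)): the running sum is linear between
# hits, so its extremes occur immediately before or after a hit (or at the
# ends, where it is 0). Used for the permutation null.
es_from_hits <- function(hit_idx, w_all, n) {
  hit_idx <- sort(hit_idx)
  k <- length(hit_idx)
  w <- unname(w_all[hit_idx])
  nr <- sum(w)
  cw <- if (nr > 0) cumsum(w) / nr else seq_len(k) / k
  miss_after <- (hit_idx - seq_len(k)) / (n - k)
  after <- cw - miss_after              # value just after each hit
  before <- c(0, cw[-k]) - miss_after   # value just before each hit
  es_max <- max(0, after)
  es_min <- min(0, before)
  if (es_max > -es_min) es_max else es_min
}

#' NES and permutation q-values for a gene-set collection
#'
#' Gene-set (label) permutation null, appropriate for a preranked list:
#' for each set, `n_permutations` random same-size gene sets are scored;
#' NES is the observed ES divided by the mean magnitude of same-sign null
#' ES; the nominal p-value is the same-sign null tail; and q-values follow
#' the standard GSEA FDR procedure over the pooled normalized null.
#'
#' @param scores Named numeric ranking vector (see [rank_by_fold_change()]).
#' @param collection Named list of gene sets (e.g. from [read_gmt()] or
#'   [make_gene_sets()]).
#' @param n_permutations Number of null sets per gene set (>= 100).
#' @param seed Integer seed; identical seeds give identical results.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   universe; sets outside are dropped.
#' @param weight Score exponent passed to the enrichment score.
#' @return Data frame: `set`, `size`, `es`, `nes`, `p_value`, `q_value`,
#'   `leading_edge` (comma-separated). `nes` is `NA` (flagged) when no null
#'   ES of the matching sign exists.
#' @export
nes_and_q <- function(scores, collection, n_permutations = 1000L, seed = 1L,
                      min_size = 5L, max_size = 500L, weight = 1) {
  if (n_permutations < 100L)
    stop("use at least 100 permutations", call. = FALSE)
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  n <- length(scores)
  w_all <- abs(scores)^weight

  sizes <- vapply(collection, function(s) sum(names(scores) %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  collection <- collection[keep]
  sizes <- sizes[keep]
  if (length(collection) == 0L)
    stop("no gene set within the size bounds", call. = FALSE)

  obs <- lapply(collection, function(s) enrichment_score(scores, s, weight))
  es <- vapply(obs, `[[`, numeric(1), "es")

  null_es <- with_seed(seed, {
    lapply(sizes, function(k) {
      vapply(seq_len(n_permutations), function(b) {
        es_from_hits(sample.int(n, k), w_all, n)
      }, numeric(1))
    })
  })

  nes <- numeric(length(es)); p <- numeric(length(es))
  null_nes <- vector("list", length(es))
  for (i in seq_along(es)) {
    nu <- null_es[[i]]
    pos <- nu[nu >= 0]; neg <- nu[nu < 0]
    null_nes[[i]] <- c(if (length(pos)) pos / mean(pos),
                       if (length(neg)) neg / mean(-neg))
    if (es[i] >= 0) {
      if (length(pos) == 0L) { nes[i] <- NA; p[i] <- NA; next }
      nes[i] <- es[i] / mean(pos)
      p[i] <- (1 + sum(pos >= es[i])) / (1 + length(pos))
    } else {
      if (length(neg) == 0L) { nes[i] <- NA; p[i] <- NA; next }
      nes[i] <- es[i] / mean(-neg)
      p[i] <- (1 + sum(neg <= es[i])) / (1 + length(neg))
    }
  }

  pooled <- unlist(null_nes)
  q <- rep(NA_real_, length(nes))
  ok <- !is.na(nes)
  for (i in which(ok)) {
    if (nes[i] >= 0) {
      num_den <- sum(pooled >= 0)
      num <- if (num_den > 0) sum(pooled >= nes[i]) / num_den else 1
      obs_den <- sum(nes[ok] >= 0)
      den <- if (obs_den > 0) sum(nes[ok] >= nes[i]) / obs_den else 1
    } else {
      num_den <- sum(pooled < 0)
      num <- if (num_den > 0) sum(pooled <= nes[i]) / num_den else 1
      obs_den <- sum(nes[ok] < 0)
      den <- if (obs_den > 0) sum(nes[ok] <= nes[i]) / obs_den else 1
    }
    q[i] <- max(0, min(1, if (den > 0) num / den else 1))
  }

  data.frame(
    set = names(collection), size = sizes, es = es, nes = nes,
    p_value = p, q_value = q,
    leading_edge = vapply(obs, function(o) paste(o$leading_edge, collapse = ","),
                          character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
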