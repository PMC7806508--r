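#' Configuration for a synthetic immunohistochemistry cohort
#'
#' Emulates the sampling structure of a tissue-microarray cohort: a fixed
#' number of samples per tumor class, and for each (class, marker) pair a
#' Bernoulli positivity rate. Positive samples receive a staining profile —
#' percent of tumor cells at intensity 0 (negative) to 3 (intense) — with a
#' uniform negative fraction and the stained remainder split by a Dirichlet
#' over intensities 1–3, so every positive sample has a Histoscore well
#' above zero. Negative samples are 100% intensity 0.
#'
#' @param cohort_name Label stored in each record.
#' @param n_per_class Named integer vector: samples per tumor class.
#' @param positivity_rate Data frame with columns `tumor_class`, `marker`,
#'   `rate` (each rate in `[0, 1]`); pairs not listed default to rate 0.
#' @param intensity_alpha Dirichlet concentration over intensities 1–3 for
#'   positive samples.
#' @param max_negative_pct Upper bound (percent) of the intensity-0 fraction
#'   of a positive sample.
#' @param seed Integer seed.
#' @return An object of class `ihc_config`.
#' @export
ihc_cohort_config <- function(cohort_name = "simulated",
                              n_per_class = c(ATC = 20L, PDTC = 18L, PTC = 82L, FTC = 29L),
                              positivity_rate,
                              intensity_alpha = c(2, 3, 2),
                              max_negative_pct = 60,
                              seed = 1L) {
  if (missing(positivity_rate) || !is.data.frame(positivity_rate) ||
      !all(c("tumor_class", "marker", "rate") %in% names(positivity_rate)))
    stop("'positivity_rate' must be a data.frame with columns tumor_class, marker, rate",
         call. = FALSE)
  if (any(positivity_rate$rate < 0 | positivity_rate$rate > 1))
    stop("positivity rates must lie in [0, 1]", call. = FALSE)
  if (is.null(names(n_per_class)) || any(n_per_class < 1))
    stop("'n_per_class' must be a named vector of positive counts", call. = FALSE)
  if (length(intensity_alpha) != 3L || any(intensity_alpha <= 0))
    stop("'intensity_alpha' must be 3 positive concentrations", call. = FALSE)
  structure(list(cohort_name = cohort_name,
                 n_per_class = vapply(n_per_class, as.integer, integer(1)),
                 positivity_rate = positivity_rate,
                 intensity_alpha = as.numeric(intensity_alpha),
                 max_negative_pct = max_negative_pct,
                 seed = as.integer(seed)),
            class = "ihc_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate per-sample immunohistochemistry records
#'
#' One record per (sample, marker): the cohort, tumor class, marker, and the
#' percent-at-intensity vector (columns `pct_intensity_0` .. `pct_intensity_3`,
#' summing to 100). Positivity frequencies converge to the configured rates
#' as the cohort grows.
#'
#' @param config An [ihc_cohort_config()].
#' @return A data.frame of IHC records.
#' @export
simulate_ihc_cohort <- function(config) {
  stopifnot(inherits(config, "ihc_config"))
  with_seed(config$seed, {
    markers <- unique(config$positivity_rate$marker)
    classes <- names(config$n_per_class)
    out <- list()
    for (cl in classes) {
      n <- config$n_per_class[[cl]]
      ids <- sprintf("%s_%s_%03d", config$cohort_name, cl, seq_len(n))
      for (mk in markers) {
        hit <- config$positivity_rate$tumor_class == cl &
          config$positivity_rate$marker == mk
        rate <- if (any(hit)) config$positivity_rate$rate[hit][1] else 0
        pos <- stats::runif(n) < rate
        pct <- matrix(0, nrow = n, ncol = 4)
        pct[, 1] <- 100
        for (i in which(pos)) {
          neg <- stats::runif(1, 0, config$max_negative_pct)
          pct[i, ] <- c(neg, (100 - neg) * rdirichlet1(config$intensity_alpha))
        }
        out[[length(out) + 1L]] <- data.frame(
          sample_id = ids, cohort = config$cohort_name, tumor_class = cl,
          marker = mk,
          pct_intensity_0 = pct[, 1], pct_intensity_1 = pct[, 2],
          pct_intensity_2 = pct[, 3], pct_intensity_3 = pct[, 4],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}
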