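#' Histoscore from a percent-at-intensity profile
#'
#' `H = sum_i i * pct_i` over staining intensities i = 0 (negative),
#' 1 (weak), 2 (moderate), 3 (intense), where `pct_i` is the percent of
#' tumor cells at intensity i. Range 0–300.
#'
#' @param pct Numeric vector of length 4 (intensities 0–3), or a matrix /
#'   data.frame with four such columns; percentages must be non-negative
#'   and sum to 100.
#' @return Numeric Histoscore(s).
#' @export
histoscore <- function(pct) {
  m <- if (is.null(dim(pct))) matrix(as.numeric(pct), nrow = 1)
       else as.matrix(pct)
  if (ncol(m) != 4L)
    stop("expected four intensity columns (0-3)", call. = FALSE)
  if (any(m < 0)) stop("percentages must be non-negative", call. = FALSE)
  if (any(abs(rowSums(m) - 100) > 1e-9))
    stop("percentages must sum to 100", call. = FALSE)
  drop(m %*% c(0, 1, 2, 3))
}

#' Classify a Histoscore into expression strength
#'
#' Bins: absent (0), low (1–100), intermediate (101–200), strong
#' (201–300). Non-integer scores fall in the same half-open intervals:
#' 0 is absent, (0, 100] low, (100, 200] intermediate, (200, 300] strong.
#'
#' @param h Numeric Histoscore(s) in `[0, 300]`.
#' @return Factor with levels absent, low, intermediate, strong.
#' @export
classify_histoscore <- function(h) {
  if (any(h < 0 | h > 300)) stop("Histoscore outside [0, 300]", call. = FALSE)
  cut(h, breaks = c(-Inf, 0, 100, 200, 300),
      labels = c("absent", "low", "intermediate", "strong"), right = TRUE)
}

#' Positivity call from a Histoscore
#'
#' Default rule: any detectable staining, i.e. Histoscore at or above 1
#' (samples with low scores count as positive, matching the use of "any
#' detectable expression" as positivity in the cohorts). The threshold is
#' configurable, e.g. `threshold = 101` calls only at least intermediate
#' expression positive.
#'
#' @param h Numeric Histoscore(s).
#' @param threshold Minimum score called positive.
#' @return Logical vector.
#' @export
call_positive <- function(h, threshold = 1) {
  h >= threshold
}

#' Pooled 2x2 contingency table for a marker versus ATC
#'
#' Builds TP/FN/FP/TN for "marker positive" against "tumor is ATC", pooled
#' across cohorts. Accepts either per-sample IHC records (columns `cohort`,
#' `tumor_class`, `marker`, `pct_intensity_0..3`) or a cohort count table
#' (columns `cohort`, `tumor_class`, `marker`, `n_total`, `n_positive`).
#' Normal tissue is excluded by default: the diagnostic question is ATC
#' versus other thyroid carcinomas.
#'
#' @param x IHC records or cohort count table.
#' @param marker Marker name.
#' @param disease_class Class treated as diseased (default `"ATC"`).
#' @param exclude_classes Classes dropped before tabulation (default `"NT"`).
#' @param threshold Positivity threshold passed to [call_positive()]
#'   (records input only).
#' @return List of class `contingency_2x2`: `tp`, `fn`, `fp`, `tn`,
#'   `marker`.
#' @export
build_contingency <- function(x, marker, disease_class = "ATC",
                              exclude_classes = "NT", threshold = 1) {
  if (!marker %in% x$marker)
    stop("marker not present: ", marker, call. = FALSE)
  x <- x[x$marker == marker & !(x$tumor_class %in% exclude_classes), ]
  if (all(c("n_total", "n_positive") %in% names(x))) {
    if (any(x$n_positive > x$n_total))
      stop("positive counts exceed totals", call. = FALSE)
    dis <- x$tumor_class == disease_class
    tp <- sum(x$n_positive[dis]); fn <- sum(x$n_total[dis]) - tp
    fp <- sum(x$n_positive[!dis]); tn <- sum(x$n_total[!dis]) - fp
  } else {
    pct_cols <- paste0("pct_intensity_", 0:3)
    if (!all(pct_cols %in% names(x)))
      stop("records need pct_intensity_0..3 or n_total/n_positive columns",
           call. = FALSE)
    pos <- call_positive(histoscore(x[, pct_cols]), threshold)
    dis <- x$tumor_class == disease_class
    tp <- sum(pos & dis); fn <- sum(!pos & dis)
    fp <- sum(pos & !dis); tn <- sum(!pos & !dis)
  }
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, marker = marker),
            class = "contingency_2x2")
}

haldane <- function(tab) {
  cells <- c(tab$tp, tab$fn, tab$fp, tab$tn)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(tp = cells[1], fn = cells[2], fp = cells[3], tn = cells[4],
       corrected = corrected)
}

#' Diagnostic odds ratio with log-method confidence interval
#'
#' `DOR = (TP * TN) / (FN * FP)`. When any cell is zero, 0.5 is added to
#' every cell (Haldane–Anscombe) before both the point estimate and the
#' interval. CI: `exp(ln DOR +/- z * sqrt(1/TP + 1/FN + 1/FP + 1/TN))` on
#' the (corrected) cells.
#'
#' @param tab A `contingency_2x2` from [build_contingency()], or a list
#'   with elements `tp`, `fn`, `fp`, `tn`.
#' @param alpha Two-sided error rate (default 0.05).
#' @return List: `dor`, `ci_lower`, `ci_upper`, `correction_applied`.
#' @export
dor_with_ci <- function(tab, alpha = 0.05) {
  h <- haldane(tab)
  if ((h$tp + h$fn) == 0 || (h$fp + h$tn) == 0)
    stop("empty margin: DOR undefined", call. = FALSE)
  d <- (h$tp * h$tn) / (h$fn * h$fp)
  se <- sqrt(1 / h$tp + 1 / h$fn + 1 / h$fp + 1 / h$tn)
  z <- stats::qnorm(1 - alpha / 2)
  list(dor = d, ci_lower = exp(log(d) - z * se),
       ci_upper = exp(log(d) + z * se), correction_applied = h$corrected)
}

wilson_ci <- function(k, n, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Sensitivity and specificity with Wilson confidence intervals
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (FP + TN)`;
#' intervals by the Wilson score method.
#'
#' @inheritParams dor_with_ci
#' @return List with `sensitivity` and `specificity`, each a list
#'   `estimate`, `ci_lower`, `ci_upper` (undefined margins give `NA`).
#' @export
sens_spec_with_ci <- function(tab, alpha = 0.05) {
  metric <- function(k, n) {
    if (n == 0) return(list(estimate = NA_real_, ci_lower = NA_real_,
                            ci_upper = NA_real_))
    ci <- wilson_ci(k, n, alpha)
    list(estimate = k / n, ci_lower = unname(ci["lower"]),
         ci_upper = unname(ci["upper"]))
  }
  list(sensitivity = metric(tab$tp, tab$tp + tab$fn),
       specificity = metric(tab$tn, tab$fp + tab$tn))
}

#' Predictive values with standard-logit confidence intervals
#'
#' `PPV = se * pi / (se * pi + (1 - sp)(1 - pi))` and
#' `NPV = sp (1 - pi) / ((1 - se) pi + sp (1 - pi))` at prevalence `pi`
#' (default: sample prevalence, where PPV and NPV reduce to the column
#' proportions TP/(TP+FP) and TN/(TN+FN)). Intervals use the standard-logit
#' method: logit variance `(1-se)/(se n1) + sp/((1-sp) n0)` for PPV and
#' `se/((1-se) n1) + (1-sp)/(sp n0)` for NPV, back-transformed. When
#' sensitivity or specificity is 0 or 1 the logit variance is undefined;
#' the Haldane 0.5 cell correction is then applied for the interval and
#' flagged.
#'
#' @inheritParams dor_with_ci
#' @param prevalence Disease prevalence in `(0, 1)`, or `NULL` for the
#'   sample prevalence `(TP + FN) / N`.
#' @return List with `ppv` and `npv` (`estimate`, `ci_lower`, `ci_upper`),
#'   `prevalence`, and `correction_applied`.
#' @export
ppv_npv_with_ci <- function(tab, prevalence = NULL, alpha = 0.05) {
  n1 <- tab$tp + tab$fn
  n0 <- tab$fp + tab$tn
  if (n1 == 0 || n0 == 0) stop("empty margin", call. = FALSE)
  if (is.null(prevalence)) prevalence <- n1 / (n1 + n0)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  se <- tab$tp / n1
  sp <- tab$tn / n0
  corrected <- se %in% c(0, 1) || sp %in% c(0, 1)
  se_c <- se; sp_c <- sp
  if (corrected) {
    h <- haldane(tab)
    se_c <- h$tp / (h$tp + h$fn)
    sp_c <- h$tn / (h$fp + h$tn)
  }
  pv <- function(s, p, pi) {  # point estimates on uncorrected rates
    ppv <- s * pi / (s * pi + (1 - p) * (1 - pi))
    npv <- p * (1 - pi) / ((1 - s) * pi + p * (1 - pi))
    c(ppv, npv)
  }
  pt <- pv(se, sp, prevalence)
  ptc <- pv(se_c, sp_c, prevalence)
  z <- stats::qnorm(1 - alpha / 2)
  logit <- function(x) log(x / (1 - x))
  inv <- function(x) 1 / (1 + exp(-x))
  v_ppv <- (1 - se_c) / (se_c * n1) + sp_c / ((1 - sp_c) * n0)
  v_npv <- se_c / ((1 - se_c) * n1) + (1 - sp_c) / (sp_c * n0)
  ci <- function(point, v) {
    c(inv(logit(point) - z * sqrt(v)), inv(logit(point) + z * sqrt(v)))
  }
  ci_ppv <- ci(ptc[1], v_ppv)
  ci_npv <- ci(ptc[2], v_npv)
  # boundary estimates (0 or 1) lie outside the corrected-scale interval;
  # extend it so the interval always brackets the point estimate
  ci_ppv <- c(min(ci_ppv[1], pt[1]), max(ci_ppv[2], pt[1]))
  ci_npv <- c(min(ci_npv[1], pt[2]), max(ci_npv[2], pt[2]))
  list(ppv = list(estimate = pt[1], ci_lower = ci_ppv[1], ci_upper = ci_ppv[2]),
       npv = list(estimate = pt[2], ci_lower = ci_npv[1], ci_upper = ci_npv[2]),
       prevalence = prevalence, correction_applied = corrected)
}

#' Diagnostic accuracy report per marker
#'
#' For each marker: pooled 2x2 table, sensitivity, specificity, PPV, NPV
#' and diagnostic odds ratio, each with 95% confidence intervals.
#'
#' @param x IHC records or cohort count table (see [build_contingency()]).
#' @param markers Markers to report; default: all present.
#' @param prevalence Passed to [ppv_npv_with_ci()].
#' @param alpha Two-sided error rate.
#' @param ... Passed to [build_contingency()].
#' @return Data frame, one row per marker: cells, point estimates and CI
#'   bounds for every metric.
#' @export
diagnostic_report <- function(x, markers = unique(x$marker),
                              prevalence = NULL, alpha = 0.05, ...) {
  if (length(markers) == 0L) {
    return(data.frame(marker = character(0), tp = integer(0), fn = integer(0),
                      fp = integer(0), tn = integer(0)))
  }
  rows <- lapply(markers, function(mk) {
    tab <- build_contingency(x, mk, ...)
    ss <- sens_spec_with_ci(tab, alpha)
    pn <- ppv_npv_with_ci(tab, prevalence, alpha)
    d <- dor_with_ci(tab, alpha)
    data.frame(
      marker = mk, tp = tab$tp, fn = tab$fn, fp = tab$fp, tn = tab$tn,
      sensitivity = ss$sensitivity$estimate,
      sensitivity_lo = ss$sensitivity$ci_lower,
      sensitivity_hi = ss$sensitivity$ci_upper,
      specificity = ss$specificity$estimate,
      specificity_lo = ss$specificity$ci_lower,
      specificity_hi = ss$specificity$ci_upper,
      ppv = pn$ppv$estimate, ppv_lo = pn$ppv$ci_lower, ppv_hi = pn$ppv$ci_upper,
      npv = pn$npv$estimate, npv_lo = pn$npv$ci_lower, npv_hi = pn$npv$ci_upper,
      dor = d$dor, dor_lo = d$ci_lower, dor_hi = d$ci_upper,
      haldane_corrected = d$correction_applied,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
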