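#' Configuration for the synthetic RNA-seq cohort
#'
#' Defines the generative model for a multi-class thyroid-carcinoma count
#' matrix with known ground truth. Counts are negative binomial with
#' `Var = mu + phi * mu^2`; per-gene baseline expression is log-normal and
#' per-gene dispersion is gamma-distributed. A configurable number of
#' "spiked" ATC-exclusive markers is planted: near-zero expected expression
#' (in fragments per million, FPM) in every non-ATC class, a large fold
#' induction in ATC, and low relative standard deviation (RSD) across ATC
#' samples. Two kinds of decoys probe the two screen criteria separately:
#' ATC-induced genes with high dispersion (pass the expression filters but
#' rank poorly by RSD) and genes detectably expressed outside ATC (fail the
#' de novo filter).
#'
#' @param n_genes Number of background genes (spiked markers and decoys are
#'   added on top).
#' @param n_samples_per_class Named integer vector of samples per class;
#'   names must come from `ATC`, `PTC`, `FTC`, `PDTC`, `NT`. The default is
#'   the test-cohort layout: 10 ATC, 6 PTC, 6 FTC, 6 NT.
#' @param baseline_logmean_mu,baseline_logmean_sigma Mean and SD of the
#'   natural-log expected count of background genes at unit library-size
#'   factor.
#' @param dispersion_shape,dispersion_rate Gamma parameters of the per-gene
#'   dispersion phi for background genes (default mean 0.1).
#' @param libsize_range Multiplicative range of per-sample library-size
#'   factors, drawn log-uniformly.
#' @param n_spiked_markers Number of planted ATC-exclusive markers.
#' @param spike_fold_change Expected ATC / non-ATC fold change of spiked
#'   markers; must exceed 50 so spikes pass the screen by construction.
#' @param spike_noatc_mean_fpm Upper bound on the expected non-ATC mean FPM
#'   of spiked markers; must be below 1.
#' @param spike_rsd_target Target biological RSD of spiked markers in ATC
#'   (their dispersion is `spike_rsd_target^2`); in (0, 0.5). Counting noise
#'   adds roughly `1/sqrt(mu)` on top.
#' @param n_decoy_markers Total decoys, split evenly between high-RSD and
#'   expressed-outside-ATC types.
#' @param decoy_dispersion Dispersion of high-RSD decoys.
#' @param seed Integer seed; identical configurations give byte-identical
#'   output.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_samples_per_class = c(ATC = 10L, PTC = 6L, FTC = 6L, NT = 6L),
                       baseline_logmean_mu = 4,
                       baseline_logmean_sigma = 1.8,
                       dispersion_shape = 2,
                       dispersion_rate = 20,
                       libsize_range = c(0.6, 1.6),
                       n_spiked_markers = 20L,
                       spike_fold_change = 200,
                       spike_noatc_mean_fpm = 0.5,
                       spike_rsd_target = 0.15,
                       n_decoy_markers = 20L,
                       decoy_dispersion = 1.5,
                       seed = 1L) {
  classes <- c("ATC", "PTC", "FTC", "PDTC", "NT")
  if (length(n_samples_per_class) == 0L || is.null(names(n_samples_per_class)))
    stop("'n_samples_per_class' must be a named vector", call. = FALSE)
  if (!all(names(n_samples_per_class) %in% classes))
    stop("class labels must be among: ", paste(classes, collapse = ", "), call. = FALSE)
  if (any(n_samples_per_class != as.integer(n_samples_per_class)) ||
      any(n_samples_per_class < 1))
    stop("sample numbers per class must be positive integers", call. = FALSE)
  if (n_genes < 1 || n_genes != as.integer(n_genes))
    stop("'n_genes' must be a positive integer", call. = FALSE)
  if (n_spiked_markers > 0 && !"ATC" %in% names(n_samples_per_class))
    stop("spiked markers require an ATC class", call. = FALSE)
  if (n_spiked_markers > 0 && spike_fold_change <= 50)
    stop("'spike_fold_change' must exceed 50", call. = FALSE)
  if (n_spiked_markers > 0 && spike_noatc_mean_fpm >= 1)
    stop("'spike_noatc_mean_fpm' must be below 1", call. = FALSE)
  if (spike_rsd_target <= 0 || spike_rsd_target >= 0.5)
    stop("'spike_rsd_target' must lie in (0, 0.5)", call. = FALSE)
  if (length(libsize_range) != 2L || any(libsize_range <= 0) ||
      libsize_range[1] > libsize_range[2])
    stop("'libsize_range' must be an increasing pair of positive reals", call. = FALSE)
  if (dispersion_shape <= 0 || dispersion_rate <= 0)
    stop("dispersion gamma parameters must be positive", call. = FALSE)

  structure(list(
    n_genes = as.integer(n_genes),
    n_samples_per_class = vapply(n_samples_per_class, as.integer, integer(1)),
    baseline_logmean_mu = baseline_logmean_mu,
    baseline_logmean_sigma = baseline_logmean_sigma,
    dispersion_shape = dispersion_shape,
    dispersion_rate = dispersion_rate,
    libsize_range = as.numeric(libsize_range),
    n_spiked_markers = as.integer(n_spiked_markers),
    spike_fold_change = spike_fold_change,
    spike_noatc_mean_fpm = spike_noatc_mean_fpm,
    spike_rsd_target = spike_rsd_target,
    n_decoy_markers = as.integer(n_decoy_markers),
    decoy_dispersion = decoy_dispersion,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Run `expr` under a seeded RNG without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

rnbinom_phi <- function(n, mu, phi) {
  if (phi <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate a multi-class thyroid-carcinoma count matrix
#'
#' Draws a gene-by-sample integer count matrix, a sample sheet, and a truth
#' table recording the role of every planted gene
#' (`spiked_marker`, `decoy_high_rsd`, `decoy_expressed`, `background`).
#'
#' Spiked markers satisfy the de novo screen's thresholds in expectation by
#' construction: each draws an expected non-ATC FPM uniformly in
#' `(0.5, 0.9) * spike_noatc_mean_fpm` and an ATC mean of exactly
#' `spike_fold_change` times that. Expected FPM is converted to expected
#' counts through the expected library size implied by the background genes,
#' so the screen's unit (FPM) and the generator's unit (counts) agree up to
#' sampling noise.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (integer matrix, genes x samples),
#'   `samples` (data.frame: `sample_id`, `class`, `cohort`), and
#'   `truth` (data.frame: `gene_id`, `role`, `true_fold_change`,
#'   `true_noatc_mean_fpm`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nps <- config$n_samples_per_class
    class_of_sample <- rep(names(nps), nps)
    n_samples <- length(class_of_sample)
    sample_ids <- sprintf("%s_%02d", class_of_sample,
                          unlist(lapply(nps, seq_len), use.names = FALSE))

    n_spike <- config$n_spiked_markers
    n_decoy <- config$n_decoy_markers
    n_decoy_rsd <- n_decoy %/% 2L
    n_decoy_expr <- n_decoy - n_decoy_rsd
    n_total <- config$n_genes + n_spike + n_decoy
    gene_ids <- sprintf("gene_%05d", seq_len(n_total))

    # background genes: one mean vector shared by all classes (global null)
    base_mu <- exp(stats::rnorm(config$n_genes, config$baseline_logmean_mu,
                                config$baseline_logmean_sigma))
    phi <- stats::rgamma(config$n_genes, shape = config$dispersion_shape,
                         rate = config$dispersion_rate)

    # expected library size (unit size factor) -> FPM-to-count conversion
    exp_libsize <- config$n_genes *
      exp(config$baseline_logmean_mu + config$baseline_logmean_sigma^2 / 2)
    fpm_to_count <- exp_libsize / 1e6

    mu_mat <- matrix(base_mu, nrow = config$n_genes, ncol = n_samples)
    roles <- rep("background", config$n_genes)
    true_fc <- rep(1, config$n_genes)
    true_noatc <- base_mu / fpm_to_count

    add_gene <- function(noatc_fpm, fc, gene_phi, role) {
      atc_fpm <- noatc_fpm * fc
      mu_row <- ifelse(class_of_sample == "ATC", atc_fpm, noatc_fpm) * fpm_to_count
      mu_mat <<- rbind(mu_mat, mu_row)
      phi <<- c(phi, gene_phi)
      roles <<- c(roles, role)
      true_fc <<- c(true_fc, fc)
      true_noatc <<- c(true_noatc, noatc_fpm)
    }

    if (n_spike > 0) {
      noatc_fpm <- stats::runif(n_spike, 0.5, 0.9) * config$spike_noatc_mean_fpm
      for (i in seq_len(n_spike))
        add_gene(noatc_fpm[i], config$spike_fold_change,
                 config$spike_rsd_target^2, "spiked_marker")
    }
    if (n_decoy_rsd > 0) {
      noatc_fpm <- stats::runif(n_decoy_rsd, 0.5, 0.9) * config$spike_noatc_mean_fpm
      for (i in seq_len(n_decoy_rsd))
        add_gene(noatc_fpm[i], config$spike_fold_change,
                 config$decoy_dispersion, "decoy_high_rsd")
    }
    if (n_decoy_expr > 0) {
      noatc_fpm <- stats::runif(n_decoy_expr, 2, 5)
      for (i in seq_len(n_decoy_expr))
        add_gene(noatc_fpm[i], config$spike_fold_change / 2,
                 config$spike_rsd_target^2, "decoy_expressed")
    }

    size_factors <- exp(stats::runif(n_samples, log(config$libsize_range[1]),
                                     log(config$libsize_range[2])))

    counts <- matrix(0L, nrow = n_total, ncol = n_samples,
                     dimnames = list(gene_ids, sample_ids))
    for (g in seq_len(n_total))
      counts[g, ] <- rnbinom_phi(n_samples, mu_mat[g, ] * size_factors, phi[g])
    storage.mode(counts) <- "integer"

    list(
      counts = counts,
      samples = data.frame(sample_id = sample_ids, class = class_of_sample,
                           cohort = "simulated", stringsAsFactors = FALSE),
      truth = data.frame(gene_id = gene_ids, role = roles,
                         true_fold_change = true_fc,
                         true_noatc_mean_fpm = true_noatc,
                         stringsAsFactors = FALSE)
    )
  })
}
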