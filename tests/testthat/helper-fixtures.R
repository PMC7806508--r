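# Shared fixtures, built in code and cached across test files.

.fixture_env <- new.env(parent = emptyenv())

# Default simulated cohort (test-cohort layout, 20 spikes, 20 decoys) and
# its full screen result; computed once per test run.
default_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_counts(sim_config(seed = 1))
  .fixture_env$sim
}

default_screen <- function() {
  if (is.null(.fixture_env$screen)) {
    sim <- default_sim()
    .fixture_env$screen <- run_marker_screen(sim$counts, sim$samples,
                                             ct_genes = ct_gene_list())
  }
  .fixture_env$screen
}

# Small reproducible NB count matrix.
toy_counts <- function(n_genes = 8, n_samples = 6, seed = 42, phi = 0.5,
                       logmean_range = c(1, 6)) {
  set.seed(seed)
  mu <- exp(stats::runif(n_genes, logmean_range[1], logmean_range[2]))
  m <- sapply(seq_len(n_samples),
              function(s) stats::rnbinom(n_genes, mu = mu, size = 1 / phi))
  dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  storage.mode(m) <- "integer"
  m
}

# Independent direct-formula TMM factor for one sample against a reference:
# explicit M/A/weight computation with rank trimming, no code shared with
# the implementation.
oracle_tmm_pair <- function(obs, ref, trim_m = 0.3, trim_a = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m_g <- log2((obs / n_obs) / (ref / n_ref))
  a_g <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  v_g <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(m_g)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  sel <- rank(m_g) >= lo_m & rank(m_g) <= hi_m &
    rank(a_g) >= lo_a & rank(a_g) <= hi_a
  2^(sum(m_g[sel] / v_g[sel]) / sum(1 / v_g[sel]))
}

# Tie-inclusive minimum-likelihood two-sided p by exhaustive enumeration of
# all splits of the total (binomial conditional law, Poisson limit).
oracle_binom_p <- function(y_a, y_b, n_a, n_b) {
  t_tot <- y_a + y_b
  if (t_tot == 0) return(1)
  pr <- stats::dbinom(0:t_tot, t_tot, n_a / (n_a + n_b))
  min(1, sum(pr[pr <= pr[y_a + 1] * (1 + 1e-8)]))
}

# Same by enumeration under NB(phi): negative-hypergeometric weights.
oracle_nb_p <- function(y_a, y_b, n_a, n_b, phi) {
  t_tot <- y_a + y_b
  if (t_tot == 0) return(1)
  r_a <- n_a / phi; r_b <- n_b / phi
  lw <- lchoose(0:t_tot + r_a - 1, 0:t_tot) + lchoose(t_tot:0 + r_b - 1, t_tot:0)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  min(1, sum(w[w <= w[y_a + 1] * (1 + 1e-8)]))
}

# Position-by-position running-sum enrichment score.
oracle_es <- function(scores, set, p = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  hit <- names(s) %in% set
  nr <- sum(abs(s[hit])^p)
  run <- 0; best <- 0
  for (i in seq_along(s)) {
    run <- run + if (hit[i]) abs(s[i])^p / nr else -1 / (length(s) - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  best
}
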