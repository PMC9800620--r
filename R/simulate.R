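# --- Synthetic data generators ------------------------------------------
#
# The generators emulate the two data streams of a batch-fed MEC
# experiment: (1) a current trace with a lag phase, feed/depletion batch
# cycles and a rise-then-decline envelope; (2) compositional ASV count
# tables drawn from a logistic-normal-multinomial model with planted
# associations, plus a random phylogeny carrying near-identical tip pairs.

#' Parameters for a synthetic current trace
#'
#' @param duration_days experiment length in days (> 0).
#' @param sample_interval_s sampling interval in seconds (default 30).
#' @param lag_days days of near-zero current before the anode biofilm
#'   starts producing (default 10).
#' @param feed_interval_days days between batch feedings (default 2.5;
#'   reactors of this kind are fed every 2-3 days).
#' @param peak_day day at which the envelope reaches the plateau
#'   (default 30).
#' @param plateau_density_A_m2 peak envelope current density in A/m^2
#'   (default 5).
#' @param decline_fraction fractional envelope decline from the plateau by
#'   the end of the run, in `[0, 1]` (default 0.4).
#' @param noise_sd_A_m2 Gaussian noise s.d. on current density (default
#'   0.05 A/m^2).
#' @param electrode_area_m2 projected anode area (default 1e-3 m^2).
#' @param volume_L reactor liquid volume (default 0.07 L).
#' @param seed optional integer seed.
#' @return list of class `mec_trace_params`.
#' @export
trace_params <- function(duration_days = 60, sample_interval_s = 30,
                         lag_days = 10, feed_interval_days = 2.5,
                         peak_day = 30, plateau_density_A_m2 = 5,
                         decline_fraction = 0.4, noise_sd_A_m2 = 0.05,
                         electrode_area_m2 = 1e-3, volume_L = 0.07,
                         seed = NULL) {
  if (duration_days <= 0) stop("duration_days must be positive")
  if (sample_interval_s <= 0) stop("sample_interval_s must be positive")
  if (decline_fraction < 0 || decline_fraction > 1)
    stop("decline_fraction must be in [0, 1]")
  if (noise_sd_A_m2 < 0) stop("noise_sd_A_m2 must be >= 0")
  if (feed_interval_days <= 0) stop("feed_interval_days must be positive")
  if (peak_day <= lag_days) stop("peak_day must exceed lag_days")
  structure(as.list(environment()), class = "mec_trace_params")
}

logit <- function(p) log(p / (1 - p))

#' Simulate a batch-cycle current trace
#'
#' Current density is zero (plus noise) before `lag_days`. From the lag
#' onwards, each feeding triggers a fast exponential rise followed by an
#' exponential decay as electron donors are depleted, repeating every
#' `feed_interval_days`. The cycle peaks are modulated by an envelope:
#' a logistic rise reaching the plateau at `peak_day` multiplied by a
#' linear decline of `decline_fraction` between `peak_day` and the end,
#' mimicking the maturation and subsequent thickening of the anode biofilm.
#' The envelope at the lag is ~30% of the plateau, so with the default
#' 5 A/m^2 plateau the 1 A/m^2 "substantial current" threshold is crossed
#' within a bin of the lag.
#'
#' @param params a [trace_params()] list.
#' @return a [current_trace()].
#' @export
simulate_current_trace <- function(params) {
  stopifnot(inherits(params, "mec_trace_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  t_s <- seq(0, p$duration_days * 86400, by = p$sample_interval_s)
  t_d <- t_s / 86400

  # logistic envelope: 30% of plateau at the lag, 95% at peak_day
  k <- (logit(0.95) - logit(0.30)) / (p$peak_day - p$lag_days)
  t_mid <- p$lag_days - logit(0.30) / k
  rise <- 1 / (1 + exp(-k * (t_d - t_mid)))
  decline <- ifelse(
    t_d <= p$peak_day, 1,
    1 - p$decline_fraction * (t_d - p$peak_day) /
      max(p$duration_days - p$peak_day, 1e-9))
  env <- p$plateau_density_A_m2 * rise * pmax(decline, 0)

  # within-cycle shape: fast rise on feeding (tau ~ 1 min), depletion decay
  u <- (t_d - p$lag_days) %% p$feed_interval_days
  tau_rise <- 60 / 86400
  tau_decay <- p$feed_interval_days / 2
  cyc <- (1 - exp(-u / tau_rise)) * exp(-u / tau_decay)

  dens <- ifelse(t_d < p$lag_days, 0, env * cyc)
  dens <- dens + stats::rnorm(length(dens), sd = p$noise_sd_A_m2)
  current_trace(t_s, dens * p$electrode_area_m2,
                p$electrode_area_m2, p$volume_L)
}

#' Simulate a random bifurcating phylogeny with planted near-identical tips
#'
#' Generates a random bifurcating tree with positive branch lengths and
#' tips `ASV1 ... ASVn`. Each pair in `near_identical_pairs` is re-grafted
#' as a cherry whose two tips sit at cophenetic distance `pair_distance`
#' (emulating ASVs differing by a single base), while all other tip pairs
#' remain far apart on the ordinary branch-length scale.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed optional integer seed.
#' @param near_identical_pairs list of integer pairs `c(i, j)`: tip `ASVj`
#'   is placed at `pair_distance` from tip `ASVi`.
#' @param pair_distance cophenetic distance for planted pairs
#'   (default 0.002).
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, near_identical_pairs = NULL,
                          pair_distance = 0.002) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(n_taxa, br = function(n) stats::runif(n, 0.05, 0.3))
  tree$tip.label <- paste0("ASV", seq_len(n_taxa))
  for (pr in near_identical_pairs) {
    i <- paste0("ASV", pr[1]); j <- paste0("ASV", pr[2])
    tree <- ape::drop.tip(tree, j)
    tree <- phytools::bind.tip(tree, j,
                               edge.length = pair_distance / 2,
                               where = which(tree$tip.label == i),
                               position = pair_distance / 2)
  }
  tree
}

#' Build a planted basis covariance for the community generator
#'
#' Diagonal covariance of the per-sample log-abundances, with selected
#' pairs given correlation `rho` (positive for planted co-occurrence,
#' negative for co-exclusion).
#'
#' @param n_asvs dimension.
#' @param pairs optional data.frame with columns `i`, `j`, `rho`.
#' @param var common log-abundance variance (default 1).
#' @return symmetric positive semi-definite matrix.
#' @export
planted_covariance <- function(n_asvs, pairs = NULL, var = 1) {
  sigma <- diag(var, n_asvs)
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]
      sigma[i, j] <- sigma[j, i] <- pairs$rho[r] * var
    }
  }
  sigma
}

#' Parameters for the synthetic community generator
#'
#' @param n_samples number of samples (default 60).
#' @param n_asvs number of ASVs (default 30).
#' @param library_size reads per sample (default 20000).
#' @param base_log_abundance mean log-abundance per ASV; the default spans
#'   4 natural-log units so a few ASVs dominate, as in real amplicon data.
#' @param planted_covariance covariance of log-abundances
#'   ([planted_covariance()]); default independence (identity).
#' @param habitat_labels optional per-sample habitat (anode / cathode /
#'   suspension ...).
#' @param habitat_effects optional habitats x ASVs matrix of log-abundance
#'   offsets (rownames = habitat levels) making some taxa dominant in
#'   specific habitats.
#' @param near_identical_pairs list of ASV index pairs placed at small
#'   cophenetic distance in the simulated tree.
#' @param pair_distance cophenetic distance of those pairs (default 0.002).
#' @param seed optional integer seed.
#' @return list of class `mec_community_params`.
#' @export
community_params <- function(n_samples = 60, n_asvs = 30,
                             library_size = 20000,
                             base_log_abundance = NULL,
                             planted_covariance = NULL,
                             habitat_labels = NULL,
                             habitat_effects = NULL,
                             near_identical_pairs = NULL,
                             pair_distance = 0.002,
                             seed = NULL) {
  if (library_size <= 0) stop("library_size must be positive")
  if (is.null(base_log_abundance))
    base_log_abundance <- seq(2, -2, length.out = n_asvs)
  if (is.null(planted_covariance))
    planted_covariance <- diag(1, n_asvs)
  sigma <- planted_covariance
  if (!isSymmetric(sigma, tol = 1e-8))
    stop("planted_covariance must be symmetric")
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("planted_covariance must be positive semi-definite")
  if (!is.null(habitat_labels) && length(habitat_labels) != n_samples)
    stop("habitat_labels must have one entry per sample")
  structure(as.list(environment())[
    c("n_samples", "n_asvs", "library_size", "base_log_abundance",
      "planted_covariance", "habitat_labels", "habitat_effects",
      "near_identical_pairs", "pair_distance", "seed")],
    class = "mec_community_params")
}

#' Simulate compositional ASV count tables with a matching phylogeny
#'
#' Logistic-normal-multinomial generator: per-sample log-abundances are
#' drawn from a multivariate normal with the planted covariance (plus any
#' habitat offsets), softmax-transformed to proportions, and `library_size`
#' reads are drawn multinomially, so every sample's counts sum exactly to
#' the library size and all association structure lives on the latent log
#' scale — the compositional regime SparCC assumes. A random tree over the
#' ASVs is emitted alongside, with `near_identical_pairs` grafted at small
#' cophenetic distance.
#'
#' @param params a [community_params()] list.
#' @return list with `table` (a [count_table()] carrying habitat metadata),
#'   `tree` (an [ape::phylo]), and `params`.
#' @export
simulate_count_tables <- function(params) {
  stopifnot(inherits(params, "mec_community_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  mu <- matrix(rep(p$base_log_abundance, each = p$n_samples),
               p$n_samples, p$n_asvs)
  if (!is.null(p$habitat_effects) && !is.null(p$habitat_labels)) {
    eff <- as.matrix(p$habitat_effects)
    mu <- mu + eff[as.character(p$habitat_labels), , drop = FALSE]
  }
  z <- mu + MASS::mvrnorm(p$n_samples, mu = rep(0, p$n_asvs),
                          Sigma = p$planted_covariance)
  prob <- exp(z - apply(z, 1, max))
  prob <- prob / rowSums(prob)
  counts <- t(apply(prob, 1, function(pr)
    stats::rmultinom(1, p$library_size, pr)))
  dimnames(counts) <- list(paste0("S", seq_len(p$n_samples)),
                           paste0("ASV", seq_len(p$n_asvs)))
  meta <- if (!is.null(p$habitat_labels))
    data.frame(location = p$habitat_labels) else NULL
  tree_seed <- if (is.null(p$seed)) NULL else p$seed + 10000L
  tree <- simulate_tree(p$n_asvs, seed = tree_seed,
                        near_identical_pairs = p$near_identical_pairs,
                        pair_distance = p$pair_distance)
  list(table = count_table(counts, sample_meta = meta), tree = tree,
       params = p)
}
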