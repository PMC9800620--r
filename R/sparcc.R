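# --- SparCC: correlation inference for compositional count data ---------
#
# Read counts only carry relative information, so ordinary correlations of
# relative abundances are biased by the closure to 1. SparCC works from
# log-ratio variances t_ij = var(log(x_i / x_j)), which are invariant to the
# closure, and recovers basis variances w_i under a sparsity assumption
# (most true correlations are near zero): t_ij ~ w_i + w_j - 2 rho_ij
# sqrt(w_i w_j), so with rho ~ 0 the w_i solve a linear system in the
# row sums of t. Strongly correlated pairs violate the assumption and are
# excluded one at a time, re-solving after each exclusion.

# log-ratio variance matrix from a fractions matrix (samples x ASVs)
logratio_var <- function(frac) {
  v <- log(frac)
  cv <- stats::cov(v)
  dv <- diag(cv)
  outer(dv, dv, "+") - 2 * cv
}

# solve basis variances given the t matrix and a logical matrix of pairs
# still included in the sparsity system
solve_basis <- function(t_mat, include) {
  deg <- rowSums(include)
  a <- include * 1
  diag(a) <- deg
  b <- rowSums(t_mat * include)
  w <- tryCatch(solve(a, b), error = function(e) rep(mean(b) / max(deg, 1),
                                                     length(b)))
  pmax(w, 1e-12)
}

basis_correlation <- function(t_mat, w) {
  sw <- sqrt(w)
  rho <- (outer(w, w, "+") - t_mat) / (2 * outer(sw, sw))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}

# one SparCC estimate from one Dirichlet resample of the fractions
sparcc_once <- function(frac, exclusion_threshold, max_exclusion_iters) {
  d <- ncol(frac)
  t_mat <- logratio_var(frac)
  include <- matrix(TRUE, d, d)
  diag(include) <- FALSE
  w <- solve_basis(t_mat, include)
  rho <- basis_correlation(t_mat, w)
  for (it in seq_len(max_exclusion_iters)) {
    cand <- abs(rho)
    cand[!include] <- 0
    cand[lower.tri(cand, diag = TRUE)] <- 0
    m <- which.max(cand)
    if (cand[m] <= exclusion_threshold) break
    i <- (m - 1) %% d + 1
    j <- (m - 1) %/% d + 1
    # keep every ASV in at least two ratio equations so the system stays
    # identifiable
    if (sum(include[i, ]) <= 2 || sum(include[j, ]) <= 2) break
    include[i, j] <- include[j, i] <- FALSE
    w_new <- solve_basis(t_mat, include)
    rho_new <- basis_correlation(t_mat, w_new)
    # collapsed variances or correlations pinned at +-1 mean the reduced
    # system lost identifiability: undo the exclusion, keep the previous
    # solution
    off <- abs(rho_new)[upper.tri(rho_new)]
    if (any(w_new <= 1e-8) || any(off > 0.999)) {
      include[i, j] <- include[j, i] <- TRUE
      break
    }
    w <- w_new
    rho <- rho_new
  }
  rho
}

#' SparCC correlations from an ASV count table
#'
#' Estimates taxon-taxon correlations from compositional count data.
#' For each of `n_resamples` resamples, per-sample fractions are drawn from
#' Dirichlet(counts + 1), log-ratio variances are computed, basis variances
#' are solved under the sparsity approximation, and correlations are formed
#' and clipped to `[-1, 1]`; pairs whose correlation magnitude exceeds
#' `exclusion_threshold` are excluded from the sparsity system one at a time
#' (strongest first), re-solving up to `max_exclusion_iters` times. The
#' reported matrix is the element-wise median over resamples.
#'
#' @param table a [count_table()] or counts matrix (samples x ASVs); needs
#'   at least 4 samples and 4 ASVs.
#' @param n_resamples Dirichlet resamples (default 20).
#' @param exclusion_threshold correlation magnitude above which a pair is
#'   removed from the basis-variance system (default 0.1).
#' @param max_exclusion_iters maximum pair exclusions per resample
#'   (default 10).
#' @param seed optional integer seed.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sparcc <- function(table, n_resamples = 20, exclusion_threshold = 0.1,
                   max_exclusion_iters = 10, seed = NULL) {
  m <- if (inherits(table, "mec_count_table")) table$counts else as.matrix(table)
  n <- nrow(m); d <- ncol(m)
  if (n < 4) stop("SparCC needs at least 4 samples")
  if (d < 4) stop("SparCC needs at least 4 ASVs (basis system underdetermined)")
  if (!is.null(seed)) set.seed(seed)
  est <- array(NA_real_, c(d, d, n_resamples))
  for (b in seq_len(n_resamples)) {
    g <- matrix(stats::rgamma(n * d, shape = as.vector(m) + 1), n, d)
    frac <- g / rowSums(g)
    est[, , b] <- sparcc_once(frac, exclusion_threshold, max_exclusion_iters)
  }
  rho <- apply(est, c(1, 2), stats::median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(m), colnames(m))
  rho
}

#' Permutation p-values for SparCC correlations
#'
#' Two-sided significance per pair against a permutation null: in each
#' bootstrap every ASV column is permuted independently across samples
#' (destroying all between-ASV association while keeping marginal count
#' distributions), SparCC is recomputed, and
#' `p = (1 + #{|r_null| >= |r_obs|}) / (1 + n_bootstraps)`.
#'
#' @param table the count table `observed_r` was computed on.
#' @param observed_r SparCC correlation matrix from [sparcc()].
#' @param n_bootstraps permutation rounds (default 99).
#' @param seed optional integer seed.
#' @param n_resamples,exclusion_threshold,max_exclusion_iters passed to the
#'   inner SparCC runs.
#' @return symmetric matrix of p-values in `(0, 1]` (`NA` diagonal).
#' @export
sparcc_pvalues <- function(table, observed_r, n_bootstraps = 99, seed = NULL,
                           n_resamples = 20, exclusion_threshold = 0.1,
                           max_exclusion_iters = 10) {
  m <- if (inherits(table, "mec_count_table")) table$counts else as.matrix(table)
  if (n_bootstraps < 1) stop("n_bootstraps must be >= 1")
  d <- ncol(m)
  if (!all(dim(observed_r) == c(d, d)))
    stop("observed_r does not match the table")
  if (!is.null(seed)) set.seed(seed)
  exceed <- matrix(0, d, d)
  for (b in seq_len(n_bootstraps)) {
    perm <- apply(m, 2, sample)
    r_null <- sparcc(perm, n_resamples = n_resamples,
                     exclusion_threshold = exclusion_threshold,
                     max_exclusion_iters = max_exclusion_iters)
    exceed <- exceed + (abs(r_null) >= abs(observed_r))
  }
  p <- (1 + exceed) / (1 + n_bootstraps)
  p <- (p + t(p)) / 2
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(observed_r)
  p
}
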