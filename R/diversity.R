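#' Hill-number alpha diversity
#'
#' Effective number of ASVs of diversity order `q` for one community:
#' `(sum(p_i^q))^(1/(1-q))` for `q != 1`, and `exp(-sum(p_i log p_i))` at
#' `q = 1`, with zero-abundance terms excluded. `q = 0` counts ASVs
#' (richness); `q = 1` weights them by abundance (exp Shannon); `q = 2`
#' emphasises dominants (inverse Simpson).
#'
#' @param p non-negative abundance vector (counts or proportions; normalised
#'   internally).
#' @param q diversity order, `q >= 0`.
#' @return effective number of ASVs.
#' @examples
#' hill_alpha(c(0.5, 0.25, 0.25), q = 0)  # 3
#' hill_alpha(c(0.5, 0.25, 0.25), q = 1)  # 2^1.5
#' hill_alpha(c(0.5, 0.25, 0.25), q = 2)  # 8/3
#' @export
hill_alpha <- function(p, q) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("abundances must be non-negative")
  if (!is.numeric(q) || length(q) != 1L || q < 0)
    stop("q must be a single number >= 0")
  s <- sum(p)
  if (s <= 0) stop("all abundances are zero")
  p <- p[p > 0] / s
  if (abs(q - 1) < 1e-10) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

# row-wise two-sample Hill dissimilarity for matrices of proportions
# (each row of p1 pairs with the same row of p2); returns (beta - 1) with
# beta = gamma/alpha in [1, 2]
dissim_rows <- function(p1, p2, q) {
  pool <- (p1 + p2) / 2
  if (abs(q - 1) < 1e-10) {
    xlogx <- function(m) {
      r <- m * log(m)
      r[m == 0] <- 0
      r
    }
    gamma <- exp(-rowSums(xlogx(pool)))
    alpha <- exp(-rowSums(xlogx(p1 / 2)) - rowSums(xlogx(p2 / 2))) / 2
  } else {
    if (q == 0) {
      # 0^0 = 1 in R; zero cells must not count towards richness
      gamma <- rowSums(pool > 0)
      alpha <- (rowSums(p1 > 0) + rowSums(p2 > 0)) / 2
    } else {
      gamma <- rowSums(pool^q)^(1 / (1 - q))
      alpha <- (rowSums((p1 / 2)^q) + rowSums((p2 / 2)^q))^(1 / (1 - q)) / 2
    }
  }
  pmin(pmax(gamma / alpha - 1, 0), 1)
}

#' Pairwise Hill dissimilarity matrix
#'
#' For each pair of samples, the local two-sample dissimilarity
#' `(beta_q - 1)/(N - 1)` with `N = 2`, where `beta_q` is the ratio of the
#' pooled-community (gamma) to the mean within-sample (alpha) Hill number of
#' order `q`. 0 for identical compositions, 1 for disjoint ASV sets.
#'
#' @param table a [count_table()] (or counts matrix) with at least 2 samples.
#' @param q diversity order.
#' @return symmetric matrix in `[0, 1]` with zero diagonal.
#' @export
dissimilarity_matrix <- function(table, q = 1) {
  ra <- relative_abundance(table)
  n <- nrow(ra)
  if (n < 2) stop("need at least 2 samples")
  if (any(rowSums(ra) == 0)) stop("empty samples are not allowed")
  d <- matrix(0, n, n, dimnames = list(rownames(ra), rownames(ra)))
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    d[i, js] <- dissim_rows(ra[rep(i, length(js)), , drop = FALSE],
                            ra[js, , drop = FALSE], q)
    d[js, i] <- d[i, js]
  }
  d
}

# assemble one null sample: richness ASVs drawn without replacement with
# probability proportional to `incl_w`; reads beyond the presence-guarantee
# distributed multinomially by `read_w`
assemble_null <- function(richness, depth, incl_w, read_w, presence_only) {
  d <- length(incl_w)
  idx <- sample.int(d, richness, replace = FALSE, prob = incl_w)
  if (presence_only) {
    out <- logical(d)
    out[idx] <- TRUE
    return(out)
  }
  cnt <- numeric(d)
  cnt[idx] <- 1
  extra <- depth - richness
  if (extra > 0) {
    w <- read_w[idx]
    if (sum(w) <= 0) w <- rep(1, length(idx))
    cnt[idx] <- cnt[idx] + as.numeric(stats::rmultinom(1, extra, w))
  }
  cnt
}

#' Raup-Crick null model for pairwise community similarity
#'
#' For each sample pair, compares the observed Hill dissimilarity of order
#' `q` with a null ensemble in which each sample is reassembled at random
#' while keeping its observed ASV richness and read depth fixed. ASVs enter
#' a null sample with probability proportional to their occupancy frequency
#' across the table (for `q = 0`) or their metacommunity mean relative
#' abundance (for abundance-weighted orders); reads beyond the one
#' guaranteeing presence are distributed multinomially by mean relative
#' abundance. The score for a pair is the percentile of the observed
#' dissimilarity in the null ensemble, with ties given half weight:
#' `qrc = (#{null < obs} + 0.5 #{null = obs}) / iterations`.
#' Values below 0.05 flag pairs significantly more similar than chance;
#' above 0.95, significantly more dissimilar.
#'
#' @param table a [count_table()] (or counts matrix), >= 2 samples.
#' @param q diversity order of the underlying dissimilarity.
#' @param iterations null-ensemble size (default 999).
#' @param seed optional integer seed for reproducibility.
#' @param pairs optional 2-column matrix of sample index pairs to score;
#'   default all pairs.
#' @return object of class `mec_raup_crick`: list with `qrc` (symmetric
#'   matrix, `NA` off the requested pairs and on the diagonal), `order`,
#'   `iterations`.
#' @export
raup_crick <- function(table, q = 0, iterations = 999, seed = NULL,
                       pairs = NULL) {
  m <- if (inherits(table, "mec_count_table")) table$counts else as.matrix(table)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 samples")
  if (iterations < 1) stop("iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pres <- m > 0
  richness <- rowSums(pres)
  depth <- rowSums(m)
  if (any(richness == 0)) stop("empty samples are not allowed")
  occupancy <- colSums(pres)
  mean_ra <- colMeans(relative_abundance(m))
  incl_w <- if (q == 0) occupancy else mean_ra
  presence_only <- (q == 0)
  ra <- relative_abundance(m)

  if (is.null(pairs)) {
    pairs <- t(utils::combn(n, 2))
  } else {
    pairs <- as.matrix(pairs)
    stopifnot(ncol(pairs) == 2)
  }
  needed <- sort(unique(as.vector(pairs)))

  # one null ensemble per sample; pairs compare matching iterations
  ens <- vector("list", n)
  for (s in needed) {
    ens[[s]] <- t(vapply(seq_len(iterations), function(k)
      assemble_null(richness[s], depth[s], incl_w, mean_ra, presence_only),
      if (presence_only) logical(ncol(m)) else numeric(ncol(m))))
  }

  qrc <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (presence_only) {
      shared <- sum(pres[i, ] & pres[j, ])
      obs <- (richness[i] + richness[j] - 2 * shared) /
             (richness[i] + richness[j])
      sh_null <- rowSums(ens[[i]] & ens[[j]])
      ri <- rowSums(ens[[i]]); rj <- rowSums(ens[[j]])
      null_d <- (ri + rj - 2 * sh_null) / (ri + rj)
    } else {
      obs <- dissim_rows(ra[i, , drop = FALSE], ra[j, , drop = FALSE], q)
      p_i <- ens[[i]] / rowSums(ens[[i]])
      p_j <- ens[[j]] / rowSums(ens[[j]])
      null_d <- dissim_rows(p_i, p_j, q)
    }
    val <- (sum(null_d < obs - 1e-12) +
            0.5 * sum(abs(null_d - obs) <= 1e-12)) / iterations
    qrc[i, j] <- qrc[j, i] <- val
  }
  structure(list(qrc = qrc, order = q, iterations = iterations),
            class = "mec_raup_crick")
}

#' @export
print.mec_raup_crick <- function(x, ...) {
  v <- x$qrc[upper.tri(x$qrc)]
  v <- v[!is.na(v)]
  cat("Raup-Crick null model (order q =", x$order, ",", x$iterations,
      "iterations):", length(v), "pairs scored\n")
  cat("  significantly similar (qRC < 0.05):", sum(v < 0.05), "\n")
  cat("  significantly dissimilar (qRC > 0.95):", sum(v > 0.95), "\n")
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with a
#' significance level from joint row/column permutations of the second
#' matrix: `p = (1 + #{r_perm >= r_obs}) / (1 + permutations)`.
#'
#' @param d1,d2 symmetric distance matrices (or `dist` objects) of the same
#'   dimension with zero diagonals.
#' @param permutations number of permutations (default 999).
#' @param seed optional integer seed.
#' @return list with elements `r`, `p`, `permutations`.
#' @export
mantel <- function(d1, d2, permutations = 999, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2)))
    stop("distance matrices must have the same dimensions")
  if (nrow(d1) != ncol(d1) || max(abs(d1 - t(d1))) > 1e-8 ||
      max(abs(d2 - t(d2))) > 1e-8)
    stop("matrices must be square and symmetric")
  if (permutations < 1) stop("permutations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(d1)
  r_obs <- stats::cor(d1[ut], d2[ut])
  n <- nrow(d1)
  r_perm <- vapply(seq_len(permutations), function(k) {
    idx <- sample.int(n)
    stats::cor(d1[ut], d2[idx, idx][ut])
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs)) / (1 + permutations)
  list(r = r_obs, p = p, permutations = permutations)
}
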