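# shared fixtures and independent oracles, built in code at test time

# trace with arbitrary sampling; area/volume as in a 70-mL single-chamber MEC
make_trace <- function(time_s, current_A, area = 1e-3, volume = 0.07) {
  current_trace(time_s, current_A, electrode_area_m2 = area,
                volume_L = volume)
}

# 3 samples x 4 ASVs, library 10000: ASV_a present once (50%), ASV_b in two
# samples at >= 5%, ASV_c in all three but never above 0.06%, ASV_d
# everywhere and abundant
toy_filter_table <- function() {
  m <- rbind(S1 = c(a = 5000, b = 600, c = 6, d = 4394),
             S2 = c(a = 0,    b = 500, c = 4, d = 9496),
             S3 = c(a = 0,    b = 0,   c = 5, d = 9995))
  colnames(m) <- paste0("ASV_", colnames(m))
  count_table(m)
}

# electrons from oxidising C_c H_h O_o (charge z) completely to CO2:
# oxidation-state bookkeeping gives b = 4c + h - 2o - z
half_reaction_electrons <- function(c, h, o, z) 4 * c + h - 2 * o - z

# cophenetic oracle: shortest tip-to-tip path sums on the tree seen as a
# weighted graph (independent of ape's cophenetic)
cophenetic_graph_oracle <- function(tree) {
  g <- igraph::graph_from_edgelist(tree$edge, directed = FALSE)
  d <- igraph::distances(g, weights = tree$edge.length)
  ntip <- length(tree$tip.label)
  out <- d[seq_len(ntip), seq_len(ntip)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# union-find oracle for single-linkage clustering at distance <= eps
union_find_clusters <- function(d, eps) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (d[i, j] <= eps) parent[find(j)] <- find(i)
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# random small count table
random_table <- function(n_samples, n_asvs, seed, lambda = 30) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_asvs, lambda), n_samples, n_asvs,
              dimnames = list(paste0("S", seq_len(n_samples)),
                              paste0("ASV", seq_len(n_asvs))))
  count_table(m)
}

# samples assembled by the Raup-Crick null process itself: richness drawn
# per sample, ASVs included by weighted sampling without replacement, reads
# distributed by the same weights
null_process_table <- function(n_samples, n_asvs, weights, depth = 1000,
                               richness_range = 12:30, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, n_samples, n_asvs,
              dimnames = list(paste0("S", seq_len(n_samples)),
                              paste0("ASV", seq_len(n_asvs))))
  for (s in seq_len(n_samples)) {
    r <- sample(richness_range, 1)
    idx <- sample.int(n_asvs, r, prob = weights)
    m[s, idx] <- 1L + as.integer(rmultinom(1, depth - r, weights[idx]))
  }
  m
}

# analytic test signal: I(t) = A sin^2(pi t / T) on [0, T], integral A T / 2
sin2_trace <- function(amp_A, period_s, dt = 30) {
  tt <- seq(0, period_s, by = dt)
  make_trace(tt, amp_A * sin(pi * tt / period_s)^2)
}
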