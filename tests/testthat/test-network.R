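test_that("ASV filtering applies the prevalence and abundance rules", {
  filt <- filter_asvs(toy_filter_table())
  expect_setequal(colnames(filt$counts), c("ASV_b", "ASV_d"))
  expect_equal(nrow(filt$counts), 3)  # sample set unchanged
  # idempotence
  filt2 <- filter_asvs(filt)
  expect_identical(filt$counts, filt2$counts)
  expect_warning(filter_asvs(toy_filter_table(), min_samples = 10),
                 "all ASVs removed")
})

test_that("filtering matches a brute-force predicate check", {
  for (seed in c(71, 72, 73)) {
    tab <- random_table(6, 25, seed = seed, lambda = 2)
    ra <- relative_abundance(tab)
    kept <- colnames(filter_asvs(tab)$counts)
    ref <- colnames(tab$counts)[vapply(seq_len(25), function(j) {
      sum(tab$counts[, j] > 0) >= 2 && any(ra[, j] > 0.001)
    }, logical(1))]
    expect_identical(kept, ref)
  }
})

test_that("cophenetic distances are tip-to-tip branch-length sums", {
  d <- cophenetic_distances("(A:0.1,B:0.2);")
  expect_equal(unname(d["A", "B"]), 0.3)
  expect_equal(unname(diag(d)), c(0, 0))
  # random tree vs an independent shortest-path oracle
  tree <- simulate_tree(12, seed = 81)
  d2 <- cophenetic_distances(tree)
  ref <- cophenetic_graph_oracle(tree)
  expect_equal(d2[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
  expect_error(cophenetic_distances(tree, asv_ids = c("ASV1", "ASVX")),
               "ASVX")
})

test_that("phylogenetic merging is single-linkage and conserves reads", {
  m <- rbind(S1 = c(A = 100, B = 50, C = 10, D = 500),
             S2 = c(A = 80, B = 60, C = 20, D = 400))
  tab <- count_table(m)
  # chain: A-B 0.003, B-C 0.003, A-C 0.006 -- all three merge at eps 0.004
  d <- matrix(1, 4, 4, dimnames = list(colnames(m), colnames(m)))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.003
  d["B", "C"] <- d["C", "B"] <- 0.003
  d["A", "C"] <- d["C", "A"] <- 0.006
  res <- merge_close_asvs(tab, d, epsilon = 0.004)
  expect_setequal(colnames(res$table$counts), c("A", "D"))  # A most abundant
  expect_equal(unname(res$table$counts[, "A"]), c(160, 160))
  expect_equal(rowSums(res$table$counts), rowSums(m))       # reads invariant
  expect_equal(unname(res$merge_map[c("A", "B", "C")]), rep("A", 3))
  # epsilon 0 is the identity
  res0 <- merge_close_asvs(tab, d, epsilon = 0)
  expect_identical(res0$table$counts, tab$counts)
  expect_error(merge_close_asvs(tab, d, epsilon = -1), "epsilon")
})

test_that("merging agrees with a union-find oracle on random distances", {
  set.seed(82)
  for (k in 1:5) {
    n <- 10
    tab <- random_table(4, n, seed = 82 + k, lambda = 40)
    d <- as.matrix(dist(matrix(runif(n * 2, 0, 0.05), n)))
    dimnames(d) <- list(colnames(tab$counts), colnames(tab$counts))
    eps <- 0.02
    res <- merge_close_asvs(tab, d, epsilon = eps)
    cl <- union_find_clusters(d, eps)
    expect_equal(ncol(res$table$counts), length(unique(cl)))
    # members of one oracle cluster map to one merged id
    for (g in unique(cl)) {
      ids <- colnames(tab$counts)[cl == g]
      expect_length(unique(res$merge_map[ids]), 1)
    }
    expect_equal(rowSums(res$table$counts), rowSums(tab$counts))
  }
})

test_that("Spearman matrix handles monotone, reversed and tied data", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 9, 20),
             c = c(20, 9, 6, 4, 2), d = c(1, 1, 2, 2, 3))
  # pad rows to a common depth so relative abundances keep the count ranks
  m <- cbind(m, pad = 100 - rowSums(m))
  tab <- count_table(m)
  sp <- spearman_matrix(tab)
  expect_equal(sp$rho["a", "b"], 1)
  expect_equal(sp$rho["a", "c"], -1)
  # ties: brute-force average-rank then Pearson, p from the t formula
  ra <- relative_abundance(tab)
  r_ref <- cor(rank(ra[, "a"]), rank(ra[, "d"]))
  expect_equal(unname(sp$rho["a", "d"]), r_ref, tolerance = 1e-12)
  t_ref <- r_ref * sqrt(3 / (1 - r_ref^2))
  expect_equal(unname(sp$p["a", "d"]), 2 * pt(-abs(t_ref), 3),
               tolerance = 1e-12)
  # constant column is flagged NA, not silently zero
  m2 <- cbind(m[, 1:4], e = rep(5, 5))
  m2 <- cbind(m2, pad = 100 - rowSums(m2))
  expect_warning(sp2 <- spearman_matrix(count_table(m2)), "constant")
  expect_true(is.na(sp2$rho["a", "e"]))
})

test_that("dual-criterion edge validation enforces all four rules", {
  ids <- paste0("ASV", 1:4)
  mk <- function(val, diag_val = 1) {
    m <- matrix(0, 4, 4, dimnames = list(ids, ids))
    diag(m) <- diag_val
    m
  }
  rho <- mk(0); p_s <- mk(1, NA); r_c <- mk(0); p_c <- mk(1, NA)
  set_pair <- function(m, i, j, v) { m[i, j] <- m[j, i] <- v; m }
  # pair 1-2: everything passes -> positive edge
  rho <- set_pair(rho, 1, 2, 0.9); p_s <- set_pair(p_s, 1, 2, 0.001)
  r_c <- set_pair(r_c, 1, 2, 0.8); p_c <- set_pair(p_c, 1, 2, 0.01)
  # pair 1-3: SparCC magnitude fails
  rho <- set_pair(rho, 1, 3, 0.9); p_s <- set_pair(p_s, 1, 3, 0.001)
  r_c <- set_pair(r_c, 1, 3, 0.4); p_c <- set_pair(p_c, 1, 3, 0.01)
  # pair 2-4: sign conflict invalidates the edge
  rho <- set_pair(rho, 2, 4, 0.7); p_s <- set_pair(p_s, 2, 4, 0.01)
  r_c <- set_pair(r_c, 2, 4, -0.7); p_c <- set_pair(p_c, 2, 4, 0.01)
  # pair 3-4: valid negative edge
  rho <- set_pair(rho, 3, 4, -0.8); p_s <- set_pair(p_s, 3, 4, 0.001)
  r_c <- set_pair(r_c, 3, 4, -0.75); p_c <- set_pair(p_c, 3, 4, 0.02)

  net <- build_network(list(rho = rho, p = p_s), r_c, p_c)
  expect_equal(nrow(net$edges), 2)
  e12 <- net$edges[net$edges$from == "ASV1" & net$edges$to == "ASV2", ]
  expect_equal(e12$sign, "+")
  expect_equal(e12$weight, 0.8)   # weight comes from SparCC
  e34 <- net$edges[net$edges$from == "ASV3" & net$edges$to == "ASV4", ]
  expect_equal(e34$sign, "-")
  expect_setequal(net$nodes, ids)  # all four touch an edge here
  expect_error(build_network(list(rho = rho, p = p_s), r_c, p_c,
                             threshold = 2), "threshold")
})

test_that("isolated nodes are dropped from the network node set", {
  ids <- paste0("ASV", 1:5)
  rho <- diag(1, 5); r_c <- diag(1, 5)
  p_s <- matrix(1, 5, 5); p_c <- matrix(1, 5, 5)
  rho[1, 2] <- rho[2, 1] <- r_c[1, 2] <- r_c[2, 1] <- 0.9
  p_s[1, 2] <- p_s[2, 1] <- p_c[1, 2] <- p_c[2, 1] <- 0.001
  dimnames(rho) <- dimnames(r_c) <- dimnames(p_s) <- dimnames(p_c) <-
    list(ids, ids)
  net <- build_network(list(rho = rho, p = p_s), r_c, p_c)
  expect_setequal(net$nodes, c("ASV1", "ASV2"))
})

test_that("network properties match hand computations on toy graphs", {
  mk_net <- function(edges) {
    structure(list(nodes = unique(c(edges$from, edges$to)), edges = edges),
              class = "mec_network")
  }
  # two disjoint triangles
  tri <- data.frame(
    from = c("a", "b", "c", "d", "e", "f"),
    to = c("b", "c", "a", "e", "f", "d"),
    sign = "+", weight = 0.8, sparcc_r = 0.8, spearman_rho = 0.8,
    sparcc_p = 0.01, spearman_p = 0.01, stringsAsFactors = FALSE)
  pr <- network_properties(mk_net(tri))
  expect_equal(pr$n_nodes, 6)
  expect_equal(pr$n_edges, 6)
  expect_equal(pr$n_modules, 2)
  expect_equal(pr$modularity, 0.5)
  expect_equal(pr$clustering, 1)
  expect_equal(pr$edge_density, 12 / 30)
  expect_equal(pr$positive_pct + pr$negative_pct, 100)

  # 5-node graph: triangle 1-2-3 plus tail 3-4, 4-5
  g5 <- data.frame(
    from = c("v1", "v2", "v3", "v3", "v4"),
    to = c("v2", "v3", "v1", "v4", "v5"),
    sign = c("+", "+", "-", "+", "+"), weight = c(.8, .7, -.9, .7, .7),
    sparcc_r = 0.7, spearman_rho = 0.7, sparcc_p = 0.01, spearman_p = 0.01,
    stringsAsFactors = FALSE)
  pr5 <- network_properties(mk_net(g5))
  # local clustering: v1 = 1, v2 = 1, v3 = 1/3, v4 = 0, v5 undefined
  expect_equal(pr5$clustering, mean(c(1, 1, 1 / 3, 0)))
  expect_equal(pr5$negative_edges, 1)
  expect_equal(pr5$negative_pct, 20)
  # found partition beats a random one in modularity
  g <- as_igraph(mk_net(g5))
  set.seed(9)
  rand_part <- sample(1:2, 5, replace = TRUE)
  expect_gte(pr5$modularity, igraph::modularity(g, rand_part))

  empty <- structure(list(nodes = character(0),
                          edges = tri[0, ]), class = "mec_network")
  expect_warning(pr0 <- network_properties(empty), "empty")
  expect_equal(pr0$n_edges, 0)
})

test_that("derived edge statistics follow from counts exactly", {
  s <- signed_edge_stats(10, 6, 2)
  expect_equal(s$n_edges, 8)
  expect_equal(s$positive_pct, 75)
  expect_equal(s$negative_pct, 25)
  expect_equal(s$edge_density, 16 / 90)
  expect_equal(s$positive_pct + s$negative_pct, 100)
})

test_that("the full network stage recovers planted association signs", {
  planted <- data.frame(i = c(1, 3, 5, 7, 9, 11), j = c(2, 4, 6, 8, 10, 12),
                        rho = c(0.9, -0.9, 0.85, -0.85, 0.8, -0.8))
  sim <- simulate_count_tables(community_params(
    seed = 42, n_samples = 60, n_asvs = 30,
    planted_covariance = planted_covariance(30, planted),
    near_identical_pairs = list(c(25, 26))))
  filt <- filter_asvs(sim$table)
  d <- cophenetic_distances(sim$tree, colnames(filt$counts))
  merged <- merge_close_asvs(filt, d, epsilon = 0.004)
  # the planted near-identical pair collapsed into one taxon
  expect_equal(length(unique(merged$merge_map[c("ASV25", "ASV26")])), 1)
  sp <- spearman_matrix(merged$table)
  r <- sparcc(merged$table, seed = 100)
  p <- sparcc_pvalues(merged$table, r, n_bootstraps = 99, seed = 101)
  net <- build_network(sp, r, p)
  hits <- 0
  for (k in seq_len(nrow(planted))) {
    a <- paste0("ASV", planted$i[k]); b <- paste0("ASV", planted$j[k])
    e <- net$edges[(net$edges$from == a & net$edges$to == b) |
                   (net$edges$from == b & net$edges$to == a), ]
    hits <- hits + (nrow(e) == 1 &&
                    e$sign == ifelse(planted$rho[k] > 0, "+", "-"))
  }
  expect_gt(hits / nrow(planted), 0.8)
})
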