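#' Filter ASVs by prevalence and relative abundance
#'
#' Keeps an ASV only if it is present (nonzero) in at least `min_samples`
#' samples AND its per-sample relative abundance exceeds `min_relabund` in
#' at least one sample. The sample set is unchanged. Filtering is applied
#' within the group being analysed (e.g. anode samples only), so subset the
#' table first.
#'
#' @param table a [count_table()].
#' @param min_samples minimum number of samples with nonzero counts
#'   (default 2).
#' @param min_relabund relative-abundance threshold, exceeded strictly in at
#'   least one sample (default 0.001, i.e. 0.1\%).
#' @return filtered `mec_count_table` (warns if no ASV survives).
#' @export
filter_asvs <- function(table, min_samples = 2, min_relabund = 0.001) {
  stopifnot(inherits(table, "mec_count_table"))
  m <- table$counts
  ra <- relative_abundance(m)
  keep <- colSums(m > 0) >= min_samples &
          apply(ra, 2, max) > min_relabund
  if (!any(keep)) warning("all ASVs removed by filtering")
  count_table(m[, keep, drop = FALSE], sample_meta = table$sample_meta)
}

#' Cophenetic distances between tree tips
#'
#' Tip-to-tip distances on a phylogenetic tree, summing branch lengths along
#' the connecting path (via [ape::cophenetic.phylo()]).
#'
#' @param tree an [ape::phylo] object, a Newick string, or a path to a
#'   Newick file.
#' @param asv_ids optional ids that must all be present among the tips;
#'   unmatched ids are an error naming the offenders.
#' @return symmetric non-negative distance matrix over the tips.
#' @export
cophenetic_distances <- function(tree, asv_ids = NULL) {
  tree <- as_phylo(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is.null(asv_ids)) {
    missing_ids <- setdiff(asv_ids, tree$tip.label)
    if (length(missing_ids) > 0)
      stop("ASV ids absent from the tree: ",
           paste(missing_ids, collapse = ", "))
  }
  stats::cophenetic(tree)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, a Newick string, or a file path")
}

#' Merge phylogenetically close ASVs
#'
#' ASVs within cophenetic distance `epsilon` of each other are merged by
#' single-linkage clustering (so chains a-b, b-c merge all three even when
#' a-c exceeds `epsilon`). Counts are summed per sample within each cluster
#' and the merged column takes the id of the most abundant member, keeping
#' per-sample read totals invariant. This collapses pairs of ASVs that are
#' effectively one taxon, e.g. sequences differing by a single base over the
#' 253-bp V4 region.
#'
#' @param table a [count_table()].
#' @param dist cophenetic distance matrix covering all ASVs in the table.
#' @param epsilon merge radius in branch-length units; the default 0.004
#'   corresponds to roughly one substitution over a 253-bp amplicon.
#'   `epsilon = 0` is the identity.
#' @return list with `table` (merged `mec_count_table`) and `merge_map`
#'   (named character vector: member ASV -> merged id).
#' @export
merge_close_asvs <- function(table, dist, epsilon = 0.004) {
  stopifnot(inherits(table, "mec_count_table"))
  if (epsilon < 0) stop("epsilon must be >= 0")
  m <- table$counts
  ids <- colnames(m)
  missing_ids <- setdiff(ids, rownames(dist))
  if (length(missing_ids) > 0)
    stop("distance matrix does not cover: ",
         paste(missing_ids, collapse = ", "))
  d <- as.matrix(dist)[ids, ids, drop = FALSE]
  if (epsilon == 0 || length(ids) < 2) {
    mm <- stats::setNames(ids, ids)
    return(list(table = table, merge_map = mm))
  }
  cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = "single"),
                      h = epsilon)
  totals <- colSums(m)
  merged <- vapply(split(ids, cl), function(members) {
    members[which.max(totals[members])]
  }, character(1))
  merge_map <- stats::setNames(merged[as.character(cl)], ids)
  newm <- t(rowsum(t(m), group = merge_map[ids]))
  # keep merged columns ordered as their representative appeared originally
  newm <- newm[, intersect(ids, colnames(newm)), drop = FALSE]
  list(table = count_table(newm, sample_meta = table$sample_meta),
       merge_map = merge_map)
}

#' Pairwise Spearman correlations with t-approximation p-values
#'
#' Spearman's rank correlation on per-sample relative abundances, with
#' average ranks for ties, and a two-sided p-value from the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom. Pairs
#' involving a constant ASV have undefined rank correlation and are
#' returned as `NA` (with a warning), never silently 0.
#'
#' @param table a [count_table()] with at least 4 samples.
#' @return list with matrices `rho` and `p` (diagonal `NA` in `p`).
#' @export
spearman_matrix <- function(table) {
  ra <- relative_abundance(table)
  n <- nrow(ra)
  if (n < 4) stop("need at least 4 samples for meaningful p-values")
  const <- apply(ra, 2, function(x) max(x) == min(x))
  rho <- suppressWarnings(stats::cor(ra, method = "spearman"))
  if (any(const)) {
    warning("constant ASV column(s): ",
            paste(colnames(ra)[const], collapse = ", "),
            "; their correlations are NA")
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(rho) <- 1
  diag(p) <- NA_real_
  list(rho = rho, p = p)
}

#' Build a signed co-occurrence network by dual-criterion validation
#'
#' An edge between two ASVs is valid only if BOTH correlation models agree
#' it is strong and significant: `|rho| > threshold` (Spearman),
#' `|r| > threshold` (SparCC), both p-values `< alpha`, and the two
#' coefficients have the same sign (a sign conflict invalidates the edge).
#' Edge weight and sign come from the SparCC coefficient. ASVs left with no
#' edge are dropped from the node set.
#'
#' @param spearman list from [spearman_matrix()] (`rho`, `p`).
#' @param sparcc_r SparCC correlation matrix.
#' @param sparcc_p SparCC p-value matrix.
#' @param threshold correlation-magnitude threshold in `[0, 1]`
#'   (default 0.6, strict inequality).
#' @param alpha significance level (default 0.05, strict inequality).
#' @param p_adjust optional multiple-testing correction applied to both
#'   p-value sets before thresholding, e.g. `"BH"`; default `"none"`.
#' @return object of class `mec_network`: list with `nodes` (character) and
#'   `edges` (data.frame: from, to, sign, weight, sparcc_r, spearman_rho,
#'   sparcc_p, spearman_p).
#' @export
build_network <- function(spearman, sparcc_r, sparcc_p, threshold = 0.6,
                          alpha = 0.05, p_adjust = "none") {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  rho <- spearman$rho; p_s <- spearman$p
  d <- ncol(rho)
  stopifnot(all(dim(sparcc_r) == c(d, d)), all(dim(sparcc_p) == c(d, d)))
  ids <- colnames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  ps <- p_s[ut]; pc <- sparcc_p[ut]
  if (p_adjust != "none") {
    ps <- stats::p.adjust(ps, method = p_adjust)
    pc <- stats::p.adjust(pc, method = p_adjust)
  }
  r_sp <- rho[ut]; r_sc <- sparcc_r[ut]
  ok <- !is.na(r_sp) & !is.na(r_sc) & !is.na(ps) & !is.na(pc) &
        abs(r_sp) > threshold & abs(r_sc) > threshold &
        ps < alpha & pc < alpha & sign(r_sp) == sign(r_sc) & r_sc != 0
  edges <- data.frame(
    from = ids[ut[ok, 1]],
    to = ids[ut[ok, 2]],
    sign = ifelse(r_sc[ok] > 0, "+", "-"),
    weight = r_sc[ok],
    sparcc_r = r_sc[ok],
    spearman_rho = r_sp[ok],
    sparcc_p = pc[ok],
    spearman_p = ps[ok],
    stringsAsFactors = FALSE)
  nodes <- ids[ids %in% c(edges$from, edges$to)]
  structure(list(nodes = nodes, edges = edges), class = "mec_network")
}

#' @export
print.mec_network <- function(x, ...) {
  cat("Signed co-occurrence network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (", sum(x$edges$sign == "+"), "positive /",
      sum(x$edges$sign == "-"), "negative )\n")
  invisible(x)
}

#' Convert a signed network to an igraph graph
#'
#' @param net a `mec_network`.
#' @return undirected [igraph::graph] with `weight` and `sign` edge
#'   attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mec_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "sign", "weight")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

#' Summary properties of a signed network
#'
#' Node and edge counts, signed-edge percentages, edge density
#' `2E / (N (N - 1))`, module count and modularity from community detection
#' on the unsigned graph, and the mean local clustering coefficient.
#' Percentages are computed from counts, so positive + negative = 100
#' exactly.
#'
#' @param net a `mec_network`.
#' @param community community-detection algorithm on the unsigned graph:
#'   `"fast_greedy"` (greedy modularity maximisation, default) or
#'   `"louvain"`.
#' @param clustering `"localaverage"` (mean local clustering coefficient
#'   over vertices where it is defined, default) or `"global"`
#'   (transitivity).
#' @return data.frame with one row: n_nodes, n_edges, positive_edges,
#'   positive_pct, negative_edges, negative_pct, edge_density, n_modules,
#'   modularity, clustering.
#' @export
network_properties <- function(net, community = c("fast_greedy", "louvain"),
                               clustering = c("localaverage", "global")) {
  stopifnot(inherits(net, "mec_network"))
  community <- match.arg(community)
  clustering <- match.arg(clustering)
  if (length(net$nodes) == 0 || nrow(net$edges) == 0) {
    warning("empty network")
    return(data.frame(n_nodes = 0, n_edges = 0, positive_edges = 0,
                      positive_pct = NA_real_, negative_edges = 0,
                      negative_pct = NA_real_, edge_density = NA_real_,
                      n_modules = 0, modularity = NA_real_,
                      clustering = NA_real_))
  }
  g <- as_igraph(net)
  n_nodes <- igraph::vcount(g)
  n_edges <- igraph::ecount(g)
  n_pos <- sum(net$edges$sign == "+")
  n_neg <- n_edges - n_pos
  comm <- switch(community,
    fast_greedy = igraph::cluster_fast_greedy(g, weights = NA),
    louvain = igraph::cluster_louvain(g, weights = NA))
  clus <- switch(clustering,
    localaverage = igraph::transitivity(g, type = "localaverage"),
    global = igraph::transitivity(g, type = "global"))
  data.frame(
    n_nodes = n_nodes,
    n_edges = n_edges,
    positive_edges = n_pos,
    positive_pct = 100 * n_pos / n_edges,
    negative_edges = n_neg,
    negative_pct = 100 * n_neg / n_edges,
    edge_density = 2 * n_edges / (n_nodes * (n_nodes - 1)),
    n_modules = length(comm),
    modularity = igraph::modularity(comm),
    clustering = clus)
}

#' Derived network statistics from node and signed-edge counts
#'
#' The arithmetic layer of the network summary: given the number of nodes
#' and of positive and negative validated edges, returns edge density
#' `2E / (N (N - 1))` and signed-edge percentages. Useful for checking a
#' published property table against its own counts.
#'
#' @param n_nodes number of nodes.
#' @param n_positive,n_negative signed edge counts.
#' @return data.frame with n_edges, positive_pct, negative_pct,
#'   edge_density.
#' @examples
#' signed_edge_stats(133, 236, 101)  # density 0.038, 70.03% / 29.97%
#' @export
signed_edge_stats <- function(n_nodes, n_positive, n_negative) {
  stopifnot(n_nodes >= 2, n_positive >= 0, n_negative >= 0)
  e <- n_positive + n_negative
  data.frame(
    n_edges = e,
    positive_pct = 100 * n_positive / e,
    negative_pct = 100 * n_negative / e,
    edge_density = 2 * e / (n_nodes * (n_nodes - 1)))
}

#' Write a network edge list as TSV / GraphML
#'
#' @param net a `mec_network`.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "mec_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
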