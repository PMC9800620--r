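#' Default pipeline configuration
#'
#' A nested list of every stage parameter with its conventional default:
#' dual-criterion threshold 0.6 and alpha 0.05, 999 Raup-Crick iterations,
#' ASV retention at >= 2 samples and > 0.1% relative abundance, 10-sample
#' (5-min) current bins, a 1 A/m^2 lag threshold, and the electron yields
#' b = 8 / 14 / 20 for acetate / propionate / butyrate. A YAML file read by
#' [read_run_config()] overrides any subset of these.
#'
#' @param seed master seed; per-stage substreams are derived from it so
#'   adding a stage does not perturb earlier draws.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    stages = c("simulate", "electrochem", "diversity", "network"),
    inputs = list(trace_csv = NULL, count_table_tsv = NULL,
                  tree_newick = NULL, deltas_tsv = NULL,
                  electrode_area_m2 = 1e-3, volume_L = 0.07),
    simulate = list(
      trace = list(duration_days = 40, lag_days = 8, peak_day = 20,
                   plateau_density_A_m2 = 5, noise_sd_A_m2 = 0.05),
      community = list(n_samples = 24, n_asvs = 20, library_size = 10000,
                       planted_pairs = list(list(i = 1, j = 2, rho = 0.9),
                                            list(i = 3, j = 4, rho = -0.9)))),
    electrochem = list(group_size = 10, lag_threshold_A_m2 = 1,
                       b = list(acetate = 8, propionate = 14, butyrate = 20)),
    diversity = list(alpha_orders = c(0, 1, 2), dissimilarity_q = 1,
                     raup_crick_q = 0, raup_crick_iterations = 999,
                     mantel_permutations = 999),
    network = list(min_samples = 2, min_relabund = 0.001,
                   merge_epsilon = 0.004, threshold = 0.6, alpha = 0.05,
                   sparcc_resamples = 20, sparcc_bootstraps = 99))
}

# recursively overlay user values onto defaults
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Values in the file override [default_config()]; anything omitted keeps
#' its default.
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  merge_config(default_config(), yaml::read_yaml(path))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages (`simulate`, `electrochem`, `diversity`,
#' `network`) in order, writing per-stage TSV/CSV/Newick/GraphML outputs
#' and a run log with every resolved parameter into `out_dir`. When the
#' simulate stage runs, its outputs feed the later stages; otherwise the
#' paths in `config$inputs` are used. Identical config and seed give
#' identical outputs.
#'
#' @param config configuration list ([default_config()] /
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(..., "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("mecnet pipeline run")
  logf("resolved configuration:")
  cat(yaml::as.yaml(config), file = log_path, append = TRUE)
  res <- list()
  seed <- config$seed
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% config$stages) {
    res$simulate <- run_stage("simulate", {
      tp <- do.call(trace_params, c(config$simulate$trace,
                                    list(seed = seed)))
      trace <- simulate_current_trace(tp)
      comm_cfg <- config$simulate$community
      if (!is.null(comm_cfg$planted_pairs)) {
        pairs <- do.call(rbind, lapply(comm_cfg$planted_pairs, as.data.frame))
        comm_cfg$planted_pairs <- NULL
        comm_cfg$planted_covariance <-
          planted_covariance(comm_cfg$n_asvs, pairs)
      }
      cp <- do.call(community_params, c(comm_cfg, list(seed = seed + 1L)))
      sim <- simulate_count_tables(cp)
      write_trace_csv(trace, file.path(out_dir, "trace.csv"))
      write_count_table(sim$table, file.path(out_dir, "counts.tsv"))
      ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
      logf("simulate: trace with ", length(trace$time_s), " samples; ",
           "table ", nrow(sim$table$counts), " x ", ncol(sim$table$counts))
      list(trace = trace, table = sim$table, tree = sim$tree)
    })
  }

  get_trace <- function() {
    if (!is.null(res$simulate)) return(res$simulate$trace)
    path <- config$inputs$trace_csv
    if (is.null(path)) stop("no trace available: set inputs$trace_csv")
    read_trace_csv(path, config$inputs$electrode_area_m2,
                   config$inputs$volume_L)
  }
  get_table <- function() {
    if (!is.null(res$simulate)) return(res$simulate$table)
    path <- config$inputs$count_table_tsv
    if (is.null(path)) stop("no count table: set inputs$count_table_tsv")
    read_count_table(path)
  }
  get_tree <- function() {
    if (!is.null(res$simulate)) return(res$simulate$tree)
    path <- config$inputs$tree_newick
    if (is.null(path)) stop("no tree: set inputs$tree_newick")
    ape::read.tree(path)
  }

  if ("electrochem" %in% config$stages) {
    res$electrochem <- run_stage("electrochem", {
      trace <- get_trace()
      ec <- config$electrochem
      span <- range(trace$time_s)
      out <- data.frame(
        peak_current_A = peak_current(trace, span[1], span[2],
                                      group_size = ec$group_size),
        total_charge_C = total_charge(trace, span[1], span[2]),
        lag_days = as.numeric(lag_time(trace, ec$lag_threshold_A_m2,
                                       ec$group_size)))
      if (!is.null(config$inputs$deltas_tsv)) {
        deltas <- utils::read.delim(config$inputs$deltas_tsv)
        out$coulombic_efficiency <- coulombic_efficiency(
          trace, span[1], span[2], deltas, b = unlist(ec$b))
      }
      utils::write.table(out, file.path(out_dir, "electrochem.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logf("electrochem: peak ", signif(out$peak_current_A, 4), " A, charge ",
           signif(out$total_charge_C, 6), " C")
      out
    })
  }

  if ("diversity" %in% config$stages) {
    res$diversity <- run_stage("diversity", {
      table <- get_table()
      dv <- config$diversity
      ra <- relative_abundance(table)
      alpha <- sapply(dv$alpha_orders, function(q)
        apply(ra, 1, hill_alpha, q = q))
      colnames(alpha) <- paste0("q", dv$alpha_orders)
      dmat <- dissimilarity_matrix(table, q = dv$dissimilarity_q)
      rc <- raup_crick(table, q = dv$raup_crick_q,
                       iterations = dv$raup_crick_iterations,
                       seed = seed + 2L)
      utils::write.table(data.frame(sample = rownames(ra), alpha),
                         file.path(out_dir, "hill_alpha.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(dmat, file.path(out_dir, "dissimilarity.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(rc$qrc, file.path(out_dir, "raup_crick.tsv"),
                         sep = "\t", quote = FALSE)
      logf("diversity: ", nrow(ra), " samples; qRC < 0.05 in ",
           sum(rc$qrc[upper.tri(rc$qrc)] < 0.05, na.rm = TRUE), " pairs")
      list(alpha = alpha, dissimilarity = dmat, raup_crick = rc)
    })
  }

  if ("network" %in% config$stages) {
    res$network <- run_stage("network", {
      table <- get_table()
      nw <- config$network
      filt <- filter_asvs(table, nw$min_samples, nw$min_relabund)
      logf("network: filter kept ", ncol(filt$counts), " of ",
           ncol(table$counts), " ASVs")
      dmat <- cophenetic_distances(get_tree(),
                                   asv_ids = colnames(filt$counts))
      merged <- merge_close_asvs(filt, dmat, nw$merge_epsilon)
      logf("network: merge kept ", ncol(merged$table$counts), " of ",
           ncol(filt$counts), " ASVs")
      sp <- spearman_matrix(merged$table)
      r_sc <- sparcc(merged$table, n_resamples = nw$sparcc_resamples,
                     seed = seed + 3L)
      p_sc <- sparcc_pvalues(merged$table, r_sc,
                             n_bootstraps = nw$sparcc_bootstraps,
                             seed = seed + 4L,
                             n_resamples = nw$sparcc_resamples)
      net <- build_network(sp, r_sc, p_sc, threshold = nw$threshold,
                           alpha = nw$alpha)
      props <- network_properties(net)
      write_edge_list(net, file.path(out_dir, "edges.tsv"))
      if (nrow(net$edges) > 0)
        write_graphml(net, file.path(out_dir, "network.graphml"))
      utils::write.table(props, file.path(out_dir, "network_properties.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logf("network: ", nrow(net$edges), " validated edges on ",
           length(net$nodes), " nodes")
      list(table = merged$table, merge_map = merged$merge_map,
           network = net, properties = props)
    })
  }

  logf("done")
  invisible(res)
}
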