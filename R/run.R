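#' @title End-to-end runs and result bundles
#' @name cli_report
#' @description
#' High-level drivers that take a model plus one or more flux states
#' through the whole pipeline — graph construction, ShReD matrix, root
#' modularity matrix, hierarchical partition, homogeneity table, H-V pair
#' table — and write every artifact with a machine-readable manifest. A
#' thin command-line wrapper over these functions ships in
#' `inst/cli/fluxshred.R`.
NULL

#' Assemble a run configuration
#'
#' @param model_path path to a reactions TSV (or JSON).
#' @param flux_paths named character vector, state label -> flux TSV path.
#'   May be empty for unit/degree weighting.
#' @param weighting `"unit"`, `"flux"` or `"degree"` (no default: the
#'   scheme changes the science and must be chosen explicitly).
#' @param cap ShReD cap (default 100).
#' @param ga a [ga_params()].
#' @param h_min,v_min robust-pair thresholds (defaults 0.7 and 3.0).
#' @param seed global seed; fed into the GA parameters.
#' @param out_dir output directory (created if needed).
#' @return a `run_config` list.
#' @export
run_config <- function(model_path, flux_paths = character(0), weighting,
                       cap = 100, ga = ga_params(), h_min = 0.7, v_min = 3.0,
                       seed = 1, out_dir = ".") {
  weighting <- match.arg(weighting, c("unit", "flux", "degree"))
  if (!file.exists(model_path)) stop("model file not found: ", model_path)
  if (length(flux_paths) > 0L) {
    if (is.null(names(flux_paths)) || any(!nzchar(names(flux_paths)))) {
      stop("flux_paths must be a named vector (label = path)")
    }
    if (anyDuplicated(names(flux_paths))) stop("state labels must be unique")
    missing <- flux_paths[!file.exists(flux_paths)]
    if (length(missing) > 0L) {
      stop("flux file(s) not found: ", paste(missing, collapse = ", "))
    }
  } else if (weighting == "flux") {
    stop("flux weighting requires at least one flux state")
  }
  ga$seed <- as.integer(seed)
  structure(list(model_path = model_path, flux_paths = flux_paths,
                 weighting = weighting, cap = cap, ga = ga,
                 h_min = h_min, v_min = v_min, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

state_slug <- function(label) gsub("[^A-Za-z0-9._-]+", "_", label)

partition_one_state <- function(model, state, config) {
  graph <- if (config$weighting == "flux") {
    canon <- canonicalize_directions(model, state)
    build_graph(canon$model, "flux", canon$state)
  } else {
    g <- build_graph(model, config$weighting)
    g$state_label <- if (!is.null(state)) state$label else NA_character_
    g
  }
  graph <- collapse_parallel_edges(graph)
  sm <- all_pairs_shred(graph, cap = config$cap)
  rootV <- build_modularity_matrix(sm)
  tree <- hierarchical_partition(graph, params = config$ga, cap = config$cap)
  groups <- stats::setNames(model$reactions$group, model$reactions$id)
  list(graph = graph, shred = sm, summary = shred_summary(sm),
       rootV = rootV, tree = tree,
       homogeneity = mean_homogeneity_by_height(tree, groups),
       scores = pair_scores(tree, rootV),
       groups = groups)
}

#' Run the full partition pipeline over every configured state
#'
#' Per state, writes the collapsed edge list, ShReD matrix and summary,
#' root modularity matrix, partition tree (JSON and DOT), homogeneity-by-
#' height table, and H-V pair table into `out_dir/<state>/`, plus a
#' `manifest.json` recording inputs, configuration and seed. For unit or
#' degree weighting without flux states, a single pseudo-state
#' `"static"` is produced.
#'
#' @param config a [run_config()].
#' @return invisibly, a named list of per-state results (graph, shred,
#'   summary, rootV, tree, homogeneity, scores).
#' @export
run_partition <- function(config) {
  stopifnot(inherits(config, "run_config"))
  model <- load_model(config$model_path)
  states <- if (length(config$flux_paths) > 0L) {
    stats::setNames(lapply(names(config$flux_paths), function(lab) {
      load_flux_state(config$flux_paths[[lab]], model, label = lab)
    }), names(config$flux_paths))
  } else {
    list(static = NULL)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (lab in names(states)) {
    res <- partition_one_state(model, states[[lab]], config)
    results[[lab]] <- res
    d <- file.path(config$out_dir, state_slug(lab))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    write_edge_list(res$graph, file.path(d, "edges.tsv"))
    write_shred_matrix(res$shred, file.path(d, "shred.csv"))
    write_modularity_matrix(res$rootV, file.path(d, "modularity.csv"))
    write_tree_json(res$tree, file.path(d, "tree.json"), groups = res$groups)
    write_tree_dot(res$tree, file.path(d, "tree.dot"))
    utils::write.csv(data.frame(height = names(res$homogeneity),
                                mean_homogeneity = res$homogeneity,
                                row.names = NULL),
                     file.path(d, "homogeneity.csv"), row.names = FALSE)
    utils::write.csv(res$scores, file.path(d, "hv_scores.csv"),
                     row.names = FALSE)
    s <- res$summary
    jsonlite::write_json(
      s[c("skewness", "skewness_below_cap", "mean_finite", "mean_noncapped",
          "fraction_capped", "n_pairs_defined")],
      file.path(d, "shred_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    model = config$model_path,
    flux_states = as.list(config$flux_paths),
    weighting = config$weighting,
    cap = config$cap,
    seed = config$seed,
    h_min = config$h_min, v_min = config$v_min,
    ga = config$ga[setdiff(names(config$ga), "seed")],
    package_version = as.character(utils::packageVersion("fluxshred"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Robust-pair report across all partitioned states
#'
#' @param results the list returned by [run_partition()].
#' @param config the same [run_config()] (thresholds, output directory).
#' @return the [robust_pairs()] data frame, invisibly; written to
#'   `robust_pairs.csv` in the output directory.
#' @export
run_robust <- function(results, config) {
  stopifnot(inherits(config, "run_config"))
  scores <- lapply(results, `[[`, "scores")
  rp <- robust_pairs(scores, h_min = config$h_min, v_min = config$v_min)
  utils::write.csv(rp, file.path(config$out_dir, "robust_pairs.csv"),
                   row.names = FALSE)
  invisible(rp)
}

#' Normalized H-V distance between two partitioned states
#'
#' @param results the list returned by [run_partition()].
#' @param stateA,stateB state labels present in `results`.
#' @param config the [run_config()] (output directory).
#' @return the [hv_distance()] data frame, invisibly; written to
#'   `hv_distance_<A>_vs_<B>.csv`.
#' @export
run_compare <- function(results, stateA, stateB, config) {
  stopifnot(inherits(config, "run_config"))
  for (lab in c(stateA, stateB)) {
    if (!lab %in% names(results)) stop("state not partitioned: ", lab)
  }
  d <- hv_distance(results[[stateA]]$scores, results[[stateB]]$scores)
  utils::write.csv(d, file.path(config$out_dir,
                                paste0("hv_distance_", state_slug(stateA),
                                       "_vs_", state_slug(stateB), ".csv")),
                   row.names = FALSE)
  invisible(d)
}
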