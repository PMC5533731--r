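#' Identify the slow and rapid decliner clusters
#'
#' Among the named clusters, the one with the worse (higher) mean
#' baseline ADAS-Cog13 is called rapid, the one with the best slow; any
#' further named clusters keep their size-rank labels.
#'
#' @param cohort a `cohort_table`.
#' @param clustering a `clustering`.
#' @param score_descriptor baseline descriptor used for the ordering.
#' @return named character vector `c(slow = , rapid = )` of cluster
#'   labels, or `NULL` when fewer than two named clusters exist.
#' @export
identify_decliner_clusters <- function(cohort, clustering,
                                       score_descriptor = "ADAS13") {
  named <- setdiff(unique(clustering$label), "unclustered")
  if (length(named) < 2L) return(NULL)
  v <- cohort$baseline[[score_descriptor]]
  ids <- cohort$baseline$subject_id
  score <- vapply(named, function(lab) {
    sel <- clustering$subject_id[clustering$label == lab]
    mean(v[ids %in% sel], na.rm = TRUE)
  }, numeric(1L))
  c(slow = named[which.min(score)], rapid = named[which.max(score)])
}

default_run_config <- function() {
  list(
    input = list(synthetic = TRUE),
    seed = 1L,
    est = est_params(),
    min_size = 20L,
    network_threshold = 0.5,
    classifier_features = c("ADAS13", "ADAS11", "MMSE", "RAVLT_immediate"),
    out_dir = NULL
  )
}

stage <- function(name, expr, out_dir = NULL) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir)) {
      writeLines(paste0("FAILED at stage '", name, "': ",
                        conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    }
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full multilayer-clustering analysis
#'
#' Orchestrates the pipeline from a single configuration: cohort input
#' (CSV path or synthetic generation) -> two data layers -> one
#' similarity table per layer -> multilayer clustering -> cluster
#' profiling (overall and per sex), transition rates, descriptor
#' correlation network, and cut-off classifier search with cross-cohort
#' validation. All randomness derives from `config$seed`; a manifest
#' records every parameter for exact rerun.
#'
#' @param config a list (or YAML file path) overriding the defaults:
#'   `input` (`list(csv = path)` or `list(synthetic = TRUE, ...generator
#'   overrides)`), `seed`, `est` ([est_params()]), `min_size`,
#'   `network_threshold`, `classifier_features` (empty vector skips the
#'   classifier stage), `out_dir` (optional; reports are written there).
#' @return a `run_bundle` list: `cohort`, `truth` (synthetic runs),
#'   `layers`, `ests`, `trace`, `clustering`, `roles`, `comparisons`,
#'   `transitions`, `network`, `classifiers`, `manifest`.
#' @export
run_analysis <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  seed <- as.integer(cfg$seed)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(fname) if (is.null(out_dir)) NULL else
    file.path(out_dir, fname)

  input <- stage("input", {
    if (!is.null(cfg$input$csv)) {
      list(cohort = read_cohort(cfg$input$csv), truth = NULL)
    } else {
      gen_cfg <- default_config()
      overrides <- cfg$input[setdiff(names(cfg$input), "synthetic")]
      for (nm in names(overrides)) gen_cfg[[nm]] <- overrides[[nm]]
      validate_config(gen_cfg)
      syn <- generate_cohort(gen_cfg, seed = seed)
      list(cohort = syn$cohort, truth = syn$truth)
    }
  }, out_dir)
  cohort <- input$cohort
  truth <- input$truth
  message("input: ", nrow(cohort$subjects), " subjects")

  layers <- stage("layers", build_layers(cohort), out_dir)
  ests <- stage("similarity", {
    imputed <- lapply(layers, impute_for_similarity)
    list(
      baseline = compute_est(imputed$baseline, cfg$est, seed = seed + 1L),
      slope = compute_est(imputed$slope, cfg$est, seed = seed + 2L))
  }, out_dir)

  trace <- stage("clustering", mlc_cluster(unname(ests)), out_dir)
  clustering <- label_unclustered(trace, min_size = cfg$min_size)
  message("clustering: ", nrow(trace$merges), " merges, ",
          length(setdiff(unique(clustering$label), "unclustered")),
          " named clusters, ",
          sum(clustering$label == "unclustered"), " unclustered")
  roles <- identify_decliner_clusters(cohort, clustering)

  comparisons <- NULL
  if (!is.null(roles)) {
    comparisons <- stage("profiling", {
      labs <- c(roles[["slow"]], roles[["rapid"]])
      list(
        overall = compare_clusters(cohort, clustering, labels = labs),
        female = compare_clusters(cohort, clustering, labels = labs,
                                  stratum = "Female"),
        male = compare_clusters(cohort, clustering, labels = labs,
                                stratum = "Male"))
    }, out_dir)
  }
  transitions <- stage("transitions", transition_rates(cohort, clustering),
                       out_dir)

  network <- stage("network", {
    build_network(spearman_matrix(descriptor_values(cohort)),
                  threshold = cfg$network_threshold)
  }, out_dir)

  classifiers <- NULL
  if (length(cfg$classifier_features) > 0L && !is.null(roles)) {
    classifiers <- stage("classifiers", {
      frame <- classifier_frame(cohort, clustering, roles[["rapid"]],
                                features = cfg$classifier_features)
      cohorts <- sort(unique(stats::na.omit(frame$cohort)))
      if (length(cohorts) < 2L) {
        NULL
      } else {
        train <- frame[frame$cohort == cohorts[1L], ]
        test <- frame[frame$cohort == cohorts[2L], ]
        lower_is_worse <- c("MMSE", "MOCA", "RAVLT_immediate",
                            "RAVLT_learning")
        rows <- lapply(cfg$classifier_features, function(f) {
          dir <- if (f %in% lower_is_worse) "<" else ">"
          cross_cohort_validate(search_univariate(f, train, dir),
                                train, test)
        })
        if (all(c("ADAS11", "ADAS13") %in% cfg$classifier_features)) {
          rows <- c(rows, list(cross_cohort_validate(
            search_conjunction("ADAS11", "ADAS13", train), train, test)))
        }
        do.call(rbind, rows)
      }
    }, out_dir)
  }

  manifest <- list(
    seed = seed,
    input = if (!is.null(cfg$input$csv)) list(csv = cfg$input$csv) else
      c(list(synthetic = TRUE),
        cfg$input[setdiff(names(cfg$input), "synthetic")]),
    est = cfg$est[!vapply(cfg$est, is.null, logical(1L))],
    min_size = cfg$min_size,
    network_threshold = cfg$network_threshold,
    classifier_features = cfg$classifier_features,
    n_subjects = nrow(cohort$subjects),
    n_dropped = cohort$n_dropped,
    n_merges = nrow(trace$merges),
    cluster_sizes = as.list(table(clustering$label)),
    classifier_stage = if (is.null(classifiers)) "skipped" else "run")

  if (!is.null(out_dir)) {
    write_clustering(clustering, emit("clustering.csv"))
    write_trace(trace, emit("merge_trace.json"))
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons$overall, emit("comparison_overall.csv"),
                       row.names = FALSE)
      utils::write.csv(comparisons$female, emit("comparison_female.csv"),
                       row.names = FALSE)
      utils::write.csv(comparisons$male, emit("comparison_male.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(transitions, emit("transitions.csv"),
                     row.names = FALSE)
    export_graph(network, emit("network.graphml"))
    if (!is.null(classifiers)) {
      utils::write.csv(classifiers, emit("classifiers.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, emit("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(
    list(cohort = cohort, truth = truth, layers = layers, ests = ests,
         trace = trace, clustering = clustering, roles = roles,
         comparisons = comparisons, transitions = transitions,
         network = network, classifiers = classifiers,
         manifest = manifest),
    class = "run_bundle")
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("run_bundle: N =", x$manifest$n_subjects, "| clusters:",
      paste(names(x$manifest$cluster_sizes),
            unlist(x$manifest$cluster_sizes),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write the two analysis layers as CSV matrices
#'
#' @param layers list of `data_layer`s from [build_layers()].
#' @param dir output directory.
#' @export
write_layers <- function(layers, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (l in layers) {
    df <- data.frame(subject_id = rownames(l$matrix), l$matrix,
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, paste0("layer_", l$layer_id,
                                               ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
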