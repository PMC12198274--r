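#' Fixed force-directed node layout
#'
#' Computes a Fruchterman-Reingold layout on one reference network (absolute
#' weights as attraction) so that the same coordinates can be reused for
#' every group's rendering, making the group networks visually comparable.
#'
#' @param model A [fit_mgm()] result or a symmetric weight matrix. For a
#'   model, the layout is computed on the element-wise maximum absolute
#'   weight across the group-conditioned networks (the pooled reference).
#' @param seed Integer seed; the same seed gives identical coordinates.
#' @return Tibble with `node`, `x`, `y`.
#' @export
layout_positions <- function(model, seed = 1) {
  W <- if (inherits(model, "moderated_mgm")) {
    Reduce(pmax, lapply(model$conditioned, abs))
  } else {
    abs(model)
  }
  check_weight_matrix(W)
  if (!nrow(W)) abort("empty network.")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  tibble(node = rownames(W) %||% as.character(seq_len(nrow(W))),
         x = xy[, 1], y = xy[, 2])
}

#' Run the full moderated-network analysis pipeline
#'
#' Orchestrates load/simulate -> missingness filter -> multiple imputation
#' (or complete cases) -> moderated network fit -> optional bootstrap
#' stability -> local metrics and between-group correlations -> cohort
#' descriptive table -> optional trajectory features and Louvain subgroups
#' -> fixed layout, writing every result as CSV/JSON into `out_dir` along
#' with a run log recording seeds and stage outcomes.
#'
#' @param config A named list (or path to a YAML file with the same fields):
#'   \describe{
#'     \item{symptom_csv}{Path to a symptom CSV (see [write_symptom_csv()]),
#'       or omit and supply `simulate`.}
#'     \item{simulate}{List passed to the synthetic generator:
#'       `n_per_group`, optional `moderated_edges` (data frame),
#'       `missing_rate`.}
#'     \item{groups}{Ordered group labels (default [default_groups()]).}
#'     \item{gamma, rule, covariates}{Estimator settings; `covariates` is a
#'       character vector such as `c("age", "sex", "site")` or `NULL`.}
#'     \item{complete_cases}{If `TRUE`, skip imputation and keep only
#'       participants with complete items.}
#'     \item{m, iterations}{Multiple-imputation settings.}
#'     \item{B}{Bootstrap samples for stability (0 skips the bootstrap).}
#'     \item{persons_csv, records_csv}{Optional prescription inputs for the
#'       trajectory stage.}
#'     \item{min_community_size}{Louvain community retention threshold.}
#'     \item{seed}{Integer seed used for every stochastic stage.}
#'     \item{out_dir}{Output directory.}
#'   }
#' @return Invisibly, a list with `data`, `fit`, `stability`, `metrics`,
#'   `metric_correlations`, `cohort`, `trajectories`, `communities`,
#'   `layout`, `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    groups = default_groups(), gamma = 0.5, rule = "OR", covariates = NULL,
    complete_cases = FALSE, m = 5, iterations = 10, B = 0,
    min_community_size = 10, seed = 1, out_dir = tempfile("modnet_run_")
  ), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("stage '", name, "' FAILED: ", conditionMessage(e))
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  logf("modnet ", as.character(utils::packageVersion("modnet")),
       " | seed ", cfg$seed)

  data <- stage("load", {
    if (!is.null(cfg$symptom_csv)) {
      read_symptom_csv(cfg$symptom_csv, groups = cfg$groups)
    } else if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      truth <- symptom_truth(
        moderated_edges = sim$moderated_edges,
        groups = cfg$groups
      )
      d <- simulate_symptoms(truth, n_per_group = sim$n_per_group %||% 200,
                             seed = cfg$seed)
      if (!is.null(sim$missing_rate) && sim$missing_rate > 0) {
        d <- inject_missingness(d, sim$missing_rate, seed = cfg$seed)
      }
      d
    } else {
      abort("config needs either `symptom_csv` or `simulate`.")
    }
  })
  items <- item_cols(data)
  logf("loaded ", nrow(data), " participants, ", length(items), " items")

  filt <- stage("filter", filter_missingness(data, items = items))
  logf("missingness filter excluded ", sum(filt$log$excluded),
       " participant(s)")

  completed <- stage("impute", {
    if (isTRUE(cfg$complete_cases)) {
      logf("complete-cases analysis: imputation stage skipped")
      cc <- filt$data[rowSums(is.na(as.matrix(filt$data[items]))) == 0, ]
      attr(cc, "items") <- items
      cc
    } else {
      impute_items(filt$data, m = cfg$m, iterations = cfg$iterations,
                   seed = cfg$seed, items = items)
    }
  })

  est <- estimator_config(gamma = cfg$gamma, rule = cfg$rule,
                          covariates = cfg$covariates)
  fit <- stage("fit", fit_mgm(completed, est, items = items))
  logf("fit: ", glance(fit)$n_edges, " edges, ",
       glance(fit)$n_moderation, " moderation effects")

  stab <- NULL
  if (cfg$B > 0) {
    stab_data <- if (inherits(completed, "completed_datasets")) {
      completed$completed[[1]]
    } else completed
    stab <- stage("bootstrap",
                  moderation_stability(stab_data, est, B = cfg$B,
                                       seed = cfg$seed, items = items))
    logf("bootstrap: B = ", cfg$B, ", ",
         sum(stab$class != "insufficient"), " effect(s) of sufficient stability")
  }

  metrics <- stage("metrics", local_metrics(fit))
  pairs <- utils::combn(as.character(fit$groups), 2, simplify = FALSE)
  metric_cor <- dplyr::bind_rows(lapply(pairs, function(pr) {
    tryCatch(compare_metrics(metrics, pr[1], pr[2]),
             error = function(e) tibble())
  }))

  cohort_data <- if (inherits(completed, "completed_datasets")) {
    completed$completed[[1]]
  } else completed
  cohort_data$sum_score <- rowSums(as.matrix(cohort_data[items]))
  cohort <- stage("cohort", dplyr::bind_rows(lapply(pairs, function(pr) {
    out <- cohort_table(cohort_data, groups = pr,
                        continuous = "age", binary = c("sex", "site"),
                        ordinal = "sum_score")
    out$group_1 <- pr[1]; out$group_2 <- pr[2]
    out
  })))

  traj <- NULL
  comms <- NULL
  if (!is.null(cfg$persons_csv) && !is.null(cfg$records_csv)) {
    traj <- stage("trajectories", {
      persons <- readr::read_csv(cfg$persons_csv, show_col_types = FALSE)
      records <- readr::read_csv(cfg$records_csv, show_col_types = FALSE)
      trajectory_features(persons, records)
    })
    comms <- stage("communities",
                   louvain_subgroups(traj,
                                     min_community_size = cfg$min_community_size,
                                     seed = cfg$seed))
    logf("communities: Q = ", signif(attr(comms, "modularity"), 3))
  }

  layout <- stage("layout", layout_positions(fit, seed = cfg$seed))

  paths <- list(model = file.path(cfg$out_dir, "model.json"),
                metrics = file.path(cfg$out_dir, "metrics.csv"),
                metric_correlations = file.path(cfg$out_dir,
                                                "metric_correlations.csv"),
                cohort = file.path(cfg$out_dir, "cohort.csv"),
                layout = file.path(cfg$out_dir, "layout.csv"),
                log = log_path)
  mgm_to_json(fit, paths$model)
  write_edge_lists(fit, cfg$out_dir)
  readr::write_csv(as_tibble(metrics), paths$metrics)
  readr::write_csv(metric_cor, paths$metric_correlations)
  readr::write_csv(cohort, paths$cohort)
  readr::write_csv(layout, paths$layout)
  if (!is.null(stab)) {
    paths$stability <- file.path(cfg$out_dir, "stability.csv")
    write_stability(stab, paths$stability)
  }
  if (!is.null(traj)) {
    paths$trajectories <- file.path(cfg$out_dir, "trajectory_features.csv")
    paths$communities <- file.path(cfg$out_dir, "communities.csv")
    readr::write_csv(traj, paths$trajectories)
    readr::write_csv(as_tibble(comms), paths$communities)
  }
  logf("done")

  invisible(list(data = data, fit = fit, stability = stab, metrics = metrics,
                 metric_correlations = metric_cor, cohort = cohort,
                 trajectories = traj, communities = comms, layout = layout,
                 paths = paths))
}
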