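#' Fit a group-moderated mixed graphical model
#'
#' Estimates a pairwise symptom network together with group-specific
#' moderation effects by nodewise regression: each item is regressed on all
#' other items, non-reference group dummies, and item-by-group interaction
#' terms, with an L1 penalty selected per node by the extended Bayesian
#' information criterion (EBIC). Pairwise weights are aggregated across the
#' two regressions of each node pair under the OR-rule (edge kept if either
#' coefficient is selected; weight = signed mean of the two absolute
#' coefficients) or the AND-rule. The network conditioned on a group is the
#' base (reference-group) network plus that group's moderation increments,
#' so groups without selected interactions share the reference network
#' exactly.
#'
#' When `data` is a [impute_items()] result with `m > 1` completed copies,
#' the model is fitted on every copy and all selected parameters are
#' averaged element-wise (set `use_first_only = TRUE` to fit only the first
#' copy).
#'
#' @param data Completed symptom tibble, a `completed_datasets` object, or a
#'   list of completed tibbles.
#' @param config [estimator_config()].
#' @param items Item columns.
#' @param group_col Moderator column name.
#' @param use_first_only With multiply-imputed input, fit only the first
#'   completed dataset instead of averaging across all of them.
#'
#' @return Object of class `moderated_mgm` with elements `items`, `groups`,
#'   `reference`, `base_weights` (symmetric, zero diagonal), `moderation`
#'   (tibble of per-(edge, group) increments), `conditioned` (named list of
#'   per-group weight matrices), `covariate_effects`, `node_fits` (selected
#'   penalty, EBIC, and selected-term count per node), `sign_conflicts`,
#'   `config`, `m`.
#' @export
#' @examples
#' truth <- symptom_truth(base_pcor = example_base_pcor()[1:6, 1:6],
#'                        groups = c("A", "B"))
#' d <- simulate_symptoms(truth, n_per_group = 200, seed = 7)
#' fit <- fit_mgm(d)
#' glance(fit)
fit_mgm <- function(data, config = estimator_config(), items = NULL,
                    group_col = "group", use_first_only = FALSE) {
  datasets <- if (inherits(data, "completed_datasets")) {
    if (use_first_only) data$completed[1] else data$completed
  } else if (is.data.frame(data)) {
    list(data)
  } else if (is.list(data)) {
    data
  } else {
    abort("`data` must be a data frame, list of data frames, or completed_datasets.")
  }
  items <- items %||% item_cols(datasets[[1]])

  fits <- lapply(datasets, fit_mgm_one, config = config, items = items,
                 group_col = group_col)

  if (length(fits) == 1) {
    model <- fits[[1]]
  } else {
    model <- fits[[1]]
    model$base_weights <- Reduce(`+`, lapply(fits, `[[`, "base_weights")) / length(fits)
    inc <- Reduce(`+`, lapply(fits, `[[`, "increments")) / length(fits)
    model$increments <- inc
    if (!is.null(model$covariate_matrix)) {
      model$covariate_matrix <-
        Reduce(`+`, lapply(fits, `[[`, "covariate_matrix")) / length(fits)
    }
    model$sign_conflicts <- dplyr::distinct(
      dplyr::bind_rows(lapply(fits, `[[`, "sign_conflicts"))
    )
  }
  model$m <- length(fits)
  # averaging across imputations can leave sign-cancelled values at machine
  # precision; treat those as structural zeros
  model$base_weights[abs(model$base_weights) < 1e-10] <- 0
  model$increments[abs(model$increments) < 1e-10] <- 0
  model$moderation <- increments_to_tibble(model$increments, model$items)
  model$conditioned <- conditioned_matrices(model)
  model$covariate_effects <- covariate_tibble(model)
  model$increments <- NULL
  model$covariate_matrix <- NULL
  class(model) <- "moderated_mgm"
  model
}

fit_mgm_one <- function(data, config, items, group_col) {
  p <- length(items)
  grp <- data[[group_col]]
  if (!is.factor(grp)) grp <- factor(grp)
  tab <- table(grp)
  small <- names(tab)[tab < config$min_group_n]
  if (length(small)) {
    abort(paste0("group(s) below min_group_n = ", config$min_group_n, ": ",
                 paste(small, collapse = ", ")))
  }
  ref <- config$reference_group %||% levels(grp)[1]
  nonref <- setdiff(levels(grp), ref)
  n <- nrow(data)

  beta_main <- matrix(0, p, p, dimnames = list(items, items))
  beta_int <- array(0, dim = c(p, p, length(nonref)),
                    dimnames = list(items, items, nonref))
  ncov <- length(config$covariates)
  beta_cov <- if (ncov) {
    matrix(0, p, ncov, dimnames = list(items, config$covariates))
  } else NULL
  node_fits <- vector("list", p)

  for (s in seq_len(p)) {
    node <- items[s]
    des <- build_moderated_design(data, node, config, items = items,
                                  group_col = group_col)
    fit <- lasso_path(des$y, des$X, nlambda = config$nlambda,
                      lambda_min_ratio = config$lambda_min_ratio,
                      tol = config$tol)
    idx <- select_ebic(fit, n = n, P = ncol(des$X), gamma = config$gamma)
    b <- fit$beta[, idx]
    sel <- des$map
    sel$coef <- b
    node_fits[[s]] <- tibble(node = node, lambda = fit$lambdas[idx],
                             ebic = ebic(fit$rss[idx], n, fit$df[idx],
                                         ncol(des$X), config$gamma),
                             k = fit$df[idx])
    mi <- sel[sel$kind == "item", ]
    beta_main[node, mi$item] <- mi$coef
    for (g in nonref) {
      gi <- sel[sel$kind == "interaction" & sel$group == g, ]
      beta_int[node, gi$item, g] <- gi$coef
    }
    if (ncov) {
      ci <- sel[sel$kind == "covariate", ]
      beta_cov[node, ci$item] <- ci$coef
    }
  }

  base <- matrix(0, p, p, dimnames = list(items, items))
  inc <- array(0, dim = c(p, p, length(nonref)),
               dimnames = list(items, items, nonref))
  conflicts <- list()
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      cw <- combine_pair(beta_main[i, j], beta_main[j, i], config$rule)
      base[i, j] <- base[j, i] <- cw$w
      if (cw$conflict) {
        conflicts[[length(conflicts) + 1]] <-
          tibble(item_i = items[i], item_j = items[j], group = NA_character_)
      }
      for (g in nonref) {
        cwi <- combine_pair(beta_int[i, j, g], beta_int[j, i, g], config$rule)
        inc[i, j, g] <- inc[j, i, g] <- cwi$w
        if (cwi$conflict) {
          conflicts[[length(conflicts) + 1]] <-
            tibble(item_i = items[i], item_j = items[j], group = g)
        }
      }
    }
  }

  list(
    items = items, groups = levels(grp), reference = ref,
    base_weights = base, increments = inc,
    covariate_matrix = beta_cov,
    node_fits = dplyr::bind_rows(node_fits),
    sign_conflicts = if (length(conflicts)) dplyr::bind_rows(conflicts) else
      tibble(item_i = character(), item_j = character(), group = character()),
    config = config
  )
}

# Pairwise aggregation of the two nodewise coefficients for one edge.
combine_pair <- function(b1, b2, rule) {
  nz1 <- b1 != 0
  nz2 <- b2 != 0
  present <- if (rule == "OR") nz1 || nz2 else nz1 && nz2
  if (!present) return(list(w = 0, conflict = FALSE))
  if (nz1 && nz2 && sign(b1) != sign(b2)) {
    return(list(w = (b1 + b2) / 2, conflict = TRUE))
  }
  s <- if (nz1) sign(b1) else sign(b2)
  list(w = s * (abs(b1) + abs(b2)) / 2, conflict = FALSE)
}

increments_to_tibble <- function(inc, items) {
  if (is.null(inc) || !length(inc)) {
    return(tibble(item_i = character(), item_j = character(),
                  group = character(), increment = numeric()))
  }
  out <- list()
  for (g in dimnames(inc)[[3]]) {
    m <- inc[, , g]
    idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
    if (nrow(idx)) {
      out[[g]] <- tibble(item_i = items[idx[, 1]], item_j = items[idx[, 2]],
                         group = g, increment = m[idx])
    }
  }
  if (!length(out)) {
    return(tibble(item_i = character(), item_j = character(),
                  group = character(), increment = numeric()))
  }
  dplyr::bind_rows(out)
}

conditioned_matrices <- function(model) {
  out <- lapply(model$groups, function(g) {
    m <- model$base_weights
    if (g != model$reference) {
      rows <- model$moderation[model$moderation$group == g, ]
      if (nrow(rows)) {
        for (r in seq_len(nrow(rows))) {
          i <- rows$item_i[r]; j <- rows$item_j[r]
          m[i, j] <- m[i, j] + rows$increment[r]
          m[j, i] <- m[i, j]
        }
      }
    }
    m
  })
  names(out) <- model$groups
  out
}

covariate_tibble <- function(model) {
  cm <- model$covariate_matrix
  if (is.null(cm)) {
    return(tibble(item = character(), covariate = character(),
                  coefficient = numeric()))
  }
  out <- as_tibble(cm, rownames = "item")
  out <- tidyr::pivot_longer(out, -"item", names_to = "covariate",
                             values_to = "coefficient")
  out[out$coefficient != 0, ]
}

#' Network conditioned on one moderator group
#'
#' Returns the symmetric weight matrix of the network for `group`: the base
#' (reference) weights plus that group's moderation increments. The
#' reference group returns the base weights themselves.
#'
#' @param model A [fit_mgm()] result.
#' @param group Group label.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
condition_on_group <- function(model, group) {
  stopifnot(inherits(model, "moderated_mgm"))
  if (!group %in% model$groups) {
    abort(paste0("unknown group '", group, "'; model groups: ",
                 paste(model$groups, collapse = ", ")))
  }
  model$conditioned[[group]]
}

#' @export
print.moderated_mgm <- function(x, ...) {
  cat("Moderated mixed graphical model\n")
  cat("  nodes:", length(x$items), " groups:",
      paste(x$groups, collapse = ", "), "\n")
  cat("  reference:", x$reference, " rule:", x$config$rule,
      " gamma:", x$config$gamma, "\n")
  cat("  edges (base):", sum(x$base_weights[upper.tri(x$base_weights)] != 0),
      " moderation effects:", nrow(x$moderation),
      " imputations averaged:", x$m, "\n")
  invisible(x)
}

#' Tidy a moderated network model
#'
#' One row per (edge, group) of the conditioned networks, restricted to
#' edges present in at least one group. `moderated` marks edges carrying a
#' moderation increment for that group.
#'
#' @param x A `moderated_mgm`.
#' @param ... Unused.
#' @return Tibble with `item_i`, `item_j`, `group`, `weight`, `moderated`,
#'   `increment`.
#' @export
tidy.moderated_mgm <- function(x, ...) {
  ut <- upper.tri(x$base_weights)
  keep <- Reduce(`|`, lapply(x$conditioned, function(m) m != 0)) & ut
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble(item_i = x$items[idx[, 1]], item_j = x$items[idx[, 2]])
  out <- tidyr::crossing(edges, group = x$groups)
  out$weight <- purrr::pmap_dbl(out, function(item_i, item_j, group) {
    x$conditioned[[group]][item_i, item_j]
  })
  out <- dplyr::left_join(
    out,
    dplyr::mutate(x$moderation, moderated = TRUE),
    by = c("item_i", "item_j", "group")
  )
  out$moderated <- !is.na(out$moderated)
  out$increment <- dplyr::coalesce(out$increment, 0)
  out$group <- factor(out$group, levels = x$groups)
  dplyr::arrange(out, .data$item_i, .data$item_j, .data$group)
}

#' @rdname tidy.moderated_mgm
#' @export
glance.moderated_mgm <- function(x, ...) {
  tibble(
    n_nodes = length(x$items),
    n_edges = sum(x$base_weights[upper.tri(x$base_weights)] != 0),
    n_moderation = nrow(x$moderation),
    gamma = x$config$gamma,
    rule = x$config$rule,
    reference = x$reference,
    m = x$m
  )
}

#' Serialize a moderated network model
#'
#' `mgm_to_json()` writes the node labels, base weights, moderation map,
#' per-group conditioned matrices, and configuration as JSON.
#' `write_edge_lists()` writes one weighted edge-list CSV per group
#' (`node_i, node_j, weight`, nonzero edges only) and, optionally, GraphML.
#'
#' @param model A `moderated_mgm`.
#' @param path Output JSON file.
#' @param dir Output directory for edge lists.
#' @param graphml Also write `network_<group>.graphml` files.
#' @return The written path(s), invisibly.
#' @export
mgm_to_json <- function(model, path) {
  obj <- list(
    items = model$items, groups = model$groups, reference = model$reference,
    base_weights = model$base_weights, moderation = model$moderation,
    conditioned = model$conditioned,
    config = unclass(model$config), m = model$m
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname mgm_to_json
#' @export
write_edge_lists <- function(model, dir, graphml = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (g in model$groups) {
    w <- model$conditioned[[g]]
    idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
    el <- tibble(node_i = model$items[idx[, 1]],
                 node_j = model$items[idx[, 2]],
                 weight = w[idx])
    fg <- gsub("[^A-Za-z0-9_-]", "_", g)
    p <- file.path(dir, paste0("network_", fg, ".csv"))
    readr::write_csv(el, p)
    paths <- c(paths, p)
    if (graphml) {
      gr <- igraph::graph_from_adjacency_matrix(abs(w), mode = "undirected",
                                                weighted = TRUE)
      gp <- file.path(dir, paste0("network_", fg, ".graphml"))
      igraph::write_graph(gr, gp, format = "graphml")
      paths <- c(paths, gp)
    }
  }
  invisible(paths)
}
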