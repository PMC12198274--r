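#' Node strength of a weighted network
#'
#' The strength of node i is the sum of absolute weights of its incident
#' edges, `s_i = sum_j |w_ij|`.
#'
#' @param W Symmetric weight matrix with zero diagonal.
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(W) {
  check_weight_matrix(W)
  rowSums(abs(W))
}

#' Weighted local clustering coefficient
#'
#' How interconnected a node's neighbors are, generalized to weighted
#' graphs. Weights are first scaled to `[0, 1]` by the maximum absolute
#' weight; the default Zhang-Horvath form is
#' `C_i = sum_{j != k} w_ij w_jk w_ik / sum_{j != k} w_ij w_ik`, the Onnela
#' form replaces products by geometric means of triangle weights over
#' `k_i (k_i - 1)`, and the Barrat form weights the binary triangle count by
#' incident strength. Nodes with fewer than two neighbors have an empty
#' denominator and clustering 0. On a binary 0/1 matrix every variant
#' reduces to the unweighted local clustering coefficient.
#'
#' @param W Symmetric weight matrix with zero diagonal.
#' @param variant `"zhang"` (default), `"onnela"`, or `"barrat"`.
#' @return Named numeric vector of clustering coefficients in `[0, 1]`.
#' @export
#' @examples
#' W <- matrix(0, 3, 3)
#' W[1, 2] <- W[2, 1] <- 0.5
#' W[1, 3] <- W[3, 1] <- 0.5
#' W[2, 3] <- W[3, 2] <- 0.25
#' local_clustering(W) # node 1: (1 * 1 * 0.5) / (1 * 1) = 0.5
local_clustering <- function(W, variant = c("zhang", "onnela", "barrat")) {
  variant <- match.arg(variant)
  check_weight_matrix(W)
  w <- abs(W)
  mx <- max(w)
  if (mx > 0) w <- w / mx
  p <- nrow(w)
  out <- numeric(p)
  if (variant == "zhang") {
    num <- diag(w %*% w %*% w)
    s1 <- rowSums(w)
    s2 <- rowSums(w^2)
    den <- s1^2 - s2
    out <- ifelse(den > 1e-12, num / den, 0)
  } else if (variant == "onnela") {
    a <- (w > 0) + 0
    k <- rowSums(a)
    wc <- w^(1 / 3)
    num <- diag(wc %*% wc %*% wc)
    den <- k * (k - 1)
    out <- ifelse(den > 0, num / den, 0)
  } else {
    a <- (w > 0) + 0
    k <- rowSums(a)
    s <- rowSums(w)
    num <- diag((w %*% a %*% a + a %*% a %*% w)) / 2
    den <- s * (k - 1)
    out <- ifelse(den > 1e-12, num / den, 0)
  }
  out <- pmin(pmax(out, 0), 1)
  names(out) <- rownames(W)
  out
}

check_weight_matrix <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) abort("W must be a square matrix.")
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10))) {
    abort("W must be symmetric.")
  }
  if (any(abs(diag(W)) > 1e-12)) abort("W must have zero diagonal.")
  invisible(TRUE)
}

#' Local network metrics per group
#'
#' Node strength and weighted local clustering for each group-conditioned
#' network of a moderated model, raw and standardized (z-scored across the
#' nodes within one network).
#'
#' @param model A [fit_mgm()] result, or a named list of weight matrices.
#' @param variant Clustering variant, see [local_clustering()].
#' @return Tibble of class `local_metrics`: `group`, `node`, `strength`,
#'   `clustering`, `strength_z`, `clustering_z`.
#' @export
local_metrics <- function(model, variant = "zhang") {
  mats <- if (inherits(model, "moderated_mgm")) model$conditioned else model
  stopifnot(is.list(mats), !is.null(names(mats)))
  zscore <- function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  out <- purrr::imap(mats, function(W, g) {
    s <- node_strength(W)
    cc <- local_clustering(W, variant)
    tibble(group = g, node = rownames(W) %||% as.character(seq_len(nrow(W))),
           strength = unname(s), clustering = unname(cc),
           strength_z = zscore(unname(s)), clustering_z = zscore(unname(cc)))
  })
  out <- dplyr::bind_rows(out)
  out$group <- factor(out$group, levels = names(mats))
  class(out) <- c("local_metrics", class(out))
  out
}

#' Between-group correlation of local network metrics
#'
#' Pearson correlation, over the nodes, of each local metric between two
#' groups' networks. Errors if a metric has zero variance in either group
#' (correlation undefined).
#'
#' @param metrics A [local_metrics()] tibble.
#' @param group_a,group_b Group labels to compare.
#' @return Tibble with `metric`, `group_a`, `group_b`, `correlation`.
#' @export
compare_metrics <- function(metrics, group_a, group_b) {
  a <- metrics[metrics$group == group_a, ]
  b <- metrics[metrics$group == group_b, ]
  if (!nrow(a) || !nrow(b)) abort("unknown group label.")
  stopifnot(identical(a$node, b$node))
  one <- function(m) {
    x <- a[[m]]; y <- b[[m]]
    if (sd(x) == 0 || sd(y) == 0) {
      abort(paste0("zero variance in '", m, "'; correlation undefined."))
    }
    cor(x, y)
  }
  tibble(
    metric = c("strength", "clustering"),
    group_a = group_a, group_b = group_b,
    correlation = c(one("strength"), one("clustering"))
  )
}

#' Mean and SD summary of local metrics per network
#'
#' @param metrics A [local_metrics()] tibble.
#' @return Tibble with per-group mean and SD of strength and clustering.
#' @export
summarize_metrics <- function(metrics) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(metrics), .data$group),
    strength_mean = mean(.data$strength),
    strength_sd = sd(.data$strength),
    clustering_mean = mean(.data$clustering),
    clustering_sd = sd(.data$clustering),
    .groups = "drop"
  )
}
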