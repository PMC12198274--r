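#' Ground-truth moderated network for simulation
#'
#' Bundles a base partial-correlation network over the symptom items with a
#' set of planted group-specific moderation effects. Each group's network is
#' the base matrix plus that group's deltas; groups without planted deltas
#' share the base matrix exactly. The implied precision matrix (unit
#' diagonal, off-diagonal `-pcor`) must be positive definite for every
#' group, otherwise the latent Gaussian has no valid distribution.
#'
#' @param base_pcor Symmetric matrix of partial correlations (zero
#'   diagonal, entries in (-1, 1)) with one row/column per item. Defaults to
#'   a sparse, positively connected 18-item network typical of symptom
#'   scales (see [example_base_pcor()]).
#' @param moderated_edges Data frame with columns `item_i`, `item_j`,
#'   `group`, `delta`: additive increments applied to single edges for
#'   single non-reference groups. `NULL` for no moderation.
#' @param items Character vector of item labels; must match the dimnames of
#'   `base_pcor` if those are set.
#' @param groups Ordered character vector of group labels; the first is the
#'   reference.
#'
#' @return An object of class `symptom_truth`: a list with `items`,
#'   `groups`, `partial_corr` (named list of per-group matrices) and
#'   `moderated_edges` (tibble).
#' @export
#' @examples
#' truth <- symptom_truth(
#'   moderated_edges = data.frame(
#'     item_i = "fidget", item_j = "run",
#'     group = "ADHD-stim", delta = 0.25
#'   )
#' )
#' truth$moderated_edges
symptom_truth <- function(base_pcor = example_base_pcor(),
                          moderated_edges = NULL,
                          items = colnames(base_pcor),
                          groups = default_groups()) {
  if (is.null(items)) items <- cprs_items()[seq_len(ncol(base_pcor))]
  p <- length(items)
  stopifnot(is.matrix(base_pcor), nrow(base_pcor) == p, ncol(base_pcor) == p)
  if (!isTRUE(all.equal(base_pcor, t(base_pcor)))) {
    abort("`base_pcor` must be symmetric.")
  }
  if (any(abs(diag(base_pcor)) > 1e-12)) abort("`base_pcor` must have zero diagonal.")
  if (any(abs(base_pcor) >= 1)) abort("partial correlations must lie in (-1, 1).")
  dimnames(base_pcor) <- list(items, items)

  med <- if (is.null(moderated_edges)) {
    tibble(item_i = character(), item_j = character(),
           group = character(), delta = numeric())
  } else {
    as_tibble(moderated_edges)[, c("item_i", "item_j", "group", "delta")]
  }
  bad_items <- setdiff(c(med$item_i, med$item_j), items)
  if (length(bad_items)) abort(paste0("unknown item(s) in moderated_edges: ",
                                      paste(bad_items, collapse = ", ")))
  bad_groups <- setdiff(med$group, groups)
  if (length(bad_groups)) abort(paste0("unknown group(s) in moderated_edges: ",
                                       paste(bad_groups, collapse = ", ")))

  pcor <- lapply(groups, function(g) {
    m <- base_pcor
    rows <- med[med$group == g, ]
    if (nrow(rows)) {
      for (r in seq_len(nrow(rows))) {
        i <- rows$item_i[r]; j <- rows$item_j[r]
        m[i, j] <- m[i, j] + rows$delta[r]
        m[j, i] <- m[i, j]
      }
    }
    m
  })
  names(pcor) <- groups

  for (g in groups) {
    omega <- pcor_to_precision(pcor[[g]])
    ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10) {
      abort(paste0("implied precision matrix for group '", g,
                   "' is not positive definite (min eigenvalue ",
                   signif(ev, 3), ")."))
    }
  }

  structure(
    list(items = items, groups = groups, partial_corr = pcor,
         moderated_edges = med),
    class = "symptom_truth"
  )
}

# Precision with unit diagonal implied by a partial-correlation matrix:
# omega_ij = -pcor_ij for i != j.
pcor_to_precision <- function(pcor) {
  omega <- -pcor
  diag(omega) <- 1
  omega
}

# Latent correlation matrix implied by a partial-correlation matrix.
pcor_to_sigma <- function(pcor) {
  omega <- pcor_to_precision(pcor)
  sigma <- solve(omega)
  stats::cov2cor(sigma)
}

#' Default base partial-correlation network
#'
#' A fixed, sparse 18-item network with positive partial correlations in the
#' 0.08-0.30 range: a backbone within the inattentive and
#' hyperactive-impulsive domains plus a few cross-domain edges, mirroring
#' the qualitative structure reported for parent-rated ADHD symptom scales
#' (all edges positive, strongest links within domains).
#'
#' @return Symmetric 18 x 18 matrix with `cprs_items()` dimnames.
#' @export
example_base_pcor <- function() {
  items <- cprs_items()
  p <- length(items)
  m <- matrix(0, p, p, dimnames = list(items, items))
  set_edge <- function(i, j, w) {
    m[i, j] <<- w
    m[j, i] <<- w
  }
  # inattentive backbone
  set_edge("closeatt", "susatt", 0.22)
  set_edge("susatt", "listen", 0.18)
  set_edge("listen", "instruct", 0.15)
  set_edge("instruct", "org", 0.20)
  set_edge("org", "avoid", 0.18)
  set_edge("avoid", "lose", 0.12)
  set_edge("lose", "distract", 0.14)
  set_edge("distract", "forget", 0.18)
  set_edge("closeatt", "org", 0.10)
  set_edge("susatt", "distract", 0.15)
  set_edge("instruct", "forget", 0.12)
  # hyperactive-impulsive backbone
  set_edge("fidget", "seat", 0.22)
  set_edge("seat", "run", 0.25)
  set_edge("run", "motor", 0.20)
  set_edge("motor", "quiet", 0.15)
  set_edge("quiet", "talk", 0.12)
  set_edge("talk", "blurt", 0.20)
  set_edge("blurt", "turn", 0.16)
  set_edge("turn", "interrupt", 0.22)
  set_edge("fidget", "motor", 0.12)
  set_edge("run", "quiet", 0.10)
  set_edge("blurt", "interrupt", 0.14)
  # cross-domain links
  set_edge("distract", "fidget", 0.10)
  set_edge("susatt", "talk", 0.08)
  set_edge("instruct", "interrupt", 0.08)
  m
}
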