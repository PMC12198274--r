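#' Estimator configuration
#'
#' Settings for the moderated mixed-graphical-model fit.
#'
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param nlambda,lambda_min_ratio Penalty path: `nlambda` log-spaced values
#'   from the per-node `lambda_max` down to `lambda_max * lambda_min_ratio`.
#' @param rule Edge rule: `"OR"` keeps an edge when either of the two
#'   nodewise coefficients is selected, `"AND"` requires both.
#' @param reference_group Reference level of the moderator; defaults to the
#'   first group level (the largest group by convention).
#' @param covariates Optional character vector of covariate columns entered
#'   as main-effect nodes (e.g. `c("age", "sex", "site")`).
#' @param standardize Standardize dummy and interaction columns (items are
#'   always standardized). Interaction columns are standardized after the
#'   product is formed, so the penalty acts on a comparable scale.
#' @param min_group_n Minimum participants per moderator group.
#' @param tol Coordinate-descent convergence tolerance.
#'
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(gamma = 0.5, nlambda = 50, lambda_min_ratio = 1e-4,
                             rule = c("OR", "AND"), reference_group = NULL,
                             covariates = NULL, standardize = TRUE,
                             min_group_n = 10, tol = 1e-8) {
  rule <- match.arg(rule)
  stopifnot(gamma >= 0, nlambda >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(
    list(gamma = gamma, nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
         rule = rule, reference_group = reference_group,
         covariates = covariates, standardize = standardize,
         min_group_n = min_group_n, tol = tol),
    class = "estimator_config"
  )
}

#' Build the moderated nodewise design for one item
#'
#' For the response item `node`, the candidate predictors are: all other
#' items (standardized), one dummy per non-reference moderator group, the
#' products of each other item with each non-reference dummy (the moderation
#' terms), and any configured covariates as main effects. With 18 items and
#' 3 groups this gives 17 + 2 + 34 = 53 predictors (56 with age/sex/site).
#' The column map ties every design column to its (item, group) meaning.
#'
#' @param data Completed (no missing items) symptom tibble.
#' @param node Item name used as the response.
#' @param config [estimator_config()].
#' @param items Item columns.
#' @param group_col Name of the moderator column.
#'
#' @return List with `y` (centered, scaled response), `X` (standardized
#'   design), `map` (tibble: `col`, `kind`, `item`, `group`), `dropped`
#'   (names of constant columns removed), `reference`, `groups`.
#' @export
build_moderated_design <- function(data, node, config = estimator_config(),
                                   items = item_cols(data),
                                   group_col = "group") {
  stopifnot(node %in% items)
  grp <- data[[group_col]]
  if (!is.factor(grp)) grp <- factor(grp)
  tab <- table(grp)
  if (length(tab) < 2) abort("need at least 2 moderator groups.")
  small <- names(tab)[tab < 2]
  if (length(small)) {
    abort(paste0("group(s) with < 2 participants: ", paste(small, collapse = ", ")))
  }
  ref <- config$reference_group %||% levels(grp)[1]
  if (!ref %in% levels(grp)) abort(paste0("unknown reference group '", ref, "'."))
  nonref <- setdiff(levels(grp), ref)

  xmat <- as.matrix(data[items])
  storage.mode(xmat) <- "double"
  if (anyNA(xmat)) abort("design requires completed data (no missing items).")
  sds <- apply(xmat, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant item(s): ",
                 paste(items[sds == 0], collapse = ", ")))
  }
  z <- standardize_cols(xmat)

  others <- setdiff(items, node)
  blocks <- list(z[, others, drop = FALSE])
  map <- tibble(col = others, kind = "item", item = others, group = NA_character_)

  for (g in nonref) {
    d <- as.numeric(grp == g)
    dn <- paste0("grp:", g)
    blocks <- c(blocks, list(matrix(d, ncol = 1, dimnames = list(NULL, dn))))
    map <- dplyr::bind_rows(map, tibble(col = dn, kind = "group",
                                        item = NA_character_, group = g))
    inter <- z[, others, drop = FALSE] * d
    colnames(inter) <- paste0(others, ":", g)
    blocks <- c(blocks, list(inter))
    map <- dplyr::bind_rows(map, tibble(col = colnames(inter),
                                        kind = "interaction",
                                        item = others, group = g))
  }

  if (!is.null(config$covariates)) {
    missing_cov <- setdiff(config$covariates, names(data))
    if (length(missing_cov)) {
      abort(paste0("covariate column(s) not found: ",
                   paste(missing_cov, collapse = ", ")))
    }
    cv <- as.matrix(data[config$covariates])
    storage.mode(cv) <- "double"
    colnames(cv) <- paste0("cov:", config$covariates)
    blocks <- c(blocks, list(cv))
    map <- dplyr::bind_rows(map, tibble(col = colnames(cv), kind = "covariate",
                                        item = config$covariates,
                                        group = NA_character_))
  }

  X <- do.call(cbind, blocks)
  dropped <- character()
  if (config$standardize) {
    X <- standardize_cols(X)
    dropped <- attr(X, "dropped")
  } else {
    keep <- apply(X, 2, function(x) sd(x) > 1e-12)
    dropped <- colnames(X)[!keep]
    X <- X[, keep, drop = FALSE]
  }
  map <- map[map$col %in% colnames(X), ]
  map <- map[match(colnames(X), map$col), ]

  y <- drop(standardize_cols(xmat[, node, drop = FALSE]))
  list(y = y, X = X, map = map, dropped = dropped, reference = ref,
       groups = levels(grp))
}
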