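#' Exclude participants with too many missing item scores
#'
#' Removes participants whose fraction of missing items is greater than or
#' equal to `max_missing_fraction` (default 0.5, i.e. half the items or
#' more). The exclusion log records every removed participant and their
#' missing-item count; retained participants with any missingness are
#' flagged for imputation.
#'
#' @param data Symptom tibble.
#' @param max_missing_fraction Exclusion threshold on the missing fraction;
#'   participants at or above it are dropped.
#' @param items Item column names.
#'
#' @return A list with `data` (the filtered tibble) and `log` (tibble of
#'   `participant_id`, `n_missing`, `excluded`, `needs_imputation`).
#' @export
filter_missingness <- function(data, max_missing_fraction = 0.5,
                               items = item_cols(data)) {
  if (!nrow(data)) abort("empty dataset.")
  m <- as.matrix(data[items])
  n_miss <- rowSums(is.na(m))
  frac <- n_miss / length(items)
  excluded <- frac >= max_missing_fraction
  if (all(excluded)) abort("all participants excluded by the missingness filter.")
  log <- tibble(
    participant_id = data$participant_id,
    n_missing = as.integer(n_miss),
    excluded = excluded,
    needs_imputation = !excluded & n_miss > 0
  )
  out <- data[!excluded, , drop = FALSE]
  attr(out, "items") <- items
  mask <- attr(data, "miss_mask")
  if (!is.null(mask)) attr(out, "miss_mask") <- mask[!excluded, , drop = FALSE]
  list(data = out, log = log)
}

#' Multiple imputation of missing item scores
#'
#' Chained-equations imputation with predictive mean matching (PMM).
#' Missing cells are initialized from the observed marginal of their item;
#' then, for a fixed number of iterations, each item with missingness is
#' regressed (ordinary least squares) on all other items over its observed
#' rows, and every missing cell is filled with the observed value of one of
#' the `donors` cases whose predictions are closest to the missing case's
#' prediction. PMM draws from the observed support, so imputed scores are
#' always valid category values. `m` chains are run independently, giving
#' `m` completed datasets; observed entries are identical across all copies.
#'
#' @param data Symptom tibble that has passed [filter_missingness()].
#' @param m Number of completed datasets.
#' @param iterations Chained-equation sweeps per chain.
#' @param donors Size of the PMM donor pool.
#' @param seed Integer seed.
#' @param items Item column names.
#'
#' @return Object of class `completed_datasets`: list with `completed`
#'   (list of `m` completed tibbles), `m`, `iterations`, `donors`, `seed`.
#' @export
impute_items <- function(data, m = 5, iterations = 10, donors = 5, seed = 1,
                         items = item_cols(data)) {
  x <- as.matrix(data[items])
  storage.mode(x) <- "double"
  miss <- is.na(x)
  all_missing <- colnames(x)[colSums(!miss) == 0]
  if (length(all_missing)) {
    abort(paste0("item(s) missing for all participants: ",
                 paste(all_missing, collapse = ", ")))
  }

  complete_once <- function(chain_seed) {
    set.seed(chain_seed)
    xc <- x
    miss_items <- which(colSums(miss) > 0)
    # initialize from observed marginals
    for (j in miss_items) {
      obs <- xc[!miss[, j], j]
      xc[miss[, j], j] <- sample(obs, sum(miss[, j]), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (j in miss_items) {
        obs_rows <- !miss[, j]
        df <- as.data.frame(xc[, -j, drop = FALSE])
        fit <- lm(xc[obs_rows, j] ~ ., data = df[obs_rows, , drop = FALSE])
        # collinear predictors give a rank-deficient fit; PMM only needs the
        # fitted ordering, so the prediction warning is irrelevant here
        pred <- suppressWarnings(predict(fit, newdata = df))
        pred_obs <- pred[obs_rows]
        y_obs <- xc[obs_rows, j]
        for (i in which(miss[, j])) {
          d <- abs(pred_obs - pred[i])
          pool <- order(d)[seq_len(min(donors, length(d)))]
          xc[i, j] <- y_obs[sample(pool, 1)]
        }
      }
    }
    xc
  }

  if (!any(miss)) {
    completed <- replicate(m, data, simplify = FALSE)
  } else {
    completed <- lapply(seq_len(m), function(k) {
      xc <- complete_once(seed + k - 1L)
      out <- data
      out[items] <- as_tibble(xc)
      out[items] <- lapply(out[items], as.integer)
      attr(out, "items") <- items
      out
    })
  }
  structure(
    list(completed = completed, m = m, iterations = iterations,
         donors = donors, seed = seed, items = items),
    class = "completed_datasets"
  )
}
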