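#' Stratified (block) bootstrap resampling indices
#'
#' Samples participants with replacement within each moderator group, so
#' every resample preserves the group sizes exactly and every resampled row
#' keeps its original group label. Set `stratified = FALSE` for a simple
#' unstratified bootstrap of the whole sample.
#'
#' @param group_labels Factor (or vector) of group labels, one per
#'   participant; every group must be nonempty.
#' @param seed Integer seed.
#' @param stratified Resample within groups (default) or over the pooled
#'   sample.
#' @return Integer vector of row indices of length `length(group_labels)`.
#' @export
bootstrap_indices <- function(group_labels, seed = 1, stratified = TRUE) {
  grp <- as.factor(group_labels)
  if (any(table(grp) == 0)) abort("every group must be nonempty.")
  set.seed(seed)
  if (!stratified) {
    return(sample(seq_along(grp), length(grp), replace = TRUE))
  }
  idx <- unlist(lapply(levels(grp), function(g) {
    rows <- which(grp == g)
    sample(rows, length(rows), replace = TRUE)
  }), use.names = FALSE)
  idx
}

#' Classify moderation-effect stability
#'
#' Bootstrap presence proportions are classed as `good` when >= 0.80,
#' `moderate` when in `[0.50, 0.80)`, and `insufficient` below 0.50; effects
#' of at least moderate stability are considered interpretable.
#'
#' @param proportion Numeric vector of presence proportions in `[0, 1]`.
#' @return Factor with levels `insufficient`, `moderate`, `good`.
#' @export
#' @examples
#' classify_stability(c(0.95, 0.80, 0.79, 0.50, 0.47))
classify_stability <- function(proportion) {
  stopifnot(all(proportion >= 0 & proportion <= 1))
  cut(proportion, breaks = c(-Inf, 0.5, 0.8, Inf),
      labels = c("insufficient", "moderate", "good"), right = FALSE)
}

#' Bootstrap stability of moderation effects
#'
#' Refits the full moderated network (penalty re-selected by EBIC within
#' each replicate) on `B` stratified bootstrap resamples and reports, for
#' every moderation effect seen in the reference fit or in any replicate,
#' the proportion of replicates in which that (edge, group) interaction was
#' selected, together with its stability class.
#'
#' @param data Completed symptom tibble.
#' @param config [estimator_config()].
#' @param B Number of bootstrap samples (default 500).
#' @param seed Integer seed; replicate `b` uses `seed + b`.
#' @param reference_fit Optional pre-computed [fit_mgm()] on `data`
#'   (computed if omitted).
#' @param items,group_col Passed to [fit_mgm()].
#' @param stratified Passed to [bootstrap_indices()].
#'
#' @return Object of class `stability_report`: a tibble with `item_i`,
#'   `item_j`, `group`, `proportion`, `class`, `in_reference`, plus
#'   attributes `B` and `seed`.
#' @export
moderation_stability <- function(data, config = estimator_config(), B = 500,
                                 seed = 1, reference_fit = NULL,
                                 items = NULL, group_col = "group",
                                 stratified = TRUE) {
  if (B < 1) abort("B must be >= 1.")
  items <- items %||% item_cols(data)
  reference_fit <- reference_fit %||%
    fit_mgm(data, config, items = items, group_col = group_col)

  counts <- list()
  key <- function(i, j, g) paste(i, j, g, sep = "\r")
  for (b in seq_len(B)) {
    idx <- bootstrap_indices(data[[group_col]], seed = seed + b,
                             stratified = stratified)
    db <- data[idx, , drop = FALSE]
    attr(db, "items") <- items
    fit_b <- fit_mgm(db, config, items = items, group_col = group_col)
    mod <- fit_b$moderation
    if (nrow(mod)) {
      for (r in seq_len(nrow(mod))) {
        k <- key(mod$item_i[r], mod$item_j[r], mod$group[r])
        counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      }
    }
  }

  ref_keys <- if (nrow(reference_fit$moderation)) {
    with(reference_fit$moderation, key(item_i, item_j, group))
  } else character()
  all_keys <- union(ref_keys, names(counts))
  if (!length(all_keys)) {
    out <- tibble(item_i = character(), item_j = character(),
                  group = character(), proportion = numeric(),
                  class = classify_stability(numeric()),
                  in_reference = logical())
  } else {
    parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
    out <- tibble(
      item_i = parts[, 1], item_j = parts[, 2], group = parts[, 3],
      proportion = vapply(all_keys, function(k) (counts[[k]] %||% 0L) / B,
                          numeric(1), USE.NAMES = FALSE)
    )
    out$class <- classify_stability(out$proportion)
    out$in_reference <- all_keys %in% ref_keys
    out <- dplyr::arrange(out, dplyr::desc(.data$proportion))
  }
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  class(out) <- c("stability_report", class(out))
  out
}

#' Write a stability report
#'
#' @param report A [moderation_stability()] result.
#' @param path Output path; `.csv` or `.json` chosen by extension.
#' @return `path`, invisibly.
#' @export
write_stability <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(B = attr(report, "B"), seed = attr(report, "seed"),
           effects = as.data.frame(report)),
      path, digits = NA, auto_unbox = TRUE, pretty = TRUE
    )
  } else {
    readr::write_csv(as_tibble(report), path)
  }
  invisible(path)
}
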