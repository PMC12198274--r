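#' Simulate ordinal symptom data from a ground-truth network
#'
#' Draws, for each group, latent multivariate-normal vectors whose
#' correlation structure is implied by that group's partial-correlation
#' matrix (precision with unit diagonal, off-diagonal `-pcor`), then
#' discretizes each latent variable at three cutpoints into ordinal scores
#' 0-3. The default cutpoints at standard-normal quantiles 0.5, 1.0 and 1.5
#' give the right-skewed score distribution typical of community samples.
#' Covariates (age, sex, site) are drawn independently of the items with
#' group-specific marginals resembling a multi-site case-control cohort.
#'
#' @param truth A [symptom_truth()] object.
#' @param n_per_group Integer vector of per-group sample sizes, recycled to
#'   the number of groups; every entry must be >= 1.
#' @param thresholds Strictly increasing numeric vector of 3 latent
#'   cutpoints, or a matrix with one row per item.
#' @param seed Integer seed; the same seed and inputs reproduce the dataset
#'   exactly.
#'
#' @return A tibble with columns `participant_id`, `group` (factor with the
#'   truth's level order), `age`, `sex` (0 female / 1 male), `site`
#'   (0/1), and one integer column per item.
#' @export
#' @examples
#' truth <- symptom_truth()
#' d <- simulate_symptoms(truth, n_per_group = 50, seed = 1)
#' dplyr::count(d, group)
simulate_symptoms <- function(truth, n_per_group, thresholds = c(0.5, 1, 1.5),
                              seed = 1) {
  stopifnot(inherits(truth, "symptom_truth"))
  groups <- truth$groups
  items <- truth$items
  p <- length(items)
  n_per_group <- rep_len(as.integer(n_per_group), length(groups))
  if (any(n_per_group < 1)) abort("every group needs n >= 1.")

  thr <- if (is.matrix(thresholds)) thresholds else
    matrix(thresholds, nrow = p, ncol = 3, byrow = TRUE)
  stopifnot(ncol(thr) == 3, nrow(thr) == p)
  if (any(apply(thr, 1, function(x) any(diff(x) <= 0)))) {
    abort("thresholds must be strictly increasing per item.")
  }

  # group-specific covariate marginals: mean age / % female / % site-A
  cov_par <- covariate_marginals(groups)

  set.seed(seed)
  out <- vector("list", length(groups))
  offset <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- n_per_group[gi]
    sigma <- pcor_to_sigma(truth$partial_corr[[g]])
    ch <- tryCatch(chol(sigma), error = function(e) {
      abort(paste0("implied covariance for group '", g,
                   "' is not positive definite."))
    })
    z <- matrix(rnorm(n * p), n, p) %*% ch
    scores <- matrix(0L, n, p, dimnames = list(NULL, items))
    for (j in seq_len(p)) {
      scores[, j] <- findInterval(z[, j], thr[j, ])
    }
    out[[gi]] <- tibble(
      participant_id = sprintf("P%05d", offset + seq_len(n)),
      group = g,
      age = round(pmax(6, rnorm(n, cov_par$age_mean[gi], cov_par$age_sd[gi])), 1),
      sex = as.integer(rbinom(n, 1, 1 - cov_par$p_female[gi])),
      site = as.integer(rbinom(n, 1, 1 - cov_par$p_site_a[gi]))
    )
    out[[gi]] <- dplyr::bind_cols(out[[gi]], as_tibble(scores))
    offset <- offset + n
  }
  res <- dplyr::bind_rows(out)
  res$group <- factor(res$group, levels = groups)
  attr(res, "items") <- items
  res
}

covariate_marginals <- function(groups) {
  k <- length(groups)
  list(
    age_mean = rep_len(c(16.9, 17.3, 16.4), k),
    age_sd = rep_len(c(3.9, 4.4, 3.4), k),
    p_female = rep_len(c(0.55, 0.49, 0.29), k),
    p_site_a = rep_len(c(0.61, 0.79, 0.41), k)
  )
}

#' Mask item scores completely at random
#'
#' Sets each item cell to `NA` independently with probability `rate`
#' (missing completely at random). The realized mask is recorded in the
#' `"miss_mask"` attribute of the result.
#'
#' @param data Symptom tibble as returned by [simulate_symptoms()].
#' @param rate Masking probability in `[0, 1)`.
#' @param seed Integer seed; the same seed reproduces the mask.
#' @param items Item column names; defaults to the dataset's recorded items.
#'
#' @return The tibble with masked cells set to `NA` and a logical mask
#'   matrix attached as attribute `miss_mask`.
#' @export
inject_missingness <- function(data, rate, seed = 1, items = item_cols(data)) {
  if (rate < 0 || rate >= 1) abort("`rate` must be in [0, 1).")
  m <- as.matrix(data[items])
  set.seed(seed)
  mask <- matrix(runif(length(m)) < rate, nrow(m), ncol(m),
                 dimnames = dimnames(m))
  m[mask] <- NA
  data[items] <- as_tibble(m)
  attr(data, "items") <- items
  attr(data, "miss_mask") <- mask
  data
}

# Item columns of a symptom tibble: the recorded attribute if present, else
# the intersection with the canonical CPRS codes.
item_cols <- function(data) {
  it <- attr(data, "items")
  if (!is.null(it)) return(it)
  it <- intersect(cprs_items(), names(data))
  if (!length(it)) abort("cannot identify item columns; pass `items`.")
  it
}

#' Simulate lifetime stimulant prescription histories
#'
#' Generates prescription records for one treatment-trajectory archetype.
#' `early_intense` participants start treatment at age 6-9 on 30-60 mg/day
#' (methylphenidate equivalents) for 4-8 years; `late_moderate` participants
#' start at age 12-16 on 10-25 mg/day for 1-4 years. Each history is split
#' into two consecutive prescription records with a dose adjustment at the
#' midpoint, emulating titration. About 20% of records are dexamphetamine,
#' written at half the methylphenidate-equivalent dose.
#'
#' @param archetype `"early_intense"` or `"late_moderate"`.
#' @param n Number of participants (>= 1).
#' @param seed Integer seed.
#' @param id_prefix Prefix for participant ids.
#' @param onset_range,dose_range,duration_range Optional length-2 numeric
#'   overrides of the archetype defaults (years, mg/day, years).
#'
#' @return A list with two tibbles: `persons` (`participant_id`,
#'   `birth_date`, `assessment_date`) and `records` (`participant_id`,
#'   `start_date`, `end_date`, `drug`, `dose_mg_per_day`).
#' @export
simulate_prescriptions <- function(archetype = c("early_intense", "late_moderate"),
                                   n, seed = 1, id_prefix = NULL,
                                   onset_range = NULL, dose_range = NULL,
                                   duration_range = NULL) {
  archetype <- match.arg(archetype)
  if (n < 1) abort("`n` must be >= 1.")
  defaults <- switch(archetype,
    early_intense = list(onset = c(6, 9), dose = c(30, 60), dur = c(4, 8)),
    late_moderate = list(onset = c(12, 16), dose = c(10, 25), dur = c(1, 4))
  )
  onset_range <- onset_range %||% defaults$onset
  dose_range <- dose_range %||% defaults$dose
  duration_range <- duration_range %||% defaults$dur
  id_prefix <- id_prefix %||% switch(archetype, early_intense = "EI",
                                     late_moderate = "LM")

  set.seed(seed)
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  birth <- as.Date("1994-03-15") + round(runif(n, -180, 180))
  assess_age <- runif(n, 20.5, 21.5)
  assessment <- birth + round(assess_age * 365.25)

  onset <- runif(n, onset_range[1], onset_range[2])
  dose <- runif(n, dose_range[1], dose_range[2])
  dur <- runif(n, duration_range[1], duration_range[2])
  adj <- runif(n, 0.9, 1.3)
  dex <- runif(n) < 0.2

  start1 <- birth + round(onset * 365.25)
  mid <- start1 + round(dur / 2 * 365.25)
  end2 <- pmin(start1 + round(dur * 365.25), assessment)
  mid <- pmin(mid, end2)

  rec <- function(id, s, e, d_eq, is_dex) {
    tibble(
      participant_id = id, start_date = s, end_date = e,
      drug = ifelse(is_dex, "dexamphetamine", "methylphenidate"),
      dose_mg_per_day = ifelse(is_dex, d_eq / 2, d_eq)
    )
  }
  records <- dplyr::bind_rows(
    rec(ids, start1, mid, dose, dex),
    rec(ids, mid + 1, end2, dose * adj, dex)
  )
  records <- records[records$start_date <= records$end_date, ]
  records <- dplyr::arrange(records, .data$participant_id, .data$start_date)

  list(
    persons = tibble(participant_id = ids, birth_date = birth,
                     assessment_date = assessment),
    records = records
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write symptom tables as CSV
#'
#' One row per participant; columns `participant_id`, `group`, `age`,
#' `sex`, `site`, then the item columns. Missing item scores are written as
#' empty cells.
#'
#' @param data Symptom tibble.
#' @param path File path.
#' @param groups Ordered group labels used to re-level the `group` column on
#'   read.
#' @return `write_symptom_csv()` returns `path` invisibly;
#'   `read_symptom_csv()` returns the symptom tibble.
#' @export
write_symptom_csv <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' @rdname write_symptom_csv
#' @export
read_symptom_csv <- function(path, groups = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE, na = "")
  if (!is.null(groups)) d$group <- factor(d$group, levels = groups)
  else d$group <- factor(d$group, levels = unique(d$group))
  items <- intersect(cprs_items(), names(d))
  if (!length(items)) {
    items <- setdiff(names(d), c("participant_id", "group", "age", "sex", "site"))
  }
  d[items] <- lapply(d[items], as.integer)
  attr(d, "items") <- items
  d
}
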