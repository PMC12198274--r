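#' Monthly stimulant-dose trajectory for one participant
#'
#' Builds the lifetime trajectory of mean daily stimulant dose, one value
#' per calendar month from the month of birth to the month of assessment.
#' Each month's value is the sum over prescription records of
#' `dose * days covered in that month / days in month`; overlapping records
#' add. Dexamphetamine doses are converted to methylphenidate equivalents by
#' `meq_factor` (default 2).
#'
#' @param records Tibble of prescription records for one participant:
#'   `start_date`, `end_date`, `drug`, `dose_mg_per_day`.
#' @param birth_date,assessment_date Dates bounding the trajectory.
#' @param meq_factor Dexamphetamine-to-methylphenidate dose equivalence.
#' @return Tibble with `month` (first day of month), `age` (years since
#'   birth at the month start, floored at 0), `days_in_month`, `dose`
#'   (mg/day, methylphenidate equivalents), and attribute `birth_date`.
#' @export
monthly_trajectory <- function(records, birth_date, assessment_date,
                               meq_factor = 2) {
  birth_date <- as.Date(birth_date)
  assessment_date <- as.Date(assessment_date)
  stopifnot(birth_date <= assessment_date)
  month_start <- function(d) as.Date(format(d, "%Y-%m-01"))
  months <- seq(month_start(birth_date), month_start(assessment_date),
                by = "month")
  next_month <- seq(months[length(months)], by = "month", length.out = 2)[2]
  bounds <- c(months, next_month)
  days_in_month <- as.integer(diff(bounds))
  dose <- numeric(length(months))

  if (!is.null(records) && nrow(records)) {
    s <- as.Date(records$start_date)
    e <- as.Date(records$end_date)
    if (any(e < s)) abort("prescription record ends before it starts.")
    if (any(records$dose_mg_per_day < 0)) abort("negative dose.")
    eq <- records$dose_mg_per_day *
      ifelse(records$drug == "dexamphetamine", meq_factor, 1)
    for (r in seq_along(s)) {
      lo <- pmax(s[r], months)
      hi <- pmin(e[r], bounds[-1] - 1)
      overlap <- pmax(0, as.integer(hi - lo) + 1L)
      dose <- dose + eq[r] * overlap / days_in_month
    }
  }
  out <- tibble(
    month = months,
    age = pmax(0, as.numeric(months - birth_date) / 365.25),
    days_in_month = days_in_month,
    dose = dose
  )
  attr(out, "birth_date") <- birth_date
  out
}

#' Raw trajectory features
#'
#' Onset age (age at the first month with any dose), stop age (age at the
#' last such month), and total lifetime dose (sum of monthly mean dose times
#' days in month, in mg) from the unsmoothed trajectory. An all-zero
#' trajectory is flagged `never_treated` with undefined onset/stop.
#'
#' @param traj A [monthly_trajectory()] tibble (or any tibble with `age`,
#'   `days_in_month`, `dose` columns).
#' @return One-row tibble: `onset_age`, `stop_age`, `total_dose`,
#'   `never_treated`.
#' @export
extract_raw_features <- function(traj) {
  stopifnot(nrow(traj) > 0)
  treated <- which(traj$dose > 0)
  if (!length(treated)) {
    return(tibble(onset_age = NA_real_, stop_age = NA_real_,
                  total_dose = 0, never_treated = TRUE))
  }
  tibble(
    onset_age = traj$age[treated[1]],
    stop_age = traj$age[treated[length(treated)]],
    total_dose = sum(traj$dose * traj$days_in_month),
    never_treated = FALSE
  )
}

#' GAM-smoothed trajectory features
#'
#' Fits a penalized cubic regression spline of dose on age (generalized
#' additive model, smoothing parameter by generalized cross-validation) and
#' extracts: treatment duration (total time the smoothed curve exceeds
#' `threshold`, default 1 mg/day — a smoothed spline never returns exactly
#' to zero), maximum daily dose (curve maximum, floored at 0), and dose
#' variability (SD of the smoothed curve over the treated span).
#'
#' @param traj A [monthly_trajectory()] tibble with at least 8 months.
#' @param basis_size Maximum spline basis dimension.
#' @param threshold Near-zero dose threshold (mg/day) defining the treated
#'   span on the smoothed curve.
#' @return List with `smoothed` (tibble `age`, `fitted`), `duration`
#'   (years), `max_daily_dose` (mg/day), `dose_sd` (mg/day).
#' @export
fit_smoothed_trajectory <- function(traj, basis_size = 10, threshold = 1) {
  if (nrow(traj) < 8) abort("need at least 8 months of trajectory data.")
  k <- max(3, min(basis_size, length(unique(traj$age)) - 1))
  fit <- mgcv::gam(dose ~ s(age, k = k, bs = "cr"), data = traj,
                   method = "GCV.Cp")
  fitted <- as.numeric(predict(fit, newdata = traj["age"]))
  treated <- fitted > threshold
  duration <- sum(traj$days_in_month[treated]) / 365.25
  dose_sd <- if (sum(treated) >= 2) sd(fitted[treated]) else 0
  list(
    smoothed = tibble(age = traj$age, fitted = fitted),
    duration = duration,
    max_daily_dose = max(c(fitted, 0)),
    dose_sd = dose_sd
  )
}

#' Six trajectory features per participant
#'
#' Builds each participant's monthly trajectory and extracts the six
#' clustering features: onset age, stop age and total dose from the raw
#' trajectory; duration, maximum daily dose and dose SD from the
#' GAM-smoothed trajectory. Participants without any prescription are
#' flagged `never_treated` (their smoothed features are 0).
#'
#' @param persons Tibble with `participant_id`, `birth_date`,
#'   `assessment_date`.
#' @param records Prescription records tibble (all participants).
#' @param meq_factor,basis_size,threshold See [monthly_trajectory()] and
#'   [fit_smoothed_trajectory()].
#' @return Tibble with one row per participant and columns `participant_id`,
#'   `onset_age`, `stop_age`, `total_dose`, `duration`, `max_daily_dose`,
#'   `dose_sd`, `never_treated`.
#' @export
trajectory_features <- function(persons, records, meq_factor = 2,
                                basis_size = 10, threshold = 1) {
  purrr::pmap_dfr(persons, function(participant_id, birth_date,
                                    assessment_date, ...) {
    rec <- records[records$participant_id == participant_id, , drop = FALSE]
    traj <- monthly_trajectory(rec, birth_date, assessment_date, meq_factor)
    raw <- extract_raw_features(traj)
    if (raw$never_treated) {
      sm <- list(duration = 0, max_daily_dose = 0, dose_sd = 0)
    } else {
      sm <- fit_smoothed_trajectory(traj, basis_size, threshold)
    }
    tibble(participant_id = participant_id,
           onset_age = raw$onset_age, stop_age = raw$stop_age,
           total_dose = raw$total_dose, duration = sm$duration,
           max_daily_dose = sm$max_daily_dose, dose_sd = sm$dose_sd,
           never_treated = raw$never_treated)
  })
}

#' Louvain treatment-trajectory subgroups
#'
#' Partitions participants into treatment-trajectory communities. The six
#' features are z-scored column-wise; participant similarity is the Pearson
#' correlation between feature vectors, with negative similarities set to 0;
#' Louvain community detection (resolution 1) maximizes weighted modularity
#' on this similarity graph. Communities smaller than `min_community_size`
#' are flagged excluded, mirroring the exclusion of groups too small for
#' network comparison.
#'
#' @param features A [trajectory_features()] tibble (never-treated rows and
#'   rows with incomplete features are dropped before clustering).
#' @param min_community_size Minimum retained community size.
#' @param seed Integer seed (Louvain tie-breaking).
#' @return Object of class `community_partition`: tibble `participant_id`,
#'   `community`, `community_size`, `excluded`; attributes `modularity`
#'   (Q of the returned partition on the similarity graph) and `seed`.
#' @export
louvain_subgroups <- function(features, min_community_size = 10, seed = 1) {
  fcols <- c("onset_age", "stop_age", "total_dose", "duration",
             "max_daily_dose", "dose_sd")
  keep <- stats::complete.cases(features[fcols])
  if ("never_treated" %in% names(features)) keep <- keep & !features$never_treated
  f <- features[keep, , drop = FALSE]
  if (nrow(f) < 2) abort("need at least 2 participants with complete features.")
  z <- scale(as.matrix(f[fcols]))
  z[is.nan(z)] <- 0
  S <- cor(t(z))
  S[S < 0] <- 0
  diag(S) <- 0
  if (all(S == 0)) abort("all pairwise similarities are zero; no structure to cluster.")

  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = 1)
  membership <- igraph::membership(cl)
  Q <- igraph::modularity(g, membership,
                          weights = igraph::E(g)$weight)
  sizes <- table(membership)
  out <- tibble(
    participant_id = f$participant_id,
    community = as.integer(membership),
    community_size = as.integer(sizes[as.character(membership)]),
    excluded = as.integer(sizes[as.character(membership)]) < min_community_size
  )
  attr(out, "modularity") <- Q
  attr(out, "seed") <- seed
  attr(out, "min_community_size") <- min_community_size
  class(out) <- c("community_partition", class(out))
  out
}

#' Weighted modularity of a given partition
#'
#' Newman's weighted modularity
#' `Q = (1 / 2W) * sum_ij (w_ij - s_i s_j / 2W) * 1[c_i = c_j]` with
#' `W` the total edge weight and `s_i` the node strengths.
#'
#' @param W Symmetric nonnegative weight matrix with zero diagonal.
#' @param membership Integer community labels, one per node.
#' @return The modularity Q.
#' @export
partition_modularity <- function(W, membership) {
  check_weight_matrix(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  igraph::modularity(g, membership, weights = igraph::E(g)$weight)
}
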