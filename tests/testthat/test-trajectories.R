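one_record <- function(start, end, dose, drug = "methylphenidate",
                       id = "P1") {
  tibble::tibble(participant_id = id, start_date = as.Date(start),
                 end_date = as.Date(end), drug = drug,
                 dose_mg_per_day = dose)
}

test_that("monthly averaging is day-weighted and handles empty histories", {
  birth <- as.Date("2000-01-01")
  assess <- as.Date("2010-12-31")
  # full 30-day month (June 2005) at 10 mg/day
  traj <- monthly_trajectory(one_record("2005-06-01", "2005-06-30", 10),
                             birth, assess)
  expect_equal(traj$dose[traj$month == as.Date("2005-06-01")], 10)
  # 15 of 30 days -> 5 mg/day
  traj2 <- monthly_trajectory(one_record("2005-06-01", "2005-06-15", 10),
                              birth, assess)
  expect_equal(traj2$dose[traj2$month == as.Date("2005-06-01")], 5)
  # no records -> all zero, correct length
  traj3 <- monthly_trajectory(NULL, birth, assess)
  expect_true(all(traj3$dose == 0))
  expect_equal(nrow(traj3), 132)
  # dexamphetamine doubled into methylphenidate equivalents
  traj4 <- monthly_trajectory(one_record("2005-06-01", "2005-06-30", 10,
                                         drug = "dexamphetamine"),
                              birth, assess)
  expect_equal(traj4$dose[traj4$month == as.Date("2005-06-01")], 20)
  # overlapping records add
  rec <- rbind(one_record("2005-06-01", "2005-06-30", 10),
               one_record("2005-06-01", "2005-06-30", 5))
  traj5 <- monthly_trajectory(rec, birth, assess)
  expect_equal(traj5$dose[traj5$month == as.Date("2005-06-01")], 15)
  expect_error(monthly_trajectory(one_record("2005-06-30", "2005-06-01", 10),
                                  birth, assess), "ends before")
  expect_error(monthly_trajectory(one_record("2005-06-01", "2005-06-30", -1),
                                  birth, assess), "negative dose")
})

test_that("raw features match hand-computed oracles", {
  # idealized 12 x 30-day months at 10 mg/day
  traj <- tibble::tibble(age = 8 + (0:11) / 12, days_in_month = 30,
                         dose = 10)
  f <- extract_raw_features(traj)
  expect_equal(f$total_dose, 3600)
  expect_equal(f$onset_age, 8)
  expect_equal(f$stop_age, 8 + 11 / 12)
  expect_false(f$never_treated)
  # single treated month
  traj1 <- tibble::tibble(age = c(7.9, 8, 8.1), days_in_month = 30,
                          dose = c(0, 12, 0))
  f1 <- extract_raw_features(traj1)
  expect_equal(f1$onset_age, 8)
  expect_equal(f1$stop_age, 8)
  # never treated
  f0 <- extract_raw_features(tibble::tibble(age = 1:20 / 2,
                                            days_in_month = 30, dose = 0))
  expect_true(f0$never_treated)
  expect_equal(f0$total_dose, 0)
})

test_that("total dose is additive over non-overlapping records", {
  birth <- as.Date("2000-01-01")
  assess <- as.Date("2012-01-01")
  r1 <- one_record("2006-02-01", "2007-01-31", 20)
  r2 <- one_record("2008-02-01", "2009-01-31", 30)
  tot <- function(rec) {
    extract_raw_features(monthly_trajectory(rec, birth, assess))$total_dose
  }
  expect_equal(tot(rbind(r1, r2)), tot(r1) + tot(r2))
})

test_that("the GAM smoother recovers constants, bounded peaks and empty spans", {
  birth <- as.Date("2000-01-01")
  assess <- as.Date("2011-12-31")
  traj <- monthly_trajectory(one_record("2000-01-01", "2011-12-31", 20),
                             birth, assess)
  sm <- fit_smoothed_trajectory(traj)
  expect_lt(abs(sm$max_daily_dose - 20), 0.5)
  expect_lte(sm$dose_sd, 0.5)
  expect_lt(abs(sm$duration - 12), 0.25)

  # noiseless half-sine bump peaking at 40 mg/day over 5 years
  bump <- tibble::tibble(
    age = seq(0, 20, by = 1 / 12),
    days_in_month = 30,
    dose = ifelse(age >= 8 & age <= 13, 40 * sin(pi * (age - 8) / 5), 0)
  )
  smb <- fit_smoothed_trajectory(bump, basis_size = 20)
  expect_lt(abs(smb$max_daily_dose - 40) / 40, 0.1)
  expect_gt(smb$dose_sd, 0)
  expect_gt(smb$duration, 4)
  expect_lt(smb$duration, 7)

  zero <- tibble::tibble(age = 1:24 / 2, days_in_month = 30, dose = 0)
  smz <- fit_smoothed_trajectory(zero)
  expect_equal(smz$duration, 0)
  expect_error(fit_smoothed_trajectory(zero[1:5, ]), "8 months")
})

test_that("Louvain modularity matches the brute-force oracle on small graphs", {
  set.seed(11)
  for (rep in 1:5) {
    W <- random_binary_graph(12, 0.35) * matrix(runif(144, 0.5, 1), 12)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    if (sum(W) == 0) next
    membership <- sample(1:3, 12, replace = TRUE)
    expect_equal(partition_modularity(W, membership),
                 brute_modularity(W, membership), tolerance = 1e-10)
  }
})

test_that("planted feature blobs are recovered as pure communities with small ones excluded", {
  set.seed(12)
  blob <- function(center, n, id_prefix) {
    f <- matrix(rep(center, each = n), n) + rnorm(n * 6, sd = 0.15)
    colnames(f) <- c("onset_age", "stop_age", "total_dose", "duration",
                     "max_daily_dose", "dose_sd")
    out <- tibble::as_tibble(f)
    out$participant_id <- sprintf("%s%03d", id_prefix, seq_len(n))
    out
  }
  feats <- dplyr::bind_rows(
    blob(c(7, 14, 9000, 6, 45, 8), 40, "EI"),
    blob(c(14, 16, 1500, 2, 15, 3), 40, "LM"),
    # a third, atypical trajectory profile too rare to retain
    blob(c(7, 16, 9000, 2, 15, 8), 4, "EM")
  )
  part <- louvain_subgroups(feats, min_community_size = 10, seed = 3)
  expect_s3_class(part, "community_partition")
  # blob purity among retained communities
  arch <- substr(part$participant_id, 1, 2)
  big <- part[!part$excluded, ]
  purity <- mean(vapply(split(substr(big$participant_id, 1, 2), big$community),
                        function(a) max(table(a)) / length(a), numeric(1)))
  expect_gte(purity, 0.95)
  em <- part[arch == "EM", ]
  expect_true(all(em$excluded))
  expect_equal(unique(em$community_size), 4L)
  expect_gt(attr(part, "modularity"), 0)
})

test_that("end-to-end archetype recovery separates early-intense from late-moderate use", {
  ei <- simulate_prescriptions("early_intense", n = 60, seed = 21)
  lm_ <- simulate_prescriptions("late_moderate", n = 60, seed = 22)
  persons <- rbind(ei$persons, lm_$persons)
  records <- rbind(ei$records, lm_$records)
  feats <- trajectory_features(persons, records)
  part <- louvain_subgroups(feats, seed = 4)
  arch <- substr(part$participant_id, 1, 2)
  tab <- table(arch, part$community)
  purity <- sum(apply(tab, 2, max)) / sum(tab)
  expect_gte(purity, 0.95)
  # direction: early-intense community has earlier onset and higher max dose
  joined <- dplyr::left_join(part, feats, by = "participant_id")
  means <- dplyr::summarise(dplyr::group_by(joined, .data$community),
                            onset = mean(onset_age),
                            maxd = mean(max_daily_dose), .groups = "drop")
  ei_comm <- names(which.max(table(part$community[arch == "EI"])))
  other <- means[means$community != as.integer(ei_comm), ]
  ei_row <- means[means$community == as.integer(ei_comm), ]
  expect_true(all(ei_row$onset < other$onset))
  expect_true(all(ei_row$maxd > other$maxd))
})
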