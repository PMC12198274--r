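test_that("simulated scores are ordinal 0-3 and deterministic under a seed", {
  truth <- small_truth()
  d1 <- simulate_symptoms(truth, n_per_group = 40, seed = 11)
  d2 <- simulate_symptoms(truth, n_per_group = 40, seed = 11)
  expect_identical(d1, d2)
  items <- attr(d1, "items")
  expect_true(all(as.matrix(d1[items]) %in% 0:3))
  d3 <- simulate_symptoms(truth, n_per_group = 40, seed = 12)
  expect_false(identical(d1, d3))
})

test_that("independent items stay uncorrelated at large n", {
  items <- cprs_items()
  m <- matrix(0, 18, 18, dimnames = list(items, items))
  truth <- symptom_truth(base_pcor = m, groups = "G")
  d <- simulate_symptoms(truth, n_per_group = 5000, seed = 2)
  cm <- cor(as.matrix(d[items]))
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.05)
})

test_that("a group-specific partial correlation raises that group's observed correlation", {
  truth <- symptom_truth(
    base_pcor = matrix(0, 18, 18, dimnames = list(cprs_items(), cprs_items())),
    moderated_edges = data.frame(item_i = "fidget", item_j = "run",
                                 group = "ADHD-stim", delta = 0.4)
  )
  d <- simulate_symptoms(truth, n_per_group = 5000, seed = 5)
  r <- vapply(default_groups(), function(g) {
    sub <- d[d$group == g, ]
    cor(sub$fidget, sub$run)
  }, numeric(1))
  expect_gte(r["ADHD-stim"] - max(r[c("NAC", "ADHD-nostim")]), 0.1)
})

test_that("category frequencies match the latent normal mass between cutpoints", {
  truth <- small_truth(p = 4, edges = list())
  thr <- c(0.5, 1, 1.5)
  n <- 20000
  d <- simulate_symptoms(truth, n_per_group = c(n, 1), seed = 9,
                         thresholds = thr)
  x <- d$closeatt[d$group == "A"]
  expected <- diff(pnorm(c(-Inf, thr, Inf)))
  for (k in 0:3) {
    p_hat <- mean(x == k)
    se <- sqrt(expected[k + 1] * (1 - expected[k + 1]) / n)
    expect_lt(abs(p_hat - expected[k + 1]), 3 * se)
  }
})

test_that("groups sharing a matrix are exchangeable and non-moderated groups share the truth", {
  truth <- symptom_truth(moderated_edges = data.frame(
    item_i = "fidget", item_j = "run", group = "ADHD-stim", delta = 0.2
  ))
  expect_identical(truth$partial_corr[["NAC"]],
                   truth$partial_corr[["ADHD-nostim"]])
  expect_false(identical(truth$partial_corr[["NAC"]],
                         truth$partial_corr[["ADHD-stim"]]))
  # exchangeability of generated scores across two same-matrix groups
  d <- simulate_symptoms(truth, n_per_group = 4000, seed = 21)
  for (it in c("fidget", "run", "closeatt")) {
    p1 <- prop.table(table(factor(d[[it]][d$group == "NAC"], levels = 0:3)))
    p2 <- prop.table(table(factor(d[[it]][d$group == "ADHD-nostim"],
                                  levels = 0:3)))
    expect_lt(max(abs(p1 - p2)), 0.04)
  }
})

test_that("non-positive-definite implied precision is rejected naming the group", {
  items <- cprs_items()[1:3]
  m <- matrix(0.6, 3, 3, dimnames = list(items, items))
  diag(m) <- 0
  expect_error(symptom_truth(base_pcor = m, groups = c("A", "B")), "group 'A'")
  # PD base but a delta pushing one group over the edge
  expect_error(
    small_truth(p = 3, edges = list(c(1, 2, 0.6), c(2, 3, 0.6)),
                moderated_edges = data.frame(item_i = "closeatt",
                                             item_j = "listen",
                                             group = "B", delta = 0.6)),
    "group 'B'"
  )
})

test_that("missingness injection is MCAR at the requested rate and seeded", {
  truth <- small_truth()
  d <- simulate_symptoms(truth, n_per_group = 500, seed = 3)
  expect_equal(as.matrix(inject_missingness(d, 0, seed = 1)[attr(d, "items")]),
               as.matrix(d[attr(d, "items")]))
  items <- cprs_items()
  truth18 <- symptom_truth(base_pcor = matrix(0, 18, 18,
                                              dimnames = list(items, items)),
                           groups = "G")
  d18 <- simulate_symptoms(truth18, n_per_group = 1000, seed = 3)
  dm <- inject_missingness(d18, 0.1, seed = 7)
  frac <- mean(is.na(as.matrix(dm[items])))
  expect_lt(abs(frac - 0.1), 0.01)
  dm2 <- inject_missingness(d18, 0.1, seed = 7)
  expect_identical(attr(dm, "miss_mask"), attr(dm2, "miss_mask"))
  expect_error(inject_missingness(d, 1), "rate")
})

test_that("prescription archetypes have disjoint onset supports and valid records", {
  ei <- simulate_prescriptions("early_intense", n = 100, seed = 4)
  lm_ <- simulate_prescriptions("late_moderate", n = 100, seed = 5)
  onset_age <- function(sim) {
    first <- dplyr::summarise(dplyr::group_by(sim$records, participant_id),
                              s = min(start_date), .groups = "drop")
    m <- dplyr::left_join(first, sim$persons, by = "participant_id")
    as.numeric(m$s - m$birth_date) / 365.25
  }
  expect_lt(max(onset_age(ei)), min(onset_age(lm_)))
  expect_true(all(ei$records$start_date <= ei$records$end_date))
  expect_true(all(ei$records$dose_mg_per_day >= 0))
  expect_error(simulate_prescriptions("early_intense", n = 0), "n")
})
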