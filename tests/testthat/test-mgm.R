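test_that("the moderated design has the documented predictor count and map", {
  truth <- symptom_truth()
  d <- simulate_symptoms(truth, n_per_group = 40, seed = 41)
  des <- build_moderated_design(d, "fidget")
  # 17 items + 2 dummies + 34 interactions
  expect_equal(ncol(des$X), 53)
  expect_equal(sum(des$map$kind == "item"), 17)
  expect_equal(sum(des$map$kind == "group"), 2)
  expect_equal(sum(des$map$kind == "interaction"), 34)
  expect_false("fidget" %in% des$map$item)
  expect_equal(des$reference, "NAC")

  # covariates enter as 3 extra main effects
  des_cov <- build_moderated_design(
    d, "fidget", estimator_config(covariates = c("age", "sex", "site"))
  )
  expect_equal(ncol(des_cov$X), 56)

  # two groups: 17 + 1 + 17
  truth2 <- small_truth(p = 18, edges = list(), groups = c("A", "B"))
  d2 <- simulate_symptoms(truth2, n_per_group = 40, seed = 42)
  expect_equal(ncol(build_moderated_design(d2, "run")$X), 35)
})

test_that("degenerate inputs are rejected with informative errors", {
  truth <- small_truth()
  d <- simulate_symptoms(truth, n_per_group = c(30, 1), seed = 43)
  expect_error(build_moderated_design(d, "closeatt"), "< 2 participants")

  d2 <- simulate_symptoms(truth, n_per_group = 30, seed = 44)
  d2$closeatt <- 2L
  expect_error(build_moderated_design(d2, "susatt"), "constant item")
  expect_error(fit_mgm(d2), "constant item|min_group_n")

  d3 <- simulate_symptoms(truth, n_per_group = c(30, 5), seed = 45)
  expect_error(fit_mgm(d3), "min_group_n")
})

test_that("conditioning is additive and the reference returns the base weights", {
  truth <- small_truth(
    p = 8, edges = list(c(1, 2, 0.3), c(3, 4, 0.3), c(5, 6, 0.3)),
    moderated_edges = data.frame(item_i = "closeatt", item_j = "susatt",
                                 group = "B", delta = 0.3)
  )
  d <- simulate_symptoms(truth, n_per_group = 600, seed = 46)
  fit <- fit_mgm(d)
  expect_identical(condition_on_group(fit, "A"), fit$base_weights)
  expect_error(condition_on_group(fit, "nope"), "unknown group")
  for (g in fit$groups) {
    W <- condition_on_group(fit, g)
    expect_equal(W, t(W))
    expect_true(all(diag(W) == 0))
  }
  # conditioned = base + stored increments, and only there
  WB <- condition_on_group(fit, "B")
  diff <- WB - fit$base_weights
  mod <- fit$moderation
  expect_gt(nrow(mod), 0)
  for (r in seq_len(nrow(mod))) {
    expect_equal(diff[mod$item_i[r], mod$item_j[r]], mod$increment[r])
    diff[mod$item_i[r], mod$item_j[r]] <- 0
    diff[mod$item_j[r], mod$item_i[r]] <- 0
  }
  expect_true(all(diff == 0))
})

test_that("a model without moderation terms conditions identically for all groups", {
  truth <- small_truth(p = 6, edges = list(c(1, 2, 0.35)))
  d <- simulate_symptoms(truth, n_per_group = 400, seed = 47)
  fit <- fit_mgm(d)
  if (nrow(fit$moderation) == 0) {
    expect_identical(condition_on_group(fit, "A"), condition_on_group(fit, "B"))
  }
  # the planted strong edge is recovered
  expect_true(fit$base_weights["closeatt", "susatt"] != 0)
})

test_that("EBIC selection is invariant to participant order and respects n", {
  truth <- small_truth(p = 6)
  d <- simulate_symptoms(truth, n_per_group = 150, seed = 48)
  fit1 <- fit_mgm(d)
  set.seed(99)
  dp <- d[sample(nrow(d)), ]
  attr(dp, "items") <- attr(d, "items")
  fit2 <- fit_mgm(dp)
  expect_equal(fit1$node_fits$lambda, fit2$node_fits$lambda)
  expect_equal(fit1$base_weights, fit2$base_weights)
  expect_true(all(fit1$node_fits$k <= nrow(d)))
})

test_that("averaging across imputations keeps structure and tidy/glance are consistent", {
  truth <- small_truth(p = 6, edges = list(c(1, 2, 0.35), c(3, 4, 0.3)))
  d <- simulate_symptoms(truth, n_per_group = 250, seed = 49)
  dm <- inject_missingness(d, 0.03, seed = 1)
  imp <- impute_items(filter_missingness(dm)$data, m = 3, iterations = 3,
                      seed = 2)
  fit <- fit_mgm(imp)
  expect_equal(fit$m, 3)
  expect_equal(fit$base_weights, t(fit$base_weights))

  td <- tidy(fit)
  expect_true(all(c("item_i", "item_j", "group", "weight", "moderated",
                    "increment") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_edges,
               sum(fit$base_weights[upper.tri(fit$base_weights)] != 0))
  expect_equal(gl$n_moderation, nrow(fit$moderation))

  fit_first <- fit_mgm(imp, use_first_only = TRUE)
  expect_equal(fit_first$m, 1)
})

test_that("serialization writes JSON and per-group edge lists", {
  truth <- small_truth(p = 6, edges = list(c(1, 2, 0.35)))
  d <- simulate_symptoms(truth, n_per_group = 200, seed = 50)
  fit <- fit_mgm(d)
  tmp <- withr::local_tempdir()
  jp <- file.path(tmp, "model.json")
  mgm_to_json(fit, jp)
  obj <- jsonlite::read_json(jp)
  expect_equal(unlist(obj$items), fit$items)
  write_edge_lists(fit, tmp)
  for (g in fit$groups) {
    el <- readr::read_csv(file.path(tmp, paste0("network_", g, ".csv")),
                          show_col_types = FALSE)
    W <- condition_on_group(fit, g)
    expect_equal(nrow(el), sum(W[upper.tri(W)] != 0))
  }
})
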