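# Random-forest activity models, RFE, feature correlation.

ml_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- simulate_locus(n_v = 60, seed = 3)
      cfg <- sim_config(n_molecules = 1000, seed = 3)
      truth <- simulate_repertoire(ref, cfg, planted_effect = 1)
      sig <- simulate_signal_tracks(ref, truth, cfg, n_tracks = 12,
                                    noise_sd = 0.1)
      fm <- assemble_feature_matrix(ref, sig$tracks, sig$manifest, "preB")
      resp <- tibble::tibble(v_gene = rownames(truth$freq),
                             value = log(rowSums(truth$freq)))
      cache <<- list(ref = ref, truth = truth, sig = sig, fm = fm,
                     resp = resp)
    }
    cache
  }
})

test_that("cross-validation folds partition the genes", {
  fx <- ml_fixture()
  fit <- rf_regress(fx$fm, fx$resp, n_trees = 200, seed = 5)
  expect_setequal(fit$cv$v_gene, fx$fm$v_gene)
  expect_equal(anyDuplicated(fit$cv$v_gene), 0L)
  sizes <- table(fit$cv$fold)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), nrow(fx$fm))
})

test_that("a planted regression effect tops the importance ranking", {
  fx <- ml_fixture()
  fit <- rf_regress(fx$fm, fx$resp, n_trees = 500, seed = 7)
  expect_equal(tidy(fit)$feature[1], fx$sig$planted_feature)
  expect_equal(fit$importance$metric[1], "mean_decrease_node_purity")
  # shuffling the response destroys the planted feature's top rank
  drops <- vapply(1:10, function(s) {
    set.seed(100 + s)
    perm <- fx$resp
    perm$value <- sample(perm$value)
    pfit <- rf_regress(fx$fm, perm, n_trees = 150, seed = s)
    rank <- match(fx$sig$planted_feature, tidy(pfit)$feature)
    rank > 5
  }, logical(1))
  expect_gte(mean(drops), 0.9)
})

test_that("labels determined by a planted feature are classified accurately", {
  fx <- ml_fixture()
  labels <- tibble::tibble(
    v_gene = fx$fm$v_gene,
    active = fx$fm[[fx$sig$planted_feature]] >
      stats::median(fx$fm[[fx$sig$planted_feature]])
  )
  fit <- rf_classify(fx$fm, labels, n_trees = 500, seed = 9)
  expect_gte(glance(fit)$performance, 0.85)
  expect_equal(tidy(fit)$feature[1], fx$sig$planted_feature)
  expect_equal(fit$importance$metric[1], "mean_decrease_gini")

  # random labels: accuracy near the majority-class rate
  set.seed(42)
  null_labels <- dplyr::mutate(labels, active = sample(active))
  null_fit <- rf_classify(fx$fm, null_labels, n_trees = 300, seed = 10)
  expect_lt(glance(null_fit)$performance, 0.75)

  # single-class labels are refused
  expect_error(rf_classify(fx$fm, dplyr::mutate(labels, active = TRUE),
                           n_trees = 50), "single-class")
})

test_that("degenerate regressions behave predictably", {
  fx <- ml_fixture()
  # constant response: RMSE 0
  const <- dplyr::mutate(fx$resp, value = 1)
  fit <- suppressWarnings(rf_regress(fx$fm, const, n_trees = 100, seed = 4))
  expect_equal(glance(fit)$performance, 0)
  # response independent of features: CV RMSE near the response SD
  set.seed(8)
  indep <- dplyr::mutate(fx$resp, value = stats::rnorm(dplyr::n()))
  fit2 <- rf_regress(fx$fm, indep, n_trees = 300, seed = 4)
  expect_lt(abs(glance(fit2)$performance - stats::sd(indep$value)), 0.4)
  # too few observations are refused
  expect_error(rf_regress(fx$fm[1:10, ], fx$resp[1:10, ], n_trees = 50),
               "refusing")
})

test_that("RFE keeps the planted feature and plateaus early", {
  fx <- ml_fixture()
  fit <- rf_regress(fx$fm, fx$resp, n_trees = 500, seed = 7)
  rfe <- rfe_select(fx$fm, fx$resp, fit, top_k = 20, n_trees = 200, seed = 7)
  expect_equal(nrow(rfe$curve), 20L)
  expect_true(fx$sig$planted_feature %in% rfe$selected)
  expect_lte(rfe$best_size, 3L)
  # the single-feature model performs within noise of the full model
  r1 <- rfe$curve$performance[rfe$curve$size == 1]
  rbest <- min(rfe$curve$performance)
  expect_lt(r1, rbest + 3 * max(rfe$curve$se))
  # top_k beyond the feature count clamps with a warning
  expect_warning(
    small <- rfe_select(fx$fm[, 1:4], fx$resp, local({
      f <- fit
      f$importance <- f$importance[f$importance$feature %in%
                                     names(fx$fm)[2:4], ]
      f
    }), top_k = 20, n_trees = 50, seed = 7),
    "clamp"
  )
  expect_equal(nrow(small$curve), 3L)
})

test_that("feature-response correlation matches closed forms", {
  fx <- ml_fixture()
  # response = 2 * feature: r = 1
  lin <- tibble::tibble(v_gene = fx$fm$v_gene,
                        value = 2 * fx$fm$ric_score)
  out <- correlate_feature(fx$fm, lin, "ric_score")
  expect_equal(out$estimate, 1)
  expect_lt(out$p.value, 1e-10)
  # planted log-linear effect at low noise: r -> 1 on the log scale
  out2 <- correlate_feature(fx$fm, fx$resp, fx$sig$planted_feature)
  expect_gt(out2$estimate, 0.9)
  # zero variance flagged undefined
  fm0 <- dplyr::mutate(fx$fm, flat = 1)
  expect_warning(out0 <- correlate_feature(fm0, lin, "flat"), "variance")
  expect_true(is.na(out0$estimate))
  # null: p-values roughly uniform over repeats
  set.seed(3)
  ps <- vapply(1:40, function(i) {
    rnd <- tibble::tibble(v_gene = fx$fm$v_gene,
                          value = stats::rnorm(nrow(fx$fm)))
    correlate_feature(fx$fm, rnd, "ric_score")$p.value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.75)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("model objects print, tidy and plot", {
  fx <- ml_fixture()
  fit <- rf_regress(fx$fm, fx$resp, n_trees = 100, seed = 2)
  expect_output(print(fit), "kappa_rf")
  expect_s3_class(glance(fit), "tbl_df")
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  rfe <- rfe_select(fx$fm, fx$resp, fit, top_k = 5, n_trees = 50, seed = 2)
  expect_s3_class(autoplot(rfe), "ggplot")
  expect_output(print(rfe), "selected")
  freq <- repertoire_frequencies(tibble::tibble(
    sample_id = "s", v_gene = fx$fm$v_gene[1:5], jk = "Jk1", n = 1:5
  ))
  expect_s3_class(plot_repertoire(freq, fx$ref), "ggplot")
})
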