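test_that("stratified rotation folds balance classes across groups", {
  labels <- rep(1:6, each = 20)
  plan <- make_rotation_folds(labels, G = 4, stratified = TRUE, seed = 7)
  expect_equal(as.numeric(table(plan$groups)), rep(30, 4))
  per_class <- table(labels, plan$groups)
  expect_true(all(per_class == 5))
  # partition property: every sample in exactly one group
  expect_length(plan$groups, 120)
  expect_true(all(plan$groups %in% 1:4))

  # uneven classes: per-class counts across groups differ by at most 1
  lab2 <- rep(1:3, times = c(7, 9, 11))
  plan2 <- make_rotation_folds(lab2, G = 4, stratified = TRUE, seed = 1)
  rng <- apply(table(lab2, plan2$groups), 1, function(r) max(r) - min(r))
  expect_true(all(rng <= 1))

  # determinism, leave-one-out degeneracy, and G validation
  expect_identical(make_rotation_folds(labels, 4, TRUE, seed = 7)$groups,
                   plan$groups)
  loo <- make_rotation_folds(1:5, G = 5, stratified = FALSE, seed = 2)
  expect_equal(sort(unique(loo$groups)), 1:5)
  expect_equal(as.numeric(table(loo$groups)), rep(1, 5))
  expect_error(make_rotation_folds(1:3, G = 4), "exceeds")
  expect_error(make_rotation_folds(labels, G = 1), "G must be")
})

test_that("every sample is tested exactly once across the rotation", {
  set <- generate_tea_spectra(synth_config(seed = 2, n_points = 300,
                                           samples_per_class = 8))
  plan <- make_rotation_folds(set$label, 4, TRUE, seed = 3)
  res <- run_rotation_evaluation(set, "svm_fixed", 10, plan,
                                 quick_eval_control(seed = 1))
  tested <- sort(unlist(lapply(res$details, `[[`, "test_idx")))
  expect_identical(tested, seq_len(nrow(set$values)))
  expect_true(all(res$folds$test_acc >= 0 & res$folds$test_acc <= 1))
  expect_equal(res$mean_test, mean(res$folds$test_acc))
  # deterministic under the same control seed
  res2 <- run_rotation_evaluation(set, "svm_fixed", 10, plan,
                                  quick_eval_control(seed = 1))
  expect_identical(res$folds, res2$folds)
})

test_that("PCA sees only the training partition (leakage canary)", {
  set <- generate_tea_spectra(synth_config(seed = 4, n_points = 300,
                                           samples_per_class = 6))
  plan <- make_rotation_folds(set$label, 4, TRUE, seed = 5)
  ctrl <- quick_eval_control(seed = 1)
  base <- run_rotation_evaluation(set, "svm_fixed", 8, plan, ctrl)
  # corrupt the samples held out in fold 1 and re-run
  corrupted <- set
  idx <- which(plan$groups == 1)
  corrupted$values[idx, ] <- corrupted$values[idx, ] + 3
  base2 <- run_rotation_evaluation(corrupted, "svm_fixed", 8, plan, ctrl)
  expect_equal(base2$details[[1]]$pca_mean, base$details[[1]]$pca_mean,
               tolerance = 1e-12)
  # the paper-faithful global-PCA switch must trip the canary
  ctrl_g <- quick_eval_control(seed = 1, global_pca = TRUE)
  g1 <- run_rotation_evaluation(set, "svm_fixed", 8, plan, ctrl_g)
  g2 <- run_rotation_evaluation(corrupted, "svm_fixed", 8, plan, ctrl_g)
  expect_gt(max(abs(g2$details[[1]]$pca_mean - g1$details[[1]]$pca_mean)), 0.01)
})

test_that("all four methods run through the rotation protocol", {
  set <- generate_tea_spectra(synth_config(seed = 6, n_points = 250,
                                           samples_per_class = 6))
  plan <- make_rotation_folds(set$label, 4, TRUE, seed = 6)
  ctrl <- quick_eval_control(seed = 2)
  for (m in c("svm_fixed", "plsda", "pso_svm", "clpso_svm")) {
    res <- run_rotation_evaluation(set, m, 8, plan, ctrl)
    expect_equal(nrow(res$folds), 4)
    expect_true(all(res$folds$train_acc >= 0 & res$folds$train_acc <= 1))
    if (m %in% c("pso_svm", "clpso_svm"))
      expect_true(all(is.finite(res$folds$c) & res$folds$c > 0))
  }
  expect_error(run_rotation_evaluation(set, "nope", 8, plan, ctrl))
})

test_that("failures inside a fold are reported with fold context", {
  set <- generate_tea_spectra(synth_config(seed = 7, n_points = 200,
                                           samples_per_class = 5,
                                           n_classes = 1))
  # a one-class dataset cannot train a one-vs-rest model
  plan <- make_rotation_folds(set$label, 4, TRUE, seed = 1)
  expect_error(run_rotation_evaluation(set, "svm_fixed", 3, plan,
                                       quick_eval_control(seed = 1)),
               "fold 1")
})

test_that("pc_sweep aggregates folds exactly and breaks ties low", {
  set <- generate_tea_spectra(synth_config(seed = 8, n_points = 250,
                                           samples_per_class = 6))
  plan <- make_rotation_folds(set$label, 4, TRUE, seed = 2)
  ctrl <- quick_eval_control(seed = 3)
  sw <- pc_sweep(set, "svm_fixed", pc_range = 4:8, plan, ctrl)
  expect_equal(nrow(sw$table), 5)
  # independent re-aggregation oracle from the stored per-fold values
  for (k in 4:8) {
    rows <- sw$folds[sw$folds$pc == k, ]
    expect_equal(sw$table$mean_test[sw$table$pc == k], mean(rows$test_acc))
    expect_equal(sw$table$mean_train[sw$table$pc == k], mean(rows$train_acc))
  }
  # best pc is the argmax; ties resolve to the smallest count
  expect_equal(sw$best_pc,
               sw$table$pc[which(sw$table$mean_test ==
                                 max(sw$table$mean_test))][1])
  # a single-point range yields a single-entry report
  sw1 <- pc_sweep(set, "svm_fixed", pc_range = 5, plan, ctrl)
  expect_equal(nrow(sw1$table), 1)
  expect_equal(sw1$best_pc, 5L)
  expect_error(pc_sweep(set, "svm_fixed", integer(0), plan, ctrl), "non-empty")
})

test_that("compare_methods reports the four methods in protocol order", {
  # easy mode: each class boosts its own absorption band, so the six class
  # means point in six distinct directions and every method can solve it
  set <- generate_tea_spectra(synth_config(seed = 9, n_points = 250,
                                           samples_per_class = 8,
                                           band_centers = seq(7800, 9800, by = 400),
                                           band_widths = rep(150, 6),
                                           band_depths = rep(0.3, 6),
                                           class_effect = matrix(1, 6, 6) + 1.5 * diag(6),
                                           noise_sd = 5e-4,
                                           strength_sd = 0.001,
                                           band_jitter_sd = 0.001))
  plan <- make_rotation_folds(set$label, 4, TRUE, seed = 4)
  cmp <- compare_methods(set, pc_range = 8:9, plan,
                         quick_eval_control(seed = 5))
  expect_identical(cmp$table$method, c("SVM", "PLS-DA", "PSO-SVM", "CLPSO-SVM"))
  expect_equal(nrow(cmp$table), 4)
  expect_true(all(cmp$table$test_accuracy >= 0 & cmp$table$test_accuracy <= 1))
  # an easy, widely separated panel is solved perfectly by every method
  expect_true(all(cmp$table$test_accuracy == 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_comparison_csv(cmp, path)
  expect_identical(nrow(utils::read.csv(path)), 4L)
})
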