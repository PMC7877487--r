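test_that("compute_metrics matches hand-computed confusion arithmetic", {
  # confusion TP=13, FN=3, TN=11, FP=5
  labels <- c(rep(1, 16), rep(0, 16))
  scores <- c(rep(0.9, 13), rep(0.1, 3), rep(0.1, 11), rep(0.9, 5))
  rep_ <- compute_metrics(labels, scores)
  expect_equal(unname(rep_$confusion), c(13L, 5L, 11L, 3L), ignore_attr = TRUE)
  expect_equal(rep_$sensitivity, 0.8125)
  expect_equal(rep_$accuracy, 0.75)
  expect_equal(rep_$specificity, 11 / 16)
  expect_equal(rep_$f1, 2 * (13 / 18) * 0.8125 / ((13 / 18) + 0.8125), tolerance = 1e-12)
  expect_equal(rep_$f1, 0.7647, tolerance = 1e-4)

  perfect <- compute_metrics(c(1, 1, 0, 0), c(0.99, 0.9, 0.1, 0.2))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
})

test_that("single-class inputs yield NA metrics, not zeros", {
  rep_ <- compute_metrics(c(0, 0, 0), c(0.2, 0.3, 0.1))
  expect_true(is.na(rep_$sensitivity))
  expect_true(is.na(rep_$auc))
  expect_false(is.na(rep_$specificity))
  rep2 <- compute_metrics(c(1, 1), c(0.2, 0.3))
  expect_true(is.na(rep2$specificity))
  expect_true(is.na(rep2$f1) || rep2$f1 >= 0) # no precision when nothing predicted positive
})

test_that("roc_auc agrees with the O(n^2) pairwise oracle and its symmetries", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0)
  set.seed(5)
  for (i in 1:5) {
    y <- sample(c(0, 1), 25, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    s <- round(stats::runif(25), 2) # rounding forces some ties
    expect_equal(roc_auc(y, s), bf_auc(y, s), tolerance = 1e-12)
    expect_equal(roc_auc(y, -s), 1 - roc_auc(y, s), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 1), c(0.5, 0.6)), "both classes")
  pts <- roc_points(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_equal(range(pts$tpr), c(0, 1))
})

test_that("permutation test flips the exact label count and is reproducible", {
  nets <- lapply(1:20, function(i) random_network(side = 10, seed = i))
  y <- rep(c(1, 0), 10)
  seen <- new.env()
  fit_eval <- function(networks, labels) {
    key <- paste(labels, collapse = "")
    assign(key, TRUE, envir = seen)
    mean(labels == y) # records how many labels differ from the originals
  }
  res <- permutation_test(fit_eval, nets, y, n_perm = 25, flip_fraction = 0.2, seed = 3)
  expect_s3_class(res, "permutation_result")
  expect_length(res$null_accuracies, 25)
  # every null evaluation saw exactly floor(0.2 * 20) = 4 flipped labels
  expect_true(all(abs(res$null_accuracies - 16 / 20) < 1e-12))
  expect_equal(res$observed_accuracy, 1)
  expect_equal(res$empirical_p, 1 / 26)

  res2 <- permutation_test(fit_eval, nets, y, n_perm = 25, flip_fraction = 0.2, seed = 3)
  expect_identical(res$null_accuracies, res2$null_accuracies)
  expect_error(
    permutation_test(fit_eval, nets, y, n_perm = 5, flip_fraction = 1.2),
    "flip_fraction"
  )
})

test_that("the surrogate classifier separates signal and stays honest at chance", {
  atlas <- small_atlas(n_regions = 10, grid = 12, seed = 9)
  coh <- small_cohort(
    n_asd = 12, n_tc = 12, shift = 1.0, seed = 2, atlas = atlas,
    pairs = list(c(1L, 2L), c(3L, 4L))
  )
  nets <- lapply(coh$gm_maps, build_network,
    atlas = atlas,
    config = network_config(excluded_labels = integer(0), grid_size = 32L)
  )
  fe <- make_surrogate_fit_eval(nets, seed = 4)
  acc_signal <- fe(nets, coh$phenotypes$dx)
  expect_gt(acc_signal, 0.8)

  coh0 <- small_cohort(
    n_asd = 12, n_tc = 12, shift = 0, seed = 3, atlas = atlas,
    pairs = list(c(1L, 2L))
  )
  nets0 <- lapply(coh0$gm_maps, build_network,
    atlas = atlas,
    config = network_config(excluded_labels = integer(0), grid_size = 32L)
  )
  fe0 <- make_surrogate_fit_eval(nets0, seed = 4)
  accs <- vapply(1:10, function(i) {
    set.seed(i)
    fe0(nets0, sample(as_binary_labels(coh0$phenotypes$dx)))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("baselines recover strong signal and degrade to majority vote on noise", {
  atlas <- small_atlas(n_regions = 10, grid = 12, seed = 9)
  coh <- small_cohort(
    n_asd = 20, n_tc = 20, shift = 1.0, seed = 6, atlas = atlas,
    pairs = list(c(1L, 2L), c(3L, 4L))
  )
  nets <- lapply(coh$gm_maps, build_network,
    atlas = atlas,
    config = network_config(excluded_labels = integer(0), grid_size = 32L)
  )
  expect_equal(ncol(flatten_networks(nets)), 100) # 10 x 10 regions
  plan <- make_cv_plan(coh$phenotypes, n_folds = 4, n_repeats = 2, seed = 8)
  reports <- run_baselines(nets, coh$phenotypes$dx, plan,
    methods = c("RF", "SVM", "XGB", "AE"), seed = 10, ae_epochs = 8
  )
  for (m in names(reports)) {
    expect_gt(reports[[m]]$accuracy, 0.8)
    expect_gt(reports[[m]]$auc, 0.85)
  }
  expect_error(run_baselines(nets, coh$phenotypes$dx, plan, methods = "LDA"), "unknown")

  # constant features: accuracy collapses to the majority class proportion
  const_nets <- lapply(seq_len(12), function(i) {
    nw <- random_network(side = 6, seed = 1)
    nw$matrix[] <- 1
    nw$subject_id <- sprintf("c%02d", i)
    nw
  })
  labs <- c(rep("ASD", 4), rep("TC", 8))
  plan_c <- make_cv_plan(
    data.frame(subject_id = sprintf("c%02d", 1:12)),
    n_folds = 3, n_repeats = 2, seed = 2
  )
  rep_c <- run_baselines(const_nets, labs, plan_c, methods = "XGB", seed = 3)
  expect_lt(abs(rep_c$XGB$accuracy - 2 / 3), 0.35)
})

test_that("cnn and baselines consume identical fold assignments", {
  ph <- data.frame(subject_id = sprintf("s%02d", 1:30))
  p1 <- make_cv_plan(ph, n_folds = 5, n_repeats = 3, seed = 11)
  p2 <- make_cv_plan(ph, n_folds = 5, n_repeats = 3, seed = 11)
  expect_identical(morphnet:::cv_plan_hash(p1), morphnet:::cv_plan_hash(p2))
  p3 <- make_cv_plan(ph, n_folds = 5, n_repeats = 3, seed = 12)
  expect_false(identical(morphnet:::cv_plan_hash(p1), morphnet:::cv_plan_hash(p3)))
})
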