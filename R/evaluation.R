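#' Confusion-matrix classification metrics
#'
#' ASD (label 1) is the positive class: sensitivity is the ASD detection
#' rate, specificity the TC detection rate. AUC is computed from the raw
#' scores, not the thresholded predictions. Metrics whose denominator is
#' empty (e.g. sensitivity with no positive subjects) are reported as
#' \code{NA}, not 0.
#'
#' @param labels 0/1 (or ASD/TC) true labels.
#' @param scores Numeric classifier scores in [0, 1].
#' @param threshold Decision threshold on the score (default 0.5).
#' @return An object of class \code{metrics_report}: list with
#'   \code{accuracy}, \code{sensitivity}, \code{specificity}, \code{f1},
#'   \code{auc}, and \code{confusion} (named TP/FP/TN/FN counts).
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(scores))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sen <- safe_div(tp, tp + fn)
  spe <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sen) || (prec + sen) == 0) NA_real_ else 2 * prec * sen / (prec + sen)
  auc <- if (length(unique(y)) < 2) NA_real_ else roc_auc(y, scores)
  structure(
    list(
      accuracy = (tp + tn) / length(y), sensitivity = sen, specificity = spe,
      f1 = f1, auc = auc,
      confusion = c(TP = tp, FP = fp, TN = tn, FN = fn)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> ACC %.4f | SEN %s | SPE %s | F1 %s | AUC %s (TP %d FP %d TN %d FN %d)\n",
    x$accuracy, format(round(x$sensitivity, 4)), format(round(x$specificity, 4)),
    format(round(x$f1, 4)), format(round(x$auc, 4)),
    x$confusion["TP"], x$confusion["FP"], x$confusion["TN"], x$confusion["FN"]
  ))
  invisible(x)
}

#' Area under the ROC curve
#'
#' The probability that a uniformly random positive subject outscores a
#' uniformly random negative one, with ties counted 1/2.
#'
#' @param labels 0/1 (or ASD/TC) labels; both classes must be present.
#' @param scores Numeric scores; larger means more ASD-like.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present to compute AUC")
  as.numeric(pROC::auc(pROC::roc(y, scores,
    levels = c(0, 1),
    direction = "<", quiet = TRUE
  )))
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame with columns \code{fpr} and \code{tpr}, suitable for
#'   plotting or export.
#' @export
roc_points <- function(labels, scores) {
  y <- as_binary_labels(labels)
  r <- pROC::roc(y, scores, levels = c(0, 1), direction = "<", quiet = TRUE)
  data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
}

#' Label-flip permutation test for classification accuracy
#'
#' In each of \code{n_perm} iterations a uniformly random subset of
#' \code{floor(flip_fraction * n)} labels is inverted and the training/
#' evaluation procedure is re-run on the perturbed labels; the empirical
#' p-value is \code{(1 + #\{null >= observed\}) / (1 + n_perm)}. The
#' reference protocol uses 5,000 iterations with 20\% flips; desk-scale runs
#' reduce \code{n_perm} and use a fast surrogate \code{fit_eval} (see
#' \code{\link{make_surrogate_fit_eval}}).
#'
#' @param fit_eval Function \code{(networks, labels) -> accuracy in [0, 1]}.
#' @param networks List of \code{morph_network} (or any object
#'   \code{fit_eval} accepts).
#' @param labels 0/1 or ASD/TC labels.
#' @param n_perm Number of permutation iterations (default 5000).
#' @param flip_fraction Fraction of labels inverted per iteration, in (0, 1).
#' @param seed Integer seed; the null draw is deterministic per seed.
#' @return An object of class \code{permutation_result}: list with
#'   \code{observed_accuracy}, \code{null_accuracies}, \code{empirical_p},
#'   \code{flip_fraction}, \code{n_perm}.
#' @export
permutation_test <- function(fit_eval, networks, labels, n_perm = 5000L,
                             flip_fraction = 0.2, seed = 1L) {
  if (flip_fraction <= 0 || flip_fraction >= 1) {
    stop("flip_fraction must be in (0, 1)")
  }
  y <- as_binary_labels(labels)
  n <- length(y)
  n_flip <- floor(flip_fraction * n)
  if (n_flip < 1) stop("flip_fraction too small: no label would be flipped")

  observed <- fit_eval(networks, y)
  rng <- local_rng(derive_seed(seed, 613L))
  on.exit(restore_rng(rng))
  null_acc <- vapply(seq_len(n_perm), function(i) {
    flipped <- y
    idx <- sample.int(n, n_flip)
    flipped[idx] <- 1 - flipped[idx]
    fit_eval(networks, flipped)
  }, numeric(1))
  structure(
    list(
      observed_accuracy = observed,
      null_accuracies = null_acc,
      empirical_p = (1 + sum(null_acc >= observed)) / (1 + n_perm),
      flip_fraction = flip_fraction,
      n_perm = as.integer(n_perm)
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed ACC %.4f vs null mean %.4f over %d iterations (%.0f%% flips): p = %.4g\n",
    x$observed_accuracy, mean(x$null_accuracies), x$n_perm,
    100 * x$flip_fraction, x$empirical_p
  ))
  invisible(x)
}

#' Fast surrogate classifier handle for the permutation test
#'
#' Returns a \code{fit_eval(networks, labels)} closure that scores held-out
#' subjects with a ridge-regularized linear model on the flattened network
#' features, fitted in the kernel (Gram) form. The Gram matrix and the fold
#' split are computed once, so each permutation iteration costs one small
#' linear solve instead of a full classifier retraining; under label
#' permutation the statistic remains exchangeable, which is what the test
#' requires.
#'
#' @param networks List of \code{morph_network} used for every evaluation.
#' @param n_folds Cross-validation folds for the accuracy estimate.
#' @param lambda Ridge penalty.
#' @param seed Seed for the (fixed) fold split.
#' @return Function \code{(networks, labels) -> accuracy}.
#' @export
make_surrogate_fit_eval <- function(networks, n_folds = 2L, lambda = 1,
                                    seed = 1L) {
  X <- flatten_networks(networks)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  K <- tcrossprod(Xc)
  n <- nrow(K)
  rng <- local_rng(derive_seed(seed, 271L))
  folds <- sample(rep_len(seq_len(n_folds), n))
  restore_rng(rng)

  function(nets_ignored, labels) {
    y <- as_binary_labels(labels)
    z <- 2 * y - 1
    correct <- 0L
    for (f in seq_len(n_folds)) {
      te <- which(folds == f)
      tr <- which(folds != f)
      alpha <- solve(K[tr, tr] + lambda * diag(length(tr)), z[tr])
      scores <- drop(K[te, tr, drop = FALSE] %*% alpha)
      correct <- correct + sum((scores >= 0) == (y[te] == 1))
    }
    correct / n
  }
}

# ---------------------------------------------------------------------------
# Baseline classifiers on flattened networks

#' Run conventional baseline classifiers under a CV plan
#'
#' Flattens every network into an 11,664-feature vector (for the default
#' 108 x 108 networks) and trains random forest, SVM, gradient boosting,
#' and/or an autoencoder baseline under the same fold assignments as the
#' CNN: per repeat, fit on all non-test subjects, score the test fold.
#' Scores are pooled over repeats before computing metrics.
#'
#' @param networks List of \code{morph_network} in plan subject order.
#' @param labels 0/1 or ASD/TC labels.
#' @param plan A \code{cv_plan}.
#' @param methods Subset of \code{c("RF", "SVM", "XGB", "AE")}.
#' @param test_folds \code{"last"} or \code{"all"} (as in
#'   \code{\link{train_cnn_cv}}).
#' @param seed Integer seed.
#' @param ae_epochs Reconstruction-pretraining epochs for the AE baseline.
#' @return Named list of \code{metrics_report}, one per method, each with a
#'   \code{scores} data.frame attached (subject_id, repeat_id, fold, score,
#'   label).
#' @export
run_baselines <- function(networks, labels, plan,
                          methods = c("RF", "SVM", "XGB", "AE"),
                          test_folds = c("last", "all"), seed = 1L,
                          ae_epochs = 15L) {
  test_folds <- match.arg(test_folds)
  bad <- setdiff(methods, c("RF", "SVM", "XGB", "AE"))
  if (length(bad) > 0) stop("unknown baseline method(s): ", paste(bad, collapse = ", "))
  y <- as_binary_labels(labels)
  X <- flatten_networks(networks)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  folds_to_test <- if (test_folds == "last") plan$n_folds else seq_len(plan$n_folds)

  all_scores <- stats::setNames(vector("list", length(methods)), methods)
  for (r in seq_len(plan$n_repeats)) {
    outer_fold <- plan$repeats[[r]]$outer
    for (tf in folds_to_test) {
      te <- which(outer_fold == tf)
      tr <- which(outer_fold != tf)
      for (m in methods) {
        sc <- .fit_baseline(
          m, X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE],
          seed = derive_seed(seed, 100L * r + tf), ae_epochs = ae_epochs
        )
        all_scores[[m]][[length(all_scores[[m]]) + 1L]] <- data.frame(
          subject_id = plan$subject_id[te], repeat_id = r, fold = tf,
          score = sc, label = y[te], stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- lapply(methods, function(m) {
    df <- do.call(rbind, all_scores[[m]])
    rep <- compute_metrics(df$label, df$score)
    rep$scores <- df
    rep
  })
  stats::setNames(out, methods)
}

.fit_baseline <- function(method, X_tr, y_tr, X_te, seed, ae_epochs = 15L) {
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  if (length(unique(y_tr)) < 2) {
    return(rep(mean(y_tr), nrow(X_te)))
  }
  if (method == "RF") {
    fit <- ranger::ranger(
      x = X_tr, y = factor(y_tr, levels = c(0, 1)),
      num.trees = 300, probability = TRUE, seed = seed,
      num.threads = 1
    )
    return(stats::predict(fit, data = X_te, num.threads = 1)$predictions[, "1"])
  }
  if (method == "SVM") {
    # KLS features are already bounded in (0, 1]; internal scaling would
    # only warn about the constant unit-diagonal features
    fit <- e1071::svm(
      x = X_tr, y = factor(y_tr, levels = c(0, 1)),
      kernel = "radial", probability = TRUE, scale = FALSE
    )
    pr <- stats::predict(fit, newdata = X_te, probability = TRUE)
    return(attr(pr, "probabilities")[, "1"])
  }
  if (method == "XGB") {
    fit <- xgboost::xgboost(
      X_tr, factor(y_tr, levels = c(0, 1)),
      nrounds = 60, max_depth = 3, learning_rate = 0.3,
      verbosity = 0, nthread = 1
    )
    return(as.numeric(stats::predict(fit, X_te)))
  }
  # AE: reconstruction-pretrained encoder, then a ridge-logistic head on the
  # frozen latent features
  enc <- .fit_autoencoder(X_tr, epochs = ae_epochs)
  Z_tr <- .ae_encode(enc, X_tr)
  Z_te <- .ae_encode(enc, X_te)
  head <- glmnet::glmnet(Z_tr, y_tr,
    family = "binomial", alpha = 0,
    lambda = 0.05, standardize = TRUE
  )
  drop(stats::predict(head, Z_te, type = "response"))
}

# Two-layer tied-free autoencoder (p -> d1 -> d2, tanh hidden units, linear
# reconstruction), trained by Adam on mean squared reconstruction error.
# Deliberately small: the latent features, not reconstruction fidelity, are
# what the baseline consumes.
.fit_autoencoder <- function(X, d1 = 512L, d2 = 64L, epochs = 15L,
                             batch_size = 32L, lr = 1e-3) {
  p <- ncol(X)
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  d1 <- min(d1, p)
  d2 <- min(d2, d1)
  params <- list(
    W1 = matrix(stats::rnorm(p * d1, sd = sqrt(1 / p)), d1, p), b1 = numeric(d1),
    W2 = matrix(stats::rnorm(d1 * d2, sd = sqrt(1 / d1)), d2, d1), b2 = numeric(d2),
    W3 = matrix(stats::rnorm(d2 * d1, sd = sqrt(1 / d2)), d1, d2), b3 = numeric(d1),
    W4 = matrix(stats::rnorm(d1 * p, sd = sqrt(1 / d1)), p, d1), b4 = numeric(p)
  )
  state <- adam_init(params)
  n <- nrow(Xs)
  Xt <- t(Xs) # p x n, column per subject
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      Xb <- Xt[, b, drop = FALSE]
      h1 <- tanh(params$W1 %*% Xb + params$b1)
      z <- tanh(params$W2 %*% h1 + params$b2)
      h3 <- tanh(params$W3 %*% z + params$b3)
      recon <- params$W4 %*% h3 + params$b4
      err <- recon - Xb
      m <- length(err)
      d_recon <- 2 * err / m
      g <- list()
      g$W4 <- d_recon %*% t(h3)
      g$b4 <- rowSums(d_recon)
      d_h3 <- crossprod(params$W4, d_recon) * (1 - h3^2)
      g$W3 <- d_h3 %*% t(z)
      g$b3 <- rowSums(d_h3)
      d_z <- crossprod(params$W3, d_h3) * (1 - z^2)
      g$W2 <- d_z %*% t(h1)
      g$b2 <- rowSums(d_z)
      d_h1 <- crossprod(params$W2, d_z) * (1 - h1^2)
      g$W1 <- d_h1 %*% t(Xb)
      g$b1 <- rowSums(d_h1)
      upd <- adam_step(params, g[names(params)], state, lr = lr)
      params <- upd$params
      state <- upd$state
    }
  }
  list(params = params, mu = mu, sd = sdv)
}

.ae_encode <- function(enc, X) {
  Xs <- sweep(sweep(X, 2, enc$mu), 2, enc$sd, `/`)
  h1 <- tanh(enc$params$W1 %*% t(Xs) + enc$params$b1)
  t(tanh(enc$params$W2 %*% h1 + enc$params$b2))
}
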