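#' Build a nested cross-validation plan
#'
#' For every repeat, all subjects are randomly partitioned into
#' \code{n_folds} equal-sized groups S1..Sk (sizes differ by at most one);
#' the last group is the held-out test set. The remaining subjects are then
#' repartitioned into \code{n_inner} subgroups, one of which (the last) is
#' the validation set for early stopping; the rest are the training data.
#' Each repeat re-randomizes both partitions.
#'
#' @param phenotypes Data frame with a \code{subject_id} column (one row per
#'   subject), as produced by \code{\link{simulate_cohort}}.
#' @param n_folds Number of outer groups (default 10).
#' @param n_repeats Number of independent repetitions (default 20).
#' @param seed Integer seed; the plan is deterministic per seed.
#' @param n_inner Number of inner subgroups (default 10).
#' @return An object of class \code{cv_plan}: list with \code{subject_id},
#'   \code{n_folds}, \code{n_repeats}, \code{seed}, and \code{repeats}, a
#'   list of per-repeat lists holding \code{outer} (fold index per subject,
#'   1..n_folds), \code{inner} (subgroup index per subject, NA for test-fold
#'   subjects), and \code{val_subgroup} (the subgroup used for validation).
#' @export
make_cv_plan <- function(phenotypes, n_folds = 10L, n_repeats = 20L,
                         seed = 1L, n_inner = 10L) {
  ids <- phenotypes$subject_id
  n <- length(ids)
  if (anyDuplicated(ids) > 0) stop("subject_id values must be unique")
  if (n < n_folds) stop("fewer subjects than folds")

  equal_partition <- function(n_items, k) {
    # fold sizes differ by at most one; assignment order randomized
    sizes <- rep(n_items %/% k, k) + (seq_len(k) <= n_items %% k)
    sample(rep.int(seq_len(k), sizes))
  }

  rng <- local_rng(derive_seed(seed, 31L))
  on.exit(restore_rng(rng))
  repeats <- lapply(seq_len(n_repeats), function(r) {
    outer_fold <- equal_partition(n, n_folds)
    inner <- rep(NA_integer_, n)
    train_idx <- which(outer_fold != n_folds)
    inner[train_idx] <- equal_partition(length(train_idx), n_inner)
    list(outer = outer_fold, inner = inner, val_subgroup = as.integer(n_inner))
  })
  structure(
    list(
      subject_id = ids, n_folds = as.integer(n_folds),
      n_repeats = as.integer(n_repeats), seed = as.integer(seed),
      repeats = repeats
    ),
    class = "cv_plan"
  )
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf(
    "<cv_plan> %d subjects, %d folds x %d repeats (test = S%d, inner validation subgroup %d)\n",
    length(x$subject_id), x$n_folds, x$n_repeats, x$n_folds,
    x$repeats[[1]]$val_subgroup
  ))
  invisible(x)
}

# Hash of a plan's fold assignments, used to assert that two evaluations
# consumed identical partitions.
cv_plan_hash <- function(plan) {
  txt <- paste(
    vapply(plan$repeats, function(r) {
      paste(c(r$outer, ifelse(is.na(r$inner), 0L, r$inner)), collapse = ",")
    }, ""),
    collapse = ";"
  )
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' Train the CNN under a nested cross-validation plan
#'
#' For each repeat (and each requested test fold): fits the model on the
#' inner training subgroups, early-stops on the validation subgroup, and
#' scores the held-out test fold. The test fold's subjects never enter a
#' training or validation batch.
#'
#' @param networks List of \code{morph_network}, one per subject, in the
#'   plan's subject order.
#' @param labels Character (\code{"ASD"}/\code{"TC"}) or numeric 0/1 labels;
#'   ASD is the positive class.
#' @param plan A \code{cv_plan}.
#' @param hyper A \code{hyperparameters} object.
#' @param config A \code{model_config} (its \code{input_size} must match the
#'   networks).
#' @param test_folds \code{"last"} (the plan's designated test group, the
#'   reference protocol) or \code{"all"} (rotate every fold through the test
#'   role within each repeat).
#' @param seed Integer seed for weight initialization and shuffling.
#' @return List with \code{fold_results} (data.frame: subject_id, repeat_id,
#'   fold, score, label, pred) and \code{models} (one trained
#'   \code{morphnet_cnn} per repeat x test fold).
#' @export
train_cnn_cv <- function(networks, labels, plan, hyper = hyperparameters(),
                         config = model_config(), test_folds = c("last", "all"),
                         seed = 1L) {
  test_folds <- match.arg(test_folds)
  y <- as_binary_labels(labels)
  stopifnot(length(networks) == length(y), length(y) == length(plan$subject_id))
  X <- networks_to_input(networks)
  stopifnot(nrow(X) == config$input_size^2)

  folds_to_test <- if (test_folds == "last") plan$n_folds else seq_len(plan$n_folds)
  results <- list()
  models <- list()
  for (r in seq_len(plan$n_repeats)) {
    rep_plan <- plan$repeats[[r]]
    for (tf in folds_to_test) {
      idx_test <- which(rep_plan$outer == tf)
      if (tf == plan$n_folds) {
        inner <- rep_plan$inner
      } else {
        # rotated test fold: rebuild an inner partition over the remainder,
        # deterministically from the plan seed
        inner <- rep(NA_integer_, length(y))
        rest <- which(rep_plan$outer != tf)
        rng <- local_rng(derive_seed(plan$seed, 1000L * r + tf))
        sizes <- rep(length(rest) %/% 10L, 10L) + (seq_len(10L) <= length(rest) %% 10L)
        inner[rest] <- sample(rep.int(seq_len(10L), sizes))
        restore_rng(rng)
      }
      idx_val <- which(!is.na(inner) & inner == rep_plan$val_subgroup & rep_plan$outer != tf)
      idx_train <- which(!is.na(inner) & inner != rep_plan$val_subgroup & rep_plan$outer != tf)
      stopifnot(
        length(intersect(idx_test, c(idx_train, idx_val))) == 0,
        length(idx_train) > 0
      )

      cfg <- config
      cfg$seed <- derive_seed(seed, 7000L * r + tf)
      model <- build_model(cfg)
      model <- fit_cnn(model, X, y,
        idx_train = idx_train, idx_val = idx_val,
        hyper = hyper, seed = derive_seed(seed, 9000L * r + tf)
      )
      score <- predict(model, X[, idx_test, drop = FALSE])
      results[[length(results) + 1L]] <- data.frame(
        subject_id = plan$subject_id[idx_test],
        repeat_id = r, fold = tf,
        score = score, label = y[idx_test],
        pred = as.integer(score >= 0.5),
        stringsAsFactors = FALSE
      )
      models[[length(models) + 1L]] <- model
    }
  }
  list(fold_results = do.call(rbind, results), models = models)
}

#' Coerce diagnosis labels to numeric 0/1 with ASD as the positive class
#'
#' @param labels Character (\code{"ASD"}/\code{"TC"}), factor, logical, or
#'   numeric 0/1.
#' @return Numeric vector of 0/1.
#' @export
as_binary_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.numeric(labels))
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("ASD", "TC"))) stop("labels must be ASD/TC or 0/1")
  as.numeric(labels == "ASD")
}
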