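#' Default desk-scale pipeline configuration
#'
#' A nested list understood by \code{\link{run_pipeline}}; amend fields or
#' supply a YAML file with the same structure. All stage seeds derive from
#' the single master seed.
#'
#' @param seed Master seed.
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("morphnet_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulation = list(
      grid = 48L, n_regions = 116L, n_asd = 30L, n_tc = 30L,
      shift_magnitude = 0.6, noise_sd = 0.1
    ),
    network = list(
      excluded_labels = 109:116, grid_size = 128L,
      bandwidth_rule = "silverman", prob_floor = 1e-10
    ),
    model = list(
      channels = c(16L, 32L, 64L, 128L, 256L),
      learning_rate = 1e-3, batch_size = 32L,
      max_epochs = 12L, early_stop_patience = 5L
    ),
    cv = list(n_folds = 5L, n_repeats = 2L),
    evaluation = list(
      methods = character(0), n_perm = 49L, flip_fraction = 0.2, k_sd = 3
    )
  )
}

.validate_run_config <- function(config) {
  need <- c("seed", "out_dir", "simulation", "network", "model", "cv", "evaluation")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    stop("run config is missing section(s): ", paste(missing, collapse = ", "))
  }
  sim <- config$simulation
  n <- sim$n_asd + sim$n_tc
  if (config$cv$n_folds > n) {
    stop(sprintf("cv.n_folds (%d) exceeds the number of subjects (%d)", config$cv$n_folds, n))
  }
  if (sim$shift_magnitude < 0) stop("simulation.shift_magnitude must be >= 0")
  ev <- config$evaluation
  if (ev$flip_fraction <= 0 || ev$flip_fraction >= 1) {
    stop("evaluation.flip_fraction must be in (0, 1)")
  }
  invisible(config)
}

#' Run the full pipeline: simulate, build networks, train, explain, evaluate
#'
#' Executes every stage in order under one master seed, writes all artifacts
#' (phenotypes CSV, per-subject network TSVs, fold-result CSV, fused
#' Grad-CAM TSV + edge CSV, metrics JSON) under \code{config$out_dir}, and
#' returns/writes a manifest listing every artifact with its MD5 hash.
#' Re-running with an identical configuration reproduces identical metric
#' summaries.
#'
#' @param config Nested configuration list (see
#'   \code{\link{default_run_config}}) or the path to a YAML file with the
#'   same structure.
#' @param verbose Print stage progress.
#' @return The manifest, invisibly: list with \code{config}, \code{seeds},
#'   \code{artifacts} (paths + md5), and \code{metrics}.
#' @export
run_pipeline <- function(config = default_run_config(), verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  # -- simulate -------------------------------------------------------------
  sim <- config$simulation
  say("[simulate] %d ASD + %d TC on a %d^3 grid (%d regions)", sim$n_asd, sim$n_tc, sim$grid, sim$n_regions)
  atlas <- generate_atlas(rep(sim$grid, 3), sim$n_regions, seed = derive_seed(config$seed, 1L))
  eff_args <- list(shift_magnitude = sim$shift_magnitude, noise_sd = sim$noise_sd)
  if (!is.null(sim$affected_region_pairs)) {
    eff_args$affected_region_pairs <- lapply(sim$affected_region_pairs, as.integer)
  }
  effect <- do.call(effect_config, eff_args)
  cohort <- simulate_cohort(atlas, sim$n_asd, sim$n_tc,
    effect = effect,
    seed = derive_seed(config$seed, 2L)
  )
  utils::write.csv(cohort$phenotypes, file.path(out_dir, "phenotypes.csv"),
    row.names = FALSE, quote = FALSE
  )

  # -- networks -------------------------------------------------------------
  net <- config$network
  net_config <- network_config(
    excluded_labels = net$excluded_labels, grid_size = net$grid_size,
    bandwidth_rule = net$bandwidth_rule, prob_floor = net$prob_floor
  )
  say("[build-net] %d subjects -> %d x %d KLS matrices",
    nrow(cohort$phenotypes),
    sim$n_regions - length(net$excluded_labels),
    sim$n_regions - length(net$excluded_labels)
  )
  networks <- lapply(cohort$gm_maps, build_network, atlas = atlas, config = net_config)
  net_dir <- file.path(out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (nw in networks) {
    write_network(nw, file.path(net_dir, paste0(nw$subject_id, "_network.tsv")))
  }
  jsonlite::write_json(unclass(net_config), file.path(net_dir, "network_config.json"),
    auto_unbox = TRUE, digits = NA
  )

  # -- train ----------------------------------------------------------------
  side <- nrow(networks[[1]]$matrix)
  plan <- make_cv_plan(cohort$phenotypes,
    n_folds = config$cv$n_folds,
    n_repeats = config$cv$n_repeats, seed = derive_seed(config$seed, 3L)
  )
  hyper <- hyperparameters(
    learning_rate = config$model$learning_rate,
    batch_size = config$model$batch_size,
    max_epochs = config$model$max_epochs,
    early_stop_patience = config$model$early_stop_patience
  )
  mconfig <- model_config(input_size = side, channels = config$model$channels)
  say("[train] %d repeats x fold S%d, <= %d epochs", plan$n_repeats, plan$n_folds, hyper$max_epochs)
  cv_fit <- train_cnn_cv(networks, cohort$phenotypes$dx, plan,
    hyper = hyper,
    config = mconfig, seed = derive_seed(config$seed, 4L)
  )
  utils::write.csv(cv_fit$fold_results, file.path(out_dir, "fold_results.csv"), row.names = FALSE)
  logs <- do.call(rbind, lapply(seq_along(cv_fit$models), function(i) {
    cbind(model = i, cv_fit$models[[i]]$training_log)
  }))
  utils::write.csv(logs, file.path(out_dir, "training_log.csv"), row.names = FALSE)

  # -- gradcam --------------------------------------------------------------
  say("[gradcam] fusing maps of correctly classified ASD test subjects")
  maps <- gradcam_maps_correct_asd(cv_fit, networks, plan)
  selection <- NULL
  if (length(maps) > 0) {
    selection <- fuse_and_select(maps,
      k_sd = config$evaluation$k_sd,
      region_labels = networks[[1]]$region_labels
    )
    write_selection(selection, file.path(out_dir, "gradcam"), atlas$label_names)
  } else {
    say("[gradcam] no correctly classified ASD subject in any test fold; skipping selection")
  }

  # -- evaluate -------------------------------------------------------------
  metrics <- compute_metrics(cv_fit$fold_results$label, cv_fit$fold_results$score)
  say(
    "[evaluate] pooled test metrics: ACC %.3f, AUC %s", metrics$accuracy,
    format(round(metrics$auc, 3))
  )
  baselines <- NULL
  if (length(config$evaluation$methods) > 0) {
    baselines <- run_baselines(networks, cohort$phenotypes$dx, plan,
      methods = config$evaluation$methods, seed = derive_seed(config$seed, 5L)
    )
  }
  fit_eval <- make_surrogate_fit_eval(networks, seed = derive_seed(config$seed, 6L))
  perm <- permutation_test(fit_eval, networks, cohort$phenotypes$dx,
    n_perm = config$evaluation$n_perm,
    flip_fraction = config$evaluation$flip_fraction,
    seed = derive_seed(config$seed, 7L)
  )
  utils::write.csv(
    data.frame(null_accuracy = perm$null_accuracies),
    file.path(out_dir, "permutation_null.csv"),
    row.names = FALSE
  )

  metrics_out <- list(
    cnn = metrics[c("accuracy", "sensitivity", "specificity", "f1", "auc")],
    baselines = if (is.null(baselines)) {
      NULL
    } else {
      lapply(baselines, function(b) b[c("accuracy", "sensitivity", "specificity", "f1", "auc")])
    },
    permutation = list(
      observed_accuracy = perm$observed_accuracy,
      empirical_p = perm$empirical_p, n_perm = perm$n_perm
    ),
    n_selected_edges = if (is.null(selection)) NA_integer_ else nrow(selection$edges)
  )
  jsonlite::write_json(metrics_out, file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )

  # -- manifest -------------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    created = format(t0, "%Y-%m-%dT%H:%M:%S"),
    config = config,
    seeds = list(
      master = config$seed,
      atlas = derive_seed(config$seed, 1L), cohort = derive_seed(config$seed, 2L),
      cv_plan = derive_seed(config$seed, 3L), training = derive_seed(config$seed, 4L),
      baselines = derive_seed(config$seed, 5L), surrogate = derive_seed(config$seed, 6L),
      permutation = derive_seed(config$seed, 7L)
    ),
    artifacts = lapply(files, function(f) {
      list(path = sub(paste0("^", out_dir, "/?"), "", f), md5 = unname(tools::md5sum(f)))
    }),
    metrics = metrics_out
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  say("[done] artifacts in %s", out_dir)
  invisible(manifest)
}
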