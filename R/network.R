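#' Configure morphological network construction
#'
#' @param excluded_labels Integer labels dropped before network construction;
#'   the default \code{109:116} removes the eight cerebellar vermis parcels of
#'   a 116-region SRI24-style atlas, leaving a 108-node network.
#' @param grid_size Number of equally spaced density evaluation points shared
#'   by all regions of a subject (>= 16).
#' @param bandwidth_rule Either \code{"silverman"} (rule-of-thumb bandwidth
#'   per region) or a fixed positive numeric bandwidth.
#' @param prob_floor Positive floor applied to raw kernel densities before
#'   normalization so the divergence logs stay finite; must be < 1/grid_size.
#' @param grid_pad Grid padding in units of the largest per-region bandwidth,
#'   added on both sides of the pooled value range.
#'
#' @return An object of class \code{network_config}.
#' @export
network_config <- function(excluded_labels = 109:116, grid_size = 128L,
                           bandwidth_rule = "silverman", prob_floor = 1e-10,
                           grid_pad = 3) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 16L) stop("grid_size must be >= 16")
  if (!(identical(bandwidth_rule, "silverman") ||
    (is.numeric(bandwidth_rule) && length(bandwidth_rule) == 1L && bandwidth_rule > 0))) {
    stop("bandwidth_rule must be \"silverman\" or a single positive number")
  }
  if (prob_floor <= 0 || prob_floor >= 1 / grid_size) {
    stop("prob_floor must be in (0, 1/grid_size)")
  }
  structure(
    list(
      excluded_labels = as.integer(excluded_labels),
      grid_size = grid_size,
      bandwidth_rule = bandwidth_rule,
      prob_floor = prob_floor,
      grid_pad = grid_pad
    ),
    class = "network_config"
  )
}

#' Extract per-region voxel values
#'
#' Collects, for every retained atlas label in ascending order, the
#' gray-matter values of the voxels carrying that label. Excluded labels
#' (by default the vermis, 109-116) are absent from the result.
#'
#' @param gm A \code{gm_volume_map} sharing the atlas grid.
#' @param atlas A \code{parcellation_atlas}.
#' @param config A \code{network_config}.
#' @return Named list (names = retained labels, ascending) of numeric vectors.
#' @export
extract_region_values <- function(gm, atlas, config = network_config()) {
  if (!identical(dim(gm$values), dim(atlas$label_volume))) {
    stop("GM map and atlas must share the same grid shape")
  }
  labels <- setdiff(seq_len(atlas$n_regions), config$excluded_labels)
  lab <- as.integer(atlas$label_volume)
  vals <- as.numeric(gm$values)
  keep <- lab %in% labels
  out <- split(vals[keep], lab[keep])
  missing <- setdiff(as.character(labels), names(out))
  if (length(missing) > 0) {
    stop(sprintf(
      "retained region(s) %s have no voxels in the atlas",
      paste(missing, collapse = ", ")
    ))
  }
  out[order(as.integer(names(out)))]
}

# Per-region bandwidth under the configured rule, with a fixed minimal
# fallback (and warning) for degenerate zero-spread samples.
.region_bandwidth <- function(values, config) {
  if (is.numeric(config$bandwidth_rule)) {
    return(config$bandwidth_rule)
  }
  if (length(values) < 2L || stats::sd(values) == 0) {
    warning("zero-variance sample: falling back to a fixed minimal bandwidth")
    return(max(abs(values[1]), 1) * 1e-3)
  }
  h <- stats::bw.nrd0(values)
  if (!is.finite(h) || h <= 0) {
    warning("degenerate bandwidth: falling back to a fixed minimal bandwidth")
    h <- max(stats::sd(values), 1e-3) * 1e-3
  }
  h
}

#' Estimate a region's discretized value density
#'
#' Gaussian kernel density of the sample evaluated at the shared grid points,
#' floored at \code{prob_floor}, then normalized to sum to one — a discrete
#' probability distribution over the grid rather than a continuous density.
#'
#' @param values Numeric vector of voxel values (>= 1 finite value).
#' @param config A \code{network_config} (bandwidth rule, floor).
#' @param grid Optional numeric vector of evaluation points (strictly
#'   increasing). When omitted, a grid spanning the sample range padded by
#'   \code{grid_pad} bandwidths is built from the sample itself.
#' @return An object of class \code{density_profile}: list of \code{grid},
#'   \code{probs} (sums to 1), and \code{bandwidth}.
#' @export
estimate_density <- function(values, config = network_config(), grid = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 1L) stop("need at least one finite value")
  h <- .region_bandwidth(values, config)
  if (is.null(grid)) {
    lo <- min(values) - config$grid_pad * h
    hi <- max(values) + config$grid_pad * h
    if (hi <= lo) hi <- lo + 1e-6
    grid <- seq(lo, hi, length.out = config$grid_size)
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  # f(g) = (1/nh) sum_j K((g - v_j)/h), Gaussian kernel, compiled single pass
  f <- kde_gauss(values, grid, h)
  f <- pmax(f, config$prob_floor)
  structure(
    list(grid = grid, probs = f / sum(f), bandwidth = h),
    class = "density_profile"
  )
}

#' Symmetrized Kullback-Leibler divergence between two density profiles
#'
#' \eqn{D(P,Q) = \sum_g [P_g \log(P_g/Q_g) + Q_g \log(Q_g/P_g)]}; symmetric in
#' its arguments and zero iff the profiles coincide.
#'
#' @param P,Q \code{density_profile} objects on identical grids.
#' @return Non-negative scalar divergence.
#' @export
symmetric_kl <- function(P, Q) {
  p <- if (inherits(P, "density_profile")) P$probs else as.numeric(P)
  q <- if (inherits(Q, "density_profile")) Q$probs else as.numeric(Q)
  if (inherits(P, "density_profile") && inherits(Q, "density_profile") &&
    !isTRUE(all.equal(P$grid, Q$grid, tolerance = 1e-12))) {
    stop("density profiles must share the same grid")
  }
  if (length(p) != length(q)) stop("profiles must have equal length")
  if (any(p <= 0) || any(q <= 0)) stop("probabilities must be strictly positive")
  sum(p * log(p / q) + q * log(q / p))
}

#' KL-divergence-based similarity (KLS) between two density profiles
#'
#' \eqn{KLS(P,Q) = e^{-D(P,Q)}} with \eqn{D} the symmetrized KL divergence;
#' identical profiles score 1, increasingly divergent profiles approach 0.
#'
#' @inheritParams symmetric_kl
#' @return Similarity in (0, 1].
#' @export
kls <- function(P, Q) exp(-symmetric_kl(P, Q))

#' Build an individual morphological covariance brain network
#'
#' For one subject: extracts retained-region voxel values, estimates every
#' region's value density on one shared grid spanning the pooled value range
#' (padded by \code{grid_pad} of the largest region bandwidth), and fills a
#' symmetric matrix of pairwise KLS similarities with unit diagonal. With the
#' default 116-label atlas and vermis exclusion the matrix is 108 x 108.
#'
#' @inheritParams extract_region_values
#' @return An object of class \code{morph_network}: list of
#'   \code{region_labels} (ascending retained labels), \code{matrix}
#'   (symmetric, entries in (0,1], unit diagonal, dimnames = labels), and
#'   \code{subject_id}.
#' @export
#' @examples
#' atlas <- generate_atlas(c(16, 16, 16), n_regions = 10, seed = 1)
#' cohort <- simulate_cohort(atlas, 1, 1, effect_config(
#'   affected_region_pairs = list(c(1L, 2L)),
#'   shift_magnitude = 0
#' ), seed = 1)
#' net <- build_network(cohort$gm_maps[[1]], atlas, network_config(excluded_labels = 9:10))
#' dim(net$matrix)
build_network <- function(gm, atlas, config = network_config()) {
  samples <- extract_region_values(gm, atlas, config)
  labels <- as.integer(names(samples))
  n <- length(labels)

  h <- vapply(samples, .region_bandwidth, numeric(1), config = config)
  pooled <- range(unlist(samples, use.names = FALSE))
  pad <- config$grid_pad * max(h)
  grid <- seq(pooled[1] - pad, pooled[2] + pad, length.out = config$grid_size)

  probs <- matrix(0, nrow = n, ncol = config$grid_size)
  for (i in seq_len(n)) {
    probs[i, ] <- estimate_density(samples[[i]], config, grid = grid)$probs
  }

  # D(P_a, P_b) = s_a + s_b - C[a,b] - C[b,a] with s_a = sum_g P_a log P_a and
  # C = P log(P)^T the cross-entropy-like Gram matrix: all pairs in one matmul.
  L <- log(probs)
  s <- rowSums(probs * L)
  C <- probs %*% t(L)
  D <- outer(s, s, "+") - C - t(C)
  M <- exp(-D)
  M <- (M + t(M)) / 2 # remove float asymmetry from the two matmul paths
  diag(M) <- 1 # KLS(P, P) is exactly 1
  dimnames(M) <- list(labels, labels)

  structure(
    list(region_labels = labels, matrix = M, subject_id = gm$subject_id %||% NA_character_),
    class = "morph_network"
  )
}

#' @export
print.morph_network <- function(x, ...) {
  cat(sprintf(
    "<morph_network> %s: %d x %d, edge range [%.4f, %.4f]\n",
    x$subject_id, nrow(x$matrix), ncol(x$matrix),
    min(x$matrix[upper.tri(x$matrix)]), max(x$matrix[upper.tri(x$matrix)])
  ))
  invisible(x)
}

#' Write a morphological network as a dense TSV matrix
#'
#' The header row carries the region labels; a sidecar JSON (same stem,
#' \code{.json}) records the construction configuration when given.
#'
#' @param net A \code{morph_network}.
#' @param path Output TSV path.
#' @param config Optional \code{network_config} to record alongside.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path, config = NULL) {
  df <- as.data.frame(net$matrix)
  names(df) <- as.character(net$region_labels)
  utils::write.table(df, path,
    sep = "\t", row.names = FALSE,
    col.names = TRUE, quote = FALSE
  )
  if (!is.null(config)) {
    jsonlite::write_json(
      unclass(config),
      sub("\\.tsv$", ".json", path),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read a morphological network from a TSV matrix
#'
#' @param path TSV written by \code{\link{write_network}}.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @return A \code{morph_network}.
#' @export
read_network <- function(path, subject_id = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  M <- as.matrix(df)
  labels <- as.integer(colnames(df))
  dimnames(M) <- list(labels, labels)
  if (is.null(subject_id)) {
    subject_id <- sub("_network$", "", sub("\\.tsv$", "", basename(path)))
  }
  structure(
    list(region_labels = labels, matrix = M, subject_id = subject_id),
    class = "morph_network"
  )
}

#' Flatten networks into a feature matrix for conventional classifiers
#'
#' Collapses each subject's full similarity matrix into one row vector
#' (108 x 108 = 11,664 features for the default network size).
#'
#' @param networks List of \code{morph_network} objects of equal size.
#' @return Numeric matrix, one row per subject, rownames = subject IDs.
#' @export
flatten_networks <- function(networks) {
  stopifnot(length(networks) >= 1)
  X <- t(vapply(
    networks, function(nw) as.numeric(nw$matrix),
    numeric(length(networks[[1]]$matrix))
  ))
  rownames(X) <- vapply(networks, function(nw) nw$subject_id, "")
  X
}
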