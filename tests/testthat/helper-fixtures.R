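# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (explicit loops, O(n^2) scans) so they cannot share a
# code path with the implementation they check.

small_atlas <- function(n_regions = 10L, grid = 16L, seed = 1L) {
  generate_atlas(rep(grid, 3L), n_regions = n_regions, seed = seed)
}

small_cohort <- function(n_asd = 4L, n_tc = 4L, shift = 0, seed = 1L,
                         atlas = small_atlas(), pairs = list(c(1L, 2L))) {
  simulate_cohort(atlas, n_asd, n_tc,
    effect = effect_config(
      affected_region_pairs = pairs,
      shift_magnitude = shift
    ),
    seed = seed
  )
}

# Brute-force Gaussian KDE evaluated point by point (the direct reading of
# the kernel sum, no vectorization).
bf_kde_probs <- function(values, grid, h, floor) {
  f <- numeric(length(grid))
  for (g in seq_along(grid)) {
    acc <- 0
    for (v in values) acc <- acc + stats::dnorm((grid[g] - v) / h)
    f[g] <- acc / (length(values) * h)
  }
  f <- pmax(f, floor)
  f / sum(f)
}

# Naive network construction: per-region KDE, then an explicit double loop
# over region pairs and grid points for the symmetric KL divergence.
bf_build_network <- function(gm, atlas, config) {
  samples <- extract_region_values(gm, atlas, config)
  h <- vapply(samples, function(v) {
    if (is.numeric(config$bandwidth_rule)) config$bandwidth_rule else stats::bw.nrd0(v)
  }, numeric(1))
  rng <- range(unlist(samples))
  pad <- config$grid_pad * max(h)
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = config$grid_size)
  probs <- lapply(seq_along(samples), function(i) {
    bf_kde_probs(samples[[i]], grid, h[i], config$prob_floor)
  })
  n <- length(samples)
  M <- diag(1, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      d <- 0
      for (g in seq_along(grid)) {
        p <- probs[[a]][g]
        q <- probs[[b]][g]
        d <- d + p * log(p / q) + q * log(q / p)
      }
      M[a, b] <- exp(-d)
    }
  }
  dimnames(M) <- list(names(samples), names(samples))
  M
}

# Pairwise AUC oracle: P(score_pos > score_neg), ties counted 1/2.
bf_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

tiny_model <- function(input_size = 12L, n_stages = 2L, channels = c(4L, 8L),
                       seed = 3L) {
  build_model(model_config(
    input_size = input_size, n_stages = n_stages,
    channels = channels, bottleneck_factor = 2L, seed = seed
  ))
}

random_network <- function(side = 108L, seed = 1L, labels = seq_len(side)) {
  set.seed(seed)
  M <- matrix(stats::runif(side^2, 0.01, 1), side, side)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  dimnames(M) <- list(labels, labels)
  structure(
    list(
      region_labels = labels, matrix = M,
      subject_id = sprintf("rand-%03d", seed)
    ),
    class = "morph_network"
  )
}
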