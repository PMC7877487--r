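test_that("extract_region_values retains exactly the non-excluded labels", {
  atlas <- small_atlas(n_regions = 10, grid = 14)
  cohort <- small_cohort(n_asd = 1, n_tc = 1, atlas = atlas)
  config <- network_config(excluded_labels = 9:10)
  samples <- extract_region_values(cohort$gm_maps[[1]], atlas, config)
  expect_identical(names(samples), as.character(1:8))
  lab <- as.integer(atlas$label_volume)
  for (r in c(1L, 5L, 8L)) {
    expect_equal(
      sort(samples[[as.character(r)]]),
      sort(as.numeric(cohort$gm_maps[[1]]$values)[lab == r])
    )
  }
})

test_that("extraction errors are informative", {
  atlas <- small_atlas(n_regions = 6, grid = 10)
  cohort <- small_cohort(n_asd = 1, n_tc = 1, atlas = atlas)
  gm_bad <- cohort$gm_maps[[1]]
  gm_bad$values <- gm_bad$values[1:5, 1:5, 1:5]
  expect_error(
    extract_region_values(gm_bad, atlas, network_config(excluded_labels = integer(0))),
    "grid shape"
  )
  # an atlas advertising a label with no voxels
  atlas$n_regions <- 7L
  expect_error(
    extract_region_values(cohort$gm_maps[[1]], atlas, network_config(excluded_labels = integer(0))),
    "7"
  )
})

test_that("constant GM maps give constant region values", {
  atlas <- small_atlas(n_regions = 6, grid = 10)
  gm <- structure(
    list(subject_id = "const", values = array(0.42, dim = dim(atlas$label_volume))),
    class = "gm_volume_map"
  )
  samples <- extract_region_values(gm, atlas, network_config(excluded_labels = integer(0)))
  expect_true(all(vapply(samples, function(v) all(v == 0.42), TRUE)))
})

test_that("estimate_density matches the brute-force kernel sum and normalizes", {
  set.seed(21)
  values <- stats::rgamma(50, shape = 3, scale = 0.3)
  config <- network_config(grid_size = 64L, bandwidth_rule = 0.05)
  prof <- estimate_density(values, config)
  expect_s3_class(prof, "density_profile")
  expect_equal(sum(prof$probs), 1, tolerance = 1e-9)
  expect_true(all(diff(prof$grid) > 0))
  oracle <- bf_kde_probs(values, prof$grid, 0.05, config$prob_floor)
  expect_equal(prof$probs, oracle, tolerance = 1e-12)

  # Silverman rule matches the rule-of-thumb bandwidth
  prof_s <- estimate_density(values, network_config(grid_size = 64L))
  expect_equal(prof_s$bandwidth, stats::bw.nrd0(values))
})

test_that("single-value and zero-variance samples are handled", {
  config <- network_config(grid_size = 32L)
  expect_warning(prof <- estimate_density(0.7, config), "bandwidth")
  expect_equal(sum(prof$probs), 1, tolerance = 1e-9)
  expect_equal(prof$grid[which.max(prof$probs)], 0.7, tolerance = diff(prof$grid[1:2]))
  expect_warning(estimate_density(rep(1.3, 10), config), "zero-variance")
  expect_error(estimate_density(numeric(0), config), "at least one")
})

test_that("symmetric_kl matches hand evaluation and is symmetric", {
  # term-by-term: 0.5 ln(0.5/0.9) + 0.5 ln(0.5/0.1) + 0.9 ln(0.9/0.5) + 0.1 ln(0.1/0.5)
  expect_equal(symmetric_kl(c(0.5, 0.5), c(0.9, 0.1)), 0.8789, tolerance = 1e-4)
  expect_equal(symmetric_kl(c(0.3, 0.7), c(0.3, 0.7)), 0)
  set.seed(4)
  for (i in 1:10) {
    p <- stats::runif(16)
    p <- p / sum(p)
    q <- stats::runif(16)
    q <- q / sum(q)
    expect_equal(symmetric_kl(p, q), symmetric_kl(q, p))
    expect_gte(symmetric_kl(p, q), 0)
  }
  expect_error(symmetric_kl(c(0.5, 0.5), c(1, 0)), "strictly positive")
  g1 <- structure(list(grid = 1:4 / 4, probs = rep(0.25, 4)), class = "density_profile")
  g2 <- structure(list(grid = 1:4 / 2, probs = rep(0.25, 4)), class = "density_profile")
  expect_error(symmetric_kl(g1, g2), "same grid")
})

test_that("kls is exp(-divergence) with the right range and ordering", {
  expect_equal(kls(c(0.2, 0.8), c(0.2, 0.8)), 1)
  # a pair whose divergence is exactly ln 2 must score similarity 1/2;
  # locate such a pair by root finding, independent of the kls code path
  p <- c(0.5, 0.5)
  root <- stats::uniroot(
    function(t) symmetric_kl(p, c(t, 1 - t)) - log(2),
    c(0.51, 0.999), tol = 1e-14
  )$root
  expect_equal(kls(p, c(root, 1 - root)), 0.5, tolerance = 1e-9)
  set.seed(9)
  sims <- replicate(20, {
    a <- stats::runif(8)
    a <- a / sum(a)
    b <- stats::runif(8)
    b <- b / sum(b)
    c(symmetric_kl(a, b), kls(a, b))
  })
  expect_true(all(sims[2, ] > 0 & sims[2, ] <= 1))
  # exp is monotone decreasing: larger divergence, smaller similarity
  ord <- order(sims[1, ])
  expect_identical(order(sims[2, ], decreasing = TRUE), ord)
})

test_that("build_network matches the naive brute-force oracle", {
  atlas <- small_atlas(n_regions = 5, grid = 10, seed = 2)
  cohort <- small_cohort(n_asd = 1, n_tc = 1, atlas = atlas, pairs = list(c(1L, 2L)), shift = 0.4)
  config <- network_config(excluded_labels = integer(0), grid_size = 16L)
  net <- build_network(cohort$gm_maps[[1]], atlas, config)
  oracle <- bf_build_network(cohort$gm_maps[[1]], atlas, config)
  expect_equal(dim(net$matrix), c(5L, 5L))
  expect_equal(unname(net$matrix), unname(oracle), tolerance = 1e-10)
})

test_that("networks are symmetric, unit-diagonal, bounded, and deterministic", {
  atlas <- small_atlas(n_regions = 12, grid = 14, seed = 3)
  cohort <- small_cohort(n_asd = 1, n_tc = 1, atlas = atlas, shift = 0.5)
  config <- network_config(excluded_labels = 11:12, grid_size = 64L)
  net <- build_network(cohort$gm_maps[[1]], atlas, config)
  expect_identical(net$region_labels, 1:10)
  expect_identical(net$matrix, t(net$matrix))
  expect_true(all(diag(net$matrix) == 1))
  expect_true(all(net$matrix > 0 & net$matrix <= 1))
  again <- build_network(cohort$gm_maps[[1]], atlas, config)
  expect_identical(net$matrix, again$matrix)
})

test_that("relabeling regions permutes network rows and columns consistently", {
  atlas <- small_atlas(n_regions = 6, grid = 10, seed = 5)
  cohort <- small_cohort(n_asd = 1, n_tc = 1, atlas = atlas)
  config <- network_config(excluded_labels = integer(0), grid_size = 32L)
  net1 <- build_network(cohort$gm_maps[[1]], atlas, config)

  perm <- c(3L, 1L, 6L, 2L, 5L, 4L) # new label of old region r is perm[r]
  atlas2 <- atlas
  atlas2$label_volume <- array(perm[atlas$label_volume], dim = dim(atlas$label_volume))
  net2 <- build_network(cohort$gm_maps[[1]], atlas2, config)

  for (a in 1:6) {
    for (b in 1:6) {
      expect_equal(
        net2$matrix[as.character(perm[a]), as.character(perm[b])],
        net1$matrix[as.character(a), as.character(b)],
        tolerance = 1e-12
      )
    }
  }
})

test_that("well-separated value distributions score lower KLS than close ones", {
  set.seed(11)
  config <- network_config(grid_size = 128L, bandwidth_rule = 0.02)
  grid <- seq(0, 1, length.out = 128)
  base <- estimate_density(stats::rnorm(400, 0.30, 0.05), config, grid = grid)
  far <- estimate_density(stats::rnorm(400, 0.70, 0.05), config, grid = grid)
  near <- estimate_density(stats::rnorm(400, 0.35, 0.05), config, grid = grid)
  expect_lt(kls(base, far), kls(base, near))
})

test_that("networks round-trip through TSV and flatten to side^2 features", {
  net <- random_network(side = 12, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_network(net, path, config = network_config())
  back <- read_network(path)
  expect_equal(back$matrix, net$matrix, tolerance = 1e-12)
  expect_identical(back$region_labels, net$region_labels)
  expect_true(file.exists(sub("\\.tsv$", ".json", path)))

  X <- flatten_networks(list(net, random_network(side = 12, seed = 3)))
  expect_identical(dim(X), c(2L, 144L))
  unlink(c(path, sub("\\.tsv$", ".json", path)))
})
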