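test_that("neuron weights match a finite-difference gradient oracle", {
  model <- tiny_model(seed = 11)
  net <- random_network(side = 12, seed = 3)
  alpha <- neuron_weights(model, net, target_class = 1L)
  expect_length(alpha, model$final_channels)

  # oracle: perturb each activation element of the final stage, rerun the
  # head (GAP + linear) by hand, average the per-element gradients
  fwd <- morphnet:::cnn_forward(model, networks_to_input(list(net)),
    train = FALSE, keep_cache = FALSE
  )
  C <- model$final_channels
  npix <- model$final_size^2
  A <- matrix(fwd$activations[, 1], C, npix)
  w <- model$params$head$w
  b <- model$params$head$b
  logit_of <- function(Am) sum(w * rowMeans(Am)) + b
  eps <- 1e-6
  for (k in c(1, C %/% 2, C)) {
    g <- numeric(npix)
    for (p in seq_len(npix)) {
      Ap <- A
      Ap[k, p] <- Ap[k, p] + eps
      Am <- A
      Am[k, p] <- Am[k, p] - eps
      g[p] <- (logit_of(Ap) - logit_of(Am)) / (2 * eps)
    }
    expect_equal(alpha[k], mean(g), tolerance = 1e-6)
  }
  # TC weights are the negated ASD weights under a single sigmoid output
  expect_equal(neuron_weights(model, net, target_class = 0L), -alpha)
  # a zero-weight output channel contributes zero importance
  model$params$head$w[2] <- 0
  expect_equal(neuron_weights(model, net)[2], 0)
})

test_that("the rectified weighted combination matches hand evaluation", {
  A <- rbind(c(1, 0, -1, 3)) # one channel, 2x2 map (column-major)
  out <- morphnet:::gradcam_combine(alpha = 2, A = A, side = 2)
  expect_equal(out, matrix(c(2, 0, 0, 6), 2, 2))
  # negative weighted sums are clipped at zero
  out2 <- morphnet:::gradcam_combine(alpha = -2, A = A, side = 2)
  expect_equal(out2, matrix(c(0, 0, 2, 0), 2, 2))
})

test_that("gradcam_map equals a hand-rolled chain-rule computation on a frozen CNN", {
  model <- tiny_model(input_size = 16L, seed = 13)
  net <- random_network(side = 16, seed = 5)
  map <- gradcam_map(model, net, target_class = 1L)
  expect_s3_class(map, "importance_map")
  expect_identical(dim(map$matrix), c(16L, 16L))
  expect_true(all(map$matrix >= 0))

  # chain rule by hand: d(logit)/dA[k, p] = w_k / npix, so the pre-upsample
  # map is ReLU(sum_k (w_k/npix) A^k); upsample independently re-derived
  fwd <- morphnet:::cnn_forward(model, networks_to_input(list(net)),
    train = FALSE, keep_cache = FALSE
  )
  C <- model$final_channels
  npix <- model$final_size^2
  A <- matrix(fwd$activations[, 1], C, npix)
  hand <- matrix(0, model$final_size, model$final_size)
  for (k in seq_len(C)) {
    hand <- hand + (model$params$head$w[k] / npix) *
      matrix(A[k, ], model$final_size, model$final_size)
  }
  hand[hand < 0] <- 0
  expect_equal(map$raw, hand, tolerance = 1e-6)
  expect_equal(map$matrix, upsample_bilinear(hand, 16L), tolerance = 1e-6)
})

test_that("bilinear upsampling preserves constants and interpolates linearly", {
  expect_equal(upsample_bilinear(matrix(3.5, 4, 4), 108), matrix(3.5, 108, 108))
  m <- matrix(as.numeric(1:2), 2, 2) # rows 1,2 constant across columns
  up <- upsample_bilinear(m, 4)
  expect_identical(dim(up), c(4L, 4L))
  expect_true(all(diff(up[, 1]) >= 0)) # monotone along the interpolated axis
  expect_equal(up[, 1], up[, 4]) # constant axis stays constant
  expect_equal(range(up), c(1, 2))
})

test_that("fuse_and_select finds dominant cells and ignores constants", {
  side <- 108
  m <- matrix(0, side, side)
  m[10, 87] <- 100
  sel <- fuse_and_select(list(m), k_sd = 3)
  # the single hot cell (symmetrized onto both triangles) is the only edge
  expect_identical(nrow(sel$edges), 1L)
  expect_equal(sel$edges$region_a, 10)
  expect_equal(sel$edges$region_b, 87)
  expect_setequal(sel$region_set, c(10, 87))

  sel_const <- fuse_and_select(list(matrix(2, side, side)), k_sd = 3)
  expect_identical(nrow(sel_const$edges), 0L)
  expect_error(fuse_and_select(list()), "at least one")
})

test_that("edge selection respects ordering invariants and scale invariance", {
  set.seed(17)
  side <- 30
  maps <- lapply(1:4, function(i) {
    m <- matrix(stats::rexp(side^2), side, side)
    m[3, 25] <- m[25, 3] <- 40 + i
    m
  })
  sel <- fuse_and_select(maps, k_sd = 3)
  expect_true(all(sel$edges$region_a < sel$edges$region_b))
  expect_true(all(sel$edges$weight > sel$threshold))
  # scaling every map by a positive constant selects the same edges
  sel_scaled <- fuse_and_select(lapply(maps, function(m) 7.3 * m), k_sd = 3)
  expect_identical(sel$edges[, c("region_a", "region_b")],
    sel_scaled$edges[, c("region_a", "region_b")])
  # fused map is the symmetrized mean
  fused_hand <- Reduce(`+`, maps) / 4
  fused_hand <- (fused_hand + t(fused_hand)) / 2
  expect_equal(sel$fused$matrix, fused_hand)
})

test_that("selection files are written with region names", {
  m <- matrix(0, 8, 8)
  m[2, 6] <- 50
  sel <- fuse_and_select(list(m), k_sd = 1, region_labels = c(1:4, 101:104))
  dir <- tempfile("sel_")
  nm <- stats::setNames(sprintf("R%d", c(1:4, 101:104)), c(1:4, 101:104))
  write_selection(sel, dir, label_names = nm)
  edges <- utils::read.csv(file.path(dir, "selected_edges.csv"))
  expect_true(all(c("region_a", "region_b", "weight", "name_a", "name_b") %in% names(edges)))
  expect_identical(edges$name_a[1], "R2")
  expect_true(file.exists(file.path(dir, "fused_gradcam.tsv")))
  unlink(dir, recursive = TRUE)
})
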