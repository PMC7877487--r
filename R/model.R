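#' Configure the bottleneck residual CNN
#'
#' The classifier is a stack of \code{n_stages} serial bottleneck residual
#' stages (stride-2 1x1 reduce, 3x3, 1x1 expand, plus a projection shortcut
#' whenever resolution or width changes), batch normalization after every
#' convolution and before activation, no dropout, followed by global average
#' pooling and a single sigmoid output unit. With the defaults the spatial
#' size runs 108 -> 54 -> 27 -> 14 -> 7 -> 4.
#'
#' @param input_size Side length of the square input matrix (default 108).
#' @param n_stages Number of bottleneck stages (default 5).
#' @param channels Output channels per stage.
#' @param bottleneck_factor Width reduction inside each bottleneck.
#' @param stage_stride Downsampling stride per stage (default 2).
#' @param use_batch_norm,use_dropout Architecture switches; dropout is
#'   intentionally disabled by default.
#' @param seed Integer seed for weight initialization.
#' @return An object of class \code{model_config}.
#' @export
model_config <- function(input_size = 108L, n_stages = 5L,
                         channels = c(16L, 32L, 64L, 128L, 256L),
                         bottleneck_factor = 4L, stage_stride = 2L,
                         use_batch_norm = TRUE, use_dropout = FALSE,
                         seed = 1L) {
  if (length(channels) != n_stages) stop("channels must have one entry per stage")
  if (use_dropout) stop("dropout is not part of this architecture")
  size <- as.integer(input_size)
  for (s in seq_len(n_stages)) {
    size <- (size - 1L) %/% as.integer(stage_stride) + 1L
    # a non-final stage collapsing to 1x1 leaves the remaining stride-2
    # stages without anything to downsample
    if (size < 1L || (size < 2L && s < n_stages)) {
      stop(sprintf(
        "input_size %d is incompatible with %d stride-%d stages",
        input_size, n_stages, stage_stride
      ))
    }
  }
  structure(
    list(
      input_size = as.integer(input_size), n_stages = as.integer(n_stages),
      channels = as.integer(channels), bottleneck_factor = as.integer(bottleneck_factor),
      stage_stride = as.integer(stage_stride), use_batch_norm = use_batch_norm,
      use_dropout = use_dropout, seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

#' Training hyperparameters
#'
#' Defaults follow the reference protocol: Adam, learning rate 1e-5,
#' minibatch size 32; epoch budget and early-stopping patience are left to
#' the caller (the validation subgroup of the nested CV plan exists for the
#' early-stopping role).
#'
#' @param optimizer Only \code{"adam"} is supported.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping; \code{Inf} disables early stopping.
#' @return An object of class \code{hyperparameters}.
#' @export
hyperparameters <- function(optimizer = "adam", learning_rate = 1e-5,
                            batch_size = 32L, max_epochs = 200L,
                            early_stop_patience = 20L) {
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is supported")
  structure(
    list(
      optimizer = optimizer, learning_rate = learning_rate,
      batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
      early_stop_patience = early_stop_patience
    ),
    class = "hyperparameters"
  )
}

#' Build an (untrained) bottleneck residual CNN
#'
#' @param config A \code{model_config}.
#' @return An object of class \code{morphnet_cnn} holding the stage
#'   geometries and randomly initialized parameters (deterministic per
#'   \code{config$seed}).
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  rng <- local_rng(config$seed)
  on.exit(restore_rng(rng))

  stages <- vector("list", config$n_stages)
  params <- list()
  H <- config$input_size
  C_in <- 1L
  for (s in seq_len(config$n_stages)) {
    C_out <- config$channels[s]
    C_mid <- max(1L, C_out %/% config$bottleneck_factor)
    st <- config$stage_stride
    # the stride sits on the 1x1 entry conv, so the 3x3 transform and all
    # following tensors live at the reduced resolution
    conv_a <- conv_geom(C_in, H, H, C_mid, k = 1L, stride = st, pad = 0L)
    H_out <- conv_a$H_out
    g <- list(
      conv_a = conv_a,
      conv_b = conv_geom(C_mid, H_out, H_out, C_mid, k = 3L, stride = 1L, pad = 1L),
      conv_c = NULL, proj = NULL
    )
    g$conv_c <- conv_geom(C_mid, H_out, H_out, C_out, k = 1L, stride = 1L, pad = 0L)
    g$use_proj <- (C_in != C_out) || (st != 1L)
    if (g$use_proj) {
      g$proj <- conv_geom(C_in, H, H, C_out, k = 1L, stride = st, pad = 0L)
      stopifnot(g$proj$H_out == H_out)
    }
    g$C_in <- C_in
    g$C_mid <- C_mid
    g$C_out <- C_out
    g$H_in <- H
    g$H_out <- H_out
    stages[[s]] <- g

    p <- list(
      conv_a = conv_init(g$conv_a), bn_a = bn_init(C_mid),
      conv_b = conv_init(g$conv_b), bn_b = bn_init(C_mid),
      conv_c = conv_init(g$conv_c), bn_c = bn_init(C_out)
    )
    if (g$use_proj) {
      p$proj <- conv_init(g$proj)
      p$bn_p <- bn_init(C_out)
    }
    params[[paste0("stage", s)]] <- p

    H <- H_out
    C_in <- C_out
  }
  C_last <- config$channels[config$n_stages]
  params$head <- list(
    w = stats::rnorm(C_last, sd = sqrt(1 / C_last)),
    b = 0
  )
  structure(
    list(
      config = config, stages = stages, params = params,
      final_size = H, final_channels = C_last, trained = FALSE,
      training_log = NULL
    ),
    class = "morphnet_cnn"
  )
}

#' @export
print.morphnet_cnn <- function(x, ...) {
  sizes <- c(x$config$input_size, vapply(x$stages, function(s) s$H_out, 0L))
  cat(sprintf(
    "<morphnet_cnn> %d bottleneck stages, spatial %s, channels %s, %s\n",
    x$config$n_stages, paste(sizes, collapse = " -> "),
    paste(x$config$channels, collapse = "/"),
    if (x$trained) "trained" else "untrained"
  ))
  invisible(x)
}

# Mean-pooling operator: (npix*B x B) block matrix so GAP and its adjoint are
# single matrix products.
.gap_matrix <- function(npix, B) {
  S <- matrix(0, npix * B, B)
  S[cbind(seq_len(npix * B), rep(seq_len(B), each = npix))] <- 1 / npix
  S
}

# Full forward pass. X: (input_size^2 x B) matrix, one column per subject.
# Returns logits, sigmoid probabilities, the post-ReLU activations of the
# final stage (Grad-CAM's A^k), and caches for backprop when train = TRUE.
cnn_forward <- function(model, X, train = FALSE, keep_cache = train) {
  stopifnot(is.matrix(X), nrow(X) == model$config$input_size^2)
  caches <- if (keep_cache) vector("list", model$config$n_stages) else NULL
  cur <- X
  for (s in seq_len(model$config$n_stages)) {
    g <- model$stages[[s]]
    p <- model$params[[paste0("stage", s)]]
    ca <- conv_forward(g$conv_a, p$conv_a, cur)
    ba <- bn_forward(p$bn_a, ca$out, g$C_mid, train = train)
    ra <- relu_forward(ba$out)
    cb <- conv_forward(g$conv_b, p$conv_b, ra$out)
    bb <- bn_forward(p$bn_b, cb$out, g$C_mid, train = train)
    rb <- relu_forward(bb$out)
    cc <- conv_forward(g$conv_c, p$conv_c, rb$out)
    bc <- bn_forward(p$bn_c, cc$out, g$C_out, train = train)
    if (g$use_proj) {
      cp <- conv_forward(g$proj, p$proj, cur)
      bp <- bn_forward(p$bn_p, cp$out, g$C_out, train = train)
      shortcut <- bp$out
    } else {
      cp <- NULL
      bp <- NULL
      shortcut <- cur
    }
    rs <- relu_forward(nn_add(bc$out, shortcut))
    if (train) {
      # commit the batch-norm running statistics updated during this pass
      model$params[[paste0("stage", s)]]$bn_a[c("run_mean", "run_var")] <-
        ba$par[c("run_mean", "run_var")]
      model$params[[paste0("stage", s)]]$bn_b[c("run_mean", "run_var")] <-
        bb$par[c("run_mean", "run_var")]
      model$params[[paste0("stage", s)]]$bn_c[c("run_mean", "run_var")] <-
        bc$par[c("run_mean", "run_var")]
      if (g$use_proj) {
        model$params[[paste0("stage", s)]]$bn_p[c("run_mean", "run_var")] <-
          bp$par[c("run_mean", "run_var")]
      }
    }
    if (keep_cache) {
      caches[[s]] <- list(
        input = cur, ca = ca, ba = ba, ra = ra, cb = cb, bb = bb,
        rb = rb, cc = cc, bc = bc, cp = cp, bp = bp, rs = rs
      )
    }
    cur <- rs$out
  }
  B <- ncol(X)
  npix <- model$final_size^2
  S <- .gap_matrix(npix, B)
  gap <- matrix(cur, model$final_channels, npix * B) %*% S
  logit <- drop(crossprod(model$params$head$w, gap)) + model$params$head$b
  prob <- 1 / (1 + exp(-logit))
  list(
    logit = logit, prob = prob, activations = cur, gap = gap, S = S,
    caches = caches, model = model
  )
}

# Backward pass from d(loss)/d(logit); returns gradients mirroring
# model$params plus d(logit)/d(activations of the final stage) on request.
cnn_backward <- function(model, fwd, dlogit) {
  grads <- list()
  C_last <- model$final_channels
  grads$head <- list(
    w = drop(fwd$gap %*% dlogit),
    b = sum(dlogit)
  )
  dgap <- outer(model$params$head$w, dlogit) # C_last x B
  dcur <- dgap %*% t(fwd$S) # C_last x (npix*B)
  dim(dcur) <- c(C_last * model$final_size^2, ncol(fwd$gap))
  for (s in rev(seq_len(model$config$n_stages))) {
    g <- model$stages[[s]]
    p <- model$params[[paste0("stage", s)]]
    ch <- fwd$caches[[s]]
    d_sum <- relu_backward(ch$rs, dcur)
    # main branch
    b3 <- bn_backward(p$bn_c, ch$bc, d_sum, g$C_out)
    c3 <- conv_backward(g$conv_c, p$conv_c, ch$cc, b3$dX)
    d_rb <- relu_backward(ch$rb, c3$dX)
    b2 <- bn_backward(p$bn_b, ch$bb, d_rb, g$C_mid)
    c2 <- conv_backward(g$conv_b, p$conv_b, ch$cb, b2$dX)
    d_ra <- relu_backward(ch$ra, c2$dX)
    b1 <- bn_backward(p$bn_a, ch$ba, d_ra, g$C_mid)
    c1 <- conv_backward(g$conv_a, p$conv_a, ch$ca, b1$dX)
    dinput <- c1$dX
    sg <- list(
      conv_a = c1$grads, bn_a = b1$grads,
      conv_b = c2$grads, bn_b = b2$grads,
      conv_c = c3$grads, bn_c = b3$grads
    )
    if (g$use_proj) {
      bp <- bn_backward(p$bn_p, ch$bp, d_sum, g$C_out)
      cp <- conv_backward(g$proj, p$proj, ch$cp, bp$dX)
      dinput <- dinput + cp$dX
      sg$proj <- cp$grads
      sg$bn_p <- bp$grads
    } else {
      dinput <- dinput + d_sum
    }
    grads[[paste0("stage", s)]] <- sg
    dcur <- dinput
  }
  # order gradients to mirror model$params exactly (Adam walks by name)
  grads[names(model$params)]
}

#' Binary cross-entropy loss
#'
#' \eqn{L = -(y \log \hat y + (1-y) \log(1-\hat y))}, with the prediction
#' clamped to \code{[delta, 1 - delta]} so the loss stays finite at saturated
#' outputs. Vectorized; returns the mean over elements.
#'
#' @param y True labels in \{0, 1\}.
#' @param y_hat Predicted probabilities in (0, 1).
#' @param delta Clamping constant (default 1e-7).
#' @return Mean non-negative loss.
#' @export
bce_loss <- function(y, y_hat, delta = 1e-7) {
  y_hat <- pmin(pmax(y_hat, delta), 1 - delta)
  mean(-(y * log(y_hat) + (1 - y) * log(1 - y_hat)))
}

#' Gradient of the binary cross-entropy loss in the prediction
#'
#' @inheritParams bce_loss
#' @return Vector of d(loss)/d(y_hat) per element (not averaged).
#' @export
bce_loss_grad <- function(y, y_hat, delta = 1e-7) {
  y_hat <- pmin(pmax(y_hat, delta), 1 - delta)
  -(y / y_hat - (1 - y) / (1 - y_hat))
}

#' Predict classification scores for a set of networks
#'
#' @param object A trained \code{morphnet_cnn}.
#' @param networks List of \code{morph_network} objects, or a pre-flattened
#'   (input_size^2 x n) numeric matrix.
#' @param ... Unused.
#' @return Numeric vector of sigmoid scores in (0, 1), one per subject.
#' @export
predict.morphnet_cnn <- function(object, networks, ...) {
  X <- if (is.matrix(networks)) networks else networks_to_input(networks)
  cnn_forward(object, X, train = FALSE, keep_cache = FALSE)$prob
}

#' Stack networks into the CNN input matrix
#'
#' @param networks List of \code{morph_network} objects of equal size.
#' @return (side^2 x n) numeric matrix, one column per subject.
#' @export
networks_to_input <- function(networks) {
  vapply(
    networks, function(nw) as.numeric(nw$matrix),
    numeric(length(networks[[1]]$matrix))
  )
}

#' Fit the CNN on a training split with validation-based early stopping
#'
#' Minibatch Adam on binary cross-entropy. After every epoch the validation
#' loss (evaluation mode: batch-norm running statistics) is recorded; the
#' parameters with the best validation loss are restored at the end. All
#' randomness (shuffling) derives from \code{seed}.
#'
#' @param model An untrained or trained \code{morphnet_cnn} to start from.
#' @param X (input_size^2 x n) input matrix.
#' @param y Numeric 0/1 labels, length n (1 = ASD, the positive class).
#' @param idx_train,idx_val Integer column indices of the training and
#'   validation subjects; they must not overlap.
#' @param hyper A \code{hyperparameters} object.
#' @param seed Integer seed for minibatch shuffling.
#' @return The trained model with a \code{training_log} data.frame
#'   (epoch, train_loss, val_loss).
#' @export
fit_cnn <- function(model, X, y, idx_train, idx_val = integer(0),
                    hyper = hyperparameters(), seed = 1L) {
  stopifnot(inherits(model, "morphnet_cnn"), length(y) == ncol(X))
  if (length(intersect(idx_train, idx_val)) > 0) {
    stop("training and validation indices overlap")
  }
  if (!all(is.finite(X[, c(idx_train, idx_val)]))) {
    stop("non-finite values in the input matrices")
  }
  rng <- local_rng(derive_seed(seed, 977L))
  on.exit(restore_rng(rng))

  state <- adam_init(model$params)
  has_val <- length(idx_val) > 0
  best_val <- Inf
  best_params <- model$params
  wait <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))

  for (epoch in seq_len(hyper$max_epochs)) {
    order_idx <- idx_train[sample.int(length(idx_train))]
    batches <- split(order_idx, ceiling(seq_along(order_idx) / hyper$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      fwd <- cnn_forward(model, X[, b, drop = FALSE], train = TRUE)
      model <- fwd$model # batch-norm running stats updated in-pass
      loss <- bce_loss(y[b], fwd$prob)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d (lr too high or degenerate input)", epoch))
      }
      epoch_loss <- epoch_loss + loss * length(b)
      # d(mean BCE)/d(logit) for a sigmoid output: (p - y)/batch
      dlogit <- (fwd$prob - y[b]) / length(b)
      grads <- cnn_backward(model, fwd, dlogit)
      upd <- adam_step(model$params, grads, state, lr = hyper$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    train_loss <- epoch_loss / length(idx_train)
    val_loss <- NA_real_
    if (has_val) {
      val_prob <- cnn_forward(model, X[, idx_val, drop = FALSE],
        train = FALSE, keep_cache = FALSE
      )$prob
      val_loss <- bce_loss(y[idx_val], val_prob)
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_params <- model$params
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = train_loss, val_loss = val_loss))
    if (has_val && is.finite(hyper$early_stop_patience) && wait >= hyper$early_stop_patience) {
      break
    }
  }
  if (has_val) model$params <- best_params
  model$trained <- TRUE
  model$training_log <- log
  model
}
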