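#' Channel importance weights for a prediction (Grad-CAM)
#'
#' The gradient of the class score (the pre-sigmoid logit for the ASD class,
#' its negation for TC) is taken with respect to the post-activation feature
#' maps of the final convolutional stage, and spatially averaged: one weight
#' per channel. For this architecture the path from those activations to the
#' score is global average pooling followed by the linear head, so the
#' backward pass is exact.
#'
#' @param model A trained \code{morphnet_cnn}.
#' @param network A \code{morph_network} (or a single-column input matrix).
#' @param target_class 1 for ASD (default), 0 for TC.
#' @return Numeric vector of per-channel weights (length = final-stage
#'   channels).
#' @export
neuron_weights <- function(model, network, target_class = 1L) {
  fwd <- .gradcam_forward(model, network)
  .neuron_weights_from_fwd(model, fwd, target_class)
}

.gradcam_forward <- function(model, network) {
  X <- if (is.matrix(network)) network else networks_to_input(list(network))
  cnn_forward(model, X, train = FALSE, keep_cache = FALSE)
}

.neuron_weights_from_fwd <- function(model, fwd, target_class) {
  npix <- model$final_size^2
  # d(logit)/d(A[c, p]) = w_c / npix (GAP then linear head); the TC score is
  # the negated ASD logit under a single sigmoid output.
  sign <- if (target_class == 1L) 1 else -1
  sign * model$params$head$w / npix
}

# ReLU-rectified weighted combination of activation maps (the Grad-CAM
# localization map before upsampling). alpha: per-channel weights; A:
# (C x npix) activation matrix. Returns an (side x side) matrix.
gradcam_combine <- function(alpha, A, side) {
  stopifnot(length(alpha) == nrow(A), ncol(A) == side^2)
  map <- drop(crossprod(A, alpha))
  matrix(pmax(map, 0), side, side)
}

#' Bilinear upsampling of a square map
#'
#' Half-pixel-centered bilinear interpolation, the standard choice for
#' resizing class-activation maps to input resolution.
#'
#' @param m Square numeric matrix.
#' @param size Output side length.
#' @return \code{size x size} numeric matrix.
#' @export
upsample_bilinear <- function(m, size) {
  n <- nrow(m)
  if (n == size) {
    return(m)
  }
  scale <- n / size
  pos <- (seq_len(size) - 0.5) * scale - 0.5
  lo <- pmin(pmax(floor(pos), 0), n - 1)
  hi <- pmin(lo + 1, n - 1)
  w <- pmin(pmax(pos - lo, 0), 1)
  i_lo <- lo + 1
  i_hi <- hi + 1
  rows <- m[i_lo, , drop = FALSE] * (1 - w) + m[i_hi, , drop = FALSE] * w
  rows[, i_lo, drop = FALSE] * rep(1 - w, each = size) +
    rows[, i_hi, drop = FALSE] * rep(w, each = size)
}

#' Grad-CAM importance map for one subject
#'
#' Combines the final-stage activation maps with the channel importance
#' weights, rectifies, and bilinearly upsamples from the final stage's
#' spatial resolution to the input resolution (108 x 108 by default), giving
#' a non-negative importance weight for every connectivity cell.
#'
#' @inheritParams neuron_weights
#' @return An object of class \code{importance_map}: list with
#'   \code{matrix} (input_size x input_size, all entries >= 0),
#'   \code{raw} (the pre-upsample map), \code{source = "subject"}, and
#'   \code{subject_ids}.
#' @export
gradcam_map <- function(model, network, target_class = 1L) {
  fwd <- .gradcam_forward(model, network)
  alpha <- .neuron_weights_from_fwd(model, fwd, target_class)
  A <- matrix(fwd$activations[, 1], model$final_channels, model$final_size^2)
  raw <- gradcam_combine(alpha, A, model$final_size)
  up <- upsample_bilinear(raw, model$config$input_size)
  sid <- if (inherits(network, "morph_network")) network$subject_id else NA_character_
  structure(
    list(matrix = up, raw = raw, source = "subject", subject_ids = sid),
    class = "importance_map"
  )
}

#' @export
print.importance_map <- function(x, ...) {
  cat(sprintf(
    "<importance_map> %s, %d x %d, max weight %.4g (%d subject%s)\n",
    x$source, nrow(x$matrix), ncol(x$matrix), max(x$matrix),
    length(x$subject_ids), if (length(x$subject_ids) == 1) "" else "s"
  ))
  invisible(x)
}

#' Fuse importance maps and select supra-threshold connectivities
#'
#' Element-wise mean of the maps, symmetrized as \code{(M + t(M))/2} (edges
#' are unordered region pairs), then thresholded at mean + \code{k_sd} x SD
#' computed over the upper-triangle off-diagonal entries. Edges strictly
#' above the threshold are returned with their region labels.
#'
#' @param maps List of \code{importance_map} objects of identical shape.
#' @param k_sd Threshold multiplier (default 3, i.e. mean + 3SD).
#' @param region_labels Optional integer region labels for the matrix rows
#'   (defaults to 1..side).
#' @return An object of class \code{connectivity_selection}: list with
#'   \code{edges} (data.frame region_a, region_b, weight; region_a <
#'   region_b), \code{threshold}, \code{region_set}, \code{fused} (the
#'   symmetrized fused \code{importance_map}), and \code{n_maps}.
#' @export
fuse_and_select <- function(maps, k_sd = 3, region_labels = NULL) {
  if (length(maps) < 1) stop("need at least one importance map")
  mats <- lapply(maps, function(m) if (inherits(m, "importance_map")) m$matrix else m)
  side <- nrow(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == side), TRUE))) {
    stop("all maps must have identical shape")
  }
  fused <- Reduce(`+`, mats) / length(mats)
  fused <- (fused + t(fused)) / 2
  if (is.null(region_labels)) region_labels <- seq_len(side)

  ut <- upper.tri(fused, diag = FALSE)
  vals <- fused[ut]
  threshold <- mean(vals) + k_sd * stats::sd(vals)
  hit <- which(ut & fused > threshold, arr.ind = TRUE)
  edges <- data.frame(
    region_a = region_labels[hit[, 1]],
    region_b = region_labels[hit[, 2]],
    weight = fused[hit],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-edges$weight), , drop = FALSE]
  rownames(edges) <- NULL

  subject_ids <- unlist(lapply(maps, function(m) {
    if (inherits(m, "importance_map")) m$subject_ids else NA_character_
  }))
  structure(
    list(
      edges = edges, threshold = threshold,
      region_set = sort(unique(c(edges$region_a, edges$region_b))),
      fused = structure(
        list(
          matrix = fused, raw = NULL, source = "fused",
          subject_ids = subject_ids
        ),
        class = "importance_map"
      ),
      n_maps = length(maps), k_sd = k_sd
    ),
    class = "connectivity_selection"
  )
}

#' @export
print.connectivity_selection <- function(x, ...) {
  cat(sprintf(
    "<connectivity_selection> %d edge(s) over threshold %.4g (mean + %g SD) across %d region(s), fused from %d map(s)\n",
    nrow(x$edges), x$threshold, x$k_sd, length(x$region_set), x$n_maps
  ))
  invisible(x)
}

#' Grad-CAM maps for correctly classified ASD test subjects
#'
#' The fusion population of the reference protocol: held-out subjects whose
#' true label is ASD and whose prediction is correct. Maps are computed per
#' (repeat, fold) model on that model's own test subjects.
#'
#' @param cv_fit Result of \code{\link{train_cnn_cv}}.
#' @param networks The networks used for training, in plan subject order.
#' @param plan The \code{cv_plan} used.
#' @return List of \code{importance_map} objects (possibly empty when no ASD
#'   subject is correctly classified).
#' @export
gradcam_maps_correct_asd <- function(cv_fit, networks, plan) {
  ids <- vapply(networks, function(nw) nw$subject_id, "")
  maps <- list()
  fr <- cv_fit$fold_results
  model_keys <- unique(fr[, c("repeat_id", "fold")])
  for (k in seq_len(nrow(model_keys))) {
    model <- cv_fit$models[[k]]
    rows <- fr[fr$repeat_id == model_keys$repeat_id[k] & fr$fold == model_keys$fold[k], ]
    hits <- rows[rows$label == 1 & rows$pred == 1, ]
    for (sid in hits$subject_id) {
      nw <- networks[[match(sid, ids)]]
      maps[[length(maps) + 1L]] <- gradcam_map(model, nw, target_class = 1L)
    }
  }
  maps
}

#' Write a fused importance map and edge selection to disk
#'
#' @param selection A \code{connectivity_selection}.
#' @param dir Output directory.
#' @param label_names Optional named character vector mapping region labels
#'   to names (as in a \code{parcellation_atlas}).
#' @return \code{dir}, invisibly.
#' @export
write_selection <- function(selection, dir, label_names = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    selection$fused$matrix, file.path(dir, "fused_gradcam.tsv"),
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  edges <- selection$edges
  if (!is.null(label_names)) {
    edges$name_a <- unname(label_names[as.character(edges$region_a)])
    edges$name_b <- unname(label_names[as.character(edges$region_b)])
  }
  utils::write.csv(edges, file.path(dir, "selected_edges.csv"), row.names = FALSE)
  invisible(dir)
}
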