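softmax_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

# loss and gradient at the logits for one scene
seg_loss_grad <- function(logits, truth, loss = "combined", jaccard_weight = 1) {
  d <- dim(logits)
  K <- d[3]
  N <- d[1] * d[2]
  lm <- matrix(logits, N, K)
  p <- softmax_rows(lm)
  yi <- as.vector(truth) + 1L
  Y <- matrix(0, N, K)
  Y[cbind(seq_len(N), yi)] <- 1
  ce <- -mean(log(pmax(p[cbind(seq_len(N), yi)], 1e-12)))
  # soft Jaccard over classes present in the truth
  present <- which(colSums(Y) > 0)
  I <- colSums(p * Y)
  U <- colSums(p) + colSums(Y) - I
  iou_soft <- I[present] / U[present]
  jl <- 1 - mean(iou_soft)
  g_ce <- (p - Y) / N
  g_j <- matrix(0, N, K)
  m <- length(present)
  for (c in present) {
    g_j[, c] <- -(Y[, c] * U[c] - I[c] * (1 - Y[, c])) / (U[c]^2) / m
  }
  # soft Jaccard gradient through the softmax
  gj_logits <- p * (g_j - rowSums(g_j * p))
  loss_val <- switch(loss,
    cross_entropy = ce,
    jaccard = jl,
    combined = ce + jaccard_weight * jl)
  d_logits <- switch(loss,
    cross_entropy = g_ce,
    jaccard = gj_logits,
    combined = g_ce + jaccard_weight * gj_logits)
  pred <- max.col(p, ties.method = "first") - 1L
  list(loss = loss_val, ce = ce, jaccard_loss = jl,
       d_logits = array(d_logits, d),
       pred = matrix(pred, d[1], d[2]), probs = p)
}

adam_init <- function(params) {
  lapply(params, function(pp) list(mW = pp$W * 0, vW = pp$W * 0,
                                   mb = pp$b * 0, vb = pp$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

prepare_scene_input <- function(cube, mask, spec, norm = NULL) {
  x <- if (inherits(cube, "reflectance_cube")) cube$data else cube
  if (dim(x)[3] != spec$in_channels) {
    stop("channel mismatch: cube has ", dim(x)[3], " bands but the model expects ",
         spec$in_channels)
  }
  if (!is.null(norm)) {
    x <- sweep(sweep(x, 3, norm$mean, "-"), 3, norm$sd, "/")
  }
  mult <- 2^spec$depth
  H2 <- ceiling(dim(x)[1] / mult) * mult
  W2 <- ceiling(dim(x)[2] / mult) * mult
  orig <- dim(x)[1:2]
  if (H2 != dim(x)[1] || W2 != dim(x)[2]) {
    x <- pad_reflect(x, H2, W2)
    if (!is.null(mask)) mask <- pad_reflect(mask, H2, W2)
  }
  list(x = x, mask = mask, orig = orig)
}

#' Train a U-Net on annotated scenes
#'
#' Full-scene gradient training with Adam: each epoch visits every training
#' scene in a seeded shuffled order and takes one optimizer step per scene.
#' Input bands are standardized per channel with statistics computed over
#' the training scenes and stored in the model, so prediction applies the
#' identical transform.
#' The history records, per epoch, the mean training loss, the Jaccard loss
#' (1 - mean soft IoU) and the hard mean IoU of the training predictions.
#' With a fixed seed the run is reproducible on a single-threaded BLAS.
#'
#' @param model A [build_unet()] model.
#' @param cubes List of training cubes ([reflectance_cube()] or 3D arrays),
#'   already restricted to the selected band subset.
#' @param masks List of integer label matrices (0 = background, 1..K
#'   classes), aligned with `cubes`.
#' @param config A [training_config()].
#' @return List with `model` (trained) and `history` (data frame with
#'   `epoch`, `loss`, `jaccard_loss`, `mean_iou`).
#' @export
train_unet <- function(model, cubes, masks, config = training_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "training_config"))
  stopifnot(length(cubes) >= 1, length(cubes) == length(masks))
  spec <- model$spec
  # per-channel standardization over the training scenes, stored with the
  # model so prediction applies the identical transform
  ch_stats <- function(f) {
    vapply(seq_len(spec$in_channels), function(k) {
      f(unlist(lapply(cubes, function(cb) {
        x <- if (inherits(cb, "reflectance_cube")) cb$data else cb
        as.vector(x[, , k])
      })))
    }, numeric(1))
  }
  norm <- list(mean = ch_stats(mean), sd = pmax(ch_stats(stats::sd), 1e-8))
  model$input_norm <- norm
  prep <- mapply(prepare_scene_input, cubes, masks,
                 MoreArgs = list(spec = spec, norm = norm), SIMPLIFY = FALSE)
  for (pm in prep) {
    if (max(pm$mask) >= spec$n_classes) {
      stop("mask contains label ", max(pm$mask), " but the model has ",
           spec$n_classes, " classes (including background)")
    }
  }
  if (inherits(cubes[[1]], "reflectance_cube")) {
    model$band_wavelengths <- cubes[[1]]$wavelengths
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        jaccard_loss = numeric(0), mean_iou = numeric(0))
  t <- 0
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(prep))
    losses <- numeric(0); jls <- numeric(0); ious <- numeric(0)
    for (si in ord) {
      sc <- prep[[si]]
      fw <- unet_forward(model, sc$x)
      lg <- seg_loss_grad(fw$logits, sc$mask, config$loss, config$jaccard_weight)
      if (!is.finite(lg$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      t <- t + 1
      grads <- unet_backward(model, fw$cache, lg$d_logits)
      upd <- adam_step(model$params, grads, state, config$learning_rate, t)
      model$params <- upd$params
      state <- upd$state
      losses <- c(losses, lg$loss)
      jls <- c(jls, lg$jaccard_loss)
      ev <- evaluate_segmentation(lg$pred, sc$mask)
      ious <- c(ious, ev$mean_iou)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = mean(losses), jaccard_loss = mean(jls),
      mean_iou = mean(ious)))
  }
  list(model = model, history = history)
}

#' Predict a tissue label map for a cube
#'
#' The cube must be restricted to the model's training band subset in the
#' same order (checked against the stored wavelengths when available);
#' non-divisible spatial sizes are reflection-padded and the prediction is
#' cropped back. Per-pixel class scores are softmax-normalized to a
#' probability simplex; labels are the argmax.
#'
#' @param model A trained [build_unet()] model.
#' @param cube A [reflectance_cube()] or 3D array with `in_channels` bands.
#' @return List with `labels` (integer matrix, 0 = background) and `probs`
#'   (rows x cols x classes array).
#' @export
predict_unet <- function(model, cube) {
  stopifnot(inherits(model, "unet_model"))
  if (inherits(cube, "reflectance_cube") && !is.null(model$band_wavelengths)) {
    if (!isTRUE(all.equal(cube$wavelengths, model$band_wavelengths))) {
      stop("band-order mismatch: cube wavelengths differ from the model's ",
           "training band subset")
    }
  }
  sc <- prepare_scene_input(cube, NULL, model$spec, model$input_norm)
  fw <- unet_forward(model, sc$x)
  d <- dim(fw$logits)
  p <- softmax_rows(matrix(fw$logits, d[1] * d[2], d[3]))
  labels <- matrix(max.col(p, ties.method = "first") - 1L, d[1], d[2])
  probs <- array(p, d)
  labels <- labels[seq_len(sc$orig[1]), seq_len(sc$orig[2]), drop = FALSE]
  probs <- probs[seq_len(sc$orig[1]), seq_len(sc$orig[2]), , drop = FALSE]
  list(labels = labels, probs = probs)
}

#' Jaccard index (IoU) between predicted and true masks
#'
#' IoU = |pred intersect truth| / |pred union truth| for a class. Classes
#' with an empty union are excluded from per-class reporting (`NA` when
#' requested explicitly).
#'
#' @param pred,truth Integer label matrices of the same shape.
#' @param class_id A single class label, or `NULL` for a named vector over
#'   every class present in either mask.
#' @return IoU score(s) in \[0, 1\].
#' @export
jaccard_iou <- function(pred, truth, class_id = NULL) {
  if (!all(dim(pred) == dim(truth))) stop("mask shape mismatch")
  one <- function(cl) {
    pi <- pred == cl; ti <- truth == cl
    u <- sum(pi | ti)
    if (u == 0) return(NA_real_)
    sum(pi & ti) / u
  }
  if (!is.null(class_id)) return(one(class_id))
  classes <- sort(unique(c(as.vector(pred), as.vector(truth))))
  out <- vapply(classes, one, numeric(1))
  names(out) <- classes
  out
}

#' Evaluate a predicted segmentation against ground truth
#'
#' @param pred Predicted integer label matrix.
#' @param truth Ground-truth label matrix of the same shape.
#' @return Object of class `segmentation_result`: `label_map`,
#'   `per_class_iou` (classes with empty union excluded), `mean_iou`,
#'   `jaccard_loss` (1 - mean IoU) and `pixel_accuracy`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shape mismatch")
  per <- jaccard_iou(pred, truth)
  per <- per[!is.na(per)]
  mean_iou <- if (length(per) > 0) mean(per) else NA_real_
  structure(list(label_map = pred, per_class_iou = per, mean_iou = mean_iou,
                 jaccard_loss = 1 - mean_iou,
                 pixel_accuracy = mean(pred == truth)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: pixel accuracy %.2f%%, mean IoU %.3f\n",
              100 * x$pixel_accuracy, x$mean_iou))
  invisible(x)
}

#' Default tissue display palette
#'
#' Red for intact ICA, blue for peeled ICA, orange for distal FN, green for
#' proximal FN; background is dark gray.
#'
#' @return Named vector of hex colors, one per class label (plus background).
#' @export
default_palette <- function() {
  c(BACKGROUND = "#303030", ICA_NORMAL = "#FF0000", ICA_PEELED = "#0000FF",
    FN_PROXIMAL = "#00A000", FN_DISTAL = "#FF8C00")
}

#' Render a label map as a class-colored border overlay
#'
#' Draws class-colored region borders (pixels whose label differs from a
#' 4-neighbor) over a grayscale base image, mirroring how automatic
#' segmentation results are displayed over a single-band view.
#'
#' @param labels Integer label matrix (0 = background).
#' @param palette Named colors; position k + 1 colors class k.
#' @param base Optional grayscale base matrix in \[0, 1\] (defaults to 0.5).
#' @return RGB array (rows x cols x 3) in \[0, 1\].
#' @export
render_overlay <- function(labels, palette = default_palette(), base = NULL) {
  h <- nrow(labels); w <- ncol(labels)
  if (is.null(base)) base <- matrix(0.5, h, w)
  img <- array(rep(pmin(1, pmax(0, base)), 3), c(h, w, 3))
  differs <- matrix(FALSE, h, w)
  differs[-1, ] <- differs[-1, ] | (labels[-1, ] != labels[-h, ])
  differs[-h, ] <- differs[-h, ] | (labels[-h, ] != labels[-1, ])
  differs[, -1] <- differs[, -1] | (labels[, -1] != labels[, -w])
  differs[, -w] <- differs[, -w] | (labels[, -w] != labels[, -1])
  rgb <- grDevices::col2rgb(palette) / 255
  for (cl in sort(unique(labels[differs]))) {
    if (cl == 0) next
    sel <- differs & labels == cl
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- rgb[ch, cl + 1]
      img[, , ch] <- plane
    }
  }
  img
}
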