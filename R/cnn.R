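# Markerless pose-delta regression: a compact convolutional network that
# maps four stacked camera views (two cameras x two timepoints) to the
# 6-DOF inter-frame pose change.

#' Network configuration
#'
#' The fixed three-block architecture: blocks of increasing depth
#' (4, 16, 64), each with two 3x3 stride-1 pad-1 convolutions with ReLU,
#' a 20% dropout layer, and a 2x2 stride-2 max-pool; input is the
#' 4-channel 180 x 120 image stack, which three pool stages reduce to
#' 22 x 15 (integer floor), flattened (21120 features) into a 128-unit
#' ReLU layer and a 6-unit linear output. The compiled engine implements
#' exactly this shape; the configuration object records it and validates
#' requested deviations.
#'
#' @param depths conv block depths.
#' @param fc hidden width of the fully-connected head.
#' @param dropout per-block dropout rate.
#' @return object of class \code{hpnet_config}.
#' @export
hpnet_config <- function(depths = c(4, 16, 64), fc = 128, dropout = 0.2) {
  if (!identical(as.numeric(depths), c(4, 16, 64)) || fc != 128)
    stop("hpnet_config: the compiled engine implements depths (4,16,64) with a 128-unit head")
  stopifnot(dropout >= 0, dropout < 1)
  structure(list(depths = depths, kernel = c(3, 3), stride = 1, pad = 1,
                 pool = c(2, 2), fc = fc, dropout = dropout,
                 input = c(120, 180, 4), output = 6),
            class = "hpnet_config")
}

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param weight_decay L2 regularisation coefficient.
#' @param epochs training epochs.
#' @param batch minibatch size.
#' @param split dataset split \code{c(train, val, test)}; must sum to the
#'   dataset size at training time.
#' @param seed seed for initialisation, shuffling and dropout.
#' @return object of class \code{hpnet_train_config}.
#' @export
hpnet_train_config <- function(lr = 1e-4, weight_decay = 1e-5, epochs = 100,
                               batch = 32, split = c(1400, 400, 200),
                               seed = 1) {
  stopifnot(lr > 0, weight_decay >= 0, epochs >= 1, batch >= 1,
            length(split) == 3, all(split > 0))
  structure(list(lr = lr, weight_decay = weight_decay, epochs = epochs,
                 batch = batch, split = split, seed = seed),
            class = "hpnet_train_config")
}

#' Min-max label scaler
#'
#' Learns per-DOF minimum and maximum from the training + validation
#' labels only (test isolation) and maps each DOF to \[0, 1\]. The saved
#' mapping is applied at inference time and inverted exactly; test
#' labels transformed with it may fall outside \[0, 1\].
#'
#' @param labels n x 6 matrix of unscaled pose deltas (train+val only).
#' @return object of class \code{label_scaler}.
#' @export
label_scaler <- function(labels) {
  labels <- as.matrix(labels)
  stopifnot(ncol(labels) == 6)
  mn <- apply(labels, 2, min); mx <- apply(labels, 2, max)
  if (any(mx <= mn))
    stop("label_scaler: degenerate DOF (max = min)")
  structure(list(min = mn, max = mx), class = "label_scaler")
}

#' @rdname label_scaler
#' @param scaler a \code{label_scaler}.
#' @export
scale_labels <- function(labels, scaler) {
  sweep(sweep(as.matrix(labels), 2, scaler$min), 2,
        scaler$max - scaler$min, "/")
}

#' @rdname label_scaler
#' @param outputs scaled network outputs (n x 6).
#' @export
unscale_predictions <- function(outputs, scaler) {
  sweep(sweep(as.matrix(outputs), 2, scaler$max - scaler$min, "*"), 2,
        -scaler$min)
}

#' Bilinear image resize
#'
#' @param img numeric matrix.
#' @param width,height output size.
#' @return resized matrix.
#' @export
resize_bilinear <- function(img, width, height) {
  H <- nrow(img); W <- ncol(img)
  rs <- (seq_len(height) - 0.5) * H / height + 0.5
  cs <- (seq_len(width) - 0.5) * W / width + 0.5
  g <- expand.grid(r = rs, c = cs)
  matrix(.bilinear_sample(img, g$r, g$c, fill = 0), nrow = height)
}

#' Build a 4-channel input stack from two stereo frame pairs
#'
#' Pre-processing of the network inputs: each grayscale frame is scaled
#' from \[0, 255\] to \[0, 1\], resized to 180 x 120 (bilinear) and the
#' four frames stacked in the fixed channel order camera 1 at t0,
#' camera 2 at t0, camera 1 at t1, camera 2 at t1. No augmentation is
#' applied (geometric augmentation would corrupt the fine pose signal).
#'
#' @param cam1_t0,cam2_t0,cam1_t1,cam2_t1 [new_frame()]s of equal size.
#' @return 120 x 180 x 4 numeric array.
#' @export
preprocess_inputs <- function(cam1_t0, cam2_t0, cam1_t1, cam2_t1) {
  frames <- list(cam1_t0, cam2_t0, cam1_t1, cam2_t1)
  dims <- vapply(frames, function(f) c(f$height, f$width), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("preprocess_inputs: frames must share one resolution")
  out <- array(0, c(120, 180, 4))
  for (k in 1:4)
    out[, , k] <- resize_bilinear(frames[[k]]$pixels / 255, 180, 120)
  out
}

#' Train the pose-delta network
#'
#' Trains the fixed architecture with Adam (learning rate 1e-4, weight
#' decay 1e-5 by default), mean-squared-error loss on min-max scaled
#' labels, Kaiming initialisation and per-epoch shuffling of the
#' training set -- all seeded, so two runs with identical inputs and
#' seeds produce identical loss curves. Validation loss is computed each
#' epoch without gradient updates.
#'
#' @param x input stacks: a 120 x 180 x 4 x n array, or an
#'   \code{hp_dataset} from [build_hp_dataset()] (whose samples live in
#'   a compact single-precision store).
#' @param labels n x 6 unscaled pose deltas.
#' @param train_idx,val_idx sample indices.
#' @param config a [hpnet_config()].
#' @param train a [hpnet_train_config()].
#' @param scaler a [label_scaler()]; fitted on the train+val labels when
#'   NULL.
#' @return object of class \code{hpnet}: weights, configs, the saved
#'   scaler and the per-epoch loss history.
#' @export
hpnet_train <- function(x, labels, train_idx, val_idx,
                        config = hpnet_config(),
                        train = hpnet_train_config(), scaler = NULL) {
  n <- if (inherits(x, "hp_dataset")) x$n else dim(x)[4]
  stopifnot(nrow(labels) == n)
  if (length(train_idx) == 0 || length(val_idx) == 0)
    stop("hpnet_train: empty split")
  if (is.null(scaler))
    scaler <- label_scaler(labels[c(train_idx, val_idx), , drop = FALSE])
  y <- scale_labels(labels, scaler)
  if (inherits(x, "hp_dataset")) {
    res <- .hp_cnn_train_ptr(x$store, y, as.integer(train_idx),
                             as.integer(val_idx), as.integer(train$epochs),
                             as.integer(train$batch), train$lr,
                             train$weight_decay, config$dropout,
                             as.integer(train$seed))
  } else {
    res <- .hp_cnn_train(x, y, as.integer(train_idx), as.integer(val_idx),
                         as.integer(train$epochs), as.integer(train$batch),
                         train$lr, train$weight_decay, config$dropout,
                         as.integer(train$seed))
  }
  structure(list(weights = res$weights, config = config,
                 train_config = train, scaler = scaler,
                 train_loss = res$train_loss, val_loss = res$val_loss),
            class = "hpnet")
}

#' @export
print.hpnet <- function(x, ...) {
  e <- length(x$train_loss)
  cat(sprintf(paste0("hpnet pose-delta regressor: blocks (4,16,64), ",
                     "%d epochs trained\n  final loss train %.4g / val %.4g",
                     " (scaled units)\n"),
              e, x$train_loss[e], x$val_loss[e]))
  invisible(x)
}

#' Predict pose deltas
#'
#' Forward pass in evaluation mode (no dropout). Outputs are unscaled
#' through the model's saved label scaler by default, returning mm /
#' degrees.
#'
#' @param object a trained [hpnet_train()] model.
#' @param x 120 x 180 x 4 x n input array or an \code{hp_dataset}.
#' @param unscale return unscaled (mm/deg) predictions.
#' @param batch evaluation batch size.
#' @param idx sample indices when \code{x} is an \code{hp_dataset}.
#' @param ... unused.
#' @return n x 6 matrix of predicted deltas.
#' @export
predict.hpnet <- function(object, x, unscale = TRUE, batch = 64,
                          idx = NULL, ...) {
  if (inherits(x, "hp_dataset")) {
    if (is.null(idx)) idx <- seq_len(x$n)
    p <- .hp_cnn_predict_ptr(object$weights, x$store, as.integer(idx),
                             as.integer(batch))
  } else {
    if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
    p <- .hp_cnn_predict(object$weights, x, as.integer(batch))
  }
  colnames(p) <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
  if (unscale) unscale_predictions(p, object$scaler) else p
}

#' Evaluate per-DOF RMSE of a trained model
#'
#' Compares unscaled predictions with unscaled true deltas and reports
#' the root-mean-squared error per DOF plus their unweighted mean (the
#' "average" figure of merit, in mm / degrees).
#'
#' @param model a trained \code{hpnet}.
#' @param x test input stacks (array or \code{hp_dataset}).
#' @param labels n x 6 true unscaled deltas.
#' @param idx sample indices when \code{x} is an \code{hp_dataset}.
#' @return list with \code{per_dof} (named, 6) and \code{average}.
#' @export
evaluate_hpnet <- function(model, x, labels, idx = NULL) {
  n <- if (inherits(x, "hp_dataset")) {
    if (is.null(idx)) x$n else length(idx)
  } else if (is.null(dim(x))) 0 else dim(x)[4]
  if (n == 0 || nrow(labels) == 0)
    stop("evaluate_hpnet: empty test set")
  if (nrow(labels) != n)
    stop("evaluate_hpnet: labels do not match the test set size")
  pred <- predict(model, x, idx = idx)
  err <- pred - as.matrix(labels)
  per <- sqrt(colMeans(err^2))
  names(per) <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
  list(per_dof = per, average = mean(per))
}

#' Split-distribution diagnostic
#'
#' Summarises each DOF's label distribution (mean, median, sd, min, max)
#' per dataset split -- the consistency check reported alongside
#' training, not a gate.
#'
#' @param labels n x 6 label matrix.
#' @param split list with \code{train}, \code{val}, \code{test} index
#'   vectors.
#' @return data.frame with one row per (set, DOF).
#' @export
split_summary <- function(labels, split) {
  labels <- as.matrix(labels)
  dof <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
  do.call(rbind, lapply(names(split), function(s) {
    L <- labels[split[[s]], , drop = FALSE]
    data.frame(set = s, dof = dof,
               mean = colMeans(L), median = apply(L, 2, median),
               sd = apply(L, 2, sd), min = apply(L, 2, min),
               max = apply(L, 2, max), row.names = NULL)
  }))
}
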