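#' Training configuration
#'
#' Optimizer, loss and schedule settings for [dr_cct()]. Defaults follow
#' the final model's training recipe: Adam with learning rate 0.001 and
#' decoupled weight decay 0.001, batch size 256, categorical cross-entropy,
#' and a stratified 70/20/10 train/validation/test split.
#'
#' @param optimizer One of `adam`, `nadam`, `sgd`, `adamax`, `rmsprop`.
#' @param learning_rate Step size (default 0.001).
#' @param weight_decay Decoupled weight-decay coefficient (default 0.001).
#' @param batch_size Minibatch size (default 256).
#' @param epochs Number of passes over the training data (default 200).
#' @param loss One of `categorical_ce`, `binary_ce`, `mse`, `mae`, `msle`.
#' @param split_fractions Named or positional `(train, val, test)`
#'   fractions summing to 1.
#' @param rng_seed Seed controlling data order, dropout, stochastic depth
#'   and splitting.
#' @return An object of class `train_control`.
#' @export
train_control <- function(optimizer = c("adam", "nadam", "sgd", "adamax", "rmsprop"),
                          learning_rate = 0.001, weight_decay = 0.001,
                          batch_size = 256, epochs = 200,
                          loss = c("categorical_ce", "binary_ce", "mse", "mae", "msle"),
                          split_fractions = c(train = 0.7, val = 0.2, test = 0.1),
                          rng_seed = 1) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  stopifnot(batch_size >= 1, epochs >= 0, learning_rate >= 0,
            abs(sum(split_fractions) - 1) < 1e-8)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 split_fractions = split_fractions,
                 rng_seed = as.integer(rng_seed)),
            class = "train_control")
}

# inverse of unlist() for a nested list of numeric arrays: refill the
# skeleton's leaves (with their dim attributes) from one flat vector
relist_params <- function(flesh, skeleton) {
  i <- 0L
  fill <- function(sk) {
    if (is.list(sk)) return(lapply(sk, fill))
    v <- flesh[(i + 1L):(i + length(sk))]
    i <<- i + length(sk)
    attributes(v) <- attributes(sk)
    v
  }
  fill(skeleton)
}

# reorder a gradient tree to match the weight tree so both unlist identically
align_tree <- function(g, w) {
  if (!is.list(w)) return(g)
  nm <- names(w)
  if (!is.null(nm) && all(nzchar(nm))) g <- g[nm]
  out <- Map(align_tree, g, w)
  names(out) <- nm
  out
}

# Adam-family steppers with the conventional moment decays
make_optimizer <- function(kind, lr, n, beta1 = 0.9, beta2 = 0.999) {
  eps <- 1e-7
  state <- new.env(parent = emptyenv())
  state$t <- 0
  state$m <- numeric(n); state$v <- numeric(n)
  function(g) {
    state$t <- state$t + 1
    t <- state$t
    switch(kind,
      sgd = lr * g,
      rmsprop = {
        state$v <- 0.9 * state$v + 0.1 * g^2
        lr * g / (sqrt(state$v) + eps)
      },
      adam = {
        state$m <- beta1 * state$m + (1 - beta1) * g
        state$v <- beta2 * state$v + (1 - beta2) * g^2
        mhat <- state$m / (1 - beta1^t)
        vhat <- state$v / (1 - beta2^t)
        lr * mhat / (sqrt(vhat) + eps)
      },
      nadam = {
        state$m <- beta1 * state$m + (1 - beta1) * g
        state$v <- beta2 * state$v + (1 - beta2) * g^2
        mhat <- state$m / (1 - beta1^(t + 1))
        vhat <- state$v / (1 - beta2^t)
        lr * (beta1 * mhat + (1 - beta1) * g / (1 - beta1^t)) /
          (sqrt(vhat) + eps)
      },
      adamax = {
        state$m <- beta1 * state$m + (1 - beta1) * g
        state$v <- pmax(beta2 * state$v, abs(g))
        lr * (state$m / (1 - beta1^t)) / (state$v + eps)
      }
    )
  }
}

onehot <- function(y, C) {
  Y <- matrix(0, length(y), C)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

#' Fit a compact convolutional transformer grade classifier
#'
#' Trains the configured model on a set of fundus images with grade labels
#' 0-4 by minimizing the configured loss with the configured optimizer and
#' decoupled weight decay. Fully seeded: initialization, data order,
#' dropout and stochastic depth all derive from the model seed and
#' `control$rng_seed`. Images that do not match the model input size are
#' resized bilinearly.
#'
#' @param x Training images: a list of raster images or an `(H, W, 3, B)`
#'   array with intensities in \[0, 255\].
#' @param y Integer grade labels in `0..4` (or a factor with those levels).
#' @param model A [cct_config()].
#' @param control A [train_control()].
#' @param validation Optional `list(x, y)` evaluated (in eval mode) after
#'   every epoch.
#' @param verbose Print per-epoch progress.
#' @return An object of class `dr_cct` with components `weights`, `config`,
#'   `control`, `history` (per-epoch data frame), `n_params`, `classes`.
#' @export
dr_cct <- function(x, y, model = cct_config(), control = train_control(),
                   validation = NULL, verbose = FALSE) {
  xb <- prep_model_input(x, model)
  y <- as_grade(y, model$num_classes)
  B <- dim(xb)[4]
  if (length(y) != B) stop("x and y lengths differ", call. = FALSE)
  if (B == 0L) stop("empty training set", call. = FALSE)
  Y <- onehot(y, model$num_classes)

  weights <- cct_init(model)
  theta <- unlist(weights, use.names = FALSE)
  skeleton <- unclass(weights)
  opt <- make_optimizer(control$optimizer, control$learning_rate, length(theta))
  hist <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0))
  val <- if (!is.null(validation))
    list(x = prep_model_input(validation$x, model),
         y = as_grade(validation$y, model$num_classes)) else NULL

  with_seed(control$rng_seed, {
    for (epoch in seq_len(control$epochs)) {
      ord <- sample.int(B)
      ep_loss <- 0; ep_acc <- 0; seen <- 0
      for (start in seq(1, B, by = control$batch_size)) {
        idx <- ord[start:min(start + control$batch_size - 1L, B)]
        weights <- relist_params(theta, skeleton)
        class(weights) <- "cct_weights"
        gs <- cct_grad_step(xb[, , , idx, drop = FALSE],
                            Y[idx, , drop = FALSE], weights, model,
                            control$loss, train = TRUE)
        gvec <- unlist(align_tree(gs$grad, skeleton), use.names = FALSE)
        theta <- theta - opt(gvec) -
          control$learning_rate * control$weight_decay * theta
        ep_loss <- ep_loss + gs$loss * length(idx)
        ep_acc <- ep_acc + gs$acc * length(idx)
        seen <- seen + length(idx)
      }
      vl <- NA_real_; va <- NA_real_
      if (!is.null(val)) {
        weights <- relist_params(theta, skeleton)
        class(weights) <- "cct_weights"
        pv <- predict_probs(weights, model, val$x)
        ld <- loss_and_dlogits(pv, onehot(val$y, model$num_classes), control$loss)
        vl <- ld$loss
        va <- mean(max.col(pv, ties.method = "first") - 1L == val$y)
      }
      hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss / seen,
                                     acc = ep_acc / seen,
                                     val_loss = vl, val_acc = va))
      if (verbose)
        cat(sprintf("epoch %3d  loss %.4f  acc %.4f%s\n", epoch,
                    ep_loss / seen, ep_acc / seen,
                    if (is.na(va)) "" else sprintf("  val_acc %.4f", va)))
    }
  })
  weights <- relist_params(theta, skeleton)
  class(weights) <- "cct_weights"
  structure(list(weights = weights, config = model, control = control,
                 history = hist, n_params = count_parameters(model),
                 classes = 0:(model$num_classes - 1L), call = match.call()),
            class = "dr_cct")
}

prep_model_input <- function(x, model) {
  if (is.list(x))
    x <- simplify2array(lapply(x, function(im) {
      im <- as_raster(im)
      if (dim(im)[1] != model$image_size || dim(im)[2] != model$image_size)
        im <- raster_resize(im, model$image_size, model$image_size)
      im
    }))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x / 255
}

as_grade <- function(y, C) {
  if (is.factor(y)) y <- as.integer(as.character(y))
  y <- as.integer(y)
  if (anyNA(y) || any(y < 0L | y >= C))
    stop("labels must lie in 0..", C - 1L, call. = FALSE)
  y
}

predict_probs <- function(weights, model, xb, batch_size = 128L) {
  B <- dim(xb)[4]
  out <- matrix(0, B, model$num_classes)
  for (start in seq(1, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B)
    out[idx, ] <- cct_fwd_full(xb[, , , idx, drop = FALSE], weights, model,
                               train = FALSE, want_cache = FALSE)$probs
  }
  out
}

#' @export
print.dr_cct <- function(x, ...) {
  cat("Compact convolutional transformer DR grade classifier\n")
  cat(sprintf("  %s trainable parameters; input %dx%dx3; %d classes\n",
              format(x$n_params, big.mark = ","), x$config$image_size,
              x$config$image_size, x$config$num_classes))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epoch(s) [%s, lr %g]; final train loss %.4f, accuracy %.4f\n",
                nrow(x$history), x$control$optimizer,
                x$control$learning_rate, last$loss, last$acc))
    if (!is.na(last$val_acc))
      cat(sprintf("  validation accuracy %.4f\n", last$val_acc))
  }
  invisible(x)
}

#' @export
summary.dr_cct <- function(object, ...) {
  print(object)
  cat("\nConfiguration:\n")
  print(object$config)
  if (nrow(object$history)) {
    cat("\nLast epochs:\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.dr_cct <- function(object, ...) object$weights

#' Predict grades or class probabilities
#'
#' @param object A fitted [dr_cct()] model.
#' @param newdata Images (list or `(H, W, 3, B)` array, 0-255).
#' @param type `"class"` for integer grades, `"prob"` for the probability
#'   matrix.
#' @param batch_size Evaluation chunk size.
#' @param ... Unused.
#' @return Integer grades or a `B x 5` probability matrix.
#' @export
predict.dr_cct <- function(object, newdata, type = c("class", "prob"),
                           batch_size = 128, ...) {
  type <- match.arg(type)
  xb <- prep_model_input(newdata, object$config)
  p <- predict_probs(object$weights, object$config, xb, as.integer(batch_size))
  if (type == "prob") return(p)
  max.col(p, ties.method = "first") - 1L
}

#' @export
plot.dr_cct <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("model has no training history", call. = FALSE)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
                 main = "Loss", ...)
  if (!all(is.na(h$val_loss))) graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::plot(h$epoch, h$acc, type = "l", xlab = "epoch",
                 ylab = "accuracy", ylim = c(0, 1), main = "Accuracy", ...)
  if (!all(is.na(h$val_acc))) graphics::lines(h$epoch, h$val_acc, lty = 2)
  invisible(x)
}

#' Stratified train/validation/test split
#'
#' Partitions every grade independently into the configured fractions
#' (default 70/20/10) using largest-remainder rounding, so per-class counts
#' are within one entry of the exact fractions. Reproducible given the
#' seed. Grades with fewer than three members trigger a warning and go to
#' the training split.
#'
#' @param manifest A [dr_manifest()] with unassigned splits.
#' @param cfg A [train_control()] providing `split_fractions` and
#'   `rng_seed`.
#' @return The manifest with the `split` column filled in.
#' @export
split_manifest <- function(manifest, cfg = train_control()) {
  f <- cfg$split_fractions
  splits <- c("train", "val", "test")
  out <- manifest
  with_seed(cfg$rng_seed, {
    for (g in 0:4) {
      idx <- which(manifest$grade == g)
      n <- length(idx)
      if (n == 0L) next
      if (n < 3L) {
        warning("grade ", g, " has fewer than 3 members; assigned to train")
        out$split[idx] <- "train"
        next
      }
      base <- floor(n * f)
      rem <- n - sum(base)
      frac <- n * f - base
      extra <- order(-frac, seq_along(f))[seq_len(rem)]
      counts <- base
      counts[extra] <- counts[extra] + 1L
      idx <- sample(idx)
      assign_to <- rep(splits, counts)
      out$split[idx] <- assign_to
    }
  })
  out
}

#' Train from a manifest and report test performance
#'
#' Convenience wrapper tying the pieces together: splits the manifest
#' (unless already split), fits [dr_cct()] on the training entries with the
#' validation entries monitored per epoch, and evaluates the held-out test
#' entries into a confusion matrix and ten-metric report.
#'
#' @param manifest A [dr_manifest()].
#' @param images Named list of raster images keyed by `manifest$image_ref`.
#' @param model A [cct_config()].
#' @param control A [train_control()].
#' @param verbose Print progress.
#' @return A list with `fit` (the `dr_cct` object), `manifest` (with
#'   splits), `confusion` (test confusion matrix) and `metrics` (test
#'   [metric_report()]).
#' @export
train_cct <- function(manifest, images, model = cct_config(),
                      control = train_control(), verbose = FALSE) {
  if (all(manifest$split == "unassigned"))
    manifest <- split_manifest(manifest, control)
  pick <- function(s) manifest$image_ref[manifest$split == s]
  tr <- pick("train"); va <- pick("val"); te <- pick("test")
  if (!length(tr)) stop("empty training split", call. = FALSE)
  grade_of <- function(refs) manifest$grade[match(refs, manifest$image_ref)]
  fit <- dr_cct(images[tr], grade_of(tr), model, control,
                validation = if (length(va)) list(x = images[va], y = grade_of(va)),
                verbose = verbose)
  confusion <- NULL; metrics <- NULL
  if (length(te)) {
    pred <- predict(fit, images[te])
    confusion <- confusion_matrix(grade_of(te), pred,
                                  labels = 0:(model$num_classes - 1L))
    metrics <- metric_report(confusion)
  }
  list(fit = fit, manifest = manifest, confusion = confusion, metrics = metrics)
}

#' Image-reduction robustness protocol
#'
#' Measures how test accuracy degrades as the training pool shrinks: for
#' each requested fraction the training entries are subsampled uniformly
#' (a fresh seeded draw per repeat), the model is retrained from scratch,
#' and accuracy is measured on the fixed test split. Reported per fraction
#' are the mean accuracy over repeats and the max-minus-mean spread.
#'
#' @param manifest A [dr_manifest()] (split applied if unassigned).
#' @param images Named list of raster images.
#' @param model A [cct_config()].
#' @param control A [train_control()].
#' @param fractions Training-pool fractions, default
#'   `c(1, 0.75, 0.5, 0.25)`.
#' @param repeats Repeats per fraction (default 3).
#' @return A `data.frame` with columns `fraction`, `mean_accuracy`,
#'   `spread`, `n_train`.
#' @export
reduction_protocol <- function(manifest, images, model = cct_config(),
                               control = train_control(),
                               fractions = c(1, 0.75, 0.5, 0.25),
                               repeats = 3) {
  if (any(fractions <= 0) || any(fractions > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  if (all(manifest$split == "unassigned"))
    manifest <- split_manifest(manifest, control)
  tr <- which(manifest$split == "train")
  te <- manifest$image_ref[manifest$split == "test"]
  if (!length(te)) stop("empty test split", call. = FALSE)
  te_y <- manifest$grade[manifest$split == "test"]
  rows <- list()
  for (fi in seq_along(fractions)) {
    fr <- fractions[fi]
    accs <- numeric(repeats)
    for (r in seq_len(repeats)) {
      sub <- if (fr < 1)
        with_seed(control$rng_seed + 1000L * r + fi,
                  sample(tr, max(1L, floor(fr * length(tr))))) else tr
      refs <- manifest$image_ref[sub]
      ctl <- control
      ctl$rng_seed <- control$rng_seed + r
      fit <- dr_cct(images[refs], manifest$grade[sub], model, ctl)
      accs[r] <- mean(predict(fit, images[te]) == te_y)
    }
    rows[[fi]] <- data.frame(fraction = fr, mean_accuracy = mean(accs),
                             spread = max(accs) - mean(accs),
                             n_train = if (fr < 1) max(1L, floor(fr * length(tr)))
                                       else length(tr))
  }
  do.call(rbind, rows)
}
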