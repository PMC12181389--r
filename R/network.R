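# Model construction and training: the hybrid network (conv + batch-norm trunk,
# fc1..fc4, QuantClass head) and the classical baseline (two 16-filter 3x3
# convolutions, one 2x2 max-pool, dense-32, dense-4 softmax on 32x215 input),
# with cross-entropy loss, Adam, polynomial learning-rate decay and label-noise
# augmentation.

#' Declarative model specification
#'
#' `kind = "classical"` is the baseline: conv16\@3x3 (same padding) -> dropout
#' -> max-pool 2x2 -> conv16\@3x3 -> dropout -> flatten -> dense-32 -> dropout
#' 0.5 -> dense-4 softmax, on images resized to 32x215. `kind = "hybrid"` is
#' the quantum-inspired network: optional Quantvolution preprocessing, two
#' conv + batch-norm + pool + dropout blocks, dense layers fc1..fc4 and either
#' the QuantClass head (fc4 has 2 units feeding the angle encoding) or, for the
#' filter-only ablation arms, the classical dense-32/softmax-4 inference head.
#'
#' @param kind `"classical"` or `"hybrid"`.
#' @param quantvolution `NULL`, or a [quantvolution_config()] applied as fixed
#'   preprocessing before the network.
#' @param head `"quantclass"` or `"softmax"`.
#' @param head_mode QuantClass circuit mode, `"functional"` or `"literal"`.
#' @param input_shape height/width the images are resized to (default
#'   `c(32, 215)`, bilinear).
#' @param conv_filters filters per convolutional layer (default 16).
#' @param fc_widths hybrid dense widths fc1..fc4 (default `c(256, 64, 16, 2)`).
#' @param dropout_conv dropout rate after conv blocks (default 0.2).
#' @param dropout_dense dropout rate before the final dense layer (default 0.5).
#' @param jitter_sigma forward jitter of the QuantClass angle (default 0).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(kind = c("hybrid", "classical"),
                       quantvolution = if (match.arg(kind) == "hybrid")
                         quantvolution_config() else NULL,
                       head = if (match.arg(kind) == "hybrid") "quantclass" else "softmax",
                       head_mode = c("functional", "literal"),
                       input_shape = c(32L, 215L),
                       conv_filters = 16L,
                       fc_widths = c(256L, 64L, 16L, 2L),
                       dropout_conv = 0.2, dropout_dense = 0.5,
                       jitter_sigma = 0) {
  kind <- match.arg(kind)
  head <- match.arg(head, c("quantclass", "softmax"))
  if (kind == "classical" && head != "softmax") {
    qt_stop("the classical baseline uses the softmax head", class = "qtremor_structural_error")
  }
  structure(list(kind = kind, quantvolution = quantvolution, head = head,
                 head_mode = match.arg(head_mode),
                 input_shape = as.integer(input_shape),
                 conv_filters = as.integer(conv_filters),
                 fc_widths = as.integer(fc_widths),
                 dropout_conv = dropout_conv, dropout_dense = dropout_dense,
                 jitter_sigma = jitter_sigma),
            class = "model_spec")
}

# Shape of the array entering the network (after resize and optional filter).
input_dims <- function(spec) {
  h <- spec$input_shape[1]; w <- spec$input_shape[2]
  if (!is.null(spec$quantvolution)) {
    k <- spec$quantvolution$k
    c(h %/% k, w %/% k, k^2)
  } else {
    c(h, w, 1L)
  }
}

#' Build a trainable model from a specification
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for the weight initialisation.
#' @return object of class `qtremor_model` (list of layers plus bookkeeping).
#' @export
build_model <- function(spec, seed = 1L) {
  dims <- input_dims(spec)
  layers <- with_seed(seed, {
    L <- list()
    f <- spec$conv_filters
    if (spec$kind == "classical") {
      L <- c(L, list(layer_conv(dims[3], f), layer_relu(),
                     layer_dropout(spec$dropout_conv), layer_pool()))
      h <- dims[1] %/% 2L; w <- dims[2] %/% 2L
      L <- c(L, list(layer_conv(f, f), layer_relu(),
                     layer_dropout(spec$dropout_conv), layer_flatten()))
      flat <- h * w * f
      L <- c(L, list(layer_dense(flat, 32L), layer_relu(),
                     layer_dropout(spec$dropout_dense),
                     layer_dense(32L, 4L), layer_softmax()))
    } else {
      L <- c(L, list(layer_conv(dims[3], f), layer_batchnorm(f), layer_relu(),
                     layer_pool(), layer_dropout(spec$dropout_conv)))
      h <- dims[1] %/% 2L; w <- dims[2] %/% 2L
      L <- c(L, list(layer_conv(f, f), layer_batchnorm(f), layer_relu(),
                     layer_pool(), layer_dropout(spec$dropout_conv)))
      h <- h %/% 2L; w <- w %/% 2L
      flat <- h * w * f
      L <- c(L, list(layer_flatten()))
      if (spec$head == "quantclass") {
        wid <- spec$fc_widths
        L <- c(L, list(layer_dense(flat, wid[1]), layer_relu(),
                       layer_dense(wid[1], wid[2]), layer_relu(),
                       layer_dense(wid[2], wid[3]), layer_relu(),
                       layer_dense(wid[3], 2L),
                       layer_qclass(spec$head_mode, jitter_sigma = spec$jitter_sigma)))
      } else {
        wid <- spec$fc_widths
        L <- c(L, list(layer_dense(flat, wid[1]), layer_relu(),
                       layer_dense(wid[1], wid[2]), layer_relu(),
                       layer_dense(wid[2], wid[3]), layer_relu(),
                       layer_dense(wid[3], 32L), layer_relu(),
                       layer_dropout(spec$dropout_dense),
                       layer_dense(32L, 4L), layer_softmax()))
      }
    }
    L
  })
  structure(list(layers = layers, spec = spec, seed = as.integer(seed),
                 n_classes = 4L),
            class = "qtremor_model")
}

model_forward <- function(model, x, train = FALSE) {
  x <- aperm(x, c(1L, 2L, 4L, 3L))   # public (H,W,C,N) -> internal (H,W,N,C)
  for (l in model$layers) x <- layer_forward(l, x, train)
  x
}

model_backward <- function(model, dout) {
  for (l in rev(model$layers)) dout <- layer_backward(l, dout)
  invisible(dout)
}

#' Cross-entropy loss
#'
#' `L = -(1/N) sum_i sum_c y_ic log p_ic`, with predictions clipped to
#' `[1e-12, 1]`.
#'
#' @param targets one-hot matrix, N x C.
#' @param predictions probability matrix, N x C (rows sum to 1 within 1e-6).
#' @return non-negative scalar loss.
#' @export
cross_entropy <- function(targets, predictions) {
  if (!all(dim(targets) == dim(predictions))) {
    qt_stop("targets/predictions shape mismatch", class = "qtremor_structural_error")
  }
  if (any(abs(rowSums(predictions) - 1) > 1e-6)) {
    qt_stop("prediction rows must sum to 1", class = "qtremor_domain_error")
  }
  p <- pmin(pmax(predictions, 1e-12), 1)
  -mean(rowSums(targets * log(p)))
}

#' Polynomial learning-rate decay
#'
#' `lr = end_lr + (lr0 - end_lr) * (1 - step/horizon)^power`, clamped to
#' `end_lr` past the horizon.
#'
#' @param step 0-based optimisation step.
#' @param cfg a [train_config()] (uses `lr0`, `end_lr`, `power`, `horizon`).
#' @return learning rate.
#' @export
polynomial_lr <- function(step, cfg) {
  if (step >= cfg$horizon) return(cfg$end_lr)
  cfg$end_lr + (cfg$lr0 - cfg$end_lr) * (1 - step / cfg$horizon)^cfg$power
}

#' Label-noise augmentation
#'
#' Each label is independently replaced, with probability `rate`, by a
#' uniformly chosen *different* class.
#'
#' @param labels integer class vector (0-based).
#' @param rate flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @param n_classes number of classes (default 4).
#' @return perturbed label vector.
#' @export
add_label_noise <- function(labels, rate, seed = NULL, n_classes = 4L) {
  if (rate < 0 || rate > 1) qt_stop("rate must be in [0, 1]", class = "qtremor_domain_error")
  if (any(!labels %in% 0:(n_classes - 1L))) {
    qt_stop("invalid class values", class = "qtremor_domain_error")
  }
  with_seed(seed, {
    flip <- runif(length(labels)) < rate
    shift <- sample.int(n_classes - 1L, length(labels), replace = TRUE)
    out <- labels
    out[flip] <- (labels[flip] + shift[flip]) %% n_classes
    out
  })
}

#' Training configuration
#'
#' @param epochs fixed number of epochs (default 100; training never
#'   early-stops).
#' @param batch_size minibatch size (default 32).
#' @param lr0,end_lr,power polynomial decay parameters (defaults 3e-3, 1e-5, 1).
#' @param horizon decay horizon in steps (`NULL` = total training steps).
#' @param label_noise training-split label-flip rate (default 0.05).
#' @param beta1,beta2,eps Adam moments and stabiliser (defaults 0.9, 0.999,
#'   1e-8).
#' @param seed integer seed governing shuffling, dropout and label noise.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L,
                         lr0 = 3e-3, end_lr = 1e-5, power = 1, horizon = NULL,
                         label_noise = 0.05,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = 1L) {
  if (epochs < 1) qt_stop("epochs must be >= 1", class = "qtremor_domain_error")
  if (label_noise < 0 || label_noise > 1) {
    qt_stop("label_noise must be in [0, 1]", class = "qtremor_domain_error")
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr0 = lr0, end_lr = end_lr, power = power, horizon = horizon,
                 label_noise = label_noise,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Prepare network inputs from a labeled dataset
#'
#' Normalizes each image to `[0, 1]`, resizes it to the model's input shape
#' (bilinear) and, if the spec carries a Quantvolution configuration, runs the
#' filter as fixed preprocessing. Feature maps are computed once per image and
#' shared by all training runs of a study.
#'
#' The resulting values (pixels or filter marginals, both in `[0, 1]`) are
#' centered at zero by subtracting 1/2, the encoder's zero-signal gray level.
#'
#' @param dataset a [generate_dataset()] result.
#' @param spec a [model_spec()].
#' @return list with `x` (H, W, C, N array), `y` (0-based labels) and `split`.
#' @export
prepare_inputs <- function(dataset, spec) {
  n <- length(dataset$images)
  dims <- input_dims(spec)
  x <- array(0, c(dims, n))
  for (i in seq_len(n)) {
    img <- resize_image(normalized_pixels(dataset$images[[i]]),
                        spec$input_shape[1], spec$input_shape[2])
    if (!is.null(spec$quantvolution)) {
      x[, , , i] <- quantvolve_image(img, spec$quantvolution)
    } else {
      x[, , 1L, i] <- img
    }
  }
  list(x = x - 0.5, y = dataset$labels, split = dataset$split)
}

one_hot <- function(y, n_classes = 4L) {
  Y <- matrix(0, n_classes, length(y))
  Y[cbind(y + 1L, seq_along(y))] <- 1
  Y
}

take <- function(x, idx) x[, , , idx, drop = FALSE]

#' Train a model
#'
#' Runs exactly `cfg$epochs` epochs of minibatch Adam with polynomial
#' learning-rate decay and (training-split only) label-noise augmentation,
#' then evaluates all three splits in inference mode. Deterministic for fixed
#' `(seed, config, data)` under exact head evaluation.
#'
#' @param model a [build_model()] result (updated in place).
#' @param data a prepared input list from [prepare_inputs()], or a
#'   `labeled_dataset` (prepared on the fly using the model's spec).
#' @param cfg a [train_config()].
#' @return `train_result`: per-epoch training loss, final loss/accuracy for
#'   train/val/test, wall-clock seconds, seed and config snapshot.
#' @export
train <- function(model, data, cfg = train_config()) {
  if (inherits(data, "labeled_dataset")) data <- prepare_inputs(data, model$spec)
  t_start <- Sys.time()
  idx_tr <- which(data$split == "train")
  idx_va <- which(data$split == "val")
  idx_te <- which(data$split == "test")
  if (!length(idx_tr) || !length(idx_va) || !length(idx_te)) {
    qt_stop("all of train/val/test must be non-empty", class = "qtremor_domain_error")
  }
  x_tr <- take(data$x, idx_tr)
  y_tr <- add_label_noise(data$y[idx_tr], cfg$label_noise,
                          derive_seed(cfg$seed, 7L))
  n_tr <- length(idx_tr)
  steps_per_epoch <- ceiling(n_tr / cfg$batch_size)
  horizon <- cfg$horizon %||% (cfg$epochs * steps_per_epoch)
  cfg_run <- cfg; cfg_run$horizon <- horizon

  epoch_loss <- numeric(cfg$epochs)
  step <- 0L
  with_seed(derive_seed(cfg$seed, 11L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n_tr)
      losses <- numeric(steps_per_epoch)
      for (bi in seq_len(steps_per_epoch)) {
        take_idx <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n_tr)]
        xb <- take(x_tr, take_idx)
        yb <- y_tr[take_idx]
        Y <- one_hot(yb)
        p <- model_forward(model, xb, train = TRUE)
        losses[bi] <- cross_entropy(t(Y), t(p))
        nb <- length(take_idx)
        top <- model$layers[[length(model$layers)]]
        if (top$type == "softmax") {
          dout <- (p - Y) / nb              # fused softmax + cross-entropy
        } else {
          dout <- -Y / (pmin(pmax(p, 1e-12), 1) * nb)
        }
        model_backward(model, dout)
        lr <- polynomial_lr(step, cfg_run)
        step <- step + 1L
        for (l in model$layers) {
          if (length(l$grads)) adam_step(l, lr, cfg$beta1, cfg$beta2, cfg$eps, step)
        }
      }
      epoch_loss[ep] <- mean(losses)
    }
  })

  metrics <- list(
    train = evaluate_model(model, x_tr, data$y[idx_tr]),
    val = evaluate_model(model, take(data$x, idx_va), data$y[idx_va]),
    test = evaluate_model(model, take(data$x, idx_te), data$y[idx_te])
  )
  structure(list(epoch_loss = epoch_loss, metrics = metrics,
                 seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
                 seed = cfg$seed, config = cfg_run, spec = model$spec),
            class = "train_result")
}

#' Evaluate a model on a split
#'
#' Inference mode (no dropout, batch-norm running statistics). Accuracy uses
#' the argmax rule with ties broken toward the lowest class index.
#'
#' @param model a trained model.
#' @param x input array (H, W, C, N).
#' @param y 0-based integer labels.
#' @return list with `loss` and `accuracy`.
#' @export
evaluate_model <- function(model, x, y) {
  if (!length(y)) qt_stop("empty split", class = "qtremor_domain_error")
  p <- model_forward(model, x, train = FALSE)
  pred <- apply(p, 2L, which.max) - 1L
  list(loss = cross_entropy(t(one_hot(y)), t(p)),
       accuracy = mean(pred == y))
}

#' Class predictions
#'
#' @param model a trained model.
#' @param x input array (H, W, C, N).
#' @return 0-based predicted classes.
#' @export
predict_classes <- function(model, x) {
  apply(model_forward(model, x, train = FALSE), 2L, which.max) - 1L
}

#' @export
print.train_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<train_result: %d epochs, %.1fs\n",
                     "  train loss %.4f acc %.3f | val loss %.4f acc %.3f | ",
                     "test loss %.4f acc %.3f>\n"),
              length(x$epoch_loss), x$seconds,
              m$train$loss, m$train$accuracy, m$val$loss, m$val$accuracy,
              m$test$loss, m$test$accuracy))
  invisible(x)
}

#' Serialize a training result
#'
#' Writes the final metrics and configuration as JSON and the per-epoch loss
#' trace as CSV.
#'
#' @param res a `train_result`.
#' @param path JSON output path (the trace CSV sits next to it).
#' @return invisibly, `path`.
#' @export
write_train_result <- function(res, path) {
  out <- list(metrics = res$metrics, seconds = res$seconds, seed = res$seed,
              epochs = length(res$epoch_loss),
              spec_kind = res$spec$kind, head = res$spec$head,
              head_mode = res$spec$head_mode)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write.csv(data.frame(epoch = seq_along(res$epoch_loss), loss = res$epoch_loss),
            sub("\\.json$", "_trace.csv", path), row.names = FALSE)
  invisible(path)
}

#' Save / load model weights
#'
#' A portable container: a JSON header (layer types, parameter names and
#' dimensions, batch-norm running statistics) followed by the concatenated
#' parameter values as little-endian doubles.
#'
#' @param model a `qtremor_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_model_weights <- function(model, path) {
  header <- list(package = "qtremor", layers = list())
  values <- numeric(0)
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    entry <- list(type = l$type, params = list())
    for (nm in names(l$params)) {
      p <- l$params[[nm]]
      entry$params[[nm]] <- list(dim = if (is.matrix(p)) dim(p) else length(p),
                                 offset = length(values), n = length(p))
      values <- c(values, as.numeric(p))
    }
    if (l$type == "batchnorm") {
      entry$run_mean <- l$run_mean
      entry$run_var <- l$run_var
    }
    header$layers[[i]] <- entry
  }
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(hjson))
  writeBin(as.numeric(length(hraw)), con, size = 8L, endian = "little")
  writeBin(hraw, con)
  writeBin(values, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_model_weights
#' @param model a freshly built model with the same architecture to load the
#'   weights into (updated in place).
#' @export
read_model_weights <- function(model, path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- as.integer(readBin(con, "double", 1L, size = 8L, endian = "little"))
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = FALSE)
  values <- readBin(con, "double", 1e8, size = 8L, endian = "little")
  if (length(header$layers) != length(model$layers)) {
    qt_stop("weights file does not match the model architecture",
            class = "qtremor_structural_error")
  }
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    entry <- header$layers[[i]]
    if (!identical(entry$type, l$type)) {
      qt_stop("layer ", i, " type mismatch", class = "qtremor_structural_error")
    }
    for (nm in names(entry$params)) {
      meta <- entry$params[[nm]]
      v <- values[meta$offset + seq_len(meta$n)]
      dm <- unlist(meta$dim)
      l$params[[nm]] <- if (length(dm) == 2L) matrix(v, dm[1], dm[2]) else v
    }
    if (l$type == "batchnorm") {
      l$run_mean <- unlist(entry$run_mean)
      l$run_var <- unlist(entry$run_var)
    }
  }
  invisible(model)
}
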