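#' Deeply supervised composite loss
#'
#' Mean absolute error of the main (`out`) prediction plus weighted MAE of
#' each auxiliary prediction against the same target waveform:
#' `total = w[1] * MAE(main, y) + sum_j w[1 + j] * MAE(aux[[j]], y)`.
#' With the default weights `c(1, 0.9, 0.8, 0.7, 0.6)` and all five per-head
#' MAEs equal to `m`, the total is `4 * m`.
#'
#' @param outputs List with `main` (numeric matrix/vector) and `aux` (list of
#'   same-shaped predictions).
#' @param target Ground-truth waveform(s), same shape as `main`.
#' @param weights Numeric vector of length `1 + length(aux)`.
#' @return Scalar loss.
#' @export
deep_supervision_loss <- function(outputs, target,
                                  weights = c(1, 0.9, 0.8, 0.7, 0.6)) {
  if (length(weights) != 1L + length(outputs$aux)) {
    stop("need one weight for the main head plus one per auxiliary head (",
         1L + length(outputs$aux), "), got ", length(weights), call. = FALSE)
  }
  total <- weights[1L] * mean(abs(outputs$main - target))
  for (j in seq_along(outputs$aux)) {
    total <- total + weights[1L + j] * mean(abs(outputs$aux[[j]] - target))
  }
  total
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate. The reference protocol uses 1e-4
#'   with batch 256 (the `"paper"` profile); the `"desk"` profile defaults to
#'   1e-3, scaled up for its much smaller batches.
#' @param batch_size Mini-batch size. The reference protocol uses 256; the
#'   `"desk"` profile (default) uses 32, sized for single-CPU runs.
#' @param max_epochs Maximum epochs (default 100).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param min_delta Minimum decrease of the monitored validation loss that
#'   counts as an improvement (default 1e-6).
#' @param seed Seed controlling initialization order and batch shuffling.
#' @param profile `"desk"` or `"paper"`; selects the batch-size default when
#'   `batch_size` is not given.
#' @return A list of class `ppgbp_train_config`.
#' @export
train_config <- function(learning_rate = NULL, batch_size = NULL,
                         max_epochs = 100L, patience = 10L, min_delta = 1e-6,
                         seed = 1L, profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (is.null(batch_size)) batch_size <- if (profile == "desk") 32L else 256L
  if (is.null(learning_rate)) {
    learning_rate <- if (profile == "desk") 1e-3 else 1e-4
  }
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, patience < max_epochs || max_epochs == 1)
  structure(list(
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    min_delta = min_delta, seed = as.integer(seed), profile = profile
  ), class = "ppgbp_train_config")
}

# ---- Adam optimizer over the model's parameterized modules ------------------

adam_init <- function(leaves) {
  for (m in leaves) {
    m$adam_m <- lapply(m$params, function(p) p * 0)
    m$adam_v <- lapply(m$params, function(p) p * 0)
  }
  invisible(leaves)
}

adam_step <- function(leaves, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (m in leaves) {
    for (nm in names(m$params)) {
      g <- m$grads[[nm]]
      m$adam_m[[nm]] <- beta1 * m$adam_m[[nm]] + (1 - beta1) * g
      m$adam_v[[nm]] <- beta2 * m$adam_v[[nm]] + (1 - beta2) * g * g
      m$params[[nm]] <- m$params[[nm]] -
        lr * (m$adam_m[[nm]] / c1) / (sqrt(m$adam_v[[nm]] / c2) + eps)
    }
  }
  invisible(leaves)
}

zero_grads <- function(leaves) {
  for (m in leaves) zero_grads_module(m)
  invisible(leaves)
}

# snapshot / restore all parameters and batch-norm running statistics
get_weights <- function(net) {
  lapply(net$leaves, function(m) {
    list(params = m$params, running_mean = m$running_mean,
         running_var = m$running_var)
  })
}

set_weights <- function(net, w) {
  for (i in seq_along(net$leaves)) {
    net$leaves[[i]]$params <- w[[i]]$params
    if (!is.null(w[[i]]$running_mean)) {
      net$leaves[[i]]$running_mean <- w[[i]]$running_mean
      net$leaves[[i]]$running_var <- w[[i]]$running_var
    }
  }
  invisible(net)
}

# per-head supervision weights in attachment order (aux[[1]] = shallowest)
resolve_weights <- function(cfg) {
  w <- cfg$supervision_weights
  if (identical(cfg$aux_weight_order, "deep_first")) {
    w <- c(w[1L], rev(w[-1L]))
  }
  w
}

# forward + loss + backward + per-head MAEs on one batch; returns the loss
train_batch <- function(net, Xb, Yb, weights) {
  out <- net$forward(Xb, train = TRUE)
  n <- length(Yb)
  d_main <- weights[1L] * sign(out$main - Yb) / n
  d_aux <- lapply(seq_along(out$aux), function(j)
    weights[1L + j] * sign(out$aux[[j]] - Yb) / n)
  net$backward(d_main, d_aux)
  deep_supervision_loss(out, Yb, weights)
}

eval_losses <- function(net, X, Y, weights, batch_size = 64L) {
  n <- nrow(X)
  heads <- numeric(1L + length(net$aux_head))
  sq <- 0
  total_abs_main <- 0
  bs <- seq(1L, n, batch_size)
  for (s in bs) {
    idx <- s:min(n, s + batch_size - 1L)
    out <- net$forward(X[idx, , drop = FALSE], train = FALSE)
    Yb <- Y[idx, , drop = FALSE]
    heads[1L] <- heads[1L] + sum(abs(out$main - Yb))
    for (j in seq_along(out$aux)) {
      heads[1L + j] <- heads[1L + j] + sum(abs(out$aux[[j]] - Yb))
    }
    sq <- sq + sum((out$main - Yb)^2)
  }
  heads <- heads / (n * ncol(X))
  list(composite = sum(weights * heads), head_mae = heads,
       mse = sq / (n * ncol(X)))
}

#' Train the network with Adam, MAE loss and early stopping
#'
#' Minimizes the deeply supervised composite MAE ([deep_supervision_loss()])
#' with Adam. After each epoch the composite loss and the main-head MSE are
#' computed on the validation set; training stops when the validation loss
#' has not improved by at least `min_delta` for `patience` consecutive
#' epochs, and the best-validation parameters are restored.
#'
#' @param net A model from [build_unet1d()].
#' @param x_train,y_train,x_val,y_val Numeric matrices (segments in rows,
#'   standardized units).
#' @param config A [train_config()].
#' @param monitor_override Optional function `(epoch, val_loss) -> value`
#'   replacing the monitored quantity; a diagnostic hook for exercising the
#'   stopping rule.
#' @param verbose Print one line per epoch.
#' @return List with the trained `net`, a per-epoch `history` tibble
#'   (train/validation losses, validation MSE, per-head validation MAEs),
#'   `best_epoch` and `stop_reason`.
#' @export
train_unet <- function(net, x_train, y_train, x_val, y_val,
                       config = train_config(), monitor_override = NULL,
                       verbose = FALSE) {
  stopifnot(nrow(x_train) > 0, nrow(x_val) > 0,
            nrow(x_train) == nrow(y_train), nrow(x_val) == nrow(y_val))
  weights <- resolve_weights(net$cfg)
  adam_init(net$leaves)
  n <- nrow(x_train)
  bs <- config$batch_size
  history <- vector("list", config$max_epochs)
  best_val <- Inf; best_epoch <- 0L; best_w <- NULL
  since_improved <- 0L; step <- 0L
  stop_reason <- "max_epochs"
  for (epoch in seq_len(config$max_epochs)) {
    perm <- withr::with_seed(config$seed + epoch, sample.int(n))
    train_loss <- 0; nb <- 0L
    for (s in seq(1L, n, bs)) {
      idx <- perm[s:min(n, s + bs - 1L)]
      zero_grads(net$leaves)
      loss <- train_batch(net, x_train[idx, , drop = FALSE],
                          y_train[idx, , drop = FALSE], weights)
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             ", step ", step + 1L, call. = FALSE)
      }
      step <- step + 1L
      adam_step(net$leaves, config$learning_rate, step)
      train_loss <- train_loss + loss; nb <- nb + 1L
    }
    ev <- eval_losses(net, x_val, y_val, weights)
    monitored <- if (is.null(monitor_override)) ev$composite
                 else monitor_override(epoch, ev$composite)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = train_loss / nb, val_loss = ev$composite,
      val_mse = ev$mse,
      head = list(stats::setNames(ev$head_mae,
                                  c("out", paste0("level", seq_along(net$aux_head)))))
    )
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  val_mse %.5f",
                      epoch, train_loss / nb, ev$composite, ev$mse))
    }
    if (monitored < best_val - config$min_delta) {
      best_val <- monitored; best_epoch <- epoch
      best_w <- get_weights(net)
      since_improved <- 0L
    } else {
      since_improved <- since_improved + 1L
      if (since_improved >= config$patience) {
        stop_reason <- "early_stop"
        history <- history[seq_len(epoch)]
        break
      }
    }
  }
  if (!is.null(best_w)) set_weights(net, best_w)
  list(net = net,
       history = dplyr::bind_rows(history),
       best_epoch = best_epoch, best_val_loss = best_val,
       stop_reason = stop_reason)
}

#' Fit the blood-pressure model on a preprocessed segment table
#'
#' Prepares matrices from the `train` and `val` splits (PPG as input; ABP
#' standardized with the stored training-set mean/sd as target), builds the
#' network and trains it.
#'
#' @param segments Segment tibble from [preprocess_records()] (or a store).
#' @param model_config A [unet_config()]; its `input_len` must equal the
#'   segment window length.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `ppgbp_fit`.
#' @export
fit_bp_model <- function(segments, model_config = unet_config(),
                         config = train_config(), verbose = FALSE) {
  check_segments(segments)
  stopifnot("split" %in% names(segments))
  norm <- list(mu = segments$norm_mu[[1]], sigma = segments$norm_sigma[[1]])
  mk <- function(split) {
    sub <- segments[segments$split == split, ]
    list(x = segments_matrix(sub$ppg),
         y = (segments_matrix(sub$abp) - norm$mu) / norm$sigma)
  }
  tr <- mk("train"); va <- mk("val")
  net <- build_unet1d(model_config, seed = config$seed)
  res <- train_unet(net, tr$x, tr$y, va$x, va$y, config, verbose = verbose)
  structure(list(
    net = res$net, history = res$history, best_epoch = res$best_epoch,
    best_val_loss = res$best_val_loss, stop_reason = res$stop_reason,
    norm = norm, model_config = model_config, train_config = config
  ), class = "ppgbp_fit")
}

#' Predict ABP waveforms for PPG segments
#'
#' Runs the trained network in evaluation mode (frozen batch-norm
#' statistics) and inverts the stored target standardization so predictions
#' are in mmHg. Results are independent of batch composition.
#'
#' @param object A `ppgbp_fit`.
#' @param segments Segment tibble with a `ppg` list-column (window length
#'   must match the model input).
#' @param ... Unused.
#' @return `segments` with a `pred_abp` list-column added (mmHg).
#' @export
predict.ppgbp_fit <- function(object, segments, ...) {
  check_segments(segments)
  X <- segments_matrix(segments$ppg)
  if (ncol(X) != object$model_config$input_len) {
    stop("segment length ", ncol(X), " does not match the model input length ",
         object$model_config$input_len, call. = FALSE)
  }
  pred <- matrix(0, nrow(X), ncol(X))
  for (s in seq(1L, nrow(X), 64L)) {
    idx <- s:min(nrow(X), s + 63L)
    out <- object$net$forward(X[idx, , drop = FALSE], train = FALSE)
    pred[idx, ] <- out$main
  }
  pred <- pred * object$norm$sigma + object$norm$mu
  segments$pred_abp <- lapply(seq_len(nrow(pred)), function(i) pred[i, ])
  segments
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single file holding all parameters, batch-norm
#' statistics, the architecture configuration and the target normalization.
#'
#' @param object A `ppgbp_fit`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `ppgbp_fit` ready for prediction.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "ppgbp_fit"))
  saveRDS(list(weights = get_weights(object$net),
               model_config = object$model_config,
               train_config = object$train_config,
               norm = object$norm, history = object$history,
               best_epoch = object$best_epoch,
               stop_reason = object$stop_reason), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_unet1d(ck$model_config, seed = 1L)
  set_weights(net, ck$weights)
  structure(list(net = net, history = ck$history, best_epoch = ck$best_epoch,
                 best_val_loss = min(ck$history$val_loss), norm = ck$norm,
                 stop_reason = ck$stop_reason, model_config = ck$model_config,
                 train_config = ck$train_config), class = "ppgbp_fit")
}

#' @export
print.ppgbp_fit <- function(x, ...) {
  cat("Fitted PPG->ABP model (", x$model_config$block_type, " blocks, ",
      x$model_config$skip_type, " skips)\n", sep = "")
  cat("  epochs trained:", nrow(x$history), " best epoch:", x$best_epoch,
      " stop:", x$stop_reason, "\n")
  cat("  best validation loss:", format(x$best_val_loss, digits = 5), "\n")
  invisible(x)
}

#' Tidy the training history of a fitted model
#'
#' @param x A `ppgbp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch and head (`out`, `level1`..):
#'   columns `epoch`, `train_loss`, `val_loss`, `val_mse`, `head`,
#'   `val_head_mae`.
#' @export
#' @importFrom generics tidy
tidy.ppgbp_fit <- function(x, ...) {
  h <- x$history
  tidyr::unnest_longer(
    dplyr::mutate(h, head = lapply(.data$head, function(v)
      tibble::tibble(head = names(v), val_head_mae = unname(v)))),
    "head"
  ) |> tidyr::unpack("head")
}

#' One-row summary of a fitted model
#'
#' @param x A `ppgbp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: epochs trained, best epoch, best validation
#'   loss, final validation MSE, stop reason.
#' @export
#' @importFrom generics glance
glance.ppgbp_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    final_val_mse = x$history$val_mse[nrow(x$history)],
    stop_reason = x$stop_reason
  )
}
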