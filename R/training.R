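#' Alpha-weighted binary cross-entropy
#'
#' Loss for one prediction `y` in `(0, 1)` against a label `t` in `{0, 1}`:
#' `-[((1 - alpha) / alpha) * t * log(y) + (1 - t) * log(1 - y)]`.
#' The positive branch is weighted by `(1 - alpha) / alpha`, where `alpha` is
#' the fraction of positive labels in the training set, so that positives and
#' negatives contribute equally to the total loss whatever the class balance
#' (with `alpha = 1/2` this is the standard binary cross-entropy). Scores are
#' clamped to `[eps, 1 - eps]` so the loss is always finite.
#'
#' @param y Numeric vector of scores in `(0, 1)`.
#' @param t Integer labels in `{0, 1}`.
#' @param alpha Positive-label fraction in `(0, 1)`.
#' @param eps Clamping constant (default `1e-7`).
#' @return Numeric vector of per-example losses.
#' @examples
#' weighted_bce(0.5, 1, 0.5) # log(2)
#' @export
weighted_bce <- function(y, t, alpha, eps = 1e-7) {
  stopifnot(alpha > 0, alpha < 1, all(t %in% c(0, 1)))
  yc <- pmin(pmax(y, eps), 1 - eps)
  -(((1 - alpha) / alpha) * t * log(yc) + (1 - t) * log(1 - yc))
}

#' Epoch count for a training-set size
#'
#' The number of epochs is `8e4 / N` (rounded half-up, floor of 1), so that
#' every model takes about the same number of gradient steps regardless of
#' `N`: with batch size 256 that is roughly `8e4 / 256` (about 312) steps
#' whenever `N >= 256`.
#'
#' @param N Training-set size.
#' @return Integer epoch count.
#' @examples
#' epochs_for(4000) # 20
#' @export
epochs_for <- function(N) {
  stopifnot(N >= 1)
  as.integer(max(1, floor(8e4 / N + 0.5)))
}

#' Total gradient steps the protocol will take
#'
#' @param N Training-set size.
#' @param batch_size Mini-batch size (default 256).
#' @return Integer step count `epochs_for(N) * ceiling(N / batch_size)`.
#' @export
planned_steps <- function(N, batch_size = 256L) {
  epochs_for(N) * as.integer(ceiling(N / batch_size))
}

#' Training configuration
#'
#' Fixed optimisation protocol: Adam (`beta1 = 0.9`, `beta2 = 0.999`,
#' `eps = 1e-8`) with learning rate `1e-3`, weight decay `1e-3` added to the
#' gradient (L2-style coupling), shuffled mini-batches of 256, and
#' [epochs_for()] epochs unless `epochs` is given explicitly.
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 weight-decay coefficient.
#' @param batch_size Mini-batch size.
#' @param epochs Optional explicit epoch count overriding the `8e4 / N` rule.
#' @param seed Integer seed driving batch shuffling and dropout masks.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-3,
                         batch_size = 256L, epochs = NULL, seed = 1) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = epochs,
                 seed = seed, beta1 = 0.9, beta2 = 0.999, eps = 1e-8),
            class = "train_config")
}

clone_model <- function(model) {
  model$bn <- lapply(model$bn, function(st) {
    e <- new.env(parent = emptyenv())
    e$mean <- st$mean
    e$var <- st$var
    e
  })
  model
}

#' Train a classifier on a hairpin dataset
#'
#' Minimises the mean [weighted_bce()] over shuffled mini-batches with Adam.
#' The loss weight `alpha` is recomputed from the observed (possibly flipped)
#' labels of the training set, following the loss definition literally.
#' Training is deterministic given the model, dataset and config seeds.
#'
#' @param model A `hairpin_model` from [build_model()]. The input model is not
#'   modified.
#' @param ds A train-role `hairpin_dataset`.
#' @param config A [train_config()].
#' @param theta Threshold for the final training-accuracy report (default 0.5).
#' @return A `hairpin_fit` object: the trained model plus a per-epoch loss
#'   trace, the final training accuracy and step counts. Use [tidy()] for the
#'   loss trace and [glance()] for a one-row summary.
#' @export
train_model <- function(model, ds, config = train_config(), theta = 0.5) {
  if (!identical(attr(ds, "role"), "train")) {
    stop("train_model() requires a train-role dataset", call. = FALSE)
  }
  tokens <- encode_dataset(ds, model$spec$max_len)
  labels <- ds$observed_label
  N <- nrow(tokens)
  alpha_obs <- min(max(mean(labels), 1 / (2 * N)), 1 - 1 / (2 * N))
  epochs <- if (is.null(config$epochs)) epochs_for(N) else as.integer(config$epochs)
  model <- clone_model(model)
  set.seed(config$seed)
  m1 <- lapply(model$params, function(p) p * 0)
  m2 <- m1
  b1 <- config$beta1
  b2 <- config$beta2
  lr <- config$learning_rate
  wd <- config$weight_decay
  ae <- config$eps
  step <- 0L
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(N)
    nb <- ceiling(N / config$batch_size)
    batches <- split(perm, rep(seq_len(nb), each = config$batch_size,
                               length.out = N))
    # batch normalisation needs at least 2 examples per batch
    if (length(batches) > 1L && length(batches[[nb]]) == 1L) {
      batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
      batches[[nb]] <- NULL
    }
    ep_loss <- 0
    for (bidx in batches) {
      fg <- forward_graph(model, tokens[bidx, , drop = FALSE], training = TRUE)
      loss <- tp_wbce(fg$tape, fg$y, labels[bidx], alpha_obs)
      tape_backward(fg$tape, loss)
      step <- step + 1L
      bc1 <- 1 - b1^step
      bc2 <- 1 - b2^step
      for (nm in names(model$params)) {
        g <- fg$params[[nm]]$grad
        if (is.null(g)) next
        g <- g + wd * model$params[[nm]]
        m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * g
        m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * g * g
        model$params[[nm]] <- model$params[[nm]] -
          lr * (m1[[nm]] / bc1) / (sqrt(m2[[nm]] / bc2) + ae)
      }
      ep_loss <- ep_loss + loss$val * length(bidx)
    }
    losses[ep] <- ep_loss / N
  }
  train_scores <- predict_scores(model, tokens)
  structure(
    list(model = model,
         record = tibble::tibble(epoch = seq_len(epochs), loss = losses),
         steps = step,
         final_train_accuracy = mean(as.integer(train_scores > theta) == labels),
         alpha = alpha_obs, n_train = N, config = config),
    class = "hairpin_fit")
}

#' @export
print.hairpin_fit <- function(x, ...) {
  cat(sprintf(
    "<hairpin_fit> %s trained on %d examples: %d steps, final loss %.4f, train accuracy %.3f\n",
    x$model$spec$family, x$n_train, x$steps,
    x$record$loss[nrow(x$record)], x$final_train_accuracy))
  invisible(x)
}

#' @rdname train_model
#' @param x A `hairpin_fit`.
#' @param ... Unused.
#' @export
tidy.hairpin_fit <- function(x, ...) x$record

#' @rdname train_model
#' @export
glance.hairpin_fit <- function(x, ...) {
  tibble::tibble(
    family = x$model$spec$family, H = x$model$spec$H, U = x$model$spec$U,
    parameters = count_parameters(x$model), n_train = x$n_train,
    epochs = nrow(x$record), steps = x$steps, alpha = x$alpha,
    final_loss = x$record$loss[nrow(x$record)],
    train_accuracy = x$final_train_accuracy)
}

#' @export
predict.hairpin_fit <- function(object, newdata, ...) {
  predict_scores(object$model, newdata)
}
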