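#' Training configuration
#'
#' Defaults follow the reference training recipe for this model family:
#' SGD, batch size 128, initial learning rate 0.01, weight decay 5e-4,
#' momentum 0.9, inputs resized to 224. The epoch count is task-bound
#' and always explicit in the config.
#'
#' @param batch_size Minibatch size.
#' @param initial_lr Initial SGD learning rate.
#' @param weight_decay L2 weight decay coefficient.
#' @param momentum SGD momentum.
#' @param epochs Number of passes over the training set.
#' @param seed Seed controlling batch order (recorded in outputs).
#' @param input_size Image size the training images are resized to;
#'   must match the model's configured input size.
#' @param lr_schedule `"constant"` (default) or `"cosine"`.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 128L, initial_lr = 0.01,
                         weight_decay = 5e-4, momentum = 0.9,
                         epochs = 90L, seed = 0L, input_size = 224L,
                         lr_schedule = c("constant", "cosine")) {
  lr_schedule <- match.arg(lr_schedule)
  if (batch_size < 1L || epochs < 0L || initial_lr < 0 ||
      weight_decay < 0 || momentum < 0 || input_size < 1L)
    stop("train_config: all settings must be non-negative (batch size and ",
         "input size positive)")
  structure(list(batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, weight_decay = weight_decay,
                 momentum = momentum, epochs = as.integer(epochs),
                 seed = as.integer(seed), input_size = as.integer(input_size),
                 lr_schedule = lr_schedule),
            class = "train_config")
}

epoch_lr <- function(cfg, epoch) {
  if (cfg$lr_schedule == "cosine" && cfg$epochs > 1L)
    cfg$initial_lr * 0.5 * (1 + cos(pi * (epoch - 1) / cfg$epochs))
  else cfg$initial_lr
}

#' Train a model with SGD
#'
#' Minibatch stochastic gradient descent with momentum and weight decay
#' on the softmax cross-entropy loss. Given the same starting weights,
#' data and seed, training is deterministic. Models are trained from
#' scratch or warm-started ([finetune_model()]) with the identical loop.
#'
#' @param model A `pcenet_model`.
#' @param train_set A [labeled_image_set()]; images are resized to the
#'   model's input size if needed.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return `list(model, history)` of class `training_run`; `history` has
#'   one row per epoch (epoch, loss, lr, train_acc, seed).
#' @export
train_model <- function(model, train_set, config, verbose = FALSE) {
  stopifnot(inherits(model, "pcenet_model"),
            inherits(train_set, "labeled_image_set"),
            inherits(config, "train_config"))
  n <- dim(train_set$images)[4]
  if (n == 0L) stop("train_model: empty training set")
  if (any(train_set$labels < 0L) ||
      any(train_set$labels >= model$arch$n_classes))
    stop("train_model: labels out of range 0..",
         model$arch$n_classes - 1L)
  if (config$input_size != model$arch$input_size)
    stop("train_model: config input_size (", config$input_size,
         ") differs from the model's (", model$arch$input_size, ")")
  x <- resize_images(train_set$images, model$arch$input_size)
  y <- train_set$labels
  vel <- lapply(model$params, function(p) p * 0)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        lr = numeric(0), train_acc = numeric(0),
                        seed = integer(0))
  with_preserved_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      lr <- epoch_lr(config, ep)
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      losses <- numeric(length(batches))
      correct <- 0L
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        fw <- model_forward(model, x[, , , b, drop = FALSE],
                            training = TRUE, keep_cache = TRUE)
        model$buffers <- fw$buffers
        ls <- op_softmax_ce(fw$logits, y[b])
        losses[bi] <- ls$loss
        correct <- correct +
          sum(max.col(fw$logits, ties.method = "first") - 1L == y[b])
        if (lr > 0) {
          grads <- model_backward(model, fw$cache, ls$dlogits)
          for (pn in names(model$params)) {
            g <- grads[[pn]] + config$weight_decay * model$params[[pn]]
            vel[[pn]] <- config$momentum * vel[[pn]] - lr * g
            model$params[[pn]] <- model$params[[pn]] + vel[[pn]]
          }
        }
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = mean(losses), lr = lr,
                                  train_acc = correct / n,
                                  seed = config$seed))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  lr %.4g  acc %.3f",
                        ep, mean(losses), lr, correct / n))
    }
  })
  structure(list(model = model, history = history, config = config),
            class = "training_run")
}

#' Fine-tune a pruned model
#'
#' Retrains a compressed model starting from its surviving (copied)
#' weights; identical contract to [train_model()], provided as the
#' explicit post-pruning retraining phase. Zero epochs return the model
#' unchanged.
#'
#' @inheritParams train_model
#' @return A `training_run`.
#' @export
finetune_model <- function(model, train_set, config, verbose = FALSE) {
  train_model(model, train_set, config, verbose)
}

#' @export
print.training_run <- function(x, ...) {
  h <- x$history
  cat(sprintf("Training run: %d epochs, final loss %.4f, final train acc %.3f (seed %d)\n",
              nrow(h), if (nrow(h)) h$loss[nrow(h)] else NA,
              if (nrow(h)) h$train_acc[nrow(h)] else NA,
              x$config$seed))
  invisible(x)
}

#' Evaluate a model on a labeled set
#'
#' @param model A `pcenet_model`.
#' @param eval_set A non-empty [labeled_image_set()].
#' @param batch_size Forward-pass batch size.
#' @return Object of class `eval_report`: `accuracy`, `confusion`
#'   (rows = true class, columns = predicted class), `per_class_recall`,
#'   `n_eval`.
#' @export
evaluate_model <- function(model, eval_set, batch_size = 64L) {
  stopifnot(inherits(model, "pcenet_model"),
            inherits(eval_set, "labeled_image_set"))
  n <- dim(eval_set$images)[4]
  if (n == 0L) stop("evaluate_model: empty evaluation set")
  pred <- predict(model, eval_set, type = "class", batch_size = batch_size)
  confusion_report(eval_set$labels, pred, eval_set$class_names)
}

# Build an eval_report from true/predicted 0-based labels.
confusion_report <- function(truth, pred, class_names) {
  k <- length(class_names)
  cm <- table(factor(truth, levels = 0:(k - 1)),
              factor(pred, levels = 0:(k - 1)))
  cm <- matrix(as.integer(cm), k, k,
               dimnames = list(true = class_names, predicted = class_names))
  rs <- rowSums(cm)
  structure(list(accuracy = sum(diag(cm)) / length(truth),
                 confusion = cm,
                 per_class_recall = ifelse(rs > 0, diag(cm) / rs, NA_real_),
                 n_eval = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation: accuracy %.3f on %d images\n", x$accuracy,
              x$n_eval))
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Random train/eval split
#'
#' Disjoint, exhaustive and reproducible: the train part has
#' `round(train_fraction * n)` images (half up), the eval part the
#' rest.
#'
#' @param set A [labeled_image_set()] with at least 2 images.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed for the permutation.
#' @return `list(train, eval)` of labeled image sets tagged with their
#'   split.
#' @export
split_dataset <- function(set, train_fraction = 0.8, seed = 0L) {
  stopifnot(inherits(set, "labeled_image_set"))
  n <- dim(set$images)[4]
  if (n < 2L) stop("split_dataset: need at least 2 images")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("split_dataset: train_fraction must lie in (0, 1)")
  n_train <- as.integer(floor(train_fraction * n + 0.5))
  n_train <- min(max(n_train, 1L), n - 1L)
  perm <- with_preserved_seed(seed, sample.int(n))
  list(train = subset_image_set(set, sort(perm[seq_len(n_train)]), "train"),
       eval = subset_image_set(set, sort(perm[(n_train + 1L):n]), "eval"))
}
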