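# Training protocol and evaluation metrics.
#
# Protocol defaults follow the study conditions: plain SGD, learning rate
# 0.001, batch 32, up to 100 epochs, cross-entropy loss, early stopping on
# the monitored accuracy (patience 10, min-delta 0), ten repeats reported as
# mean +- SD. Momentum is exposed (default 0) for small-scale smoke runs.

#' Training configuration
#'
#' @param learning_rate SGD learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 32).
#' @param max_epochs Epoch cap (default 100).
#' @param momentum SGD momentum (default 0, i.e. plain SGD).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param min_delta Minimum improvement of the monitored metric (default 0).
#' @param monitor `"test_accuracy"` (the protocol default; note it monitors
#'   the held-out set) or `"train_accuracy"`.
#' @param target_train_accuracy Optional early exit once the running training
#'   accuracy (percent) reaches this value (default `NA`, disabled).
#' @param repeats Number of repeated runs for [repeat_experiment()]
#'   (default 10).
#' @param seed Base RNG seed (default 0).
#' @param shuffle Reshuffle training batches each epoch (default TRUE).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32,
                         max_epochs = 100, momentum = 0, patience = 10,
                         min_delta = 0,
                         monitor = c("test_accuracy", "train_accuracy"),
                         target_train_accuracy = NA, repeats = 10, seed = 0,
                         shuffle = TRUE) {
  stopifnot(learning_rate >= 0, batch_size >= 1, max_epochs >= 1,
            momentum >= 0, momentum < 1, patience >= 1,
            patience < max_epochs || max_epochs == 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, momentum = momentum,
                 patience = patience, min_delta = min_delta,
                 monitor = match.arg(monitor),
                 target_train_accuracy = target_train_accuracy,
                 repeats = repeats, seed = seed, shuffle = shuffle),
            class = "train_config")
}

sgd_step <- function(params, grads, vel, lr, momentum) {
  if (is.list(params)) {
    if (is.null(vel)) vel <- vector("list", length(params))
    for (nm in names(params)) {
      if (is.null(grads[[nm]])) next
      r <- sgd_step(params[[nm]], grads[[nm]], vel[[nm]], lr, momentum)
      params[[nm]] <- r$params
      vel[[nm]] <- r$vel
    }
    return(list(params = params, vel = vel))
  }
  if (is.null(vel)) vel <- params * 0
  vel <- momentum * vel + grads
  list(params = params - lr * vel, vel = vel)
}

#' Train a network
#'
#' Minimizes softmax cross-entropy with (momentum) SGD. Training stops at
#' `max_epochs`, when the monitored accuracy has not improved by more than
#' `min_delta` for `patience` consecutive epochs, or when the optional
#' training-accuracy target is reached. Deterministic for a fixed seed.
#'
#' @param network A `weednet` (freshly assembled or pre-trained).
#' @param train_data,test_data `weed_dataset` bundles; `test_data` may be
#'   `NULL` (then `monitor` falls back to training accuracy).
#' @param tc A [train_config()].
#' @param verbose Print one line per epoch (default FALSE).
#' @return List with `network` (trained), `history` (data frame with epoch,
#'   loss, train_accuracy_pct, test_accuracy_pct), and `stopped_epoch`.
#' @export
train_network <- function(network, train_data, test_data = NULL,
                          tc = train_config(), verbose = FALSE) {
  stopifnot(inherits(network, "weednet"), inherits(train_data, "weed_dataset"))
  n <- length(train_data$labels)
  monitor <- tc$monitor
  if (is.null(test_data)) monitor <- "train_accuracy"
  vel <- NULL
  history <- NULL
  best <- -Inf
  stale <- 0L
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      idx <- if (tc$shuffle) sample(n) else seq_len(n)
      epoch_loss <- 0
      correct <- 0L
      for (start in seq(1, n, by = tc$batch_size)) {
        bidx <- idx[start:min(start + tc$batch_size - 1, n)]
        xb <- train_data$images[, , , bidx, drop = FALSE]
        yb <- train_data$labels[bidx]
        fw <- network_forward(network, xb, training = TRUE)
        network <- fw$net
        ce <- softmax_xent(fw$logits, yb)
        if (!is.finite(ce$loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               call. = FALSE)
        epoch_loss <- epoch_loss + ce$loss * length(bidx)
        correct <- correct + sum(max.col(t(ce$probs), "first") - 1L == yb)
        if (tc$learning_rate > 0) {
          grads <- network_backward(network, fw$caches, ce$dlogits)
          upd <- sgd_step(network$params, grads, vel, tc$learning_rate,
                          tc$momentum)
          network$params <- upd$params
          vel <- upd$vel
        }
      }
      train_acc <- 100 * correct / n
      test_acc <- NA_real_
      if (!is.null(test_data))
        test_acc <- evaluate_network(network, test_data)$accuracy_pct
      history <- rbind(history, data.frame(
        epoch = epoch, loss = epoch_loss / n, train_accuracy_pct = train_acc,
        test_accuracy_pct = test_acc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  train %.1f%%  test %s", epoch,
                        epoch_loss / n, train_acc,
                        ifelse(is.na(test_acc), "-",
                               sprintf("%.1f%%", test_acc))))
      metric <- if (monitor == "test_accuracy") test_acc else train_acc
      if (metric > best + tc$min_delta) {
        best <- metric
        stale <- 0L
      } else stale <- stale + 1L
      if (!is.na(tc$target_train_accuracy) &&
          train_acc >= tc$target_train_accuracy) break
      if (stale >= tc$patience) break
    }
  })
  list(network = network, history = history, stopped_epoch = max(history$epoch))
}

#' Accuracy, macro-F1 and confusion matrix for fixed predictions
#'
#' @param predicted,truth Integer vectors of 0-based class labels.
#' @param num_classes Number of classes K (default: inferred).
#' @return List with `accuracy_pct`, `macro_f1_pct`, `per_class` (precision,
#'   recall, f1 per class) and `confusion` (K x K, rows = true class).
#' @export
classification_metrics <- function(predicted, truth,
                                   num_classes = max(c(predicted, truth)) + 1L) {
  stopifnot(length(predicted) == length(truth))
  k <- num_classes
  lv <- 0:(k - 1)
  confusion <- table(factor(truth, levels = lv),
                     factor(predicted, levels = lv))
  confusion <- matrix(confusion, k, k,
                      dimnames = list(true = lv, predicted = lv))
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(accuracy_pct = 100 * mean(predicted == truth),
       macro_f1_pct = 100 * mean(f1),
       per_class = data.frame(class = lv, precision = precision,
                              recall = recall, f1 = f1),
       confusion = confusion)
}

#' Evaluate a trained network on a dataset
#'
#' @param network A `weednet`.
#' @param data A `weed_dataset`.
#' @param batch_size Forward chunk size (default 32).
#' @return A `metrics_summary` (see [classification_metrics()]).
#' @export
evaluate_network <- function(network, data, batch_size = 32) {
  preds <- predict(network, data$images, type = "class",
                   batch_size = batch_size)
  m <- classification_metrics(preds, data$labels,
                              length(data$class_names))
  class(m) <- "metrics_summary"
  m
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  macro-F1 %.2f%%\n", x$accuracy_pct,
              x$macro_f1_pct))
  invisible(x)
}

#' Repeat a training experiment with re-seeded initializations
#'
#' Re-seeds the weight initialization (and batch order) for each repeat while
#' keeping the data split fixed, then reports the sample mean and standard
#' deviation of accuracy and macro-F1 on the test set.
#'
#' @param config An [arch_config()].
#' @param train_data,test_data `weed_dataset` bundles.
#' @param tc A [train_config()]; `tc$repeats` runs are performed with seeds
#'   `tc$seed + 0 ... tc$seed + repeats - 1`.
#' @param reseed Re-seed each repeat (default TRUE). With `FALSE` every
#'   repeat uses `tc$seed` and the runs are identical (SD exactly 0).
#' @return List with `summary` (metric, mean, sd), and `runs` (per-repeat
#'   accuracy/F1).
#' @export
repeat_experiment <- function(config, train_data, test_data,
                              tc = train_config(), reseed = TRUE) {
  stopifnot(tc$repeats >= 2)
  runs <- lapply(seq_len(tc$repeats) - 1L, function(r) {
    tcr <- tc
    tcr$seed <- if (reseed) tc$seed + r else tc$seed
    net <- assemble_network(config, seed = tcr$seed)
    fit <- train_network(net, train_data, test_data, tcr)
    m <- evaluate_network(fit$network, test_data)
    data.frame(repeat_ = r, accuracy_pct = m$accuracy_pct,
               macro_f1_pct = m$macro_f1_pct,
               epochs = fit$stopped_epoch)
  })
  runs <- do.call(rbind, runs)
  summary <- data.frame(
    metric = c("accuracy_pct", "macro_f1_pct"),
    mean = c(mean(runs$accuracy_pct), mean(runs$macro_f1_pct)),
    sd = c(stats::sd(runs$accuracy_pct), stats::sd(runs$macro_f1_pct)))
  list(summary = summary, runs = runs)
}
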