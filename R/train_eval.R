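# Nesterov-momentum SGD training and evaluation metrics.

#' Training configuration
#'
#' Defaults mirror the histopathology protocol: mini-batches of 20,
#' momentum 0.9, weight decay 1e-4, 300 epochs, three repeats.
#'
#' @param scheduler an `lr_schedule`.
#' @param batch_size mini-batch size (>= 1).
#' @param momentum momentum coefficient `m`, in \[0, 1).
#' @param weight_decay L2 coefficient added to the gradient (coupled decay).
#' @param epochs training epochs; defaults to the scheduler's horizon.
#' @param seed base RNG seed for shuffling/augmentation/initialization.
#' @param repeats independent runs for the repeat protocol.
#' @param augment apply random shift/flip augmentation to each training
#'   batch.
#' @param shift_frac augmentation shift fraction.
#' @return an object of class `train_config`.
#' @export
train_config <- function(scheduler, batch_size = 20, momentum = 0.9,
                         weight_decay = 1e-4, epochs = scheduler$epochs,
                         seed = 1L, repeats = 3L, augment = FALSE,
                         shift_frac = 0.125) {
  if (!inherits(scheduler, "lr_schedule")) stopf("'scheduler' must be an lr_schedule")
  check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_number(momentum, "momentum", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(weight_decay, "weight_decay", lower = 0)
  if (is.null(epochs)) stopf("scheduler has no horizon; supply 'epochs'")
  check_number(epochs, "epochs", lower = 1, integer = TRUE)
  structure(list(scheduler = scheduler, batch_size = as.integer(batch_size),
                 momentum = momentum, weight_decay = weight_decay,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 repeats = as.integer(repeats), augment = isTRUE(augment),
                 shift_frac = shift_frac),
            class = "train_config")
}

#' One Nesterov-momentum SGD step
#'
#' Evaluates the gradient at the interim point \eqn{\tilde\theta = \theta +
#' m v}, then updates \eqn{v \leftarrow m v - \varepsilon g} and
#' \eqn{\theta \leftarrow \theta + v}. Weight decay is added to the gradient
#' as an L2 term (`g + wd * theta_interim`) before the velocity update.
#' Parameters may be a plain numeric vector or an arbitrarily nested list of
#' arrays (as used by the networks); the velocity mirrors their structure.
#'
#' @param state list with `theta` (parameters) and `v` (velocity; zeros of
#'   the same structure on the first call).
#' @param grad_fn function of the (interim) parameters returning a list
#'   with at least `loss` and `grad` (gradient, same structure as `theta`).
#' @param lr learning rate \eqn{\varepsilon} for this step (from the
#'   epoch's scheduler value).
#' @param momentum,weight_decay see [train_config()].
#' @return the updated `state`, with `loss` and any extra fields returned
#'   by `grad_fn` attached.
#' @export
nesterov_step <- function(state, grad_fn, lr, momentum = 0.9,
                          weight_decay = 0) {
  interim <- if (momentum == 0) state$theta
             else ptree_map2(state$theta, state$v,
                             function(t, v) t + momentum * v)
  res <- grad_fn(interim)
  if (!is.finite(res$loss))
    stopf("non-finite loss (%s) during training; lr=%g", res$loss, lr)
  g <- if (weight_decay > 0)
    ptree_map2(res$grad, interim, function(g, t) g + weight_decay * t)
  else res$grad
  state$v <- ptree_map2(state$v, g, function(v, g) momentum * v - lr * g)
  state$theta <- ptree_map2(state$theta, state$v, `+`)
  state$loss <- res$loss
  state$extra <- res[setdiff(names(res), c("loss", "grad"))]
  state
}

#' Train a network
#'
#' Runs mini-batch Nesterov SGD for `config$epochs` epochs. The learning
#' rate is recomputed from the scheduler once per epoch; batches are
#' reshuffled each epoch; optional shift/flip augmentation is applied per
#' batch. Deterministic for a given `config$seed`.
#'
#' @param model a [build_network()] model (trained in place functionally;
#'   the returned copy carries the final weights).
#' @param x training images `(H, W, 3, N)`, already preprocessed.
#' @param y integer class labels (1..K).
#' @param config a [train_config()].
#' @return an object of class `bhcnet_fit`: list with `model` and `log`
#'   (data.frame: epoch, lr, loss, accuracy).
#' @export
train_network <- function(model, x, y, config) {
  n <- length(y)
  if (n == 0L) stopf("empty training set")
  if (dim(x)[4] != n) stopf("x/y size mismatch")
  state <- list(theta = model$params, v = ptree_zero(model$params))
  log <- vector("list", config$epochs)
  net <- model
  with_seed(config$seed, {
    for (e in seq_len(config$epochs)) {
      eps <- schedule_rate(config$scheduler, e)
      ord <- sample.int(n)
      losses <- accs <- c()
      for (b in seq_len(ceiling(n / config$batch_size))) {
        ix <- ord[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, n)]
        xb <- x[, , , ix, drop = FALSE]
        if (config$augment)
          for (j in seq_along(ix))
            xb[, , , j] <- augment_image(xb[, , , j], config$shift_frac)
        yb <- y[ix]
        grad_fn <- function(theta) {
          net$params <<- theta
          r <- network_loss_grad(net, xb, yb, train = TRUE)
          net$buffers <<- r$buffers
          list(loss = r$loss, grad = r$grads, acc = r$acc)
        }
        state <- nesterov_step(state, grad_fn, eps, config$momentum,
                               config$weight_decay)
        losses <- c(losses, state$loss)
        accs <- c(accs, state$extra$acc)
      }
      log[[e]] <- data.frame(epoch = e, lr = eps, loss = mean(losses),
                             accuracy = mean(accs))
    }
  })
  net$params <- state$theta
  structure(list(model = net, log = do.call(rbind, log), config = config),
            class = "bhcnet_fit")
}

#' Repeat-protocol training
#'
#' Trains `repeats` independent models (fresh He initialization and data
#' order, seeds `seed, seed+1, ...`), evaluates each on the test set, and
#' summarizes test accuracy as mean +/- standard deviation in percent.
#'
#' @param spec architecture spec (or registry name) rebuilt per run.
#' @param train_data,test_data lists with `x` and `y` (see [load_images()]).
#' @param config a [train_config()].
#' @return list with `runs` (per-run fits and reports), `accuracies`
#'   (percent), and `summary` (formatted like `"98.87 ± 0.10"`).
#' @export
train_repeated <- function(spec, train_data, test_data, config) {
  runs <- lapply(seq_len(config$repeats) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    model <- build_network(spec, seed = cfg$seed)
    fit <- train_network(model, train_data$x, train_data$y, cfg)
    rep <- evaluate_network(fit$model, test_data$x, test_data$y)
    list(fit = fit, report = rep)
  })
  acc <- vapply(runs, function(r) 100 * r$report$accuracy, numeric(1))
  list(runs = runs, accuracies = acc, summary = format_mean_sd(acc))
}

format_mean_sd <- function(x) {
  sprintf("%.2f ± %.2f", mean(x), if (length(x) > 1) sd(x) else 0)
}

# --- metrics ----------------------------------------------------------------

#' Confusion matrix
#'
#' @param true,pred integer class labels (1..K).
#' @param K number of classes.
#' @return integer `K x K` matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true, pred, K = max(true, pred)) {
  cm <- matrix(0L, K, K)
  for (i in seq_along(true)) cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1L
  cm
}

#' Matthews correlation coefficient
#'
#' For a 2x2 confusion matrix this is the classical
#' \eqn{(TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}; for K > 2
#' the standard multi-category generalization over the full confusion
#' matrix is used (they coincide at K = 2). Returns 0 when any marginal is
#' zero (degenerate predictor convention).
#'
#' @param cm square nonnegative confusion matrix (rows = true).
#' @return a value in \[-1, 1\].
#' @export
mcc <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stopf("'cm' must be square")
  if (any(cm < 0)) stopf("'cm' must be nonnegative")
  cm <- matrix(as.numeric(cm), nrow(cm))
  s <- sum(cm); tr <- sum(diag(cm))
  t <- rowSums(cm); p <- colSums(cm)
  num <- tr * s - sum(p * t)
  den <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
  if (den == 0) return(0)
  num / den
}

#' Per-class and macro metrics from a confusion matrix
#'
#' Precision, recall and F-measure per class (0 when the denominator is
#' empty), their unweighted macro averages, overall accuracy, and the
#' Matthews correlation.
#'
#' @param cm confusion matrix, rows = true class.
#' @return list with `accuracy`, `precision`, `recall`, `f1` (per class),
#'   `macro_precision`, `macro_recall`, `macro_f1`, `mcc`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- matrix(as.numeric(cm), nrow(cm))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = sum(tp) / sum(cm), precision = prec, recall = rec, f1 = f1,
       macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1), mcc = mcc(cm))
}

#' Macro one-vs-rest AUC
#'
#' Rank-based (Mann-Whitney) AUC of each class's predicted probability
#' against the rest, averaged over classes present with both positives and
#' negatives; `NA` if no class qualifies (e.g. a single-class test set).
#'
#' @param probs `K x N` probability matrix.
#' @param y integer labels (1..K).
#' @return macro AUC in \[0, 1\], or `NA`.
#' @export
auc_ovr_macro <- function(probs, y) {
  K <- nrow(probs)
  aucs <- c()
  for (k in seq_len(K)) {
    pos <- y == k
    if (!any(pos) || all(pos)) next
    r <- rank(probs[k, ])
    npos <- sum(pos); nneg <- sum(!pos)
    aucs <- c(aucs, (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg))
  }
  if (!length(aucs)) NA_real_ else mean(aucs)
}

#' Evaluate a network on a test set
#'
#' @param model a `bhcnet_network`.
#' @param x test images `(H, W, 3, N)`, preprocessed with the training-set
#'   statistics.
#' @param y integer labels (1..K).
#' @param class_names optional label names for the report.
#' @return an object of class `eval_report`: confusion matrix, accuracy,
#'   macro precision/recall/F-measure, MCC, macro one-vs-rest AUC, and the
#'   per-class breakdown.
#' @export
evaluate_network <- function(model, x, y, class_names = NULL) {
  if (!length(y)) stopf("empty test set")
  probs <- predict(model, x, type = "prob")
  pred <- max.col(t(probs), ties.method = "first")
  K <- model$spec$num_classes
  cm <- confusion_matrix(y, pred, K)
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  predicted = class_names)
  m <- metrics_from_confusion(cm)
  structure(c(list(confusion = cm, auc = auc_ovr_macro(probs, y),
                   n = length(y)), m),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d images\n", x$n))
  cat(sprintf("  accuracy        %6.2f%%\n", 100 * x$accuracy))
  cat(sprintf("  macro precision %6.2f%%\n", 100 * x$macro_precision))
  cat(sprintf("  macro recall    %6.2f%%\n", 100 * x$macro_recall))
  cat(sprintf("  macro F-measure %6.2f%%\n", 100 * x$macro_f1))
  cat(sprintf("  MCC             %6.2f%%\n", 100 * x$mcc))
  cat(sprintf("  AUC (macro OvR) %s\n",
              if (is.na(x$auc)) "n/a" else sprintf("%6.2f%%", 100 * x$auc)))
  cat("  confusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @export
report_to_json <- function(report, path) {
  out <- unclass(report)
  out$confusion <- unname(apply(report$confusion, 1, as.integer, simplify = FALSE))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
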