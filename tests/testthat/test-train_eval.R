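test_that("nesterov_step matches the hand-computed quadratic step", {
  # L(theta) = theta^2 / 2: interim 1.0, g = 1.0, v = -0.1, theta = 0.9
  grad_fn <- function(th) list(loss = th^2 / 2, grad = th)
  st <- list(theta = 1, v = 0)
  st <- nesterov_step(st, grad_fn, lr = 0.1, momentum = 0.9, weight_decay = 0)
  expect_equal(st$v, -0.1)
  expect_equal(st$theta, 0.9)
  expect_equal(st$loss, 0.5)
  # g = 0 and v = 0 is a fixed point
  z <- nesterov_step(list(theta = 3, v = 0),
                     function(th) list(loss = 0, grad = 0 * th), lr = 0.1)
  expect_equal(z$theta, 3)
  expect_error(nesterov_step(list(theta = 1, v = 0),
                             function(th) list(loss = NaN, grad = th), 0.1),
               "non-finite")
})

test_that("nesterov_step matches an explicit-formula oracle over 10 steps", {
  # 3-parameter quadratic L = 0.5 * sum(a * theta^2), exact recursion oracle
  a <- c(1, 0.5, 2)
  m <- 0.9; lr <- 0.05; wd <- 0.01
  theta_ref <- c(1, -2, 0.5); v_ref <- c(0, 0, 0)
  st <- list(theta = theta_ref, v = v_ref)
  grad_fn <- function(th) list(loss = 0.5 * sum(a * th^2), grad = a * th)
  for (k in 1:10) {
    interim <- theta_ref + m * v_ref
    g <- a * interim + wd * interim
    v_ref <- m * v_ref - lr * g
    theta_ref <- theta_ref + v_ref
    st <- nesterov_step(st, grad_fn, lr, m, wd)
  }
  expect_equal(st$theta, theta_ref, tolerance = 1e-10)
  expect_equal(st$v, v_ref, tolerance = 1e-10)
})

test_that("momentum zero reduces to plain SGD, including on parameter trees", {
  grad_fn <- function(th) list(loss = 0, grad = lapply(th, function(x) x * 2))
  theta <- list(a = c(1, 2), b = matrix(1:4 / 10, 2))
  st <- list(theta = theta, v = bhcnet:::ptree_zero(theta))
  st <- nesterov_step(st, grad_fn, lr = 0.25, momentum = 0)
  expect_equal(st$theta$a, c(1, 2) - 0.25 * 2 * c(1, 2))
  expect_equal(st$theta$b, matrix(1:4 / 10, 2) * 0.5)
  expect_identical(dim(st$theta$b), c(2L, 2L))
})

test_that("confusion metrics match from-definition oracles on random matrices", {
  set.seed(123)
  for (rep in 1:200) {
    K <- sample(2:8, 1)
    cm <- matrix(rpois(K * K, lambda = sample(c(1, 5, 20), 1)), K, K)
    if (sum(cm) == 0) cm[1, 1] <- 1
    m <- metrics_from_confusion(cm)
    # definition oracle, written independently with scalar loops
    prec <- rec <- f1 <- numeric(K)
    for (k in 1:K) {
      tp <- cm[k, k]; colsum <- sum(cm[, k]); rowsum <- sum(cm[k, ])
      prec[k] <- if (colsum > 0) tp / colsum else 0
      rec[k] <- if (rowsum > 0) tp / rowsum else 0
      f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
    }
    expect_equal(m$macro_precision, mean(prec))
    expect_equal(m$macro_recall, mean(rec))
    expect_equal(m$macro_f1, mean(f1))
    expect_equal(m$accuracy, sum(diag(cm)) / sum(cm))
    # MCC oracle: covariance form over indicator matrices
    n <- sum(cm)
    cov_xy <- sum(diag(cm)) * n - sum(rowSums(cm) * colSums(cm))
    cov_xx <- n^2 - sum(rowSums(cm)^2)
    cov_yy <- n^2 - sum(colSums(cm)^2)
    want <- if (cov_xx == 0 || cov_yy == 0) 0 else cov_xy / sqrt(cov_xx * cov_yy)
    expect_equal(m$mcc, want)
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
  }
})

test_that("binary MCC agrees with the classical TP/TN/FP/FN formula", {
  cm <- matrix(c(6, 1, 2, 11), 2)  # rows true: (6,2 / 1,11)
  tp <- 6; fn <- 2; fp <- 1; tn <- 11
  classical <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(mcc(cm), classical)
  expect_equal(mcc(diag(c(10, 10))), 1)
  expect_equal(mcc(matrix(c(0, 10, 10, 0), 2)), -1)
  # all-one-class predictor on a balanced set: zero marginal convention
  expect_identical(mcc(matrix(c(25, 25, 0, 0), 2)), 0)
  expect_error(mcc(matrix(0, 2, 3)), "square")
})

test_that("one-vs-rest AUC is the rank statistic and degenerates to NA", {
  probs <- rbind(c(0.9, 0.8, 0.3, 0.1), c(0.1, 0.2, 0.7, 0.9))
  y <- c(1L, 1L, 2L, 2L)
  expect_equal(auc_ovr_macro(probs, y), 1)
  expect_equal(auc_ovr_macro(probs[, c(3, 4, 1, 2)], y), 0)
  # ties give 0.5 via midranks
  expect_equal(auc_ovr_macro(matrix(0.5, 2, 4), y), 0.5)
  expect_true(is.na(auc_ovr_macro(probs, c(1L, 1L, 1L, 1L))))
})

test_that("evaluate_network produces a complete, consistent report", {
  net <- build_network(bhcnet_spec(1, num_classes = 2, input_size = 8,
                                   widths = c(3L, 4L, 5L)), seed = 2)
  set.seed(20)
  x <- array(rnorm(8 * 8 * 3 * 12), c(8, 8, 3, 12))
  y <- rep(1:2, 6)
  rep_ <- evaluate_network(net, x, y, class_names = c("benign", "malignant"))
  expect_s3_class(rep_, "eval_report")
  expect_identical(sum(rep_$confusion), 12L)
  expect_identical(rownames(rep_$confusion), c("benign", "malignant"))
  for (f in c("accuracy", "macro_precision", "macro_recall", "macro_f1"))
    expect_true(rep_[[f]] >= 0 && rep_[[f]] <= 1)
  expect_true(rep_$mcc >= -1 && rep_$mcc <= 1)
  f <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep_, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$accuracy, rep_$accuracy)
  bc <- back$confusion
  if (is.list(bc)) bc <- do.call(rbind, bc)
  expect_equal(unname(bc), unname(rep_$confusion), ignore_attr = TRUE)
})

test_that("a short training run learns a separable toy and logs the schedule", {
  # linearly separable two-class images: channel-mean offset of opposite sign
  set.seed(30)
  n <- 40
  x <- array(rnorm(8 * 8 * 3 * n, sd = 0.3), c(8, 8, 3, n))
  y <- rep(1:2, each = n / 2)
  x[, , , y == 1] <- x[, , , y == 1] + 1
  x[, , , y == 2] <- x[, , , y == 2] - 1
  net <- build_network(bhcnet_spec(1, num_classes = 2, input_size = 8,
                                   widths = c(3L, 4L, 5L)), seed = 4)
  sched <- erf_schedule(0.05, 1e-3, -3, 3, 5)
  cfg <- train_config(sched, batch_size = 10, epochs = 5, seed = 1,
                      weight_decay = 1e-4)
  fit <- train_network(net, x, y, cfg)
  expect_identical(nrow(fit$log), 5L)
  # the logged rate sequence is exactly the scheduler table
  expect_equal(fit$log$lr, tabulate_schedule(sched)$learning_rate)
  expect_lt(fit$log$loss[5], fit$log$loss[1])
  # determinism of the whole loop
  fit2 <- train_network(build_network(bhcnet_spec(1, num_classes = 2,
                                                  input_size = 8,
                                                  widths = c(3L, 4L, 5L)),
                                      seed = 4), x, y, cfg)
  expect_identical(fit$log, fit2$log)
  expect_error(train_network(net, x[, , , 0, drop = FALSE], integer(), cfg),
               "empty")
})

test_that("train_repeated summarizes repeats in mean-sd form", {
  set.seed(40)
  n <- 24
  x <- array(rnorm(8 * 8 * 3 * n, sd = 0.3), c(8, 8, 3, n))
  y <- rep(1:2, each = n / 2)
  x[, , , y == 1] <- x[, , , y == 1] + 1
  x[, , , y == 2] <- x[, , , y == 2] - 1
  sched <- erf_schedule(0.05, 1e-3, -3, 3, 2)
  cfg <- train_config(sched, batch_size = 12, epochs = 2, seed = 1, repeats = 2)
  res <- train_repeated(bhcnet_spec(1, num_classes = 2, input_size = 8,
                                    widths = c(3L, 4L, 5L)),
                        list(x = x, y = y), list(x = x, y = y), cfg)
  expect_length(res$accuracies, 2)
  expect_match(res$summary, "^\\d+\\.\\d{2} ± \\d+\\.\\d{2}$")
  # distinct seeds give distinct runs
  expect_false(identical(res$runs[[1]]$fit$log$loss, res$runs[[2]]$fit$log$loss))
})
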