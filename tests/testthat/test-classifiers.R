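make_mlp <- function(w1, b1, w2, b2, classes) {
  structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, classes = classes,
                 hidden_size = nrow(w1), learning_rate = 0.01,
                 epochs_run = 0L, seed = 1L, loss = numeric(0)),
            class = "ecg_mlp")
}

blobs <- function(n = 100, seed = 1, sep = 4) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n), n / 2),
             matrix(rnorm(n, mean = sep), n / 2))
  list(x = x, y = factor(rep(c("a", "b"), each = n / 2)))
}

test_that("forward pass reproduces closed-form values", {
  m0 <- make_mlp(matrix(0, 3, 2), rep(0, 3), matrix(0, 4, 3), rep(0, 4),
                 c("N", "LBBB", "RBBB", "P"))
  sc <- mlp_forward(m0, c(1.7, -2.4))
  expect_equal(unname(sc[1, ]), rep(0.5, 4))  # zero net input everywhere
  # 1 hidden unit, unit weights, no bias: sigmoid(sigmoid(1))
  m1 <- make_mlp(matrix(c(1, 0), 1, 2), 0, matrix(1, 1, 1), 0, "a")
  sig <- function(z) 1 / (1 + exp(-z))
  expect_equal(unname(mlp_forward(m1, c(1, 0))[1, 1]), sig(sig(1)))
  expect_error(mlp_forward(m1, c(1, 2, 3)), "expected 2 features")
})

test_that("backprop gradient matches numerical differentiation", {
  set.seed(123)
  for (trial in 1:3) {
    p <- sample(2:6, 1); h <- sample(2:5, 1); k <- sample(2:4, 1); n <- 7
    m <- make_mlp(matrix(rnorm(h * p), h, p), rnorm(h),
                  matrix(rnorm(k * h), k, h), rnorm(k), paste0("c", 1:k))
    x <- matrix(rnorm(n * p), n, p)
    target <- diag(k)[, sample(k, n, replace = TRUE), drop = FALSE]
    g <- wavecg:::.mlp_gradient(m, x, target)
    eps <- 1e-6
    num_grad <- function(field, i, j) {
      mp <- m; mm <- m
      if (is.matrix(m[[field]])) {
        mp[[field]][i, j] <- mp[[field]][i, j] + eps
        mm[[field]][i, j] <- mm[[field]][i, j] - eps
      } else {
        mp[[field]][i] <- mp[[field]][i] + eps
        mm[[field]][i] <- mm[[field]][i] - eps
      }
      (wavecg:::.mlp_loss(mp, x, target) -
         wavecg:::.mlp_loss(mm, x, target)) / (2 * eps)
    }
    worst <- 0
    for (field in c("w1", "w2")) {
      for (i in seq_len(nrow(m[[field]]))) {
        for (j in seq_len(ncol(m[[field]]))) {
          worst <- max(worst, abs(g[[field]][i, j] - num_grad(field, i, j)))
        }
      }
    }
    for (field in c("b1", "b2")) {
      for (i in seq_along(m[[field]])) {
        worst <- max(worst, abs(g[[field]][i] - num_grad(field, i, 1)))
      }
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("training separates Gaussian blobs and is seed-reproducible", {
  d <- blobs(n = 100, seed = 42)
  m <- mlp_train(d$x, d$y, hidden_size = 5, learning_rate = 0.1,
                 epochs = 500, seed = 7)
  expect_gte(evaluate_classifier(m, d$x, d$y)$accuracy, 0.99)
  # loss broadly decreases over training
  expect_lt(m$loss[length(m$loss)], 0.5 * m$loss[1])
  m2 <- mlp_train(d$x, d$y, hidden_size = 5, learning_rate = 0.1,
                  epochs = 500, seed = 7)
  expect_identical(m$w1, m2$w1)
  expect_identical(m$w2, m2$w2)
  expect_error(mlp_train(d$x, rep("a", nrow(d$x))), "2 classes")
})

test_that("SVM kernels handle XOR and separable data", {
  set.seed(5)
  n <- 200
  x <- matrix(runif(2 * n, -1, 1), n)
  y <- factor(ifelse(x[, 1] * x[, 2] > 0, "pos", "neg"))
  m <- svm_train(x, y, kernel = "rbf", cost = 100, gamma = 2)
  expect_equal(evaluate_classifier(m, x, y)$accuracy, 1.0)
  d <- blobs(n = 100, seed = 9, sep = 6)
  mq <- svm_train(d$x, d$y, kernel = "quadratic", cost = 10)
  expect_equal(evaluate_classifier(mq, d$x, d$y)$accuracy, 1.0)
  mp <- svm_train(d$x, d$y, kernel = "polynomial")
  expect_s3_class(mp, "ecg_svm")
  expect_error(svm_train(d$x, d$y, kernel = "sigmoid"), "arg")
})

test_that("evaluate_classifier tallies the confusion table like a hand count", {
  truth <- factor(c("a", "a", "a", "b", "b", "b", "c", "c", "c", "c"))
  pred <- factor(c("a", "a", "b", "b", "b", "c", "c", "c", "a", "c"))
  fake <- structure(list(pred = pred), class = "fake_clf")
  # predict method for the stub classifier
  assign("predict.fake_clf", function(object, newdata, ...) object$pred,
         envir = globalenv())
  on.exit(rm("predict.fake_clf", envir = globalenv()))
  ev <- evaluate_classifier(fake, matrix(0, 10, 1), truth)
  expect_equal(ev$accuracy, 7 / 10)
  expect_equal(as.vector(ev$confusion["a", ]), c(2L, 1L, 0L))
  expect_equal(as.vector(ev$confusion["c", ]), c(1L, 0L, 3L))
  expect_error(evaluate_classifier(fake, matrix(0, 0, 1), factor()), "empty")
})

test_that("four synthetic beat classes are separable on held-out data", {
  fd <- generate_feature_dataset(
    synthesis_config(seed = 77, noise = noise_preset("clean")),
    n_per_class = 40)
  x <- normalize_features(fd)
  y <- factor(fd$label)
  set.seed(31)
  test_idx <- unlist(lapply(split(seq_along(y), y),
                            function(i) sample(i, round(0.3 * length(i)))))
  msv <- svm_train(x[-test_idx, ], y[-test_idx], kernel = "rbf")
  expect_gte(evaluate_classifier(msv, x[test_idx, ], y[test_idx])$accuracy, 0.95)
})
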