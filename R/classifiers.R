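# Beat classifiers: a from-scratch single-hidden-layer perceptron trained by
# per-sample gradient descent with the delta rule (sigmoid activations,
# one-hot targets, squared error), and a kernel SVM (e1071 solver) with the
# quadratic / polynomial / radial-basis kernels, one-vs-one multiclass.

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a multilayer perceptron beat classifier
#'
#' One hidden layer of sigmoid units and a sigmoid output layer (one unit
#' per class, one-hot targets), trained by per-sample stochastic gradient
#' descent with the delta rule: each weight moves by
#' `learning_rate * delta_j * a_i`, where `delta` carries the
#' sigmoid-derivative backpropagated error. Bias units are included in both
#' layers. The presentation order is reshuffled every epoch from the seeded
#' RNG stream, so training is exactly reproducible.
#'
#' @param x Numeric feature matrix (rows = beats; normalized, see
#'   [normalize_features()]). The ECG chain uses 8 columns.
#' @param y Class labels (factor or character); at least two classes.
#' @param hidden_size Hidden units. Default 10.
#' @param learning_rate Step size eta. Default 0.01.
#' @param epochs Maximum passes over the data. Default 500; training stops
#'   early when the epoch loss plateaus.
#' @param seed Integer seed controlling weight initialization and the
#'   shuffle schedule.
#' @param patience Consecutive plateau epochs tolerated before stopping.
#' @return An object of class `"ecg_mlp"`: weight matrices `w1`, `w2`, bias
#'   vectors `b1`, `b2`, `classes`, per-epoch `loss`, and the call
#'   parameters.
#' @seealso [mlp_forward()], [predict.ecg_mlp()]
#' @export
mlp_train <- function(x, y, hidden_size = 10, learning_rate = 0.01,
                      epochs = 500, seed = 1, patience = 10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes to train")
  if (nrow(x) != length(y)) stop("x rows and y length differ")
  n <- nrow(x); p <- ncol(x); k <- nlevels(y)
  set.seed(as.integer(seed))
  w1 <- matrix(stats::runif(hidden_size * p, -0.5, 0.5), hidden_size, p)
  b1 <- stats::runif(hidden_size, -0.5, 0.5)
  w2 <- matrix(stats::runif(k * hidden_size, -0.5, 0.5), k, hidden_size)
  b2 <- stats::runif(k, -0.5, 0.5)
  target <- diag(k)[, as.integer(y), drop = FALSE]  # k x n one-hot
  eta <- learning_rate
  loss_hist <- numeric(0)
  flat <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    loss <- 0
    for (i in ord) {
      xi <- x[i, ]
      h <- .sigmoid(w1 %*% xi + b1)
      o <- .sigmoid(w2 %*% h + b2)
      e <- target[, i] - o
      loss <- loss + 0.5 * sum(e^2)
      delta_o <- e * o * (1 - o)
      delta_h <- (h * (1 - h)) * crossprod(w2, delta_o)
      w2 <- w2 + eta * tcrossprod(delta_o, h)
      b2 <- b2 + eta * as.vector(delta_o)
      w1 <- w1 + eta * tcrossprod(delta_h, xi)
      b1 <- b1 + eta * as.vector(delta_h)
    }
    loss <- loss / n
    if (length(loss_hist) &&
        loss > loss_hist[length(loss_hist)] - 1e-9 * max(1, loss_hist[length(loss_hist)])) {
      flat <- flat + 1L
    } else {
      flat <- 0L
    }
    loss_hist <- c(loss_hist, loss)
    if (flat >= patience) break
  }
  structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2,
                 classes = levels(y), hidden_size = hidden_size,
                 learning_rate = learning_rate, epochs_run = length(loss_hist),
                 seed = seed, loss = loss_hist),
            class = "ecg_mlp")
}

#' Forward pass of the perceptron
#'
#' @param model An `"ecg_mlp"`.
#' @param x Numeric vector (one beat) or matrix (rows = beats).
#' @return Matrix of class scores in (0, 1), one row per input row, columns
#'   named by class.
#' @export
mlp_forward <- function(model, x) {
  stopifnot(inherits(model, "ecg_mlp"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$w1)) {
    stop(sprintf("expected %d features, got %d", ncol(model$w1), ncol(x)))
  }
  h <- .sigmoid(tcrossprod(x, model$w1) +
                  matrix(model$b1, nrow(x), length(model$b1), byrow = TRUE))
  o <- .sigmoid(tcrossprod(h, model$w2) +
                  matrix(model$b2, nrow(x), length(model$b2), byrow = TRUE))
  colnames(o) <- model$classes
  o
}

# Full-batch analytic gradient of the summed squared-error loss; used by the
# gradient-check tests against numerical differentiation.
.mlp_gradient <- function(model, x, target) {
  x <- as.matrix(x)
  g_w1 <- model$w1 * 0; g_b1 <- model$b1 * 0
  g_w2 <- model$w2 * 0; g_b2 <- model$b2 * 0
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    h <- .sigmoid(model$w1 %*% xi + model$b1)
    o <- .sigmoid(model$w2 %*% h + model$b2)
    e <- target[, i] - o
    delta_o <- e * o * (1 - o)
    delta_h <- (h * (1 - h)) * crossprod(model$w2, delta_o)
    g_w2 <- g_w2 - tcrossprod(delta_o, h)   # gradient of loss (descent dir = -g)
    g_b2 <- g_b2 - as.vector(delta_o)
    g_w1 <- g_w1 - tcrossprod(delta_h, xi)
    g_b1 <- g_b1 - as.vector(delta_h)
  }
  list(w1 = g_w1, b1 = g_b1, w2 = g_w2, b2 = g_b2)
}

.mlp_loss <- function(model, x, target) {
  o <- mlp_forward(model, x)
  0.5 * sum((t(target) - o)^2)
}

#' @export
print.ecg_mlp <- function(x, ...) {
  cat(sprintf(
    "MLP beat classifier: %d-%d-%d, eta=%g, %d epoch(s), final loss %.4g\n",
    ncol(x$w1), x$hidden_size, length(x$classes), x$learning_rate,
    x$epochs_run, x$loss[length(x$loss)]))
  invisible(x)
}

#' Predict beat classes with a trained perceptron
#'
#' @param object An `"ecg_mlp"`.
#' @param newdata Feature matrix or vector.
#' @param ... Unused.
#' @return Factor of predicted classes (argmax of the output scores; ties
#'   resolve to the lowest class index).
#' @export
predict.ecg_mlp <- function(object, newdata, ...) {
  sc <- mlp_forward(object, newdata)
  factor(object$classes[apply(sc, 1, which.max)], levels = object$classes)
}

#' Train a kernel SVM beat classifier
#'
#' Maximum-margin kernel classifier (one-vs-one for more than two classes).
#' `"quadratic"` is a degree-2 polynomial kernel, `"polynomial"` degree 3,
#' `"rbf"` the radial basis kernel. The solver is e1071's SMO
#' implementation; inputs are expected pre-normalized so internal scaling is
#' disabled.
#'
#' @param x Numeric feature matrix.
#' @param y Class labels; at least two classes.
#' @param kernel `"rbf"` (default), `"quadratic"` or `"polynomial"`.
#' @param cost Regularization constant C. Default 1.
#' @param gamma Kernel width; default `1/ncol(x)`.
#' @param degree Polynomial degree override for `kernel = "polynomial"`.
#' @return An object of class `"ecg_svm"` wrapping the fitted solver.
#' @export
svm_train <- function(x, y, kernel = c("rbf", "quadratic", "polynomial"),
                      cost = 1, gamma = NULL, degree = 3) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes to train")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  args <- switch(kernel,
    rbf = list(kernel = "radial", gamma = gamma),
    quadratic = list(kernel = "polynomial", degree = 2, gamma = gamma,
                     coef0 = 1),
    polynomial = list(kernel = "polynomial", degree = degree, gamma = gamma,
                      coef0 = 1)
  )
  fit <- do.call(e1071::svm,
                 c(list(x = x, y = y, cost = cost, scale = FALSE), args))
  structure(list(fit = fit, kernel = kernel, classes = levels(y),
                 cost = cost), class = "ecg_svm")
}

#' @export
print.ecg_svm <- function(x, ...) {
  cat(sprintf("SVM beat classifier: %s kernel, C=%g, %d support vectors, %d classes\n",
              x$kernel, x$cost, x$fit$tot.nSV, length(x$classes)))
  invisible(x)
}

#' Predict beat classes with a trained SVM
#'
#' @param object An `"ecg_svm"`.
#' @param newdata Feature matrix or vector.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.ecg_svm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  stats::predict(object$fit, as.matrix(newdata))
}

#' Evaluate a beat classifier
#'
#' @param model An `"ecg_mlp"` or `"ecg_svm"` (anything with a `predict`
#'   method returning class labels).
#' @param x Feature matrix.
#' @param y True class labels.
#' @return List with `confusion` (true classes in rows, predictions in
#'   columns) and `accuracy` (fraction correct, trace over total).
#' @export
evaluate_classifier <- function(model, x, y) {
  if (NROW(x) == 0L) stop("empty evaluation set")
  pred <- stats::predict(model, x)
  lev <- union(levels(factor(y)), levels(factor(pred)))
  confusion <- table(truth = factor(y, levels = lev),
                     predicted = factor(pred, levels = lev))
  list(confusion = confusion,
       accuracy = sum(diag(confusion)) / sum(confusion))
}
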