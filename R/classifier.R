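#' Multinomial linear classifier on embedding vectors
#'
#' A deliberately small, fully deterministic trainer used by the benchmark:
#' softmax regression on the raw embedding vectors, fitted by full-batch
#' gradient descent on the categorical cross-entropy for a fixed number of
#' epochs. When a validation split is supplied, the weights with the lowest
#' validation loss seen during training are kept (mirroring best-checkpoint
#' selection). This stands in for fine-tuning an image classifier at desk
#' scale; the benchmark's trainer contract accepts any drop-in replacement.
#'
#' @param x n x d numeric matrix of training embeddings
#' @param y training labels, coerced to a factor over `classLevels`
#' @param classLevels full class set the model predicts over
#' @param epochs gradient-descent epochs (default 200)
#' @param lr learning rate (default 0.1)
#' @param seed seed for the weight initialization
#' @param xVal,yVal optional validation split for best-epoch selection
#' @return an object of class `softmaxModel` with a `predict` method
#' @export
softmaxTrain <- function(x, y, classLevels, epochs = 200L, lr = 0.1,
                         seed = 1L, xVal = NULL, yVal = NULL) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = classLevels)
  if (anyNA(y)) stop("training labels outside classLevels")
  n <- nrow(x); d <- ncol(x); C <- length(classLevels)
  X <- cbind(1, x)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  set.seed(as.integer(seed))
  W <- matrix(rnorm((d + 1) * C, sd = 0.01), d + 1, C)

  hasVal <- !is.null(xVal) && nrow(as.matrix(xVal)) > 0
  if (hasVal) {
    Xv <- cbind(1, as.matrix(xVal))
    yv <- factor(as.character(yVal), levels = classLevels)
    bestW <- W
    bestLoss <- Inf
  }
  softmax <- function(Z) {
    Z <- Z - apply(Z, 1L, max)
    E <- exp(Z)
    E / rowSums(E)
  }
  for (ep in seq_len(epochs)) {
    P <- softmax(X %*% W)
    W <- W - lr * crossprod(X, P - Y) / n
    if (hasVal) {
      Pv <- softmax(Xv %*% W)
      loss <- -mean(log(pmax(Pv[cbind(seq_along(yv), as.integer(yv))],
                             1e-12)))
      if (loss < bestLoss) { bestLoss <- loss; bestW <- W }
    }
  }
  if (hasVal) W <- bestW
  structure(list(weights = W, classLevels = classLevels),
            class = "softmaxModel")
}

#' @rdname softmaxTrain
#' @param object a fitted `softmaxModel`
#' @param newdata embedding matrix to classify
#' @param ... unused
#' @return character vector of predicted class labels
#' @exportS3Method stats::predict
predict.softmaxModel <- function(object, newdata, ...) {
  Z <- cbind(1, as.matrix(newdata)) %*% object$weights
  object$classLevels[max.col(Z, ties.method = "first")]
}
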