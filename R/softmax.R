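#' Softmax classifier hyperparameters
#'
#' Full-batch gradient descent on the multiclass cross-entropy with an
#' L2 penalty on the weights. The larger default learning rate (relative
#' to the autoencoder stages) is appropriate for the convex softmax
#' objective on [0,1]-bounded codes.
#'
#' @param learning_rate Step size.
#' @param epochs Number of full-batch epochs (0 leaves the
#'   zero-initialized parameters untouched, i.e. uniform predictions).
#' @param weight_decay L2 coefficient on the weight matrix.
#' @param seed Seed (kept for interface symmetry; initialization is
#'   deterministic zeros).
#' @return A `softmax_hyper` list.
#' @export
softmax_hyper <- function(learning_rate = 0.5, epochs = 2000,
                          weight_decay = 1e-4, seed = 1L) {
  stopifnot(learning_rate >= 0, epochs >= 0, weight_decay >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "softmax_hyper")
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

one_hot <- function(labels, n_classes = 3L) {
  codes <- label_code(labels)
  Y <- matrix(0, length(codes), n_classes)
  Y[cbind(seq_along(codes), codes + 1L)] <- 1
  Y
}

#' Softmax class probabilities
#'
#' softmax(W_s z + b_s); rows are positive and sum to one, invariant to
#' adding a constant to all logits.
#'
#' @param Z Code vector (length h) or n x h matrix.
#' @param params List with `W` (C x h) and `b` (length C), C = 3 classes.
#' @return n x C probability matrix with columns named by class.
#' @export
softmax_predict <- function(Z, params) {
  Z <- as_matrix_input(Z)
  if (ncol(Z) != ncol(params$W)) {
    stop("code dimension ", ncol(Z), " does not match softmax input (",
         ncol(params$W), ")")
  }
  P <- softmax_rows(sweep(Z %*% t(params$W), 2, params$b, "+"))
  colnames(P) <- class_levels()[seq_len(ncol(P))]
  P
}

softmax_cost <- function(Z, Y, params, weight_decay) {
  P <- softmax_predict(Z, params)
  -mean(log(pmax(rowSums(Y * P), 1e-300))) + weight_decay * sum(params$W^2)
}

softmax_gradient <- function(Z, Y, params, weight_decay) {
  n <- nrow(Z)
  P <- softmax_predict(Z, params)
  delta <- (P - Y) / n
  list(W = t(delta) %*% Z + 2 * weight_decay * params$W,
       b = colSums(delta),
       delta = delta)   # reused by fine-tuning backprop
}

#' Train the softmax head on autoencoder codes
#'
#' Zero initialization, full-batch gradient descent on cross-entropy plus
#' L2 weight penalty. Deterministic.
#'
#' @param Z n x h code matrix.
#' @param labels Class labels aligned with the rows of `Z`; every fitted
#'   problem needs at least two distinct classes.
#' @param hyper A [softmax_hyper()].
#' @param n_classes Number of classes (3 for this pipeline).
#' @return List with `params` (W, b) and `trace` (cross-entropy per epoch).
#' @export
train_softmax <- function(Z, labels, hyper = softmax_hyper(), n_classes = 3L) {
  Z <- as_matrix_input(Z)
  labels <- class_label(labels)
  if (length(unique(labels)) < 2L) {
    stop("softmax training needs at least two distinct classes")
  }
  Y <- one_hot(labels, n_classes)
  params <- list(W = matrix(0, n_classes, ncol(Z)), b = numeric(n_classes))
  trace <- numeric(hyper$epochs)
  for (ep in seq_len(hyper$epochs)) {
    trace[ep] <- softmax_cost(Z, Y, params, hyper$weight_decay)
    g <- softmax_gradient(Z, Y, params, hyper$weight_decay)
    params$W <- params$W - hyper$learning_rate * g$W
    params$b <- params$b - hyper$learning_rate * g$b
  }
  list(params = params, trace = trace)
}
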