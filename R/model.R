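#' Assemble a stacked sparse autoencoder classifier
#'
#' Cascades the encoder halves of the pretrained autoencoders (decoders
#' are discarded) and wires the last code layer into the softmax head.
#'
#' @param layers List of `sae_params` from [stack_train()].
#' @param softmax Softmax parameter list (`W`, `b`) from [train_softmax()].
#' @param feature_scaling Optional feature scaling statistics
#'   (min/max vectors) recorded for reuse at prediction time.
#' @param seed Seed that produced the model (provenance).
#' @return An `ssae_model` object.
#' @export
ssae_model <- function(layers, softmax, feature_scaling = NULL, seed = NA_integer_) {
  sizes <- vapply(layers, function(p) nrow(p$W), integer(1))
  for (i in seq_along(layers)[-1]) {
    if (ncol(layers[[i]]$W) != sizes[i - 1L]) {
      stop("layer ", i, " input size ", ncol(layers[[i]]$W),
           " does not match previous hidden size ", sizes[i - 1L])
    }
  }
  if (ncol(softmax$W) != sizes[length(sizes)]) {
    stop("softmax input size ", ncol(softmax$W),
         " does not match last hidden size ", sizes[length(sizes)])
  }
  structure(list(layers = layers, softmax = softmax,
                 layer_sizes = sizes,
                 input_size = ncol(layers[[1]]$W),
                 feature_scaling = feature_scaling,
                 seed = seed,
                 trace = NULL),
            class = "ssae_model")
}

#' @export
print.ssae_model <- function(x, ...) {
  cat(sprintf("<ssae_model> %d -> %s -> %d classes\n", x$input_size,
              paste(x$layer_sizes, collapse = " -> "), nrow(x$softmax$W)))
  invisible(x)
}

forward_codes <- function(model, X) {
  acts <- vector("list", length(model$layers) + 1L)
  acts[[1L]] <- as_matrix_input(X)
  for (i in seq_along(model$layers)) {
    acts[[i + 1L]] <- encode(acts[[i]], model$layers[[i]])
  }
  acts
}

#' Supervised fine-tuning of the assembled network
#'
#' Joint backpropagation of the multiclass cross-entropy through the
#' softmax head and every encoder layer (decoders have been discarded).
#' Full-batch gradient descent; the returned model stores the per-epoch
#' cross-entropy in `$trace`.
#'
#' @param model An [ssae_model()].
#' @param X n x d feature matrix (scaled as in training).
#' @param labels Class labels aligned with rows of `X`.
#' @param learning_rate Step size.
#' @param epochs Number of epochs.
#' @param weight_decay Optional L2 penalty on all weight matrices.
#' @return The fine-tuned `ssae_model` with `$trace` set.
#' @export
fine_tune <- function(model, X, labels, learning_rate = 0.1, epochs = 1000,
                      weight_decay = 0) {
  stopifnot(inherits(model, "ssae_model"))
  X <- as_matrix_input(X)
  labels <- class_label(labels)
  Y <- one_hot(labels, nrow(model$softmax$W))
  n <- nrow(X)
  L <- length(model$layers)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    acts <- forward_codes(model, X)
    P <- softmax_predict(acts[[L + 1L]], model$softmax)
    trace[ep] <- -mean(log(pmax(rowSums(Y * P), 1e-300))) +
      weight_decay * (sum(model$softmax$W^2) +
                      sum(vapply(model$layers, function(p) sum(p$W^2), numeric(1))))
    if (learning_rate == 0) next
    delta <- (P - Y) / n
    gWs <- t(delta) %*% acts[[L + 1L]] + 2 * weight_decay * model$softmax$W
    gbs <- colSums(delta)
    back <- delta %*% model$softmax$W
    grads <- vector("list", L)
    for (i in L:1) {
      Zi <- acts[[i + 1L]]
      di <- back * Zi * (1 - Zi)
      grads[[i]] <- list(W = t(di) %*% acts[[i]] +
                           2 * weight_decay * model$layers[[i]]$W,
                         b = colSums(di))
      if (i > 1L) back <- di %*% model$layers[[i]]$W
    }
    model$softmax$W <- model$softmax$W - learning_rate * gWs
    model$softmax$b <- model$softmax$b - learning_rate * gbs
    for (i in seq_len(L)) {
      model$layers[[i]]$W <- model$layers[[i]]$W - learning_rate * grads[[i]]$W
      model$layers[[i]]$b <- model$layers[[i]]$b - learning_rate * grads[[i]]$b
    }
  }
  model$trace <- trace
  model
}

#' Predict classes and probabilities
#'
#' Probabilities are softmax over the deepest code; the label is the
#' argmax with ties broken towards the lowest class code (EGC < AGC <
#' HEALTHY).
#'
#' @param object An [ssae_model()].
#' @param X n x d feature matrix (scaled with the training statistics).
#' @param ... Unused.
#' @return List with `labels` (factor) and `prob` (n x 3 matrix).
#' @export
predict.ssae_model <- function(object, X, ...) {
  X <- as_matrix_input(X)
  if (ncol(X) != object$input_size) {
    stop("feature dimension mismatch: expected ", object$input_size,
         ", got ", ncol(X))
  }
  codes <- forward_codes(object, X)[[length(object$layers) + 1L]]
  P <- softmax_predict(codes, object$softmax)
  # max.col with ties.method="first" picks the lowest class code on ties
  idx <- max.col(P, ties.method = "first")
  list(labels = class_label(idx - 1L), prob = P)
}

#' Train the full stacked sparse autoencoder classifier
#'
#' Greedy unsupervised pretraining of the autoencoder stack on the
#' (unlabeled) feature matrix, softmax training on the deepest codes,
#' then supervised fine-tuning of the whole network.
#'
#' @param X n x d scaled feature matrix.
#' @param labels Class labels (used only by the softmax and fine-tuning
#'   stages).
#' @param layer_sizes Hidden sizes, default `c(100, 40)`.
#' @param sae Template [sae_hyper()] for the pretraining stages.
#' @param softmax A [softmax_hyper()].
#' @param finetune_rate,finetune_epochs Fine-tuning step size and epochs.
#' @param feature_scaling Scaling statistics to store on the model.
#' @return A fine-tuned [ssae_model()]; `$pretrain_traces` and
#'   `$softmax_trace` keep the stage costs.
#' @export
train_dssaenn <- function(X, labels, layer_sizes = c(100, 40),
                          sae = sae_hyper(layer_sizes[1]),
                          softmax = softmax_hyper(),
                          finetune_rate = 0.1, finetune_epochs = 1000,
                          feature_scaling = NULL) {
  X <- as_matrix_input(X)
  stack <- stack_train(X, layer_sizes, sae)
  codes <- X
  for (p in stack$layers) codes <- encode(codes, p)
  sm <- train_softmax(codes, labels, softmax)
  model <- ssae_model(stack$layers, sm$params,
                      feature_scaling = feature_scaling, seed = sae$seed)
  model <- fine_tune(model, X, labels, learning_rate = finetune_rate,
                     epochs = finetune_epochs)
  model$pretrain_traces <- stack$traces
  model$softmax_trace <- sm$trace
  model
}
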