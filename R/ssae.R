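#' Sparse autoencoder hyperparameters
#'
#' Defaults follow the study configuration: logistic sigmoid activations,
#' sparsity proportion p = 0.05, sparsity regularization weight 4,
#' learning rate 0.001, 1000 full-batch gradient-descent epochs.
#'
#' @param hidden_size Number of hidden units.
#' @param sparsity_target Target mean hidden activation p in (0,1).
#' @param sparsity_weight Coefficient on the KL sparsity penalty (>= 0).
#' @param weight_decay Coefficient beta on the squared-weight penalty.
#' @param learning_rate Gradient-descent step size.
#' @param epochs Number of full-batch epochs.
#' @param seed Seed for weight initialization.
#' @return An `sae_hyper` list.
#' @export
sae_hyper <- function(hidden_size, sparsity_target = 0.05,
                      sparsity_weight = 4, weight_decay = 1e-4,
                      learning_rate = 0.001, epochs = 1000, seed = 1L) {
  stopifnot(hidden_size >= 1, sparsity_target > 0, sparsity_target < 1,
            sparsity_weight >= 0, weight_decay >= 0, learning_rate >= 0,
            epochs >= 0)
  structure(list(hidden_size = as.integer(hidden_size),
                 sparsity_target = sparsity_target,
                 sparsity_weight = sparsity_weight,
                 weight_decay = weight_decay,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "sae_hyper")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

as_matrix_input <- function(X) {
  if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
}

#' Initialize autoencoder parameters
#'
#' Encoder and decoder weights are drawn uniformly in
#' +/- sqrt(6 / (d + h)) (Glorot-style for sigmoid units); biases start
#' at zero. Decoder weights are untied from encoder weights.
#'
#' @param d Input dimension.
#' @param h Hidden dimension.
#' @param seed Integer seed.
#' @return An `sae_params` list with `W` (h x d), `b` (h), `W_dec`
#'   (d x h), `b_dec` (d).
#' @export
sae_init <- function(d, h, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  r <- sqrt(6 / (d + h))
  structure(list(
    W = matrix(stats::runif(h * d, -r, r), h, d),
    b = numeric(h),
    W_dec = matrix(stats::runif(d * h, -r, r), d, h),
    b_dec = numeric(d)
  ), class = "sae_params")
}

#' Encoder: z = sigmoid(W x + b)
#'
#' @param X Input vector (length d) or n x d matrix.
#' @param params An `sae_params` object.
#' @return n x h matrix of hidden activations in (0,1) (a vector input
#'   returns a 1 x h matrix).
#' @export
encode <- function(X, params) {
  X <- as_matrix_input(X)
  if (ncol(X) != ncol(params$W)) {
    stop("input dimension ", ncol(X), " does not match encoder (",
         ncol(params$W), ")")
  }
  sigmoid(sweep(X %*% t(params$W), 2, params$b, "+"))
}

#' Decoder: x_hat = sigmoid(W' z + b')
#'
#' @param Z Hidden vector (length h) or n x h matrix.
#' @param params An `sae_params` object.
#' @return n x d matrix of reconstructions in (0,1).
#' @export
decode <- function(Z, params) {
  Z <- as_matrix_input(Z)
  if (ncol(Z) != ncol(params$W_dec)) {
    stop("code dimension ", ncol(Z), " does not match decoder (",
         ncol(params$W_dec), ")")
  }
  sigmoid(sweep(Z %*% t(params$W_dec), 2, params$b_dec, "+"))
}

#' Reconstruction: decode(encode(x))
#' @inheritParams encode
#' @export
reconstruct <- function(X, params) decode(encode(X, params), params)

#' Mean hidden activation over a batch
#'
#' rho_hat_j = mean over samples of the j-th hidden activation.
#'
#' @param X n x d input matrix, n >= 1.
#' @param params An `sae_params` object.
#' @return Length-h vector with entries in (0,1).
#' @export
average_activation <- function(X, params) {
  X <- as_matrix_input(X)
  if (nrow(X) < 1L) stop("empty batch")
  colMeans(encode(X, params))
}

#' Bernoulli Kullback-Leibler divergence KL(p || rho_hat)
#'
#' p*log(p/rho) + (1-p)*log((1-p)/(1-rho)), natural logarithm.
#' Arguments are clamped to [1e-8, 1 - 1e-8] to avoid infinities at the
#' boundary. Vectorized over `rho_hat`.
#'
#' @param p Sparsity target in (0,1).
#' @param rho_hat Observed mean activation(s).
#' @return Nonnegative divergence, zero iff `rho_hat == p`.
#' @export
kl_divergence <- function(p, rho_hat) {
  eps <- 1e-8
  p <- min(max(p, eps), 1 - eps)
  rho_hat <- pmin(pmax(rho_hat, eps), 1 - eps)
  p * log(p / rho_hat) + (1 - p) * log((1 - p) / (1 - rho_hat))
}

#' Squared Frobenius norm of the weights
#'
#' tr(W^T W) summed over all weight matrices passed in; biases are
#' excluded from weight decay.
#'
#' @param ... Numeric matrices.
#' @return Sum of squared entries.
#' @export
weight_decay_term <- function(...) {
  sum(vapply(list(...), function(W) sum(W^2), numeric(1)))
}

#' Sparse autoencoder cost
#'
#' J = (1/n) sum_i 0.5 ||x_i - x_hat_i||^2
#'     + sparsity_weight * sum_j KL(p || rho_hat_j)
#'     + weight_decay * (||W||^2 + ||W_dec||^2)
#'
#' @param X n x d input matrix.
#' @param params An `sae_params` object.
#' @param hyper An [sae_hyper()].
#' @return List with `total` and `components` (named: `reconstruction`,
#'   `sparsity`, `weight_decay`); `total` equals their sum.
#' @export
sae_cost <- function(X, params, hyper) {
  X <- as_matrix_input(X)
  Z <- encode(X, params)
  Xhat <- decode(Z, params)
  rec <- mean(0.5 * rowSums((X - Xhat)^2))
  rho <- colMeans(Z)
  sp <- hyper$sparsity_weight * sum(kl_divergence(hyper$sparsity_target, rho))
  wd <- hyper$weight_decay * weight_decay_term(params$W, params$W_dec)
  list(total = rec + sp + wd,
       components = c(reconstruction = rec, sparsity = sp, weight_decay = wd))
}

#' Analytic gradient of the sparse autoencoder cost
#'
#' Backpropagation through reconstruction, the KL sparsity penalty
#' (routed through each sample's hidden pre-activation via
#' sparsity_weight * (-p/rho_j + (1-p)/(1-rho_j)) / n), and weight decay.
#'
#' @inheritParams sae_cost
#' @return List of gradients `W`, `b`, `W_dec`, `b_dec` with the same
#'   shapes as `params`.
#' @export
sae_gradient <- function(X, params, hyper) {
  X <- as_matrix_input(X)
  n <- nrow(X)
  Z <- encode(X, params)                       # n x h
  Xhat <- decode(Z, params)                    # n x d
  delta_out <- (Xhat - X) * Xhat * (1 - Xhat) / n
  gW_dec <- t(delta_out) %*% Z + 2 * hyper$weight_decay * params$W_dec
  gb_dec <- colSums(delta_out)

  eps <- 1e-8
  rho <- pmin(pmax(colMeans(Z), eps), 1 - eps)
  p <- hyper$sparsity_target
  sparse_grad <- hyper$sparsity_weight *
    (-p / rho + (1 - p) / (1 - rho)) / n       # length h
  delta_hidden <- (delta_out %*% params$W_dec +
                   matrix(sparse_grad, n, length(rho), byrow = TRUE)) *
                  Z * (1 - Z)
  gW <- t(delta_hidden) %*% X + 2 * hyper$weight_decay * params$W
  gb <- colSums(delta_hidden)
  list(W = gW, b = gb, W_dec = gW_dec, b_dec = gb_dec)
}

#' Train a sparse autoencoder by full-batch gradient descent
#'
#' Glorot-initialized from `hyper$seed`, then `hyper$epochs` full-batch
#' gradient steps with fixed learning rate. The returned trace records,
#' per epoch, the cost (before that epoch's update) and its three
#' components.
#'
#' @param X n x d training matrix (n >= 2), entries ideally in [0,1].
#' @param hyper An [sae_hyper()].
#' @return List with `params` (`sae_params`) and `trace` (data.frame with
#'   columns `epoch`, `total`, `reconstruction`, `sparsity`,
#'   `weight_decay`).
#' @export
train_sae <- function(X, hyper) {
  X <- as_matrix_input(X)
  if (nrow(X) < 2L) stop("need at least 2 training samples")
  d <- ncol(X)
  params <- sae_init(d, hyper$hidden_size, seed = hyper$seed)
  trace <- matrix(NA_real_, hyper$epochs, 4L)
  for (ep in seq_len(hyper$epochs)) {
    cost <- sae_cost(X, params, hyper)
    if (!is.finite(cost$total)) {
      stop("non-finite cost at epoch ", ep,
           " (learning rate too large or degenerate input)")
    }
    trace[ep, ] <- c(cost$total, cost$components)
    if (hyper$learning_rate > 0) {
      g <- sae_gradient(X, params, hyper)
      params$W <- params$W - hyper$learning_rate * g$W
      params$b <- params$b - hyper$learning_rate * g$b
      params$W_dec <- params$W_dec - hyper$learning_rate * g$W_dec
      params$b_dec <- params$b_dec - hyper$learning_rate * g$b_dec
    }
  }
  trace <- as.data.frame(trace)
  names(trace) <- c("total", "reconstruction", "sparsity", "weight_decay")
  trace <- cbind(epoch = seq_len(nrow(trace)), trace)
  list(params = params, trace = trace)
}

#' Greedy layer-wise pretraining of a stacked sparse autoencoder
#'
#' The first autoencoder is trained on `X`; its codes become the training
#' input of the second, and so on. Entirely unsupervised: labels are
#' never consulted.
#'
#' @param X n x d training matrix.
#' @param layer_sizes Integer vector of hidden sizes, e.g. `c(100, 40)`.
#' @param hyper A single [sae_hyper()] template (its `hidden_size` is
#'   overridden per layer) or a list of one hyper per layer.
#' @return List with `layers` (list of `sae_params`) and `traces`.
#' @export
stack_train <- function(X, layer_sizes = c(100, 40), hyper = sae_hyper(100)) {
  stopifnot(length(layer_sizes) >= 1)
  if (inherits(hyper, "sae_hyper")) {
    hyper <- lapply(seq_along(layer_sizes), function(i) {
      h <- hyper
      h$hidden_size <- as.integer(layer_sizes[i])
      h$seed <- h$seed + i - 1L
      h
    })
  }
  stopifnot(length(hyper) == length(layer_sizes))
  input <- as_matrix_input(X)
  layers <- vector("list", length(layer_sizes))
  traces <- vector("list", length(layer_sizes))
  for (i in seq_along(layer_sizes)) {
    stopifnot(hyper[[i]]$hidden_size == layer_sizes[i])
    fit <- train_sae(input, hyper[[i]])
    layers[[i]] <- fit$params
    traces[[i]] <- fit$trace
    input <- encode(input, fit$params)
  }
  list(layers = layers, traces = traces)
}
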