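test_that("encoder and decoder evaluate the logistic maps exactly", {
  p <- list(W = matrix(0, 3, 2), b = numeric(3),
            W_dec = matrix(0, 2, 3), b_dec = numeric(2))
  expect_equal(as.numeric(encode(c(1, -1), p)), rep(0.5, 3))   # sigmoid(0)
  expect_equal(as.numeric(decode(c(1, 0, 0), p)), rep(0.5, 2))

  # saturation at large bias
  p$b <- rep(10, 3)
  expect_true(all(encode(c(0, 0), p) > 0.999))

  # scalar evaluation: d=2, h=1, W=(1,1), b=0, x=(0.5,0.5) -> sigmoid(1)
  p1 <- list(W = matrix(c(1, 1), 1, 2), b = 0,
             W_dec = matrix(2, 1, 1), b_dec = -1)
  expect_equal(as.numeric(encode(c(0.5, 0.5), p1)), 0.731058578630005,
               tolerance = 1e-12)
  # h=1, d=1, W_dec=2, b_dec=-1, z=0.5 -> sigmoid(0) = 0.5
  expect_equal(as.numeric(decode(0.5, p1)), 0.5)

  expect_error(encode(c(1, 2, 3), p1), "dimension")
  expect_error(decode(c(1, 2), p1), "dimension")

  # composition is defined and finite for any finite input
  pr <- sae_init(4, 3, seed = 2)
  x <- c(-100, 0, 0.5, 100)
  expect_true(all(is.finite(reconstruct(x, pr))))
})

test_that("average activation is the sample mean of the codes", {
  p <- sae_init(3, 2, seed = 1)
  x <- c(0.1, 0.2, 0.3)
  expect_equal(average_activation(x, p), as.numeric(encode(x, p)))
  X <- rbind(c(0.1, 0.2, 0.3), c(0.9, 0.8, 0.7))
  expect_equal(average_activation(X, p), colMeans(encode(X, p)))

  p0 <- list(W = matrix(0, 2, 3), b = numeric(2),
             W_dec = matrix(0, 3, 2), b_dec = numeric(3))
  expect_equal(average_activation(X, p0), rep(0.5, 2))
  expect_error(average_activation(matrix(numeric(0), 0, 3), p), "empty batch")
})

test_that("Bernoulli KL divergence matches direct evaluation", {
  expect_equal(kl_divergence(0.05, 0.05), 0)
  # 0.5*ln2 + 0.5*ln(2/3) = 0.5*ln(4/3)
  expect_equal(kl_divergence(0.5, 0.25), 0.14384103622589045, tolerance = 1e-12)
  # 0.05*ln(0.05/0.95) + 0.95*ln(0.95/0.05) = 0.9*ln(19)
  expect_equal(kl_divergence(0.05, 0.95), 2.649995081249796, tolerance = 1e-12)
  # boundary arguments are clamped, not infinite
  expect_true(is.finite(kl_divergence(0.05, 0)))
  expect_true(is.finite(kl_divergence(0.05, 1)))
})

test_that("KL is nonnegative, zero only at the target, increasing away from it", {
  p <- 0.05
  grid_lo <- seq(0.001, p, length.out = 30)
  grid_hi <- seq(p, 0.999, length.out = 30)
  v_lo <- kl_divergence(p, grid_lo)
  v_hi <- kl_divergence(p, grid_hi)
  expect_true(all(v_lo >= 0) && all(v_hi >= 0))
  expect_lt(kl_divergence(p, p), 1e-12)
  expect_true(all(diff(v_lo) <= 1e-12))  # decreasing towards p from below
  expect_true(all(diff(v_hi) >= -1e-12)) # increasing away from p above
})

test_that("weight decay is the sum of squared entries, biases excluded", {
  expect_equal(weight_decay_term(matrix(0, 3, 3)), 0)
  expect_equal(weight_decay_term(diag(2)), 2)
  expect_equal(weight_decay_term(matrix(1:4, 2, 2)), 30)
  expect_equal(weight_decay_term(diag(2), matrix(1:4, 2, 2)), 32)
})

test_that("sae_cost decomposes exactly and matches a naive oracle", {
  withr::with_seed(101, {
    X <- matrix(runif(4 * 7), 4, 7)
  })
  params <- sae_init(7, 5, seed = 3)
  hyper <- sae_hyper(5, sparsity_weight = 4, weight_decay = 0.01)
  cost <- sae_cost(X, params, hyper)
  expect_equal(cost$total, sum(cost$components), tolerance = 1e-12)
  expect_equal(cost$total, naive_sae_cost(X, params, hyper), tolerance = 1e-12)
  expect_gte(cost$total, 0)

  # component isolation: pure weight decay
  h0 <- sae_hyper(5, sparsity_weight = 0, weight_decay = 0.5)
  c0 <- sae_cost(X, params, h0)
  expect_equal(c0$components[["weight_decay"]],
               0.5 * (sum(params$W^2) + sum(params$W_dec^2)), tolerance = 1e-12)
  expect_equal(c0$components[["sparsity"]], 0)
})

test_that("analytic SAE gradients match central finite differences", {
  errs <- vapply(1:10, function(i) {
    withr::with_seed(i, {
      d <- sample(3:7, 1); h <- sample(2:5, 1); n <- sample(2:4, 1)
      X <- matrix(runif(n * d), n, d)
    })
    params <- sae_init(d, h, seed = i)
    hyper <- sae_hyper(h, sparsity_weight = 4, weight_decay = 0.01)
    g <- sae_gradient(X, params, hyper)
    fd <- fd_gradient(function(p) sae_cost(X, p, hyper)$total, params)
    max_rel_err(g, fd)
  }, numeric(1))
  expect_lt(max(errs), 1e-6)
})

test_that("doubling the weight-decay coefficient doubles that gradient part", {
  withr::with_seed(41, X <- matrix(runif(3 * 4), 3, 4))
  params <- sae_init(4, 3, seed = 5)
  g0 <- sae_gradient(X, params, sae_hyper(3, sparsity_weight = 0, weight_decay = 0))
  g1 <- sae_gradient(X, params, sae_hyper(3, sparsity_weight = 0, weight_decay = 0.1))
  g2 <- sae_gradient(X, params, sae_hyper(3, sparsity_weight = 0, weight_decay = 0.2))
  expect_equal(g2$W - g0$W, 2 * (g1$W - g0$W), tolerance = 1e-12)
})

test_that("training is deterministic, inert at lr = 0, and reduces cost", {
  withr::with_seed(55, {
    basis <- matrix(runif(2 * 6), 2, 6)
    coef <- matrix(runif(50 * 2), 50, 2)
    X <- sigmoid_like <- pmin(pmax(coef %*% basis, 0), 1)  # rank-2 in [0,1]
  })
  hz <- sae_hyper(2, learning_rate = 0, epochs = 5, seed = 9)
  fit0 <- train_sae(X, hz)
  expect_equal(fit0$params, sae_init(6, 2, seed = 9))
  expect_equal(var(fit0$trace$total), 0)

  h <- sae_hyper(2, learning_rate = 0.5, epochs = 1000, seed = 9,
                 sparsity_weight = 0.1, weight_decay = 1e-5)
  fit1 <- train_sae(X, h)
  fit2 <- train_sae(X, h)
  expect_identical(fit1$params, fit2$params)
  expect_equal(nrow(fit1$trace), 1000L)
  expect_lt(fit1$trace$total[1000], fit1$trace$total[1])
  # reconstruction error halves from epoch 0
  expect_lt(fit1$trace$reconstruction[1000],
            0.5 * fit1$trace$reconstruction[1])
  expect_error(train_sae(X[1, , drop = FALSE], h), "at least 2")
})

test_that("greedy stacking trains layer-on-codes, unsupervised", {
  withr::with_seed(77, X <- matrix(runif(30 * 8), 30, 8))
  st <- stack_train(X, layer_sizes = c(5, 3),
                    hyper = sae_hyper(5, epochs = 20, seed = 4))
  expect_length(st$layers, 2L)
  expect_equal(dim(st$layers[[1]]$W), c(5L, 8L))
  expect_equal(dim(st$layers[[2]]$W), c(3L, 5L))
  codes1 <- encode(X, st$layers[[1]])
  expect_equal(ncol(codes1), 5L)
  expect_equal(ncol(encode(codes1, st$layers[[2]])), 3L)

  # single layer equals train_sae
  one <- stack_train(X, 4, sae_hyper(4, epochs = 20, seed = 4))
  direct <- train_sae(X, sae_hyper(4, epochs = 20, seed = 4))
  expect_equal(one$layers[[1]], direct$params)
})

test_that("softmax probabilities are proper and shift-invariant", {
  prm <- list(W = diag(3), b = rep(0, 3))
  expect_equal(as.numeric(softmax_predict(c(0, 0, 0), prm)), rep(1 / 3, 3))
  p <- softmax_predict(log(c(1, 2, 3)), prm)
  expect_equal(as.numeric(p), c(1, 2, 3) / 6, tolerance = 1e-12)
  p_shift <- softmax_predict(log(c(1, 2, 3)) + 5, prm)
  expect_equal(as.numeric(p_shift), as.numeric(p), tolerance = 1e-12)

  withr::with_seed(6, Z <- matrix(rnorm(10 * 3), 10, 3))
  P <- softmax_predict(Z, prm)
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-12)
  expect_true(all(P > 0))
})

test_that("softmax training solves a separable toy problem and checks out", {
  toy <- separable_toy()
  fit <- train_softmax(toy$X, toy$labels,
                       softmax_hyper(learning_rate = 1, epochs = 2000,
                                     weight_decay = 1e-5))
  pred <- max.col(softmax_predict(toy$X, fit$params), ties.method = "first")
  expect_equal(mean(class_label(pred - 1L) == toy$labels), 1)

  # zero epochs: zero-initialized params, uniform predictions
  fit0 <- train_softmax(toy$X, toy$labels, softmax_hyper(epochs = 0))
  expect_equal(unique(as.numeric(softmax_predict(toy$X, fit0$params))), 1 / 3,
               tolerance = 1e-12)

  expect_error(train_softmax(toy$X[1:5, ], rep("EGC", 5)),
               "two distinct classes")
})

test_that("softmax gradients match finite differences", {
  errs <- vapply(1:10, function(i) {
    withr::with_seed(100 + i, {
      n <- sample(3:6, 1); h <- sample(2:5, 1)
      Z <- matrix(runif(n * h), n, h)
      y <- c(0:2, sample(0:2, n - 3, replace = TRUE))
    })
    Y <- matrix(0, n, 3); Y[cbind(1:n, y + 1)] <- 1
    prm <- list(W = matrix(rnorm(3 * h, sd = 0.2), 3, h), b = rnorm(3, sd = 0.2))
    g <- breathsae:::softmax_gradient(Z, Y, prm, 0.01)
    fd <- fd_gradient(function(p)
      breathsae:::softmax_cost(Z, Y, p, 0.01), prm[c("W", "b")])
    max_rel_err(g[c("W", "b")], fd)
  }, numeric(1))
  expect_lt(max(errs), 1e-6)
})

test_that("fine-tuning backpropagates correctly through the whole stack", {
  # gradient check via one tiny gradient-descent step against FD on all params
  withr::with_seed(202, {
    X <- matrix(runif(5 * 4), 5, 4)
    y <- c(0, 1, 2, 0, 1)
  })
  st <- stack_train(X, c(3, 2), sae_hyper(3, epochs = 10, seed = 8))
  codes <- encode(encode(X, st$layers[[1]]), st$layers[[2]])
  sm <- train_softmax(codes, class_label(y), softmax_hyper(epochs = 10))
  model <- ssae_model(st$layers, sm$params)

  flat <- c(W1 = list(model$layers[[1]]$W), b1 = list(model$layers[[1]]$b),
            W2 = list(model$layers[[2]]$W), b2 = list(model$layers[[2]]$b),
            Ws = list(model$softmax$W), bs = list(model$softmax$b))
  ce_of <- function(p) {
    m <- model
    m$layers[[1]]$W <- p$W1; m$layers[[1]]$b <- p$b1
    m$layers[[2]]$W <- p$W2; m$layers[[2]]$b <- p$b2
    m$softmax$W <- p$Ws; m$softmax$b <- p$bs
    m0 <- fine_tune(m, X, class_label(y), learning_rate = 0, epochs = 1)
    m0$trace[1]
  }
  fd <- fd_gradient(ce_of, flat)
  # recover the analytic gradient from a single unit-step update
  m1 <- fine_tune(model, X, class_label(y), learning_rate = 1, epochs = 1)
  analytic <- list(W1 = model$layers[[1]]$W - m1$layers[[1]]$W,
                   b1 = model$layers[[1]]$b - m1$layers[[1]]$b,
                   W2 = model$layers[[2]]$W - m1$layers[[2]]$W,
                   b2 = model$layers[[2]]$b - m1$layers[[2]]$b,
                   Ws = model$softmax$W - m1$softmax$W,
                   bs = model$softmax$b - m1$softmax$b)
  expect_lt(max_rel_err(analytic, fd), 1e-6)

  # lr = 0 leaves the model unchanged
  m0 <- fine_tune(model, X, class_label(y), learning_rate = 0, epochs = 5)
  expect_equal(m0$layers, model$layers)
  expect_equal(m0$softmax, model$softmax)
  expect_equal(var(m0$trace), 0)
})

test_that("fine-tuning does not hurt training fit on separable data", {
  toy <- separable_toy(n_per_class = 15, seed = 12)
  st <- stack_train(toy$X, c(6, 4), sae_hyper(6, epochs = 100, seed = 2))
  codes <- toy$X
  for (p in st$layers) codes <- encode(codes, p)
  sm <- train_softmax(codes, toy$labels, softmax_hyper(epochs = 500))
  model <- ssae_model(st$layers, sm$params)

  acc <- function(m) {
    pred <- predict(m, toy$X)$labels
    mean(pred == toy$labels)
  }
  pre <- acc(model)
  tuned <- fine_tune(model, toy$X, toy$labels, learning_rate = 0.5,
                     epochs = 300)
  expect_gte(acc(tuned), pre)
  expect_lte(tuned$trace[length(tuned$trace)], tuned$trace[1])
})

test_that("sparsity penalty pulls mean activation towards the target", {
  cfg <- tiny_cohort_config(seed = 61)
  fm <- suppressWarnings(
    scale_features(featurize(preprocess_set(generate_cohort(cfg)), k = 50)))
  X <- fm$values
  base <- sae_hyper(20, sparsity_weight = 0, sparsity_target = 0.05,
                    learning_rate = 0.5, epochs = 400, seed = 7)
  sparse <- base; sparse$sparsity_weight <- 4
  rho_plain <- mean(average_activation(X, train_sae(X, base)$params))
  rho_sparse <- mean(average_activation(X, train_sae(X, sparse)$params))
  expect_lt(abs(rho_sparse - 0.05), abs(rho_plain - 0.05))
})

test_that("prediction is deterministic with proper probability rows", {
  toy <- separable_toy(seed = 9)
  st <- stack_train(toy$X, c(4, 3), sae_hyper(4, epochs = 50, seed = 3))
  codes <- toy$X
  for (p in st$layers) codes <- encode(codes, p)
  sm <- train_softmax(codes, toy$labels, softmax_hyper(epochs = 200))
  model <- ssae_model(st$layers, sm$params)
  p1 <- predict(model, toy$X)
  p2 <- predict(model, toy$X)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1$prob), rep(1, nrow(toy$X)), tolerance = 1e-12)
  expect_error(predict(model, toy$X[, 1, drop = FALSE]), "dimension mismatch")
})

test_that("labels play no role in unsupervised pretraining", {
  withr::with_seed(88, X <- matrix(runif(20 * 6), 20, 6))
  a <- stack_train(X, c(4, 2), sae_hyper(4, epochs = 30, seed = 1))
  b <- stack_train(X, c(4, 2), sae_hyper(4, epochs = 30, seed = 1))
  expect_identical(a$layers, b$layers)
})
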