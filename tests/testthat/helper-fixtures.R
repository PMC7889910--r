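# shared fixtures: everything is generated in code at test time

# single Gaussian band on a unit-spaced axis
gaussian_spectrum <- function(center = 700, sd = 10, height = 1,
                              axis = seq(400, 1000, by = 1), id = "gauss") {
  spectrum(axis, height * exp(-0.5 * ((axis - center) / sd)^2), sample_id = id)
}

# small fast cohort configuration for pipeline-level tests
tiny_cohort_config <- function(seed = 11, ...) {
  cohort_config(n_egc = 6, n_agc = 6, n_healthy = 6, n_points = 400,
                seed = seed, ...)
}

# linearly separable 3-class toy features (2-d)
separable_toy <- function(n_per_class = 10, seed = 3, noise = 0.05) {
  withr::with_seed(seed, {
    centers <- rbind(c(0.2, 0.2), c(0.8, 0.2), c(0.5, 0.9))
    X <- do.call(rbind, lapply(1:3, function(k)
      sweep(matrix(stats::rnorm(2 * n_per_class, 0, noise), ncol = 2),
            2, centers[k, ], "+")))
    list(X = X, labels = class_label(rep(0:2, each = n_per_class)))
  })
}

# independent single-formula evaluation of the sparse autoencoder cost,
# written as plain loops so it shares nothing with the package code path
naive_sae_cost <- function(X, params, hyper) {
  n <- nrow(X); d <- ncol(X); h <- nrow(params$W)
  sig <- function(v) 1 / (1 + exp(-v))
  Z <- matrix(0, n, h); Xhat <- matrix(0, n, d)
  for (i in 1:n) {
    for (j in 1:h) Z[i, j] <- sig(sum(params$W[j, ] * X[i, ]) + params$b[j])
    for (k in 1:d) Xhat[i, k] <- sig(sum(params$W_dec[k, ] * Z[i, ]) + params$b_dec[k])
  }
  rec <- 0
  for (i in 1:n) rec <- rec + 0.5 * sum((X[i, ] - Xhat[i, ])^2)
  rec <- rec / n
  p <- hyper$sparsity_target
  kl <- 0
  for (j in 1:h) {
    rho <- mean(Z[, j])
    kl <- kl + p * log(p / rho) + (1 - p) * log((1 - p) / (1 - rho))
  }
  rec + hyper$sparsity_weight * kl +
    hyper$weight_decay * (sum(params$W^2) + sum(params$W_dec^2))
}

# central finite-difference gradient of an arbitrary scalar function of a
# parameter list (oracle for all analytic gradients)
fd_gradient <- function(f, params, step = 1e-5) {
  g <- params
  for (nm in names(params)) {
    v <- params[[nm]]
    gv <- v
    for (i in seq_along(v)) {
      up <- params; up[[nm]][i] <- v[i] + step
      dn <- params; dn[[nm]][i] <- v[i] - step
      gv[i] <- (f(up) - f(dn)) / (2 * step)
    }
    g[[nm]] <- gv
  }
  g
}

max_rel_err <- function(analytic, numeric) {
  a <- unlist(analytic); b <- unlist(numeric)
  max(abs(a - b) / pmax(abs(a) + abs(b), 1e-8))
}

# brute-force AUC by concordant-pair counting (ties count 1/2)
pairwise_auc <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  tot <- 0
  for (a in ps) for (b in ns) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}
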