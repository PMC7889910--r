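#' Preprocessing configuration
#'
#' Controls the four-stage chain applied to each raw spectrum: spike
#' removal, median filtering, baseline correction and Savitzky-Golay
#' smoothing. Any stage can be disabled.
#'
#' @param despike,denoise,baseline,smoothing Logical flags enabling each stage.
#' @param spike_width_max Maximum run length (points) of an excursion that
#'   can be flagged as a spike; broader features are never touched.
#' @param spike_z_threshold Modified z-score cutoff on first differences.
#' @param median_window Odd window (points) of the median filter.
#' @param baseline_method `"als"` (asymmetric least squares, default) or
#'   `"polynomial"` (iteratively reweighted polynomial fit).
#' @param baseline_degree Polynomial degree for the polynomial method.
#' @param als_lambda,als_p ALS smoothness penalty and asymmetry; `als_p`
#'   must lie in (0,1).
#' @param smooth_window,smooth_polyorder Savitzky-Golay window (odd) and
#'   polynomial order (< window).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(despike = TRUE, denoise = TRUE,
                              baseline = TRUE, smoothing = TRUE,
                              spike_width_max = 3, spike_z_threshold = 6,
                              median_window = 5,
                              baseline_method = c("als", "polynomial"),
                              baseline_degree = 3,
                              als_lambda = 1e5, als_p = 0.01,
                              smooth_window = 7, smooth_polyorder = 2) {
  baseline_method <- match.arg(baseline_method)
  if (median_window %% 2 == 0 || median_window < 1) {
    stop("median_window must be odd and >= 1")
  }
  if (smooth_window %% 2 == 0 || smooth_window <= smooth_polyorder) {
    stop("smooth_window must be odd and > smooth_polyorder")
  }
  if (als_p <= 0 || als_p >= 1) stop("als_p must be in (0,1)")
  stopifnot(spike_width_max >= 1, spike_z_threshold > 0, baseline_degree >= 0,
            als_lambda > 0)
  structure(list(
    despike = despike, denoise = denoise, baseline = baseline,
    smoothing = smoothing,
    spike_width_max = as.integer(spike_width_max),
    spike_z_threshold = spike_z_threshold,
    median_window = as.integer(median_window),
    baseline_method = baseline_method,
    baseline_degree = as.integer(baseline_degree),
    als_lambda = als_lambda, als_p = als_p,
    smooth_window = as.integer(smooth_window),
    smooth_polyorder = as.integer(smooth_polyorder)
  ), class = "preprocess_config")
}

with_intensity <- function(s, y, step = NULL) {
  out <- spectrum(s$axis, y, sample_id = s$sample_id, meta = s$meta)
  if (!is.null(step)) {
    out$meta$preprocess_steps <- c(s$meta$preprocess_steps, step)
  }
  out
}

#' Remove narrow positive spikes from a spectrum
#'
#' Detector: the modified z-score (0.6745 * (d - median) / MAD) of the
#' first differences marks abrupt jumps. A spike is a sharp rise
#' immediately followed, within `spike_width_max` points, by a sharp
#' fall; the enclosed points are replaced by linear interpolation from
#' the flanking clean points. Two gates keep genuine bands intact: the
#' run between rise and fall can be at most `spike_width_max` points
#' wide, and the jump magnitude must also exceed a fixed fraction (5%)
#' of the signal range, so the tiny curvature step at a smooth band apex
#' is never mistaken for a spike. The pass is repeated until no further
#' point is flagged, which makes the operation idempotent.
#'
#' @param s A [spectrum()].
#' @param config A [preprocess_config()].
#' @return Despiked spectrum (axis unchanged).
#' @export
remove_spikes <- function(s, config = preprocess_config()) {
  stopifnot(is_spectrum(s))
  y <- s$intensity
  n <- length(y)
  w <- config$spike_width_max
  if (n <= 2L * w) stop("spectrum too short for spike_width_max = ", w)
  for (pass in 1:5) {
    d <- diff(y)
    med <- stats::median(d)
    mad0 <- stats::median(abs(d - med))
    if (mad0 == 0) mad0 <- mean(abs(d - med))
    rng <- diff(range(y))
    if (mad0 == 0 || rng == 0) break  # flat signal
    z <- 0.6745 * (d - med) / mad0
    big <- abs(d) > 0.05 * rng
    rises <- which(z > config$spike_z_threshold & big & d > 0)
    falls <- which(z < -config$spike_z_threshold & big & d < 0)
    flag <- logical(n)
    for (i in rises) {
      j <- falls[falls >= i & falls <= i + w]
      if (length(j) > 0L) flag[(i + 1L):j[1L]] <- TRUE
    }
    if (!any(flag)) break
    good <- which(!flag)
    y[flag] <- stats::approx(x = s$axis[good], y = y[good],
                             xout = s$axis[flag], rule = 2)$y
  }
  with_intensity(s, y, "despike")
}

reflect_pad <- function(y, k) {
  n <- length(y)
  if (k == 0L) return(y)
  k <- min(k, n - 1L)
  c(y[(k + 1L):2L], y, y[(n - 1L):(n - k)])
}

#' Median-filter a spectrum
#'
#' Each output point is the median of the odd-length window centered
#' there; edges are handled by reflection padding. The axis is unchanged.
#'
#' @param s A [spectrum()].
#' @param window Odd window length in points.
#' @return Filtered spectrum.
#' @export
median_filter <- function(s, window = 5) {
  stopifnot(is_spectrum(s))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("median filter window must be odd")
  if (window > length(s$axis)) stop("window larger than spectrum")
  if (window == 1L) return(with_intensity(s, s$intensity, "median_filter"))
  k <- (window - 1L) %/% 2L
  yp <- reflect_pad(s$intensity, k)
  out <- stats::runmed(yp, window, endrule = "keep")
  with_intensity(s, out[(k + 1L):(k + length(s$intensity))], "median_filter")
}

als_baseline <- function(y, lambda, p, n_iter = 15) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(n_iter)) {
    W <- Matrix::Diagonal(n, w)
    z_new <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z_new, p, 1 - p)
    if (max(abs(z_new - z)) < 1e-12 * (1 + max(abs(y)))) { z <- z_new; break }
    z <- z_new
    w <- w_new
  }
  z
}

modpoly_baseline <- function(x, y, degree, n_iter = 50) {
  t01 <- (x - x[1]) / (x[length(x)] - x[1])
  X <- outer(t01, 0:degree, `^`)
  yw <- y
  fit <- drop(X %*% stats::lm.fit(X, yw)$coefficients)
  for (it in seq_len(n_iter)) {
    yw <- pmin(yw, fit)
    new_fit <- drop(X %*% stats::lm.fit(X, yw)$coefficients)
    if (max(abs(new_fit - fit)) < 1e-10 * (1 + max(abs(y)))) { fit <- new_fit; break }
    fit <- new_fit
  }
  fit
}

#' Estimate and subtract the slowly-varying baseline
#'
#' Two estimators: asymmetric least squares (default; second-difference
#' smoothness penalty `als_lambda`, asymmetry `als_p`, iteratively
#' reweighted so the baseline hugs the signal from below) or an
#' iteratively reweighted polynomial fit where the signal is clipped to
#' the current fit between iterations. Both leave band heights above
#' baseline essentially intact.
#'
#' @param s A [spectrum()].
#' @param config A [preprocess_config()].
#' @return Baseline-corrected spectrum (signal minus estimated baseline).
#' @export
baseline_correct <- function(s, config = preprocess_config()) {
  stopifnot(is_spectrum(s))
  y <- s$intensity
  if (config$baseline_method == "polynomial" &&
      config$baseline_degree >= length(y)) {
    stop("baseline_degree must be smaller than the spectrum length")
  }
  base <- switch(config$baseline_method,
    als = als_baseline(y, config$als_lambda, config$als_p),
    polynomial = modpoly_baseline(s$axis, y, config$baseline_degree))
  with_intensity(s, y - base, "baseline")
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; polynomial signals of degree
#' at most `smooth_polyorder` pass through unchanged (including at the
#' edges, where the fit matrix handles the transient).
#'
#' @param s A [spectrum()].
#' @param config A [preprocess_config()].
#' @return Smoothed spectrum.
#' @export
smooth_spectrum <- function(s, config = preprocess_config()) {
  stopifnot(is_spectrum(s))
  if (config$smooth_window > length(s$axis)) stop("window larger than spectrum")
  out <- signal::sgolayfilt(s$intensity, p = config$smooth_polyorder,
                            n = config$smooth_window)
  with_intensity(s, as.numeric(out), "smooth")
}

#' Full preprocessing chain
#'
#' Applies, in order: spike removal, median filtering, baseline
#' correction, smoothing — each stage only if enabled in the config. The
#' applied steps are recorded in `meta$preprocess_steps`.
#'
#' @param s A [spectrum()].
#' @param config A [preprocess_config()].
#' @return Preprocessed spectrum with identical axis and length.
#' @export
preprocess <- function(s, config = preprocess_config()) {
  stopifnot(is_spectrum(s))
  if (config$despike)   s <- remove_spikes(s, config)
  if (config$denoise)   s <- median_filter(s, config$median_window)
  if (config$baseline)  s <- baseline_correct(s, config)
  if (config$smoothing) s <- smooth_spectrum(s, config)
  s
}

#' Preprocess every spectrum in a set
#'
#' @param set A [spectrum_set()].
#' @param config A [preprocess_config()].
#' @return A [spectrum_set()] of preprocessed spectra.
#' @export
preprocess_set <- function(set, config = preprocess_config()) {
  spectrum_set(lapply(set$spectra, preprocess, config = config), set$labels)
}
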