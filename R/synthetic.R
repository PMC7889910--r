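#' Default per-class band library for the synthetic breath cohort
#'
#' Twelve shared band centers across the 400-1500 axis with class-dependent
#' mean amplitudes: a handful of bands are progressively elevated (or one
#' suppressed) going healthy -> early gastric cancer -> advanced gastric
#' cancer, emulating disease-dependent volatile-metabolite concentration
#' changes. Amplitude spread models biological between-subject variability.
#'
#' @return Named list with one data.frame per class (`EGC`, `AGC`,
#'   `HEALTHY`), columns `center`, `width` (Gaussian sd / Lorentzian
#'   half-width, axis units), `amp_mean`, `amp_sd`.
#' @export
default_band_library <- function() {
  centers <- c(520, 610, 700, 780, 860, 940, 1020, 1100, 1180, 1260, 1340, 1430)
  widths  <- c( 10,  12,   9,  11,  10,  12,  10,    9,   11,   10,   12,  10)
  healthy <- c(1.0, 0.8, 1.2, 0.6, 0.9, 1.1, 0.7, 1.0, 0.8, 0.9, 0.6, 1.0)
  # disease-elevated bands: 2, 5, 8, 11; band 3 suppressed in cancer,
  # bands 4 and 10 elevated only in advanced disease
  egc     <- c(1.0, 1.2, 0.9, 0.6, 1.3, 1.1, 0.7, 1.4, 0.8, 0.9, 1.0, 1.0)
  agc     <- c(1.0, 1.6, 0.9, 0.9, 1.7, 1.1, 0.7, 1.8, 0.8, 1.2, 1.4, 1.0)
  mk <- function(amp) data.frame(center = centers, width = widths,
                                 amp_mean = amp, amp_sd = 0.08)
  list(EGC = mk(egc), AGC = mk(agc), HEALTHY = mk(healthy))
}

#' Configuration of the synthetic breath cohort generator
#'
#' Defaults mirror the study conditions: cohort sizes 55 EGC / 89 AGC /
#' 56 healthy (200 samples), 1200-point spectra over a 400-1500 axis,
#' class-dependent band amplitudes, a smooth polynomial baseline drift,
#' additive Gaussian noise, and rare narrow positive spikes much narrower
#' than any genuine band.
#'
#' @param n_egc,n_agc,n_healthy Per-class sample counts (default 55/89/56).
#' @param n_points Points per spectrum (default 1200).
#' @param axis_range Two reals, low/high axis limits (default 400, 1500).
#' @param band_library Per-class band table, see [default_band_library()].
#' @param band_shape `"gaussian"` (default) or `"lorentzian"` profiles.
#' @param baseline_order Polynomial degree of the baseline drift.
#' @param baseline_scale Amplitude scale of the random baseline
#'   coefficients; 0 disables the baseline.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param spike_rate Expected (Poisson) spike count per spectrum.
#' @param spike_width_max Maximum spike full width in points; must be
#'   strictly smaller than the narrowest band FWHM in points so spikes
#'   remain distinguishable from genuine bands.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_egc = 55, n_agc = 89, n_healthy = 56,
                          n_points = 1200, axis_range = c(400, 1500),
                          band_library = default_band_library(),
                          band_shape = c("gaussian", "lorentzian"),
                          baseline_order = 2, baseline_scale = 0.4,
                          noise_sd = 0.02, spike_rate = 0.5,
                          spike_width_max = 3, seed = 1L) {
  band_shape <- match.arg(band_shape)
  stopifnot(n_egc >= 0, n_agc >= 0, n_healthy >= 0, n_points >= 2,
            length(axis_range) == 2L, axis_range[2] > axis_range[1],
            baseline_order >= 0, baseline_scale >= 0, noise_sd >= 0,
            spike_rate >= 0, spike_width_max >= 1)
  stopifnot(identical(sort(names(band_library)), sort(class_levels())))
  step <- diff(axis_range) / (n_points - 1)
  min_fwhm_pts <- min(vapply(band_library, function(df)
    min(2.3548 * df$width), numeric(1))) / step
  if (spike_width_max >= min_fwhm_pts) {
    stop("spike_width_max (", spike_width_max, " points) must be smaller ",
         "than the narrowest band FWHM (", round(min_fwhm_pts, 1), " points)")
  }
  structure(list(
    n_egc = as.integer(n_egc), n_agc = as.integer(n_agc),
    n_healthy = as.integer(n_healthy), n_points = as.integer(n_points),
    axis_range = as.numeric(axis_range), band_library = band_library,
    band_shape = band_shape, baseline_order = as.integer(baseline_order),
    baseline_scale = baseline_scale, noise_sd = noise_sd,
    spike_rate = spike_rate, spike_width_max = as.integer(spike_width_max),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

cohort_axis <- function(config) {
  seq(config$axis_range[1], config$axis_range[2], length.out = config$n_points)
}

band_profile <- function(axis, center, width, amp, shape) {
  if (shape == "gaussian") {
    amp * exp(-0.5 * ((axis - center) / width)^2)
  } else {
    amp / (1 + ((axis - center) / width)^2)
  }
}

#' Noiseless class-mean spectrum implied by a cohort configuration
#'
#' Sum of the class's band profiles at their mean amplitudes, with no
#' baseline, noise or spikes. Useful as ground truth in tests and for
#' checking class separation at the band centers.
#'
#' @param label A single class label.
#' @param config A [cohort_config()].
#' @return Numeric vector of length `config$n_points`.
#' @export
class_mean_signal <- function(label, config) {
  axis <- cohort_axis(config)
  bands <- config$band_library[[as.character(class_label(label))]]
  sig <- numeric(length(axis))
  for (i in seq_len(nrow(bands))) {
    sig <- sig + band_profile(axis, bands$center[i], bands$width[i],
                              bands$amp_mean[i], config$band_shape)
  }
  sig
}

#' Generate one synthetic breath spectrum
#'
#' intensity = sum of class bands (amplitudes jittered per sample)
#' + polynomial baseline + i.i.d. Gaussian noise + a Poisson-count number
#' of narrow positive spikes (triangular, full width <= `spike_width_max`
#' points, amplitude 2-5x the strongest band).
#'
#' @param label Class label of the sample.
#' @param config A [cohort_config()].
#' @param spectrum_seed Integer seed for this spectrum's random draws.
#' @param sample_id Sample id stored on the spectrum.
#' @return A [spectrum()] whose `meta` records the label and generation
#'   parameters.
#' @export
generate_spectrum <- function(label, config, spectrum_seed = config$seed,
                              sample_id = "synthetic") {
  label <- class_label(label)
  axis <- cohort_axis(config)
  n <- config$n_points
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(spectrum_seed %% .Machine$integer.max))

  bands <- config$band_library[[as.character(label)]]
  sig <- numeric(n)
  max_amp <- 0
  for (i in seq_len(nrow(bands))) {
    amp <- max(0, stats::rnorm(1, bands$amp_mean[i], bands$amp_sd[i]))
    max_amp <- max(max_amp, amp)
    sig <- sig + band_profile(axis, bands$center[i], bands$width[i], amp,
                              config$band_shape)
  }

  if (config$baseline_scale > 0) {
    t01 <- seq(0, 1, length.out = n)
    coefs <- stats::runif(config$baseline_order + 1L, -1, 1) * config$baseline_scale
    sig <- sig + drop(outer(t01, 0:config$baseline_order, `^`) %*% coefs)
  }

  if (config$noise_sd > 0) sig <- sig + stats::rnorm(n, 0, config$noise_sd)

  n_spikes <- if (config$spike_rate > 0) stats::rpois(1, config$spike_rate) else 0L
  if (n_spikes > 0) {
    for (k in seq_len(n_spikes)) {
      pos <- sample.int(n, 1)
      half <- sample.int(max(1L, config$spike_width_max %/% 2L + 1L), 1) - 1L
      amp <- stats::runif(1, 2, 5) * max(max_amp, 1)
      idx <- max(1L, pos - half):min(n, pos + half)
      # triangular profile peaking at pos
      sig[idx] <- sig[idx] + amp * (1 - abs(idx - pos) / (half + 1))
    }
  }

  spectrum(axis, sig, sample_id = sample_id,
           meta = list(label = as.character(label), synthetic = TRUE,
                       seed = as.integer(spectrum_seed %% .Machine$integer.max),
                       n_spikes = n_spikes, augmented = FALSE))
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_egc + n_agc + n_healthy` spectra; one per-spectrum substream
#' is derived from the cohort seed up front, so the output is a pure,
#' order-independent function of (config, seed).
#'
#' @param config A [cohort_config()].
#' @return A [spectrum_set()].
#' @export
generate_cohort <- function(config) {
  counts <- c(EGC = config$n_egc, AGC = config$n_agc, HEALTHY = config$n_healthy)
  if (sum(counts) == 0L) stop("all class counts are zero")
  labels <- rep(names(counts), counts)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(labels))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  ids <- sprintf("%s_%03d", labels, unlist(lapply(counts, seq_len)))
  spectra <- mapply(function(lab, sd, id)
    generate_spectrum(lab, config, spectrum_seed = sd, sample_id = id),
    labels, sub_seeds, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  spectrum_set(spectra, labels)
}
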