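#' Augmentation configuration
#'
#' The cohort is expanded by cropping each spectrum to a fixed length and
#' adding copies shifted to the right along the wavenumber axis.
#'
#' @param crop_length Points kept per spectrum (default 1200).
#' @param shift_amount Rightward shift in axis units (default 2).
#' @param directions Character subset of `"right"`; empty vector disables
#'   shifting so only cropped originals are returned.
#' @return An `augment_config` list.
#' @export
augment_config <- function(crop_length = 1200, shift_amount = 2,
                           directions = "right") {
  stopifnot(crop_length >= 2, shift_amount >= 0,
            all(directions %in% "right"))
  structure(list(crop_length = as.integer(crop_length),
                 shift_amount = shift_amount,
                 directions = directions),
            class = "augment_config")
}

#' Crop a spectrum to a centered window
#'
#' Keeps the centered contiguous window of `crop_length` points with its
#' original axis values.
#'
#' @param s A [spectrum()].
#' @param crop_length Number of points to keep.
#' @return Cropped spectrum.
#' @export
crop_spectrum <- function(s, crop_length = 1200) {
  stopifnot(is_spectrum(s))
  n <- length(s$axis)
  crop_length <- as.integer(crop_length)
  if (crop_length > n) {
    stop("crop_length (", crop_length, ") exceeds spectrum length (", n, ")")
  }
  start <- (n - crop_length) %/% 2L + 1L
  idx <- start:(start + crop_length - 1L)
  spectrum(s$axis[idx], s$intensity[idx], sample_id = s$sample_id,
           meta = s$meta)
}

#' Shift a spectrum to the right along the axis
#'
#' Intensities are re-associated with `axis + shift_amount` and then
#' resampled back onto the original axis by linear interpolation; the
#' leading gap (points with no shifted source) is filled with the edge
#' value. `meta$augmented` and `meta$shift_applied` are set.
#'
#' @param s A [spectrum()].
#' @param shift_amount Nonnegative shift in axis units.
#' @return Shifted spectrum on the original axis.
#' @export
shift_spectrum <- function(s, shift_amount = 2) {
  stopifnot(is_spectrum(s), shift_amount >= 0)
  if (shift_amount == 0) {
    out <- s
  } else {
    y <- stats::approx(x = s$axis + shift_amount, y = s$intensity,
                       xout = s$axis, rule = 2)$y
    out <- spectrum(s$axis, y, sample_id = s$sample_id, meta = s$meta)
  }
  out$meta$augmented <- TRUE
  out$meta$shift_applied <- shift_amount
  out
}

#' Augment a cohort by cropping and wavenumber shifting
#'
#' Returns every cropped original plus, per configured direction, one
#' shifted copy with the same label. Originals carry
#' `meta$augmented = FALSE`, copies `TRUE`; copies also record
#' `meta$source_id` so data splits can keep a sample and its augmented
#' copy in the same partition.
#'
#' @param set A [spectrum_set()].
#' @param config An [augment_config()].
#' @return A [spectrum_set()] of size `length(set) * (1 + #directions)`.
#' @export
augment_cohort <- function(set, config = augment_config()) {
  cropped <- lapply(set$spectra, function(s) {
    s <- crop_spectrum(s, config$crop_length)
    s$meta$augmented <- FALSE
    s$meta$source_id <- s$sample_id
    s
  })
  spectra <- cropped
  labels <- as.character(set$labels)
  for (dir in config$directions) {
    copies <- lapply(cropped, function(s) {
      out <- shift_spectrum(s, config$shift_amount)
      out$sample_id <- paste0(s$sample_id, "_shift", config$shift_amount)
      out$meta$source_id <- s$sample_id
      out
    })
    spectra <- c(spectra, copies)
    labels <- c(labels, as.character(set$labels))
  }
  spectrum_set(spectra, labels)
}

#' Detect peaks in a baseline-corrected spectrum
#'
#' Local maxima whose topographic prominence exceeds `min_prominence`
#' (default half the intensity standard deviation). For each peak the
#' half-height crossings are located by linear interpolation to give the
#' full width at half maximum and the trapezoid area between crossings.
#'
#' @param s A [spectrum()], baseline-corrected.
#' @param min_prominence Prominence floor; peaks below it are discarded.
#' @return A `peak_table` data.frame with columns `position`, `height`,
#'   `width`, `area`, `prominence`, `placeholder`, sorted by position.
#' @export
detect_peaks <- function(s, min_prominence = NULL) {
  stopifnot(is_spectrum(s))
  x <- s$axis
  y <- s$intensity
  n <- length(y)
  if (is.null(min_prominence)) min_prominence <- 0.5 * stats::sd(y)
  # interior local maxima (plateau: keep the left edge point)
  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  if (length(cand) == 0L) return(empty_peak_table())

  prominence <- vapply(cand, function(i) {
    h <- y[i]
    left_min <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) { left_min <- min(left_min, y[j]); j <- j - 1L }
    if (j < 1L) left_min <- min(left_min, min(y[1:i]))
    right_min <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) { right_min <- min(right_min, y[j]); j <- j + 1L }
    if (j > n) right_min <- min(right_min, min(y[i:n]))
    h - max(left_min, right_min)
  }, numeric(1))

  keep <- prominence >= min_prominence & y[cand] > 0
  cand <- cand[keep]
  prominence <- prominence[keep]
  if (length(cand) == 0L) return(empty_peak_table())

  rows <- lapply(seq_along(cand), function(k) {
    i <- cand[k]
    h <- y[i]
    half <- h / 2
    # left crossing
    j <- i
    while (j > 1L && y[j - 1L] < y[j] && y[j - 1L] > half) j <- j - 1L
    if (j > 1L && y[j - 1L] <= half) {
      xl <- x[j - 1L] + (x[j] - x[j - 1L]) * (half - y[j - 1L]) / (y[j] - y[j - 1L])
    } else xl <- x[max(1L, j - 1L)]
    j <- i
    while (j < n && y[j + 1L] < y[j] && y[j + 1L] > half) j <- j + 1L
    if (j < n && y[j + 1L] <= half) {
      xr <- x[j] + (x[j + 1L] - x[j]) * (y[j] - half) / (y[j] - y[j + 1L])
    } else xr <- x[min(n, j + 1L)]
    seg <- x >= xl & x <= xr
    area <- if (sum(seg) >= 2L) {
      xs <- x[seg]; ys <- y[seg]
      sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
    } else h * (xr - xl)
    data.frame(position = x[i], height = h, width = xr - xl,
               area = max(area, 0), prominence = prominence[k],
               placeholder = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

empty_peak_table <- function() {
  out <- data.frame(position = numeric(0), height = numeric(0),
                    width = numeric(0), area = numeric(0),
                    prominence = numeric(0), placeholder = logical(0))
  class(out) <- c("peak_table", "data.frame")
  out
}

placeholder_peaks <- function(k) {
  out <- data.frame(position = rep(0, k), height = rep(0, k),
                    width = rep(0, k), area = rep(0, k),
                    prominence = rep(0, k), placeholder = rep(TRUE, k))
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Select the k most prominent peaks
#'
#' The `k` peaks of largest prominence are kept (ties broken towards the
#' smaller position) and re-ordered by ascending position. If fewer than
#' `k` peaks exist, zero-height placeholder peaks at position 0 pad the
#' table and are flagged in the `placeholder` column.
#'
#' @param peaks A `peak_table` from [detect_peaks()].
#' @param k Number of peaks to keep (default 50).
#' @return A `peak_table` with exactly `k` rows.
#' @export
select_top_peaks <- function(peaks, k = 50) {
  stopifnot(k >= 1)
  if (nrow(peaks) > k) {
    ord <- order(-peaks$prominence, peaks$position)
    peaks <- peaks[ord[seq_len(k)], , drop = FALSE]
  }
  pad <- k - nrow(peaks)
  if (pad > 0) peaks <- rbind(peaks, placeholder_peaks(pad))
  peaks <- peaks[order(peaks$position), , drop = FALSE]
  rownames(peaks) <- NULL
  class(peaks) <- c("peak_table", "data.frame")
  peaks
}

#' Turn a cohort into the network's n x k feature matrix
#'
#' Per sample, the feature vector holds the `k` selected peak heights
#' ordered by ascending position (placeholders contribute 0). Scaling to
#' [0,1] is a separate step ([scale_features()]) so that training-set
#' statistics can be reused on validation/test partitions.
#'
#' @param set A [spectrum_set()] of preprocessed spectra.
#' @param k Number of peak features per sample (default 50).
#' @param min_prominence Passed to [detect_peaks()].
#' @return A `feature_matrix`: list with `values` (n x k matrix),
#'   `sample_ids`, `labels`, `feature_names`, `groups` (source sample ids
#'   for leakage-safe splitting), `scaling` (NULL until scaled).
#' @export
featurize <- function(set, k = 50, min_prominence = NULL) {
  vals <- t(vapply(set$spectra, function(s) {
    pk <- select_top_peaks(detect_peaks(s, min_prominence), k)
    pk$height
  }, numeric(k)))
  ids <- sample_ids(set)
  groups <- vapply(set$spectra, function(s)
    if (!is.null(s$meta$source_id)) s$meta$source_id else s$sample_id,
    character(1))
  structure(list(
    values = vals, sample_ids = ids, labels = set$labels,
    feature_names = sprintf("f%02d", seq_len(k)),
    groups = groups, scaling = NULL
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$scaling)) " (unscaled)" else " (min-max scaled)"))
  invisible(x)
}

#' Min-max scale a feature matrix to [0,1]
#'
#' When `scaling` is NULL the per-feature minima and maxima are fitted on
#' this matrix (training use); otherwise the provided statistics are
#' applied unchanged (validation/test use), which may produce values
#' slightly outside [0,1]. A constant (all-equal) feature column scales
#' to 0 with a warning.
#'
#' @param fm A `feature_matrix` from [featurize()].
#' @param scaling NULL, or the `scaling` element of a previously scaled
#'   training feature matrix (list with `min` and `max` vectors).
#' @return The feature matrix with scaled `values` and `scaling` set.
#' @export
scale_features <- function(fm, scaling = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  if (is.null(scaling)) {
    scaling <- list(min = apply(v, 2, min), max = apply(v, 2, max))
    if (any(scaling$max == scaling$min)) {
      warning("constant feature column(s) scaled to 0: ",
              paste(fm$feature_names[scaling$max == scaling$min], collapse = ", "))
    }
  }
  rng <- scaling$max - scaling$min
  rng[rng == 0] <- 1
  fm$values <- sweep(sweep(v, 2, scaling$min), 2, rng, "/")
  fm$scaling <- scaling
  fm
}

#' Subset a feature matrix by row indices
#'
#' Keeps `values`, `sample_ids`, `labels` and `groups` aligned.
#'
#' @param fm A `feature_matrix`.
#' @param idx Integer row indices.
#' @return The subsetted `feature_matrix`.
#' @export
subset_features <- function(fm, idx) {
  fm$values <- fm$values[idx, , drop = FALSE]
  fm$sample_ids <- fm$sample_ids[idx]
  fm$labels <- fm$labels[idx]
  fm$groups <- fm$groups[idx]
  fm
}

#' Write a feature matrix as CSV
#'
#' Columns: `sample_id`, `label`, then one column per feature.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(sample_id = fm$sample_ids, label = as.character(fm$labels),
                   fm$values)
  names(df)[-(1:2)] <- fm$feature_names
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
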