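#' Construct a breath spectrum
#'
#' A spectrum is one breath sample's intensity series over an ordered
#' wavenumber-like axis. The axis is treated as unitless but named in
#' cm^-1 by convention, so that the augmentation shift of 2 axis units
#' is commensurate with band positions.
#'
#' @param axis Numeric vector of strictly increasing positions, length >= 2.
#' @param intensity Numeric vector of finite intensities, same length as
#'   `axis`. Negative values are allowed (e.g. after baseline correction).
#' @param sample_id Character scalar identifying the sample.
#' @param meta Named list of free-form metadata (e.g. `augmented`,
#'   `shift_applied`, generation parameters).
#' @return An object of class `breath_spectrum` with fields `axis`,
#'   `intensity`, `sample_id`, `meta`.
#' @examples
#' s <- spectrum(400:410, rnorm(11), sample_id = "demo")
#' length(s$axis)
#' @export
spectrum <- function(axis, intensity, sample_id = "sample", meta = list()) {
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity)) {
    stop("axis and intensity must have equal length (", length(axis), " vs ",
         length(intensity), ")")
  }
  if (length(axis) < 2L) stop("a spectrum needs at least 2 points")
  if (anyNA(axis) || any(!is.finite(axis))) stop("axis values must be finite")
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("intensities must be finite (no NA/NaN/Inf)")
  }
  if (any(diff(axis) <= 0)) {
    ord <- order(axis)
    axis <- axis[ord]
    intensity <- intensity[ord]
    dup <- which(diff(axis) == 0)
    if (length(dup) > 0L) {
      stop("duplicate axis value: ", format(axis[dup[1L]]))
    }
  }
  if (!is.character(sample_id) || length(sample_id) != 1L) {
    stop("sample_id must be a single string")
  }
  stopifnot(is.list(meta))
  structure(
    list(axis = axis, intensity = intensity, sample_id = sample_id, meta = meta),
    class = "breath_spectrum"
  )
}

#' @export
print.breath_spectrum <- function(x, ...) {
  cat(sprintf("<breath_spectrum> %s: %d points, axis [%g, %g]\n",
              x$sample_id, length(x$axis), min(x$axis), max(x$axis)))
  if (isTRUE(x$meta$augmented)) {
    cat(sprintf("  augmented copy (shift %g)\n", x$meta$shift_applied))
  }
  invisible(x)
}

#' @export
length.breath_spectrum <- function(x) length(x$axis)

is_spectrum <- function(x) inherits(x, "breath_spectrum")

#' Class labels for the three-group breath cohort
#'
#' The cohort distinguishes early gastric cancer (EGC), advanced gastric
#' cancer (AGC) and healthy controls. Integer codes follow the convention
#' EGC = 0, AGC = 1, HEALTHY = 2.
#'
#' @param x Character vector of label names, a factor, or integer codes
#'   in 0:2.
#' @return A factor with levels `EGC`, `AGC`, `HEALTHY`.
#' @examples
#' class_label(c("EGC", "HEALTHY"))
#' class_label(0:2)
#' @export
class_label <- function(x) {
  levels <- class_levels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (any(is.na(x)) || any(!(x %in% 0:2))) {
      stop("integer label codes must be 0 (EGC), 1 (AGC) or 2 (HEALTHY)")
    }
    return(factor(levels[x + 1L], levels = levels))
  }
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0L) stop("unknown class label: ", paste(bad, collapse = ", "))
  factor(x, levels = levels)
}

#' @rdname class_label
#' @export
class_levels <- function() c("EGC", "AGC", "HEALTHY")

#' @rdname class_label
#' @param labels A factor produced by [class_label()].
#' @export
label_code <- function(labels) as.integer(class_label(labels)) - 1L

#' A labeled cohort of spectra
#'
#' @param spectra List of [spectrum()] objects with unique sample ids.
#' @param labels Vector coercible by [class_label()], aligned with `spectra`.
#' @return An object of class `spectrum_set` with fields `spectra` and
#'   `labels`.
#' @export
spectrum_set <- function(spectra, labels) {
  stopifnot(is.list(spectra), all(vapply(spectra, is_spectrum, logical(1))))
  labels <- class_label(labels)
  if (length(spectra) != length(labels)) {
    stop("spectra and labels lengths differ")
  }
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in set: ", ids[anyDuplicated(ids)])
  }
  structure(list(spectra = spectra, labels = labels), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra (%s)\n", length(x$spectra),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

sample_ids <- function(set) vapply(set$spectra, function(s) s$sample_id, character(1))

#' Read a spectrum from a two-column text file
#'
#' Files are delimited text (comma, tab or whitespace, autodetected) with
#' columns wavenumber and intensity. A header line is optional. Lines of
#' the form `# key=value` are parsed into spectrum metadata. Rows are
#' sorted by axis on load.
#'
#' @param path Path to the file.
#' @param sample_id Sample id; defaults to the file name without extension.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  comment <- grepl("^\\s*#", lines)
  for (ln in lines[comment]) {
    kv <- sub("^\\s*#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*$", "", kv)
      val <- sub("^[^=]*=", "", kv)
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(key)]] <- if (!is.na(num)) num else trimws(val)
    }
  }
  lines <- lines[!comment & nzchar(trimws(lines))]
  sep <- if (any(grepl(",", lines, fixed = TRUE))) "," else ""
  parse_row <- function(ln) {
    fields <- if (sep == ",") strsplit(ln, ",", fixed = TRUE)[[1]]
              else strsplit(trimws(ln), "\\s+")[[1]]
    suppressWarnings(as.numeric(trimws(fields[1:2])))
  }
  vals <- vapply(lines, parse_row, numeric(2), USE.NAMES = FALSE)
  ok <- !is.na(vals[1L, ]) & !is.na(vals[2L, ])
  vals <- vals[, ok, drop = FALSE]
  if (ncol(vals) < 2L) stop("fewer than 2 valid data rows in ", path)
  ax <- vals[1L, ]
  dup <- unique(ax[duplicated(ax)])
  if (length(dup) > 0L) {
    stop("duplicate axis value ", format(dup[1L]), " in ", path)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  spectrum(ax, vals[2L, ], sample_id = sample_id, meta = meta)
}

#' Write a spectrum to a two-column CSV file
#'
#' Metadata are stored as `# key=value` comment lines; values round-trip
#' through [read_spectrum()] at full double precision.
#'
#' @param s A [spectrum()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(is_spectrum(s))
  scalar_meta <- s$meta[vapply(s$meta, function(v)
    (is.numeric(v) || is.character(v) || is.logical(v)) && length(v) == 1L,
    logical(1))]
  header <- c(
    vapply(names(scalar_meta), function(k)
      sprintf("# %s=%s", k, format(scalar_meta[[k]], digits = 17)),
      character(1)),
    "wavenumber,intensity"
  )
  rows <- sprintf("%s,%s",
                  formatC(s$axis, digits = 17, format = "g"),
                  formatC(s$intensity, digits = 17, format = "g"))
  ok <- tryCatch({
    writeLines(c(header, rows), path)
    TRUE
  }, error = function(e) stop("cannot write spectrum to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read/write a cohort label table
#'
#' The label table is a CSV with columns `sample_id,label`.
#'
#' @param path Path of the CSV file.
#' @return `read_label_table` returns a data.frame with columns
#'   `sample_id` and `label` (a [class_label()] factor).
#' @export
read_label_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("label table must have columns sample_id,label")
  }
  df$label <- class_label(df$label)
  df[c("sample_id", "label")]
}

#' @rdname read_label_table
#' @param set A [spectrum_set()].
#' @export
write_label_table <- function(set, path) {
  df <- data.frame(sample_id = sample_ids(set),
                   label = as.character(set$labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a directory of spectrum files plus a label table
#'
#' @param dir Directory containing one spectrum file per sample and a
#'   `labels.csv` label table.
#' @return A [spectrum_set()].
#' @export
read_cohort <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) stop("no labels.csv in ", dir)
  labs <- read_label_table(lab_path)
  if (nrow(labs) == 0L) stop("empty label table in ", dir)
  files <- list.files(dir, pattern = "\\.(csv|tsv|txt)$", full.names = TRUE)
  files <- files[basename(files) != "labels.csv"]
  by_id <- stats::setNames(files, sub("\\.[^.]*$", "", basename(files)))
  missing <- setdiff(labs$sample_id, names(by_id))
  if (length(missing) > 0L) {
    stop("no spectrum file for sample(s): ", paste(missing, collapse = ", "))
  }
  spectra <- lapply(labs$sample_id, function(id)
    read_spectrum(by_id[[id]], sample_id = id))
  spectrum_set(spectra, labs$label)
}
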