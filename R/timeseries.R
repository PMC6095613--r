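#' Sampled time series
#'
#' Light container for a uniformly sampled, real-valued signal: the auditory
#' amplitude envelope, the lip-area trace, or a neural node's activity.
#'
#' @param values Numeric vector of samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Optional name for the signal.
#'
#' @return An object of class `avp_ts` with fields `values`, `fs`, `label`.
#' @examples
#' ts <- avp_ts(sin(2 * pi * 5 * seq(0, 1, by = 1 / 250)), fs = 250, label = "demo")
#' ts
#' @export
avp_ts <- function(values, fs, label = "") {
  if (!is.numeric(values) || length(values) < 2) {
    stop("`values` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs), label = as.character(label)),
    class = "avp_ts"
  )
}

#' @export
print.avp_ts <- function(x, ...) {
  cat(sprintf(
    "<avp_ts%s: %d samples @ %g Hz (%.2f s)>\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    length(x$values), x$fs, length(x$values) / x$fs
  ))
  invisible(x)
}

#' @export
length.avp_ts <- function(x) length(x$values)

#' @method as_tibble avp_ts
#' @export
as_tibble.avp_ts <- function(x, ...) {
  tibble(
    time = (seq_along(x$values) - 1) / x$fs,
    value = x$values
  )
}

# Coerce numeric vectors on the fly; fs required then.
as_avp_ts <- function(x, fs = NULL, label = "") {
  if (inherits(x, "avp_ts")) return(x)
  if (is.null(fs)) stop("`fs` must be supplied when passing a bare numeric vector", call. = FALSE)
  avp_ts(x, fs, label)
}

#' Band-limited analytic signal
#'
#' Complex-valued analytic representation of a band-pass filtered signal;
#' the unit every phase-based estimator consumes.
#'
#' @param values Complex vector.
#' @param fs Sampling rate (Hz).
#' @param band_center,band_halfwidth Band parameters in Hz;
#'   `band_center - band_halfwidth` must be positive.
#' @return An object of class `avp_analytic`.
#' @export
avp_analytic <- function(values, fs, band_center, band_halfwidth) {
  if (!is.complex(values)) stop("`values` must be complex", call. = FALSE)
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values)))) {
    stop("analytic signal contains non-finite values", call. = FALSE)
  }
  if (band_center - band_halfwidth <= 0) {
    stop("`band_center - band_halfwidth` must be > 0", call. = FALSE)
  }
  structure(
    list(
      values = values, fs = as.numeric(fs),
      band_center = as.numeric(band_center),
      band_halfwidth = as.numeric(band_halfwidth)
    ),
    class = "avp_analytic"
  )
}

#' @export
print.avp_analytic <- function(x, ...) {
  cat(sprintf(
    "<avp_analytic: %d samples @ %g Hz, band %g +/- %g Hz>\n",
    length(x$values), x$fs, x$band_center, x$band_halfwidth
  ))
  invisible(x)
}

#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for the real-data path: 16- or 32-bit integer PCM
#' and 32- or 64-bit IEEE float, mono (multi-channel files are averaged to
#' mono with a warning). Samples are rescaled to `[-1, 1]` for integer PCM.
#'
#' @param path Path to a `.wav` file.
#' @return An [avp_ts] at the file's sampling rate.
#' @export
read_wav_mono <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path, call. = FALSE)

  bytes <- fmt$bits / 8
  n <- length(data_raw) %/% bytes
  x <- if (fmt$audio_format == 1L) {
    if (fmt$bits == 16) {
      readBin(data_raw, "integer", n, 2, signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 32) {
      readBin(data_raw, "integer", n, 4, endian = "little") / 2147483648
    } else {
      stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
    }
  } else if (fmt$audio_format == 3L) {
    readBin(data_raw, "double", n, bytes, endian = "little")
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")", call. = FALSE)
  }
  if (fmt$n_channels > 1) {
    warning("averaging ", fmt$n_channels, " channels to mono")
    x <- rowMeans(matrix(x, ncol = fmt$n_channels, byrow = TRUE))
  }
  avp_ts(x, fs = fmt$sample_rate, label = basename(path))
}

#' Read / write a columnar signal file
#'
#' Delimited text with one column per series, a header row naming the series,
#' and a `# fs=<Hz>` comment line carrying the sampling rate.
#'
#' @param path File path.
#' @return `read_signal_tsv()`: a named list of [avp_ts].
#' @export
read_signal_tsv <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("^#\\s*fs\\s*=\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2) stop("missing '# fs=<Hz>' header line in ", path, call. = FALSE)
  fs <- as.numeric(m[2])
  dat <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  purrr::imap(as.list(dat), function(v, nm) avp_ts(v, fs = fs, label = nm))
}

#' @rdname read_signal_tsv
#' @param signals Named list of [avp_ts] sharing one sampling rate.
#' @export
write_signal_tsv <- function(signals, path) {
  stopifnot(length(signals) >= 1)
  fs <- unique(vapply(signals, function(s) s$fs, numeric(1)))
  if (length(fs) != 1) stop("all signals must share one sampling rate", call. = FALSE)
  n <- unique(vapply(signals, length, integer(1)))
  if (length(n) != 1) stop("all signals must share one length", call. = FALSE)
  dat <- as_tibble(purrr::map(signals, "values"))
  writeLines(sprintf("# fs=%.10g", fs), path)
  readr::write_tsv(dat, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
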