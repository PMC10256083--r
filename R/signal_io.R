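#' Construct a voice signal
#'
#' A `voice_signal` is the basic container for a sampled sustained-vowel
#' recording: an amplitude vector (dimensionless, nominal range \[-1, 1\]),
#' its sampling rate in Hz, an identifier and an optional class label.
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param rate Sampling frequency in Hz (positive scalar).
#' @param id Opaque sample identifier (coerced to character).
#' @param label Optional label, `"healthy"` or `"dysphonic"`.
#' @return An object of class `voice_signal` with fields `samples`, `rate`,
#'   `id` and `label`.
#' @export
voice_signal <- function(samples, rate, id = "signal", label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  if (!is.null(label)) label <- match.arg(label, c("healthy", "dysphonic"))
  structure(
    list(samples = samples, rate = as.numeric(rate),
         id = as.character(id), label = label),
    class = "voice_signal"
  )
}

#' @export
print.voice_signal <- function(x, ...) {
  cat(sprintf("<voice_signal '%s'> %d samples @ %g Hz (%.3f s)%s\n",
              x$id, length(x$samples), x$rate,
              length(x$samples) / x$rate,
              if (is.null(x$label)) "" else paste0(", label: ", x$label)))
  invisible(x)
}

#' @export
length.voice_signal <- function(x) length(x$samples)

#' Construct a labeled corpus
#'
#' Bundles a list of [voice_signal()] objects with per-sample metadata
#' (vowel, pitch regime and, for synthetic corpora, the ground-truth
#' synthesis parameters). Every signal must carry a label and ids must be
#' unique.
#'
#' @param signals List of [voice_signal()] objects, all labeled.
#' @param metadata Optional data.frame with one row per signal; an `id`
#'   column is added/checked against the signal ids.
#' @return An object of class `labeled_corpus` with fields `signals` and
#'   `metadata`.
#' @export
labeled_corpus <- function(signals, metadata = NULL) {
  stopifnot(is.list(signals), length(signals) >= 1L)
  ids <- vapply(signals, function(s) s$id, character(1))
  labels <- vapply(signals, function(s) {
    if (is.null(s$label)) stop("every signal in a corpus must have a label")
    s$label
  }, character(1))
  if (anyDuplicated(ids)) stop("signal ids must be unique")
  if (is.null(metadata)) metadata <- data.frame(id = ids)
  if (!"id" %in% names(metadata)) metadata$id <- ids
  if (nrow(metadata) != length(signals))
    stop("metadata must have one row per signal")
  metadata$label <- labels
  structure(list(signals = signals, metadata = metadata),
            class = "labeled_corpus")
}

#' @export
print.labeled_corpus <- function(x, ...) {
  tab <- table(x$metadata$label)
  cat(sprintf("<labeled_corpus> %d signals (%s)\n", length(x$signals),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
length.labeled_corpus <- function(x) length(x$signals)

#' Corpus labels
#' @param corpus A [labeled_corpus()].
#' @return Character vector of per-signal labels.
#' @export
corpus_labels <- function(corpus) {
  vapply(corpus$signals, function(s) s$label, character(1))
}

#' Class-proportion arithmetic for a two-class corpus
#'
#' Given healthy and dysphonic counts (or a corpus), returns the percentage
#' of each class, e.g. 384 healthy and 324 dysphonic recordings give a
#' healthy proportion of 54.24%.
#'
#' @param n_healthy Healthy count, or a [labeled_corpus()].
#' @param n_dysphonic Dysphonic count (ignored when a corpus is given).
#' @return Named numeric vector `c(healthy = ..., dysphonic = ...)` in
#'   percent.
#' @export
label_proportions <- function(n_healthy, n_dysphonic = NULL) {
  if (inherits(n_healthy, "labeled_corpus")) {
    lab <- corpus_labels(n_healthy)
    n_h <- sum(lab == "healthy"); n_d <- sum(lab == "dysphonic")
  } else {
    n_h <- n_healthy; n_d <- n_dysphonic
  }
  tot <- n_h + n_d
  if (tot <= 0) stop("corpus is empty")
  c(healthy = 100 * n_h / tot, dysphonic = 100 * n_d / tot)
}

# ---- WAV (RIFF) I/O ---------------------------------------------------------
# Minimal RIFF/WAVE codec: 16-bit PCM canonical output; reader also accepts
# 8/24/32-bit PCM and 32/64-bit IEEE float, any channel count (averaged to
# mono).

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file into a [voice_signal()]. Integer PCM samples are
#' rescaled to \[-1, 1\]; multichannel input is averaged to mono; the
#' sampling rate is preserved.
#'
#' @param path Path to an existing WAV file.
#' @param id Identifier for the resulting signal (default: file base name).
#' @return A [voice_signal()].
#' @export
read_wav <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    tag <- readChar(con, 4, useBytes = TRUE)
    if (length(tag) == 0L || nchar(tag) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(tag, "fmt ")) {
      chunk <- readBin(con, "raw", size + size %% 2L)
      fmt <- list(
        format    = readBin(chunk[1:2], "integer", 1, 2, signed = FALSE,
                            endian = "little"),
        channels  = readBin(chunk[3:4], "integer", 1, 2, signed = FALSE,
                            endian = "little"),
        rate      = readBin(chunk[5:8], "integer", 1, 4, endian = "little"),
        bits      = readBin(chunk[15:16], "integer", 1, 2, signed = FALSE,
                            endian = "little")
      )
    } else if (identical(tag, "data")) {
      data_raw <- readBin(con, "raw", size)
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("corrupt WAV file (missing fmt or data chunk): ", path)
  if (fmt$format == 0xFFFE) fmt$format <- 1L  # extensible header, assume PCM

  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$format),
    "1" = {  # integer PCM
      if (fmt$bits == 8L) {
        (readBin(data_raw, "integer", n_total, 1, signed = FALSE) - 128) / 128
      } else if (fmt$bits == 16L) {
        readBin(data_raw, "integer", n_total, 2, signed = TRUE,
                endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        b <- matrix(as.integer(data_raw), nrow = 3L)
        v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else if (fmt$bits == 32L) {
        readBin(data_raw, "integer", n_total, 4, endian = "little") / 2147483648
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = readBin(data_raw, "double", n_total, bytes, endian = "little"),
    stop("unsupported WAV format code: ", fmt$format)
  )
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  if (is.null(id)) id <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  voice_signal(x, fmt$rate, id = id)
}

#' Write a WAV file
#'
#' Writes a [voice_signal()] as mono 16-bit PCM at the signal's rate
#' (matching the resolution of typical clinical voice corpora). Values are
#' clipped to \[-1, 1 - 2^-15\] before quantization.
#'
#' @param signal A [voice_signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "voice_signal"))
  x <- pmin(pmax(signal$samples, -1), 1 - 2^-15)
  q <- as.integer(round(x * 32768))
  q <- pmin(pmax(q, -32768L), 32767L)
  n <- length(q)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(round(signal$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(signal$rate) * 2L), con, size = 4,
           endian = "little")                       # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

#' Band-limited resampling
#'
#' Resamples a signal to a new rate with the Fourier method: the spectrum is
#' zero-padded (upsampling) or truncated (downsampling) so the result is
#' exactly band-limited. Output length is `round(n * target_rate / rate)`;
#' the amplitude of any sub-Nyquist sinusoid is preserved.
#'
#' @param signal A [voice_signal()].
#' @param target_rate Target sampling rate in Hz.
#' @return A [voice_signal()] at `target_rate`.
#' @export
resample_signal <- function(signal, target_rate) {
  stopifnot(inherits(signal, "voice_signal"), target_rate > 0)
  if (target_rate == signal$rate) return(signal)
  x <- signal$samples
  n <- length(x)
  m <- max(1L, as.integer(round(n * target_rate / signal$rate)))
  X <- stats::fft(x)
  Y <- complex(m)
  keep <- min(n, m)
  half <- keep %/% 2L
  # DC .. positive frequencies
  Y[seq_len(half + 1L)] <- X[seq_len(half + 1L)]
  # negative frequencies
  if (half >= 1L) {
    idx <- seq_len(half - as.integer(keep %% 2L == 0L))
    if (length(idx) > 0L) Y[m + 1L - idx] <- X[n + 1L - idx]
  }
  # split the shared Nyquist bin when truncating to an even length
  if (keep %% 2L == 0L && m < n) {
    nyq <- X[half + 1L] / 2 + Conj(X[n + 1L - half]) / 2
    Y[half + 1L] <- nyq
    Y[m + 1L - half] <- Conj(nyq)
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
  voice_signal(y, target_rate, id = signal$id, label = signal$label)
}

# ---- corpus I/O -------------------------------------------------------------

#' Write a corpus as WAV files plus a manifest
#'
#' Writes each signal as `<id>.wav` in `dir` and a `manifest.csv` with one
#' row per signal (id, label and all metadata columns).
#'
#' @param corpus A [labeled_corpus()].
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in corpus$signals) write_wav(s, file.path(dir, paste0(s$id, ".wav")))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(corpus$metadata, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a corpus from a manifest
#'
#' Reads `manifest.csv` (or a directory containing one) written by
#' [write_corpus()] and loads the WAV files alongside it.
#'
#' @param path Manifest file or its directory.
#' @return A [labeled_corpus()].
#' @export
read_corpus <- function(path) {
  manifest <- if (dir.exists(path)) file.path(path, "manifest.csv") else path
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  meta <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  signals <- lapply(seq_len(nrow(meta)), function(i) {
    s <- read_wav(file.path(dir, paste0(meta$id[i], ".wav")), id = meta$id[i])
    s$label <- meta$label[i]
    s
  })
  labeled_corpus(signals, meta)
}
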