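# Cepstral-coefficient extraction: shared framing/spectral front end, six
# filterbank families (mel, inverse mel, linear, bark, gammatone,
# gammachirp), LPC-derived cepstra and constant-Q cepstra, plus delta
# dynamics and cepstral mean-variance normalization (CMVN).

CC_TECHNIQUES <- c("CQCC", "MFCC", "iMFCC", "LFCC", "GFCC", "BFCC",
                   "LPCC", "NGCC")

#' Framing parameters for spectral analysis
#'
#' @param win_len Analysis window length in seconds (default 25 ms).
#' @param hop_len Hop between frame starts in seconds (default 10 ms).
#' @param preemph Pre-emphasis coefficient in `[0, 1)` (default 0.97),
#'   compensating the spectral tilt of voiced speech.
#' @param window Taper name: `"hamming"`, `"hann"` or `"rect"`.
#' @param n_fft FFT size; `NULL` selects the next power of two at or above
#'   the window length in samples.
#' @return An object of class `frame_params`.
#' @export
frame_params <- function(win_len = 0.025, hop_len = 0.010, preemph = 0.97,
                         window = "hamming", n_fft = NULL) {
  if (!(hop_len > 0 && hop_len <= win_len))
    stop("need 0 < hop_len <= win_len")
  if (preemph < 0 || preemph >= 1) stop("preemph must be in [0, 1)")
  window <- match.arg(window, c("hamming", "hann", "rect"))
  structure(list(win_len = win_len, hop_len = hop_len, preemph = preemph,
                 window = window, n_fft = n_fft),
            class = "frame_params")
}

.taper <- function(name, n) {
  switch(name,
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)),
    hann    = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)),
    rect    = rep(1, n)
  )
}

.next_pow2 <- function(n) 2^ceiling(log2(n))

# Slice a vector into frames of `win` samples every `hop` samples
# (columns = frames); the last partial frame, if any, is zero-padded.
.frame_matrix <- function(x, win, hop) {
  n <- length(x)
  nframes <- 1L + floor((n - win) / hop)
  idx <- outer(seq_len(win), (seq_len(nframes) - 1L) * hop, `+`)
  matrix(x[idx], nrow = win)
}

#' Framed power spectra
#'
#' Applies pre-emphasis `y[t] = x[t] - preemph * x[t-1]`, slices the signal
#' into tapered frames and returns the per-frame magnitude-squared FFT
#' spectrum. The frame count is `1 + floor((n - win) / hop)`.
#'
#' @param signal A [voice_signal()].
#' @param params A [frame_params()].
#' @return List with `power` (nframes x (n_fft/2+1) matrix), `freqs` (Hz per
#'   bin), `n_fft`, `rate` and `nframes`.
#' @export
preprocess_frames <- function(signal, params = frame_params()) {
  stopifnot(inherits(signal, "voice_signal"))
  rate <- signal$rate
  win <- as.integer(round(params$win_len * rate))
  hop <- as.integer(round(params$hop_len * rate))
  if (length(signal$samples) < win)
    stop("signal shorter than one analysis window")
  x <- signal$samples
  y <- c(x[1] * (1 - params$preemph), x[-1] - params$preemph * x[-length(x)])
  frames <- .frame_matrix(y, win, hop) * .taper(params$window, win)
  n_fft <- params$n_fft %||% .next_pow2(win)
  if (n_fft < win) stop("n_fft must be >= window length in samples")
  nb <- n_fft %/% 2L + 1L
  padded <- rbind(frames, matrix(0, n_fft - win, ncol(frames)))
  spec <- stats::mvfft(padded)[seq_len(nb), , drop = FALSE]
  list(power = t(Mod(spec)^2),
       freqs = (seq_len(nb) - 1L) * rate / n_fft,
       n_fft = n_fft, rate = rate, nframes = ncol(frames))
}

# ---- frequency warps --------------------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
# Traunmueller bark warp
hz_to_bark <- function(f) 26.81 * f / (1960 + f) - 0.53
bark_to_hz <- function(z) 1960 * (z + 0.53) / (26.81 - (z + 0.53))
hz_to_erbs <- function(f) 21.4 * log10(1 + 0.00437 * f)
erbs_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Build a cepstral filterbank
#'
#' Triangular filterbanks with centers equally spaced on the mel, inverse
#' mel, linear or bark axis, or 4th-order gammatone / gammachirp auditory
#' magnitude responses at ERB-spaced centers. The inverse-mel bank is the
#' mel bank mirrored along the frequency axis; gammachirp rows are scaled
#' to unit maximum (the "normalized" of NGCC).
#'
#' @param scale One of `"mel"`, `"imel"`, `"linear"`, `"bark"`,
#'   `"gammatone"`, `"gammachirp"`.
#' @param n_filters Number of filters (default 26).
#' @param n_fft FFT size the bank applies to.
#' @param rate Sampling rate in Hz.
#' @param fmin,fmax Band edges in Hz (defaults 0 and `rate/2`; auditory
#'   scales floor `fmin` at 40 Hz to keep ERB centers positive).
#' @return An object of class `filter_bank`: list with `weights`
#'   (n_filters x (n_fft/2+1)), `scale`, `centers`, `rate`, `n_fft`.
#' @export
build_filterbank <- function(scale, n_filters = 26, n_fft = 2048, rate,
                             fmin = 0, fmax = rate / 2) {
  scale <- match.arg(scale, c("mel", "imel", "linear", "bark",
                              "gammatone", "gammachirp"))
  if (!(fmin >= 0 && fmin < fmax && fmax <= rate / 2))
    stop("need 0 <= fmin < fmax <= rate/2")
  nb <- n_fft %/% 2L + 1L
  freqs <- (seq_len(nb) - 1L) * rate / n_fft

  triangles <- function(fwd, inv) {
    pts <- inv(seq(fwd(fmin), fwd(fmax), length.out = n_filters + 2L))
    W <- matrix(0, n_filters, nb)
    for (k in seq_len(n_filters)) {
      lo <- pts[k]; c0 <- pts[k + 1L]; hi <- pts[k + 2L]
      up <- (freqs - lo) / (c0 - lo)
      dn <- (hi - freqs) / (hi - c0)
      W[k, ] <- pmax(0, pmin(up, dn))
    }
    list(W = W, centers = pts[2:(n_filters + 1L)])
  }

  if (scale %in% c("mel", "imel")) {
    tb <- triangles(hz_to_mel, mel_to_hz)
    W <- tb$W; centers <- tb$centers
    if (scale == "imel") {
      # mirror along the frequency axis: flip filters and bins
      W <- W[rev(seq_len(n_filters)), rev(seq_len(nb)), drop = FALSE]
      centers <- rev(fmax + fmin - centers)
    }
  } else if (scale == "linear") {
    tb <- triangles(identity, identity)
    W <- tb$W; centers <- tb$centers
  } else if (scale == "bark") {
    tb <- triangles(hz_to_bark, bark_to_hz)
    W <- tb$W; centers <- tb$centers
  } else {
    fmin_a <- max(fmin, 40)
    centers <- erbs_to_hz(seq(hz_to_erbs(fmin_a), hz_to_erbs(fmax * 0.95),
                              length.out = n_filters))
    W <- matrix(0, n_filters, nb)
    for (k in seq_len(n_filters)) {
      b <- 1.019 * erb_bandwidth(centers[k])
      u <- (freqs - centers[k]) / b
      mag <- (1 + u^2)^(-2)            # 4th-order gammatone magnitude
      if (scale == "gammachirp") {
        mag <- mag * exp(-1 * atan(u)) # fixed chirp term c = -1
        mag <- mag / max(mag)          # unit-maximum rows (NGCC)
      }
      W[k, ] <- mag
    }
  }
  structure(list(weights = W, scale = scale, centers = centers,
                 rate = rate, n_fft = n_fft),
            class = "filter_bank")
}

# Orthonormal type-II DCT matrix (rows = coefficients).
.dct_matrix <- function(n) {
  k <- seq_len(n) - 1L
  D <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Filterbank cepstra from framed power spectra
#'
#' Per frame: filterbank energies `e = W s`, log with floor, orthonormal
#' type-II DCT across filters, first `nceps` coefficients retained.
#'
#' @param spectra Output of [preprocess_frames()] (or a compatible list
#'   with a `power` matrix).
#' @param bank A [build_filterbank()] bank with matching FFT size.
#' @param nceps Number of cepstral coefficients to keep.
#' @return `nceps` x `nframes` matrix.
#' @export
filterbank_cepstra <- function(spectra, bank, nceps = 20) {
  W <- bank$weights
  S <- spectra$power
  if (ncol(S) != ncol(W)) stop("filterbank bins do not match spectra bins")
  if (nceps > nrow(W)) stop("nceps cannot exceed the number of filters")
  E <- S %*% t(W)                       # nframes x n_filters
  L <- log(pmax(E, LOG_FLOOR))
  D <- .dct_matrix(nrow(W))[seq_len(nceps), , drop = FALSE]
  C <- D %*% t(L)                       # nceps x nframes
  C
}

# ---- LPCC -------------------------------------------------------------------

# Levinson-Durbin solution of the autocorrelation normal equations.
# Returns prediction coefficients a (x[t] ~ sum a_k x[t-k]) and the final
# prediction-error energy.
levinson_durbin <- function(r, order) {
  a <- numeric(order)
  err <- r[1]
  if (err <= 0) return(list(a = a, err = 0))
  for (m in seq_len(order)) {
    acc <- r[m + 1L]
    if (m > 1L) acc <- acc - sum(a[seq_len(m - 1L)] * r[m:2])
    k <- acc / err
    a_new <- a
    a_new[m] <- k
    if (m > 1L)
      a_new[seq_len(m - 1L)] <- a[seq_len(m - 1L)] - k * a[(m - 1L):1]
    a <- a_new
    err <- err * (1 - k^2)
    if (err <= 0) { err <- 0; break }
  }
  list(a = a, err = err)
}

# Cepstra from LPC coefficients by the standard recursion
# (prediction-coefficient convention).
.lpc_to_cepstra <- function(a, gain2, nceps) {
  p <- length(a)
  cc <- numeric(nceps)
  cc[1] <- log(max(gain2, LOG_FLOOR))
  if (nceps > 1L) {
    for (m in seq_len(nceps - 1L)) {
      cm <- if (m <= p) a[m] else 0
      ks <- seq_len(m - 1L)
      if (m > 1L) {
        valid <- ks[m - ks <= p & m - ks >= 1L]
        if (length(valid))
          cm <- cm + sum((valid / m) * cc[valid + 1L] * a[m - valid])
      }
      cc[m + 1L] <- cm
    }
  }
  cc
}

#' Linear-prediction cepstral coefficients
#'
#' Per frame: autocorrelation-method LPC via Levinson-Durbin, then the
#' standard LPC-to-cepstrum recursion with `c0 = ln(G^2)` (G^2 the
#' prediction-error energy). Zero-energy frames yield
#' `c = (ln eps, 0, ..., 0)`.
#'
#' @param signal A [voice_signal()].
#' @param params A [frame_params()].
#' @param order LPC order (default 16, covering 4-5 formants plus tilt).
#' @param nceps Number of cepstral coefficients.
#' @return `nceps` x `nframes` matrix.
#' @export
lpcc <- function(signal, params = frame_params(), order = 16, nceps = 20) {
  rate <- signal$rate
  win <- as.integer(round(params$win_len * rate))
  hop <- as.integer(round(params$hop_len * rate))
  if (order >= win) stop("LPC order must be below the frame length")
  if (length(signal$samples) < win)
    stop("signal shorter than one analysis window")
  x <- signal$samples
  y <- c(x[1] * (1 - params$preemph), x[-1] - params$preemph * x[-length(x)])
  frames <- .frame_matrix(y, win, hop) * .taper(params$window, win)
  out <- apply(frames, 2L, function(fr) {
    r <- vapply(0:order, function(k) {
      sum(fr[seq_len(win - k)] * fr[seq_len(win - k) + k])
    }, numeric(1))
    if (r[1] <= 0) return(c(log(LOG_FLOOR), numeric(nceps - 1L)))
    ld <- levinson_durbin(r, order)
    .lpc_to_cepstra(ld$a, ld$err, nceps)
  })
  matrix(out, nrow = nceps)
}

# ---- CQCC -------------------------------------------------------------------

.cqt_cache <- new.env(parent = emptyenv())

# Sparse frequency-domain constant-Q kernels (Brown-Puckette method).
# Kernel windows longer than `cap` samples are truncated, which matches
# the behaviour of zero-padding short signals.
.cqt_kernels <- function(rate, bins_per_octave, n_octaves, cap = 2^16) {
  key <- paste(rate, bins_per_octave, n_octaves, cap, sep = "_")
  if (!is.null(.cqt_cache[[key]])) return(.cqt_cache[[key]])
  fmax <- rate / 2
  fmin <- fmax / 2^n_octaves
  n_bins <- bins_per_octave * n_octaves
  fk <- fmin * 2^((seq_len(n_bins) - 1L) / bins_per_octave)
  Q <- 1 / (2^(1 / bins_per_octave) - 1)
  Nk <- pmin(as.integer(round(Q * rate / fk)), as.integer(cap))
  n_fft <- .next_pow2(max(Nk))

  ti <- list(); tj <- list(); tre <- list(); tim <- list()
  for (k in seq_len(n_bins)) {
    nk <- Nk[k]
    t <- seq_len(nk) - 1L
    w <- .taper("hamming", nk) / nk
    kern <- w * exp(2i * pi * fk[k] * (t - (nk - 1) / 2) / rate)
    # center the kernel so frame-centered FFTs align in phase
    buf <- complex(length.out = n_fft)
    start <- (n_fft - nk) %/% 2L
    buf[start + t + 1L] <- kern
    K <- stats::fft(buf)
    keep <- which(Mod(K) > 0.005 * max(Mod(K)))
    ti[[k]] <- rep.int(k, length(keep)); tj[[k]] <- keep
    tre[[k]] <- Re(K[keep]); tim[[k]] <- Im(K[keep])
  }
  i <- unlist(ti); j <- unlist(tj)
  kernels <- list(
    Kre = Matrix::sparseMatrix(i = i, j = j, x = unlist(tre),
                               dims = c(n_bins, n_fft)),
    Kim = Matrix::sparseMatrix(i = i, j = j, x = unlist(tim),
                               dims = c(n_bins, n_fft)),
    n_fft = n_fft, freqs = fk, n_bins = n_bins, rate = rate
  )
  .cqt_cache[[key]] <- kernels
  kernels
}

# Constant-Q power spectrogram: n_bins x nframes magnitudes^2, with frames
# centered every `hop` samples.
.cqt_power <- function(signal, bins_per_octave = 96, n_octaves = 9,
                       fps = 100) {
  ker <- .cqt_kernels(signal$rate, bins_per_octave, n_octaves)
  x <- signal$samples
  n <- length(x)
  hop <- max(1L, as.integer(round(signal$rate / fps)))
  centers <- seq(1L, n, by = hop)
  n_fft <- ker$n_fft
  half <- n_fft %/% 2L
  P <- matrix(0, ker$n_bins, length(centers))
  chunk <- 16L
  for (s in seq(1L, length(centers), by = chunk)) {
    cols <- s:min(s + chunk - 1L, length(centers))
    Fm <- matrix(0, n_fft, length(cols))
    for (ci in seq_along(cols)) {
      c0 <- centers[cols[ci]]
      lo <- c0 - half; hi <- c0 + half - 1L
      src <- max(1L, lo):min(n, hi)
      Fm[src - lo + 1L, ci] <- x[src]
    }
    Ff <- stats::mvfft(Fm)
    Fr <- Re(Ff); Fi <- Im(Ff)
    # C = conj(K) %*% F
    Cr <- as.matrix(ker$Kre %*% Fr + ker$Kim %*% Fi)
    Ci <- as.matrix(ker$Kre %*% Fi - ker$Kim %*% Fr)
    P[, cols] <- (Cr^2 + Ci^2) / n_fft^2
  }
  list(power = P, freqs = ker$freqs, nframes = length(centers))
}

#' Constant-Q cepstral coefficients
#'
#' Constant-Q transform (geometrically spaced bins, constant
#' centre-to-bandwidth ratio), log power with floor, uniform spline
#' resampling of the log spectrum along a linear frequency axis, orthonormal
#' DCT, first `nceps` coefficients.
#'
#' @param signal A [voice_signal()].
#' @param nceps Number of cepstral coefficients (default 20).
#' @param bins_per_octave Constant-Q resolution (default 96).
#' @param n_octaves Octaves below Nyquist analysed (default 9).
#' @param fps Frame rate of the transform in frames per second
#'   (default 100).
#' @return `nceps` x `nframes` matrix.
#' @export
cqcc <- function(signal, nceps = 20, bins_per_octave = 96, n_octaves = 9,
                 fps = 100) {
  cq <- .cqt_power(signal, bins_per_octave, n_octaves, fps)
  L <- log(pmax(cq$power, LOG_FLOOR))
  # uniform resampling of the log spectrum on a linear frequency axis
  f_lin <- seq(cq$freqs[1], cq$freqs[length(cq$freqs)],
               length.out = length(cq$freqs))
  Lu <- apply(L, 2L, function(col) {
    stats::spline(cq$freqs, col, xout = f_lin)$y
  })
  D <- .dct_matrix(length(f_lin))[seq_len(nceps), , drop = FALSE]
  D %*% Lu
}

# ---- dynamics and normalization --------------------------------------------

#' Regression delta features
#'
#' `d_t = sum_{n=1..N} n (c_{t+n} - c_{t-n}) / (2 sum n^2)` with edge frames
#' replicated; same shape as the input. Second-order dynamics are
#' `cc_delta(cc_delta(C))`.
#'
#' @param mat Cepstral matrix (coefficients x frames).
#' @param half_window Regression half-window N (default 2).
#' @return Matrix of the same shape.
#' @export
cc_delta <- function(mat, half_window = 2) {
  if (half_window < 1) stop("half_window must be >= 1")
  nf <- ncol(mat)
  denom <- 2 * sum(seq_len(half_window)^2)
  d <- matrix(0, nrow(mat), nf)
  for (n in seq_len(half_window)) {
    fwd <- pmin(seq_len(nf) + n, nf)
    bwd <- pmax(seq_len(nf) - n, 1L)
    d <- d + n * (mat[, fwd, drop = FALSE] - mat[, bwd, drop = FALSE])
  }
  d / denom
}

#' Cepstral mean-variance normalization
#'
#' Each coefficient trajectory (row) is centred by its mean across frames
#' and scaled by its population standard deviation; zero-variance rows map
#' to zeros. Idempotent.
#'
#' @param mat Cepstral matrix (coefficients x frames).
#' @return Normalized matrix of the same shape.
#' @export
cmvn <- function(mat) {
  mu <- rowMeans(mat)
  ctr <- mat - mu
  sdv <- sqrt(rowMeans(ctr^2))
  out <- ctr / pmax(sdv, LOG_FLOOR)
  out[sdv < 1e-12, ] <- 0
  out
}

#' Extract a cepstral set (static + dynamics) for one technique
#'
#' Dispatches to the appropriate extractor, computes first- and second-order
#' regression dynamics from the static matrix and applies CMVN to each of
#' the three matrices independently.
#'
#' @param signal A [voice_signal()].
#' @param technique One of `"CQCC"`, `"MFCC"`, `"iMFCC"`, `"LFCC"`,
#'   `"GFCC"`, `"BFCC"`, `"LPCC"`, `"NGCC"`.
#' @param nceps Number of cepstral coefficients (default 20).
#' @param params A [frame_params()] shared by the spectral techniques
#'   (CQCC framing is intrinsic to the constant-Q transform).
#' @param half_window Delta regression half-window (default 2).
#' @param n_filters Filterbank size (default 26).
#' @param lpc_order LPC order for LPCC (default 16).
#' @return An object of class `cepstral_set`: list with matrices `C`, `D1`,
#'   `D2` (each `nceps` x `nframes`) and the `technique` tag.
#' @export
extract_cc <- function(signal, technique, nceps = 20,
                       params = frame_params(), half_window = 2,
                       n_filters = 26, lpc_order = 16) {
  technique <- match.arg(technique, CC_TECHNIQUES)
  C <- switch(
    technique,
    CQCC = cqcc(signal, nceps = nceps),
    LPCC = lpcc(signal, params, order = lpc_order, nceps = nceps),
    {
      scale <- c(MFCC = "mel", iMFCC = "imel", LFCC = "linear",
                 GFCC = "gammatone", BFCC = "bark",
                 NGCC = "gammachirp")[[technique]]
      sp <- preprocess_frames(signal, params)
      bank <- build_filterbank(scale, n_filters = n_filters,
                               n_fft = sp$n_fft, rate = sp$rate)
      filterbank_cepstra(sp, bank, nceps = nceps)
    }
  )
  D1 <- cc_delta(C, half_window)
  D2 <- cc_delta(D1, half_window)
  structure(list(C = cmvn(C), D1 = cmvn(D1), D2 = cmvn(D2),
                 technique = technique,
                 nceps = nrow(C), nframes = ncol(C)),
            class = "cepstral_set")
}

#' @export
print.cepstral_set <- function(x, ...) {
  cat(sprintf("<cepstral_set %s> %d coefficients x %d frames (+ delta, delta-delta)\n",
              x$technique, x$nceps, x$nframes))
  invisible(x)
}
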