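# Noncepstral acoustic measures: F0 statistics, the jitter and shimmer
# perturbation families, harmonic-to-noise ratio, formant statistics and
# derived vocal-tract measures, assembled into a fixed-layout feature
# vector with training-corpus imputation for undefined measures.

#' Layout of the noncepstral feature vector
#'
#' The fixed, documented order of the 28 noncepstral coordinates produced
#' by [noncepstral_vector()].
#' @format Character vector of length 28.
#' @export
NONCEPSTRAL_LAYOUT <- c(
  "f0_mean", "f0_std", "hnr",
  "jitter_local", "jitter_local_abs", "jitter_rap",
  "shimmer_local_db", "shimmer_apq3", "shimmer_apq5", "shimmer_apq11",
  "shimmer_dda",
  "jitter_pca", "shimmer_pca",
  "fvtl",
  "f1_mean", "f2_mean", "f3_mean", "f4_mean",
  "f1_median", "f2_median", "f3_median", "f4_median",
  "formant_dispersion", "formant_mean", "formant_position",
  "delta_f", "vtl_delta_f", "mff"
)

.jitter_cols <- c("jitter_local", "jitter_local_abs", "jitter_rap")
.shimmer_cols <- c("shimmer_local_db", "shimmer_apq3", "shimmer_apq5",
                   "shimmer_apq11", "shimmer_dda")

# Normalized autocorrelation of one mean-removed frame via FFT. Uses the
# normalized cross-correlation form r(lag) = sum(x_t x_{t+lag}) /
# sqrt(E1 E2) with E1, E2 the energies of the two overlapping segments, so
# |r| <= 1 and a perfectly periodic frame scores ~1 at its pitch lag
# despite the finite window.
.frame_nacf <- function(fr) {
  fr <- fr - mean(fr)
  n <- length(fr)
  m <- .next_pow2(2L * n)
  sp <- stats::fft(c(fr, numeric(m - n)))
  num <- Re(stats::fft(Mod(sp)^2, inverse = TRUE))[seq_len(n)] / m
  cs <- cumsum(fr^2)
  tot <- cs[n]
  if (tot <= 0) return(numeric(n))
  lags <- seq_len(n) - 1L
  e_head <- cs[n - lags]                      # energy of x[1..n-lag]
  e_tail <- tot - c(0, cs[lags[-1L]])         # energy of x[lag+1..n]
  den <- sqrt(pmax(e_head * e_tail, 1e-300))
  r <- num / den
  r[1] <- 1
  pmin(pmax(r, -1), 1)
}

# Parabolic refinement of a discrete peak at index i of y; returns
# c(offset, height).
.parabolic <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(c(0, y[i]))
  a <- y[i - 1L]; b <- y[i]; c0 <- y[i + 1L]
  denom <- a - 2 * b + c0
  if (abs(denom) < 1e-12) return(c(0, b))
  d <- 0.5 * (a - c0) / denom
  c(d, b - 0.25 * (a - c0) * d)
}

#' Fundamental-frequency contour
#'
#' Framewise normalized autocorrelation; within each frame the lag of the
#' maximum inside `[1/fmax, 1/fmin]` is refined by parabolic interpolation,
#' and the frame is voiced iff the normalized peak reaches the voicing
#' threshold.
#'
#' @param signal A [voice_signal()].
#' @param fmin,fmax F0 search range in Hz (defaults 60-500).
#' @param win_len,hop_len Frame length and hop in seconds (40 ms / 10 ms;
#'   the window must span at least two periods of `fmin`).
#' @param threshold Voicing threshold on the normalized autocorrelation
#'   peak (default 0.45).
#' @return An object of class `f0_track`: list with `times` (frame centres,
#'   s), `f0` (Hz, `NA` where unvoiced) and `voiced` (logical).
#' @export
f0_contour <- function(signal, fmin = 60, fmax = 500, win_len = 0.04,
                       hop_len = 0.01, threshold = 0.45) {
  stopifnot(fmin < fmax, fmax <= signal$rate / 2)
  rate <- signal$rate
  win <- as.integer(round(win_len * rate))
  hop <- as.integer(round(hop_len * rate))
  x <- signal$samples
  if (length(x) < win)
    return(structure(list(times = numeric(0), f0 = numeric(0),
                          voiced = logical(0), rate = rate),
                     class = "f0_track"))
  frames <- .frame_matrix(x, win, hop)
  lag_min <- max(2L, as.integer(floor(rate / fmax)))
  lag_max <- min(win - 1L, as.integer(ceiling(rate / fmin)))
  nf <- ncol(frames)
  f0 <- rep(NA_real_, nf); voiced <- logical(nf)
  for (j in seq_len(nf)) {
    ac <- .frame_nacf(frames[, j])
    if (length(ac) < lag_max + 1L || all(ac == 0)) next
    seg <- ac[(lag_min + 1L):(lag_max + 1L)]
    # local maxima; among those near the global peak prefer the shortest
    # lag, which suppresses octave (subharmonic) errors
    m <- length(seg)
    is_peak <- c(FALSE, seg[2:(m - 1L)] > seg[1:(m - 2L)] &
                   seg[2:(m - 1L)] >= seg[3:m], FALSE)
    cand <- which(is_peak)
    if (length(cand) == 0L) cand <- which.max(seg)
    best <- max(seg[cand])
    i <- cand[seg[cand] >= 0.87 * best][1L]
    pk <- .parabolic(ac, lag_min + i)
    if (pk[2] >= threshold) {
      lag <- lag_min + i - 1L + pk[1]
      voiced[j] <- TRUE
      f0[j] <- rate / lag
    }
  }
  structure(list(times = (seq_len(nf) - 1L) * hop / rate + win / (2 * rate),
                 f0 = f0, voiced = voiced, rate = rate),
            class = "f0_track")
}

#' Glottal pulse marks
#'
#' Locates cycle peaks by walking one expected period at a time from the
#' strongest peak in the voiced region, searching within +/-25% of the
#' local period. Cycles whose period falls outside `[0.5, 2]` times the
#' median period are discarded (the longest consecutive valid run is kept).
#'
#' @param signal A [voice_signal()].
#' @param track An [f0_contour()] track (computed if missing).
#' @return An object of class `pulse_seq` (lists `times`, `periods`,
#'   `amplitudes`, with `length(amplitudes) == length(periods) + 1`), or
#'   `NULL` when fewer than 3 voiced frames are available.
#' @export
pulse_marks <- function(signal, track = NULL) {
  if (is.null(track)) track <- f0_contour(signal)
  if (sum(track$voiced) < 3L) return(NULL)
  rate <- signal$rate
  x <- signal$samples
  n <- length(x)

  # median-smoothed voiced f0 makes the expected period robust to
  # occasional octave errors in individual frames
  vi <- which(track$voiced)
  f0s <- if (length(vi) >= 5L) stats::runmed(track$f0[vi], 5L)
         else track$f0[vi]
  period_at <- function(t) {
    j <- which.min(abs(track$times[vi] - t))
    1 / f0s[j]
  }

  t_lo <- min(track$times[track$voiced]); t_hi <- max(track$times[track$voiced])
  s_lo <- max(1L, as.integer(floor(t_lo * rate)))
  s_hi <- min(n, as.integer(ceiling(t_hi * rate)))
  seed <- s_lo - 1L + which.max(abs(x[s_lo:s_hi]))

  walk <- function(start, dir) {
    out <- integer(0)
    cur <- start
    repeat {
      Tn <- period_at(cur / rate) * rate
      lo <- as.integer(round(cur + dir * 0.75 * Tn))
      hi <- as.integer(round(cur + dir * 1.25 * Tn))
      rng <- sort(c(lo, hi))
      if (rng[1] < 1L || rng[2] > n) break
      nxt <- rng[1] - 1L + which.max(abs(x[rng[1]:rng[2]]))
      out <- c(out, nxt)
      cur <- nxt
    }
    out
  }
  marks <- sort(unique(c(rev(walk(seed, -1)), seed, walk(seed, +1))))
  if (length(marks) < 4L) return(NULL)

  periods <- diff(marks) / rate
  med <- stats::median(periods)
  ok <- periods >= 0.5 * med & periods <= 2 * med
  # keep the longest consecutive run of valid cycles
  r <- rle(ok)
  if (!any(r$values)) return(NULL)
  best <- which(r$values)[which.max(r$lengths[r$values])]
  ends <- cumsum(r$lengths)
  i1 <- if (best == 1L) 1L else ends[best - 1L] + 1L
  i2 <- ends[best]
  keep <- marks[i1:(i2 + 1L)]
  structure(list(times = keep / rate,
                 periods = diff(keep) / rate,
                 amplitudes = abs(x[keep])),
            class = "pulse_seq")
}

#' Jitter measures
#'
#' Cycle-to-cycle period perturbation: local jitter
#' `mean|T[i+1]-T[i]| / mean(T) * 100` (%), local absolute jitter
#' `mean|T[i+1]-T[i]|` (s), and RAP jitter, the mean absolute deviation of
#' each interior period from its centred three-period average, relative to
#' the mean period (%).
#'
#' @param p A `pulse_seq` from [pulse_marks()] (or `NULL`).
#' @return Named list `jitter_local`, `jitter_local_abs`, `jitter_rap`
#'   (all `NA` when fewer than 3 periods are available).
#' @export
jitter_measures <- function(p) {
  nas <- list(jitter_local = NA_real_, jitter_local_abs = NA_real_,
              jitter_rap = NA_real_)
  if (is.null(p) || length(p$periods) < 3L) return(nas)
  Ti <- p$periods
  mT <- mean(Ti)
  dabs <- mean(abs(diff(Ti)))
  ii <- 2:(length(Ti) - 1L)
  rap <- mean(abs(Ti[ii] - (Ti[ii - 1L] + Ti[ii] + Ti[ii + 1L]) / 3)) / mT * 100
  list(jitter_local = dabs / mT * 100, jitter_local_abs = dabs,
       jitter_rap = rap)
}

#' Shimmer measures
#'
#' Cycle-to-cycle amplitude perturbation: local shimmer
#' `mean|20 log10(A[i+1]/A[i])|` (dB); APQ-K shimmer for K in {3, 5, 11},
#' the mean over centred length-K windows of `|A[i] - window mean|`
#' relative to the overall mean amplitude (%); and DDA = 3 * APQ3.
#' Sequences shorter than K leave the corresponding APQ undefined.
#'
#' @param p A `pulse_seq` from [pulse_marks()] (or `NULL`).
#' @return Named list `shimmer_local_db`, `shimmer_apq3`, `shimmer_apq5`,
#'   `shimmer_apq11`, `shimmer_dda` (`NA` where undefined).
#' @export
shimmer_measures <- function(p) {
  nas <- list(shimmer_local_db = NA_real_, shimmer_apq3 = NA_real_,
              shimmer_apq5 = NA_real_, shimmer_apq11 = NA_real_,
              shimmer_dda = NA_real_)
  if (is.null(p) || length(p$amplitudes) < 2L) return(nas)
  A <- p$amplitudes
  if (any(A <= 0)) return(nas)
  local_db <- mean(abs(20 * log10(A[-1] / A[-length(A)])))
  apq <- function(K) {
    if (length(A) < K) return(NA_real_)
    h <- (K - 1L) %/% 2L
    ii <- (h + 1L):(length(A) - h)
    devs <- vapply(ii, function(i) abs(A[i] - mean(A[(i - h):(i + h)])),
                   numeric(1))
    mean(devs) / mean(A) * 100
  }
  a3 <- apq(3L)
  list(shimmer_local_db = local_db, shimmer_apq3 = a3,
       shimmer_apq5 = apq(5L), shimmer_apq11 = apq(11L),
       shimmer_dda = if (is.na(a3)) NA_real_ else 3 * a3)
}

#' Harmonic-to-noise ratio
#'
#' Per voiced frame the normalized autocorrelation at the pitch lag `r'`
#' gives a frame HNR of `10 log10(r'/(1-r'))`, clamped to `[-20, 60]` dB;
#' the utterance value is the mean over voiced frames.
#'
#' @param signal A [voice_signal()].
#' @param track An [f0_contour()] track (computed if missing).
#' @return HNR in dB, or `NA` when no frame is voiced.
#' @export
hnr <- function(signal, track = NULL) {
  if (is.null(track)) track <- f0_contour(signal)
  if (!any(track$voiced)) return(NA_real_)
  rate <- signal$rate
  win <- as.integer(round(0.04 * rate))
  hop <- as.integer(round(0.01 * rate))
  frames <- .frame_matrix(signal$samples, win, hop)
  vals <- numeric(0)
  for (j in which(track$voiced)) {
    if (j > ncol(frames)) next
    ac <- .frame_nacf(frames[, j])
    lag <- rate / track$f0[j]
    lo <- max(2L, as.integer(floor(lag * 0.9)))
    hi <- min(length(ac) - 1L, as.integer(ceiling(lag * 1.1)))
    if (hi <= lo) next
    i <- lo - 1L + which.max(ac[(lo + 1L):(hi + 1L)])
    rp <- .parabolic(ac, i + 1L)[2]
    rp <- min(max(rp, 1e-6), 1 - 1e-6)
    vals <- c(vals, min(max(10 * log10(rp / (1 - rp)), -20), 60))
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Formant frequency statistics
#'
#' Resamples to 10 kHz, applies pre-emphasis and framewise autocorrelation
#' LPC (order 16, 25 ms Gaussian-tapered frames, 10 ms hop), converts LPC
#' polynomial roots above the real axis to candidate (frequency, bandwidth)
#' pairs, keeps frequencies in `[90, 4800]` Hz with bandwidth below 400 Hz,
#' and assigns the lowest four per frame as F1..F4. Means and medians are
#' reported over frames with four candidates; fewer than 5 such frames
#' leaves the measures undefined.
#'
#' @param signal A [voice_signal()].
#' @param order LPC order (default 16).
#' @return List with `means` and `medians` (named F1..F4, Hz) and
#'   `n_frames`, or `NULL` when undefined.
#' @export
formant_tracks <- function(signal, order = 16) {
  s <- resample_signal(signal, 10000)
  rate <- s$rate
  x <- s$samples
  y <- c(x[1] * 0.03, x[-1] - 0.97 * x[-length(x)])
  win <- as.integer(round(0.025 * rate))
  hop <- as.integer(round(0.010 * rate))
  if (length(y) < win) return(NULL)
  t0 <- (seq_len(win) - (win + 1) / 2) / win
  gauss <- exp(-0.5 * (6 * t0)^2)  # Gaussian taper, ~3 sigma at the edges
  frames <- .frame_matrix(y, win, hop) * gauss
  cand <- matrix(NA_real_, 4L, ncol(frames))
  for (j in seq_len(ncol(frames))) {
    fr <- frames[, j]
    r <- vapply(0:order, function(k) {
      sum(fr[seq_len(win - k)] * fr[seq_len(win - k) + k])
    }, numeric(1))
    if (r[1] <= 0) next
    ld <- levinson_durbin(r, order)
    roots <- polyroot(c(1, -ld$a))      # roots in z^-1
    z <- 1 / roots                       # poles
    ang <- Arg(z)
    keep <- ang > 0
    fr_hz <- ang[keep] * rate / (2 * pi)
    bw <- -rate / pi * log(pmin(Mod(z[keep]), 1 - 1e-12))
    sel <- fr_hz >= 90 & fr_hz <= 4800 & bw < 400
    fs <- sort(fr_hz[sel])
    if (length(fs) >= 1L) cand[seq_len(min(4L, length(fs))), j] <- fs[seq_len(min(4L, length(fs)))]
  }
  # per-formant statistics over the frames where that slot is filled;
  # a slot needs at least 5 frames to be reported
  n_per <- rowSums(!is.na(cand))
  if (n_per[1] < 5L) return(NULL)
  means <- medians <- rep(NA_real_, 4L)
  for (k in 1:4) {
    if (n_per[k] >= 5L) {
      means[k] <- mean(cand[k, ], na.rm = TRUE)
      medians[k] <- stats::median(cand[k, ], na.rm = TRUE)
    }
  }
  names(means) <- names(medians) <- paste0("F", 1:4)
  list(means = means, medians = medians, n_frames = as.integer(n_per[1]))
}

#' Vocal-tract measures derived from formant medians
#'
#' Dispersion `(F4-F1)/3`; arithmetic mean of the medians; minimum formant
#' spacing `delta_f` as the least-squares slope of `F_i` against
#' `(2i-1)/2`; two vocal-tract length estimates
#' `vtl_delta_f = c/(2 delta_f)` and `fvtl = c/(2 dispersion)` (cm); mean
#' formant frequency `mff = (F1 F2 F3 F4)^(1/4)`; and the standardized mean
#' formant position, z-scored against training-corpus statistics when
#' available (0 otherwise).
#'
#' @param medians Positive increasing numeric vector F1..F4 (Hz).
#' @param c_sound Speed of sound in air, m/s (default 350).
#' @param position_stats Optional list with `mean` and `sd` vectors (per
#'   formant) from the training corpus.
#' @return Named list `formant_dispersion`, `formant_mean`,
#'   `formant_position`, `delta_f`, `vtl_delta_f`, `fvtl`, `mff`.
#' @export
formant_derived <- function(medians, c_sound = 350, position_stats = NULL) {
  if (length(medians) != 4L || any(diff(medians) <= 0) || any(medians <= 0))
    stop("medians must be four positive increasing frequencies")
  F1 <- medians[1]; F4 <- medians[4]
  dispersion <- (F4 - F1) / 3
  xs <- (2 * (1:4) - 1) / 2
  slope <- sum((xs - mean(xs)) * (medians - mean(medians))) /
    sum((xs - mean(xs))^2)
  vtl_df <- if (slope > 0) c_sound / (2 * slope) * 100 else NA_real_   # cm
  fvtl <- if (dispersion > 0) c_sound / (2 * dispersion) * 100 else NA_real_
  pos <- if (is.null(position_stats)) 0 else {
    sdv <- pmax(position_stats$sd, 1e-12)
    mean((medians - position_stats$mean) / sdv)
  }
  list(formant_dispersion = dispersion, formant_mean = mean(medians),
       formant_position = pos, delta_f = slope, vtl_delta_f = vtl_df,
       fvtl = fvtl, mff = prod(medians)^(1 / 4))
}

#' Raw acoustic measures of one signal
#'
#' Computes every corpus-independent noncepstral measure (F0 statistics,
#' HNR, the jitter and shimmer families, formant statistics and derived
#' vocal-tract measures), leaving measures that are undefined for the
#' signal as `NA`. Corpus-dependent coordinates (`jitter_pca`,
#' `shimmer_pca`, `formant_position`) and imputation are handled by
#' [noncepstral_vector()] with fitted [fit_acoustic_stats()] statistics.
#'
#' @param signal A [voice_signal()].
#' @return Named numeric vector over `NONCEPSTRAL_LAYOUT` minus the
#'   corpus-dependent entries (which are returned as `NA` placeholders).
#' @export
acoustic_measures <- function(signal) {
  out <- stats::setNames(rep(NA_real_, length(NONCEPSTRAL_LAYOUT)),
                         NONCEPSTRAL_LAYOUT)
  track <- f0_contour(signal)
  if (any(track$voiced)) {
    f0v <- track$f0[track$voiced]
    out["f0_mean"] <- mean(f0v)
    out["f0_std"] <- stats::sd(f0v)
    if (sum(track$voiced) == 1L) out["f0_std"] <- 0
    out["hnr"] <- hnr(signal, track)
  }
  p <- pulse_marks(signal, track)
  jm <- jitter_measures(p)
  sm <- shimmer_measures(p)
  out[names(jm)] <- unlist(jm)
  out[names(sm)] <- unlist(sm)
  ft <- formant_tracks(signal)
  if (!is.null(ft)) {
    out[paste0("f", 1:4, "_mean")] <- ft$means
    out[paste0("f", 1:4, "_median")] <- ft$medians
    if (!any(is.na(ft$medians)) && all(diff(ft$medians) > 0)) {
      fd <- formant_derived(ft$medians)
      out["formant_dispersion"] <- fd$formant_dispersion
      out["formant_mean"] <- fd$formant_mean
      out["delta_f"] <- fd$delta_f
      out["vtl_delta_f"] <- fd$vtl_delta_f
      out["fvtl"] <- fd$fvtl
      out["mff"] <- fd$mff
    }
  }
  out
}

# First principal axis of a centred block (columns = features); sign fixed
# so the largest-magnitude loading is positive.
.pca_axis <- function(X) {
  mu <- colMeans(X)
  ctr <- sweep(X, 2L, mu)
  v <- svd(ctr, nu = 0, nv = 1L)$v[, 1L]
  if (v[which.max(abs(v))] < 0) v <- -v
  list(mean = mu, axis = v)
}

#' Fit training-corpus statistics for the noncepstral vector
#'
#' Fits, on training data only: per-measure imputation medians,
#' one-dimensional principal axes for the jitter (3-dim) and shimmer
#' (5-dim) blocks, and per-formant mean/sd for the standardized formant
#' position.
#'
#' @param measures Matrix (samples x measures) of [acoustic_measures()]
#'   outputs.
#' @return An object of class `acoustic_stats`.
#' @export
fit_acoustic_stats <- function(measures) {
  measures <- as.matrix(measures)
  med <- apply(measures, 2L, function(col) {
    m <- stats::median(col, na.rm = TRUE)
    if (is.finite(m)) m else 0
  })
  fit_block <- function(cols) {
    X <- measures[, cols, drop = FALSE]
    ok <- stats::complete.cases(X)
    if (sum(ok) >= 2L) .pca_axis(X[ok, , drop = FALSE]) else NULL
  }
  fcols <- paste0("f", 1:4, "_median")
  Fm <- measures[, fcols, drop = FALSE]
  okf <- stats::complete.cases(Fm)
  pos <- if (sum(okf) >= 2L)
    list(mean = colMeans(Fm[okf, , drop = FALSE]),
         sd = apply(Fm[okf, , drop = FALSE], 2L, stats::sd)) else NULL
  structure(list(medians = med,
                 jitter_pca = fit_block(.jitter_cols),
                 shimmer_pca = fit_block(.shimmer_cols),
                 formant_position = pos),
            class = "acoustic_stats")
}

# Assemble the final 28-coordinate vector from raw measures + fitted stats.
.assemble_noncepstral <- function(raw, stats = NULL) {
  out <- raw[NONCEPSTRAL_LAYOUT]
  names(out) <- NONCEPSTRAL_LAYOUT
  score <- function(ax, cols) {
    if (is.null(ax)) return(0)
    v <- raw[cols]
    if (any(is.na(v))) return(NA_real_)
    sum((v - ax$mean) * ax$axis)
  }
  if (!is.null(stats)) {
    out["jitter_pca"] <- score(stats$jitter_pca, .jitter_cols)
    out["shimmer_pca"] <- score(stats$shimmer_pca, .shimmer_cols)
    ps <- stats$formant_position
    fmed <- raw[paste0("f", 1:4, "_median")]
    out["formant_position"] <- if (is.null(ps) || any(is.na(fmed))) NA_real_
      else mean((fmed - ps$mean) / pmax(ps$sd, 1e-12))
    na <- is.na(out)
    out[na] <- stats$medians[NONCEPSTRAL_LAYOUT][na]
    out[is.na(out)] <- 0
  } else {
    out[c("jitter_pca", "shimmer_pca", "formant_position")] <- 0
    out[is.na(out)] <- 0
  }
  out
}

#' Noncepstral feature vector
#'
#' Assembles all noncepstral measures in the fixed 28-coordinate layout
#' (`NONCEPSTRAL_LAYOUT`). The `jitter_pca` / `shimmer_pca` coordinates are
#' scores on one-dimensional principal axes fitted on the training corpus;
#' undefined measures are imputed with the training-corpus median (0 when
#' no statistics are supplied), so downstream fusion never sees missing
#' values.
#'
#' @param signal A [voice_signal()], or a named raw-measure vector from
#'   [acoustic_measures()].
#' @param stats Optional fitted [fit_acoustic_stats()] statistics.
#' @return Named finite numeric vector of length 28.
#' @export
noncepstral_vector <- function(signal, stats = NULL) {
  raw <- if (inherits(signal, "voice_signal")) acoustic_measures(signal)
         else signal
  .assemble_noncepstral(raw, stats)
}
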