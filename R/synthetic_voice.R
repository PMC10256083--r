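# Source-filter synthesizer of sustained vowels with ground-truth F0,
# jitter, shimmer, HNR and formants. Provides two-class (healthy/dysphonic)
# corpora so the detection framework can be developed and validated without
# access-restricted clinical databases.

# Classic phonetic reference formant frequencies (Hz) and bandwidths.
.vowel_formants <- list(
  a = c(730, 1090, 2440, 3400),
  i = c(270, 2290, 3010, 3700),
  u = c(300,  870, 2240, 3400)
)
.formant_bandwidths <- c(60, 100, 120, 150)

# Pitch regime multipliers applied to the base f0.
.pitch_factors <- c(high = 1.25, low = 0.8, normal = 1.0,
                    "low-high-low" = 1.0)

#' Specification of a synthetic sustained vowel
#'
#' Collects the ground-truth parameters of one synthetic utterance: the
#' fundamental frequency, the targeted cycle-to-cycle perturbations (local
#' jitter in percent, local shimmer in dB), the harmonic-to-noise ratio in
#' dB (`Inf` = no additive noise), four formant resonances, duration, rate
#' and the vowel/pitch regime labels.
#'
#' @param vowel One of `"a"`, `"i"`, `"u"` (selects formant presets).
#' @param pitch One of `"normal"`, `"high"`, `"low"`, `"low-high-low"`.
#'   The first three scale the base f0 by 1.0, 1.25 and 0.8; the last keeps
#'   the base f0 but ramps it up 20% mid-utterance and back down.
#' @param f0 Base fundamental frequency in Hz (before the pitch factor).
#' @param jitter_pct Target local jitter in percent (>= 0).
#' @param shimmer_db Target local shimmer in dB (>= 0).
#' @param hnr_db Target harmonic-to-noise ratio in dB; `Inf` for noiseless.
#' @param formants Optional 4x2 matrix of (frequency, bandwidth) pairs in Hz
#'   overriding the vowel preset; frequencies must be strictly increasing.
#' @param duration Utterance duration in seconds.
#' @param rate Sampling rate in Hz.
#' @return An object of class `vowel_spec`.
#' @export
vowel_spec <- function(vowel = "a", pitch = "normal", f0 = 120,
                       jitter_pct = 0.3, shimmer_db = 0.2, hnr_db = 30,
                       formants = NULL, duration = 1, rate = 50000) {
  vowel <- match.arg(vowel, c("a", "i", "u"))
  pitch <- match.arg(pitch, names(.pitch_factors))
  f0_eff <- f0 * .pitch_factors[[pitch]]
  if (is.null(formants))
    formants <- cbind(.vowel_formants[[vowel]], .formant_bandwidths)
  formants <- as.matrix(formants)
  if (!(f0_eff > 0 && f0_eff < rate / 4)) stop("need 0 < f0 < rate/4")
  if (jitter_pct < 0 || shimmer_db < 0) stop("perturbations must be >= 0")
  if (any(diff(formants[, 1]) <= 0) || any(formants[, 1] >= rate / 2))
    stop("formant frequencies must be strictly increasing and < rate/2")
  if (duration <= 0) stop("duration must be positive")
  structure(
    list(vowel = vowel, pitch = pitch, f0 = f0_eff,
         jitter_pct = jitter_pct, shimmer_db = shimmer_db, hnr_db = hnr_db,
         formants = formants, duration = duration, rate = rate),
    class = "vowel_spec"
  )
}

# Rosenberg-style glottal pulse sampled over one cycle of `n` samples:
# smooth rise over the opening phase, faster cosine fall, closed phase zero.
.rosenberg_pulse <- function(n, open_quotient = 0.6, rise_fraction = 0.67) {
  t <- seq_len(n) - 1L
  tp <- max(1, open_quotient * rise_fraction * n)   # end of rising phase
  tn <- max(1, open_quotient * (1 - rise_fraction) * n)  # falling phase
  g <- numeric(n)
  rise <- t <= tp
  g[rise] <- 0.5 * (1 - cos(pi * t[rise] / tp))
  fall <- t > tp & t <= tp + tn
  g[fall] <- cos(pi * (t[fall] - tp) / (2 * tn))
  g
}

# Cascade of second-order resonators at the given (frequency, bandwidth)
# pairs, applied with stats::filter in recursive form.
.formant_filter <- function(x, formants, rate) {
  for (k in seq_len(nrow(formants))) {
    f <- formants[k, 1]; b <- formants[k, 2]
    r <- exp(-pi * b / rate)
    theta <- 2 * pi * f / rate
    a1 <- 2 * r * cos(theta); a2 <- -r^2
    gain <- 1 - a1 - a2  # unit gain at DC keeps magnitudes bounded
    x <- as.numeric(stats::filter(gain * x, c(a1, a2), method = "recursive"))
  }
  x
}

#' Synthesize a sustained vowel
#'
#' Source-filter synthesis: a train of Rosenberg-style glottal pulses whose
#' cycle periods and peak amplitudes are perturbed by independent Gaussian
#' deviates, rescaled so the realized local jitter and local shimmer of the
#' *generated* cycle sequence hit the targets exactly; the train is filtered
#' through cascaded second-order resonators at the four formants; white
#' noise is added with gain set so that
#' `10*log10(harmonic_energy/noise_energy) = hnr_db`. The output is
#' peak-normalized to 0.9 and is fully determined by `(spec, seed)`.
#'
#' The ground-truth cycle sequence (pulse times, periods, amplitudes) is
#' attached as `attr(x, "pulses")` for validation against independent
#' analyzers.
#'
#' @param spec A [vowel_spec()].
#' @param seed Integer seed controlling all randomness.
#' @return A [voice_signal()] with the ground-truth pulse table attached.
#' @export
synthesize_vowel <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "vowel_spec"))
  with_seed(seed, {
    rate <- spec$rate
    n <- as.integer(round(spec$duration * rate))

    f0_at <- function(t) {
      if (spec$pitch == "low-high-low") {
        spec$f0 * (1 + 0.2 * sin(pi * t / spec$duration)^2)
      } else rep(spec$f0, length(t))
    }

    # draw enough cycle perturbations, then rescale to hit targets exactly
    n_max <- as.integer(ceiling(spec$duration * spec$f0 * 1.2 * 2)) + 10L
    eps <- stats::rnorm(n_max)
    eta <- stats::rnorm(n_max)
    if (spec$jitter_pct > 0) {
      eps <- eps - mean(eps)
      md <- mean(abs(diff(eps)))
      eps <- if (md > 0) eps * (spec$jitter_pct / 100) / md else eps * 0
    } else eps <- eps * 0
    if (spec$shimmer_db > 0) {
      # log-amplitudes: |20*log10(A[i+1]/A[i])| is linear in eta
      md <- mean(abs(diff(eta)))
      eta <- if (md > 0) eta * (spec$shimmer_db * log(10) / 20) / md else eta * 0
    } else eta <- eta * 0
    amps <- exp(eta)

    harmonic <- numeric(n + as.integer(rate / spec$f0) + 2L)
    t <- 0; i <- 1L
    starts <- numeric(0); periods <- numeric(0); used_amps <- numeric(0)
    while (t < spec$duration && i <= n_max) {
      T0i <- 1 / f0_at(t)
      Ti <- T0i * (1 + eps[i])
      if (Ti <= 0) Ti <- T0i
      s0 <- as.integer(round(t * rate)) + 1L
      # pulse shape follows the *nominal* local period, so the period
      # perturbation moves the closed phase only and waveform landmarks
      # track the cycle starts exactly
      np <- max(2L, as.integer(round(T0i * rate)))
      pulse <- .rosenberg_pulse(np) * amps[i]
      harmonic[s0:(s0 + np - 1L)] <- harmonic[s0:(s0 + np - 1L)] + pulse
      starts <- c(starts, t); periods <- c(periods, Ti)
      used_amps <- c(used_amps, amps[i])
      t <- t + Ti; i <- i + 1L
    }
    # the four controllable formants plus a fixed higher tract resonance
    # (F5 ~ 4.5 kHz), which real vocal tracts exhibit; without it the
    # 3.5-5 kHz band is unrealistically flat
    resonances <- spec$formants
    if (4500 > resonances[nrow(resonances), 1] && 4500 < rate / 2)
      resonances <- rbind(resonances, c(4500, 300))
    harmonic <- .formant_filter(harmonic[seq_len(n)], resonances, rate)
    # lip-radiation high-pass (first difference) flattens the source tilt
    harmonic <- c(harmonic[1], diff(harmonic))

    x <- harmonic
    if (is.finite(spec$hnr_db)) {
      noise <- stats::rnorm(n)
      target_ratio <- 10^(spec$hnr_db / 10)
      scale <- sqrt(sum(harmonic^2) / (target_ratio * sum(noise^2)))
      x <- harmonic + scale * noise
    }
    peak <- max(abs(x))
    if (peak > 0) x <- x * (0.9 / peak)

    sig <- voice_signal(x, rate, id = sprintf("synth_seed%d", seed))
    attr(sig, "pulses") <- data.frame(
      time = starts, period = periods, amplitude = used_amps
    )
    sig
  })
}

#' Specification of a synthetic two-class corpus
#'
#' Defines the number of healthy and dysphonic samples and the uniform
#' ranges from which per-sample ground-truth parameters are drawn. The
#' default ranges encode the intended class contrast: healthy voices with
#' low perturbation and high HNR (jitter 0.2-0.5%, shimmer 0.1-0.3 dB,
#' HNR 25-35 dB), dysphonic voices with elevated perturbation and low HNR
#' (jitter 2-5%, shimmer 1-2 dB, HNR 5-15 dB).
#'
#' @param n_healthy,n_dysphonic Sample counts per class.
#' @param healthy,dysphonic Named lists of `c(low, high)` ranges for
#'   `f0`, `jitter_pct`, `shimmer_db`, `hnr_db`.
#' @param vowels,pitches Candidate vowel and pitch regimes, sampled
#'   uniformly per signal.
#' @param duration,rate Utterance duration (s) and sampling rate (Hz).
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   corpus.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_healthy = 100, n_dysphonic = 100,
                        healthy = list(f0 = c(100, 220),
                                       jitter_pct = c(0.2, 0.5),
                                       shimmer_db = c(0.1, 0.3),
                                       hnr_db = c(25, 35)),
                        dysphonic = list(f0 = c(100, 220),
                                         jitter_pct = c(2, 5),
                                         shimmer_db = c(1, 2),
                                         hnr_db = c(5, 15)),
                        vowels = c("a", "i", "u"),
                        pitches = c("normal", "high", "low"),
                        duration = 1, rate = 50000, seed = 0L) {
  stopifnot(n_healthy >= 0, n_dysphonic >= 0)
  structure(
    list(n_healthy = n_healthy, n_dysphonic = n_dysphonic,
         healthy = healthy, dysphonic = dysphonic,
         vowels = vowels, pitches = pitches,
         duration = duration, rate = rate, seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' Generate a labeled synthetic corpus
#'
#' Draws per-sample ground-truth parameters uniformly from the class ranges
#' of a [corpus_spec()] and synthesizes each signal with [synthesize_vowel()].
#' The drawn parameters are stored in the corpus metadata.
#'
#' @param spec A [corpus_spec()].
#' @return A [labeled_corpus()] with `n_healthy + n_dysphonic` signals.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  n_tot <- spec$n_healthy + spec$n_dysphonic
  if (n_tot < 1L) stop("empty corpus requested")
  labels <- c(rep("healthy", spec$n_healthy),
              rep("dysphonic", spec$n_dysphonic))
  draw <- function(range) stats::runif(1, range[1], range[2])

  rows <- vector("list", n_tot)
  signals <- vector("list", n_tot)
  with_seed(spec$seed, {
    for (i in seq_len(n_tot)) {
      rng <- if (labels[i] == "healthy") spec$healthy else spec$dysphonic
      vowel <- sample(spec$vowels, 1)
      pitch <- sample(spec$pitches, 1)
      pars <- list(f0 = draw(rng$f0), jitter_pct = draw(rng$jitter_pct),
                   shimmer_db = draw(rng$shimmer_db), hnr_db = draw(rng$hnr_db))
      sseed <- child_seed(spec$seed, i)
      vs <- vowel_spec(vowel = vowel, pitch = pitch, f0 = pars$f0,
                       jitter_pct = pars$jitter_pct,
                       shimmer_db = pars$shimmer_db, hnr_db = pars$hnr_db,
                       duration = spec$duration, rate = spec$rate)
      sig <- synthesize_vowel(vs, seed = sseed)
      sig$id <- sprintf("%s_%03d", substr(labels[i], 1, 1), i)
      sig$label <- labels[i]
      signals[[i]] <- sig
      rows[[i]] <- data.frame(
        id = sig$id, label = labels[i], vowel = vowel, pitch = pitch,
        f0 = vs$f0, jitter_pct = pars$jitter_pct,
        shimmer_db = pars$shimmer_db, hnr_db = pars$hnr_db,
        duration = spec$duration, rate = spec$rate, seed = sseed
      )
    }
  })
  labeled_corpus(signals, do.call(rbind, rows))
}
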