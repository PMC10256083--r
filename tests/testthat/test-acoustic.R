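test_that("f0 contour tracks a pulse train, rejects noise and silence", {
  # 100 Hz pulse train
  n <- 50000; x <- numeric(n); x[seq(1, n, by = 500)] <- 1
  x <- as.numeric(stats::filter(x, 0.6, method = "recursive"))
  tr <- f0_contour(voice_signal(x, 50000))
  expect_gt(mean(tr$voiced), 0.8)
  expect_true(all(abs(tr$f0[tr$voiced] - 100) < 1))

  # white noise: few voiced frames (statistical, over seeds)
  voiced_frac <- vapply(1:5, function(sd) {
    set.seed(sd)
    trn <- f0_contour(voice_signal(rnorm(16000), 16000))
    mean(trn$voiced)
  }, numeric(1))
  expect_lt(mean(voiced_frac), 0.2)

  # silence: all unvoiced
  trs <- f0_contour(voice_signal(numeric(16000), 16000))
  expect_false(any(trs$voiced))
})

test_that("pulse marks recover periodic cycles and are sign-invariant", {
  sig <- ref_vowel(seed = 2, f0 = 100, jitter = 0, shimmer = 0,
                   hnr_db = Inf)
  pm <- pulse_marks(sig)
  # perfectly periodic: all periods equal 10 ms within one sample
  expect_lt(max(abs(pm$periods - 0.01)), 1.5 / sig$rate)
  # pulse count within +/-2 of the generator's cycle count
  expect_lt(abs(length(pm$times) - nrow(attr(sig, "pulses"))), 3)
  expect_equal(length(pm$amplitudes), length(pm$periods) + 1)

  flipped <- voice_signal(-sig$samples, sig$rate)
  pm2 <- pulse_marks(flipped)
  expect_equal(pm2$periods, pm$periods)
})

test_that("jitter formulas reproduce hand-computed values", {
  expect_equal(jitter_measures(make_pulse_seq(rep(0.01, 10))),
               list(jitter_local = 0, jitter_local_abs = 0,
                    jitter_rap = 0))
  p <- make_pulse_seq(c(10, 11, 10, 11) / 1000)
  j <- jitter_measures(p)
  expect_equal(j$jitter_local, (1 / 10.5) * 100, tolerance = 1e-10)
  expect_equal(j$jitter_local_abs, 0.001, tolerance = 1e-12)
  # rap from the stated formula: interior deviations |11-31/3|, |10-32/3|
  expect_equal(j$jitter_rap, mean(c(abs(11 - 31 / 3), abs(10 - 32 / 3))) /
                 10.5 * 100, tolerance = 1e-10)
  expect_true(all(is.na(unlist(jitter_measures(make_pulse_seq(c(0.01,
                                                                0.011)))))))
})

test_that("shimmer formulas reproduce hand-computed values", {
  s0 <- shimmer_measures(make_pulse_seq(rep(0.01, 11), rep(2, 12)))
  expect_equal(s0$shimmer_local_db, 0)
  expect_equal(s0$shimmer_apq11, 0)

  p <- make_pulse_seq(rep(0.01, 3), c(1.0, 1.1, 1.0, 1.1))
  s <- shimmer_measures(p)
  expect_equal(s$shimmer_local_db, abs(20 * log10(1.1)), tolerance = 1e-10)
  # apq3 from the stated formula: centred windows around i = 2, 3
  apq3_oracle <- mean(c(abs(1.1 - 3.1 / 3), abs(1.0 - 3.2 / 3))) /
    mean(c(1.0, 1.1, 1.0, 1.1)) * 100
  expect_equal(s$shimmer_apq3, apq3_oracle, tolerance = 1e-10)
  expect_equal(s$shimmer_dda, 3 * s$shimmer_apq3)
  expect_true(is.na(s$shimmer_apq11))  # fewer than 11 amplitudes
  expect_true(is.na(shimmer_measures(
    make_pulse_seq(rep(0.01, 3), c(1, 0, 1, 1)))$shimmer_local_db))
})

test_that("time dilation leaves relative jitter unchanged, scales absolute", {
  set.seed(20)
  per <- 0.01 * (1 + rnorm(40, 0, 0.02))
  j1 <- jitter_measures(make_pulse_seq(per))
  j2 <- jitter_measures(make_pulse_seq(2 * per))
  expect_equal(j2$jitter_local, j1$jitter_local)
  expect_equal(j2$jitter_rap, j1$jitter_rap)
  expect_equal(j2$jitter_local_abs, 2 * j1$jitter_local_abs)
})

test_that("HNR is high for clean periodic vowels and ordered in the target", {
  # f0 = 100 Hz at 50 kHz: the period is an integer number of samples, so
  # the noiseless pulse train is exactly periodic
  clean <- ref_vowel(seed = 3, f0 = 100, jitter = 0, shimmer = 0,
                     hnr_db = Inf)
  expect_gt(hnr(clean), 40)
  ests <- vapply(c(30, 20, 10), function(h)
    hnr(ref_vowel(seed = 4, hnr_db = h)), numeric(1))
  expect_true(all(diff(ests) < 0))  # 30 > 20 > 10 strictly ordered
  expect_true(is.na(hnr(voice_signal(numeric(16000), 16000))))
})

test_that("formant machinery recovers a single 1000 Hz resonator", {
  n <- 50000; x <- numeric(n); x[seq(1, n, by = 500)] <- 1
  y <- voicedysph:::.formant_filter(x, matrix(c(1000, 80), 1), 50000)
  ft <- formant_tracks(voice_signal(y / max(abs(y)), 50000))
  expect_equal(unname(ft$medians[1]), 1000, tolerance = 30 / 1000)
})

test_that("LPC root frequencies agree with a polynomial-evaluation oracle", {
  # poles placed by construction: resonator at known frequency/bandwidth
  rate <- 10000; f <- 1200; b <- 150
  r <- exp(-pi * b / rate); th <- 2 * pi * f / rate
  a <- c(2 * r * cos(th), -r^2)   # prediction coefficients of the pole pair
  roots <- polyroot(c(1, -a))
  z <- 1 / roots
  freqs <- Arg(z) * rate / (2 * pi)
  got <- sort(freqs[freqs > 0])
  expect_equal(got, f, tolerance = 1e-8)
  # and the polynomial indeed vanishes at the roots
  pv <- vapply(seq_along(roots), function(i)
    Mod(1 - a[1] * roots[i] - a[2] * roots[i]^2), numeric(1))
  expect_lt(max(pv), 1e-10)
})

test_that("formant-derived measures reproduce printed definitions and scale", {
  med <- c(500, 1500, 2500, 3500)
  fd <- formant_derived(med, c_sound = 350)
  expect_equal(fd$formant_dispersion, 1000)
  expect_equal(fd$delta_f, 1000)          # exact regression on equispaced
  expect_equal(fd$vtl_delta_f, 17.5)      # cm
  expect_equal(fd$fvtl, 17.5)
  expect_equal(fd$formant_mean, 2000)
  expect_equal(fd$mff, prod(med)^(1 / 4))
  expect_equal(fd$formant_position, 0)    # no corpus statistics supplied

  # homogeneity: scaling medians by alpha scales spectra measures, divides VTL
  a <- 1.3
  fda <- formant_derived(a * med, c_sound = 350)
  expect_equal(fda$formant_dispersion, a * fd$formant_dispersion)
  expect_equal(fda$delta_f, a * fd$delta_f)
  expect_equal(fda$mff, a * fd$mff)
  expect_equal(fda$vtl_delta_f, fd$vtl_delta_f / a)
  expect_equal(fda$fvtl, fd$fvtl / a)
  expect_error(formant_derived(c(500, 400, 2500, 3500)), "increasing")
})

test_that("noncepstral vector has the fixed 28-length layout and imputes", {
  expect_length(voicedysph::NONCEPSTRAL_LAYOUT, 28)
  v <- noncepstral_vector(fast_vowel(seed = 6))
  expect_length(v, 28)
  expect_named(v, voicedysph::NONCEPSTRAL_LAYOUT)
  expect_true(all(is.finite(v)))

  # fully unvoiced input: all measures imputed with training medians
  set.seed(30)
  noise <- voice_signal(rnorm(16000) * 0.1, 16000)
  corp <- small_corpus()
  stats <- fit_acoustic_stats(t(vapply(corp$signals, acoustic_measures,
                                       numeric(28))))
  vn <- noncepstral_vector(noise, stats)
  expect_true(all(is.finite(vn)))
  expect_equal(unname(vn["jitter_local"]),
               unname(stats$medians["jitter_local"]))
})

test_that("jitter PCA axis explains at least any single feature's variance", {
  corp <- small_corpus()
  M <- t(vapply(corp$signals, acoustic_measures, numeric(28)))
  stats <- fit_acoustic_stats(M)
  jb <- M[stats::complete.cases(M[, c("jitter_local", "jitter_local_abs",
                                      "jitter_rap")]),
          c("jitter_local", "jitter_local_abs", "jitter_rap")]
  scores <- sweep(jb, 2, stats$jitter_pca$mean) %*% stats$jitter_pca$axis
  expect_gte(stats::var(as.numeric(scores)) + 1e-12,
             max(apply(jb, 2, stats::var)))
})

test_that("perturbation measures are amplitude-scale invariant", {
  sig <- fast_vowel(seed = 8, jitter = 1, shimmer = 0.5, hnr_db = 25)
  base <- acoustic_measures(sig)
  keep <- c("jitter_local", "jitter_local_abs", "jitter_rap",
            "shimmer_local_db", "shimmer_apq3", "shimmer_apq5",
            "shimmer_apq11", "shimmer_dda", "hnr",
            "f1_median", "f2_median", "f3_median", "f4_median")
  for (alpha in c(0.5, 2)) {
    scaled <- acoustic_measures(voice_signal(sig$samples * alpha, sig$rate))
    expect_equal(scaled[keep], base[keep], tolerance = 1e-6)
  }
})
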