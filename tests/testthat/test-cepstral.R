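test_that("framing arithmetic, zero input and sinusoid peak behave as specified", {
  s <- voice_signal(rnorm(50000), 50000)
  sp <- preprocess_frames(s, frame_params())
  expect_equal(sp$nframes, 1 + floor((50000 - 1250) / 500))  # 98
  expect_equal(nrow(sp$power), sp$nframes)
  expect_equal(ncol(sp$power), sp$n_fft / 2 + 1)

  z <- voice_signal(numeric(4000), 16000)
  expect_true(all(preprocess_frames(z)$power == 0))

  tone <- voice_signal(sin(2 * pi * 1000 * (0:15999) / 16000), 16000)
  spt <- preprocess_frames(tone, frame_params(preemph = 0))
  peaks <- apply(spt$power, 1L, which.max)
  expect_true(all(abs(spt$freqs[peaks] - 1000) < spt$rate / spt$n_fft))

  expect_error(preprocess_frames(voice_signal(rnorm(100), 16000)),
               "shorter")
})

test_that("linear filterbank centres are equally spaced and mel warp inverts", {
  fb <- build_filterbank("linear", n_filters = 26, n_fft = 1024,
                         rate = 16000, fmin = 0, fmax = 8000)
  expect_equal(diff(fb$centers), rep(8000 / 27, 25))

  # mel warp closed form is invertible within 0.1 Hz at the centres
  fm <- build_filterbank("mel", n_filters = 26, n_fft = 1024, rate = 16000)
  expect_lt(max(abs(mel_to_hz(hz_to_mel(fm$centers)) - fm$centers)), 0.1)
  # centres equally spaced on the mel axis
  expect_equal(diff(hz_to_mel(fm$centers)),
               rep(diff(hz_to_mel(fm$centers))[1], 25), tolerance = 1e-8)
})

test_that("inverse-mel bank is the mirrored mel bank", {
  nf <- 26; nfft <- 1024
  Wm <- build_filterbank("mel", nf, nfft, 16000)$weights
  Wi <- build_filterbank("imel", nf, nfft, 16000)$weights
  nb <- nfft / 2 + 1
  expect_equal(Wi, Wm[rev(seq_len(nf)), rev(seq_len(nb))],
               ignore_attr = TRUE)
})

test_that("every filter of every scale has positive weight and finite rows", {
  for (sc in c("mel", "imel", "linear", "bark", "gammatone", "gammachirp")) {
    W <- build_filterbank(sc, 26, 2048, 50000)$weights
    expect_true(all(apply(W, 1, max) > 0), info = sc)
    expect_true(all(is.finite(W)), info = sc)
  }
  expect_error(build_filterbank("chroma", 26, 1024, 16000), "arg")
})

test_that("DCT stage matches a cosine-sum oracle and degenerate spectra collapse", {
  set.seed(42)
  v <- runif(26, 0.1, 2)
  D <- voicedysph:::.dct_matrix(26)
  oracle <- vapply(0:25, function(k) {
    w <- if (k == 0) sqrt(1 / 26) else sqrt(2 / 26)
    w * sum(v * cos(pi * (0:25 + 0.5) * k / 26))
  }, numeric(1))
  expect_lt(max(abs(drop(D %*% v) - oracle)), 1e-10)

  # white spectrum through a row-normalized bank: only coefficient 0 nonzero
  bank <- build_filterbank("linear", 10, 512, 8000)
  bank$weights <- bank$weights / rowSums(bank$weights)
  flat <- list(power = matrix(1, 3, 257))
  C <- filterbank_cepstra(flat, bank, nceps = 10)
  expect_lt(max(abs(C[-1, ])), 1e-10)

  # zero spectra with the log floor map every frame identically
  C0 <- filterbank_cepstra(list(power = matrix(0, 4, 257)), bank, 10)
  expect_equal(C0[, 1], C0[, 4])
  expect_error(filterbank_cepstra(flat, bank, nceps = 11), "exceed")
})

test_that("full filterbank pipeline equals a literal scalar-loop oracle", {
  set.seed(7)
  S <- matrix(runif(5 * 257, 0, 2), 5, 257)
  bank <- build_filterbank("mel", 12, 512, 8000)
  C <- filterbank_cepstra(list(power = S), bank, nceps = 8)
  for (fr in 1:5) {
    e <- as.numeric(bank$weights %*% S[fr, ])
    l <- log(pmax(e, 1e-10))
    cc <- vapply(0:7, function(k) {
      w <- if (k == 0) sqrt(1 / 12) else sqrt(2 / 12)
      w * sum(l * cos(pi * (0:11 + 0.5) * k / 12))
    }, numeric(1))
    expect_lt(max(abs(C[, fr] - cc)), 1e-8)
  }
})

test_that("Levinson-Durbin equals the direct Toeplitz solve", {
  set.seed(3)
  for (rep in 1:5) {
    x <- as.numeric(arima.sim(list(ar = c(0.6, -0.3)), 400))
    r <- vapply(0:8, function(k)
      sum(x[seq_len(400 - k)] * x[seq_len(400 - k) + k]), numeric(1))
    ld <- voicedysph:::levinson_durbin(r, 8)
    direct <- solve(toeplitz(r[1:8]), r[2:9])
    expect_lt(max(abs(ld$a - direct)), 1e-8)
  }
})

test_that("LPC recovers a known AR(2) process and degenerates safely", {
  set.seed(10)
  x <- as.numeric(arima.sim(list(ar = c(1.0, -0.5)), 16000))
  x <- x / max(abs(x))
  s <- voice_signal(x, 16000)
  # average LPC(2) prediction coefficients over frames
  win <- 400; hop <- 160
  frames <- voicedysph:::.frame_matrix(x, win, hop)
  A <- apply(frames, 2, function(fr) {
    r <- vapply(0:2, function(k)
      sum(fr[seq_len(win - k)] * fr[seq_len(win - k) + k]), numeric(1))
    voicedysph:::levinson_durbin(r, 2)$a
  })
  expect_equal(rowMeans(A), c(1.0, -0.5), tolerance = 0.05)

  # all-zero signal: every frame collapses to (log eps, 0, ..., 0)
  z <- voice_signal(numeric(4000), 16000)
  Cz <- lpcc(z, nceps = 6)
  expect_true(all(Cz[1, ] == log(1e-10)))
  expect_true(all(Cz[-1, ] == 0))
})

test_that("LPCC cepstral recursion matches a direct power-series oracle", {
  # for a known stable AR polynomial the cepstrum of 1/A(z) has the closed
  # form c_m = sum over poles p_i of p_i^m / m
  a <- c(0.9, -0.3)  # prediction coefficients; A(z) = 1 - 0.9 z^-1 + 0.3 z^-2
  poles <- polyroot(rev(c(1, -a)))  # roots of z^2 - 0.9 z + 0.3
  cc <- voicedysph:::.lpc_to_cepstra(a, 1, 12)
  for (m in 1:11) {
    expect_equal(cc[m + 1], Re(sum(poles^m)) / m, tolerance = 1e-10)
  }
})

test_that("CQT peaks at the bin nearest a pure tone and CQCC has the paper shape", {
  tone <- voice_signal(sin(2 * pi * 440 * (0:49999) / 50000), 50000)
  cq <- voicedysph:::.cqt_power(tone)
  pk <- which.max(rowMeans(cq$power))
  expect_equal(which.min(abs(cq$freqs - 440)), pk)

  C <- cqcc(ref_signal(), nceps = 20)
  expect_equal(nrow(C), 20)
  expect_equal(ncol(C), 100)  # ~100 frames/s on a 1 s signal
})

test_that("delta features satisfy closed forms and a convolution oracle", {
  # constant matrix -> zero deltas
  expect_true(all(cc_delta(matrix(3, 4, 10)) == 0))
  # linear ramp rows -> constant slope on interior frames
  ramp <- outer(c(1, 2), 1:12)
  d <- cc_delta(ramp, half_window = 2)
  expect_equal(d[, 3:10], outer(c(1, 2), rep(1, 8)), ignore_attr = TRUE)

  # brute-force oracle with edge replication on random input
  set.seed(5)
  M <- matrix(rnorm(20 * 30), 20, 30)
  N <- 2
  oracle <- matrix(0, 20, 30)
  for (t in 1:30) {
    for (n in 1:N) {
      oracle[, t] <- oracle[, t] +
        n * (M[, min(t + n, 30)] - M[, max(t - n, 1)])
    }
  }
  oracle <- oracle / (2 * sum((1:N)^2))
  expect_lt(max(abs(cc_delta(M, N) - oracle)), 1e-12)
  expect_error(cc_delta(M, 0), "half_window")
})

test_that("cmvn centres and scales rows, is idempotent, zeroes constant rows", {
  set.seed(6)
  M <- rbind(matrix(rnorm(3 * 40), 3, 40), rep(2, 40))
  out <- cmvn(M)
  expect_lt(max(abs(rowMeans(out))), 1e-9)
  sds <- sqrt(rowMeans((out - rowMeans(out))^2))
  expect_true(all(abs(sds - c(1, 1, 1, 0)) < 1e-9))
  expect_lt(max(abs(cmvn(out) - out)), 1e-9)
  expect_true(all(out[4, ] == 0))
})

test_that("extract_cc yields 20 x nframes CMVN'd matrices for all techniques", {
  sig <- ref_signal()
  shared_frames <- NULL
  for (tech in c("MFCC", "iMFCC", "LFCC", "BFCC", "GFCC", "NGCC", "LPCC")) {
    cc <- extract_cc(sig, tech)
    expect_equal(dim(cc$C), c(20, 98), info = tech)
    expect_equal(dim(cc$D1), dim(cc$C))
    expect_equal(dim(cc$D2), dim(cc$C))
    if (is.null(shared_frames)) shared_frames <- ncol(cc$C)
    expect_equal(ncol(cc$C), shared_frames, info = tech)
    # CMVN invariants on all three matrices
    for (M in list(cc$C, cc$D1, cc$D2)) {
      expect_lt(max(abs(rowMeans(M))), 1e-9)
      sds <- sqrt(rowMeans((M - rowMeans(M))^2))
      expect_true(all(sds < 1 + 1e-9 & (sds > 1 - 1e-9 | sds < 1e-9)))
    }
  }
  cc <- extract_cc(sig, "CQCC")
  expect_equal(nrow(cc$C), 20)
  expect_error(extract_cc(sig, "PLP"), "arg")
})

test_that("extract_cc is deterministic and amplitude-scale invariant after CMVN", {
  sig <- ref_signal()
  a <- extract_cc(sig, "MFCC")
  b <- extract_cc(sig, "MFCC")
  expect_identical(a, b)
  for (alpha in c(0.5, 2)) {
    scaled <- voice_signal(sig$samples * alpha, sig$rate)
    for (tech in c("MFCC", "LPCC")) {
      cs <- extract_cc(scaled, tech)
      co <- extract_cc(sig, tech)
      expect_lt(max(abs(cs$C - co$C)), 1e-6)
      expect_lt(max(abs(cs$D1 - co$D1)), 1e-6)
    }
  }
})
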