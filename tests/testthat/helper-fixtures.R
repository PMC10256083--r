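# Shared fixtures, built in code. Expensive objects are cached for the
# duration of the test run.

.fx <- new.env(parent = emptyenv())

# A synthetic sustained vowel at the reference 50 kHz rate.
ref_vowel <- function(seed = 1, f0 = 120, jitter = 0.3, shimmer = 0.2,
                      hnr_db = 30, vowel = "a", pitch = "normal",
                      duration = 1, rate = 50000) {
  synthesize_vowel(
    vowel_spec(vowel = vowel, pitch = pitch, f0 = f0, jitter_pct = jitter,
               shimmer_db = shimmer, hnr_db = hnr_db, duration = duration,
               rate = rate),
    seed = seed)
}

# A lighter vowel for unit tests where the sampling rate is immaterial.
fast_vowel <- function(seed = 1, ...) {
  ref_vowel(seed = seed, rate = 16000, ...)
}

# Small cached two-class corpus at 16 kHz for pipeline unit tests.
small_corpus <- function() {
  if (is.null(.fx$small_corpus)) {
    .fx$small_corpus <- generate_dataset(
      corpus_spec(n_healthy = 12, n_dysphonic = 12, rate = 16000,
                  seed = 11))
  }
  .fx$small_corpus
}

# Cached reference signal shared by cepstral tests.
ref_signal <- function() {
  if (is.null(.fx$ref_signal)) .fx$ref_signal <- ref_vowel(seed = 5)
  .fx$ref_signal
}

# Build a pulse sequence object directly (for the perturbation formulas).
make_pulse_seq <- function(periods, amplitudes = rep(1, length(periods) + 1)) {
  structure(list(times = cumsum(c(0, periods)), periods = periods,
                 amplitudes = amplitudes),
            class = "pulse_seq")
}

# Corpus with the same signals but permuted labels (for chance-level runs).
shuffle_labels <- function(corpus, seed) {
  labs <- corpus_labels(corpus)
  perm <- withr::with_seed(seed, sample(labs))
  for (i in seq_along(corpus$signals)) corpus$signals[[i]]$label <- perm[i]
  corpus$metadata$label <- perm
  corpus
}
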