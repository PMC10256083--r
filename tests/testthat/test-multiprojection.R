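test_that("mapping and technique sets validate names, order and aliases", {
  expect_equal(as.character(mapping_set("M9")),
               c("PCA", "SUM", "STD", "SKEW"))
  expect_equal(as.character(mapping_set(c("STD", "SUM"))), c("STD", "SUM"))
  expect_error(mapping_set(character(0)), "non-empty")
  expect_error(mapping_set(c("SUM", "SUM")), "duplicates")
  expect_error(mapping_set("MAX"), "unknown")
  expect_equal(as.character(technique_set("P15")),
               c("CQCC", "MFCC", "BFCC"))
  expect_error(technique_set("PLP"), "unknown")
  expect_length(voicedysph:::TECHNIQUE_SETS, 15)
  expect_length(voicedysph:::MAPPING_SETS, 9)
})

test_that("mappings match scalar-loop oracles on a random matrix", {
  set.seed(9)
  M <- matrix(rnorm(5 * 7), 5, 7)
  # brute-force oracles
  o_sum <- vapply(1:5, function(i) sum(M[i, ]), numeric(1))
  o_std <- vapply(1:5, function(i) {
    mu <- mean(M[i, ]); sqrt(mean((M[i, ] - mu)^2))
  }, numeric(1))
  o_skew <- vapply(1:5, function(i) {
    mu <- mean(M[i, ])
    m2 <- mean((M[i, ] - mu)^2); m3 <- mean((M[i, ] - mu)^3)
    m3 / m2^1.5
  }, numeric(1))
  expect_lt(max(abs(apply_mapping(M, "SUM") - o_sum)), 1e-10)
  expect_lt(max(abs(apply_mapping(M, "STD") - o_std)), 1e-10)
  expect_lt(max(abs(apply_mapping(M, "SKEW") - o_skew)), 1e-10)

  # PCA scores from an eigendecomposition of the Gram matrix of centred rows
  B <- sweep(M, 2, colMeans(M))
  G <- B %*% t(B)
  eg <- eigen(G, symmetric = TRUE)
  v <- drop(t(B) %*% eg$vectors[, 1])
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  o_pca <- drop(B %*% v)
  expect_lt(max(abs(apply_mapping(M, "PCA") - o_pca)), 1e-8)
})

test_that("zero and degenerate matrices project to zeros (SUM to the column)", {
  Z <- matrix(0, 20, 80)
  for (m in c("PCA", "SUM", "STD", "SKEW")) {
    expect_equal(apply_mapping(Z, m), rep(0, 20))
  }
  one <- matrix(1:4, 4, 1)
  expect_equal(apply_mapping(one, "SUM"), 1:4, ignore_attr = TRUE)
  expect_equal(apply_mapping(one, "STD"), rep(0, 4))
  expect_equal(apply_mapping(one, "SKEW"), rep(0, 4))
  expect_equal(apply_mapping(one, "PCA"), rep(0, 4))
})

test_that("a 20x80 matrix projects to length 20 under any single mapping", {
  set.seed(2)
  M <- matrix(rnorm(20 * 80), 20, 80)
  for (m in c("PCA", "SUM", "STD", "SKEW")) {
    expect_length(apply_mapping(M, m), 20)
  }
})

test_that("multiproject lays out mapping-major blocks of 3*nceps", {
  set.seed(4)
  C <- matrix(rnorm(20 * 15), 20, 15)
  cc <- list(C = C, D1 = matrix(0, 20, 15), D2 = matrix(0, 20, 15))
  v <- multiproject(cc, mapping_set("SUM"))
  expect_length(v, 60)
  expect_equal(unname(v), c(rowSums(C), rep(0, 40)))

  v2 <- multiproject(cc, mapping_set(c("SUM", "STD")))
  expect_length(v2, 120)  # 3 * 20 * 2
  expect_equal(unname(v2[1:20]), rowSums(C))
  expect_equal(unname(v2[61:80]),
               unname(apply_mapping(C, "STD")))
})

test_that("mappings are equivariant under coefficient-row permutation", {
  set.seed(11)
  C <- matrix(rnorm(10 * 30), 10, 30)
  D1 <- matrix(rnorm(10 * 30), 10, 30)
  D2 <- matrix(rnorm(10 * 30), 10, 30)
  perm <- sample(10)
  cc <- list(C = C, D1 = D1, D2 = D2)
  ccp <- list(C = C[perm, ], D1 = D1[perm, ], D2 = D2[perm, ])
  v <- multiproject(cc, mapping_set("M9"))
  vp <- multiproject(ccp, mapping_set("M9"))
  # each contiguous nceps-block is permuted identically
  for (b in seq_len(length(v) / 10)) {
    idx <- (b - 1) * 10 + seq_len(10)
    expect_equal(unname(vp[idx]), unname(v[idx][perm]))
  }
})

test_that("SUM is linear; STD/SKEW are translation invariant; STD scales", {
  set.seed(12)
  X <- matrix(rnorm(6 * 20), 6, 20)
  Y <- matrix(rnorm(6 * 20), 6, 20)
  expect_equal(apply_mapping(2 * X + 3 * Y, "SUM"),
               2 * apply_mapping(X, "SUM") + 3 * apply_mapping(Y, "SUM"))
  shift <- X + 5
  expect_equal(apply_mapping(shift, "STD"), apply_mapping(X, "STD"))
  expect_equal(apply_mapping(shift, "SKEW"), apply_mapping(X, "SKEW"))
  expect_equal(apply_mapping(3 * X, "STD"), 3 * apply_mapping(X, "STD"))
  expect_equal(apply_mapping(3 * X, "SKEW"), apply_mapping(X, "SKEW"))
})

test_that("fused cepstral vector length obeys nP * 3 * nceps * nM everywhere", {
  # arithmetic over every Table-2 x Table-3 combination via the layout law
  set.seed(13)
  fake_cc <- function(nceps, nframes = 9) {
    list(C = matrix(rnorm(nceps * nframes), nceps),
         D1 = matrix(rnorm(nceps * nframes), nceps),
         D2 = matrix(rnorm(nceps * nframes), nceps))
  }
  for (P in names(voicedysph:::TECHNIQUE_SETS)) {
    for (M in names(voicedysph:::MAPPING_SETS)) {
      techs <- technique_set(P); maps <- mapping_set(M)
      v <- unlist(lapply(seq_along(techs), function(i)
        multiproject(fake_cc(20), maps)))
      expect_length(v, length(techs) * 3 * 20 * length(maps))
    }
  }
})

test_that("fuse_cepstral produces the published vector dimensions on audio", {
  sig <- voice_signal(ref_signal()$samples[1:16000], 50000)
  # 1 technique x 1 mapping -> 60 (spectral technique, fast)
  expect_length(fuse_cepstral(sig, "LPCC", "PCA"), 60)
  # 2 techniques x 2 mappings -> 240
  v <- fuse_cepstral(sig, c("MFCC", "LFCC"), c("SUM", "STD"))
  expect_length(v, 2 * 3 * 20 * 2)
  # names carry technique and mapping blocks in order
  expect_match(names(v)[1], "^MFCC\\.SUM\\.C")
  expect_match(names(v)[240], "^LFCC\\.STD\\.D2")
})
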