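# Multi-scale convolution, feature agreement, the joint softmax attention
# matrix, and mixed-scale features.

test_that("raw scaled convolution matches the hand example and the sliding oracle", {
  # constant-one input, single channel, kernel of ones, size 3: interior
  # rows see a window sum of 3, divided by sqrt(3)
  l <- 7
  X <- matrix(1, l, 1)
  sp <- list(size = 3L, K = lapply(1:3, function(s) matrix(1, 1, 1)),
             b = 0, Wp = NULL, bp = NULL)
  out <- extract_scale_features(X, rep(TRUE, l), list(sp),
                                activation = FALSE, project = FALSE)[[1]]
  expect_equal(out[2:(l - 1), 1], rep(3 / sqrt(3), l - 2))
  expect_equal(out[1, 1], 2 / sqrt(3))       # leading zero padding
  expect_equal(out[l, 1], 2 / sqrt(3))

  set.seed(1)
  for (i in 1:10) {
    l <- sample(6:12, 1); f <- sample(2:4, 1); S <- sample(2:5, 1)
    C <- sample(2:3, 1)
    sp <- list(size = S,
               K = lapply(seq_len(S), function(s) matrix(rnorm(f * C), f, C)),
               b = rnorm(C), Wp = NULL, bp = NULL)
    X <- matrix(rnorm(l * f), l, f)
    out <- extract_scale_features(X, rep(TRUE, l), list(sp),
                                  activation = FALSE, project = FALSE)[[1]]
    expect_equal(out, oracle_conv(X, sp$K, sp$b), tolerance = 1e-8)
  }
})

test_that("feature maps keep l rows and zero PAD-centered rows", {
  set.seed(2)
  cfg <- dsattn_config(l = 32, f = 8, h = 2, scales = c(3, 5),
                       channels_per_size = 2)
  params <- dsattn:::init_model(cfg)
  mask <- c(rep(TRUE, 25), rep(FALSE, 7))
  G <- matrix(rnorm(32 * 8), 32, 8); G[!mask, ] <- 0
  maps <- extract_scale_features(G, mask, params$scales)
  for (m in maps) {
    expect_equal(nrow(m), 32)
    expect_equal(m[!mask, ], matrix(0, 7, 8))
  }
  expect_error(extract_scale_features(G[1:2, ], rep(TRUE, 2), params$scales),
               "kernel size")
})

test_that("central vectors average the global and scale features", {
  u <- c(1, 2, 3)
  maps <- list(matrix(u, 1, 3), matrix(u, 1, 3))
  expect_equal(central_vectors(matrix(u, 1, 3), maps)[1, ], u)
  # N = 1 two-dimensional example
  expect_equal(central_vectors(matrix(c(1, 0), 1, 2),
                               list(matrix(c(0, 1), 1, 2)))[1, ],
               c(0.5, 0.5))
  set.seed(3)
  for (i in 1:10) {
    N <- 3; l <- 6; f <- 4
    G <- matrix(rnorm(l * f), l, f)
    maps <- rand_maps(N, l, f)
    expect_equal(central_vectors(G, maps), oracle_central(G, maps),
                 tolerance = 1e-7)
  }
  expect_error(central_vectors(matrix(0, 2, 2), list(matrix(0, 3, 2))),
               "shape")
})

test_that("agreement is the scaled dot product with the central vector", {
  f <- 4
  u <- c(1, -2, 0.5, 3)
  m <- matrix(u, 1, f)
  expect_equal(agreement_scores(list(m), m, TRUE)[1, 1],
               sum(u^2) / sqrt(f))
  perp <- matrix(c(2, 1, 0, 0), 1, f)   # orthogonal to (1,-2,.5,3)? no: use explicit
  a <- c(1, 0, 0, 0); b <- c(0, 1, 0, 0)
  expect_equal(agreement_scores(list(matrix(a, 1, f)), matrix(b, 1, f),
                                TRUE)[1, 1], 0)
  set.seed(4)
  for (i in 1:10) {
    N <- 2; l <- 5; f <- 6
    maps <- rand_maps(N, l, f)
    centers <- matrix(rnorm(l * f), l, f)
    expect_equal(agreement_scores(maps, centers, rep(TRUE, l)),
                 oracle_agreement(maps, centers, sqrt(f)), tolerance = 1e-7)
    expect_equal(agreement_scores(maps, centers, rep(TRUE, l), divisor = "f"),
                 oracle_agreement(maps, centers, f), tolerance = 1e-7)
  }
  # PAD columns become -Inf sentinels
  A <- agreement_scores(rand_maps(2, 4, 3), matrix(rnorm(12), 4, 3),
                        c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(A[, 3:4] == -Inf))
})

test_that("the joint softmax yields a normalized W with zero PAD mass", {
  A <- matrix(0.7, 3, 10)                  # constant scores
  att <- attention_matrix(A)
  expect_equal(att$W, matrix(1 / 30, 3, 10))
  expect_equal(sum(att$W), 1, tolerance = 1e-6)
  expect_equal(sum(att$v), 1, tolerance = 1e-6)
  expect_equal(att$v, colSums(att$W))

  A2 <- matrix(rnorm(30), 3, 10)
  A2[, 8:10] <- -Inf
  att2 <- attention_matrix(A2)
  expect_lt(sum(att2$W[, 8:10]), 1e-8)
  expect_equal(sum(att2$W), 1, tolerance = 1e-6)
  expect_error(attention_matrix(matrix(-Inf, 2, 3)), "degenerate")
})

test_that("feature mixing is the position-wise conditional mixture", {
  set.seed(5)
  l <- 6; f <- 3
  mask <- rep(TRUE, l)
  # N = 1: mixing returns the single map
  maps1 <- rand_maps(1, l, f)
  A <- agreement_scores(maps1, matrix(rnorm(l * f), l, f), mask)
  att <- attention_matrix(A)
  expect_equal(mix_features(att, maps1, mask), maps1[[1]], tolerance = 1e-8)
  # equal weights average the maps
  maps3 <- rand_maps(3, l, f)
  attu <- structure(list(W = matrix(1 / (3 * l), 3, l),
                         v = rep(1 / l, l)), class = "dsattn_attention")
  expect_equal(mix_features(attu, maps3, mask),
               Reduce(`+`, maps3) / 3, tolerance = 1e-8)
  # random instances against the explicit loop oracle
  for (i in 1:10) {
    maps <- rand_maps(3, l, f)
    A <- agreement_scores(maps, matrix(rnorm(l * f), l, f), mask)
    att <- attention_matrix(A)
    expect_equal(mix_features(att, maps, mask),
                 oracle_mix(att$W, att$v, maps), tolerance = 1e-7)
  }
})

test_that("conditional scale weights normalize and mixing stays in the convex hull", {
  set.seed(6)
  l <- 9; f <- 4
  mask <- c(rep(TRUE, 7), FALSE, FALSE)
  maps <- rand_maps(3, l, f, mask)
  G <- matrix(rnorm(l * f), l, f); G[!mask, ] <- 0
  A <- agreement_scores(maps, central_vectors(G, maps), mask)
  att <- attention_matrix(A)
  cond <- sweep(att$W, 2L, att$v, "/")[, mask]
  expect_equal(colSums(cond), rep(1, 7), tolerance = 1e-6)
  Fm <- mix_features(att, maps, mask)
  for (j in which(mask)) {
    norms <- sapply(maps, function(m) sqrt(sum(m[j, ]^2)))
    expect_lte(sqrt(sum(Fm[j, ]^2)), max(norms) + 1e-9)
  }
})

test_that("permuting the scale order permutes A and W and leaves mixing invariant", {
  set.seed(7)
  l <- 8; f <- 5
  mask <- rep(TRUE, l)
  maps <- rand_maps(3, l, f)
  G <- matrix(rnorm(l * f), l, f)
  perm <- c(3, 1, 2)
  A1 <- agreement_scores(maps, central_vectors(G, maps), mask)
  A2 <- agreement_scores(maps[perm], central_vectors(G, maps[perm]), mask)
  expect_equal(A2, A1[perm, ], tolerance = 1e-10)
  att1 <- attention_matrix(A1); att2 <- attention_matrix(A2)
  expect_equal(att2$W, att1$W[perm, ], tolerance = 1e-10)
  expect_equal(mix_features(att2, maps[perm], mask),
               mix_features(att1, maps, mask), tolerance = 1e-8)
})

test_that("excluding the global features from the central vector changes the scores", {
  set.seed(8)
  l <- 6; f <- 4
  mask <- rep(TRUE, l)
  maps <- rand_maps(2, l, f)
  G <- matrix(rnorm(l * f), l, f)
  A_with <- agreement_scores(maps, central_vectors(G, maps, TRUE), mask)
  A_without <- agreement_scores(maps, central_vectors(G, maps, FALSE), mask)
  expect_gt(max(abs(A_with - A_without)), 1e-8)
})
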