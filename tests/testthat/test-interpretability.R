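# Motif matching against the double-scale attention matrix.

# Hand-constructed explanation objects with full control over W and v.
fake_explanation <- function(W, mask = rep(TRUE, ncol(W)),
                             scales = c(5L, 10L, 20L), window_start = 0L) {
  structure(list(W = W, v = colSums(W), mask = mask, scales = scales,
                 window_start = window_start, raw_length = ncol(W),
                 probs = NULL, seq_id = "s1"),
            class = "dsattn_explanation")
}

test_that("uniform attention never matches (ratio is exactly 1)", {
  W <- matrix(1 / 60, 3, 20)
  ex <- fake_explanation(W)
  for (st in c(0, 5, 11)) {
    m <- match_annotation(ex, st, st + 5)
    expect_equal(m$status, "no_match")
    expect_equal(m$center_weight_ratio, 1)
  }
})

test_that("both match conditions must hold at the motif middle", {
  l <- 30
  # motif of length 9 at [10, 19): middle = (10+19-1)/2 = 14
  W <- matrix(1 / (100 * l), 3, l)
  W[2, 15] <- W[2, 15] + 0.5            # scale 10 dominant at the middle
  W <- W / sum(W)
  ex <- fake_explanation(W)
  m <- match_annotation(ex, 10, 19)
  expect_equal(m$status, "match")       # |9-10| = 1 beats |9-5| = 4
  expect_equal(m$matched_scale, 10)
  expect_equal(m$score, W[2, 15])
  expect_gt(m$center_weight_ratio, 2)

  # length 7: the closest kernel is 5 (|7-5| = 2 < |7-10| = 3), so an
  # argmax at scale 10 cannot match even with a strong margin
  m7 <- match_annotation(ex, 11, 18)
  expect_equal(m7$closest_scale, 5)
  expect_equal(m7$status, "no_match")

  # same length 9 but a weak margin fails condition 2
  W2 <- matrix(1 / (3 * l), 3, l)
  W2[2, 15] <- W2[2, 15] * 1.2
  ex2 <- fake_explanation(W2 / sum(W2))
  expect_equal(match_annotation(ex2, 10, 19)$status, "no_match")
})

test_that("kernel-size ties break toward the smaller kernel", {
  # length 15 is equidistant from 10 and 20
  expect_equal(dsattn:::closest_kernel(c(5L, 10L, 20L), 15), 10)
  expect_equal(dsattn:::closest_kernel(c(5L, 10L, 20L), 19), 20)
  expect_equal(dsattn:::closest_kernel(c(5L, 10L, 20L), 7), 5)
})

test_that("annotations outside the chop window yield the out-of-window signal", {
  W <- matrix(1 / 30, 3, 10)
  ex <- fake_explanation(W, mask = c(rep(TRUE, 8), FALSE, FALSE))
  expect_equal(match_annotation(ex, 4, 8)$status, "no_match")
  expect_equal(match_annotation(ex, 5, 9)$status, "out_of_window")
  ex2 <- fake_explanation(W, window_start = 4L)
  expect_equal(match_annotation(ex2, 2, 6)$status, "out_of_window")
  expect_error(match_annotation(ex, 6, 6), "start < end")
})

test_that("match decisions are invariant to a consistent positive rescaling", {
  set.seed(1)
  W <- matrix(rexp(3 * 20), 3, 20); W <- W / sum(W)
  ex1 <- fake_explanation(W)
  ex3 <- fake_explanation(W)
  ex3$W <- 3.7 * ex3$W; ex3$v <- 3.7 * ex3$v
  for (st in c(0, 4, 9)) {
    m1 <- match_annotation(ex1, st, st + 6)
    m3 <- match_annotation(ex3, st, st + 6)
    expect_equal(m1$status, m3$status)
    expect_equal(m1$center_weight_ratio, m3$center_weight_ratio,
                 tolerance = 1e-10)
  }
})

test_that("ranking sorts by score, breaks ties by start, and keeps 16", {
  expect_equal(nrow(rank_and_select(list())), 0)
  set.seed(2)
  mk <- function(score, start) list(seq_id = "s", start = start,
                                    end = start + 5, label = "m",
                                    matched_scale = 5,
                                    center_weight_ratio = 2,
                                    score = score, status = "match")
  ms <- lapply(1:20, function(i) mk(runif(1), i))
  sel <- rank_and_select(ms)
  expect_equal(nrow(sel), 16)
  expect_true(all(diff(sel$score) <= 1e-12))
  # equal scores: earlier start first
  tied <- rank_and_select(list(mk(0.5, 9), mk(0.5, 2), mk(0.9, 30)))
  expect_equal(tied$start, c(30, 2, 9))
  # non-matches are dropped
  nm <- mk(1, 1); nm$status <- "no_match"
  expect_equal(nrow(rank_and_select(list(nm))), 0)
})

test_that("match_rate contracts: named sequences, in-window denominator", {
  set.seed(3)
  cfg <- dsattn_config(l = 24, f = 8, h = 2, n_layers = 1, scales = c(2, 3, 5),
                       channels_per_size = 2, n_classes = 2)
  model <- rand_tiny_model(cfg)
  seqs <- stats::setNames(replicate(3, rand_aa(20)), c("s1", "s2", "s3"))
  ann <- data.frame(seq_id = c("s1", "s2", "s3"), start = c(0L, 5L, 2L),
                    end = c(5L, 10L, 7L), label = "m")
  mr <- match_rate(model, seqs, ann, n_perm = 5)
  expect_gte(mr$observed, 0); expect_lte(mr$observed, 1)
  expect_gte(mr$baseline, 0); expect_lte(mr$baseline, 1)
  expect_equal(mr$n_annotations, 3)
  expect_error(match_rate(model, unname(seqs), ann, 2), "named")
  far <- data.frame(seq_id = "s1", start = 50L, end = 60L, label = "m")
  expect_error(match_rate(model, seqs, far, 2), "inside")
})

test_that("1-based closed coordinates convert to 0-based half-open", {
  cv <- coords_from_1based(c(1, 10), c(5, 12))
  expect_equal(cv$start, c(0, 9))
  expect_equal(cv$end, c(5, 12))
  expect_equal(cv$end - cv$start, c(5, 3))   # lengths preserved
})
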