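# Masked-LM corruption, learning-rate schedules, optimizer behavior, and
# evaluation metrics.

test_that("corruption targets 15% of eligible positions, never PAD or unknowns", {
  voc <- aa_vocab()
  set.seed(1)
  ts <- regularize_length(strsplit(rand_aa(100), "")[[1]], 100)
  cor <- mlm_corrupt(ts)
  expect_length(cor$positions, 15)
  expect_identical(cor$original, ts$ids[cor$positions])

  # all-PAD and all-unknown sequences yield the skip-record signal
  allpad <- structure(list(ids = rep(voc$pad_id, 8), mask = rep(FALSE, 8),
                           raw_length = 0L, window_start = 0L),
                      class = "token_sequence")
  expect_null(mlm_corrupt(allpad))
  allx <- regularize_length(rep("MASK", 6), 6)
  expect_null(mlm_corrupt(allx))

  # fuzz: selected positions are always real, never originally MASK
  for (i in 1:50) {
    raw <- paste(sample(c(voc$residues, "X"), sample(5:40, 1), replace = TRUE),
                 collapse = "")
    ts <- encode_sequence(raw, 30)
    cor <- mlm_corrupt(ts)
    if (is.null(cor)) next
    expect_true(all(ts$mask[cor$positions]))
    expect_true(all(ts$ids[cor$positions] != voc$mask_id))
  }
})

test_that("corruption actions follow the 80/10/10 proportions", {
  set.seed(2)
  ts <- regularize_length(strsplit(rand_aa(80), "")[[1]], 80)
  actions <- character(0)
  while (length(actions) < 10000)
    actions <- c(actions, mlm_corrupt(ts)$action)
  actions <- actions[1:10000]
  expect_gte(mean(actions == "mask"), 0.78)
  expect_lte(mean(actions == "mask"), 0.82)
  expect_gte(mean(actions == "random"), 0.085)
  expect_lte(mean(actions == "random"), 0.115)
})

test_that("masked-LM loss matches the uniform, perfect, and hand-computed cases", {
  f <- 6
  G <- matrix(rnorm(5 * f), 5, f)
  # zero decoder: uniform over the 22 residue tokens
  p0 <- list(Wd = matrix(0, f, 22), bd = numeric(22))
  expect_equal(mlm_loss(G, c(1L, 3L), c(4L, 7L), p0), log(22),
               tolerance = 1e-9)
  # near-perfect decoder via a huge bias on the true token
  pp <- list(Wd = matrix(0, f, 22), bd = c(1000, rep(0, 21)))
  expect_equal(mlm_loss(G, 2L, 1L, pp), 0, tolerance = 1e-9)
  # random instance against a direct computation
  set.seed(3)
  pr <- list(Wd = matrix(rnorm(f * 22), f, 22), bd = rnorm(22))
  pos <- c(2L, 4L); orig <- c(11L, 20L)
  manual <- mean(sapply(1:2, function(i) {
    z <- as.vector(G[pos[i], ] %*% pr$Wd) + pr$bd
    -log(exp(z[orig[i]]) / sum(exp(z)))
  }))
  expect_equal(mlm_loss(G, pos, orig, pr), manual, tolerance = 1e-7)
  expect_error(mlm_loss(G, integer(0), integer(0), p0), "empty")
})

test_that("learning-rate schedules reproduce the shipped configurations", {
  cfg6 <- read_model_config(system.file("configs", "full-6layer.yaml",
                                        package = "dsattn"))
  cfg3 <- read_model_config(system.file("configs", "full-3layer.yaml",
                                        package = "dsattn"))
  expect_equal(pretrain_lr(50000, cfg6$pretrain$warmup_steps,
                           cfg6$pretrain$peak_lr), 5e-5)
  expect_equal(pretrain_lr(50000, cfg3$pretrain$warmup_steps,
                           cfg3$pretrain$peak_lr), 1e-4)
  expect_equal(pretrain_lr(0, 50000, 5e-5), 0)
  expect_equal(finetune_lr(0, cfg6$finetune$initial_lr), 1e-5)
  expect_equal(finetune_lr(100, cfg6$finetune$initial_lr), 9.5e-6)
  expect_equal(finetune_lr(250, 1e-5), 1e-5 * 0.95^2)
  # continuity at the warm-up boundary and non-negativity
  expect_equal(pretrain_lr(50000 - 1, 50000, 5e-5),
               pretrain_lr(50000 + 1, 50000, 5e-5), tolerance = 1e-4)
  steps <- c(0, 10, 1000, 49999, 50000, 50001, 1e6)
  expect_true(all(sapply(steps, pretrain_lr, warmup_steps = 50000,
                         peak_lr = 5e-5) >= 0))
})

test_that("one AdamW step on a convex softmax head decreases its loss", {
  set.seed(4)
  l <- 6; f <- 4; M <- 3
  Fm <- matrix(rnorm(l * f), l, f)
  v <- rep(1 / l, l)
  params <- list(Wc = matrix(rnorm(f * M, sd = 0.1), f, M), bc = rnorm(M))
  label <- 2L
  loss_of <- function(p) {
    C <- positional_predictions(Fm, p)
    -log(aggregate_predictions(C, v)[label])
  }
  hd <- dsattn:::head_forward(Fm, v, 1L, l, params)
  dP <- matrix(0, 1, M); dP[1, label] <- -1 / hd$P[1, label]
  bk <- dsattn:::head_backward(dP, hd, Fm, v, 1L, l, params)
  upd <- dsattn:::adamw_step(params, bk$grads, dsattn:::adamw_init(),
                             lr = 1e-2, wd = 0)
  expect_lt(loss_of(upd$params), loss_of(params))
})

test_that("pre-training is deterministic under a fixed seed and logs traces", {
  set.seed(5)
  seqs <- replicate(24, rand_aa(sample(12:20, 1)))
  cfg <- dsattn_config(l = 16, f = 8, h = 2, n_layers = 1, scales = c(2, 3),
                       channels_per_size = 2)
  r1 <- dsattn_pretrain(seqs, cfg, epochs = 2, batch_size = 8,
                        warmup_steps = 4, peak_lr = 1e-3, seed = 77)
  r2 <- dsattn_pretrain(seqs, cfg, epochs = 2, batch_size = 8,
                        warmup_steps = 4, peak_lr = 1e-3, seed = 77)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$params, r2$params)
  expect_equal(nrow(r1$trace), 2)
  expect_true(all(is.finite(r1$trace$train_loss)))
})

test_that("fine-tuning is deterministic under a fixed seed", {
  set.seed(6)
  seqs <- replicate(30, rand_aa(sample(12:20, 1)))
  labels <- rep(c("a", "b"), 15)
  cfg <- dsattn_config(l = 16, f = 8, h = 2, n_layers = 1, scales = c(2, 3),
                       channels_per_size = 2)
  f1 <- dsattn(seqs, labels, cfg, epochs = 1, batch_size = 10, seed = 5)
  f2 <- dsattn(seqs, labels, cfg, epochs = 1, batch_size = 10, seed = 5)
  expect_identical(f1$trace, f2$trace)
  expect_s3_class(f1, "dsattn")
  p <- predict(f1, seqs[1:4], type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-6)
})

test_that("metrics match hand-computed confusion tables", {
  m <- evaluate_predictions(c("a", "b"), c("a", "b"))
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)

  # constant predictor on a balanced 2-class set
  m2 <- evaluate_predictions(rep("a", 10), rep(c("a", "b"), 5))
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$macro_f1, (2 / 3 + 0) / 2)

  # 3-class confusion counts [[5,0,0],[0,4,1],[0,2,3]]
  truth <- rep(c("x", "y", "z"), c(5, 5, 5))
  pred <- c(rep("x", 5), rep("y", 4), "z", rep("y", 2), rep("z", 3))
  m3 <- evaluate_predictions(pred, truth)
  expect_equal(m3$accuracy, 12 / 15)
  expect_lte(m3$macro_f1, max(m3$per_class$f1))
  expect_true(all(m3$per_class$f1 >= 0 & m3$per_class$f1 <= 1))

  # class absent from both predictions and truth is flagged with F1 = 0
  m4 <- evaluate_predictions(c("a", "a"), c("a", "a"), classes = c("a", "b"))
  expect_true(m4$per_class$absent[m4$per_class$class == "b"])
  expect_equal(m4$per_class$f1[m4$per_class$class == "b"], 0)
  expect_error(evaluate_predictions(character(0), character(0)), "empty|equal")
})
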