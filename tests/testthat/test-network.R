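test_that("the multi-scale residual block matches its unrolled loop oracle", {
  set.seed(11)
  ## random weights, s = 4 on an 8-channel 4x4 input
  blk <- new_res2net_block(8L, 4L)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  expect_equal(res2net_apply(blk, x), oracle_res2net(blk, x), tolerance = 1e-5)
  ## hand-set identity kernels: centre tap 1 connecting channel j to j
  w <- 2L
  ident <- array(0, c(3, 3, w, w))
  for (j in seq_len(w)) ident[2, 2, j, j] <- 1
  for (i in 2:4) blk[[paste0("W", i)]]$val <- conv_kernel_matrix(ident)
  for (i in 2:4) blk[[paste0("b", i)]]$val <- rep(0, w)
  blk$fuseW$val <- diag(8)
  blk$fuseb$val <- rep(0, 8)
  xp <- array(abs(rnorm(4 * 4 * 8)), c(4, 4, 8))   # positive: ReLU transparent
  out <- res2net_apply(blk, xp)
  ## with identity kernels the cascade is a running prefix sum of the groups
  g <- function(i) xp[, , ((i - 1) * w + 1):(i * w), drop = FALSE]
  y2 <- g(2) + g(1); y3 <- g(3) + y2; y4 <- g(4) + y3
  manual_cat <- array(c(g(1), y2, y3, y4), dim(xp))
  expect_equal(out, xp + manual_cat, tolerance = 1e-12)
  ## zero input with zero-initialized convolutions stays zero
  zero_blk <- new_res2net_block(8L, 4L)
  for (nm in setdiff(names(zero_blk), c("channels", "scale")))
    zero_blk[[nm]]$val <- zero_blk[[nm]]$val * 0
  expect_equal(res2net_apply(zero_blk, array(0, c(4, 4, 8))),
               array(0, c(4, 4, 8)))
  ## s = 1 reduces to a standard residual conv block (shape-preserving)
  blk1 <- new_res2net_block(8L, 1L)
  expect_equal(dim(res2net_apply(blk1, x)), dim(x))
  expect_equal(res2net_apply(blk1, x), oracle_res2net(blk1, x), tolerance = 1e-5)
  expect_error(new_res2net_block(6L, 4L), "divisible")
})

test_that("shallow attention gates the upsampled deeper feature by the ReLU conv map", {
  ## 2x2 deep feature upsampled (nearest-equivalent for factor 2 with these
  ## weights checked against explicit arithmetic)
  f_shallow <- array(c(1, -1, 2, -2, 0.5, 3, -4, 1), c(2, 2, 2))
  W <- matrix(c(1, 0.5), 2, 1)    # 1x1 conv: 2 channels -> 1
  b <- 0
  f_deep2 <- array(seq_len(4) / 2, c(2, 2, 1))
  sa <- shallow_attention(f_shallow, f_deep2, W, b)
  manual_att <- pmax(f_shallow[, , 1] * 1 + f_shallow[, , 2] * 0.5, 0)
  expect_equal(sa$attention[, , 1], manual_att, tolerance = 1e-12)
  expect_equal(sa$output[, , 1], f_deep2[, , 1] * manual_att, tolerance = 1e-12)
  ## bias forcing the attention map to 1 makes the output the upsampled deep map
  big_b <- 100
  sa1 <- shallow_attention(f_shallow * 1e-9, f_deep2, W * 0, big_b)
  expect_equal(sa1$output[, , 1], 100 * f_deep2[, , 1], tolerance = 1e-9)
  ## all-negative pre-activation annihilates the output
  sa0 <- shallow_attention(-abs(f_shallow), f_deep2, abs(W), -1)
  expect_true(all(sa0$attention == 0))
  expect_true(all(sa0$output == 0))
  ## channel mismatch between map and deep feature is a configuration error
  expect_error(shallow_attention(f_shallow, array(1, c(2, 2, 3)), W, b),
               "channels")
  expect_error(shallow_attention(array(1, c(2, 2, 2)), array(1, c(4, 4, 1)),
                                 W, b), "coarser")
})

test_that("a three-stage attention chain matches step-by-step manual evaluation", {
  set.seed(5)
  D <- 1
  f1 <- array(runif(16), c(4, 4, 1)); f2 <- array(runif(4), c(2, 2, 1))
  sa3 <- array(runif(4), c(2, 2, 1))           # deepest SA feature, stage-2 res
  W <- matrix(0.8, 1, 1); b <- 0.1
  step2 <- shallow_attention(f2, sa3, W, b)    # gate at stage 2
  step1 <- shallow_attention(f1, array(step2$output, c(2, 2, 1)), W, b)
  m2 <- pmax(f2[, , 1] * 0.8 + 0.1, 0)
  manual2 <- sa3[, , 1] * m2                   # same resolution: upsample = identity
  expect_equal(step2$output[, , 1], manual2, tolerance = 1e-12)
  m1 <- pmax(f1[, , 1] * 0.8 + 0.1, 0)
  A <- aodmeter:::interp_matrix(2, 4)
  up_exact <- A %*% manual2 %*% t(A)
  expect_equal(step1$output[, , 1], up_exact * m1, tolerance = 1e-12)
})

test_that("forward pass yields working-resolution probabilities with non-negative attention", {
  cfg <- tiny_model_config(seed = 2)
  m <- build_model(cfg)
  img <- array(rnorm(96 * 96 * 3), c(96, 96, 3))
  fw <- model_forward(m, img)
  expect_equal(dim(fw$prob), c(96, 96))
  ## sigmoid output; extreme logits may underflow to exactly 0/1 in double
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  expect_true(all(vapply(fw$attention, min, 1) >= 0))
  expect_identical(predict_prob(m, img), predict_prob(m, img))
  expect_error(model_forward(m, array(0, c(64, 64, 3))), "96x96x3")
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- tiny_model_config(seed = 31, channels = c(4L, 8L), working_size = 32L,
                           decoder_channels = 4L)
  m <- build_model(cfg)
  img <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  y <- matrix(0, 32, 32); y[10:20, 12:22] <- 1
  loss_of <- function() {
    fw <- model_forward(m, img)
    aodmeter:::bce_dice_loss(fw$logits$val[, , 1], y)$loss
  }
  aodmeter:::ag_zero_grad(m$params)
  fw <- model_forward(m, img)
  lg <- aodmeter:::bce_dice_loss(fw$logits$val[, , 1], y)
  aodmeter:::ag_backward(fw$tape, fw$logits, array(lg$grad, dim(fw$logits$val)))
  set.seed(77)
  for (nm in c("stage1.conv.W", "stage2.block.W3", "att1.conv.W",
               "head1.bn.gamma", "final.conv.W", "stage2.conv.b")) {
    p <- m$params[[nm]]
    i <- sample(length(p$val), 1)
    eps <- 1e-5; v0 <- p$val[i]
    p$val[i] <- v0 + eps; lp <- loss_of()
    p$val[i] <- v0 - eps; lm <- loss_of()
    p$val[i] <- v0
    num <- (lp - lm) / (2 * eps)
    expect_equal(p$grad[i], num, tolerance = 5e-3,
                 label = paste("analytic grad of", nm))
  }
})

test_that("binarization counts exceedances exactly", {
  expect_equal(sum(binarize(matrix(0.4, 8, 8), 0.5)), 0)
  expect_equal(sum(binarize(matrix(0.6, 8, 8), 0.5)), 64)
  set.seed(3)
  pm <- matrix(runif(400), 20)
  bz <- binarize(pm, 0.3)
  brute <- 0L
  for (i in 1:20) for (j in 1:20) if (pm[i, j] > 0.3) brute <- brute + 1L
  expect_equal(sum(bz), brute)
  expect_error(binarize(pm, 1), "threshold")
})

test_that("checkpoints restore forward passes bit-identically", {
  cfg <- tiny_model_config(seed = 8, channels = c(4L, 8L), working_size = 32L,
                           decoder_channels = 4L)
  m <- build_model(cfg)
  img <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  p0 <- predict_prob(m, img)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(predict_prob(m2, img), p0)
  expect_equal(m2$config, cfg)
})

test_that("configuration invariants are enforced", {
  expect_error(model_config(threshold = 1.2), "threshold")
  expect_error(model_config(epochs = 0), "epochs")
  expect_error(model_config(channels = c(6L, 12L), res2net_scale = 4L),
               "divisible")
  expect_error(model_config(working_size = 100L, channels = c(8L, 16L, 32L)),
               "divisible")
})
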