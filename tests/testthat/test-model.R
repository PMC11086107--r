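# Blocks, architecture assembly, ablation variants, composite loss.

test_that("sparse residual encoder blocks reduce to identity with zero convs", {
  set.seed(41)
  b <- ppgbp:::unet_block(4L, 4L, 3L, "sparse_residual", "encoder")
  for (leaf in b$leaves) {
    if ("W" %in% names(leaf$params)) leaf$params$W[] <- 0
    if ("b" %in% names(leaf$params)) leaf$params$b[] <- 0
  }
  x <- array(abs(rnorm(4 * 8 * 2)), c(4, 8, 2))   # nonnegative input
  # eval mode: batch-norm uses its (identity) running statistics
  y <- b$forward(x, train = FALSE)
  expect_equal(y, x, tolerance = 1e-9)            # both skips pass x through
  expect_equal(dim(b$forward(array(rnorm(64), c(4, 8, 2)), FALSE)), c(4, 8, 2))
})

test_that("ordinary residual unit with zero residual function is activation(x)", {
  set.seed(42)
  b <- ppgbp:::unet_block(3L, 3L, 3L, "residual", "encoder")
  for (leaf in b$leaves) {
    if ("W" %in% names(leaf$params)) leaf$params$W[] <- 0
    if ("b" %in% names(leaf$params)) leaf$params$b[] <- 0
  }
  x <- array(rnorm(3 * 8 * 2), c(3, 8, 2))
  y <- b$forward(x, train = FALSE)
  expect_equal(y, x * (x > 0), tolerance = 1e-9)  # f(h(x)) with F = 0
})

test_that("blocks preserve shape and decoder sparse blocks use a single stage", {
  set.seed(43)
  for (type in c("plain", "residual", "sparse_residual")) {
    enc <- ppgbp:::unet_block(2L, 6L, 3L, type, "encoder")
    dec <- ppgbp:::unet_block(6L, 3L, 3L, type, "decoder")
    x <- array(rnorm(2 * 8 * 2), c(2, 8, 2))
    expect_equal(dim(enc$forward(x)), c(6, 8, 2))
    expect_equal(dim(dec$forward(enc$forward(x))), c(3, 8, 2))
  }
  # sparse decoder has one conv (+ projection), encoder two convs (+ proj)
  n_convs <- function(b) sum(vapply(b$leaves, function(l)
    "W" %in% names(l$params) && length(dim(l$params$W)) == 3, logical(1)))
  expect_equal(n_convs(ppgbp:::unet_block(4L, 4L, 3L, "sparse_residual", "encoder")), 2L)
  expect_equal(n_convs(ppgbp:::unet_block(4L, 4L, 3L, "sparse_residual", "decoder")), 1L)
})

test_that("configuration invariants are enforced at build time", {
  expect_error(unet_config(input_len = 1000), "divisible")
  expect_error(unet_config(supervision_weights = c(1, 0.9)), "depth \\+ 1")
  expect_error(unet_config(base_channels = 12L, se_reduction = 8L), "divide")
  expect_silent(unet_config(base_channels = 12L, skip_type = "plain",
                            se_reduction = 8L))
})

test_that("the model forward maps a batch to main plus four auxiliary outputs", {
  cfg <- unet_config(base_channels = 8L)
  net <- build_unet1d(cfg, seed = 1)
  X <- matrix(rnorm(2 * 1024), 2)
  out <- net$forward(X, train = FALSE)
  expect_equal(dim(out$main), c(2L, 1024L))
  expect_length(out$aux, 4L)
  for (a in out$aux) expect_equal(dim(a), c(2L, 1024L))
  expect_true(all(is.finite(out$main)))
  # same config and seed: identical parameters and outputs
  net2 <- build_unet1d(cfg, seed = 1)
  out2 <- net2$forward(X, train = FALSE)
  expect_identical(out$main, out2$main)
  net3 <- build_unet1d(cfg, seed = 2)
  expect_false(identical(net3$forward(X, FALSE)$main, out$main))
})

test_that("the seven ablation variants assemble the advertised modules", {
  grid <- ablation_grid()
  expect_equal(nrow(grid), 7L)
  inventories <- character(7)
  X <- matrix(rnorm(2 * 256), 2)
  for (i in seq_len(7)) {
    cfg <- unet_config(base_channels = 8L, input_len = 256L,
                       block_type = grid$block_type[i],
                       skip_type = grid$skip_type[i])
    net <- build_unet1d(cfg, seed = 3)
    out <- net$forward(X, train = FALSE)
    expect_true(all(is.finite(out$main)), info = grid$variant[i])
    # attention inventory matches the skip type
    has_se <- any(vapply(net$attn, function(a) "W1" %in% names(a$params),
                         logical(1)))
    has_gru <- any(vapply(net$attn, function(a) "W_r" %in% names(a$params),
                          logical(1)))
    expect_equal(has_se, grid$skip_type[i] == "se")
    expect_equal(has_gru, grid$skip_type[i] == "se_gru")
    n_par <- sum(vapply(net$leaves, function(l) sum(lengths(l$params)),
                        numeric(1)))
    inventories[i] <- paste(grid$block_type[i], grid$skip_type[i], n_par)
  }
  expect_equal(anyDuplicated(inventories), 0L)     # 7 distinct architectures
})

test_that("the deeply supervised loss is the advertised weighted MAE sum", {
  # equal per-head MAE m gives 4 m under the default weights
  y <- matrix(0, 2, 8)
  m_val <- 0.37
  outputs <- list(main = y + m_val,
                  aux = replicate(4, y + m_val, simplify = FALSE))
  expect_equal(deep_supervision_loss(outputs, y), 4 * m_val)
  # only the main head weighted: plain MAE
  expect_equal(deep_supervision_loss(outputs, y, c(1, 0, 0, 0, 0)),
               mean(abs(outputs$main - y)))
  # random case against an independently composed weighted sum
  set.seed(44)
  outputs <- list(main = matrix(rnorm(16), 2),
                  aux = replicate(4, matrix(rnorm(16), 2), simplify = FALSE))
  y <- matrix(rnorm(16), 2)
  w <- c(1, 0.9, 0.8, 0.7, 0.6)
  oracle <- w[1] * mean(abs(outputs$main - y)) +
    sum(sapply(1:4, function(j) w[j + 1] * mean(abs(outputs$aux[[j]] - y))))
  expect_equal(deep_supervision_loss(outputs, y, w), oracle, tolerance = 1e-7)
  expect_error(deep_supervision_loss(outputs, y, c(1, 0.9)), "one weight")
})
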