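# a small configuration used where full width is unnecessary
tiny_config <- function(...) {
  base <- list(image_size = 8, conv_channels = c(4, 8), embed_dim = 8,
               num_heads = 2, head_key_dim = 4, mlp_dense_layers = 1,
               seed = 3)
  do.call(cct_config, utils::modifyList(base, list(...)))
}

test_that("parameter counts reproduce the closed form and the enumeration oracle", {
  # params(k) = 8384 k^2 + 150022 for the final one-block family
  for (k in 1:4)
    expect_identical(count_parameters(cct_config(conv_kernel = k)),
                     as.integer(8384 * k^2 + 150022))

  # each extra MLP dense layer adds exactly 16512 parameters
  p <- vapply(1:3, function(l)
    count_parameters(cct_config(conv_kernel = 4, mlp_dense_layers = l)),
    integer(1))
  expect_equal(diff(p), c(16512L, 16512L))

  # count_parameters equals a per-tensor enumeration of the instantiated
  # network across the ablation grid
  grid <- expand.grid(k = c(1, 3, 4), mlp = c(1, 3), blocks = c(1, 2),
                      pos = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    cfg <- cct_config(conv_kernel = grid$k[i], mlp_dense_layers = grid$mlp[i],
                      num_encoder_blocks = grid$blocks[i],
                      positional_embedding = grid$pos[i])
    expect_identical(length(unlist(cct_init(cfg))), count_parameters(cfg))
  }

  # image size does not change the count without positional embeddings
  for (s in c(16, 24, 28, 32))
    expect_identical(count_parameters(cct_config(image_size = s)), 225478L)
  expect_false(count_parameters(cct_config(positional_embedding = TRUE,
                                           image_size = 16)) ==
               count_parameters(cct_config(positional_embedding = TRUE,
                                           image_size = 32)))
})

test_that("configuration invariants are enforced", {
  expect_error(cct_config(conv_channels = c(64, 64)), "embed_dim")
  expect_equal(token_count(cct_config(image_size = 16)), 16L)
  expect_equal(token_count(cct_config(image_size = 32)), 64L)
  expect_equal(token_count(cct_config(), image_size = 24), 36L)
})

test_that("tokenization yields the expected sequence shapes", {
  cfg <- cct_config()
  w <- cct_init(cfg)
  img16 <- array(runif(16 * 16 * 3), c(16, 16, 3))
  seq16 <- tokenize(img16, w, cfg)
  expect_equal(dim(seq16), c(16L, 128L))
  img32 <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(dim(tokenize(img32, w, cfg)), c(64L, 128L))

  # zero input with a bias-free tokenizer gives all-zero tokens
  expect_true(all(tokenize(array(0, c(16, 16, 3)), w, cfg) == 0))

  expect_error(tokenize(array(0.5, c(3, 3, 3)), w, cfg), "smaller")
})

test_that("encoder blocks preserve shape and are permutation-equivariant", {
  cfg <- tiny_config()
  w <- cct_init(cfg)
  set.seed(10)
  seq <- matrix(rnorm(7 * 8), 7, 8)
  out <- encoder_block(seq, w, cfg)
  expect_equal(dim(out), dim(seq))

  perm <- sample(7)
  out_p <- encoder_block(seq[perm, ], w, cfg)
  expect_equal(out_p, out[perm, ], tolerance = 1e-10)

  # stochastic depth rate 1 drops both residual branches
  cfg1 <- tiny_config(stochastic_depth_rate = 1)
  w1 <- cct_init(cfg1)
  set.seed(1)
  expect_equal(encoder_block(seq, w1, cfg1, train = TRUE), seq)
})

test_that("sequence pooling is a softmax-weighted token average", {
  set.seed(4)
  v <- rnorm(6)
  same <- matrix(rep(v, each = 5), 5, 6)
  sp <- sequence_pool(same, w = rnorm(6), b = 0.3)
  expect_equal(sp$embedding, v, tolerance = 1e-12)
  expect_equal(sum(sp$weights), 1, tolerance = 1e-12)

  single <- matrix(rnorm(6), 1, 6)
  expect_equal(sequence_pool(single, w = rnorm(6))$embedding,
               as.vector(single))

  # logits (ln 3, 0) give weights (0.75, 0.25)
  tok <- matrix(c(log(3), 0, 5, 7), 2, 2)
  sp2 <- sequence_pool(tok, w = c(1, 0))
  expect_equal(sp2$weights, c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(sp2$embedding, 0.75 * tok[1, ] + 0.25 * tok[2, ],
               tolerance = 1e-12)

  expect_error(sequence_pool(matrix(0, 0, 6), w = rnorm(6)), "empty")
})

test_that("the forward pass emits normalized, deterministic probabilities", {
  cfg <- cct_config()
  w <- cct_init(cfg)
  set.seed(11)
  x <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  p <- cct_forward(x, w, cfg)
  expect_equal(dim(p), c(4L, 5L))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)

  # duplicated sample in one batch produces identical rows
  x2 <- x; x2[, , , 2] <- x[, , , 1]
  p2 <- cct_forward(x2, w, cfg)
  expect_equal(p2[1, ], p2[2, ], tolerance = 1e-12)

  # the same weights accept 16x16 and 32x32 inputs
  x32 <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  p32 <- cct_forward(x32, w, cfg)
  expect_equal(rowSums(p32), rep(1, 2), tolerance = 1e-6)

  # moving pixels changes the output: no accidental global pooling
  xa <- array(0, c(16, 16, 3)); xa[2, 2, ] <- 1
  xb <- array(0, c(16, 16, 3)); xb[14, 9, ] <- 1
  expect_gt(max(abs(cct_forward(xa, w, cfg) - cct_forward(xb, w, cfg))), 1e-8)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_config(mlp_dense_layers = 2)
  w <- cct_init(cfg)
  set.seed(1)
  x <- array(runif(8 * 8 * 3 * 3), c(8, 8, 3, 3))
  y <- matrix(0, 3, 5); y[cbind(1:3, c(1, 3, 5))] <- 1
  sk <- unclass(w); th <- unlist(sk)
  gs <- drcctnet:::cct_grad_step(x, y, w, cfg, "categorical_ce", train = FALSE)
  gv <- unlist(drcctnet:::align_tree(gs$grad, sk))
  lossat <- function(t) {
    ww <- drcctnet:::relist_params(t, sk)
    f <- drcctnet:::cct_fwd_full(x, ww, cfg, train = FALSE, want_cache = FALSE)
    drcctnet:::loss_and_dlogits(f$probs, y, "categorical_ce")$loss
  }
  set.seed(2)
  idx <- sample(length(th), 15)
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    tp <- th; tp[i] <- tp[i] + eps
    tm <- th; tm[i] <- tm[i] - eps
    (lossat(tp) - lossat(tm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - gv[idx])), 1e-6)
})
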