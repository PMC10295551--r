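# Compact convolutional transformer: weight initialization, forward pass and
# hand-written reverse-mode gradients. Tensors use channels-last layout
# (H, W, C, B); token matrices are (n*B) x d with rows grouped by sample and
# tokens ordered row-major over the spatial map.

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

# Glorot-scaled truncated normal: sd = sqrt(2 / (fan_in + fan_out))
glorot <- function(fan_in, fan_out, n = fan_in * fan_out) {
  trunc_normal(n, sqrt(2 / (fan_in + fan_out)))
}

#' Initialize trainable weights for a configuration
#'
#' Dense and convolution kernels draw from a Glorot-scaled truncated
#' normal (sd `sqrt(2 / (fan_in + fan_out))`, clipped at two standard
#' deviations); layer-norm scales start at one, all shifts and biases at
#' zero; positional embeddings (when enabled) use sd 0.02. Deterministic
#' given the seed.
#'
#' @param cfg A [cct_config()].
#' @param seed Initialization seed (defaults to `cfg$seed`).
#' @return A nested list of weight arrays of class `cct_weights`.
#' @export
cct_init <- function(cfg, seed = cfg$seed) {
  d <- cfg$embed_dim; w <- cfg$num_heads * cfg$head_key_dim
  with_seed(seed, {
    k <- cfg$conv_kernel
    cins <- c(3L, cfg$conv_channels[-length(cfg$conv_channels)])
    conv <- Map(function(cin, cout) {
      st <- list(W = array(glorot(k * k * cin, k * k * cout, k * k * cin * cout),
                           c(k, k, cin, cout)))
      if (cfg$conv_bias) st$b <- numeric(cout)
      st
    }, cins, cfg$conv_channels)
    blocks <- lapply(seq_len(cfg$num_encoder_blocks), function(i) list(
      ln1 = list(g = rep(1, d), b = numeric(d)),
      attn = list(Wq = matrix(glorot(d, w), d, w), bq = numeric(w),
                  Wk = matrix(glorot(d, w), d, w), bk = numeric(w),
                  Wv = matrix(glorot(d, w), d, w), bv = numeric(w),
                  Wo = matrix(glorot(w, d), w, d), bo = numeric(d)),
      ln2 = list(g = rep(1, d), b = numeric(d)),
      mlp = lapply(seq_len(cfg$mlp_dense_layers), function(j)
        list(W = matrix(glorot(d, d), d, d), b = numeric(d)))
    ))
    weights <- list(conv = conv, blocks = blocks,
                    ln_f = list(g = rep(1, d), b = numeric(d)),
                    pool = list(w = glorot(d, 1L, d), b = 0),
                    head = list(W = matrix(glorot(d, cfg$num_classes), d,
                                           cfg$num_classes),
                                b = numeric(cfg$num_classes)))
    if (cfg$positional_embedding)
      weights$pos <- matrix(trunc_normal(token_count(cfg) * d),
                            token_count(cfg), d)
    structure(weights, class = "cct_weights")
  })
}

# --- basic layers ---------------------------------------------------------

same_pad <- function(size, k, stride) {
  out <- as.integer(ceiling(size / stride))
  total <- max(0L, (out - 1L) * stride + k - size)
  # indices: [1] output size, [2] leading pad, [3] total pad
  unname(c(out, total %/% 2L, total))
}

pad_spatial <- function(x, pr, pc, fill = 0) {
  d <- dim(x)
  if (pr[3] == 0 && pc[3] == 0) return(x)
  xp <- array(fill, c(d[1] + pr[3], d[2] + pc[3], d[3], d[4]))
  xp[pr[2] + seq_len(d[1]), pc[2] + seq_len(d[2]), , ] <- x
  xp
}

conv2d_fwd <- function(x, st, stride) {
  d <- dim(x); k <- dim(st$W)[1]
  cin <- dim(st$W)[3]; cout <- dim(st$W)[4]
  pr <- same_pad(d[1], k, stride); pc <- same_pad(d[2], k, stride)
  Ho <- pr[1]; Wo <- pc[1]
  xp4 <- aperm(pad_spatial(x, pr, pc), c(1, 2, 4, 3))  # (Hp, Wp, B, Cin)
  B <- d[4]
  out_mat <- matrix(0, Ho * Wo * B, cout)
  for (a in seq_len(k)) {
    ri <- seq(a, by = stride, length.out = Ho)
    for (b2 in seq_len(k)) {
      ci <- seq(b2, by = stride, length.out = Wo)
      sm <- xp4[ri, ci, , , drop = FALSE]
      dim(sm) <- c(Ho * Wo * B, cin)
      out_mat <- out_mat + sm %*% matrix(st$W[a, b2, , ], cin, cout)
    }
  }
  if (!is.null(st$b)) out_mat <- out_mat + rep(st$b, each = Ho * Wo * B)
  out <- aperm(array(out_mat, c(Ho, Wo, B, cout)), c(1, 2, 4, 3))
  list(out = out, cache = list(xp4 = xp4, pr = pr, pc = pc, stride = stride,
                               k = k, in_dim = d))
}

conv2d_bwd <- function(dout, st, cache) {
  k <- cache$k; stride <- cache$stride
  xp4 <- cache$xp4
  Ho <- dim(dout)[1]; Wo <- dim(dout)[2]; cout <- dim(dout)[3]; B <- dim(dout)[4]
  cin <- dim(st$W)[3]
  dout_mat <- aperm(dout, c(1, 2, 4, 3))
  dim(dout_mat) <- c(Ho * Wo * B, cout)
  dW <- array(0, dim(st$W))
  dxp4 <- array(0, dim(xp4))
  for (a in seq_len(k)) {
    ri <- seq(a, by = stride, length.out = Ho)
    for (b2 in seq_len(k)) {
      ci <- seq(b2, by = stride, length.out = Wo)
      sm <- xp4[ri, ci, , , drop = FALSE]
      dim(sm) <- c(Ho * Wo * B, cin)
      dW[a, b2, , ] <- crossprod(sm, dout_mat)
      dsm <- dout_mat %*% t(matrix(st$W[a, b2, , ], cin, cout))
      dxp4[ri, ci, , ] <- dxp4[ri, ci, , , drop = FALSE] +
        array(dsm, c(Ho, Wo, B, cin))
    }
  }
  d <- cache$in_dim
  dx <- aperm(dxp4, c(1, 2, 4, 3))[cache$pr[2] + seq_len(d[1]),
                                   cache$pc[2] + seq_len(d[2]), , ,
                                   drop = FALSE]
  g <- list(W = dW)
  if (!is.null(st$b)) g$b <- colSums(dout_mat)
  list(dx = dx, grad = g)
}

maxpool_fwd <- function(x, k, stride, want_idx = TRUE) {
  d <- dim(x)
  pr <- same_pad(d[1], k, stride); pc <- same_pad(d[2], k, stride)
  Ho <- pr[1]; Wo <- pc[1]
  xp <- pad_spatial(x, pr, pc, fill = -Inf)
  nout <- Ho * Wo * d[3] * d[4]
  if (want_idx) {
    M <- matrix(0, nout, k * k)
    o <- 0L
    for (b2 in seq_len(k)) {
      ci <- seq(b2, by = stride, length.out = Wo)
      for (a in seq_len(k)) {
        o <- o + 1L
        M[, o] <- xp[seq(a, by = stride, length.out = Ho), ci, , ]
      }
    }
    idx <- max.col(M, ties.method = "first")
    val <- M[cbind(seq_len(nout), idx)]
    out <- array(val, c(Ho, Wo, d[3], d[4]))
    list(out = out, cache = list(idx = idx, k = k, stride = stride,
                                 dim_xp = dim(xp), pr = pr, pc = pc,
                                 in_dim = d))
  } else {
    out <- array(-Inf, c(Ho, Wo, d[3], d[4]))
    for (a in seq_len(k)) {
      ri <- seq(a, by = stride, length.out = Ho)
      for (b2 in seq_len(k)) {
        ci <- seq(b2, by = stride, length.out = Wo)
        out <- pmax(out, xp[ri, ci, , , drop = FALSE])
      }
    }
    list(out = out, cache = NULL)
  }
}

maxpool_bwd <- function(dout, cache) {
  k <- cache$k; stride <- cache$stride
  Ho <- dim(dout)[1]; Wo <- dim(dout)[2]; C <- dim(dout)[3]; B <- dim(dout)[4]
  Hp <- cache$dim_xp[1]; Wp <- cache$dim_xp[2]
  dval <- as.vector(dout)
  dxp <- numeric(prod(cache$dim_xp))
  cb <- rep((0:(C * B - 1)) * (Hp * Wp), each = Ho * Wo)
  o <- 0L
  for (b2 in seq_len(k)) {
    ci <- seq(b2, by = stride, length.out = Wo)
    colpart <- rep((ci - 1) * Hp, each = Ho)
    for (a in seq_len(k)) {
      o <- o + 1L
      ri <- seq(a, by = stride, length.out = Ho)
      lin <- rep(ri, times = Wo) + colpart
      lin_full <- rep(lin, times = C * B) + cb
      sel <- cache$idx == o
      if (any(sel)) dxp[lin_full[sel]] <- dxp[lin_full[sel]] + dval[sel]
    }
  }
  dxp <- array(dxp, cache$dim_xp)
  d <- cache$in_dim
  dxp[cache$pr[2] + seq_len(d[1]), cache$pc[2] + seq_len(d[2]), , ,
      drop = FALSE]
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  out <- xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X))
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dout, cache) {
  R <- nrow(dout)
  xhat <- cache$xhat
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- dout * rep(cache$g, each = R)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, g = dg, b = db)
}

activation_fwd <- function(x, kind) {
  switch(kind,
    relu = pmax(x, 0),
    tanh = tanh(x),
    elu = ifelse(x > 0, x, expm1(x)),
    softsign = x / (1 + abs(x)),
    softplus = log1p(exp(-abs(x))) + pmax(x, 0),
    gelu = 0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
  )
}

activation_grad <- function(x, y, kind) {
  switch(kind,
    relu = (x > 0) * 1,
    tanh = 1 - y^2,
    elu = ifelse(x > 0, 1, exp(x)),
    softsign = 1 / (1 + abs(x))^2,
    softplus = 1 / (1 + exp(-x)),
    gelu = {
      u <- sqrt(2 / pi) * (x + 0.044715 * x^3)
      t <- tanh(u)
      0.5 * (1 + t) + 0.5 * x * (1 - t^2) * sqrt(2 / pi) * (1 + 3 * 0.044715 * x^2)
    }
  )
}

attention_fwd <- function(X, aw, n, B, heads, dk) {
  Q <- X %*% aw$Wq + rep(aw$bq, each = nrow(X))
  K <- X %*% aw$Wk + rep(aw$bk, each = nrow(X))
  V <- X %*% aw$Wv + rep(aw$bv, each = nrow(X))
  scale <- 1 / sqrt(dk)
  O <- matrix(0, nrow(X), heads * dk)
  A_all <- array(0, c(n, n, heads, B))
  for (bi in seq_len(B)) {
    rows <- ((bi - 1) * n + 1):(bi * n)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) * scale
      S <- exp(S - apply(S, 1, max))
      A <- S / rowSums(S)
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      A_all[, , h, bi] <- A
    }
  }
  out <- O %*% aw$Wo + rep(aw$bo, each = nrow(X))
  list(out = out,
       cache = list(Q = Q, K = K, V = V, O = O, A = A_all, X = X,
                    n = n, B = B, heads = heads, dk = dk, scale = scale))
}

attention_bwd <- function(dout, aw, cache) {
  n <- cache$n; B <- cache$B; heads <- cache$heads; dk <- cache$dk
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(aw$Wo)
  dQ <- matrix(0, nrow(dout), heads * dk)
  dK <- dQ; dV <- dQ
  for (bi in seq_len(B)) {
    rows <- ((bi - 1) * n + 1):(bi * n)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      A <- cache$A[, , h, bi]
      dOh <- dO[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[rows, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(A * dA)) * cache$scale
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE]
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE])
    }
  }
  X <- cache$X
  list(dx = dQ %*% t(aw$Wq) + dK %*% t(aw$Wk) + dV %*% t(aw$Wv),
       grad = list(Wq = crossprod(X, dQ), bq = colSums(dQ),
                   Wk = crossprod(X, dK), bk = colSums(dK),
                   Wv = crossprod(X, dV), bv = colSums(dV),
                   Wo = dWo, bo = dbo))
}

seqpool_fwd <- function(X, w, b, n, B) {
  logits <- as.vector(X %*% w) + b
  L <- matrix(logits, n, B)
  E <- exp(sweep(L, 2, apply(L, 2, max)))
  a <- as.vector(sweep(E, 2, colSums(E), "/"))
  emb <- rowsum(X * a, group = rep(seq_len(B), each = n), reorder = FALSE)
  rownames(emb) <- NULL
  list(out = emb, cache = list(a = a, X = X, n = n, B = B))
}

seqpool_bwd <- function(demb, w, cache) {
  n <- cache$n; B <- cache$B
  rep_idx <- rep(seq_len(B), each = n)
  dX <- demb[rep_idx, , drop = FALSE] * cache$a
  da <- rowSums(cache$X * demb[rep_idx, , drop = FALSE])
  amat <- matrix(cache$a, n, B)
  damat <- matrix(da, n, B)
  dlog <- as.vector(amat * sweep(damat, 2, colSums(amat * damat)))
  dX <- dX + outer(dlog, w)
  list(dx = dX, w = colSums(cache$X * dlog), b = sum(dlog))
}

# --- composed model -------------------------------------------------------

# flatten a spatial map (h, w, d, B) into the (n*B) x d token matrix with
# row-major token order
flatten_tokens <- function(x) {
  d <- dim(x)
  xa <- aperm(x, c(2, 1, 3, 4))          # (w, h, d, B)
  dim(xa) <- c(d[1] * d[2], d[3], d[4])  # (n, d, B), token row-major
  xb <- aperm(xa, c(1, 3, 2))            # (n, B, d)
  dim(xb) <- c(d[1] * d[2] * d[4], d[3])
  xb
}

unflatten_tokens <- function(X, h, w, B) {
  d <- ncol(X)
  xb <- array(X, c(w * h, B, d))
  xa <- aperm(xb, c(1, 3, 2))
  dim(xa) <- c(w, h, d, B)
  aperm(xa, c(2, 1, 3, 4))
}

#' Convolutional tokenization
#'
#' Runs the tokenizer stages (convolution, ReLU, max-pool, same padding)
#' and flattens the resulting spatial map row-major into a token sequence.
#' No positional embedding is added unless the configuration enables one.
#'
#' @param images An `(H, W, 3, B)` array of inputs scaled to \[0, 1\] (a
#'   single `(H, W, 3)` image is promoted to a batch of one).
#' @param weights A [cct_init()] weight set.
#' @param cfg The matching [cct_config()].
#' @return For a single image an `n x d` token matrix; for a batch an
#'   `(n, d, B)` array.
#' @export
tokenize <- function(images, weights, cfg) {
  x <- prep_batch(images)
  if (dim(x)[1] < 4 || dim(x)[2] < 4) stop("image smaller than 4x4", call. = FALSE)
  B <- dim(x)[4]
  f <- tokenizer_fwd(x, weights, cfg, want_idx = FALSE)
  n <- nrow(f$X) / B
  if (B == 1L) return(f$X)
  out <- array(0, c(n, ncol(f$X), B))
  for (bi in seq_len(B)) out[, , bi] <- f$X[((bi - 1) * n + 1):(bi * n), ]
  out
}

prep_batch <- function(images) {
  if (is.list(images)) {
    images <- simplify2array(images)  # (H, W, 3, B)
  }
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  stopifnot(length(dim(images)) == 4L, dim(images)[3] == 3L)
  images
}

tokenizer_fwd <- function(x, weights, cfg, want_idx = TRUE) {
  caches <- list()
  for (i in seq_along(weights$conv)) {
    cv <- conv2d_fwd(x, weights$conv[[i]], cfg$conv_stride)
    r <- pmax(cv$out, 0)
    mp <- maxpool_fwd(r, cfg$pool_kernel, cfg$pool_stride, want_idx = want_idx)
    caches[[i]] <- list(conv = cv$cache, relu = cv$out, pool = mp$cache,
                        pool_in_dim = dim(r))
    x <- mp$out
  }
  X <- flatten_tokens(x)
  if (cfg$positional_embedding) {
    n <- dim(x)[1] * dim(x)[2]
    if (n != nrow(weights$pos))
      stop("positional embedding size does not match token count", call. = FALSE)
    X <- X + weights$pos[rep(seq_len(n), dim(x)[4]), , drop = FALSE]
  }
  list(X = X, h = dim(x)[1], w = dim(x)[2], caches = caches)
}

#' One transformer encoder block
#'
#' Pre-norm residual block: `x1 = x + SD(MHA(LN(x)))`, then
#' `out = x1 + SD(MLP(LN(x1)))`, where SD is stochastic depth (identity in
#' evaluation mode) and the MLP is the configured stack of dense +
#' activation + dropout layers. Shape-preserving.
#'
#' @param seq An `n x d` token matrix (single sample).
#' @param weights A [cct_init()] weight set.
#' @param cfg The matching [cct_config()].
#' @param block Which encoder block's weights to use (default 1).
#' @param train Training mode: applies stochastic depth and dropout using
#'   the current RNG stream.
#' @return An `n x d` token matrix.
#' @export
encoder_block <- function(seq, weights, cfg, block = 1, train = FALSE) {
  stopifnot(is.matrix(seq), ncol(seq) == cfg$embed_dim)
  encoder_fwd(seq, weights$blocks[[block]], cfg, n = nrow(seq), B = 1L,
              train = train)$out
}

# stochastic-depth per-sample keep factors, expanded to token rows
sd_factors <- function(rate, n, B, train) {
  if (!train || rate <= 0) return(rep(1, n * B))
  keep <- stats::runif(B) >= rate
  if (rate >= 1) return(rep(0, n * B))
  rep(ifelse(keep, 1 / (1 - rate), 0), each = n)
}

encoder_fwd <- function(X, bw, cfg, n, B, train) {
  cache <- list()
  ln1 <- layernorm_fwd(X, bw$ln1$g, bw$ln1$b)
  at <- attention_fwd(ln1$out, bw$attn, n, B, cfg$num_heads, cfg$head_key_dim)
  f1 <- sd_factors(cfg$stochastic_depth_rate, n, B, train)
  X1 <- X + at$out * f1
  ln2 <- layernorm_fwd(X1, bw$ln2$g, bw$ln2$b)
  h <- ln2$out
  mlp_cache <- list()
  for (j in seq_along(bw$mlp)) {
    z <- h %*% bw$mlp[[j]]$W + rep(bw$mlp[[j]]$b, each = nrow(h))
    act <- activation_fwd(z, cfg$mlp_activation)
    drop_mask <- if (train && cfg$dropout_rate > 0)
      (matrix(stats::runif(length(z)), nrow(z)) >= cfg$dropout_rate) /
        (1 - cfg$dropout_rate) else NULL
    out_j <- if (is.null(drop_mask)) act else act * drop_mask
    mlp_cache[[j]] <- list(h_in = h, z = z, act = act, drop = drop_mask)
    h <- out_j
  }
  f2 <- sd_factors(cfg$stochastic_depth_rate, n, B, train)
  out <- X1 + h * f2
  list(out = out, cache = list(ln1 = ln1$cache, at = at$cache, f1 = f1,
                               X1 = X1, ln2 = ln2$cache, mlp = mlp_cache,
                               f2 = f2, mlp_out = h))
}

encoder_bwd <- function(dout, bw, cfg, cache) {
  g <- list(mlp = vector("list", length(bw$mlp)))
  dh <- dout * cache$f2
  dX1 <- dout
  for (j in rev(seq_along(bw$mlp))) {
    mc <- cache$mlp[[j]]
    if (!is.null(mc$drop)) dh <- dh * mc$drop
    dz <- dh * activation_grad(mc$z, mc$act, cfg$mlp_activation)
    g$mlp[[j]] <- list(W = crossprod(mc$h_in, dz), b = colSums(dz))
    dh <- dz %*% t(bw$mlp[[j]]$W)
  }
  ln2b <- layernorm_bwd(dh, cache$ln2)
  g$ln2 <- list(g = ln2b$g, b = ln2b$b)
  dX1 <- dX1 + ln2b$dx
  datt <- dX1 * cache$f1
  ab <- attention_bwd(datt, bw$attn, cache$at)
  g$attn <- ab$grad
  ln1b <- layernorm_bwd(ab$dx, cache$ln1)
  g$ln1 <- list(g = ln1b$g, b = ln1b$b)
  list(dx = dX1 + ln1b$dx, grad = g)
}

#' Sequence pooling
#'
#' Attention-style pooling replacing a class token: a learnable scorer maps
#' each token to a logit, a per-sample softmax turns the logits into
#' non-negative weights summing to one, and the pooled embedding is the
#' weighted sum of the tokens.
#'
#' @param seq An `n x d` token matrix (one sample).
#' @param w Length-d scorer weight vector.
#' @param b Scorer bias scalar (default 0).
#' @return A list with `embedding` (length-d vector) and `weights`
#'   (length-n attention probabilities).
#' @export
sequence_pool <- function(seq, w, b = 0) {
  if (!is.matrix(seq) || nrow(seq) == 0)
    stop("sequence must be a non-empty n x d matrix", call. = FALSE)
  sp <- seqpool_fwd(seq, w, b, n = nrow(seq), B = 1L)
  list(embedding = as.vector(sp$out), weights = sp$cache$a)
}

#' Full forward pass of the classifier
#'
#' Composes tokenization, the encoder blocks, the final layer norm,
#' sequence pooling, and the linear classification head with softmax.
#'
#' @param images `(H, W, 3, B)` array (or single image / list of images)
#'   scaled to \[0, 1\].
#' @param weights A [cct_init()] weight set.
#' @param cfg The matching [cct_config()].
#' @param train Training mode (stochastic depth and dropout active; the
#'   caller is responsible for seeding the RNG).
#' @return A `B x num_classes` matrix of class probabilities (rows sum
#'   to 1).
#' @export
cct_forward <- function(images, weights, cfg, train = FALSE) {
  x <- prep_batch(images)
  cct_fwd_full(x, weights, cfg, train = train, want_cache = FALSE)$probs
}

cct_fwd_full <- function(x, weights, cfg, train, want_cache) {
  if (dim(x)[1] < 4 || dim(x)[2] < 4) stop("image smaller than 4x4", call. = FALSE)
  B <- dim(x)[4]
  tok <- tokenizer_fwd(x, weights, cfg, want_idx = want_cache)
  X <- tok$X
  n <- tok$h * tok$w
  bcaches <- vector("list", length(weights$blocks))
  for (i in seq_along(weights$blocks)) {
    ef <- encoder_fwd(X, weights$blocks[[i]], cfg, n, B, train)
    bcaches[[i]] <- ef$cache
    X <- ef$out
  }
  lnf <- layernorm_fwd(X, weights$ln_f$g, weights$ln_f$b)
  sp <- seqpool_fwd(lnf$out, weights$pool$w, weights$pool$b, n, B)
  logits <- sp$out %*% weights$head$W + rep(weights$head$b, each = B)
  probs <- exp(logits - apply(logits, 1, max))
  probs <- probs / rowSums(probs)
  res <- list(probs = probs)
  if (want_cache)
    res$cache <- list(tok = tok, blocks = bcaches, lnf = lnf$cache, sp = sp,
                      emb = sp$out, n = n, B = B)
  res
}

# loss value and gradient w.r.t. the pre-softmax logits
loss_and_dlogits <- function(probs, y_onehot, loss) {
  B <- nrow(probs); C <- ncol(probs)
  eps <- 1e-12
  if (loss == "categorical_ce") {
    L <- -mean(rowSums(y_onehot * log(probs + eps)))
    dlogits <- (probs - y_onehot) / B
    return(list(loss = L, dlogits = dlogits))
  }
  dp <- switch(loss,
    mse = {
      Lv <- mean((probs - y_onehot)^2)
      attr(Lv, "dp") <- 2 * (probs - y_onehot) / (B * C); Lv
    },
    mae = {
      Lv <- mean(abs(probs - y_onehot))
      attr(Lv, "dp") <- sign(probs - y_onehot) / (B * C); Lv
    },
    msle = {
      r <- log1p(probs) - log1p(y_onehot)
      Lv <- mean(r^2)
      attr(Lv, "dp") <- 2 * r / ((1 + probs) * B * C); Lv
    },
    binary_ce = {
      p <- pmin(pmax(probs, eps), 1 - eps)
      Lv <- -mean(y_onehot * log(p) + (1 - y_onehot) * log(1 - p))
      attr(Lv, "dp") <- (p - y_onehot) / (p * (1 - p)) / (B * C); Lv
    },
    stop("unknown loss: ", loss, call. = FALSE)
  )
  dpm <- attr(dp, "dp")
  dlogits <- probs * (dpm - rowSums(dpm * probs))
  list(loss = as.numeric(dp), dlogits = dlogits)
}

cct_bwd_full <- function(dlogits, weights, cfg, cache) {
  B <- cache$B; n <- cache$n
  g <- list()
  g$head <- list(W = crossprod(cache$emb, dlogits), b = colSums(dlogits))
  demb <- dlogits %*% t(weights$head$W)
  spb <- seqpool_bwd(demb, weights$pool$w, cache$sp$cache)
  g$pool <- list(w = spb$w, b = spb$b)
  lnfb <- layernorm_bwd(spb$dx, cache$lnf)
  g$ln_f <- list(g = lnfb$g, b = lnfb$b)
  dX <- lnfb$dx
  g$blocks <- vector("list", length(weights$blocks))
  for (i in rev(seq_along(weights$blocks))) {
    eb <- encoder_bwd(dX, weights$blocks[[i]], cfg, cache$blocks[[i]])
    g$blocks[[i]] <- eb$grad
    dX <- eb$dx
  }
  if (cfg$positional_embedding)
    g$pos <- rowsum(dX, group = rep(seq_len(n), B), reorder = FALSE)
  # back through the tokenizer stages
  tok <- cache$tok
  dmap <- unflatten_tokens(dX, tok$h, tok$w, B)
  g$conv <- vector("list", length(weights$conv))
  for (i in rev(seq_along(tok$caches))) {
    tc <- tok$caches[[i]]
    dr <- maxpool_bwd(dmap, tc$pool)
    dr <- dr * (tc$relu > 0)
    cb <- conv2d_bwd(dr, weights$conv[[i]], tc$conv)
    g$conv[[i]] <- cb$grad
    dmap <- cb$dx
  }
  g
}

# training-objective gradient for one minibatch; returns loss, accuracy and
# the weight-structured gradient list
cct_grad_step <- function(x, y_onehot, weights, cfg, loss, train = TRUE) {
  f <- cct_fwd_full(x, weights, cfg, train = train, want_cache = TRUE)
  ld <- loss_and_dlogits(f$probs, y_onehot, loss)
  g <- cct_bwd_full(ld$dlogits, weights, cfg, f$cache)
  pred <- max.col(f$probs, ties.method = "first")
  truth <- max.col(y_onehot, ties.method = "first")
  list(loss = ld$loss, acc = mean(pred == truth), grad = g)
}
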