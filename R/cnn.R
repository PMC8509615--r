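# Minimal convolutional network engine (CPU, base R + BLAS).
#
# Batches are 4D arrays [h, w, channels, n]. Convolutions are 3x3, stride 1,
# zero padding 1 ("same"), implemented by im2col with precomputed indices so
# the inner loop is a single matrix multiplication; max-pooling is 2x2
# stride 2 with first-maximum tie routing (deterministic backward pass).
# All randomness (weight init, batch shuffling) is drawn from the R RNG,
# which callers seed.

im2col_indices <- function(h, w, ch, k = 3L, pad = 1L) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  # linear index into padded array [hp, wp, ch] for kernel offset (di,dj,c)
  # and output position (i,j) (output h x w, stride 1)
  di <- rep(seq_len(k), times = k * ch)
  dj <- rep(rep(seq_len(k), each = k), times = ch)
  dc <- rep(seq_len(ch), each = k * k)
  oi <- rep(seq_len(h), times = w)
  oj <- rep(seq_len(w), each = h)
  # rows: kernel entries; cols: output positions
  ri <- outer(di - 1L, oi, `+`)             # row in padded
  rj <- outer(dj - 1L, oj, `+`)             # col in padded
  idx <- ri + (rj - 1L) * hp + (dc - 1L) * hp * wp
  storage.mode(idx) <- "integer"
  idx
}

pad_batch <- function(x, pad) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

im2col <- function(xp, idx, n) {
  per <- prod(dim(xp)[1:3])
  offs <- (seq_len(n) - 1L) * per
  full <- rep(as.vector(idx), times = n) +
    rep(offs, each = length(idx))
  matrix(xp[full], nrow = nrow(idx))
}

conv_forward <- function(x, W, b, idx) {
  d <- dim(x); n <- d[4]; h <- d[1]; w <- d[2]
  xp <- pad_batch(x, 1L)
  cols <- im2col(xp, idx, n)
  out <- crossprod(W, cols) + b          # co x (h*w*n)
  co <- ncol(W)
  a <- array(out, c(co, h, w, n))
  list(out = aperm(a, c(2, 3, 1, 4)), cols = cols, xp_dim = dim(xp))
}

conv_backward <- function(dout, cache, W, idx) {
  d <- dim(dout); h <- d[1]; w <- d[2]; co <- d[3]; n <- d[4]
  dm <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = co)
  dW <- cache$cols %*% t(dm)
  db <- rowSums(dm)
  dcols <- W %*% dm
  per <- prod(cache$xp_dim[1:3])
  offs <- (seq_len(n) - 1L) * per
  full <- rep(as.vector(idx), times = n) + rep(offs, each = length(idx))
  acc <- rowsum(as.vector(dcols), group = full)
  dxp <- numeric(per * n)
  dxp[as.integer(rownames(acc))] <- acc[, 1]
  dxp <- array(dxp, c(cache$xp_dim[1:3], n))
  hp <- cache$xp_dim[1]; wp <- cache$xp_dim[2]
  list(dx = dxp[2:(hp - 1), 2:(wp - 1), , , drop = FALSE], dW = dW, db = db)
}

maxpool_forward <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]
  o1 <- seq(1, h, 2); o2 <- seq(2, h, 2); p1 <- seq(1, w, 2); p2 <- seq(2, w, 2)
  x11 <- x[o1, p1, , , drop = FALSE]; x12 <- x[o1, p2, , , drop = FALSE]
  x21 <- x[o2, p1, , , drop = FALSE]; x22 <- x[o2, p2, , , drop = FALSE]
  m <- pmax(x11, x12, x21, x22)
  w11 <- x11 == m
  w12 <- (x12 == m) & !w11
  w21 <- (x21 == m) & !w11 & !w12
  w22 <- !(w11 | w12 | w21)
  list(out = m, masks = list(w11, w12, w21, w22), in_dim = d)
}

maxpool_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  o1 <- seq(1, d[1], 2); o2 <- seq(2, d[1], 2)
  p1 <- seq(1, d[2], 2); p2 <- seq(2, d[2], 2)
  dx[o1, p1, , ] <- dout * cache$masks[[1]]
  dx[o1, p2, , ] <- dout * cache$masks[[2]]
  dx[o2, p1, , ] <- dout * cache$masks[[3]]
  dx[o2, p2, , ] <- dout * cache$masks[[4]]
  dx
}

softmax_xent <- function(logits, y) {
  # logits: 2 x n; y: integer 0/1
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  p <- sweep(e, 2, colSums(e), `/`)
  n <- length(y)
  loss <- -mean(log(pmax(p[cbind(y + 1L, seq_len(n))], 1e-12)))
  dlogits <- p
  dlogits[cbind(y + 1L, seq_len(n))] <- dlogits[cbind(y + 1L, seq_len(n))] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

he_init <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

#' @noRd
init_cnn <- function(input_size, architecture = "small_cnn") {
  channels <- switch(architecture,
    small_cnn = c(8L, 16L, 32L),
    googlenet_like = c(16L, 32L, 64L, 128L),
    stop_snap("snap_config", "unknown architecture '%s'", architecture))
  s <- input_size
  if (s %% 2L^length(channels) != 0L)
    stop_snap("snap_config", "input_size must be divisible by %d", 2L^length(channels))
  cin <- 3L
  layers <- list()
  for (li in seq_along(channels)) {
    co <- channels[li]
    layers[[li]] <- list(
      W = he_init(9L * cin, co, 9L * cin), b = numeric(co),
      idx = im2col_indices(s, s, cin), h = s, cin = cin, co = co
    )
    cin <- co; s <- s %/% 2L
  }
  feat <- s * s * cin
  list(conv = layers,
       Wd = he_init(feat, 2L, feat), bd = numeric(2L),
       input_size = input_size, architecture = architecture, feat = feat)
}

cnn_forward <- function(model, x, keep_cache = TRUE) {
  caches <- list()
  for (li in seq_along(model$conv)) {
    L <- model$conv[[li]]
    cv <- conv_forward(x, L$W, L$b, L$idx)
    a <- pmax(cv$out, 0)
    mp <- maxpool_forward(a)
    caches[[li]] <- if (keep_cache) list(conv = cv, relu_in = cv$out, pool = mp) else NULL
    x <- mp$out
  }
  n <- dim(x)[4]
  Fm <- matrix(x, model$feat, n)
  logits <- crossprod(model$Wd, Fm) + model$bd
  list(logits = logits, Fm = Fm, caches = caches, top_dim = dim(x))
}

cnn_backward <- function(model, fwd, dlogits) {
  grads <- list(conv = vector("list", length(model$conv)))
  grads$Wd <- fwd$Fm %*% t(dlogits)
  grads$bd <- rowSums(dlogits)
  dF <- model$Wd %*% dlogits
  dx <- array(dF, fwd$top_dim)
  for (li in rev(seq_along(model$conv))) {
    L <- model$conv[[li]]; C <- fwd$caches[[li]]
    dx <- maxpool_backward(dx, C$pool)
    dx <- dx * (C$relu_in > 0)
    cb <- conv_backward(dx, C$conv, L$W, L$idx)
    grads$conv[[li]] <- list(dW = cb$dW, db = cb$db)
    dx <- cb$dx
  }
  grads
}

adam_init <- function(model) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  st <- list(t = 0L, conv = lapply(model$conv, function(L)
    list(mW = zero_like(L$W), vW = zero_like(L$W),
         mb = zero_like(L$b), vb = zero_like(L$b))),
    mWd = zero_like(model$Wd), vWd = zero_like(model$Wd),
    mbd = zero_like(model$bd), vbd = zero_like(model$bd))
  st
}

adam_update <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adam_step <- function(model, grads, state, lr) {
  state$t <- state$t + 1L; t <- state$t
  for (li in seq_along(model$conv)) {
    u <- adam_update(model$conv[[li]]$W, grads$conv[[li]]$dW,
                     state$conv[[li]]$mW, state$conv[[li]]$vW, lr, t)
    model$conv[[li]]$W <- u$p; state$conv[[li]]$mW <- u$m; state$conv[[li]]$vW <- u$v
    u <- adam_update(model$conv[[li]]$b, grads$conv[[li]]$db,
                     state$conv[[li]]$mb, state$conv[[li]]$vb, lr, t)
    model$conv[[li]]$b <- u$p; state$conv[[li]]$mb <- u$m; state$conv[[li]]$vb <- u$v
  }
  u <- adam_update(model$Wd, grads$Wd, state$mWd, state$vWd, lr, t)
  model$Wd <- u$p; state$mWd <- u$m; state$vWd <- u$v
  u <- adam_update(model$bd, grads$bd, state$mbd, state$vbd, lr, t)
  model$bd <- u$p; state$mbd <- u$m; state$vbd <- u$v
  list(model = model, state = state)
}

# mean cross-entropy + class-1 probabilities over a (possibly large) set,
# evaluated in chunks to bound memory
cnn_evaluate <- function(model, x, y, chunk = 64L) {
  n <- dim(x)[4]
  loss <- 0; probs <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    ix <- start:min(n, start + chunk - 1L)
    fwd <- cnn_forward(model, x[, , , ix, drop = FALSE], keep_cache = FALSE)
    sx <- softmax_xent(fwd$logits, y[ix])
    loss <- loss + sx$loss * length(ix)
    probs[ix] <- sx$probs[2L, ]
  }
  list(loss = loss / n, probs = probs)
}
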