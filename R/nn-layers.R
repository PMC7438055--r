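# Neural-network primitives: all layers carry an analytic backward pass and
# operate on base-R arrays via BLAS matrix products. Shapes:
#   frame batches  [N, H, W, C]   (N = batch * seq_len, sample index fastest)
#   sequences      [B, T, D]
# Forward passes return caches sufficient for the backward passes; gradients
# mirror the parameter structures.

sigmoid <- function(x) 1 / (1 + exp(-x))

swish <- function(x) x * sigmoid(x)

swish_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# ---- 3x3 same-padding convolution (im2col) ---------------------------------

conv_init <- function(c_in, c_out) {
  list(W = glorot(9 * c_in, c_out, c(9 * c_in, c_out)), b = numeric(c_out))
}

# The convolution is computed as one dense x sparse product per layer: with
# the batch flattened to an N x (h*w*c) matrix X (spatial index y fastest,
# then x, channel slowest -- the column-major layout of [N, h, w, c]), the
# output is X %*% K where the sparse operator K[(y', x', ci), (y, x, f)]
# holds kernel weight W[(k-1)*c + ci, f] whenever (y', x') = (y, x) + the
# k-th 3x3 offset lies inside the frame. The sparsity pattern depends only
# on (h, w, c, c_out) and is memoized; K's values are refilled from W on
# every call so training updates take effect.
conv_pattern_memo <- new.env(parent = emptyenv())

conv_pattern <- function(h, w, c, f) {
  key <- paste(h, w, c, f, sep = "x")
  hit <- conv_pattern_memo[[key]]
  if (!is.null(hit)) return(hit)
  # enumerate (y, x, fi, k, ci); k runs over offsets with dx fastest to
  # match conv_init's row blocks (k-1)*c + ci
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  ee <- expand.grid(y = 1:h, x = 1:w, fi = 1:f, k = 1:9, ci = 1:c)
  yy <- ee$y + offs$dy[ee$k]
  xx <- ee$x + offs$dx[ee$k]
  ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
  ee <- ee[ok, ]; yy <- yy[ok]; xx <- xx[ok]
  pat <- list(
    i = yy + h * (xx - 1) + h * w * (ee$ci - 1),
    j = ee$y + h * (ee$x - 1) + h * w * (ee$fi - 1),
    wmap = (ee$k - 1) * c + ee$ci + 9 * c * (ee$fi - 1),
    dims = c(h * w * c, h * w * f))
  conv_pattern_memo[[key]] <- pat
  pat
}

conv_operator <- function(p, h, w) {
  c <- nrow(p$W) / 9L; f <- ncol(p$W)
  pat <- conv_pattern(h, w, c, f)
  Matrix::sparseMatrix(i = pat$i, j = pat$j, x = as.vector(p$W)[pat$wmap],
                       dims = pat$dims)
}

conv_forward <- function(x, p) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]; c <- d[4]
  f <- ncol(p$W)
  K <- conv_operator(p, h, w)
  X <- x; dim(X) <- c(n, h * w * c)
  out <- as.matrix(X %*% K)
  out <- out + rep(p$b, each = n * h * w)  # bias: one value per filter block
  dim(out) <- c(n, h, w, f)
  list(out = out, dim = d, X = X, K = K)
}

conv_backward <- function(dout, cache, p) {
  d <- cache$dim; n <- d[1]; h <- d[2]; w <- d[3]; c <- d[4]
  f <- dim(dout)[4]
  dm <- dout; dim(dm) <- c(n, h * w * f)
  dx <- as.matrix(dm %*% Matrix::t(cache$K))
  dim(dx) <- d
  db <- colSums(matrix(colSums(dm), h * w, f))
  # dW[(k-1)*c + ci, fi] = sum over (n, y, x) of x[n, y+dy, x+dx, ci] *
  # dout[n, y, x, fi]: gather only the in-frame (y, x) columns of the k-th
  # spatial shift, then one small crossprod per offset.
  dW <- matrix(0, 9 * c, f)
  hw <- h * w
  col_y <- rep.int(1:h, w)          # y of each (y, x) column pair
  col_x <- rep.int(1:w, rep.int(h, w))
  k <- 1
  for (dy2 in -1:1) for (dx2 in -1:1) {
    sy <- col_y + dy2; sx <- col_x + dx2
    ok <- which(sy >= 1 & sy <= h & sx >= 1 & sx <= w)
    src <- sy[ok] + h * (sx[ok] - 1)
    m <- length(ok)
    Ar <- cache$X[, rep(src, c) + hw * rep(0:(c - 1), each = m)]
    dim(Ar) <- c(n * m, c)
    Br <- dm[, rep(ok, f) + hw * rep(0:(f - 1), each = m)]
    dim(Br) <- c(n * m, f)
    dW[((k - 1) * c + 1):(k * c), ] <- crossprod(Ar, Br)
    k <- k + 1
  }
  list(dx = dx, grad = list(W = dW, b = db))
}

# ---- 2x2 max pooling --------------------------------------------------------

# Linear indices into an (n, h, w, c) array of the top-left corner of each
# 2x2 pooling window, in output (n, h2, w2, c) column-major order, plus the
# index shifts of the window's four cells.
pool_index_memo <- new.env(parent = emptyenv())

pool_index <- function(n, h, w, c) {
  key <- paste(n, h, w, c, sep = "x")
  hit <- pool_index_memo[[key]]
  if (!is.null(hit)) return(hit)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  hh <- rep(rep.int(seq(0, by = 2, length.out = h2), rep.int(n, h2)),
            times = w2 * c)
  ww <- rep(rep.int(seq(0, by = 2, length.out = w2), rep.int(n * h2, w2)),
            times = c)
  cc <- rep.int(0:(c - 1), rep.int(n * h2 * w2, c))
  base <- rep.int(1:n, h2 * w2 * c) + n * hh + n * h * ww + n * h * w * cc
  res <- list(base = base, offs = c(0L, n, n * h, n + n * h))
  pool_index_memo[[key]] <- res
  res
}

pool_forward <- function(x) {
  d <- dim(x); n <- d[1]; c <- d[4]
  h2 <- d[2] %/% 2L; w2 <- d[3] %/% 2L
  ix <- pool_index(n, d[2], d[3], c)
  xv <- as.vector(x)
  out <- xv[ix$base]
  arg <- rep.int(1L, length(out))
  for (k in 2:4) {
    v <- xv[ix$base + ix$offs[k]]
    gt <- v > out
    out[gt] <- v[gt]
    arg[gt] <- k
  }
  dim(out) <- c(n, h2, w2, c)
  list(out = out, arg = arg, in_dim = d, ix = ix)
}

pool_backward <- function(dout, cache) {
  ix <- cache$ix
  dx <- numeric(prod(cache$in_dim))
  # pooling windows are disjoint, so the scatter has no duplicate targets
  dx[ix$base + ix$offs[cache$arg]] <- as.vector(dout)
  dim(dx) <- cache$in_dim
  dx
}

# ---- temporal soft attention ------------------------------------------------
# score_t = va' tanh(Wa f_t + ba); weights softmax over time; features are
# rescaled by T * alpha_t so an uninformative (uniform) attention is identity.

att_init <- function(d, a) {
  list(Wa = glorot(d, a), ba = numeric(a), va = glorot(a, 1, c(a, 1)))
}

att_forward <- function(feat, p, B, T) {
  h <- tanh(sweep(feat %*% p$Wa, 2, p$ba, `+`))
  e <- h %*% p$va                         # (BT) x 1
  E <- matrix(e, B, T)
  E <- E - apply(E, 1, max)
  A <- exp(E); A <- A / rowSums(A)
  av <- as.vector(A)                      # row order matches feat (b fastest)
  g <- feat * (av * T)
  list(out = g, feat = feat, h = h, alpha = A, av = av, B = B, T = T)
}

att_backward <- function(dg, cache, p) {
  B <- cache$B; T <- cache$T
  dfeat <- dg * (cache$av * T)
  dav <- T * rowSums(dg * cache$feat)
  dA <- matrix(dav, B, T)
  A <- cache$alpha
  dE <- A * (dA - rowSums(dA * A))
  de <- matrix(as.vector(dE), ncol = 1)
  dva <- crossprod(cache$h, de)
  dh <- tcrossprod(de, p$va)              # (BT) x A
  dpre <- dh * (1 - cache$h^2)
  list(dfeat = dfeat + tcrossprod(dpre, p$Wa),
       grad = list(Wa = crossprod(cache$feat, dpre), ba = colSums(dpre),
                   va = dva))
}

# ---- LSTM -------------------------------------------------------------------

lstm_init <- function(d_in, hid) {
  list(Wx = glorot(d_in, 4 * hid, c(d_in, 4 * hid)),
       Wh = glorot(hid, 4 * hid, c(hid, 4 * hid)),
       b = c(numeric(hid), rep(1, hid), numeric(2 * hid)))  # forget bias 1
}

lstm_forward <- function(x, p) {
  d <- dim(x); B <- d[1]; T <- d[2]; D <- d[3]
  hid <- ncol(p$Wh) / 4L
  H <- array(0, dim = c(B, T, hid))
  gates <- array(0, dim = c(B, T, 4 * hid))
  cs <- array(0, dim = c(B, T, hid))
  h <- matrix(0, B, hid); cc <- matrix(0, B, hid)
  idx <- function(k) ((k - 1) * hid + 1):(k * hid)
  for (t in seq_len(T)) {
    xt <- matrix(x[, t, ], B, D)
    z <- xt %*% p$Wx + h %*% p$Wh
    z <- sweep(z, 2, p$b, `+`)
    i <- sigmoid(z[, idx(1), drop = FALSE])
    f <- sigmoid(z[, idx(2), drop = FALSE])
    o <- sigmoid(z[, idx(3), drop = FALSE])
    g <- tanh(z[, idx(4), drop = FALSE])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    gates[, t, ] <- cbind(i, f, o, g)
    cs[, t, ] <- cc
    H[, t, ] <- h
  }
  list(out = H, x = x, gates = gates, cs = cs, hid = hid)
}

lstm_backward <- function(dH, cache, p, dh_last = NULL) {
  x <- cache$x
  d <- dim(x); B <- d[1]; T <- d[2]; D <- d[3]
  hid <- cache$hid
  idx <- function(k) ((k - 1) * hid + 1):(k * hid)
  dWx <- array(0, dim = dim(p$Wx)); dWh <- array(0, dim = dim(p$Wh))
  db <- numeric(length(p$b))
  dx <- array(0, dim = d)
  dh_next <- if (is.null(dh_last)) matrix(0, B, hid) else dh_last
  dc_next <- matrix(0, B, hid)
  for (t in rev(seq_len(T))) {
    dh <- matrix(dH[, t, ], B, hid) + dh_next
    i <- matrix(cache$gates[, t, idx(1)], B, hid)
    f <- matrix(cache$gates[, t, idx(2)], B, hid)
    o <- matrix(cache$gates[, t, idx(3)], B, hid)
    g <- matrix(cache$gates[, t, idx(4)], B, hid)
    cc <- matrix(cache$cs[, t, ], B, hid)
    tc <- tanh(cc)
    c_prev <- if (t > 1) matrix(cache$cs[, t - 1, ], B, hid) else matrix(0, B, hid)
    h_prev <- if (t > 1) matrix(cache$out[, t - 1, ], B, hid) else matrix(0, B, hid)
    do_ <- dh * tc
    dc <- dc_next + dh * o * (1 - tc^2)
    di <- dc * g; df <- dc * c_prev; dg <- dc * i
    dz <- cbind(di * i * (1 - i), df * f * (1 - f),
                do_ * o * (1 - o), dg * (1 - g^2))
    xt <- matrix(x[, t, ], B, D)
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- tcrossprod(dz, p$Wx)
    dh_next <- tcrossprod(dz, p$Wh)
    dc_next <- dc * f
  }
  list(dx = dx, grad = list(Wx = dWx, Wh = dWh, b = db))
}

rev_time <- function(x) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]

bilstm_init <- function(d_in, hid)
  list(fwd = lstm_init(d_in, hid), bwd = lstm_init(d_in, hid))

bilstm_forward <- function(x, p) {
  f <- lstm_forward(x, p$fwd)
  b <- lstm_forward(rev_time(x), p$bwd)
  hid <- f$hid
  B <- dim(x)[1]; T <- dim(x)[2]
  out <- array(0, dim = c(B, T, 2 * hid))
  out[, , 1:hid] <- f$out
  out[, , (hid + 1):(2 * hid)] <- rev_time(b$out)
  list(out = out, f = f, b = b, hid = hid)
}

bilstm_backward <- function(dH, cache, p) {
  hid <- cache$hid
  df <- lstm_backward(dH[, , 1:hid, drop = FALSE], cache$f, p$fwd)
  db <- lstm_backward(rev_time(dH[, , (hid + 1):(2 * hid), drop = FALSE]),
                      cache$b, p$bwd)
  list(dx = df$dx + rev_time(db$dx),
       grad = list(fwd = df$grad, bwd = db$grad))
}

# ---- RMSprop ----------------------------------------------------------------
# Walks the (possibly nested) parameter and gradient structures in lockstep.

rmsprop_update <- function(params, grads, state, lr = 1e-3, rho = 0.9,
                           eps = 1e-7) {
  step <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- if (is.null(s)) vector("list", length(p)) else s
      for (nm in names(p)) {
        r <- step(p[[nm]], g[[nm]], out_s[[nm]])
        out_p[[nm]] <- r$p
        out_s[[nm]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      if (is.null(s)) s <- array(0, dim = dim(p) %||% length(p))
      s <- rho * s + (1 - rho) * g^2
      list(p = p - lr * g / (sqrt(s) + eps), s = s)
    }
  }
  step(params, grads, state)
}

# elementwise sum of two nested gradient structures
grads_add <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grads_add(a[[nm]], b[[nm]])
    a
  } else a + b
}
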