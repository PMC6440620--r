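# Low-level differentiable layer primitives.
#
# Activations are numeric arrays of dimension (H, W, C, N); convolution
# kernels are (kH, kW, Cin, Cout). Every forward returns what its matching
# backward needs in a `cache` list. Convolutions use "same" zero padding of
# floor(k/2) per side with the stride applied on the padded grid, so spatial
# extent is preserved at stride 1 and halved (ceiling) at stride 2.

conv2d_forward <- function(x, w, stride = 1L) {
  .conv2d_forward_cpp(x, w, as.integer(stride))
}

conv2d_backward <- function(x, w, dy, stride = 1L) {
  .conv2d_backward_cpp(x, w, dy, as.integer(stride))
}

# --- batch normalization (per channel over H, W, N) ------------------------

# per-channel totals of an (H, W, C, N) array
channel_sums <- function(x) {
  rowSums(colSums(x, dims = 2L))
}

# recycle a length-C vector over the spatial extent; multiplying/adding the
# result against an (H, W, C, N) array broadcasts it per channel (the
# length-(H*W*C) vector recycles across the batch dimension)
ch_vec <- function(v, d) rep(v, each = d[1] * d[2])

bn_forward <- function(x, gamma, beta, buf, train, momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  if (train) {
    mu <- channel_sums(x) / m
    var <- channel_sums(x * x) / m - mu^2
    var <- pmax(var, 0)
    buf$mean <- momentum * buf$mean + (1 - momentum) * mu
    buf$var <- momentum * buf$var + (1 - momentum) * var
  } else {
    mu <- buf$mean
    var <- buf$var
  }
  invstd <- 1 / sqrt(var + eps)
  xhat <- (x - ch_vec(mu, d)) * ch_vec(invstd, d)
  y <- xhat * ch_vec(gamma, d) + ch_vec(beta, d)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, train = train, m = m),
       buf = buf)
}

bn_backward <- function(dy, cache, gamma) {
  d <- dim(dy)
  dbeta <- channel_sums(dy)
  dgamma <- channel_sums(dy * cache$xhat)
  gi <- ch_vec(gamma * cache$invstd, d)
  if (cache$train) {
    m <- cache$m
    dx <- gi * (dy - ch_vec(dbeta / m, d) -
                  cache$xhat * ch_vec(dgamma / m, d))
  } else {
    dx <- gi * dy
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- simple activations -----------------------------------------------------

relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- 2x2 stride-2 max pooling (used by the large-input stem) ---------------

maxpool2_forward <- function(x) {
  d <- dim(x)
  oh <- d[1] %/% 2L; ow <- d[2] %/% 2L
  i1 <- seq_len(oh) * 2L - 1L; i2 <- i1 + 1L
  j1 <- seq_len(ow) * 2L - 1L; j2 <- j1 + 1L
  cand <- array(0, dim = c(oh, ow, d[3], d[4], 4L))
  cand[, , , , 1] <- x[i1, j1, , , drop = FALSE]
  cand[, , , , 2] <- x[i2, j1, , , drop = FALSE]
  cand[, , , , 3] <- x[i1, j2, , , drop = FALSE]
  cand[, , , , 4] <- x[i2, j2, , , drop = FALSE]
  y <- pmax(cand[, , , , 1], cand[, , , , 2], cand[, , , , 3], cand[, , , , 4])
  list(y = y, cache = list(cand = cand, y = y, d = d))
}

maxpool2_backward <- function(dy, cache) {
  d <- cache$d
  oh <- d[1] %/% 2L; ow <- d[2] %/% 2L
  i1 <- seq_len(oh) * 2L - 1L; i2 <- i1 + 1L
  j1 <- seq_len(ow) * 2L - 1L; j2 <- j1 + 1L
  dx <- array(0, dim = d)
  # route gradient to the (first) arg-max among the four candidates
  taken <- array(FALSE, dim = dim(dy))
  for (k in 1:4) {
    hit <- (cache$cand[, , , , k] == cache$y) & !taken
    taken <- taken | hit
    g <- dy * hit
    if (k == 1) dx[i1, j1, , ] <- dx[i1, j1, , , drop = FALSE] + g
    if (k == 2) dx[i2, j1, , ] <- dx[i2, j1, , , drop = FALSE] + g
    if (k == 3) dx[i1, j2, , ] <- dx[i1, j2, , , drop = FALSE] + g
    if (k == 4) dx[i2, j2, , ] <- dx[i2, j2, , , drop = FALSE] + g
  }
  dx
}

# --- head: global average pool, linear classifier, softmax -----------------

gap_forward <- function(x) {
  d <- dim(x)
  list(y = colSums(x, dims = 2L) / (d[1] * d[2]), d = d)
}

gap_backward <- function(dy, d) {
  array(rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  ez <- exp(z)
  sweep(ez, 2, colSums(ez), "/")
}

# cross-entropy loss and logit gradient; y is an integer class vector (1..K)
softmax_ce <- function(logits, y) {
  p <- softmax_cols(logits)
  n <- ncol(p)
  idx <- cbind(y, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}
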