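# Squeeze-and-excitation residual modules.
#
# A module is: pre-activation convolution branch (BN -> ReLU -> conv,
# repeated), an SE gate on the branch output, channel-wise recalibration,
# and a residual sum with the module input (identity shortcut, or a
# 1x1 strided projection + BN when shape changes). Three branch layouts:
#   basic:      conv3x3 - conv3x3                        (18 C^2 weights)
#   bottleneck: conv1x1(C) - conv3x3(C) - conv1x1(4C)    (17 C^2)
#   small:      conv1x3 - conv3x1 - conv1x3 - conv3x1    (12 C^2)
# Convolutions carry no bias (normalization absorbs shifts); the SE fully
# connected layers are bias-free as well.

#' Squeeze a feature map to channel statistics
#'
#' Global average pooling over the spatial extent: for each channel `c`,
#' \eqn{s_c = \frac{1}{HW}\sum_{i,j} o_c(i,j)}.
#'
#' @param o a feature map: numeric array `(H, W, C)` or a batch
#'   `(H, W, C, N)`.
#' @return a length-`C` vector, or a `C x N` matrix for a batch.
#' @export
squeeze <- function(o) {
  d <- dim(o)
  if (is.null(d) || !length(d) %in% 3:4) stopf("squeeze() expects an (H, W, C[, N]) array")
  if (d[1] < 1 || d[2] < 1) stopf("empty spatial extent")
  if (any(!is.finite(o))) stopf("feature map must be finite")
  colSums(o, dims = 2L) / (d[1] * d[2])
}

#' Excitation gate weights
#'
#' Holds the two bias-free fully connected layers of the SE gate:
#' `W1` is `Cbar x C`, `W2` is `C x Cbar`, with bottleneck width
#' `Cbar = max(1, floor(C / r))` for reduction ratio `r` (default 16).
#'
#' @param C number of channels gated.
#' @param r reduction ratio (positive integer).
#' @param W1,W2 optional explicit weight matrices; random (He-scaled) when
#'   omitted.
#' @return an object of class `excitation_weights`.
#' @export
excitation_weights <- function(C, r = 16, W1 = NULL, W2 = NULL) {
  C <- as.integer(check_number(C, "C", lower = 1, integer = TRUE))
  r <- as.integer(check_number(r, "r", lower = 1, integer = TRUE))
  cbar <- max(1L, C %/% r)
  if (is.null(W1)) W1 <- matrix(rnorm(cbar * C, sd = sqrt(2 / C)), cbar, C)
  if (is.null(W2)) W2 <- matrix(rnorm(C * cbar, sd = sqrt(2 / cbar)), C, cbar)
  if (!identical(dim(W1), as.integer(c(cbar, C))))
    stopf("W1 must be %d x %d", cbar, C)
  if (!identical(dim(W2), as.integer(c(C, cbar))))
    stopf("W2 must be %d x %d", C, cbar)
  structure(list(W1 = W1, W2 = W2, r = r, C = C, Cbar = cbar),
            class = "excitation_weights")
}

#' Excitation: channel gates from channel statistics
#'
#' Computes \eqn{\tilde{S} = \sigma(W_2\, \delta(W_1 S))} with
#' \eqn{\delta} = ReLU and \eqn{\sigma} = sigmoid. Every gate lies strictly
#' in (0, 1).
#'
#' @param s channel statistics: length-`C` vector or `C x N` matrix.
#' @param w an [excitation_weights()] object.
#' @return gates with the same shape as `s`.
#' @export
excitation <- function(s, w) {
  vec <- is.null(dim(s))
  sm <- if (vec) matrix(s, ncol = 1) else s
  if (nrow(sm) != ncol(w$W1)) stopf("length of S (%d) != C (%d)", nrow(sm), ncol(w$W1))
  g <- sigmoid(w$W2 %*% pmax(w$W1 %*% sm, 0))
  if (vec) g[, 1] else g
}

#' Recalibrate a feature map by channel gates
#'
#' Channel-wise multiplication \eqn{\tilde{o}_c(i,j) = \tilde{s}_c\, o_c(i,j)}.
#'
#' @param o feature map `(H, W, C)` or `(H, W, C, N)`.
#' @param gates length-`C` vector, or `C x N` matrix for a batch.
#' @return the recalibrated feature map, same shape as `o`.
#' @export
recalibrate <- function(o, gates) {
  d <- dim(o)
  C <- d[3]
  if (length(d) == 3L) {
    if (length(gates) != C) stopf("need %d gates, got %d", C, length(gates))
    o * rep(gates, each = d[1] * d[2])
  } else {
    gm <- if (is.null(dim(gates))) matrix(gates, C, d[4]) else gates
    if (nrow(gm) != C || ncol(gm) != d[4]) stopf("gate matrix must be %d x %d", C, d[4])
    o * rep(as.vector(gm), each = d[1] * d[2])
  }
}

#' Residual combination
#'
#' Elementwise sum \eqn{\tilde{X} = X_0 + \tilde{O}} of the (possibly
#' projected) module input and the recalibrated branch output.
#'
#' @param x0 shortcut tensor.
#' @param o_tilde recalibrated branch output; same shape as `x0`.
#' @return elementwise sum.
#' @export
residual_combine <- function(x0, o_tilde) {
  if (!identical(dim(x0), dim(o_tilde)))
    stopf("shapes differ (%s vs %s); use a projection shortcut",
          paste(dim(x0), collapse = "x"), paste(dim(o_tilde), collapse = "x"))
  x0 + o_tilde
}

#' Specify an SE-ResNet module
#'
#' @param kind `"basic"`, `"bottleneck"`, or `"small"`.
#' @param in_channels channels of the module input.
#' @param width branch width `C`; output channels are `C` (basic, small) or
#'   `4 C` (bottleneck).
#' @param stride 1 or 2; applied at the first branch convolution (and the
#'   projection shortcut).
#' @param r SE reduction ratio.
#' @param shortcut `"identity"` or `"projection"`; by default projection is
#'   chosen exactly when the input/output shapes differ.
#' @return an object of class `module_spec`.
#' @export
module_spec <- function(kind = c("basic", "bottleneck", "small"),
                        in_channels, width, stride = 1L, r = 16L,
                        shortcut = NULL) {
  kind <- match.arg(kind)
  in_channels <- check_number(in_channels, "in_channels", lower = 1, integer = TRUE)
  width <- check_number(width, "width", lower = 1, integer = TRUE)
  if (!stride %in% c(1, 2)) stopf("stride must be 1 or 2")
  r <- check_number(r, "r", lower = 1, integer = TRUE)
  out <- if (kind == "bottleneck") 4L * width else width
  need_proj <- (in_channels != out) || stride == 2
  if (is.null(shortcut)) shortcut <- if (need_proj) "projection" else "identity"
  shortcut <- match.arg(shortcut, c("identity", "projection"))
  if (shortcut == "identity" && need_proj)
    stopf("identity shortcut impossible: %d -> %d channels, stride %d",
          in_channels, out, stride)
  structure(list(kind = kind, in_channels = as.integer(in_channels),
                 width = as.integer(width), out_channels = as.integer(out),
                 stride = as.integer(stride), r = as.integer(r),
                 shortcut = shortcut),
            class = "module_spec")
}

# convolution layer geometry of a module's branch: list of (kh, kw, cin, cout)
module_conv_defs <- function(spec) {
  C <- spec$width; cin <- spec$in_channels
  switch(spec$kind,
    basic = list(c(3L, 3L, cin, C), c(3L, 3L, C, C)),
    bottleneck = list(c(1L, 1L, cin, C), c(3L, 3L, C, C), c(1L, 1L, C, 4L * C)),
    small = list(c(1L, 3L, cin, C), c(3L, 1L, C, C), c(1L, 3L, C, C), c(3L, 1L, C, C)))
}

he_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

module_init <- function(spec) {
  defs <- module_conv_defs(spec)
  params <- list(
    convs = lapply(defs, function(d) he_conv(d[1], d[2], d[3], d[4])),
    bn = lapply(defs, function(d) list(gamma = rep(1, d[3]), beta = rep(0, d[3]))),
    se = unclass(excitation_weights(spec$out_channels, spec$r))[c("W1", "W2")]
  )
  buffers <- list(bn = lapply(defs, function(d) list(mean = rep(0, d[3]),
                                                     var = rep(1, d[3]))))
  if (spec$shortcut == "projection") {
    params$proj <- list(w = he_conv(1L, 1L, spec$in_channels, spec$out_channels),
                        gamma = rep(1, spec$out_channels),
                        beta = rep(0, spec$out_channels))
    buffers$proj <- list(mean = rep(0, spec$out_channels),
                         var = rep(1, spec$out_channels))
  }
  list(params = params, buffers = buffers)
}

#' Build an SE-ResNet module
#'
#' Instantiates trainable weights for a [module_spec()] (He-scaled random
#' convolution and gate weights, unit-gain normalization). Run it with
#' [module_forward()].
#'
#' @param spec a [module_spec()].
#' @param seed optional integer; fixes the weight draw.
#' @return an object of class `se_module` with elements `spec`, `params`,
#'   `buffers`.
#' @export
build_module <- function(spec, seed = NULL) {
  if (!inherits(spec, "module_spec")) stopf("'spec' must be a module_spec")
  st <- with_seed(seed, module_init(spec))
  structure(list(spec = spec, params = st$params, buffers = st$buffers),
            class = "se_module")
}

#' Run an SE-ResNet module forward
#'
#' @param module an [build_module()] object.
#' @param x input array `(H, W, in_channels, N)` (a single `(H, W, C)` map is
#'   promoted to a batch of one).
#' @param train logical; batch statistics (and running-statistic updates) vs
#'   stored statistics for normalization.
#' @return output array `(H', W', out_channels, N)`.
#' @export
module_forward <- function(module, x, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  mod_fwd(module$spec, module$params, module$buffers, x, train = train)$out
}

# Full forward with caches; `skip_shortcut` returns the recalibrated branch
# output alone (used by the residual-gradient diagnostics).
mod_fwd <- function(spec, params, buffers, x, train = FALSE, skip_shortcut = FALSE) {
  defs <- module_conv_defs(spec)
  h <- x
  caches <- vector("list", length(defs))
  for (i in seq_along(defs)) {
    bn <- bn_forward(h, params$bn[[i]]$gamma, params$bn[[i]]$beta,
                     buffers$bn[[i]], train)
    buffers$bn[[i]] <- bn$buf
    act <- relu_forward(bn$y)
    stride <- if (i == 1L) spec$stride else 1L
    caches[[i]] <- list(bn = bn$cache, mask = act$mask, a = act$y, stride = stride)
    h <- conv2d_forward(act$y, params$convs[[i]], stride)
  }
  o <- h
  d <- dim(o)
  # SE gate on the branch output
  s <- squeeze(o)
  z1 <- params$se$W1 %*% s
  a1 <- pmax(z1, 0)
  z2 <- params$se$W2 %*% a1
  g <- sigmoid(z2)
  o_t <- o * rep(as.vector(g), each = d[1] * d[2])
  se_cache <- list(s = s, z1 = z1, a1 = a1, g = g, o = o)
  if (skip_shortcut) {
    sc <- array(0, dim = d)
    proj_cache <- NULL
  } else if (spec$shortcut == "identity") {
    sc <- x
    proj_cache <- NULL
  } else {
    pc <- conv2d_forward(x, params$proj$w, spec$stride)
    pbn <- bn_forward(pc, params$proj$gamma, params$proj$beta, buffers$proj, train)
    buffers$proj <- pbn$buf
    sc <- pbn$y
    proj_cache <- list(pc = pc, bn = pbn$cache)
  }
  list(out = sc + o_t, caches = caches, se = se_cache, proj = proj_cache,
       x = x, buffers = buffers)
}

mod_bwd <- function(spec, params, fwd, dout) {
  d <- dim(fwd$se$o)
  hw <- d[1] * d[2]
  se <- fwd$se
  grads <- list(convs = vector("list", length(params$convs)),
                bn = vector("list", length(params$bn)),
                se = list(W1 = NULL, W2 = NULL))
  # recalibration: out = o * g (broadcast over space)
  gexp <- rep(as.vector(se$g), each = hw)
  do <- dout * gexp
  dg <- colSums(dout * se$o, dims = 2L)
  dz2 <- dg * se$g * (1 - se$g)
  grads$se$W2 <- dz2 %*% t(se$a1)
  dz1 <- (t(params$se$W2) %*% dz2) * (se$z1 > 0)
  grads$se$W1 <- dz1 %*% t(se$s)
  ds <- t(params$se$W1) %*% dz1
  do <- do + rep(as.vector(ds), each = hw) / hw
  # branch convolutions, in reverse
  dh <- do
  for (i in rev(seq_along(params$convs))) {
    cc <- fwd$caches[[i]]
    cb <- conv2d_backward(cc$a, params$convs[[i]], dh, cc$stride)
    grads$convs[[i]] <- cb$dw
    dact <- cb$dx * cc$mask
    bb <- bn_backward(dact, cc$bn, params$bn[[i]]$gamma)
    grads$bn[[i]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    dh <- bb$dx
  }
  dx <- dh
  # shortcut path
  if (spec$shortcut == "identity") {
    dx <- dx + dout
  } else {
    pb <- bn_backward(dout, fwd$proj$bn, params$proj$gamma)
    cb <- conv2d_backward(fwd$x, params$proj$w, pb$dx, spec$stride)
    grads$proj <- list(w = cb$dw, gamma = pb$dgamma, beta = pb$dbeta)
    dx <- dx + cb$dx
  }
  list(dx = dx, grads = grads)
}

#' Explicit-loop reference forward pass
#'
#' Re-evaluates an SE-ResNet module with naive nested loops — direct
#' convolution sums, scalar normalization, two-loop matrix-vector products
#' for the gate — sharing no numerical code with [module_forward()]. Only
#' intended for tiny inputs; it is the test oracle against which the fast
#' path is validated.
#'
#' @param module an `se_module`.
#' @param x input `(H, W, C)` array or `(H, W, C, N)` batch.
#' @return output array shaped like the fast path's (stored statistics are
#'   used for normalization, i.e. evaluation mode).
#' @export
reference_forward <- function(module, x) {
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  out <- NULL
  for (n in seq_len(d[4])) {
    y <- ref_forward_one(module$spec, module$params, module$buffers,
                         array(x[, , , n], d[1:3]))
    if (is.null(out)) out <- array(0, dim = c(dim(y), d[4]))
    out[, , , n] <- y
  }
  if (single) array(out, dim(out)[1:3]) else out
}

ref_bn_eval <- function(x, gamma, beta, mean, var, eps = 1e-5) {
  y <- x
  for (c in seq_len(dim(x)[3]))
    y[, , c] <- gamma[c] * (x[, , c] - mean[c]) / sqrt(var[c] + eps) + beta[c]
  y
}

ref_conv <- function(x, w, stride) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  ph <- kh %/% 2L; pw <- kw %/% 2L
  oh <- (H + 2L * ph - kh) %/% stride + 1L
  ow <- (W + 2L * pw - kw) %/% stride + 1L
  y <- array(0, dim = c(oh, ow, cout))
  for (co in seq_len(cout)) for (ox in seq_len(ow)) for (oy in seq_len(oh)) {
    acc <- 0
    for (ci in seq_len(cin)) for (kx in seq_len(kw)) for (ky in seq_len(kh)) {
      iy <- (oy - 1L) * stride - ph + ky
      ix <- (ox - 1L) * stride - pw + kx
      if (iy >= 1L && iy <= H && ix >= 1L && ix <= W)
        acc <- acc + w[ky, kx, ci, co] * x[iy, ix, ci]
    }
    y[oy, ox, co] <- acc
  }
  y
}

ref_forward_one <- function(spec, params, buffers, x) {
  h <- x
  for (i in seq_along(params$convs)) {
    h <- ref_bn_eval(h, params$bn[[i]]$gamma, params$bn[[i]]$beta,
                     buffers$bn[[i]]$mean, buffers$bn[[i]]$var)
    h[h < 0] <- 0
    h <- ref_conv(h, params$convs[[i]], if (i == 1L) spec$stride else 1L)
  }
  C <- dim(h)[3]; H <- dim(h)[1]; W <- dim(h)[2]
  s <- numeric(C)
  for (c in seq_len(C)) {
    acc <- 0
    for (i in seq_len(H)) for (j in seq_len(W)) acc <- acc + h[i, j, c]
    s[c] <- acc / (H * W)
  }
  W1 <- params$se$W1; W2 <- params$se$W2
  a1 <- numeric(nrow(W1))
  for (i in seq_len(nrow(W1))) {
    acc <- 0
    for (j in seq_len(ncol(W1))) acc <- acc + W1[i, j] * s[j]
    a1[i] <- max(acc, 0)
  }
  g <- numeric(C)
  for (i in seq_len(C)) {
    acc <- 0
    for (j in seq_len(ncol(W2))) acc <- acc + W2[i, j] * a1[j]
    g[i] <- 1 / (1 + exp(-acc))
  }
  for (c in seq_len(C)) h[, , c] <- h[, , c] * g[c]
  if (spec$shortcut == "identity") {
    h + x
  } else {
    sc <- ref_conv(x, params$proj$w, spec$stride)
    sc <- ref_bn_eval(sc, params$proj$gamma, params$proj$beta,
                      buffers$proj$mean, buffers$proj$var)
    h + sc
  }
}
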