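# Declarative architecture specs and the network builder.
#
# A network is: a plain stem convolution (3x3 stride 1 for 32x32 inputs; a
# strided stem plus 2x2 max-pool for large histology inputs), a sequence of
# SE-ResNet stages (each stacking modules of one kind and width, with the
# stage entry stride carried by its first module), a final BN + ReLU, global
# average pooling, and a single fully connected softmax classifier.

#' Architecture specification
#'
#' Low-level constructor; prefer [se_resnet_spec()] and [bhcnet_spec()].
#'
#' @param name display name.
#' @param stem list with `k` (kernel `c(kh, kw)`), `out` (channels),
#'   `stride`, `max_pool` (logical: 2x2 stride-2 max pooling after the stem).
#' @param stages list of stages, each `list(kind, width, n, stride)`.
#' @param num_classes number of output classes (>= 2).
#' @param input_size expected square input size in pixels.
#' @param input_channels image channels (3 for RGB).
#' @param r SE reduction ratio used by every module.
#' @return an object of class `bhcnet_arch_spec`.
#' @export
architecture_spec <- function(name, stem, stages, num_classes,
                              input_size = 32L, input_channels = 3L, r = 16L) {
  num_classes <- check_number(num_classes, "num_classes", lower = 2, integer = TRUE)
  stages <- lapply(stages, function(st) {
    st$width <- as.integer(check_number(st$width, "stage width", lower = 1,
                                        integer = TRUE))
    st$n <- as.integer(check_number(st$n, "stage module count", lower = 1,
                                    integer = TRUE))
    if (!st$stride %in% c(1, 2)) stopf("stage stride must be 1 or 2")
    st$stride <- as.integer(st$stride)
    st
  })
  structure(list(name = name, stem = stem, stages = stages,
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 input_channels = as.integer(input_channels),
                 r = as.integer(r)),
            class = "bhcnet_arch_spec")
}

#' Cifar-scale SE-ResNet family
#'
#' Five variants over the three module kinds, all with stage widths
#' 64/128/256/512 and downsampling at the entry of stages 2-4:
#' variants 18 (basic), 26 (bottleneck) and 34 (small) stack 2 modules per
#' stage; variants 50 (bottleneck) and 66 (small) stack (3, 4, 6, 3). The
#' stem is a single 3x3, 64, stride-1 convolution with no max pooling,
#' matching the 32x32-input adaptation of the family.
#'
#' @param variant one of 18, 26, 34, 50, 66.
#' @param num_classes classifier width (default 10).
#' @param input_size square input size (default 32).
#' @return a `bhcnet_arch_spec`.
#' @export
se_resnet_spec <- function(variant, num_classes = 10, input_size = 32) {
  variant <- as.integer(variant)
  kinds <- c(`18` = "basic", `26` = "bottleneck", `34` = "small",
             `50` = "bottleneck", `66` = "small")
  counts <- list(`18` = c(2, 2, 2, 2), `26` = c(2, 2, 2, 2), `34` = c(2, 2, 2, 2),
                 `50` = c(3, 4, 6, 3), `66` = c(3, 4, 6, 3))
  key <- as.character(variant)
  if (!key %in% names(kinds)) stopf("unknown SE-ResNet variant %s", variant)
  widths <- c(64L, 128L, 256L, 512L)
  stages <- Map(function(w, n, s) list(kind = unname(kinds[key]), width = w,
                                       n = n, stride = s),
                widths, counts[[key]], c(1L, 2L, 2L, 2L))
  architecture_spec(sprintf("se_resnet-%d", variant),
                    stem = list(k = c(3L, 3L), out = 64L, stride = 1L,
                                max_pool = FALSE),
                    stages = stages, num_classes = num_classes,
                    input_size = input_size)
}

#' BHCNet family
#'
#' One plain stem convolution, three blocks of `N` small SE-ResNet modules
#' at widths 16/32/64 (blocks 2 and 3 downsample on entry), global average
#' pooling, and a softmax classifier. For inputs of 64 pixels or larger the
#' stem uses stride 2 followed by a 2x2 max pool to keep activation maps
#' tractable; for small (e.g. 32x32) inputs the stem is stride 1 with no
#' pooling.
#'
#' @param N number of small modules per block (>= 1).
#' @param num_classes classifier width (2 for benign/malignant, 8 for
#'   subtypes).
#' @param input_size square input size.
#' @param widths channel ladder of the three blocks.
#' @return a `bhcnet_arch_spec`.
#' @export
bhcnet_spec <- function(N, num_classes = 2, input_size = 32,
                        widths = c(16L, 32L, 64L)) {
  N <- check_number(N, "N", lower = 1, integer = TRUE)
  if (length(widths) != 3L) stopf("'widths' must have length 3")
  big <- input_size >= 64
  stages <- Map(function(w, s) list(kind = "small", width = as.integer(w),
                                    n = N, stride = s),
                widths, c(1L, 2L, 2L))
  architecture_spec(sprintf("bhcnet-%d", N),
                    stem = list(k = c(3L, 3L), out = as.integer(widths[1]),
                                stride = if (big) 2L else 1L, max_pool = big),
                    stages = stages, num_classes = num_classes,
                    input_size = input_size)
}

#' Look up an architecture by registry name
#'
#' Known names: `"se_resnet-18/26/34/50/66"`, `"bhcnet-3"`, `"bhcnet-6"`,
#' and generally `"bhcnet-<N>"`.
#'
#' @param name registry name.
#' @param num_classes,input_size forwarded to the spec constructor.
#' @return a `bhcnet_arch_spec`.
#' @export
architecture_from_name <- function(name, num_classes = 2, input_size = 32) {
  if (grepl("^se_resnet-\\d+$", name))
    return(se_resnet_spec(sub("^se_resnet-", "", name), num_classes, input_size))
  if (grepl("^bhcnet-\\d+$", name))
    return(bhcnet_spec(as.integer(sub("^bhcnet-", "", name)), num_classes,
                       input_size))
  stopf("unknown architecture '%s'", name)
}

# expand an architecture spec into the ordered list of module specs
network_module_specs <- function(spec) {
  out <- list()
  cin <- spec$stem$out
  for (st in spec$stages) {
    for (i in seq_len(st$n)) {
      ms <- module_spec(st$kind, in_channels = cin, width = st$width,
                        stride = if (i == 1L) st$stride else 1L, r = spec$r)
      out[[length(out) + 1L]] <- ms
      cin <- ms$out_channels
    }
  }
  out
}

#' Build a trainable network from an architecture spec
#'
#' Weights are drawn with He-style scaling (normal with variance
#' `2 / fan_in`); normalization layers start at unit gain and zero shift.
#' Two builds from the same seed are weight-identical.
#'
#' @param spec a `bhcnet_arch_spec` (or a registry name).
#' @param seed optional integer fixing the weight draw.
#' @return an object of class `bhcnet_network`.
#' @export
build_network <- function(spec, seed = NULL) {
  if (is.character(spec)) spec <- architecture_from_name(spec)
  if (!inherits(spec, "bhcnet_arch_spec")) stopf("'spec' must be a bhcnet_arch_spec")
  mspecs <- network_module_specs(spec)
  with_seed(seed, {
    stem <- he_conv(spec$stem$k[1], spec$stem$k[2], spec$input_channels,
                    spec$stem$out)
    inits <- lapply(mspecs, module_init)
    cout <- mspecs[[length(mspecs)]]$out_channels
    params <- list(
      stem = stem,
      modules = lapply(inits, `[[`, "params"),
      final_bn = list(gamma = rep(1, cout), beta = rep(0, cout)),
      fc = list(W = matrix(rnorm(spec$num_classes * cout, sd = sqrt(2 / cout)),
                           spec$num_classes, cout),
                b = rep(0, spec$num_classes)))
    buffers <- list(modules = lapply(inits, `[[`, "buffers"),
                    final_bn = list(mean = rep(0, cout), var = rep(1, cout)))
    structure(list(spec = spec, module_specs = mspecs, params = params,
                   buffers = buffers),
              class = "bhcnet_network")
  })
}

#' @export
print.bhcnet_network <- function(x, ...) {
  cat(sprintf("<bhcnet_network> %s: %d modules, %d classes, input %dx%d\n",
              x$spec$name, length(x$module_specs), x$spec$num_classes,
              x$spec$input_size, x$spec$input_size))
  invisible(x)
}

network_forward <- function(net, x, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  params <- net$params
  buffers <- net$buffers
  h <- conv2d_forward(x, params$stem, net$spec$stem$stride)
  pool_cache <- NULL
  if (isTRUE(net$spec$stem$max_pool)) {
    mp <- maxpool2_forward(h)
    pool_cache <- mp$cache
    h <- mp$y
  }
  stem_in <- x
  mod_caches <- vector("list", length(net$module_specs))
  for (i in seq_along(net$module_specs)) {
    fw <- mod_fwd(net$module_specs[[i]], params$modules[[i]],
                  buffers$modules[[i]], h, train = train)
    buffers$modules[[i]] <- fw$buffers
    mod_caches[[i]] <- fw
    h <- fw$out
  }
  bn <- bn_forward(h, params$final_bn$gamma, params$final_bn$beta,
                   buffers$final_bn, train)
  buffers$final_bn <- bn$buf
  act <- relu_forward(bn$y)
  gp <- gap_forward(act$y)
  logits <- params$fc$W %*% gp$y + params$fc$b
  list(logits = logits, probs = softmax_cols(logits),
       caches = list(stem_in = stem_in, pool = pool_cache, modules = mod_caches,
                     final_bn = bn$cache, final_mask = act$mask, gap = gp),
       buffers = buffers)
}

network_backward <- function(net, fwd, dlogits) {
  params <- net$params
  ca <- fwd$caches
  feat <- ca$gap$y
  gfc <- list(W = dlogits %*% t(feat), b = rowSums(dlogits))
  dfeat <- t(params$fc$W) %*% dlogits
  dh <- gap_backward(dfeat, ca$gap$d) * ca$final_mask
  bb <- bn_backward(dh, ca$final_bn, params$final_bn$gamma)
  gfbn <- list(gamma = bb$dgamma, beta = bb$dbeta)
  dh <- bb$dx
  gmods <- vector("list", length(net$module_specs))
  for (i in rev(seq_along(net$module_specs))) {
    mb <- mod_bwd(net$module_specs[[i]], params$modules[[i]], ca$modules[[i]], dh)
    gmods[[i]] <- mb$grads
    dh <- mb$dx
  }
  if (!is.null(ca$pool)) dh <- maxpool2_backward(dh, ca$pool)
  cb <- conv2d_backward(ca$stem_in, params$stem, dh, net$spec$stem$stride)
  list(grads = list(stem = cb$dw, modules = gmods, final_bn = gfbn, fc = gfc),
       dx = cb$dx)
}

# loss, accuracy and parameter gradients for one minibatch
network_loss_grad <- function(net, x, y, train = TRUE) {
  fwd <- network_forward(net, x, train = train)
  ce <- softmax_ce(fwd$logits, y)
  bwd <- network_backward(net, fwd, ce$dlogits)
  pred <- max.col(t(fwd$probs), ties.method = "first")
  list(loss = ce$loss, acc = mean(pred == y), grads = bwd$grads,
       buffers = fwd$buffers, probs = ce$probs)
}

#' Predict class probabilities
#'
#' @param object a `bhcnet_network`.
#' @param x image batch `(H, W, C, N)`, already preprocessed.
#' @param type `"prob"` for a `K x N` probability matrix (columns sum to 1)
#'   or `"class"` for the arg-max class index.
#' @param ... unused.
#' @export
predict.bhcnet_network <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- network_forward(object, x, train = FALSE)$probs
  if (type == "prob") p else max.col(t(p), ties.method = "first")
}

#' Save / load network weights
#'
#' Weights and running statistics are serialized with R's native RDS
#' format, together with the architecture spec so the model can be rebuilt
#' without outside information.
#'
#' @param model a `bhcnet_network`.
#' @param path file path (conventionally `.rds`).
#' @return `load_network()` returns the restored `bhcnet_network`.
#' @export
save_network <- function(model, path) {
  saveRDS(list(spec = model$spec, params = model$params,
               buffers = model$buffers), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  st <- readRDS(path)
  net <- build_network(st$spec)
  net$params <- st$params
  net$buffers <- st$buffers
  net
}

# --- parameter-tree arithmetic (used by the optimizer) ---------------------

ptree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- ptree_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

ptree_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- ptree_map(a[[i]], f)
    out
  } else f(a)
}

ptree_zero <- function(a) ptree_map(a, function(x) x * 0)

# rebuild a parameter tree from a flat numeric vector (inverse of unlist);
# preserves array dimensions, unlike utils::relist
ptree_unflatten <- function(skeleton, v) {
  pos <- 0L
  fill <- function(a) {
    if (is.list(a)) return(lapply(a, fill))
    n <- length(a)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(a)
    out
  }
  out <- fill(skeleton)
  stopifnot(pos == length(v))
  out
}
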