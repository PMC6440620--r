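# Analytic convolution-weight accounting.
#
# A convolution with C input channels, an H x W kernel and K filters holds
# C*H*W*K weights (no bias). At equal input/output width C the three module
# branches therefore hold 18 C^2 (basic), 17 C^2 (bottleneck, with the 4C
# expansion), and 12 C^2 (small) weights — the factorized 1x3/3x1 pairs cut
# 29.4% versus bottleneck and 33.3% versus basic, independent of C.

#' Convolution layer parameter count
#'
#' @param in_channels,kernel_h,kernel_w,out_channels layer geometry (all
#'   positive integers).
#' @return the number of weights, `in_channels * kernel_h * kernel_w *
#'   out_channels`.
#' @export
conv_param_count <- function(in_channels, kernel_h, kernel_w, out_channels) {
  for (v in list(in_channels, kernel_h, kernel_w, out_channels))
    check_number(v, "conv shape", lower = 1, integer = TRUE)
  in_channels * kernel_h * kernel_w * out_channels
}

#' Convolution weights of one SE-ResNet module
#'
#' Closed-form counts at equal input/output width: `18 C^2` (basic),
#' `17 C^2` (bottleneck), `12 C^2` (small). Each equals the sum of
#' [conv_param_count()] over the module's convolution list.
#'
#' @param kind `"basic"`, `"bottleneck"`, or `"small"`.
#' @param width channel width `C`.
#' @return integer-valued count.
#' @export
module_conv_params <- function(kind = c("basic", "bottleneck", "small"), width) {
  kind <- match.arg(kind)
  width <- check_number(width, "width", lower = 1, integer = TRUE)
  spec <- module_spec(kind, in_channels = if (kind == "bottleneck") 4L * width else width,
                      width = width)
  sum(vapply(module_conv_defs(spec),
             function(d) conv_param_count(d[3], d[1], d[2], d[4]), numeric(1)))
}

#' Parameter reduction between module kinds
#'
#' `100 * (1 - params(to) / params(from))`, rounded to one decimal place.
#' Independent of the width since all counts scale as `C^2`.
#'
#' @param from,to module kinds.
#' @param width channel width (any value; default 64).
#' @return percentage, one decimal.
#' @export
reduction_percent <- function(from, to, width = 64) {
  round(100 * (1 - module_conv_params(to, width) / module_conv_params(from, width)), 1)
}

# Exact convolution-weight total implied by an architecture spec: stem,
# branch convolutions of every module (with true input widths at stage
# transitions), and projection shortcuts.
analytic_conv_params <- function(spec) {
  total <- conv_param_count(spec$input_channels, spec$stem$k[1], spec$stem$k[2],
                            spec$stem$out)
  for (ms in network_module_specs(spec)) {
    total <- total + sum(vapply(module_conv_defs(ms),
                                function(d) conv_param_count(d[3], d[1], d[2], d[4]),
                                numeric(1)))
    if (ms$shortcut == "projection")
      total <- total + conv_param_count(ms$in_channels, 1, 1, ms$out_channels)
  }
  total
}

#' Audit a built network's parameters
#'
#' Itemizes every weight array of a [build_network()] model, checks that the
#' convolution subtotal equals the analytic count implied by the
#' architecture spec (an error is raised on mismatch), and totals the
#' trainable parameters.
#'
#' @param model a `bhcnet_network`.
#' @return an object of class `param_audit`: a list with `layers`
#'   (data.frame: layer, category, params), `by_category`, `conv_subtotal`,
#'   `analytic_conv`, and `total`.
#' @export
audit_network <- function(model) {
  if (!inherits(model, "bhcnet_network")) stopf("'model' must be a bhcnet_network")
  rows <- list()
  add <- function(layer, category, n) rows[[length(rows) + 1L]] <<-
    data.frame(layer = layer, category = category, params = n)
  add("stem.conv", "conv", length(model$params$stem))
  for (i in seq_along(model$params$modules)) {
    p <- model$params$modules[[i]]
    id <- sprintf("module%02d", i)
    for (k in seq_along(p$convs))
      add(sprintf("%s.conv%d", id, k), "conv", length(p$convs[[k]]))
    for (k in seq_along(p$bn))
      add(sprintf("%s.bn%d", id, k), "norm",
          length(p$bn[[k]]$gamma) + length(p$bn[[k]]$beta))
    add(sprintf("%s.se", id), "se", length(p$se$W1) + length(p$se$W2))
    if (!is.null(p$proj)) {
      add(sprintf("%s.shortcut.conv", id), "conv", length(p$proj$w))
      add(sprintf("%s.shortcut.bn", id), "norm",
          length(p$proj$gamma) + length(p$proj$beta))
    }
  }
  add("final.bn", "norm",
      length(model$params$final_bn$gamma) + length(model$params$final_bn$beta))
  add("classifier.fc", "classifier",
      length(model$params$fc$W) + length(model$params$fc$b))
  layers <- do.call(rbind, rows)
  by_cat <- tapply(layers$params, layers$category, sum)
  conv_subtotal <- as.numeric(by_cat[["conv"]])
  analytic <- analytic_conv_params(model$spec)
  if (conv_subtotal != analytic)
    stopf("audit mismatch: built conv weights %d != analytic %d",
          conv_subtotal, analytic)
  structure(list(layers = layers, by_category = by_cat,
                 conv_subtotal = conv_subtotal, analytic_conv = analytic,
                 total = sum(layers$params)),
            class = "param_audit")
}

#' @export
print.param_audit <- function(x, ...) {
  cat("Parameter audit\n")
  for (nm in names(x$by_category))
    cat(sprintf("  %-10s %10s\n", nm, format(x$by_category[[nm]], big.mark = ",")))
  cat(sprintf("  conv subtotal matches analytic count (%s)\n",
              format(x$analytic_conv, big.mark = ",")))
  cat(sprintf("  total trainable %s\n", format(x$total, big.mark = ",")))
  invisible(x)
}
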