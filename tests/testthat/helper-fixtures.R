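# Shared fixtures, all built in code at test time.

# quadrature oracle for the Gauss error function (independent of pnorm)
erf_quadrature <- function(x) {
  vapply(x, function(xi) {
    s <- sign(xi)
    if (xi == 0) return(0)
    2 / sqrt(pi) * s * stats::integrate(function(t) exp(-t^2), 0, abs(xi),
                                        rel.tol = 1e-13)$value
  }, numeric(1))
}

# tiny module with randomized weights AND randomized running statistics,
# so evaluation-mode normalization is non-trivial
random_tiny_module <- function(kind, in_channels, width, stride, seed) {
  m <- build_module(module_spec(kind, in_channels = in_channels,
                                width = width, stride = stride, r = 2),
                    seed = seed)
  set.seed(seed + 1000)
  for (i in seq_along(m$buffers$bn)) {
    m$buffers$bn[[i]]$mean <- rnorm(length(m$buffers$bn[[i]]$mean), sd = 0.3)
    m$buffers$bn[[i]]$var <- runif(length(m$buffers$bn[[i]]$var), 0.5, 1.5)
  }
  if (!is.null(m$buffers$proj)) {
    m$buffers$proj$mean <- rnorm(length(m$buffers$proj$mean), sd = 0.3)
    m$buffers$proj$var <- runif(length(m$buffers$proj$var), 0.5, 1.5)
  }
  m
}

# small two-class synthetic dataset on disk (cached per session)
toy_dataset_dir <- local({
  dir <- NULL
  function(n_per_cell = 6, image_size = 16, seed = 99) {
    if (!is.null(dir)) return(dir)
    census <- breakhis_census()
    census[] <- n_per_cell
    d <- file.path(tempdir(), sprintf("breakhis_toy_%d_%d", n_per_cell, image_size))
    generate_synthetic_breakhis(
      synthetic_spec(census = census, image_size = image_size, seed = seed), d)
    dir <<- d
    dir
  }
})
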