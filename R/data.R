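# BreakHis-layout dataset handling and the synthetic texture generator.
#
# The BreakHis collection holds 7,909 RGB PNGs of breast-tumor tissue at
# four optical magnifications (40x/100x/200x/400x), two classes and eight
# subtypes. No images ship with this package; generate_synthetic_breakhis()
# emulates the directory/filename layout and the published per-subtype
# census with class-dependent textures so that pipelines (and a small CNN)
# can be exercised end to end.

benign_subtypes <- c("A", "F", "TA", "PT")
malignant_subtypes <- c("DC", "LC", "MC", "PC")
all_subtypes <- c(benign_subtypes, malignant_subtypes)
magnifications <- c(40L, 100L, 200L, 400L)

#' Published BreakHis census
#'
#' Image counts per subtype and magnification for the reference collection:
#' 7,909 images in total, 2,480 benign and 5,429 malignant. Used as the
#' default census of [synthetic_spec()].
#'
#' @return an 8 x 4 integer matrix (subtypes x magnifications).
#' @export
breakhis_census <- function() {
  m <- matrix(c(
    114, 113, 111, 106,   # Adenosis
    253, 260, 264, 237,   # Fibroadenoma
    109, 121, 108, 115,   # Tubular adenoma
    149, 150, 140, 130,   # Phyllodes tumor
    864, 903, 896, 788,   # Ductal carcinoma
    156, 170, 163, 137,   # Lobular carcinoma
    205, 222, 196, 169,   # Mucinous carcinoma
    145, 142, 135, 138),  # Papillary carcinoma
    nrow = 8, byrow = TRUE,
    dimnames = list(all_subtypes, as.character(magnifications)))
  storage.mode(m) <- "integer"
  m
}

subtype_class <- function(subtype) {
  ifelse(subtype %in% benign_subtypes, "benign", "malignant")
}

#' Synthetic dataset specification
#'
#' @param census subtype x magnification count matrix (rows named by
#'   subtype code, columns by magnification); defaults to the full
#'   published census, [breakhis_census()].
#' @param image_size square image size in pixels (default 64; the reference
#'   images are 700x460 but small sizes keep tests fast).
#' @param seed integer; fixes the generated files byte-for-byte.
#' @param texture list of texture parameters, see [synthetic_texture()].
#' @param patients_per_subtype synthetic patient identifiers to spread
#'   images over.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(census = breakhis_census(), image_size = 64L,
                           seed = 1L, texture = list(),
                           patients_per_subtype = 3L) {
  if (is.null(rownames(census)) || !all(rownames(census) %in% all_subtypes))
    stopf("census rows must be named with subtype codes (%s)",
          paste(all_subtypes, collapse = ", "))
  if (any(census < 0) || any(census != round(census)))
    stopf("census counts must be nonnegative integers")
  tex <- utils::modifyList(default_texture_params(), texture)
  structure(list(census = census, image_size = as.integer(image_size),
                 seed = as.integer(seed), texture = tex,
                 patients_per_subtype = as.integer(patients_per_subtype)),
            class = "synthetic_spec")
}

# Texture statistics per subtype. Benign tissue is rendered as smooth
# low-frequency blob fields (large correlation length), malignant as dense
# high-frequency speckle (short correlation length, higher amplitude), and
# subtypes within a class vary the blob scale/density. `margin` is the
# minimum separation in mean per-image pixel variance between the classes
# that the generator promises (verified post hoc in the tests).
default_texture_params <- function() {
  list(
    sigma = c(A = 5, F = 7, TA = 4, PT = 6, DC = 0.6, LC = 0.9, MC = 0.7, PC = 1.1),
    amplitude = c(A = 26, F = 30, TA = 28, PT = 24,
                  DC = 55, LC = 50, MC = 52, PC = 48),
    tint = list(benign = c(185, 150, 180), malignant = c(160, 115, 155)),
    noise_sd = 4,
    margin = 500
  )
}

# dense Gaussian smoothing operator for one axis, rows renormalized so
# constants are preserved at the borders
smoothing_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * sigma^2))
  K / rowSums(K)
}

#' Render one synthetic tissue texture
#'
#' A smoothed Gaussian random field, rescaled to a subtype-specific
#' amplitude around a class tint, plus fine sensor noise. Deterministic
#' given the RNG state.
#'
#' @param subtype subtype code (one of A, F, TA, PT, DC, LC, MC, PC).
#' @param size square image size.
#' @param params texture parameter list (see [synthetic_spec()]).
#' @return integer `size x size x 3` array in \[0, 255\].
#' @export
synthetic_texture <- function(subtype, size, params = default_texture_params()) {
  sigma <- params$sigma[[subtype]]
  amp <- params$amplitude[[subtype]]
  tint <- params$tint[[subtype_class(subtype)]]
  K <- smoothing_matrix(size, sigma)
  field <- K %*% matrix(rnorm(size * size), size, size) %*% t(K)
  field <- field / max(sd(field), 1e-8)
  img <- array(0, dim = c(size, size, 3L))
  for (c in 1:3)
    img[, , c] <- tint[c] + amp * field + rnorm(size * size, sd = params$noise_sd)
  pmin(pmax(round(img), 0), 255)
}

breakhis_filename <- function(class, subtype, patient, mag, index) {
  sprintf("SOB_%s_%s-%s-%d-%03d.png",
          if (class == "benign") "B" else "M", subtype, patient, mag, index)
}

#' Generate a synthetic BreakHis-layout dataset
#'
#' Writes PNG files under `out_dir` in the community directory layout
#' `class/subtype/patient/<mag>X/` with standard `SOB_*` filenames, one file
#' per census cell entry. Two runs with the same spec produce byte-identical
#' file sets.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return the [scan_breakhis()] index of the generated tree.
#' @export
generate_synthetic_breakhis <- function(spec, out_dir) {
  if (!inherits(spec, "synthetic_spec")) stopf("'spec' must be a synthetic_spec")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  census <- spec$census
  with_seed(spec$seed, {
    for (st in rownames(census)) {
      cls <- subtype_class(st)
      for (mg in colnames(census)) {
        n <- census[st, mg]
        if (n == 0) next
        mag <- as.integer(mg)
        dir_base <- file.path(out_dir, cls, st)
        for (i in seq_len(n)) {
          patient <- sprintf("S%02d", ((i - 1L) %% spec$patients_per_subtype) + 1L)
          d <- file.path(dir_base, patient, paste0(mag, "X"))
          if (!dir.exists(d)) dir.create(d, recursive = TRUE)
          img <- synthetic_texture(st, spec$image_size, spec$texture)
          write_png(img, file.path(d, breakhis_filename(cls, st, patient, mag, i)))
        }
      }
    }
  })
  scan_breakhis(out_dir)
}

parse_breakhis_name <- function(name) {
  m <- regmatches(name,
    regexec("^SOB_([BM])_([A-Z]+)-([A-Za-z0-9.]+)-(40|100|200|400)-(\\d+)\\.png$",
            name))[[1]]
  if (length(m) == 0L || !m[3] %in% all_subtypes) return(NULL)
  cls <- if (m[2] == "B") "benign" else "malignant"
  if (cls != subtype_class(m[3])) return(NULL)
  list(class_label = cls, subtype = m[3], patient = m[4],
       magnification = as.integer(m[5]), index = as.integer(m[6]))
}

#' Index a BreakHis-layout directory tree
#'
#' Recursively finds PNG files whose names follow the
#' `SOB_<B|M>_<subtype>-<patient>-<magnification>-<index>.png` convention
#' and builds a magnification-stratified census. Files with unparseable
#' names are reported in a warning (and in the `unparsed` attribute).
#'
#' @param root dataset root directory.
#' @return an object of class `breakhis_index`: list with `records` (a
#'   data.frame: path, magnification, class_label, subtype, patient) and
#'   `census` (subtype x magnification counts).
#' @export
scan_breakhis <- function(root) {
  if (!dir.exists(root)) stopf("'%s' is not a directory", root)
  files <- list.files(root, pattern = "\\.png$", recursive = TRUE,
                      full.names = TRUE)
  if (!length(files)) stopf("no PNG files found under '%s'", root)
  parsed <- lapply(basename(files), parse_breakhis_name)
  ok <- !vapply(parsed, is.null, logical(1))
  if (any(!ok))
    warning(sprintf("%d files with unparseable names, e.g.: %s", sum(!ok),
                    paste(head(basename(files)[!ok], 5), collapse = ", ")))
  records <- do.call(rbind, lapply(which(ok), function(i) {
    p <- parsed[[i]]
    data.frame(path = files[i], magnification = p$magnification,
               class_label = p$class_label, subtype = p$subtype,
               patient = p$patient)
  }))
  if (is.null(records)) stopf("no parseable BreakHis files under '%s'", root)
  idx <- new_breakhis_index(records)
  attr(idx, "unparsed") <- files[!ok]
  idx
}

new_breakhis_index <- function(records) {
  records$subtype <- factor(records$subtype, levels = all_subtypes)
  records$class_label <- factor(records$class_label,
                                levels = c("benign", "malignant"))
  census <- table(subtype = records$subtype,
                  magnification = factor(records$magnification,
                                         levels = magnifications))
  structure(list(records = records,
                 census = unclass(census)),
            class = "breakhis_index")
}

#' @export
print.breakhis_index <- function(x, ...) {
  cat(sprintf("<breakhis_index> %d images (%d benign / %d malignant)\n",
              nrow(x$records), sum(x$records$class_label == "benign"),
              sum(x$records$class_label == "malignant")))
  print(x$census)
  invisible(x)
}

#' Train/test split of a dataset index
#'
#' Randomly partitions the records of each magnification into train and
#' test, stratified by label (class for `level = "binary"`, subtype for
#' `level = "subtype"`), reproducibly for a given seed. The two censuses
#' sum exactly to the input census.
#'
#' @param index a `breakhis_index`.
#' @param train_fraction fraction of each stratum assigned to training,
#'   in (0, 1).
#' @param seed integer seed.
#' @param level stratification level.
#' @return list with `train` and `test`, both `breakhis_index` objects.
#' @export
split_index <- function(index, train_fraction = 0.6, seed = 1L,
                        level = c("binary", "subtype")) {
  level <- match.arg(level)
  check_number(train_fraction, "train_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  rec <- index$records
  strat <- interaction(rec$magnification,
                       if (level == "binary") rec$class_label else rec$subtype,
                       drop = TRUE)
  tr_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(rec)), strat), function(ix) {
      if (length(ix) < 2L)
        stopf("stratum with fewer than 2 images cannot be split")
      ntr <- round(length(ix) * train_fraction)
      ntr <- min(max(ntr, 1L), length(ix) - 1L)
      sample(ix, ntr)
    }), use.names = FALSE)
  })
  list(train = new_breakhis_index(rec[sort(tr_idx), , drop = FALSE]),
       test = new_breakhis_index(rec[-sort(tr_idx), , drop = FALSE]))
}

# --- preprocessing ----------------------------------------------------------

#' Bilinear resize
#'
#' @param img numeric `(H, W, C)` array.
#' @param out_h,out_w target size.
#' @return resized `(out_h, out_w, C)` array.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  map_axis <- function(n_out, n_in) {
    # pixel-center alignment
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    s <- pmin(pmax(s, 0), n_in - 1)
    lo <- floor(s)
    list(lo = as.integer(lo) + 1L, hi = as.integer(pmin(lo + 1, n_in - 1)) + 1L,
         w = s - lo)
  }
  ry <- map_axis(out_h, d[1]); rx <- map_axis(out_w, d[2])
  out <- array(0, dim = c(out_h, out_w, d[3]))
  wy <- matrix(ry$w, out_h, out_w)
  wx <- matrix(rx$w, out_h, out_w, byrow = TRUE)
  for (c in seq_len(d[3])) {
    ch <- img[, , c]
    tl <- ch[ry$lo, rx$lo]; bl <- ch[ry$hi, rx$lo]
    tr <- ch[ry$lo, rx$hi]; br <- ch[ry$hi, rx$hi]
    top <- tl * (1 - wx) + tr * wx
    bot <- bl * (1 - wx) + br * wx
    out[, , c] <- top * (1 - wy) + bot * wy
  }
  out
}

#' Per-channel standardization statistics of a training set
#'
#' @param x image batch `(H, W, C, N)` (pixel scale).
#' @return list with per-channel `mean` and `sd` (floored at 1e-6).
#' @export
channel_stats <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  list(mean = colMeans(m), sd = pmax(apply(m, 2, sd), 1e-6))
}

#' Preprocess an image for the network
#'
#' Bilinear down-sampling to the target size, then zero-mean/unit-variance
#' standardization with per-channel statistics computed on the training
#' split (never on test data).
#'
#' @param img `(H, W, 3)` array in pixel scale, e.g. from [read_png()].
#' @param size target square size.
#' @param stats a [channel_stats()] list; `NULL` skips standardization.
#' @return numeric `(size, size, 3)` array.
#' @export
preprocess_image <- function(img, size, stats = NULL) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stopf("preprocess_image() expects an RGB image")
  out <- if (d[1] == size && d[2] == size) img * 1.0
         else resize_bilinear(img, size, size)
  if (!is.null(stats))
    for (c in 1:3) out[, , c] <- (out[, , c] - stats$mean[c]) / stats$sd[c]
  out
}

#' Load an indexed image set as a preprocessed batch
#'
#' Reads every record of an index, resizes to `size`, and standardizes with
#' `stats` (compute them from the training batch first). Labels follow
#' `level`: 1/2 for benign/malignant, or the subtype index 1..8.
#'
#' @param index a `breakhis_index`.
#' @param size target square size.
#' @param stats optional [channel_stats()]; `NULL` returns pixel-scale data.
#' @param level `"binary"` or `"subtype"` labels.
#' @return list with `x` (`size x size x 3 x N` array), `y` (integer
#'   labels), `levels` (label names).
#' @export
load_images <- function(index, size, stats = NULL,
                        level = c("binary", "subtype")) {
  level <- match.arg(level)
  rec <- index$records
  x <- array(0, dim = c(size, size, 3L, nrow(rec)))
  for (i in seq_len(nrow(rec)))
    x[, , , i] <- preprocess_image(read_png(rec$path[i]), size, stats)
  y <- if (level == "binary") as.integer(rec$class_label)
       else as.integer(rec$subtype)
  lev <- if (level == "binary") levels(rec$class_label) else levels(rec$subtype)
  list(x = x, y = y, levels = lev)
}

# --- augmentation -----------------------------------------------------------

#' Random shift-and-flip augmentation
#'
#' Translates the image by up to `shift_frac` of each dimension (integer
#' pixel offsets, constant fill) and flips it horizontally with probability
#' 1/2, the standard augmentation recipe for this task. Pass `shift` /
#' `flip` explicitly for deterministic behavior; otherwise they are drawn
#' from R's RNG.
#'
#' @param img `(H, W, C)` array (pixel or standardized scale).
#' @param shift_frac maximum shift as a fraction of each dimension.
#' @param fill constant fill value for exposed pixels (0 = the
#'   post-standardization mean).
#' @param shift optional integer `c(dy, dx)` override.
#' @param flip optional logical override.
#' @return augmented array, same shape and scale.
#' @export
augment_image <- function(img, shift_frac = 0.125, fill = 0,
                          shift = NULL, flip = NULL) {
  d <- dim(img)
  max_dy <- floor(d[1] * shift_frac); max_dx <- floor(d[2] * shift_frac)
  if (is.null(shift))
    shift <- c(sample(-max_dy:max_dy, 1L), sample(-max_dx:max_dx, 1L))
  if (is.null(flip)) flip <- runif(1) < 0.5
  out <- array(fill, dim = d)
  dy <- shift[1]; dx <- shift[2]
  ys <- seq_len(d[1]); xs <- seq_len(d[2])
  ty <- ys + dy; tx <- xs + dx
  ky <- ty >= 1L & ty <= d[1]; kx <- tx >= 1L & tx <= d[2]
  out[ty[ky], tx[kx], ] <- img[ys[ky], xs[kx], , drop = FALSE]
  if (flip) out <- out[, rev(seq_len(d[2])), , drop = FALSE]
  out
}

#' Write a dataset index to CSV
#'
#' @param index a `breakhis_index`.
#' @param path output CSV path.
#' @export
index_to_csv <- function(index, path) {
  write.csv(index$records, path, row.names = FALSE)
  invisible(path)
}
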