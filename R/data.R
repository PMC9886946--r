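# Synthetic labelled-image generation, pixel normalization, augmentation,
# and readers/writers for the MNIST IDX and CIFAR-10 binary formats.

#' Labelled image batch
#'
#' @param x numeric array `(channels, height, width, samples)` with pixel
#'   values in `[-1, 1]`.
#' @param y integer class labels in `1..classes` (raw 0-based file labels are
#'   shifted by one on reading).
#' @param classes number of classes.
#' @return an `image_batch`.
#' @export
image_batch <- function(x, y, classes = max(y)) {
  stopifnot(length(dim(x)) == 4L, dim(x)[4] == length(y))
  y <- as.integer(y)
  if (any(y < 1L) || any(y > classes)) {
    stop("labels must lie in 1..", classes)
  }
  structure(list(x = x, y = y, classes = as.integer(classes)),
            class = "image_batch")
}

#' @export
print.image_batch <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<image_batch> %d samples, %d x %d x %d (C x H x W), %d classes\n",
              d[4], d[1], d[2], d[3], x$classes))
  cat(sprintf("  pixel range [%.3f, %.3f]\n", min(x$x), max(x$x)))
  invisible(x)
}

#' Synthetic classification task configuration
#'
#' Each class carries a distinct 5x5 localized +-amplitude patch pattern at a
#' class-specific position, superimposed on Gaussian pixel noise and clipped
#' to `[-1, 1]` — so the 5x5 kernels of the first convolution layer are the
#' natural detectors, and a small tree network can beat chance without any
#' external dataset. Patterns and positions are a fixed property of the task
#' (derived deterministically from the class index); `seed` drives only the
#' noise, so different seeds are fresh draws of the same task.
#'
#' @param height,width,channels image geometry (default 12 x 12 x 1, the
#'   smallest geometry accommodating a 5x5 convolution, 2x2 pooling and 2-row
#'   tree slabs).
#' @param classes number of classes (>= 2).
#' @param train_per_class,test_per_class samples per class in each split
#'   (train and test are disjoint by construction: independent draws).
#' @param amplitude class-signal strength (patch height before clipping).
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param patch_size side of the class patch (default 5).
#' @param seed integer seed.
#' @return a `synthetic_task_config`.
#' @export
synthetic_task_config <- function(height = 12, width = 12, channels = 1,
                                  classes = 10, train_per_class = 40,
                                  test_per_class = 20, amplitude = 1.0,
                                  noise_sd = 0.3, patch_size = 5,
                                  seed = 1L) {
  stopifnot(amplitude >= 0, noise_sd >= 0, patch_size <= height,
            patch_size <= width)
  if (classes < 2) stop("classes must be >= 2")
  structure(list(height = as.integer(height), width = as.integer(width),
                 channels = as.integer(channels),
                 classes = as.integer(classes),
                 train_per_class = as.integer(train_per_class),
                 test_per_class = as.integer(test_per_class),
                 amplitude = amplitude, noise_sd = noise_sd,
                 patch_size = as.integer(patch_size),
                 seed = as.integer(seed)),
            class = "synthetic_task_config")
}

# Fixed +-1 patch pattern and position for a class: a deterministic function
# of the class index only (internal fixed seed), independent of the data seed.
class_signature <- function(class, cfg) {
  p <- cfg$patch_size
  pattern <- with_seed(9000L + class, {
    matrix(sample(c(-1, 1), p * p, replace = TRUE), p, p)
  })
  max_r <- cfg$height - p + 1L
  max_c <- cfg$width - p + 1L
  pos <- with_seed(7000L + class, {
    c(sample.int(max_r, 1L), sample.int(max_c, 1L))
  })
  chan <- ((class - 1L) %% cfg$channels) + 1L
  list(pattern = pattern, row = pos[1], col = pos[2], channel = chan)
}

#' Generate the synthetic labelled-image task
#'
#' @param config a [synthetic_task_config()].
#' @return list with `train` and `test` [image_batch()]es, deterministic
#'   given `config$seed`, with exactly balanced labels.
#' @export
generate_synthetic_task <- function(config) {
  stopifnot(inherits(config, "synthetic_task_config"))
  sigs <- lapply(seq_len(config$classes), class_signature, cfg = config)
  make_split <- function(per_class, split_seed) {
    n <- per_class * config$classes
    y <- rep(seq_len(config$classes), each = per_class)
    x <- with_seed(split_seed, {
      arr <- array(stats::rnorm(config$channels * config$height *
                                  config$width * n, 0, config$noise_sd),
                   c(config$channels, config$height, config$width, n))
      p <- config$patch_size
      for (i in seq_len(n)) {
        s <- sigs[[y[i]]]
        rows <- s$row:(s$row + p - 1L)
        cols <- s$col:(s$col + p - 1L)
        arr[s$channel, rows, cols, i] <-
          arr[s$channel, rows, cols, i] + config$amplitude * s$pattern
      }
      arr[arr > 1] <- 1
      arr[arr < -1] <- -1
      arr
    })
    image_batch(x, y, classes = config$classes)
  }
  base <- fan_seed(config$seed, "data")
  list(train = make_split(config$train_per_class, base),
       test = make_split(config$test_per_class, base + 1L))
}

#' Normalize raw byte pixels to [-1, 1]
#'
#' Maps `v -> 2 * (v / 255) - 1`, so 0 -> -1, 255 -> +1.
#'
#' @param raw numeric array with values in `[0, 255]`.
#' @return array of the same shape with values in `[-1, 1]`.
#' @export
normalize_pixels <- function(raw) {
  if (any(raw < 0) || any(raw > 255)) {
    stop("raw pixel values must lie in [0, 255]; range is [",
         min(raw), ", ", max(raw), "]")
  }
  2 * (raw / 255) - 1
}

#' Augment a batch by flips and integer translations
#'
#' With `flip = TRUE` each image is mirrored horizontally with probability
#' 1/2; each image is then translated by integer offsets drawn uniformly from
#' `[-max_shift, +max_shift]` per axis, with vacated pixels zero-filled.
#' Labels and shapes are preserved; deterministic given `seed`.
#'
#' @param batch an `image_batch`.
#' @param max_shift maximum translation in pixels per direction (the
#'   canonical recipes use 2, or 4 for the widest architecture).
#' @param flip enable horizontal flips.
#' @param seed integer seed.
#' @return an augmented `image_batch`.
#' @export
augment_batch <- function(batch, max_shift = 2, flip = TRUE, seed = 1L) {
  stopifnot(inherits(batch, "image_batch"), max_shift >= 0)
  d <- dim(batch$x)
  if (max_shift >= d[2] || max_shift >= d[3]) {
    stop("max_shift ", max_shift, " must be smaller than the image side")
  }
  n <- d[4]
  draws <- with_seed(seed, {
    list(flip = stats::runif(n) < 0.5,
         dr = sample.int(2L * max_shift + 1L, n, replace = TRUE) -
           max_shift - 1L,
         dc = sample.int(2L * max_shift + 1L, n, replace = TRUE) -
           max_shift - 1L)
  })
  x <- batch$x
  for (i in seq_len(n)) {
    img <- x[, , , i, drop = FALSE]
    dim(img) <- d[1:3]
    if (flip && draws$flip[i]) img <- img[, , rev(seq_len(d[3])), drop = FALSE]
    dr <- draws$dr[i]; dc <- draws$dc[i]
    if (max_shift > 0 && (dr != 0 || dc != 0)) {
      out <- array(0, d[1:3])
      src_r <- seq_len(d[2]) - dr
      src_c <- seq_len(d[3]) - dc
      ok_r <- src_r >= 1L & src_r <= d[2]
      ok_c <- src_c >= 1L & src_c <= d[3]
      out[, which(ok_r), which(ok_c)] <-
        img[, src_r[ok_r], src_c[ok_c], drop = FALSE]
      img <- out
    }
    x[, , , i] <- img
  }
  image_batch(x, batch$y, classes = batch$classes)
}

# ---- MNIST IDX format ------------------------------------------------------

read_u32be <- function(con) {
  v <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(v) == 0L) stop("truncated IDX file: header incomplete")
  v
}

#' Read an MNIST IDX image/label pair
#'
#' Parses the standard IDX format: magic 0x00000803 for image files
#' (unsigned bytes, dims n x rows x cols) and 0x00000801 for label files.
#'
#' @param image_file path to an IDX image file.
#' @param label_file optional path to the matching IDX label file; when
#'   absent all labels are set to 1.
#' @param normalize apply [normalize_pixels()] (default `TRUE`); otherwise
#'   raw 0..255 values are returned.
#' @return an [image_batch()] with one channel; file labels `0..9` become
#'   classes `1..10`.
#' @export
read_idx <- function(image_file, label_file = NULL, normalize = TRUE) {
  con <- file(image_file, "rb")
  on.exit(close(con), add = TRUE)
  magic <- read_u32be(con)
  if (magic != 0x0803L) {
    stop("bad IDX image magic at offset 0: got 0x",
         format(as.hexmode(magic), width = 8), ", expected 0x00000803")
  }
  n <- read_u32be(con); rows <- read_u32be(con); cols <- read_u32be(con)
  raw <- readBin(con, "integer", n = n * rows * cols, size = 1L,
                 signed = FALSE)
  if (length(raw) < n * rows * cols) {
    stop("truncated IDX image file at offset ",
         16L + length(raw), ": expected ", n * rows * cols, " pixel bytes")
  }
  # IDX stores row-major per image: cols fastest, then rows, then images
  x <- aperm(array(as.numeric(raw), c(cols, rows, n)), c(2, 1, 3))
  xx <- array(0, c(1L, rows, cols, n))
  xx[1L, , , ] <- x
  if (normalize) xx <- normalize_pixels(xx)
  y <- rep(1L, n)
  classes <- 1L
  if (!is.null(label_file)) {
    lab <- read_idx_labels(label_file)
    if (length(lab) != n) {
      stop("label file has ", length(lab), " entries for ", n, " images")
    }
    y <- lab + 1L
    classes <- max(10L, max(y))
  }
  image_batch(xx, y, classes = classes)
}

read_idx_labels <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- read_u32be(con)
  if (magic != 0x0801L) {
    stop("bad IDX label magic at offset 0: got 0x",
         format(as.hexmode(magic), width = 8), ", expected 0x00000801")
  }
  n <- read_u32be(con)
  lab <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  if (length(lab) < n) {
    stop("truncated IDX label file at offset ", 8L + length(lab))
  }
  lab
}

#' Write an image batch as an IDX image/label pair
#'
#' Inverse of [read_idx()]; pixels are mapped from `[-1, 1]` back to bytes
#' (rounded), labels to `0..classes-1`. Used so generated fixtures and real
#' files share one reading path.
#'
#' @param batch a single-channel `image_batch`.
#' @param image_file,label_file output paths.
#' @return invisibly, the two paths.
#' @export
write_idx <- function(batch, image_file, label_file) {
  stopifnot(inherits(batch, "image_batch"), dim(batch$x)[1] == 1L)
  d <- dim(batch$x)
  raw_px <- round((batch$x + 1) / 2 * 255)
  raw_px[raw_px < 0] <- 0; raw_px[raw_px > 255] <- 255
  con <- file(image_file, "wb")
  writeBin(c(0x0803L, d[4], d[2], d[3]), con, size = 4L, endian = "big")
  # row-major per image: cols fastest
  img <- aperm(array(raw_px, d[2:4]), c(2, 1, 3))
  writeBin(as.integer(img), con, size = 1L)
  close(con)
  con <- file(label_file, "wb")
  writeBin(c(0x0801L, d[4]), con, size = 4L, endian = "big")
  writeBin(as.integer(batch$y - 1L), con, size = 1L)
  close(con)
  invisible(c(image_file, label_file))
}

# ---- CIFAR-10 binary batch format ------------------------------------------

#' Read a CIFAR-10 binary batch file
#'
#' Each record is 3073 bytes: 1 label byte followed by 3072 pixel bytes
#' (1024 red, 1024 green, 1024 blue, each 32x32 row-major).
#'
#' @param path path to a binary batch file.
#' @param normalize apply [normalize_pixels()] (default `TRUE`).
#' @return an [image_batch()] with 3 channels and classes `1..10`.
#' @export
read_cifar_binary <- function(path, normalize = TRUE) {
  size <- file.info(path)$size
  if (is.na(size) || size == 0L) stop("cannot read ", path)
  if (size %% 3073 != 0) {
    stop("truncated CIFAR binary file: ", size,
         " bytes is not a multiple of the 3073-byte record",
         " (offset of partial record: ", (size %/% 3073) * 3073, ")")
  }
  n <- size %/% 3073
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, "integer", n = size, size = 1L, signed = FALSE)
  rec <- matrix(raw, nrow = 3073L)
  y <- rec[1L, ] + 1L
  if (any(y > 10L)) stop("bad CIFAR label byte > 9 in record ",
                         which(y > 10L)[1])
  px <- rec[-1L, , drop = FALSE]                 # 3072 x n
  # per channel: 32 x 32 row-major (cols fastest)
  x <- array(0, c(3L, 32L, 32L, n))
  for (ch in 1:3) {
    block <- px[((ch - 1L) * 1024L + 1L):(ch * 1024L), , drop = FALSE]
    x[ch, , , ] <- aperm(array(as.numeric(block), c(32L, 32L, n)),
                         c(2, 1, 3))
  }
  if (normalize) x <- normalize_pixels(x)
  image_batch(x, y, classes = 10L)
}

#' Write an image batch as a CIFAR-10 binary batch file
#'
#' Inverse of [read_cifar_binary()] for 3-channel, 32x32 batches.
#'
#' @param batch a 3-channel 32x32 `image_batch` with classes `1..10`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cifar_binary <- function(batch, path) {
  d <- dim(batch$x)
  stopifnot(d[1] == 3L, d[2] == 32L, d[3] == 32L)
  raw_px <- round((batch$x + 1) / 2 * 255)
  raw_px[raw_px < 0] <- 0; raw_px[raw_px > 255] <- 255
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(d[4])) {
    writeBin(as.integer(batch$y[i] - 1L), con, size = 1L)
    for (ch in 1:3) {
      img <- t(matrix(raw_px[ch, , , i], 32L, 32L))  # row-major
      writeBin(as.integer(img), con, size = 1L)
    }
  }
  invisible(path)
}
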