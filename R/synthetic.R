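# Synthetic RGB classification fixtures.  Small class-separable image sets
# standing in for natural/biomedical benchmarks at smoke scale, so every
# test and example runs without downloads.

#' Generate a balanced synthetic image classification set
#'
#' Produces `n` RGB images of `size x size` pixels in `[0, 1]`, evenly
#' split over `classes` classes.  Each class has its own mean colour, blob
#' count and texture frequency: images are a class-coloured background
#' with `class` Gaussian blobs at random positions plus a sinusoidal
#' texture of class-dependent frequency, corrupted by additive uniform
#' noise.  The classes are separable by mean colour alone, so a linear
#' probe (and hence a short training run) can exceed chance accuracy.
#' Deterministic given `seed`.
#'
#' @param classes Number of classes (>= 2).
#' @param n Total number of images; must allow an exact `n / classes`
#'   split.
#' @param size Image side length in pixels.
#' @param seed Integer seed.
#' @param noise Amplitude of the additive uniform noise (default 0.15).
#' @return A list of class `"synthetic_set"`: `images` (`n x size x size
#'   x 3` array), `labels` (integer vector, 1-based), and the generator
#'   `params`.
#' @examples
#' s <- generate_synthetic_set(4, 32, size = 16, seed = 1)
#' table(s$labels)
#' @export
generate_synthetic_set <- function(classes, n, size = 32L, seed = 1L,
                                   noise = 0.15) {
  classes <- check_count(classes, "classes")
  if (classes < 2) stop("`classes` must be at least 2")
  n <- check_count(n, "n"); size <- check_count(size, "size")
  if (n %% classes != 0)
    stop("`n` must be a multiple of `classes` (balanced design)")
  set.seed(seed)
  per <- n %/% classes
  labels <- rep(seq_len(classes), each = per)
  # distinct base colours around the hue circle
  hue <- (seq_len(classes) - 1) / classes
  base <- t(sapply(hue, function(h) {
    c(0.5 + 0.35 * cos(2 * pi * h),
      0.5 + 0.35 * cos(2 * pi * (h + 1 / 3)),
      0.5 + 0.35 * cos(2 * pi * (h + 2 / 3)))
  }))
  gx <- matrix(seq_len(size), size, size)
  gy <- t(gx)
  images <- array(0, c(n, size, size, 3L))
  for (i in seq_len(n)) {
    k <- labels[i]
    img <- array(rep(base[k, ], each = size * size), c(size, size, 3L))
    # class-dependent sinusoidal texture
    freq <- k / size * 2 * pi * 2
    tex <- 0.08 * sin(freq * gx + stats::runif(1, 0, 2 * pi)) *
      cos(freq * gy + stats::runif(1, 0, 2 * pi))
    for (cch in 1:3) img[, , cch] <- img[, , cch] + tex
    # k Gaussian blobs at random positions
    for (b in seq_len(k)) {
      cx <- stats::runif(1, 1, size); cy <- stats::runif(1, 1, size)
      s2 <- (size / 8)^2
      blob <- 0.25 * exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * s2))
      ch <- 1L + (b - 1L) %% 3L
      img[, , ch] <- img[, , ch] + blob
    }
    img <- img + stats::runif(length(img), -noise, noise)
    images[i, , , ] <- pmin(pmax(img, 0), 1)
  }
  structure(list(images = images, labels = labels,
                 params = list(classes = classes, n = n, size = size,
                               seed = seed, noise = noise)),
            class = "synthetic_set")
}

#' @export
print.synthetic_set <- function(x, ...) {
  p <- x$params
  cat(sprintf("synthetic image set: %d images, %d classes, %dx%d px, seed %d\n",
              p$n, p$classes, p$size, p$size, p$seed))
  invisible(x)
}

#' Linear probe accuracy on mean-colour features
#'
#' Fits a multinomial linear classifier (one ridge-regularised least
#' squares indicator regression per class) on the per-image mean RGB
#' features and reports its training accuracy.  Used to certify that a
#' synthetic set is learnable before spending time on a network.
#'
#' @param data A [generate_synthetic_set()] result.
#' @return Accuracy in `[0, 1]`.
#' @export
linear_probe_accuracy <- function(data) {
  n <- dim(data$images)[1L]
  feat <- t(vapply(seq_len(n), function(i)
    colMeans(matrix(data$images[i, , , ], ncol = 3L)), numeric(3L)))
  X <- cbind(1, feat)
  Y <- outer(data$labels, seq_len(max(data$labels)), "==") * 1
  B <- solve(crossprod(X) + diag(1e-6, ncol(X)), crossprod(X, Y))
  mean(max.col(X %*% B) == data$labels)
}

#' Export synthetic images as PNG files
#'
#' Writes each image (or the first `limit`) as an individual PNG for
#' visual inspection.  Requires the `png` package.
#'
#' @param data A [generate_synthetic_set()] result.
#' @param dir Output directory (created if missing).
#' @param limit Maximum number of images to write (default 16).
#' @return The directory, invisibly.
#' @export
export_synthetic_png <- function(data, dir, limit = 16L) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the `png` package is required for PNG export")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- min(dim(data$images)[1L], limit)
  for (i in seq_len(n)) {
    img <- data$images[i, , , ]
    png::writePNG(img, file.path(dir, sprintf("class%d_img%03d.png",
                                              data$labels[i], i)))
  }
  invisible(dir)
}
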