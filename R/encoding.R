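#' Gray-level digit images
#'
#' A `gray_image` is the raw object of a sequence: 784 integer pixel values
#' (a 28 x 28 raster stored row-major) in gray-level units `[0, 255]`, plus
#' an integer class label in `[0, 9]`.
#'
#' @param pixels numeric vector of 784 values in `[0, 255]`.
#' @param label integer in `[0, 9]`.
#' @return an object of class `gray_image` with elements `pixels` (integer)
#'   and `label`.
#' @export
#' @examples
#' img <- gray_image(rep(0L, 784), label = 0)
gray_image <- function(pixels, label) {
  pixels <- as.integer(round(pixels))
  if (length(pixels) != 784L)
    stop("a gray_image needs exactly 784 pixels, got ", length(pixels))
  if (anyNA(pixels) || any(pixels < 0L) || any(pixels > 255L))
    stop("pixel values must lie in [0, 255]")
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || label < 0L || label > 9L)
    stop("label must be a single integer in [0, 9]")
  structure(list(pixels = pixels, label = label), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat("<gray_image> label", x$label,
      " mean gray", round(mean(x$pixels), 1),
      " bright(>100)", sum(x$pixels > 100L), "px\n")
  invisible(x)
}

#' Convert gray levels to firing probabilities
#'
#' Each of the 784 pixels is divided by 255 so that its gray level becomes
#' the per-frame firing probability of the corresponding input node.
#'
#' @param image a [gray_image].
#' @return numeric vector of 784 probabilities in `[0, 1]`
#'   (class `firing_prob_map`).
#' @export
normalize_to_prob <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  structure(image$pixels / 255, class = "firing_prob_map")
}

#' Encode firing probabilities as Boolean spike frames
#'
#' Generates `d` Boolean frames for one digit presentation: pixel `p` spikes
#' in frame `k` iff an independent uniform draw `u` in `[0, 1)` satisfies
#' `u < prob[p]` (strict, so probability 0 never spikes and probability 1
#' always does).  Consecutive frames are nominally `frame_spacing` ms apart.
#'
#' @param probs a `firing_prob_map` (or numeric vector of probabilities).
#' @param d number of frames, `>= 1`.
#' @param seed integer RNG seed; identical seeds give bit-identical trains.
#' @param frame_spacing frame spacing in ms (default 10).
#' @return a `frame_train`: logical `d x n` matrix with attributes
#'   `frame_spacing`.
#' @export
encode_frames <- function(probs, d, seed, frame_spacing = 10) {
  p <- unclass(probs)
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]")
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1")
  n <- length(p)
  u <- with_seed(seed, matrix(stats::runif(d * n), nrow = d))
  frames <- u < matrix(p, nrow = d, ncol = n, byrow = TRUE)
  structure(frames, frame_spacing = frame_spacing, class = c("frame_train", "matrix"))
}

#' Add writer-style flat noise to bright pixels
#'
#' Emulates repeated handwriting by one individual: every pixel whose gray
#' level exceeds `gray_floor` receives an independent integer uniform draw
#' in `[noise_lo, noise_hi]`, after which values are clipped to `[0, 255]`.
#' Pixels at or below `gray_floor` are untouched.
#'
#' @param image a [gray_image].
#' @param noise_lo,noise_hi integer noise bounds (defaults -20, 20).
#' @param gray_floor gray level above which noise applies (default 100).
#' @param seed integer RNG seed.
#' @return a [gray_image] with the same label.
#' @export
handwriting_variant <- function(image, noise_lo = -20L, noise_hi = 20L,
                                gray_floor = 100L, seed) {
  stopifnot(inherits(image, "gray_image"))
  if (noise_lo > noise_hi) stop("noise_lo must be <= noise_hi")
  px <- image$pixels
  bright <- px > gray_floor
  noise <- with_seed(seed,
    sample(seq.int(noise_lo, noise_hi), sum(bright), replace = TRUE))
  px[bright] <- pmin(255L, pmax(0L, px[bright] + as.integer(noise)))
  gray_image(px, image$label)
}

#' Handwriting distance between two images
#'
#' The maximal absolute gray-level difference over pixels that exceed gray
#' level 100 in *both* images; 0 when no pixel qualifies.  Two images of the
#' same handwriting (generated by [handwriting_variant] noise in
#' `[-20, 20]` around one base image) stay within distance 20 of the base,
#' whereas independent writers are far apart.
#'
#' @param a,b [gray_image] objects of the same shape.
#' @param gray_floor gray level both pixels must exceed (default 100).
#' @return non-negative scalar.
#' @export
handwriting_distance <- function(a, b, gray_floor = 100L) {
  stopifnot(inherits(a, "gray_image"), inherits(b, "gray_image"))
  if (length(a$pixels) != length(b$pixels)) stop("images differ in shape")
  both <- a$pixels > gray_floor & b$pixels > gray_floor
  if (!any(both)) return(0)
  max(abs(a$pixels[both] - b$pixels[both]))
}

#' Export a gray image as PNG (debugging aid)
#'
#' @param image a [gray_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  png::writePNG(matrix(image$pixels / 255, 28, 28, byrow = TRUE), path)
  invisible(path)
}
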