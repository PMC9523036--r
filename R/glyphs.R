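# Synthetic glyph generator: programmatic thick-stroke digit templates with
# elastic jitter and per-writer noise.  Serves as a download-free stand-in
# for scanned handwritten digits with controllable intra-class variability.

# Digit stroke paths as polylines in the unit square (x right, y down).
# Curved parts are polygonal approximations of ellipse arcs.
.ellipse_path <- function(cx, cy, rx, ry, from = 0, to = 2 * pi, n = 17) {
  t <- seq(from, to, length.out = n)
  cbind(cx + rx * cos(t), cy + ry * sin(t))
}

.glyph_paths <- function(label) {
  switch(as.character(label),
    "0" = list(.ellipse_path(0.50, 0.50, 0.30, 0.42)),
    "1" = list(rbind(c(0.32, 0.20), c(0.55, 0.05), c(0.55, 0.95)),
               rbind(c(0.35, 0.95), c(0.75, 0.95))),
    "2" = list(rbind(c(0.15, 0.22), c(0.30, 0.06), c(0.68, 0.06),
                     c(0.85, 0.24), c(0.78, 0.42), c(0.15, 0.94),
                     c(0.87, 0.94))),
    "3" = list(rbind(c(0.16, 0.10), c(0.72, 0.05), c(0.85, 0.25), c(0.45, 0.45)),
               rbind(c(0.45, 0.45), c(0.88, 0.60), c(0.80, 0.90), c(0.15, 0.93))),
    "4" = list(rbind(c(0.70, 0.95), c(0.70, 0.05), c(0.12, 0.62), c(0.90, 0.62))),
    "5" = list(rbind(c(0.80, 0.06), c(0.22, 0.06), c(0.18, 0.45), c(0.60, 0.40),
                     c(0.86, 0.62), c(0.74, 0.90), c(0.15, 0.92))),
    "6" = list(rbind(c(0.70, 0.05), c(0.34, 0.34), c(0.21, 0.62)),
               .ellipse_path(0.50, 0.70, 0.29, 0.24)),
    "7" = list(rbind(c(0.12, 0.06), c(0.88, 0.06), c(0.40, 0.95)),
               rbind(c(0.30, 0.52), c(0.72, 0.52))),
    "8" = list(.ellipse_path(0.50, 0.27, 0.26, 0.21),
               .ellipse_path(0.50, 0.72, 0.30, 0.24)),
    "9" = list(.ellipse_path(0.50, 0.30, 0.28, 0.24),
               rbind(c(0.78, 0.32), c(0.70, 0.95))),
    stop("unknown label: ", label)
  )
}

# Distance from each pixel centre to a segment, vectorised over pixels.
.seg_dist <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx * vx + vy * vy
  if (L2 < 1e-12) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / L2))
  sqrt((px - x1 - t * vx)^2 + (py - y1 - t * vy)^2)
}

# Render a label's strokes on the 28x28 grid.  dx/dy shift in pixels,
# width in pixels, amp peak gray level.
.render_glyph <- function(label, dx = 0, dy = 0, width = 1.1, amp = 240) {
  grid <- expand.grid(col = 1:28, row = 1:28) # row-major pixel order
  px <- grid$col - 0.5
  py <- grid$row - 0.5
  val <- numeric(784)
  for (path in .glyph_paths(label)) {
    gx <- 4.5 + path[, 1] * 19 + dx
    gy <- 2.5 + path[, 2] * 23 + dy
    for (s in seq_len(nrow(path) - 1L)) {
      d <- .seg_dist(px, py, gx[s], gy[s], gx[s + 1L], gy[s + 1L])
      val <- pmax(val, amp * exp(-(d / width)^2))
    }
  }
  pmin(255, pmax(0, round(val)))
}

#' Generate a synthetic gray-level digit image
#'
#' Renders a thick-stroke template glyph for the requested digit and, in the
#' default mode, perturbs it with elastic jitter (sub-pixel shift, stroke
#' width and intensity variation) plus flat pixel noise, giving the
#' intra-class variability of a small handwritten training set.  In
#' same-writer mode (`writer` given) the geometry is fixed and the image is
#' the writer's base glyph -- a fixed per-writer intensity offset field on
#' bright pixels -- plus per-image integer noise in `[-10, 10]` on bright
#' pixels, so any two images of one writer have
#' `handwriting_distance() <= 20` while different writers are far apart.
#'
#' @param label digit in `[0, 9]`.
#' @param seed integer RNG seed; calls with identical arguments are
#'   bit-identical.
#' @param writer `NULL` for generic mode, or an integer writer id.
#' @param jitter_px maximum absolute sub-pixel translation (generic mode).
#' @param pixel_noise half-width of the flat pixel noise (generic mode).
#' @return a [gray_image].
#' @export
#' @examples
#' img <- synthetic_digit(3, seed = 1)
#' a <- synthetic_digit(3, seed = 2, writer = 1)
#' b <- synthetic_digit(3, seed = 3, writer = 1)
#' handwriting_distance(a, b) # <= 20
synthetic_digit <- function(label, seed, writer = NULL,
                            jitter_px = 1.5, pixel_noise = 45L) {
  label <- as.integer(label)
  if (is.na(label) || label < 0L || label > 9L) stop("unknown label: ", label)
  if (is.null(writer)) {
    px <- with_seed(seed, {
      dx <- stats::runif(1, -jitter_px, jitter_px)
      dy <- stats::runif(1, -jitter_px, jitter_px)
      w <- stats::runif(1, 1.4, 2.0)  # 2-3 px strokes, as in scanned digits
      amp <- stats::runif(1, 235, 255) # saturated stroke cores
      base <- .render_glyph(label, dx, dy, w, amp)
      noise <- sample(seq.int(-pixel_noise, pixel_noise), 784, replace = TRUE)
      pmin(255, pmax(0, base + noise))
    })
    return(gray_image(px, label))
  }
  wid <- if (is.list(writer)) writer$id else writer
  base <- writer_base_image(label, wid)
  handwriting_variant(base, noise_lo = -10L, noise_hi = 10L, seed = seed)
}

#' A writer's base glyph for one digit
#'
#' Deterministic per `(label, writer_id)`: the template glyph under a fixed
#' writer-specific deformation (sub-pixel shift and stroke width -- an
#' individual's hand) plus a fixed integer intensity offset field in
#' `[-35, 35]` on its bright (> 100) pixels.  Peak amplitude 200 keeps
#' offsets clear of the 255 ceiling.
#'
#' @param label digit in `[0, 9]`.
#' @param writer_id integer writer identity.
#' @return a [gray_image].
#' @export
writer_base_image <- function(label, writer_id) {
  base <- with_seed(derive_seed(writer_id, 88L), {
    dx <- stats::runif(1, -1, 1)
    dy <- stats::runif(1, -1, 1)
    w <- stats::runif(1, 1.5, 1.9)
    .render_glyph(label, dx, dy, w, amp = 200)
  })
  bright <- base > 100
  off <- with_seed(derive_seed(writer_id, label, 77L),
                   sample(-35:35, sum(bright), replace = TRUE))
  base[bright] <- pmin(255, pmax(0, base[bright] + off))
  gray_image(base, label)
}
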