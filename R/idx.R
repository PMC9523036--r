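# IDX is the big-endian binary dialect used by the classic handwritten-digit
# benchmark: magic 0x00000803 + dims for image files, 0x00000801 + count for
# label files, then raw unsigned bytes.

#' Read an IDX image/label file pair
#'
#' @param images_path path to an IDX3 image file (magic `0x00000803`).
#' @param labels_path path to the matching IDX1 label file
#'   (magic `0x00000801`).
#' @return list of [gray_image] objects.
#' @export
read_idx <- function(images_path, labels_path) {
  for (p in c(images_path, labels_path))
    if (!file.exists(p)) stop("file not found: ", p)

  icon <- file(images_path, "rb"); on.exit(close(icon), add = TRUE)
  magic <- readBin(icon, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2051L))
    stop("bad magic number in image file: ", magic, " (expected 2051)")
  dims <- readBin(icon, "integer", 3, size = 4, endian = "big")
  n <- dims[1]; nr <- dims[2]; nc <- dims[3]
  raw <- readBin(icon, "integer", n * nr * nc, size = 1, signed = FALSE)
  if (length(raw) != n * nr * nc) stop("truncated image file: ", images_path)

  lcon <- file(labels_path, "rb"); on.exit(close(lcon), add = TRUE)
  lmagic <- readBin(lcon, "integer", 1, size = 4, endian = "big")
  if (!identical(lmagic, 2049L))
    stop("bad magic number in label file: ", lmagic, " (expected 2049)")
  nl <- readBin(lcon, "integer", 1, size = 4, endian = "big")
  if (nl != n) stop("image/label count mismatch: ", n, " vs ", nl)
  labels <- readBin(lcon, "integer", nl, size = 1, signed = FALSE)
  if (length(labels) != nl) stop("truncated label file: ", labels_path)

  lapply(seq_len(n), function(i) {
    gray_image(raw[((i - 1) * nr * nc + 1):(i * nr * nc)], labels[i])
  })
}

#' Write gray images as an IDX file pair
#'
#' Counterpart of [read_idx], used to build small test fixtures.
#'
#' @param images list of [gray_image] objects.
#' @param images_path,labels_path output paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_idx <- function(images, images_path, labels_path) {
  n <- length(images)
  icon <- file(images_path, "wb"); on.exit(close(icon), add = TRUE)
  writeBin(c(2051L, n, 28L, 28L), icon, size = 4, endian = "big")
  for (img in images)
    writeBin(as.raw(img$pixels), icon)
  lcon <- file(labels_path, "wb"); on.exit(close(lcon), add = TRUE)
  writeBin(c(2049L, n), lcon, size = 4, endian = "big")
  writeBin(as.raw(vapply(images, function(i) i$label, integer(1))), lcon)
  invisible(c(images_path, labels_path))
}
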