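#' Image stack container
#'
#' Wraps a 2D/3D grayscale intensity array together with its physical voxel
#' size. All downstream code assumes a *dark* foreground (cells darker than
#' the background); stacks acquired with light foreground are inverted at
#' construction so the rest of the pipeline never has to branch on polarity.
#'
#' @param data integer array, dimensions `(nx, ny)` or `(nx, ny, nz)`.
#' @param voxel_size numeric length-3, physical voxel edge lengths
#'   `(dx, dy, dz)` in micrometres; all strictly positive. For 2D data `dz`
#'   is still required (slice thickness) but only enters 3D measures.
#' @param polarity `"dark"` if the foreground (cells) is darker than the
#'   background, `"light"` otherwise; light-foreground data is inverted to
#'   `max_int - v`.
#' @param bit_depth 8 or 16; defaults to the smallest depth containing the
#'   data.
#' @return An object of class `image_stack`: a list with elements `data`
#'   (3D integer array, z extent 1 for 2D input), `voxel_size`, `bit_depth`
#'   and `max_int`.
#' @seealso [read_stack()] to build one from a TIFF file.
#' @export
image_stack <- function(data, voxel_size, polarity = c("dark", "light"),
                        bit_depth = NULL) {
  polarity <- match.arg(polarity)
  if (!is.array(data) && !is.matrix(data)) stop("`data` must be an array")
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3) stop("`data` must be 2D or 3D")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three strictly positive values (μm)")
  storage.mode(data) <- "integer"
  if (anyNA(data) || min(data) < 0) stop("intensities must be non-negative")
  if (is.null(bit_depth)) bit_depth <- if (max(data) > 255L) 16L else 8L
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  max_int <- as.integer(2^bit_depth - 1)
  if (max(data) > max_int) stop("intensities exceed the declared bit depth")
  if (polarity == "light") data[] <- max_int - data
  structure(list(data = data, voxel_size = voxel_size,
                 bit_depth = as.integer(bit_depth), max_int = max_int),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d voxels, %d-bit\n", d[1], d[2], d[3],
              x$bit_depth))
  cat(sprintf("  voxel size: %.3g x %.3g x %.3g μm\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range: [%d, %d]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Read a TIFF stack
#'
#' Reads a single- or multi-page TIFF (grayscale or RGB) into an
#' [image_stack()]. Fluorescence stacks are often RGB with the signal in one
#' channel (typically green); `channel` selects that plane. Light-foreground
#' images are inverted on read so that downstream code always sees dark
#' cells on a light background.
#'
#' @param path path to a TIFF file.
#' @param voxel_size `(dx, dy, dz)` in micrometres.
#' @param channel for RGB input, which channel carries the signal
#'   (`"red"`, `"green"`, `"blue"` or an index 1..3). Ignored for grayscale.
#' @param polarity `"dark"` (default) or `"light"` foreground.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, voxel_size, channel = NULL,
                       polarity = c("dark", "light")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # readTIFF returns some samples rescaled to [0, 1]; undo via the recorded
  # sample depth
  pages <- lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    if (is.double(p) && max(p) <= 1) round(p * (2^bits - 1)) else p
  })
  bit <- if (max(vapply(pages, max, 0)) > 255) 16L else 8L
  pick <- function(p) {
    if (length(dim(p)) == 3) {           # RGB page: rows x cols x channels
      if (is.null(channel))
        stop("multi-channel TIFF: `channel` must be given")
      ch <- if (is.character(channel))
        match(match.arg(channel, c("red", "green", "blue")),
              c("red", "green", "blue"))
      else as.integer(channel)
      if (is.na(ch) || ch < 1 || ch > dim(p)[3])
        stop("channel out of range")
      p <- p[, , ch]
    }
    t(p)                                 # rows=y, cols=x -> (x, y)
  }
  planes <- lapply(pages, pick)
  arr <- array(0L, dim = c(dim(planes[[1]]), length(planes)))
  for (k in seq_along(planes)) arr[, , k] <- as.integer(planes[[k]])
  image_stack(arr, voxel_size, polarity = polarity, bit_depth = bit)
}

#' Write an image stack as a multi-page TIFF
#'
#' Inverse of [read_stack()] for dark-foreground grayscale data; used by the
#' phantom generator to persist synthetic stacks.
#'
#' @param stack an `image_stack`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  pages <- lapply(seq_len(d[3]), function(k)
    t(stack$data[, , k]) / stack$max_int)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  invisible(path)
}

#' Threshold an image stack
#'
#' Foreground indicator at threshold `t`: a voxel is set when its intensity
#' is less than or equal to `t` (dark foreground convention).
#'
#' @param stack an `image_stack`.
#' @param t intensity threshold, within the stack's intensity range.
#' @return logical array of the stack's dimensions.
#' @export
binarize <- function(stack, t) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.finite(t) || t < 0 || t > stack$max_int)
    stop("threshold outside the intensity range")
  stack$data <= t
}

#' Minimum-intensity projection over a central slab
#'
#' Projects a dark-foreground stack to 2D by taking, per (x, y) column, the
#' minimum intensity over a central slab of the given physical thickness.
#' For dark cells on a light background this is the analogue of a maximum
#' intensity projection. Restricting to a roughly one-cell-thick slab
#' (default 30 micrometres) limits how many cells overlap in the projection;
#' threshold selection then runs on this 2D image rather than the full
#' volume.
#'
#' @param stack an `image_stack`.
#' @param slab_um slab thickness in micrometres (> 0). A slab thinner than
#'   one z-step falls back to the single central slice.
#' @return integer matrix `(nx, ny)`.
#' @export
min_projection <- function(stack, slab_um = 30) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.finite(slab_um) || slab_um <= 0) stop("`slab_um` must be > 0")
  nz <- dim(stack$data)[3]
  nsl <- max(1L, min(nz, as.integer(round(slab_um / stack$voxel_size[3]))))
  lo <- (nz - nsl) %/% 2 + 1L
  slab <- stack$data[, , lo:(lo + nsl - 1L), drop = FALSE]
  apply(slab, c(1, 2), min)
}
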