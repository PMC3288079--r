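# Pixel-affinity graph construction for stability-based image segmentation.
# Each pixel is a node; pixels within a Chebyshev radius are connected with a
# Gaussian affinity in intensity difference and Euclidean pixel distance.
# Community detection on this graph segments the image; the communities are
# inherently non clique-like because the graph inherits the planar geometry.

#' Load a grayscale image as an intensity grid
#'
#' Reads PNG or TIFF; RGB images are converted with the Rec. 601 luminance
#' weights. Values are in `[0, 1]`.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @return numeric matrix (rows = image rows).
#' @export
load_grayscale <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    img <- if (ch >= 3L) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  img
}

#' Pixel-affinity graph of a grayscale image
#'
#' Connects every pixel pair within Chebyshev distance `radius` with weight
#' \deqn{w = \exp(-\Delta I^2 / 2\sigma_I^2)\,\exp(-\Delta d^2 / 2\sigma_d^2)}
#' where \eqn{\Delta I} is the intensity difference and \eqn{\Delta d} the
#' Euclidean pixel distance. Node ids are row-major over the grid. The graph
#' is connected for any `radius >= 1` since the kernel is strictly positive.
#'
#' @param intensities numeric h-by-w matrix with values in `[0, 1]`.
#' @param radius neighborhood Chebyshev radius (`>= 1`).
#' @param sigma_intensity intensity kernel scale (`> 0`).
#' @param sigma_distance distance kernel scale in pixels (`> 0`).
#' @return list with `graph` (a [weighted_graph()]) and `map` (a
#'   `pixel_graph_map`: `height`, `width`, and the row-major pixel/node
#'   bijection helpers `node_of_pixel(row, col)` / `pixel_of_node(id)`).
#' @export
image_to_graph <- function(intensities, radius = 1L, sigma_intensity = 0.1,
                           sigma_distance = 2) {
  if (!is.matrix(intensities) || length(intensities) == 0L) {
    stop("intensities must be a non-empty numeric matrix")
  }
  if (radius < 1L) stop("radius must be at least 1")
  if (sigma_intensity <= 0 || sigma_distance <= 0) stop("kernel scales must be positive")
  h <- nrow(intensities); w <- ncol(intensities)
  n <- h * w
  node <- function(r, c) (r - 1L) * w + c   # row-major, 1-based
  offs <- expand.grid(dr = 0:radius, dc = -radius:radius)
  offs <- offs[offs$dr > 0 | (offs$dr == 0 & offs$dc > 0), ]  # half-plane, no double count
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    r1 <- seq_len(h - dr)
    c1 <- seq.int(max(1L, 1L - dc), min(w, w - dc))
    if (length(r1) == 0L || length(c1) == 0L) next
    rr <- rep(r1, times = length(c1)); cc <- rep(c1, each = length(r1))
    a <- node(rr, cc); b <- node(rr + dr, cc + dc)
    dI <- intensities[cbind(rr, cc)] - intensities[cbind(rr + dr, cc + dc)]
    d2 <- dr^2 + dc^2
    wk <- exp(-dI^2 / (2 * sigma_intensity^2)) * exp(-d2 / (2 * sigma_distance^2))
    from <- c(from, a); to <- c(to, b); wt <- c(wt, wk)
  }
  A <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = c(wt, wt),
                            dims = c(n, n))
  map <- structure(list(height = h, width = w,
                        node_of_pixel = function(row, col) (row - 1L) * w + col,
                        pixel_of_node = function(id) {
                          id <- as.integer(id)
                          cbind(row = (id - 1L) %/% w + 1L,
                                col = (id - 1L) %% w + 1L)
                        }),
                   class = "pixel_graph_map")
  list(graph = weighted_graph(A), map = map)
}

#' @export
print.pixel_graph_map <- function(x, ...) {
  cat(sprintf("pixel_graph_map: %d x %d image, %d nodes (row-major)\n",
              x$height, x$width, x$height * x$width))
  invisible(x)
}

#' Render a partition of a pixel graph as a label grid
#'
#' @param map the `pixel_graph_map` from [image_to_graph()].
#' @param p an [partition()] over the `h * w` pixel nodes.
#' @return integer h-by-w matrix of community ids.
#' @export
partition_to_labels <- function(map, p) {
  if (!inherits(map, "pixel_graph_map")) stop("expected a pixel_graph_map")
  p <- as_partition(p)
  if (length(p) != map$height * map$width) {
    stop(sprintf("partition covers %d nodes but the image has %d pixels",
                 length(p), map$height * map$width))
  }
  matrix(as.integer(p), nrow = map$height, ncol = map$width, byrow = TRUE)
}

#' Write a label grid as a false-color PNG and/or CSV
#'
#' @param labels integer label matrix from [partition_to_labels()].
#' @param png_path,csv_path output paths (either may be `NULL`).
#' @export
write_label_image <- function(labels, png_path = NULL, csv_path = NULL) {
  if (!is.null(png_path)) {
    k <- max(labels)
    cols <- grDevices::hsv(h = (seq_len(k) - 1) / max(k, 1), s = 0.65, v = 0.95)
    rgb <- grDevices::col2rgb(cols[labels]) / 255
    img <- array(0, dim = c(nrow(labels), ncol(labels), 3))
    img[, , 1] <- matrix(rgb[1, ], nrow(labels)); img[, , 2] <- matrix(rgb[2, ], nrow(labels))
    img[, , 3] <- matrix(rgb[3, ], nrow(labels))
    png::writePNG(img, png_path)
  }
  if (!is.null(csv_path)) {
    utils::write.table(labels, csv_path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(labels)
}
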