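#' Rasterize a polygon ROI to a pixel mask
#'
#' Converts a simple closed polygon in 0-based pixel coordinates into a
#' logical mask over an image of the given dimensions. A pixel belongs to
#' the ROI iff its center falls inside the polygon (pixel `(r, c)`, 0-based,
#' has center `(r + 0.5, c + 0.5)`), which makes masks bit-reproducible.
#' Membership is decided by the even-odd (crossing-number) rule, vectorized
#' over pixel centers; vertices should avoid half-integer coordinates so no
#' pixel center lies exactly on an edge.
#'
#' @param poly List with numeric vectors `x` and `y` (equal length >= 3),
#'   vertices in order; the polygon is closed implicitly.
#' @param dim Image dimensions `c(height, width)`.
#' @return Logical matrix of dimension `dim`.
#' @export
rasterize_polygon <- function(poly, dim) {
  stopifnot(is.list(poly), length(poly$x) == length(poly$y),
            length(poly$x) >= 3)
  h <- dim[1]; w <- dim[2]
  if (any(poly$x < 0 | poly$x > w | poly$y < 0 | poly$y > h)) {
    stop("ROI polygon extends outside the image bounds")
  }
  r0 <- max(1L, floor(min(poly$y)) + 1L); r1 <- min(h, ceiling(max(poly$y)))
  c0 <- max(1L, floor(min(poly$x)) + 1L); c1 <- min(w, ceiling(max(poly$x)))
  mask <- matrix(FALSE, h, w)
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  nv <- length(poly$x)
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly$x[i]; yi <- poly$y[i]
    xj <- poly$x[j]; yj <- poly$y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mask[rows, cols] <- matrix(inside, length(rows), length(cols))
  mask
}

# Accept either a logical mask or a polygon; return a validated mask.
resolve_roi <- function(roi, dim) {
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == dim)) {
      stop("ROI mask dimensions do not match the image")
    }
    mask <- roi
  } else if (is.list(roi) && !is.null(roi$x)) {
    mask <- rasterize_polygon(roi, dim)
  } else {
    stop("roi must be a logical mask or a polygon list(x, y)")
  }
  if (!any(mask)) stop("ROI is empty (zero pixels)")
  mask
}

write_roi_json <- function(poly, roi_id, region, path) {
  jsonlite::write_json(
    list(roi_id = roi_id, region = region,
         coordinate_system = "pixel_0based",
         x = poly$x, y = poly$y),
    path, auto_unbox = TRUE, digits = NA
  )
}

read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(x = as.numeric(obj$x), y = as.numeric(obj$y),
       roi_id = obj$roi_id, region = obj$region)
}
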