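# Region-of-interest polygons. ROI1 delimits the whole defect, ROI2 the
# regenerated area colonized by new bone; ROI2 must lie inside ROI1.

#' Construct a region of interest
#'
#' @param polygon numeric matrix (n x 2) or list of `c(x, y)` pairs giving
#'   the closed ring vertices in pixel coordinates (0-based, x right,
#'   y down). The ring is closed implicitly; do not repeat the first vertex.
#' @param name ROI name, conventionally `"ROI1"` (defect area) or `"ROI2"`
#'   (regenerated area).
#' @return An object of class `roi`.
#' @export
roi <- function(polygon, name = "ROI1") {
  if (is.list(polygon)) polygon <- do.call(rbind, polygon)
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3)
    stop("ROI polygon needs at least 3 (x, y) vertices")
  if (anyNA(polygon) || !all(is.finite(polygon)))
    stop("ROI polygon vertices must be finite")
  structure(list(name = as.character(name), polygon = polygon), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi %s: %d vertices, bbox x [%g, %g] y [%g, %g]>\n",
              x$name, nrow(x$polygon),
              min(x$polygon[, 1]), max(x$polygon[, 1]),
              min(x$polygon[, 2]), max(x$polygon[, 2])))
  invisible(x)
}

#' Axis-aligned rectangular ROI
#'
#' @param x0,y0,x1,y1 rectangle corners in pixel coordinates.
#' @param name ROI name.
#' @return An [roi] object.
#' @export
roi_rect <- function(x0, y0, x1, y1, name = "ROI1") {
  roi(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)), name = name)
}

#' Rasterize an ROI polygon onto the pixel grid
#'
#' A pixel is included iff its center lies inside the polygon under the
#' even-odd (ray crossing) rule. Pixel `(x, y)` (0-based column x, row y)
#' has its center at the point `(x, y)`.
#'
#' @param r an [roi] object.
#' @param height,width image dimensions in pixels.
#' @return Logical matrix `height x width`.
#' @export
rasterize_roi <- function(r, height, width) {
  stopifnot(inherits(r, "roi"))
  poly <- r$polygon
  n <- nrow(poly)
  if (n < 3) stop("degenerate polygon")
  px <- rep(seq_len(width) - 1, each = height)
  py <- rep(seq_len(height) - 1, times = width)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  matrix(inside, nrow = height, ncol = width)
}

#' Read / write ROI polygons as JSON
#'
#' The on-disk form is `{"name": "ROI1", "polygon": [[x, y], ...]}`.
#'
#' @param path file path.
#' @return `read_roi_json` returns an [roi]; `write_roi_json` returns
#'   `path` invisibly.
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  roi(obj$polygon, name = obj$name)
}

#' @rdname read_roi_json
#' @param r an [roi] object to write.
#' @export
write_roi_json <- function(r, path) {
  stopifnot(inherits(r, "roi"))
  obj <- list(name = r$name, polygon = unname(r$polygon))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
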