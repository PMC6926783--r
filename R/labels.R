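# Tissue label codes used in every label mask. OUTSIDE marks pixels beyond
# the region of interest and never enters area or contact denominators.

#' Tissue class codes
#'
#' Integer codes used in label masks: `OUTSIDE = 0`, `BONE = 1`,
#' `BIOMATERIAL = 2`, `SOFT = 3`. The fixed ordering BONE < BIOMATERIAL <
#' SOFT also serves as the deterministic tie-break in nearest-centroid
#' segmentation.
#'
#' @format A named integer vector of length 4.
#' @export
TISSUE_CLASSES <- c(OUTSIDE = 0L, BONE = 1L, BIOMATERIAL = 2L, SOFT = 3L)

#' Construct a label mask
#'
#' A label mask is an integer matrix whose entries are the codes in
#' [TISSUE_CLASSES]. Dimensions follow R matrix convention (rows = image
#' height, columns = width); the package-wide pixel coordinate convention is
#' 0-based with x to the right (columns) and y downward (rows), and the
#' center of pixel `(x, y)` at the point `(x, y)`.
#'
#' @param m integer matrix of class codes.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(m) {
  if (!is.matrix(m)) stop("label mask must be a matrix")
  storage.mode(m) <- "integer"
  bad <- !(m %in% TISSUE_CLASSES)
  if (any(bad)) stop("label mask contains codes outside the tissue class set")
  structure(m, class = c("label_mask", "matrix", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  cts <- table(factor(as.vector(x), levels = TISSUE_CLASSES,
                      labels = names(TISSUE_CLASSES)))
  cat(sprintf("<label_mask %d x %d>\n", nrow(x), ncol(x)))
  print(cts)
  invisible(x)
}

#' Extract one tissue class as a binary mask
#'
#' @param mask a label mask (integer matrix of [TISSUE_CLASSES] codes).
#' @param cls class name (`"BONE"`, `"BIOMATERIAL"` or `"SOFT"`) or its
#'   integer code.
#' @return Logical matrix, `TRUE` exactly where `mask` equals `cls`.
#' @examples
#' m <- matrix(c(1L, 2L, 3L, 0L), 2, 2)
#' binarize(m, "BONE")
#' @export
binarize <- function(mask, cls) {
  code <- if (is.character(cls)) {
    if (!cls %in% names(TISSUE_CLASSES)[-1])
      stop("cls must be one of BONE, BIOMATERIAL, SOFT")
    TISSUE_CLASSES[[cls]]
  } else {
    cls <- as.integer(cls)
    if (!cls %in% TISSUE_CLASSES[-1]) stop("cls must be a tissue class code")
    cls
  }
  out <- unclass(mask) == code
  dim(out) <- dim(mask)
  out
}
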