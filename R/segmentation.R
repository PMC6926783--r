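# Three-class color segmentation of stained sections. Methylene blue /
# basic fuchsin staining renders bone, biomaterial and soft tissue in three
# distinguishable hues; each in-ROI pixel is assigned the class of the
# nearest palette centroid. Classification runs in CIELAB by default: stain
# hues separate better there than in raw RGB, and distances are closer to
# perceptual.

#' Default stain palette
#'
#' RGB centroids (0-255) for the three segmentation classes, in the fixed
#' order bone (red), biomaterial (green), soft tissue (purple).
#'
#' @return 3 x 3 numeric matrix with rownames `BONE`, `BIOMATERIAL`, `SOFT`.
#' @export
default_palette <- function() {
  m <- rbind(BONE = c(200, 60, 60),
             BIOMATERIAL = c(70, 160, 90),
             SOFT = c(150, 80, 170))
  colnames(m) <- c("R", "G", "B")
  m
}

.to_colorspace <- function(rgb255, colorspace) {
  rgb01 <- pmin(pmax(rgb255 / 255, 0), 1)
  switch(colorspace,
         RGB = rgb255,
         Lab = grDevices::convertColor(rgb01, from = "sRGB", to = "Lab"),
         stop("unsupported color space: ", colorspace))
}

#' Segment an RGB image into three tissue classes
#'
#' Nearest-centroid classification of every in-ROI pixel against the three
#' palette colors, with Euclidean distance in the configured color space.
#' Exact distance ties are broken deterministically by the fixed class order
#' BONE < BIOMATERIAL < SOFT and reported via a message.
#'
#' @param image numeric array `h x w x 3`, intensities in `[0, 255]`.
#' @param palette 3 x 3 matrix of RGB centroids in class order
#'   (bone, biomaterial, soft); default [default_palette()].
#' @param roi an [roi] polygon or logical mask; pixels outside it are
#'   labelled `OUTSIDE`. `NULL` means the whole image.
#' @param colorspace `"Lab"` (default) or `"RGB"`.
#' @param majority_filter apply a 3x3 majority post-pass to suppress
#'   salt-and-pepper noise (default `FALSE` so that accuracy reflects the
#'   classifier alone).
#' @return A [label_mask].
#' @export
segment_colors <- function(image, palette = default_palette(), roi = NULL,
                           colorspace = c("Lab", "RGB"),
                           majority_filter = FALSE) {
  colorspace <- match.arg(colorspace)
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  palette <- as.matrix(palette)
  if (nrow(palette) != 3 || ncol(palette) != 3)
    stop("palette must be a 3 x 3 RGB matrix")
  d2 <- as.matrix(stats::dist(palette))
  if (any(d2[upper.tri(d2)] == 0))
    stop("palette centroids must be pairwise distinct")
  h <- dim(image)[1]; w <- dim(image)[2]
  roi_mask <- if (is.null(roi)) matrix(TRUE, h, w)
              else if (inherits(roi, "roi")) rasterize_roi(roi, h, w)
              else roi
  if (!any(roi_mask)) stop("empty ROI: nothing to segment")

  px <- cbind(as.vector(image[, , 1])[roi_mask],
              as.vector(image[, , 2])[roi_mask],
              as.vector(image[, , 3])[roi_mask])
  feat <- .to_colorspace(px, colorspace)
  cent <- .to_colorspace(palette, colorspace)

  bestd <- rowSums((feat - matrix(cent[1, ], nrow(feat), 3, byrow = TRUE))^2)
  cls <- rep(TISSUE_CLASSES[["BONE"]], nrow(feat))
  ties <- 0L
  for (k in 2:3) {
    dk <- rowSums((feat - matrix(cent[k, ], nrow(feat), 3, byrow = TRUE))^2)
    ties <- ties + sum(dk == bestd)
    upd <- dk < bestd          # strict: ties keep the earlier class
    cls[upd] <- TISSUE_CLASSES[[rownames(default_palette())[k]]]
    bestd[upd] <- dk[upd]
  }
  if (ties > 0)
    message(sprintf("segment_colors: %d pixel(s) tie-broken by class order", ties))

  lab <- matrix(TISSUE_CLASSES[["OUTSIDE"]], h, w)
  lab[roi_mask] <- cls
  out <- label_mask(lab)
  if (majority_filter) out <- .majority3x3(out, roi_mask)
  out
}

# 3x3 majority vote among the three tissue classes; OUTSIDE pixels are left
# untouched and do not vote. Ties keep the original label.
.majority3x3 <- function(mask, roi_mask) {
  m <- unclass(mask)
  h <- nrow(m); w <- ncol(m)
  counts <- lapply(1:3, function(code) {
    hit <- (m == code) & roi_mask
    acc <- matrix(0L, h, w)
    for (dr in -1:1) for (dc in -1:1) {
      rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
      rok <- rs >= 1 & rs <= h; cok <- cs >= 1 & cs <= w
      acc[which(rok), which(cok)] <- acc[which(rok), which(cok)] +
        hit[rs[rok], cs[cok], drop = FALSE]
    }
    acc
  })
  best <- counts[[1]]; lab <- matrix(1L, h, w)
  for (k in 2:3) {
    upd <- counts[[k]] > best
    lab[upd] <- k; best[upd] <- counts[[k]][upd]
  }
  # keep original where it already attains the max (tie-stability)
  orig_cnt <- matrix(0L, h, w)
  for (k in 1:3) orig_cnt[m == k] <- counts[[k]][m == k]
  keep <- roi_mask & m != 0L & orig_cnt == best
  lab[keep] <- m[keep]
  lab[!roi_mask | m == 0L] <- 0L
  label_mask(lab)
}
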