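# Histomorphometric measurements on label masks: area fractions inside ROI1
# and ROI2, percent regeneration (ROI2/ROI1), and the bone-to-material
# contact (BMC) osteoconductivity statistic.
#
# Perimeter metric: 4-connectivity boundary-edge count. The contact length
# is necessarily an edge count, so using the identical metric for the
# perimeter denominator guarantees contact <= perimeter (hence BMC <= 100)
# and exact ratio semantics; any absolute length bias of the edge metric
# cancels in the ratio. An edge is counted only when BOTH incident pixels
# lie inside the ROI, so particle arcs clipped by the ROI border leave the
# numerator and denominator symmetrically.

# Per-direction 4-neighbour edge tally. Returns, for each direction, the
# logical matrix of material pixels whose neighbour in that direction exists,
# is inside `roi`, and is not material.
.edge_stencil <- function(material, roi) {
  h <- nrow(material); w <- ncol(material)
  inroi_mat <- material & roi
  out <- list()
  # shift helpers return the neighbour's value aligned to each pixel, FALSE
  # when the neighbour falls off the image
  shift <- function(m, dr, dc) {
    res <- matrix(FALSE, h, w)
    rs <- seq_len(h); cs <- seq_len(w)
    rsrc <- rs + dr; csrc <- cs + dc
    rok <- rsrc >= 1 & rsrc <= h; cok <- csrc >= 1 & csrc <= w
    res[rs[rok], cs[cok]] <- m[rsrc[rok], csrc[cok], drop = FALSE]
    res
  }
  dirs <- list(N = c(-1L, 0L), S = c(1L, 0L), W = c(0L, -1L), E = c(0L, 1L))
  for (d in names(dirs)) {
    dr <- dirs[[d]][1]; dc <- dirs[[d]][2]
    nb_mat <- shift(material, dr, dc)
    nb_roi <- shift(roi, dr, dc)
    out[[d]] <- inroi_mat & nb_roi & !nb_mat
  }
  out
}

# Perimeter and contact edge counts in one pass; `contact_with` may be NULL.
.edge_counts <- function(material, roi, contact_with = NULL) {
  st <- .edge_stencil(material, roi)
  h <- nrow(material); w <- ncol(material)
  shiftv <- function(m, dr, dc) {
    res <- matrix(FALSE, h, w)
    rs <- seq_len(h); cs <- seq_len(w)
    rsrc <- rs + dr; csrc <- cs + dc
    rok <- rsrc >= 1 & rsrc <= h; cok <- csrc >= 1 & csrc <= w
    res[rs[rok], cs[cok]] <- m[rsrc[rok], csrc[cok], drop = FALSE]
    res
  }
  dirs <- list(N = c(-1L, 0L), S = c(1L, 0L), W = c(0L, -1L), E = c(0L, 1L))
  perim <- 0L; contact <- 0L
  for (d in names(dirs)) {
    e <- st[[d]]
    perim <- perim + sum(e)
    if (!is.null(contact_with)) {
      nb_other <- shiftv(contact_with, dirs[[d]][1], dirs[[d]][2])
      contact <- contact + sum(e & nb_other)
    }
  }
  list(perimeter = perim, contact = contact)
}

#' Boundary edges of a material mask within an ROI
#'
#' Enumerates every unit edge between a material pixel and a 4-adjacent
#' non-material pixel where both pixels lie inside the ROI. The number of
#' edges times the pixel pitch is the perimeter length used throughout the
#' package.
#'
#' @param material logical matrix marking biomaterial pixels.
#' @param roi logical matrix of in-ROI pixels (same dimensions).
#' @return A data frame with 0-based coordinates `x`, `y` of the material
#'   pixel and `dir` (`"N"`, `"S"`, `"W"`, `"E"`; y increases downward, so
#'   `"N"` is row above), one row per oriented edge.
#' @export
boundary_edges <- function(material, roi = NULL) {
  stopifnot(is.logical(material))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(material), ncol(material))
  if (!all(dim(material) == dim(roi)))
    stop("material and roi masks must have identical dimensions")
  st <- .edge_stencil(material, roi)
  rows <- lapply(names(st), function(d) {
    idx <- which(st[[d]], arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    data.frame(x = idx[, 2] - 1L, y = idx[, 1] - 1L, dir = d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(x = integer(), y = integer(), dir = character(),
                      stringsAsFactors = FALSE)
  out[order(out$y, out$x, out$dir), , drop = FALSE]
}

#' Tissue area fractions within an ROI
#'
#' @param mask a label mask (codes of [TISSUE_CLASSES]).
#' @param roi logical matrix of in-ROI pixels.
#' @return Named numeric vector `c(bone, biomaterial, soft)` of percentages
#'   of the in-ROI pixel count; sums to 100 when the ROI is fully labelled.
#' @export
area_fractions <- function(mask, roi) {
  if (!all(dim(mask) == dim(roi)))
    stop("mask and roi must have identical dimensions")
  n <- sum(roi)
  if (n == 0) stop("empty ROI: area fractions undefined")
  v <- unclass(mask)[roi]
  if (any(v == TISSUE_CLASSES[["OUTSIDE"]]))
    warning("ROI contains unlabelled (OUTSIDE) pixels; fractions will not sum to 100")
  100 * c(bone = sum(v == TISSUE_CLASSES[["BONE"]]),
          biomaterial = sum(v == TISSUE_CLASSES[["BIOMATERIAL"]]),
          soft = sum(v == TISSUE_CLASSES[["SOFT"]])) / n
}

#' Percent regeneration: area of ROI2 relative to ROI1
#'
#' @param roi1,roi2 logical masks of the defect area and the regenerated
#'   area; ROI2 must be contained in ROI1.
#' @return Percentage `100 * |ROI2| / |ROI1|`.
#' @export
percent_regeneration <- function(roi1, roi2) {
  if (!all(dim(roi1) == dim(roi2)))
    stop("roi1 and roi2 must have identical dimensions")
  if (any(roi2 & !roi1)) stop("ROI2 is not contained in ROI1")
  n1 <- sum(roi1)
  if (n1 == 0) stop("empty ROI1")
  100 * sum(roi2) / n1
}

#' Bone-to-material contact (BMC)
#'
#' The osteoconductivity statistic: the percentage of the biomaterial
#' particle perimeter in direct contact with newly formed bone within the
#' regenerated area (ROI2). Contact length is the number of boundary edges
#' whose non-material pixel is bone; the perimeter uses the identical edge
#' metric, so BMC is bounded by 100 by construction.
#'
#' @param bone,material logical masks (disjoint) of bone and biomaterial.
#' @param roi2 logical mask of the regenerated area.
#' @return A list with `perimeter_edges`, `contact_edges`, `bmc_pct`.
#' @export
bmc <- function(bone, material, roi2) {
  if (!all(dim(bone) == dim(material)) || !all(dim(bone) == dim(roi2)))
    stop("bone, material and roi2 masks must have identical dimensions")
  if (any(bone & material))
    stop("bone and material masks overlap; they must be disjoint")
  if (!any(material & roi2))
    stop("no particles in ROI2: BMC undefined")
  ec <- .edge_counts(material, roi2, contact_with = bone)
  list(perimeter_edges = ec$perimeter,
       contact_edges = ec$contact,
       bmc_pct = if (ec$perimeter == 0) NA_real_
                 else 100 * ec$contact / ec$perimeter)
}

#' Measure all histomorphometric parameters for one defect
#'
#' Computes the defect and regenerated areas, percent regeneration, tissue
#' fractions with both denominators (ROI1 and ROI2), and the BMC statistic.
#'
#' @param mask a label mask.
#' @param roi1,roi2 [roi] polygons or logical masks; ROI2 must be contained
#'   in ROI1.
#' @param scale_um_per_px optional pixel pitch in micrometres; when given,
#'   areas are also reported in mm^2.
#' @param defect_id optional identifier carried into the result.
#' @return An object of class `histo_result`.
#' @export
measure_defect <- function(mask, roi1, roi2, scale_um_per_px = NULL,
                           defect_id = NA_character_) {
  h <- nrow(mask); w <- ncol(mask)
  m1 <- if (inherits(roi1, "roi")) rasterize_roi(roi1, h, w) else roi1
  m2 <- if (inherits(roi2, "roi")) rasterize_roi(roi2, h, w) else roi2
  bone <- binarize(mask, "BONE")
  material <- binarize(mask, "BIOMATERIAL")
  fr1 <- area_fractions(mask, m1)
  fr2 <- area_fractions(mask, m2)
  reg <- percent_regeneration(m1, m2)
  ct <- bmc(bone, material, m2)
  px_area_mm2 <- if (is.null(scale_um_per_px)) NA_real_
                 else (scale_um_per_px / 1000)^2
  res <- list(
    defect_id = defect_id,
    area_roi1_px = sum(m1), area_roi2_px = sum(m2),
    area_roi1_mm2 = sum(m1) * px_area_mm2,
    area_roi2_mm2 = sum(m2) * px_area_mm2,
    pct_regeneration = reg,
    pct_bone_roi1 = fr1[["bone"]], pct_bone_roi2 = fr2[["bone"]],
    pct_material_roi1 = fr1[["biomaterial"]],
    pct_material_roi2 = fr2[["biomaterial"]],
    pct_soft_roi1 = fr1[["soft"]], pct_soft_roi2 = fr2[["soft"]],
    perimeter_edges = ct$perimeter_edges,
    contact_edges = ct$contact_edges,
    bmc_pct = ct$bmc_pct,
    scale_um_per_px = if (is.null(scale_um_per_px)) NA_real_
                      else scale_um_per_px)
  class(res) <- "histo_result"
  res
}

#' @export
print.histo_result <- function(x, ...) {
  cat("Histomorphometric measurement",
      if (!is.na(x$defect_id)) sprintf("(defect %s)", x$defect_id), "\n")
  if (is.na(x$scale_um_per_px)) {
    cat(sprintf("  defect area (ROI1): %d px  |  regenerated (ROI2): %d px  [pixel units: no scale set]\n",
                x$area_roi1_px, x$area_roi2_px))
  } else {
    cat(sprintf("  defect area (ROI1): %d px = %.3f mm^2  |  regenerated (ROI2): %d px = %.3f mm^2\n",
                x$area_roi1_px, x$area_roi1_mm2, x$area_roi2_px, x$area_roi2_mm2))
  }
  cat(sprintf("  regeneration: %.2f %%\n", x$pct_regeneration))
  cat(sprintf("  within ROI1:  bone %.2f %%, biomaterial %.2f %%, soft %.2f %%\n",
              x$pct_bone_roi1, x$pct_material_roi1, x$pct_soft_roi1))
  cat(sprintf("  within ROI2:  bone %.2f %%, biomaterial %.2f %%, soft %.2f %%\n",
              x$pct_bone_roi2, x$pct_material_roi2, x$pct_soft_roi2))
  cat(sprintf("  BMC: %d / %d contact edges = %.2f %%\n",
              x$contact_edges, x$perimeter_edges, x$bmc_pct))
  invisible(x)
}

#' @export
as.data.frame.histo_result <- function(x, ...) {
  data.frame(defect_id = x$defect_id,
             area_roi1_px = x$area_roi1_px, area_roi2_px = x$area_roi2_px,
             pct_regeneration = x$pct_regeneration,
             pct_bone_roi1 = x$pct_bone_roi1, pct_bone_roi2 = x$pct_bone_roi2,
             pct_material_roi1 = x$pct_material_roi1,
             pct_material_roi2 = x$pct_material_roi2,
             pct_soft_roi1 = x$pct_soft_roi1, pct_soft_roi2 = x$pct_soft_roi2,
             perimeter_edges = x$perimeter_edges,
             contact_edges = x$contact_edges,
             bmc_pct = x$bmc_pct,
             stringsAsFactors = FALSE)
}

#' Write per-defect histomorphometric results to CSV
#'
#' @param results a `histo_result` or list of them.
#' @param path output CSV path.
#' @export
write_histo_csv <- function(results, path) {
  if (inherits(results, "histo_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
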