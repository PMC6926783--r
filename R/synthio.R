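# Seeded generators for synthetic study data with planted ground truth:
# stained-section phantoms (biomaterial particles, a bone rim covering a
# controllable fraction of each particle boundary, soft tissue elsewhere)
# and per-defect study tables with animal random effects.
#
# Phantom geometry: particles are discretized ellipses with eccentricity up
# to 2:1 and random orientation, placed without overlap and fully inside
# ROI2. Bone is laid down by dilating a contiguous arc of the particle
# boundary, so bone-material pixel adjacency occurs exactly along the chosen
# arc. Ground truth (boundary and contact edge counts per particle, area
# fractions, BMC) is measured from the generated label mask itself with the
# same 4-connectivity edge metric the measurement code uses, so it is exact
# by construction.

#' Specification of a synthetic histology scene
#'
#' @param size image side in pixels (square image).
#' @param scale_um_per_px pixel pitch in micrometres.
#' @param n_particles number of biomaterial particles.
#' @param particle_um_range range of particle diameters (major axis) in
#'   micrometres; the graft granules emulated here are sieved to
#'   250-1000 um.
#' @param contact_fraction target fraction of each particle boundary in
#'   contact with bone: a single number in `[0, 1]`, a vector of length
#'   `n_particles`, or a function `f(n)` returning `n` such fractions.
#' @param palette 3 x 3 RGB matrix of class colors ([default_palette()]).
#' @param noise_sd per-channel Gaussian color noise s.d. (intensity units).
#' @param rim_px bone rim thickness in pixels (dilation radius).
#' @param background_rgb RGB color of pixels outside ROI1.
#' @param seed integer seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(size = 1024, scale_um_per_px = 5, n_particles = 8,
                       particle_um_range = c(250, 1000),
                       contact_fraction = 0.5,
                       palette = default_palette(), noise_sd = 15,
                       rim_px = 3, background_rgb = c(235, 235, 235),
                       seed = 1L) {
  stopifnot(size >= 32, scale_um_per_px > 0, n_particles >= 1,
            length(particle_um_range) == 2, all(particle_um_range > 0),
            particle_um_range[1] <= particle_um_range[2], rim_px >= 1)
  if (is.numeric(contact_fraction) &&
      any(contact_fraction < 0 | contact_fraction > 1))
    stop("contact fractions must lie in [0, 1]")
  palette <- as.matrix(palette)
  dmat <- as.matrix(stats::dist(palette))
  if (any(dmat[upper.tri(dmat)] == 0))
    stop("palette centroids must be pairwise distinct")
  structure(list(size = as.integer(size),
                 scale_um_per_px = scale_um_per_px,
                 n_particles = as.integer(n_particles),
                 particle_um_range = particle_um_range,
                 contact_fraction = contact_fraction,
                 palette = palette, noise_sd = noise_sd,
                 rim_px = as.integer(rim_px),
                 background_rgb = background_rgb,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# disc dilation of a logical matrix (in place on the full image), vectorized
# over integer offsets within the Euclidean radius
.dilate_disc <- function(seeds, radius) {
  h <- nrow(seeds); w <- ncol(seeds)
  out <- matrix(FALSE, h, w)
  for (dr in -radius:radius) for (dc in -radius:radius) {
    if (dr * dr + dc * dc > radius * radius) next
    rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
    rok <- rs >= 1 & rs <= h; cok <- cs >= 1 & cs <= w
    sub <- seeds[rs[rok], cs[cok], drop = FALSE]
    out[which(rok), which(cok)] <- out[which(rok), which(cok)] | sub
  }
  out
}

#' Generate a synthetic stained-section scene with ground truth
#'
#' @param spec a [scene_spec].
#' @return A list with `image` (numeric `h x w x 3`, 0-255) and `truth`
#'   (class `scene_truth`: the exact label mask, ROI polygons, per-particle
#'   boundary and contact edge counts, true area fractions and true BMC).
#' @export
make_histology_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  n <- spec$size
  inset1 <- max(2L, round(0.04 * n))
  inset2 <- max(4L, round(0.12 * n))
  roi1 <- roi_rect(inset1 - 0.5, inset1 - 0.5,
                   n - inset1 - 0.5, n - inset1 - 0.5, name = "ROI1")
  roi2 <- roi_rect(inset2 - 0.5, inset2 - 0.5,
                   n - inset2 - 0.5, n - inset2 - 0.5, name = "ROI2")
  roi1_mask <- rasterize_roi(roi1, n, n)
  roi2_mask <- rasterize_roi(roi2, n, n)

  np <- spec$n_particles
  cf <- spec$contact_fraction
  frac <- if (is.function(cf)) cf(np)
          else if (length(cf) == 1) rep(cf, np)
          else if (length(cf) == np) cf
          else stop("contact_fraction must have length 1 or n_particles")
  if (any(frac < 0 | frac > 1)) stop("contact fractions must lie in [0, 1]")

  gap <- 2 * spec$rim_px + 3
  # sample particle geometry with non-overlap rejection
  parts <- vector("list", np)
  placed <- matrix(numeric(0), ncol = 3)  # cx, cy, major semi-axis
  for (i in seq_len(np)) {
    ok <- FALSE
    for (try in seq_len(500)) {
      d_um <- runif(1, spec$particle_um_range[1], spec$particle_um_range[2])
      A <- d_um / spec$scale_um_per_px / 2
      ecc <- runif(1, 1, 2)
      B <- A / ecc
      ang <- runif(1, 0, pi)
      margin <- inset2 + A + spec$rim_px + 2
      if (2 * margin >= n)
        stop("particle of ", round(d_um), " um cannot fit inside ROI2 at this image size/scale")
      cx <- runif(1, margin, n - 1 - margin)
      cy <- runif(1, margin, n - 1 - margin)
      if (nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
              placed[, 3] + A + gap)) {
        parts[[i]] <- list(cx = cx, cy = cy, a = A, b = B, angle = ang,
                           diameter_um = d_um, requested_contact = frac[i])
        placed <- rbind(placed, c(cx, cy, A))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place particle ", i, " of ", np,
           " without overlap after 500 retries; reduce n_particles or particle size")
  }

  material <- matrix(FALSE, n, n)
  particle_masks <- vector("list", np)
  for (i in seq_len(np)) {
    p <- parts[[i]]
    r0 <- max(1L, floor(p$cy - p$a)); r1 <- min(n, ceiling(p$cy + p$a) + 1L)
    c0 <- max(1L, floor(p$cx - p$a)); c1 <- min(n, ceiling(p$cx + p$a) + 1L)
    xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE) - p$cx
    Y <- matrix(ys, length(ys), length(xs)) - p$cy
    u <- X * cos(p$angle) + Y * sin(p$angle)
    v <- -X * sin(p$angle) + Y * cos(p$angle)
    inside <- (u / p$a)^2 + (v / p$b)^2 <= 1
    loc <- matrix(FALSE, n, n)
    loc[r0:r1, c0:c1] <- inside
    particle_masks[[i]] <- loc
    material <- material | loc
  }

  # bone rim along a contiguous boundary arc of each particle
  bone <- matrix(FALSE, n, n)
  for (i in seq_len(np)) {
    f <- parts[[i]]$requested_contact
    if (f <= 0) next
    ed <- boundary_edges(particle_masks[[i]], roi2_mask)
    # outside pixel of each edge
    dx <- c(N = 0L, S = 0L, W = -1L, E = 1L)[ed$dir]
    dy <- c(N = -1L, S = 1L, W = 0L, E = 0L)[ed$dir]
    ox <- ed$x + dx; oy <- ed$y + dy
    theta <- atan2((ed$y + oy) / 2 - parts[[i]]$cy,
                   (ed$x + ox) / 2 - parts[[i]]$cx)
    ord <- order(theta)
    n_ed <- nrow(ed)
    n_sel <- round(f * n_ed)
    if (n_sel == 0) next
    start <- sample.int(n_ed, 1)
    sel <- ord[((start - 1 + seq_len(n_sel) - 1) %% n_ed) + 1]
    seeds <- matrix(FALSE, n, n)
    seeds[cbind(oy[sel] + 1L, ox[sel] + 1L)] <- TRUE
    bone <- bone | .dilate_disc(seeds, spec$rim_px)
  }
  bone <- bone & !material & roi2_mask

  lab <- matrix(TISSUE_CLASSES[["OUTSIDE"]], n, n)
  lab[roi1_mask] <- TISSUE_CLASSES[["SOFT"]]
  lab[bone] <- TISSUE_CLASSES[["BONE"]]
  lab[material] <- TISSUE_CLASSES[["BIOMATERIAL"]]
  mask <- label_mask(lab)

  # exact per-particle bookkeeping from the generated mask
  perim <- integer(np); contact <- integer(np)
  for (i in seq_len(np)) {
    ec <- .edge_counts(particle_masks[[i]], roi2_mask, contact_with = bone)
    perim[i] <- ec$perimeter
    contact[i] <- ec$contact
  }
  particles <- data.frame(
    id = seq_len(np),
    cx = vapply(parts, `[[`, 0, "cx"), cy = vapply(parts, `[[`, 0, "cy"),
    semi_major_px = vapply(parts, `[[`, 0, "a"),
    semi_minor_px = vapply(parts, `[[`, 0, "b"),
    angle = vapply(parts, `[[`, 0, "angle"),
    diameter_um = vapply(parts, `[[`, 0, "diameter_um"),
    requested_contact = vapply(parts, `[[`, 0, "requested_contact"),
    perimeter_edges = perim, contact_edges = contact)

  truth <- structure(list(
    mask = mask, roi1 = roi1, roi2 = roi2,
    roi1_mask = roi1_mask, roi2_mask = roi2_mask,
    particles = particles,
    fractions_roi1 = area_fractions(mask, roi1_mask),
    fractions_roi2 = area_fractions(mask, roi2_mask),
    pct_regeneration = percent_regeneration(roi1_mask, roi2_mask),
    perimeter_edges = sum(perim), contact_edges = sum(contact),
    bmc_pct = 100 * sum(contact) / sum(perim),
    scale_um_per_px = spec$scale_um_per_px),
    class = "scene_truth")

  # render: palette centroid + Gaussian color noise, clipped to [0, 255]
  img <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    base <- matrix(spec$background_rgb[ch], n, n)
    for (k in 1:3) base[lab == k] <- spec$palette[k, ch]
    if (spec$noise_sd > 0)
      base <- base + matrix(rnorm(n * n, 0, spec$noise_sd), n, n)
    img[, , ch] <- pmin(pmax(round(base), 0), 255)
  }

  list(image = img, truth = truth)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth: %d particles, true BMC %.2f %% (%d/%d edges)>\n",
              nrow(x$particles), x$bmc_pct, x$contact_edges, x$perimeter_edges))
  cat(sprintf("  ROI1 fractions: bone %.2f / biomaterial %.2f / soft %.2f %%\n",
              x$fractions_roi1[["bone"]], x$fractions_roi1[["biomaterial"]],
              x$fractions_roi1[["soft"]]))
  invisible(x)
}

#' Write a generated scene to disk
#'
#' Writes `image.png`, `truth_mask.png`, `roi1.json`, `roi2.json` and
#' `particles.json` into `dir`.
#'
#' @param scene result of [make_histology_scene()].
#' @param dir output directory (created if absent).
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(scene$image, file.path(dir, "image.png"))
  write_label_mask(scene$truth$mask, file.path(dir, "truth_mask.png"))
  write_roi_json(scene$truth$roi1, file.path(dir, "roi1.json"))
  write_roi_json(scene$truth$roi2, file.path(dir, "roi2.json"))
  jsonlite::write_json(scene$truth$particles, file.path(dir, "particles.json"),
                       digits = NA)
  invisible(dir)
}

# ---- study tables ----------------------------------------------------------

#' Specification of a synthetic study table
#'
#' Emulates the in-vivo design: several animals, a fixed number of defects
#' per animal, the three materials allocated in balance within each animal,
#' and outcomes generated as group mean + animal random intercept +
#' residual noise.
#'
#' @param n_animals number of animals (default 5).
#' @param defects_per_animal defects per animal (default 6); must be a
#'   multiple of the number of groups so allocation is balanced within
#'   animal.
#' @param groups group labels (default `HAN`, `HA820`, `HA1200`).
#' @param means per-group outcome means, on the percent scale.
#' @param sd_animal animal random-intercept s.d. (>= 0).
#' @param sd_resid residual s.d. (>= 0).
#' @param truncate `c(lo, hi)` bounds for the outcome (default 0-100), or
#'   `NULL` for unbounded.
#' @param seed integer seed.
#' @return Object of class `study_spec`.
#' @export
study_spec <- function(n_animals = 5, defects_per_animal = 6,
                       groups = c("HAN", "HA820", "HA1200"),
                       means = c(HAN = 30, HA820 = 28, HA1200 = 15),
                       sd_animal = 5, sd_resid = 10,
                       truncate = c(0, 100), seed = 1L) {
  if (n_animals < 1 || defects_per_animal < 1)
    stop("animal and defect counts must be positive")
  if (defects_per_animal %% length(groups) != 0)
    stop("defects_per_animal must be a multiple of the number of groups")
  if (sd_animal < 0 || sd_resid < 0) stop("s.d. values must be non-negative")
  if (length(means) != length(groups))
    stop("means must match groups")
  structure(list(n_animals = as.integer(n_animals),
                 defects_per_animal = as.integer(defects_per_animal),
                 groups = groups, means = setNames(means, groups),
                 sd_animal = sd_animal, sd_resid = sd_resid,
                 truncate = truncate, seed = as.integer(seed)),
            class = "study_spec")
}

#' Generate a synthetic per-defect study table
#'
#' @param spec a [study_spec].
#' @return Data frame with columns `animal`, `group`, `defect_id`,
#'   `outcome`; one row per defect, groups balanced within each animal.
#' @export
make_study_table <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  set.seed(spec$seed)
  k <- length(spec$groups)
  reps <- spec$defects_per_animal / k
  intercepts <- rnorm(spec$n_animals, 0, spec$sd_animal)
  rows <- list()
  did <- 0L
  for (a in seq_len(spec$n_animals)) {
    grp <- rep(spec$groups, times = reps)
    for (j in seq_along(grp)) {
      did <- did + 1L
      y <- spec$means[[grp[j]]] + intercepts[a] + rnorm(1, 0, spec$sd_resid)
      rows[[did]] <- data.frame(animal = sprintf("A%02d", a),
                                group = grp[j],
                                defect_id = sprintf("D%03d", did),
                                outcome = y, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(spec$truncate)) {
    lo <- spec$truncate[1]; hi <- spec$truncate[2]
    n_trunc <- sum(tab$outcome < lo | tab$outcome > hi)
    if (n_trunc > 0) {
      warning(sprintf("%d outcome(s) truncated to [%g, %g]", n_trunc, lo, hi))
      tab$outcome <- pmin(pmax(tab$outcome, lo), hi)
    }
  }
  tab$group <- factor(tab$group, levels = spec$groups)
  tab
}
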