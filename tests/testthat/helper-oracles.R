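# Independent oracles used across the suite. These deliberately avoid the
# vectorized code paths of the package: edges are enumerated pixel by pixel
# through linear indexing, point-in-polygon goes through mgcv, and profile
# breadths come from numerical quadrature.

# Brute-force 4-neighbour edge enumeration: walk every material pixel and
# inspect its four neighbours by scalar indexing.
oracle_edges <- function(material, roi = NULL, bone = NULL) {
  h <- nrow(material); w <- ncol(material)
  if (is.null(roi)) roi <- matrix(TRUE, h, w)
  perim <- 0L; contact <- 0L
  edges <- list()
  idx <- which(material & roi, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    for (q in seq_len(nrow(idx))) {
      r <- idx[q, 1]; c <- idx[q, 2]
      for (d in list(c(-1L, 0L, "N"), c(1L, 0L, "S"),
                     c(0L, -1L, "W"), c(0L, 1L, "E"))) {
        rr <- r + as.integer(d[1]); cc <- c + as.integer(d[2])
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        if (!roi[rr, cc]) next
        if (material[rr, cc]) next
        perim <- perim + 1L
        if (!is.null(bone) && bone[rr, cc]) contact <- contact + 1L
        edges[[length(edges) + 1L]] <- c(c - 1L, r - 1L, d[3])
      }
    }
  }
  list(perimeter = perim, contact = contact,
       edges = if (length(edges)) do.call(rbind, edges) else
         matrix(character(), ncol = 3))
}

# random blob mask with a given fill probability
random_mask <- function(h, w, p = 0.3) {
  matrix(runif(h * w) < p, h, w)
}

# closed-form expected-mean-squares variance components for the balanced
# animal-blocked one-way layout (a animals, each seeing all k groups r times)
ems_varcomps <- function(tab, outcome = "outcome") {
  y <- tab[[outcome]]
  an <- factor(tab$animal); gr <- factor(tab$group)
  a <- nlevels(an); k <- nlevels(gr)
  m <- nrow(tab) / a                # observations per animal
  N <- nrow(tab)
  gm <- mean(y)
  ss_animal <- m * sum((tapply(y, an, mean) - gm)^2)
  ss_group <- (N / k) * sum((tapply(y, gr, mean) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_animal - ss_group
  df_err <- N - a - k + 1
  ms_err <- ss_err / df_err
  ms_animal <- ss_animal / (a - 1)
  list(sigma2_resid = ms_err,
       sigma2_animal = max(0, (ms_animal - ms_err) / m))
}

# pure Gaussian / Lorentzian profiles for quadrature oracles
gauss_profile <- function(x, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-x^2 / (2 * s^2))
}
lorentz_profile <- function(x, fwhm) {
  g <- fwhm / 2
  g^2 / (x^2 + g^2)
}

# nearest-neighbour integer upscale of a logical matrix
upscale <- function(m, k) {
  m[rep(seq_len(nrow(m)), each = k), rep(seq_len(ncol(m)), each = k)]
}
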