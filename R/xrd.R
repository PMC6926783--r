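# Powder X-ray diffraction: peak positions from unit cells via Bragg's law,
# Voigt peak simulation and fitting, and crystallite size from the Scherrer
# relation CS = lambda / (beta cos theta), where beta is the integral
# breadth (peak area / maximum height) of the size-broadened Lorentzian
# component. The instrumental contribution is modelled as a single fixed
# Gaussian FWHM convolved with the Lorentzian, i.e. the peaks are Voigt
# profiles. Units discipline: user-facing angles in degrees of 2theta;
# beta and theta enter the Scherrer formula in radians.

#' Cu K-alpha1 wavelength in Angstrom
#' @export
CU_KALPHA1 <- 1.540598

#' Construct a unit cell
#'
#' @param system `"cubic"`, `"hexagonal"` or `"orthorhombic"`.
#' @param a,b,c cell lengths in Angstrom. For cubic only `a` is needed; for
#'   hexagonal `a` and `c` (with `b = a`).
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell("hexagonal", a = 9.424, c = 6.879)   # hydroxyapatite
#' unit_cell("cubic", a = 4.8152)                 # CaO
#' @export
unit_cell <- function(system = c("cubic", "hexagonal", "orthorhombic"),
                      a, b = NULL, c = NULL) {
  system <- match.arg(system)
  if (a <= 0) stop("cell length a must be positive")
  cell <- switch(system,
    cubic = list(a = a, b = a, c = a, angles = c(90, 90, 90)),
    hexagonal = {
      if (is.null(c)) stop("hexagonal cell needs c")
      if (!is.null(b) && b != a) stop("hexagonal cell requires b = a")
      list(a = a, b = a, c = c, angles = c(90, 90, 120))
    },
    orthorhombic = {
      if (is.null(b) || is.null(c)) stop("orthorhombic cell needs a, b, c")
      list(a = a, b = b, c = c, angles = c(90, 90, 90))
    })
  if (any(unlist(cell[c("a", "b", "c")]) <= 0))
    stop("cell lengths must be positive")
  structure(c(list(system = system), cell), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell %s: a=%g b=%g c=%g Angstrom>\n",
              x$system, x$a, x$b, x$c))
  invisible(x)
}

#' Lattice-plane spacing d(hkl)
#'
#' Closed-form interplanar spacing for the supported crystal systems:
#' cubic `1/d^2 = (h^2+k^2+l^2)/a^2`; hexagonal
#' `1/d^2 = (4/3)(h^2+hk+k^2)/a^2 + l^2/c^2`; orthorhombic
#' `1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2`.
#'
#' @param cell a [unit_cell].
#' @param h,k,l Miller indices (not all zero); vectorized.
#' @return d-spacing in Angstrom.
#' @export
d_spacing <- function(cell, h, k, l) {
  stopifnot(inherits(cell, "unit_cell"))
  if (any(h == 0 & k == 0 & l == 0))
    stop("Miller indices must not all be zero")
  inv_d2 <- switch(cell$system,
    cubic = (h^2 + k^2 + l^2) / cell$a^2,
    hexagonal = (4 / 3) * (h^2 + h * k + k^2) / cell$a^2 + l^2 / cell$c^2,
    orthorhombic = h^2 / cell$a^2 + k^2 / cell$b^2 + l^2 / cell$c^2)
  1 / sqrt(inv_d2)
}

#' Bragg angle for a given d-spacing
#'
#' @param d d-spacing in Angstrom (vectorized).
#' @param wavelength wavelength in Angstrom (default Cu K-alpha1).
#' @return Diffraction angle 2theta in degrees.
#' @export
bragg_two_theta <- function(d, wavelength = CU_KALPHA1) {
  s <- wavelength / (2 * d)
  if (any(s > 1))
    stop("wavelength exceeds 2d: reflection unobservable")
  2 * asin(s) * 180 / pi
}

#' Construct a diffraction pattern
#'
#' @param two_theta strictly increasing 2theta grid in degrees.
#' @param intensity intensities (arbitrary units), same length.
#' @param wavelength wavelength in Angstrom.
#' @return An object of class `diffraction_pattern`.
#' @export
diffraction_pattern <- function(two_theta, intensity,
                                wavelength = CU_KALPHA1) {
  if (length(two_theta) != length(intensity))
    stop("two_theta and intensity lengths differ")
  if (any(diff(two_theta) <= 0)) stop("2theta grid must be strictly increasing")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  structure(list(two_theta = two_theta, intensity = intensity,
                 wavelength = wavelength),
            class = "diffraction_pattern")
}

#' @export
print.diffraction_pattern <- function(x, ...) {
  cat(sprintf("<diffraction_pattern: %d points, 2theta %.2f-%.2f deg, lambda %.6f A>\n",
              length(x$two_theta), min(x$two_theta), max(x$two_theta),
              x$wavelength))
  invisible(x)
}

#' @export
plot.diffraction_pattern <- function(x, ...) {
  plot(x$two_theta, x$intensity, type = "l",
       xlab = expression(2 * theta ~ (degrees)),
       ylab = "intensity (a.u.)", ...)
}

# ---- Voigt profile ---------------------------------------------------------

#' Faddeeva function w(z)
#'
#' Scaled complex complementary error function
#' `w(z) = exp(-z^2) erfc(-iz)`, evaluated for `Im(z) >= 0` by Weideman's
#' rational approximation (N = 36 terms, near machine precision). This is
#' the standard route to the Voigt profile.
#'
#' @param z complex vector with non-negative imaginary part.
#' @return Complex vector `w(z)`.
#' @export
faddeeva_w <- function(z) {
  a <- .weideman_coefs$a
  L <- .weideman_coefs$L
  iz <- 1i * z
  Z <- (L + iz) / (L - iz)
  p <- 0 + 0i
  for (cc in a) p <- p * Z + cc
  2 * p / (L - iz)^2 + (1 / sqrt(pi)) / (L - iz)
}

# Weideman expansion coefficients, computed once at load time.
.make_weideman <- function(N = 36L) {
  M <- 2L * N; M2 <- 2L * M
  L <- sqrt(N / sqrt(2))
  theta <- seq.int(-M + 1L, M - 1L) * pi / M
  t <- L * tan(theta / 2)
  f <- c(0, exp(-t^2) * (L^2 + t^2))
  fsh <- c(f[(M + 1L):M2], f[1L:M])
  coefs <- Re(stats::fft(fsh)) / M2
  list(a = rev(coefs[2L:(N + 1L)]), L = L)
}
.weideman_coefs <- .make_weideman()

#' Voigt profile (unit area)
#'
#' Convolution of a Gaussian of standard deviation `sigma` with a
#' Lorentzian of half-width `gamma`, normalized to unit area:
#' `V(x) = Re(w((x + i gamma)/(sigma sqrt(2)))) / (sigma sqrt(2 pi))`.
#'
#' @param x evaluation points (offset from the peak center).
#' @param sigma Gaussian standard deviation (> 0).
#' @param gamma Lorentzian half-width at half-maximum (>= 0).
#' @return Profile values.
#' @export
voigt <- function(x, sigma, gamma) {
  stopifnot(sigma > 0, gamma >= 0)
  Re(faddeeva_w((x + 1i * gamma) / (sigma * sqrt(2)))) / (sigma * sqrt(2 * pi))
}

# FWHM <-> component parameters
.sigma_from_fwhm_g <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
.gamma_from_fwhm_l <- function(fwhm) fwhm / 2

#' Integral breadths of peak profiles
#'
#' The integral breadth beta of a peak is its area divided by its maximum
#' height. Closed forms: Lorentzian `beta = (pi/2) FWHM`; Gaussian
#' `beta = (FWHM/2) sqrt(pi / ln 2)`; Voigt
#' `beta = sigma sqrt(2 pi) / Re(w(i gamma / (sigma sqrt 2)))`.
#'
#' @param fwhm full width at half maximum (same units as the returned
#'   breadth).
#' @return Integral breadth.
#' @export
beta_lorentzian <- function(fwhm) (pi / 2) * fwhm

#' @rdname beta_lorentzian
#' @export
beta_gaussian <- function(fwhm) (fwhm / 2) * sqrt(pi / log(2))

#' @rdname beta_lorentzian
#' @param sigma,gamma Voigt component parameters as in [voigt()].
#' @export
beta_voigt <- function(sigma, gamma) {
  1 / voigt(0, sigma, gamma)
}

# ---- Scherrer relation -----------------------------------------------------

#' Crystallite size from the Scherrer relation
#'
#' `CS = lambda / (beta cos(theta))` with `beta` the integral breadth of
#' the size-broadened Lorentzian component in radians (of 2theta) and
#' `theta` half the diffraction angle, in radians.
#'
#' @param beta integral breadth in radians (> 0).
#' @param theta Bragg angle theta in radians, in `(0, pi/2)`.
#' @param wavelength wavelength in Angstrom.
#' @return Crystallite size in nanometres.
#' @export
crystallite_size <- function(beta, theta, wavelength = CU_KALPHA1) {
  if (any(beta <= 0)) stop("beta must be positive: size unresolvable")
  if (any(theta <= 0 | theta >= pi / 2)) stop("theta must lie in (0, pi/2)")
  (wavelength / (beta * cos(theta))) / 10   # Angstrom -> nm
}

# Lorentzian FWHM (degrees of 2theta) produced by a crystallite size CS (nm)
# at peak center 2theta (degrees): inverse of the Scherrer relation through
# beta_L = (pi/2) FWHM_L.
.fwhm_l_from_cs <- function(cs_nm, center_deg, wavelength = CU_KALPHA1) {
  theta <- center_deg / 2 * pi / 180
  beta <- (wavelength / 10) / (cs_nm * cos(theta))   # radians of 2theta
  (2 / pi) * beta * 180 / pi                         # -> FWHM in degrees
}

# ---- Simulation ------------------------------------------------------------

#' Simulate a powder diffraction pattern
#'
#' Each peak is a Voigt profile: the Gaussian instrumental contribution
#' (fixed FWHM) convolved with a Lorentzian size-broadening component whose
#' integral breadth satisfies the Scherrer relation at that peak's angle
#' for the requested crystallite size. A linear background and Gaussian
#' counting noise are added.
#'
#' @param peaks data frame (or 2-column matrix) with columns `two_theta`
#'   (degrees) and `intensity` (relative peak heights).
#' @param cs_nm crystallite size in nm (> 0).
#' @param instrument_fwhm instrumental Gaussian FWHM in degrees of 2theta.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param seed integer seed for the noise stream.
#' @param grid 2theta grid in degrees (default 3-70, step 0.02).
#' @param background `c(intercept, slope)` of the linear background.
#' @param wavelength wavelength in Angstrom.
#' @return A [diffraction_pattern].
#' @export
simulate_pattern <- function(peaks, cs_nm, instrument_fwhm = 0.05,
                             noise_sd = 0, seed = NULL,
                             grid = seq(3, 70, by = 0.02),
                             background = c(10, 0),
                             wavelength = CU_KALPHA1) {
  peaks <- as.data.frame(peaks)
  if (is.null(peaks$two_theta)) names(peaks)[1:2] <- c("two_theta", "intensity")
  stopifnot(cs_nm > 0, instrument_fwhm > 0, all(diff(grid) > 0))
  y <- background[1] + background[2] * grid
  sigma <- .sigma_from_fwhm_g(instrument_fwhm)
  for (i in seq_len(nrow(peaks))) {
    ctr <- peaks$two_theta[i]
    if (ctr < min(grid) || ctr > max(grid)) {
      warning(sprintf("peak at %.3f deg outside grid: skipped", ctr))
      next
    }
    gam <- .gamma_from_fwhm_l(.fwhm_l_from_cs(cs_nm, ctr, wavelength))
    prof <- voigt(grid - ctr, sigma, gam)
    y <- y + peaks$intensity[i] * prof / voigt(0, sigma, gam)  # unit height
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(grid), 0, noise_sd)
  }
  diffraction_pattern(grid, y, wavelength = wavelength)
}

# ---- Fitting ---------------------------------------------------------------

#' Fit a single Voigt peak with fixed instrumental width
#'
#' Least-squares fit of `background + height * Voigt` over a 2theta window
#' containing one dominant peak. The Gaussian component is fixed at the
#' instrumental FWHM; the free parameters are the center, height, the
#' Lorentzian FWHM and a linear background. The Lorentzian integral breadth
#' `beta = (pi/2) FWHM_L` (radians) and the Scherrer crystallite size are
#' derived from the fit.
#'
#' @param pattern a [diffraction_pattern].
#' @param window `c(lo, hi)` 2theta interval in degrees.
#' @param instrument_fwhm instrumental Gaussian FWHM in degrees.
#' @return An object of class `peak_fit` with elements `center_deg`,
#'   `theta_rad`, `height`, `area`, `fwhm_l_deg`, `fwhm_l_rad`,
#'   `instrument_fwhm_deg`, `beta_rad`, `cs_nm`, `background`, `fitted`,
#'   `rss`, `convergence`.
#' @export
fit_peak <- function(pattern, window, instrument_fwhm = 0.05) {
  stopifnot(inherits(pattern, "diffraction_pattern"), length(window) == 2)
  sel <- pattern$two_theta >= window[1] & pattern$two_theta <= window[2]
  if (sum(sel) < 8) stop("window contains too few points to fit")
  x <- pattern$two_theta[sel]
  y <- pattern$intensity[sel]
  sigma <- .sigma_from_fwhm_g(instrument_fwhm)

  # initialisation: background from window edges, center from the maximum,
  # Lorentzian width from the background-corrected half-maximum width
  n_edge <- max(3L, round(length(x) * 0.1))
  bg0 <- stats::median(c(utils::head(y, n_edge), utils::tail(y, n_edge)))
  imax <- which.max(y)
  h0 <- y[imax] - bg0
  edge_sd <- stats::sd(c(utils::head(y, n_edge), utils::tail(y, n_edge)))
  if (h0 <= 3 * edge_sd)
    stop("no discernible peak in window (flat background)")
  x0 <- x[imax]
  above <- y - bg0 > h0 / 2
  w_obs <- max(diff(range(x[above])), diff(x)[1])
  fw0 <- max(w_obs - instrument_fwhm, diff(x)[1] / 10)

  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b0 + b1 * (x - x0) +
        h * voigt(x - ctr, sigma, fl / 2) / voigt(0, sigma, fl / 2),
      data = dat,
      start = list(b0 = bg0, b1 = 0, h = h0, ctr = x0, fl = fw0),
      lower = c(-Inf, -Inf, 0, window[1], 0),
      upper = c(Inf, Inf, Inf, window[2], Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("peak fit failed to converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  if (cf[["h"]] <= 0) stop("fitted peak height is zero: no peak in window")
  fl_deg <- cf[["fl"]]
  if (fl_deg < 0) {
    warning("negative Lorentzian width clamped to 0")
    fl_deg <- 0
  }
  fl_rad <- fl_deg * pi / 180
  beta_rad <- beta_lorentzian(fl_rad)
  theta <- cf[["ctr"]] / 2 * pi / 180
  gam <- .gamma_from_fwhm_l(fl_deg)
  height <- cf[["h"]]
  area <- height / voigt(0, sigma, gam)   # unit-height scaling => area = h / V(0)
  res <- list(center_deg = cf[["ctr"]],
              theta_rad = theta,
              height = height,
              area = area,
              fwhm_l_deg = fl_deg,
              fwhm_l_rad = fl_rad,
              instrument_fwhm_deg = instrument_fwhm,
              beta_rad = beta_rad,
              cs_nm = if (beta_rad > 0)
                        crystallite_size(beta_rad, theta, pattern$wavelength)
                      else Inf,
              background = c(intercept = cf[["b0"]], slope = cf[["b1"]]),
              fitted = stats::fitted(fit),
              window = window,
              rss = sum(resid(fit)^2),
              convergence = TRUE)
  class(res) <- "peak_fit"
  res
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("<peak_fit: center %.4f deg 2theta, height %.1f, FWHM_L %.5f deg>\n",
              x$center_deg, x$height, x$fwhm_l_deg))
  cat(sprintf("  integral breadth beta = %.6g rad;  Scherrer CS = %.4g nm\n",
              x$beta_rad, x$cs_nm))
  invisible(x)
}

#' @export
coef.peak_fit <- function(object, ...) {
  c(center_deg = object$center_deg, height = object$height,
    fwhm_l_deg = object$fwhm_l_deg, beta_rad = object$beta_rad,
    cs_nm = object$cs_nm)
}

# ---- Phase matching --------------------------------------------------------

#' Define a crystalline phase for matching
#'
#' @param name phase name.
#' @param cell a [unit_cell].
#' @param hkl integer matrix (n x 3) of Miller indices to consider.
#' @return Object of class `phase`.
#' @export
phase <- function(name, cell, hkl) {
  hkl <- matrix(as.integer(hkl), ncol = 3)
  structure(list(name = name, cell = cell, hkl = hkl), class = "phase")
}

#' Assign observed peaks to candidate phase reflections
#'
#' Each observed 2theta center is assigned to the candidate reflection with
#' the smallest absolute angular difference, provided it lies within
#' `tolerance`; otherwise it is reported unassigned.
#'
#' @param observed numeric vector of observed peak centers (degrees 2theta).
#' @param phases list of [phase] objects.
#' @param tolerance maximum `|delta 2theta|` in degrees (> 0).
#' @param wavelength wavelength in Angstrom.
#' @return Data frame with `observed`, `phase`, `h`, `k`, `l`,
#'   `predicted`, `delta`; unassigned peaks have `phase = NA`.
#' @export
match_phases <- function(observed, phases, tolerance = 0.2,
                         wavelength = CU_KALPHA1) {
  stopifnot(tolerance > 0)
  if (inherits(phases, "phase")) phases <- list(phases)
  cand <- do.call(rbind, lapply(phases, function(p) {
    d <- d_spacing(p$cell, p$hkl[, 1], p$hkl[, 2], p$hkl[, 3])
    ok <- wavelength <= 2 * d
    if (!any(ok)) return(NULL)
    data.frame(phase = p$name,
               h = p$hkl[ok, 1], k = p$hkl[ok, 2], l = p$hkl[ok, 3],
               predicted = bragg_two_theta(d[ok], wavelength),
               stringsAsFactors = FALSE)
  }))
  out <- lapply(observed, function(obs) {
    if (is.null(cand) || nrow(cand) == 0) {
      return(data.frame(observed = obs, phase = NA_character_,
                        h = NA_integer_, k = NA_integer_, l = NA_integer_,
                        predicted = NA_real_, delta = NA_real_))
    }
    dd <- abs(cand$predicted - obs)
    i <- which.min(dd)
    if (dd[i] <= tolerance) {
      data.frame(observed = obs, phase = cand$phase[i],
                 h = cand$h[i], k = cand$k[i], l = cand$l[i],
                 predicted = cand$predicted[i],
                 delta = cand$predicted[i] - obs)
    } else {
      data.frame(observed = obs, phase = NA_character_,
                 h = NA_integer_, k = NA_integer_, l = NA_integer_,
                 predicted = NA_real_, delta = NA_real_)
    }
  })
  do.call(rbind, out)
}

#' Read phase definitions from YAML
#'
#' Expected structure: a list of entries with `name`, `system`, `a`
#' (and `b`, `c` as the system requires) and `hkl` (list of 3-vectors).
#'
#' @param path YAML file path.
#' @return List of [phase] objects.
#' @export
read_phases_yaml <- function(path) {
  defs <- yaml::read_yaml(path)
  lapply(defs, function(d) {
    cell <- unit_cell(d$system, a = d$a,
                      b = if (!is.null(d$b)) d$b else NULL,
                      c = if (!is.null(d$c)) d$c else NULL)
    phase(d$name, cell, do.call(rbind, d$hkl))
  })
}
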