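# Centered 2-D FFT helpers. The pupil grids place DC at (N/2+1, N/2+1), so
# propagation is ifftshift -> FFT -> fftshift with a unitary 1/N
# normalization (energy in the pupil equals energy in the image).

.fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((n / 2 + 1):n, 1:(n / 2)), c((m / 2 + 1):m, 1:(m / 2))]
}

.ifftshift2 <- .fftshift2 # even dimensions only: shift is its own inverse

.centered_ifft2 <- function(x) {
  .fftshift2(stats::fft(.ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

.centered_fft2 <- function(x) {
  .fftshift2(stats::fft(.ifftshift2(x))) / sqrt(length(x))
}

#' Propagate the pupil field to a defocused image plane
#'
#' Applies the reflection-mode defocus transfer function `exp(2i kz z)` (the
#' factor 2 accounts for the double pass to the sample and back) and takes
#' the centered inverse Fourier transform of each field component:
#' `IMPx = IFFT(Ex exp(2i kz z))`, likewise `IMPy`. Positive `z` defocuses
#' the sample away from the objective; `kz` is real inside the NA mask so
#' the defocus factor is unit-modulus and total energy is conserved.
#'
#' @param field a [compute_bfp_fields()] result.
#' @param z defocus in micrometres (converted to nm internally).
#' @return an object of class `image_field` with complex matrices `IMPx`,
#'   `IMPy`, the defocus `z` (um) and the `grid` provenance.
#' @export
propagate_defocus <- function(field, z = 0) {
  stopifnot(inherits(field, "bfp_field"), is.finite(z))
  z_nm <- z * 1000
  defoc <- exp(2i * field$grid$kz * z_nm)
  defoc[!field$grid$mask] <- 0 + 0i
  structure(list(IMPx = .centered_ifft2(field$Ex * defoc),
                 IMPy = .centered_ifft2(field$Ey * defoc),
                 z = z, grid = field$grid),
            class = "image_field")
}

#' Image-plane intensity
#'
#' Per-pixel `|IMPx|^2 + |IMPy|^2`, the camera image at the (possibly
#' defocused) image plane.
#'
#' @param image an [propagate_defocus()] result.
#' @return a numeric matrix.
#' @export
imp_intensity <- function(image) {
  stopifnot(inherits(image, "image_field"))
  Mod(image$IMPx)^2 + Mod(image$IMPy)^2
}

#' Confocal V(z) response of a sample
#'
#' The confocal signal versus defocus,
#' `V(z) = sum_pupil w(kx, ky) * Ex * exp(2i kz z)`,
#' with a unit pupil weight by default. For plasmonic samples and `z < 0`
#' the interference between the surface-plasmon angle and the remaining
#' pupil produces periodic ripples with period
#' `lambda / (2 n0 (1 - cos(theta_sp)))`.
#'
#' @param field a [compute_bfp_fields()] result.
#' @param z_values defocus values in micrometres.
#' @param pupil_weight optional weight matrix over the pupil (defaults to 1
#'   inside the NA mask).
#' @return an object of class `vz_curve`: `z` (um), complex `V`, and
#'   `V_norm` = `|V|` scaled to max 1.
#' @export
vz_signal <- function(field, z_values, pupil_weight = NULL) {
  stopifnot(inherits(field, "bfp_field"), all(is.finite(z_values)))
  g <- field$grid
  if (is.null(pupil_weight)) {
    pupil_weight <- matrix(0, g$n_pixels, g$n_pixels)
    pupil_weight[g$mask] <- 1
  }
  stopifnot(all(dim(pupil_weight) == dim(g$kz)))
  w_ex <- (pupil_weight * field$Ex)[g$mask]
  kz <- g$kz[g$mask]
  V <- vapply(z_values, function(z) {
    sum(w_ex * exp(2i * kz * (z * 1000)))
  }, complex(1))
  structure(list(z = z_values, V = V, V_norm = Mod(V) / max(Mod(V))),
            class = "vz_curve")
}

#' Apodized pupil weight for confocal V(z) measurement
#'
#' A practical confocal system never weights the pupil rim fully: the
#' illumination profile and the pinhole roll the response off towards the
#' aperture edge. This weight is 1 up to a fractional pupil radius `edge`
#' and falls as a raised cosine to 0 at the NA circle. Without it, the
#' hard-edge diffraction of the numerical aperture beats against the
#' surface-plasmon contribution and masks the plasmon ripple period.
#'
#' @param grid a [build_pupil_grid()] result.
#' @param edge fractional pupil radius where the roll-off starts
#'   (default 0.7).
#' @return a weight matrix, zero outside the NA mask.
#' @export
vz_pupil_weight <- function(grid, edge = 0.7) {
  stopifnot(inherits(grid, "pupil_grid"), edge > 0, edge < 1)
  s0 <- sin(grid$theta0) * grid$n0 / grid$na # 0..1 inside the pupil
  w <- matrix(1, grid$n_pixels, grid$n_pixels)
  t <- (s0 - edge) / (1 - edge)
  roll <- t > 0
  w[roll] <- 0.5 * (1 + cos(pi * pmin(t[roll], 1)))
  w[!grid$mask] <- 0
  w
}

#' Ripple period of a V(z) curve
#'
#' Detrends `|V(z)|` with a centered running mean and returns the median
#' spacing of successive local minima of the residual — the ripple period.
#' For plasmonic samples at negative defocus this measures the beat between
#' the surface plasmon and the low-angle reference,
#' `lambda / (2 n0 (1 - cos(theta_sp)))`.
#'
#' @param vz a [vz_signal()] result (uniformly spaced `z`).
#' @param detrend_window running-mean window in samples (odd; default 31).
#' @return the median minima spacing in the units of `vz$z`, or `NA` if
#'   fewer than two minima are found.
#' @export
vz_ripple_period <- function(vz, detrend_window = 31L) {
  stopifnot(inherits(vz, "vz_curve"))
  v <- vz$V_norm
  trend <- stats::filter(v, rep(1 / detrend_window, detrend_window),
                         sides = 2)
  resid <- as.numeric(v - trend)
  mins <- local_minima(resid)
  mins <- mins[!is.na(resid[mins])]
  if (length(mins) < 2) return(NA_real_)
  stats::median(diff(vz$z[mins]))
}

#' Azimuthally averaged radial intensity profile
#'
#' Mean intensity over integer-radius annuli about the image center
#' (the DC pixel at `n/2 + 1`), used to locate diffraction rings of
#' defocused images.
#'
#' @param image square intensity matrix (even side).
#' @param max_radius largest radius bin (default `n/2 - 1`).
#' @return data.frame with `radius` (pixels) and `intensity`.
#' @export
radial_profile <- function(image, max_radius = NULL) {
  n <- nrow(image)
  stopifnot(ncol(image) == n, n %% 2 == 0)
  if (is.null(max_radius)) max_radius <- n / 2 - 1
  ctr <- n / 2 + 1
  r <- floor(sqrt((row(image) - ctr)^2 + (col(image) - ctr)^2))
  keep <- r <= max_radius
  means <- tapply(image[keep], r[keep], mean)
  data.frame(radius = as.integer(names(means)),
             intensity = as.numeric(means))
}

#' Locate local minima of a sampled curve
#'
#' Simple three-point local-minimum finder used to measure V(z) ripple
#' periods and reflectance dips.
#'
#' @param y numeric vector.
#' @return integer indices of strict interior local minima.
#' @export
local_minima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[y[i] < y[i - 1] & y[i] < y[i + 1]]
}
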