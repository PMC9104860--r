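#' Build the back-focal-plane k-space grid
#'
#' The pupil of the objective is sampled on an `n_pixels` x `n_pixels`
#' Cartesian grid of transverse wave-vectors. `kx` and `ky` span
#' `+/- 2*pi*NA/lambda` across the pupil diameter; the DC sample
#' (`kx = ky = 0`) sits at pixel `(n_pixels/2 + 1, n_pixels/2 + 1)`
#' (1-based), the FFT-center convention. Pixels whose center lies at or
#' outside the NA circle are excluded from the mask, so every masked-in
#' pixel has a mirror partner about both axes and `kz` is real inside the
#' mask (requires `NA < n0`).
#'
#' At the defaults (512 pixels, NA 1.49, n0 1.52) the per-pixel increment of
#' `sin(theta0)` is `2*(NA/n0)/512 = 0.0038`.
#'
#' @param n_pixels even pixel count per side (default 512).
#' @param na numerical aperture of the objective (default 1.49, oil).
#' @param wavelength wavelength in nm.
#' @param n0 substrate/immersion refractive index (default 1.52).
#' @return an object of class `pupil_grid` with matrices `kx`, `ky`, `kz`
#'   (rad/nm), `phi` (azimuth, rad), `theta0` (incidence angle in the
#'   substrate, rad), logical `mask`, and scalars `n_pixels`, `na`,
#'   `wavelength`, `n0`, `dsin_theta0`.
#' @export
build_pupil_grid <- function(n_pixels = 512, na = 1.49, wavelength = 633,
                             n0 = 1.52) {
  stopifnot(n_pixels %% 2 == 0, n_pixels >= 4)
  if (na >= n0) {
    stop("unsupported configuration: NA must be smaller than n0 ",
         "(kz would be complex inside the pupil)")
  }
  kmax <- 2 * pi * na / wavelength
  dk <- 2 * kmax / n_pixels
  idx <- seq_len(n_pixels) - (n_pixels / 2 + 1) # DC at index N/2 + 1
  kvals <- idx * dk
  kx <- matrix(kvals, n_pixels, n_pixels, byrow = FALSE) # rows vary kx
  ky <- matrix(kvals, n_pixels, n_pixels, byrow = TRUE)
  kr2 <- kx^2 + ky^2
  mask <- kr2 < kmax^2 # strict: edge pixels excluded
  k0n0 <- 2 * pi * n0 / wavelength
  kz <- sqrt(pmax(k0n0^2 - kr2, 0))
  phi <- atan2(ky, kx)
  sin_theta0 <- sqrt(kr2) / k0n0
  theta0 <- asin(pmin(sin_theta0, 1))
  structure(list(n_pixels = n_pixels, na = na, wavelength = wavelength,
                 n0 = n0, kx = kx, ky = ky, kz = kz, phi = phi,
                 theta0 = theta0, mask = mask,
                 dsin_theta0 = 2 * (na / n0) / n_pixels),
            class = "pupil_grid")
}

#' @export
print.pupil_grid <- function(x, ...) {
  cat(sprintf("<pupil_grid> %dx%d | NA %.2f | n0 %.2f | lambda %g nm | dsin(theta0) %.4f\n",
              x$n_pixels, x$n_pixels, x$na, x$n0, x$wavelength, x$dsin_theta0))
  invisible(x)
}

#' Vectorial back-focal-plane fields of a layered sample
#'
#' For x-polarized plane-wave illumination, each pupil pixel corresponds to
#' an incident direction `theta0` in the substrate; the sample returns the
#' complex Fresnel amplitudes `r_p(theta0)` and `r_s(theta0)` which mix into
#' Cartesian components
#' `Ex = r_p cos^2(phi) + r_s sin^2(phi)` and
#' `Ey = (r_p - r_s) sin(phi) cos(phi)`.
#' Illumination is uniform over the pupil and no aplanatic apodization is
#' applied; the reflection coefficients alone shape the field.
#'
#' The reflection coefficients are evaluated once per unique radial angle
#' and broadcast around the pupil, so the cost is linear in `n_pixels`.
#'
#' @param grid a [build_pupil_grid()] result.
#' @param stack a [layer_stack()]; its wavelength must match the grid's.
#' @return an object of class `bfp_field` with complex matrices `Ex`, `Ey`
#'   (zero outside the mask) and the `grid`/`stack` provenance.
#' @export
compute_bfp_fields <- function(grid, stack) {
  stopifnot(inherits(grid, "pupil_grid"), inherits(stack, "layer_stack"))
  if (abs(grid$wavelength - stack$wavelength) > 1e-9) {
    stop("stack wavelength must equal grid wavelength")
  }
  theta <- grid$theta0[grid$mask]
  uth <- sort(unique(as.vector(theta)))
  rp_u <- stack_reflection(stack, uth, "p")
  rs_u <- stack_reflection(stack, uth, "s")
  pos <- match(theta, uth)
  rp <- rp_u[pos]
  rs <- rs_u[pos]
  # trig factors written as rational functions of kx^2, ky^2 so the field
  # is bitwise mirror-symmetric about both axes on the sampled grid
  kx2 <- grid$kx[grid$mask]^2
  ky2 <- grid$ky[grid$mask]^2
  kxy <- grid$kx[grid$mask] * grid$ky[grid$mask]
  kr2 <- kx2 + ky2
  cphi2 <- ifelse(kr2 > 0, kx2 / kr2, 1) # phi = 0 at the DC pixel
  sphi2 <- ifelse(kr2 > 0, ky2 / kr2, 0)
  scphi <- ifelse(kr2 > 0, kxy / kr2, 0)
  n <- grid$n_pixels
  Ex <- matrix(0 + 0i, n, n); Ey <- Ex
  Ex[grid$mask] <- rp * cphi2 + rs * sphi2
  Ey[grid$mask] <- (rp - rs) * scphi
  structure(list(Ex = Ex, Ey = Ey, grid = grid, stack = stack),
            class = "bfp_field")
}

#' Back-focal-plane intensity image
#'
#' Per-pixel `|Ex|^2 + |Ey|^2`, the intensity a camera records at the BFP;
#' zero outside the NA mask.
#'
#' @param field a [compute_bfp_fields()] result.
#' @return a numeric matrix.
#' @export
bfp_intensity <- function(field) {
  stopifnot(inherits(field, "bfp_field"))
  Mod(field$Ex)^2 + Mod(field$Ey)^2
}

#' Back-focal-plane wrapped phase map
#'
#' Argument of the chosen field component, wrapped to `[-pi, pi)`; defined
#' as 0 outside the NA mask.
#'
#' @param field a [compute_bfp_fields()] result.
#' @param component `"x"` (default) or `"y"`.
#' @return a numeric matrix of phases in radians.
#' @export
bfp_phase <- function(field, component = c("x", "y")) {
  component <- match.arg(component)
  stopifnot(inherits(field, "bfp_field"))
  E <- if (component == "x") field$Ex else field$Ey
  ph <- wrap_phase(Arg(E))
  ph[!field$grid$mask] <- 0
  ph
}
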