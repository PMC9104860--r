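#' @useDynLib canqpi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Time convention: fields ~ exp(-i*omega*t). Absorbing media therefore have
# Im(n) > 0 and evanescent/absorbed waves carry Im(kz) > 0 so that
# exp(+i*kz*z) decays into the medium. Used consistently everywhere; it only
# affects the sign of phase maps, never their structure.

.canqpi_env <- new.env(parent = emptyenv())

.material_tables <- function() {
  if (is.null(.canqpi_env$materials)) {
    gold <- utils::read.csv(system.file("extdata", "gold_johnson_christy.csv",
                                        package = "canqpi"))
    fixed <- utils::read.csv(system.file("extdata", "materials.csv",
                                         package = "canqpi"))
    .canqpi_env$materials <- list(gold = gold, fixed = fixed)
  }
  .canqpi_env$materials
}

#' Override the optical-constant fixture tables
#'
#' Replaces the packaged gold dispersion table and/or the fixed-index table
#' with user-supplied CSV files of the same layout
#' (`wavelength_nm,n,k` and `material,n` respectively).
#'
#' @param gold_csv path to a gold dispersion CSV, or `NULL` to keep current.
#' @param fixed_csv path to a fixed-index CSV, or `NULL` to keep current.
#' @return invisibly, the active tables.
#' @export
set_material_tables <- function(gold_csv = NULL, fixed_csv = NULL) {
  tabs <- .material_tables()
  if (!is.null(gold_csv)) tabs$gold <- utils::read.csv(gold_csv)
  if (!is.null(fixed_csv)) tabs$fixed <- utils::read.csv(fixed_csv)
  .canqpi_env$materials <- tabs
  invisible(tabs)
}

#' Complex refractive index of a material
#'
#' Gold ("gold") is linearly interpolated from the embedded Johnson & Christy
#' (1972) tabulation and may be scaled by up to +/-10% (the perturbation used
#' when drawing random plasmonic samples). BK7 glass, PMMA, water and air are
#' fixed real indices at the working wavelengths.
#'
#' @param material_id one of `"gold"`, `"bk7"`, `"pmma"`, `"water"`, `"air"`
#'   (case-insensitive).
#' @param wavelength wavelength in nm; must lie inside the dispersion table
#'   for gold.
#' @param scale real multiplier applied to the complex index; restricted to
#'   `[0.9, 1.1]` for gold and exactly 1 for the fixed-index materials.
#' @param scale_k optional separate multiplier for the imaginary part
#'   (gold only); by default `scale` multiplies the full complex index.
#' @return a complex scalar (or vector along `wavelength`).
#' @examples
#' material_index("gold", 633)
#' material_index("bk7", 633)
#' @export
material_index <- function(material_id, wavelength, scale = 1.0,
                           scale_k = NULL) {
  tabs <- .material_tables()
  id <- tolower(material_id)
  if (id == "gold") {
    tab <- tabs$gold
    if (any(wavelength < min(tab$wavelength_nm) |
            wavelength > max(tab$wavelength_nm))) {
      stop("wavelength outside the gold dispersion table (",
           min(tab$wavelength_nm), "-", max(tab$wavelength_nm), " nm)")
    }
    if (scale < 0.9 - 1e-12 || scale > 1.1 + 1e-12) {
      stop("gold index scale must lie in [0.9, 1.1]")
    }
    n <- stats::approx(tab$wavelength_nm, tab$n, xout = wavelength)$y
    k <- stats::approx(tab$wavelength_nm, tab$k, xout = wavelength)$y
    if (is.null(scale_k)) {
      return(scale * complex(real = n, imaginary = k))
    }
    return(complex(real = scale * n, imaginary = scale_k * k))
  }
  row <- match(id, tolower(tabs$fixed$material))
  if (is.na(row)) stop("unknown material: ", material_id)
  if (abs(scale - 1) > 1e-12) {
    stop("index scaling is only supported for gold")
  }
  rep(complex(real = tabs$fixed$n[row], imaginary = 0), length(wavelength))
}

#' Define a layered sample
#'
#' The geometry is incidence-side glass substrate (`n0`, real), zero or more
#' deposited layers, then a semi-infinite backing medium (`ns`, real):
#' the sample of a reflection-mode high-NA microscope. The reflection phase
#' is referenced at the substrate/first-layer interface.
#'
#' @param n0 real substrate (glass) refractive index.
#' @param layers list of `list(n = <complex>, d = <thickness nm>)`, outermost
#'   first (adjacent to the substrate). May be empty.
#' @param ns real backing (sample medium) refractive index.
#' @param wavelength wavelength in nm.
#' @return an object of class `layer_stack`.
#' @examples
#' gold50 <- layer_stack(1.52, list(list(n = material_index("gold", 633),
#'                                       d = 50)), 1.0, 633)
#' @export
layer_stack <- function(n0, layers = list(), ns = 1.0, wavelength = 633) {
  stopifnot(is.numeric(n0), length(n0) == 1L, n0 > 0,
            is.numeric(ns), length(ns) == 1L, ns > 0,
            is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0)
  for (ly in layers) {
    stopifnot(is.list(ly), !is.null(ly$n), !is.null(ly$d))
    if (ly$d < 0) stop("layer thicknesses must be >= 0")
    if (Im(as.complex(ly$n)) < -1e-12) {
      stop("absorbing layers must have Im(n) >= 0 under the e^{-i omega t} convention")
    }
  }
  structure(list(n0 = n0, layers = layers, ns = ns, wavelength = wavelength),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("<layer_stack> n0 =", x$n0, "| ns =", x$ns,
      "| lambda =", x$wavelength, "nm\n")
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    cat(sprintf("  layer %d: n = %.4f%+.4fi, d = %g nm\n",
                i, Re(ly$n), Im(ly$n), ly$d))
  }
  invisible(x)
}

# Branch of the longitudinal wavenumber: Im(kz) >= 0 so evanescent fields
# decay along +z; for lossless propagating waves kz is real positive.
.kz_branch <- function(n, n0_sin_theta, k0) {
  kz <- k0 * sqrt(as.complex(n^2 - n0_sin_theta^2))
  flip <- Im(kz) < 0 | (abs(Im(kz)) < 1e-300 & Re(kz) < 0)
  kz[flip] <- -kz[flip]
  kz
}

#' Fresnel amplitude reflection coefficient of a single interface
#'
#' Sign conventions: `r_s = (n1 cos t1 - n2 cos t2) / (n1 cos t1 + n2 cos t2)`
#' and `r_p = (n2 cos t1 - n1 cos t2) / (n2 cos t1 + n1 cos t2)`, so the
#' p-polarized coefficient vanishes at the Brewster angle and equals
#' `(n2 - n1)/(n2 + n1)` at normal incidence. Angles beyond the critical
#' angle are handled through a complex transmitted-angle cosine
#' (evanescent transmission), never clamped.
#'
#' @param n1 incidence-side refractive index (real).
#' @param n2 transmission-side refractive index (possibly complex).
#' @param theta1 incidence angle(s) in radians, in `[0, pi/2)`. Vectorized.
#' @param polarization `"s"` or `"p"`.
#' @return complex reflection coefficient(s).
#' @export
fresnel_interface <- function(n1, n2, theta1, polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  stopifnot(all(theta1 >= 0 & theta1 < pi / 2))
  k0 <- 1 # wavelength cancels for a bare interface
  st <- n1 * sin(theta1)
  kz1 <- .kz_branch(n1, st, k0)
  kz2 <- .kz_branch(n2, st, k0)
  if (polarization == "s") {
    (kz1 - kz2) / (kz1 + kz2)
  } else {
    q1 <- kz1 / as.complex(n1)^2
    q2 <- kz2 / as.complex(n2)^2
    (q1 - q2) / (q1 + q2)
  }
}

#' Reflection coefficient of a layered stack (transfer-matrix method)
#'
#' Builds the 2x2 characteristic matrix of every deposited layer with
#' polarization-dependent tilted admittances and combines them with the
#' substrate and backing admittances. With no layers (or zero-thickness
#' layers) it reduces exactly to [fresnel_interface()]. Phase is referenced
#' at the substrate / first-layer interface.
#'
#' @param stack a [layer_stack()].
#' @param theta0 incidence angle(s) in the substrate, radians. Vectorized.
#' @param polarization `"s"` or `"p"`.
#' @return complex reflection coefficient(s), same length as `theta0`.
#' @export
stack_reflection <- function(stack, theta0, polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(stack, "layer_stack"), all(theta0 >= 0 & theta0 < pi / 2))
  k0 <- 2 * pi / stack$wavelength
  st <- stack$n0 * sin(theta0)

  admittance <- function(n, kz) {
    if (polarization == "s") kz else kz / as.complex(n)^2
  }

  kz0 <- .kz_branch(stack$n0, st, k0)
  kzb <- .kz_branch(stack$ns, st, k0)
  q0 <- admittance(stack$n0, kz0)
  qb <- admittance(stack$ns, kzb)

  # characteristic matrix product, elementwise over angles
  m11 <- rep(1 + 0i, length(theta0)); m12 <- rep(0 + 0i, length(theta0))
  m21 <- m12; m22 <- m11
  for (ly in stack$layers) {
    kzl <- .kz_branch(ly$n, st, k0)
    ql <- admittance(ly$n, kzl)
    # characteristic matrix under the e^{-i omega t} convention (the
    # classic e^{+i omega t} form with delta -> -delta)
    delta <- kzl * ly$d
    cd <- cos(delta); sd <- sin(delta)
    a11 <- cd;            a12 <- -1i * sd / ql
    a21 <- -1i * ql * sd; a22 <- cd
    n11 <- m11 * a11 + m12 * a21; n12 <- m11 * a12 + m12 * a22
    n21 <- m21 * a11 + m22 * a21; n22 <- m21 * a12 + m22 * a22
    m11 <- n11; m12 <- n12; m21 <- n21; m22 <- n22
  }
  bb <- m11 + m12 * qb
  cc <- m21 + m22 * qb
  (q0 * bb - cc) / (q0 * bb + cc)
}
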