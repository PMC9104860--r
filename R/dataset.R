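# Dataset generation: random layered-sample parameters, field simulation,
# quadrant cropping, normalization and channel stacking for the five
# network input configurations.

.z_defaults <- list(CAN1 = numeric(0), CAN2 = 0, CAN3 = 6,
                    CAN4 = c(6, 9), CAN5 = c(6, 7.5, 9))

#' Draw random sample parameters
#'
#' Each physical parameter is drawn independently and uniformly within its
#' range. Plasmonic (SPR) samples: gold thickness 30-60 nm, a +/-10% scale
#' on the tabulated gold complex index, backing index 1.0-1.4, wavelength
#' 600-700 nm. Dielectric waveguides: thickness 0.95-1.05 um, layer index
#' 1.20-1.50 (real, lossless), backing index 1.0-1.4, wavelength
#' 600-700 nm.
#'
#' @param sample_type `"spr"` or `"waveguide"`.
#' @param n_draws number of parameter sets.
#' @param seed integer RNG seed (reproducible draws).
#' @return list of `parameter_set` lists with fields `sample_type`, `d_m`
#'   (nm for SPR, um for waveguide), `n_m` (complex for gold), `scale`
#'   (gold only), `n_s`, `wavelength` (nm), `seed`.
#' @export
sample_parameters <- function(sample_type = c("spr", "waveguide"),
                              n_draws, seed = 1L) {
  sample_type <- match.arg(sample_type)
  stopifnot(n_draws >= 1)
  set.seed(seed)
  out <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    lambda <- stats::runif(1, 600, 700)
    ns <- stats::runif(1, 1.0, 1.4)
    if (sample_type == "spr") {
      d <- stats::runif(1, 30, 60)
      sc <- stats::runif(1, 0.9, 1.1)
      nm <- material_index("gold", lambda, sc)
    } else {
      d <- stats::runif(1, 0.95, 1.05)
      sc <- NA_real_
      nm <- complex(real = stats::runif(1, 1.20, 1.50), imaginary = 0)
    }
    out[[i]] <- structure(list(sample_type = sample_type, d_m = d, n_m = nm,
                               scale = sc, n_s = ns, wavelength = lambda,
                               seed = seed, case_id = NULL),
                          class = "parameter_set")
  }
  out
}

#' The six fixed test cases per sample type
#'
#' SPR: gold films of 30, 40 and 50 nm over air and over water at 633 nm.
#' Waveguide: PMMA films of 0.95, 1.00 and 1.05 um over air and over water
#' at 633 nm. These cases are held out of training/validation draws.
#'
#' @param sample_type `"spr"` or `"waveguide"`.
#' @return a list of 6 `parameter_set`s with `case_id` 1-6.
#' @export
make_test_set <- function(sample_type = c("spr", "waveguide")) {
  sample_type <- match.arg(sample_type)
  backs <- c(rep(material_index("air", 633), 3),
             rep(material_index("water", 633), 3))
  if (sample_type == "spr") {
    ds <- c(30, 40, 50, 30, 40, 50)
    nm <- material_index("gold", 633, 1.0)
  } else {
    ds <- c(0.95, 1, 1.05, 0.95, 1, 1.05)
    nm <- material_index("pmma", 633)
  }
  lapply(1:6, function(i) {
    structure(list(sample_type = sample_type, d_m = ds[i], n_m = nm,
                   scale = if (sample_type == "spr") 1.0 else NA_real_,
                   n_s = Re(backs[i]), wavelength = 633, seed = NA_integer_,
                   case_id = i),
              class = "parameter_set")
  })
}

#' Layer stack corresponding to a parameter set
#'
#' @param params a `parameter_set`.
#' @param n0 substrate index (default BK7 glass, 1.52).
#' @return a [layer_stack()]. Waveguide thicknesses are converted um -> nm.
#' @export
params_to_stack <- function(params, n0 = 1.52) {
  stopifnot(inherits(params, "parameter_set"))
  d_nm <- if (params$sample_type == "waveguide") params$d_m * 1000 else params$d_m
  layer_stack(n0, list(list(n = params$n_m, d = d_nm)), params$n_s,
              params$wavelength)
}

#' Crop the upper-right quadrant of an even-sized square map
#'
#' Keeps rows/columns `n/2 + 1` to `n` — the quadrant with `kx >= 0`,
#' `ky >= 0` including the center row and column. By the twofold mirror
#' symmetry of x-polarized pupil maps, one quadrant carries the full
#' information; [reconstruct_quadrant()] is its inverse.
#'
#' @param image an `n x n` matrix, `n` even.
#' @return an `n/2 x n/2` matrix.
#' @export
crop_quadrant <- function(image) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image),
            nrow(image) %% 2 == 0)
  n <- nrow(image)
  image[(n / 2 + 1):n, (n / 2 + 1):n]
}

#' Z-score normalize an image
#'
#' Subtracts the mean and divides by the standard deviation, giving mean 0
#' and sd 1; affine-invariant by construction.
#'
#' @param image numeric matrix with nonzero variance.
#' @return normalized matrix.
#' @export
zscore_normalize <- function(image) {
  s <- stats::sd(image)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: zero-variance image cannot be z-scored")
  }
  (image - mean(image)) / s
}

#' Assemble a supervised record for one sample
#'
#' Simulates the pupil field of the sample, crops one quadrant, and stacks
#' the input channels of the requested network variant: CAN1 `[BFP]`, CAN2
#' `[BFP, IMP(z1)]`, CAN3 `[IMP(z1)]`, CAN4 `[IMP(z1), IMP(z2)]`, CAN5
#' `[IMP(z1), IMP(z2), IMP(z3)]`. IMP channels are z-score normalized; the
#' BFP intensity channel is left on its natural scale unless
#' `normalize_bfp`. The label is the cropped wrapped phase of `Ex`.
#' Default defocus lists: z = 0 um for CAN2 and z = 6 (and 9, 7.5) um for
#' CAN3-CAN5.
#'
#' @param params a `parameter_set`.
#' @param can_variant `"CAN1"` to `"CAN5"`.
#' @param z_list defocus values in um for the IMP channels (`NULL` for the
#'   variant default).
#' @param n_pixels pupil grid size (512 at full scale; 128 gives 64x64
#'   records for CPU-sized runs).
#' @param na,n0 objective NA and substrate index.
#' @param normalize_bfp also z-score the BFP channel.
#' @param imp_amplitude use amplitude `sqrt(intensity)` for IMP channels
#'   instead of intensity.
#' @return a `dataset_record`: `inputs` (`n/2 x n/2 x N` array), `label`
#'   (`n/2 x n/2`, rad, in `[-pi, pi)`), `params`, `variant`, `z_list`.
#' @export
assemble_record <- function(params, can_variant = "CAN1", z_list = NULL,
                            n_pixels = 512, na = 1.49, n0 = 1.52,
                            normalize_bfp = FALSE, imp_amplitude = FALSE) {
  stopifnot(can_variant %in% names(.z_defaults))
  if (is.null(z_list)) z_list <- .z_defaults[[can_variant]]
  n_imp <- c(CAN1 = 0L, CAN2 = 1L, CAN3 = 1L, CAN4 = 2L, CAN5 = 3L)[[can_variant]]
  if (length(z_list) != n_imp) {
    stop(can_variant, " needs ", n_imp, " defocus value(s), got ",
         length(z_list))
  }
  grid <- build_pupil_grid(n_pixels, na, params$wavelength, n0)
  field <- compute_bfp_fields(grid, params_to_stack(params, n0))
  chans <- list()
  if (can_variant %in% c("CAN1", "CAN2")) {
    bfp <- crop_quadrant(bfp_intensity(field))
    chans <- c(chans, list(if (normalize_bfp) zscore_normalize(bfp) else bfp))
  }
  for (z in z_list) {
    imp <- imp_intensity(propagate_defocus(field, z))
    if (imp_amplitude) imp <- sqrt(imp)
    chans <- c(chans, list(zscore_normalize(crop_quadrant(imp))))
  }
  h <- n_pixels / 2
  inputs <- array(unlist(chans), dim = c(h, h, length(chans)))
  label <- crop_quadrant(bfp_phase(field, "x"))
  structure(list(inputs = inputs, label = label, params = params,
                 variant = can_variant, z_list = z_list),
            class = "dataset_record")
}

#' Generate a full supervised dataset
#'
#' Draws `n` random parameter sets and assembles one record per draw. The
#' fixed test cases are excluded by construction (continuous draws never hit
#' them); this is asserted and an error raised should a draw coincide.
#'
#' @inheritParams sample_parameters
#' @inheritParams assemble_record
#' @param n number of records.
#' @param ... passed on to [assemble_record()].
#' @return list of `dataset_record`s.
#' @export
generate_dataset <- function(sample_type = c("spr", "waveguide"), n,
                             can_variant = "CAN1", seed = 1L,
                             n_pixels = 512, ...) {
  sample_type <- match.arg(sample_type)
  draws <- sample_parameters(sample_type, n, seed)
  test <- make_test_set(sample_type)
  for (p in draws) {
    for (tcase in test) {
      if (abs(p$d_m - tcase$d_m) < 1e-12 &&
          abs(p$n_s - tcase$n_s) < 1e-12 &&
          abs(p$wavelength - tcase$wavelength) < 1e-12) {
        stop("a random draw coincides with a held-out test case")
      }
    }
  }
  lapply(draws, assemble_record, can_variant = can_variant,
         n_pixels = n_pixels, ...)
}

#' Split records into training and validation sets
#'
#' Deterministic shuffled split: `round(fraction * n)` records train, the
#' rest validate; disjoint, union = all.
#'
#' @param records list of records.
#' @param fraction training fraction in (0, 1), default 0.9.
#' @param seed RNG seed for the shuffle.
#' @return a `dataset_split` with `train`, `validation`, `fraction`.
#' @export
split_dataset <- function(records, fraction = 0.9, seed = 1L) {
  stopifnot(length(records) >= 1, fraction > 0, fraction < 1)
  set.seed(seed)
  ord <- sample.int(length(records))
  n_train <- round(fraction * length(records))
  structure(list(train = records[ord[seq_len(n_train)]],
                 validation = records[ord[-seq_len(n_train)]],
                 fraction = fraction),
            class = "dataset_split")
}

#' Save / load a dataset
#'
#' Records (or a split) are serialized to one file with a small JSON
#' sidecar recording the generation configuration.
#'
#' @param x records or a `dataset_split`.
#' @param path output file.
#' @param config optional named list stored in the sidecar.
#' @return `save_dataset`: the path, invisibly; `load_dataset`: the object.
#' @export
save_dataset <- function(x, path, config = list()) {
  saveRDS(x, path)
  n <- if (inherits(x, "dataset_split")) {
    c(train = length(x$train), validation = length(x$validation))
  } else c(records = length(x))
  jsonlite::write_json(c(list(counts = as.list(n)), config),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)
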