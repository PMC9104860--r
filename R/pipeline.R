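# End-to-end orchestration: resolved run configurations, simulation export,
# and the simulate -> dataset -> train -> evaluate pipeline.

.presets <- list(
  # reference-scale profiles (GPU-sized): full 512 pupil, M = 64
  "spr-paper" = list(sample_type = "spr", variant = "CAN2", n_pixels = 512,
                     na = 1.49, n0 = 1.52, n_records = 1000, features = 64,
                     epochs = 100, learning_rate = 1e-4, fraction = 0.9),
  "waveguide-paper" = list(sample_type = "waveguide", variant = "CAN2",
                           n_pixels = 512, na = 1.49, n0 = 1.52,
                           n_records = 1000, features = 64, epochs = 100,
                           learning_rate = 1e-4, fraction = 0.9),
  # desk profiles: 64x64 records, M = 8, shorter schedule with a larger
  # Adam step (see the methods vignette)
  "spr-desk" = list(sample_type = "spr", variant = "CAN2", n_pixels = 128,
                    na = 1.49, n0 = 1.52, n_records = 200, features = 8,
                    epochs = 30, learning_rate = 1e-3, fraction = 0.9),
  "waveguide-desk" = list(sample_type = "waveguide", variant = "CAN2",
                          n_pixels = 128, na = 1.49, n0 = 1.52,
                          n_records = 200, features = 8, epochs = 30,
                          learning_rate = 1e-3, fraction = 0.9)
)

#' Resolve a run configuration
#'
#' Starts from a named preset (`"spr-paper"`, `"waveguide-paper"`,
#' `"spr-desk"`, `"waveguide-desk"`), optionally merges a YAML file, then
#' merges explicit overrides, validates, and returns the resolved list.
#'
#' @param preset preset name.
#' @param yaml_file optional YAML file of overrides.
#' @param ... explicit overrides (e.g. `epochs = 5`).
#' @return a validated `run_config` list, including `seed` and `z_list`.
#' @export
run_config <- function(preset = "spr-desk", yaml_file = NULL, ...) {
  if (!preset %in% names(.presets)) {
    stop("unknown preset; available: ", paste(names(.presets), collapse = ", "))
  }
  cfg <- .presets[[preset]]
  cfg$preset <- preset
  cfg$seed <- 1L
  cfg$z_list <- NULL # variant default
  if (!is.null(yaml_file)) {
    cfg[names(yaml::read_yaml(yaml_file))] <- yaml::read_yaml(yaml_file)
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$sample_type %in% c("spr", "waveguide"),
            cfg$variant %in% paste0("CAN", 1:5),
            cfg$n_pixels %% 2 == 0, cfg$na < cfg$n0,
            cfg$n_records >= 2, cfg$features >= 1, cfg$epochs >= 1,
            cfg$learning_rate > 0, cfg$fraction > 0, cfg$fraction < 1)
  cfg
}

.write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
}

.write_png_preview <- function(m, path) {
  if (!requireNamespace("png", quietly = TRUE)) return(invisible(NULL))
  rng <- range(m)
  scaled <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  png::writePNG(scaled, path) # 16-bit grayscale preview
  invisible(path)
}

#' Simulate and export the imaging planes of one sample
#'
#' Writes the BFP intensity, the wrapped BFP phase of `Ex`, and defocused
#' image-plane intensities as lossless CSV arrays plus PNG previews (when
#' the `png` package is available).
#'
#' @param params a `parameter_set` (e.g. one of [make_test_set()]).
#' @param out_dir output directory, created if missing.
#' @param z_list defocus planes in um for the exported IMP images.
#' @param n_pixels,na,n0 grid parameters.
#' @return invisibly, the list of files written.
#' @export
run_simulate <- function(params, out_dir, z_list = c(0, 6),
                         n_pixels = 512, na = 1.49, n0 = 1.52) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- build_pupil_grid(n_pixels, na, params$wavelength, n0)
  field <- compute_bfp_fields(grid, params_to_stack(params, n0))
  files <- character(0)
  emit <- function(m, stem) {
    csv <- file.path(out_dir, paste0(stem, ".csv"))
    .write_matrix_csv(m, csv)
    .write_png_preview(m, file.path(out_dir, paste0(stem, ".png")))
    files <<- c(files, csv)
  }
  emit(bfp_intensity(field), "bfp_intensity")
  emit(bfp_phase(field, "x"), "bfp_phase_x")
  for (z in z_list) {
    emit(imp_intensity(propagate_defocus(field, z)),
         sprintf("imp_intensity_z%+g", z))
  }
  invisible(files)
}

#' Run the full pipeline: dataset, training, evaluation
#'
#' Generates the dataset of the resolved configuration, splits it, trains
#' the network, evaluates it on the six held-out test cases (plus requested
#' channel switch-offs), and writes all artifacts (dataset, model, history,
#' evaluation CSVs, JSON run manifest) under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, created if missing.
#' @param ablations character vector among `"bfp_off"`, `"imp_off"`.
#' @param n_offsets SSIM offset-grid size for the evaluation stage.
#' @param verbose print per-stage progress.
#' @return a list with `model`, `eval` (an `eval_table`), `eval_ablations`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, ablations = character(0),
                         n_offsets = 90L, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  timing <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    val <- force(expr)
    timing[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    say("[%s] %.1f s", stage, timing[[stage]])
    val
  }

  records <- tick("dataset", generate_dataset(
    config$sample_type, config$n_records, config$variant,
    seed = config$seed, n_pixels = config$n_pixels, na = config$na,
    n0 = config$n0, z_list = config$z_list))
  split <- split_dataset(records, config$fraction, seed = config$seed + 1L)
  save_dataset(split, file.path(out_dir, "dataset.rds"),
               config = config[c("sample_type", "variant", "n_pixels",
                                 "n_records", "seed")])

  cfg_net <- can_config(dim(records[[1]]$inputs)[3], config$features,
                        config$n_pixels / 2)
  tc <- train_config(learning_rate = config$learning_rate,
                     epochs = config$epochs, seed = config$seed + 2L)
  model <- tick("train", train_can(build_can(cfg_net, seed = config$seed + 3L),
                                   split, tc, verbose = verbose))
  save_can(model, file.path(out_dir, "model.rds"))
  utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)

  test <- lapply(make_test_set(config$sample_type), assemble_record,
                 can_variant = config$variant, z_list = config$z_list,
                 n_pixels = config$n_pixels, na = config$na, n0 = config$n0)
  ev <- tick("evaluate", evaluate_model(model, test, n_offsets = n_offsets))
  utils::write.csv(ev, file.path(out_dir, "evaluation.csv"), row.names = FALSE)
  ev_abl <- lapply(ablations, function(a) {
    tab <- evaluate_model(model, test, a, n_offsets = n_offsets)
    utils::write.csv(tab, file.path(out_dir, paste0("evaluation_", a, ".csv")),
                     row.names = FALSE)
    tab
  })
  names(ev_abl) <- ablations

  manifest <- list(config = config, timing = timing,
                   config_hash = digest_config(config),
                   average_ssim = attr(ev, "average"),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(model = model, eval = ev, eval_ablations = ev_abl, manifest = manifest)
}

#' Stable hash of a configuration
#'
#' Short hex digest of the serialized configuration, recorded in run
#' manifests so artifacts are traceable to seed + configuration.
#'
#' @param config any R object.
#' @return a hex string.
#' @export
digest_config <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  # FNV-1a over the serialized bytes; dependency-free and stable
  h <- 0
  for (b in as.integer(raw)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
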