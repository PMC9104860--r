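test_that("random parameter draws respect the sampling ranges and are reproducible", {
  for (typ in c("spr", "waveguide")) {
    ps <- sample_parameters(typ, 200, seed = 7)
    d <- sapply(ps, `[[`, "d_m")
    ns <- sapply(ps, `[[`, "n_s")
    wl <- sapply(ps, `[[`, "wavelength")
    expect_true(all(ns >= 1.0 & ns <= 1.4))
    expect_true(all(wl >= 600 & wl <= 700))
    if (typ == "spr") {
      expect_true(all(d >= 30 & d <= 60))
      sc <- sapply(ps, `[[`, "scale")
      expect_true(all(sc >= 0.9 & sc <= 1.1))
      expect_true(all(sapply(ps, function(p) Im(p$n_m) > 0)))
    } else {
      expect_true(all(d >= 0.95 & d <= 1.05))
      nm <- sapply(ps, function(p) Re(p$n_m))
      expect_true(all(nm >= 1.20 & nm <= 1.50))
      expect_true(all(sapply(ps, function(p) Im(p$n_m) == 0)))
    }
    expect_identical(sample_parameters(typ, 200, seed = 7), ps)
  }
  expect_error(sample_parameters("metamaterial", 5))
})

test_that("the held-out test cases are the six fixed samples per type", {
  spr <- make_test_set("spr")
  wg <- make_test_set("waveguide")
  expect_length(spr, 6)
  expect_length(wg, 6)
  expect_equal(spr[[3]]$d_m, 50)
  expect_equal(spr[[3]]$n_s, 1.0)   # air backing
  expect_equal(spr[[3]]$wavelength, 633)
  expect_equal(spr[[3]]$n_m, material_index("gold", 633))
  expect_equal(wg[[5]]$d_m, 1)
  expect_equal(wg[[5]]$n_s, 1.33)   # water backing
  expect_equal(wg[[5]]$n_m, material_index("pmma", 633))
  expect_equal(sapply(spr, `[[`, "d_m"), c(30, 40, 50, 30, 40, 50))
  expect_equal(sapply(wg, `[[`, "n_s"), c(1, 1, 1, 1.33, 1.33, 1.33))
})

test_that("quadrant cropping is deterministic and captures the plasmon arc", {
  const <- matrix(3.2, 64, 64)
  expect_equal(crop_quadrant(const), matrix(3.2, 32, 32))
  expect_error(crop_quadrant(matrix(0, 64, 32)))
  f <- gold_field_128()
  I <- bfp_intensity(f)
  q <- crop_quadrant(I)
  qmask <- crop_quadrant(ifelse(f$grid$mask, 1, 0)) > 0
  # the dark plasmon arc is fully contained in one quadrant
  expect_equal(min(q[qmask]), min(I[f$grid$mask]))
  # mirror symmetry: cropping a mirrored image equals the crop itself
  n <- nrow(I)
  mirrored <- I[c(1, n:2), ]
  expect_equal(crop_quadrant(mirrored), q)
})

test_that("z-score normalization has mean 0, sd 1 and affine invariance", {
  set.seed(13)
  x <- matrix(rnorm(400, 5, 3), 20)
  z <- zscore_normalize(x)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(z), 1, tolerance = 1e-10)
  expect_equal(zscore_normalize(2.5 * x - 7), z, tolerance = 1e-10)
  expect_error(zscore_normalize(matrix(1, 4, 4)), "degenerate")
})

test_that("records stack the channels of each network variant", {
  p <- make_test_set("spr")[[2]]
  r1 <- assemble_record(p, "CAN1", n_pixels = 64)
  expect_equal(dim(r1$inputs), c(32, 32, 1))
  r2 <- assemble_record(p, "CAN2", n_pixels = 64)
  expect_equal(dim(r2$inputs), c(32, 32, 2))
  expect_equal(r2$z_list, 0)
  r5 <- assemble_record(p, "CAN5", z_list = c(6, 7.5, 9), n_pixels = 64)
  expect_equal(dim(r5$inputs), c(32, 32, 3))
  expect_error(assemble_record(p, "CAN4", z_list = 6, n_pixels = 64),
               "defocus")
  # label is the cropped wrapped phase of Ex (pipeline identity)
  g <- build_pupil_grid(64, 1.49, p$wavelength, 1.52)
  f <- compute_bfp_fields(g, params_to_stack(p))
  expect_equal(r1$label, crop_quadrant(bfp_phase(f, "x")))
  expect_true(all(r1$label >= -pi & r1$label < pi))
  expect_true(all(is.finite(r2$inputs)))
  # IMP channels are z-scored, BFP channel keeps its natural scale
  expect_equal(mean(r2$inputs[, , 2]), 0, tolerance = 1e-10)
  expect_equal(stats::sd(r2$inputs[, , 2]), 1, tolerance = 1e-10)
  expect_gt(mean(r2$inputs[, , 1]), 0.05)
})

test_that("dataset split is exact, disjoint and seed-deterministic", {
  recs <- as.list(seq_len(10))
  sp <- split_dataset(recs, 0.9, seed = 3)
  expect_length(sp$train, 9)
  expect_length(sp$validation, 1)
  expect_length(intersect(unlist(sp$train), unlist(sp$validation)), 0)
  expect_setequal(c(unlist(sp$train), unlist(sp$validation)), 1:10)
  sp2 <- split_dataset(recs, 0.9, seed = 3)
  expect_identical(sp, sp2)
  expect_error(split_dataset(list(), 0.9))
})

test_that("datasets round-trip through serialization bit-equal", {
  p <- make_test_set("spr")[[1]]
  recs <- list(assemble_record(p, "CAN2", n_pixels = 64))
  path <- tempfile(fileext = ".rds")
  save_dataset(recs, path, config = list(note = "roundtrip"))
  expect_identical(load_dataset(path), recs)
  expect_true(file.exists(paste0(path, ".json")))
  unlink(c(path, paste0(path, ".json")))
})
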