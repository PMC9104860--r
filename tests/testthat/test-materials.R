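test_that("gold index interpolates the embedded dispersion table", {
  # hand interpolation between the 616.8 nm (0.21 + 3.272i) and 659.5 nm
  # (0.14 + 3.697i) rows: t = (633 - 616.8) / (659.5 - 616.8)
  t <- 16.2 / 42.7
  expected <- complex(real = 0.21 - 0.07 * t, imaginary = 3.272 + 0.425 * t)
  expect_equal(material_index("gold", 633), expected, tolerance = 1e-9)
  # scaling identity
  expect_equal(material_index("gold", 633, 1.1),
               1.1 * material_index("gold", 633), tolerance = 1e-12)
  # fixed indices
  expect_equal(material_index("bk7", 633), 1.52 + 0i)
  expect_equal(material_index("pmma", 633), 1.489 + 0i)
  expect_equal(material_index("water", 633), 1.33 + 0i)
  # absorbing medium has positive imaginary part under e^{-i omega t}
  expect_gt(Im(material_index("gold", 650)), 0)
})

test_that("material lookup rejects bad inputs", {
  expect_error(material_index("gold", 500), "outside")
  expect_error(material_index("gold", 633, 1.5), "scale")
  expect_error(material_index("unobtainium", 633), "unknown material")
  expect_error(material_index("bk7", 633, 1.1), "only supported for gold")
})

test_that("Fresnel coefficients match closed forms at a bare interface", {
  # normal incidence
  expect_equal(fresnel_interface(1.52, 1.0, 0, "s"), (1.52 - 1) / (1.52 + 1) + 0i,
               tolerance = 1e-12)
  expect_equal(fresnel_interface(1.52, 1.0, 0, "p"), (1 - 1.52) / (1 + 1.52) + 0i,
               tolerance = 1e-12)
  # total internal reflection beyond arcsin(1/1.52)
  th_tir <- seq(asin(1 / 1.52) + 0.01, 1.5, length.out = 20)
  for (pol in c("s", "p")) {
    expect_equal(Mod(fresnel_interface(1.52, 1.0, th_tir, pol)),
                 rep(1, 20), tolerance = 1e-12)
  }
  # Brewster zero for p
  expect_lt(Mod(fresnel_interface(1.52, 1.0, atan(1 / 1.52), "p")), 1e-12)
})

test_that("stack reflection reduces to Fresnel for empty and zero-thickness stacks", {
  set.seed(11)
  th <- runif(100, 0, pi / 2 - 1e-3)
  empty <- layer_stack(1.52, list(), 1.0, 633)
  zero <- layer_stack(1.52, list(list(n = material_index("gold", 633), d = 0)),
                      1.0, 633)
  for (pol in c("s", "p")) {
    ref <- fresnel_interface(1.52, 1.0, th, pol)
    expect_lt(max(Mod(stack_reflection(empty, th, pol) - ref)), 1e-12)
    expect_lt(max(Mod(stack_reflection(zero, th, pol) - ref)), 1e-12)
  }
})

test_that("stack reflection agrees with the independent Airy-summation oracle", {
  set.seed(21)
  th <- runif(60, 0, pi / 2 - 1e-3)
  cases <- list(
    list(nl = material_index("gold", 633), d = 47, ns = 1.12, lambda = 633),
    list(nl = 1.35 + 0i, d = 800, ns = 1.0, lambda = 633),
    list(nl = material_index("gold", 650) * 0.95, d = 33, ns = 1.33,
         lambda = 650)
  )
  for (cs in cases) {
    stk <- layer_stack(1.52, list(list(n = cs$nl, d = cs$d)), cs$ns,
                       cs$lambda)
    for (pol in c("s", "p")) {
      ref <- airy_reflection(1.52, cs$nl, cs$d, cs$ns, stk$wavelength, th, pol)
      expect_lt(max(Mod(stack_reflection(stk, th, pol) - ref)), 1e-12)
    }
  }
})

test_that("energy bounds hold: |r| <= 1 for passive stacks, = 1 beyond TIR when lossless", {
  th <- seq(0, asin(1.49 / 1.52), length.out = 500)
  wg <- pmma_stack_633()
  gold <- gold_stack_633()
  for (pol in c("s", "p")) {
    expect_true(all(Mod(stack_reflection(wg, th, pol)) <= 1 + 1e-12))
    expect_true(all(Mod(stack_reflection(gold, th, pol)) <= 1 + 1e-12))
    beyond <- th[th > asin(1 / 1.52) + 1e-3]
    expect_lt(max(abs(1 - Mod(stack_reflection(wg, beyond, pol)))), 1e-10)
  }
})

test_that("reflection is continuous in angle and thickness", {
  th <- seq(0, asin(1.49 / 1.52), length.out = 4000)
  gold <- gold_stack_633()
  for (pol in c("s", "p")) {
    r <- stack_reflection(gold, th, pol)
    # steepest physical feature is the plasmon transit (~0.03 per step
    # at this sampling); a branch-cut jump would be O(1)
    expect_lt(max(Mod(diff(r))), 0.2)
  }
  ds <- seq(0, 80, by = 0.25)
  r_d <- sapply(ds, function(d) {
    stack_reflection(gold_stack_633(d = d), 0.76, "p")
  })
  expect_lt(max(Mod(diff(r_d))), 0.2)
})

test_that("conjugating the time convention leaves reflectance magnitudes unchanged", {
  # independent e^{+i omega t} oracle: conjugated indices, Im(kz) <= 0
  # branch, conjugated round-trip phase factor
  airy_conj <- function(n0, nl, d, ns, lambda, theta, pol) {
    k0 <- 2 * pi / lambda
    st <- n0 * sin(theta)
    kz <- function(n) {
      v <- k0 * sqrt(as.complex(n^2 - st^2))
      ifelse(Im(v) > 0, -v, v)
    }
    q <- function(n) if (pol == "s") kz(n) else kz(n) / as.complex(n)^2
    r01 <- (q(n0) - q(nl)) / (q(n0) + q(nl))
    r12 <- (q(nl) - q(ns)) / (q(nl) + q(ns))
    ph <- exp(-2i * kz(nl) * d)
    (r01 + r12 * ph) / (1 + r01 * r12 * ph)
  }
  th <- seq(0.05, 1.3, length.out = 40)
  nl <- material_index("gold", 633)
  for (pol in c("s", "p")) {
    ours <- stack_reflection(gold_stack_633(), th, pol)
    flipped <- airy_conj(1.52, Conj(nl), 50, 1.0, 633, th, pol)
    expect_equal(Mod(ours), Mod(flipped), tolerance = 1e-12)
    expect_equal(ours, Conj(flipped), tolerance = 1e-12)
  }
})

test_that("the plasmonic dip sits beyond the critical angle and is deep", {
  th <- seq(0.001, asin(1.49 / 1.52), length.out = 8000)
  rp <- Mod(stack_reflection(gold_stack_633(), th, "p"))^2
  i <- which.min(rp)
  expect_gt(th[i], asin(1 / 1.52))
  expect_lt(rp[i], 0.05)
  # frozen regression: dip near 43.6 degrees (dense-scan fixture)
  expect_equal(th[i] * 180 / pi, 43.60, tolerance = 0.01)
  # single deep minimum: only one local minimum below 0.5
  deep <- local_minima(rp)[rp[local_minima(rp)] < 0.5]
  expect_length(deep, 1)
})
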