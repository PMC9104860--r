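# Shared fixtures, memoized per test run. Everything is generated in code;
# grids are kept small except where the physics needs the full 512 pupil.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

gold_stack_633 <- function(d = 50, ns = 1.0) {
  layer_stack(1.52, list(list(n = material_index("gold", 633), d = d)),
              ns, 633)
}

pmma_stack_633 <- function(d_nm = 1000, ns = 1.0) {
  layer_stack(1.52, list(list(n = material_index("pmma", 633), d = d_nm)),
              ns, 633)
}

gold_field_128 <- function() {
  fixture("gold_field_128", function() {
    compute_bfp_fields(build_pupil_grid(128, 1.49, 633, 1.52),
                       gold_stack_633())
  })
}

gold_field_512 <- function() {
  fixture("gold_field_512", function() {
    compute_bfp_fields(build_pupil_grid(512, 1.49, 633, 1.52),
                       gold_stack_633())
  })
}

# angle of the p-pol reflectance dip of 50 nm gold / air / 633 nm,
# located by a dense 1-D scan (the oracle used by several tests)
spr_dip_angle <- function() {
  fixture("spr_dip_angle", function() {
    th <- seq(0.001, asin(1.49 / 1.52), length.out = 8000)
    rp <- Mod(stack_reflection(gold_stack_633(), th, "p"))^2
    th[which.min(rp)]
  })
}

# independent two-interface (Airy summation) reflection oracle for a
# single-layer stack; same e^{-i omega t} convention as the package
airy_reflection <- function(n0, nl, d, ns, lambda, theta, pol) {
  k0 <- 2 * pi / lambda
  st <- n0 * sin(theta)
  kz <- function(n) {
    v <- k0 * sqrt(as.complex(n^2 - st^2))
    ifelse(Im(v) < 0, -v, v)
  }
  q <- function(n) if (pol == "s") kz(n) else kz(n) / as.complex(n)^2
  r01 <- (q(n0) - q(nl)) / (q(n0) + q(nl))
  r12 <- (q(nl) - q(ns)) / (q(nl) + q(ns))
  ph <- exp(2i * kz(nl) * d)
  (r01 + r12 * ph) / (1 + r01 * r12 * ph)
}
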