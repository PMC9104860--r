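#' Wrap phase values into [-pi, pi)
#'
#' @param x numeric vector/matrix of phases in radians.
#' @return same shape, values in `[-pi, pi)`.
#' @export
wrap_phase <- function(x) {
  stopifnot(all(is.finite(x)))
  x - 2 * pi * floor((x + pi) / (2 * pi))
}

# Windowed SSIM between two maps on a known dynamic range. Gaussian window
# (11 px, sigma 1.5), K1 = 0.01, K2 = 0.03; the half-window border is
# cropped before averaging, as in the reference implementation.
.ssim_mean <- function(x, y, L, sigma = 1.5, win = 11L) {
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  mu_x <- gauss_filter2(x, sigma, win)
  mu_y <- gauss_filter2(y, sigma, win)
  sxx <- gauss_filter2(x * x, sigma, win) - mu_x^2
  syy <- gauss_filter2(y * y, sigma, win) - mu_y^2
  sxy <- gauss_filter2(x * y, sigma, win) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  pad <- (win - 1L) %/% 2L
  n <- nrow(s); m <- ncol(s)
  mean(s[(pad + 1):(n - pad), (pad + 1):(m - pad)])
}

#' Offset-invariant SSIM between wrapped phase maps
#'
#' A recovered phase map is only defined up to a constant offset, so the
#' structural similarity index is maximized over a uniform grid of constant
#' offsets `delta` in `[0, 2*pi)`: `SSIM(wrap(recovered + delta),
#' wrap(theoretical))` with dynamic range `L = 2*pi`. SSIM of 1 means
#' identical structure; values are reported as computed (they can in
#' principle be negative on wrapped maps).
#'
#' @param recovered,theoretical phase maps in radians, same shape.
#' @param n_offsets number of offsets tried over `[0, 2*pi)` (default 360).
#' @param refine polish the best offset by a bounded 1-D optimization
#'   within one grid step (default `TRUE`), so an exactly offset-shifted
#'   recovery scores 1 rather than the best grid value.
#' @return a list with `ssim` (the best value), `best_offset` (rad, in
#'   `[0, 2*pi)`) and `ssim_by_offset` (the full grid scan).
#' @export
ssim_phase <- function(recovered, theoretical, n_offsets = 360L,
                       refine = TRUE) {
  stopifnot(all(dim(recovered) == dim(theoretical)), n_offsets >= 2)
  theo_w <- wrap_phase(theoretical)
  score <- function(d) .ssim_mean(wrap_phase(recovered + d), theo_w,
                                  L = 2 * pi)
  offsets <- (seq_len(n_offsets) - 1) * 2 * pi / n_offsets
  vals <- vapply(offsets, score, numeric(1))
  best <- which.max(vals)
  ssim_best <- vals[best]
  off_best <- offsets[best]
  if (refine) {
    step <- 2 * pi / n_offsets
    opt <- stats::optimize(score, c(off_best - step, off_best + step),
                           maximum = TRUE, tol = 1e-8)
    if (opt$objective > ssim_best) {
      ssim_best <- opt$objective
      off_best <- opt$maximum %% (2 * pi)
    }
  }
  list(ssim = ssim_best, best_offset = off_best,
       ssim_by_offset = data.frame(offset = offsets, ssim = vals))
}

#' Rebuild a full pupil map from its upper-right quadrant
#'
#' Back-focal-plane maps of x-polarized illumination have twofold mirror
#' symmetry about both k-axes, so one quadrant determines the rest. This
#' inverts [crop_quadrant()]: the cropped quadrant (which contains the
#' center row/column) is mirrored about both axes; the unpaired first
#' row/column of the even grid lies outside the NA mask and is set to 0.
#'
#' @param q an `n x n` quadrant map.
#' @return a `2n x 2n` map.
#' @export
reconstruct_quadrant <- function(q) {
  n <- nrow(q)
  stopifnot(ncol(q) == n)
  full <- matrix(0, 2 * n, 2 * n)
  ctr <- n + 1 # DC row/col of the full grid
  full[ctr:(2 * n), ctr:(2 * n)] <- q
  full[ctr:(2 * n), (ctr - 1):2] <- q[, 2:n]
  full[(ctr - 1):2, ctr:(2 * n)] <- q[2:n, ]
  full[(ctr - 1):2, (ctr - 1):2] <- q[2:n, 2:n]
  full
}

#' Evaluate a trained network on test records
#'
#' Runs [predict_can()] on each record (optionally with a channel switched
#' off), scores the recovered phase against the analytic wrapped-phase label
#' with [ssim_phase()], and tabulates per-case rows plus their average.
#'
#' @param model a [train_can()] result (or an untrained [build_can()] model).
#' @param records list of dataset records ([assemble_record()]).
#' @param ablation `"none"`, `"bfp_off"` (zero the BFP channel) or
#'   `"imp_off"` (zero all IMP channels).
#' @param n_offsets offset-grid size for [ssim_phase()].
#' @return an `eval_table`: a data.frame with columns `case_id`, `variant`,
#'   `ablation`, `ssim`, `best_offset`, and attribute `average`.
#' @export
evaluate_model <- function(model, records,
                           ablation = c("none", "bfp_off", "imp_off"),
                           n_offsets = 360L) {
  ablation <- match.arg(ablation)
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    x <- rec$inputs
    if (ablation != "none") {
      idx <- channel_indices(rec$variant, ablation)
      for (j in idx) x <- ablate_channel(x, j)
    }
    pred <- predict_can(model, x)
    sc <- ssim_phase(pred, rec$label, n_offsets = n_offsets)
    data.frame(case_id = if (!is.null(rec$params$case_id)) rec$params$case_id else i,
               variant = rec$variant, ablation = ablation,
               ssim = sc$ssim, best_offset = sc$best_offset)
  })
  tab <- do.call(rbind, rows)
  attr(tab, "average") <- mean(tab$ssim)
  class(tab) <- c("eval_table", "data.frame")
  tab
}

#' @export
print.eval_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("Average SSIM: %.4f\n", attr(x, "average")))
  invisible(x)
}

#' Which input channels a switch-off targets
#'
#' Maps an ablation label to channel indices for each network variant:
#' the BFP intensity is channel 1 of CAN1/CAN2; IMP channels are channel 2
#' of CAN2 and all channels of CAN3-CAN5.
#'
#' @param variant `"CAN1"` to `"CAN5"`.
#' @param ablation `"bfp_off"` or `"imp_off"`.
#' @return integer channel indices (possibly empty).
#' @export
channel_indices <- function(variant, ablation) {
  has_bfp <- variant %in% c("CAN1", "CAN2")
  n_imp <- c(CAN1 = 0, CAN2 = 1, CAN3 = 1, CAN4 = 2, CAN5 = 3)[[variant]]
  if (ablation == "bfp_off") {
    if (has_bfp) 1L else integer(0)
  } else if (ablation == "imp_off") {
    if (n_imp == 0) integer(0) else seq_len(n_imp) + as.integer(has_bfp)
  } else {
    integer(0)
  }
}

#' Compare V(z) curves from the true and a recovered phase
#'
#' Rebuilds a full-pupil surrogate field `|Ex| * exp(i * recovered_phase)`
#' from a recovered quadrant phase map (mirrored by symmetry), computes
#' `V(z)` for it and for the true field over `z_range`, and reports both
#' max-normalized `|V|` curves plus their maximum discrepancy. A constant
#' phase error cancels in `|V|`, which is what makes this comparison
#' offset-insensitive.
#'
#' @param field the theoretical [compute_bfp_fields()] result (full pupil).
#' @param recovered_phase quadrant phase map (`n_pixels/2` square), rad.
#' @param z_range defocus values in micrometres.
#' @return list with `z`, `V_theory`, `V_recovered` (normalized moduli) and
#'   `max_discrepancy` = `max |dV|` on the normalized curves.
#' @export
compare_vz <- function(field, recovered_phase, z_range) {
  stopifnot(inherits(field, "bfp_field"))
  g <- field$grid
  stopifnot(nrow(recovered_phase) == g$n_pixels / 2)
  ph_full <- reconstruct_quadrant(recovered_phase)
  surrogate <- field
  surrogate$Ex <- Mod(field$Ex) * exp(1i * ph_full)
  surrogate$Ex[!g$mask] <- 0 + 0i
  v_th <- vz_signal(field, z_range)
  v_rec <- vz_signal(surrogate, z_range)
  list(z = z_range, V_theory = v_th$V_norm, V_recovered = v_rec$V_norm,
       max_discrepancy = max(abs(v_th$V_norm - v_rec$V_norm)))
}
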