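# Translation-only rigid registration by spectral cross-correlation.
#
# Transform convention: a transform (dy, dx) is the displacement of the scene
# in a frame relative to the reference, i.e. frame(y, x) = scene(y - dy, x - dx).
# apply_transforms() resamples frame(y + dy, x + dx) and therefore undoes the
# motion. Positive dy shifts content toward increasing row index.

#' Rigid (translation) transform series for a stack
#'
#' @param dy,dx numeric vectors of per-frame displacements in pixels
#'   (subpixel-valued; scene displacement relative to the reference frame).
#' @param reference_index 1-based index of the reference frame; its transform
#'   must be (0, 0).
#' @return A data frame of class `transform_series` with columns
#'   `frame`, `dy`, `dx` and attribute `reference_index`.
#' @export
transform_series <- function(dy, dx, reference_index = 1L) {
  assert_that(length(dy) == length(dx), "`dy` and `dx` lengths differ")
  assert_that(all(is.finite(dy)) && all(is.finite(dx)),
              "transforms must be finite")
  assert_that(reference_index >= 1L && reference_index <= length(dy),
              "`reference_index` out of range")
  assert_that(abs(dy[reference_index]) < 1e-12 &&
                abs(dx[reference_index]) < 1e-12,
              "reference-frame transform must be (0, 0)")
  structure(
    data.frame(frame = seq_along(dy), dy = as.numeric(dy), dx = as.numeric(dx)),
    reference_index = as.integer(reference_index),
    class = c("transform_series", "data.frame")
  )
}

# Bilinear resampling of `m` at (row + dy, col + dx); zero outside the frame.
shift_image <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  if (dy == 0 && dx == 0) return(m)
  ys <- seq_len(h) + dy
  xs <- seq_len(w) + dx
  y0 <- floor(ys); fy <- ys - y0
  x0 <- floor(xs); fx <- xs - x0
  gather <- function(r, c) {
    ok_r <- r >= 1 & r <= h
    ok_c <- c >= 1 & c <= w
    out <- m[pmin(pmax(r, 1L), h), pmin(pmax(c, 1L), w), drop = FALSE]
    if (!all(ok_r)) out[!ok_r, ] <- 0
    if (!all(ok_c)) out[, !ok_c] <- 0
    out
  }
  outer(1 - fy, 1 - fx) * gather(y0, x0) +
    outer(1 - fy, fx)   * gather(y0, x0 + 1) +
    outer(fy, 1 - fx)   * gather(y0 + 1, x0) +
    outer(fy, fx)       * gather(y0 + 1, x0 + 1)
}

# wrapped integer FFT frequencies 0..n-1 -> 0..n/2-1, -n/2..-1
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= (n - 1) %/% 2, k, k - n)
}

# Evaluate the (band-limited) cross-correlation Re(ifft(CP)) on arbitrary
# real shift grids us x vs by direct matrix DFT; CP is the normalized
# cross-power spectrum.
upsampled_xcorr <- function(cp, us, vs) {
  nr <- nrow(cp); nc <- ncol(cp)
  er <- exp(2i * pi / nr * outer(us, fft_freq(nr)))
  ec <- exp(2i * pi / nc * outer(fft_freq(nc), vs))
  Re(er %*% cp %*% ec) / (nr * nc)
}

# Subpixel shift of `img` relative to `ref` (scene-displacement convention):
# phase correlation (Hann windowed, lightly regularized cross-power
# normalization so that aperture edges do not dominate smooth spectra) with
# local DFT upsampling, followed by a Gauss-Newton least-squares polish on
# interior pixels. Whitened correlation alone is biased by a substantial
# fraction of a pixel on smooth, aperture-limited images; the intensity
# least-squares step removes that bias.
phase_corr_shift <- function(ref_fft, img, window, upsample = 20) {
  f2 <- fft(window * (img - mean(img)))
  cp <- ref_fft$conj_f * f2
  mag <- Mod(cp)
  cp <- cp / (mag + 0.01 * mean(mag) + .Machine$double.xmin)
  cc <- Re(fft(cp, inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  nr <- nrow(cc); nc <- ncol(cc)
  dy0 <- fft_freq(nr)[peak[1L]]
  dx0 <- fft_freq(nc)[peak[2L]]
  if (upsample > 1) {
    step <- 1 / upsample
    us <- dy0 + seq(-1, 1, by = step)
    vs <- dx0 + seq(-1, 1, by = step)
    fine <- upsampled_xcorr(cp, us, vs)
    pk <- which(fine == max(fine), arr.ind = TRUE)[1L, ]
    dy0 <- us[pk[1L]]
    dx0 <- vs[pk[2L]]
  }
  refine_shift_lsq(ref_fft$ref, img, dy0, dx0)
}

# Translation-only Gauss-Newton refinement of the SSD between the
# back-shifted image and the reference, over interior pixels (a fixed margin
# excludes zero-filled borders). Image gradients by central differences.
refine_shift_lsq <- function(ref, img, dy, dx, max_iter = 12L, tol = 1e-4) {
  h <- nrow(ref); w <- ncol(ref)
  margin <- 4L + ceiling(max(abs(dy), abs(dx)))
  if (h - 2L * margin < 4L || w - 2L * margin < 4L) return(c(dy = dy, dx = dx))
  rr <- (margin + 1L):(h - margin)
  cc <- (margin + 1L):(w - margin)
  for (i in seq_len(max_iter)) {
    warped <- shift_image(img, dy, dx)
    gy <- (warped[pmin(rr + 1L, h), cc] - warped[pmax(rr - 1L, 1L), cc]) / 2
    gx <- (warped[rr, pmin(cc + 1L, w)] - warped[rr, pmax(cc - 1L, 1L)]) / 2
    res <- ref[rr, cc] - warped[rr, cc]
    # res ~ gy * ddy + gx * ddx  (increment applied to the resampling shift)
    a11 <- sum(gy * gy); a12 <- sum(gy * gx); a22 <- sum(gx * gx)
    b1 <- sum(gy * res); b2 <- sum(gx * res)
    det <- a11 * a22 - a12 * a12
    if (!is.finite(det) || det < .Machine$double.eps * (a11 + a22 + 1)) break
    ddy <- (a22 * b1 - a12 * b2) / det
    ddx <- (a11 * b2 - a12 * b1) / det
    if (!is.finite(ddy) || !is.finite(ddx)) break
    # clamp runaway steps; the initialization is within ~1 px already
    ddy <- max(min(ddy, 1), -1)
    ddx <- max(min(ddx, 1), -1)
    dy <- dy + ddy
    dx <- dx + ddx
    if (max(abs(ddy), abs(ddx)) < tol) break
  }
  c(dy = dy, dx = dx)
}

#' Estimate per-frame rigid transforms from the anatomy channel
#'
#' Each frame is aligned to the reference frame by phase correlation (Hann
#' windowed, normalized cross-power spectrum) followed by local DFT
#' upsampling, giving subpixel translation estimates. Rotation is out of
#' scope: cross-sectional breathing motion in this geometry is dominantly
#' translational.
#'
#' @param anatomy a [dynamic_stack()] (the anatomical/structural channel).
#' @param reference_index frame all others are mapped onto (default first).
#' @param upsample correlation upsampling factor; the default 20 resolves
#'   shifts to 0.05 px.
#' @return A [transform_series()]; the transform of a frame is the estimated
#'   scene displacement relative to the reference, so feeding the series to
#'   [apply_transforms()] aligns the stack.
#' @examples
#' ph <- phantom_spec(32, 32)
#' cls <- list(kinetic_class(1, 1, 0, 2, 0.1), kinetic_class(2, 1, 0, 2, 0))
#' sim <- simulate_msot_pair(ph, cls,
#'   motion_spec(breathing_amplitude = 1.5), n_frames = 16, seed = 7)
#' est <- estimate_transforms(sim$anatomy)
#' head(est)
#' @export
estimate_transforms <- function(anatomy, reference_index = 1L, upsample = 20) {
  stopifnot(inherits(anatomy, "dynamic_stack"))
  nf <- n_frames(anatomy)
  assert_that(nf >= 2L, "need at least 2 frames to register")
  assert_that(reference_index >= 1L && reference_index <= nf,
              "`reference_index` out of range")
  ref <- get_frame(anatomy, reference_index)
  h <- nrow(ref); w <- ncol(ref)
  hann <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  window <- outer(hann(h), hann(w))
  if (sd(ref) < 1e-12) {
    warning("reference frame has zero variance; returning identity transforms")
    return(transform_series(rep(0, nf), rep(0, nf), reference_index))
  }
  ref_fft <- list(conj_f = Conj(fft(window * (ref - mean(ref)))), ref = ref)
  dy <- dx <- numeric(nf)
  for (f in seq_len(nf)) {
    if (f == reference_index) next
    frame <- get_frame(anatomy, f)
    if (sd(frame) < 1e-12) {
      warning(sprintf("frame %d has zero variance; using identity transform", f))
      next
    }
    s <- phase_corr_shift(ref_fft, frame, window, upsample)
    dy[f] <- s[["dy"]]
    dx[f] <- s[["dx"]]
  }
  transform_series(dy, dx, reference_index)
}

#' Apply a transform series to a stack
#'
#' Resamples every frame back onto the reference grid with first-order
#' (bilinear) interpolation and zero fill outside the frame. Intended to be
#' used cross-channel: transforms estimated on the anatomy channel are
#' applied unchanged to the contrast channel.
#'
#' @param stack a [dynamic_stack()].
#' @param series a [transform_series()] with one row per frame.
#' @return A registered [dynamic_stack()] of identical shape and frame
#'   interval; the reference frame is returned unchanged.
#' @export
apply_transforms <- function(stack, series) {
  stopifnot(inherits(stack, "dynamic_stack"),
            inherits(series, "transform_series"))
  nf <- n_frames(stack)
  assert_that(nrow(series) == nf,
              "transform series length does not match frame count")
  out <- stack$data
  for (f in seq_len(nf)) {
    if (series$dy[f] == 0 && series$dx[f] == 0) next
    out[, , f] <- shift_image(stack$data[, , f], series$dy[f], series$dx[f])
  }
  dynamic_stack(out, stack$frame_interval, stack$channel)
}

#' @export
print.transform_series <- function(x, ...) {
  cat(sprintf("<transform_series> %d frames, reference %d, max |shift| %.2f px\n",
              nrow(x), attr(x, "reference_index"),
              max(abs(c(x$dy, x$dx)))))
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
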