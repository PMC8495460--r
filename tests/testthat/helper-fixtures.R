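# Shared fixtures, built in code at test time.

# deterministic smooth aperiodic test image (registration target): blobs on
# a gentle ramp, qualitatively like an anatomical cross-section
smooth_image <- function(h = 32, w = 32) {
  r <- matrix(seq_len(h), h, w) / h
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE) / w
  g <- function(cy, cx, s, a) a * exp(-((r - cy)^2 + (c_ - cx)^2) / s)
  1 + 0.3 * r + 0.2 * c_ + g(0.42, 0.37, 0.03, 2) + g(0.7, 0.68, 0.015, 1.2) +
    g(0.25, 0.75, 0.02, -0.8) + g(0.65, 0.2, 0.025, 1.5)
}

# two standard kinetic classes used across clearance tests
test_classes <- function(elim = 0.12) {
  list(kinetic_class(1L, amplitude = 1.5, onset_time = 120,
                     uptake_rate = 3, elimination_rate = 4 * elim),
       kinetic_class(2L, amplitude = 3, onset_time = 120,
                     uptake_rate = 1.5, elimination_rate = elim))
}

tiny_sim <- function(n_frames = 16, size = 24, motion = motion_spec(),
                     seed = 1, elim = 0.12) {
  simulate_msot_pair(phantom_spec(size, size), test_classes(elim),
                     motion, n_frames = n_frames, frame_interval = 15,
                     seed = seed)
}

# brute-force optimal 2-partition (min within-cluster SS) of row vectors
brute_force_kmeans2 <- function(v) {
  n <- nrow(v)
  stopifnot(n <= 14)
  best <- NULL
  best_ss <- Inf
  wss <- function(m) {
    if (nrow(m) == 0L) return(0)
    sum(sweep(m, 2L, colMeans(m))^2)
  }
  for (mask in 1:(2^(n - 1L) - 1L)) {   # fix vector 1 in cluster 1
    in1 <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2L)))))
    ss <- wss(v[in1, , drop = FALSE]) + wss(v[!in1, , drop = FALSE])
    if (ss < best_ss) {
      best_ss <- ss
      best <- in1
    }
  }
  list(in1 = best, ss = best_ss)
}

# exhaustive SSD grid search for a rigid shift, 0.05-px steps around `around`
grid_search_shift <- function(ref, img, around, halfwidth = 0.6, step = 0.05) {
  dys <- seq(around[1] - halfwidth, around[1] + halfwidth, by = step)
  dxs <- seq(around[2] - halfwidth, around[2] + halfwidth, by = step)
  h <- nrow(ref); w <- ncol(ref)
  core_r <- 5:(h - 4); core_c <- 5:(w - 4)
  best <- c(NA, NA); best_ssd <- Inf
  for (dy in dys) for (dx in dxs) {
    shifted <- hepaclear:::shift_image(img, dy, dx)
    ssd <- sum((shifted[core_r, core_c] - ref[core_r, core_c])^2)
    if (ssd < best_ssd) {
      best_ssd <- ssd
      best <- c(dy, dx)
    }
  }
  best
}

# fine-grid Riemann quadrature of the linear interpolant of (x, y)
riemann_auc <- function(x, y, refine = 100L) {
  xx <- seq(min(x), max(x), length.out = (length(x) - 1L) * refine + 1L)
  yy <- approx(x, y, xout = xx)$y
  sum((yy[-1L] + yy[-length(yy)]) / 2 * diff(xx))
}
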