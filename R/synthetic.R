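#' Kinetic class specification
#'
#' Parametric description of one per-pixel contrast-kinetics class: saturating
#' uptake followed by first-order elimination,
#' \deqn{I(t) = A\,(1 - e^{-k_u \Delta t})\, e^{-k_e \Delta t},\qquad
#'       \Delta t = t - t_0 \ge 0,} and 0 before onset. Real pixel kinetics in
#' dynamic contrast imaging are empirical; this two-rate product is the
#' simplest form that reproduces both net-accumulating and rapid-washout
#' behaviours with interpretable parameters.
#'
#' @param class_id small integer label, used in region maps and truth images.
#' @param amplitude peak-scale intensity (arbitrary units, >= 0).
#' @param onset_time time of contrast arrival, seconds (>= 0).
#' @param uptake_rate uptake rate constant, 1/min (> 0).
#' @param elimination_rate elimination rate constant, 1/min (>= 0); 0 means
#'   the class retains contrast indefinitely.
#' @return An object of class `kinetic_class`.
#' @seealso [make_class_curve()], [simulate_msot_pair()]
#' @export
kinetic_class <- function(class_id, amplitude, onset_time = 0,
                          uptake_rate, elimination_rate) {
  assert_that(amplitude >= 0, "`amplitude` must be >= 0")
  assert_that(onset_time >= 0, "`onset_time` must be >= 0")
  assert_that(uptake_rate > 0, "`uptake_rate` must be > 0")
  assert_that(elimination_rate >= 0, "`elimination_rate` must be >= 0")
  structure(
    list(class_id = as.integer(class_id), amplitude = amplitude,
         onset_time = onset_time, uptake_rate = uptake_rate,
         elimination_rate = elimination_rate),
    class = "kinetic_class"
  )
}

#' Evaluate a kinetic class curve at given times
#'
#' @param spec a [kinetic_class()].
#' @param times strictly increasing times in seconds.
#' @return Numeric vector of intensities, one per time, non-negative.
#' @examples
#' cl <- kinetic_class(1, amplitude = 1, uptake_rate = 10,
#'                     elimination_rate = log(2) / 20)
#' make_class_curve(cl, times = seq(0, 1200, by = 15))
#' @export
make_class_curve <- function(spec, times) {
  stopifnot(inherits(spec, "kinetic_class"))
  assert_that(length(times) >= 1L && all(diff(times) > 0),
              "`times` must be strictly increasing")
  dt_min <- (times - spec$onset_time) / 60   # rates are per minute
  y <- ifelse(dt_min >= 0,
              spec$amplitude * (1 - exp(-spec$uptake_rate * dt_min)) *
                exp(-spec$elimination_rate * dt_min),
              0)
  pmax(y, 0)
}

#' Phantom geometry for simulated optoacoustic sections
#'
#' Defines the static scene: an elliptical "animal contour" ROI inside the
#' frame, horizontal bands inside the ROI assigned to kinetic classes, and a
#' uniform background. The anatomy channel carries a fixed smooth texture on
#' top of the ROI so that intensity-based registration has gradients to work
#' with.
#'
#' @param height,width frame size in pixels.
#' @param class_layout integer vector of `class_id`s; the ROI is split into
#'   `length(class_layout)` horizontal bands of equal height (top to bottom),
#'   each assigned the corresponding class.
#' @param center ellipse centre `c(row, col)`; default frame centre.
#' @param semiaxes ellipse semi-axes `c(rows, cols)`; default 35% of the
#'   frame, keeping the contour strictly inside the frame even under the
#'   simulated motion.
#' @param background_level background intensity (arbitrary units).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64, width = 64, class_layout = c(1L, 2L),
                         center = NULL, semiaxes = NULL,
                         background_level = 1) {
  if (is.null(center)) center <- c((height + 1) / 2, (width + 1) / 2)
  if (is.null(semiaxes)) semiaxes <- c(0.35 * height, 0.35 * width)
  assert_that(center[1] - semiaxes[1] >= 1 && center[1] + semiaxes[1] <= height &&
                center[2] - semiaxes[2] >= 1 && center[2] + semiaxes[2] <= width,
              "ROI ellipse must lie strictly inside the frame")
  assert_that(length(class_layout) >= 1L, "`class_layout` must be non-empty")
  structure(
    list(height = as.integer(height), width = as.integer(width),
         class_layout = as.integer(class_layout),
         center = center, semiaxes = semiaxes,
         background_level = background_level),
    class = "phantom_spec"
  )
}

#' Motion and noise specification for simulated stacks
#'
#' Frame-to-frame motion is a vertical breathing sinusoid plus a linear drift
#' in both axes; noise is additive Gaussian. The noise level is the effective
#' per-frame SD, i.e. already reflects any on-device frame averaging.
#'
#' @param breathing_amplitude peak breathing excursion in pixels (>= 0),
#'   applied to the row axis.
#' @param breathing_period breathing period in seconds (> 0).
#' @param drift_per_frame length-2 `c(dy, dx)` linear drift in pixels per
#'   frame (a scalar is applied to both axes).
#' @param noise_sd additive Gaussian noise SD in intensity units (>= 0).
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(breathing_amplitude = 0, breathing_period = 60,
                        drift_per_frame = c(0, 0), noise_sd = 0) {
  if (length(drift_per_frame) == 1L) drift_per_frame <- rep(drift_per_frame, 2L)
  assert_that(breathing_amplitude >= 0, "`breathing_amplitude` must be >= 0")
  assert_that(breathing_period > 0, "`breathing_period` must be > 0")
  assert_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  structure(
    list(breathing_amplitude = breathing_amplitude,
         breathing_period = breathing_period,
         drift_per_frame = drift_per_frame, noise_sd = noise_sd),
    class = "motion_spec"
  )
}

# Static scene pieces -------------------------------------------------------

# The scene is defined in continuous coordinates, so moved frames are
# evaluated analytically at shifted positions rather than resampled: the
# recorded true transforms are exact properties of the generated stacks and
# no generator-side interpolation error enters the motion bookkeeping.

phantom_grid <- function(phantom) {
  list(r = matrix(seq_len(phantom$height), phantom$height, phantom$width),
       c = matrix(seq_len(phantom$width), phantom$height, phantom$width,
                  byrow = TRUE))
}

# continuous class field: class_id inside the contour, 0 outside; horizontal
# bands of equal height over the ellipse's row extent
phantom_class_at <- function(phantom, r, c_) {
  cy <- phantom$center[1L]; ay <- phantom$semiaxes[1L]
  e2 <- ((r - cy) / ay)^2 + ((c_ - phantom$center[2L]) / phantom$semiaxes[2L])^2
  n_bands <- length(phantom$class_layout)
  band <- pmin(n_bands, pmax(1L, 1L + floor((r - (cy - ay)) / (2 * ay) * n_bands)))
  lab <- matrix(0L, nrow(r), ncol(r))
  inside <- e2 <= 1
  lab[inside] <- phantom$class_layout[band[inside]]
  lab
}

phantom_roi_mask <- function(phantom) {
  g <- phantom_grid(phantom)
  phantom_class_at(phantom, g$r, g$c) != 0L
}

phantom_class_map <- function(phantom, roi = NULL) {
  g <- phantom_grid(phantom)
  phantom_class_at(phantom, g$r, g$c)
}

# deterministic smooth anatomy texture (gives registration its gradients);
# the contour edge falls off smoothly over ~2 px, emulating the finite
# resolution of reconstructed tomographic sections
phantom_anatomy_at <- function(phantom, r, c_) {
  h <- phantom$height; w <- phantom$width
  e <- sqrt(((r - phantom$center[1L]) / phantom$semiaxes[1L])^2 +
              ((c_ - phantom$center[2L]) / phantom$semiaxes[2L])^2)
  soft <- pmin(1, pmax(0, (1.04 - e) / 0.1))
  rn <- r / h; cn <- c_ / w
  texture <- 0.6 * sin(2 * pi * 2.0 * cn) * cos(2 * pi * 1.5 * rn) +
    0.4 * sin(2 * pi * (rn + cn))
  phantom$background_level + soft * (1 + 0.5 * texture)
}

phantom_anatomy <- function(phantom) {
  g <- phantom_grid(phantom)
  phantom_anatomy_at(phantom, g$r, g$c)
}

motion_transforms <- function(motion, n_frames, frame_interval) {
  t_s <- (seq_len(n_frames) - 1L) * frame_interval
  dy <- motion$breathing_amplitude * sin(2 * pi * t_s / motion$breathing_period) +
    (seq_len(n_frames) - 1L) * motion$drift_per_frame[1L]
  dx <- (seq_len(n_frames) - 1L) * motion$drift_per_frame[2L]
  cbind(dy = dy, dx = dx)
}

#' Simulate a two-channel optoacoustic acquisition with ground truth
#'
#' Produces an anatomy stack (static scene + motion + noise) and an ICG stack
#' (anatomy background + per-pixel kinetic-class curve + motion + noise), both
#' corrupted by the same rigid per-frame translations, together with the
#' complete ground truth (class label image, true transforms, true class
#' curves). Defaults mirror a 15-s acquisition interval over 20 min.
#'
#' @param phantom a [phantom_spec()].
#' @param classes list of [kinetic_class()] objects covering every class id in
#'   the phantom layout.
#' @param motion a [motion_spec()].
#' @param n_frames number of frames (>= 16, so that down-sampling by 4 leaves
#'   a usable tail).
#' @param frame_interval seconds between frames.
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   output.
#' @return A list with elements `anatomy` and `icg` (both [dynamic_stack()]s),
#'   `roi` (logical mask), and `truth` (class `synthetic_truth`: fields
#'   `class_label_image`, `true_transforms`, `true_class_curves`, `times`,
#'   `seed`).
#' @examples
#' ph <- phantom_spec(32, 32, class_layout = c(1, 2))
#' cls <- list(kinetic_class(1, 2, 120, 1.5, 0.15),
#'             kinetic_class(2, 2, 120, 1.5, 0.02))
#' sim <- simulate_msot_pair(ph, cls, motion_spec(), n_frames = 16, seed = 1)
#' sim$icg
#' @export
simulate_msot_pair <- function(phantom, classes, motion = motion_spec(),
                               n_frames = 80, frame_interval = 15,
                               seed = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(motion, "motion_spec"))
  assert_that(n_frames >= 16, "`n_frames` must be >= 16")
  assert_that(motion$breathing_period > 2 * frame_interval,
              "breathing period must exceed twice the frame interval")
  ids <- vapply(classes, function(cl) cl$class_id, integer(1L))
  missing <- setdiff(phantom$class_layout, ids)
  assert_that(length(missing) == 0L,
              paste("phantom layout references kinetic classes absent from",
                    "`classes`:", paste(missing, collapse = ", ")))
  assert_that(all(vapply(classes, function(cl)
    cl$onset_time <= (n_frames - 1L) * frame_interval, logical(1L))),
    "class onset_time outside the acquisition window")

  roi <- phantom_roi_mask(phantom)
  lab <- phantom_class_map(phantom)
  times <- (seq_len(n_frames) - 1L) * frame_interval
  curves <- lapply(classes, make_class_curve, times = times)
  names(curves) <- as.character(ids)
  tf <- motion_transforms(motion, n_frames, frame_interval)

  h <- phantom$height; w <- phantom$width
  g <- phantom_grid(phantom)
  anat <- array(0, c(h, w, n_frames))
  icg <- array(0, c(h, w, n_frames))
  curve_mat <- do.call(rbind, curves)            # one row per class
  for (f in seq_len(n_frames)) {
    # scene moves by +tf: frame(y, x) = scene(y - dy, x - dx), evaluated
    # analytically at the shifted coordinates (no resampling error)
    rs <- g$r - tf[f, 1L]; cs <- g$c - tf[f, 2L]
    anat_f <- phantom_anatomy_at(phantom, rs, cs)
    lab_f <- phantom_class_at(phantom, rs, cs)
    row_of <- match(lab_f, ids)                  # NA outside the contour
    uptake <- matrix(0, h, w)
    inside <- !is.na(row_of)
    uptake[inside] <- curve_mat[cbind(row_of[inside], f)]
    anat[, , f] <- anat_f
    icg[, , f] <- anat_f + uptake
  }
  if (motion$noise_sd > 0) {
    with_seed(seed, {
      anat <- anat + array(rnorm(length(anat), 0, motion$noise_sd), dim(anat))
      icg <- icg + array(rnorm(length(icg), 0, motion$noise_sd), dim(icg))
    })
  }
  truth <- structure(
    list(class_label_image = lab, true_transforms = tf,
         true_class_curves = curves, times = times,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "synthetic_truth"
  )
  list(anatomy = dynamic_stack(anat, frame_interval, "anatomy"),
       icg = dynamic_stack(icg, frame_interval, "icg"),
       roi = roi, truth = truth)
}

#' Simulate a plasma-disappearance fluorescence trace
#'
#' Mono-exponential decay above an autofluorescence baseline:
#' \deqn{F(t) = b + A\, 2^{-(t - t_i)/t_{1/2}}} for `t >= injection_time`,
#' and `b` before injection. Defaults mirror 30-s sampling over 45 min with
#' injection 1 min into the recording.
#'
#' @param t_half true half-life in minutes (> 0).
#' @param baseline autofluorescence baseline intensity.
#' @param amplitude decay amplitude at the injection time.
#' @param injection_time minutes after recording start.
#' @param times sampling times in minutes, strictly increasing.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed integer seed.
#' @param roi_id,animal_id identifiers carried through to the trace.
#' @return An [intensity_trace()] data frame.
#' @examples
#' tr <- simulate_decay_trace(55.9, baseline = 10, amplitude = 100)
#' head(tr)
#' @export
simulate_decay_trace <- function(t_half, baseline = 0, amplitude = 1,
                                 injection_time = 1,
                                 times = seq(0, 45, by = 0.5),
                                 noise_sd = 0, seed = NULL,
                                 roi_id = "roi1", animal_id = "animal1") {
  assert_that(t_half > 0, "`t_half` must be > 0")
  assert_that(all(diff(times) > 0), "`times` must be strictly increasing")
  v <- ifelse(times >= injection_time,
              baseline + amplitude * 2^(-(times - injection_time) / t_half),
              baseline)
  if (noise_sd > 0) v <- with_seed(seed, v + rnorm(length(v), 0, noise_sd))
  intensity_trace(times, v, roi_id = roi_id, animal_id = animal_id)
}

#' Simulate a competitive-inhibition dose-response table
#'
#' Four-parameter log-logistic response
#' \deqn{y(c) = bottom + \frac{top - bottom}{1 + (c/IC_{50})^{hill}},}
#' so uptake falls from `top` (no inhibitor) to `bottom` (full inhibition)
#' with midpoint at `c = ic50`.
#'
#' @param ic50 true half-inhibitory concentration, nmol/l (> 0).
#' @param hill Hill slope (unitless).
#' @param top,bottom asymptotic normalized uptake values.
#' @param concentrations inhibitor concentrations in nmol/l (> 0).
#' @param n_replicates wells per concentration.
#' @param noise_sd additive Gaussian noise SD in response units.
#' @param seed integer seed.
#' @return A data frame with columns `conc_nmol_l`, `uptake`, `replicate`.
#' @examples
#' simulate_dose_response(344, concentrations = 10^seq(1, 4, length.out = 8))
#' @export
simulate_dose_response <- function(ic50, hill = 1, top = 1, bottom = 0,
                                   concentrations, n_replicates = 1,
                                   noise_sd = 0, seed = NULL) {
  assert_that(ic50 > 0, "`ic50` must be > 0")
  assert_that(all(concentrations > 0),
              "`concentrations` must all be positive")
  conc <- rep(concentrations, each = n_replicates)
  y <- bottom + (top - bottom) / (1 + (conc / ic50)^hill)
  if (noise_sd > 0) y <- with_seed(seed, y + rnorm(length(y), 0, noise_sd))
  data.frame(conc_nmol_l = conc, uptake = y,
             replicate = rep(seq_len(n_replicates), times = length(concentrations)))
}

#' Simulate a treatment-group cohort for the clearance pipeline
#'
#' Generates `n_animals` two-channel acquisitions sharing the same kinetic
#' conditions. The scene has two kinetic classes: a parenchyma-like class
#' (slow uptake, elimination at `elimination_rate`) occupying the lower part
#' of the contour, and a vascular-like class (faster uptake, 4-fold faster
#' washout) above it. Contrast arrives at `onset_time` (default 120 s,
#' i.e. after a 2-min pre-injection baseline). An impaired-clearance group is
#' obtained by reducing `elimination_rate`, which increases late-phase
#' contrast retention and hence the linear-tail AUC.
#'
#' @param n_animals animals in the group.
#' @param group group label.
#' @param elimination_rate parenchymal elimination rate, 1/min.
#' @param onset_time contrast arrival, seconds.
#' @param size frame side length in pixels.
#' @param n_frames,frame_interval acquisition length and spacing (seconds).
#' @param breathing_amplitude,noise_sd motion/noise conditions (pixels /
#'   intensity units).
#' @param seed integer; animal `i` uses `seed + i`.
#' @return A list of animal records (`animal_id`, `group`, `icg`, `anatomy`,
#'   `roi`, `truth`) accepted by [run_clearance()].
#' @export
simulate_cohort <- function(n_animals, group, elimination_rate = 0.12,
                            onset_time = 120, size = 64, n_frames = 80,
                            frame_interval = 15, breathing_amplitude = 2,
                            noise_sd = 0.05, seed) {
  ph <- phantom_spec(size, size, class_layout = c(1L, 2L))
  cls <- list(
    kinetic_class(1L, amplitude = 1.5, onset_time = onset_time,
                  uptake_rate = 3, elimination_rate = 4 * elimination_rate),
    kinetic_class(2L, amplitude = 3, onset_time = onset_time,
                  uptake_rate = 1.5, elimination_rate = elimination_rate)
  )
  mo <- motion_spec(breathing_amplitude = breathing_amplitude,
                    breathing_period = 60, drift_per_frame = 0.01,
                    noise_sd = noise_sd)
  lapply(seq_len(n_animals), function(i) {
    sim <- simulate_msot_pair(ph, cls, mo, n_frames = n_frames,
                              frame_interval = frame_interval,
                              seed = seed + i)
    list(animal_id = sprintf("%s_%02d", group, i), group = group,
         icg = sim$icg, anatomy = sim$anatomy, roi = sim$roi,
         truth = sim$truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d frames, %d kinetic classes, seed %s\n",
              nrow(x$true_transforms), length(x$true_class_curves),
              format(x$seed)))
  invisible(x)
}
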