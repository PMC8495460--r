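# ICG-clearance quantification from registered optoacoustic stacks.
#
# Fixed processing order (enforced by process_animal_stack / run_pipeline):
# register -> z-transform -> down-sample in time -> crop/zero to ROI ->
# per-pixel change rates -> k-means characteristic curves (per group) ->
# pixel assignment -> net-increase filter -> abundance-weighted average ->
# linear-tail AUC -> group comparison.

#' First-frame z-normalization of a stack
#'
#' Standardizes every intensity by the mean and SD of the first time frame,
#' `Z = (X - mu) / sigma`, computed over in-ROI pixels of frame 1. This makes
#' scans comparable regardless of per-acquisition gain or offset: the whole
#' downstream pipeline is invariant to affine rescaling of the raw
#' intensities.
#'
#' @param stack a [dynamic_stack()] (registered contrast channel).
#' @param roi logical mask of in-contour pixels, same spatial shape as the
#'   frames. `mu` and `sigma` are computed over these pixels only, since
#'   outside-contour pixels carry no tissue signal.
#' @return An object of class `zstack`: fields `data` (z-values, all pixels),
#'   `mu`, `sigma`, `roi`, `frame_interval`. `mu`/`sigma` allow exact
#'   inversion of the transform.
#' @export
ztransform <- function(stack, roi) {
  stopifnot(inherits(stack, "dynamic_stack"))
  roi <- check_roi(roi, dim(stack$data)[1:2])
  first <- stack$data[, , 1L][roi]
  mu <- mean(first)
  sigma <- sd(first)
  assert_that(is.finite(sigma) && sigma > 1e-12,
              "first-frame in-ROI SD is (near) zero: degenerate stack, cannot z-transform",
              class = "hepaclear_degenerate_input")
  structure(
    list(data = (stack$data - mu) / sigma, mu = mu, sigma = sigma,
         roi = roi, frame_interval = stack$frame_interval),
    class = "zstack"
  )
}

check_roi <- function(roi, spatial_dim) {
  assert_that(is.matrix(roi) || is.array(roi), "`roi` must be a matrix mask")
  roi <- matrix(as.logical(roi), nrow(roi), ncol(roi))
  assert_that(all(dim(roi) == spatial_dim),
              "ROI mask shape does not match the frames")
  assert_that(any(roi), "ROI mask is empty")
  roi
}

#' Invert a z-transform
#'
#' @param z a `zstack`.
#' @return The original-intensity [dynamic_stack()].
#' @export
ztransform_invert <- function(z) {
  stopifnot(inherits(z, "zstack"))
  dynamic_stack(z$data * z$sigma + z$mu, z$frame_interval)
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<zstack> %d x %d px, %d frames @ %g s; mu = %.4g, sigma = %.4g, %d ROI px\n",
              d[1], d[2], d[3], x$frame_interval, x$mu, x$sigma, sum(x$roi)))
  invisible(x)
}

#' Temporal down-sampling by block averaging
#'
#' Replaces each block of `factor` consecutive frames by their mean,
#' suppressing breathing-frequency fluctuation; trailing frames that do not
#' fill a block are dropped. Block means (rather than decimation) are used
#' because the purpose is breathing suppression, not data reduction.
#'
#' @param x a `zstack` or [dynamic_stack()].
#' @param factor block size (default 4).
#' @return Object of the same class with `floor(T / factor)` frames and the
#'   frame interval multiplied by `factor`.
#' @export
downsample_time <- function(x, factor = 4L) {
  stopifnot(inherits(x, c("zstack", "dynamic_stack")))
  factor <- as.integer(factor)
  assert_that(factor >= 1L, "`factor` must be >= 1")
  nt <- dim(x$data)[3L]
  assert_that(nt >= factor, "fewer frames than the down-sampling factor")
  n_out <- nt %/% factor
  d <- dim(x$data)
  out <- array(0, c(d[1L], d[2L], n_out))
  for (b in seq_len(n_out)) {
    idx <- ((b - 1L) * factor + 1L):(b * factor)
    out[, , b] <- rowMeans(x$data[, , idx, drop = FALSE], dims = 2L)
  }
  x$data <- out
  x$frame_interval <- x$frame_interval * factor
  x
}

#' Crop a stack to the ROI bounding box and zero outside-ROI pixels
#'
#' @param x a `zstack` or [dynamic_stack()].
#' @param roi logical mask; defaults to the mask stored in a `zstack`.
#' @return Same class as `x`, spatially cropped to the bounding box of the
#'   mask, with every outside-ROI pixel set to exactly 0 in every frame. For
#'   a `zstack`, the stored ROI is cropped alongside.
#' @export
mask_and_crop <- function(x, roi = NULL) {
  stopifnot(inherits(x, c("zstack", "dynamic_stack")))
  if (is.null(roi)) {
    assert_that(inherits(x, "zstack"), "`roi` is required for a dynamic_stack")
    roi <- x$roi
  }
  roi <- check_roi(roi, dim(x$data)[1:2])
  rr <- range(which(apply(roi, 1L, any)))
  cr <- range(which(apply(roi, 2L, any)))
  sub <- x$data[rr[1L]:rr[2L], cr[1L]:cr[2L], , drop = FALSE]
  roi_c <- roi[rr[1L]:rr[2L], cr[1L]:cr[2L], drop = FALSE]
  sub <- sub * array(roi_c, dim(sub))     # exact zeros outside
  x$data <- sub
  if (inherits(x, "zstack")) x$roi <- roi_c
  x
}

#' Per-pixel signal change-rate vectors
#'
#' For every in-ROI pixel, the vector of intensity differences between
#' consecutive (down-sampled) time frames. These vectors are the feature
#' space in which characteristic kinetic curves are clustered. By
#' construction the entries of each vector telescope: their sum equals the
#' last minus the first frame value at that pixel.
#'
#' @param z a `zstack` (z-transformed, down-sampled, cropped).
#' @return An object of class `change_rate_matrix`: `vectors` (n_pixels x
#'   T-1 matrix), `pixel_index` (n_pixels x 2 matrix of row/col in the
#'   cropped frame), `spatial_dim`.
#' @export
change_rates <- function(z) {
  stopifnot(inherits(z, "zstack"))
  nt <- dim(z$data)[3L]
  assert_that(nt >= 2L, "need at least 2 frames for change rates")
  idx <- which(z$roi, arr.ind = TRUE)
  n <- nrow(idx)
  flat <- matrix(z$data, ncol = nt)       # (h*w) x T
  lin <- idx[, 1L] + (idx[, 2L] - 1L) * dim(z$data)[1L]
  series <- flat[lin, , drop = FALSE]
  structure(
    list(vectors = series[, -1L, drop = FALSE] - series[, -nt, drop = FALSE],
         pixel_index = idx, spatial_dim = dim(z$data)[1:2]),
    class = "change_rate_matrix"
  )
}

#' @export
print.change_rate_matrix <- function(x, ...) {
  cat(sprintf("<change_rate_matrix> %d pixels x %d rate bins\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Extract characteristic kinetic curves by k-means clustering
#'
#' Pools the change-rate vectors of all animals in one treatment group and
#' clusters them with k-means (Euclidean distance, multiple seeded restarts),
#' yielding `k` centroid curves — the group's characteristic signal-change
#' behaviours. No per-bin standardization is applied: the vectors are already
#' in z-units.
#'
#' @param x a `change_rate_matrix`, a plain matrix of row vectors, or a list
#'   of `change_rate_matrix` objects (pooled by row-binding).
#' @param k number of characteristic curves (default 4).
#' @param seed integer seed controlling the restarts.
#' @param nstart number of k-means restarts (best objective kept).
#' @param group_label optional treatment-group name.
#' @return An object of class `characteristic_curves`: `centroids` (k x T-1
#'   matrix), `net_increase` (logical per curve: do its change rates sum to a
#'   strictly positive value), `k`, `tot_withinss`, `group_label`, `seed`.
#' @export
extract_characteristic_curves <- function(x, k = 4L, seed = NULL,
                                          nstart = 10L, group_label = NULL) {
  v <- pool_vectors(x)
  k <- as.integer(k)
  assert_that(nrow(v) >= k, "fewer pooled pixels than clusters")
  assert_that(nrow(unique(v)) >= k,
              "fewer distinct change-rate vectors than clusters",
              class = "hepaclear_degenerate_input")
  km <- with_seed(seed, kmeans(v, centers = k, nstart = nstart,
                               iter.max = 100L))
  centroids <- unname(km$centers)
  structure(
    list(centroids = centroids,
         net_increase = rowSums(centroids) > 0,
         k = k, tot_withinss = km$tot.withinss,
         group_label = group_label,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "characteristic_curves"
  )
}

pool_vectors <- function(x) {
  if (inherits(x, "change_rate_matrix")) return(x$vectors)
  if (is.matrix(x)) return(x)
  if (is.list(x)) {
    return(do.call(rbind, lapply(x, function(e) {
      if (inherits(e, "change_rate_matrix")) e$vectors else as.matrix(e)
    })))
  }
  stop_hepaclear("cannot interpret `x` as change-rate vectors",
                 "hepaclear_invalid_input")
}

#' @export
print.characteristic_curves <- function(x, ...) {
  cat(sprintf("<characteristic_curves> k = %d%s, %d net-increase curve(s), within-SS %.4g\n",
              x$k,
              if (is.null(x$group_label)) "" else paste0(" (", x$group_label, ")"),
              sum(x$net_increase), x$tot_withinss))
  invisible(x)
}

#' Assign each pixel to its nearest characteristic curve
#'
#' Every in-ROI pixel of one animal is assigned to the characteristic curve
#' with the smallest Euclidean distance to its change-rate vector; distance
#' ties break deterministically to the lowest curve index (tie events are
#' reported via a message).
#'
#' @param x a `change_rate_matrix` for one animal.
#' @param curves a `characteristic_curves` set fitted on the animal's
#'   treatment group.
#' @return A list: `assignment` (curve index per pixel), `abundance` (pixel
#'   counts per curve, summing to the in-ROI pixel count), `label_image`
#'   (matrix in the cropped geometry, 0 outside the ROI).
#' @export
assign_pixels <- function(x, curves) {
  stopifnot(inherits(x, "change_rate_matrix"),
            inherits(curves, "characteristic_curves"))
  assert_that(ncol(x$vectors) == ncol(curves$centroids),
              "change-rate vector length does not match the curves")
  d2 <- vapply(seq_len(curves$k), function(j) {
    rowSums(sweep(x$vectors, 2L, curves$centroids[j, ])^2)
  }, numeric(nrow(x$vectors)))
  d2 <- matrix(d2, nrow = nrow(x$vectors))
  assignment <- max.col(-d2, ties.method = "first")
  n_tie <- sum(rowSums(d2 == d2[cbind(seq_len(nrow(d2)), assignment)]) > 1L)
  if (n_tie > 0L) {
    message(sprintf("assign_pixels: %d distance tie(s) broken to the lowest curve index", n_tie))
  }
  label_image <- matrix(0L, x$spatial_dim[1L], x$spatial_dim[2L])
  label_image[x$pixel_index] <- assignment
  list(assignment = assignment,
       abundance = tabulate(assignment, nbins = curves$k),
       label_image = label_image)
}

#' Indices of net-increase characteristic curves
#'
#' Restricts quantification to contrast uptake: a curve is retained iff the
#' sum of its change-rate entries is strictly positive (a net gain of signal
#' from first to last frame); a zero sum drops the curve.
#'
#' @param curves a `characteristic_curves` set.
#' @return Integer vector of retained curve indices (possibly empty).
#' @export
filter_net_increase <- function(curves) {
  stopifnot(inherits(curves, "characteristic_curves"))
  which(curves$net_increase)
}

#' Abundance-weighted average of retained characteristic curves
#'
#' @param curves a `characteristic_curves` set.
#' @param abundance per-curve pixel counts for one animal (length `k`), from
#'   [assign_pixels()].
#' @param retained indices of curves to average; defaults to the
#'   net-increase subset.
#' @return The weighted average change-rate curve
#'   `sum_j w_j c_j / sum_j w_j` over retained curves `j`, or `NULL` (with a
#'   warning) if no retained curve has positive abundance for this animal —
#'   the animal's clearance readout is then undefined.
#' @export
weighted_average_curve <- function(curves, abundance,
                                   retained = filter_net_increase(curves)) {
  stopifnot(inherits(curves, "characteristic_curves"))
  assert_that(length(abundance) == curves$k,
              "`abundance` must have one entry per curve")
  if (length(retained) == 0L || sum(abundance[retained]) == 0) {
    warning("no retained curve with positive abundance; clearance result undefined for this animal")
    return(NULL)
  }
  w <- abundance[retained]
  drop(w %*% curves$centroids[retained, , drop = FALSE]) / sum(w)
}

#' Area under the linear tail of a clearance curve
#'
#' Trapezoidal area under the weighted-average change-rate curve from the
#' frame where its tail becomes linear (fixed by inspection to down-sampled
#' frame 8, 1-based) to the last frame, with unit frame spacing on the
#' abscissa. A larger tail AUC means more retained contrast, i.e. poorer
#' excretory function.
#'
#' @param curve numeric weighted-average curve (length T_ds - 1).
#' @param linear_start_frame 1-based index into the down-sampled curve where
#'   the linear tail starts (default 8).
#' @return The AUC (z-units; dimensionless frame abscissa).
#' @export
linear_tail_auc <- function(curve, linear_start_frame = 8L) {
  assert_that(is.numeric(curve) && length(curve) >= 2L,
              "`curve` must be a numeric vector of length >= 2")
  s <- as.integer(linear_start_frame)
  assert_that(s >= 1L && s < length(curve),
              "`linear_start_frame` must lie before the end of the curve")
  idx <- s:length(curve)
  trapz(idx, curve[idx])
}

#' Rank-based comparison of per-animal AUCs across treatment groups
#'
#' Kruskal-Wallis omnibus test over all groups, followed by pairwise Wilcoxon
#' rank-sum comparisons with Benjamini-Hochberg control of the false
#' discovery rate.
#'
#' @param aucs data frame with columns `animal_id`, `group`, `auc`.
#' @return An object of class `group_comparison`: `omnibus` (statistic, df,
#'   p-value), `pairwise` (data frame with W statistic, p and BH-adjusted q
#'   per pair), `summary` (median AUC and n per group), `excluded` (groups
#'   dropped for having fewer than 2 animals).
#' @export
compare_groups <- function(aucs) {
  assert_that(is.data.frame(aucs) && all(c("group", "auc") %in% names(aucs)),
              "`aucs` must have columns `group` and `auc`")
  aucs <- aucs[is.finite(aucs$auc), , drop = FALSE]
  n_by <- table(aucs$group)
  excluded <- names(n_by)[n_by < 2L]
  if (length(excluded) > 0L) {
    warning(sprintf("excluding group(s) with < 2 animals: %s",
                    paste(excluded, collapse = ", ")))
    aucs <- aucs[!(aucs$group %in% excluded), , drop = FALSE]
  }
  groups <- unique(aucs$group)
  assert_that(length(groups) >= 2L, "need at least 2 groups with >= 2 animals")
  kw <- kruskal.test(aucs$auc, factor(aucs$group))
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(p) {
    x <- aucs$auc[aucs$group == p[1L]]
    y <- aucs$auc[aucs$group == p[2L]]
    wt <- suppressWarnings(wilcox.test(x, y))
    data.frame(group1 = p[1L], group2 = p[2L],
               W = unname(wt$statistic), p = wt$p.value)
  }))
  pw$q <- p.adjust(pw$p, method = "BH")
  smry <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g, n = sum(aucs$group == g),
               median_auc = median(aucs$auc[aucs$group == g]))
  }))
  structure(
    list(omnibus = list(statistic = unname(kw$statistic),
                        df = unname(kw$parameter), p = kw$p.value),
         pairwise = pw, summary = smry, excluded = excluded),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Kruskal-Wallis omnibus: chi-squared =",
      format(x$omnibus$statistic, digits = 4),
      "df =", x$omnibus$df, "p =", format.pval(x$omnibus$p, digits = 3), "\n")
  cat("Group summaries:\n")
  print(x$summary, row.names = FALSE)
  cat("Pairwise Wilcoxon (BH-adjusted):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
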