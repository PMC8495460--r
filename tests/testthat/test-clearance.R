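test_that("z-transform standardizes against the first frame and inverts exactly", {
  # first frame constructed with in-ROI mean 10, SD 2
  h <- 6; w <- 6
  roi <- matrix(TRUE, h, w)
  f1 <- matrix(10, h, w)
  f1[1:18] <- 10 + 2 * scale(rnorm(18))      # mean 10, sd != 2 yet
  f1 <- matrix(10 + (f1 - mean(f1)) * 2 / sd(f1), h, w)
  f2 <- matrix(14, h, w)
  st <- dynamic_stack(array(c(f1, f2), c(h, w, 2)), 15)
  z <- ztransform(st, roi)
  expect_equal(z$mu, 10, tolerance = 1e-12)
  expect_equal(z$sigma, 2, tolerance = 1e-12)
  expect_equal(z$data[1, 1, 2], 2.0, tolerance = 1e-12)  # (14 - 10) / 2
  # first frame self-normalizes
  expect_lt(abs(mean(z$data[, , 1][roi])), 1e-10)
  expect_lt(abs(sd(z$data[, , 1][roi]) - 1), 1e-10)
  # affine inversion to machine precision
  inv <- ztransform_invert(z)
  expect_equal(inv$data, st$data, tolerance = 1e-12)
  # degenerate first frame rejected
  flat <- dynamic_stack(array(3, c(4, 4, 2)), 15)
  expect_error(ztransform(flat, matrix(TRUE, 4, 4)), "degenerate")
})

test_that("temporal down-sampling takes non-overlapping block means", {
  arr <- array(0, c(1, 1, 8))
  arr[1, 1, ] <- 0:7
  st <- dynamic_stack(arr, 15)
  ds <- downsample_time(st, 4L)
  expect_equal(dim(ds$data)[3L], 2L)
  expect_equal(as.vector(ds$data), c(1.5, 5.5))
  expect_equal(ds$frame_interval, 60)
  # 16 frames -> 4; constant stack unchanged
  cst <- dynamic_stack(array(2, c(2, 2, 16)), 15)
  dcst <- downsample_time(cst, 4L)
  expect_equal(dim(dcst$data)[3L], 4L)
  expect_true(all(dcst$data == 2))
  # trailing remainder dropped: 10 frames, factor 4 -> 2 blocks
  arr10 <- array(rep(1:10, each = 4), c(2, 2, 10))
  expect_equal(dim(downsample_time(dynamic_stack(arr10, 15), 4L)$data)[3L], 2L)
  expect_error(downsample_time(st, 0L), "factor")
})

test_that("mask_and_crop crops to the bounding box and zeroes outside", {
  sim <- tiny_sim(seed = 1)
  z <- ztransform(sim$icg, sim$roi)
  # full-frame mask leaves the data unchanged
  full <- matrix(TRUE, 24, 24)
  zf <- z; zf$roi <- full
  expect_identical(mask_and_crop(zf)$data, z$data)
  # single-pixel mask carries that pixel's series
  single <- matrix(FALSE, 24, 24); single[7, 9] <- TRUE
  zs <- z; zs$roi <- single
  out <- mask_and_crop(zs)
  expect_equal(dim(out$data)[1:2], c(1L, 1L))
  expect_equal(as.vector(out$data), z$data[7, 9, ])
  # L-shaped mask: per-pixel recomputation oracle
  L <- matrix(FALSE, 24, 24)
  L[5:15, 5] <- TRUE; L[15, 5:12] <- TRUE
  zl <- z; zl$roi <- L
  out_l <- mask_and_crop(zl)
  expect_equal(dim(out_l$data)[1:2], c(11L, 8L))
  for (f in c(1L, 4L)) {
    manual <- z$data[5:15, 5:12, f] * L[5:15, 5:12]
    expect_equal(out_l$data[, , f], manual, tolerance = 1e-15)
  }
  expect_error(mask_and_crop(zl, matrix(FALSE, 24, 24)), "empty")
})

test_that("change-rate vectors are consecutive differences that telescope", {
  arr <- array(0, c(2, 2, 4))
  series <- c(0, 1, 3, 6)
  for (f in 1:4) arr[, , f] <- series[f]
  z <- structure(list(data = arr, mu = 0, sigma = 1,
                      roi = matrix(TRUE, 2, 2), frame_interval = 60),
                 class = "zstack")
  cr <- change_rates(z)
  expect_equal(dim(cr$vectors), c(4L, 3L))
  expect_true(all(apply(cr$vectors, 1L, identical, y = c(1, 2, 3))))
  # constant series gives zero vector
  zc <- z; zc$data <- array(5, c(2, 2, 4))
  expect_true(all(change_rates(zc)$vectors == 0))
  # telescoping on random data, per pixel
  set.seed(42)
  zr <- z; zr$data <- array(rnorm(2 * 2 * 6), c(2, 2, 6))
  crr <- change_rates(zr)
  for (i in seq_len(nrow(crr$vectors))) {
    px <- crr$pixel_index[i, ]
    expect_equal(sum(crr$vectors[i, ]),
                 zr$data[px[1L], px[2L], 6] - zr$data[px[1L], px[2L], 1],
                 tolerance = 1e-12)
  }
})

test_that("k-means centroids match closed forms and the brute-force optimum", {
  # two point-masses, k = 2: centroids equal the two vectors, objective 0
  v <- rbind(matrix(rep(c(1, 0, 0), 5), 5, byrow = TRUE),
             matrix(rep(c(0, 0, 1), 5), 5, byrow = TRUE))
  cc <- extract_characteristic_curves(v, k = 2, seed = 1)
  expect_equal(cc$tot_withinss, 0, tolerance = 1e-12)
  expect_setequal(apply(cc$centroids, 1L, paste, collapse = ","),
                  c("1,0,0", "0,0,1"))
  # k = 1: centroid is the grand mean
  set.seed(10)
  vr <- matrix(rnorm(30), 10, 3)
  c1 <- extract_characteristic_curves(vr, k = 1, seed = 1)
  expect_equal(as.vector(c1$centroids), colMeans(vr), tolerance = 1e-12)
  # 12 vectors, k = 2: final partition equals the exhaustive optimum
  set.seed(11)
  v12 <- matrix(rnorm(36), 12, 3)
  c2 <- extract_characteristic_curves(v12, k = 2, seed = 3, nstart = 20)
  bf <- brute_force_kmeans2(v12)
  expect_equal(c2$tot_withinss, bf$ss, tolerance = 1e-9)
  asg <- assign_pixels(
    structure(list(vectors = v12, pixel_index = cbind(1:12, 1L),
                   spatial_dim = c(12L, 1L)), class = "change_rate_matrix"),
    c2)
  expect_true(identical(asg$assignment == asg$assignment[1L], bf$in1) ||
                identical(asg$assignment != asg$assignment[1L], bf$in1))
  # degenerate: fewer distinct vectors than clusters
  vdup <- matrix(1, 5, 3)
  expect_error(extract_characteristic_curves(vdup, k = 2, seed = 1),
               "distinct")
  # seeded reproducibility
  expect_identical(extract_characteristic_curves(v12, k = 3, seed = 5)$centroids,
                   extract_characteristic_curves(v12, k = 3, seed = 5)$centroids)
})

test_that("pixel assignment is a nearest-centroid scan with deterministic ties", {
  set.seed(12)
  v <- matrix(rnorm(200 * 4), 200, 4)
  crm <- structure(list(vectors = v, pixel_index = cbind(1:200, 1L),
                        spatial_dim = c(200L, 1L)),
                   class = "change_rate_matrix")
  cc <- extract_characteristic_curves(v, k = 3, seed = 2)
  asg <- assign_pixels(crm, cc)
  # brute-force O(n k) oracle
  oracle <- apply(v, 1L, function(row) {
    which.min(colSums((t(cc$centroids) - row)^2))
  })
  expect_identical(asg$assignment, as.integer(oracle))
  expect_equal(sum(asg$abundance), 200L)
  # a pixel vector equal to centroid j is assigned to j
  crm1 <- structure(list(vectors = cc$centroids[2L, , drop = FALSE],
                         pixel_index = cbind(1L, 1L), spatial_dim = c(1L, 1L)),
                    class = "change_rate_matrix")
  expect_equal(assign_pixels(crm1, cc)$assignment, 2L)
  # equidistant vector ties to the lowest curve index, with a message
  ctr <- rbind(c(1, 0), c(-1, 0))
  cc2 <- structure(list(centroids = ctr, net_increase = c(TRUE, FALSE),
                        k = 2L, tot_withinss = 0, group_label = NULL,
                        seed = NA_integer_),
                   class = "characteristic_curves")
  crm2 <- structure(list(vectors = matrix(c(0, 5), 1), pixel_index = cbind(1L, 1L),
                         spatial_dim = c(1L, 1L)), class = "change_rate_matrix")
  expect_message(tie <- assign_pixels(crm2, cc2), "tie")
  expect_equal(tie$assignment, 1L)
})

test_that("net-increase filtering uses a strict positive-sum rule", {
  mk <- function(m) structure(
    list(centroids = m, net_increase = rowSums(m) > 0, k = nrow(m),
         tot_withinss = 0, group_label = NULL, seed = NA_integer_),
    class = "characteristic_curves")
  cc <- mk(rbind(rep(0.1, 4),       # retained
                 rep(-0.1, 4),      # dropped
                 c(1, -1, 1, -1)))  # sum 0: dropped under strict rule
  expect_identical(filter_net_increase(cc), 1L)
  # weighted average: single curve, equal weights, and 10/30/60 oracle
  cc3 <- mk(rbind(c(1, 1), c(2, 4), c(5, 0)))
  expect_equal(weighted_average_curve(cc3, c(7, 0, 0), retained = 1L),
               c(1, 1))
  expect_equal(weighted_average_curve(cc3, c(3, 3, 0), retained = 1:2),
               c(1.5, 2.5))
  expect_equal(weighted_average_curve(cc3, c(10, 30, 60), retained = 1:3),
               (10 * c(1, 1) + 30 * c(2, 4) + 60 * c(5, 0)) / 100,
               tolerance = 1e-12)
  # nothing retained -> undefined with a warning
  ccneg <- mk(matrix(-0.1, 2, 4))
  expect_warning(res <- weighted_average_curve(ccneg, c(5, 5)), "undefined")
  expect_null(res)
})

test_that("linear-tail AUC matches rectangles and fine-grid quadrature", {
  expect_equal(linear_tail_auc(rep(0, 19), 8L), 0)
  expect_equal(linear_tail_auc(rep(2, 19), 8L), 2 * 11)  # c * m intervals
  set.seed(13)
  curve <- rnorm(19)
  auc <- linear_tail_auc(curve, 8L)
  expect_equal(auc, riemann_auc(8:19, curve[8:19]), tolerance = 1e-6)
  expect_error(linear_tail_auc(rep(1, 5), 5L), "before the end")
})

test_that("group comparison reproduces exact rank statistics and BH by hand", {
  # identical groups: omnibus p ~ 1
  same <- data.frame(animal_id = 1:8,
                     group = rep(c("a", "b"), each = 4L),
                     auc = rep(c(1, 2, 3, 4), 2L))
  gc0 <- compare_groups(same)
  expect_gt(gc0$omnibus$p, 0.9)

  # {1,2,3} vs {101,102,103}: W = 0 and exact-enumeration p-value
  two <- data.frame(animal_id = 1:6, group = rep(c("lo", "hi"), each = 3L),
                    auc = c(1, 2, 3, 101, 102, 103))
  gc <- compare_groups(two)
  expect_equal(gc$pairwise$W, 0)
  # exact permutation null: rank-sum of group "lo" over all C(6,3) splits
  ranks <- 1:6
  sums <- utils::combn(ranks, 3L, sum)
  w_obs <- sum(1:3) - 3 * 4 / 2          # Mann-Whitney U of observed split
  u_all <- sums - 3 * 4 / 2
  p_exact <- 2 * mean(u_all <= w_obs)
  expect_equal(gc$pairwise$p, p_exact, tolerance = 1e-12)

  # three groups: BH adjustment equals the step-up definition by hand
  three <- data.frame(animal_id = 1:9, group = rep(c("a", "b", "c"), each = 3L),
                      auc = c(1, 2, 3, 2.5, 3.5, 4.5, 10, 11, 12))
  gc3 <- compare_groups(three)
  p <- gc3$pairwise$p
  o <- order(p, decreasing = TRUE)
  by_hand <- rev(cummin(rev(sort(p) * 3 / seq_len(3))))[rank(p)]
  expect_equal(gc3$pairwise$q, pmin(by_hand, 1), tolerance = 1e-12)

  # undersized group excluded with a warning
  small <- rbind(three, data.frame(animal_id = 10, group = "d", auc = 5))
  expect_warning(gcx <- compare_groups(small), "excluding")
  expect_identical(gcx$excluded, "d")
})
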