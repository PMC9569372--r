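## small synthetic planes/stacks built in code

disc_mask <- function(ny, nx, cy, cx, r) {
  outer(seq_len(ny), seq_len(nx),
        function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

test_that("dual-Otsu plane segmentation recovers objects and guards degeneracy", {
  ## bimodal image: background 10, bright disc 200
  plane <- matrix(10, 80, 80)
  d <- disc_mask(80, 80, 40, 40, 15)
  plane[d] <- 200
  m <- segment_plane(plane, block_size_px = 40)
  expect_identical(m, d)
  ## constant plane -> empty mask
  expect_false(any(segment_plane(matrix(7, 50, 50))))
  ## linear gradient background + two bright blobs: Jaccard >= 0.9
  grad <- matrix(rep(seq(0, 60, length.out = 120), each = 120), 120, 120)
  b1 <- disc_mask(120, 120, 30, 30, 10); b2 <- disc_mask(120, 120, 90, 95, 12)
  img <- grad; img[b1] <- img[b1] + 300; img[b2] <- img[b2] + 300
  m2 <- segment_plane(img, block_size_px = 40)
  jac <- sum(m2 & (b1 | b2)) / sum(m2 | b1 | b2)
  expect_gte(jac, 0.9)
  expect_error(segment_plane(plane, block_size_px = 4), "block_size")
})

test_that("watershed splitting separates touching discs", {
  px <- 0.5  # um/pixel
  ## single disc -> one label
  m1 <- disc_mask(60, 60, 30, 30, 10)
  l1 <- split_touching(m1, px, nominal_diameter = 10)
  expect_identical(max(l1), 1L)
  ## two overlapping discs, centres 10 um (20 px) apart -> two labels
  m2 <- disc_mask(80, 100, 40, 40, 12) | disc_mask(80, 100, 40, 60, 12)
  l2 <- split_touching(m2, px, nominal_diameter = 10)
  expect_identical(max(l2), 2L)
  cen <- lapply(1:2, function(i) {
    w <- which(l2 == i, arr.ind = TRUE); colMeans(w) * px
  })
  gap <- sqrt(sum((cen[[1]] - cen[[2]])^2))
  expect_lt(abs(gap - 10), 1.5)
  ## empty mask -> zero labels
  expect_identical(max(split_touching(matrix(FALSE, 20, 20), px)), 0L)
})

test_that("z-linking follows drifting centroids up to the 1 um threshold", {
  px <- 0.25
  mk_planes <- function(drift_um) {
    lapply(0:7, function(k) {
      cx <- 30 + k * drift_um / px
      m <- disc_mask(120, 120, 60, cx, 12)
      matrix(as.integer(m), 120, 120)
    })
  }
  ## identical disc across planes -> one 3D label
  same <- link_z(mk_planes(0), px, z_step = 1, max_link_dist = 1)
  expect_identical(max(same$labels), 1L)
  ## drift 0.5 um/plane: still one nucleus
  slow <- link_z(mk_planes(0.5), px, z_step = 1, max_link_dist = 1)
  expect_identical(max(slow$labels), 1L)
  ## drift 2 um/plane: chain breaks at every step
  fast <- link_z(mk_planes(2), px, z_step = 1, max_link_dist = 1)
  expect_identical(max(fast$labels), 8L)
  ## two columns offset 5 um laterally stay distinct
  two <- lapply(1:5, function(k) {
    m <- disc_mask(120, 120, 40, 40, 8) | disc_mask(120, 120, 40, 60, 8)
    matrix(as.integer(EBImage::bwlabel(EBImage::Image(m * 1))), 120, 120)
  })
  expect_identical(max(link_z(two, px, 1, 1)$labels), 2L)
})

test_that("volume filter applies the strict 100 um^3 rule and is idempotent", {
  ## voxel = 1 um^3 -> voxel count equals volume
  lab <- array(0L, c(20, 20, 6))
  lab[1:5, 1:5, 1:2] <- 1L     # 50 um^3: removed
  lab[10:14, 10:14, 1:6] <- 2L # 150 um^3: kept
  vol <- new_lv <- prizenet:::new_labeled_volume(lab, 1, 1)
  f <- filter_small(vol, 100)
  expect_identical(sort(unique(as.vector(f$labels))), c(0L, 1L))
  expect_identical(sum(f$labels == 1L), 150L)
  ## exactly at the threshold: kept
  lab2 <- array(0L, c(10, 10, 4)); lab2[1:5, 1:5, 1:4] <- 1L  # 100
  f2 <- filter_small(prizenet:::new_labeled_volume(lab2, 1, 1), 100)
  expect_identical(max(f2$labels), 1L)
  ## idempotent; foreground never grows
  f3 <- filter_small(f, 100)
  expect_identical(f3$labels, f$labels)
  expect_lte(sum(f$labels > 0), sum(vol$labels > 0))
})

test_that("nucleus measurement recovers painted volumes and means", {
  lab <- array(0L, c(20, 20, 8))
  lab[2:11, 2:11, 2:5] <- 1L    # 10*10*4 = 400 voxels
  lab[14:18, 14:18, 2:3] <- 2L  # 5*5*2 = 50 voxels
  ch <- array(0, dim(lab)); ch[lab == 1L] <- 100; ch[lab == 2L] <- 400
  st <- zstack(list(dapi = (lab > 0) * 500, marker = ch),
               pixel_size_xy = 0.5, z_step = 1)
  vol <- prizenet:::new_labeled_volume(lab, 0.5, 1)
  ms <- measure_nuclei(vol, st)
  expect_equal(ms$volume_um3, c(400, 50) * 0.25, tolerance = 1e-12)
  expect_equal(ms$mean_marker, c(100, 400))
  expect_equal(ms$mean_dapi, c(500, 500))
  ## 1000 voxels at 0.5 x 0.5 x 1 um = 250 um^3
  lab3 <- array(0L, c(10, 10, 10)); lab3[] <- 1L
  ms3 <- measure_nuclei(prizenet:::new_labeled_volume(lab3, 0.5, 1),
                        zstack(list(d = array(1, dim(lab3))), 0.5, 1))
  expect_equal(ms3$volume_um3, 250)
  expect_error(measure_nuclei(vol, zstack(list(d = array(1, c(5, 5, 5))),
                                          0.5, 1)), "geometr")
})

test_that("high-marker fractions use a strict threshold", {
  ms <- data.frame(mean_oct4 = c(100, 400, 500))
  expect_equal(fraction_high(ms, "oct4", 300), 2 / 3)
  expect_equal(fraction_high(data.frame(mean_oct4 = c(10, 20)), "oct4"), 0)
  expect_equal(fraction_high(data.frame(mean_oct4 = c(300, 300)), "oct4"), 0)
  expect_error(fraction_high(data.frame(mean_oct4 = numeric()), "oct4"),
               "empty")
})

test_that("per-nucleus channel correlation matches direct computation", {
  ms <- data.frame(mean_a = c(1, 4, 2, 8, 5), mean_b = c(2, 5, 1, 9, 4))
  expect_equal(nuclear_correlation(ms, "a", "b"),
               cor(ms$mean_a, ms$mean_b), tolerance = 1e-12)
  ms$mean_c <- ms$mean_a
  expect_equal(nuclear_correlation(ms, "a", "c"), 1.0)
  ms$mean_d <- -ms$mean_a + 10
  expect_equal(nuclear_correlation(ms, "a", "d"), -1.0)
  ms$mean_e <- 5
  expect_error(nuclear_correlation(ms, "a", "e"), "variance")
  expect_error(nuclear_correlation(ms[1:2, ], "a", "b"), "3 nuclei")
})

test_that("colocalization ratios cover identical, disjoint and half cases", {
  lab <- array(0L, c(12, 12, 4)); lab[3:10, 3:10, ] <- 1L
  idx <- which(lab == 1L)
  mk <- function(fgidx, hi = 300, lo = 10) {
    a <- array(lo, dim(lab)); a[fgidx] <- hi; a
  }
  half1 <- idx[seq_len(length(idx) / 2)]
  half2 <- idx[(length(idx) / 2 + 1):length(idx)]
  st <- zstack(list(a = mk(idx), b = mk(idx), c = mk(half1), d = mk(half2),
                    flat = array(5, dim(lab))), 0.5, 1)
  vol <- prizenet:::new_labeled_volume(lab, 0.5, 1)
  expect_equal(coloc_ratio(vol, st, c("a", "b"))$coloc_ratio, 1.0)
  expect_equal(coloc_ratio(vol, st, c("c", "d"))$coloc_ratio, 0.0)
  expect_equal(coloc_ratio(vol, st, c("a", "c"))$coloc_ratio, 0.5)
  expect_warning(r0 <- coloc_ratio(vol, st, c("a", "flat")), "constant")
  expect_equal(r0$coloc_ratio, 0)
  rr <- coloc_ratio(vol, st, c("a", "b", "c"))$coloc_ratio
  expect_true(rr >= 0 && rr <= 1)
})

test_that("spheroid projected area fills holes and scales by pixel size", {
  img <- matrix(5, 150, 260)
  img[21:120, 31:230] <- 250                 # 100 x 200 px rectangle
  img[60:70, 100:120] <- 5                   # hole, must be filled
  expect_equal(spheroid_projected_area(img, 0.5), 100 * 200 * 0.25)
  ## rasterized disc within 3% of pi r^2
  d <- disc_mask(200, 200, 100, 100, 30)
  img2 <- matrix(5, 200, 200); img2[d] <- 300
  a <- spheroid_projected_area(img2, 1)
  expect_lt(abs(a - pi * 30^2) / (pi * 30^2), 0.03)
  expect_warning(a0 <- spheroid_projected_area(matrix(3, 40, 40), 1), "empty")
  expect_equal(a0, 0)
})

test_that("stacks round-trip through TIFF with a YAML geometry sidecar", {
  d <- file.path(tempdir(), "ziotest")
  g <- gen_confocal_stack(n_nuclei = 2, min_center_dist_um = 14,
                          channel_intensity_map = list(mk = c(100, 400)),
                          radius_range_um = c(3, 4),
                          field_um = c(36, 36, 14), seed = 13, dir = d)
  st <- read_zstack(file.path(d, "stack.tiff"))
  expect_identical(names(st$channels), c("dapi", "mk"))
  expect_equal(st$pixel_size_xy, g$stack$pixel_size_xy)
  expect_equal(st$z_step, g$stack$z_step)
  ## intensities recovered up to 16-bit quantization
  mx <- max(vapply(g$stack$channels, max, 0))
  for (chn in names(st$channels))
    expect_lt(max(abs(st$channels[[chn]] - g$stack$channels[[chn]])),
              mx / 65535)
  ## labeled volumes serialize as 16-bit TIFF
  vol <- segment_stack(g$stack)
  write_labeled_volume(vol, file.path(d, "labels.tiff"))
  back <- tiff::readTIFF(file.path(d, "labels.tiff"), all = TRUE)
  expect_identical(length(back), dim(vol$labels)[3])
  expect_equal(round(back[[1]] * 65535), vol$labels[, , 1],
               ignore_attr = TRUE)
})

test_that("segmentation and measurement are invariant to intensity rescaling", {
  g <- gen_confocal_stack(n_nuclei = 4, min_center_dist_um = 16,
                          channel_intensity_map = list(mk = c(200, 400)),
                          noise_sd = 0, field_um = c(50, 50, 18), seed = 11)
  v1 <- segment_stack(g$stack)
  st2 <- g$stack
  st2$channels$dapi <- st2$channels$dapi * 7.3
  v2 <- segment_stack(st2)
  expect_identical(v1$labels, v2$labels)
})
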