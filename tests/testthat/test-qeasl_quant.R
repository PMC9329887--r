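test_that("phase subtraction is exact, conserving, and validates labels", {
  g <- image_grid(c(10, 10, 10), c(1, 1, 1))
  ph <- flat_phases(g, unenh = 100, art = 100)
  expect_true(all(subtract_phases(ph$arterial, ph$unenhanced)$values == 0))
  ph2 <- flat_phases(g, unenh = 100, art = 150)
  s <- subtract_phases(ph2$arterial, ph2$unenhanced)
  expect_true(all(s$values == 50))
  expect_equal(s$phase, "subtracted")
  # conservation: subtracted + unenhanced == arterial voxelwise
  set.seed(11)
  a <- volume_image(array(rnorm(1000, 200, 30), dim = g$shape), g, "arterial_T1")
  u <- volume_image(array(rnorm(1000, 100, 30), dim = g$shape), g, "unenhanced_T1")
  expect_equal(subtract_phases(a, u)$values + u$values, a$values)
  expect_error(subtract_phases(u, u), "phase labels")
})

test_that("realized reference ROI hits its target volume with grid refinement", {
  # 1 cm^3 ball radius: (3 * 1000 / (4 pi))^(1/3) = 6.2035 mm
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  expect_equal(r, 6.2035, tolerance = 1e-4)
  g1 <- image_grid(c(20, 20, 20), c(1, 1, 1))
  roi1 <- realize_roi(roi_spec(c(9.5, 9.5, 9.5)), g1)
  expect_lt(abs(mask_volume_cm3(roi1) - 1) , 0.05)
  g2 <- image_grid(c(40, 40, 40), c(0.5, 0.5, 0.5))
  roi2 <- realize_roi(roi_spec(c(9.75, 9.75, 9.75)), g2)
  expect_lt(abs(mask_volume_cm3(roi2) - 1), 0.01)
})

test_that("ROI placement errors name the violated constraint", {
  g <- image_grid(c(30, 30, 30), c(1, 1, 1))
  lesion <- array(FALSE, dim = g$shape); lesion[12:18, 12:18, 12:18] <- TRUE
  lm <- segmentation_mask(lesion, g, "L9")
  expect_error(realize_roi(roi_spec(c(14.5, 14.5, 14.5)), g, list(lm)), "L9")
  expect_error(realize_roi(roi_spec(c(1, 14, 14)), g), "boundary")
  expect_error(realize_roi(roi_spec(c(-5, 14, 14)), g), "outside")
})

test_that("ROI statistics: mean and population SD with a minimum size guard", {
  g <- image_grid(c(6, 6, 6), c(1, 1, 1))
  s <- volume_image(array(10, dim = g$shape), g, "subtracted")
  roi <- segmentation_mask(array(TRUE, dim = g$shape), g, "roi")
  st <- roi_stats(s, roi)
  expect_equal(st$mean, 10); expect_equal(st$sd, 0)
  # two-voxel ROI {8, 12}: mean 10, population sd 2
  vals <- array(0, dim = g$shape); vals[1, 1, 1] <- 8; vals[2, 1, 1] <- 12
  two <- array(FALSE, dim = g$shape); two[1:2, 1, 1] <- TRUE
  st2 <- roi_stats(volume_image(vals, g, "subtracted"),
                   segmentation_mask(two, g, "roi"), min_voxels = 2)
  expect_equal(st2$mean, 10); expect_equal(st2$sd, 2); expect_equal(st2$n_voxels, 2L)
  expect_error(roi_stats(s, segmentation_mask(two, g, "roi")), "at least 10")
})

test_that("sampled ROI mean stays within the sampling-error bound", {
  g <- image_grid(c(24, 24, 24), c(1, 1, 1))
  set.seed(123)
  s <- volume_image(array(rnorm(prod(g$shape), 30, 5), dim = g$shape), g, "subtracted")
  roi <- realize_roi(roi_spec(c(11.5, 11.5, 11.5)), g)
  st <- roi_stats(s, roi)
  expect_lt(abs(st$mean - 30), 3 * 5 / sqrt(st$n_voxels))
})

test_that("enhancing classification thresholds at mean + k*SD and is monotone in k", {
  g <- image_grid(c(12, 12, 12), c(1, 1, 1))
  tum <- array(FALSE, dim = g$shape); tum[4:9, 4:9, 4:9] <- TRUE
  tumor <- segmentation_mask(tum, g, "L1")
  ref <- structure(list(mean = 50, sd = 5, n_voxels = 100), class = "roi_stats")
  # subtracted equal to the reference mean nowhere exceeds mean + 2 sd
  s_eq <- volume_image(array(50, dim = g$shape), g, "subtracted")
  expect_equal(sum(classify_enhancing(s_eq, tumor, ref)$voxels), 0L)
  # k = 0 with intensities just above the mean: the whole tumor is enhancing
  s_hi <- volume_image(array(51, dim = g$shape), g, "subtracted")
  e0 <- classify_enhancing(s_hi, tumor, ref, qeasl_config(enhancement_k = 0))
  expect_identical(e0$voxels, tumor$voxels)
  # monotone: larger k never adds enhancing voxels; output always inside tumor
  set.seed(5)
  s_rand <- volume_image(array(rnorm(prod(g$shape), 55, 10), dim = g$shape), g, "subtracted")
  prev <- NULL
  for (k in c(0, 0.5, 1, 2, 4)) {
    e <- classify_enhancing(s_rand, tumor, ref, qeasl_config(enhancement_k = k))
    expect_true(all(!e$voxels | tumor$voxels))
    if (!is.null(prev)) expect_true(all(e$voxels <= prev))
    prev <- e$voxels
  }
})

test_that("lesion measurement spans fully necrotic to fully enhancing phantoms", {
  for (f in c(0, 1)) {
    ph <- generate_phantom(quick_phantom_spec(fraction = f, noise_sd = 0))
    m <- measure_lesion(ph$arterial, ph$unenhanced, ph$masks$L1, roi_spec(ph$roi_center))
    expect_gt(m$whole_volume_cm3, 0)
    expect_lte(m$enhancing_volume_cm3, m$whole_volume_cm3)
    if (f == 0) expect_equal(m$enhancing_volume_cm3, 0)
    if (f == 1) expect_equal(m$enhancing_volume_cm3, m$whole_volume_cm3)
  }
})

test_that("reader averaging pools volumes arithmetically and validates ids", {
  m1 <- data.frame(lesion_id = "L1", session_id = 1, reader_id = "r1",
                   whole_volume_cm3 = 20, enhancing_volume_cm3 = 10)
  m2 <- data.frame(lesion_id = "L1", session_id = 1, reader_id = "r2",
                   whole_volume_cm3 = 22, enhancing_volume_cm3 = 12)
  avg <- average_readers(rbind(m1, m2))
  expect_equal(avg$whole_volume_cm3, 21)
  expect_equal(avg$enhancing_volume_cm3, 11)
  expect_equal(avg$reader_id, "mean")
  expect_equal(average_readers(m1)$whole_volume_cm3, 20)  # single reader: identity
  m3 <- m2; m3$lesion_id <- "L2"
  expect_error(average_readers(rbind(m1, m3)), "mix")
  expect_error(average_readers(list()), "no measurements")
  avg2 <- average_readers(rbind(
    data.frame(lesion_id = "L1", session_id = 1, reader_id = "r1",
               whole_volume_cm3 = 20, enhancing_volume_cm3 = 8),
    data.frame(lesion_id = "L1", session_id = 1, reader_id = "r2",
               whole_volume_cm3 = 22, enhancing_volume_cm3 = 10)))
  expect_equal(c(avg2$whole_volume_cm3, avg2$enhancing_volume_cm3), c(21, 9))
})

test_that("the color map partitions the tumor into red and blue", {
  ph <- generate_phantom(quick_phantom_spec(fraction = 0.4, noise_sd = 0))
  sub <- subtract_phases(ph$arterial, ph$unenhanced)
  roi <- realize_roi(roi_spec(ph$roi_center), sub$grid, ph$masks)
  ref <- roi_stats(sub, roi)
  lab <- color_map(sub, ph$masks$L1, ref)
  enh <- classify_enhancing(sub, ph$masks$L1, ref)
  expect_identical(lab == 1L, enh$voxels)                    # red set
  expect_identical(lab > 0L, ph$masks$L1$voxels)             # red + blue = tumor
  # fully enhancing lesion: all red; fully necrotic: all blue
  for (f in c(1, 0)) {
    p2 <- generate_phantom(quick_phantom_spec(fraction = f, noise_sd = 0))
    s2 <- subtract_phases(p2$arterial, p2$unenhanced)
    r2 <- roi_stats(s2, realize_roi(roi_spec(p2$roi_center), s2$grid, p2$masks))
    l2 <- color_map(s2, p2$masks$L1, r2)
    expect_equal(sum(l2 == ifelse(f == 1, 2L, 1L)), 0L)
  }
  # overlay export round-trips through NIfTI
  f <- tempfile(fileext = ".nii.gz")
  color_map(sub, ph$masks$L1, ref, file = f)
  back <- RNifti::readNifti(f)
  expect_equal(array(as.integer(back), dim = dim(back)),
               array(as.integer(lab), dim = dim(lab)))
})

test_that("measured enhancing volume never exceeds whole volume (property)", {
  for (seed in 1:5) {
    ph <- generate_phantom(quick_phantom_spec(fraction = 0.3, noise_sd = 60,
                                              seed = seed))
    m <- measure_lesion(ph$arterial, ph$unenhanced, ph$masks$L1,
                        roi_spec(ph$roi_center))
    expect_lte(m$enhancing_volume_cm3, m$whole_volume_cm3)
    expect_gte(m$enhancing_volume_cm3, 0)
  }
})
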