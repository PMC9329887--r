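test_that("phantom truth is voxel-exact and the requested fraction is hit", {
  ph <- generate_phantom(quick_phantom_spec(fraction = 0.4, noise_sd = 0))
  vv <- voxel_volume_cm3(ph$unenhanced$grid)
  expect_equal(ph$truth$whole_volume_cm3, ph$truth$n_voxels * vv)
  expect_equal(ph$truth$enhancing_volume_cm3, ph$truth$n_enhancing * vv)
  expect_equal(sum(ph$masks$L1$voxels), ph$truth$n_voxels)
  expect_equal(sum(ph$enhancing_masks$L1$voxels), ph$truth$n_enhancing)
  expect_lt(abs(ph$truth$enhancing_fraction - 0.4), 0.02)
  # enhancing compartment is the outer shell of the lesion
  expect_true(all(ph$enhancing_masks$L1$voxels <= ph$masks$L1$voxels))
})

test_that("noise-free phantoms are measured exactly; fraction extremes behave", {
  ph0 <- generate_phantom(quick_phantom_spec(fraction = 0, noise_sd = 0))
  m0 <- measure_lesion(ph0$arterial, ph0$unenhanced, ph0$masks$L1,
                       roi_spec(ph0$roi_center))
  expect_equal(m0$enhancing_volume_cm3, 0)
  expect_gt(m0$whole_volume_cm3, 0)
  ph1 <- generate_phantom(quick_phantom_spec(fraction = 1, noise_sd = 0))
  m1 <- measure_lesion(ph1$arterial, ph1$unenhanced, ph1$masks$L1,
                       roi_spec(ph1$roi_center))
  expect_equal(m1$enhancing_volume_cm3, m1$whole_volume_cm3)
})

test_that("infeasible fractions on tiny lesions raise a granularity error", {
  sp <- phantom_spec(shape = c(16L, 16L, 16L),
                     lesions = data.frame(lesion_id = "t", cx = 8, cy = 8, cz = 8,
                                          radius_mm = 1.4, enhancing_fraction = 0.4),
                     noise_sd = 0)
  expect_error(generate_phantom(sp), "granularity")
  bad <- data.frame(lesion_id = "o", cx = 2, cy = 8, cz = 8,
                    radius_mm = 5, enhancing_fraction = 0.5)
  expect_error(phantom_spec(shape = c(16L, 16L, 16L), lesions = bad), "beyond the grid")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- generate_phantom(quick_phantom_spec(noise_sd = 50, seed = 17))
  b <- generate_phantom(quick_phantom_spec(noise_sd = 50, seed = 17))
  expect_identical(a$arterial$values, b$arterial$values)
  expect_identical(a$unenhanced$values, b$unenhanced$values)
  c1 <- generate_cohort(cohort_sim_spec(n_patients = 30, seed = 5))
  c2 <- generate_cohort(cohort_sim_spec(n_patients = 30, seed = 5))
  expect_identical(c1$truth, c2$truth)
  t1 <- generate_trajectory(c("SD", "PR"), seed = 2)
  t2 <- generate_trajectory(c("SD", "PR"), seed = 2)
  expect_identical(t1, t2)
})

test_that("trajectories realize requested sequences and reject contradictions", {
  tr <- generate_trajectory("CR")
  expect_equal(tr$sum_enh_post_cm3, 0)
  expect_error(generate_trajectory(c("CR", "PR")), "contradictory")
  expect_error(generate_trajectory(c("CR", "SD")), "contradictory")
  expect_error(generate_trajectory(character(0)), "at least one")
  expect_error(generate_trajectory("XX"), "CR, PR, SD or PD")
  # regrowth after complete response is progression
  tr2 <- generate_trajectory(c("CR", "PD"), seed = 4)
  expect_equal(tr2$category, c("CR", "PD"))
  expect_gt(tr2$sum_enh_post_cm3[2], 0)
})

test_that("the preset worked case classifies SD then PR", {
  pre <- trajectory_preset_case()
  expect_equal(pre$sum_enh_ref_cm3, c(653.8, 401.9))
  cats <- vapply(seq_len(nrow(pre)), function(k)
    as.character(classify_response(pre$sum_enh_ref_cm3[k],
                                   pre$sum_enh_post_cm3[k])$category),
    character(1))
  expect_equal(cats, c("SD", "PR"))
})

test_that("cohort truth is internally consistent and matches its volumes", {
  co <- generate_cohort(cohort_sim_spec(n_patients = 94, seed = 7))
  expect_equal(nrow(co$truth), 94)
  # session-1 responder count within the binomial 95% band around 28/94
  n_resp1 <- sum(co$truth$category1 %in% c("CR", "PR"))
  p <- 0.032 + 0.266
  band <- qbinom(c(0.025, 0.975), 94, p)
  expect_gte(n_resp1, band[1]); expect_lte(n_resp1, band[2])
  # stored sums re-classify to the stored categories (truth consistency)
  for (pt in co$patients[1:20]) {
    s <- pt$sessions
    for (k in seq_len(nrow(s))) {
      got <- classify_response(s$sum_enh_ref_cm3[k], s$sum_enh_post_cm3[k])
      expect_equal(as.character(got$category), as.character(s$category[k]))
    }
  }
  # survival truth: observed time never exceeds true event time, event flag consistent
  expect_true(all(co$truth$time_months <= co$truth$true_time_months + 1e-12))
  expect_true(all(co$truth$event == (co$truth$time_months == co$truth$true_time_months)))
})

test_that("a null hazard ratio yields log-rank rejections near the nominal level", {
  co <- generate_cohort(cohort_sim_spec(n_patients = 400, hr_nonresponse = 1,
                                        censoring_rate = 0.2, seed = 19))
  tr <- co$truth
  a <- survival_records(tr$patient_id[tr$true_group == "responder"],
                        tr$time_months[tr$true_group == "responder"],
                        tr$event[tr$true_group == "responder"])
  b <- survival_records(tr$patient_id[tr$true_group == "non_responder"],
                        tr$time_months[tr$true_group == "non_responder"],
                        tr$event[tr$true_group == "non_responder"])
  expect_gt(logrank_test(a, b)$p, 0.01)
})
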