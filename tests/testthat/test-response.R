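test_that("target-lesion selection filters, ranks by diameter, caps at two", {
  lesions <- data.frame(lesion_id = c("a", "b", "c"),
                        diameter_cm = c(5, 3, 2),
                        therapy_naive = TRUE, artifact_free = TRUE)
  expect_equal(select_target_lesions(lesions), c("a", "b"))
  small <- data.frame(lesion_id = "x", diameter_cm = 0.9,
                      therapy_naive = TRUE, artifact_free = TRUE)
  expect_error(select_target_lesions(small), "no eligible")
  mixed <- data.frame(lesion_id = c("keep", "prior"),
                      diameter_cm = c(2, 4),
                      therapy_naive = c(TRUE, FALSE), artifact_free = TRUE)
  expect_equal(select_target_lesions(mixed), "keep")
  # deterministic tie-break by lesion id
  tie <- data.frame(lesion_id = c("z2", "z1", "z3"), diameter_cm = 3,
                    therapy_naive = TRUE, artifact_free = TRUE)
  expect_equal(select_target_lesions(tie), c("z1", "z2"))
})

test_that("percent change matches the worked two-session case", {
  expect_equal(percent_change(653.8, 401.9), -38.5, tolerance = 0.05)
  expect_equal(percent_change(401.9, 131.4), -67.3, tolerance = 0.05)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(0, 0), 0)        # sustained complete response
  expect_true(is.na(percent_change(0, 5)))     # regrowth from zero: undefined
  expect_error(percent_change(-1, 5), "non-negative")
})

test_that("response categories honor the closed 65/73 percent bounds", {
  cat_of <- function(ref, post) as.character(classify_response(ref, post)$category)
  expect_equal(cat_of(100, 35), "PR")     # -65.0%: boundary inclusive
  expect_equal(cat_of(100, 35.1), "SD")   # -64.9%
  expect_equal(cat_of(100, 173), "PD")    # +73.0%: boundary inclusive
  expect_equal(cat_of(100, 172.9), "SD")  # +72.9%
  expect_equal(cat_of(100, 0), "CR")
  expect_equal(cat_of(0, 7), "PD")        # enhancement reappearing from zero
  # worked case: stable disease after session 1, partial response after session 2
  expect_equal(cat_of(653.8, 401.9), "SD")
  expect_equal(cat_of(401.9, 131.4), "PR")
  # responder flag is CR or PR
  expect_true(classify_response(100, 0)$responder)
  expect_true(classify_response(100, 30)$responder)
  expect_false(classify_response(100, 80)$responder)
  expect_false(classify_response(100, 200)$responder)
})

test_that("category is monotone as the post volume decreases", {
  ord <- c(CR = 1, PR = 2, SD = 3, PD = 4)
  posts <- seq(250, 0, by = -5)
  cats <- vapply(posts, function(p) as.character(classify_response(100, p)$category),
                 character(1))
  expect_true(all(diff(ord[cats]) <= 0))
})

test_that("cr_epsilon absorbs residual single-voxel volumes", {
  expect_equal(as.character(classify_response(100, 0.004, cr_epsilon_cm3 = 0.005)$category),
               "CR")
  expect_equal(as.character(classify_response(100, 0.004)$category), "PR")
})

test_that("session labelling follows the retreatment-window flow", {
  mk <- function(cats, gap2 = NA, imaging = NULL) {
    s <- data.frame(session_index = seq_along(cats),
                    months_since_prev = c(NA, gap2)[seq_along(cats)],
                    category = cats)
    if (!is.null(imaging)) s$has_imaging <- imaging
    patient_record("p", s)
  }
  lab <- function(p) as.character(label_sessions(p)$label)
  expect_equal(lab(mk(c("SD", "PR"), gap2 = 0.8)), "secondary_responder")
  expect_equal(lab(mk("PR")), "initial_responder")
  expect_equal(lab(mk(c("CR", "PD"), gap2 = 1)), "initial_responder")
  expect_equal(lab(mk(c("SD", "PR"), gap2 = 3.5)), "excluded_window")
  expect_equal(lab(mk(c("SD", "SD"), gap2 = 1)), "non_responder")
  expect_equal(lab(mk("SD")), "non_responder")
  expect_equal(lab(mk(c("SD", NA), gap2 = 1, imaging = c(TRUE, FALSE))), "lost_followup")
  expect_error(patient_record("p", data.frame(session_index = c(2, 1),
                                              category = c("SD", "SD"))),
               "ordered")
})

test_that("ISO dates convert to months with 30.4375-day months", {
  m <- months_between_sessions(c("2020-01-01", "2020-01-25", "2020-07-01"))
  expect_true(is.na(m[1]))
  expect_equal(m[2], 24 / 30.4375)
  expect_equal(m[3], 158 / 30.4375)
  expect_error(months_between_sessions(c("2020-02-01", "2020-01-01")), "non-decreasing")
})

test_that("cohort flow conserves counts at every session", {
  expect_equal(nrow(cohort_flow(list())), 0)
  one <- patient_record("p1", data.frame(session_index = 1, category = "CR"))
  f1 <- cohort_flow(list(one))
  expect_equal(f1$n_treated, 1); expect_equal(f1$n_CR, 1); expect_equal(f1$n_responder, 1)
  co <- generate_cohort(cohort_sim_spec(n_patients = 60, seed = 11))
  fl <- cohort_flow(co$patients)
  for (k in seq_len(nrow(fl))) {
    expect_equal(fl$n_CR[k] + fl$n_PR[k] + fl$n_SD[k] + fl$n_PD[k] +
                   fl$n_no_imaging[k] + fl$n_excluded_window[k],
                 fl$n_treated[k])
    expect_equal(fl$n_responder[k] + fl$n_nonresponder[k],
                 fl$n_CR[k] + fl$n_PR[k] + fl$n_SD[k] + fl$n_PD[k])
    if (k > 1) expect_lte(fl$n_treated[k], fl$n_nonresponder[k - 1])
  }
  # exact count recovery against generator truth at session 1
  expect_equal(fl$n_CR[1], sum(co$truth$category1 == "CR"))
  expect_equal(fl$n_PR[1], sum(co$truth$category1 == "PR"))
  expect_equal(fl$n_SD[1], sum(co$truth$category1 == "SD"))
  expect_equal(fl$n_PD[1], sum(co$truth$category1 == "PD"))
})
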