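test_that("virtual surgery edits exactly the prescribed actuators", {
  m <- frontal_model()
  # identity scenario leaves the model untouched
  id_sc <- surgical_scenario(removed = character(0), psoas_factor = 1)
  m_id <- apply_surgery(m, id_sc)
  expect_identical(names(m_id$muscles), names(m$muscles))
  expect_identical(lapply(m_id$muscles, `[[`, "f_max"),
                   lapply(m$muscles, `[[`, "f_max"))
  # removal list shrinks the actuator set by exactly its length
  rem <- default_resection_list(m)
  m_cut <- apply_surgery(m, surgical_scenario(psoas_factor = 1))
  expect_equal(length(m_cut$muscles), length(m$muscles) - length(rem))
  expect_false(any(rem %in% names(m_cut$muscles)))
  # psoas scaling multiplies operated-side heads only, bit-exact elsewhere
  m_150 <- apply_surgery(m, surgical_scenario(removed = character(0),
                                              psoas_factor = 1.5))
  for (nm in names(m$muscles)) {
    mus <- m$muscles[[nm]]
    scaled <- startsWith(mus$group, "psoas") && mus$side == "operated"
    expect_identical(m_150$muscles[[nm]]$f_max,
                     mus$f_max * if (scaled) 1.5 else 1)
    expect_identical(m_150$muscles[[nm]]$geometry$coef, mus$geometry$coef)
  }
  # factor 0 removes the psoas heads entirely
  m_0 <- apply_surgery(m, surgical_scenario(removed = character(0),
                                            psoas_factor = 0))
  expect_false(any(grepl("^psoas_._r$", names(m_0$muscles))))
  expect_true(any(grepl("^psoas_._l$", names(m_0$muscles))))
  # idempotence
  m_cut2 <- apply_surgery(m_cut, surgical_scenario(removed = character(0),
                                                   psoas_factor = 1))
  expect_identical(names(m_cut2$muscles), names(m_cut$muscles))
  # unknown names are rejected with near-match hints
  expect_error(apply_surgery(m, surgical_scenario(removed = "glut_med_antr_r")),
               "did you mean")
  # contralateral removals are rejected
  expect_error(apply_surgery(m, surgical_scenario(removed = "glut_med_ant_l")),
               "non-operated")
})

test_that("synergy weights restrict to the post-surgery muscle set", {
  b <- planar_bundle()
  m2 <- apply_surgery(b$model,
                      surgical_scenario(removed = character(0),
                                        psoas_factor = 0))
  W2 <- restrict_synergy_weights(b$W, m2)
  expect_equal(rownames(W2), names(m2$muscles))
  expect_equal(ncol(W2), ncol(b$W))
})

test_that("identity treatment sweep reproduces the verification prediction", {
  b <- planar_bundle()
  pre <- planar_predict()
  sw <- identity_sweep()
  r <- sw$results[[1]]
  expect_equal(r$status, "success")
  # surgery-is-identity: solution matches the pre-surgery prediction
  # within solver tolerance
  expect_lt(abs(r$solution$T - pre$T) / pre$T, 0.01)
  expect_lt(rel_state_dev(r$solution, pre), 0.01)
  # comparison table carries both rows in the standard schema
  expect_equal(nrow(sw$comparison), 2)
  expect_true(all(c("cost_of_transport", "metabolic_cost",
                    "spatial_symmetry", "temporal_symmetry", "stance_width",
                    "stride_length", "stride_time") %in%
                    names(sw$comparison)))
  # identity sweep measures track the pre-surgery measures
  expect_lt(abs(sw$comparison$stride_length[2] -
                  sw$comparison$stride_length[1]), 0.02)
  # RMS-difference report on two identical solutions is identically zero
  z <- hemigait:::rms_diff_report(pre$q, pre$q, b$model$dof_names)
  expect_true(all(z$rms_difference == 0))
})

test_that("treatment sweep records non-convergence and continues", {
  b <- planar_bundle()
  pre <- planar_predict()
  # a 1-iteration budget cannot converge the resected problem; the sweep
  # must record the failure and still report the scenario
  sc <- surgical_scenario(removed = character(0), psoas_factor = 0.5)
  sw <- suppressWarnings(
    run_treatment_sweep(b$model, b, pre, list(sc), seeds = 1,
                        max_iter = 1, n_outer = 1))
  expect_length(sw$results, 1)
  expect_true(sw$results[[1]]$status %in% c("success", "failed"))
  if (sw$results[[1]]$status == "failed")
    expect_null(sw$results[[1]]$measures)
})
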