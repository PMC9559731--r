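test_that("transcription counts variables by the scheme formula", {
  b <- planar_bundle()
  m <- b$model
  d <- length(m$dofs); nsyn <- ncol(b$W)
  for (N in c(12, 20)) {
    for (kind in c("verification_track", "verification_predict")) {
      spec <- ocp_spec(kind, N = N)
      prob <- transcribe(spec, m, b)
      M <- N + 1
      expected <- M * 3 * d + M * d + M * nsyn +
        as.integer(spec$free_time)
      expect_equal(n_ocp_variables(prob), expected)
    }
  }
  # contact calibration adds three static parameters
  spec <- ocp_spec("contact_calibration", N = 12)
  prob <- transcribe(spec, m, b)
  expect_equal(n_ocp_variables(prob), 13 * (4 * 9 + 12) + 3)
  # unactuated coordinates add one reserve control per node
  f <- frontal_bundle()
  fm <- f$model
  specf <- ocp_spec("verification_track", N = 12)
  probf <- transcribe(specf, fm, f)
  d2 <- length(fm$dofs)
  n_res <- d2 - length(actuated_dofs(fm)) -
    length(fm$segments$pelvis$dofs)
  expect_equal(probf$nres, n_res)
  expect_equal(n_ocp_variables(probf),
               13 * (4 * d2 + 12 + n_res))
})

test_that("defects vanish on an exactly integrated cubic trajectory", {
  b <- planar_bundle()
  spec <- ocp_spec("verification_track", N = 12)
  prob <- transcribe(spec, b$model, b)
  d <- prob$d; M <- prob$M
  Tc <- b$T_cycle
  tt <- seq(0, Tc, length.out = M)
  # per-DOF cubic with constant jerk: q = a0 + a1 t + a2 t^2 + (j/6) t^3
  set.seed(12)
  a0 <- runif(d); a1 <- runif(d); a2 <- runif(d); j <- runif(d, -2, 2)
  P <- list(
    q = a0 + outer(a1, tt) + outer(a2, tt^2) + outer(j / 6, tt^3),
    qd = outer(a1, rep(1, M)) + 2 * outer(a2, tt) + outer(j / 2, tt^2),
    qdd = 2 * outer(a2, rep(1, M)) + outer(j, tt),
    u = outer(j, rep(1, M)),
    C = matrix(0.1, prob$nsyn, M), R = matrix(0, 0, M),
    statics = numeric(0), T = Tc)
  cv <- prob$lin_constraints(P)
  defects <- cv[seq_len(3 * d * spec$N)]
  expect_lt(max(abs(defects)), 1e-10)
})

test_that("zero-weight tracking at the reference seed has zero objective", {
  b <- planar_bundle()
  spec <- ocp_spec("verification_track", N = 12,
                   weights = list(q_track = 0, grf_track = 0, mom_track = 0,
                                  act_track = 0, c_track = 0, jerk = 0))
  prob <- transcribe(spec, b$model, b)
  X0 <- ocp_initial_guess(prob)
  P <- prob$unpack(X0)
  ev <- prob$nl_eval(P)
  expect_equal(hemigait:::tracking_objective(prob, P, ev), 0)
})

test_that("tracking solve reproduces the synthetic subject", {
  b <- planar_bundle()
  sol <- planar_track()
  expect_equal(sol$status, "success")
  M <- ncol(sol$q)
  qt <- hemigait:::resample_targets(b$q, M)
  # joint angles within one degree of the generator ground truth
  expect_lt(rms(sol$q - qt) * 180 / pi, 1)
  # ground reactions reproduced at the documented solve budget
  for (sd_ in c("operated", "non_operated")) {
    gref <- hemigait:::resample_targets(b$grf[[sd_]]$force, M)
    expect_lt(rms(sol$grf[[sd_]]$force - gref), 15)
  }
  # feasibility contract of a successful solution
  f <- sol$feasibility
  expect_lt(f$resid_force, 1)
  expect_lt(f$resid_moment, 1)
  expect_lt(f$moment_match, 2.5)
  expect_lt(f$periodicity, 1e-3)
})

test_that("free-final-time prediction pins the speed and periodicity", {
  sol <- planar_predict()
  track <- planar_track()
  expect_equal(sol$status, "success")
  # periodicity residual of joint angles at a successful solution
  expect_lt(sol$feasibility$periodicity, 1e-4 + 1e-6)
  # average-speed constraint: displacement = speed * T
  disp <- sol$q["pelvis_tx", ncol(sol$q)] - sol$q["pelvis_tx", 1]
  expect_equal(unname(disp), 1.4 * sol$T, tolerance = 1e-4)
})

test_that("contact calibration recovers stiffness from perturbed guesses", {
  b <- planar_bundle()
  cc <- contact_recovery()
  expect_true(cc$identifiable)
  # true multipliers are 1 (the bundle was generated with the model's own
  # contact parameters); stiffness recovered within 10%
  expect_lt(abs(cc$scales[1] - 1), 0.10)
  # zero-weight GRF tracking is flagged as unidentifiable
  expect_warning(
    calibrate_contact(b$model, b, N = 12,
                      weights = list(grf_track = 0),
                      max_iter = 1, n_outer = 1),
    "unidentifiable")
})
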