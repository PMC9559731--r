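# Shared fixtures, built once per test run and memoised.
# Everything is generated in code; nothing is read from disk.

rms <- function(x) sqrt(mean(x^2))

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

planar_model <- function() memo("planar_model", function() {
  make_fixture("planar9")
})

frontal_model <- function() memo("frontal_model", function() {
  make_fixture("frontal3d")
})

# the symmetric reference cycle (ground truth for most recovery tests)
planar_bundle <- function() memo("planar_bundle", function() {
  generate_gait(planar_model(), seed = 1, gn_iter = 120)
})

frontal_bundle <- function() memo("frontal_bundle", function() {
  generate_gait(frontal_model(), seed = 1, gn_iter = 130)
})

# two-link pendulum fixture (closed-form dynamics oracle)
two_link_model <- function(m1 = 3, m2 = 2, l1 = 0.4, c1 = 0.18, c2 = 0.2,
                           I1 = 0.03, I2 = 0.02) {
  segs <- list(
    list(name = "pelvis", parent = "ground", joint_loc = c(0, 0, 0),
         mass = m1, com = c(0, -c1, 0), inertia = diag(3) * I1,
         dofs = list(list(name = "q1", type = "rot", axis = c(0, 0, 1),
                          bounds = c(-10, 10)))),
    list(name = "link2", parent = "pelvis", joint_loc = c(0, -l1, 0),
         mass = m2, com = c(0, -c2, 0), inertia = diag(3) * I2,
         dofs = list(list(name = "q2", type = "rot", axis = c(0, 0, 1),
                          bounds = c(-10, 10)))))
  walker_model("two_link", segs)
}

# closed-form generalized forces of the two-link pendulum
two_link_tau <- function(q, w, a, m1 = 3, m2 = 2, l1 = 0.4, c1 = 0.18,
                         c2 = 0.2, I1 = 0.03, I2 = 0.02, g0 = 9.80665) {
  M11 <- I1 + I2 + m1 * c1^2 + m2 * (l1^2 + c2^2 + 2 * l1 * c2 * cos(q[2]))
  M12 <- I2 + m2 * (c2^2 + l1 * c2 * cos(q[2]))
  M22 <- I2 + m2 * c2^2
  h <- -m2 * l1 * c2 * sin(q[2])
  g1 <- m1 * g0 * c1 * sin(q[1]) +
    m2 * g0 * (l1 * sin(q[1]) + c2 * sin(q[1] + q[2]))
  g2 <- m2 * g0 * c2 * sin(q[1] + q[2])
  c(M11 * a[1] + M12 * a[2] + h * (2 * w[1] * w[2] + w[2]^2) + g1,
    M12 * a[1] + M22 * a[2] - h * w[1]^2 + g2)
}

# a single-hinge test muscle with linear geometry
hinge_muscle <- function(r = 0.05, l0 = 0.3, f_max = 1000, ...) {
  muscle_spec("hinge", "operated", f_max = f_max, l_opt = 0.4 * l0,
              l_slack = 0.6 * l0,
              geometry = surrogate_geometry(1, matrix(c(0, 1), 2, 1),
                                            c(l0, -r)),
              ...)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-12), tol)
}

# shared collocation solutions (the expensive artifacts), memoised
planar_track <- function() memo("planar_track", function() {
  b <- planar_bundle()
  spec <- ocp_spec("verification_track", N = 32,
                   weights = list(grf_track = 10))
  prob <- transcribe(spec, b$model, b)
  solve_ocp(prob, max_iter = 35, n_outer = 1)
})

planar_predict <- function() memo("planar_predict", function() {
  b <- planar_bundle()
  track <- planar_track()
  spec <- ocp_spec("verification_predict", N = 32, speed = b$speed)
  prob <- transcribe(spec, b$model, b)
  track$T_cycle <- track$T
  solve_ocp(prob, guess = ocp_initial_guess(prob, from = track),
            max_iter = 30, n_outer = 1)
})

# mean per-DOF RMS deviation as a fraction of each DOF's cycle range
rel_state_dev <- function(sol, ref) {
  rng <- apply(ref$q, 1, function(x) diff(range(x)))
  mean(apply(sol$q - ref$q, 1, rms) / rng)
}

# identity-scenario treatment sweep (shared by surgery and acceptance tests)
identity_sweep <- function() memo("identity_sweep", function() {
  b <- planar_bundle()
  pre <- planar_predict()
  run_treatment_sweep(b$model, b, pre,
                      list(surgical_scenario(removed = character(0),
                                             psoas_factor = 1)),
                      seeds = 1, max_iter = 20, n_outer = 1)
})

# contact calibration from perturbed guesses (shared)
contact_recovery <- function() memo("contact_recovery", function() {
  b <- planar_bundle()
  calibrate_contact(b$model, b, N = 14, guess_scales = c(1.2, 0.8, 1.2),
                    max_iter = 18, n_outer = 1)
})

# EMG-driven calibration recovery at zero noise (shared); the trials are
# manufactured to be exactly consistent with the true parameters
emg_recovery <- function() memo("emg_recovery", function() {
  m <- planar_model()
  idx <- c(1, 7, 9)   # glut_max, vasti, soleus: one per joint
  true_mus <- m$muscles[idx]
  dt <- 0.011; Tn <- 101
  make_trial <- function(seed) {
    set.seed(seed)
    tt <- (seq_len(Tn) - 1) * dt
    q <- matrix(0.1, 9, Tn)
    q[4:9, ] <- 0.15 * sin(outer(runif(6, 1, 3), tt * 2 * pi / 1.1)) +
      matrix(c(0.2, -1, 0.25, 0.2, -1, 0.25), 6, Tn)
    qd <- rbind(matrix(0, 3, Tn),
                t(apply(q[4:9, ], 1, function(x) c(diff(x) / dt, 0))))
    e <- t(vapply(seq_along(idx), function(j)
      pmin(pmax(0.45 + 0.35 * sin(2 * pi * (2 + j) * tt / 1.1 + j), 0), 1),
      numeric(Tn)))
    a <- matrix(0, length(idx), Tn)
    tf <- seq(0, (Tn - 1) * dt, by = 0.002)
    for (j in seq_along(idx)) {
      ef <- approx(tt, e[j, ], xout = tf, rule = 2)$y
      af <- excitation_to_activation(ef, 0.002, true_mus[[j]])
      a[j, ] <- approx(tf, af, xout = tt, rule = 2)$y
    }
    mom <- hemigait:::moments_of_muscles(true_mus, m$curves, q, qd, a, 9)
    list(q = q, qd = qd, moments = mom, emg = e, dt = dt)
  }
  m_pert <- m
  for (j in idx) {
    m_pert$muscles[[j]]$emg_scale <- m$muscles[[j]]$emg_scale * 0.92
    m_pert$muscles[[j]]$emg_delay <- m$muscles[[j]]$emg_delay * 1.1
    m_pert$muscles[[j]]$tau_act <- m$muscles[[j]]$tau_act * 1.1
    m_pert$muscles[[j]]$tau_deact <- m$muscles[[j]]$tau_deact * 0.9
  }
  fit <- calibrate_emg_driven(m_pert, lapply(c(31, 32), make_trial),
                              muscle_idx = idx,
                              free = c("emg_scale", "emg_delay",
                                       "tau_act", "tau_deact"),
                              max_iter = 40)
  list(fit = fit, true_mus = true_mus, idx = idx)
})
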