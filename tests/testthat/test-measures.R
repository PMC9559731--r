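test_that("symmetry ratios follow their printed definitions", {
  expect_equal(spatial_symmetry(0.60, 1.20), 0.5)
  expect_equal(spatial_symmetry(0.70, 1.20), 0.70 / 1.20)
  expect_equal(temporal_symmetry(0.53, 1.06), 0.5)
  expect_equal(temporal_symmetry(0.47 * 1.05, 1.05), 0.47)
  expect_error(spatial_symmetry(0.6, 0), "positive")
  expect_error(temporal_symmetry(0.5, -1), "positive")
})

test_that("cost of transport is energy per unit mass and distance", {
  expect_equal(cost_of_transport(1, 1, 1), 1)
  m <- 66.7; d <- 1.55
  expect_equal(cost_of_transport(m * d, m, d), 1)
  # internal identity: CoT * mass * distance reproduces the energy
  E <- 612.3
  expect_equal(cost_of_transport(E, m, d) * m * d, E, tolerance = 1e-9)
  expect_error(cost_of_transport(100, 0, 1), "positive")
})

test_that("spatiotemporal metrics follow the event definitions", {
  ev <- list(operated = list(times = c(0, 1.2), heel_x = c(0, 1.4)),
             non_operated = list(times = 0.55, heel_x = 0.65))
  st <- spatiotemporal_from_events(ev)
  expect_equal(st$stride_length, 1.4)
  expect_equal(st$stride_time, 1.2)
  expect_equal(st$step_length$non_operated, 0.65)
  expect_equal(st$step_length$operated, 0.75)
  # step lengths sum to the stride length (definition identity)
  expect_equal(st$step_length$operated + st$step_length$non_operated,
               st$stride_length, tolerance = 1e-9)
  expect_equal(st$step_time$operated + st$step_time$non_operated,
               st$stride_time, tolerance = 1e-9)
  # stance width from per-side flat windows, stationary feet 0.2 m apart
  hz <- list(operated = rep(0.1, 10), non_operated = rep(-0.1, 10),
             flat_operated = c(rep(TRUE, 5), rep(FALSE, 5)),
             flat_non_operated = c(rep(FALSE, 5), rep(TRUE, 5)))
  st2 <- spatiotemporal_from_events(ev, heel_z = hz)
  expect_equal(st2$stance_width, 0.2)
  # treadmill belt compensation adds belt travel to displacements
  stb <- spatiotemporal_from_events(ev, belt_speed = 1)
  expect_equal(stb$stride_length, 1.4 + 1.2)
  # missing contralateral event flagged
  ev2 <- ev; ev2$non_operated$times <- 5
  expect_warning(st3 <- spatiotemporal_from_events(ev2), "undefined")
  expect_true(is.na(st3$step_length$operated))
})

test_that("metabolic model matches hand-evaluated heat and work terms", {
  # one hinge muscle held isometric: the work term is exactly zero and the
  # total equals the integral of the hand-computed heat terms
  seg <- list(list(name = "pelvis", parent = "ground", joint_loc = c(0, 0, 0),
                   mass = 1, com = c(0, 0, 0), inertia = diag(3),
                   dofs = list(list(name = "hinge", type = "rot",
                                    axis = c(0, 0, 1), bounds = c(-1, 1)))))
  mus <- hinge_muscle(r = 0.05, l0 = 0.3, f_max = 1000)
  mus$geometry$dofs <- "hinge"
  mdl <- walker_model("one", seg, list(mus))
  spec <- metabolic_spec()
  Tn <- 51
  time <- seq(0, 0.5, length.out = Tn)
  theta <- (0.3 - (mus$l_slack + mus$l_opt)) / 0.05  # lnorm = 1
  q <- matrix(theta, 1, Tn); qd <- matrix(0, 1, Tn)
  a <- matrix(0.6, 1, Tn)
  out <- metabolic_cost(mdl, q, qd, a, time, spec)
  mass <- spec$rho * (1000 / spec$sigma) * mus$l_opt
  rate_hand <- mass * (spec$decay_act[1] * 0.5 * sin(pi / 2 * 0.6) +
                         spec$decay_act[2] * 0.5 * (1 - cos(pi / 2 * 0.6))) +
    mass * 1 * (spec$decay_maint[1] * 0.5 * sin(pi / 2 * 0.6) +
                  spec$decay_maint[2] * 0.5 * (1 - cos(pi / 2 * 0.6)))
  expect_equal(out$total, rate_hand * 0.5, tolerance = 1e-9)
  # zero activation, no movement, basal off: zero cost
  out0 <- metabolic_cost(mdl, q, qd, a * 0, time, spec)
  expect_equal(out0$total, 0)
  # concentric work identity: constant force and shortening speed
  # contribute F * v * t of mechanical work
  qd2 <- matrix(0.2, 1, Tn)   # shortening at 0.01 m/s (arm 0.05)
  out2 <- metabolic_cost(mdl, q, qd2, a, time, spec)
  st <- hemigait:::rigid_tendon_state(mus, 0.3 - 0.05 * theta, -0.05 * 0.2)
  Fce <- 1000 * 0.6 * mdl$curves$fl_active(st$lnorm) *
    mdl$curves$fv(st$vnorm / mdl$curves$vmax)
  v_fiber <- st$vnorm * mus$l_opt
  w_expect <- -Fce * v_fiber * 0.5   # positive work over the window
  alpha <- 1000 * 0.6 * mdl$curves$fl_active(st$lnorm)
  heat_sl <- -(0.16 * alpha + 0.18 * Fce) * v_fiber * 0.5
  expect_equal(out2$total - out$total -
                 (heat_sl + w_expect),
               0, tolerance = out$total * 0.02)
  # metabolic cost is monotone under uniform activation scaling
  outs <- vapply(c(0.6, 0.8, 1), function(s)
    metabolic_cost(mdl, q, qd, a * s / 0.6, time, spec)$total, 0)
  expect_true(all(diff(outs) > 0))
})

test_that("measure rows keep the internal CoT identity", {
  b <- planar_bundle()
  st <- measures_from_bundle(b)
  met <- metabolic_cost(b$model, b$q, b$qd, b$activations, b$time)
  gm <- gait_measures(st, metabolic = met, body_mass = model_mass(b$model))
  expect_equal(gm$cost_of_transport * model_mass(b$model) * gm$stride_length,
               gm$metabolic_cost, tolerance = 1e-9)
  expect_s3_class(gm, "gait_measures")
})
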