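test_that("inverse dynamics matches the closed-form two-link equations", {
  mdl <- two_link_model()
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    q <- runif(2, -2, 2); w <- runif(2, -3, 3); a <- runif(2, -5, 5)
    tau <- inverse_dynamics(mdl, matrix(q, 2, 1), matrix(w, 2, 1),
                            matrix(a, 2, 1))
    ref <- two_link_tau(q, w, a)
    worst <- max(worst, max(abs(as.numeric(tau) - ref)))
  }
  expect_lt(worst, 1e-8)
})

test_that("static pose residuals equal model weight; zero gravity gives zeros", {
  m <- planar_model()
  q <- matrix(0, 9, 1); q[2] <- 1.5   # standing tall, feet clear of ground
  tau <- inverse_dynamics(m, q, q * 0, q * 0)
  expect_equal(unname(tau["pelvis_ty", 1]), model_mass(m) * 9.80665,
               tolerance = 1e-9)
  expect_equal(unname(tau["pelvis_tx", 1]), 0, tolerance = 1e-9)
  m0 <- m; m0$gravity <- c(0, 0, 0)
  tau0 <- inverse_dynamics(m0, q, q * 0, q * 0)
  expect_lt(max(abs(tau0)), 1e-10)
})

test_that("residuals agree with the free-body total momentum-rate oracle", {
  b <- planar_bundle()
  m <- b$model
  kin <- body_kinematics(m, b$q, b$qd, b$qdd)
  # total COM acceleration from the per-segment kinematics
  masses <- vapply(m$segments, `[[`, 0, "mass")
  acom <- matrix(0, 3, ncol(b$q))
  for (s in m$segments) {
    bk <- kin$bodies[[s$name]]
    rc <- rot_apply(bk$R, s$com)
    acom <- acom + s$mass *
      (bk$a + cross3(bk$alpha, rc) + cross3(bk$omega, cross3(bk$omega, rc)))
  }
  Fg <- sum(masses) * m$gravity
  Fgrf <- b$grf$operated$force + b$grf$non_operated$force
  resid_pred <- acom - Fg - Fgrf
  resid <- residual_loads(m, b$tau)
  expect_lt(max(abs(resid[1, ] - resid_pred[1, ])), 1e-6)
  expect_lt(max(abs(resid[2, ] - resid_pred[2, ])), 1e-6)
})

test_that("jerk chain derivative and integration behave as a triple integrator", {
  x <- list(q = c(1, 2), qd = c(0.5, -1), qdd = c(0.1, 0.2))
  u <- c(3, -3)
  dx <- jerk_state_derivative(x, u)
  expect_equal(dx$q, x$qd)
  expect_equal(dx$qd, x$qdd)
  expect_equal(dx$qdd, u)
  # constant jerk integrates to a cubic with leading coefficient j/6
  integrate_jerk <- function(x0, u_fn, tt) {
    n <- length(tt); dt <- tt[2] - tt[1]
    out <- matrix(0, 3, n); out[, 1] <- unlist(x0)
    for (k in seq_len(n - 1)) {
      # RK4 on the linear chain with stage-time forcing
      f <- function(s, tcur) c(s[2], s[3], u_fn(tcur))
      s <- out[, k]
      k1 <- f(s, tt[k]); k2 <- f(s + dt / 2 * k1, tt[k] + dt / 2)
      k3 <- f(s + dt / 2 * k2, tt[k] + dt / 2)
      k4 <- f(s + dt * k3, tt[k] + dt)
      out[, k + 1] <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out
  }
  tt <- seq(0, 1, by = 0.01)
  traj <- integrate_jerk(list(0, 0, 0), function(t) 6, tt)
  expect_lt(max(abs(traj[1, ] - tt^3)), 1e-10)
  # refinement: dt vs dt/10 agree to high order for a smooth jerk profile
  u_fn <- function(t) sin(2 * pi * t)
  c1 <- integrate_jerk(list(0, 0, 0), u_fn, seq(0, 1, by = 0.02))
  c2 <- integrate_jerk(list(0, 0, 0), u_fn, seq(0, 1, by = 0.002))
  expect_lt(abs(c1[1, ncol(c1)] - c2[1, ncol(c2)]), 1e-5)
})

test_that("forward-integrated torques are recovered by inverse dynamics", {
  mdl <- two_link_model()
  # forward-integrate known torques with the closed-form dynamics, then
  # check the package's RNEA recovers them along the trajectory
  tau_fn <- function(t) c(2 * sin(2 * t), cos(3 * t))
  dt <- 1e-4
  tt <- seq(0, 1, by = dt)
  q <- matrix(0, 2, length(tt)); qd <- matrix(0, 2, length(tt))
  qdd <- matrix(0, 2, length(tt))
  M_of <- function(q2) {
    m1 <- 3; m2 <- 2; l1 <- 0.4; c1 <- 0.18; c2 <- 0.2; I1 <- 0.03; I2 <- 0.02
    M11 <- I1 + I2 + m1 * c1^2 + m2 * (l1^2 + c2^2 + 2 * l1 * c2 * cos(q2))
    M12 <- I2 + m2 * (c2^2 + l1 * c2 * cos(q2))
    matrix(c(M11, M12, M12, I2 + m2 * c2^2), 2, 2)
  }
  for (k in seq_along(tt)) {
    rhs <- tau_fn(tt[k]) - two_link_tau(q[, k], qd[, k], c(0, 0))
    qdd[, k] <- solve(M_of(q[, k][2]), rhs)
    if (k < length(tt)) {
      qd[, k + 1] <- qd[, k] + dt * qdd[, k]
      q[, k + 1] <- q[, k] + dt * qd[, k] + dt^2 / 2 * qdd[, k]
    }
  }
  pick <- seq(1, length(tt), by = 500)
  tau_rec <- inverse_dynamics(mdl, q[, pick], qd[, pick], qdd[, pick])
  ref <- vapply(pick, function(k) tau_fn(tt[k]), numeric(2))
  expect_lt(max(abs(tau_rec - ref)), 1e-3)
})
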