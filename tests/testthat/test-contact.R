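test_that("normal force follows the spring-damper law with smooth clamping", {
  el <- contact_element(c(0, 0, 0), k = 2e4, c = 1.5)
  # above ground
  expect_equal(normal_force(el, -0.01), 0, tolerance = 1e-12)
  # static arithmetic (smoothing negligible at 5 mm)
  expect_equal(normal_force(el, 0.005), 2e4 * 0.005, tolerance = 1e-3)
  # hand evaluation including the damping clamp boundary
  expect_equal(normal_force(el, 0.005, -0.5),
               max(0, 2e4 * 0.005 * (1 + 1.5 * -0.5)), tolerance = 1e-3)
  expect_equal(normal_force(el, 0.005, -0.9), 0)   # 1 + c*ddot < 0 clamps
  # continuity across the contact boundary
  d <- seq(-5e-4, 5e-4, length.out = 400)
  F <- normal_force(el, d)
  expect_lt(max(abs(diff(F))), 2e4 * 2e-4)
})

test_that("friction is odd, zero at rest, and saturates at mu_d * F_n", {
  el <- contact_element(c(0, 0, 0), mu_d = 0.8, mu_v = 0, v_t = 0.05)
  expect_equal(friction_force(el, 100, matrix(0, 2, 1)),
               matrix(0, 2, 1))
  # tanh asymptote: within 1% of mu_d F_n at |v| = 3 v_t
  f <- friction_force(el, 100, matrix(c(3 * 0.05, 0), 2, 1))
  expect_lt(abs(sqrt(sum(f^2)) - 0.8 * 100) / (0.8 * 100), 0.01)
  # odd symmetry over random slip directions
  set.seed(4)
  for (i in 1:20) {
    v <- matrix(rnorm(2, sd = 0.1), 2, 1)
    expect_equal(friction_force(el, 50, v),
                 -friction_force(el, 50, -v), tolerance = 1e-12)
  }
})

test_that("grid reactions sum elements and locate the center of pressure", {
  mk <- function(x, z) contact_element(c(x, 0, z), k = 1e4)
  grid <- contact_grid("operated", "foot",
                       rear = list(mk(-0.05, -0.02), mk(-0.05, 0.02)),
                       toes = list(mk(0.05, -0.02), mk(0.05, 0.02)))
  R <- rot_identity <- diag(3)
  # flat foot, equal penetration: resultant through grid centroid
  o <- c(0.3, -0.004, 0.1)
  out <- grid_reactions(grid, diag(3), o, rep(0, 3), rep(0, 3))
  expect_equal(out$cop[1, 1], 0.3, tolerance = 1e-9)
  expect_equal(out$cop[3, 1], 0.1, tolerance = 1e-9)
  expect_equal(out$force[2, 1], 4 * 1e4 * 0.004, tolerance = 1)
  # single element: cop at its ground projection
  g1 <- contact_grid("operated", "foot", rear = list(mk(-0.05, 0.01)),
                     toes = list(contact_element(c(0.05, 1, 0))))  # airborne
  out1 <- grid_reactions(g1, diag(3), o, rep(0, 3), rep(0, 3))
  expect_equal(out1$cop[1, 1], 0.25, tolerance = 1e-6)
  # unloaded foot: cop undefined and flagged
  out2 <- grid_reactions(grid, diag(3), c(0, 0.05, 0), rep(0, 3), rep(0, 3))
  expect_false(out2$cop_defined[1])
  expect_true(is.na(out2$cop[1, 1]))
})

test_that("rolling-contact reactions match a brute-force element summation", {
  m <- planar_model()
  grid <- m$contact[[1]]
  Tn <- 25
  th <- seq(-0.2, 0.3, length.out = Tn)
  R <- rot_axis(c(0, 0, 1), th)
  o <- rbind(seq(0, 0.3, length.out = Tn),
             0.068 + 0.01 * sin(seq(0, pi, length.out = Tn)),
             rep(0.09, Tn))
  om <- rbind(rep(0, Tn), rep(0, Tn), rep(0.5, Tn))
  v <- rbind(rep(0.3, Tn), rep(-0.05, Tn), rep(0, Tn))
  out <- grid_reactions(grid, R, o, om, v)
  # independent brute-force summation, element by element, sample by sample
  Fb <- matrix(0, 3, Tn); Mb <- matrix(0, 3, Tn)
  for (el in c(grid$rear, grid$toes)) {
    for (t in seq_len(Tn)) {
      pw <- o[, t] + R[, , t] %*% el$pos
      vw <- v[, t] + pracma::cross(om[, t], as.numeric(R[, , t] %*% el$pos))
      dn <- -pw[2]; dd <- -vw[2]
      Fn <- max(0, el$k * 1e-4 * log1p(exp(min(dn / 1e-4, 30))) *
                  (1 + el$c * dd))
      if (dn / 1e-4 > 30) Fn <- max(0, el$k * dn * (1 + el$c * dd))
      sp <- sqrt(vw[1]^2 + vw[3]^2)
      mag <- Fn * (el$mu_d * tanh(sp / el$v_t) + el$mu_v * sp)
      ft <- if (sp > 0) -mag * c(vw[1], vw[3]) / sp else c(0, 0)
      f <- c(ft[1], Fn, ft[2])
      Fb[, t] <- Fb[, t] + f
      Mb[, t] <- Mb[, t] + pracma::cross(as.numeric(pw), f)
    }
  }
  expect_equal(out$force, Fb, tolerance = 1e-10)
  expect_equal(out$moment, Mb, tolerance = 1e-10)
})

test_that("contact work over a closed penetration cycle dissipates energy", {
  el <- contact_element(c(0, 0, 0), k = 2e4, c = 1.5)
  t <- seq(0, 1, length.out = 2000)
  delta <- 0.003 * sin(2 * pi * t)         # closed loop
  ddot <- 0.003 * 2 * pi * cos(2 * pi * t)
  F <- normal_force(el, delta, ddot)
  # work done BY the ground on the foot over the loop is non-positive
  W <- sum(F * ddot) * (t[2] - t[1]) * -1
  expect_lte(W, 0)
})
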