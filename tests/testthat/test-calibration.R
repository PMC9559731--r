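test_that("Latin-hypercube poses stratify every dimension", {
  p1 <- latin_hypercube_poses(matrix(c(0, 1), 1, 2), 4, seed = 1)
  expect_equal(sort(findInterval(p1[, 1], seq(0, 1, 0.25),
                                 rightmost.closed = TRUE)), 1:4)
  # determinism
  expect_identical(latin_hypercube_poses(matrix(c(0, 1), 1, 2), 4, seed = 1),
                   p1)
  # counting oracle: n = 1000 in 3-D, one sample per bin per dimension
  bounds <- cbind(c(-1, 0, 2), c(1, 3, 5))
  p <- latin_hypercube_poses(bounds, 1000, seed = 2)
  for (j in 1:3) {
    bins <- findInterval(p[, j],
                         seq(bounds[j, 1], bounds[j, 2], length.out = 1001),
                         rightmost.closed = TRUE)
    expect_equal(sort(bins), 1:1000)
  }
})

test_that("muscle-head reduction matches exhaustive enumeration with NNLS", {
  # 5-head fan sharing one DOF with distinct moment arms and strengths
  mk_head <- function(i) {
    r <- 0.03 + 0.01 * i
    muscle_spec(paste0("head_", i), "operated", group = "fan",
                f_max = 500 + 150 * i, l_opt = 0.09, l_slack = 0.14,
                geometry = surrogate_geometry(
                  1, matrix(c(0, 1, 2), 3, 1),
                  c(0.23 + 0.005 * i, -r, 0.002 * i)))
  }
  heads <- lapply(1:5, mk_head)
  bounds <- matrix(c(-0.6, 0.9), 1, 2)
  red <- reduce_muscle_heads(heads, bounds, target_heads = 2,
                             n_poses = 200, seed = 5, subsets = "all")
  # independent oracle: hand-evaluated polynomial geometry and Hill curves
  # over the same pose set, dense NNLS over every C(5,2) subset
  poses <- latin_hypercube_poses(bounds, 200, seed = 5)[, 1]
  phi <- sapply(1:5, function(i) {
    r <- 0.03 + 0.01 * i
    len <- 0.23 + 0.005 * i - r * poses + 0.002 * i * poses^2
    arm <- r - 2 * 0.002 * i * poses
    l_opt <- 0.09; l_slack <- 0.14
    lnorm <- pmax(len - l_slack, 0.01 * l_opt) / l_opt
    fl <- exp(-(lnorm - 1)^2 / 0.45)
    fp <- ifelse(lnorm <= 1, 0,
                 (exp(4 * (lnorm - 1) / 0.6) - 1) / (exp(4) - 1))
    arm * (fl + fp)
  })
  M0 <- phi %*% (500 + 150 * (1:5))
  best <- NULL
  for (S in utils::combn(5, 2, simplify = FALSE)) {
    fit <- pracma::lsqnonneg(phi[, S], as.numeric(M0))
    r <- sqrt(mean((phi[, S] %*% fit$x - M0)^2))
    if (is.null(best) || r < best$rms)
      best <- list(S = S, f = fit$x, rms = r)
  }
  expect_equal(red$retained, best$S)
  expect_lt(max(abs(red$f_max - best$f)), 1e-8)
  expect_lt(abs(red$rms - best$rms), 1e-8)
  # the admissible-spacing rule retains the anatomic extremes
  red2 <- reduce_muscle_heads(heads, bounds, target_heads = 2,
                              n_poses = 200, seed = 5)
  expect_equal(red2$retained, c(1, 5))
})

test_that("head reduction identities: full retention and duplicate heads", {
  mk_head <- function(i, r, f) {
    muscle_spec(paste0("h", i), "operated", group = "g",
                f_max = f, l_opt = 0.09, l_slack = 0.14,
                geometry = surrogate_geometry(1, matrix(c(0, 1), 2, 1),
                                              c(0.23, -r)))
  }
  heads <- list(mk_head(1, 0.04, 800), mk_head(2, 0.05, 600),
                mk_head(3, 0.06, 400))
  bounds <- matrix(c(-0.5, 0.8), 1, 2)
  full <- reduce_muscle_heads(heads, bounds, target_heads = 3,
                              n_poses = 60, seed = 1)
  expect_equal(full$retained, 1:3)
  expect_lt(max(abs(full$f_max - c(800, 600, 400))), 1e-6)
  expect_lt(full$rms, 1e-9)
  # two geometrically identical heads collapse to the strength sum
  twins <- list(mk_head(1, 0.05, 700), mk_head(2, 0.05, 300))
  red <- reduce_muscle_heads(twins, bounds, target_heads = 1,
                             n_poses = 40, seed = 1)
  expect_equal(length(red$retained), 1)
  expect_lt(abs(red$f_max - 1000), 1e-6)
  expect_lt(red$rms, 1e-9)
  # nested subsets: RMS non-increasing with retained-head count
  five <- lapply(1:5, function(i) mk_head(i, 0.03 + 0.01 * i, 500))
  rms_by_k <- vapply(c(2, 3, 5), function(k)
    reduce_muscle_heads(five, bounds, target_heads = k,
                        n_poses = 100, seed = 2)$rms, 0)
  expect_true(all(diff(rms_by_k) <= 1e-10))
})

test_that("EMG-driven calibration recovers known parameters at zero noise", {
  rec <- emg_recovery()
  fit <- rec$fit
  for (j in seq_along(rec$idx)) {
    tm <- rec$true_mus[[j]]
    for (p in c("emg_scale", "emg_delay", "tau_act", "tau_deact"))
      expect_lt(abs(fit$muscles[[j]][[p]] - tm[[p]]) / tm[[p]], 0.02)
  }
  expect_lt(mean(unlist(fit$rms_per_dof)), 0.1)
  # peak isometric strengths never enter the design vector
  expect_identical(vapply(fit$muscles, `[[`, 0, "f_max"),
                   vapply(rec$true_mus, `[[`, 0, "f_max"))
  # accepted deviance trace is non-increasing (optimizer descent log)
  expect_true(all(diff(fit$deviance_trace) <= 1e-9))
})

test_that("calibration at the optimum returns essentially unchanged", {
  m <- planar_model()
  idx <- 9
  dt <- 0.011; Tn <- 101
  tt <- (seq_len(Tn) - 1) * dt
  q <- matrix(0.1, 9, Tn); q[6, ] <- 0.25 + 0.2 * sin(2 * pi * tt / 1.1)
  qd <- q * 0; qd[6, ] <- c(diff(q[6, ]) / dt, 0)
  e <- matrix(pmin(pmax(0.5 + 0.3 * sin(2 * pi * 3 * tt / 1.1), 0), 1), 1)
  tfine <- seq(0, (Tn - 1) * dt, by = 0.002)
  ef <- approx(tt, e[1, ], xout = tfine, rule = 2)$y
  af <- excitation_to_activation(ef, 0.002, m$muscles[[idx]])
  a <- matrix(approx(tfine, af, xout = tt, rule = 2)$y, 1)
  mom <- hemigait:::moments_of_muscles(m$muscles[idx], m$curves, q, qd, a, 9)
  fit <- calibrate_emg_driven(m, list(list(q = q, qd = qd, moments = mom,
                                           emg = e, dt = dt)),
                              muscle_idx = idx,
                              free = c("emg_scale", "emg_delay"),
                              max_iter = 10)
  expect_lt(abs(fit$params["emg_scale", 1] -
                  m$muscles[[idx]]$emg_scale), 1e-4)
  expect_lt(abs(fit$params["emg_delay", 1] -
                  m$muscles[[idx]]$emg_delay), 1e-4)
})
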