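test_that("NMF recovers exact factorizations and VAF grows with k", {
  set.seed(21)
  W0 <- matrix(runif(12 * 2), 12, 2)
  C0 <- matrix(runif(2 * 101), 2, 101)
  A <- W0 %*% C0
  fit <- extract_synergies(A, 2, seed = 1, restarts = 5)
  expect_gte(fit$vaf, 0.999)
  # unit-norm renormalization leaves the product unchanged
  expect_true(all(abs(sqrt(colSums(fit$W^2)) - 1) < 1e-9))
  expect_lt(max(abs(fit$W %*% fit$C - A)) / max(A), 0.05)
  # nested feasibility: VAF non-decreasing in k (best of restarts)
  vafs <- vapply(1:4, function(k)
    extract_synergies(A, k, seed = 2, restarts = 4)$vaf, 0)
  expect_true(all(diff(vafs) > -1e-6))
  expect_error(extract_synergies(-A, 2), "non-negative")
})

test_that("six synergies explain a 6-synergy synthetic set at 98% VAF", {
  set.seed(22)
  W0 <- matrix(0, 12, 6)
  for (k in 1:6) W0[sample(12, 4), k] <- runif(4, 0.3, 1)
  s <- seq(0, 1, length.out = 101)
  C0 <- t(vapply(1:6, function(k)
    exp(-((s - (k - 1) / 6) %% 1 / 0.12)^2), numeric(101)))
  A <- W0 %*% C0
  A <- A * (1 + 0.02 * matrix(rnorm(length(A)), nrow(A)))
  A <- pmax(A, 0)
  vaf6 <- extract_synergies(A, 6, seed = 3, restarts = 8)$vaf
  expect_gte(vaf6, 0.98)
  vaf_k <- vapply(c(1, 2, 4, 6), function(k)
    extract_synergies(A, k, seed = 3, restarts = 4)$vaf, 0)
  expect_true(all(diff(vaf_k) > 0))
})

test_that("synergy weights of unmeasured muscles are recovered from moments", {
  # fixed synergy activations, two unmeasured muscles with known weights;
  # their moment contributions generate the target and must be recovered
  set.seed(23)
  k <- 3; Tn <- 101
  C <- pmax(matrix(rnorm(k * Tn, 0.4, 0.2), k, Tn), 0)
  nm <- 2; ndt <- 2
  B <- array(rnorm(ndt * nm * Tn, sd = 10), c(ndt, nm, Tn))
  W_true <- matrix(runif(nm * k, 0.1, 0.8), nm, k)
  Mtarget <- sapply(seq_len(Tn), function(t)
    B[, , t] %*% (W_true %*% C[, t]))
  fit <- estimate_missing_activations(C, Mtarget, B, lambda1 = 1e-6,
                                      lambda2 = 0)
  expect_lt(hemigait:::rms(fit$W - W_true) / hemigait:::rms(W_true), 0.05)
  expect_lt(fit$moment_rms, 0.05 * fit$baseline_rms)
  # zero moments with a magnitude penalty drive all weights to zero
  fit0 <- estimate_missing_activations(C, Mtarget * 0, B, lambda1 = 1e-2)
  expect_lt(max(fit0$W), 1e-6)
  # single-muscle analytic check against the normal-equations oracle
  B1 <- B[, 1, , drop = FALSE]
  M1 <- sapply(seq_len(Tn), function(t) B1[, , t] * sum(W_true[1, ] * C[, t]))
  f1 <- estimate_missing_activations(C, M1, B1, lambda1 = 0, lambda2 = 0)
  G <- t(sapply(seq_len(Tn), function(t)
    kronecker(t(C[, t]), B1[, 1, t])))
  G <- do.call(rbind, lapply(seq_len(Tn), function(t)
    kronecker(t(C[, t]), B1[, 1, t, drop = TRUE])))
  w_ls <- solve(t(G) %*% G, t(G) %*% as.numeric(M1))
  if (all(w_ls >= 0))
    expect_equal(as.numeric(f1$W), as.numeric(w_ls), tolerance = 1e-6)
})

test_that("half-cycle mirroring reproduces the contralateral side", {
  b <- planar_bundle()
  side <- vapply(b$model$muscles, `[[`, "", "side")
  a_r <- b$activations[side == "operated", , drop = FALSE]
  a_l <- b$activations[side == "non_operated", , drop = FALSE]
  mir <- mirror_activations(a_r, n_harmonics = 12)
  # symmetric gait: mirrored estimate matches the true left side closely
  expect_lt(hemigait:::rms(mir$activations - a_l), 0.02)
  # Fourier shift theorem: a cosine flips sign under a half-cycle shift
  s <- seq(0, 1, length.out = 101)
  cosr <- matrix(0.5 + 0.4 * cos(2 * pi * s), 1)
  mc <- mirror_activations(cosr, n_harmonics = 4)
  expect_lt(max(abs(mc$activations - (0.5 - 0.4 * cos(2 * pi * s)))), 1e-9)
  # band-limited input is reconstructed exactly before the shift
  band <- matrix(0.4 + 0.2 * sin(2 * pi * s) + 0.1 * cos(6 * pi * s), 1)
  mb <- mirror_activations(band, n_harmonics = 10)
  expect_lt(max(mb$fit_rms), 1e-10)
})

test_that("mirrored-activation adjustment recovers a known perturbation", {
  b <- planar_bundle()
  m <- b$model
  side <- vapply(m$muscles, `[[`, "", "side")
  lidx <- which(side == "non_operated")
  # lift the traces away from the [0, 1] bounds so the clamp in the
  # transform never engages (at the bounds the drift term is
  # unidentifiable by construction)
  a_l <- 0.25 + 0.5 * b$activations[lidx, , drop = FALSE]
  arr <- muscle_moment_arrays(m, b$q, b$qd)
  lact <- intersect(actuated_dofs(m), grep("_l$", m$dof_names))
  B <- arr$B[lact, lidx, , drop = FALSE]
  moments_of <- function(a)
    sapply(seq_len(ncol(a)), function(t) B[, , t] %*% a[, t])
  # perturb one muscle by a known (scale, delay, aperiodicity)
  pert <- a_l
  drift <- (seq_len(101) - 1) / 100 - 0.5
  j <- which.max(apply(a_l, 1, max))
  pert[j, ] <- pmin(pmax(
    1.2 * hemigait:::periodic_shift(a_l[j, , drop = FALSE], 0.02,
                                    b$T_cycle) + 0.05 * drift, 0), 1)
  target <- moments_of(pert)
  fit <- adjust_mirrored_activations(a_l, target, B, b$T_cycle,
                                     w_dev = 1e-4)
  expect_lte(fit$post_rms, fit$pre_rms)
  expect_lt(abs(fit$params[j, "scale"] - 1.2) / 1.2, 0.10)
  expect_lt(abs(fit$params[j, "delay"] - 0.02), 0.1 * 0.02 + 0.003)
  expect_lt(abs(fit$params[j, "aper"] - 0.05), 0.1 * 0.05 + 0.01)
  # identity optimum: already-consistent estimate keeps (1, 0, 0)
  fit0 <- adjust_mirrored_activations(a_l, moments_of(a_l), B, b$T_cycle)
  expect_lt(max(abs(fit0$params[, "scale"] - 1)), 0.02)
  expect_lt(max(abs(fit0$params[, "delay"])), 0.005)
})
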