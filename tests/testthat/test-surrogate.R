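test_that("surrogate length and moment arms follow the derivative identity", {
  g <- surrogate_geometry(1, matrix(c(0, 1), 2, 1), c(0.30, -0.05))
  r <- mtu_length_and_moment_arms(g, 0.2)
  expect_equal(r$length, 0.29)
  expect_equal(r$moment_arms[1, 1], 0.05)

  # cubic surrogate: analytic arms match finite differences and an
  # independent naive polynomial evaluation
  set.seed(7)
  basis <- poly_basis(2, 3)
  cf <- rnorm(nrow(basis), sd = 0.01)
  cf[1] <- 0.35
  g2 <- surrogate_geometry(1:2, basis, cf)
  naive_len <- function(q) sum(cf * apply(basis, 1, function(e)
    prod(q^e)))
  for (i in 1:10) {
    q <- runif(2, -1, 1)
    r2 <- mtu_length_and_moment_arms(g2, matrix(q, 2, 1))
    expect_equal(r2$length, naive_len(q), tolerance = 1e-12)
    eps <- 1e-7
    for (j in 1:2) {
      qp <- q; qp[j] <- qp[j] + eps
      fd <- -(naive_len(qp) - naive_len(q)) / eps
      expect_lt(abs(r2$moment_arms[j, 1] - fd) / max(abs(fd), 1e-9), 1e-5)
    }
  }
})

test_that("moment-arm identity holds across fixture muscles at random poses", {
  m <- planar_model()
  bounds <- dof_bounds(m)
  poses <- latin_hypercube_poses(bounds, 50, seed = 3)
  eps <- 1e-7
  for (mus in m$muscles[c(1, 5, 9)]) {
    g <- mus$geometry
    for (i in seq(1, 50, by = 7)) {
      qs <- poses[i, g$dofs]
      r <- mtu_length_and_moment_arms(g, matrix(qs, length(qs), 1))
      for (j in seq_along(g$dofs)) {
        qp <- qs; qp[j] <- qp[j] + eps
        lp <- mtu_length_and_moment_arms(g, matrix(qp, length(qp), 1))$length
        fd <- -(lp - r$length) / eps
        expect_lt(abs(r$moment_arms[j, 1] - fd) /
                    max(abs(r$moment_arms[j, 1]), 1e-6), 1e-5)
      }
    }
  }
})

test_that("surrogate fitting recovers polynomials exactly and reports errors", {
  # linear geometry recovered exactly
  th <- seq(-1, 1, length.out = 24)
  fit <- fit_surrogate(matrix(th, ncol = 1), 0.30 - 0.05 * th,
                       poly_basis(1, 1))
  expect_equal(fit$coef, c(0.30, -0.05), tolerance = 1e-12)
  expect_lt(attr(fit, "rms_residual"), 1e-12)
  # nesting: quadratic data, cubic basis
  y <- 0.25 + 0.03 * th - 0.02 * th^2
  fit2 <- fit_surrogate(matrix(th, ncol = 1), y, poly_basis(1, 3))
  expect_lt(attr(fit2, "rms_residual"), 1e-10)
  # noisy quadratic: coefficients within 3 SE of an independent
  # normal-equations oracle
  set.seed(11)
  thn <- runif(200, -1, 1)
  yn <- 0.25 + 0.03 * thn - 0.02 * thn^2 + rnorm(200, sd = 1e-3)
  fit3 <- fit_surrogate(matrix(thn, ncol = 1), yn, poly_basis(1, 2))
  X <- cbind(1, thn, thn^2)
  beta <- solve(t(X) %*% X, t(X) %*% yn)
  se <- sqrt(diag(solve(t(X) %*% X)) *
               sum((yn - X %*% beta)^2) / (200 - 3))
  expect_true(all(abs(fit3$coef - c(0.25, 0.03, -0.02)) < 3 * se +
                    abs(beta - c(0.25, 0.03, -0.02))))
  # degenerate basis reported by term
  expect_error(fit_surrogate(matrix(th, ncol = 1), y,
                             rbind(c(0), c(1), c(1))),
               "rank-deficient")
  # sample-count precondition
  expect_error(fit_surrogate(matrix(th[1:3], ncol = 1), y[1:3],
                             poly_basis(1, 2)), "2x")
})

test_that("affine landmark fitting recovers exact transforms", {
  set.seed(5)
  src <- matrix(rnorm(24), 8, 3)
  # identity
  fit <- fit_affine_landmarks(src, src)
  expect_equal(fit$A, diag(3), tolerance = 1e-10)
  expect_lt(fit$rms, 1e-12)
  # pure translation
  tgt_tr <- src; tgt_tr[, 1] <- tgt_tr[, 1] - 0.1
  fit2 <- fit_affine_landmarks(src, tgt_tr)
  expect_equal(fit2$b, c(-0.1, 0, 0), tolerance = 1e-10)
  # construct-then-recover a random affine map
  A <- matrix(rnorm(9), 3, 3); b <- rnorm(3)
  tgt <- src %*% t(A) + matrix(b, 8, 3, byrow = TRUE)
  fit3 <- fit_affine_landmarks(src, tgt)
  expect_lt(max(abs(fit3$A - A)), 1e-9)
  expect_lt(max(abs(fit3$b - b)), 1e-9)
  expect_equal(fit3$transform(src), tgt, tolerance = 1e-9)
  # coplanar source set
  flat <- cbind(src[, 1:2], 0)
  expect_error(fit_affine_landmarks(flat, flat), "coplanar")
})
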