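#' Muscle synergy extraction by non-negative matrix factorization
#'
#' Factorizes a non-negative activation matrix `A (muscles x time)` as
#' `A ~ W C` with `W >= 0` (muscles x k time-invariant synergy vectors) and
#' `C >= 0` (k x time synergy activations), using Frobenius-norm
#' multiplicative updates from seeded random initializations and keeping the
#' best of `restarts` runs. Synergy vectors are normalized to unit Euclidean
#' norm with compensating row scaling of `C` (leaving `W C` unchanged).
#'
#' @param A Non-negative activation matrix (muscles x time).
#' @param k Number of synergies (6 per body side by convention).
#' @param seed RNG seed.
#' @param restarts Number of random restarts (best kept).
#' @param max_iter Maximum multiplicative updates per restart.
#' @param tol Relative fit-change convergence tolerance.
#' @return Object of class `synergy_fit`: `W`, `C`, `vaf`
#'   (`1 - ||A - WC||_F^2 / ||A||_F^2`), `rss`, `restart_rss`.
#' @export
extract_synergies <- function(A, k, seed = 1, restarts = 10,
                              max_iter = 500, tol = 1e-8) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("activation matrix must be non-negative")
  if (k > min(dim(A))) stop("k exceeds matrix dimensions")
  if (k > qr(A)$rank)
    warning("k = ", k, " exceeds the numerical rank of A")
  set.seed(seed)
  best <- NULL
  restart_rss <- numeric(restarts)
  nrmA <- sum(A^2)
  epsm <- 1e-12
  for (r in seq_len(restarts)) {
    W <- matrix(runif(nrow(A) * k, 0.1, 1), nrow(A), k) * sqrt(mean(A))
    C <- matrix(runif(k * ncol(A), 0.1, 1), k, ncol(A)) * sqrt(mean(A))
    rss_old <- Inf
    for (it in seq_len(max_iter)) {
      C <- C * (t(W) %*% A) / (t(W) %*% W %*% C + epsm)
      W <- W * (A %*% t(C)) / (W %*% (C %*% t(C)) + epsm)
      if (it %% 10 == 0) {
        rss <- sum((A - W %*% C)^2)
        if (abs(rss_old - rss) < tol * max(rss, 1e-30)) break
        rss_old <- rss
      }
    }
    rss <- sum((A - W %*% C)^2)
    restart_rss[r] <- rss
    if (is.null(best) || rss < best$rss) best <- list(W = W, C = C, rss = rss)
  }
  nrm <- sqrt(colSums(best$W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(best$W, 2, nrm, `/`)
  C <- sweep(best$C, 1, nrm, `*`)
  structure(list(W = W, C = C, vaf = 1 - best$rss / nrmA, rss = best$rss,
                 restart_rss = restart_rss, k = k),
            class = "synergy_fit")
}

#' @export
print.synergy_fit <- function(x, ...) {
  cat("<synergy_fit> k =", x$k, " VAF =", round(x$vaf, 4), "\n")
  invisible(x)
}

#' Estimate synergy weights for muscles without EMG
#'
#' Given fixed synergy activations `C` extracted from measured muscles,
#' finds non-negative time-invariant weights for a set of unmeasured muscles
#' such that their moment contributions track target (inverse-dynamics)
#' moments, with an activation-magnitude penalty and a similarity penalty
#' tying heads of the same muscle together. Because joint moments are
#' linear in activations at fixed kinematics, the problem is a
#' bound-constrained (non-negative) linear least squares solved exactly.
#'
#' @param C Synergy activations (k x T, fixed).
#' @param target_moments Moments to reproduce (nDOF_t x T), net of any
#'   passive contribution.
#' @param B Moment-per-unit-activation array for the unmeasured muscles
#'   (nDOF_t x nMuscle x T), e.g. sliced from [muscle_moment_arrays()].
#' @param lambda1 Weight of the sum-of-squared-activations penalty.
#' @param lambda2 Weight of the head-similarity penalty.
#' @param groups Factor/character vector of muscle group labels (heads of
#'   one muscle share a label); similarity penalties are built within groups.
#' @return list with `W` (nMuscle x k non-negative weights), `activations`
#'   (nMuscle x T), `moment_rms` achieved, and the zero-weight baseline RMS.
#' @export
estimate_missing_activations <- function(C, target_moments, B,
                                         lambda1 = 1e-2, lambda2 = 1e-1,
                                         groups = NULL) {
  C <- as.matrix(C); target_moments <- as.matrix(target_moments)
  k <- nrow(C); Tn <- ncol(C)
  nm <- dim(B)[2]; ndt <- dim(B)[1]
  stopifnot(dim(B)[3] == Tn, ncol(target_moments) == Tn)
  # stack G w = m over time: row block t is kron(C_t', B_t)
  G <- matrix(0, ndt * Tn, nm * k)
  mvec <- as.numeric(target_moments)
  for (t in seq_len(Tn)) {
    rows <- (t - 1) * ndt + seq_len(ndt)
    G[rows, ] <- kronecker(t(C[, t]), B[, , t])
  }
  blocks <- list(G)
  rhs <- list(mvec)
  if (lambda1 > 0) {
    # activations a(t) = W C(t): penalise their 2-norm over time
    P1 <- matrix(0, nm * Tn, nm * k)
    for (t in seq_len(Tn)) {
      rows <- (t - 1) * nm + seq_len(nm)
      P1[rows, ] <- kronecker(t(C[, t]), diag(nm))
    }
    blocks <- c(blocks, list(sqrt(lambda1) * P1))
    rhs <- c(rhs, list(numeric(nm * Tn)))
  }
  if (lambda2 > 0 && !is.null(groups) && nm > 1) {
    pairs <- NULL
    for (gl in unique(groups)) {
      id <- which(groups == gl)
      if (length(id) > 1)
        pairs <- rbind(pairs, t(utils::combn(id, 2)))
    }
    if (!is.null(pairs) && nrow(pairs)) {
      D <- matrix(0, nrow(pairs) * k, nm * k)
      for (pi in seq_len(nrow(pairs))) {
        for (kk in seq_len(k)) {
          row <- (pi - 1) * k + kk
          D[row, (kk - 1) * nm + pairs[pi, 1]] <- 1
          D[row, (kk - 1) * nm + pairs[pi, 2]] <- -1
        }
      }
      blocks <- c(blocks, list(sqrt(lambda2) * D))
      rhs <- c(rhs, list(numeric(nrow(D))))
    }
  }
  Gfull <- do.call(rbind, blocks)
  bfull <- unlist(rhs)
  w <- pracma::lsqnonneg(Gfull, bfull)$x
  W <- matrix(w, nm, k)
  act <- W %*% C
  fitted <- matrix(G %*% w, ndt, Tn)
  list(W = W, activations = act,
       moment_rms = rms(fitted - target_moments),
       baseline_rms = rms(target_moments))
}

#' Initial contralateral activation estimate by half-cycle mirroring
#'
#' Enforces periodicity on each operated-side activation over the cycle
#' (averaging the endpoints), duplicates it for two consecutive cycles, fits
#' a least-squares Fourier series, and evaluates the fit shifted by half a
#' cycle on the 101-point grid. Negative values (Fourier overshoot) are
#' clamped at zero and the clamped fraction is reported.
#'
#' @param a_op Operated-side activations over one cycle (nMuscle x 101).
#' @param n_harmonics Number of Fourier harmonics (default 10).
#' @return list with `activations` (nMuscle x 101 mirrored estimate),
#'   `clamp_fraction`, and `fit_rms` (pre-shift reconstruction RMS).
#' @export
mirror_activations <- function(a_op, n_harmonics = 10) {
  a_op <- as.matrix(a_op)
  n <- ncol(a_op)
  nm <- nrow(a_op)
  # periodicity: common endpoint value
  a_per <- a_op
  ends <- (a_op[, 1] + a_op[, n]) / 2
  a_per[, 1] <- ends; a_per[, n] <- ends
  # duplicate two cycles (drop the duplicated shared sample)
  tiled <- cbind(a_per, a_per[, -1, drop = FALSE])
  ntile <- ncol(tiled)
  # phase over the tiled signal; fundamental period = one cycle
  ph <- 2 * pi * (seq_len(ntile) - 1) / (n - 1)
  X <- cbind(1, do.call(cbind, lapply(seq_len(n_harmonics), function(h)
    cbind(cos(h * ph), sin(h * ph)))))
  qrX <- qr(X)
  ph_out <- 2 * pi * ((seq_len(n) - 1) / (n - 1) + 0.5)   # half-cycle shift
  Xout <- cbind(1, do.call(cbind, lapply(seq_len(n_harmonics), function(h)
    cbind(cos(h * ph_out), sin(h * ph_out)))))
  out <- matrix(0, nm, n)
  fit_rms <- numeric(nm)
  for (m in seq_len(nm)) {
    cf <- qr.coef(qrX, tiled[m, ])
    fit_rms[m] <- rms(X %*% cf - tiled[m, ])
    out[m, ] <- Xout %*% cf
  }
  clamped <- mean(out < 0)
  out <- pmax(out, 0)
  rownames(out) <- rownames(a_op)
  list(activations = out, clamp_fraction = clamped, fit_rms = fit_rms)
}

#' Adjust mirrored activations to match contralateral moments
#'
#' Per-muscle transform `a'(t) = scale * a(t - delay) + aperiodicity *
#' (t/T - 1/2)` (the aperiodicity term is a zero-mean linear-in-time drift),
#' with bounded parameters, minimising moment-tracking RMS plus a
#' deviation-from-initial penalty.
#'
#' @param a_init Initial (mirrored) activations, nMuscle x 101.
#' @param target_moments Contralateral inverse-dynamics moments net of
#'   passive contributions (nDOF_t x 101).
#' @param B Moment-per-unit-activation array for these muscles
#'   (nDOF_t x nMuscle x 101).
#' @param T_cycle Cycle period (s).
#' @param w_dev Weight of the deviation penalty.
#' @param bounds list with `scale`, `delay`, `aper` 2-vectors.
#' @return list with `params` (nMuscle x 3 matrix scale/delay/aper),
#'   `activations`, `pre_rms`, `post_rms`, `converged`.
#' @export
adjust_mirrored_activations <- function(a_init, target_moments, B, T_cycle,
                                        w_dev = 0.05,
                                        bounds = list(scale = c(0.5, 2),
                                                      delay = c(-0.1, 0.1),
                                                      aper = c(-0.2, 0.2))) {
  a_init <- as.matrix(a_init)
  nm <- nrow(a_init); Tn <- ncol(a_init)
  drift <- (seq_len(Tn) - 1) / (Tn - 1) - 0.5
  apply_params <- function(th) {
    P <- matrix(th, nm, 3)
    a <- matrix(0, nm, Tn)
    for (m in seq_len(nm)) {
      shifted <- periodic_shift(a_init[m, , drop = FALSE], P[m, 2], T_cycle)
      a[m, ] <- P[m, 1] * shifted + P[m, 3] * drift
    }
    pmin(pmax(a, 0), 1)
  }
  moments_of <- function(a) {
    M <- matrix(0, dim(B)[1], Tn)
    for (t in seq_len(Tn)) M[, t] <- B[, , t] %*% a[, t]
    M
  }
  obj <- function(th) {
    a <- apply_params(th)
    sum((moments_of(a) - target_moments)^2) + w_dev * sum((a - a_init)^2)
  }
  th0 <- as.numeric(cbind(rep(1, nm), rep(0, nm), rep(0, nm)))
  lo <- as.numeric(cbind(rep(bounds$scale[1], nm), rep(bounds$delay[1], nm),
                         rep(bounds$aper[1], nm)))
  hi <- as.numeric(cbind(rep(bounds$scale[2], nm), rep(bounds$delay[2], nm),
                         rep(bounds$aper[2], nm)))
  pre_rms <- rms(moments_of(a_init) - target_moments)
  fit <- tryCatch(
    optim(th0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
          control = list(maxit = 600, factr = 1e2)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(params = matrix(th0, nm, 3,
                                dimnames = list(rownames(a_init),
                                                c("scale", "delay", "aper"))),
                activations = a_init, pre_rms = pre_rms, post_rms = pre_rms,
                converged = FALSE))
  }
  a_fit <- apply_params(fit$par)
  post_rms <- rms(moments_of(a_fit) - target_moments)
  if (post_rms > pre_rms) {   # optimizer descent contract
    a_fit <- a_init
    fit$par <- th0
    post_rms <- pre_rms
  }
  list(params = matrix(fit$par, nm, 3,
                       dimnames = list(rownames(a_init),
                                       c("scale", "delay", "aper"))),
       activations = a_fit, pre_rms = pre_rms, post_rms = post_rms,
       converged = fit$convergence == 0)
}
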