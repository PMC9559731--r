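#' Latin-hypercube pose sampling
#'
#' Stratified random poses over coordinate bounds: one sample per stratum
#' per dimension.
#'
#' @param bounds d x 2 matrix of lower/upper bounds.
#' @param n Number of poses.
#' @param seed RNG seed (same seed gives an identical matrix).
#' @return n x d matrix of poses.
#' @export
latin_hypercube_poses <- function(bounds, n, seed = 1) {
  bounds <- as.matrix(bounds)
  stopifnot(ncol(bounds) == 2, all(bounds[, 1] < bounds[, 2]))
  set.seed(seed)
  u <- lhs::randomLHS(n, nrow(bounds))
  sweep(sweep(u, 2, bounds[, 2] - bounds[, 1], `*`), 2, bounds[, 1], `+`)
}

#' Reduce the heads of a multi-head muscle group
#'
#' Finds the smallest faithful subset of heads: moments produced by all
#' heads at full activation are computed over Latin-hypercube poses, then
#' for each admissible retained subset new peak isometric strengths are
#' found by non-negative least squares (moments are linear in strength at
#' fixed activation) and the subset with minimum RMS moment error is kept.
#' Admissible subsets span the anatomic range (first and last head
#' retained) with approximately equal index spacing (pairwise gaps differ
#' by at most one).
#'
#' @param heads List of [muscle_spec()] heads sharing spanned DOFs
#'   (anatomical order).
#' @param bounds Pose bounds for the spanned coordinates (d x 2), e.g.
#'   joint ranges of motion inflated by ~10%.
#' @param target_heads Integer vector of admissible retained-subset sizes.
#' @param n_poses Number of Latin-hypercube poses (>= 10 x heads).
#' @param seed RNG seed.
#' @param curves A [hill_curves()] object.
#' @param subsets `"admissible"` (anatomic-range-spanning,
#'   approximately equally spaced subsets; the default rule) or `"all"`
#'   (exhaustive enumeration of every subset of the target sizes).
#' @return list with `retained` (indices), `f_max` (re-optimized strengths),
#'   `rms` (moment RMS error), and `all_subsets` diagnostics.
#' @export
reduce_muscle_heads <- function(heads, bounds, target_heads,
                                n_poses = 1000, seed = 1,
                                curves = hill_curves(),
                                subsets = c("admissible", "all")) {
  subsets <- match.arg(subsets)
  nh <- length(heads)
  if (n_poses < 10 * nh)
    stop("n_poses must be at least 10x the number of heads")
  span <- heads[[1]]$geometry$dofs
  for (h in heads)
    if (!all(h$geometry$dofs %in% span) && !all(span %in% h$geometry$dofs))
      stop("heads must share spanned DOFs")
  poses <- latin_hypercube_poses(bounds, n_poses, seed)
  # per-head moment traces at activation 1, zero velocity, unit strength
  d <- length(span)
  Phi <- matrix(0, n_poses * d, nh)
  for (h in seq_len(nh)) {
    mus <- heads[[h]]
    geo <- mtu_length_and_moment_arms(mus$geometry, t(poses))
    st <- rigid_tendon_state(mus, geo$length, 0)
    fscale <- (curves$fl_active(st$lnorm) * curves$fv(0) +
                 curves$fl_passive(st$lnorm)) * st$cos_alpha
    Phi[, h] <- as.numeric(geo$moment_arms * rep(fscale, each = d))
  }
  f0 <- vapply(heads, `[[`, 0, "f_max")
  M0 <- Phi %*% f0
  cand <- if (subsets == "all")
    unlist(lapply(target_heads, function(sz)
      utils::combn(nh, sz, simplify = FALSE)), recursive = FALSE)
  else admissible_subsets(nh, target_heads)
  if (!length(cand)) stop("no admissible retained-head subset")
  results <- lapply(cand, function(S) {
    fit <- pracma::lsqnonneg(Phi[, S, drop = FALSE], as.numeric(M0))
    list(retained = S, f_max = fit$x,
         rms = rms(Phi[, S, drop = FALSE] %*% fit$x - M0))
  })
  best <- results[[which.min(vapply(results, `[[`, 0, "rms"))]]
  best$all_subsets <- results
  best
}

#' Admissible retained-head subsets
#'
#' Subsets containing the first and last head whose sorted pairwise index
#' gaps differ by at most one (approximately equal spacing across the
#' anatomic range). Size-1 groups and full retention are always admissible.
#' @noRd
admissible_subsets <- function(nh, sizes) {
  sizes <- sizes[sizes >= 1 & sizes <= nh]
  out <- list()
  for (sz in sizes) {
    if (sz == nh) { out <- c(out, list(seq_len(nh))); next }
    if (sz == 1) {
      out <- c(out, lapply(seq_len(nh), identity)); next
    }
    cand <- utils::combn(2:(nh - 1), sz - 2, simplify = FALSE)
    for (mid in cand) {
      S <- sort(c(1, mid, nh))
      gaps <- diff(S)
      if (max(gaps) - min(gaps) <= 1) out <- c(out, list(S))
    }
  }
  unique(out)
}

#' EMG-driven muscle-tendon calibration
#'
#' Adjusts EMG-to-activation parameters (EMG scale factors,
#' electromechanical delays, activation time constants, non-linearisation
#' shape factors) and Hill-model parameters (optimal fiber length and tendon
#' slack length multipliers) of a muscle set so that the net joint moments
#' produced from the EMG reproduce inverse-dynamics moments over all trials
#' jointly. Peak isometric strengths are held fixed (they come from
#' height/weight regression, not calibration). Solved as bound-constrained
#' non-linear least squares (Levenberg-Marquardt).
#'
#' @param model A [walker_model()] whose `muscles[muscle_idx]` are calibrated.
#' @param trials List of trials; each a list with `q`, `qd` (nDOF x T),
#'   `moments` (nDOF x T inverse-dynamics moments; only actuated rows are
#'   used), `emg` (nMuscle x T envelopes, rows matching `muscle_idx`), and
#'   `dt` (sample interval of the 101-point grid, s).
#' @param muscle_idx Indices of the calibrated muscles within
#'   `model$muscles` (default: all with EMG rows).
#' @param free Character vector of free parameters among
#'   `c("emg_scale","emg_delay","tau_act","tau_deact","shape_A",
#'   "lopt_mult","lslack_mult")`.
#' @param bounds Named list of 2-vectors overriding default bounds.
#' @param act_dt Internal activation-dynamics integration step (s); EMG is
#'   upsampled to this grid so the step guard of
#'   [excitation_to_activation()] holds.
#' @param max_iter Maximum optimizer iterations.
#' @return list with `muscles` (calibrated specs), `params` (matrix),
#'   `rms_per_dof` (per trial), `objective_trace`, `converged`.
#' @export
calibrate_emg_driven <- function(model, trials, muscle_idx = NULL,
                                 free = c("emg_scale", "emg_delay", "tau_act",
                                          "tau_deact", "shape_A",
                                          "lopt_mult", "lslack_mult"),
                                 bounds = list(), act_dt = 0.002,
                                 max_iter = 60) {
  if (is.null(muscle_idx)) muscle_idx <- seq_len(nrow(trials[[1]]$emg))
  nm <- length(muscle_idx)
  act_idx <- actuated_dofs(model)
  default_bounds <- list(emg_scale = c(0.05, 1), emg_delay = c(0, 0.1),
                         tau_act = c(0.008, 0.06), tau_deact = c(0.02, 0.12),
                         shape_A = c(-3, -0.01),
                         lopt_mult = c(0.75, 1.25), lslack_mult = c(0.75, 1.25))
  bounds <- modifyList(default_bounds, bounds)
  for (b in bounds) if (!all(is.finite(b))) stop("unbounded parameter spec")
  np <- length(free)
  base <- model$muscles[muscle_idx]
  pack0 <- vapply(base, function(m) {
    v <- c(emg_scale = m$emg_scale, emg_delay = m$emg_delay,
           tau_act = m$tau_act, tau_deact = m$tau_deact,
           shape_A = m$shape_A, lopt_mult = 1, lslack_mult = 1)
    v[free]
  }, numeric(np))
  x0 <- as.numeric(pack0)
  lo <- rep(vapply(free, function(f) bounds[[f]][1], 0), times = nm)
  hi <- rep(vapply(free, function(f) bounds[[f]][2], 0), times = nm)
  # interleave: parameters grouped per muscle
  lo <- as.numeric(matrix(vapply(free, function(f) bounds[[f]][1], 0), np, nm))
  hi <- as.numeric(matrix(vapply(free, function(f) bounds[[f]][2], 0), np, nm))

  apply_params <- function(x) {
    P <- matrix(x, np, nm, dimnames = list(free, NULL))
    mus <- base
    for (j in seq_len(nm)) {
      for (f in free) {
        if (f == "lopt_mult") mus[[j]]$l_opt <- base[[j]]$l_opt * P[f, j]
        else if (f == "lslack_mult")
          mus[[j]]$l_slack <- base[[j]]$l_slack * P[f, j]
        else mus[[j]][[f]] <- P[f, j]
      }
    }
    mus
  }

  trace_env <- new.env()
  trace_env$obj <- numeric(0)

  residual_fn <- function(x) {
    mus <- apply_params(x)
    res <- numeric(0)
    for (tr in trials) {
      Tn <- ncol(tr$q)
      a <- matrix(0, nm, Tn)
      tfine <- seq(0, (Tn - 1) * tr$dt, by = act_dt)
      tgrid <- (seq_len(Tn) - 1) * tr$dt
      for (j in seq_len(nm)) {
        efine <- approx(tgrid, tr$emg[j, ], xout = tfine, rule = 2)$y
        af <- excitation_to_activation(efine, act_dt, mus[[j]])
        a[j, ] <- approx(tfine, af, xout = tgrid, rule = 2)$y
      }
      M <- moments_of_muscles(mus, model$curves, tr$q, tr$qd, a,
                              length(model$dofs))
      res <- c(res, as.numeric(M[act_idx, ] - tr$moments[act_idx, ]))
    }
    trace_env$obj <- c(trace_env$obj, sum(res^2))
    res
  }

  fit <- minpack.lm::nls.lm(par = x0, lower = lo, upper = hi,
                            fn = residual_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ptol = 1e-10, ftol = 1e-12))
  mus_fit <- apply_params(fit$par)
  # per-DOF RMS report
  rms_per_dof <- lapply(trials, function(tr) {
    Tn <- ncol(tr$q)
    a <- matrix(0, nm, Tn)
    tfine <- seq(0, (Tn - 1) * tr$dt, by = act_dt)
    tgrid <- (seq_len(Tn) - 1) * tr$dt
    for (j in seq_len(nm)) {
      efine <- approx(tgrid, tr$emg[j, ], xout = tfine, rule = 2)$y
      af <- excitation_to_activation(efine, act_dt, mus_fit[[j]])
      a[j, ] <- approx(tfine, af, xout = tgrid, rule = 2)$y
    }
    M <- moments_of_muscles(mus_fit, model$curves, tr$q, tr$qd, a,
                            length(model$dofs))
    apply(M[act_idx, , drop = FALSE] - tr$moments[act_idx, , drop = FALSE],
          1, rms)
  })
  # objective is non-increasing over accepted LM iterates by construction;
  # keep the raw evaluation trace for the descent-log assertion
  list(muscles = mus_fit,
       params = matrix(fit$par, np, nm, dimnames = list(free, names(base))),
       rms_per_dof = rms_per_dof,
       objective_trace = trace_env$obj,
       deviance_trace = fit$rsstrace,
       converged = fit$info %in% 1:4,
       info = fit$info)
}

#' Net moments of a muscle subset (helper shared with calibration)
#' @noRd
moments_of_muscles <- function(muscles, curves, q, qd, a, ndof) {
  Tn <- ncol(q)
  M <- matrix(0, ndof, Tn)
  for (j in seq_along(muscles)) {
    mus <- muscles[[j]]
    g <- mus$geometry
    geo <- mtu_length_and_moment_arms(g, q)
    v_mt <- mtu_velocity(geo$moment_arms, qd[g$dofs, , drop = FALSE])
    F <- rigid_tendon_force(mus, curves, a[j, ], geo$length, v_mt)
    for (jj in seq_along(g$dofs))
      M[g$dofs[jj], ] <- M[g$dofs[jj], ] + geo$moment_arms[jj, ] * F
  }
  M
}
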